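# Instrument construction: p-value selection, greedy LD clumping and
# exposure/outcome allele harmonization.

#' Select candidate instrument SNPs by p-value
#'
#' Keeps rows with `p < p_threshold` (strict), preserving input order.
#'
#' @param stats summary-statistic data.frame.
#' @param p_threshold selection threshold (suggestive-significance default
#'   5e-6).
#' @return subset of `stats`.
#' @export
selectCandidates <- function(stats, p_threshold = 5e-6) {
  stats[!is.na(stats$p) & stats$p < p_threshold, , drop = FALSE]
}

# Pairwise r^2 between candidate variants from a dosage panel (Pearson
# correlation of dosages, squared); variants absent from the panel get NA.
.r2FromPanel <- function(panel, variants) {
  present <- intersect(variants, rownames(panel))
  r2 <- matrix(NA_real_, length(variants), length(variants),
               dimnames = list(variants, variants))
  if (length(present) >= 2) {
    cc <- suppressWarnings(cor(t(dosages(panel)[present, , drop = FALSE])))
    r2[present, present] <- cc^2
  }
  diag(r2) <- 1
  r2
}

#' Greedy LD clumping of candidate SNPs
#'
#' PLINK-style greedy clumping: candidates are ranked by ascending p (ties
#' broken by chromosome, then position); the best remaining SNP becomes an
#' index SNP and removes every remaining candidate on the same chromosome
#' within `window_kb` (inclusive) whose r-squared with it is at or above
#' `r2_threshold`.  Variants in different chromosomes are never clumped
#' against each other.  The retained set is a function only of the p-value
#' order, positions and r-squared values, never of input row order.
#'
#' @param candidates summary-statistic data.frame (needs `variant`,
#'   `chrom`, `pos`, `p`).
#' @param ld a [GenotypePanel-class] LD reference, or a square r-squared
#'   matrix with variant dimnames.
#' @param r2_threshold clumping threshold (default 0.05).
#' @param window_kb physical distance threshold in kb (default 1000).
#' @param missing_policy what to do with candidates absent from the LD
#'   source: `"assume_independent"` (kept, never clumped away) or `"drop"`.
#' @return the retained rows of `candidates`, with a `clumpLog` attribute
#'   (data.frame `variant`, `action`, `index_snp`).
#' @export
ldClump <- function(candidates, ld, r2_threshold = 0.05, window_kb = 1000,
                    missing_policy = c("assume_independent", "drop")) {
  missing_policy <- match.arg(missing_policy)
  if (!nrow(candidates)) {
    attr(candidates, "clumpLog") <-
      data.frame(variant = character(0), action = character(0),
                 index_snp = character(0))
    return(candidates)
  }
  if (is(ld, "GenotypePanel")) {
    r2 <- .r2FromPanel(ld, candidates$variant)
    haveLd <- candidates$variant %in% rownames(ld)
  } else {
    m <- matrix(NA_real_, nrow(candidates), nrow(candidates),
                dimnames = list(candidates$variant, candidates$variant))
    shared <- intersect(candidates$variant, rownames(ld))
    m[shared, shared] <- as.matrix(ld)[shared, shared]
    diag(m) <- 1
    r2 <- m
    haveLd <- candidates$variant %in% rownames(ld)
  }
  log <- list()
  keepMask <- rep(TRUE, nrow(candidates))
  if (missing_policy == "drop" && any(!haveLd)) {
    for (i in which(!haveLd)) {
      log[[length(log) + 1L]] <- data.frame(
        variant = candidates$variant[i], action = "dropped_no_ld",
        index_snp = NA_character_, stringsAsFactors = FALSE)
    }
    keepMask[!haveLd] <- FALSE
  }
  chromN <- suppressWarnings(as.numeric(candidates$chrom))
  chromKey <- if (anyNA(chromN)) as.character(candidates$chrom) else chromN
  ord <- order(candidates$p, chromKey, candidates$pos)
  ord <- ord[keepMask[ord]]
  retained <- integer(0)
  removed <- rep(FALSE, nrow(candidates))
  for (i in ord) {
    if (removed[i]) next
    retained <- c(retained, i)
    sameChrom <- candidates$chrom == candidates$chrom[i]
    inWindow <- sameChrom &
      abs(candidates$pos - candidates$pos[i]) <= window_kb * 1000
    rr <- r2[candidates$variant[i], candidates$variant]
    linked <- inWindow & !is.na(rr) & rr >= r2_threshold
    linked[i] <- FALSE
    newly <- which(linked & !removed & keepMask)
    newly <- setdiff(newly, retained)
    for (j in newly) {
      removed[j] <- TRUE
      log[[length(log) + 1L]] <- data.frame(
        variant = candidates$variant[j], action = "clumped",
        index_snp = candidates$variant[i], stringsAsFactors = FALSE)
    }
  }
  out <- candidates[sort(retained), , drop = FALSE]
  attr(out, "clumpLog") <- if (length(log)) do.call(rbind, log) else
    data.frame(variant = character(0), action = character(0),
               index_snp = character(0))
  out
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns, for every SNP shared between the two tables (matched on
#' chromosome and position), the outcome effect to the exposure's effect
#' allele: identical orientation is copied; swapped alleles flip the
#' outcome beta sign and frequency; alleles matching only after strand
#' complement are complemented first.  Palindromic SNPs (A/T, C/G) cannot
#' be resolved by strand, so under the default `"frequency"` policy they
#' are dropped when the minor-allele frequency in either table exceeds
#' `palindromic_maf` (0.42) and otherwise aligned by allele frequency;
#' policy `"drop"` removes them all.  Unmatchable allele pairs are dropped.
#' Every action is recorded in the provenance log.
#'
#' @param exposure,outcome summary-statistic data.frames.
#' @param metabolite_id,phenotype_id identifiers stored on the instrument.
#' @param palindromic_policy `"frequency"` or `"drop"`.
#' @param palindromic_maf frequency-ambiguity threshold (default 0.42).
#' @return a [HarmonizedInstrument-class].
#' @export
harmonizeInstruments <- function(exposure, outcome, metabolite_id = "",
                                 phenotype_id = "",
                                 palindromic_policy = c("frequency", "drop"),
                                 palindromic_maf = 0.42) {
  palindromic_policy <- match.arg(palindromic_policy)
  log <- list()
  note <- function(variant, action, detail = "") {
    log[[length(log) + 1L]] <<- data.frame(
      variant = variant, action = action, detail = detail,
      stringsAsFactors = FALSE)
  }
  oKey <- paste(outcome$chrom, outcome$pos)
  rows <- list()
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    j <- match(paste(ex$chrom, ex$pos), oKey)
    if (is.na(j)) {
      note(ex$variant, "dropped", "absent from outcome table")
      next
    }
    ou <- outcome[j, ]
    if (is.na(ou$beta) || is.na(ou$se) || ou$se <= 0) {
      note(ex$variant, "dropped", "outcome effect unavailable")
      next
    }
    ea <- ex$effect_allele; oa <- ex$other_allele
    oea <- ou$effect_allele; ooa <- ou$other_allele
    bOut <- ou$beta; eafOut <- ou$eaf
    if (.isPalindromic(ea, oa)) {
      if (palindromic_policy == "drop") {
        note(ex$variant, "dropped", "palindromic SNP")
        next
      }
      mafE <- min(ex$eaf, 1 - ex$eaf)
      mafO <- min(ou$eaf, 1 - ou$eaf)
      if (is.na(mafE) || is.na(mafO) || mafE > palindromic_maf ||
          mafO > palindromic_maf) {
        note(ex$variant, "dropped", "palindromic, frequency-ambiguous")
        next
      }
      # strand is unresolvable; align by which allele is major
      if ((ex$eaf > 0.5) != (ou$eaf > 0.5)) {
        bOut <- -bOut
        eafOut <- 1 - eafOut
        note(ex$variant, "flipped", "palindromic, aligned by frequency")
      } else {
        note(ex$variant, "copied", "palindromic, aligned by frequency")
      }
    } else if (setequal(c(oea, ooa), c(ea, oa))) {
      if (oea == ea) {
        note(ex$variant, "copied", "same effect allele")
      } else {
        bOut <- -bOut
        eafOut <- 1 - eafOut
        note(ex$variant, "flipped", "effect allele swapped")
      }
    } else if (setequal(.complementAllele(c(oea, ooa)), c(ea, oa))) {
      if (.complementAllele(oea) == ea) {
        note(ex$variant, "copied", "strand complement")
      } else {
        bOut <- -bOut
        eafOut <- 1 - eafOut
        note(ex$variant, "flipped", "strand complement + swap")
      }
    } else {
      note(ex$variant, "dropped",
           sprintf("allele mismatch (%s/%s vs %s/%s)", ea, oa, oea, ooa))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variant = ex$variant, chrom = ex$chrom, pos = ex$pos,
      effect_allele = ea, other_allele = oa, beta_exp = ex$beta,
      se_exp = ex$se, beta_out = bOut, se_out = ou$se, eaf_exp = ex$eaf,
      eaf_out = eafOut, stringsAsFactors = FALSE)
  }
  prov <- if (length(log)) do.call(rbind, log) else
    data.frame(variant = character(0), action = character(0),
               detail = character(0))
  .assertThat(length(rows) > 0, "virtmet_instrument_error",
              "no SNP survived harmonization for %s -> %s",
              metabolite_id, phenotype_id)
  new("HarmonizedInstrument", metaboliteId = metabolite_id,
      phenotypeId = phenotype_id, snps = do.call(rbind, rows),
      provenance = prov)
}

#' Construct a harmonized instrument directly
#'
#' Lightweight constructor for already-aligned effect pairs, used by
#' simulations and tests.
#'
#' @param beta_exp,se_exp,beta_out,se_out aligned per-SNP effects and SEs.
#' @param variant,chrom,pos optional identifiers (generated when missing).
#' @param metabolite_id,phenotype_id labels.
#' @return a [HarmonizedInstrument-class].
#' @export
harmonizedInstrument <- function(beta_exp, se_exp, beta_out, se_out,
                                 variant = NULL, chrom = NULL, pos = NULL,
                                 metabolite_id = "exposure",
                                 phenotype_id = "outcome") {
  n <- length(beta_exp)
  if (is.null(variant)) variant <- sprintf("snp%03d", seq_len(n))
  if (is.null(chrom)) chrom <- as.character(seq_len(n))
  if (is.null(pos)) pos <- rep(1e6, n)
  new("HarmonizedInstrument", metaboliteId = metabolite_id,
      phenotypeId = phenotype_id,
      snps = data.frame(variant = variant, chrom = chrom, pos = pos,
                        effect_allele = "A", other_allele = "G",
                        beta_exp = beta_exp, se_exp = se_exp,
                        beta_out = beta_out, se_out = se_out,
                        stringsAsFactors = FALSE),
      provenance = data.frame(variant = character(0),
                              action = character(0),
                              detail = character(0)))
}
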