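# Readers and writers for the formats the pipeline touches.  Every reader
# validates records at the boundary and rejects exactly what the type
# invariants forbid; coordinates are 1-based, inclusive (VCF convention)
# throughout.

.SUMSTAT_COLS <- c("variant", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "p", "n")

.checkColumns <- function(df, need, what) {
  miss <- setdiff(need, colnames(df))
  .assertThat(length(miss) == 0, "virtmet_parse_error",
              "%s is missing required column(s): %s", what,
              paste(miss, collapse = ", "))
}

#' Read a genotype panel from VCF or dosage TSV
#'
#' VCF genotypes are counted on the alt allele from the GT field (`0/1` ->
#' 1); `./.` is flagged missing (`NA`), never imputed here (missing-dosage
#' policy belongs to the PGS engine).  The dosage TSV dialect has columns
#' `variant chrom pos ref alt` followed by one column per individual.
#' Variant order is preserved.
#'
#' @param path file path.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return a [GenotypePanel-class].
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  .assertThat(file.exists(path), "virtmet_parse_error",
              "file not found: %s", path)
  if (format == "vcf") .readVcfPanel(path) else .readDosageTsv(path)
}

.readVcfPanel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || all(is.na(gt)))
    .virtmetStop("virtmet_parse_error", "VCF has no GT field")
  gtc <- gsub("\\|", "/", gt)
  ok <- is.na(gtc) | gtc %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (!all(ok)) {
    bad <- unique(gtc[!ok])
    if (any(!grepl("^[.01]/[.01]$", bad)))
      .virtmetStop("virtmet_parse_error",
                   "unsupported genotype encoding (mixed ploidy?): %s",
                   paste(utils::head(bad, 3), collapse = ", "))
  }
  dos <- matrix(NA_real_, nrow(gtc), ncol(gtc), dimnames = dimnames(gtc))
  dos[gtc == "0/0"] <- 0
  dos[gtc %in% c("0/1", "1/0")] <- 1
  dos[gtc == "1/1"] <- 2
  vf <- data.frame(
    variant = if (all(is.na(fix$ID)) || any(fix$ID == "."))
      sprintf("%s:%s", fix$CHROM, fix$POS) else fix$ID,
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, id = ifelse(is.na(fix$ID), "", fix$ID),
    stringsAsFactors = FALSE
  )
  .assertThat(all(vf$pos >= 1), "virtmet_parse_error",
              "positions must be >= 1")
  .assertThat(all(grepl("^[ACGT]+$", vf$ref)) &&
                all(grepl("^[ACGT]+$", vf$alt)),
              "virtmet_parse_error", "alleles must be over {A,C,G,T}")
  .genotypePanel(dos, vf, colnames(dos))
}

.readDosageTsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  .checkColumns(df, c("variant", "chrom", "pos", "ref", "alt"), "dosage TSV")
  idCols <- setdiff(colnames(df), c("variant", "chrom", "pos", "ref", "alt"))
  .assertThat(length(idCols) > 0, "virtmet_parse_error",
              "dosage TSV has no individual columns")
  dos <- as.matrix(df[, idCols, drop = FALSE])
  if (!is.numeric(dos)) {
    bad <- which(apply(df[, idCols, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))) &
                                         r != "NA")))
    .virtmetStop("virtmet_parse_error",
                 "non-numeric dosage at line %d", bad[1] + 1L)
  }
  storage.mode(dos) <- "double"
  vf <- df[, c("variant", "chrom", "pos", "ref", "alt")]
  vf$chrom <- as.character(vf$chrom)
  vf$id <- vf$variant
  .genotypePanel(dos, vf, idCols)
}

#' Write a genotype panel
#'
#' VCF output encodes integer dosages as GT (`0/0`, `0/1`, `1/1`; `NA` as
#' `./.`); the dosage TSV keeps fractional dosages exactly.  Round-trips
#' through [readGenotypes()] are lossless.
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @export
writeGenotypes <- function(panel, path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  vf <- variantInfo(panel)
  dos <- dosages(panel)
  if (format == "dosage_tsv") {
    out <- cbind(vf[, c("variant", "chrom", "pos", "ref", "alt")],
                 as.data.frame(dos, check.names = FALSE))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  .assertThat(all(is.na(dos) | dos %in% c(0, 1, 2)), "virtmet_parse_error",
              "VCF GT output requires integer dosages (use dosage_tsv)")
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gtmap[dos[ok] + 1L]
  body <- cbind(vf$chrom, vf$pos, vf$id, vf$ref, vf$alt, ".", "PASS", ".",
                "GT", gt)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dos)), collapse = "\t"),
    apply(body, 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a metabolite score model
#'
#' Expects a PLINK-score-style TSV with header `variant chrom pos ref alt
#' effect_allele weight`.  Duplicate variants, non-finite weights and effect
#' alleles outside \{ref, alt\} are rejected.
#'
#' @param path file path.
#' @param metabolite_id identifier; defaults to the file stem.
#' @param source_p_threshold p-value threshold the SNPs were selected at.
#' @return a [ScoreModel-class].
#' @export
readScoreModel <- function(path, metabolite_id = NULL,
                           source_p_threshold = 5e-8) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  .checkColumns(df, c("variant", "chrom", "pos", "ref", "alt",
                      "effect_allele", "weight"), "score file")
  .assertThat(!anyDuplicated(df$variant), "virtmet_parse_error",
              "duplicate variants in score file: %s",
              paste(unique(df$variant[duplicated(df$variant)]),
                    collapse = ", "))
  .assertThat(all(is.finite(df$weight)), "virtmet_parse_error",
              "non-numeric or non-finite weight(s) in score file")
  if (is.null(metabolite_id))
    metabolite_id <- sub("\\.[^.]*$", "", basename(path))
  new("ScoreModel", metaboliteId = metabolite_id, entries = df,
      sourcePThreshold = source_p_threshold)
}

#' @rdname readScoreModel
#' @param model a [ScoreModel-class] to serialize.
#' @export
writeScoreModel <- function(model, path) {
  write.table(model@entries, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Dialect: TSV with header `variant chrom pos effect_allele other_allele
#' eaf beta se p n`.  Records violating the type invariants are rejected
#' with their line numbers: `se` must be positive, `p` in (0,1], `eaf` in
#' [0,1], and `p` must agree with the two-sided normal tail of `beta/se` to
#' within 1e-6.
#'
#' @param path file path.
#' @return validated summary-statistic data.frame.
#' @seealso [writeSummaryStats()]
#' @export
readSummaryStats <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  .checkColumns(df, .SUMSTAT_COLS, "summary-statistic table")
  validateSummaryStats(df)
}

#' Validate a summary-statistic table
#'
#' Applies the record invariants (positive `se`, `p` in (0,1], `eaf` in
#' [0,1], normal-approximation consistency of `p` with `beta/se`) and
#' errors on the first offending rows.  Rows with `NA` effect estimates
#' (flagged monomorphic variants) are tolerated.
#'
#' @param df a summary-statistic data.frame.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validateSummaryStats <- function(df) {
  .checkColumns(df, .SUMSTAT_COLS, "summary-statistic table")
  est <- !is.na(df$beta) & !is.na(df$se)
  bad <- which(est & df$se <= 0)
  .assertThat(length(bad) == 0, "virtmet_parse_error",
              "se must be > 0 (rows %s)",
              paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(est & (df$p <= 0 | df$p > 1))
  .assertThat(length(bad) == 0, "virtmet_parse_error",
              "p must be in (0,1] (rows %s)",
              paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1))
  .assertThat(length(bad) == 0, "virtmet_parse_error",
              "eaf must be in [0,1] (rows %s)",
              paste(utils::head(bad, 5), collapse = ", "))
  pExp <- .normP(df$beta[est] / df$se[est])
  bad <- which(abs(pExp - df$p[est]) > 1e-6)
  .assertThat(length(bad) == 0, "virtmet_parse_error",
              "p inconsistent with beta/se under the normal approximation (rows %s)",
              paste(utils::head(which(est)[bad], 5), collapse = ", "))
  df
}

#' @rdname readSummaryStats
#' @param stats summary-statistic data.frame to serialize.
#' @export
writeSummaryStats <- function(stats, path) {
  write.table(stats[, .SUMSTAT_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a PheCode event table
#'
#' Dialect: TSV `individual_id phecode count`.  Counts must be positive
#' integers.
#'
#' @param path file path.
#' @return event data.frame.
#' @export
readEvents <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "integer"),
                   stringsAsFactors = FALSE)
  .checkColumns(df, c("individual_id", "phecode", "count"), "event table")
  bad <- which(is.na(df$count) | df$count < 1)
  .assertThat(length(bad) == 0, "virtmet_parse_error",
              "counts must be positive integers (rows %s)",
              paste(utils::head(bad, 5), collapse = ", "))
  df
}

#' @rdname readEvents
#' @param events event data.frame to serialize.
#' @export
writeEvents <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read covariates
#'
#' TSV with `individual_id` plus numeric covariate columns (age, sex,
#' principal components).
#'
#' @param path file path.
#' @export
readCovariates <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  .checkColumns(df, "individual_id", "covariate table")
  df$individual_id <- as.character(df$individual_id)
  df
}

#' @rdname readCovariates
#' @param covariates covariate data.frame to serialize.
#' @export
writeCovariates <- function(covariates, path) {
  write.table(covariates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PheCode exclusion-range map
#'
#' Dialect: TSV `phecode low high`, one row per exclusion interval (numeric
#' PheCode ranges; several rows per code allowed).  The invariant that the
#' range contains the code itself is enforced: missing self-intervals are
#' auto-added with a warning.
#'
#' @param path file path.
#' @return data.frame with columns `phecode`, `low`, `high`.
#' @export
readPhecodeMap <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric", "numeric"),
                   stringsAsFactors = FALSE)
  .checkColumns(df, c("phecode", "low", "high"), "phecode map")
  .assertThat(all(df$low <= df$high), "virtmet_parse_error",
              "exclusion intervals must have low <= high")
  for (code in unique(df$phecode)) {
    x <- as.numeric(code)
    rows <- df[df$phecode == code, ]
    if (!any(rows$low <= x & x <= rows$high)) {
      warning(sprintf(
        "phecode %s missing from its own exclusion range; auto-added", code))
      df <- rbind(df, data.frame(phecode = code, low = x, high = x))
    }
  }
  df
}

#' Pipeline thresholds
#'
#' Named defaults for every analysis threshold: `pgs_snp_p` (score-model
#' SNP selection, 5e-8), `instrument_p` (MR instrument selection, 5e-6),
#' `clump_r2` and `clump_kb` (LD clumping, 0.05 within 1,000 kb), `fdr`
#' (Benjamini-Hochberg level, 0.05), `min_cases` (100) and `min_instances`
#' (2) for PheCode case/control assembly, `min_snps_validation` (3) and
#' `het_p` (Cochran's Q gate, 0.05) for validation eligibility, plus
#' MR-PRESSO simulation size `presso_nsim` and the weighted-median
#' bootstrap size `wm_boot`.
#'
#' @param ... overrides of the named defaults.
#' @return named list of thresholds.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(pgs_snp_p = 5e-8, instrument_p = 5e-6, clump_r2 = 0.05,
              clump_kb = 1000, fdr = 0.05, min_cases = 100,
              min_instances = 2, min_snps_validation = 3, het_p = 0.05,
              presso_nsim = 1000, wm_boot = 1000, fdr_scope = "phenotype")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  .assertThat(length(unknown) == 0, "virtmet_config_error",
              "unknown pipeline option(s): %s",
              paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file whose top-level keys override the defaults.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Serialize / restore ground truth as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path output path.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(list(
    metabolite_weights = truth@metaboliteWeights,
    direct_effects = as.list(truth@directEffects),
    causal_effect = truth@causalEffect,
    causal_metabolite = truth@causalMetabolite,
    ld_latent_r = truth@ldLatentR
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  de <- unlist(x$direct_effects)
  new("GroundTruth",
      metaboliteWeights = as.data.frame(x$metabolite_weights),
      directEffects = if (is.null(de)) numeric(0) else de,
      causalEffect = x$causal_effect,
      causalMetabolite = x$causal_metabolite, ldLatentR = x$ld_latent_r)
}
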