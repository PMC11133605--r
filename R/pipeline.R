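# Stage-gated orchestration: discovery PheWAS -> MR screen with
# heterogeneity routing to MR-PRESSO -> replication against an external
# outcome table, with a complete filter ledger recording every gate
# decision per (metabolite, phenotype) pair.

.ledgerRow <- function(metabolite, phenotype) {
  data.frame(
    metabolite_id = metabolite, phenotype_id = phenotype,
    phewas_q = NA_real_, mr_beta = NA_real_, mr_se = NA_real_,
    mr_p = NA_real_, mr_q = NA_real_, p_het = NA_real_,
    n_snps = NA_integer_, consistent = NA,
    presso_p_global = NA_real_, presso_n_outliers = NA_integer_,
    presso_beta_post = NA_real_, presso_p_distortion = NA_real_,
    replication_beta = NA_real_, replication_q = NA_real_,
    stage_reached = "phewas_sig", drop_reason = NA_character_,
    stringsAsFactors = FALSE)
}

#' Run the discovery PheWAS stage
#'
#' Computes the PGS of every metabolite with a score model on the
#' discovery panel, assembles the PheCode case/control set(s), runs the
#' phenome-wide scan with within-phenotype FDR, and returns the
#' significant pairs.  Per-cell failures (degenerate scores, non-converged
#' fits) are flagged and never abort the scan.
#'
#' @param study a [VirtualStudy-class] (or any list-like object with the
#'   same `discovery` fields and `scoreModels`).
#' @param config a [pipelineConfig()] list.
#' @return list with `phewas` (result table), `significant` (subset with
#'   `q < fdr`) and `ccSets`.
#' @export
runDiscovery <- function(study, config = pipelineConfig()) {
  disc <- study@discovery
  cc <- assembleCaseControl(disc$events, disc$phecode, map = NULL,
                            covariates = disc$covariates,
                            min_cases = config$min_cases,
                            min_instances = config$min_instances)
  ccSets <- setNames(list(cc), disc$phecode)
  pgsList <- list()
  for (m in names(study@scoreModels)) {
    pv <- tryCatch(computePgs(disc$panel, study@scoreModels[[m]]),
                   error = function(e) NULL)
    if (!is.null(pv)) pgsList[[m]] <- pv
  }
  .assertThat(length(pgsList) > 0, "virtmet_config_error",
              "no metabolite produced a usable PGS")
  phewas <- phewasScan(pgsList, ccSets, disc$covariates,
                       fdr = config$fdr,
                       fdr_scope = if (identical(config$fdr_scope,
                                                 "global")) "global"
                                   else "phenotype")
  list(phewas = phewas, significant = phewas[phewas$significant, ],
       ccSets = ccSets)
}

#' Run the MR screen over significant PheWAS pairs
#'
#' For each pair: builds the instrument from the exposure summary
#' statistics (suggestive-significance selection, greedy LD clumping
#' against the discovery panel, harmonization to the outcome table), runs
#' random-effects IVW with Cochran's Q plus MR-Egger and the weighted
#' median when at least 3 SNPs remain, applies BH FDR to the IVW p-values
#' within each phenotype, and routes heterogeneous pairs (`p_het < het_p`)
#' to MR-PRESSO.  Every decision lands in the filter ledger; pairs whose
#' instruments cannot be built are recorded with a machine-readable drop
#' reason.  A pair is `validation_eligible` when `mr_q < fdr`, the
#' instrument has at least `min_snps_validation` SNPs and `p_het >=
#' het_p`.
#'
#' @param pairs data.frame with `metabolite_id` and `phecode` (the
#'   significant PheWAS pairs, with discovery `beta` if available).
#' @param study a [VirtualStudy-class] providing exposure stats, the LD
#'   reference panel and outcome stats (computed lazily for instrument
#'   variants when the study deferred them).
#' @param config a [pipelineConfig()] list.
#' @param seed seed for the weighted-median bootstrap and MR-PRESSO.
#' @return list with `ledger`, `estimates` (per-pair named list from
#'   [mrAllMethods()]), `instruments` and `presso` results.
#' @export
runMrScreen <- function(pairs, study, config = pipelineConfig(),
                        seed = 1L) {
  ledger <- list()
  estimates <- list()
  instruments <- list()
  pressoRes <- list()
  if (!nrow(pairs)) {
    return(list(ledger = .ledgerRow("", "")[0, ],
                estimates = estimates, instruments = instruments,
                presso = pressoRes))
  }
  ldRef <- study@discovery$panel
  for (i in seq_len(nrow(pairs))) {
    met <- pairs$metabolite_id[i]
    phe <- pairs$phecode[i]
    key <- paste(met, phe, sep = "|")
    row <- .ledgerRow(met, phe)
    if (!is.null(pairs$q)) row$phewas_q <- pairs$q[i]
    expo <- study@exposureStats[[met]]
    if (is.null(expo)) {
      row$drop_reason <- "no_exposure_gwas"
      ledger[[key]] <- row
      next
    }
    cand <- selectCandidates(expo, config$instrument_p)
    if (!nrow(cand)) {
      row$drop_reason <- "no_instrument_snps"
      ledger[[key]] <- row
      next
    }
    clumped <- ldClump(cand, ldRef, r2_threshold = config$clump_r2,
                       window_kb = config$clump_kb)
    outStats <- .outcomeStatsFor(study, clumped$variant, "outcome")
    inst <- tryCatch(
      harmonizeInstruments(clumped, outStats, metabolite_id = met,
                           phenotype_id = phe),
      error = function(e) NULL)
    if (is.null(inst)) {
      row$drop_reason <- "harmonization_failed"
      ledger[[key]] <- row
      next
    }
    mr <- mrAllMethods(inst, n_boot = config$wm_boot,
                       seed = .deriveSeed(seed, i))
    row$n_snps <- nSnps(inst)
    row$mr_beta <- mr$estimates$ivw@beta
    row$mr_se <- mr$estimates$ivw@se
    row$mr_p <- mr$estimates$ivw@p
    row$p_het <- mr$heterogeneity@pHet
    row$consistent <- mr$consistent
    estimates[[key]] <- mr
    instruments[[key]] <- inst
    if (!is.na(row$p_het) && row$p_het < config$het_p &&
        nSnps(inst) >= 4) {
      pr <- runPresso(inst, n_sim = config$presso_nsim,
                      seed = .deriveSeed(seed, 1000L + i))
      pressoRes[[key]] <- pr
      row$presso_p_global <- pr@pGlobal
      row$presso_n_outliers <- length(pr@outliers)
      row$presso_beta_post <- pr@betaPost
      row$presso_p_distortion <- pr@pDistortion
    }
    ledger[[key]] <- row
  }
  ledger <- do.call(rbind, ledger)
  # BH FDR on the IVW p-values, per tested phenotype
  tested <- !is.na(ledger$mr_p)
  for (ph in unique(ledger$phenotype_id[tested])) {
    sel <- tested & ledger$phenotype_id == ph
    ledger$mr_q[sel] <- p.adjust(ledger$mr_p[sel], "BH")
  }
  sig <- !is.na(ledger$mr_q) & ledger$mr_q < config$fdr
  eligible <- sig & ledger$n_snps >= config$min_snps_validation &
    !is.na(ledger$p_het) & ledger$p_het >= config$het_p
  ledger$stage_reached[tested & sig] <- "mr_sig"
  ledger$stage_reached[tested & eligible] <- "validation_eligible"
  ledger$drop_reason[tested & !sig] <- "mr_not_significant"
  ledger$drop_reason[tested & sig & !eligible] <-
    ifelse(ledger$n_snps[tested & sig & !eligible] <
             config$min_snps_validation,
           "too_few_snps", "heterogeneity")
  rownames(ledger) <- NULL
  list(ledger = ledger, estimates = estimates, instruments = instruments,
       presso = pressoRes)
}

.outcomeStatsFor <- function(study, variants, which = c("outcome",
                                                        "replication")) {
  which <- match.arg(which)
  stats <- if (which == "outcome") study@outcomeStats
           else study@replicationStats
  if (is.null(stats)) {
    stats <- simulateSummaryStats(study@config, study@truth, "phenotype",
                                  cohort = which, variants = variants)
  }
  stats
}

#' Run the replication stage
#'
#' Re-harmonizes each validation-eligible pair's exposure instrument
#' against the replication outcome table, recomputes IVW (plus Egger and
#' weighted median for consistency checks), applies BH FDR across the
#' replication batch, and marks a pair replicated when the FDR-adjusted p
#' is below the threshold with the same direction of effect as the
#' discovery MR estimate.  Pairs without a replication table are marked
#' `no_external_data`.
#'
#' @param screen result of [runMrScreen()].
#' @param study the [VirtualStudy-class] (provides replication stats).
#' @param config a [pipelineConfig()] list.
#' @param seed weighted-median bootstrap seed.
#' @return the updated ledger plus `replication_estimates`.
#' @export
runReplication <- function(screen, study, config = pipelineConfig(),
                           seed = 2L) {
  ledger <- screen$ledger
  repEst <- list()
  elig <- which(ledger$stage_reached == "validation_eligible")
  if (!length(elig))
    return(list(ledger = ledger, replication_estimates = repEst))
  pvals <- rep(NA_real_, length(elig))
  betas <- rep(NA_real_, length(elig))
  for (k in seq_along(elig)) {
    i <- elig[k]
    key <- paste(ledger$metabolite_id[i], ledger$phenotype_id[i],
                 sep = "|")
    inst <- screen$instruments[[key]]
    expoSide <- instrumentSnps(inst)
    expoTab <- data.frame(
      variant = expoSide$variant, chrom = expoSide$chrom,
      pos = expoSide$pos, effect_allele = expoSide$effect_allele,
      other_allele = expoSide$other_allele, eaf = expoSide$eaf_exp,
      beta = expoSide$beta_exp, se = expoSide$se_exp,
      p = .normP(expoSide$beta_exp / expoSide$se_exp), n = NA_integer_,
      stringsAsFactors = FALSE)
    repStats <- tryCatch(
      .outcomeStatsFor(study, expoSide$variant, "replication"),
      error = function(e) NULL)
    if (is.null(repStats)) {
      ledger$drop_reason[i] <- "no_external_data"
      next
    }
    repInst <- tryCatch(
      harmonizeInstruments(expoTab, repStats,
                           metabolite_id = ledger$metabolite_id[i],
                           phenotype_id = ledger$phenotype_id[i]),
      error = function(e) NULL)
    if (is.null(repInst)) {
      ledger$drop_reason[i] <- "no_external_data"
      next
    }
    mr <- mrAllMethods(repInst, n_boot = config$wm_boot,
                       seed = .deriveSeed(seed, i))
    repEst[[key]] <- mr
    pvals[k] <- mr$estimates$ivw@p
    betas[k] <- mr$estimates$ivw@beta
  }
  ok <- !is.na(pvals)
  qvals <- rep(NA_real_, length(elig))
  qvals[ok] <- p.adjust(pvals[ok], "BH")
  for (k in seq_along(elig)) {
    i <- elig[k]
    if (is.na(qvals[k])) next
    ledger$replication_beta[i] <- betas[k]
    ledger$replication_q[i] <- qvals[k]
    sameSign <- sign(betas[k]) == sign(ledger$mr_beta[i])
    if (qvals[k] < config$fdr && sameSign) {
      ledger$stage_reached[i] <- "replicated"
    } else {
      ledger$drop_reason[i] <- if (qvals[k] >= config$fdr)
        "replication_not_significant" else "replication_sign_discordant"
    }
  }
  list(ledger = ledger, replication_estimates = repEst)
}

#' Run the full discovery -> MR -> replication pipeline
#'
#' Simulates (or accepts) a study, runs the discovery PheWAS, screens the
#' significant pairs with MR and pleiotropy diagnostics, and attempts
#' replication of the validation-eligible pairs.  Outcome and replication
#' summary statistics are computed lazily for instrument variants when the
#' study deferred them.
#'
#' @param cfg a [SimulationConfig-class], or a ready [VirtualStudy-class].
#' @param config a [pipelineConfig()] list.
#' @param seed analysis-stage seed (bootstrap, MR-PRESSO).
#' @return list with `phewas`, `ledger`, `estimates`,
#'   `replication_estimates` and the `study`.
#' @export
runPipeline <- function(cfg, config = pipelineConfig(), seed = 1L) {
  study <- if (is(cfg, "VirtualStudy")) cfg
           else simulateStudy(cfg, outcome_stats = FALSE,
                              pgs_snp_p = config$pgs_snp_p)
  disc <- runDiscovery(study, config)
  screen <- runMrScreen(disc$significant, study, config, seed = seed)
  rep <- runReplication(screen, study, config,
                        seed = .deriveSeed(seed, 77L))
  list(phewas = disc$phewas, ledger = rep$ledger,
       estimates = screen$estimates,
       replication_estimates = rep$replication_estimates, study = study)
}
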