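# Synthetic three-cohort study generator.
#
# Emulates the design of a virtual-metabolomics study: a discovery biobank
# cohort with genotypes, PheCode events and covariates; an independent
# exposure-GWAS cohort in which metabolite summary statistics (and PGS
# weights) are estimated; an independent outcome-GWAS cohort for per-SNP
# phenotype associations; and a fourth cohort for external replication.
# All cohorts are drawn independently (two-sample contract) and every
# output is a deterministic function of the configuration and its seed.

.COHORTS <- c(discovery = 1L, exposure = 2L, outcome = 3L, replication = 4L)

#' Create a simulation configuration
#'
#' Defaults describe the reference synthetic scenario: a discovery cohort of
#' 20,000 individuals, an exposure GWAS of 6,000 (the scale of a
#' population-based metabolite GWAS), an outcome GWAS of 20,000, 20
#' metabolites with 5-SNP sparse architectures (h2 = 0.3) of which the first
#' causally raises the phenotype risk by 0.5 log-odds per SD, and a 10%
#' prevalence binary phenotype.
#'
#' @param n_discovery,n_exposure_gwas,n_outcome_gwas cohort sizes.
#' @param n_variants,n_ld_blocks variant panel layout.
#' @param within_block_r target adjacent-variant genotype correlation.
#' @param maf_range allele-frequency range, in (0, 0.5].
#' @param n_metabolites,snps_per_metabolite metabolite architecture.
#' @param effect_dist per-SNP effect-size distribution: `"equal"`
#'   (default; every causal SNP explains the same share of the genetic
#'   variance, with random signs, emulating a handful of comparably
#'   strong metabolite QTLs) or `"gaussian"` (normal draws rescaled to
#'   the target heritability).
#' @param h2_metabolite metabolite heritability in [0,1).
#' @param causal_effect log-odds per SD of the causal (first) metabolite.
#' @param n_pleiotropic number of the causal metabolite's SNPs with direct
#'   phenotype effects.
#' @param pleiotropy_mode `"balanced"` or `"directional"`.
#' @param pleiotropy_effect absolute direct log-odds per effect allele.
#' @param prevalence marginal phenotype probability.
#' @param seed integer base seed.
#' @return a [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(n_discovery = 500, n_variants = 20,
#'                         n_ld_blocks = 5, n_metabolites = 2, seed = 1)
#' cfg
#' @export
simulationConfig <- function(n_discovery = 20000, n_exposure_gwas = 6000,
                             n_outcome_gwas = 20000, n_variants = 120,
                             n_ld_blocks = 24, within_block_r = 0.3,
                             maf_range = c(0.05, 0.5), n_metabolites = 20,
                             snps_per_metabolite = 5, effect_dist = "equal",
                             h2_metabolite = 0.3,
                             causal_effect = 0.5, n_pleiotropic = 0,
                             pleiotropy_mode = "balanced",
                             pleiotropy_effect = 0.2, prevalence = 0.1,
                             seed = 1L) {
  counts <- c(n_discovery, n_exposure_gwas, n_outcome_gwas, n_variants,
              n_ld_blocks, n_metabolites, snps_per_metabolite)
  .assertThat(all(is.finite(counts)) && all(counts >= 1),
              "virtmet_config_error", "all counts must be positive")
  obj <- try(new("SimulationConfig",
    nDiscovery = n_discovery, nExposureGwas = n_exposure_gwas,
    nOutcomeGwas = n_outcome_gwas, nVariants = n_variants,
    nLdBlocks = n_ld_blocks, withinBlockR = within_block_r,
    mafRange = as.numeric(maf_range), nMetabolites = n_metabolites,
    snpsPerMetabolite = snps_per_metabolite, effectDist = effect_dist,
    h2Metabolite = h2_metabolite,
    causalEffect = causal_effect, nPleiotropic = n_pleiotropic,
    pleiotropyMode = pleiotropy_mode, pleiotropyEffect = pleiotropy_effect,
    prevalence = prevalence, seed = as.integer(seed)), silent = TRUE)
  if (inherits(obj, "try-error"))
    .virtmetStop("virtmet_config_error", "%s",
                 conditionMessage(attr(obj, "condition")))
  obj
}

.cohortSeed <- function(cfg, cohort, stream) {
  .deriveSeed(cfg@seed, 100L * .COHORTS[[cohort]] + stream)
}

# Deterministic variant panel layout shared by all cohorts: contiguous LD
# blocks distributed across chromosomes 1..22, blocks on the same chromosome
# 5 Mb apart (well beyond any clumping window), variants 5 kb apart within a
# block.
.variantFrame <- function(cfg) {
  .withSeed(.deriveSeed(cfg@seed, 11L), {
    nV <- cfg@nVariants
    nb <- cfg@nLdBlocks
    block <- sort(rep(seq_len(nb), length.out = nV))
    chrom <- as.character(((block - 1L) %% 22L) + 1L)
    blockRow <- ((block - 1L) %/% 22L)
    within <- stats::ave(seq_len(nV), block, FUN = seq_along)
    pos <- 1e6 + blockRow * 5e6 + (within - 1L) * 5000
    maf <- runif(nV, cfg@mafRange[1], cfg@mafRange[2])
    alleles <- t(vapply(seq_len(nV),
                        function(i) sample(c("A", "C", "G", "T"), 2L),
                        character(2)))
    data.frame(
      variant = sprintf("var%04d", seq_len(nV)), chrom = chrom,
      pos = as.integer(pos), ref = alleles[, 1], alt = alleles[, 2],
      maf = maf, block = block, id = sprintf("rs%06d", 100000L + seq_len(nV)),
      stringsAsFactors = FALSE
    )
  })
}

.genotypePanel <- function(dos, vf, ids) {
  rownames(dos) <- vf$variant
  colnames(dos) <- ids
  rd <- DataFrame(chrom = vf$chrom, pos = vf$pos, ref = vf$ref, alt = vf$alt,
                  eaf = rowMeans(dos, na.rm = TRUE) / 2, id = vf$id,
                  row.names = vf$variant)
  if (!is.null(vf$block)) rd$block <- vf$block
  new("GenotypePanel",
      SummarizedExperiment(assays = list(dosage = dos), rowData = rd))
}

# Two haplotypes per individual from a Gaussian copula: within a block the
# latent variables follow an AR(1) correlation rho = sin(pi*r/2), which
# inverts the binary-threshold attenuation (2/pi)*asin(rho) so the realized
# adjacent-genotype correlation approximates the configured r for common
# variants.  Blocks are independent.
.simulateDosages <- function(vf, n, withinBlockR) {
  rho <- sin(pi * withinBlockR / 2)
  out <- matrix(0, nrow = n, ncol = nrow(vf))
  for (b in unique(vf$block)) {
    idx <- which(vf$block == b)
    m <- length(idx)
    thr <- qnorm(vf$maf[idx])
    hap <- matrix(0L, nrow = n, ncol = m)
    for (h in 1:2) {
      Z <- matrix(rnorm(n * m), n, m)
      if (m > 1 && rho > 0) {
        R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
        Z <- Z %*% chol(R)
      }
      hap <- hap + (Z < matrix(thr, n, m, byrow = TRUE))
    }
    out[, idx] <- hap
  }
  t(out)
}

#' Simulate a genotype panel for one cohort
#'
#' Draws alt-allele dosages in \{0,1,2\} for one of the four non-overlapping
#' cohorts.  The variant panel (positions, alleles, target frequencies, LD
#' blocks) is a deterministic function of the configuration seed and is
#' shared across cohorts; individual draws use a cohort-specific stream, so
#' cohort ID sets are pairwise disjoint by construction.
#'
#' @param cfg a [SimulationConfig-class].
#' @param cohort one of `"discovery"`, `"exposure"`, `"outcome"`,
#'   `"replication"`.
#' @param n optional cohort-size override.
#' @return a [GenotypePanel-class].
#' @examples
#' cfg <- simulationConfig(n_discovery = 200, n_variants = 10,
#'                         n_ld_blocks = 2, seed = 7)
#' panel <- simulateGenotypes(cfg)
#' dim(dosages(panel))
#' @export
simulateGenotypes <- function(cfg,
                              cohort = c("discovery", "exposure", "outcome",
                                         "replication"),
                              n = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  cohort <- match.arg(cohort)
  vf <- .variantFrame(cfg)
  if (is.null(n)) {
    n <- switch(cohort, discovery = cfg@nDiscovery,
                exposure = cfg@nExposureGwas, outcome = cfg@nOutcomeGwas,
                replication = cfg@nOutcomeGwas)
  }
  .assertThat(n >= 1, "virtmet_config_error", "cohort size must be positive")
  dos <- .withSeed(.cohortSeed(cfg, cohort, 1L),
                   .simulateDosages(vf, n, cfg@withinBlockR))
  ids <- sprintf("%s%06d", substr(cohort, 1, 4), seq_len(n))
  .genotypePanel(dos, vf, ids)
}

#' Simulate metabolite architectures and values
#'
#' Assigns each metabolite `snps_per_metabolite` causal variants spread over
#' distinct LD blocks, draws per-allele effects, scales them so the genetic
#' variance fraction equals `h2_metabolite`, and returns standardized
#' metabolite values (genetic value plus Gaussian noise, mean 0, SD 1)
#' together with the generating [GroundTruth-class].  Direct (pleiotropic)
#' phenotype effects are planted on the first `n_pleiotropic` SNPs of the
#' causal metabolite, with signs by `pleiotropy_mode`.
#'
#' @param panel discovery [GenotypePanel-class].
#' @param cfg the [SimulationConfig-class].
#' @return list with `values` (individuals x metabolites matrix) and `truth`
#'   (a [GroundTruth-class]).
#' @export
simulateMetabolites <- function(panel, cfg) {
  stopifnot(is(panel, "GenotypePanel"), is(cfg, "SimulationConfig"))
  .assertThat(cfg@h2Metabolite >= 0 && cfg@h2Metabolite < 1,
              "virtmet_config_error", "h2 must be in [0,1)")
  vf <- variantInfo(panel)
  block <- rowData(panel)$block
  .assertThat(!is.null(block), "virtmet_config_error",
              "panel lacks LD-block annotation (not a simulated panel?)")
  D <- dosages(panel)
  metIds <- sprintf("met%02d", seq_len(cfg@nMetabolites))
  truthDf <- .withSeed(.deriveSeed(cfg@seed, 21L), {
    rows <- vector("list", cfg@nMetabolites)
    for (k in seq_len(cfg@nMetabolites)) {
      spm <- cfg@snpsPerMetabolite
      blocks <- sample(unique(block), min(spm, length(unique(block))))
      if (length(blocks) < spm)
        blocks <- c(blocks, sample(unique(block), spm - length(blocks),
                                   replace = TRUE))
      pick <- integer(0)
      for (b in blocks) {
        cand <- setdiff(which(block == b), pick)
        if (!length(cand)) cand <- setdiff(seq_len(nrow(vf)), pick)
        pick <- c(pick, cand[sample.int(length(cand), 1L)])
      }
      Xc <- t(D[pick, , drop = FALSE])
      Xc <- sweep(Xc, 2L, colMeans(Xc))
      eff <- if (cfg@effectDist == "equal") {
        v <- pmax(apply(Xc, 2L, var), 1e-12)
        sample(c(-1, 1), spm, replace = TRUE) / sqrt(v)
      } else {
        rnorm(spm)
      }
      g <- as.numeric(Xc %*% eff)
      vg <- var(g)
      eff <- if (cfg@h2Metabolite > 0 && vg > 0) {
        eff * sqrt(cfg@h2Metabolite / vg)
      } else {
        rep(0, spm)
      }
      rows[[k]] <- data.frame(metabolite = metIds[k],
                              variant = vf$variant[pick], effect = eff,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  directs <- numeric(0)
  if (cfg@nPleiotropic > 0) {
    causalSnps <- truthDf$variant[truthDf$metabolite == metIds[1]]
    k <- cfg@nPleiotropic
    signs <- .withSeed(.deriveSeed(cfg@seed, 22L), {
      if (cfg@pleiotropyMode == "directional") rep(1, k)
      else sample(c(-1, 1), k, replace = TRUE)
    })
    directs <- setNames(signs * cfg@pleiotropyEffect, causalSnps[seq_len(k)])
  }
  truth <- new("GroundTruth", metaboliteWeights = truthDf,
               directEffects = directs, causalEffect = cfg@causalEffect,
               causalMetabolite = metIds[1],
               ldLatentR = sin(pi * cfg@withinBlockR / 2))
  values <- .metaboliteMatrix(panel, truth, cfg,
                              .cohortSeed(cfg, "discovery", 2L))
  list(values = values, truth = truth)
}

# Regenerate metabolite values on any cohort panel from the stored truth:
# genetic value on centered dosages plus N(0, 1 - h2) noise, standardized
# exactly to mean 0 / SD 1 per column.
.metaboliteMatrix <- function(panel, truth, cfg, seed) {
  D <- dosages(panel)
  n <- ncol(D)
  metIds <- unique(truth@metaboliteWeights$metabolite)
  .withSeed(seed, {
    out <- matrix(0, nrow = n, ncol = length(metIds),
                  dimnames = list(colnames(D), metIds))
    noiseSd <- sqrt(1 - cfg@h2Metabolite)
    for (k in seq_along(metIds)) {
      w <- truth@metaboliteWeights[
        truth@metaboliteWeights$metabolite == metIds[k], ]
      Xc <- t(D[w$variant, , drop = FALSE])
      Xc <- sweep(Xc, 2L, colMeans(Xc))
      y <- as.numeric(Xc %*% w$effect) + rnorm(n, 0, noiseSd)
      out[, k] <- (y - mean(y)) / sd(y)
    }
    out
  })
}

#' Simulate the binary phenotype, PheCode events and covariates
#'
#' Case status follows a logistic liability: `P(case) = logistic(alpha +
#' causal_effect * metabolite + sum(direct_effects * dosage) + covariate
#' effects)`, with the intercept `alpha` solved numerically so the marginal
#' prevalence matches the configuration.  Every case is emitted with two
#' event rows for the target PheCode (the minimum satisfying the
#' two-instance case rule; `event_jitter` adds Poisson extra rows) and a
#' small fraction of controls receive a single sub-threshold instance, so
#' exclusion logic is exercised downstream.  Covariates are age ~
#' Uniform(18, 85), sex ~ Bernoulli(0.5) and 10 standard-normal principal
#' components, independent of genotype.
#'
#' @param panel cohort [GenotypePanel-class].
#' @param metabolite numeric vector of causal-metabolite values (one per
#'   individual).
#' @param truth the [GroundTruth-class].
#' @param cfg the [SimulationConfig-class].
#' @param seed RNG seed (defaults to a discovery-cohort stream).
#' @param target_phecode PheCode assigned to simulated events.
#' @param age_effect,sex_effect covariate log-odds effects on liability.
#' @param subthreshold_frac fraction of controls given a single event row.
#' @param event_jitter Poisson mean of extra event rows per case.
#' @param pc_confounding in [0,1); when positive, the first principal
#'   component is tied to the individual's mean dosage with this squared
#'   correlation, a stress switch emulating residual population
#'   stratification (default 0: PCs independent of genotype).
#' @return list with `labels` (named 0/1 vector), `events` (data.frame
#'   `individual_id`, `phecode`, `count`), `covariates` (data.frame) and
#'   `alpha` (solved intercept).
#' @export
simulatePhenotype <- function(panel, metabolite, truth, cfg, seed = NULL,
                              target_phecode = "250.2", age_effect = 0.01,
                              sex_effect = 0.15, subthreshold_frac = 0.05,
                              event_jitter = 0, pc_confounding = 0) {
  stopifnot(is(panel, "GenotypePanel"))
  n <- ncol(panel)
  .assertThat(length(metabolite) == n, "virtmet_config_error",
              "metabolite length must equal panel size")
  .assertThat(cfg@prevalence > 0 && cfg@prevalence < 1,
              "virtmet_config_error", "prevalence must be in (0,1)")
  if (is.null(seed)) seed <- .cohortSeed(cfg, "discovery", 3L)
  ids <- individualIds(panel)
  .withSeed(seed, {
    age <- runif(n, 18, 85)
    sex <- rbinom(n, 1L, 0.5)
    pcs <- matrix(rnorm(n * 10L), n, 10L,
                  dimnames = list(NULL, sprintf("pc%d", 1:10)))
    if (pc_confounding > 0) {
      gmean <- scale(colMeans(dosages(panel)))[, 1]
      pcs[, 1] <- sqrt(pc_confounding) * gmean +
        sqrt(1 - pc_confounding) * pcs[, 1]
    }
    eta <- truth@causalEffect * metabolite +
      age_effect * (age - 51.5) + sex_effect * (sex - 0.5)
    if (length(truth@directEffects)) {
      Dg <- dosages(panel)[names(truth@directEffects), , drop = FALSE]
      eta <- eta + as.numeric(crossprod(Dg, truth@directEffects))
    }
    alpha <- uniroot(function(a) mean(plogis(a + eta)) - cfg@prevalence,
                     c(-40, 40), tol = 1e-10)$root
    y <- rbinom(n, 1L, plogis(alpha + eta))
    caseIds <- ids[y == 1L]
    nEv <- rep(2L, length(caseIds))
    if (event_jitter > 0) nEv <- nEv + rpois(length(caseIds), event_jitter)
    events <- data.frame(
      individual_id = rep(caseIds, nEv),
      phecode = target_phecode,
      count = 1L, stringsAsFactors = FALSE
    )
    ctrl <- ids[y == 0L]
    nSub <- floor(subthreshold_frac * length(ctrl))
    if (nSub > 0) {
      sub <- sample(ctrl, nSub)
      events <- rbind(events, data.frame(
        individual_id = sub, phecode = target_phecode, count = 1L,
        stringsAsFactors = FALSE))
    }
    covariates <- data.frame(individual_id = ids, age = age, sex = sex,
                             pcs, stringsAsFactors = FALSE)
    list(labels = setNames(y, ids), events = events,
         covariates = covariates, alpha = alpha)
  })
}

#' Simulate two-sample GWAS summary statistics
#'
#' Regenerates a fresh, non-overlapping cohort and computes per-variant
#' association statistics: simple linear regression of the (standardized)
#' metabolite on alt-allele dosage for metabolite traits, or logistic
#' regression of case status on dosage adjusted for age, sex and 10
#' principal components for the phenotype.  Exposure and outcome tables
#' never share individuals.
#'
#' @param cfg the [SimulationConfig-class].
#' @param truth the [GroundTruth-class].
#' @param trait a metabolite identifier (e.g. `"met01"`) or `"phenotype"`.
#' @param cohort cohort to draw; defaults to `"exposure"` for metabolites
#'   and `"outcome"` for the phenotype.
#' @param variants optional variant subset to report (default: all).
#' @return summary-statistic data.frame with columns `variant`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`.
#' @export
simulateSummaryStats <- function(cfg, truth, trait, cohort = NULL,
                                 variants = NULL) {
  stopifnot(is(cfg, "SimulationConfig"), is(truth, "GroundTruth"))
  if (is.null(cohort))
    cohort <- if (identical(trait, "phenotype")) "outcome" else "exposure"
  panel <- simulateGenotypes(cfg, cohort)
  mets <- .metaboliteMatrix(panel, truth, cfg, .cohortSeed(cfg, cohort, 2L))
  if (identical(trait, "phenotype")) {
    phe <- simulatePhenotype(panel, mets[, truth@causalMetabolite], truth,
                             cfg, seed = .cohortSeed(cfg, cohort, 3L))
    cc <- new("CaseControlSet", phecode = "synthetic",
              caseIds = names(phe$labels)[phe$labels == 1L],
              controlIds = names(phe$labels)[phe$labels == 0L],
              excludedIds = character(0), ageWindow = c(18, 85),
              analyzable = TRUE)
    snpOutcomeGwas(panel, cc, phe$covariates, variants = variants)
  } else {
    .assertThat(trait %in% colnames(mets), "virtmet_config_error",
                "unknown metabolite '%s'", trait)
    .linearGwas(panel, mets[, trait], variants = variants)
  }
}

# Vectorized per-variant simple linear regression (marginal model).
.linearGwas <- function(panel, y, variants = NULL) {
  D <- dosages(panel)
  if (!is.null(variants)) D <- D[variants, , drop = FALSE]
  vf <- variantInfo(panel)
  vf <- vf[match(rownames(D), vf$variant), ]
  n <- ncol(D)
  yc <- y - mean(y)
  Dc <- D - rowMeans(D)
  Sxx <- rowSums(Dc^2)
  Sxy <- as.numeric(Dc %*% yc)
  Syy <- sum(yc^2)
  beta <- ifelse(Sxx > 0, Sxy / Sxx, NA_real_)
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- ifelse(Sxx > 0, sqrt(rss / ((n - 2) * Sxx)), NA_real_)
  data.frame(
    variant = vf$variant, chrom = vf$chrom, pos = vf$pos,
    effect_allele = vf$alt, other_allele = vf$ref, eaf = vf$eaf,
    beta = beta, se = se, p = .normP(beta / se), n = n,
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete virtual-metabolomics study
#'
#' Builds the discovery cohort (panel, metabolites, phenotype, events,
#' covariates), trains per-metabolite score models from the exposure-cohort
#' GWAS at the genome-wide threshold, and (optionally) computes outcome and
#' replication summary statistics for the phenotype in their own cohorts.
#'
#' @param cfg a [SimulationConfig-class].
#' @param outcome_stats,replication_stats compute the per-variant phenotype
#'   GWAS now (`TRUE`) or defer (`FALSE`, e.g. when [runPipeline()] will
#'   request only instrument variants).
#' @param pgs_snp_p p-value threshold for score-model SNP selection.
#' @return a [VirtualStudy-class].
#' @examples
#' cfg <- simulationConfig(n_discovery = 400, n_exposure_gwas = 400,
#'                         n_outcome_gwas = 400, n_variants = 20,
#'                         n_ld_blocks = 5, n_metabolites = 3, seed = 3)
#' study <- simulateStudy(cfg, outcome_stats = FALSE)
#' study
#' @export
simulateStudy <- function(cfg, outcome_stats = TRUE,
                          replication_stats = outcome_stats,
                          pgs_snp_p = 5e-8) {
  stopifnot(is(cfg, "SimulationConfig"))
  panel <- simulateGenotypes(cfg, "discovery")
  met <- simulateMetabolites(panel, cfg)
  phe <- simulatePhenotype(panel, met$values[, met$truth@causalMetabolite],
                           met$truth, cfg)
  expoPanel <- simulateGenotypes(cfg, "exposure")
  expoMets <- .metaboliteMatrix(expoPanel, met$truth, cfg,
                                .cohortSeed(cfg, "exposure", 2L))
  exposureStats <- lapply(
    setNames(colnames(expoMets), colnames(expoMets)),
    function(m) .linearGwas(expoPanel, expoMets[, m]))
  scoreModels <- list()
  for (m in names(exposureStats)) {
    sm <- scoreModelFromStats(exposureStats[[m]], m, p_threshold = pgs_snp_p)
    if (!is.null(sm)) scoreModels[[m]] <- sm
  }
  new("VirtualStudy", config = cfg, truth = met$truth,
      discovery = list(panel = panel, metabolites = met$values,
                       labels = phe$labels, events = phe$events,
                       covariates = phe$covariates, phecode = "250.2"),
      scoreModels = scoreModels, exposureStats = exposureStats,
      outcomeStats = if (outcome_stats)
        simulateSummaryStats(cfg, met$truth, "phenotype", "outcome")
      else NULL,
      replicationStats = if (replication_stats)
        simulateSummaryStats(cfg, met$truth, "phenotype", "replication")
      else NULL)
}
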