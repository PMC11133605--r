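# S4 classes for the virtual-metabolomics pipeline.

#' Simulation configuration for the synthetic three-cohort study
#'
#' Holds every knob of the synthetic-data generator: cohort sizes for the
#' discovery (PGS/PheWAS) cohort and the two non-overlapping GWAS cohorts,
#' the LD-block genotype model, sparse metabolite architectures, and the
#' liability model of the binary phenotype.
#'
#' @slot nDiscovery individuals in the discovery (PheWAS) cohort.
#' @slot nExposureGwas individuals in the exposure (metabolite) GWAS cohort.
#' @slot nOutcomeGwas individuals in the outcome (phenotype) GWAS cohort.
#' @slot nVariants number of simulated variants.
#' @slot nLdBlocks number of LD blocks the variants are partitioned into.
#' @slot withinBlockR target adjacent-variant genotype correlation in [0,1).
#' @slot mafRange length-2 numeric, minor/effect allele frequency range in
#'   (0, 0.5].
#' @slot nMetabolites number of metabolites.
#' @slot snpsPerMetabolite causal SNPs per metabolite.
#' @slot effectDist `"equal"` (every causal SNP contributes the same
#'   genetic variance, random signs) or `"gaussian"` (normal effect
#'   draws, rescaled to the target heritability).
#' @slot h2Metabolite metabolite heritability in [0,1); environmental
#'   variance is 1 - h2 after standardization.
#' @slot causalEffect log-odds of the phenotype per SD of the causal
#'   metabolite (the first metabolite).
#' @slot nPleiotropic number of the causal metabolite's SNPs that also carry
#'   direct (horizontally pleiotropic) effects on the phenotype.
#' @slot pleiotropyMode "balanced" (signs symmetric, mean zero) or
#'   "directional" (all one sign).
#' @slot pleiotropyEffect absolute direct log-odds effect per effect allele
#'   for pleiotropic variants.
#' @slot prevalence marginal phenotype probability in (0,1).
#' @slot seed integer base seed; all generator outputs are deterministic
#'   functions of the configuration and this seed.
#' @seealso [simulationConfig()], [simulateStudy()]
#' @export
setClass("SimulationConfig", representation(
  nDiscovery = "numeric", nExposureGwas = "numeric", nOutcomeGwas = "numeric",
  nVariants = "numeric", nLdBlocks = "numeric", withinBlockR = "numeric",
  mafRange = "numeric", nMetabolites = "numeric",
  snpsPerMetabolite = "numeric", effectDist = "character",
  h2Metabolite = "numeric",
  causalEffect = "numeric", nPleiotropic = "numeric",
  pleiotropyMode = "character", pleiotropyEffect = "numeric",
  prevalence = "numeric", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  counts <- c(
    nDiscovery = object@nDiscovery, nExposureGwas = object@nExposureGwas,
    nOutcomeGwas = object@nOutcomeGwas, nVariants = object@nVariants,
    nLdBlocks = object@nLdBlocks, nMetabolites = object@nMetabolites,
    snpsPerMetabolite = object@snpsPerMetabolite
  )
  if (any(counts < 1)) {
    msgs <- c(msgs, paste("counts must be positive:",
                          paste(names(counts)[counts < 1], collapse = ", ")))
  }
  if (object@withinBlockR < 0 || object@withinBlockR >= 1)
    msgs <- c(msgs, "withinBlockR must be in [0,1)")
  if (length(object@mafRange) != 2 || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    msgs <- c(msgs, "mafRange must be (low, high) within (0, 0.5]")
  if (object@h2Metabolite < 0 || object@h2Metabolite >= 1)
    msgs <- c(msgs, "h2Metabolite must be in [0,1)")
  if (object@prevalence <= 0 || object@prevalence >= 1)
    msgs <- c(msgs, "prevalence must be in (0,1)")
  if (!object@pleiotropyMode %in% c("balanced", "directional"))
    msgs <- c(msgs, "pleiotropyMode must be 'balanced' or 'directional'")
  if (!object@effectDist %in% c("equal", "gaussian"))
    msgs <- c(msgs, "effectDist must be 'equal' or 'gaussian'")
  if (object@snpsPerMetabolite > object@nVariants)
    msgs <- c(msgs, "snpsPerMetabolite cannot exceed nVariants")
  if (object@nPleiotropic < 0 || object@nPleiotropic > object@snpsPerMetabolite)
    msgs <- c(msgs, "nPleiotropic must be in [0, snpsPerMetabolite]")
  if (length(msgs)) msgs else TRUE
})

#' Genotype dosage panel
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `"dosage"` assay
#' (variants in rows, individuals in columns; alt-allele dosages in [0,2],
#' `NA` for missing) and variant metadata (`chrom`, `pos`, `ref`, `alt`,
#' `eaf`, `id`) in `rowData`.  `eaf` is the empirical alt-allele frequency.
#'
#' @seealso [simulateGenotypes()], [readGenotypes()], [dosages()]
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msgs <- character()
  if (!"dosage" %in% assayNames(object))
    msgs <- c(msgs, "assay 'dosage' is required")
  need <- c("chrom", "pos", "ref", "alt", "eaf", "id")
  miss <- setdiff(need, colnames(rowData(object)))
  if (length(miss))
    msgs <- c(msgs, paste("rowData lacks:", paste(miss, collapse = ", ")))
  if ("dosage" %in% assayNames(object)) {
    d <- assay(object, "dosage")
    rng <- range(d, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
      msgs <- c(msgs, "dosages must lie in [0,2]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ground truth of a simulated study
#'
#' Records the generating parameters of a synthetic study so downstream
#' parameter-recovery tests can compare estimates with truth.
#'
#' @slot metaboliteWeights data.frame with columns `metabolite`, `variant`,
#'   `effect` (per-alt-allele effect on the standardized metabolite).
#' @slot directEffects named numeric; direct log-odds effects of variants on
#'   the phenotype (horizontal pleiotropy).  Empty when none.
#' @slot causalEffect log-odds per SD of the causal metabolite.
#' @slot causalMetabolite identifier of the causal metabolite.
#' @slot ldLatentR latent copula correlation used within LD blocks.
#' @export
setClass("GroundTruth", representation(
  metaboliteWeights = "data.frame", directEffects = "numeric",
  causalEffect = "numeric", causalMetabolite = "character",
  ldLatentR = "numeric"
))

setValidity("GroundTruth", function(object) {
  de <- object@directEffects
  if (length(de) > 1) {
    s <- sign(de[de != 0])
    # mode is not stored; only the structural constraint is checkable here
    if (any(!is.finite(de))) return("direct effects must be finite")
  }
  TRUE
})

#' One metabolite's genetic score model
#'
#' A sparse SNP weight set: the variants, the allele each weight refers to,
#' and the weight, as read from a PLINK-score-style file or trained from
#' exposure GWAS summary statistics.
#'
#' @slot metaboliteId metabolite identifier.
#' @slot entries data.frame with columns `variant`, `chrom`, `pos`, `ref`,
#'   `alt`, `effect_allele`, `weight`.
#' @slot sourcePThreshold p-value threshold the SNPs were selected at
#'   (default 5e-8).
#' @seealso [readScoreModel()], [scoreModelFromStats()], [computePgs()]
#' @export
setClass("ScoreModel", representation(
  metaboliteId = "character", entries = "data.frame",
  sourcePThreshold = "numeric"
))

setValidity("ScoreModel", function(object) {
  e <- object@entries
  msgs <- character()
  need <- c("variant", "chrom", "pos", "ref", "alt", "effect_allele", "weight")
  miss <- setdiff(need, colnames(e))
  if (length(miss))
    return(paste("entries lack columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(e$variant))
    msgs <- c(msgs, "duplicate variants in score model")
  if (nrow(e) && !all(e$effect_allele == e$ref | e$effect_allele == e$alt))
    msgs <- c(msgs, "effect_allele must be ref or alt of its variant")
  if (nrow(e) && !all(is.finite(e$weight)))
    msgs <- c(msgs, "weights must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Per-individual polygenic score vector
#'
#' @slot metaboliteId metabolite identifier.
#' @slot values named numeric, standardized (mean 0, SD 1) scores.
#' @slot nVariantsUsed score variants found in the panel and used.
#' @slot nMissingHandled missing dosage entries imputed (or variants dropped,
#'   under `drop_variant`).
#' @export
setClass("PgsVector", representation(
  metaboliteId = "character", values = "numeric",
  nVariantsUsed = "integer", nMissingHandled = "integer"
))

setValidity("PgsVector", function(object) {
  if (!all(is.finite(object@values))) "values must be finite" else TRUE
})

#' PheCode case/control partition
#'
#' @slot phecode the target PheCode.
#' @slot caseIds individuals with >= minInstances code instances.
#' @slot controlIds individuals with no code in the exclusion range and age
#'   within the observed case age window.
#' @slot excludedIds everyone else (related codes, or outside the window).
#' @slot ageWindow observed (min, max) case age.
#' @slot analyzable TRUE when the case count reaches the minimum.
#' @seealso [assembleCaseControl()]
#' @export
setClass("CaseControlSet", representation(
  phecode = "character", caseIds = "character", controlIds = "character",
  excludedIds = "character", ageWindow = "numeric", analyzable = "logical"
))

setValidity("CaseControlSet", function(object) {
  ids <- c(object@caseIds, object@controlIds, object@excludedIds)
  if (anyDuplicated(ids))
    return("case/control/excluded sets must be disjoint")
  TRUE
})

#' Harmonized two-sample MR instrument
#'
#' Exposure and outcome per-SNP effects aligned to a common effect allele,
#' with a provenance log of every drop and flip applied during
#' harmonization.
#'
#' @slot metaboliteId exposure identifier.
#' @slot phenotypeId outcome identifier.
#' @slot snps data.frame with columns `variant`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out` (and optionally `eaf_exp`, `eaf_out`).
#' @slot provenance data.frame (`variant`, `action`, `detail`) recording
#'   harmonization decisions.
#' @seealso [harmonizeInstruments()], [mrIvw()]
#' @export
setClass("HarmonizedInstrument", representation(
  metaboliteId = "character", phenotypeId = "character",
  snps = "data.frame", provenance = "data.frame"
))

setValidity("HarmonizedInstrument", function(object) {
  s <- object@snps
  need <- c("variant", "chrom", "pos", "effect_allele", "other_allele",
            "beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, colnames(s))
  if (length(miss))
    return(paste("snps lack columns:", paste(miss, collapse = ", ")))
  if (nrow(s) < 1) return("an instrument needs at least one SNP")
  if (!all(s$se_exp > 0) || !all(s$se_out > 0))
    return("all standard errors must be positive")
  TRUE
})

#' Mendelian randomization estimate
#'
#' @slot method one of `"wald"`, `"ivw_fixed"`, `"ivw_re"`, `"egger"`,
#'   `"weighted_median"`.
#' @slot beta causal estimate (log-OR outcome per unit exposure).
#' @slot se standard error.
#' @slot ci95 `beta +- 1.96 * se`.
#' @slot p two-sided normal p-value.
#' @slot intercept,interceptSe,interceptP Egger intercept (average
#'   directional pleiotropy); `NA` for other methods.
#' @slot nSnps number of SNPs used.
#' @export
setClass("MREstimate", representation(
  method = "character", beta = "numeric", se = "numeric", ci95 = "numeric",
  p = "numeric", intercept = "numeric", interceptSe = "numeric",
  interceptP = "numeric", nSnps = "integer"
))

setValidity("MREstimate", function(object) {
  if (is.finite(object@se) && length(object@ci95) == 2) {
    expect <- object@beta + c(-1, 1) * 1.96 * object@se
    if (max(abs(object@ci95 - expect)) > 1e-8)
      return("ci95 must equal beta +- 1.96*se")
  }
  TRUE
})

#' Cochran's Q heterogeneity result
#'
#' @slot Q Cochran statistic (weighted residual sum of squares).
#' @slot df degrees of freedom: nSnps - 1 (IVW) or nSnps - 2 (Egger).
#' @slot pHet chi-square tail probability; `NA` when df < 1.
#' @slot phi overdispersion Q/df.
#' @export
setClass("HeterogeneityResult", representation(
  Q = "numeric", df = "numeric", pHet = "numeric", phi = "numeric"
))

setValidity("HeterogeneityResult", function(object) {
  if (is.finite(object@Q) && object@Q < 0) return("Q must be >= 0")
  TRUE
})

#' MR-PRESSO result
#'
#' Output of the simulation-based pleiotropy residual sum and outlier test:
#' global test, per-SNP outlier test (Bonferroni-adjusted Monte-Carlo
#' p-values) and the pre/post outlier-removal distortion test.
#'
#' @slot rssObs observed leave-one-out weighted residual sum of squares.
#' @slot pGlobal Monte-Carlo global-test p-value, (1+k)/(1+nSim).
#' @slot outlierP named per-SNP adjusted outlier p-values.
#' @slot outliers variants with adjusted p below the outlier alpha.
#' @slot betaPre,betaPost IVW estimates before/after outlier removal
#'   (`betaPost` is `NA` when no outliers were flagged).
#' @slot pDistortion distortion-test p-value (`NA` when no outliers).
#' @slot nSim simulations used; @slot seed RNG seed.
#' @seealso [runPresso()]
#' @export
setClass("PressoResult", representation(
  rssObs = "numeric", pGlobal = "numeric", outlierP = "numeric",
  outliers = "character", betaPre = "numeric", betaPost = "numeric",
  pDistortion = "numeric", nSim = "integer", seed = "integer"
))

setValidity("PressoResult", function(object) {
  msgs <- character()
  if (object@pGlobal <= 0 || object@pGlobal > 1)
    msgs <- c(msgs, "pGlobal must be in (0,1]")
  if (length(object@outlierP) &&
      !all(object@outlierP > 0 & object@outlierP <= 1))
    msgs <- c(msgs, "outlier p-values must be in (0,1]")
  if (length(object@outliers) &&
      !all(object@outliers %in% names(object@outlierP)))
    msgs <- c(msgs, "outliers must be a subset of instrument SNPs")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic virtual-metabolomics study
#'
#' Container for everything [simulateStudy()] produces: the discovery cohort
#' (panel, metabolites, phenotype, events, covariates), trained score
#' models, per-metabolite exposure GWAS summary statistics, outcome and
#' replication summary statistics, and the [GroundTruth-class].
#'
#' @slot config the [SimulationConfig-class] used.
#' @slot truth the generating [GroundTruth-class].
#' @slot discovery list: `panel`, `metabolites`, `labels`, `events`,
#'   `covariates`, `phecode`.
#' @slot scoreModels named list of [ScoreModel-class] (metabolites with no
#'   genome-wide-significant SNP are absent).
#' @slot exposureStats named list of summary-stat data.frames, one per
#'   metabolite.
#' @slot outcomeStats summary-stat data.frame for the phenotype in the
#'   outcome cohort, or `NULL` when deferred.
#' @slot replicationStats as `outcomeStats`, for the replication cohort.
#' @export
setClass("VirtualStudy", representation(
  config = "SimulationConfig", truth = "GroundTruth", discovery = "list",
  scoreModels = "list", exposureStats = "list", outcomeStats = "ANY",
  replicationStats = "ANY"
))

# ---- show methods ---------------------------------------------------------

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  cohorts: discovery=%d exposure=%d outcome=%d\n",
              object@nDiscovery, object@nExposureGwas, object@nOutcomeGwas))
  cat(sprintf("  variants: %d in %d LD blocks (r=%.2f), maf [%.2f, %.2f]\n",
              object@nVariants, object@nLdBlocks, object@withinBlockR,
              object@mafRange[1], object@mafRange[2]))
  cat(sprintf("  metabolites: %d x %d SNPs, h2=%.2f\n", object@nMetabolites,
              object@snpsPerMetabolite, object@h2Metabolite))
  cat(sprintf(
    "  phenotype: prevalence=%.2f, causal=%.2f, pleiotropic=%d (%s)\n",
    object@prevalence, object@causalEffect, object@nPleiotropic,
    object@pleiotropyMode))
  cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "ScoreModel", function(object) {
  cat(sprintf("ScoreModel '%s': %d SNPs (source p < %g)\n",
              object@metaboliteId, nrow(object@entries),
              object@sourcePThreshold))
})

setMethod("show", "PgsVector", function(object) {
  cat(sprintf("PgsVector '%s': n=%d, %d variants used, %d missing handled\n",
              object@metaboliteId, length(object@values),
              object@nVariantsUsed, object@nMissingHandled))
})

setMethod("show", "CaseControlSet", function(object) {
  cat(sprintf(
    "CaseControlSet '%s': %d cases, %d controls, %d excluded%s\n",
    object@phecode, length(object@caseIds), length(object@controlIds),
    length(object@excludedIds),
    if (object@analyzable) "" else " [not analyzable]"))
})

setMethod("show", "HarmonizedInstrument", function(object) {
  cat(sprintf("HarmonizedInstrument %s -> %s: %d SNPs (%d log entries)\n",
              object@metaboliteId, object@phenotypeId, nrow(object@snps),
              nrow(object@provenance)))
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s]: beta=%.4f se=%.4f p=%.3g (n=%d SNPs)\n",
              object@method, object@beta, object@se, object@p, object@nSnps))
  if (is.finite(object@intercept))
    cat(sprintf("  intercept=%.4f se=%.4f p=%.3g\n", object@intercept,
                object@interceptSe, object@interceptP))
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran's Q = %.3f on %g df, p = %.3g (phi = %.2f)\n",
              object@Q, object@df, object@pHet, object@phi))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("PressoResult: RSS=%.3f, global p=%.3g, %d outlier(s)\n",
              object@rssObs, object@pGlobal, length(object@outliers)))
  if (length(object@outliers)) {
    cat(sprintf("  outliers: %s\n", paste(object@outliers, collapse = ", ")))
    cat(sprintf("  beta pre=%.4f post=%.4f, distortion p=%.3g\n",
                object@betaPre, object@betaPost, object@pDistortion))
  }
})

setMethod("show", "VirtualStudy", function(object) {
  cat("VirtualStudy\n")
  cat(sprintf("  discovery: %d individuals, %d metabolites, phecode %s\n",
              ncol(object@discovery$panel), object@config@nMetabolites,
              object@discovery$phecode))
  cat(sprintf("  score models: %d; exposure GWAS tables: %d\n",
              length(object@scoreModels), length(object@exposureStats)))
  cat(sprintf("  outcome stats: %s; replication stats: %s\n",
              if (is.null(object@outcomeStats)) "deferred" else "ready",
              if (is.null(object@replicationStats)) "deferred" else "ready"))
})
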