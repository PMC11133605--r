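# Shared fixtures built in code.

# Summary-level two-sample instrument with known causal effect.  SE scales
# correspond to a metabolite GWAS and a binary-trait GWAS of ~50,000
# individuals; exposure effects span close to an order of magnitude, as
# metabolite QTLs do, keeping the exposure-effect dispersion well above
# its measurement error (high I2_GX, the regime MR-Egger assumes).
# `pleioFrac` SNPs receive direct outcome effects drawn from `pleioRange`;
# balanced pleiotropy draws symmetric signs, directional all positive.
simInstrument <- function(nSnps = 20, beta = 0.25, seed = 1,
                          sx = 0.007, sy = 0.023,
                          gammaRange = c(0.03, 0.25),
                          pleioFrac = 0, pleioRange = c(0.05, 0.15),
                          pleioMode = c("directional", "balanced"),
                          orientGamma = FALSE) {
  # orientGamma: orient every SNP to its exposure-increasing allele (the
  # convention under which directional outcome-side pleiotropy biases the
  # causal estimate in one direction; with random allele orientation the
  # ratio displacements alpha/gamma cancel in expectation)
  pleioMode <- match.arg(pleioMode)
  set.seed(seed)
  g <- runif(nSnps, gammaRange[1], gammaRange[2]) *
    (if (orientGamma) 1 else sample(c(-1, 1), nSnps, replace = TRUE))
  alpha <- rep(0, nSnps)
  nP <- round(pleioFrac * nSnps)
  if (nP > 0) {
    sgn <- if (pleioMode == "directional") rep(1, nP)
           else sample(c(-1, 1), nP, replace = TRUE)
    alpha[seq_len(nP)] <- sgn * runif(nP, pleioRange[1], pleioRange[2])
  }
  bx <- rnorm(nSnps, g, sx)
  by <- rnorm(nSnps, beta * g + alpha, sy)
  harmonizedInstrument(bx, rep(sx, nSnps), by, rep(sy, nSnps))
}

# Small discovery-style configuration for fast unit tests.
smallConfig <- function(...) {
  defaults <- list(n_discovery = 1500, n_exposure_gwas = 1500,
                   n_outcome_gwas = 1500, n_variants = 24, n_ld_blocks = 6,
                   n_metabolites = 3, snps_per_metabolite = 4,
                   seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulationConfig, args)
}

# Tiny dosage panel built directly from a matrix (variants x individuals).
tinyPanel <- function(dos, chrom = NULL, pos = NULL, ref = "A", alt = "G") {
  nV <- nrow(dos)
  vf <- data.frame(
    variant = sprintf("v%02d", seq_len(nV)),
    chrom = if (is.null(chrom)) rep("1", nV) else chrom,
    pos = if (is.null(pos)) seq_len(nV) * 1000L else pos,
    ref = rep_len(ref, nV), alt = rep_len(alt, nV),
    id = sprintf("v%02d", seq_len(nV)), stringsAsFactors = FALSE)
  colnames(dos) <- sprintf("i%03d", seq_len(ncol(dos)))
  virtmet:::.genotypePanel(dos, vf, colnames(dos))
}
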