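# Two-sample Mendelian randomization estimators and heterogeneity
# diagnostics, written from first principles on harmonized per-SNP effect
# pairs (gamma_j, sigma_Xj) for the exposure and (Gamma_j, sigma_Yj) for
# the outcome.
#
# Conventions: per-SNP Wald ratios beta_j = Gamma_j / gamma_j with
# first-order SE sigma_Yj / |gamma_j|; IVW weights w_j = gamma_j^2 /
# sigma_Yj^2; p-values are two-sided normal (large-sample GWAS
# convention, not t).

.mrEstimate <- function(method, beta, se, nSnps, intercept = NA_real_,
                        interceptSe = NA_real_, interceptP = NA_real_) {
  new("MREstimate", method = method, beta = beta, se = se,
      ci95 = beta + c(-1, 1) * 1.96 * se, p = .normP(beta / se),
      intercept = intercept, interceptSe = interceptSe,
      interceptP = interceptP, nSnps = as.integer(nSnps))
}

.instVectors <- function(inst) {
  s <- instrumentSnps(inst)
  list(bx = s$beta_exp, sx = s$se_exp, by = s$beta_out, sy = s$se_out,
       variant = s$variant)
}

#' Single-SNP Wald ratio
#'
#' `beta = Gamma / gamma` with first-order standard error
#' `sigma_Y / |gamma|`.
#'
#' @param beta_exp,se_exp,beta_out,se_out the SNP's aligned effects, or a
#'   single-row [HarmonizedInstrument-class] in `beta_exp`.
#' @return an [MREstimate-class].
#' @examples
#' waldRatio(0.1, 0.01, 0.2, 0.05)  # beta 2, se 0.5
#' @export
waldRatio <- function(beta_exp, se_exp = NULL, beta_out = NULL,
                      se_out = NULL) {
  if (is(beta_exp, "HarmonizedInstrument")) {
    v <- .instVectors(beta_exp)
    .assertThat(length(v$bx) == 1, "virtmet_instrument_error",
                "waldRatio needs a single SNP")
    beta_exp <- v$bx; se_exp <- v$sx; beta_out <- v$by; se_out <- v$sy
  }
  .assertThat(beta_exp != 0, "virtmet_instrument_error",
              "undefined Wald ratio: exposure effect is zero")
  .mrEstimate("wald", beta_out / beta_exp, se_out / abs(beta_exp), 1L)
}

.ivwCore <- function(bx, sy, by) {
  w <- bx^2 / sy^2
  ratio <- by / bx
  beta <- sum(w * ratio) / sum(w)
  seF <- 1 / sqrt(sum(w))
  Q <- sum(w * (ratio - beta)^2)
  list(w = w, ratio = ratio, beta = beta, seFixed = seF, Q = Q)
}

#' Inverse-variance weighted estimator with Cochran's Q
#'
#' Pools per-SNP Wald ratios with weights `w_j = gamma_j^2 / sigma_Yj^2`
#' (equivalent to weighted least squares of `Gamma` on `gamma` through the
#' origin).  The multiplicative random-effects model inflates the
#' fixed-effect SE by `max(1, sqrt(Q/(n-1)))`, so it can never fall below
#' the fixed-effect SE.  With a single SNP the estimate collapses to the
#' Wald ratio and Q is undefined (reported absent).
#'
#' @param inst a [HarmonizedInstrument-class].
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return list with `estimate` ([MREstimate-class]) and `heterogeneity`
#'   ([HeterogeneityResult-class]).
#' @examples
#' inst <- harmonizedInstrument(c(1, 1, 1), rep(0.01, 3),
#'                              c(0.1, 0.2, 0.3), rep(1, 3))
#' mrIvw(inst)$estimate  # beta 0.2, Q = 0.02
#' @export
mrIvw <- function(inst, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  v <- .instVectors(inst)
  n <- length(v$bx)
  .assertThat(n >= 1, "virtmet_instrument_error", "empty instrument")
  .assertThat(all(v$bx != 0), "virtmet_instrument_error",
              "zero exposure effect in instrument")
  if (model == "multiplicative_random")
    .assertThat(n >= 2, "virtmet_instrument_error",
                "random-effects IVW needs >= 2 SNPs")
  core <- .ivwCore(v$bx, v$sy, v$by)
  if (n == 1) {
    est <- .mrEstimate("ivw_fixed", core$beta, core$seFixed, 1L)
    het <- new("HeterogeneityResult", Q = NA_real_, df = 0,
               pHet = NA_real_, phi = NA_real_)
    return(list(estimate = est, heterogeneity = het))
  }
  df <- n - 1
  phi <- core$Q / df
  se <- if (model == "fixed") core$seFixed
        else core$seFixed * max(1, sqrt(phi))
  est <- .mrEstimate(if (model == "fixed") "ivw_fixed" else "ivw_re",
                     core$beta, se, n)
  het <- new("HeterogeneityResult", Q = core$Q, df = df,
             pHet = pchisq(core$Q, df, lower.tail = FALSE), phi = phi)
  list(estimate = est, heterogeneity = het)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with a free
#' intercept (weights `1 / sigma_Yj^2`), after orienting every SNP so the
#' exposure effect is non-negative (the InSIDE convention).  The slope is
#' the pleiotropy-corrected causal estimate; the intercept estimates
#' average directional pleiotropy.  Standard errors carry the
#' multiplicative overdispersion `max(1, sqrt(Q_Egger/(n-2)))`, where
#' `Q_Egger` is the weighted residual sum of squares.
#'
#' @param inst a [HarmonizedInstrument-class] with at least 3 SNPs.
#' @return list with `estimate` (slope plus intercept fields) and
#'   `heterogeneity` (Q on n-2 df).
#' @export
mrEgger <- function(inst) {
  v <- .instVectors(inst)
  n <- length(v$bx)
  .assertThat(n >= 3, "virtmet_instrument_error",
              "MR-Egger needs >= 3 SNPs")
  flip <- sign(v$bx)
  flip[flip == 0] <- 1
  bx <- v$bx * flip
  by <- v$by * flip
  w <- 1 / v$sy^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X * sqrt(w))
  XtWy <- crossprod(X, w * by)
  coefs <- solve(XtWX, XtWy)
  resid <- by - X %*% coefs
  Q <- sum(w * resid^2)
  df <- n - 2
  phi <- max(1, sqrt(Q / df))
  V <- solve(XtWX) * phi^2
  est <- .mrEstimate("egger", coefs[2], sqrt(V[2, 2]), n,
                     intercept = coefs[1], interceptSe = sqrt(V[1, 1]),
                     interceptP = .normP(coefs[1] / sqrt(V[1, 1])))
  het <- new("HeterogeneityResult", Q = Q, df = df,
             pHet = pchisq(Q, df, lower.tail = FALSE), phi = Q / df)
  list(estimate = est, heterogeneity = het)
}

# Cumulative-weight median of ordered ratios: with normalized weights w',
# plot cumulative weight minus w'/2 against the ordered ratios and read off
# the 0.5 crossing by linear interpolation.
.weightedMedian <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(b[1])
  if (0.5 >= cw[length(cw)]) return(b[length(b)])
  stats::approx(cw, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' The causal estimate at the 50% point of the cumulative IVW-weight
#' distribution over ordered Wald ratios (linear interpolation between the
#' bracketing ratios); consistent when at least half the weight comes from
#' valid instruments.  The SE is a parametric bootstrap: exposure and
#' outcome effects are resampled from normal distributions centred on the
#' observed values with their reported SEs, and the median recomputed.
#'
#' @param inst a [HarmonizedInstrument-class] with at least 3 SNPs.
#' @param n_boot bootstrap replicates (>= 1000 recommended for reported
#'   SEs; 0 skips the bootstrap and returns only the point estimate).
#' @param seed bootstrap RNG seed.
#' @return an [MREstimate-class].
#' @export
mrWeightedMedian <- function(inst, n_boot = 1000, seed = 1L) {
  v <- .instVectors(inst)
  n <- length(v$bx)
  .assertThat(n >= 3, "virtmet_instrument_error",
              "weighted median needs >= 3 SNPs")
  w <- v$bx^2 / v$sy^2
  beta <- .weightedMedian(v$by / v$bx, w)
  if (n_boot < 1) {
    return(new("MREstimate", method = "weighted_median", beta = beta,
               se = NA_real_, ci95 = c(NA_real_, NA_real_), p = NA_real_,
               intercept = NA_real_, interceptSe = NA_real_,
               interceptP = NA_real_, nSnps = as.integer(n)))
  }
  boots <- .withSeed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(n, v$bx, v$sx)
      by <- rnorm(n, v$by, v$sy)
      bx[bx == 0] <- .Machine$double.eps
      .weightedMedian(by / bx, bx^2 / v$sy^2)
    }, numeric(1))
  })
  .mrEstimate("weighted_median", beta, sd(boots), n)
}

#' Sign consistency across MR methods
#'
#' A set of estimates is consistent when every point estimate shares one
#' sign (a single estimate is vacuously consistent).
#'
#' @param estimates list of [MREstimate-class], or a numeric vector of
#'   betas.
#' @return `TRUE`/`FALSE`.
#' @export
methodConsistency <- function(estimates) {
  betas <- if (is.numeric(estimates)) estimates
           else vapply(estimates, function(e) e@beta, numeric(1))
  .assertThat(length(betas) >= 1, "virtmet_config_error", "no estimates")
  if (length(betas) == 1) return(TRUE)
  all(betas > 0) || all(betas < 0)
}

#' Run all applicable MR methods on one instrument
#'
#' IVW (random-effects) always; MR-Egger and the weighted median when the
#' instrument has at least 3 SNPs.
#'
#' @param inst a [HarmonizedInstrument-class].
#' @param n_boot weighted-median bootstrap size.
#' @param seed bootstrap seed.
#' @return list with `estimates` (named list of [MREstimate-class]),
#'   `heterogeneity` (IVW [HeterogeneityResult-class]) and `consistent`.
#' @export
mrAllMethods <- function(inst, n_boot = 1000, seed = 1L) {
  n <- nSnps(inst)
  ivw <- mrIvw(inst, model = if (n >= 2) "multiplicative_random" else "fixed")
  ests <- list(ivw = ivw$estimate)
  if (n >= 3) {
    ests$egger <- mrEgger(inst)$estimate
    ests$weighted_median <- mrWeightedMedian(inst, n_boot = n_boot,
                                             seed = seed)
  }
  list(estimates = ests, heterogeneity = ivw$heterogeneity,
       consistent = methodConsistency(ests))
}
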