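# MR-PRESSO: simulation-based pleiotropy residual sum and outlier test.
#
# The observed statistic is the leave-one-out weighted residual sum of
# squares RSS = sum_j (Gamma_j - beta_(-j) * gamma_j)^2 / sigma_Yj^2,
# where beta_(-j) is the IVW estimate with SNP j excluded.  The null
# distribution is built by simulating Gamma*_j ~ N(beta_(-j) gamma_j,
# sigma_Yj) and gamma*_j ~ N(gamma_j, sigma_Xj) and recomputing the same
# leave-one-out RSS on the simulated effects.  Monte-Carlo p-values use
# the (1 + k) / (1 + n_sim) estimator so they are never zero.

# Leave-one-out IVW slopes and weighted residuals for a matrix of
# simulated (or observed) effect pairs.  BX, BY: nSim x n matrices.
.looResiduals <- function(BX, BY, sy) {
  W <- sweep(BX^2, 2L, sy^2, "/")
  WB <- sweep(BX * BY, 2L, sy^2, "/")  # w_j * ratio_j, avoids 0/0
  sw <- rowSums(W)
  swb <- rowSums(WB)
  bLoo <- (swb - WB) / (sw - W)
  sweep((BY - bLoo * BX)^2, 2L, sy^2, "/")
}

.pressoCore <- function(inst, n_sim, seed) {
  v <- .instVectors(inst)
  n <- length(v$bx)
  .assertThat(n >= 4, "virtmet_instrument_error",
              "MR-PRESSO needs >= 4 SNPs (leave-one-out)")
  .assertThat(n_sim >= 1000, "virtmet_config_error",
              "n_sim must be >= 1000")
  obsRes <- .looResiduals(matrix(v$bx, 1), matrix(v$by, 1), v$sy)[1, ]
  # expected outcome effects under the null use the observed-data
  # leave-one-out slopes
  W <- v$bx^2 / v$sy^2
  bLoo <- (sum(W * (v$by / v$bx)) - W * (v$by / v$bx)) / (sum(W) - W)
  sims <- .withSeed(seed, {
    BXs <- matrix(rnorm(n_sim * n, mean = rep(v$bx, each = n_sim),
                        sd = rep(v$sx, each = n_sim)), n_sim, n)
    BYs <- matrix(rnorm(n_sim * n, mean = rep(bLoo * v$bx, each = n_sim),
                        sd = rep(v$sy, each = n_sim)), n_sim, n)
    .looResiduals(BXs, BYs, v$sy)
  })
  list(v = v, n = n, obsRes = obsRes, rssObs = sum(obsRes), simRes = sims)
}

#' MR-PRESSO global pleiotropy test
#'
#' @param inst a [HarmonizedInstrument-class] with at least 4 SNPs.
#' @param n_sim Monte-Carlo simulations (>= 1000; default 5000).
#' @param seed RNG seed; a fixed seed gives identical p-values on reruns.
#' @return list with `rss_obs` and `p_global`.
#' @seealso [runPresso()] for the full global/outlier/distortion chain.
#' @export
pressoGlobal <- function(inst, n_sim = 5000, seed = 1L) {
  core <- .pressoCore(inst, n_sim, seed)
  rssSim <- rowSums(core$simRes)
  list(rss_obs = core$rssObs,
       p_global = (1 + sum(rssSim >= core$rssObs)) / (1 + n_sim))
}

#' MR-PRESSO per-SNP outlier test
#'
#' Each SNP's observed squared residual is compared with its simulated
#' null residual distribution; the Monte-Carlo p-value is Bonferroni
#' multiplied by the number of SNPs (capped at 1) before the
#' `outlier_alpha` cut.
#'
#' @inheritParams pressoGlobal
#' @param outlier_alpha adjusted-p threshold flagging outliers (0.05).
#' @return list with `outlier_p` (named, adjusted) and `outliers`.
#' @export
pressoOutlier <- function(inst, n_sim = 5000, seed = 1L,
                          outlier_alpha = 0.05) {
  core <- .pressoCore(inst, n_sim, seed)
  pRaw <- (1 + colSums(core$simRes >=
                         matrix(core$obsRes, n_sim, core$n,
                                byrow = TRUE))) / (1 + n_sim)
  pAdj <- setNames(pmin(1, pRaw * core$n), core$v$variant)
  list(outlier_p = pAdj, outliers = names(pAdj)[pAdj < outlier_alpha])
}

#' MR-PRESSO distortion test
#'
#' Compares the IVW estimate before and after removing the flagged
#' outliers: the observed distortion is `D = (beta_pre - beta_post) /
#' |beta_post|`, referenced to the distortions obtained by removing
#' `n_sim` random non-outlier subsets of the same size instead.  The
#' p-value is the two-sided empirical tail probability with the +1
#' correction.
#'
#' @inheritParams pressoGlobal
#' @param outliers character vector of flagged variants (nonempty).
#' @return list with `beta_pre`, `beta_post`, `distortion`,
#'   `p_distortion`.
#' @export
pressoDistortion <- function(inst, outliers, n_sim = 5000, seed = 1L) {
  v <- .instVectors(inst)
  .assertThat(length(outliers) > 0, "virtmet_config_error",
              "distortion test needs a nonempty outlier set")
  keep <- !(v$variant %in% outliers)
  .assertThat(any(keep), "virtmet_instrument_error",
              "all SNPs flagged as outliers; distortion undefined")
  ivwBeta <- function(sel) {
    w <- v$bx[sel]^2 / v$sy[sel]^2
    sum(w * v$by[sel] / v$bx[sel]) / sum(w)
  }
  betaPre <- ivwBeta(rep(TRUE, length(v$bx)))
  betaPost <- ivwBeta(keep)
  D <- (betaPre - betaPost) / abs(betaPost)
  nonOut <- which(keep)
  k <- sum(!keep)
  .assertThat(length(nonOut) > k, "virtmet_instrument_error",
              "too few non-outlier SNPs for the distortion null")
  Dnull <- .withSeed(.deriveSeed(seed, 1L), {
    vapply(seq_len(n_sim), function(b) {
      drop <- sample(nonOut, k)
      sel <- setdiff(seq_along(v$bx), drop)
      bAlt <- ivwBeta(sel)
      (betaPre - bAlt) / abs(bAlt)
    }, numeric(1))
  })
  list(beta_pre = betaPre, beta_post = betaPost, distortion = D,
       p_distortion = (1 + sum(abs(Dnull) >= abs(D))) / (1 + n_sim))
}

#' Run the full MR-PRESSO workflow
#'
#' Global test, outlier test (on the same simulated null, same seed) and,
#' when outliers are flagged, the distortion test.  `beta_post` equals the
#' IVW estimate on the outlier-free instrument exactly.
#'
#' @inheritParams pressoGlobal
#' @param outlier_alpha adjusted-p threshold for the outlier test.
#' @return a [PressoResult-class].
#' @export
runPresso <- function(inst, n_sim = 5000, seed = 1L, outlier_alpha = 0.05) {
  core <- .pressoCore(inst, n_sim, seed)
  rssSim <- rowSums(core$simRes)
  pGlobal <- (1 + sum(rssSim >= core$rssObs)) / (1 + n_sim)
  pRaw <- (1 + colSums(core$simRes >=
                         matrix(core$obsRes, n_sim, core$n,
                                byrow = TRUE))) / (1 + n_sim)
  pAdj <- setNames(pmin(1, pRaw * core$n), core$v$variant)
  outliers <- names(pAdj)[pAdj < outlier_alpha]
  w <- core$v$bx^2 / core$v$sy^2
  ratio <- core$v$by / core$v$bx
  betaPre <- sum(w * ratio) / sum(w)
  betaPost <- NA_real_
  pDist <- NA_real_
  k <- length(outliers)
  if (k > 0 && k < core$n) {
    keep <- !(core$v$variant %in% outliers)
    betaPost <- sum(w[keep] * ratio[keep]) / sum(w[keep])
    # the distortion null needs more clean SNPs than outliers removed
    if (core$n - k > k) {
      dist <- pressoDistortion(inst, outliers, n_sim = n_sim, seed = seed)
      pDist <- dist$p_distortion
    }
  }
  new("PressoResult", rssObs = core$rssObs, pGlobal = pGlobal,
      outlierP = pAdj, outliers = outliers, betaPre = betaPre,
      betaPost = betaPost, pDistortion = pDist, nSim = as.integer(n_sim),
      seed = as.integer(seed))
}
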