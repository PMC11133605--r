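# Independent reference implementations used as oracles.  These stay
# deliberately naive (loops, lm(), textbook formulas) and never share code
# with the package internals they check.

# Weighted least squares of by on bx through the origin via lm();
# multiplicative random-effects SE floored at the fixed-effect SE.
wlsIvwOracle <- function(bx, sy, by) {
  w <- bx^2 / sy^2
  fit <- lm(I(by / bx) ~ 1, weights = w)
  beta <- unname(coef(fit)[1])
  seFixed <- 1 / sqrt(sum(w))
  Q <- sum(w * (by / bx - beta)^2)
  n <- length(bx)
  list(beta = beta, seFixed = seFixed, Q = Q,
       seRandom = seFixed * max(1, sqrt(Q / (n - 1))))
}

# Weighted regression with intercept via lm() on SNPs oriented to
# non-negative exposure effects; SEs carry max(1, sqrt(Q/(n-2))).
wlsEggerOracle <- function(bx, sy, by) {
  flip <- ifelse(bx < 0, -1, 1)
  bx <- bx * flip
  by <- by * flip
  w <- 1 / sy^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  Q <- sum(w * residuals(fit)^2)
  n <- length(bx)
  scale <- max(1, sqrt(Q / (n - 2))) / sm$sigma
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       interceptSe = sm$coefficients[1, 2] * scale,
       slopeSe = sm$coefficients[2, 2] * scale, Q = Q)
}

# Brute-force cumulative-weight scan for the weighted median.
weightedMedianOracle <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  cum <- 0
  pPrev <- NA_real_
  bPrev <- NA_real_
  for (j in seq_along(b)) {
    pj <- cum + w[j] / 2
    if (pj >= 0.5) {
      if (j == 1 || pj == 0.5) {
        if (pj == 0.5) return(b[j])
        return(b[1])
      }
      return(bPrev + (b[j] - bPrev) * (0.5 - pPrev) / (pj - pPrev))
    }
    cum <- cum + w[j]
    pPrev <- pj
    bPrev <- b[j]
  }
  b[length(b)]
}

# Exhaustive reference of the greedy clumping rule: repeatedly pick the
# remaining SNP with the smallest p (ties by chrom, pos), retain it, and
# scan every remaining SNP for removal.
clumpOracle <- function(df, r2, r2Threshold, windowKb) {
  remaining <- seq_len(nrow(df))
  retained <- integer(0)
  while (length(remaining)) {
    best <- remaining[1]
    for (i in remaining) {
      if (df$p[i] < df$p[best] ||
          (df$p[i] == df$p[best] &&
           (df$chrom[i] < df$chrom[best] ||
            (df$chrom[i] == df$chrom[best] && df$pos[i] < df$pos[best]))))
        best <- i
    }
    retained <- c(retained, best)
    remaining <- setdiff(remaining, best)
    for (i in remaining) {
      sameChrom <- df$chrom[i] == df$chrom[best]
      close <- abs(df$pos[i] - df$pos[best]) <= windowKb * 1000
      rr <- r2[df$variant[best], df$variant[i]]
      if (sameChrom && close && !is.na(rr) && rr >= r2Threshold)
        remaining <- setdiff(remaining, i)
    }
  }
  sort(df$variant[retained])
}

# Textbook Benjamini-Hochberg step-up.
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    i <- ord[k]
    val <- min(prev, p[i] * m / k)
    adj[i] <- val
    prev <- val
  }
  adj
}

# Hand-rolled IRLS (Fisher scoring) for logistic regression.
irlsOracle <- function(X, y, maxit = 50, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    XtWX <- crossprod(X * sqrt(W))
    betaNew <- solve(XtWX, crossprod(X, W * z))
    if (max(abs(betaNew - beta)) < tol) {
      beta <- betaNew
      break
    }
    beta <- betaNew
  }
  eta <- as.numeric(X %*% beta)
  mu <- plogis(eta)
  V <- solve(crossprod(X * sqrt(mu * (1 - mu))))
  list(coef = as.numeric(beta), se = unname(sqrt(diag(V))))
}
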