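# Internal helpers shared across modules.

# Derive a child RNG seed from a base seed and a stream index.  Kept below
# 2^31 - 1 so it is always a valid integer seed.
.deriveSeed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) %% 2147483647) * 1103 + 7919 * as.numeric(k)
  as.integer(s %% 2147483629)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream (the global .Random.seed is restored on exit).
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

.complementAllele <- function(x) chartr("ACGT", "TGCA", toupper(x))

.isPalindromic <- function(a1, a2) .complementAllele(a1) == a2

# Two-sided p-value from a z statistic (large-sample GWAS convention).
.normP <- function(z) 2 * pnorm(-abs(z))

.virtmetStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "virtmet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

.assertThat <- function(ok, class, msg, ...) {
  if (!ok) .virtmetStop(class, msg, ...)
  invisible(TRUE)
}
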