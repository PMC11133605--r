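# Instrument construction: selection, clumping, harmonization.

sumstatRow <- function(variant, chrom, pos, ea, oa, beta, se, eaf = 0.3,
                       n = 5000L) {
  data.frame(variant = variant, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)), n = n,
             stringsAsFactors = FALSE)
}

test_that("candidate selection is a strict p-value cut preserving order", {
  s <- sumstatRow(c("a", "b", "c"), "1", c(1L, 2L, 3L), "A", "G",
                  beta = c(0.6, 0.4, 0.2), se = 0.1)
  s$p <- c(1e-7, 1e-5, 1e-3)
  expect_equal(selectCandidates(s, 5e-6)$variant, "a")
  expect_equal(nrow(selectCandidates(s, 1e-9)), 0)
  expect_equal(selectCandidates(s, 1.0)$variant, c("a", "b", "c"))
})

test_that("greedy clumping follows the p-order / window / r2 rule", {
  s <- sumstatRow(c("a", "b", "c"), c("1", "1", "2"),
                  c(1000000L, 1010000L, 1000000L), "A", "G",
                  beta = c(0.6, 0.5, 0.4), se = 0.1)
  s$p <- c(1e-8, 1e-7, 1e-7)
  r2 <- matrix(0, 3, 3, dimnames = list(s$variant, s$variant))
  diag(r2) <- 1
  r2["a", "b"] <- r2["b", "a"] <- 0.9
  out <- ldClump(s, r2, r2_threshold = 0.05, window_kb = 1000)
  # b is 10 kb from index a with r2 0.9 -> removed; c on another chromosome
  expect_setequal(out$variant, c("a", "c"))
  log <- attr(out, "clumpLog")
  expect_equal(log$variant, "b")
  expect_equal(log$index_snp, "a")
  # outside the window nothing is clumped
  s2 <- s
  s2$pos[2] <- s$pos[1] + 1000 * 1000 + 1
  expect_setequal(ldClump(s2, r2)$variant, c("a", "b", "c"))
  # inclusive at exactly window_kb
  s3 <- s
  s3$pos[2] <- s$pos[1] + 1000 * 1000
  expect_setequal(ldClump(s3, r2)$variant, c("a", "c"))
})

test_that("clumping is invariant to input row order and r2 constraint holds post hoc", {
  cfg <- smallConfig(n_discovery = 2000, within_block_r = 0.6,
                     n_variants = 30, n_ld_blocks = 5, seed = 301L)
  panel <- simulateGenotypes(cfg)
  vf <- variantInfo(panel)
  set.seed(31)
  cand <- sumstatRow(vf$variant, vf$chrom, vf$pos, vf$alt, vf$ref,
                     beta = rnorm(30, 0, 0.3), se = 0.05)
  out1 <- ldClump(cand, panel)
  perm <- sample(nrow(cand))
  out2 <- ldClump(cand[perm, ], panel)
  expect_setequal(out1$variant, out2$variant)
  # retained pairwise r2 below threshold within the window
  d <- dosages(panel)[out1$variant, ]
  r2 <- cor(t(d))^2
  keep <- out1
  for (i in seq_len(nrow(keep) - 1)) {
    for (j in (i + 1):nrow(keep)) {
      if (keep$chrom[i] == keep$chrom[j] &&
          abs(keep$pos[i] - keep$pos[j]) <= 1000 * 1000)
        expect_lt(r2[i, j], 0.05)
    }
  }
})

test_that("clumping matches the exhaustive greedy reference on random instances", {
  set.seed(32)
  for (rep in 1:40) {
    n <- 10
    chrom <- as.character(sample(1:2, n, replace = TRUE))
    pos <- sample.int(3000000L, n)
    df <- sumstatRow(sprintf("s%02d", 1:n), chrom, pos, "A", "G",
                     beta = rnorm(n, 0, 0.3), se = 0.05)
    r2 <- matrix(runif(n * n), n, n, dimnames = list(df$variant, df$variant))
    r2 <- (r2 + t(r2)) / 2
    diag(r2) <- 1
    got <- sort(ldClump(df, r2, 0.3, 500)$variant)
    expect_equal(got, clumpOracle(df, r2, 0.3, 500))
  }
})

test_that("missing-LD candidates follow the configured policy", {
  s <- sumstatRow(c("a", "zz"), "1", c(1000L, 2000L), "A", "G",
                  beta = c(0.6, 0.5), se = 0.1)
  r2 <- matrix(1, 1, 1, dimnames = list("a", "a"))
  keep <- ldClump(s, r2, missing_policy = "assume_independent")
  expect_setequal(keep$variant, c("a", "zz"))
  drop <- ldClump(s, r2, missing_policy = "drop")
  expect_equal(drop$variant, "a")
  expect_true("dropped_no_ld" %in% attr(drop, "clumpLog")$action)
})

test_that("harmonization aligns, flips, complements and drops correctly", {
  expo <- sumstatRow("rs1", "1", 100L, "A", "G", beta = 0.1, se = 0.02,
                     eaf = 0.3)
  # same alleles, swapped effect allele: sign flip
  out <- sumstatRow("rs1", "1", 100L, "G", "A", beta = -0.2, se = 0.05,
                    eaf = 0.7)
  inst <- harmonizeInstruments(expo, out, "m", "p")
  expect_equal(instrumentSnps(inst)$beta_out, 0.2)
  expect_equal(instrumentSnps(inst)$eaf_out, 0.3)
  expect_true("flipped" %in% provenance(inst)$action)
  # allele mismatch: dropped (and with nothing left, an instrument error)
  out2 <- sumstatRow("rs1", "1", 100L, "A", "C", beta = 0.2, se = 0.05)
  expect_error(harmonizeInstruments(expo, out2, "m", "p"),
               class = "virtmet_instrument_error")
  # strand complement: exposure A/G vs outcome T/C with effect allele T
  out3 <- sumstatRow("rs1", "1", 100L, "T", "C", beta = 0.15, se = 0.05,
                     eaf = 0.3)
  inst3 <- harmonizeInstruments(expo, out3, "m", "p")
  expect_equal(instrumentSnps(inst3)$beta_out, 0.15)
  expect_equal(provenance(inst3)$detail, "strand complement")
})

test_that("palindromic SNPs are frequency-aligned or dropped", {
  expoAT <- sumstatRow("rs2", "1", 200L, "A", "T", beta = 0.1, se = 0.02,
                       eaf = 0.50)
  outAT <- sumstatRow("rs2", "1", 200L, "A", "T", beta = 0.2, se = 0.05,
                      eaf = 0.50)
  # frequency-ambiguous (maf > 0.42): dropped under the default policy
  expect_error(harmonizeInstruments(expoAT, outAT, "m", "p"),
               class = "virtmet_instrument_error")
  # clear frequencies on the same side: copied
  expoAT$eaf <- 0.2
  outAT$eaf <- 0.21
  inst <- harmonizeInstruments(expoAT, outAT, "m", "p")
  expect_equal(instrumentSnps(inst)$beta_out, 0.2)
  # opposite sides: flipped
  outAT$eaf <- 0.8
  inst2 <- harmonizeInstruments(expoAT, outAT, "m", "p")
  expect_equal(instrumentSnps(inst2)$beta_out, -0.2)
  # policy "drop" removes all palindromic SNPs
  expect_error(harmonizeInstruments(expoAT, outAT, "m", "p",
                                    palindromic_policy = "drop"),
               class = "virtmet_instrument_error")
})

test_that("harmonization is involution-safe", {
  expo <- rbind(
    sumstatRow("rs1", "1", 100L, "A", "G", beta = 0.10, se = 0.02,
               eaf = 0.30),
    sumstatRow("rs3", "2", 500L, "C", "T", beta = -0.07, se = 0.02,
               eaf = 0.45))
  out <- rbind(
    sumstatRow("rs1", "1", 100L, "G", "A", beta = -0.20, se = 0.05,
               eaf = 0.70),
    sumstatRow("rs3", "2", 500L, "C", "T", beta = 0.12, se = 0.04,
               eaf = 0.45))
  once <- harmonizeInstruments(expo, out, "m", "p")
  s <- instrumentSnps(once)
  outAligned <- data.frame(
    variant = s$variant, chrom = s$chrom, pos = s$pos,
    effect_allele = s$effect_allele, other_allele = s$other_allele,
    eaf = s$eaf_out, beta = s$beta_out, se = s$se_out,
    p = 2 * pnorm(-abs(s$beta_out / s$se_out)), n = 5000L,
    stringsAsFactors = FALSE)
  twice <- harmonizeInstruments(expo, outAligned, "m", "p")
  expect_equal(instrumentSnps(twice)$beta_out, s$beta_out)
  expect_equal(instrumentSnps(twice)$eaf_out, s$eaf_out)
})
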