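# Synthetic-data generator: genotypes, metabolites, phenotype, summary
# statistics, and the determinism / two-sample contracts.

test_that("genotype simulation hits target frequencies and independence", {
  cfg <- smallConfig(n_discovery = 5000, within_block_r = 0,
                     maf_range = c(0.5, 0.5), seed = 101L)
  panel <- simulateGenotypes(cfg)
  d <- dosages(panel)
  expect_true(all(d %in% 0:2))
  eaf <- rowMeans(d) / 2
  expect_true(all(eaf >= 0.45 & eaf <= 0.55))
  # independence case: mean absolute pairwise genotype correlation small
  cc <- cor(t(d))
  offDiag <- abs(cc[upper.tri(cc)])
  expect_lt(mean(offDiag), 0.05)
})

test_that("genotype EAF tracks the drawn MAF within 0.05 at n = 2000", {
  cfg <- smallConfig(n_discovery = 2000, maf_range = c(0.1, 0.4),
                     seed = 102L)
  panel <- simulateGenotypes(cfg)
  target <- virtmet:::.variantFrame(cfg)$maf
  realized <- rowMeans(dosages(panel)) / 2
  expect_true(all(abs(realized - target) <= 0.05))
})

test_that("LD blocks carry positive within-block correlation", {
  cfg <- smallConfig(n_discovery = 4000, within_block_r = 0.5,
                     n_variants = 12, n_ld_blocks = 3, seed = 103L)
  panel <- simulateGenotypes(cfg)
  d <- dosages(panel)
  block <- SummarizedExperiment::rowData(panel)$block
  adj <- c()
  for (b in unique(block)) {
    idx <- which(block == b)
    for (i in seq_len(length(idx) - 1))
      adj <- c(adj, cor(d[idx[i], ], d[idx[i + 1], ]))
  }
  expect_gt(mean(adj), 0.35)
  expect_lt(mean(adj), 0.65)
  # different blocks stay independent
  cross <- cor(d[1, ], d[nrow(d), ])
  expect_lt(abs(cross), 0.08)
})

test_that("fixed seed gives byte-identical panels; cohorts are disjoint", {
  cfg <- smallConfig(seed = 104L)
  p1 <- simulateGenotypes(cfg)
  p2 <- simulateGenotypes(cfg)
  expect_identical(dosages(p1), dosages(p2))
  ids <- lapply(c("discovery", "exposure", "outcome", "replication"),
                function(coh) individualIds(simulateGenotypes(cfg, coh,
                                                              n = 50)))
  for (i in 1:3)
    for (j in (i + 1):4)
      expect_length(intersect(ids[[i]], ids[[j]]), 0)
})

test_that("configuration errors are raised for invalid settings", {
  expect_error(simulationConfig(n_discovery = 0), class = "virtmet_config_error")
  expect_error(simulationConfig(h2_metabolite = 1.2), class = "virtmet_config_error")
  expect_error(simulationConfig(prevalence = 0), class = "virtmet_config_error")
  expect_error(simulationConfig(maf_range = c(0.4, 0.1)),
               class = "virtmet_config_error")
  expect_error(simulationConfig(n_variants = 4, snps_per_metabolite = 9),
               class = "virtmet_config_error")
})

test_that("metabolite heritability is realized within tolerance", {
  cfg <- smallConfig(n_discovery = 5000, h2_metabolite = 0.9,
                     snps_per_metabolite = 1, n_metabolites = 2,
                     seed = 105L)
  panel <- simulateGenotypes(cfg)
  met <- simulateMetabolites(panel, cfg)
  w <- met$truth@metaboliteWeights
  w1 <- w[w$metabolite == "met01", ]
  r2 <- cor(dosages(panel)[w1$variant, ], met$values[, "met01"])^2
  expect_gte(r2, 0.85)
  expect_lte(r2, 0.95)
  expect_equal(mean(met$values[, "met01"]), 0, tolerance = 1e-12)
  expect_equal(sd(met$values[, "met01"]), 1, tolerance = 1e-12)

  # h2 = 0: metabolite uncorrelated with every causal dosage
  cfg0 <- smallConfig(n_discovery = 5000, h2_metabolite = 0, seed = 106L)
  panel0 <- simulateGenotypes(cfg0)
  met0 <- simulateMetabolites(panel0, cfg0)
  w0 <- met0$truth@metaboliteWeights
  for (v in w0$variant[w0$metabolite == "met01"])
    expect_lt(abs(cor(dosages(panel0)[v, ], met0$values[, "met01"])), 0.05)
})

test_that("OLS on the true causal dosages recovers the generating effects", {
  cfg <- smallConfig(n_discovery = 5000, h2_metabolite = 0.4, seed = 107L)
  panel <- simulateGenotypes(cfg)
  met <- simulateMetabolites(panel, cfg)
  w <- met$truth@metaboliteWeights
  w1 <- w[w$metabolite == "met02", ]
  X <- t(dosages(panel)[w1$variant, ])
  fit <- summary(lm(met$values[, "met02"] ~ X))
  est <- fit$coefficients[-1, 1]
  se <- fit$coefficients[-1, 2]
  expect_true(all(abs(est - w1$effect) <= 3 * se))
})

test_that("phenotype generator calibrates prevalence and emits >=2 rows per case", {
  cfg <- smallConfig(n_discovery = 5000, causal_effect = 0,
                     prevalence = 0.5, seed = 108L)
  panel <- simulateGenotypes(cfg)
  met <- simulateMetabolites(panel, cfg)
  phe <- simulatePhenotype(panel, met$values[, 1], met$truth, cfg,
                           age_effect = 0, sex_effect = 0)
  expect_gte(mean(phe$labels), 0.48)
  expect_lte(mean(phe$labels), 0.52)
  cases <- names(phe$labels)[phe$labels == 1]
  perCase <- table(phe$events$individual_id[
    phe$events$individual_id %in% cases])
  expect_true(all(perCase >= 2))
  expect_setequal(names(perCase), cases)
  # controls never reach two instances
  ctrlRows <- phe$events[!phe$events$individual_id %in% cases, ]
  if (nrow(ctrlRows))
    expect_true(all(table(ctrlRows$individual_id) < 2))
  expect_error(
    simulatePhenotype(panel, met$values[1:10, 1], met$truth, cfg),
    class = "virtmet_config_error")
  # stratification stress switch ties PC1 to mean dosage
  pheC <- simulatePhenotype(panel, met$values[, 1], met$truth, cfg,
                            pc_confounding = 0.5)
  gmean <- colMeans(dosages(panel))
  expect_gt(cor(pheC$covariates$pc1, gmean)^2, 0.3)
  expect_lt(cor(phe$covariates$pc1, gmean)^2, 0.01)
})

test_that("null-metabolite association p-values are uniform", {
  cfg <- smallConfig(n_discovery = 800, causal_effect = 0,
                     prevalence = 0.3, seed = 109L)
  panel <- simulateGenotypes(cfg)
  met <- simulateMetabolites(panel, cfg)
  pvals <- vapply(1:200, function(i) {
    phe <- simulatePhenotype(panel, met$values[, 1], met$truth, cfg,
                             seed = 5000L + i)
    sub <- phe$covariates
    fitLogistic(unname(phe$labels), met$values[, 1],
                sub[, c("age", "sex")])$p
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("summary statistics: null bound, SE scaling with n, determinism", {
  cfg <- smallConfig(n_discovery = 100, n_exposure_gwas = 2000,
                     n_variants = 1000, n_ld_blocks = 1000,
                     within_block_r = 0, h2_metabolite = 0,
                     n_metabolites = 1, seed = 110L)
  panel <- simulateGenotypes(cfg, "discovery", n = 100)
  met <- simulateMetabolites(panel, cfg)
  s1 <- simulateSummaryStats(cfg, met$truth, "met01")
  expect_identical(s1, simulateSummaryStats(cfg, met$truth, "met01"))
  # all variants are null for this trait: normal-theory 4-SE bound
  expect_gte(mean(abs(s1$beta) < 4 * s1$se), 0.99)
  validateSummaryStats(s1)
  # doubling n shrinks the median SE by ~1/sqrt(2)
  cfg2 <- smallConfig(n_discovery = 100, n_exposure_gwas = 4000,
                      n_variants = 1000, n_ld_blocks = 1000,
                      within_block_r = 0, h2_metabolite = 0,
                      n_metabolites = 1, seed = 110L)
  s2 <- simulateSummaryStats(cfg2, met$truth, "met01")
  ratio <- median(s2$se) / median(s1$se)
  expect_gt(ratio, 1 / sqrt(2) * 0.9)
  expect_lt(ratio, 1 / sqrt(2) * 1.1)
})

test_that("exposure and outcome tables never share individuals and betas track truth", {
  cfg <- smallConfig(n_exposure_gwas = 3000, h2_metabolite = 0.4,
                     within_block_r = 0, seed = 111L)
  panel <- simulateGenotypes(cfg)
  met <- simulateMetabolites(panel, cfg)
  s <- simulateSummaryStats(cfg, met$truth, "met01")
  w <- met$truth@metaboliteWeights
  w1 <- w[w$metabolite == "met01", ]
  # with independent variants the marginal beta at a causal SNP estimates
  # the generating effect
  rows <- s[match(w1$variant, s$variant), ]
  expect_true(all(abs(rows$beta - w1$effect) <= 4 * rows$se))
  expect_true(all(c("effect_allele", "other_allele", "eaf") %in%
                    colnames(s)))
})
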