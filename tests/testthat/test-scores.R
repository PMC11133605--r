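# PGS engine, case/control assembly, logistic fits, PheWAS and the
# per-SNP outcome GWAS.

makeModel <- function(panel, weights, effect = NULL) {
  vf <- variantInfo(panel)
  n <- length(weights)
  new("ScoreModel", metaboliteId = "m",
      entries = data.frame(
        variant = vf$variant[seq_len(n)], chrom = vf$chrom[seq_len(n)],
        pos = vf$pos[seq_len(n)], ref = vf$ref[seq_len(n)],
        alt = vf$alt[seq_len(n)],
        effect_allele = if (is.null(effect)) vf$alt[seq_len(n)] else effect,
        weight = weights, stringsAsFactors = FALSE),
      sourcePThreshold = 5e-8)
}

test_that("raw PGS is the weighted effect-allele dosage sum", {
  dos <- matrix(c(0, 1, 2), nrow = 3, ncol = 1)
  panel <- tinyPanel(dos)
  model <- makeModel(panel, c(0.5, 1.0, -0.2))
  pv <- computePgs(panel, model, standardize = FALSE)
  expect_equal(unname(pgsValues(pv)), 0 * 0.5 + 1 * 1.0 + 2 * (-0.2))
  # effect allele = ref counts 2 - alt dosage
  model2 <- makeModel(panel, c(0.5, 1.0, -0.2),
                      effect = variantInfo(panel)$ref[1:3])
  pv2 <- computePgs(panel, model2, standardize = FALSE)
  expect_equal(unname(pgsValues(pv2)),
               2 * 0.5 + 1 * 1.0 + 0 * (-0.2))
  # all-zero weights: constant score, standardization error reported
  expect_error(computePgs(panel, makeModel(panel, c(0, 0, 0))),
               class = "virtmet_degenerate_score")
  # no overlapping variants
  far <- makeModel(panel, 1)
  far@entries$pos <- 999999L
  expect_error(computePgs(panel, far), class = "virtmet_instrument_error")
})

test_that("missing dosages follow the mean-impute / drop-variant policies", {
  dos <- matrix(c(0, 1, NA, 2,
                  1, 1, 1, 1), nrow = 2, byrow = TRUE)
  panel <- tinyPanel(dos)
  model <- makeModel(panel, c(1, 1))
  pv <- computePgs(panel, model, "mean_impute", standardize = FALSE)
  # panel EAF of variant 1 excludes the NA: (0+1+2)/6 = 0.5, impute 2*EAF
  expect_equal(unname(pgsValues(pv)[3]), 2 * 0.5 + 1)
  expect_equal(pv@nMissingHandled, 1L)
  pv2 <- computePgs(panel, model, "drop_variant", standardize = FALSE)
  expect_equal(unname(pgsValues(pv2)), c(1, 1, 1, 1))
  expect_equal(pv2@nVariantsUsed, 1L)
})

test_that("effect-allele relabeling shifts raw scores by a constant and leaves association invariant", {
  set.seed(42)
  dos <- matrix(rbinom(5 * 400, 2, 0.3), nrow = 5)
  panel <- tinyPanel(dos)
  w <- c(0.5, -0.3, 0.2, 0.1, -0.4)
  model <- makeModel(panel, w)
  flipped <- model
  flipped@entries$effect_allele[2] <- flipped@entries$ref[2]
  flipped@entries$weight[2] <- -flipped@entries$weight[2]
  raw1 <- pgsValues(computePgs(panel, model, standardize = FALSE))
  raw2 <- pgsValues(computePgs(panel, flipped, standardize = FALSE))
  expect_equal(unname(raw2 - raw1), rep(-2 * w[2], 400), tolerance = 1e-12)
  y <- rbinom(400, 1, plogis(-0.5 + scale(raw1)[, 1] * 0.4))
  b1 <- fitLogistic(y, pgsValues(computePgs(panel, model)))$beta
  b2 <- fitLogistic(y, pgsValues(computePgs(panel, flipped)))$beta
  expect_lt(abs(b1 - b2), 1e-10)
})

test_that("PGS matches variants across strand complement", {
  dos <- matrix(c(0, 1, 2, 1), nrow = 1)
  panel <- tinyPanel(dos, ref = "A", alt = "G")
  model <- makeModel(panel, 1)
  model@entries$ref <- "T"
  model@entries$alt <- "C"
  model@entries$effect_allele <- "C"  # complement of panel alt G
  pv <- computePgs(panel, model, standardize = FALSE)
  expect_equal(unname(pgsValues(pv)), c(0, 1, 2, 1))
})

test_that("case/control assembly applies the instance, exclusion and age rules", {
  covariates <- data.frame(
    individual_id = sprintf("p%d", 1:8),
    age = c(50, 60, 55, 58, 20, 57, 52, 70))
  events <- data.frame(
    individual_id = c("p1", "p1", "p2", "p2", "p2", "p3", "p6", "p8"),
    phecode = c("250.2", "250.2", "250.2", "250.2", "250.2", "250.2",
                "250.1", "250.2"),
    count = 1L)
  map <- data.frame(phecode = "250.2", low = 249.0, high = 251.99)
  cc <- assembleCaseControl(events, "250.2", map, covariates,
                            min_cases = 2, min_instances = 2)
  expect_setequal(cc@caseIds, c("p1", "p2"))      # >= 2 instances
  expect_true("p3" %in% cc@excludedIds)           # 1 instance: in range
  expect_true("p6" %in% cc@excludedIds)           # related code 250.1
  expect_true("p8" %in% cc@excludedIds)           # age 70 outside [50, 60]
  expect_true("p5" %in% cc@excludedIds)           # age 20 outside window
  expect_setequal(cc@controlIds, c("p4", "p7"))
  expect_false(cc@analyzable && length(cc@caseIds) < 2)
  # partition property
  expect_setequal(c(cc@caseIds, cc@controlIds, cc@excludedIds),
                  covariates$individual_id)
  # empty case set is unanalyzable
  cc0 <- assembleCaseControl(events[0, ], "250.2", map, covariates)
  expect_false(cc0@analyzable)
})

test_that("logistic fit matches an independent IRLS oracle", {
  set.seed(7)
  for (i in 1:50) {
    n <- 120
    x <- rnorm(n)
    z <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 0.5 * x - 0.2 * z))
    if (length(unique(y)) < 2) next
    res <- fitLogistic(y, x, data.frame(z = z))
    if (!res$converged) next
    oracle <- irlsOracle(cbind(1, x, z), y)
    expect_equal(res$beta, oracle$coef[2], tolerance = 1e-6)
    expect_equal(res$se, oracle$se[2], tolerance = 1e-6)
  }
  # constant exposure: rank error
  expect_error(fitLogistic(rbinom(50, 1, 0.5), rep(1, 50)),
               class = "virtmet_rank_error")
  expect_error(fitLogistic(rep(1, 50), rnorm(50)),
               class = "virtmet_fit_error")
})

test_that("logistic fit recovers a known log-odds ratio at scale", {
  set.seed(21)
  n <- 20000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0.3 * x))
  res <- fitLogistic(y, x)
  expect_lt(abs(res$beta - 0.3), 3 * res$se)
})

test_that("PheWAS scan applies within-phenotype BH and flags failures", {
  set.seed(8)
  n <- 600
  covariates <- data.frame(individual_id = sprintf("i%03d", 1:n),
                           age = runif(n, 30, 70), sex = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.3)
  cc <- new("CaseControlSet", phecode = "008",
            caseIds = covariates$individual_id[y == 1],
            controlIds = covariates$individual_id[y == 0],
            excludedIds = character(0), ageWindow = c(30, 70),
            analyzable = TRUE)
  pgs <- lapply(1:3, function(k) {
    new("PgsVector", metaboliteId = paste0("m", k),
        values = setNames(rnorm(n), covariates$individual_id),
        nVariantsUsed = 5L, nMissingHandled = 0L)
  })
  names(pgs) <- paste0("m", 1:3)
  res <- phewasScan(pgs, list(`008` = cc), covariates)
  expect_equal(nrow(res), 3)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_true(all(res$q >= res$p))
  # single metabolite: q equals p
  res1 <- phewasScan(pgs[1], list(`008` = cc), covariates)
  expect_equal(res1$q, res1$p)
  # a degenerate score is flagged, not fatal
  pgs$bad <- new("PgsVector", metaboliteId = "bad",
                 values = setNames(rep(0, n), covariates$individual_id),
                 nVariantsUsed = 1L, nMissingHandled = 0L)
  resBad <- phewasScan(pgs, list(`008` = cc), covariates)
  expect_false(resBad$converged[resBad$metabolite_id == "bad"])
  expect_true(is.na(resBad$q[resBad$metabolite_id == "bad"]))
  expect_equal(sum(!is.na(resBad$q)), 3)
})

test_that("per-SNP outcome GWAS recovers a planted direct effect and flags monomorphic variants", {
  set.seed(9)
  n <- 8000
  dos <- rbind(rbinom(n, 2, 0.3), rep(1, n), rbinom(n, 2, 0.4))
  panel <- tinyPanel(dos, chrom = c("1", "1", "2"),
                     pos = c(1000L, 2000L, 1000L))
  covariates <- data.frame(individual_id = individualIds(panel),
                           age = runif(n, 30, 70), sex = rbinom(n, 1, 0.5))
  eta <- -1.5 + 0.4 * dos[1, ] + 0.02 * (covariates$age - 50)
  y <- rbinom(n, 1, plogis(eta))
  cc <- new("CaseControlSet", phecode = "x",
            caseIds = individualIds(panel)[y == 1],
            controlIds = individualIds(panel)[y == 0],
            excludedIds = character(0), ageWindow = c(30, 70),
            analyzable = TRUE)
  res <- snpOutcomeGwas(panel, cc, covariates)
  expect_lt(abs(res$beta[1] - 0.4), 3 * res$se[1])
  expect_true(is.na(res$se[2]))  # monomorphic flagged
  expect_false(is.na(res$beta[3]))
  validateSummaryStats(res[!is.na(res$beta), ])
})
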