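# Polygenic scores, PheCode case/control assembly, the PheWAS scan and the
# per-SNP outcome GWAS.

# Match score/summary entries to panel variants by (chrom, pos) and allele
# set, directly or after strand complement.  Returns the panel row index
# (NA when unmatched) and the entry's effect allele expressed on the panel
# strand.
.matchVariants <- function(entries, vf) {
  key <- paste(vf$chrom, vf$pos)
  idx <- match(paste(entries$chrom, entries$pos), key)
  ea <- entries$effect_allele
  for (i in which(!is.na(idx))) {
    pa <- c(vf$ref[idx[i]], vf$alt[idx[i]])
    ent <- c(entries$ref[i], entries$alt[i])
    if (setequal(ent, pa)) next
    entC <- .complementAllele(ent)
    if (setequal(entC, pa)) {
      ea[i] <- .complementAllele(ea[i])
    } else {
      idx[i] <- NA_integer_
    }
  }
  list(idx = idx, effectAllele = ea)
}

#' Train a score model from exposure GWAS summary statistics
#'
#' Selects SNPs below `p_threshold` and uses their per-allele betas as
#' weights, mirroring the construction of published metabolite scores from
#' genome-wide-significant SNPs.
#'
#' @param stats summary-statistic data.frame.
#' @param metabolite_id identifier for the resulting model.
#' @param p_threshold selection threshold (default 5e-8).
#' @return a [ScoreModel-class], or `NULL` when no SNP passes.
#' @export
scoreModelFromStats <- function(stats, metabolite_id, p_threshold = 5e-8) {
  keep <- which(!is.na(stats$p) & stats$p < p_threshold)
  if (!length(keep)) return(NULL)
  s <- stats[keep, ]
  new("ScoreModel", metaboliteId = metabolite_id,
      entries = data.frame(
        variant = s$variant, chrom = s$chrom, pos = s$pos,
        ref = s$other_allele, alt = s$effect_allele,
        effect_allele = s$effect_allele, weight = s$beta,
        stringsAsFactors = FALSE),
      sourcePThreshold = p_threshold)
}

#' Compute a metabolite polygenic score
#'
#' The weighted sum of effect-allele dosages, `value_i = sum_j w_j * d_ij`,
#' where `d_ij` is the alt dosage when the effect allele is alt and `2 -
#' alt dosage` otherwise.  Missing dosages are mean-imputed with `2 * EAF`
#' of the effect allele (panel frequency, the PLINK convention) or the
#' variant is dropped, per `missing_policy`.  The returned score is
#' standardized to mean 0, SD 1, so downstream association betas are per
#' SD of PGS.
#'
#' @param panel a [GenotypePanel-class].
#' @param model a [ScoreModel-class].
#' @param missing_policy `"mean_impute"` or `"drop_variant"`.
#' @param standardize return standardized scores (default) or the raw
#'   weighted sum.
#' @return a [PgsVector-class].
#' @examples
#' cfg <- simulationConfig(n_discovery = 300, n_variants = 12,
#'                         n_ld_blocks = 3, n_metabolites = 2,
#'                         h2_metabolite = 0.5, seed = 2)
#' panel <- simulateGenotypes(cfg)
#' met <- simulateMetabolites(panel, cfg)
#' w <- met$truth@metaboliteWeights
#' w <- w[w$metabolite == "met01", ]
#' vf <- variantInfo(panel)
#' i <- match(w$variant, vf$variant)
#' model <- new("ScoreModel", metaboliteId = "met01",
#'              entries = data.frame(variant = w$variant,
#'                chrom = vf$chrom[i], pos = vf$pos[i], ref = vf$ref[i],
#'                alt = vf$alt[i], effect_allele = vf$alt[i],
#'                weight = w$effect), sourcePThreshold = 5e-8)
#' computePgs(panel, model)
#' @export
computePgs <- function(panel, model,
                       missing_policy = c("mean_impute", "drop_variant"),
                       standardize = TRUE) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is(panel, "GenotypePanel"), is(model, "ScoreModel"))
  vf <- variantInfo(panel)
  entries <- model@entries
  m <- .matchVariants(entries, vf)
  if (all(is.na(m$idx))) {
    .virtmetStop("virtmet_instrument_error",
                 "no score variants found in panel; missing: %s",
                 paste(utils::head(entries$variant, 10), collapse = ", "))
  }
  use <- which(!is.na(m$idx))
  D <- dosages(panel)[m$idx[use], , drop = FALSE]
  eaIsAlt <- m$effectAllele[use] == vf$alt[m$idx[use]]
  Deff <- ifelse(matrix(eaIsAlt, nrow(D), ncol(D)), D, 2 - D)
  w <- entries$weight[use]
  nMissing <- 0L
  if (anyNA(Deff)) {
    if (missing_policy == "drop_variant") {
      bad <- which(apply(Deff, 1, anyNA))
      nMissing <- length(bad)
      if (length(bad)) {
        Deff <- Deff[-bad, , drop = FALSE]
        w <- w[-bad]
        use <- use[-bad]
      }
      .assertThat(length(w) > 0, "virtmet_instrument_error",
                  "all score variants dropped for missingness")
    } else {
      eafEff <- ifelse(eaIsAlt, vf$eaf[m$idx[use]], 1 - vf$eaf[m$idx[use]])
      for (j in which(apply(Deff, 1, anyNA))) {
        nas <- is.na(Deff[j, ])
        nMissing <- nMissing + sum(nas)
        Deff[j, nas] <- 2 * eafEff[j]
      }
    }
  }
  raw <- as.numeric(crossprod(Deff, w))
  values <- raw
  if (standardize) {
    s <- sd(raw)
    .assertThat(is.finite(s) && s > 0, "virtmet_degenerate_score",
                "constant polygenic score for '%s'; cannot standardize",
                model@metaboliteId)
    values <- (raw - mean(raw)) / s
  }
  new("PgsVector", metaboliteId = model@metaboliteId,
      values = setNames(values, individualIds(panel)),
      nVariantsUsed = length(w), nMissingHandled = as.integer(nMissing))
}

#' Assemble a PheCode case/control set
#'
#' Cases are individuals with at least `min_instances` instances of the
#' target code; individuals carrying any code inside the exclusion range
#' (without reaching case status) are excluded; everyone else is a control
#' provided their age falls inside the observed case age window.  The three
#' sets partition the cohort.
#'
#' @param events event data.frame (`individual_id`, `phecode`, `count`).
#' @param phecode target code (character).
#' @param map exclusion-range data.frame from [readPhecodeMap()]; `NULL`
#'   restricts exclusion to the code itself.
#' @param covariates covariate data.frame (needs `individual_id`, `age`).
#' @param min_cases minimum case count for the set to be analyzable.
#' @param min_instances case-defining instance count (default 2).
#' @return a [CaseControlSet-class].
#' @export
assembleCaseControl <- function(events, phecode, map = NULL, covariates,
                                min_cases = 100, min_instances = 2) {
  ids <- as.character(covariates$individual_id)
  codeNum <- suppressWarnings(as.numeric(events$phecode))
  target <- suppressWarnings(as.numeric(phecode))
  onTarget <- events$phecode == phecode
  counts <- tapply(events$count[onTarget],
                   events$individual_id[onTarget], sum)
  caseIds <- names(counts)[counts >= min_instances]
  if (is.null(map)) {
    inRange <- onTarget
  } else {
    rows <- map[map$phecode == phecode, , drop = FALSE]
    if (!nrow(rows)) rows <- data.frame(low = target, high = target)
    inRange <- rep(FALSE, nrow(events))
    for (r in seq_len(nrow(rows))) {
      inRange <- inRange |
        (!is.na(codeNum) & codeNum >= rows$low[r] & codeNum <= rows$high[r])
    }
    inRange <- inRange | onTarget
  }
  related <- unique(events$individual_id[inRange])
  excludedIds <- setdiff(related, caseIds)
  caseIds <- intersect(ids, caseIds)
  excludedIds <- intersect(ids, excludedIds)
  if (!length(caseIds)) {
    return(new("CaseControlSet", phecode = as.character(phecode),
               caseIds = character(0), controlIds = character(0),
               excludedIds = ids, ageWindow = c(NA_real_, NA_real_),
               analyzable = FALSE))
  }
  age <- setNames(covariates$age, ids)
  ageWindow <- range(age[caseIds])
  rest <- setdiff(ids, c(caseIds, excludedIds))
  inWindow <- age[rest] >= ageWindow[1] & age[rest] <= ageWindow[2]
  controlIds <- rest[inWindow]
  excludedIds <- c(excludedIds, rest[!inWindow])
  new("CaseControlSet", phecode = as.character(phecode), caseIds = caseIds,
      controlIds = controlIds, excludedIds = excludedIds,
      ageWindow = ageWindow, analyzable = length(caseIds) >= min_cases)
}

#' Maximum-likelihood logistic regression for one exposure
#'
#' Fits `y ~ x + covariates` by iteratively reweighted least squares
#' (Fisher scoring, up to 25 iterations at convergence tolerance 1e-10) and
#' returns the Wald statistics for `x` against the standard normal.  A
#' rank-deficient design is an error; non-convergence and separation are
#' returned as flagged results so the caller can exclude them from FDR
#' rather than polluting it.
#'
#' @param y 0/1 response.
#' @param x exposure vector.
#' @param covariates optional numeric data.frame/matrix of adjustments.
#' @param maxit,tol IRLS controls.
#' @return list with `beta`, `se`, `p`, `converged`, `reason`,
#'   `coefficients`.
#' @export
fitLogistic <- function(y, x, covariates = NULL, maxit = 25L, tol = 1e-10) {
  .assertThat(length(unique(y)) == 2, "virtmet_fit_error",
              "response must contain both classes")
  X <- cbind(`(Intercept)` = 1, x = x)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    storage.mode(cv) <- "double"
    X <- cbind(X, cv)
  }
  .assertThat(qr(X)$rank == ncol(X), "virtmet_rank_error",
              "design matrix is rank deficient (constant exposure?)")
  fit <- suppressWarnings(glm.fit(
    X, y, family = binomial(),
    control = glm.control(epsilon = tol, maxit = maxit)))
  beta <- coef(fit)
  # polish with Newton steps: glm.fit stops on deviance change, which can
  # leave coefficients ~1e-5 short of the optimum
  for (it in 1:5) {
    mu <- plogis(as.numeric(X %*% beta))
    W <- pmax(mu * (1 - mu), 1e-12)
    step <- tryCatch(
      solve(crossprod(X * sqrt(W)), crossprod(X, y - mu)),
      error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < 1e-10) break
  }
  fit$coefficients <- beta
  mu <- plogis(as.numeric(X %*% beta))
  separated <- any(mu > 1 - 1e-10) || any(mu < 1e-10)
  W <- mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(W))
  V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(V) || !fit$converged || separated) {
    reason <- if (is.null(V) || separated) "separation" else "non_convergence"
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                converged = FALSE, reason = reason,
                coefficients = coef(fit)))
  }
  se <- sqrt(diag(V))
  list(beta = unname(coef(fit)["x"]), se = unname(se[2]),
       p = .normP(coef(fit)["x"] / se[2]), converged = TRUE, reason = NA,
       coefficients = coef(fit))
}

#' Phenome-wide association scan of metabolite PGS
#'
#' Fits, for every analyzable (metabolite, phenotype) cell, a logistic
#' regression of case status on the standardized PGS adjusted for the
#' supplied covariates, then applies Benjamini-Hochberg FDR within each
#' phenotype across metabolites (scope `"global"` adjusts over all cells
#' instead).  Non-converged fits are flagged and left out of the FDR
#' denominator.
#'
#' @param pgsList named list of [PgsVector-class], one per metabolite.
#' @param ccSets named list of [CaseControlSet-class], one per phenotype.
#' @param covariates covariate data.frame with `individual_id` plus the
#'   adjustment columns named in `adjust`.
#' @param adjust covariate columns to adjust for (default age and sex, the
#'   PheWAS model).
#' @param fdr significance level on the adjusted p.
#' @param fdr_scope `"phenotype"` (default) or `"global"`.
#' @return data.frame with one row per tested cell: `metabolite_id`,
#'   `phecode`, `beta`, `se`, `p`, `q`, `n_cases`, `n_controls`,
#'   `converged`, `flag_reason`, `significant`.
#' @export
phewasScan <- function(pgsList, ccSets, covariates,
                       adjust = c("age", "sex"), fdr = 0.05,
                       fdr_scope = c("phenotype", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  ids <- as.character(covariates$individual_id)
  rows <- list()
  for (ph in names(ccSets)) {
    cc <- ccSets[[ph]]
    if (!cc@analyzable) next
    sub <- c(cc@caseIds, cc@controlIds)
    y <- c(rep(1L, length(cc@caseIds)), rep(0L, length(cc@controlIds)))
    cv <- covariates[match(sub, ids), adjust, drop = FALSE]
    for (m in names(pgsList)) {
      x <- pgsValues(pgsList[[m]])[sub]
      res <- tryCatch(fitLogistic(y, x, cv), error = function(e) {
        list(beta = NA_real_, se = NA_real_, p = NA_real_,
             converged = FALSE, reason = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite_id = m, phecode = ph, beta = res$beta, se = res$se,
        p = res$p, q = NA_real_, n_cases = length(cc@caseIds),
        n_controls = length(cc@controlIds), converged = res$converged,
        flag_reason = if (res$converged) NA_character_
                      else as.character(res$reason),
        stringsAsFactors = FALSE)
    }
  }
  .assertThat(length(rows) > 0, "virtmet_config_error",
              "no analyzable phenotype")
  out <- do.call(rbind, rows)
  ok <- out$converged & !is.na(out$p)
  if (fdr_scope == "global") {
    out$q[ok] <- p.adjust(out$p[ok], "BH")
  } else {
    for (ph in unique(out$phecode)) {
      sel <- ok & out$phecode == ph
      out$q[sel] <- p.adjust(out$p[sel], "BH")
    }
  }
  out$significant <- !is.na(out$q) & out$q < fdr
  out
}

# Shared per-variant logistic GWAS engine; warm-started from the
# covariate-only fit.
.perVariantLogistic <- function(D, y, covMat, vf, maxit = 25L, tol = 1e-8) {
  n <- length(y)
  X0 <- cbind(`(Intercept)` = 1, covMat)
  base <- suppressWarnings(glm.fit(X0, y, family = binomial(),
                                   control = glm.control(epsilon = tol,
                                                         maxit = maxit)))
  start <- c(coef(base), 0)
  X <- cbind(X0, dosage = 0)
  k <- ncol(X)
  res <- data.frame(
    variant = vf$variant, chrom = vf$chrom, pos = vf$pos,
    effect_allele = vf$alt, other_allele = vf$ref, eaf = vf$eaf,
    beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(D))) {
    d <- D[j, ]
    if (anyNA(d) || var(d) == 0) next  # monomorphic/missing -> flagged row
    X[, k] <- d
    fit <- suppressWarnings(glm.fit(X, y, family = binomial(), start = start,
                                    control = glm.control(epsilon = tol,
                                                          maxit = maxit)))
    if (!fit$converged) next
    V <- tryCatch(chol2inv(chol(crossprod(X * sqrt(fit$weights)))),
                  error = function(e) NULL)
    if (is.null(V)) next
    res$beta[j] <- coef(fit)[k]
    res$se[j] <- sqrt(V[k, k])
    res$p[j] <- .normP(res$beta[j] / res$se[j])
  }
  res
}

#' Per-SNP outcome association statistics
#'
#' Additive logistic regression of case status on alt-allele dosage,
#' adjusted for age, sex and 10 principal components (when present in
#' `covariates`), computed over the case/control subset.  Monomorphic
#' variants are emitted flagged (`beta`/`se`/`p` absent).  Output follows
#' the summary-statistic dialect consumed by the MR modules.
#'
#' @param panel a [GenotypePanel-class].
#' @param ccSet a [CaseControlSet-class].
#' @param covariates covariate data.frame.
#' @param variants optional variant subset (default: all panel variants).
#' @param adjust covariate columns; defaults to age, sex and any `pc*`
#'   columns.
#' @return summary-statistic data.frame.
#' @export
snpOutcomeGwas <- function(panel, ccSet, covariates, variants = NULL,
                           adjust = NULL) {
  stopifnot(is(panel, "GenotypePanel"), is(ccSet, "CaseControlSet"))
  if (is.null(adjust)) {
    adjust <- intersect(c("age", "sex", sprintf("pc%d", 1:10)),
                        colnames(covariates))
  }
  sub <- c(ccSet@caseIds, ccSet@controlIds)
  y <- c(rep(1L, length(ccSet@caseIds)), rep(0L, length(ccSet@controlIds)))
  D <- dosages(panel)[, sub, drop = FALSE]
  if (!is.null(variants)) {
    .assertThat(all(variants %in% rownames(D)), "virtmet_instrument_error",
                "variant(s) absent from panel: %s",
                paste(setdiff(variants, rownames(D)), collapse = ", "))
    D <- D[variants, , drop = FALSE]
  }
  vf <- variantInfo(panel)
  vf <- vf[match(rownames(D), vf$variant), ]
  covMat <- as.matrix(
    covariates[match(sub, as.character(covariates$individual_id)), adjust,
               drop = FALSE])
  storage.mode(covMat) <- "double"
  .perVariantLogistic(D, y, covMat, vf)
}
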