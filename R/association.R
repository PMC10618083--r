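# Association testing of a score against a binary phenotype: covariate-
# adjusted logistic regression, likelihood-based pseudo-R2 converted to
# the liability scale for ascertained case-control samples, the p-value
# threshold scan with its permutation empirical p (the permutation repeats
# the entire scan, so the minimum-over-thresholds is compared against its
# own null and the result is free of threshold-selection overfitting),
# quintile odds-ratio profiles, score-score Pearson correlation, and
# nested-model likelihood-ratio comparison.

.buildDesign <- function(n, score = NULL, covariates = NULL,
                         scaleScore = FALSE) {
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(score)) {
    score <- as.numeric(score)
    if (length(score) != n) stop("score length mismatch", call. = FALSE)
    if (scaleScore) {
      s <- sd(score)
      if (s == 0) stop("rank-deficient design: column 'score' is constant",
                       call. = FALSE)
      score <- (score - mean(score)) / s
    }
    X <- cbind(X, score = score)
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows mismatch", call. = FALSE)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  X
}

.checkFullRank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# core IRLS fit on a prebuilt full-rank design; returns the pieces the
# permutation loop needs without re-validating inputs
.glmFitCore <- function(X, y) {
  fit <- .irlsLogistic(X, y, tol = 1e-8, maxit = 100L)
  if (isTRUE(fit$singular))
    stop("singular information matrix", call. = FALSE)
  mu <- fit$fitted
  if (any(mu < 1e-8 | mu > 1 - 1e-8))
    stop("perfect or quasi-complete separation detected", call. = FALSE)
  if (!fit$converged)
    stop("IRLS did not converge in 100 iterations", call. = FALSE)
  list(coef = setNames(as.numeric(fit$coef), colnames(X)),
       se = setNames(as.numeric(fit$se), colnames(X)),
       logLik = fit$loglik, converged = fit$converged)
}

#' Fit a covariate-adjusted logistic regression
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' (tolerance 1e-8, at most 100 iterations) of `y` on an intercept, an
#' optional score, and optional covariates. Reports the two-sided Wald
#' p-value of the score coefficient and the model log-likelihood (for
#' Cox-Snell R2 and likelihood-ratio comparisons). Perfect or
#' quasi-complete separation and rank-deficient designs are explicit
#' errors, the latter naming the collinear columns.
#'
#' @param y binary 0/1 response; both classes must be present.
#' @param score optional numeric score (the TRS or PRS).
#' @param covariates optional numeric design columns (matrix or data.frame
#'   already expanded to indicators; see [covariateMatrix()]).
#' @param scaleScore divide the score by its own sample SD first, so the
#'   estimate is a per-SD log-odds ratio comparable across tissues
#'   (default FALSE).
#' @return A [LogisticFit].
#' @examples
#' y <- rep(c(1, 0), each = 30)
#' x <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
#' exp(fitLogistic(y, x)@coefficients[["score"]])  # odds ratio 4
#' @export
fitLogistic <- function(y, score = NULL, covariates = NULL,
                        scaleScore = FALSE) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("y must be strictly binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  X <- .buildDesign(length(y), score, covariates, scaleScore)
  .checkFullRank(X)
  core <- .glmFitCore(X, y)
  pv <- NA_real_
  if ("score" %in% colnames(X)) {
    z <- core$coef[["score"]] / core$se[["score"]]
    pv <- 2 * pnorm(-abs(z))
  }
  new("LogisticFit", coefficients = core$coef, se = core$se,
      scorePvalue = pv, logLik = core$logLik, n = length(y),
      nParams = ncol(X), converged = core$converged)
}

#' Cox-Snell pseudo-R2 between nested logistic fits
#'
#' `1 - exp((2/n) * (logLik_null - logLik_full))`.
#'
#' @param fitFull,fitNull nested [LogisticFit]s on the same samples.
#' @return The Cox-Snell R2.
#' @export
coxSnellR2 <- function(fitFull, fitNull) {
  stopifnot(is(fitFull, "LogisticFit"), is(fitNull, "LogisticFit"))
  if (fitFull@n != fitNull@n)
    stop("fits are on different sample sizes", call. = FALSE)
  d <- fitFull@logLik - fitNull@logLik
  if (d < -1e-8)
    stop("full model has lower likelihood than the null; ",
         "models are not nested MLEs", call. = FALSE)
  1 - exp(-(2 / fitFull@n) * max(d, 0))
}

#' Liability-scale R2 for an ascertained case-control sample
#'
#' Converts an observed-scale (Cox-Snell) R2 to the liability scale given
#' the population prevalence `K` and the sample case proportion `P`,
#' using the ascertainment-corrected transformation: with
#' `t = qnorm(1 - K)`, `z = dnorm(t)`, `m = z/K`,
#' `C = K(1-K)/z^2 * K(1-K)/(P(1-P))` and
#' `theta = m * (P-K)/(1-K) * (m * (P-K)/(1-K) - t)`, the liability-scale
#' value is `C * r2 / (1 + C * theta * r2)`. When `K = P`, `theta = 0` and
#' the transform is the simple linear scaling by `C`.
#'
#' @param r2cs Cox-Snell R2 in \[0, 1).
#' @param K population prevalence in (0, 1) (default 0.05).
#' @param P sample case proportion in (0, 1).
#' @return Named list with all intermediate quantities (`t`, `z`, `m`,
#'   `C`, `theta`, `r2_cs`) and the result `r2_liab`.
#' @examples
#' leeLiabilityR2(0.1, K = 0.5, P = 0.5)$r2_liab  # pi/2 * 0.1 ~ 0.15708
#' @export
leeLiabilityR2 <- function(r2cs, K = 0.05, P) {
  .checkScalar(r2cs, "r2cs", 0, 1, openUpper = TRUE)
  .checkScalar(K, "K", 0, 1, openLower = TRUE, openUpper = TRUE)
  .checkScalar(P, "P", 0, 1, openLower = TRUE, openUpper = TRUE)
  t <- qnorm(1 - K)
  z <- dnorm(t)
  m <- z / K
  C <- (K * (1 - K) / z^2) * (K * (1 - K) / (P * (1 - P)))
  d <- m * (P - K) / (1 - K)
  theta <- d * (d - t)
  list(t = t, z = z, m = m, C = C, theta = theta, r2_cs = r2cs,
       r2_liab = C * r2cs / (1 + C * theta * r2cs))
}

#' Liability-scale R2 increment attributable to a score
#'
#' Fits the covariates-only and covariates-plus-score models, computes
#' each model's Cox-Snell R2 against the intercept-only fit, converts both
#' to the liability scale (prevalence `K`, observed case proportion), and
#' returns the difference (`method = "transform-then-subtract"`, the
#' default). `method = "direct"` instead Lee-transforms the Cox-Snell R2
#' of the full model measured against the covariates-only model.
#'
#' @param y binary 0/1 response.
#' @param score numeric score vector.
#' @param covariates optional design columns.
#' @param K population prevalence (default 0.05).
#' @param method increment convention (see Details).
#' @param scaleScore passed to [fitLogistic()] for the score term.
#' @return The liability-scale R2 increment (a single number).
#' @export
scoreIncrementR2 <- function(y, score, covariates = NULL, K = 0.05,
                             method = c("transform-then-subtract", "direct"),
                             scaleScore = FALSE) {
  method <- match.arg(method)
  y <- as.numeric(y)
  P <- mean(y)
  fitCov <- fitLogistic(y, score = NULL, covariates = covariates)
  fitFull <- fitLogistic(y, score = score, covariates = covariates,
                         scaleScore = scaleScore)
  if (method == "direct")
    return(leeLiabilityR2(coxSnellR2(fitFull, fitCov), K, P)$r2_liab)
  fit0 <- fitLogistic(y)
  leeLiabilityR2(coxSnellR2(fitFull, fit0), K, P)$r2_liab -
    leeLiabilityR2(coxSnellR2(fitCov, fit0), K, P)$r2_liab
}

# deduplicate threshold selections that resolve to identical gene sets and
# return, per unique set, the per-SD-scaled TRS column
.uniqueScoreColumns <- function(panel, x, thresholds, alpha) {
  sels <- lapply(thresholds, function(l) selectGenes(panel, l, alpha))
  names(sels) <- thresholds
  keys <- vapply(sels, function(s)
    paste(sort(selectedGenes(s)), collapse = "|"), character(1))
  nonEmpty <- lengths(sels) > 0L
  if (!any(nonEmpty)) stop("every threshold yields an empty gene set",
                           call. = FALSE)
  sels <- sels[nonEmpty]; keys <- keys[nonEmpty]
  first <- !duplicated(keys)
  uniq <- sels[first]
  map <- match(keys, keys[first])   # threshold -> unique column
  names(map) <- names(sels)
  cols <- lapply(uniq, function(s) {
    trs <- computeTrs(x, s)
    as.numeric(scale(trs))
  })
  list(selections = sels, uniqueSelections = uniq, map = map,
       scores = do.call(cbind, cols))
}

# Wald p per score column of design [1, s, covMat]; X prebuilt with a
# placeholder score column at position 2. Failed fits (separation,
# singularity) give NA for that column.
.scanPvalues <- function(y, scores, X) {
  as.numeric(.scanMinWaldP(X, scores, y, tol = 1e-8, maxit = 100L))
}

#' Scan the threshold ladder and pick the best-fitting score
#'
#' Builds the TRS at every threshold of the ladder (skipping empty
#' selections), fits each against the phenotype with covariates, converts
#' each model's pseudo-R2 to the liability scale, and returns the scan
#' with the best threshold: smallest score Wald p, ties broken by fewer
#' genes. Scores are divided by their own sample SD before regression, so
#' estimates are per-SD log-odds ratios comparable across tissues (raw
#' scores are available via [computeTrs()]).
#'
#' @param panel a [TwasPanel].
#' @param x a standardized [TrsExperiment] (standardized automatically,
#'   with a message, if not).
#' @param thresholds threshold labels (default the full ladder).
#' @param alpha family-wise level for `"BF"`.
#' @param covariates character vector of colData covariate columns, or
#'   NULL for none (default: sex, age, wave, PC1..PC10 where present).
#' @param prevalence population prevalence for the liability conversion.
#' @return A [ThresholdScan].
#' @export
bestThresholdScan <- function(panel, x, thresholds = trsThresholdLadder(),
                              alpha = 0.05,
                              covariates = .defaultCovariates(x),
                              prevalence = 0.05) {
  stopifnot(is(panel, "TwasPanel"), is(x, "TrsExperiment"))
  if (!length(thresholds)) stop("empty threshold ladder", call. = FALSE)
  if (!isStandardized(x)) {
    .msg("standardizing expression (full analysis sample, n-1 sd)")
    x <- standardizeExpression(x)
  }
  y <- phenotype(x)
  covMat <- covariateMatrix(x, covariates)
  P <- mean(y)
  fit0 <- fitLogistic(y)
  fitCov <- if (is.null(covMat)) fit0 else
    fitLogistic(y, covariates = covMat)
  leeCov <- leeLiabilityR2(coxSnellR2(fitCov, fit0), prevalence, P)$r2_liab
  rows <- lapply(thresholds, function(l) {
    sel <- selectGenes(panel, l, alpha)
    if (!length(sel)) return(NULL)
    trs <- computeTrs(x, sel)
    fit <- fitLogistic(y, score = trs, covariates = covMat,
                       scaleScore = TRUE)
    r2 <- leeLiabilityR2(coxSnellR2(fit, fit0), prevalence, P)$r2_liab -
      leeCov
    data.frame(threshold_label = l, threshold_value = thresholdValue(sel),
               n_genes = attr(trs, "n_genes"),
               estimate = fit@coefficients[["score"]],
               se = fit@se[["score"]], pvalue = fit@scorePvalue,
               r2_liab = r2, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("every threshold yields an empty gene set",
                         call. = FALSE)
  best <- order(res$pvalue, res$n_genes)[1L]
  new("ThresholdScan", tissue = tissue(panel), results = res,
      bestIndex = as.integer(best))
}

.empiricalFromMinima <- function(observedMin, permutedMin) {
  B <- length(permutedMin)
  (sum(permutedMin <= observedMin) + 1) / (B + 1)
}

#' Permutation empirical p-value for the best-threshold score
#'
#' Permutes the phenotype `B` times (covariates stay attached to their
#' samples) and, within each permutation, repeats the full threshold scan,
#' recording the minimum score p-value across the ladder. The empirical p
#' is `(r + 1) / (B + 1)`, where `r` counts permuted minima at or below
#' the observed minimum. Because the scan itself is repeated under the
#' null, the result is free of the inflation that selecting the best
#' threshold induces in the naive minimum p-value (which is also
#' returned, for comparison). `scanPerPermutation = FALSE` switches to the
#' cheaper (anti-conservative) variant that re-tests only the observed
#' best threshold.
#'
#' @param panel a [TwasPanel].
#' @param x a [TrsExperiment].
#' @param thresholds threshold labels (default the full ladder).
#' @param B number of permutations (default 10000).
#' @param seed RNG seed for the permutation stream.
#' @param alpha family-wise level for `"BF"`.
#' @param covariates colData covariate columns, or NULL.
#' @param scanPerPermutation repeat the full scan per permutation
#'   (default TRUE).
#' @return List with `empirical_pvalue`, `observed_min_pvalue` (the naive
#'   scan minimum), `best_threshold`, `B`, and `n_thresholds_tested`.
#' @export
empiricalPvalue <- function(panel, x, thresholds = trsThresholdLadder(),
                            B = 10000L, seed = 1L, alpha = 0.05,
                            covariates = .defaultCovariates(x),
                            scanPerPermutation = TRUE) {
  stopifnot(is(panel, "TwasPanel"), is(x, "TrsExperiment"))
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (B < 99L)
    warning("B = ", B, " permutations cannot resolve empirical p below ",
            signif(1 / (B + 1), 2), "; results will be coarse")
  if (!isStandardized(x)) x <- standardizeExpression(x)
  y <- phenotype(x)
  covMat <- covariateMatrix(x, covariates)
  u <- .uniqueScoreColumns(panel, x, thresholds, alpha)
  X <- .buildDesign(length(y), score = u$scores[, 1L], covariates = covMat)
  .checkFullRank(X)
  obsP <- .scanPvalues(y, u$scores, X)
  if (all(is.na(obsP)))
    stop("no threshold produced a valid association fit", call. = FALSE)
  obsMin <- min(obsP, na.rm = TRUE)
  bestCol <- which.min(obsP)
  bestLabel <- names(u$map)[which(u$map == bestCol)][1L]
  permScores <- if (scanPerPermutation) u$scores else
    u$scores[, bestCol, drop = FALSE]
  permMin <- withSeed(seed, vapply(seq_len(B), function(b) {
    yp <- sample(y)
    suppressWarnings(min(.scanPvalues(yp, permScores, X), na.rm = TRUE))
  }, numeric(1)))
  list(empirical_pvalue = .empiricalFromMinima(obsMin, permMin),
       observed_min_pvalue = obsMin,
       best_threshold = bestLabel,
       B = as.integer(B),
       n_thresholds_tested = ncol(u$scores))
}

# equal-count bin assignment by score rank; remainder spread to lower bins
.quintileBins <- function(score, nBins = 5L) {
  n <- length(score)
  base <- n %/% nBins
  sizes <- base + as.integer(seq_len(nBins) <= n %% nBins)
  bins <- integer(n)
  bins[order(score)] <- rep.int(seq_len(nBins), sizes)
  bins
}

#' Quintile odds-ratio profile of a score
#'
#' Ranks samples by score, splits them into five equal-count bins (any
#' remainder goes to the lower bins), and fits a covariate-adjusted
#' logistic model with quintile indicators, first quintile as baseline.
#' Wald 95% confidence intervals are exponentiated to the odds-ratio
#' scale.
#'
#' @param score numeric score vector.
#' @param y binary 0/1 phenotype.
#' @param covariates optional design columns.
#' @param conf confidence level (default 0.95).
#' @return data.frame with one row per quintile: `quintile`, `n`, `or`,
#'   `lo`, `hi`, `pvalue` (Q1 row is the baseline with OR fixed at 1).
#' @export
quintileOddsRatios <- function(score, y, covariates = NULL, conf = 0.95) {
  y <- as.numeric(y)
  n <- length(score)
  if (n < 50L) stop("quintile profile needs at least 50 samples",
                    call. = FALSE)
  if (length(y) != n) stop("score/phenotype length mismatch", call. = FALSE)
  bins <- .quintileBins(score)
  tab <- table(bins, y)
  if (any(tab == 0))
    stop("quintile ", paste(rownames(tab)[rowSums(tab == 0) > 0],
                            collapse = ", "),
         " contains a single phenotype class", call. = FALSE)
  Q <- stats::model.matrix(~ factor(bins, levels = 1:5))[, -1, drop = FALSE]
  colnames(Q) <- paste0("Q", 2:5)
  X <- .buildDesign(n, covariates = if (is.null(covariates)) Q else
    cbind(Q, as.matrix(covariates)))
  .checkFullRank(X)
  core <- .glmFitCore(X, y)
  zq <- qnorm(1 - (1 - conf) / 2)
  b <- core$coef[paste0("Q", 2:5)]
  s <- core$se[paste0("Q", 2:5)]
  data.frame(quintile = paste0("Q", 1:5),
             n = as.integer(table(bins)),
             or = c(1, exp(b)),
             lo = c(NA, exp(b - zq * s)),
             hi = c(NA, exp(b + zq * s)),
             pvalue = c(NA, 2 * pnorm(-abs(b / s))),
             row.names = NULL)
}

#' Pearson correlation between scores
#'
#' Pearson r and two-sided p for each score against the reference score
#' (typically each significant TRS against the PRS), with Bonferroni
#' correction across the reported pairs.
#'
#' @param trsList named list of numeric score vectors.
#' @param prs reference score vector, sample-aligned with every element of
#'   `trsList`.
#' @return data.frame with `name`, `r`, `pvalue`, `pvalue_bonf`.
#' @export
trsPrsCorrelation <- function(trsList, prs) {
  if (!is.list(trsList)) trsList <- list(score = trsList)
  if (is.null(names(trsList)))
    names(trsList) <- paste0("score", seq_along(trsList))
  if (sd(prs) == 0) stop("reference score has zero variance", call. = FALSE)
  rows <- lapply(names(trsList), function(nm) {
    v <- trsList[[nm]]
    if (length(v) != length(prs))
      stop("score '", nm, "' is not sample-aligned", call. = FALSE)
    if (length(v) < 3L) stop("need at least 3 samples", call. = FALSE)
    if (sd(v) == 0) stop("score '", nm, "' has zero variance", call. = FALSE)
    ct <- cor.test(v, prs, method = "pearson")
    data.frame(name = nm, r = unname(ct$estimate), pvalue = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pvalue_bonf <- pmin(out$pvalue * nrow(out), 1)
  out
}

#' Likelihood-ratio comparison of nested logistic fits
#'
#' `statistic = 2 * (logLik_full - logLik_null)`, degrees of freedom equal
#' to the parameter-count difference, p-value from the upper chi-square
#' tail. Both fits must be on identical samples with the full model
#' extending the null.
#'
#' @param fitNull,fitFull nested [LogisticFit]s.
#' @return List with `statistic`, `df`, `pvalue`.
#' @export
lrtCompare <- function(fitNull, fitFull) {
  stopifnot(is(fitNull, "LogisticFit"), is(fitFull, "LogisticFit"))
  if (fitNull@n != fitFull@n)
    stop("fits are on different sample sizes", call. = FALSE)
  df <- fitFull@nParams - fitNull@nParams
  if (df < 0L) stop("full model has fewer parameters than the null; ",
                    "models are not nested", call. = FALSE)
  stat <- 2 * (fitFull@logLik - fitNull@logLik)
  if (stat < -1e-6)
    stop("full model has lower likelihood than the null; ",
         "models are not nested MLEs", call. = FALSE)
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       pvalue = if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' Tissue-by-tissue association report
#'
#' Runs, per TWAS panel: the threshold scan, the permutation empirical p
#' at the best threshold, the score-only pseudo-R2 increment, the combined
#' PRS + TRS model with its likelihood-ratio comparison against the
#' PRS + covariates model, and finally the effective number of tests
#' across tissues (Galwey on the best-threshold TRS correlation matrix)
#' with the Sidak significance flag — the machine-readable twin of a
#' per-tissue results table.
#'
#' @param panels named list of [TwasPanel]s.
#' @param x a [TrsExperiment] whose colData carries `prs`.
#' @param B permutations for the empirical p.
#' @param seed permutation seed.
#' @param alpha family-wise level.
#' @param prevalence population prevalence for liability conversion.
#' @param covariates colData covariate columns, or NULL.
#' @return List with `table` (one row per tissue: gene count, best
#'   threshold, estimate, p, empirical p, pseudo-R2, PRS+TRS estimates and
#'   combined pseudo-R2, LRT p, Sidak significance flag), `meff` (a
#'   [MeffResult]), and `prsOnly` (estimate, p, pseudo-R2 of the PRS-only
#'   model).
#' @export
associationReport <- function(panels, x, B = 1000L, seed = 1L,
                              alpha = 0.05, prevalence = 0.05,
                              covariates = .defaultCovariates(x)) {
  stopifnot(is.list(panels), length(panels) >= 1L, is(x, "TrsExperiment"))
  if (!isStandardized(x)) x <- standardizeExpression(x)
  y <- phenotype(x)
  P <- mean(y)
  covMat <- covariateMatrix(x, covariates)
  prs <- prsValues(x)
  fit0 <- fitLogistic(y)
  fitCov <- if (is.null(covMat)) fit0 else fitLogistic(y, covariates = covMat)
  leeCov <- leeLiabilityR2(coxSnellR2(fitCov, fit0), prevalence, P)$r2_liab
  prsFit <- fitLogistic(y, score = prs, covariates = covMat,
                        scaleScore = TRUE)
  prsOnly <- list(
    estimate = prsFit@coefficients[["score"]],
    pvalue = prsFit@scorePvalue,
    r2_liab = leeLiabilityR2(coxSnellR2(prsFit, fit0), prevalence,
                             P)$r2_liab - leeCov)
  prsCov <- cbind(prs = as.numeric(scale(prs)),
                  if (is.null(covMat)) NULL else covMat)
  trsBest <- list()
  rows <- lapply(names(panels), function(tt) {
    scan <- bestThresholdScan(panels[[tt]], x, alpha = alpha,
                              covariates = covariates,
                              prevalence = prevalence)
    b <- scan@results[scan@bestIndex, ]
    emp <- empiricalPvalue(panels[[tt]], x, B = B, seed = seed,
                           alpha = alpha, covariates = covariates)
    sel <- selectGenes(panels[[tt]], b$threshold_label, alpha)
    trs <- computeTrs(x, sel)
    trsBest[[tt]] <<- as.numeric(trs)
    comb <- fitLogistic(y, score = trs, covariates = prsCov,
                        scaleScore = TRUE)
    combNull <- fitLogistic(y, covariates = prsCov)
    lrt <- lrtCompare(combNull, comb)
    combR2 <- leeLiabilityR2(coxSnellR2(comb, fit0), prevalence,
                             P)$r2_liab - leeCov
    data.frame(tissue = tt, n_genes = b$n_genes,
               best_threshold = b$threshold_label,
               estimate = b$estimate, pvalue = b$pvalue,
               empirical_pvalue = emp$empirical_pvalue,
               r2_liab = b$r2_liab,
               prs_trs_estimate = comb@coefficients[["score"]],
               prs_trs_pvalue = comb@scorePvalue,
               prs_trs_r2_liab = combR2,
               lrt_pvalue = lrt$pvalue,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  meff <- NULL
  if (length(trsBest) >= 2L) {
    corr <- cor(do.call(cbind, trsBest))
    meff <- galweyMeff(corr, alpha = alpha)
    tab$significant <- tab$empirical_pvalue < meff@sidakThreshold
  }
  list(table = tab, meff = meff, prsOnly = prsOnly)
}

#' Format a result table for writing
#'
#' Applies the package's output conventions to a derived result table:
#' 6 significant digits for estimates, scientific notation for p-values.
#'
#' @param df a result data.frame (e.g. `associationReport(...)$table`).
#' @param path optional output TSV path.
#' @return The formatted data.frame (invisibly when written).
#' @export
writeResultTable <- function(df, path = NULL) {
  out <- .formatResult(df)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
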