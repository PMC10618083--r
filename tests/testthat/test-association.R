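test_that("logistic fit recovers the 2x2 closed form and flags bad designs", {
  # 2x2 cells 20/10/10/20: beta = ln(ad/bc) = ln 4
  y <- c(rep(1, 30), rep(0, 30))
  s <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  fit <- fitLogistic(y, s)
  expect_equal(fit@coefficients[["score"]], log(4), tolerance = 1e-6)

  # perfect separation is an explicit error
  expect_error(fitLogistic(c(1, 1, 0, 0), c(1, 1, 0, 0)), "separation")

  # a constant score column is rank-deficient, named
  expect_error(fitLogistic(y, rep(2, 60)), "collinear column\\(s\\) score")
  expect_error(fitLogistic(y, rep(2, 60), scaleScore = TRUE), "constant")
  expect_error(fitLogistic(y, s, covariates = cbind(dup = s)),
               "collinear column\\(s\\) dup")
  expect_error(fitLogistic(rep(1, 10), rnorm(10)), "both classes")
})

test_that("logistic fit agrees with stats::glm on random problems", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 150
    s <- rnorm(n)
    cv <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
    y <- rbinom(n, 1, plogis(-0.3 + 0.5 * s + 0.2 * cv[, "a"]))
    fit <- fitLogistic(y, s, cv)
    ref <- glm(y ~ s + cv, family = binomial())
    expect_equal(unname(fit@coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(fit@se),
                 unname(summary(ref)$coefficients[, 2]), tolerance = 1e-6)
    expect_equal(fit@logLik, as.numeric(logLik(ref)), tolerance = 1e-8)
  }
})

test_that("Cox-Snell R2 follows the likelihood-difference formula", {
  mk <- function(ll, n, p) new("LogisticFit", coefficients = c(x = 0),
                               se = c(x = 1), scorePvalue = NA_real_,
                               logLik = ll, n = as.integer(n),
                               nParams = as.integer(p), converged = TRUE)
  expect_equal(coxSnellR2(mk(-50, 100, 2), mk(-50, 100, 1)), 0)
  expect_equal(coxSnellR2(mk(-45, 100, 2), mk(-50, 100, 1)),
               1 - exp(-0.1), tolerance = 1e-12)
  expect_error(coxSnellR2(mk(-55, 100, 2), mk(-50, 100, 1)), "not nested")
  expect_error(coxSnellR2(mk(-45, 90, 2), mk(-50, 100, 1)),
               "different sample sizes")
})

test_that("liability-scale transform matches hand-computed values", {
  expect_equal(leeLiabilityR2(0, 0.05, 0.3)$r2_liab, 0)
  # K = P = 0.5: theta = 0, C = pi/2
  v <- leeLiabilityR2(0.1, 0.5, 0.5)
  expect_equal(v$theta, 0)
  expect_equal(v$r2_liab, 0.15707963, tolerance = 1e-6)
  # K = P = 0.05: t = 1.6449, z = 0.10314
  w <- leeLiabilityR2(0.01, 0.05, 0.05)
  expect_equal(w$t, 1.6448536, tolerance = 1e-6)
  expect_equal(w$z, 0.10313564, tolerance = 1e-6)
  expect_equal(w$r2_liab, 0.04465562, tolerance = 1e-6)
  expect_error(leeLiabilityR2(0.1, 0, 0.5), "outside the allowed range")

  # small-R2 limit: r2_liab -> C * r2_cs, relative error < 1% at 1e-4
  lim <- leeLiabilityR2(1e-4, 0.05, 0.45)
  expect_lt(abs(lim$r2_liab / (lim$C * 1e-4) - 1), 0.01)
  # monotone increasing in r2_cs for fixed (K, P)
  grid <- seq(0.01, 0.5, by = 0.01)
  vals <- vapply(grid, function(r) leeLiabilityR2(r, 0.05, 0.45)$r2_liab,
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("liability R2 increment behaves under null and growing signal", {
  # null score: mean increment near zero
  inc0 <- vapply(1:100, function(r) {
    set.seed(4000 + r)
    y <- rbinom(500, 1, 0.45)
    scoreIncrementR2(y, rnorm(500), K = 0.05)
  }, numeric(1))
  expect_lt(mean(inc0), 0.01)

  # increment grows with the true effect
  incAt <- function(beta) {
    mean(vapply(1:30, function(r) {
      set.seed(5000 + 97 * r + round(100 * beta))
      s <- rnorm(400)
      y <- rbinom(400, 1, plogis(-0.2 + beta * s))
      scoreIncrementR2(y, s, K = 0.05)
    }, numeric(1)))
  }
  curve <- c(incAt(0.2), incAt(0.5), incAt(0.9))
  expect_true(all(diff(curve) > 0))

  # a pure-noise covariate barely moves the increment
  dif <- vapply(1:60, function(r) {
    set.seed(6000 + r)
    s <- rnorm(400)
    y <- rbinom(400, 1, plogis(-0.2 + 0.5 * s))
    noise <- cbind(u = rnorm(400))
    scoreIncrementR2(y, s, covariates = noise, K = 0.05) -
      scoreIncrementR2(y, s, K = 0.05)
  }, numeric(1))
  expect_lt(abs(mean(dif)), 0.005)
})

test_that("threshold scan picks the smallest-p threshold", {
  cfg <- signalConfig(61, nGenes = 200L)
  s <- simPair(cfg)
  scan <- suppressMessages(bestThresholdScan(s$panel, s$x))
  expect_s4_class(scan, "ThresholdScan")
  b <- scan@results[scan@bestIndex, ]
  expect_equal(b$pvalue, min(scan@results$pvalue))
  # a one-label ladder returns that label
  one <- suppressMessages(bestThresholdScan(s$panel, s$x,
                                            thresholds = "0.5"))
  expect_equal(one@results$threshold_label, "0.5")
  # the default ladder is the nine fixed labels
  expect_identical(trsThresholdLadder(),
                   c("BF", "0.001", "0.05", "0.1", "0.2", "0.3", "0.4",
                     "0.5", "1"))
})

test_that("concentrated signal makes the Bonferroni threshold win the scan", {
  wins <- vapply(1:60, function(r) {
    cfg <- signalConfig(7000L + r, nGenes = 200L)
    s <- simPair(cfg)
    scan <- suppressMessages(
      bestThresholdScan(s$panel, s$x, covariates = NULL))
    scan@results$threshold_label[scan@bestIndex] %in% c("BF", "0.001")
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("empirical p counts permutation minima with the +1 rule", {
  emp <- trscore:::.empiricalFromMinima
  expect_equal(emp(1e-5, seq(0.01, 0.99, length.out = 99)), 1 / 100)
  permuted <- c(seq(0.01, 0.49, length.out = 50),
                seq(0.51, 0.99, length.out = 50))
  expect_equal(emp(0.5, permuted), (50 + 1) / 101)

  cfg <- signalConfig(62, nGenes = 150L)
  s <- simPair(cfg)
  res <- suppressMessages(empiricalPvalue(s$panel, s$x, B = 99, seed = 1))
  expect_gte(res$empirical_pvalue, 1 / 100)
  expect_equal(res$empirical_pvalue, 0.01)  # strong signal floors at 1/(B+1)
  expect_warning(suppressMessages(
    empiricalPvalue(s$panel, s$x, B = 20, seed = 1)), "coarse")
})

test_that("quintile binning and odds ratios match direct computation", {
  expect_equal(trscore:::.quintileBins(10:1),
               rev(rep(1:5, each = 2)))
  # remainder goes to the lower bins
  expect_equal(as.integer(table(trscore:::.quintileBins(rnorm(53)))),
               c(11, 11, 11, 10, 10))

  set.seed(30)
  n <- 300
  s <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * s))
  q <- quintileOddsRatios(s, y)
  expect_equal(q$or[1], 1)
  expect_true(all(q$lo[-1] <= q$or[-1] & q$or[-1] <= q$hi[-1]))
  # covariate-free Q5-vs-Q1 OR equals the 2x2 table OR on those samples
  bins <- trscore:::.quintileBins(s)
  tab <- table(y[bins == 5]); a <- tab[["1"]]; b <- tab[["0"]]
  tab1 <- table(y[bins == 1]); c0 <- tab1[["1"]]; d0 <- tab1[["0"]]
  expect_equal(q$or[5], (a * d0) / (b * c0), tolerance = 1e-6)

  expect_error(quintileOddsRatios(rnorm(20), rbinom(20, 1, 0.5)),
               "at least 50")
})

test_that("null-score quintile intervals cover an odds ratio of 1", {
  # per-interval coverage: each 95% CI covers OR = 1 in >= 90% of
  # replicates (joint coverage of four intervals is necessarily lower)
  cover <- vapply(1:100, function(r) {
    set.seed(8000 + r)
    y <- rbinom(250, 1, 0.45)
    q <- tryCatch(quintileOddsRatios(rnorm(250), y),
                  error = function(e) NULL)
    if (is.null(q)) return(rep(NA, 4))
    q$lo[-1] <= 1 & q$hi[-1] >= 1
  }, logical(4))
  expect_true(all(rowMeans(cover, na.rm = TRUE) >= 0.9))
})

test_that("score correlations match the textbook formula", {
  set.seed(40)
  v <- rnorm(100)
  expect_equal(trsPrsCorrelation(list(a = v), v)$r, 1)
  expect_equal(trsPrsCorrelation(list(a = -v), v)$r, -1)
  w <- rnorm(100)
  direct <- sum((v - mean(v)) * (w - mean(w))) /
    ((length(v) - 1) * sd(v) * sd(w))
  out <- trsPrsCorrelation(list(a = v, b = -v), w)
  expect_equal(out$r[1], direct, tolerance = 1e-12)
  expect_equal(out$pvalue_bonf, pmin(out$pvalue * 2, 1))
  expect_error(trsPrsCorrelation(list(a = rep(1, 100)), w), "zero variance")
})

test_that("likelihood-ratio comparison matches lmtest on real fits", {
  set.seed(50)
  n <- 200
  s <- rnorm(n)
  cv <- cbind(a = rnorm(n))
  y <- rbinom(n, 1, plogis(0.4 * s))
  fitN <- fitLogistic(y, covariates = cv)
  fitF <- fitLogistic(y, s, cv)
  got <- lrtCompare(fitN, fitF)
  expect_equal(got$df, 1L)
  ref <- lmtest::lrtest(glm(y ~ cv, family = binomial()),
                        glm(y ~ s + cv, family = binomial()))
  expect_equal(got$statistic, ref$Chisq[2], tolerance = 1e-6)
  expect_equal(got$pvalue, ref$`Pr(>Chisq)`[2], tolerance = 1e-6)

  # identical models: statistic 0, p 1
  same <- lrtCompare(fitF, fitF)
  expect_equal(same$statistic, 0)
  expect_equal(same$pvalue, 1)
  expect_error(lrtCompare(fitF, fitN), "not nested")
})

test_that("LRT p-values are uniform when the added predictor is noise", {
  pv <- vapply(1:500, function(r) {
    set.seed(9000 + r)
    y <- rbinom(80, 1, 0.5)
    f0 <- fitLogistic(y)
    f1 <- fitLogistic(y, rnorm(80))
    lrtCompare(f0, f1)$pvalue
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("Wald and 1-df LRT p-values agree at large n", {
  set.seed(60)
  n <- 3000
  s <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.2 + 0.15 * s))
  f0 <- fitLogistic(y)
  f1 <- fitLogistic(y, s)
  lw <- -log10(f1@scorePvalue)
  ll <- -log10(lrtCompare(f0, f1)$pvalue)
  expect_lt(max(lw / ll, ll / lw), 1.5)
})

test_that("the tissue report carries association, combination and meff", {
  cfg <- SimulationConfig(nGenes = 150, nTissues = 3, nCases = 100,
                          nControls = 120, seed = 70)
  b <- simulateBundle(cfg)
  x <- suppressMessages(standardizeExpression(b$experiment))
  out <- suppressMessages(associationReport(b$panels, x, B = 99, seed = 2))
  expect_equal(nrow(out$table), 3L)
  expect_true(all(out$table$empirical_pvalue >= 1 / 100))
  expect_s4_class(out$meff, "MeffResult")
  expect_true(all(c("estimate", "pvalue", "r2_liab") %in%
                  names(out$prsOnly)))
  # combined model should not explain less than the TRS alone (up to noise)
  expect_true(all(out$table$prs_trs_r2_liab > out$table$r2_liab - 0.02))
  fmt <- writeResultTable(out$table)
  expect_true(is.character(fmt$pvalue))
})
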