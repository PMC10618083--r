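# Effective number of independent tests among correlated scores
# (eigenvalue-based, Galwey) and the Sidak family-wise threshold derived
# from it.

#' Galwey effective number of independent tests
#'
#' Eigen-decomposes the correlation matrix of the test statistics, clamps
#' negative eigenvalues (possible for near-singular empirical matrices) to
#' zero, and estimates the effective number of independent tests as
#' `(sum(sqrt(lambda)))^2 / sum(lambda)`. The integer `meff` is rounded
#' half away from zero and clamped to `[1, m]`; the unrounded estimate is
#' kept alongside. The Sidak per-test threshold at level `alpha` is
#' attached.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param alpha family-wise level for the attached Sidak threshold.
#' @return A [MeffResult].
#' @examples
#' galweyMeff(diag(5))                     # meff = 5
#' r <- matrix(0.5, 3, 3); diag(r) <- 1
#' galweyMeff(r)@meffRaw                   # 8/3
#' @export
galweyMeff <- function(corr, alpha = 0.05) {
  corr <- as.matrix(corr)
  m <- nrow(corr)
  if (m < 1L || ncol(corr) != m)
    stop("corr must be a square matrix", call. = FALSE)
  if (anyNA(corr))
    stop("corr contains missing values; the score matrix must be complete",
         call. = FALSE)
  if (max(abs(corr - t(corr))) > 1e-8)
    stop("corr is not symmetric", call. = FALSE)
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop("corr does not have a unit diagonal", call. = FALSE)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(ev, 0)
  meffRaw <- sum(sqrt(lam))^2 / sum(lam)
  meff <- as.integer(min(max(floor(meffRaw + 0.5), 1), m))
  new("MeffResult", corr = corr, eigenvalues = ev, meffRaw = meffRaw,
      meff = meff, alpha = alpha,
      sidakThreshold = sidakThreshold(alpha, meff))
}

#' Sidak per-test significance threshold
#'
#' `1 - (1 - alpha)^(1/meff)`: the per-test level that keeps the
#' family-wise error at `alpha` over `meff` independent tests.
#'
#' @param alpha family-wise level in (0, 1).
#' @param meff number of independent tests (>= 1).
#' @return The per-test threshold.
#' @examples
#' sidakThreshold(0.05, 11)   # ~4.65e-03
#' @export
sidakThreshold <- function(alpha, meff) {
  .checkScalar(alpha, "alpha", 0, 1, openLower = TRUE, openUpper = TRUE)
  if (!is.numeric(meff) || length(meff) != 1L || meff < 1)
    stop("meff must be a single number >= 1", call. = FALSE)
  if (meff == 1) return(alpha)  # exact identity; avoids 1-(1-a) rounding
  1 - (1 - alpha)^(1 / meff)
}

#' Effective tests from a matrix of scores
#'
#' Convenience wrapper: Pearson correlation of the score columns, then
#' [galweyMeff()]. The score matrix must be complete (no missing values).
#'
#' @param scores numeric matrix, one column per score (e.g. the
#'   best-threshold TRS of each tissue).
#' @param alpha family-wise level.
#' @return A [MeffResult].
#' @export
meffFromScores <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  if (anyNA(scores))
    stop("score matrix must be complete (no missing scores)", call. = FALSE)
  galweyMeff(cor(scores), alpha = alpha)
}
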