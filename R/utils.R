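#' @import methods
#' @importFrom stats pnorm qnorm dnorm pchisq rnorm rbinom rbeta plogis qlogis
#'   cor cor.test
#' @importFrom utils read.delim write.table
NULL

.msg <- function(...) message("[trscore] ", ...)

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG with `seed`, evaluates `expr`, then restores the caller's
#' stream. Every stochastic generator in the package runs under its own
#' stream (`seed` + a fixed per-operation offset) so adding one generator
#' never perturbs the draws of another.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# scalar-in-range assertion; open/closed endpoints selectable
.checkScalar <- function(x, name, lower = -Inf, upper = Inf,
                         openLower = FALSE, openUpper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  okL <- if (openLower) x > lower else x >= lower
  okU <- if (openUpper) x < upper else x <= upper
  if (!okL || !okU)
    stop(sprintf("'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
                 if (openLower) "(" else "[", lower, upper,
                 if (openUpper) ")" else "]"), call. = FALSE)
  invisible(x)
}

# full-precision TSV writer for data tables (round-trip safe)
.writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = NA))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 6-significant-digit formatting for derived result tables; p-values scientific
.formatResult <- function(df, pcols = grep("pvalue", names(df), value = TRUE)) {
  for (nm in names(df)) {
    if (!is.double(df[[nm]])) next
    df[[nm]] <- if (nm %in% pcols) {
      formatC(df[[nm]], format = "e", digits = 5)
    } else {
      format(signif(df[[nm]], 6), trim = TRUE)
    }
  }
  df
}
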