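#' TwasPanel: gene-level TWAS results for one expression reference panel
#'
#' Holds, for a single tissue, the per-gene TWAS summary statistics consumed
#' by score construction: the signed Z-score (the score weight), the
#' two-sided p-value used for threshold selection, and the gene position
#' (chromosome and 1-based TSS) used for locus pruning.
#'
#' @slot tissue single tissue/panel name.
#' @slot results a [S4Vectors::DataFrame] with columns `gene_id`, `zscore`,
#'   `pvalue`, `chrom`, `tss`.
#'
#' @param tissue character(1) panel name.
#' @param results data.frame or DataFrame with the required columns.
#' @param x a `TwasPanel`.
#'
#' @return `TwasPanel()` returns a validated object; `tissue()` the panel
#'   name; `twasResults()` the results DataFrame; `nGenesTested()` the
#'   number of genes in the panel.
#' @examples
#' df <- data.frame(gene_id = c("A", "B"), zscore = c(2.1, -0.5),
#'                  pvalue = c(0.036, 0.62), chrom = "chr1",
#'                  tss = c(1e6, 2e6))
#' p <- TwasPanel("cortex", df)
#' nGenesTested(p)
#' @aliases tissue twasResults nGenesTested
#' @export TwasPanel
#' @exportClass TwasPanel
setClass("TwasPanel",
         slots = c(tissue = "character", results = "DataFrame"))

.validTwasPanel <- function(object) {
  msgs <- character()
  if (length(object@tissue) != 1L || is.na(object@tissue) ||
      !nzchar(object@tissue))
    msgs <- c(msgs, "'tissue' must be a single non-empty string")
  req <- c("gene_id", "zscore", "pvalue", "chrom", "tss")
  miss <- setdiff(req, colnames(object@results))
  if (length(miss))
    return(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  r <- object@results
  dup <- unique(r$gene_id[duplicated(r$gene_id)])
  if (length(dup))
    msgs <- c(msgs, paste0("duplicate gene_id: ",
                           paste(head(dup, 5), collapse = ", ")))
  bad <- which(!is.finite(r$zscore))
  if (length(bad))
    msgs <- c(msgs, paste0("non-finite zscore at row(s) ",
                           paste(head(bad, 5), collapse = ", ")))
  bad <- which(!(r$pvalue > 0 & r$pvalue <= 1))
  if (length(bad))
    msgs <- c(msgs, paste0("pvalue outside (0,1] at row(s) ",
                           paste(head(bad, 5), collapse = ", ")))
  bad <- which(!(is.finite(r$tss) & r$tss >= 0 & r$tss == round(r$tss)))
  if (length(bad))
    msgs <- c(msgs, paste0("tss must be a non-negative integer; bad row(s) ",
                           paste(head(bad, 5), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
}
setValidity("TwasPanel", .validTwasPanel)

TwasPanel <- function(tissue, results) {
  res <- S4Vectors::DataFrame(as.data.frame(results))
  new("TwasPanel", tissue = as.character(tissue), results = res)
}

#' @rdname TwasPanel-class
#' @export
setMethod("tissue", "TwasPanel", function(x) x@tissue)
#' @rdname TwasPanel-class
#' @export
setMethod("twasResults", "TwasPanel", function(x) x@results)
#' @rdname TwasPanel-class
#' @export
setMethod("nGenesTested", "TwasPanel", function(x) nrow(x@results))

setMethod("show", "TwasPanel", function(object) {
  cat("TwasPanel:", object@tissue, "-", nrow(object@results),
      "genes tested\n")
  z <- object@results$zscore
  cat("  |Z| range:", sprintf("%.3f .. %.3f", min(abs(z)), max(abs(z))), "\n")
})

#' TrsExperiment: expression plus cohort in one container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"expr"`
#' (genes in rows, samples in columns) and the cohort table in `colData`:
#' `phenotype` (1 = case, 0 = control), covariates (typically `sex`, `age`,
#' `wave`, `PC1`..`PC10`) and the precomputed polygenic score `prs`.
#' `metadata(x)$standardized` records whether each gene has been scaled to
#' mean 0 / sample sd 1; validity enforces those moments (to 1e-8) when the
#' flag is set.
#'
#' Construct with [alignCohort()], which intersects and orders samples, or
#' directly with `TrsExperiment()` when expression rows and cohort rows are
#' already the same samples.
#'
#' @param expr samples-by-genes numeric matrix with sample ids as rownames.
#' @param cohort data.frame with a `sample_id` column, `phenotype`, and any
#'   covariate/PRS columns.
#' @param standardized logical flag; set by [standardizeExpression()].
#' @param x a `TrsExperiment`.
#' @param ... for `covariateMatrix`: `covariates`, a character vector of
#'   colData columns to expand into a design matrix (default: whichever of
#'   sex, age, wave, PC1..PC10 are present).
#'
#' @return `phenotype()` the 0/1 vector; `prsValues()` the PRS vector;
#'   `isStandardized()` the flag; `covariateMatrix()` a numeric matrix with
#'   factors expanded to indicator columns (no intercept).
#' @aliases phenotype prsValues isStandardized covariateMatrix
#' @export TrsExperiment
#' @exportClass TrsExperiment
setClass("TrsExperiment", contains = "SummarizedExperiment")

.validTrsExperiment <- function(object) {
  msgs <- character()
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    return("assay 'expr' is required")
  a <- SummarizedExperiment::assay(object, "expr")
  if (anyNA(a))
    msgs <- c(msgs, "expression contains missing values (no imputation)")
  cd <- SummarizedExperiment::colData(object)
  if (!"phenotype" %in% colnames(cd)) {
    msgs <- c(msgs, "colData must contain 'phenotype'")
  } else {
    ph <- cd$phenotype
    if (anyNA(ph) || !all(ph %in% c(0, 1)))
      msgs <- c(msgs, "'phenotype' must be strictly binary 0/1")
  }
  std <- S4Vectors::metadata(object)$standardized
  mom <- S4Vectors::metadata(object)$standardizationMoments
  if (isTRUE(std) && (is.null(mom) || mom == "full") && ncol(a) >= 2L) {
    mu <- rowMeans(a)
    s <- apply(a, 1L, sd)
    if (max(abs(mu)) > 1e-8 || max(abs(s - 1)) > 1e-8)
      msgs <- c(msgs, "flagged standardized but gene moments are not (0, 1)")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("TrsExperiment", .validTrsExperiment)

TrsExperiment <- function(expr, cohort, standardized = FALSE) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)))
    stop("expression matrix must carry sample ids as rownames", call. = FALSE)
  cohort <- as.data.frame(cohort)
  if (!"sample_id" %in% names(cohort))
    stop("cohort table must contain a 'sample_id' column", call. = FALSE)
  if (!identical(rownames(expr), as.character(cohort$sample_id)))
    stop("expression and cohort samples differ or are out of order; ",
         "use alignCohort()", call. = FALSE)
  cd <- S4Vectors::DataFrame(cohort[setdiff(names(cohort), "sample_id")],
                             row.names = cohort$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = t(expr)), colData = cd,
    metadata = list(standardized = isTRUE(standardized)))
  new("TrsExperiment", se)
}

#' @rdname TrsExperiment-class
#' @export
setMethod("phenotype", "TrsExperiment", function(x)
  as.numeric(SummarizedExperiment::colData(x)$phenotype))

#' @rdname TrsExperiment-class
#' @export
setMethod("prsValues", "TrsExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"prs" %in% colnames(cd))
    stop("no 'prs' column in colData", call. = FALSE)
  as.numeric(cd$prs)
})

#' @rdname TrsExperiment-class
#' @export
setMethod("isStandardized", "TrsExperiment", function(x)
  isTRUE(S4Vectors::metadata(x)$standardized))

.defaultCovariates <- function(x) {
  cand <- c("sex", "age", "wave", paste0("PC", 1:10))
  intersect(cand, colnames(SummarizedExperiment::colData(x)))
}

#' @rdname TrsExperiment-class
#' @export
setMethod("covariateMatrix", "TrsExperiment",
          function(x, covariates = .defaultCovariates(x)) {
  if (is.null(covariates) || !length(covariates)) return(NULL)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  miss <- setdiff(covariates, names(cd))
  if (length(miss))
    stop("covariate column(s) not in colData: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- cd[covariates]
  chr <- vapply(df, function(v) is.character(v) || is.factor(v), logical(1))
  df[chr] <- lapply(df[chr], factor)
  # constant columns carry no information and would break the design
  const <- vapply(df, function(v) length(unique(v)) < 2L, logical(1))
  if (any(const)) {
    .msg("dropping constant covariate(s): ",
         paste(names(df)[const], collapse = ", "))
    df <- df[!const]
    if (!ncol(df)) return(NULL)
  }
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
})

setMethod("show", "TrsExperiment", function(object) {
  ph <- phenotype(object)
  cat("TrsExperiment:", nrow(object), "genes x", ncol(object), "samples (",
      sum(ph == 1), "cases /", sum(ph == 0), "controls )\n")
  cat("  standardized:", isStandardized(object), "\n")
  cat("  colData:", paste(colnames(SummarizedExperiment::colData(object)),
                          collapse = ", "), "\n")
})

#' GeneSelection: a thresholded TWAS gene set with score weights
#'
#' The genes of one panel passing one p-value threshold of the fixed ladder,
#' ordered by ascending TWAS p (ties by gene_id), each carrying its signed
#' Z-score as score weight. An empty selection is representable (the
#' downstream score is then undefined and the caller decides).
#'
#' @slot tissue panel name.
#' @slot thresholdLabel one of `"BF"`, `"0.001"`, `"0.05"`, `"0.1"`,
#'   `"0.2"`, `"0.3"`, `"0.4"`, `"0.5"`, `"1"`.
#' @slot thresholdValue the resolved numeric threshold in (0, 1].
#' @slot geneIds ordered gene identifiers.
#' @slot weights signed Z-score per selected gene.
#' @param x a `GeneSelection`.
#' @return Accessors return the respective slot.
#' @aliases selectedGenes scoreWeights thresholdLabel thresholdValue
#' @exportClass GeneSelection
setClass("GeneSelection",
         slots = c(tissue = "character", thresholdLabel = "character",
                   thresholdValue = "numeric", geneIds = "character",
                   weights = "numeric"))

setValidity("GeneSelection", function(object) {
  msgs <- character()
  if (length(object@geneIds) != length(object@weights))
    msgs <- c(msgs, "geneIds and weights lengths differ")
  if (anyDuplicated(object@geneIds))
    msgs <- c(msgs, "duplicate gene ids in selection")
  if (length(object@weights) && !all(is.finite(object@weights)))
    msgs <- c(msgs, "weights must be finite")
  if (!(object@thresholdValue > 0 && object@thresholdValue <= 1))
    msgs <- c(msgs, "thresholdValue must lie in (0,1]")
  if (length(msgs)) msgs else TRUE
})

#' @rdname GeneSelection-class
#' @export
setMethod("selectedGenes", "GeneSelection", function(x) x@geneIds)
#' @rdname GeneSelection-class
#' @export
setMethod("scoreWeights", "GeneSelection", function(x)
  setNames(x@weights, x@geneIds))
#' @rdname GeneSelection-class
#' @export
setMethod("thresholdLabel", "GeneSelection", function(x) x@thresholdLabel)
#' @rdname GeneSelection-class
#' @export
setMethod("thresholdValue", "GeneSelection", function(x) x@thresholdValue)
#' @rdname GeneSelection-class
#' @export
setMethod("tissue", "GeneSelection", function(x) x@tissue)
#' @rdname GeneSelection-class
#' @export
setMethod("length", "GeneSelection", function(x) length(x@geneIds))

setMethod("show", "GeneSelection", function(object) {
  cat(sprintf("GeneSelection: %s @ %s (p <= %.3g): %d gene(s)%s\n",
              object@tissue, object@thresholdLabel, object@thresholdValue,
              length(object@geneIds),
              if (!length(object@geneIds)) " [empty]" else ""))
})

#' LogisticFit: a covariate-adjusted logistic regression fit
#'
#' Maximum-likelihood logistic fit (IRLS) of a binary phenotype on an
#' optional score plus covariates, as produced by [fitLogistic()]. Stores
#' what downstream steps need: coefficients, Wald standard errors, the
#' two-sided Wald p-value of the score term, and the log-likelihood for
#' likelihood-ratio comparisons and Cox-Snell R2.
#'
#' @slot coefficients named coefficient vector (intercept, score, covariates).
#' @slot se named standard errors.
#' @slot scorePvalue two-sided Wald p for the `score` coefficient (NA when
#'   the model has no score term).
#' @slot logLik model log-likelihood.
#' @slot n number of samples.
#' @slot nParams number of fitted parameters.
#' @slot converged IRLS convergence flag (always TRUE for returned fits).
#' @exportClass LogisticFit
setClass("LogisticFit",
         slots = c(coefficients = "numeric", se = "numeric",
                   scorePvalue = "numeric", logLik = "numeric",
                   n = "integer", nParams = "integer",
                   converged = "logical"))

setValidity("LogisticFit", function(object) {
  if (!isTRUE(object@converged)) return("reported fits must have converged")
  p <- object@scorePvalue
  if (!is.na(p) && !(p > 0 && p <= 1)) return("scorePvalue outside (0,1]")
  TRUE
})

setMethod("show", "LogisticFit", function(object) {
  cat("LogisticFit: n =", object@n, ", params =", object@nParams,
      ", logLik =", sprintf("%.3f", object@logLik), "\n")
  if (!is.na(object@scorePvalue))
    cat(sprintf("  score beta = %.4f (se %.4f), Wald p = %.3g\n",
                object@coefficients[["score"]], object@se[["score"]],
                object@scorePvalue))
})

#' ThresholdScan: association results across the p-value threshold ladder
#'
#' One logistic association fit per threshold of the ladder for a single
#' tissue, plus the index of the best (smallest score p-value, ties broken
#' by fewer genes) threshold.
#'
#' @slot tissue panel name.
#' @slot results data.frame with one row per non-empty threshold:
#'   `threshold_label`, `threshold_value`, `n_genes`, `estimate` (per-SD
#'   log-odds), `se`, `pvalue`, `r2_liab` (liability-scale increment).
#' @slot bestIndex row index of the best threshold.
#' @exportClass ThresholdScan
setClass("ThresholdScan",
         slots = c(tissue = "character", results = "data.frame",
                   bestIndex = "integer"))

setValidity("ThresholdScan", function(object) {
  if (!nrow(object@results)) return("scan has no non-empty threshold")
  if (object@bestIndex < 1L || object@bestIndex > nrow(object@results))
    return("bestIndex out of range")
  TRUE
})

setMethod("show", "ThresholdScan", function(object) {
  b <- object@results[object@bestIndex, ]
  cat(sprintf("ThresholdScan: %s, %d threshold(s); best = %s (%d genes, p = %.3g)\n",
              object@tissue, nrow(object@results), b$threshold_label,
              b$n_genes, b$pvalue))
})

#' MeffResult: effective number of correlated tests and Sidak threshold
#'
#' Result of the eigenvalue-based (Galwey) effective-number-of-tests
#' estimate on a correlation matrix of scores, with the derived Sidak
#' per-test significance threshold.
#'
#' @slot corr the input correlation matrix.
#' @slot eigenvalues eigenvalues in descending order (negatives clamped to 0
#'   before use).
#' @slot meffRaw unrounded Galwey estimate (sum sqrt lambda)^2 / sum lambda.
#' @slot meff integer estimate (rounded half away from zero, clamped to
#'   1..m).
#' @slot alpha family-wise level.
#' @slot sidakThreshold 1 - (1 - alpha)^(1/meff).
#' @exportClass MeffResult
setClass("MeffResult",
         slots = c(corr = "matrix", eigenvalues = "numeric",
                   meffRaw = "numeric", meff = "integer",
                   alpha = "numeric", sidakThreshold = "numeric"))

setValidity("MeffResult", function(object) {
  m <- nrow(object@corr)
  msgs <- character()
  if (object@meff < 1L || object@meff > m)
    msgs <- c(msgs, "meff outside [1, m]")
  if (abs(sum(object@eigenvalues) - m) > 1e-6)
    msgs <- c(msgs, "eigenvalues do not sum to the matrix trace")
  if (!(object@sidakThreshold > 0 &&
        object@sidakThreshold <= object@alpha + 1e-12))
    msgs <- c(msgs, "sidakThreshold outside (0, alpha]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MeffResult", function(object) {
  cat(sprintf("MeffResult: m = %d, meff_raw = %.3f, meff = %d\n",
              nrow(object@corr), object@meffRaw, object@meff))
  cat(sprintf("  Sidak threshold at alpha = %g: %.3g\n",
              object@alpha, object@sidakThreshold))
})
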