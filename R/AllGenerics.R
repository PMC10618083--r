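#' @rdname TwasPanel-class
#' @export
setGeneric("tissue", function(x) standardGeneric("tissue"))

#' @rdname TwasPanel-class
#' @export
setGeneric("twasResults", function(x) standardGeneric("twasResults"))

#' @rdname TwasPanel-class
#' @export
setGeneric("nGenesTested", function(x) standardGeneric("nGenesTested"))

#' @rdname TrsExperiment-class
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname TrsExperiment-class
#' @export
setGeneric("prsValues", function(x) standardGeneric("prsValues"))

#' @rdname TrsExperiment-class
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))

#' @rdname TrsExperiment-class
#' @export
setGeneric("covariateMatrix", function(x, ...) standardGeneric("covariateMatrix"))

#' @rdname GeneSelection-class
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname GeneSelection-class
#' @export
setGeneric("scoreWeights", function(x) standardGeneric("scoreWeights"))

#' @rdname GeneSelection-class
#' @export
setGeneric("thresholdLabel", function(x) standardGeneric("thresholdLabel"))

#' @rdname GeneSelection-class
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' Standardize expression gene-wise
#'
#' Transforms each gene to mean 0 and unit sample standard deviation
#' (n - 1 denominator) across samples. Moments are taken over the full
#' analysis sample (cases and controls jointly) unless `controlOnly = TRUE`,
#' in which case control-sample moments are applied to everyone.
#'
#' @param x a samples-by-genes numeric matrix or a [TrsExperiment].
#' @param ... further arguments (`controlOnly`, and for the matrix method
#'   `phenotype`, required when `controlOnly = TRUE`).
#' @return An object of the same class with every gene column/row at mean 0
#'   and sample sd 1, flagged as standardized.
#' @examples
#' m <- cbind(g1 = c(1, 2, 3), g2 = c(5, 5, 8))
#' standardizeExpression(m)[, "g1"]   # -1 0 1
#' @export
setGeneric("standardizeExpression",
           function(x, ...) standardGeneric("standardizeExpression"))

#' Compute per-individual transcriptomic risk scores
#'
#' The TRS of individual i is the sum over selected genes g of the signed
#' TWAS Z-score weight times the individual's standardized expression:
#' TRS_i = sum_g z_g * x_ig. Expression must be standardized first.
#' Selected genes absent from the expression data are dropped from the sum
#' with a logged count.
#'
#' @param x a standardized [TrsExperiment] or samples-by-genes matrix
#'   produced by [standardizeExpression()].
#' @param selection a [GeneSelection].
#' @param ... unused.
#' @return Named numeric vector of raw scores, one per sample, with
#'   attributes `n_genes` (genes actually summed), `tissue` and
#'   `threshold_label`.
#' @export
setGeneric("computeTrs", function(x, selection, ...) standardGeneric("computeTrs"))
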