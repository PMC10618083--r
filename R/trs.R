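# Score construction: threshold ladder selection on TWAS p-values,
# gene-wise standardization of observed expression, the weighted-sum score
# itself, and the two sensitivity variants (one lead gene per 500-kb locus;
# colocalization-restricted gene sets).

#' The fixed TWAS p-value threshold ladder
#'
#' Scores are built at each of nine selection thresholds: the per-panel
#' Bonferroni level (`"BF"`) and eight fixed nominal levels.
#'
#' @return Character vector of threshold labels.
#' @examples
#' trsThresholdLadder()
#' @export
trsThresholdLadder <- function() {
  c("BF", "0.001", "0.05", "0.1", "0.2", "0.3", "0.4", "0.5", "1")
}

#' Per-panel Bonferroni selection threshold
#'
#' `alpha` divided by the number of genes tested in the panel; each panel
#' is corrected separately for its own gene count.
#'
#' @param panel a [TwasPanel].
#' @param alpha family-wise level, in (0, 1).
#' @return The threshold `alpha / nGenesTested(panel)`.
#' @examples
#' # a panel of 6213 tested genes gives 0.05 / 6213 ~ 8e-06
#' @export
bonferroniThreshold <- function(panel, alpha = 0.05) {
  stopifnot(is(panel, "TwasPanel"))
  .checkScalar(alpha, "alpha", 0, 1, openLower = TRUE, openUpper = TRUE)
  n <- nGenesTested(panel)
  if (n < 1L) stop("empty panel", call. = FALSE)
  alpha / n
}

.resolveThreshold <- function(panel, thresholdLabel, alpha) {
  ladder <- trsThresholdLadder()
  if (!thresholdLabel %in% ladder)
    stop("threshold label must be one of: ", paste(ladder, collapse = ", "),
         call. = FALSE)
  if (thresholdLabel == "BF") bonferroniThreshold(panel, alpha)
  else as.numeric(thresholdLabel)
}

#' Select signature genes under a p-value threshold
#'
#' Genes of the panel with TWAS p at or below the resolved threshold, in
#' deterministic order (ascending p, ties by gene id), each carrying its
#' signed Z as score weight. An empty selection is returned (with a logged
#' note) rather than raised: the score is then undefined and the caller
#' decides.
#'
#' @param panel a [TwasPanel].
#' @param thresholdLabel a label from [trsThresholdLadder()]; `"BF"`
#'   resolves via [bonferroniThreshold()].
#' @param alpha family-wise level used for `"BF"`.
#' @return A [GeneSelection].
#' @export
selectGenes <- function(panel, thresholdLabel, alpha = 0.05) {
  stopifnot(is(panel, "TwasPanel"))
  thr <- .resolveThreshold(panel, thresholdLabel, alpha)
  r <- twasResults(panel)
  keep <- which(r$pvalue <= thr)
  keep <- keep[order(r$pvalue[keep], r$gene_id[keep])]
  if (!length(keep))
    .msg("selection '", thresholdLabel, "' in ", tissue(panel),
         " is empty (threshold ", signif(thr, 3), ")")
  new("GeneSelection", tissue = tissue(panel),
      thresholdLabel = thresholdLabel, thresholdValue = thr,
      geneIds = as.character(r$gene_id[keep]),
      weights = as.numeric(r$zscore[keep]))
}

.standardizeMatrix <- function(m, moments = NULL) {
  if (is.null(colnames(m)))
    stop("expression matrix must carry gene ids as colnames", call. = FALSE)
  if (anyNA(m)) stop("expression contains missing values", call. = FALSE)
  if (is.null(moments)) {
    mu <- colMeans(m)
    s <- apply(m, 2L, sd)
  } else {
    mu <- moments$mean; s <- moments$sd
  }
  zero <- which(s == 0 | !is.finite(s))
  if (length(zero))
    stop("zero-variance gene(s): ",
         paste(head(colnames(m)[zero], 5), collapse = ", "), call. = FALSE)
  out <- sweep(sweep(m, 2L, mu, "-"), 2L, s, "/")
  attr(out, "standardized") <- TRUE
  out
}

#' @rdname standardizeExpression
#' @param controlOnly use control-sample moments instead of the full
#'   analysis sample (default FALSE, the convention for observed-expression
#'   risk scores).
#' @param phenotype 0/1 vector, required for the matrix method when
#'   `controlOnly = TRUE`.
#' @export
setMethod("standardizeExpression", "matrix",
          function(x, controlOnly = FALSE, phenotype = NULL) {
  if (controlOnly) {
    if (is.null(phenotype))
      stop("controlOnly standardization needs the phenotype", call. = FALSE)
    ctrl <- x[phenotype == 0, , drop = FALSE]
    .standardizeMatrix(x, list(mean = colMeans(ctrl),
                               sd = apply(ctrl, 2L, sd)))
  } else {
    .standardizeMatrix(x)
  }
})

#' @rdname standardizeExpression
#' @export
setMethod("standardizeExpression", "TrsExperiment",
          function(x, controlOnly = FALSE) {
  m <- t(SummarizedExperiment::assay(x, "expr"))
  std <- standardizeExpression(m, controlOnly = controlOnly,
                               phenotype = phenotype(x))
  SummarizedExperiment::assay(x, "expr") <- t(std)
  S4Vectors::metadata(x)$standardized <- TRUE
  S4Vectors::metadata(x)$standardizationMoments <-
    if (controlOnly) "control" else "full"
  validObject(x)
  x
})

.trsFromMatrix <- function(stdSamplesByGenes, selection) {
  if (!length(selection))
    stop("empty gene selection: TRS undefined", call. = FALSE)
  w <- scoreWeights(selection)
  avail <- intersect(names(w), colnames(stdSamplesByGenes))
  dropped <- length(w) - length(avail)
  if (dropped > 0L)
    .msg(dropped, " of ", length(w),
         " selected gene(s) absent from expression; excluded from TRS")
  if (!length(avail))
    stop("no selected gene is present in the expression data", call. = FALSE)
  scores <- drop(stdSamplesByGenes[, avail, drop = FALSE] %*% w[avail])
  structure(scores, n_genes = length(avail), tissue = tissue(selection),
            threshold_label = thresholdLabel(selection))
}

#' @rdname computeTrs
#' @export
setMethod("computeTrs", c("matrix", "GeneSelection"),
          function(x, selection) {
  if (!isTRUE(attr(x, "standardized")))
    stop("expression must be standardized before scoring", call. = FALSE)
  .trsFromMatrix(x, selection)
})

#' @rdname computeTrs
#' @export
setMethod("computeTrs", c("TrsExperiment", "GeneSelection"),
          function(x, selection) {
  if (!isStandardized(x))
    stop("TrsExperiment must be standardized before scoring; ",
         "call standardizeExpression()", call. = FALSE)
  m <- t(SummarizedExperiment::assay(x, "expr"))
  attr(m, "standardized") <- TRUE
  .trsFromMatrix(m, selection)
})

#' Cluster genes into loci by genomic proximity
#'
#' Single-linkage chaining per chromosome: genes whose TSSs are at most
#' `gapBp` apart join the same locus, and chains never span chromosomes.
#' The merge is inclusive at exactly `gapBp` (logged when a pair sits
#' exactly on the boundary).
#'
#' @param geneIds character vector of gene ids.
#' @param chrom chromosome label per gene.
#' @param tss 1-based TSS per gene.
#' @param gapBp locus-joining distance in bp (default 500,000).
#' @return data.frame with `gene_id`, `chrom`, `tss`, `locus` (a locus id
#'   of the form `chrom:index`); attribute `gap_bp` records the rule.
#' @export
clusterLoci <- function(geneIds, chrom, tss, gapBp = 500000L) {
  if (length(geneIds) == 0L) stop("no genes to cluster", call. = FALSE)
  if (anyNA(chrom) || anyNA(tss))
    stop("missing position for gene(s): ",
         paste(head(geneIds[is.na(chrom) | is.na(tss)], 5), collapse = ", "),
         call. = FALSE)
  stopifnot(length(chrom) == length(geneIds), length(tss) == length(geneIds))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(tss, width = 1L))
  # reduce() merges ranges whose gap is < min.gapwidth, i.e. two TSSs merge
  # iff their distance is <= gapBp: exactly the inclusive single-linkage rule
  merged <- GenomicRanges::reduce(gr, min.gapwidth = gapBp)
  hit <- GenomicRanges::findOverlaps(gr, merged, select = "first")
  loci <- paste0(chrom, ":", hit)
  # flag pairs exactly at the boundary, where "<500 kb joins" and
  # ">500 kb separates" leave the convention to us
  byChrom <- split(tss, chrom)
  nEdge <- sum(vapply(byChrom, function(p) sum(diff(sort(p)) == gapBp),
                      numeric(1)))
  if (nEdge > 0)
    .msg(nEdge, " adjacent TSS pair(s) at exactly ", gapBp,
         " bp merged into one locus (inclusive boundary)")
  structure(data.frame(gene_id = geneIds, chrom = chrom, tss = tss,
                       locus = loci, stringsAsFactors = FALSE),
            gap_bp = gapBp)
}

#' Prune a selection to one lead gene per locus
#'
#' Keeps, within every locus, the gene with the smallest TWAS p-value
#' (ties broken by smaller TSS, then lexicographic gene id). The result is
#' a fixed point: pruning it again changes nothing.
#'
#' @param selection a [GeneSelection].
#' @param loci locus assignment from [clusterLoci()] covering the
#'   selection's genes.
#' @param panel the [TwasPanel] supplying the p-values.
#' @return A [GeneSelection] with one gene per locus.
#' @export
pruneToLead <- function(selection, loci, panel) {
  stopifnot(is(selection, "GeneSelection"), is(panel, "TwasPanel"))
  if (!length(selection)) return(selection)
  miss <- setdiff(selectedGenes(selection), loci$gene_id)
  if (length(miss))
    stop("loci do not cover selected gene(s): ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  r <- twasResults(panel)
  idx <- match(selectedGenes(selection), r$gene_id)
  info <- data.frame(gene_id = selectedGenes(selection),
                     pvalue = r$pvalue[idx],
                     locus = loci$locus[match(selectedGenes(selection),
                                              loci$gene_id)],
                     tss = loci$tss[match(selectedGenes(selection),
                                          loci$gene_id)],
                     stringsAsFactors = FALSE)
  lead <- vapply(split(seq_len(nrow(info)), info$locus), function(rows) {
    o <- rows[order(info$pvalue[rows], info$tss[rows], info$gene_id[rows])]
    o[1L]
  }, integer(1))
  keepIds <- info$gene_id[sort(lead)]
  w <- scoreWeights(selection)
  keep <- selectedGenes(selection) %in% keepIds
  new("GeneSelection", tissue = selection@tissue,
      thresholdLabel = selection@thresholdLabel,
      thresholdValue = selection@thresholdValue,
      geneIds = selectedGenes(selection)[keep],
      weights = unname(w[keep]))
}

#' Restrict a selection to colocalized genes
#'
#' Keeps genes whose gene locus-level colocalization probability (GLCP) in
#' the selection's tissue is at or above the cutoff (inclusive). Genes
#' without a colocalization record are dropped. An all-removed result is
#' returned empty with a logged note.
#'
#' @param selection a [GeneSelection].
#' @param coloc colocalization records (`gene_id`, `tissue`, `glcp`), as
#'   from [readColoc()] or [simulateColoc()].
#' @param cutoff GLCP cutoff in \[0, 1\] (default 0.5).
#' @return A [GeneSelection].
#' @export
restrictColocalized <- function(selection, coloc, cutoff = 0.5) {
  stopifnot(is(selection, "GeneSelection"))
  .checkScalar(cutoff, "cutoff", 0, 1)
  cc <- coloc[coloc$tissue == tissue(selection), , drop = FALSE]
  glcp <- cc$glcp[match(selectedGenes(selection), cc$gene_id)]
  keep <- !is.na(glcp) & glcp >= cutoff
  if (!any(keep))
    .msg("colocalization filter removed every gene of ",
         tissue(selection), " @ ", thresholdLabel(selection))
  w <- scoreWeights(selection)
  new("GeneSelection", tissue = selection@tissue,
      thresholdLabel = selection@thresholdLabel,
      thresholdValue = selection@thresholdValue,
      geneIds = selectedGenes(selection)[keep],
      weights = unname(w[keep]))
}
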