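# Tabular I/O. Canonical dialect for every table is TSV: tab-separated,
# header row, UTF-8, "." decimal. Gene annotation additionally accepted as
# BED (0-based half-open), converted to 1-based TSS at read time. Readers
# reject rather than coerce, and every validation error names the offending
# row or column. Data tables are written at full double precision so that a
# write/read round trip is the identity; derived result tables are written
# at 6 significant digits with p-values in scientific notation.

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = c("NA", ""))
}

.requireColumns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read a per-tissue TWAS summary table
#'
#' Expects a TSV with header columns `gene_id`, `zscore`, `pvalue`,
#' `chrom`, `tss` (extra columns are ignored). Rows with missing `zscore`
#' or `pvalue` are rejected with a logged count; a p-value of 0 or a
#' duplicated `gene_id` is an error, not a silent fix.
#'
#' @param path path to the TSV file.
#' @param tissue panel name to attach.
#' @return A validated [TwasPanel].
#' @seealso [writeTwasTable()]
#' @export
readTwasTable <- function(path, tissue) {
  df <- .readTsv(path)
  .requireColumns(df, c("gene_id", "zscore", "pvalue", "chrom", "tss"),
                  paste0("TWAS table ", path))
  df <- df[c("gene_id", "zscore", "pvalue", "chrom", "tss")]
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  drop <- is.na(df$zscore) | is.na(df$pvalue)
  if (any(drop)) {
    .msg(sum(drop), " row(s) with missing zscore/pvalue rejected from ",
         basename(path))
    df <- df[!drop, , drop = FALSE]
  }
  TwasPanel(tissue, df)
}

#' Write a TWAS panel to TSV
#'
#' @param panel a [TwasPanel].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeTwasTable <- function(panel, path) {
  stopifnot(is(panel, "TwasPanel"))
  .writeTsv(as.data.frame(twasResults(panel)), path)
}

#' Read a samples-by-genes expression matrix
#'
#' First TSV column must be `sample_id`; every remaining column is one
#' gene. Any missing cell is a validation error (no imputation).
#'
#' @param path path to the TSV file.
#' @return Numeric matrix, samples in rows (named), genes in columns, with
#'   attribute `standardized = FALSE`.
#' @export
readExpression <- function(path) {
  df <- .readTsv(path)
  .requireColumns(df, "sample_id", paste0("expression table ", path))
  if (ncol(df) < 2L)
    stop("expression table ", path, ": no gene columns", call. = FALSE)
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids))
    stop("duplicated sample_id in expression table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[setdiff(names(df), "sample_id")])
  if (!is.numeric(m))
    stop("expression values must be numeric", call. = FALSE)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing expression value at sample '%s', gene '%s'",
                 ids[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
  }
  rownames(m) <- ids
  attr(m, "standardized") <- FALSE
  .msg("read expression: ", nrow(m), " samples x ", ncol(m), " genes")
  m
}

#' Write a samples-by-genes expression matrix to TSV
#'
#' @param expr numeric matrix, samples in rows with rownames set.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeExpression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  df <- data.frame(sample_id = rownames(expr), as.data.frame(expr),
                   check.names = FALSE)
  .writeTsv(df, path)
}

#' Read the cohort (phenotype/covariate/PRS) table
#'
#' Requires `sample_id` and a strictly binary `phenotype` (1 = case,
#' 0 = control); all further columns (sex, age, wave, PC1..PC10, prs, ...)
#' are carried through untouched.
#'
#' @param path path to the TSV file.
#' @return A data.frame keyed by `sample_id`.
#' @export
readCohort <- function(path) {
  df <- .readTsv(path)
  .requireColumns(df, c("sample_id", "phenotype"),
                  paste0("cohort table ", path))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in cohort table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  bad <- which(is.na(df$phenotype) | !(df$phenotype %in% c(0, 1)))
  if (length(bad))
    stop("non-binary phenotype at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  df
}

#' @rdname readCohort
#' @param cohort a cohort data.frame.
#' @export
writeCohort <- function(cohort, path) .writeTsv(as.data.frame(cohort), path)

#' Read gene-level colocalization probabilities
#'
#' TSV with columns `gene_id`, `tissue`, `glcp`; GLCP values must lie in
#' \[0, 1\].
#'
#' @param path path to the TSV file.
#' @return data.frame of colocalization records.
#' @export
readColoc <- function(path) {
  df <- .readTsv(path)
  .requireColumns(df, c("gene_id", "tissue", "glcp"),
                  paste0("colocalization table ", path))
  bad <- which(is.na(df$glcp) | df$glcp < 0 | df$glcp > 1)
  if (length(bad))
    stop("glcp outside [0,1] at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  df$gene_id <- as.character(df$gene_id)
  df$tissue <- as.character(df$tissue)
  df
}

#' @rdname readColoc
#' @param coloc a colocalization data.frame.
#' @export
writeColoc <- function(coloc, path) .writeTsv(as.data.frame(coloc), path)

#' Read gene annotation from BED
#'
#' BED is 0-based half-open; the 1-based TSS reported here is the interval
#' start converted to 1-based coordinates (the convention used everywhere
#' else in the package).
#'
#' @param path path to a BED file with gene ids in the name field.
#' @return data.frame with columns `gene_id`, `chrom`, `tss` (1-based).
#' @export
readAnnotationBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name))
    stop("BED annotation must carry gene ids in the name field",
         call. = FALSE)
  data.frame(gene_id = as.character(gr$name),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             tss = GenomicRanges::start(gr),
             stringsAsFactors = FALSE)
}

#' Align expression and cohort on shared samples
#'
#' Restricts both inputs to the intersection of their sample ids, in a
#' single consistent order (cohort order of the shared ids), and logs how
#' many samples each side dropped. Idempotent: re-aligning the aligned
#' result is a no-op.
#'
#' @param expr samples-by-genes matrix with sample ids as rownames (as from
#'   [readExpression()]).
#' @param cohort cohort data.frame (as from [readCohort()]).
#' @return A [TrsExperiment] holding the aligned expression and cohort.
#' @export
alignCohort <- function(expr, cohort) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || !nrow(expr) || !nrow(cohort))
    stop("both expression and cohort must be nonempty with sample ids",
         call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop("duplicated sample_id in expression", call. = FALSE)
  if (anyDuplicated(cohort$sample_id))
    stop("duplicated sample_id in cohort", call. = FALSE)
  shared <- intersect(cohort$sample_id, rownames(expr))
  if (!length(shared))
    stop("no shared samples between expression and cohort", call. = FALSE)
  dExpr <- nrow(expr) - length(shared)
  dCoh <- nrow(cohort) - length(shared)
  if (dExpr || dCoh)
    .msg("alignCohort: dropped ", dExpr, " expression-only and ", dCoh,
         " cohort-only sample(s); ", length(shared), " retained")
  std <- isTRUE(attr(expr, "standardized"))
  TrsExperiment(expr[shared, , drop = FALSE],
                cohort[match(shared, cohort$sample_id), , drop = FALSE],
                standardized = std && dExpr == 0L)
}
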