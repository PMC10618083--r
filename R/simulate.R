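# Synthetic input bundle: TWAS panels, expression, cohort, colocalization
# and annotation with the statistical structure the downstream analysis
# assumes, so every stage is testable without clinical data. Every
# generator is a pure function of (config, seed): each op draws from its
# own RNG stream (seed + fixed offset) and restores the caller's stream.

.GTEX_TISSUES <- c("whole_blood", "amygdala", "anterior_cingulate_cortex",
                   "caudate", "cerebellar_hemisphere", "cerebellum",
                   "cortex", "frontal_cortex", "hippocampus", "hypothalamus",
                   "nucleus_accumbens", "putamen", "spinal_cord",
                   "substantia_nigra")

.tissueNames <- function(n) {
  if (n <= length(.GTEX_TISSUES)) .GTEX_TISSUES[seq_len(n)]
  else c(.GTEX_TISSUES, sprintf("tissue_%02d", seq_len(n - length(.GTEX_TISSUES))))
}

#' SimulationConfig: parameters of the synthetic input bundle
#'
#' Defaults mirror the kind of case-control expression study the pipeline
#' targets: 222 cases and 269 controls, 14 expression reference panels with
#' strongly correlated gene Z-scores across panels (pairwise r = 0.98), a
#' sex/age/batch covariate structure matching a sex-frequency-matched adult
#' cohort, and a polygenic score shifted by 0.33 SD in cases but drawn
#' independently of expression. Effect sizes for planted signal genes
#' (`exprEffect`, standardized case-control mean difference, sign-matched
#' to the gene's TWAS Z; `twasEffect`, mean |Z| of causal genes) have no
#' published reference scale and are set so that planted signals are
#' recoverable at the per-panel Bonferroni threshold.
#'
#' @slot nGenes number of simulated genes.
#' @slot nTissues number of TWAS panels.
#' @slot nCases,nControls sample sizes (phenotype fixed by design,
#'   emulating ascertained case-control sampling).
#' @slot causalFraction fraction of genes carrying signal.
#' @slot exprEffect standardized expression mean difference per causal gene.
#' @slot twasEffect mean |Z| inflation for causal genes.
#' @slot crossTissueCorr equicorrelation of a gene's Z across panels, in
#'   \[0, 1).
#' @slot covariateEffects named length-3 vector of case shifts for
#'   `sex` (log-odds of male), `age` (years) and `wave` (log-odds of the
#'   first genotyping batch).
#' @slot prsEffect case shift of the PRS in SD units.
#' @slot discordantFraction fraction of causal genes whose observed
#'   expression shift opposes the sign of their TWAS Z.
#' @slot locusGap TSS spacing (bp) between adjacent simulated genes.
#' @slot seed base RNG seed.
#'
#' @param nGenes,nTissues,nCases,nControls,causalFraction,exprEffect
#'   see slots.
#' @param twasEffect,crossTissueCorr,covariateEffects,prsEffect see slots.
#' @param discordantFraction,locusGap,seed see slots.
#' @return `SimulationConfig()` returns a validated config object.
#' @examples
#' cfg <- SimulationConfig(nGenes = 100, nTissues = 2, seed = 7)
#' cfg
#' @export SimulationConfig
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         slots = c(nGenes = "integer", nTissues = "integer",
                   nCases = "integer", nControls = "integer",
                   causalFraction = "numeric", exprEffect = "numeric",
                   twasEffect = "numeric", crossTissueCorr = "numeric",
                   covariateEffects = "numeric", prsEffect = "numeric",
                   discordantFraction = "numeric", locusGap = "integer",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  for (nm in c("nGenes", "nTissues", "nCases", "nControls", "locusGap"))
    if (slot(object, nm) < 1L)
      msgs <- c(msgs, paste0(nm, " must be a positive integer"))
  if (object@nCases + object@nControls < 20L)
    msgs <- c(msgs, "nCases + nControls must be >= 20 for downstream fits")
  for (nm in c("causalFraction", "discordantFraction"))
    if (slot(object, nm) < 0 || slot(object, nm) > 1)
      msgs <- c(msgs, paste0(nm, " must lie in [0,1]"))
  if (object@exprEffect < 0) msgs <- c(msgs, "exprEffect must be >= 0")
  if (object@twasEffect < 0) msgs <- c(msgs, "twasEffect must be >= 0")
  if (object@crossTissueCorr < 0 || object@crossTissueCorr >= 1)
    msgs <- c(msgs, "crossTissueCorr must lie in [0,1)")
  if (!identical(names(object@covariateEffects), c("sex", "age", "wave")))
    msgs <- c(msgs, "covariateEffects must be named c(sex, age, wave)")
  if (length(msgs)) msgs else TRUE
})

SimulationConfig <- function(nGenes = 1000L, nTissues = 14L,
                             nCases = 222L, nControls = 269L,
                             causalFraction = 0.05, exprEffect = 0.3,
                             twasEffect = 6, crossTissueCorr = 0.98,
                             covariateEffects = c(sex = 0.09, age = -2.57,
                                                  wave = 0),
                             prsEffect = 0.33, discordantFraction = 0,
                             locusGap = 600000L, seed = 1L) {
  new("SimulationConfig",
      nGenes = as.integer(nGenes), nTissues = as.integer(nTissues),
      nCases = as.integer(nCases), nControls = as.integer(nControls),
      causalFraction = causalFraction, exprEffect = exprEffect,
      twasEffect = twasEffect, crossTissueCorr = crossTissueCorr,
      covariateEffects = covariateEffects, prsEffect = prsEffect,
      discordantFraction = discordantFraction,
      locusGap = as.integer(locusGap), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:\n")
  cat(sprintf("  %d genes x %d tissues; %d cases / %d controls\n",
              object@nGenes, object@nTissues, object@nCases,
              object@nControls))
  cat(sprintf("  causal %.0f%% (expr delta %.2f, |Z| shift %.1f, discordant %.0f%%)\n",
              100 * object@causalFraction, object@exprEffect,
              object@twasEffect, 100 * object@discordantFraction))
  cat(sprintf("  cross-tissue r = %.2f; PRS shift %.2f SD; seed %d\n",
              object@crossTissueCorr, object@prsEffect, object@seed))
})

#' SimulatedTruth: the planted signal of a synthetic bundle
#'
#' @slot geneIds all simulated gene ids.
#' @slot causalGenes ids of the planted signal genes
#'   (`round(causalFraction * nGenes)` of them).
#' @slot zMean per-gene mean of the TWAS Z (signed; 0 for non-causal).
#' @slot exprShift per-gene case-control expression shift on the
#'   standardized scale (sign-matched to `zMean` except for the configured
#'   discordant fraction).
#' @exportClass SimulatedTruth
setClass("SimulatedTruth",
         slots = c(geneIds = "character", causalGenes = "character",
                   zMean = "numeric", exprShift = "numeric"))

setValidity("SimulatedTruth", function(object) {
  if (!all(object@causalGenes %in% object@geneIds))
    return("causal genes must be a subset of simulated genes")
  if (length(object@zMean) != length(object@geneIds) ||
      length(object@exprShift) != length(object@geneIds))
    return("per-gene vectors must match geneIds length")
  TRUE
})

setMethod("show", "SimulatedTruth", function(object) {
  cat(sprintf("SimulatedTruth: %d genes, %d causal\n",
              length(object@geneIds), length(object@causalGenes)))
})

#' Draw the planted truth for a synthetic bundle
#'
#' Selects `round(causalFraction * nGenes)` causal genes, gives each a
#' random Z sign, a shared TWAS mean shift of magnitude `twasEffect`, and a
#' standardized expression shift of magnitude `exprEffect` whose sign
#' matches the Z sign except for a configured discordant fraction.
#'
#' @param config a [SimulationConfig].
#' @return A [SimulatedTruth].
#' @export
simulateTruth <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withSeed(config@seed + 1L, {
    ids <- sprintf("G%05d", seq_len(config@nGenes))
    nCausal <- round(config@causalFraction * config@nGenes)
    causal <- sort(sample(ids, nCausal))
    sgn <- sample(c(-1, 1), nCausal, replace = TRUE)
    zMean <- setNames(numeric(config@nGenes), ids)
    zMean[causal] <- sgn * config@twasEffect
    exprSgn <- sgn
    nDis <- round(config@discordantFraction * nCausal)
    if (nDis > 0L) {
      flip <- sample(nCausal, nDis)
      exprSgn[flip] <- -exprSgn[flip]
    }
    exprShift <- setNames(numeric(config@nGenes), ids)
    exprShift[causal] <- exprSgn * config@exprEffect
    new("SimulatedTruth", geneIds = ids, causalGenes = causal,
        zMean = zMean, exprShift = exprShift)
  })
}

#' Lay simulated genes on the genome
#'
#' Genes are placed 500 per chromosome at consecutive TSSs `locusGap` bp
#' apart, starting at 1 Mb. The layout is deterministic given the config.
#'
#' @param config a [SimulationConfig].
#' @return data.frame with `gene_id`, `chrom`, `tss` (1-based).
#' @export
simulateAnnotation <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  i <- seq_len(config@nGenes)
  perChrom <- 500L
  idx <- (i - 1L) %% perChrom
  data.frame(gene_id = sprintf("G%05d", i),
             chrom = paste0("chr", (i - 1L) %/% perChrom + 1L),
             tss = 1000000L + idx * config@locusGap,
             stringsAsFactors = FALSE)
}

#' Simulate per-tissue TWAS panels
#'
#' Per gene, the Z-scores across tissues follow an equicorrelated
#' multivariate normal with pairwise correlation `crossTissueCorr` and a
#' shared mean `zMean` from the truth (causal genes only). P-values are the
#' two-sided normal tail of the stored Z.
#'
#' @param config a [SimulationConfig].
#' @param truth a [SimulatedTruth] (default: drawn from the config).
#' @param annotation gene annotation (default: [simulateAnnotation()]).
#' @return Named list of [TwasPanel], one per tissue.
#' @export
simulateTwasPanels <- function(config, truth = simulateTruth(config),
                               annotation = simulateAnnotation(config)) {
  stopifnot(is(config, "SimulationConfig"), is(truth, "SimulatedTruth"))
  validObject(config)
  rho <- config@crossTissueCorr
  withSeed(config@seed + 2L, {
    nG <- config@nGenes
    nT <- config@nTissues
    shared <- rnorm(nG)                      # gene-level shared component
    eps <- matrix(rnorm(nG * nT), nG, nT)    # tissue-specific component
    z <- truth@zMean + sqrt(rho) * shared + sqrt(1 - rho) * eps
    tissues <- .tissueNames(nT)
    panels <- lapply(seq_len(nT), function(t) {
      TwasPanel(tissues[t],
                data.frame(gene_id = truth@geneIds,
                           zscore = z[, t],
                           pvalue = 2 * pnorm(-abs(z[, t])),
                           chrom = annotation$chrom,
                           tss = annotation$tss,
                           stringsAsFactors = FALSE))
    })
    names(panels) <- tissues
    panels
  })
}

#' Simulate the cohort: expression, phenotype, covariates and PRS
#'
#' Case/control counts are fixed by design (ascertained sampling, which the
#' liability-scale conversion later corrects for). Control expression is
#' iid standard normal per gene; case expression of causal genes is shifted
#' by the truth's signed `exprShift`. Covariates follow a sex-matched adult
#' cohort (sex ~ Bernoulli(0.57 male), age ~ Normal(36.6, 10.1) years, two
#' genotyping waves, 10 standard-normal genetic PCs), with case shifts from
#' `covariateEffects`. The PRS is standard normal, shifted by `prsEffect`
#' SD in cases, and independent of expression.
#'
#' @param config a [SimulationConfig].
#' @param truth a [SimulatedTruth].
#' @return A [TrsExperiment] (unstandardized expression).
#' @export
simulateCohort <- function(config, truth = simulateTruth(config)) {
  stopifnot(is(config, "SimulationConfig"), is(truth, "SimulatedTruth"))
  validObject(config)
  withSeed(config@seed + 3L, {
    n1 <- config@nCases; n0 <- config@nControls; n <- n1 + n0
    ph <- c(rep(1L, n1), rep(0L, n0))
    ids <- sprintf("S%04d", seq_len(n))
    expr <- matrix(rnorm(n * config@nGenes), n, config@nGenes,
                   dimnames = list(ids, truth@geneIds))
    expr[ph == 1L, ] <- expr[ph == 1L, ] +
      rep(truth@exprShift, each = n1)
    ce <- config@covariateEffects
    pMale <- plogis(qlogis(0.5725) + ce[["sex"]] * ph)
    sex <- ifelse(rbinom(n, 1L, pMale) == 1L, "male", "female")
    age <- rnorm(n, 36.6 + ce[["age"]] * ph, 10.1)
    pWave <- plogis(qlogis(163 / 491) + ce[["wave"]] * ph)
    wave <- ifelse(rbinom(n, 1L, pWave) == 1L, "wave1", "wave2")
    pcs <- matrix(rnorm(n * 10L), n, 10L,
                  dimnames = list(NULL, paste0("PC", 1:10)))
    prs <- rnorm(n) + config@prsEffect * ph
    cohort <- data.frame(sample_id = ids, phenotype = ph, sex = sex,
                         age = age, wave = wave, pcs, prs = prs,
                         stringsAsFactors = FALSE)
    TrsExperiment(expr, cohort)
  })
}

#' Simulate gene-level colocalization probabilities
#'
#' Causal genes draw their GLCP from a high-mean Beta(8, 2) (mean 0.8, 98%
#' mass at or above 0.5); non-causal genes from Beta(2, 8). One record per
#' gene and tissue; values lie in \[0, 1\] by construction.
#'
#' @param config a [SimulationConfig].
#' @param truth a [SimulatedTruth].
#' @return data.frame with `gene_id`, `tissue`, `glcp`.
#' @export
simulateColoc <- function(config, truth = simulateTruth(config)) {
  stopifnot(is(config, "SimulationConfig"), is(truth, "SimulatedTruth"))
  validObject(config)
  withSeed(config@seed + 4L, {
    tissues <- .tissueNames(config@nTissues)
    causal <- truth@geneIds %in% truth@causalGenes
    recs <- lapply(tissues, function(tt) {
      glcp <- numeric(length(truth@geneIds))
      glcp[causal] <- rbeta(sum(causal), 8, 2)
      glcp[!causal] <- rbeta(sum(!causal), 2, 8)
      data.frame(gene_id = truth@geneIds, tissue = tt, glcp = glcp,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
}

#' Generate (and optionally write) the full synthetic input bundle
#'
#' Draws truth, annotation, TWAS panels, cohort and colocalization from one
#' config. With `dir` set, writes `twas_<tissue>.tsv` per tissue,
#' `expression.tsv`, `cohort.tsv`, `coloc.tsv`, `annotation.bed`,
#' `truth.tsv` and the resolved `config.tsv`.
#'
#' @param config a [SimulationConfig].
#' @param dir optional output directory.
#' @return List with elements `config`, `truth`, `annotation`, `panels`,
#'   `experiment` (a [TrsExperiment]) and `coloc`.
#' @export
simulateBundle <- function(config = SimulationConfig(), dir = NULL) {
  truth <- simulateTruth(config)
  annotation <- simulateAnnotation(config)
  panels <- simulateTwasPanels(config, truth, annotation)
  experiment <- simulateCohort(config, truth)
  coloc <- simulateColoc(config, truth)
  bundle <- list(config = config, truth = truth, annotation = annotation,
                 panels = panels, experiment = experiment, coloc = coloc)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in panels)
      writeTwasTable(p, file.path(dir, paste0("twas_", tissue(p), ".tsv")))
    expr <- t(SummarizedExperiment::assay(experiment, "expr"))
    writeExpression(expr, file.path(dir, "expression.tsv"))
    cd <- as.data.frame(SummarizedExperiment::colData(experiment))
    writeCohort(data.frame(sample_id = rownames(cd), cd,
                           stringsAsFactors = FALSE),
                file.path(dir, "cohort.tsv"))
    writeColoc(coloc, file.path(dir, "coloc.tsv"))
    gr <- GenomicRanges::GRanges(annotation$chrom,
                                 IRanges::IRanges(annotation$tss, width = 1L),
                                 name = annotation$gene_id)
    rtracklayer::export(gr, file.path(dir, "annotation.bed"))
    .writeTsv(data.frame(gene_id = truth@geneIds, z_mean = truth@zMean,
                         expr_shift = truth@exprShift,
                         causal = truth@geneIds %in% truth@causalGenes),
              file.path(dir, "truth.tsv"))
    cfg <- data.frame(
      parameter = c("nGenes", "nTissues", "nCases", "nControls",
                    "causalFraction", "exprEffect", "twasEffect",
                    "crossTissueCorr", "covariateEffect_sex",
                    "covariateEffect_age", "covariateEffect_wave",
                    "prsEffect", "discordantFraction", "locusGap", "seed"),
      value = c(config@nGenes, config@nTissues, config@nCases,
                config@nControls, config@causalFraction, config@exprEffect,
                config@twasEffect, config@crossTissueCorr,
                config@covariateEffects, config@prsEffect,
                config@discordantFraction, config@locusGap, config@seed))
    .writeTsv(cfg, file.path(dir, "config.tsv"))
  }
  bundle
}
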