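# Shared simulation shorthand for the test suite.

# fully null bundle: no expression signal, no TWAS signal, no covariate or
# PRS shifts, independent tissues
nullConfig <- function(seed, nGenes = 80L, nTissues = 1L,
                       nCases = 50L, nControls = 50L) {
  SimulationConfig(nGenes = nGenes, nTissues = nTissues, nCases = nCases,
                   nControls = nControls, causalFraction = 0,
                   exprEffect = 0, twasEffect = 0, crossTissueCorr = 0,
                   covariateEffects = c(sex = 0, age = 0, wave = 0),
                   prsEffect = 0, seed = seed)
}

# the calibration conditions of the power analysis: 5% causal genes with a
# 0.3 SD expression shift, strong TWAS signal, 250 + 250 samples
signalConfig <- function(seed, nGenes = 500L, nTissues = 1L) {
  SimulationConfig(nGenes = nGenes, nTissues = nTissues, nCases = 250L,
                   nControls = 250L, causalFraction = 0.05,
                   exprEffect = 0.3, twasEffect = 6, crossTissueCorr = 0,
                   seed = seed)
}

# standardized experiment + first panel for a config
simPair <- function(cfg) {
  truth <- simulateTruth(cfg)
  panel <- simulateTwasPanels(cfg, truth)[[1L]]
  x <- suppressMessages(standardizeExpression(simulateCohort(cfg, truth)))
  list(truth = truth, panel = panel, x = x)
}
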