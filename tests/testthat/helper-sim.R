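# shared fixtures, built in code

# a small panel exercising all four categories
tinyPanel <- function() {
  rbind(
    geneSimParams("FIBA", "fibroblast", 0.95, 0.05, 0.3, 0.1,
                  exprMeanOn = 28, altFreq = 0.35),
    geneSimParams("FIBB", "fibroblast", 0.9, 0.1, 0.5, 0.15,
                  exprMeanOn = 27, altFreq = 0.35),
    geneSimParams("PLUA", "pluripotency", 0.05, 0.95, 0.6, 0.1,
                  exprMeanOn = 25, altFreq = 0.05),
    geneSimParams("PLUB", "pluripotency", 0.1, 0.9, 0.4, 0.2,
                  exprMeanOn = 24, altFreq = 0.05),
    geneSimParams("INTA", "intermediate", 0.1, 0.85, 0.35, 0.1,
                  exprMeanOn = 26, altFreq = 0.25,
                  amp2 = -0.6, mu2 = 0.8, sigma2 = 0.08),
    geneSimParams("CHRA", "chromatin", 0.35, 0.98, 0.12, 0.07,
                  exprMeanOn = 26, altFreq = 0.05))
}

tinySim <- function(seed = 1, ...) {
  simulateReprogramming(simConfig(genes = tinyPanel(), nFib = 6,
                                  nIntermediate = 30, nAlt = 6,
                                  nPluri = 6, qcFailFraction = 0,
                                  seed = seed, ...))
}

# ReprogramSet straight from a Ct matrix written as cells x genes rows
rsFromCt <- function(ct, group = NULL) {
  if (is.null(group)) group <- rep("unknown", ncol(ct))
  ReprogramSet(ct, annotations = data.frame(group = group))
}

# a processed default-scale dataset for grouping tests
processedSim <- function(seed = 1, ...) {
  sim <- simulateReprogramming(simConfig(seed = seed, ...))
  qc <- qcFilter(sim$experiment)
  rs <- computeTrajectory(normalizeToGapdh(qc$experiment))
  list(rs = rs, truth = sim$truth)
}
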