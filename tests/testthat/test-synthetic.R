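test_that("trueFrequency evaluates the Gaussian-CDF curve", {
  g <- geneSimParams("g", "pluripotency", baseline = 0.1, end = 0.9,
                     mu = 0.5, sigma = 0.1)
  expect_equal(trueFrequency(g, 0.5), 0.5)

  flat <- geneSimParams("g", "pluripotency", baseline = 0.2, end = 0.2,
                        mu = 0.3, sigma = 0.2)
  expect_equal(trueFrequency(flat, c(0, 0.37, 1)), rep(0.2, 3))

  full <- geneSimParams("g", "pluripotency", baseline = 0, end = 1,
                        mu = 0.5, sigma = 0.1)
  expect_equal(trueFrequency(full, 0.6), 0.8413447, tolerance = 1e-6)

  bad <- g
  bad$sigma <- -1
  expect_error(trueFrequency(bad, 0.5), "sigma")
})

test_that("gene parameters violating the unit-interval curve are rejected", {
  expect_error(geneSimParams("g", "pluripotency", baseline = 0.5,
                             end = 0.9, mu = 0.5, sigma = 0.1,
                             amp2 = 0.9, mu2 = 0.3, sigma2 = 0.05),
               "leaves")
  expect_error(simConfig(genes = tinyPanel()[0, ]), "empty gene list")
})

test_that("the generator is bit-identical under a fixed seed", {
  a <- tinySim(seed = 42)
  b <- tinySim(seed = 42)
  expect_identical(ctValues(a$experiment), ctValues(b$experiment))
  expect_identical(a$truth, b$truth)
  c <- tinySim(seed = 43)
  expect_false(identical(ctValues(a$experiment), ctValues(c$experiment)))
})

test_that("degenerate Bernoulli settings detect everything at one level", {
  panel <- geneSimParams("GX", "pluripotency", baseline = 1, end = 1,
                         mu = 0.5, sigma = 0.1, exprMeanOn = 25,
                         exprSd = 0)
  sim <- simulateReprogramming(simConfig(genes = panel, nFib = 5,
                                         nIntermediate = 20, nAlt = 0,
                                         nPluri = 5, qcFailFraction = 0,
                                         seed = 3))
  rs <- normalizeToGapdh(sim$experiment)
  expect_true(all(detectionCalls(rs)["GX", ]))
  expect_equal(unname(exprLevels(rs)["GX", ]), rep(25, ncol(rs)))
})

test_that("a vanishing sigma gives step-like detection", {
  panel <- geneSimParams("GX", "pluripotency", baseline = 0, end = 1,
                         mu = 0.5, sigma = 1e-9)
  sim <- simulateReprogramming(simConfig(genes = panel, nFib = 0,
                                         nIntermediate = 400, nAlt = 0,
                                         nPluri = 0, qcFailFraction = 0,
                                         seed = 4))
  det <- detectionCalls(sim$experiment)["GX", ]
  p <- sim$truth$cells$progression
  expect_true(all(det[p > 0.5]))
  expect_false(any(det[p < 0.5]))
})

test_that("empirical detection frequencies track the closed-form curve", {
  panel <- geneSimParams("GX", "pluripotency", baseline = 0.1, end = 0.9,
                         mu = 0.5, sigma = 0.1)
  sim <- simulateReprogramming(simConfig(genes = panel, nFib = 0,
                                         nIntermediate = 2000, nAlt = 0,
                                         nPluri = 0, qcFailFraction = 0,
                                         seed = 5))
  det <- detectionCalls(sim$experiment)["GX", ]
  p <- sim$truth$cells$progression
  mids <- seq(0.05, 0.95, by = 0.1)
  for (m in mids) {
    sel <- abs(p - m) <= 0.05
    f <- trueFrequency(panel, m)
    se <- sqrt(f * (1 - f) / sum(sel))
    expect_lt(abs(mean(det[sel]) - f), max(3 * se, 0.05))
  }
})

test_that("gene indicators are pairwise independent given progression", {
  panel <- tinyPanel()
  sim <- simulateReprogramming(simConfig(
    genes = panel, nFib = 0, nIntermediate = 2000, nAlt = 0, nPluri = 0,
    qcFailFraction = 0, seed = 6,
    progressionSampler = function(n) rep(0.5, n)))
  det <- t(detectionCalls(sim$experiment)[panel$gene, ])
  cc <- suppressWarnings(cor(det))
  offDiag <- cc[upper.tri(cc)]
  expect_true(all(abs(offDiag[!is.na(offDiag)]) < 0.08))
})

test_that("a co-regulated module breaks conditional independence", {
  mod <- list(genes = c("PLUA", "PLUB"), mu = 0.5, sigma = 0.1)
  sim <- simulateReprogramming(simConfig(
    genes = tinyPanel(), nFib = 0, nIntermediate = 2000, nAlt = 0,
    nPluri = 0, qcFailFraction = 0, seed = 7, coregModule = mod,
    progressionSampler = function(n) rep(0.5, n)))
  det <- t(detectionCalls(sim$experiment)[c("PLUA", "PLUB"), ])
  expect_gt(cor(det)[1, 2], 0.5)
})

test_that("injected QC failures follow the configured fraction", {
  sim <- simulateReprogramming(simConfig(genes = tinyPanel(), nFib = 0,
                                         nIntermediate = 500, nAlt = 0,
                                         nPluri = 0,
                                         qcFailFraction = 0.2, seed = 8))
  rejected <- qcFilter(sim$experiment)$rejected
  expect_gte(length(rejected), qbinom(0.005, 500, 0.2))
  expect_lte(length(rejected), qbinom(0.995, 500, 0.2))
  expect_setequal(rejected,
                  sim$truth$cells$cell_id[sim$truth$cells$qc_fail])
})

test_that("ground truth survives a JSON round trip", {
  sim <- tinySim(seed = 9)
  path <- tempfile(fileext = ".json")
  writeLatentTruth(sim$truth, path)
  back <- readLatentTruth(path)
  expect_equal(back$cells$progression, sim$truth$cells$progression)
  expect_equal(unname(back$probs), unname(sim$truth$probs))
})

test_that("a YAML config with the default panel reproduces a dataset", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("genes: default", "nFib: 3", "nIntermediate: 10",
               "nAlt: 2", "nPluri: 3", "qcFailFraction: 0",
               "seed: 11"), path)
  cfg <- readSimConfig(path)
  expect_s3_class(cfg, "SimConfig")
  expect_equal(nrow(cfg$genes), 47)
  expect_equal(sort(unique(cfg$genes$category)), sort(PANEL_CATEGORIES))
  sim <- simulateReprogramming(cfg)
  expect_equal(ncol(sim$experiment), 18)
  expect_equal(nrow(sim$experiment), 48)  # panel plus GAPDH
})
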