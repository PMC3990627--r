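# noise-free FrequencyCurve from a closed-form frequency function
curveFrom <- function(f, nBins = 16, width = 0.08, counts = 100) {
  centers <- seq(0, 1, length.out = nBins)
  new("FrequencyCurve", gene = "toy", centers = centers,
      counts = rep(counts, nBins), freqs = f(centers), width = width,
      nEff = 1 / width)
}

test_that("binned frequencies estimate the underlying curve", {
  set.seed(51)
  p <- runif(1000)
  f <- function(x) 0.1 + 0.8 * pnorm((x - 0.5) / 0.1)
  det <- rbinom(1000, 1, f(p))
  cv <- binFrequencies(det, p, gene = "GX")
  ok <- !is.na(cv@freqs)
  for (i in which(ok)) {
    se <- sqrt(max(f(cv@centers[i]) * (1 - f(cv@centers[i])), 0.01) /
                 cv@counts[i])
    expect_lt(abs(cv@freqs[i] - f(cv@centers[i])), max(3 * se, 0.06))
  }
  expect_equal(cv@nEff, 12.5)

  allOn <- binFrequencies(rep(TRUE, 50), runif(50))
  expect_true(all(allOn@freqs[!is.na(allOn@freqs)] == 1))

  one <- binFrequencies(det, p, binWidth = 1, nBins = 1)
  expect_equal(one@freqs, mean(det))
  expect_equal(one@counts, 1000)

  expect_error(binFrequencies(logical(0), numeric(0)), "empty")
  expect_message(binFrequencies(c(TRUE, FALSE), c(-0.2, 0.5)),
                 "clamped")
})

test_that("the uniform model anchors the trajectory endpoints", {
  lin <- curveFrom(function(x) 0.05 + 0.9 * x)
  u <- fitUniform(lin)
  expect_equal(u@mse, 0, tolerance = 1e-12)
  expect_equal(u@baseline, 0.05, tolerance = 1e-9)
  expect_equal(u@k, 2)

  const <- curveFrom(function(x) rep(0.4, length(x)))
  uc <- fitUniform(const)
  expect_equal(uc@baseline, 0.4)
  expect_equal(uc@amplitude, 0)
  expect_equal(uc@mse, 0)

  centers <- seq(0, 1, length.out = 20)
  step <- new("FrequencyCurve", gene = "s", centers = centers,
              counts = rep(60, 20),
              freqs = as.numeric(centers > 0.5), width = 0.05,
              nEff = 20)
  us <- fitUniform(step)
  oracle <- mean((0 + 1 * centers - as.numeric(centers > 0.5))^2)
  expect_equal(us@baseline, 0)
  expect_equal(us@baseline + us@amplitude, 1)
  expect_equal(us@mse, oracle, tolerance = 1e-10)
})

test_that("the Gaussian fit recovers noise-free parameters", {
  cv <- curveFrom(function(x) 0.1 + 0.8 * pnorm((x - 0.5) / 0.1))
  m <- fitGaussian(cv, 1)
  expect_equal(m@kind, "gauss1")
  expect_equal(m@k, 4)
  expect_lt(abs(m@mu - 0.5), 0.02)
  expect_lt(m@mse, 1e-4)

  const <- curveFrom(function(x) rep(0.35, length(x)))
  mc <- fitGaussian(const, 1)
  expect_lt(abs(mc@amplitude), 0.05)
  expect_lt(mc@mse, 1e-5)

  pulse <- curveFrom(function(x)
    0.05 + 0.85 * pnorm((x - 0.3) / 0.05) -
      0.8 * pnorm((x - 0.7) / 0.05))
  g1 <- fitGaussian(pulse, 1)
  g2 <- fitGaussian(pulse, 2)
  expect_lt(g2@mse, g1@mse)
  expect_equal(g2@k, 7)
  expect_equal(length(g2@mu), 2)
  expect_true(all(diff(g2@mu) > 0))   # components sorted
})

test_that("fits are nested within optimizer tolerance", {
  set.seed(52)
  for (i in 1:4) {
    p <- runif(600)
    f <- function(x) 0.1 + 0.7 * pnorm((x - runif(1, 0.3, 0.7)) / 0.15)
    cv <- binFrequencies(rbinom(600, 1, f(p)), p)
    g1 <- fitGaussian(cv, 1)
    g2 <- fitGaussian(cv, 2)
    ok <- !is.na(cv@freqs)
    constMse <- mean((cv@freqs[ok] - mean(cv@freqs[ok]))^2)
    expect_lte(g2@mse, g1@mse + 1e-6)
    expect_lte(g1@mse, constMse + 1e-6)
  }
})

test_that("a wide Gaussian component degenerates to a straight line", {
  m <- new("ActivationModel", gene = "g", kind = "gauss1",
           baseline = 0.2, amplitude = 0.6, mu = 0.5, sigma = 10,
           mse = 0, k = 4, aicc = NA_real_, fRejectRate = NA_real_)
  x <- seq(0, 1, length.out = 101)
  f <- predictFrequency(m, x)
  chord <- f[1] + (f[101] - f[1]) * x
  expect_lt(max(abs(f - chord)), 0.01)
})

test_that("AICc follows the corrected least-squares form", {
  expect_equal(aiccScore(30, 2, 0.01),
               30 * log(0.01) + 4 + 12 / 27, tolerance = 1e-12)
  expect_equal(aiccScore(30, 2, 0.01), -133.7105, tolerance = 1e-4)
  expect_gt(aiccScore(30, 4, 0.01), aiccScore(30, 2, 0.01))
  expect_equal(aiccScore(25, 3, 0.02) - aiccScore(25, 3, 0.04),
               -25 * log(2), tolerance = 1e-10)
  expect_error(aiccScore(5, 4, 0.01), "undefined")
  expect_error(aiccScore(30, 2, 0), "undefined")
})

test_that("model selection distinguishes the three dynamic classes", {
  set.seed(53)
  n <- 1000
  p <- runif(n)

  det <- rbinom(n, 1, 0.05 + 0.9 * pnorm((p - 0.5) / 0.08))
  cv <- binFrequencies(det, p)
  sel <- selectModel(list(fitUniform(cv), fitGaussian(cv, 1),
                          fitGaussian(cv, 2)))
  expect_equal(sel$chosen, "gauss1")
  expect_equal(nrow(sel$table), 3)
  expect_true(any(sel$table$delta_aicc == 0))

  det <- rbinom(n, 1, 0.02 + 0.96 * p)
  cv <- binFrequencies(det, p)
  u <- fitUniform(cv)
  g1 <- fitGaussian(cv, 1)
  expect_lte(u@aicc - g1@aicc, 2)     # uniform retained

  det <- rbinom(n, 1, 0.05 + 0.85 * pnorm((p - 0.3) / 0.08) -
                  0.8 * pnorm((p - 0.75) / 0.08))
  cv <- binFrequencies(det, p)
  sel <- selectModel(list(fitUniform(cv), fitGaussian(cv, 1),
                          fitGaussian(cv, 2)))
  expect_equal(sel$chosen, "gauss2")
})

test_that("activation windows are normal-quantile intervals, unclamped", {
  m <- new("ActivationModel", gene = "g", kind = "gauss1",
           baseline = 0.1, amplitude = 0.8, mu = 0.5, sigma = 0.1,
           mse = 0, k = 4, aicc = NA_real_, fRejectRate = NA_real_)
  w <- activationWindow(m)
  expect_equal(w$mean, 0.5)
  expect_equal(w$ci95, c(0.304, 0.696), tolerance = 1e-3)
  expect_equal(w$ci50, 0.5 + c(-1, 1) * qnorm(0.75) * 0.1)

  m@mu <- 0
  m@sigma <- 0.2
  expect_lt(activationWindow(m)$ci95[1], 0)  # no hidden clamping

  m@sigma <- 1e-9
  expect_equal(activationWindow(m)$ci95, c(0, 0), tolerance = 1e-6)

  mu <- new("ActivationModel", gene = "g", kind = "uniform",
            baseline = 0.1, amplitude = 0.5, mu = numeric(),
            sigma = numeric(), mse = 0, k = 2, aicc = NA_real_,
            fRejectRate = NA_real_)
  expect_error(activationWindow(mu), "one-component")
})

test_that("the bootstrap F-test rejects misfit and spares perfection", {
  set.seed(54)
  p <- runif(500)
  det <- rbinom(500, 1, as.numeric(p > 0.5))
  u <- fitUniform(binFrequencies(det, p))
  expect_gt(bootstrapFTest(u, det, p, nBins = 12, reps = 100), 0.95)

  allOn <- rep(TRUE, 300)
  pp <- runif(300)
  m <- fitUniform(binFrequencies(allOn, pp))
  expect_equal(bootstrapFTest(m, allOn, pp, nBins = 12, reps = 50), 0)

  expect_error(bootstrapFTest(u, det, p, reps = 0), "reps")
  expect_error(bootstrapFTest(u, det, p, nBins = 2), "exceed")
  expect_error(bootstrapFTest(u, det[1:3], p[1:3] * 0.01, nBins = 12),
               "empty")
})

test_that("fitActivationModels assembles per-gene summaries", {
  sim <- processedSim(seed = 55)
  genes <- c("NANOG", "THY1", "KRT8", "REST")
  fits <- suppressMessages(
    fitActivationModels(sim$rs, genes = genes, bootstrapReps = 20))
  expect_equal(fits$summary$gene, genes)
  expect_true(all(fits$summary$chosen %in% c("uniform", "gauss1",
                                             "gauss2")))
  expect_true(all(!is.na(fits$summary$f_reject_uniform)))
  # activating pluripotency marker: selected model rises overall
  nanog <- fits$models[["NANOG"]]$selection$model
  expect_gt(predictFrequency(nanog, 1), predictFrequency(nanog, 0))
  # inactivating fibroblast marker: falls
  thy1 <- fits$models[["THY1"]]$selection$model
  expect_lt(predictFrequency(thy1, 1), predictFrequency(thy1, 0))
  path <- tempfile(fileext = ".csv")
  writeCurveTable(fits, path)
  dumped <- read.csv(path)
  expect_setequal(unique(dumped$gene), genes)
  expect_equal(nrow(dumped), 4 * 16)
})
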