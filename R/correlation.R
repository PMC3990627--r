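#' Simulate one independence-null cell population
#'
#' Draws a population matching the observed progression distribution
#' (resampled with replacement) in which every gene is set detected or
#' undetected independently from its fitted frequency curve — the null in
#' which all co-expression arises solely from the shared progression
#' axis.
#'
#' @param progressions observed per-cell progression values.
#' @param models named list of fitted \linkS4class{ActivationModel}s, one
#'   per gene.
#' @param deconvolveWidth width of the frequency-curve bins the models
#'   were fitted to, or \code{NULL}. Binning smooths the training curve —
#'   a Gaussian-CDF component fitted to it carries
#'   \code{sigma^2 + width^2/12} — so cell-level simulation narrows each
#'   component back to the deconvolved spread.
#' @return integer cells x genes 0/1 matrix.
#' @export
simulateNullPopulation <- function(progressions, models,
                                   deconvolveWidth = NULL) {
  n <- length(progressions)
  if (!is.null(deconvolveWidth))
    models <- lapply(models, .deconvolveSigma, width = deconvolveWidth)
  p <- progressions[sample.int(n, n, replace = TRUE)]
  sim <- vapply(models, function(m)
    stats::rbinom(n, 1L, .clamp01(predictFrequency(m, p))), integer(n))
  colnames(sim) <- names(models)
  sim
}

.deconvolveSigma <- function(m, width) {
  if (m@kind != "uniform")
    m@sigma <- sqrt(pmax(m@sigma^2 - width^2 / 12, 1e-6))
  m
}

#' Mean gene-gene correlation under the independence null
#'
#' Averages, over repeated simulated populations, the pairwise Pearson
#' correlations of detection indicators. This is the background
#' correlation induced by genes converging on uniform expression at the
#' trajectory ends; pairs whose correlation is undefined in a run (a gene
#' constant in that population) are averaged over the runs where it is
#' defined.
#'
#' @inheritParams simulateNullPopulation
#' @param runs number of simulated populations.
#' @param seed optional RNG seed.
#' @return list with \code{mean} (genes x genes mean correlation),
#'   \code{atanhMean} and \code{atanhSd} (per-pair mean and SD of the
#'   Fisher-transformed per-run correlations — the empirical null
#'   sampling distribution used by \code{\link{correctedCorrelation}}),
#'   \code{runs}, and \code{se} (standard error of \code{mean}, a
#'   convergence report).
#' @export
nullCorrelation <- function(progressions, models, runs = 1000,
                            seed = NULL, deconvolveWidth = NULL) {
  if (runs < 1) stop("'runs' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(deconvolveWidth))
    models <- lapply(models, .deconvolveSigma, width = deconvolveWidth)
  ng <- length(models)
  acc <- acc2 <- za <- za2 <- nok <-
    matrix(0, ng, ng, dimnames = list(names(models), names(models)))
  for (r in seq_len(runs)) {
    cc <- suppressWarnings(stats::cor(simulateNullPopulation(
      progressions, models)))
    ok <- !is.na(cc)
    z <- atanh(.clampCor(cc))
    acc[ok] <- acc[ok] + cc[ok]
    acc2[ok] <- acc2[ok] + cc[ok]^2
    za[ok] <- za[ok] + z[ok]
    za2[ok] <- za2[ok] + z[ok]^2
    nok <- nok + ok
  }
  m <- acc / pmax(nok, 1)
  m[nok == 0] <- NA_real_
  v <- acc2 / pmax(nok, 1) - m^2
  zm <- za / pmax(nok, 1)
  zm[nok == 0] <- NA_real_
  zv <- za2 / pmax(nok, 1) - zm^2
  list(mean = m, atanhMean = zm,
       atanhSd = sqrt(pmax(zv, 0) * runs / pmax(runs - 1, 1)),
       runs = runs, se = sqrt(pmax(v, 0) / pmax(nok, 1)))
}

.clampCor <- function(r) {               # keep matrix shape intact
  r[r > 1 - 1e-12] <- 1 - 1e-12
  r[r < -1 + 1e-12] <- -1 + 1e-12
  r
}

#' Background-corrected correlations with significance calls
#'
#' Subtracts the independence-null mean correlation from the observed
#' correlation and tests each pair on the Fisher (atanh) scale. With the
#' default \code{nullVariance = "empirical"} the z statistic standardizes
#' the observed transformed correlation against the per-pair mean and SD
#' of the transformed correlations across the null simulation runs —
#' i.e. the null's own Monte-Carlo sampling distribution, which remains
#' calibrated for detection indicators whose sampling variance departs
#' from bivariate-normal theory. \code{"averaged"} uses the analytic
#' variance \code{1/(n_obs-3) + 1/((n_null-3) runs)};
#' \code{"paper"} reproduces the classical two-correlation comparison
#' (\code{1/(n_obs-3) + 1/(n_null-3)}), which ignores the averaging over
#' runs and is conservative.
#'
#' @param observed observed correlation matrix (detection indicators).
#' @param nullMean mean null correlation matrix (same gene order).
#' @param nObs number of analyzed cells.
#' @param nNull simulated population size (defaults to \code{nObs}).
#' @param runs number of null runs averaged into \code{nullMean}.
#' @param alpha significance level.
#' @param mtc multiplicity control across pairs: Benjamini-Hochberg or
#'   none.
#' @param nullVariance variance convention for the z denominator (see
#'   above).
#' @param nullAtanhMean,nullAtanhSd per-pair mean and SD of the
#'   Fisher-transformed null correlations (from
#'   \code{\link{nullCorrelation}}); required for
#'   \code{nullVariance = "empirical"}.
#' @return a \linkS4class{CorrelationResult}.
#' @export
correctedCorrelation <- function(observed, nullMean, nObs, nNull = nObs,
                                 runs = 1, alpha = 0.05,
                                 mtc = c("BH", "none"),
                                 nullVariance = c("empirical",
                                                  "averaged", "paper"),
                                 nullAtanhMean = NULL,
                                 nullAtanhSd = NULL) {
  mtc <- match.arg(mtc)
  nullVariance <- match.arg(nullVariance)
  stopifnot(identical(dim(observed), dim(nullMean)))
  genes <- rownames(observed)
  if (nullVariance == "empirical" &&
      (is.null(nullAtanhMean) || is.null(nullAtanhSd))) {
    if (runs > 1)
      stop("nullVariance = \"empirical\" needs nullAtanhMean/nullAtanhSd")
    nullVariance <- "averaged"
  }
  z <- if (nullVariance == "empirical") {
    (atanh(.clampCor(observed)) - nullAtanhMean) /
      pmax(nullAtanhSd * sqrt(1 + 1 / runs), 1e-8)
  } else {
    vNull <- switch(nullVariance,
                    averaged = 1 / ((nNull - 3) * runs),
                    paper = 1 / (nNull - 3))
    (atanh(.clampCor(observed)) - atanh(.clampCor(nullMean))) /
      sqrt(1 / (nObs - 3) + vNull)
  }
  p <- 2 * stats::pnorm(-abs(z))
  diag(p) <- NA_real_
  q <- p
  ut <- upper.tri(p)
  q[ut] <- stats::p.adjust(p[ut], method = if (mtc == "BH") "BH" else
    "none")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  sig <- q < alpha
  sig[is.na(sig)] <- FALSE
  new("CorrelationResult", genes = genes, observed = observed,
      nullMean = nullMean, corrected = observed - nullMean, z = z, p = p,
      q = q, significant = sig, alpha = alpha, nObs = nObs,
      runs = runs)
}

#' Full gene-gene correlation analysis against the independence null
#'
#' Computes observed Pearson correlations of detection indicators over
#' the analyzed cells, simulates the matched independence null from each
#' gene's fitted one-component model, and returns background-corrected
#' correlations with significance calls. Genes detected in fewer than
#' \code{lowDetect} of the analyzed cells (or detected in all of them,
#' leaving no variance) are excluded with a warning, as are genes without
#' a fitted model.
#'
#' @param x a \linkS4class{ReprogramSet} after
#'   \code{\link{computeTrajectory}}.
#' @param fits result of \code{\link{fitActivationModels}} (its
#'   \code{gauss1} fits drive the null).
#' @param cells logical vector or cell ids selecting the analyzed cells
#'   (default: non-outlier cells).
#' @param useModel which fit drives each gene's null curve:
#'   \code{"gauss2"} (default) uses the two-component fit, the most
#'   flexible marginal representation (it nests the one-component
#'   curve, which matters because the null's job is marginal fidelity);
#'   \code{"selected"} uses the AICc-selected model; \code{"gauss1"}
#'   forces the one-component model.
#' @param lowDetect exclusion threshold on detection frequency.
#' @param runs null simulation runs.
#' @param alpha significance level.
#' @param seed RNG seed for the null simulation.
#' @param mtc,nullVariance passed to \code{\link{correctedCorrelation}}.
#' @return a \linkS4class{CorrelationResult}.
#' @export
correlationAnalysis <- function(x, fits, cells = NULL,
                                useModel = c("gauss2", "selected",
                                             "gauss1"),
                                lowDetect = 0.05, runs = 1000,
                                alpha = 0.05, seed = NULL, mtc = "BH",
                                nullVariance = "empirical") {
  useModel <- match.arg(useModel)
  cd <- colData(x)
  if (is.null(cells)) cells <- !cd$outlier
  if (is.character(cells)) cells <- colnames(x) %in% cells
  det <- binarizeDetection(x)[cells, , drop = FALSE]
  prog <- .clampProgression(cd$progression[cells], quiet = TRUE)
  freq <- colMeans(det)
  genes <- intersect(colnames(det), names(fits$models))
  low <- genes[freq[genes] < lowDetect | freq[genes] > 1 - 1e-9]
  if (length(low))
    warning("excluded for low (or saturated) detection frequency: ",
            paste(low, collapse = ", "))
  genes <- setdiff(genes, low)
  if (length(genes) < 2L) stop("fewer than 2 analyzable genes")
  models <- switch(useModel,
    selected = lapply(fits$models[genes],
                      function(m) m$selection$model),
    gauss2 = lapply(fits$models[genes], `[[`, "gauss2"),
    gauss1 = lapply(fits$models[genes], `[[`, "gauss1"))
  observed <- stats::cor(det[, genes, drop = FALSE])
  nullRes <- nullCorrelation(prog, models, runs = runs, seed = seed,
                             deconvolveWidth = fits$binWidth)
  correctedCorrelation(observed, nullRes$mean, nObs = sum(cells),
                       nNull = sum(cells), runs = runs, alpha = alpha,
                       mtc = mtc, nullVariance = nullVariance,
                       nullAtanhMean = nullRes$atanhMean,
                       nullAtanhSd = nullRes$atanhSd)
}
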