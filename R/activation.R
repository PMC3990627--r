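#' Detection-frequency curve along the progression axis
#'
#' Places \code{nBins} overlapping bins of fixed width with centers evenly
#' spaced over \code{[0, 1]} and counts, per bin, the fraction of cells in
#' which the gene is detected — the training data for the activation
#' models. Progression values are clamped into \code{[0, 1]} (clamped
#' count is messaged); empty bins carry \code{NA} frequency and are
#' skipped when fitting. The curve's effective number of independent
#' sample points is the axis range over the bin width (overlapping bins
#' share cells and are not independent).
#'
#' @param detected logical (or 0/1) detection vector, one entry per cell.
#' @param progression per-cell progression values.
#' @param binWidth bin width in progression units.
#' @param nBins number of bin centers (a single bin is centered at 0.5).
#' @param gene gene identifier carried along for reporting.
#' @return a \linkS4class{FrequencyCurve}.
#' @export
binFrequencies <- function(detected, progression, binWidth = 0.08,
                           nBins = 16, gene = "gene") {
  stopifnot(length(detected) == length(progression))
  .assertScalar(binWidth, "binWidth", lo = 1e-6)
  detected <- as.logical(detected)
  p <- .clampProgression(progression)
  half <- binWidth / 2
  centers <- if (nBins == 1L) 0.5 else seq(0, 1, length.out = nBins)
  counts <- freqs <- numeric(nBins)
  for (i in seq_len(nBins)) {
    sel <- p >= centers[i] - half & p <= centers[i] + half
    counts[i] <- sum(sel)
    freqs[i] <- if (counts[i] > 0) mean(detected[sel]) else NA_real_
  }
  if (all(counts == 0)) stop("all bins empty")
  new("FrequencyCurve", gene = gene, centers = centers, counts = counts,
      freqs = freqs, width = binWidth, nEff = 1 / binWidth)
}

#' Predicted detection frequency of a fitted model
#'
#' @param model an \linkS4class{ActivationModel}.
#' @param x progression values.
#' @return predicted frequencies (not clamped; feasible fits stay inside
#'   \code{[0, 1]} by construction).
#' @export
predictFrequency <- function(model, x) {
  stopifnot(is(model, "ActivationModel"))
  if (model@kind == "uniform") {
    model@baseline + model@amplitude * x
  } else {
    f <- rep(model@baseline, length(x))
    for (i in seq_along(model@mu))
      f <- f + model@amplitude[i] *
        stats::pnorm((x - model@mu[i]) / model@sigma[i])
    f
  }
}

#' Corrected Akaike score for a least-squares fit
#'
#' Small-sample AIC in its least-squares form,
#' \deqn{AICc = n\,\ln(MSE) + 2k + \frac{2k(k+1)}{n - k - 1},}
#' with \code{n} the effective number of independent sample points of the
#' training curve.
#'
#' @param nEff effective sample size (must exceed \code{k + 1}).
#' @param k number of free model parameters.
#' @param mse mean squared error of the model against the training curve
#'   (must be positive).
#' @return the AICc score (lower is better).
#' @examples
#' aiccScore(30, 2, 0.01)  # 30*log(0.01) + 4 + 12/27
#' @export
aiccScore <- function(nEff, k, mse) {
  if (nEff <= k + 1)
    stop("undefined AICc: effective sample size (", format(nEff),
         ") must exceed k + 1 = ", k + 1)
  if (!is.numeric(mse) || mse <= 0)
    stop("undefined AICc: mse must be > 0")
  nEff * log(mse) + 2 * k + 2 * k * (k + 1) / (nEff - k - 1)
}

.safeAicc <- function(nEff, k, mse) {
  tryCatch(aiccScore(nEff, k, max(mse, 1e-12)),
           error = function(e) NA_real_)
}

# anchor estimates at progression 0 and 1: count-weighted local-linear
# extrapolation over the non-empty bins in the end's half of the axis
# (exact for linear, step and constant curves; a single half-covered edge
# bin alone would be too noisy an estimate of the endpoint frequency)
.anchorAt <- function(curve, ok, at, window = 0.5) {
  sel <- ok[abs(curve@centers[ok] - at) <= window]
  if (length(sel) >= 2L) {
    fit <- stats::lm(f ~ x, data = data.frame(f = curve@freqs[sel],
                                              x = curve@centers[sel]),
                     weights = curve@counts[sel])
    .clamp01(unname(stats::predict(fit, data.frame(x = at))))
  } else {
    near <- ok[which.min(abs(curve@centers[ok] - at))]
    if (abs(curve@centers[near] - at) > 0.2)
      warning("anchor estimation for '", curve@gene,
              "': nearest non-empty bin is > 0.2 from a trajectory ",
              "end; using nearest available")
    curve@freqs[near]
  }
}

.curveAnchors <- function(curve) {
  ok <- which(!is.na(curve@freqs))
  if (!length(ok)) stop("curve has no non-empty bins")
  list(ok = ok, start = .anchorAt(curve, ok, 0),
       end = .anchorAt(curve, ok, 1))
}

#' Fit the uniform (null) activation model
#'
#' The null hypothesis of random gradual change: a baseline detection
#' frequency at the start of the trajectory and a straight line to the
#' value at the end, with no preferred activation point. Each anchor is
#' the value at its trajectory end of a count-weighted linear fit through
#' the non-empty bins in that end's half of the axis (clamped to
#' \code{[0, 1]}), which reproduces the endpoint exactly for linear, step
#' and constant curves while averaging away single-bin noise.
#'
#' @param curve a \linkS4class{FrequencyCurve}.
#' @return an \linkS4class{ActivationModel} of kind \code{"uniform"}
#'   (k = 2).
#' @export
fitUniform <- function(curve) {
  a <- .curveAnchors(curve)
  pred <- a$start + (a$end - a$start) * curve@centers[a$ok]
  mse <- mean((pred - curve@freqs[a$ok])^2)
  new("ActivationModel", gene = curve@gene, kind = "uniform",
      baseline = a$start, amplitude = a$end - a$start, mu = numeric(),
      sigma = numeric(), mse = mse, k = 2,
      aicc = .safeAicc(curve@nEff, 2, mse), fRejectRate = NA_real_)
}

# penalized objective: mse over non-empty bins + quadratic penalties
# keeping the predicted curve in [0,1], amplitudes in [-1,1] and sigma in
# a sane range. par = (baseline, amps, mus, log sigmas)
.gaussObjective <- function(par, nc, centers, freqs, grid) {
  b <- par[1]
  a <- par[2:(1 + nc)]
  m <- par[(2 + nc):(1 + 2 * nc)]
  s <- exp(par[(2 + 2 * nc):(1 + 3 * nc)])
  predAt <- function(x) {
    f <- rep(b, length(x))
    for (i in seq_len(nc)) f <- f + a[i] * stats::pnorm((x - m[i]) / s[i])
    f
  }
  mse <- mean((predAt(centers) - freqs)^2)
  fg <- predAt(grid)
  pen <- 100 * mean(pmax(0, fg - 1)^2 + pmax(0, -fg)^2) +
    100 * sum(pmax(0, abs(a) - 1)^2) +
    100 * (pmax(0, -b)^2 + pmax(0, b - 1)^2) +
    10 * sum(pmax(0, m - 1.5)^2 + pmax(0, -0.5 - m)^2) +
    10 * sum(pmax(0, par[(2 + 2 * nc):(1 + 3 * nc)] - log(10))^2 +
               pmax(0, log(0.005) - par[(2 + 2 * nc):(1 + 3 * nc)])^2)
  mse + pen
}

#' Fit a Gaussian cumulative activation model
#'
#' Models ordered probabilistic expression change: detection frequency is
#' a baseline plus one or two Gaussian-CDF components,
#' \code{f(x) = baseline + sum_i a_i pnorm((x - mu_i)/sigma_i)}, each
#' component a sigmoidal activation (positive amplitude) or inactivation
#' (negative) centered at its \code{mu}. Fitted by Nelder-Mead
#' minimization of the mean squared error over non-empty bins, with a
#' quadratic penalty holding the curve inside \code{[0, 1]} on a dense
#' grid; multiple deterministic starts (a \code{mu} x \code{sigma} grid,
#' a gradient-located start, a flat start, and — for two components — the
#' one-component solution with a silent second component, which makes the
#' fits numerically nested).
#'
#' @param curve a \linkS4class{FrequencyCurve}.
#' @param nComponents 1 or 2.
#' @param reltol,maxit Nelder-Mead convergence tolerance and evaluation
#'   cap per start.
#' @param seedModel optional already-fitted one-component model for the
#'   same curve, used to seed the two-component nesting start (avoids
#'   refitting it internally).
#' @return an \linkS4class{ActivationModel} of kind \code{"gauss1"}
#'   (k = 4) or \code{"gauss2"} (k = 7), components sorted by \code{mu}.
#' @export
fitGaussian <- function(curve, nComponents = 1, reltol = 1e-8,
                        maxit = 5000, seedModel = NULL) {
  stopifnot(nComponents %in% 1:2)
  nc <- as.integer(nComponents)
  a <- .curveAnchors(curve)
  centers <- curve@centers[a$ok]
  freqs <- curve@freqs[a$ok]
  if (length(centers) < 3L)
    stop("curve degenerate: fewer than 3 non-empty bins")
  grid <- seq(0, 1, length.out = 101)
  b0 <- a$start
  starts <- list()
  muGrid <- c(0.25, 0.5, 0.75)
  sigGrid <- c(0.05, 0.15, 0.4)
  iMax <- which.max(abs(diff(freqs)))
  muData <- mean(centers[c(iMax, iMax + 1)])
  if (nc == 1L) {
    amp0 <- a$end - b0
    for (m in c(muGrid, muData)) for (s in sigGrid)
      starts[[length(starts) + 1L]] <- c(b0, amp0, m, log(s))
    starts[[length(starts) + 1L]] <- c(mean(freqs), 0, 0.5, log(0.15))
  } else {
    fMax <- max(freqs)
    fMin <- min(freqs)
    peak <- if (abs(fMax - b0) >= abs(fMin - b0)) fMax else fMin
    amp1 <- peak - b0
    amp2 <- a$end - peak
    for (mm in list(c(0.25, 0.5), c(0.25, 0.75), c(0.5, 0.75)))
      for (s in sigGrid)
        starts[[length(starts) + 1L]] <-
          c(b0, amp1, amp2, mm[1], mm[2], log(s), log(s))
    g1 <- if (!is.null(seedModel) && seedModel@kind == "gauss1")
      seedModel
    else
      fitGaussian(curve, 1, reltol = reltol, maxit = maxit)
    starts[[length(starts) + 1L]] <-
      c(g1@baseline, g1@amplitude, 0, g1@mu, 0.5, log(g1@sigma),
        log(0.15))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, .gaussObjective, nc = nc, centers = centers,
                   freqs = freqs, grid = grid, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("optimizer failed on every start for gene '", curve@gene, "'")
  par <- best$par
  amp <- par[2:(1 + nc)]
  mu <- par[(2 + nc):(1 + 2 * nc)]
  sigma <- exp(par[(2 + 2 * nc):(1 + 3 * nc)])
  ord <- order(mu)
  model <- new("ActivationModel", gene = curve@gene,
               kind = paste0("gauss", nc), baseline = par[1],
               amplitude = pmin(1, pmax(-1, amp[ord])), mu = mu[ord],
               sigma = sigma[ord], mse = 0, k = 1 + 3 * nc,
               aicc = NA_real_, fRejectRate = NA_real_)
  mse <- mean((predictFrequency(model, centers) - freqs)^2)
  model@mse <- mse
  model@aicc <- .safeAicc(curve@nEff, model@k, mse)
  model
}

#' Bootstrap lack-of-fit F-test
#'
#' Repeatedly resamples the training cells within a small number of
#' non-overlapping progression bins and asks, per replicate, whether the
#' systematic deviation of the resampled bin frequencies from the model
#' prediction (lack of fit) exceeds the replicate binomial variation
#' (pure error) at level \code{alpha}; the fraction of rejecting
#' replicates is the model's rejection rate.
#'
#' A resampled bin frequency fluctuates about the prediction of a model
#' fitted to the same cells with roughly \code{(2 nBins - k)} variance
#' units — one per bin from resampling, one per residual degree of
#' freedom from the original sampling, plus their cross term — so the
#' lack-of-fit sum of squares is referred to its Satterthwaite-matched
#' scale and degrees of freedom,
#' \code{df1 = 2 (2 nBins - k)^2 / (2 nBins + 6 (nBins - k))}, rather
#' than the naive \code{nBins - k}; with this accounting a true model is
#' rejected in approximately \code{alpha} of independent replicates.
#'
#' @param model a fitted \linkS4class{ActivationModel}.
#' @param detected logical detection vector, one entry per training cell.
#' @param progression per-cell progression values.
#' @param nBins number of non-overlapping resampling bins (must exceed
#'   the model's parameter count).
#' @param reps number of bootstrap replicates.
#' @param alpha test level.
#' @param resampleCount cells drawn per bin (default: the bin's own
#'   count).
#' @return fraction of replicates rejecting the model.
#' @export
bootstrapFTest <- function(model, detected, progression, nBins = 12,
                           reps = 200, alpha = 0.05,
                           resampleCount = NULL) {
  if (reps < 1) stop("'reps' must be >= 1")
  if (nBins <= model@k)
    stop("'nBins' (", nBins, ") must exceed the parameter count k = ",
         model@k)
  detected <- as.logical(detected)
  p <- .clampProgression(progression, quiet = TRUE)
  edges <- seq(0, 1, length.out = nBins + 1)
  bin <- findInterval(p, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  members <- split(seq_along(p), factor(bin, levels = seq_len(nBins)))
  counts <- lengths(members)
  centers <- (edges[-1] + edges[-(nBins + 1)]) / 2
  if (any(counts == 0)) {
    # the estimated progression axis can leave gaps; drop empty bins
    keep <- counts > 0
    if (sum(keep) <= model@k + 1)
      stop("empty resampling bin(s): only ", sum(keep),
           " populated bins for k = ", model@k)
    warning(sum(!keep), " empty resampling bin(s) dropped for '",
            model@gene, "'")
    members <- members[keep]
    counts <- counts[keep]
    centers <- centers[keep]
    nBins <- sum(keep)
  }
  draw <- if (is.null(resampleCount)) counts else rep(resampleCount,
                                                      nBins)
  pred <- .clamp01(predictFrequency(model, centers))
  # E[SS_lof / sigma^2] under H0: one unit per bin from resampling plus
  # the residual of the original fit; a k-parameter model fitted to the
  # overlapping-bin curve absorbs ~0.7 k units at this coarser bin scale
  kEff <- 0.7 * model@k
  scale <- 2 * nBins - kEff
  df1 <- 2 * scale^2 / (2 * nBins + 6 * (nBins - kEff))
  df2 <- sum(draw - 1)
  fcrit <- stats::qf(1 - alpha, df1, df2)
  reject <- vapply(seq_len(reps), function(r) {
    ssLof <- ssPe <- 0
    for (i in seq_len(nBins)) {
      x <- detected[sample(members[[i]], draw[i], replace = TRUE)]
      f <- mean(x)
      ssLof <- ssLof + draw[i] * (f - pred[i])^2
      ssPe <- ssPe + draw[i] * f * (1 - f)
    }
    if (ssPe <= 0) return(ssLof > 1e-12)
    (ssLof / scale) / (ssPe / df2) > fcrit
  }, logical(1))
  mean(reject)
}

#' Select among the fitted activation models
#'
#' Chooses the minimum-AICc model per gene and tabulates the AICc
#' differences (models with undefined AICc are not selectable).
#'
#' @param models list of \linkS4class{ActivationModel}s for one gene
#'   (typically uniform, gauss1, gauss2).
#' @return list with \code{chosen} (kind), \code{model} (the winning
#'   object) and \code{table} (data.frame kind, k, mse, aicc,
#'   delta_aicc).
#' @export
selectModel <- function(models) {
  kinds <- vapply(models, slot, character(1), "kind")
  aicc <- vapply(models, slot, numeric(1), "aicc")
  tab <- data.frame(kind = kinds,
                    k = vapply(models, slot, numeric(1), "k"),
                    mse = vapply(models, slot, numeric(1), "mse"),
                    aicc = aicc, delta_aicc = aicc - min(aicc, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  win <- which.min(aicc)
  list(chosen = kinds[win], model = models[[win]], table = tab)
}

#' Activation window of a one-component model
#'
#' Summarizes where along the trajectory a gene changes state: the fitted
#' Gaussian's mean plus its central 50\% and 95\% intervals
#' (\code{mu +/- 0.6745 sigma} and \code{mu +/- 1.96 sigma}). Raw values
#' are returned without truncation at the trajectory bounds.
#'
#' @param model an \linkS4class{ActivationModel} of kind \code{"gauss1"}.
#' @return list with \code{mean}, \code{ci50}, \code{ci95}.
#' @export
activationWindow <- function(model) {
  if (model@kind != "gauss1")
    stop("activation windows are defined for one-component models only")
  q50 <- stats::qnorm(0.75)
  q95 <- stats::qnorm(0.975)
  list(mean = model@mu,
       ci50 = c(model@mu - q50 * model@sigma,
                model@mu + q50 * model@sigma),
       ci95 = c(model@mu - q95 * model@sigma,
                model@mu + q95 * model@sigma))
}

#' Fit and select activation models for every gene
#'
#' Runs the full per-gene model pipeline on the analyzed cells: binned
#' frequency curve, uniform / one-Gaussian / two-Gaussian fits, AICc
#' selection, and (optionally) bootstrap lack-of-fit F-tests for the
#' uniform and one-component models.
#'
#' @param x a \linkS4class{ReprogramSet} after
#'   \code{\link{computeTrajectory}}.
#' @param cells logical vector (or cell ids) selecting the training cells
#'   (default: all non-outlier cells).
#' @param genes gene subset (default: all non-normalizer genes).
#' @param binWidth,nBins curve binning parameters.
#' @param bootstrapReps replicates for \code{\link{bootstrapFTest}}
#'   (0 skips the test).
#' @param bootstrapBins resampling bins for the F-test.
#' @param alpha F-test level.
#' @return list with \code{summary} (per-gene data.frame), \code{models}
#'   (per-gene list of the three fits plus the selection), \code{curves}
#'   (per-gene \linkS4class{FrequencyCurve}).
#' @export
fitActivationModels <- function(x, cells = NULL, genes = NULL,
                                binWidth = 0.08, nBins = 16,
                                bootstrapReps = 0, bootstrapBins = 12,
                                alpha = 0.05) {
  cd <- colData(x)
  if (!"progression" %in% colnames(cd))
    stop("run computeTrajectory() first")
  if (is.null(cells)) cells <- !cd$outlier
  if (is.character(cells)) cells <- colnames(x) %in% cells
  det <- detectionCalls(x)[, cells, drop = FALSE]
  prog <- .clampProgression(cd$progression[cells])
  if (is.null(genes))
    genes <- rownames(x)[!rowData(x)$normalizer]
  models <- curves <- stats::setNames(vector("list", length(genes)),
                                      genes)
  rows <- list()
  for (g in genes) {
    curve <- binFrequencies(det[g, ], prog, binWidth = binWidth,
                            nBins = nBins, gene = g)
    u <- fitUniform(curve)
    g1 <- fitGaussian(curve, 1)
    g2 <- fitGaussian(curve, 2, seedModel = g1)
    if (bootstrapReps > 0) {
      u@fRejectRate <- bootstrapFTest(u, det[g, ], prog,
                                      nBins = bootstrapBins,
                                      reps = bootstrapReps,
                                      alpha = alpha)
      g1@fRejectRate <- bootstrapFTest(g1, det[g, ], prog,
                                       nBins = bootstrapBins,
                                       reps = bootstrapReps,
                                       alpha = alpha)
    }
    sel <- selectModel(list(u, g1, g2))
    win <- activationWindow(g1)
    rows[[g]] <- data.frame(
      gene = g, chosen = sel$chosen, baseline_g1 = g1@baseline,
      amplitude_g1 = g1@amplitude, mu_g1 = g1@mu, sigma_g1 = g1@sigma,
      ci50_lo = win$ci50[1], ci50_hi = win$ci50[2],
      ci95_lo = win$ci95[1], ci95_hi = win$ci95[2],
      mse_uniform = u@mse, mse_gauss1 = g1@mse, mse_gauss2 = g2@mse,
      aicc_uniform = u@aicc, aicc_gauss1 = g1@aicc,
      aicc_gauss2 = g2@aicc,
      f_reject_uniform = u@fRejectRate, f_reject_gauss1 = g1@fRejectRate,
      stringsAsFactors = FALSE)
    models[[g]] <- list(uniform = u, gauss1 = g1, gauss2 = g2,
                        selection = sel)
    curves[[g]] <- curve
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       models = models, curves = curves, binWidth = binWidth)
}

#' Export observed and predicted frequency curves
#'
#' @param fits result of \code{\link{fitActivationModels}}.
#' @param path output CSV path.
#' @return the path, invisibly; columns gene, bin_center, bin_count,
#'   observed_freq, predicted_freq (selected model).
#' @export
writeCurveTable <- function(fits, path) {
  out <- do.call(rbind, lapply(names(fits$curves), function(g) {
    cv <- fits$curves[[g]]
    m <- fits$models[[g]]$selection$model
    data.frame(gene = g, bin_center = cv@centers, bin_count = cv@counts,
               observed_freq = cv@freqs,
               predicted_freq = predictFrequency(m, cv@centers),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
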