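#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' Gene panel categories
#'
#' The four marker classes of the 48-gene qPCR panel, plus the housekeeping
#' normalizer. Fibroblast-associated genes are expressed in the starting
#' MRC-5 state, pluripotency-associated genes in the hESC end state,
#' intermediate markers transiently along the way, and chromatin modifiers
#' mark entry into the productive trajectory.
#'
#' @export
PANEL_CATEGORIES <- c("fibroblast", "pluripotency", "intermediate",
                      "chromatin")

#' Ct value encoding "undetected"
#'
#' qPCR cycle-threshold ceiling: a transcript with Ct equal to this value is
#' called undetected; detection means Ct strictly below it.
#'
#' @export
CT_UNDETECTED <- 40

#' Container for single-cell qPCR profiles
#'
#' Extends \linkS4class{SummarizedExperiment} with genes as rows and cells
#' as columns. Mandatory assays are \code{ct} (cycle thresholds in
#' \code{(0, 40]}, 40 = undetected) and \code{detected} (logical,
#' \code{ct < 40}). After \code{\link{normalizeToGapdh}} a \code{level}
#' assay holds the inverted normalized expression \code{40 - (Ct -
#' Ct_GAPDH)}, defined only where detected. \code{rowData} carries the
#' panel \code{category} and a logical \code{normalizer} flag (exactly one
#' gene, GAPDH); \code{colData} carries cell annotations (\code{group},
#' \code{day}, \code{facs}) and, after \code{\link{computeTrajectory}}, the
#' per-cell trajectory coordinates.
#'
#' @seealso \code{\link{ReprogramSet}} (constructor),
#'   \code{\link{loadCtTable}}, \code{\link{simulateReprogramming}}
#' @export
setClass("ReprogramSet", contains = "SummarizedExperiment")

setValidity("ReprogramSet", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!all(c("ct", "detected") %in% an))
    msg <- c(msg, "assays 'ct' and 'detected' are required")
  else {
    ct <- assay(object, "ct")
    det <- assay(object, "detected")
    if (any(ct <= 0 | ct > CT_UNDETECTED, na.rm = TRUE))
      msg <- c(msg, "ct values must lie in (0, 40]")
    if (!identical(dim(ct), dim(det)) ||
        !isTRUE(all(det == (ct < CT_UNDETECTED), na.rm = TRUE)))
      msg <- c(msg, "'detected' must equal ct < 40")
  }
  rd <- rowData(object)
  if (!all(c("category", "normalizer") %in% colnames(rd)))
    msg <- c(msg, "rowData needs 'category' and 'normalizer' columns")
  else {
    if (sum(rd$normalizer) != 1L)
      msg <- c(msg, "exactly one normalizer gene (GAPDH) is required")
    bad <- setdiff(unique(rd$category),
                   c(PANEL_CATEGORIES, "normalizer", "unknown"))
    if (length(bad))
      msg <- c(msg, paste0("unknown gene categories: ",
                           paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Detection-frequency curve for one gene
#'
#' Detection fractions in overlapping bins placed uniformly along the
#' reprogramming progression axis. \code{freqs} is \code{NA} for empty
#' bins; \code{nEff} is the effective number of independent sample points
#' (range / bin width) used by \code{\link{aiccScore}}.
#'
#' @slot gene gene identifier.
#' @slot centers bin centers on the progression axis.
#' @slot counts cells per bin.
#' @slot freqs detected fraction per bin (\code{NA} when the bin is empty).
#' @slot width bin width in progression units.
#' @slot nEff effective number of independent sample points.
#' @seealso \code{\link{binFrequencies}}
#' @export
setClass("FrequencyCurve",
  representation(gene = "character", centers = "numeric",
                 counts = "numeric", freqs = "numeric", width = "numeric",
                 nEff = "numeric"))

setValidity("FrequencyCurve", function(object) {
  msg <- character()
  n <- length(object@centers)
  if (length(object@counts) != n || length(object@freqs) != n)
    msg <- c(msg, "centers, counts and freqs must have equal length")
  if (any(object@counts < 0))
    msg <- c(msg, "bin counts must be >= 0")
  f <- object@freqs[!is.na(object@freqs)]
  if (any(f < 0 | f > 1))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (n > 2) {
    sp <- diff(object@centers)
    if (max(abs(sp - sp[1])) > 1e-8)
      msg <- c(msg, "bins must be uniformly spaced")
  }
  if (length(object@width) != 1L || object@width <= 0)
    msg <- c(msg, "width must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Fitted activation/inactivation model for one gene
#'
#' Predicted detection frequency along the progression axis, either a
#' straight line anchored at the trajectory ends (\code{"uniform"}) or a
#' baseline plus one or two Gaussian-CDF components (\code{"gauss1"},
#' \code{"gauss2"}): \code{f(x) = baseline + sum_i amplitude_i *
#' pnorm((x - mu_i)/sigma_i)}. Negative amplitudes describe inactivating
#' genes.
#'
#' @slot gene gene identifier.
#' @slot kind one of \code{"uniform"}, \code{"gauss1"}, \code{"gauss2"}.
#' @slot baseline predicted frequency at progression 0 (uniform: anchor
#'   value; gaussian: intercept term).
#' @slot amplitude per-component amplitude in \code{[-1, 1]} (uniform: the
#'   single end-minus-baseline slope coefficient).
#' @slot mu per-component activation midpoint (empty for uniform).
#' @slot sigma per-component activation spread (empty for uniform).
#' @slot mse mean squared error against the training frequency curve.
#' @slot k number of free parameters (2, 4 or 7).
#' @slot aicc corrected Akaike score (may be \code{NA} when undefined).
#' @slot fRejectRate bootstrap lack-of-fit rejection fraction (\code{NA}
#'   until \code{\link{bootstrapFTest}} is run).
#' @seealso \code{\link{fitUniform}}, \code{\link{fitGaussian}},
#'   \code{\link{predictFrequency}}, \code{\link{activationWindow}}
#' @export
setClass("ActivationModel",
  representation(gene = "character", kind = "character",
                 baseline = "numeric", amplitude = "numeric",
                 mu = "numeric", sigma = "numeric", mse = "numeric",
                 k = "numeric", aicc = "numeric", fRejectRate = "numeric"))

setValidity("ActivationModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("uniform", "gauss1", "gauss2"))
    msg <- c(msg, "kind must be uniform, gauss1 or gauss2")
  nc <- switch(object@kind, uniform = 0L, gauss1 = 1L, gauss2 = 2L)
  if (object@kind != "uniform" &&
      (length(object@mu) != nc || length(object@sigma) != nc ||
       length(object@amplitude) != nc))
    msg <- c(msg, "component parameter lengths disagree with kind")
  if (any(object@sigma <= 0))
    msg <- c(msg, "sigma must be > 0")
  kexp <- switch(object@kind, uniform = 2, gauss1 = 4, gauss2 = 7)
  if (length(object@k) != 1L || object@k != kexp)
    msg <- c(msg, sprintf("k must be %d for kind '%s'", kexp, object@kind))
  if (length(msg)) msg else TRUE
})

#' Principal-components ordination of a cell population
#'
#' @slot scores cells x components score matrix.
#' @slot loadings genes x components loading matrix.
#' @slot varExplained fraction of total variance per component
#'   (non-increasing, sums to 1 over all components).
#' @seealso \code{\link{runPCA}}
#' @export
setClass("OrdinationResult",
  representation(scores = "matrix", loadings = "matrix",
                 varExplained = "numeric"))

setValidity("OrdinationResult", function(object) {
  msg <- character()
  v <- object@varExplained
  if (any(diff(v) > 1e-8))
    msg <- c(msg, "variance fractions must be non-increasing")
  if (sum(v) > 1 + 1e-6)
    msg <- c(msg, "variance fractions must sum to <= 1")
  if (ncol(object@scores) != length(v))
    msg <- c(msg, "score columns must match variance fractions")
  if (length(msg)) msg else TRUE
})

#' Background-corrected gene-gene correlation result
#'
#' Pairwise Pearson correlations of detection indicators, the mean
#' correlation under the simulated independence null, their difference
#' (background-corrected correlation), and Fisher-z significance calls.
#'
#' @slot genes gene identifiers (matrix order).
#' @slot observed observed correlation matrix.
#' @slot nullMean mean correlation over null simulation runs.
#' @slot corrected observed minus null mean.
#' @slot z Fisher z statistics for the difference.
#' @slot p two-sided p-values.
#' @slot q Benjamini-Hochberg adjusted p-values (equal to \code{p} when no
#'   multiplicity control was requested).
#' @slot significant logical calls at \code{alpha}.
#' @slot alpha significance level used for the calls.
#' @slot nObs number of analyzed cells.
#' @slot runs number of null simulation runs averaged.
#' @seealso \code{\link{correctedCorrelation}},
#'   \code{\link{correlationAnalysis}}
#' @export
setClass("CorrelationResult",
  representation(genes = "character", observed = "matrix",
                 nullMean = "matrix", corrected = "matrix", z = "matrix",
                 p = "matrix", q = "matrix", significant = "matrix",
                 alpha = "numeric", nObs = "numeric", runs = "numeric"))

setValidity("CorrelationResult", function(object) {
  msg <- character()
  n <- length(object@genes)
  for (s in c("observed", "nullMean", "corrected", "z", "p", "q",
              "significant")) {
    m <- slot(object, s)
    if (!identical(dim(m), c(n, n)))
      msg <- c(msg, paste0("slot '", s, "' must be ", n, "x", n))
  }
  if (!isTRUE(all.equal(object@observed, t(object@observed),
                        tolerance = 1e-8)))
    msg <- c(msg, "observed matrix must be symmetric")
  if (length(msg)) msg else TRUE
})
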