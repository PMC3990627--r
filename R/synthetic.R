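#' Per-gene simulation parameters
#'
#' Builds one row of a gene-parameter table for the synthetic generator.
#' The detection probability of a gene along the latent progression
#' \code{p} in \code{[0, 1]} is
#' \deqn{f(p) = baseline + (end - baseline)\,\Phi((p - \mu)/\sigma)
#'   + amp2\,\Phi((p - \mu_2)/\sigma_2)}
#' with \eqn{\Phi} the standard normal CDF; the optional second component
#' (\code{amp2}, \code{mu2}, \code{sigma2}) produces transient
#' up-then-down (or down-then-up) dynamics. The implied curve must stay
#' inside \code{[0, 1]} over the whole axis.
#'
#' @param name gene identifier.
#' @param category one of \code{\link{PANEL_CATEGORIES}}.
#' @param baseline,end detection probabilities at progression 0 and 1 (for
#'   the first component; with a second component \code{end} parameterizes
#'   the first amplitude only).
#' @param mu,sigma activation midpoint in \code{[0, 1]} and spread
#'   (\code{> 0}).
#' @param exprMeanOn,exprSd mean and SD of the quantitative
#'   \code{40 - dCt} level when the gene is detected.
#' @param altFreq flat detection probability on the alternate branch.
#' @param amp2,mu2,sigma2 optional second Gaussian-CDF component.
#' @return one-row data.frame.
#' @examples
#' g <- geneSimParams("NANOG", "pluripotency", baseline = 0.05, end = 1,
#'                    mu = 0.75, sigma = 0.05)
#' trueFrequency(g, c(0, 0.75, 1))
#' @export
geneSimParams <- function(name, category, baseline, end, mu, sigma,
                          exprMeanOn = 25, exprSd = 2, altFreq = 0.1,
                          amp2 = 0, mu2 = NA_real_, sigma2 = NA_real_) {
  .assertScalar(baseline, "baseline", 0, 1)
  .assertScalar(end, "end", 0, 1)
  .assertScalar(altFreq, "altFreq", 0, 1)
  .assertScalar(mu, "mu", 0, 1)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("'sigma' must be > 0")
  if (!is.na(amp2) && amp2 != 0) {
    .assertScalar(amp2, "amp2", -1, 1)
    .assertScalar(mu2, "mu2", 0, 1)
    if (!is.numeric(sigma2) || sigma2 <= 0) stop("'sigma2' must be > 0")
  }
  g <- data.frame(gene = name, category = category, baseline = baseline,
                  end = end, mu = mu, sigma = sigma,
                  exprMeanOn = exprMeanOn, exprSd = exprSd,
                  altFreq = altFreq, amp2 = amp2, mu2 = mu2,
                  sigma2 = sigma2, stringsAsFactors = FALSE)
  f <- .rawFrequency(g, seq(0, 1, length.out = 201))
  if (any(f < -1e-9 | f > 1 + 1e-9))
    stop("implied frequency curve for '", name, "' leaves [0, 1]")
  g
}

#' True detection frequency of a simulated gene
#'
#' Evaluates the generator's closed-form detection-probability curve.
#'
#' @param gene one-row gene-parameter data.frame
#'   (\code{\link{geneSimParams}}).
#' @param p progression values in \code{[0, 1]}.
#' @return detection probabilities in \code{[0, 1]}.
#' @export
trueFrequency <- function(gene, p) {
  if (any(p < -1e-12 | p > 1 + 1e-12))
    stop("'p' must lie in [0, 1]")
  .clamp01(.rawFrequency(gene, p))
}

.rawFrequency <- function(gene, p) {
  stopifnot(is.data.frame(gene), nrow(gene) == 1L)
  if (is.na(gene$sigma) || gene$sigma <= 0)
    stop("invalid parameter: sigma must be > 0")
  f <- gene$baseline +
    (gene$end - gene$baseline) * stats::pnorm((p - gene$mu) / gene$sigma)
  if (!is.na(gene$amp2) && gene$amp2 != 0) {
    if (is.na(gene$sigma2) || gene$sigma2 <= 0)
      stop("invalid parameter: sigma2 must be > 0")
    f <- f + gene$amp2 * stats::pnorm((p - gene$mu2) / gene$sigma2)
  }
  f
}

#' Default 48-assay simulation panel
#'
#' A synthetic gene panel shaped like the study's qPCR design: 10
#' fibroblast-associated genes inactivating along the trajectory, 23
#' pluripotency-associated genes activating at gene-specific points (two of
#' them, NR0B1 and REST, nearly undetectable throughout), 6 intermediate
#' markers (three with transient two-component dynamics) and 8 chromatin
#' modifiers activating early; GAPDH is added separately as the
#' normalizer. All parameter values are invented for simulation.
#'
#' @return data.frame of \code{\link{geneSimParams}} rows (47 genes).
#' @export
defaultGenePanel <- function() {
  g <- function(...) geneSimParams(...)
  fib <- rbind(
    g("THY1",   "fibroblast", 0.98, 0.05, 0.35, 0.12, 28, 2, 0.35),
    g("COL1A1", "fibroblast", 0.95, 0.03, 0.25, 0.10, 30, 2, 0.30),
    g("COL5A2", "fibroblast", 0.95, 0.05, 0.30, 0.15, 29, 2, 0.35),
    g("FN1",    "fibroblast", 1.00, 0.10, 0.45, 0.20, 30, 2, 0.40),
    g("VIM",    "fibroblast", 0.98, 0.15, 0.55, 0.18, 31, 2, 0.40),
    g("SNAI2",  "fibroblast", 0.90, 0.05, 0.20, 0.10, 26, 2, 0.30),
    g("TWIST1", "fibroblast", 0.92, 0.04, 0.30, 0.12, 25, 2, 0.30),
    g("PRRX1",  "fibroblast", 0.95, 0.06, 0.40, 0.15, 27, 2, 0.35),
    g("S100A4", "fibroblast", 0.96, 0.08, 0.50, 0.20, 28, 2, 0.35),
    g("DCN",    "fibroblast", 0.93, 0.02, 0.25, 0.08, 26, 2, 0.30))
  plu <- rbind(
    g("POU5F1", "pluripotency", 0.10, 1.00, 0.50, 0.25, 27, 2, 0.06),
    g("SOX2",   "pluripotency", 0.05, 1.00, 0.65, 0.20, 26, 2, 0.06),
    g("NANOG",  "pluripotency", 0.05, 1.00, 0.75, 0.05, 25, 2, 0.05),
    g("LIN28A", "pluripotency", 0.08, 0.98, 0.45, 0.15, 26, 2, 0.06),
    g("ZFP42",  "pluripotency", 0.03, 0.98, 0.80, 0.06, 24, 2, 0.05),
    g("DPPA4",  "pluripotency", 0.02, 0.97, 0.70, 0.12, 24, 2, 0.05),
    g("DNMT3B", "pluripotency", 0.05, 1.00, 0.35, 0.15, 26, 2, 0.08),
    g("TDGF1",  "pluripotency", 0.04, 0.96, 0.60, 0.18, 25, 2, 0.06),
    g("SALL4",  "pluripotency", 0.10, 0.95, 0.40, 0.22, 25, 2, 0.08),
    g("FOXD3",  "pluripotency", 0.02, 0.90, 0.70, 0.25, 23, 2, 0.05),
    g("GDF3",   "pluripotency", 0.03, 0.95, 0.75, 0.15, 24, 2, 0.05),
    g("UTF1",   "pluripotency", 0.05, 0.92, 0.65, 0.22, 24, 2, 0.06),
    g("TERT",   "pluripotency", 0.10, 0.90, 0.50, 0.30, 23, 2, 0.08),
    g("ZIC3",   "pluripotency", 0.04, 0.97, 0.60, 0.07, 25, 2, 0.05),
    g("OTX2",   "pluripotency", 0.05, 0.95, 0.55, 0.06, 25, 2, 0.06),
    g("STAT3",  "pluripotency", 0.30, 0.95, 0.30, 0.25, 27, 2, 0.20),
    g("KLF4",   "pluripotency", 0.40, 0.98, 0.25, 0.20, 27, 2, 0.20),
    g("MYC",    "pluripotency", 0.50, 0.95, 0.20, 0.25, 28, 2, 0.30),
    g("FGF4",   "pluripotency", 0.02, 0.90, 0.80, 0.10, 23, 2, 0.04),
    g("LEFTY2", "pluripotency", 0.03, 0.93, 0.70, 0.14, 24, 2, 0.05),
    g("NODAL",  "pluripotency", 0.05, 0.90, 0.60, 0.20, 24, 2, 0.06),
    g("NR0B1",  "pluripotency", 0.01, 0.04, 0.80, 0.20, 21, 2, 0.01),
    g("REST",   "pluripotency", 0.02, 0.05, 0.50, 0.30, 21, 2, 0.02))
  int <- rbind(
    g("CDH1",  "intermediate", 0.05, 0.97, 0.55, 0.06, 27, 2, 0.25),
    g("EPCAM", "intermediate", 0.05, 0.95, 0.45, 0.10, 26, 2, 0.25),
    g("ALPL",  "intermediate", 0.10, 0.90, 0.50, 0.15, 25, 2, 0.25),
    g("KRT8",  "intermediate", 0.10, 0.90, 0.30, 0.08, 26, 2, 0.25,
      amp2 = -0.70, mu2 = 0.75, sigma2 = 0.08),
    g("KRT18", "intermediate", 0.05, 0.90, 0.35, 0.10, 26, 2, 0.25,
      amp2 = -0.75, mu2 = 0.80, sigma2 = 0.08),
    g("CLDN6", "intermediate", 0.05, 0.85, 0.40, 0.10, 25, 2, 0.25,
      amp2 = -0.65, mu2 = 0.85, sigma2 = 0.07))
  chr <- rbind(
    g("EZH2",   "chromatin", 0.35, 0.99, 0.10, 0.06, 27, 2, 0.04),
    g("SUZ12",  "chromatin", 0.40, 0.98, 0.12, 0.08, 27, 2, 0.04),
    g("EED",    "chromatin", 0.30, 0.97, 0.15, 0.08, 26, 2, 0.04),
    g("JARID2", "chromatin", 0.35, 0.98, 0.10, 0.05, 26, 2, 0.04),
    g("DNMT3A", "chromatin", 0.45, 1.00, 0.20, 0.10, 27, 2, 0.05),
    g("SETDB1", "chromatin", 0.40, 0.97, 0.18, 0.09, 26, 2, 0.04),
    g("KDM5B",  "chromatin", 0.30, 0.96, 0.12, 0.07, 25, 2, 0.04),
    g("HELLS",  "chromatin", 0.35, 0.98, 0.15, 0.08, 26, 2, 0.04))
  rbind(fib, plu, int, chr)
}

#' Simulation configuration
#'
#' Study conditions for the synthetic generator: 170 cells spanning
#' fibroblast to hESC with a productive continuum and a flat-probability
#' alternate branch, GAPDH as an always-present normalizer, and explicitly
#' injected quality-control failures (GAPDH Ct forced to 25 or above).
#'
#' @param genes gene-parameter table (\code{\link{defaultGenePanel}}).
#' @param nFib,nIntermediate,nAlt,nPluri cells per group: untransduced
#'   fibroblasts (latent progression 0), productive intermediates
#'   (progression drawn from \code{progressionSampler}), alternate-branch
#'   cells, and hESC (progression 1). The 20/92/38/20 default mirrors the
#'   study's composition: 172 QC-passed cells of which 38 followed the
#'   alternate trajectory.
#' @param gapdhCtMean,gapdhCtSd normalizer Ct distribution.
#' @param qcFailFraction probability a cell is emitted with GAPDH Ct
#'   forced into \code{[25, 30)}.
#' @param seed integer RNG seed; the dataset is bit-identical under a
#'   fixed seed.
#' @param progressionSampler function of \code{n} returning latent
#'   progression values in \code{[0, 1]} for intermediate cells; default
#'   uniform.
#' @param coregModule optional positive-control module: a list with
#'   \code{genes} (names in the panel), \code{mu}, \code{sigma} and
#'   optional \code{flipNoise} (default 0.02). Member genes share one
#'   latent Bernoulli switch with probability \code{pnorm((p - mu)/sigma)}
#'   per cell, breaking conditional independence.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(genes = defaultGenePanel(), nFib = 20,
                      nIntermediate = 92, nAlt = 38, nPluri = 20,
                      gapdhCtMean = 18, gapdhCtSd = 1.2,
                      qcFailFraction = 0.05, seed = 1L,
                      progressionSampler = NULL, coregModule = NULL) {
  if (!is.data.frame(genes) || nrow(genes) == 0L)
    stop("configuration error: empty gene list")
  for (n in c("nFib", "nIntermediate", "nAlt", "nPluri"))
    .assertScalar(get(n), n, 0)
  .assertScalar(qcFailFraction, "qcFailFraction", 0, 1)
  if (any(genes$sigma <= 0)) stop("all gene sigmas must be > 0")
  if (!is.null(coregModule)) {
    miss <- setdiff(coregModule$genes, genes$gene)
    if (length(miss))
      stop("coregModule genes not in panel: ", paste(miss, collapse = ", "))
    if (is.null(coregModule$flipNoise)) coregModule$flipNoise <- 0.02
  }
  structure(list(genes = genes, nFib = as.integer(nFib),
                 nIntermediate = as.integer(nIntermediate),
                 nAlt = as.integer(nAlt), nPluri = as.integer(nPluri),
                 gapdhCtMean = gapdhCtMean, gapdhCtSd = gapdhCtSd,
                 qcFailFraction = qcFailFraction, seed = as.integer(seed),
                 progressionSampler = progressionSampler,
                 coregModule = coregModule),
            class = "SimConfig")
}

#' Simulate a single-cell reprogramming qPCR dataset
#'
#' Draws cells with a known latent progression and branch, sets each
#' gene's detection by an independent Bernoulli draw from its
#' \code{\link{trueFrequency}} curve (alternate-branch cells use the flat
#' \code{altFreq} instead), attaches Gaussian quantitative levels in
#' \code{40 - dCt} units to detected transcripts, and emits a Ct table
#' with GAPDH and injected QC failures.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with elements \code{experiment}
#'   (\linkS4class{ReprogramSet}) and \code{truth} (list: \code{cells} =
#'   data.frame of \code{cell_id}, \code{progression}, \code{branch},
#'   \code{qc_fail}; \code{probs} = genes x cells matrix of true detection
#'   probabilities).
#' @examples
#' sim <- simulateReprogramming(simConfig(nIntermediate = 10, nAlt = 2,
#'                                        nFib = 3, nPluri = 3))
#' sim$experiment
#' head(sim$truth$cells)
#' @export
simulateReprogramming <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  genes <- config$genes
  set.seed(config$seed)
  sampler <- config$progressionSampler
  if (is.null(sampler)) sampler <- stats::runif
  n <- config$nFib + config$nIntermediate + config$nAlt + config$nPluri
  if (n == 0L) stop("configuration error: no cells requested")
  ids <- sprintf("cell%04d", seq_len(n))
  branch <- rep(c("productive", "productive", "alternate", "productive"),
                c(config$nFib, config$nIntermediate, config$nAlt,
                  config$nPluri))
  group <- rep(c("MRC5", "OSKM", "OSKM", "H9"),
               c(config$nFib, config$nIntermediate, config$nAlt,
                 config$nPluri))
  p <- c(rep(0, config$nFib), sampler(config$nIntermediate),
         sampler(config$nAlt), rep(1, config$nPluri))
  p <- .clamp01(p)

  ng <- nrow(genes)
  probs <- matrix(NA_real_, ng, n, dimnames = list(genes$gene, ids))
  for (i in seq_len(ng)) {
    probs[i, ] <- trueFrequency(genes[i, ], p)
    alt <- branch == "alternate"
    probs[i, alt] <- genes$altFreq[i]
  }
  detected <- matrix(stats::rbinom(ng * n, 1L, probs), ng, n,
                     dimnames = dimnames(probs)) == 1L

  mod <- config$coregModule
  if (!is.null(mod)) {
    switchOn <- stats::rbinom(n, 1L, stats::pnorm((p - mod$mu) /
                                                    mod$sigma)) == 1L
    for (gn in mod$genes) {
      flip <- stats::runif(n) < mod$flipNoise
      det <- ifelse(flip, !switchOn, switchOn)
      det[branch == "alternate"] <-
        detected[gn, branch == "alternate"]
      detected[gn, ] <- det
      keep <- branch != "alternate"
      probs[gn, keep] <- stats::pnorm((p[keep] - mod$mu) / mod$sigma)
    }
  }

  gapdhCt <- stats::rnorm(n, config$gapdhCtMean, config$gapdhCtSd)
  gapdhCt <- pmin(pmax(gapdhCt, 5), 39.5)
  qcFail <- stats::runif(n) < config$qcFailFraction
  gapdhCt[qcFail] <- stats::runif(sum(qcFail), 25, 30)

  level <- matrix(stats::rnorm(ng * n, genes$exprMeanOn, genes$exprSd),
                  ng, n)
  ct <- matrix(CT_UNDETECTED, ng, n, dimnames = dimnames(probs))
  onCt <- sweep(CT_UNDETECTED - level, 2, gapdhCt, "+")
  ct[detected] <- pmin(pmax(onCt[detected], 0.5), 39.9)

  ct <- rbind(ct, GAPDH = gapdhCt)
  day <- rep(NA_real_, n)
  facs <- rep(NA_character_, n)
  oskm <- group == "OSKM"
  day[oskm] <- c(4, 8, 14)[findInterval(p[oskm], c(1 / 3, 2 / 3)) + 1L]
  facs[oskm] <- ifelse(p[oskm] < 0.5, "SSEA4", "TRA160")
  rs <- ReprogramSet(ct,
                     annotations = data.frame(group = group, day = day,
                                              facs = facs),
                     panel = genes[, c("gene", "category")])
  metadata(rs)$simulationSeed <- config$seed
  truth <- list(cells = data.frame(cell_id = ids, progression = p,
                                   branch = branch, qc_fail = qcFail,
                                   stringsAsFactors = FALSE),
                probs = probs)
  list(experiment = rs, truth = truth)
}

#' Write / read the latent ground truth
#'
#' JSON serialization of the generator's per-cell latent progression,
#' branch labels and per-gene true detection probabilities.
#'
#' @param truth the \code{truth} element of
#'   \code{\link{simulateReprogramming}}.
#' @param path output (input) file path.
#' @return \code{readLatentTruth} returns the truth list.
#' @export
writeLatentTruth <- function(truth, path) {
  jsonlite::write_json(list(cells = truth$cells,
                            genes = rownames(truth$probs),
                            probs = unname(truth$probs)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLatentTruth
#' @export
readLatentTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  probs <- as.matrix(x$probs)
  dimnames(probs) <- list(x$genes, x$cells$cell_id)
  list(cells = x$cells, probs = probs)
}

#' Read a simulation configuration from YAML
#'
#' The YAML file holds the scalar fields of \code{\link{simConfig}} plus
#' either \code{genes: default} (the packaged 48-assay panel) or a list of
#' per-gene parameter records.
#'
#' @param path YAML file.
#' @return a \code{SimConfig}.
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  genes <- if (is.null(y$genes) || identical(y$genes, "default"))
    defaultGenePanel()
  else
    do.call(rbind, lapply(y$genes, function(g) do.call(geneSimParams, g)))
  args <- y[setdiff(names(y), "genes")]
  do.call(simConfig, c(list(genes = genes), args))
}
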