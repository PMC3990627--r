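#' Pipeline configuration
#'
#' Bundles every stage's parameters with explicit seeds. When \code{input}
#' is \code{NULL} the synthetic generator supplies the dataset.
#'
#' @param input optional path to a wide Ct CSV (\code{\link{loadCtTable}}
#'   layout).
#' @param panel optional panel data.frame or CSV path (required with
#'   \code{input}).
#' @param sim \code{\link{simConfig}} used when no input file is given.
#' @param qcThreshold GAPDH Ct exclusion threshold.
#' @param outlierFraction off-trajectory outlier fraction.
#' @param fibGroup,pluriGroup anchor group labels.
#' @param binWidth,nBins activation-model binning.
#' @param bootstrapReps,bootstrapBins lack-of-fit F-test settings
#'   (\code{bootstrapReps = 0} skips it).
#' @param corrRuns independence-null simulation runs.
#' @param lowDetect correlation low-detection exclusion threshold.
#' @param alpha significance level for Tukey contrasts, F-tests and
#'   correlation calls.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(input = NULL, panel = NULL,
                           sim = simConfig(), qcThreshold = 25,
                           outlierFraction = 0.10, fibGroup = "MRC5",
                           pluriGroup = "H9", binWidth = 0.08,
                           nBins = 16, bootstrapReps = 200,
                           bootstrapBins = 12, corrRuns = 1000,
                           lowDetect = 0.05, alpha = 0.05, seed = 1L) {
  cfg <- list(input = input, panel = panel, sim = sim,
              qcThreshold = qcThreshold,
              outlierFraction = outlierFraction, fibGroup = fibGroup,
              pluriGroup = pluriGroup, binWidth = binWidth,
              nBins = nBins, bootstrapReps = bootstrapReps,
              bootstrapBins = bootstrapBins, corrRuns = corrRuns,
              lowDetect = lowDetect, alpha = alpha,
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes load/simulate, QC, normalization, trajectory, grouping,
#' activation modeling and correlation analysis in order, writing every
#' stage's table to \code{outdir} plus a JSON manifest with the filter
#' counts (loaded = QC-passed + QC-rejected; analyzed cells after outlier
#' and Alt exclusion), seeds and a configuration hash. Reruns with an
#' identical configuration reproduce identical numeric outputs. A stage
#' failure aborts with the stage name; outputs of completed stages are
#' left in place.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outdir output directory (created if absent).
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = tempfile()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "scReprogram",
                   version = as.character(utils::packageVersion(
                     "scReprogram")),
                   seed = config$seed, config_hash = .configHash(config),
                   counts = list(), outputs = character())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <- name
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(file) {
    manifest$outputs <<- c(manifest$outputs, file)
  }

  truth <- NULL
  rs <- stage("load", {
    if (is.null(config$input)) {
      simCfg <- config$sim
      simCfg$seed <- config$seed
      sim <- simulateReprogramming(simCfg)
      truth <- sim$truth
      writeCtTable(sim$experiment, file.path(outdir, "ct_table.csv"))
      writeLatentTruth(truth, file.path(outdir, "latent_truth.json"))
      emit("ct_table.csv")
      emit("latent_truth.json")
      sim$experiment
    } else {
      panel <- config$panel
      if (is.character(panel)) panel <- readGenePanel(panel)
      loadCtTable(config$input, panel = panel)
    }
  })
  manifest$counts$loaded <- ncol(rs)

  rs <- stage("qc", {
    qc <- qcFilter(rs, threshold = config$qcThreshold)
    jsonlite::write_json(qcReport(rs, qc$rejected),
                         file.path(outdir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("qc_report.json")
    manifest$counts$qc_rejected <- length(qc$rejected)
    manifest$counts$qc_passed <- ncol(qc$experiment)
    qc$experiment
  })

  rs <- stage("normalize", normalizeToGapdh(rs))

  rs <- stage("trajectory", {
    out <- computeTrajectory(rs, fibGroup = config$fibGroup,
                             pluriGroup = config$pluriGroup,
                             outlierFraction = config$outlierFraction)
    writeTrajectoryTable(out, file.path(outdir, "trajectory.csv"))
    emit("trajectory.csv")
    manifest$counts$outliers <- sum(colData(out)$outlier)
    out
  })

  grouping <- stage("grouping", {
    ord <- runPCA(rs)
    utils::write.csv(
      data.frame(cell_id = colnames(rs),
                 pcScores(ord)[, 1:min(5, ncol(pcScores(ord)))]),
      file.path(outdir, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(component = seq_along(varianceExplained(ord)),
                 variance_fraction = varianceExplained(ord)),
      file.path(outdir, "pca_variance.csv"), row.names = FALSE)
    rs <- somPartition(rs, ord)
    utils::write.csv(
      data.frame(cell_id = colnames(rs),
                 som_unit = colData(rs)$som_unit,
                 som_group = as.character(colData(rs)$som_group)),
      file.path(outdir, "group_assignment.csv"), row.names = FALSE)
    hc <- wardCluster(rs)
    writeLines(dendrogramToNewick(hc),
               file.path(outdir, "ward_dendrogram.nwk"))
    productive <- colData(rs)$som_group != "Alt"
    reg <- productiveRegression(pcScores(ord)[productive, 1:2,
                                              drop = FALSE])
    tk <- tukeyKramer(rs, colData(rs)$som_group, alpha = config$alpha)
    utils::write.csv(tk, file.path(outdir, "tukey_kramer.csv"),
                     row.names = FALSE)
    edges <- topCorrelationEdges(rs)
    utils::write.csv(edges, file.path(outdir, "network_edges.csv"),
                     row.names = FALSE)
    for (f in c("pca_scores.csv", "pca_variance.csv",
                "group_assignment.csv", "ward_dendrogram.nwk",
                "tukey_kramer.csv", "network_edges.csv")) emit(f)
    manifest$counts$alt_excluded <- sum(!productive)
    list(ordination = ord, regression = reg)
  })

  analyzed <- !colData(rs)$outlier & colData(rs)$som_group != "Alt"
  manifest$counts$analyzed <- sum(analyzed)

  fits <- stage("activation_models", {
    set.seed(.deriveSeed(config$seed, 3L))
    fits <- fitActivationModels(rs, cells = analyzed,
                                binWidth = config$binWidth,
                                nBins = config$nBins,
                                bootstrapReps = config$bootstrapReps,
                                bootstrapBins = config$bootstrapBins,
                                alpha = config$alpha)
    utils::write.csv(fits$summary,
                     file.path(outdir, "activation_models.csv"),
                     row.names = FALSE)
    writeCurveTable(fits, file.path(outdir, "frequency_curves.csv"))
    emit("activation_models.csv")
    emit("frequency_curves.csv")
    fits
  })

  corr <- stage("correlation_null", {
    corr <- withCallingHandlers(
      correlationAnalysis(rs, fits, cells = analyzed,
                          lowDetect = config$lowDetect,
                          runs = config$corrRuns, alpha = config$alpha,
                          seed = .deriveSeed(config$seed, 4L)),
      warning = function(w) invokeRestart("muffleWarning"))
    utils::write.csv(correlationTable(corr),
                     file.path(outdir, "correlation_pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(corr@corrected,
                     file.path(outdir, "correlation_corrected.csv"))
    emit("correlation_pairs.csv")
    emit("correlation_corrected.csv")
    corr
  })
  manifest$counts$correlation_genes <- length(corr@genes)

  manifest$summary <- list(
    pc12_variance_fraction =
      sum(varianceExplained(grouping$ordination)[1:2]),
    productive_r_squared = grouping$regression$r_squared,
    genes_choosing_gauss1 = sum(fits$summary$chosen == "gauss1"),
    genes_choosing_uniform = sum(fits$summary$chosen == "uniform"),
    genes_choosing_gauss2 = sum(fits$summary$chosen == "gauss2"),
    significant_corr_pairs = sum(.upperTri(corr@significant)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
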