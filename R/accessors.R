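#' Construct a ReprogramSet from a Ct matrix
#'
#' @param ct numeric genes x cells matrix of Ct values in \code{(0, 40]};
#'   40 encodes "undetected". Row names are gene identifiers (must include
#'   the normalizer), column names are cell identifiers.
#' @param annotations data.frame or \link[S4Vectors]{DataFrame} of per-cell
#'   annotations (\code{group}, \code{day}, \code{facs}); missing columns
#'   are filled with \code{"unknown"}/\code{NA}.
#' @param panel data.frame with columns \code{gene} and \code{category}
#'   assigning each non-normalizer gene to one of
#'   \code{\link{PANEL_CATEGORIES}}; genes absent from the panel get
#'   category \code{"unknown"}.
#' @param normalizer name of the housekeeping normalizer gene.
#' @return A \linkS4class{ReprogramSet}.
#' @examples
#' ct <- rbind(GAPDH = c(a = 18, b = 19), NANOG = c(40, 31))
#' rs <- ReprogramSet(ct, panel = data.frame(gene = "NANOG",
#'                                           category = "pluripotency"))
#' detectionCalls(rs)
#' @export
ReprogramSet <- function(ct, annotations = NULL, panel = NULL,
                         normalizer = "GAPDH") {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("'ct' must be a numeric matrix (genes x cells)")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("'ct' needs gene row names and cell column names")
  if (!normalizer %in% rownames(ct))
    stop("normalizer gene '", normalizer, "' not found in 'ct'")
  category <- rep("unknown", nrow(ct))
  names(category) <- rownames(ct)
  if (!is.null(panel)) {
    hit <- intersect(rownames(ct), panel$gene)
    category[hit] <- as.character(panel$category[match(hit, panel$gene)])
  }
  category[normalizer] <- "normalizer"
  ann <- S4Vectors::DataFrame(row.names = colnames(ct))
  ann$group <- rep("unknown", ncol(ct))
  ann$day <- rep(NA_real_, ncol(ct))
  ann$facs <- rep(NA_character_, ncol(ct))
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    for (col in intersect(c("group", "day", "facs"), colnames(annotations)))
      ann[[col]] <- annotations[[col]]
  }
  se <- SummarizedExperiment(
    assays = list(ct = ct, detected = ct < CT_UNDETECTED),
    rowData = S4Vectors::DataFrame(category = category,
                                   normalizer = rownames(ct) == normalizer),
    colData = ann)
  new("ReprogramSet", se)
}

#' @describeIn ReprogramSet Ct matrix (genes x cells).
#' @param x,object a \linkS4class{ReprogramSet}.
#' @export
ctValues <- function(x) assay(x, "ct")

#' @describeIn ReprogramSet logical detection matrix (genes x cells).
#' @export
detectionCalls <- function(x) assay(x, "detected")

#' @describeIn ReprogramSet normalized \code{40 - dCt} levels (genes x
#'   cells, \code{NA} where undetected); requires
#'   \code{\link{normalizeToGapdh}} first.
#' @export
exprLevels <- function(x) {
  if (!"level" %in% assayNames(x))
    stop("no 'level' assay; run normalizeToGapdh() first")
  assay(x, "level")
}

#' @describeIn ReprogramSet panel category per gene.
#' @export
geneCategories <- function(x) {
  stats::setNames(rowData(x)$category, rownames(x))
}

#' @describeIn ReprogramSet name of the normalizer gene.
#' @export
normalizerGene <- function(x) rownames(x)[rowData(x)$normalizer]

#' @describeIn ReprogramSet per-cell group annotation.
#' @export
cellGroups <- function(x) stats::setNames(colData(x)$group, colnames(x))

#' @describeIn ReprogramSet per-cell trajectory coordinates as a
#'   \link[S4Vectors]{DataFrame} (after \code{\link{computeTrajectory}}).
#' @export
trajectoryCoords <- function(x) {
  cols <- c("d_fib", "d_pluri", "sim_fib", "sim_pluri", "progression",
            "off_distance", "outlier")
  if (!all(cols %in% colnames(colData(x))))
    stop("trajectory coordinates absent; run computeTrajectory() first")
  colData(x)[, cols]
}

setMethod("show", "ReprogramSet", function(object) {
  callNextMethod()
  cat("normalizer:", normalizerGene(object), "\n")
  cat("categories:",
      paste(sprintf("%s(%d)", names(table(rowData(object)$category)),
                    table(rowData(object)$category)), collapse = " "), "\n")
  if ("progression" %in% colnames(colData(object)))
    cat(sprintf("trajectory: progression in [%.2f, %.2f], %d outlier(s)\n",
                min(colData(object)$progression),
                max(colData(object)$progression),
                sum(colData(object)$outlier)))
})

setMethod("show", "FrequencyCurve", function(object) {
  ok <- !is.na(object@freqs)
  cat(sprintf(
    "FrequencyCurve for %s: %d bins (width %.3f), %d non-empty, n_eff %.1f\n",
    object@gene, length(object@centers), object@width, sum(ok),
    object@nEff))
  if (any(ok))
    cat(sprintf("  detection frequency %.2f-%.2f\n",
                min(object@freqs[ok]), max(object@freqs[ok])))
})

setMethod("show", "ActivationModel", function(object) {
  cat(sprintf("ActivationModel (%s) for %s: k=%d, mse=%.3g, AICc=%.2f\n",
              object@kind, object@gene, object@k, object@mse, object@aicc))
  if (object@kind != "uniform")
    cat(sprintf("  baseline %.3f; components: %s\n", object@baseline,
                paste(sprintf("a=%.2f mu=%.3f sigma=%.3f",
                              object@amplitude, object@mu, object@sigma),
                      collapse = "; ")))
  else
    cat(sprintf("  line from %.3f to %.3f\n", object@baseline,
                object@baseline + object@amplitude))
  if (!is.na(object@fRejectRate))
    cat(sprintf("  bootstrap F-test rejection rate %.3f\n",
                object@fRejectRate))
})

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult: %d cells, %d components\n",
              nrow(object@scores), ncol(object@scores)))
  cat(sprintf("  PC1+PC2 variance fraction: %.1f%%\n",
              100 * sum(object@varExplained[seq_len(min(
                2, length(object@varExplained)))])))
})

setMethod("show", "CorrelationResult", function(object) {
  np <- choose(length(object@genes), 2)
  cat(sprintf(
    "CorrelationResult: %d genes (%d pairs), %d cells, %d null runs\n",
    length(object@genes), np, object@nObs, object@runs))
  cat(sprintf("  significant pairs at alpha=%.3g: %d\n", object@alpha,
              sum(.upperTri(object@significant))))
})

#' Long-format table of pairwise correlation results
#'
#' @param x a \linkS4class{CorrelationResult}.
#' @return data.frame with one row per gene pair: \code{gene_a},
#'   \code{gene_b}, \code{r_obs}, \code{r_null}, \code{corrected},
#'   \code{z}, \code{p}, \code{q}, \code{significant}.
#' @export
correlationTable <- function(x) {
  stopifnot(is(x, "CorrelationResult"))
  idx <- which(upper.tri(x@observed), arr.ind = TRUE)
  data.frame(
    gene_a = x@genes[idx[, 1]], gene_b = x@genes[idx[, 2]],
    r_obs = x@observed[idx], r_null = x@nullMean[idx],
    corrected = x@corrected[idx], z = x@z[idx], p = x@p[idx],
    q = x@q[idx], significant = x@significant[idx],
    stringsAsFactors = FALSE)
}
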