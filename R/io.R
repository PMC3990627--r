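#' Read a gene panel file
#'
#' Two-column CSV (\code{gene}, \code{category}) restricted to the four
#' panel classes.
#'
#' @param path CSV file.
#' @return data.frame with columns \code{gene} and \code{category}.
#' @export
readGenePanel <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "category") %in% colnames(p)))
    stop("panel file needs 'gene' and 'category' columns")
  bad <- setdiff(unique(p$category), PANEL_CATEGORIES)
  if (length(bad))
    stop("panel categories outside the four classes: ",
         paste(bad, collapse = ", "))
  p[, c("gene", "category")]
}

.ANNOTATION_COLS <- c("cell_id", "group", "day", "facs")

#' Load a wide-format single-cell Ct table
#'
#' Reads a cells x genes table (header row of gene names, annotation
#' columns \code{cell_id}, \code{group}, \code{day}, \code{facs}) into a
#' \linkS4class{ReprogramSet}. Missing Ct entries are treated as
#' undetected (Ct 40); values above 40 are clamped to 40 with a warning
#' (instrument exports vary); a missing GAPDH column is fatal.
#'
#' @param path CSV (or TSV, \code{sep = "\t"}) file.
#' @param panel optional panel data.frame (\code{\link{readGenePanel}}).
#' @param unknownGenes what to do with data columns absent from the
#'   panel: keep with a warning, drop, or error.
#' @param sep field separator.
#' @param normalizer normalizer gene name.
#' @return a \linkS4class{ReprogramSet}.
#' @examples
#' path <- system.file("extdata", "example_ct_table.csv",
#'                     package = "scReprogram")
#' panel <- readGenePanel(system.file("extdata", "example_panel.csv",
#'                                    package = "scReprogram"))
#' loadCtTable(path, panel = panel)
#' @export
loadCtTable <- function(path, panel = NULL,
                        unknownGenes = c("warn", "drop", "error"),
                        sep = ",", normalizer = "GAPDH") {
  unknownGenes <- match.arg(unknownGenes)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"cell_id" %in% colnames(tab))
    stop("fatal format error: no 'cell_id' column")
  geneCols <- setdiff(colnames(tab), .ANNOTATION_COLS)
  if (!normalizer %in% geneCols)
    stop("fatal format error: no ", normalizer, " column")
  if (!is.null(panel)) {
    unknown <- setdiff(geneCols, c(panel$gene, normalizer))
    if (length(unknown)) {
      msg <- paste0("genes absent from panel: ",
                    paste(unknown, collapse = ", "))
      switch(unknownGenes,
             error = stop(msg),
             drop = {
               warning(msg, "; dropped")
               geneCols <- setdiff(geneCols, unknown)
             },
             warn = warning(msg, "; kept with category 'unknown'"))
    }
  }
  ct <- t(as.matrix(tab[, geneCols, drop = FALSE]))
  if (!is.numeric(ct)) {
    badRow <- which(apply(tab[, geneCols, drop = FALSE], 1,
                          function(r) any(is.na(suppressWarnings(
                            as.numeric(r))) & !is.na(r) & r != "")))[1]
    stop("non-numeric Ct value in row for cell '",
         tab$cell_id[badRow], "'")
  }
  colnames(ct) <- tab$cell_id
  ct[is.na(ct)] <- CT_UNDETECTED
  if (any(ct > CT_UNDETECTED)) {
    warning(sum(ct > CT_UNDETECTED),
            " Ct value(s) above 40 clamped to 40 (undetected)")
    ct[ct > CT_UNDETECTED] <- CT_UNDETECTED
  }
  if (any(ct <= 0))
    stop("Ct values must be positive; offending cell(s): ",
         paste(unique(colnames(ct)[which(ct <= 0, arr.ind = TRUE)[, 2]]),
               collapse = ", "))
  ReprogramSet(ct, annotations = tab[, intersect(.ANNOTATION_COLS[-1],
                                                 colnames(tab)),
                                     drop = FALSE],
               panel = panel, normalizer = normalizer)
}

#' Write a ReprogramSet as a wide Ct table
#'
#' Inverse of \code{\link{loadCtTable}}: annotation columns followed by
#' one Ct column per gene (normalizer included).
#'
#' @param x a \linkS4class{ReprogramSet}.
#' @param path output CSV path.
#' @export
writeCtTable <- function(x, path) {
  cd <- colData(x)
  out <- data.frame(cell_id = colnames(x), group = cd$group, day = cd$day,
                    facs = cd$facs, t(ctValues(x)), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' GAPDH quality-control filter
#'
#' Excludes every cell whose GAPDH Ct is at or above the threshold
#' (default 25), the study's robustness criterion for single-cell
#' material.
#'
#' @param x a \linkS4class{ReprogramSet}.
#' @param threshold exclusive upper bound on acceptable GAPDH Ct.
#' @return list with \code{experiment} (retained cells) and
#'   \code{rejected} (character vector of excluded cell ids).
#' @export
qcFilter <- function(x, threshold = 25) {
  gapdh <- ctValues(x)[normalizerGene(x), ]
  keep <- gapdh < threshold
  list(experiment = x[, keep], rejected = colnames(x)[!keep])
}

#' QC report
#'
#' @param x the pre-filter \linkS4class{ReprogramSet}.
#' @param rejected rejected cell ids from \code{\link{qcFilter}}.
#' @return list ready for JSON serialization: counts retained/rejected and
#'   per-cell GAPDH Ct.
#' @export
qcReport <- function(x, rejected) {
  gapdh <- ctValues(x)[normalizerGene(x), ]
  list(n_loaded = ncol(x), n_rejected = length(rejected),
       n_retained = ncol(x) - length(rejected), rejected = rejected,
       gapdh_ct = as.list(gapdh))
}

#' Normalize Ct values to GAPDH
#'
#' Adds the \code{level} assay: \code{40 - (Ct_gene - Ct_GAPDH)} wherever
#' the gene is detected, \code{NA} elsewhere (undetected transcripts carry
#' no quantitative level).
#'
#' @param x a \linkS4class{ReprogramSet} (QC already applied).
#' @return the updated \linkS4class{ReprogramSet}.
#' @export
normalizeToGapdh <- function(x) {
  ct <- ctValues(x)
  gapdh <- ct[normalizerGene(x), ]
  level <- CT_UNDETECTED - sweep(ct, 2, gapdh, "-")
  level[!detectionCalls(x)] <- NA_real_
  assay(x, "level") <- level
  x
}

#' Binary detection matrix
#'
#' Reduces expression to 1 (detected, Ct < 40) / 0 (undetected), the
#' representation used for all trajectory geometry.
#'
#' @param x a \linkS4class{ReprogramSet}.
#' @param includeNormalizer keep the GAPDH row (always detected after QC)?
#' @return integer cells x genes matrix of 0/1.
#' @export
binarizeDetection <- function(x, includeNormalizer = FALSE) {
  det <- detectionCalls(x)
  if (!includeNormalizer)
    det <- det[!rowData(x)$normalizer, , drop = FALSE]
  t(det) * 1L
}

#' Quantitative level matrix under the undetected-level policy
#'
#' The study's quantitative analyses (PCA, Ward clustering, group
#' contrasts) run on \code{40 - dCt} levels; undetected entries contribute
#' level 0 under the default policy.
#'
#' @param x a normalized \linkS4class{ReprogramSet}.
#' @param undetected \code{"zero"} (default policy) or \code{"na"}.
#' @param includeNormalizer keep the GAPDH row (constant 40)?
#' @return numeric genes x cells matrix.
#' @export
levelMatrix <- function(x, undetected = c("zero", "na"),
                        includeNormalizer = FALSE) {
  undetected <- match.arg(undetected)
  lv <- exprLevels(x)
  if (undetected == "zero") lv[is.na(lv)] <- 0
  if (!includeNormalizer)
    lv <- lv[!rowData(x)$normalizer, , drop = FALSE]
  lv
}
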