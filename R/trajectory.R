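#' Mean Euclidean distance from one cell to an anchor group
#'
#' Average Euclidean distance between a cell's binary detection profile
#' and every member of the group, ignoring the self-comparison.
#'
#' @param b integer cells x genes binary matrix
#'   (\code{\link{binarizeDetection}}).
#' @param cell row name or index of the query cell.
#' @param groupIds row names (or indices) of the anchor group members.
#' @return mean distance (binary-profile units).
#' @examples
#' b <- rbind(a = c(0, 0), f = c(1, 1))
#' meanGroupDistance(b, "a", "f")  # sqrt(2)
#' @export
meanGroupDistance <- function(b, cell, groupIds) {
  prof <- b[cell, , drop = TRUE]
  grp <- b[groupIds, , drop = FALSE]
  if (is.character(cell)) {
    grp <- grp[rownames(grp) != cell, , drop = FALSE]
  } else if (is.numeric(groupIds)) {
    grp <- grp[groupIds != cell, , drop = FALSE]
  }
  if (nrow(grp) == 0L)
    stop("anchor group empty after self-exclusion")
  mean(sqrt(colSums((t(grp) - prof)^2)))
}

#' Similarity of a cell to an anchor group
#'
#' The study's dimensionless similarity: the ratio of (anchor separation
#' minus the cell's distance to the group) over (anchor separation minus
#' the group's internal dispersion). Equals 1 for a typical group member
#' and 0 for a cell as far from the group as the opposite anchor; values
#' outside \code{[0, 1]} are possible and deliberately not clamped.
#'
#' @param dCell the cell's mean distance to the group.
#' @param dFP mean distance between the FIB and PLURI anchor groups.
#' @param dSelf the group's mean within-group pairwise distance.
#' @return similarity value.
#' @export
groupSimilarity <- function(dCell, dFP, dSelf) {
  if (any(dFP <= dSelf))
    stop("degenerate anchors: FIB-PLURI separation (", format(dFP),
         ") must exceed within-group dispersion (", format(dSelf), ")")
  (dFP - dCell) / (dFP - dSelf)
}

#' Position on the reprogramming progression axis
#'
#' Average of the similarity to PLURI and the complement of the similarity
#' to FIB: 0 at the fibroblast anchor, 1 at the hESC anchor.
#'
#' @param simFib,simPluri similarities from \code{\link{groupSimilarity}}.
#' @return progression estimate.
#' @export
progressionScore <- function(simFib, simPluri) {
  (simPluri + (1 - simFib)) / 2
}

#' Distance off the reprogramming trajectory
#'
#' Perpendicular Euclidean distance from the point
#' \code{(simFib, simPluri)} to the trajectory diagonal
#' \code{simPluri = 1 - simFib}, i.e.
#' \code{|simFib + simPluri - 1| / sqrt(2)}. Cells leaving both anchor
#' profiles (the alternate trajectory) score high.
#'
#' @inheritParams progressionScore
#' @return non-negative distance.
#' @export
offTrajectoryDistance <- function(simFib, simPluri) {
  abs(simFib + simPluri - 1) / sqrt(2)
}

#' Flag off-trajectory outliers
#'
#' Marks the \code{ceiling(fraction * n)} cells with the largest
#' off-trajectory distance; ties are broken by stable cell order.
#'
#' @param offDistance numeric vector of off-trajectory distances.
#' @param fraction fraction of cells to flag, in \code{(0, 1)};
#'   default 0.10 (17 of the study's 170 analyzed cells).
#' @return logical vector.
#' @export
flagOutliers <- function(offDistance, fraction = 0.10) {
  .assertScalar(fraction, "fraction", lo = 1e-12, hi = 1 - 1e-12)
  n <- length(offDistance)
  k <- ceiling(fraction * n)
  ord <- order(offDistance, decreasing = TRUE)  # radix order is stable
  out <- logical(n)
  out[ord[seq_len(k)]] <- TRUE
  out
}

#' Compute per-cell trajectory coordinates
#'
#' For every cell: mean binary-profile distance to the fibroblast (FIB)
#' and pluripotent (PLURI) anchor groups, the two similarity scores, the
#' progression estimate, the off-trajectory distance and an outlier flag
#' (top \code{outlierFraction} by off-trajectory distance). The anchor
#' separation is the mean over all FIB x PLURI profile pairs; each
#' anchor's self-dispersion is the mean over its distinct within-group
#' pairs.
#'
#' @param x a \linkS4class{ReprogramSet} (QC applied).
#' @param fibGroup,pluriGroup \code{group} annotation values of the two
#'   anchor populations.
#' @param outlierFraction fraction flagged as off-trajectory outliers.
#' @return \code{x} with columns \code{d_fib}, \code{d_pluri},
#'   \code{sim_fib}, \code{sim_pluri}, \code{progression},
#'   \code{off_distance}, \code{outlier} added to \code{colData};
#'   retrieve with \code{\link{trajectoryCoords}}.
#' @export
computeTrajectory <- function(x, fibGroup = "MRC5", pluriGroup = "H9",
                              outlierFraction = 0.10) {
  b <- binarizeDetection(x)
  grp <- cellGroups(x)
  fib <- which(grp == fibGroup)
  plu <- which(grp == pluriGroup)
  if (length(fib) < 2L || length(plu) < 2L)
    stop("need at least two cells in each anchor group ('", fibGroup,
         "': ", length(fib), ", '", pluriGroup, "': ", length(plu), ")")
  dmat <- as.matrix(stats::dist(b))
  dFib <- vapply(seq_len(nrow(b)), function(i)
    mean(dmat[i, setdiff(fib, i)]), numeric(1))
  dPluri <- vapply(seq_len(nrow(b)), function(i)
    mean(dmat[i, setdiff(plu, i)]), numeric(1))
  dFP <- mean(dmat[fib, plu])
  dSelfFib <- mean(.upperTri(dmat[fib, fib]))
  dSelfPluri <- mean(.upperTri(dmat[plu, plu]))
  simFib <- groupSimilarity(dFib, dFP, dSelfFib)
  simPluri <- groupSimilarity(dPluri, dFP, dSelfPluri)
  cd <- colData(x)
  cd$d_fib <- dFib
  cd$d_pluri <- dPluri
  cd$sim_fib <- simFib
  cd$sim_pluri <- simPluri
  cd$progression <- progressionScore(simFib, simPluri)
  cd$off_distance <- offTrajectoryDistance(simFib, simPluri)
  cd$outlier <- flagOutliers(cd$off_distance, outlierFraction)
  colData(x) <- cd
  x
}

#' Write per-cell trajectory coordinates
#'
#' @param x a \linkS4class{ReprogramSet} after
#'   \code{\link{computeTrajectory}}.
#' @param path output CSV path.
#' @export
writeTrajectoryTable <- function(x, path) {
  tc <- as.data.frame(trajectoryCoords(x))
  utils::write.csv(cbind(cell_id = colnames(x), tc), path,
                   row.names = FALSE)
  invisible(path)
}
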