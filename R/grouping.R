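#' Principal components of the quantitative expression profiles
#'
#' Column-centered (unscaled, matching the clustering's "no
#' standardization") PCA of the \code{40 - dCt} levels; undetected entries
#' enter as level 0 under the default policy.
#'
#' @param x a normalized \linkS4class{ReprogramSet}.
#' @param undetected undetected-level policy passed to
#'   \code{\link{levelMatrix}}.
#' @param scale. unit-variance scaling switch (off by default).
#' @return an \linkS4class{OrdinationResult}.
#' @export
runPCA <- function(x, undetected = "zero", scale. = FALSE) {
  lv <- t(levelMatrix(x, undetected))        # cells x genes
  if (nrow(lv) < 3L || ncol(lv) < 2L)
    stop("need at least 3 cells and 2 genes")
  if (all(abs(sweep(lv, 2, colMeans(lv))) < 1e-12))
    stop("degenerate input: constant expression matrix")
  pc <- stats::prcomp(lv, center = TRUE, scale. = scale.)
  new("OrdinationResult", scores = pc$x, loadings = pc$rotation,
      varExplained = pc$sdev^2 / sum(pc$sdev^2))
}

#' @describeIn runPCA cells x components score matrix.
#' @param object an \linkS4class{OrdinationResult}.
#' @export
pcScores <- function(object) object@scores

#' @describeIn runPCA per-component variance-explained fractions.
#' @export
varianceExplained <- function(object) object@varExplained

# deterministic 1-D batch self-organizing map on a 2-D score cloud.
# prototypes start at the means of equal-size PC1-ordered slices; batch
# updates use a Gaussian neighborhood whose radius decays linearly, so
# units stay distinct instead of dying, and the final small-radius
# epochs reduce to near-Lloyd refinement.
.batchSOM1d <- function(xy, nUnits, epochs) {
  slice <- ceiling(seq_along(order(xy[, 1])) / (nrow(xy) / nUnits))
  slice <- pmin(slice, nUnits)[order(order(xy[, 1]))]
  proto <- do.call(rbind, lapply(seq_len(nUnits), function(j)
    colMeans(xy[slice == j, , drop = FALSE])))
  for (e in seq_len(epochs)) {
    radius <- max(0.05, (nUnits / 3) * (1 - (e - 1) / (0.8 * epochs)))
    d2 <- outer(rowSums(xy^2), rowSums(proto^2), "+") -
      2 * xy %*% t(proto)
    bmu <- max.col(-d2, ties.method = "first")
    h <- exp(-outer(bmu, seq_len(nUnits), "-")^2 / (2 * radius^2))
    newProto <- (t(h) %*% xy) / pmax(colSums(h), 1e-12)
    if (max(abs(newProto - proto)) < 1e-12) {
      proto <- newProto
      break
    }
    proto <- newProto
  }
  d2 <- outer(rowSums(xy^2), rowSums(proto^2), "+") - 2 * xy %*% t(proto)
  max.col(-d2, ties.method = "first")
}

#' Partition cells with a 5x1 self-organizing map
#'
#' Trains a one-dimensional, five-unit SOM on the first two PC scores and
#' assigns each cell to its best-matching unit, reproducing the study's
#' PCA-SOM grouping. The unit with the largest mean off-trajectory
#' distance is labeled \code{Alt}; the remaining units are labeled
#' \code{Fib}, \code{Early}, \code{Late}, \code{Pluri} in order of their
#' members' mean progression. The batch algorithm is deterministic for a
#' given dataset.
#'
#' @param x a \linkS4class{ReprogramSet} after
#'   \code{\link{computeTrajectory}}.
#' @param ordination an \linkS4class{OrdinationResult} (computed from
#'   \code{x} when \code{NULL}).
#' @param nUnits number of map units.
#' @param epochs training epochs (the batch map converges far earlier;
#'   the cap is a safety stop).
#' @param method \code{"som"} or the labeled exact k-means fallback
#'   (\code{stats::kmeans} started from the SOM's quantile prototypes).
#' @return \code{x} with a \code{som_group} factor (levels \code{Fib},
#'   \code{Early}, \code{Late}, \code{Pluri}, \code{Alt}) and integer
#'   \code{som_unit} in \code{colData}. Empty units are reported with a
#'   warning.
#' @export
somPartition <- function(x, ordination = NULL, nUnits = 5, epochs = 500,
                         method = c("som", "kmeans")) {
  method <- match.arg(method)
  if (is.null(ordination)) ordination <- runPCA(x)
  xy <- pcScores(ordination)[, 1:2, drop = FALSE]
  xy <- scale(xy)   # SOM inputs on a common scale, else PC1 dominates
  if (nrow(xy) < nUnits)
    stop("fewer cells (", nrow(xy), ") than map units (", nUnits, ")")
  cd <- colData(x)
  if (!"progression" %in% colnames(cd))
    stop("run computeTrajectory() before somPartition()")
  unit <- if (method == "som") {
    .batchSOM1d(xy, nUnits, epochs)
  } else {
    qs <- stats::quantile(xy[, 1],
                          probs = seq(0, 1, length.out = nUnits + 1))
    binOf <- cut(xy[, 1], unique(qs), include.lowest = TRUE,
                 labels = FALSE)
    centers <- do.call(rbind, lapply(seq_len(nUnits), function(j)
      colMeans(xy[binOf == j, , drop = FALSE])))
    stats::kmeans(xy, centers = centers)$cluster
  }
  present <- sort(unique(unit))
  if (length(present) < nUnits)
    warning(nUnits - length(present), " empty map unit(s)")
  meanOff <- tapply(cd$off_distance, unit, mean)
  altUnit <- as.integer(names(which.max(meanOff)))
  meanProg <- tapply(cd$progression, unit, mean)
  prodUnits <- setdiff(present, altUnit)
  prodUnits <- prodUnits[order(meanProg[as.character(prodUnits)])]
  labels <- c("Fib", "Early", "Late", "Pluri")[seq_along(prodUnits)]
  lab <- character(length(unit))
  lab[unit == altUnit] <- "Alt"
  for (i in seq_along(prodUnits)) lab[unit == prodUnits[i]] <- labels[i]
  cd$som_unit <- unit
  cd$som_group <- factor(lab, levels = c("Fib", "Early", "Late", "Pluri",
                                         "Alt"))
  colData(x) <- cd
  x
}

#' Ward hierarchical clustering of cells
#'
#' Agglomerative clustering of unscaled \code{40 - dCt} profiles under
#' Ward's minimum-variance criterion (no standardization, undetected
#' entries as level 0).
#'
#' @param x a normalized \linkS4class{ReprogramSet}.
#' @param undetected undetected-level policy.
#' @return an \code{\link[stats]{hclust}} object (merge heights in
#'   \code{ward.D2} distance units).
#' @export
wardCluster <- function(x, undetected = "zero") {
  lv <- t(levelMatrix(x, undetected))
  if (nrow(lv) < 2L) stop("need at least 2 cells")
  stats::hclust(stats::dist(lv), method = "ward.D2")
}

#' Serialize a dendrogram in Newick format
#'
#' @param hc an \code{\link[stats]{hclust}} object.
#' @return single Newick string (merge heights as branch lengths).
#' @export
dendrogramToNewick <- function(hc) {
  lab <- hc$labels
  if (is.null(lab)) lab <- as.character(seq_along(hc$order))
  node <- function(i, parentH) {
    if (i < 0) {
      sprintf("%s:%g", lab[-i], parentH)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%g", node(hc$merge[i, 1], h),
              node(hc$merge[i, 2], h), parentH - h)
    }
  }
  top <- nrow(hc$merge)
  paste0("(", node(hc$merge[top, 1], hc$height[top]), ",",
         node(hc$merge[top, 2], hc$height[top]), ");")
}

#' Linear regression of the productive trajectory
#'
#' Ordinary least squares of PC2 on PC1 over productive-trajectory cells,
#' quantifying how linear the fibroblast-to-hESC path is in PCA space.
#'
#' @param scores cells x >=2 matrix of PC scores (productive cells only;
#'   exclude Alt first).
#' @return list with \code{slope}, \code{intercept}, \code{r_squared}.
#' @export
productiveRegression <- function(scores) {
  if (nrow(scores) < 3L) stop("need at least 3 cells")
  fit <- stats::lm(scores[, 2] ~ scores[, 1])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Tukey-Kramer contrasts between cell groups
#'
#' For each gene, all pairwise differences in mean \code{40 - dCt} level
#' between groups, with Tukey honest-significant-difference adjusted
#' p-values (the Tukey-Kramer form for unequal group sizes). Groups with
#' fewer than two cells are dropped with a warning.
#'
#' @param x a normalized \linkS4class{ReprogramSet}.
#' @param groups factor of group labels per cell (e.g.
#'   \code{colData(x)$som_group}).
#' @param genes gene subset (default: all non-normalizer genes).
#' @param alpha significance level.
#' @param undetected undetected-level policy.
#' @return data.frame with columns \code{gene}, \code{comparison},
#'   \code{diff}, \code{lwr}, \code{upr}, \code{p_adj},
#'   \code{significant}, ordered by each gene's minimum adjusted p.
#' @export
tukeyKramer <- function(x, groups, genes = NULL, alpha = 0.05,
                        undetected = "zero") {
  lv <- levelMatrix(x, undetected)
  if (is.null(genes)) genes <- rownames(lv)
  groups <- factor(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("group(s) with < 2 cells skipped: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    lv <- lv[, keep, drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2L) stop("need at least 2 groups with >= 2 cells")
  res <- lapply(genes, function(g) {
    y <- lv[g, ]
    if (stats::sd(y) == 0) return(NULL)   # degenerate: no variation
    tk <- stats::TukeyHSD(stats::aov(y ~ grp,
                                     data = data.frame(y = y,
                                                       grp = groups)))$grp
    data.frame(gene = g, comparison = rownames(tk), diff = tk[, "diff"],
               lwr = tk[, "lwr"], upr = tk[, "upr"],
               p_adj = tk[, "p adj"],
               significant = tk[, "p adj"] < alpha,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no testable genes")
  minP <- tapply(out$p_adj, out$gene, min)
  out[order(minP[out$gene], out$gene, out$p_adj), ]
}

#' Strongest gene-gene correlations as an edge list
#'
#' The top pairwise Pearson correlations of quantitative levels over the
#' analyzed cells, exported as a network edge list (layout is left to
#' external tools).
#'
#' @param x a normalized \linkS4class{ReprogramSet}.
#' @param n number of edges to keep.
#' @param undetected undetected-level policy.
#' @return data.frame \code{gene_a}, \code{gene_b}, \code{r}, strongest
#'   first.
#' @export
topCorrelationEdges <- function(x, n = 100, undetected = "zero") {
  lv <- levelMatrix(x, undetected)
  keep <- apply(lv, 1, stats::sd) > 0
  r <- stats::cor(t(lv[keep, , drop = FALSE]))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(gene_a = rownames(r)[idx[, 1]],
                    gene_b = rownames(r)[idx[, 2]], r = r[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r)), ]
  utils::head(out, n)
}
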