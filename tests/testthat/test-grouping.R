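# build a normalized ReprogramSet whose level matrix equals `lv`
# (genes x cells), all entries detected
rsFromLevels <- function(lv) {
  ct <- 45 - lv                       # GAPDH Ct 5 => level = 45 - ct
  ct <- rbind(ct, GAPDH = rep(5, ncol(lv)))
  colnames(ct) <- paste0("c", seq_len(ncol(ct)))
  normalizeToGapdh(rsFromCt(ct))
}

test_that("PCA variance fractions match a direct eigendecomposition", {
  set.seed(31)
  lv <- matrix(rnorm(3 * 5, 25, 3), nrow = 3,
               dimnames = list(paste0("g", 1:3), NULL))
  ord <- runPCA(rsFromLevels(lv))
  ev <- eigen(cov(t(lv)))$values
  expect_equal(varianceExplained(ord), ev / sum(ev), tolerance = 1e-10)
  expect_equal(sum(varianceExplained(ord)), 1, tolerance = 1e-10)
})

test_that("rank-1 data put all variance on PC1", {
  lv <- 24 + outer(c(2, 1, 0.5), c(1, 2, 3, 4))
  ord <- runPCA(rsFromLevels(lv))
  expect_equal(varianceExplained(ord)[1], 1, tolerance = 1e-10)
})

test_that("duplicated cells get identical scores; order does not matter", {
  set.seed(32)
  lv <- matrix(rnorm(4 * 6, 25, 2), nrow = 4)
  lv <- cbind(lv, lv[, 1])            # duplicate first cell
  ord <- runPCA(rsFromLevels(lv))
  expect_equal(pcScores(ord)[1, ], pcScores(ord)[7, ],
               ignore_attr = TRUE)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  ord2 <- runPCA(rsFromLevels(lv[, perm]))
  expect_equal(varianceExplained(ord2), varianceExplained(ord))
  expect_error(runPCA(rsFromLevels(matrix(25, 3, 5))), "degenerate")
})

test_that("the 5x1 SOM separates well-separated clusters and is deterministic", {
  sim <- processedSim(seed = 33)
  rs <- sim$rs
  set.seed(33)
  clusterCenters <- cbind(c(-20, -10, 0, 10, 20), c(-2, 1, 0, -1, 2))
  idx <- rep(1:5, length.out = ncol(rs))
  scores <- clusterCenters[idx, ] + matrix(rnorm(2 * ncol(rs), 0, 0.1),
                                           ncol = 2)
  colnames(scores) <- c("PC1", "PC2")
  ord <- new("OrdinationResult", scores = cbind(scores),
             loadings = matrix(0, 2, 2), varExplained = c(0.6, 0.4))
  a <- somPartition(rs, ord)
  b <- somPartition(rs, ord)
  expect_identical(colData(a)$som_unit, colData(b)$som_unit)
  tab <- table(colData(a)$som_unit, idx)
  expect_true(all(apply(tab > 0, 2, sum) == 1))  # one unit per cluster
  expect_equal(nrow(tab), 5)                     # and no unit collapses
})

test_that("SOM groups recover the alternate branch and order the rest", {
  sim <- processedSim(seed = 34)
  rs <- somPartition(sim$rs)
  truth <- sim$truth$cells
  alt <- truth$branch[match(colnames(rs), truth$cell_id)] == "alternate"
  grp <- colData(rs)$som_group
  expect_gte(sum(grp[alt] == "Alt") / sum(alt), 0.8)
  m <- tapply(colData(rs)$progression, grp, mean)[c("Fib", "Early",
                                                    "Late", "Pluri")]
  expect_true(all(diff(m) > 0))
  expect_error(somPartition(rs[, 1:3]), "fewer cells")
  km <- somPartition(sim$rs, method = "kmeans")
  expect_gte(sum(colData(km)$som_group[alt] == "Alt") / sum(alt), 0.8)
})

test_that("Ward clustering reproduces brute-force ESS agglomeration", {
  ess <- function(x) sum(sweep(x, 2, colMeans(x))^2)
  bruteWard <- function(x) {
    cl <- lapply(seq_len(nrow(x)), identity)
    parts <- list()
    while (length(cl) > 1) {
      best <- NULL
      for (i in seq_along(cl)) for (j in seq_len(i - 1)) {
        d <- ess(x[c(cl[[i]], cl[[j]]), , drop = FALSE]) -
          ess(x[cl[[i]], , drop = FALSE]) -
          ess(x[cl[[j]], , drop = FALSE])
        if (is.null(best) || d < best$d) best <- list(d = d, i = i,
                                                      j = j)
      }
      cl[[best$j]] <- c(cl[[best$j]], cl[[best$i]])
      cl <- cl[-best$i]
      parts[[length(parts) + 1]] <-
        lapply(cl, function(ix) sort(ix))
    }
    parts
  }
  set.seed(35)
  lv <- matrix(rnorm(5 * 8, 25, 4), nrow = 5)
  hc <- wardCluster(rsFromLevels(lv))
  x <- t(lv)
  parts <- bruteWard(x)
  for (k in 7:1) {
    ct <- cutree(hc, k)
    hcPart <- lapply(split(seq_len(8), ct), sort)
    brPart <- parts[[8 - k]]
    expect_setequal(lapply(hcPart, paste, collapse = ","),
                    lapply(brPart, paste, collapse = ","))
  }
})

test_that("Ward merges coincident cells first at height zero", {
  lv <- cbind(c(25, 20, 22), c(25, 20, 22), c(30, 28, 35))
  rownames(lv) <- paste0("g", 1:3)
  hc <- wardCluster(rsFromLevels(lv))
  expect_equal(hc$height[1], 0)
  expect_setequal(-hc$merge[1, ], c(1, 2))
  nwk <- dendrogramToNewick(hc)
  expect_match(nwk, "^\\(.*\\);$")
  expect_equal(length(ape::read.tree(text = nwk)$tip.label), 3)
})

test_that("productive regression matches hand-computed least squares", {
  toy <- cbind(c(0, 1, 2, 3), c(0, 1, 2, 2))
  fit <- productiveRegression(toy)
  # Sxx = 5, Sxy = 3.5, Syy = 2.75  =>  R^2 = 3.5^2 / (5 * 2.75)
  expect_equal(fit$r_squared, 12.25 / 13.75, tolerance = 1e-10)
  expect_equal(fit$slope, 0.7, tolerance = 1e-10)

  collinear <- cbind(1:10, 2 * (1:10) + 3)
  expect_equal(productiveRegression(collinear)$r_squared, 1)

  set.seed(36)
  noise <- cbind(rnorm(3000), rnorm(3000))
  expect_lt(productiveRegression(noise)$r_squared, 0.01)
  expect_error(productiveRegression(toy[1:2, ]), "3 cells")
})

test_that("Tukey-Kramer matches a direct studentized-range computation", {
  set.seed(37)
  groups <- factor(rep(c("A", "B", "C"), times = c(8, 12, 10)))
  lv <- matrix(rnorm(30, 25, 2) + c(0, 3, 5)[as.integer(groups)],
               nrow = 1, dimnames = list("GX", NULL))
  tk <- tukeyKramer(rsFromLevels(lv), groups)
  y <- lv[1, ]
  mse <- sum(tapply(y, groups, function(v) sum((v - mean(v))^2))) /
    (30 - 3)
  ms <- tapply(y, groups, mean)
  ns <- table(groups)
  pair <- function(a, b) {
    se <- sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
    ptukey(abs(ms[[a]] - ms[[b]]) / se, 3, 27, lower.tail = FALSE)
  }
  expect_equal(tk$p_adj[tk$comparison == "B-A"], pair("A", "B"),
               tolerance = 1e-8)
  expect_equal(tk$p_adj[tk$comparison == "C-B"], pair("B", "C"),
               tolerance = 1e-8)
})

test_that("Tukey-Kramer has power and respects degenerate groups", {
  set.seed(38)
  groups <- factor(rep(c("lo", "hi"), each = 20))
  lv <- matrix(c(rnorm(20, 20, 1), rnorm(20, 30, 1)), nrow = 1,
               dimnames = list("GX", NULL))
  tk <- tukeyKramer(rsFromLevels(lv), groups)
  expect_true(all(tk$significant))

  same <- matrix(rnorm(40, 25, 5), nrow = 1,
                 dimnames = list("GX", NULL))
  tk2 <- tukeyKramer(rsFromLevels(same), groups)
  expect_false(any(tk2$significant))

  tiny <- factor(rep(c("a", "b", "c"), times = c(19, 20, 1)))
  expect_warning(tukeyKramer(rsFromLevels(lv), tiny), "skipped")
})

test_that("gene-wise Tukey families reject at the nominal rate under the null", {
  set.seed(39)
  n <- 1000
  groups <- factor(rep(c("A", "B", "C", "D"), each = 10))
  lv <- matrix(rnorm(n * 40, 25, 2), nrow = n,
               dimnames = list(paste0("g", seq_len(n)), NULL))
  tk <- tukeyKramer(rsFromLevels(lv), groups)
  famRate <- mean(tapply(tk$significant, tk$gene, any))
  se <- sqrt(0.05 * 0.95 / n)
  expect_gt(famRate, 0.05 - 2.6 * se)
  expect_lt(famRate, 0.05 + 2.6 * se)
})

test_that("top correlation edges are strongest-first and bounded", {
  sim <- processedSim(seed = 40)
  edges <- topCorrelationEdges(sim$rs, n = 25)
  expect_equal(nrow(edges), 25)
  expect_true(all(diff(abs(edges$r)) <= 1e-12))
  expect_true(all(edges$gene_a != edges$gene_b))
})
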