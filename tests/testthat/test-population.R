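test_that("PCA recovers a planted rank-1 axis and is duplication-invariant", {
  set.seed(2)
  n_genes <- 60; n_cells <- 200
  w <- rnorm(n_genes); w <- w / sqrt(sum(w^2))
  act <- rnorm(n_cells, sd = 4)
  m <- outer(w, act) + matrix(rnorm(n_genes * n_cells, sd = 0.1), n_genes)
  dimnames(m) <- list(sprintf("g%02d", 1:n_genes),
                      sprintf("c%03d", 1:n_cells))
  pca <- runPCA(m, n_pcs = 5)
  expect_gt(pca$var_explained[1], 0.9)
  cosine <- abs(sum(pca$loadings[, 1] * w))
  expect_gt(cosine, 0.99)
  ## sign convention: largest-magnitude loading is positive
  expect_gt(pca$loadings[which.max(abs(pca$loadings[, 1])), 1], 0)
  ## duplicating every cell leaves loadings unchanged
  m2 <- cbind(m, m)
  colnames(m2) <- sprintf("c%03d", 1:(2 * n_cells))
  pca2 <- runPCA(m2, n_pcs = 5)
  expect_equal(pca2$loadings[, 1], pca$loadings[, 1], tolerance = 1e-6)
  expect_error(runPCA(m, n_pcs = 60), "exceeds")
})

test_that("isotropic noise spreads variance nearly evenly over components", {
  set.seed(3)
  m <- matrix(rnorm(10 * 2000), 10, 2000,
              dimnames = list(sprintf("g%02d", 1:10),
                              sprintf("c%04d", 1:2000)))
  pca <- runPCA(m, n_pcs = 9)
  expect_lt(max(pca$var_explained) / min(pca$var_explained), 1.5)
})

test_that("SNN clustering separates two well-separated blobs and collapses degenerate geometry", {
  set.seed(4)
  blob <- rbind(matrix(rnorm(50 * 2, mean = 0, sd = 0.1), ncol = 2),
                matrix(rnorm(50 * 2, mean = 5, sd = 0.1), ncol = 2))
  rownames(blob) <- sprintf("c%03d", 1:100)
  cl <- snnCluster(blob, k = 10, resolution = 0.1, seed = 1)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:50])), 1)
  expect_equal(length(unique(cl[51:100])), 1)
  expect_equal(sort(unique(as.integer(cl))), c(0L, 1L))

  flat <- matrix(1, 30, 2, dimnames = list(sprintf("c%02d", 1:30), NULL))
  expect_equal(length(unique(snnCluster(flat, k = 5, seed = 1))), 1)
  expect_error(snnCluster(flat, k = 30, seed = 1), "lower k")
})

test_that("clustering is invariant to cell-order permutation", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(40 * 3, 0, 0.2), ncol = 3),
               matrix(rnorm(40 * 3, 4, 0.2), ncol = 3),
               matrix(rnorm(40 * 3, -4, 0.2), ncol = 3))
  rownames(pts) <- sprintf("c%03d", 1:120)
  cl1 <- snnCluster(pts, k = 10, resolution = 0.2, seed = 2)
  perm <- sample(nrow(pts))
  cl2 <- snnCluster(pts[perm, ], k = 10, resolution = 0.2, seed = 2)
  ## same partition up to label renaming
  expect_equal(mclust::adjustedRandIndex(cl1[rownames(pts)],
                                         cl2[rownames(pts)]), 1)
})

test_that("planted compartments are recovered after compartment annotation", {
  sim <- default_sim()
  sce <- scaleAndRegress(logNormalize(qcFilter(sim$sce)))
  tr <- sim$truth
  vg <- selectVariableGenes(sce)
  pca <- runPCA(sce, genes = vg, n_pcs = 7)
  cl <- snnCluster(pca$scores, k = 30, seed = 1)
  sigs <- list(
    tumor = GeneSignature("tumor", c(tr$modules$MAPK, tr$modules$AC)),
    microglia = GeneSignature("microglia", tr$modules$microglia),
    macrophage = GeneSignature("macrophage", tr$modules$macrophage),
    Tcell = GeneSignature("Tcell", tr$modules$Tcell))
  sc <- scoreCells(sce, sigs)
  ann <- annotateCompartments(cl, sc)
  merged <- setNames(ann[as.character(cl)], names(cl))
  truth <- ifelse(tr$compartment == "cancer", "tumor", tr$compartment)
  expect_gt(mclust::adjustedRandIndex(merged, truth[names(merged)]), 0.9)
  expect_gt(mean(merged == truth[names(merged)]), 0.98)
})

test_that("compartment annotation takes the argmax and breaks ties lexicographically", {
  scores <- matrix(c(2, 0.5, 0.4, 0.3), 1, 4,
                   dimnames = list("c1", c("tumor", "microglia",
                                           "macrophage", "Tcell")))
  labels <- setNames(0L, "c1")
  expect_equal(unname(annotateCompartments(labels, scores)["0"]), "tumor")
  tied <- matrix(c(1, 1), 1, 2,
                 dimnames = list("c1", c("beta", "alpha")))
  expect_warning(out <- annotateCompartments(labels, tied), "tie")
  expect_equal(unname(out["0"]), "alpha")
  expect_error(annotateCompartments(labels, scores[, 0, drop = FALSE]))
})

test_that("Wilcoxon p-values match full permutation enumeration for small groups", {
  set.seed(6)
  cases <- list(
    list(x = c(1.2, 3.4, 2.2), y = c(0.1, 0.4, 5, 2)),
    list(x = rnorm(5), y = rnorm(6)),
    list(x = c(1, 1, 2, 2), y = c(1, 2, 2, 3)),        # heavy ties
    list(x = rep(1, 4), y = rep(1, 4)),                # all tied
    list(x = c(0, 0, 0, 1), y = c(2, 3, 4, 5)),
    list(x = rpois(7, 3), y = rpois(8, 3)))
  for (cs in cases) {
    got <- wilcoxonRankSum(cs$x, cs$y)$p.value
    expect_equal(got, perm_wilcox_p(cs$x, cs$y), tolerance = 1e-12)
  }
  ## identical groups: nothing is significant
  expect_equal(wilcoxonRankSum(rep(2, 5), rep(2, 5))$p.value, 1)

  ## large-sample path against the reference implementation's tie-corrected
  ## normal approximation (no continuity correction)
  set.seed(8)
  x <- rpois(30, 5); y <- rpois(40, 6)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(wilcoxonRankSum(x, y)$p.value, ref$p.value,
               tolerance = 1e-10)
})

test_that("a gene expressed only in one group gets the exact rank-sum tail", {
  x <- c(3.1, 2.8, 3.5, 2.9)  # expressed only in group A
  y <- rep(0, 4)
  got <- wilcoxonRankSum(x, y)$p.value
  expect_equal(got, perm_wilcox_p(x, y), tolerance = 1e-12)
  expect_equal(got, 2 / choose(8, 4), tolerance = 1e-12)
})

test_that("planted marker genes are recovered at Bonferroni significance", {
  set.seed(7)
  n <- 200
  base <- matrix(rlnorm(970 * 2 * n, 0, 0.3), 970, 2 * n)
  markers <- cbind(matrix(rlnorm(30 * n, log(2), 0.3), 30, n),  # 2x in A
                   matrix(rlnorm(30 * n, 0, 0.3), 30, n))
  m <- rbind(base, markers)
  rownames(m) <- c(sprintf("b%03d", 1:970), sprintf("mk%02d", 1:30))
  colnames(m) <- sprintf("c%03d", 1:(2 * n))
  sce <- toy_lognorm(m)
  de <- clusterMarkers(sce, cells1 = colnames(m)[1:n],
                       cells2 = colnames(m)[(n + 1):(2 * n)])
  hits <- de$gene[de$p_bonferroni < 0.05 & de$log_fold_change > 0]
  expect_gte(sum(sprintf("mk%02d", 1:30) %in% hits), 27)
  ## q_bh is monotone in p and bounded by Bonferroni
  ord <- order(de$p_value)
  expect_true(all(diff(de$q_bh[ord]) >= -1e-12))
  expect_true(all(de$q_bh <= de$p_bonferroni + 1e-12))
})

test_that("marker testing warns and uses the exact test for tiny groups", {
  m <- matrix(rpois(40, 4) + 0.5, 4, 10,
              dimnames = list(sprintf("g%d", 1:4), sprintf("c%02d", 1:10)))
  sce <- toy_lognorm(m)
  expect_warning(clusterMarkers(sce, cells1 = colnames(m)[1:2]),
                 "fewer than 3")
  expect_error(clusterMarkers(sce, cells1 = character(0)),
               "non-empty")
})
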