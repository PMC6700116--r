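test_that("the fold-enrichment score is the signature/all-genes mean ratio", {
  m <- matrix(c(2, 1, 0), 3, 1, dimnames = list(c("a", "b", "c"), "cell1"))
  sce <- toy_lognorm(m)
  expect_equal(scoreCells(sce, GeneSignature("S", "a"))["cell1", "S"], 2)
  ## signature covering all genes scores exactly 1 for every cell
  set.seed(1)
  m2 <- matrix(rexp(50 * 8), 50, 8,
               dimnames = list(sprintf("g%02d", 1:50),
                               sprintf("c%d", 1:8)))
  sce2 <- toy_lognorm(m2)
  s <- scoreCells(sce2, GeneSignature("ALL", rownames(m2)))
  expect_equal(unname(s[, 1]), rep(1, 8), tolerance = 1e-12)
  expect_error(scoreCells(sce2, GeneSignature("NONE", "absent_gene")),
               "no genes")
})

test_that("scores are scale-free and conserve the expression-weighted ratio", {
  set.seed(2)
  m <- matrix(rexp(60 * 5), 60, 5,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("c%d", 1:5)))
  sigs <- list(A = GeneSignature("A", rownames(m)[1:20]),
               B = GeneSignature("B", rownames(m)[21:45]),
               C = GeneSignature("C", rownames(m)[46:60]))
  s1 <- scoreCells(toy_lognorm(m), sigs)
  s2 <- scoreCells(toy_lognorm(sweep(m, 2, c(2, 3, 0.5, 10, 1), "*")), sigs)
  expect_equal(s1, s2, tolerance = 1e-12)
  ## partition reconstruction: sum_S |S| * score / N = 1
  recon <- (20 * s1[, "A"] + 25 * s1[, "B"] + 15 * s1[, "C"]) / 60
  expect_equal(unname(recon), rep(1, 5), tolerance = 1e-12)
})

test_that("planted module carriers score high, non-carriers near 1", {
  ## homogeneous baseline, 50-gene module up-regulated 3x in carriers
  set.seed(6)
  n_genes <- 1000; n_cells <- 200
  m <- matrix(rnorm(n_genes * n_cells, 1, 0.1), n_genes, n_cells,
              dimnames = list(sprintf("g%04d", 1:n_genes),
                              sprintf("c%03d", 1:n_cells)))
  m <- pmax(m, 0)
  carriers <- sprintf("c%03d", 1:80)
  mod <- sprintf("g%04d", 1:50)
  m[mod, carriers] <- 3 * m[mod, carriers]
  s <- scoreCells(toy_lognorm(m), GeneSignature("mod", mod))[, 1]
  expect_gt(min(s[carriers]), 2)
  non <- setdiff(colnames(m), carriers)
  expect_lt(max(abs(s[non] - 1)), 0.2)

  ## in the full generator, MAPK-high cancer cells clear the subpopulation
  ## threshold while immune compartments stay near baseline
  sim <- default_sim()
  sce <- logNormalize(qcFilter(sim$sce))
  tr <- sim$truth
  can <- intersect(names(tr$compartment)[tr$compartment == "cancer"],
                   colnames(sce))
  sc <- scoreCells(sce[, can], GeneSignature("MAPK", tr$modules$MAPK))[, 1]
  expect_gt(min(sc[tr$mapk_high[can]]), 2)
})

test_that("cluster-level scores use the per-cluster mean expression", {
  set.seed(3)
  m <- matrix(rexp(40 * 6), 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("c%d", 1:6)))
  sce <- toy_lognorm(m)
  sig <- GeneSignature("S", rownames(m)[1:10])
  labels <- setNames(c(0L, 0L, 0L, 1L, 2L, 2L), colnames(m))
  cs <- scoreClusters(sce, labels, sig)
  ## a single-cell cluster equals the per-cell score
  expect_equal(cs["1", "S"], scoreCells(sce, sig)["c4", "S"])
  ## identical mean vectors give identical scores
  m2 <- cbind(m, m[, 1:3])
  colnames(m2) <- sprintf("c%d", 1:9)
  labels2 <- setNames(c(rep(0L, 3), rep(2L, 3), rep(1L, 3)), colnames(m2))
  cs2 <- scoreClusters(toy_lognorm(m2), labels2, sig)
  expect_equal(cs2["0", "S"], cs2["1", "S"])
  expect_error(scoreClusters(sce, labels[0], sig), "labels")
})

test_that("subpopulation assignment is strict at the threshold and monotone", {
  scores <- matrix(c(2.5, 2.51, 1, 3), 4, 1,
                   dimnames = list(sprintf("c%d", 1:4), "MAPK"))
  out <- assignSubpopulations(scores, "MAPK", threshold = 2.5)
  expect_length(out$c1, 0)        # exactly 2.5 is not assigned
  expect_equal(out$c2, "MAPK")
  expect_equal(out$c4, "MAPK")
  all_of <- assignSubpopulations(scores, "MAPK", threshold = -Inf)
  expect_true(all(lengths(all_of) == 1))
  none <- assignSubpopulations(scores, "MAPK", threshold = Inf)
  expect_true(all(lengths(none) == 0))
  expect_error(assignSubpopulations(scores, "bogus"), "unknown programme")
})

test_that("atlas signatures apply strict fold-change and q cutoffs and skip thin subtypes", {
  de1 <- data.frame(gene = sprintf("g%d", 1:6),
                    log_fold_change = c(log(1.5), log(1.51), log(2),
                                        log(3), log(4), -log(2)),
                    p_bonferroni = c(0.01, 0.01, 0.2, 0.01, 0.04, 0.001))
  ## g1 fails (fc not > 1.5), g3 fails q, g6 is down; g2, g4, g5 pass
  de_thin <- data.frame(gene = "only_one",
                        log_fold_change = log(5), p_bonferroni = 1e-5)
  expect_message(
    sigs <- deriveAtlasSignatures(list(good = de1, thin = de_thin),
                                  universe = c(sprintf("g%d", 1:6))),
    "skipped")
  expect_named(sigs, "good")
  expect_setequal(geneIds(sigs$good), c("g2", "g4", "g5"))
  ## without a universe restriction the single-gene subtype is kept
  sigs2 <- deriveAtlasSignatures(list(thin = de_thin))
  expect_length(geneIds(sigs2$thin), 1)
})

test_that("tumor-baseline normalization makes the tumor mean exactly 1", {
  set.seed(4)
  scores <- matrix(rexp(30 * 2, rate = 0.5), 30, 2,
                   dimnames = list(sprintf("c%02d", 1:30),
                                   c("sigA", "sigB")))
  tumor <- sprintf("c%02d", 1:10)
  out <- normalizeToTumor(scores, tumor)
  expect_equal(unname(colMeans(out[tumor, ])), c(1, 1), tolerance = 1e-12)
  ## planted ratio is preserved: cells scoring 4x the tumor baseline
  scores2 <- rbind(scores, high1 = 4 * colMeans(scores[tumor, ]))
  out2 <- normalizeToTumor(scores2, tumor)
  expect_equal(unname(out2["high1", ]), c(4, 4), tolerance = 1e-12)
  expect_error(normalizeToTumor(scores * 0, tumor), "zero tumor-baseline")
})

test_that("per-type subsampling is seeded, clamped, and unbiased", {
  set.seed(5)
  scores <- matrix(rnorm(700, mean = 5), 700, 1,
                   dimnames = list(sprintf("c%03d", 1:700), "S"))
  types <- setNames(rep(c("PA", "HGG"), c(400, 300)), rownames(scores))
  r1 <- subsampleForComparison(scores, types, n = 250L, seed = 9L)
  r2 <- subsampleForComparison(scores, types, n = 250L, seed = 9L)
  expect_identical(r1$cells, r2$cells)
  expect_warning(subsampleForComparison(scores[1:400, , drop = FALSE],
                                        types[1:400], n = 500L, seed = 9L),
                 "all used")
  r3 <- suppressWarnings(subsampleForComparison(scores, types, n = 500L,
                                                seed = 9L))
  expect_equal(sum(startsWith(r3$cells, "c") &
                   types[r3$cells] == "HGG"), 300)
  ## subsampled mean within 2 SE of the full-population mean
  full <- mean(scores[names(types)[types == "PA"], 1])
  se <- sd(scores[names(types)[types == "PA"], 1]) / sqrt(250)
  expect_lt(abs(r1$means["PA", "S"] - full), 2 * se)
})
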