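test_that("cell QC thresholds are boundary-exact", {
  ## 1200 genes; one cell expresses exactly 1000, one expresses 999
  n_genes <- 1200
  m <- matrix(0L, n_genes, 3,
              dimnames = list(sprintf("g%04d", 1:n_genes),
                              c("at1000", "at999", "rich")))
  m[1:1000, 1] <- 1L
  m[1:999, 2] <- 1L
  m[, 3] <- 1L
  sce <- toy_counts(m)
  out <- qcFilter(sce, pipelineConfig(min_cells_per_gene = 1L))
  expect_setequal(colnames(out), c("at1000", "rich"))

  ## mito fraction: exactly 4% is retained, just above is not
  m2 <- matrix(1L, 1100, 2, dimnames = list(
    c(sprintf("g%04d", 1:1099), "MT-1"), c("ok", "high")))
  m2["MT-1", "ok"] <- 0L
  m2[1:1099, "ok"] <- 3L       # zero mito
  m2["MT-1", "high"] <- 100L   # 100 / (1099 + 100) = 8.3%
  sce2 <- toy_counts(m2)
  out2 <- qcFilter(sce2, pipelineConfig(min_cells_per_gene = 1L))
  expect_identical(colnames(out2), "ok")
})

test_that("a matrix where everything passes QC is unchanged, and QC is idempotent", {
  sim <- simulateCells(generatorParams(
    n_cells = c(cancer = 30L, microglia = 20L, macrophage = 10L,
                Tcell = 10L), seed = 3L))
  f1 <- qcFilter(sim$sce)
  f2 <- qcFilter(f1)
  expect_identical(dim(f2), dim(f1))
  expect_identical(colnames(f2), colnames(f1))
  expect_identical(rownames(f2), rownames(f1))
})

test_that("planted QC failures are removed exactly (80 of 100 retained)", {
  sim <- simulateCells(generatorParams(
    n_cells = c(cancer = 40L, microglia = 20L, macrophage = 10L,
                Tcell = 10L),
    n_lowgene_fail = 10L, n_mito_fail = 10L, seed = 11L))
  out <- qcFilter(sim$sce)
  expect_equal(ncol(out), 80)
  planted_ok <- names(sim$truth$compartment)[
    !(sim$truth$lowgene_fail | sim$truth$mito_fail)]
  expect_setequal(colnames(out), planted_ok)
  rep <- metadata(out)$qc_report
  expect_equal(rep$n_removed[rep$step == "low_gene_cells"], 10)
  expect_equal(rep$n_removed[rep$step == "high_mito_cells"], 10)
})

test_that("log-normalization follows ln(1 + count/total * 10000)", {
  m <- matrix(c(10L, 90L, 0L,
                20L, 180L, 0L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  sce <- logNormalize(toy_counts(m))
  ln <- as.matrix(assay(sce, "lognorm"))
  expect_equal(ln["g1", "c1"], log(1 + 10 / 100 * 1e4), tolerance = 1e-12)
  expect_equal(ln["g1", "c1"], 6.90875, tolerance = 1e-5)
  expect_equal(ln["g3", "c1"], 0)
  ## proportional cells normalize identically
  expect_equal(ln[, "c1"], ln[, "c2"])
})

test_that("normalization conserves the scale factor per cell", {
  sim <- simulateCells(generatorParams(
    n_cells = c(cancer = 20L, microglia = 10L, macrophage = 5L,
                Tcell = 5L), seed = 8L))
  sce <- logNormalize(sim$sce)
  sums <- Matrix::colSums(expm1(assay(sce, "lognorm")))
  expect_true(max(abs(sums - 1e4)) < 1e-6)
  ## zero-total cell errors by name
  m <- matrix(c(1L, 0L), 1, 2, dimnames = list("g1", c("c1", "dead")))
  expect_error(logNormalize(toy_counts(m)), "dead")
})

test_that("scaling with no covariates reduces to a per-gene z-score", {
  set.seed(1)
  m <- matrix(rpois(200, 5), 10, 20,
              dimnames = list(sprintf("g%02d", 1:10),
                              sprintf("c%02d", 1:20)))
  sce <- logNormalize(toy_counts(m))
  sce <- scaleAndRegress(sce, covariates = character(0))
  sc <- assay(sce, "scaled")
  ln <- as.matrix(assay(sce, "lognorm"))
  manual <- t(scale(t(ln)))
  expect_equal(as.numeric(sc), as.numeric(manual), tolerance = 1e-10)
})

test_that("scaled output has mean 0 / SD 1 and zero rows for flat genes", {
  sim <- simulateCells(generatorParams(
    n_cells = c(cancer = 40L, microglia = 20L, macrophage = 10L,
                Tcell = 10L), seed = 21L))
  sce <- scaleAndRegress(logNormalize(sim$sce))
  sc <- assay(sce, "scaled")
  mus <- rowMeans(sc)
  sds <- apply(sc, 1, sd)
  nonflat <- sds > 0
  expect_true(max(abs(mus)) < 1e-8)
  expect_true(max(abs(sds[nonflat] - 1)) < 1e-6)
  ## a gene perfectly linear in detected-gene count regresses to zero
  ln <- as.matrix(assay(sce, "lognorm"))
  nd <- Matrix::colSums(assay(sce, "counts") > 0)
  ln["G0450", ] <- 0.001 * nd
  assay(sce, "lognorm") <- ln
  sce2 <- scaleAndRegress(sce, covariates = "n_detected_genes")
  expect_true(all(abs(assay(sce2, "scaled")["G0450", ]) < 1e-8))
})

test_that("covariate regression strips a planted detected-genes trend", {
  set.seed(42)
  n <- 500
  signal <- rnorm(n)
  nd <- sample(1000:4000, n)
  g <- 1 + 0.5 * signal + 0.001 * nd + rnorm(n, 0, 0.05)
  m <- rbind(target = pmax(g, 0),
             matrix(rpois(5 * n, 5), 5, n,
                    dimnames = list(sprintf("f%d", 1:5), NULL)))
  colnames(m) <- sprintf("c%03d", 1:n)
  sce <- toy_lognorm(m)
  colData(sce)$n_detected_genes <- nd
  sce <- scaleAndRegress(sce, covariates = "n_detected_genes")
  res <- assay(sce, "scaled")["target", ]
  expect_lt(abs(cor(res, nd)), 0.05)
  expect_gt(cor(res, signal), 0.9)
})

test_that("singular covariate designs error with advice", {
  m <- matrix(rpois(40, 5), 4, 10,
              dimnames = list(sprintf("g%d", 1:4), sprintf("c%d", 1:10)))
  sce <- logNormalize(toy_counts(m))
  colData(sce)$n_detected_genes <- rep(7, 10)  # collinear with intercept
  expect_error(scaleAndRegress(sce, covariates = "n_detected_genes"),
               "singular")
})

test_that("variable-gene selection applies closed mean bounds and strict SD bound", {
  ## hand-built lognorm layer: exact means and SDs
  flat <- rep(1, 8)
  lowmean <- c(rep(0, 7), 0.9)              # mean ~0.11 < 0.25
  atboundary <- c(rep(0, 4), rep(0.5, 4))   # mean 0.25, sd ~0.267 (fails SD)
  spread <- c(rep(0, 4), rep(3, 4))         # mean 1.5, sd 1.60 (passes)
  m <- rbind(flat = flat, lowmean = lowmean, atb = atboundary,
             spread = spread)
  colnames(m) <- sprintf("c%d", 1:8)
  sce <- toy_lognorm(m)
  vg <- selectVariableGenes(sce)
  expect_identical(vg, "spread")
  ## closed lower bound: mean exactly 0.25 is eligible when SD passes
  m2 <- rbind(edge = c(rep(0, 6), 1.5, 0.5), other = rep(0.1, 8))
  colnames(m2) <- sprintf("c%d", 1:8)
  expect_equal(mean(m2["edge", ]), 0.25)
  expect_gt(sd(m2["edge", ]), 0.1)
  vg2 <- selectVariableGenes(toy_lognorm(m2),
                             pipelineConfig(var_gene_sd_min = 0.1))
  expect_true("edge" %in% vg2)
  expect_error(selectVariableGenes(toy_lognorm(m2[2, , drop = FALSE])),
               "relaxing")
})

test_that("planted high-dispersion genes are selected", {
  set.seed(9)
  n <- 400
  base <- matrix(rnorm(1960 * n, mean = 1, sd = 0.3), 1960, n)
  hot <- matrix(sample(c(0, 3.2), 40 * n, replace = TRUE), 40, n)
  m <- pmax(rbind(base, hot), 0)
  rownames(m) <- c(sprintf("b%04d", 1:1960), sprintf("hot%02d", 1:40))
  colnames(m) <- sprintf("c%03d", 1:n)
  vg <- selectVariableGenes(toy_lognorm(m))
  expect_gte(sum(sprintf("hot%02d", 1:40) %in% vg), 38)
})

test_that("the immune purge is strict at the threshold and exact on planted contaminants", {
  m <- rbind(GZMB = c(1.5, 1.51, 0), other = c(1, 1, 1))
  colnames(m) <- c("at", "above", "zero")
  sce <- toy_lognorm(m)
  kept <- purgeImmuneFromCancer(colnames(m), sce)
  expect_setequal(kept, c("at", "zero"))  # strict ">"
  expect_error(purgeImmuneFromCancer(colnames(m), sce, gene = "ABSENT"),
               "absent")

  sim <- simulateCells(generatorParams(n_immune_contaminants = 14L,
                                       seed = 4L))
  sce2 <- logNormalize(qcFilter(sim$sce))
  cd <- colData(sce2)
  candidates <- intersect(rownames(cd)[cd$marker_status == "positive"],
                          colnames(sce2))
  kept2 <- purgeImmuneFromCancer(candidates, sce2)
  removed <- setdiff(candidates, kept2)
  expect_length(removed, 14)
  expect_setequal(removed,
                  names(which(sim$truth$immune_contaminant)))
})
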