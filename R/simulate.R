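## Synthetic single-cell and bulk data with planted ground truth.
##
## The generator emulates the population structure the pipeline assumes:
## four cell compartments (cancer, microglia, macrophage, T cell), cancer
## cells mixing two anti-correlated programmes (MAPK-like and
## astrocyte-like) plus a small oligodendrocyte-like branch, mutually
## exclusive cycling/senescent subsets inside MAPK-high cells, library-size
## and mitochondrial-fraction variation, chromosome-level CNV blocks, and
## bulk samples as known convex mixtures of compartment means. Counts are
## negative binomial with per-gene baselines and log-normal library sizes.

#' Generator parameters
#'
#' Returns the default parameter set for [simulateCells()] /
#' [simulateBulk()]; any field can be overridden by name. Defaults: 2000
#' genes x 1000 cells (500 cancer, 300 microglia, 100 macrophage, 100 T),
#' 50-gene modules activated at 4.5 natural-log units (~90-fold, the scale
#' of on/off cell-type markers and strongly induced immediate-early genes),
#' negative-binomial size 2 with log-normal library sizes, a quarter of
#' cancer cells MAPK-high (activity in \[0.85, 1\]) versus \[0, 0.3\]
#' otherwise with astrocyte-like activity anti-correlated by construction,
#' disjoint cycling/senescent subsets within the MAPK-high cells, a +0.4
#' log-unit expression shift over 150 contiguous genes carried by 40% of
#' cancer cells, and Dirichlet bulk mixture weights centered on the
#' compartment proportions seen in bulk low-grade glioma cohorts
#' (cancer ~57%, microglia ~30%).
#'
#' @param ... named overrides.
#' @return Named list of generator parameters.
#' @export
generatorParams <- function(...) {
  p <- list(
    n_genes = 2000L,
    n_cells = c(cancer = 500L, microglia = 300L, macrophage = 100L,
                Tcell = 100L),
    module_size = 50L,
    programme_effect = 4.5,
    compartment_effect = 4.5,
    module_baseline = 1,
    nb_size = 2,
    baseline_meanlog = 0, baseline_sdlog = 2.2,
    lib_meanlog = log(1e5), lib_sdlog = 0.3,
    dropout = 0.1,
    mito_n = 10L, mito_frac = 0.015, mito_fail_mult = 8,
    mapk_high_frac = 0.25,
    mapk_high_range = c(0.85, 1), mapk_low_range = c(0, 0.3),
    ac_jitter_sd = 0.05,
    oc_frac = 0.05,
    cycling_frac = 0.3, senescent_frac = 0.3,
    programme_grade = 0.045,
    n_lowgene_fail = 0L, n_mito_fail = 0L, fail_lib_size = 1500,
    n_immune_contaminants = 0L,
    n_chromosomes = 10L,
    cnv_chrom = "chr08", cnv_span = c(26L, 175L), cnv_shift = 0.4,
    cnv_carrier_frac = 0.4,
    n_tumors = 6L,
    n_bulk = 50L,
    dirichlet_alpha = c(cancer = 5.7, microglia = 3.0, macrophage = 0.7,
                        Tcell = 0.6),
    bulk_noise_sdlog = 0.1,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (p$module_size * 8 + p$mito_n > p$n_genes)
    stop("module sizes exceed n_genes")
  p
}

.module_layout <- function(p) {
  ms <- p$module_size
  ids <- sprintf("G%04d", seq_len(p$n_genes))
  modules <- list()
  nm <- c("MAPK", "AC", "OC", "cycling", "senescence",
          "microglia", "macrophage", "Tcell")
  for (i in seq_along(nm))
    modules[[nm[i]]] <- ids[seq((i - 1) * ms + 1, i * ms)]
  ## GZMB: a cytotoxic T-cell marker, first gene of the T-cell module
  ids[7 * ms + 1] <- "GZMB"
  modules$Tcell[1] <- "GZMB"
  mito <- paste0("MT-", seq_len(p$mito_n))
  ids[seq(p$n_genes - p$mito_n + 1, p$n_genes)] <- mito
  list(ids = ids, modules = modules, mito = mito)
}

.positions_for <- function(ids, n_chromosomes) {
  n <- length(ids)
  per <- ceiling(n / n_chromosomes)
  chrom <- sprintf("chr%02d", ((seq_len(n) - 1) %/% per) + 1)
  start <- (((seq_len(n) - 1) %% per)) * 1000L
  genePositions(ids, chrom, start)
}

#' Simulate a single-cell dataset with planted ground truth
#'
#' See [generatorParams()] for the model. The returned truth records, for
#' every cell, its compartment and programme activities, the
#' cycling/senescent/OC flags, planted QC failures and immune
#' contaminants, CNV carrier status, the planted module gene lists, the
#' gene position table, and the seed, so that every downstream statistic
#' can be recomputed independently.
#'
#' @param params list from [generatorParams()].
#' @return list with `sce` (a `SingleCellExperiment`, assay `"counts"`)
#'   and `truth`.
#' @export
simulateCells <- function(params = generatorParams()) {
  p <- params
  set.seed(p$seed)
  lay <- .module_layout(p)
  ids <- lay$ids
  modules <- lay$modules
  mito <- lay$mito
  pos <- .positions_for(ids, p$n_chromosomes)

  compartment <- rep(names(p$n_cells), p$n_cells)
  n_extra <- p$n_lowgene_fail + p$n_mito_fail + p$n_immune_contaminants
  compartment <- c(compartment,
                   rep("cancer", p$n_lowgene_fail + p$n_mito_fail),
                   rep("Tcell", p$n_immune_contaminants))
  n_cells <- length(compartment)
  cell_ids <- sprintf("C%04d", seq_len(n_cells))
  lowgene_fail <- c(rep(FALSE, sum(p$n_cells)),
                    rep(TRUE, p$n_lowgene_fail),
                    rep(FALSE, p$n_mito_fail + p$n_immune_contaminants))
  mito_fail <- c(rep(FALSE, sum(p$n_cells) + p$n_lowgene_fail),
                 rep(TRUE, p$n_mito_fail),
                 rep(FALSE, p$n_immune_contaminants))
  contaminant <- c(rep(FALSE, n_cells - p$n_immune_contaminants),
                   rep(TRUE, p$n_immune_contaminants))

  is_cancer <- compartment == "cancer"
  n_can <- sum(is_cancer)
  mapk_high <- rep(FALSE, n_cells)
  mapk_high[is_cancer] <- runif(n_can) < p$mapk_high_frac
  a <- numeric(n_cells)
  a[is_cancer & mapk_high] <- runif(sum(is_cancer & mapk_high),
                                    p$mapk_high_range[1],
                                    p$mapk_high_range[2])
  a[is_cancer & !mapk_high] <- runif(sum(is_cancer & !mapk_high),
                                     p$mapk_low_range[1],
                                     p$mapk_low_range[2])
  ac <- numeric(n_cells)
  ac[is_cancer] <- pmin(pmax(1 - a[is_cancer] +
                             rnorm(n_can, 0, p$ac_jitter_sd), 0), 1)
  oc_flag <- rep(FALSE, n_cells)
  oc_flag[is_cancer] <- runif(n_cells)[is_cancer] < p$oc_frac
  oc <- ifelse(oc_flag, runif(n_cells, 0.7, 1), 0)

  u <- runif(n_cells)
  cycling_flag <- is_cancer & mapk_high & u < p$cycling_frac
  senescent_flag <- is_cancer & mapk_high & !cycling_flag &
    u < p$cycling_frac + p$senescent_frac

  ## per-gene baselines; module genes get a fixed moderate baseline so the
  ## on/off contrast is controlled by the effect sizes alone
  b <- rlnorm(p$n_genes, p$baseline_meanlog, p$baseline_sdlog)
  names(b) <- ids
  b[unlist(modules)] <- p$module_baseline
  ## granzyme B is essentially silent outside cytotoxic lymphocytes
  b["GZMB"] <- 0.2 * p$module_baseline
  b[mito] <- 0  # set below from the target mitochondrial fraction
  b[mito] <- (p$mito_frac / (1 - p$mito_frac)) * sum(b) / p$mito_n

  ## activity per module (cells in columns); cycling and senescence carry a
  ## graded component tied to MAPK activity in all cancer cells plus a
  ## strong boost in their (mutually exclusive) flagged subsets, mirroring
  ## scores that rise with MAPK signaling but peak in disjoint cells
  g <- p$programme_grade
  activity <- rbind(
    MAPK = a, AC = ac, OC = oc,
    cycling = g * a * is_cancer + (1 - g) * cycling_flag,
    senescence = g * a * is_cancer + (1 - g) * senescent_flag,
    microglia = as.numeric(compartment == "microglia"),
    macrophage = as.numeric(compartment == "macrophage" & !contaminant),
    Tcell = as.numeric(compartment == "Tcell"))
  effects <- c(MAPK = p$programme_effect, AC = p$programme_effect,
               OC = p$programme_effect, cycling = p$programme_effect,
               senescence = p$programme_effect,
               microglia = p$compartment_effect,
               macrophage = p$compartment_effect,
               Tcell = p$compartment_effect)

  rate <- matrix(b, nrow = p$n_genes, ncol = n_cells,
                 dimnames = list(ids, cell_ids))
  for (m in rownames(activity))
    rate[modules[[m]], ] <-
      rate[modules[[m]], , drop = FALSE] *
      rep(exp(effects[m] * activity[m, ]), each = p$module_size)

  ## CNV segment: contiguous genes on one chromosome. `cnv_shift` is the
  ## planted shift in mean log-normalized expression (ln(1 + scaled)
  ## units); each gene's count rate is multiplied by the factor that
  ## realizes that shift in expectation given the gene's baseline scaled
  ## expression, so low-expressed genes get proportionally larger rate
  ## multipliers.
  seg_genes <- pos$gene_id[pos$chrom == p$cnv_chrom]
  seg_genes <- if (p$cnv_span[1] > length(seg_genes)) character(0)
               else seg_genes[seq(p$cnv_span[1],
                                  min(p$cnv_span[2], length(seg_genes)))]
  carrier <- rep(FALSE, n_cells)
  carrier[is_cancer] <- runif(n_cells)[is_cancer] < p$cnv_carrier_frac
  if (length(seg_genes) && p$cnv_shift != 0) {
    s_seg <- 1e4 * b[seg_genes] / sum(b) * (1 - p$dropout)
    mult <- (exp(p$cnv_shift) * (1 + s_seg) - 1) / s_seg
    rate[seg_genes, carrier] <- rate[seg_genes, carrier] * mult
  }

  ## planted high-mito cells
  if (any(mito_fail))
    rate[mito, mito_fail] <- rate[mito, mito_fail] * p$mito_fail_mult

  lib <- rlnorm(n_cells, p$lib_meanlog, p$lib_sdlog)
  lib[lowgene_fail] <- p$fail_lib_size
  mu <- sweep(rate, 2, lib / colSums(rate), "*")
  counts <- matrix(rnbinom(length(mu), mu = as.numeric(mu),
                           size = p$nb_size),
                   nrow = p$n_genes, dimnames = dimnames(mu))
  if (p$dropout > 0) {
    keep <- matrix(runif(length(counts)) >= p$dropout, nrow = p$n_genes)
    counts <- counts * keep
  }
  ## planted contaminants are defined by their GZMB expression: guarantee
  ## the marker survives sampling noise and dropout
  if (any(contaminant))
    counts["GZMB", contaminant] <- pmax(counts["GZMB", contaminant],
                                        round(8e-4 * lib[contaminant]))

  meta <- data.frame(
    row.names = cell_ids,
    tumor_of_origin = sprintf("BT%d", ((seq_len(n_cells) - 1) %%
                                       p$n_tumors) + 1),
    marker_status = ifelse(is_cancer | contaminant, "positive", "negative"),
    fusion_status = ifelse(is_cancer, "detected",
                           ifelse(contaminant, "not_assayed",
                                  "not_detected")),
    species = "human")

  truth <- list(
    compartment = setNames(compartment, cell_ids),
    mapk_activity = setNames(a, cell_ids),
    ac_activity = setNames(ac, cell_ids),
    mapk_high = setNames(mapk_high, cell_ids),
    oc_flag = setNames(oc_flag, cell_ids),
    cycling_flag = setNames(cycling_flag, cell_ids),
    senescent_flag = setNames(senescent_flag, cell_ids),
    lowgene_fail = setNames(lowgene_fail, cell_ids),
    mito_fail = setNames(mito_fail, cell_ids),
    immune_contaminant = setNames(contaminant, cell_ids),
    cnv_carrier = setNames(carrier, cell_ids),
    cnv_segment = list(chrom = p$cnv_chrom, genes = seg_genes,
                       shift = p$cnv_shift),
    modules = modules,
    mito_genes = mito,
    positions = pos,
    params = p,
    seed = p$seed)

  list(sce = makeCountsSCE(counts, cell_meta = meta), truth = truth)
}

#' Mean expression per compartment
#'
#' @param sce a `SingleCellExperiment` with the requested assay.
#' @param labels named character vector: cell id -> compartment.
#' @param layer assay to average.
#' @return genes x compartments matrix.
#' @export
compartmentMeans <- function(sce, labels, layer = "lognorm") {
  expr <- .expr_layer(sce, layer)
  labels <- labels[intersect(names(labels), colnames(expr))]
  comps <- sort(unique(labels))
  out <- vapply(comps, function(cp)
    rowMeans(expr[, names(labels)[labels == cp], drop = FALSE]),
    numeric(nrow(expr)))
  rownames(out) <- rownames(expr)
  out
}

#' Simulate bulk profiles as convex mixtures of compartment means
#'
#' Each bulk sample is a Dirichlet-weighted convex combination of the
#' compartment mean expression vectors, optionally with multiplicative
#' log-normal noise. The mixing weights are returned as ground truth.
#'
#' @param compartment_means genes x compartments matrix (e.g. from
#'   [compartmentMeans()]).
#' @param n_samples number of bulk samples.
#' @param alpha Dirichlet concentration per compartment (named; matched to
#'   the columns of `compartment_means`).
#' @param noise_sdlog SD of the log-normal multiplicative noise (0 = none).
#' @param seed integer seed.
#' @return list with `bulk` (genes x samples) and `weights`
#'   (samples x compartments).
#' @export
simulateBulk <- function(compartment_means, n_samples = 50L,
                         alpha = c(cancer = 5.7, microglia = 3.0,
                                   macrophage = 0.7, Tcell = 0.6),
                         noise_sdlog = 0.1, seed = 1L) {
  m <- as.matrix(compartment_means)
  if (!is.null(names(alpha))) {
    missing <- setdiff(colnames(m), names(alpha))
    if (length(missing))
      stop("alpha missing compartments: ", paste(missing, collapse = ", "))
    alpha <- alpha[colnames(m)]
  }
  set.seed(seed)
  g <- matrix(rgamma(n_samples * ncol(m), shape = alpha, rate = 1),
              nrow = ncol(m))
  w <- t(g) / colSums(g)
  colnames(w) <- colnames(m)
  rownames(w) <- sprintf("S%03d", seq_len(n_samples))
  stopifnot(max(abs(rowSums(w) - 1)) < 1e-12)
  bulk <- m %*% t(w)
  if (noise_sdlog > 0)
    bulk <- bulk * exp(matrix(rnorm(length(bulk), 0, noise_sdlog),
                              nrow = nrow(bulk)))
  list(bulk = bulk, weights = w)
}

#' Simulate mouse neural stem cells expressing oncogene constructs
#'
#' Three groups of mouse neural stem cells — empty vector, a
#' KIAA1549-BRAF-fusion-like construct, and a BRAF-V600E-like construct —
#' each with a 50-gene group-specific module, plus a shared astrocyte-like
#' module whose activity is high in the vector group and reduced in both
#' oncogene groups (oncogenic BRAF opposing glial maturation). Mouse QC
#' conventions apply: `mt-` mitochondrial prefix, species `"mouse"`.
#'
#' @param n_genes total genes.
#' @param group_sizes named sizes for `vector`, `fusion`, `v600e`.
#' @param effect group-module activation (natural-log units).
#' @param ac_effect astrocyte-like module activation.
#' @param ac_low astrocyte-like activity in the oncogene groups
#'   (vector group has activity 1).
#' @param nb_size negative-binomial size.
#' @param lib_meanlog,lib_sdlog log-normal library-size parameters.
#' @param dropout per-entry dropout probability.
#' @param seed integer seed.
#' @return list with `sce` and `truth` (group labels, module lists, seed).
#' @export
simulateMouseNSC <- function(n_genes = 5000L,
                             group_sizes = c(vector = 170L, fusion = 154L,
                                             v600e = 163L),
                             effect = 4.5, ac_effect = 4.5, ac_low = 0.2,
                             nb_size = 2, lib_meanlog = log(1e5),
                             lib_sdlog = 0.2, dropout = 0.05, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("mG%04d", seq_len(n_genes))
  mito <- paste0("mt-", 1:10)
  ids[seq(n_genes - 9, n_genes)] <- mito
  ms <- 50L
  modules <- list(vector = ids[1:ms], fusion = ids[(ms + 1):(2 * ms)],
                  v600e = ids[(2 * ms + 1):(3 * ms)],
                  AC = ids[(3 * ms + 1):(4 * ms)])
  group <- rep(names(group_sizes), group_sizes)
  n_cells <- length(group)
  cell_ids <- sprintf("M%04d", seq_len(n_cells))

  b <- rlnorm(n_genes, 0, 1.5)
  names(b) <- ids
  b[unlist(modules)] <- 1
  b[mito] <- 0
  b[mito] <- (0.015 / (1 - 0.015)) * sum(b) / 10

  ac_act <- ifelse(group == "vector", 1, ac_low)
  rate <- matrix(b, nrow = n_genes, ncol = n_cells,
                 dimnames = list(ids, cell_ids))
  for (g in names(group_sizes))
    rate[modules[[g]], group == g] <- rate[modules[[g]], group == g] *
      exp(effect)
  rate[modules$AC, ] <- rate[modules$AC, ] *
    rep(exp(ac_effect * ac_act), each = ms)

  lib <- rlnorm(n_cells, lib_meanlog, lib_sdlog)
  mu <- sweep(rate, 2, lib / colSums(rate), "*")
  counts <- matrix(rnbinom(length(mu), mu = as.numeric(mu), size = nb_size),
                   nrow = n_genes, dimnames = dimnames(mu))
  if (dropout > 0)
    counts <- counts * (matrix(runif(length(counts)), nrow = n_genes) >=
                        dropout)
  meta <- data.frame(row.names = cell_ids,
                     tumor_of_origin = group, marker_status = "unknown",
                     fusion_status = ifelse(group == "fusion", "detected",
                                            "not_detected"),
                     species = "mouse")
  truth <- list(group = setNames(group, cell_ids), modules = modules,
                mito_genes = mito, ac_activity = setNames(ac_act, cell_ids),
                seed = seed)
  list(sce = makeCountsSCE(counts, cell_meta = meta), truth = truth)
}
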