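# Core-control selection, depth factors, QC filters, z-normalization,
# knockdown measurement.

test_that("indistinguishable controls are retained, outliers removed", {
  # twenty null control constructs: essentially all should be retained
  nullcfg <- sim_config(seed = 41, n_perturbations = 0, frac_controls = 1,
                        n_control_constructs = 20,
                        cells_per_gemgroup = 300)
  ds <- generate_expression(nullcfg)
  cc <- select_core_controls(ds$experiment, deg_threshold = 8)
  expect_gte(length(cc$core) / length(cc$avg_degs), 0.95)
  # one control given a programmed 50-gene effect (on well-expressed
  # genes) is removed while the others stay
  expressed <- names(which(
    Matrix::rowMeans(SummarizedExperiment::assay(ds$experiment)) > 1.5))
  expressed <- grep("^gene_", expressed, value = TRUE)[1:50]
  eff <- list(`non-targeting_01` = list(genes = expressed, shifts = 1.5))
  cfg2 <- sim_config(seed = 41, n_perturbations = 0, frac_controls = 1,
                     n_control_constructs = 20, cells_per_gemgroup = 300,
                     effect_gene_sets = eff)
  ds2 <- generate_expression(cfg2)
  cc2 <- select_core_controls(ds2$experiment, deg_threshold = 8)
  expect_false("non-targeting_01" %in% cc2$core)
  expect_gte(length(cc2$core), 18)
  expect_error(select_core_controls(ds$experiment,
                                    controls = "non-targeting_01"),
               "at least 2")
})

test_that("depth factors equalize control totals across gemgroups", {
  ds <- small_dataset()
  ch <- norm_chain(ds)
  um <- ch$um
  cd <- SummarizedExperiment::colData(um)
  tot <- Matrix::colSums(SummarizedExperiment::assay(um))
  is_core <- cd$perturbation %in% ch$controls
  adj <- tot * ch$factors[cd$gemgroup]
  means <- tapply(adj[is_core], cd$gemgroup[is_core], mean)
  expect_lt(diff(range(means)), 1e-9 * mean(means))
  # arithmetic oracle: control means 4000 vs 8000 give 2:1 factors
  m <- tapply(tot[is_core], cd$gemgroup[is_core], mean)
  expect_equal(unname(ch$factors["gem1"] / ch$factors["gem2"]),
               unname(m[["gem2"]] / m[["gem1"]]))
  # single gemgroup: factor 1
  um1 <- um[, cd$gemgroup == "gem1"]
  f1 <- compute_depth_factors(um1, ch$controls)
  expect_equal(unname(f1), 1)
  # gemgroup without core controls is named in the error
  umx <- um[, !(cd$gemgroup == "gem2" & is_core)]
  expect_error(compute_depth_factors(umx, ch$controls), "gem2")
})

test_that("QC filters use inclusive bounds and match a brute-force scan", {
  ds <- small_dataset()
  ch <- norm_chain(ds)
  um <- ch$um
  cd <- SummarizedExperiment::colData(um)
  tot <- Matrix::colSums(SummarizedExperiment::assay(um))
  adj <- tot * ch$factors[cd$gemgroup]
  floor_val <- unname(quantile(adj, 0.2))
  mt <- SummarizedExperiment::rowData(um)$class == "mitochondrial"
  mito <- Matrix::colSums(SummarizedExperiment::assay(um)[mt, ]) / tot
  ceil_val <- unname(quantile(mito, 0.9))
  out <- apply_qc_filters(um, ch$factors, floor_val, ceil_val)
  # brute-force row-wise re-check
  keep <- adj >= floor_val & mito <= ceil_val
  expect_identical(colnames(out), colnames(um)[keep])
  # a cell exactly at the floor is retained (inclusive convention)
  at_floor <- which(abs(adj - floor_val) < 1e-12)
  if (length(at_floor))
    expect_true(all(colnames(um)[at_floor] %in% colnames(out)))
  expect_error(apply_qc_filters(um, ch$factors, -5, 0.2), "positive")
  expect_error(apply_qc_filters(um, ch$factors, 100, 1.5), "0, 1")
})

test_that("control cells have z mean 0 and SD 1 by construction", {
  ds <- small_dataset()
  ch <- norm_chain(ds)
  cm <- ch$z$cell_meta
  for (g in unique(cm$gemgroup)) {
    sel <- cm$perturbation %in% ch$controls & cm$gemgroup == g
    zz <- ch$z$z[, sel]
    mu <- rowMeans(zz, na.rm = TRUE)
    sdev <- apply(zz, 1, sd)
    expect_lt(max(abs(mu), na.rm = TRUE), 1e-6)
    expect_lt(max(abs(sdev - 1), na.rm = TRUE), 1e-6)
  }
})

test_that("the transform is the documented affine map per gene/gemgroup", {
  ds <- small_dataset()
  ch <- norm_chain(ds)
  um <- ch$um
  model <- ch$model
  cd <- SummarizedExperiment::colData(um)
  # direct formula on a handful of random cells
  set.seed(2)
  tot <- Matrix::colSums(SummarizedExperiment::assay(um))
  for (i in sample(ncol(um), 5)) {
    x <- as.numeric(SummarizedExperiment::assay(um)[, i]) *
      model$median_target / tot[i]
    g <- cd$gemgroup[i]
    expected <- (x - model$mu[, g]) / model$sigma[, g]
    expect_equal(ch$z$z[, i], expected, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  # transforming twice gives identical output
  z2 <- z_transform(um, model)
  expect_identical(ch$z$z, z2$z)
  # unknown gemgroup errors
  cd2 <- um
  SummarizedExperiment::colData(cd2)$gemgroup <- "gemX"
  expect_error(z_transform(cd2, model), "gemX")
})

test_that("an all-zero cell maps to -mu/sigma", {
  ds <- small_dataset()
  ch <- norm_chain(ds)
  um <- ch$um
  counts <- SummarizedExperiment::assay(um, "counts")
  counts[, 1] <- 0
  SummarizedExperiment::assay(um, "counts") <- counts
  z <- z_transform(um, ch$model)
  g <- z$cell_meta$gemgroup[1]
  expect_equal(z$z[, 1], -ch$model$mu[, g] / ch$model$sigma[, g],
               ignore_attr = TRUE)
})

test_that("measured knockdown recovers the programmed fraction", {
  ds <- small_dataset()  # knockdown_fraction 0.85, >= 300 cells/pert
  ch <- norm_chain(ds)
  for (p in names(ds$truth$targets)[1:3]) {
    kd <- compute_knockdown(ch$um, ch$factors, p)
    expect_true(kd$measured)
    expect_lt(abs(kd$knockdown - 0.85), 0.05)
  }
  # control pseudo-perturbation: ratio about 1
  ctl <- ch$controls[1]
  kdc <- compute_knockdown(ch$um, ch$factors, ctl,
                           target = names(ds$truth$targets)[1],
                           controls = setdiff(ch$controls, ctl))
  expect_lt(abs(kdc$ratio - 1), 0.1)
  # unmeasured target returns the sentinel
  kdx <- compute_knockdown(ch$um, ch$factors, "gene_absent")
  expect_false(kdx$measured)
})

test_that("neighbor knockdown finds expressed flanking genes", {
  ds <- small_dataset()
  ch <- norm_chain(ds)
  p <- names(ds$truth$targets)[1]
  nb <- neighbor_knockdown(ch$um, ch$factors, p, expr_floor = 0.1)
  expect_true(nrow(nb) >= 1)
  # neighbors are unaffected in this generator: change about 0
  expect_true(all(abs(nb$fractional_change) < 0.25))
  # skipped low-expression neighbors: chosen neighbors all pass the floor
  gm <- gene_table(ch$um)
  means <- Matrix::rowMeans(SummarizedExperiment::assay(ch$um))
  expect_true(all(means[nb$neighbor] > 0.1))
})

test_that("programmed neighbor co-knockdown is measured back", {
  # equal-depth gemgroups so the configured multiplier is exact
  base <- sim_config(seed = 47, n_perturbations = 1, frac_controls = 0.4,
                     cells_per_gemgroup = 500, knockdown_fraction = 0.9,
                     depth_mean_per_gemgroup = c(6000, 6000))
  ds0 <- generate_expression(base)
  p <- names(ds0$truth$targets)[1]
  gm <- gene_table(ds0$experiment)
  tgt <- gm[gm$gene == p, ]
  means <- Matrix::rowMeans(SummarizedExperiment::assay(ds0$experiment))
  same <- gm[gm$chrom == tgt$chrom & gm$gene != p, ]
  same <- same[means[same$gene] > 0.1, ]
  up <- same[same$start < tgt$start, ]
  neighbor <- up$gene[which.max(up$start)]
  # shift chosen so the mean multiplier is 0.5 (50% co-knockdown)
  mu_g <- ds0$truth$base_mu[neighbor] * ds0$truth$depth_factor[1]
  sd_g <- sqrt(mu_g + 0.2 * mu_g^2)
  shift <- -0.5 * mu_g / sd_g
  cfg <- sim_config(seed = 47, n_perturbations = 1, frac_controls = 0.4,
                    cells_per_gemgroup = 500, knockdown_fraction = 0.9,
                    depth_mean_per_gemgroup = c(6000, 6000),
                    effect_gene_sets = setNames(
                      list(list(genes = neighbor, shifts = shift)), p))
  ds <- generate_expression(cfg)
  ch <- norm_chain(ds)
  nb <- neighbor_knockdown(ch$um, ch$factors, p, expr_floor = 0.1)
  hit <- nb[nb$neighbor == neighbor, ]
  expect_equal(nrow(hit), 1L)
  expect_lt(abs(hit$fractional_change - (-0.5)), 0.12)
})
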