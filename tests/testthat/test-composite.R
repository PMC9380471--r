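# Composite phenotypes: total RNA, mitochondrial and TE fractions,
# splicing ratios, cell-cycle gating.

test_that("total RNA z-scores anchor on gemgroup controls", {
  ds <- small_dataset()
  um <- ds$expression
  tr <- total_rna(um)
  cd <- SummarizedExperiment::colData(um)
  expect_lt(abs(mean(tr$cell$total_rna_z[cd$is_control])), 0.05)
  # single-cell arithmetic matches the (total - mu)/sigma oracle
  g <- cd$gemgroup[1]
  tot <- Matrix::colSums(SummarizedExperiment::assay(um))
  ref <- tot[cd$is_control & cd$gemgroup == g]
  expect_equal(tr$cell$total_rna_z[1],
               unname((tot[1] - mean(ref)) / sd(ref)))
})

test_that("depth-doubling perturbations score strongly positive", {
  # emulate a perturbation with doubled RNA content by scaling all gene
  # means (a uniform 2x lesion across every chromosome)
  base <- sim_config(seed = 61, n_perturbations = 1, frac_controls = 0.4,
                     cells_per_gemgroup = 200, knockdown_fraction = 0)
  p <- names(generate_expression(base)$truth$targets)[1]
  lesions <- lapply(paste0("chr", 1:5), function(ch)
    list(perturbation = p, chrom = ch, copy_ratio = 2, fraction = 1))
  cfg <- sim_config(seed = 61, n_perturbations = 1, frac_controls = 0.4,
                    cells_per_gemgroup = 200, knockdown_fraction = 0,
                    cnv_lesions = c(lesions,
                                    list(list(perturbation = p,
                                              chrom = "MT",
                                              copy_ratio = 2,
                                              fraction = 1))))
  ds <- generate_expression(cfg)
  tr <- total_rna(ds$experiment)
  expect_gt(tr$perturbation[[p]], 3)
})

test_that("mitochondrial fraction is the documented per-cell ratio", {
  counts <- matrix(0L, 3, 2, dimnames = list(c("g1", "g2", "MT-X"), NULL))
  counts[, 1] <- c(50L, 40L, 10L)   # 10 MT of 100
  counts[, 2] <- c(10L, 10L, 0L)
  gm <- data.frame(gene = rownames(counts), chrom = c("chr1", "chr1", "MT"),
                   start = 1:3, end = 2:4,
                   class = c("nuclear", "nuclear", "mitochondrial"))
  um <- perturb_experiment(counts, gm, c("a", "b"), c("gem1", "gem1"))
  expect_equal(unname(fraction_mt(um)), c(0.10, 0))
  # no annotated MT genes: zero with a warning
  gm2 <- gm; gm2$class <- "nuclear"
  um2 <- perturb_experiment(counts, gm2, c("a", "b"), c("gem1", "gem1"))
  expect_warning(fr <- fraction_mt(um2), "mitochondrial")
  expect_equal(unname(fr), c(0, 0))
  # with classes partitioning genes and no TE, fractions sum to one
  fr_mt <- fraction_mt(um)
  nuc <- Matrix::colSums(SummarizedExperiment::assay(um)[1:2, ]) /
    Matrix::colSums(SummarizedExperiment::assay(um))
  expect_equal(unname(fr_mt + nuc), c(1, 1))
})

test_that("TE fraction responds to programmed TE shifts", {
  ds <- small_dataset()
  te <- fraction_te(ds$expression)
  expect_true(all(te >= 0 & te <= 1))
  # zero TE counts give zero fraction
  um <- ds$expression
  counts <- SummarizedExperiment::assay(um, "counts")
  te_rows <- SummarizedExperiment::rowData(um)$class == "TE"
  counts[te_rows, ] <- 0
  SummarizedExperiment::assay(um, "counts") <- counts
  expect_true(all(fraction_te(um) == 0))
  # doubling TE counts for one perturbation makes it the top fraction
  base <- sim_config(seed = 67, n_perturbations = 4, frac_controls = 0.3,
                     cells_per_gemgroup = 200, knockdown_fraction = 0)
  p <- names(generate_expression(base)$truth$targets)[1]
  cfg <- sim_config(seed = 67, n_perturbations = 4, frac_controls = 0.3,
                    cells_per_gemgroup = 200, knockdown_fraction = 0,
                    cnv_lesions = list(list(perturbation = p,
                                            chrom = "TE", copy_ratio = 3,
                                            fraction = 1)))
  ds2 <- generate_expression(cfg)
  te2 <- fraction_te(ds2$experiment)
  cd <- SummarizedExperiment::colData(ds2$experiment)
  means <- tapply(te2, cd$perturbation, mean)
  expect_equal(names(which.max(means)), p)
  # removing TE features disables the phenotype with a message
  um3 <- ds$expression[!te_rows, ]
  expect_message(out <- fraction_te(um3), "disabled")
  expect_null(out)
})

test_that("splicing ratios are control-anchored pseudobulk fractions", {
  cfg <- sim_config(seed = 71, n_perturbations = 3, frac_controls = 0.3,
                    cells_per_gemgroup = 250, knockdown_fraction = 0,
                    simulate_layers = TRUE)
  ds <- generate_expression(cfg)
  sr <- splicing_ratio(ds$experiment)
  expect_false(is.null(sr))
  # pooled control pseudobulk sits at 1 by construction
  ctl_rows <- rownames(sr$ratio) %in% sr$control_labels
  expect_equal(unname(colMeans(sr$ratio[ctl_rows, , drop = FALSE])),
               rep(1, ncol(sr$ratio)), tolerance = 1e-12)
  # arithmetic: fraction 0.2 against control mean 0.1 gives 2.0
  counts <- matrix(100L, 1, 4, dimnames = list("g1", NULL))
  uns <- matrix(c(10L, 10L, 20L, 20L), 1)
  spl <- counts - uns
  gm <- data.frame(gene = "g1", chrom = "chr1", start = 1, end = 2,
                   class = "nuclear")
  um <- perturb_experiment(counts, gm, paste0("c", 1:4),
                           rep("gem1", 4),
                           perturbation = c("nt", "nt", "pp", "pp"),
                           layers = list(spliced = spl, unspliced = uns))
  SummarizedExperiment::colData(um)$is_control <-
    c(TRUE, TRUE, FALSE, FALSE)
  sr2 <- splicing_ratio(um)
  expect_equal(unname(sr2$ratio["pp", "g1"]), 2.0)
  expect_equal(unname(sr2$ratio["nt", "g1"]), 1.0)
  # a splicing-factor perturbation inflates ratios genome-wide
  base2 <- sim_config(seed = 73, n_perturbations = 2, frac_controls = 0.3,
                      cells_per_gemgroup = 250, knockdown_fraction = 0,
                      simulate_layers = TRUE)
  p <- names(generate_expression(base2)$truth$targets)[1]
  cfg2 <- sim_config(seed = 73, n_perturbations = 2, frac_controls = 0.3,
                     cells_per_gemgroup = 250, knockdown_fraction = 0,
                     simulate_layers = TRUE,
                     splicing_effects = setNames(list(3), p))
  ds2 <- generate_expression(cfg2)
  sr3 <- splicing_ratio(ds2$experiment)
  expect_gt(median(sr3$ratio[p, ]), 1.5)
  # missing layers disable the phenotype
  expect_message(out <- splicing_ratio(small_dataset()$expression),
                 "disabled")
  expect_null(out)
})

test_that("cell-cycle gates assign cells by point-in-polygon", {
  square <- function(x0, x1, y0, y1)
    data.frame(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  # plain polygon test
  inside <- perturbmap:::point_in_polygon(c(0.5, 2), c(0.5, 0.5),
                                          square(0, 1, 0, 1))
  expect_equal(inside, c(TRUE, FALSE))
  cfg <- sim_config(seed = 79, n_perturbations = 2, frac_controls = 0.3,
                    cells_per_gemgroup = 120, knockdown_fraction = 0)
  ds <- generate_expression(cfg)
  cc_genes <- rownames(ds$experiment)[1:40]
  # gates tiling the plane: every cell assigned
  big <- 1e6
  gates <- list(left = square(-big, 0, -big, big),
                right = square(0, big, -big, big))
  res <- cell_cycle_phases(ds$experiment, cc_genes, gates,
                           n_neighbors = 10, seed = 1)
  expect_true(all(res$phase %in% c("left", "right")))
  expect_equal(rowSums(res$occupancy), rep(1, nrow(res$occupancy)),
               ignore_attr = TRUE)
  # empty gate list leaves all unassigned with a warning
  expect_warning(
    res0 <- cell_cycle_phases(ds$experiment, cc_genes, list(),
                              n_neighbors = 10, seed = 1),
    "unassigned")
  expect_true(all(res0$phase == "unassigned"))
})

test_that("an arrest perturbation concentrates in its phase gate", {
  # phase structure emulated with a cell-cycle program shifted up in the
  # arrested perturbation's cells
  base <- sim_config(seed = 83, n_perturbations = 2, frac_controls = 0.4,
                     cells_per_gemgroup = 200, knockdown_fraction = 0)
  p <- names(generate_expression(base)$truth$targets)[1]
  cc_genes <- sprintf("gene_%04d", 1:30)
  cfg <- sim_config(seed = 83, n_perturbations = 2, frac_controls = 0.4,
                    cells_per_gemgroup = 200, knockdown_fraction = 0,
                    effect_gene_sets = setNames(
                      list(list(genes = cc_genes, shifts = 3)), p))
  ds <- generate_expression(cfg)
  res <- cell_cycle_phases(ds$experiment, cc_genes, list(),
                           n_neighbors = 15, seed = 2) |>
    suppressWarnings()
  co <- res$embedding
  cd <- SummarizedExperiment::colData(ds$experiment)
  sel <- cd$perturbation == p & ds$truth$cells$affected
  # arrested cells occupy a distinct region: gate on their bounding box
  ctr <- colMeans(co[sel, ])
  spread <- apply(co[sel, ], 2, sd)
  gate <- data.frame(
    x = ctr[1] + 2.5 * spread[1] * c(-1, 1, 1, -1),
    y = ctr[2] + 2.5 * spread[2] * c(-1, -1, 1, 1))
  occ_p <- mean(perturbmap:::point_in_polygon(co[sel, 1], co[sel, 2],
                                              gate))
  occ_c <- mean(perturbmap:::point_in_polygon(co[cd$is_control, 1],
                                              co[cd$is_control, 2], gate))
  expect_gt(occ_p, occ_c)
})
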