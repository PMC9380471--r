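# Pseudobulk profiles, correlation clustering, polarization identity,
# embedding contract, program scores, genotype-phenotype summaries.

test_that("profiles are brute-force cell means with target masking", {
  ds <- small_dataset()
  ch <- norm_chain(ds)
  perts <- names(ds$truth$targets)[1:3]
  prof <- build_profiles(ch$z, perts)
  cm <- ch$z$cell_meta
  for (p in perts) {
    manual <- rowMeans(ch$z$z[, cm$perturbation == p, drop = FALSE],
                       na.rm = TRUE)
    manual[is.nan(manual)] <- 0
    manual[p] <- 0  # target masked
    expect_equal(prof$profile[p, ], manual, tolerance = 1e-12)
    expect_identical(unname(prof$profile[p, p]), 0)
  }
  # a control pseudo-perturbation profiles to roughly zero
  ctl_prof <- build_profiles(ch$z, ch$controls[1], mask_targets = FALSE)
  expect_lt(median(abs(ctl_prof$profile)), 0.2)
})

test_that("feature selection unions DEGs with high-variance genes", {
  base <- sim_config(seed = 59, n_perturbations = 2, frac_controls = 0.4,
                     cells_per_gemgroup = 300, knockdown_fraction = 0.9)
  p <- names(generate_expression(base)$truth$targets)
  genes <- sprintf("gene_%04d", 5:24)
  cfg <- sim_config(seed = 59, n_perturbations = 2, frac_controls = 0.4,
                    cells_per_gemgroup = 300, knockdown_fraction = 0.9,
                    effect_gene_sets = setNames(
                      list(list(genes = genes, shifts = 2)), p[1]))
  ds <- generate_expression(cfg)
  ch <- norm_chain(ds)
  de <- de_test_all(ch$z)
  feats <- select_profile_features(ch$z, de, top_n_deg = 10,
                                   expr_floor = 0.25,
                                   var_quantile = 0.30)
  # programmed effect genes are high-variance and selected
  expressed <- genes[ch$z$gene_mean_umi[genes] > 0.25]
  expect_gte(mean(expressed %in% feats), 0.9)
  expect_error(select_profile_features(ch$z, de, top_n_deg = 0,
                                       expr_floor = Inf,
                                       var_quantile = 0),
               "empty")
})

test_that("profile correlation is symmetric with unit diagonal", {
  mp <- module_profiles()
  r <- profile_correlation(mp$profile)
  expect_equal(diag(r), rep(1, nrow(r)), ignore_attr = TRUE)
  expect_equal(r, t(r))
  expect_equal(unname(cor(mp$profile[1, ], -mp$profile[1, ])), -1)
  flat <- rbind(mp$profile, flatline = rep(2, ncol(mp$profile)))
  expect_warning(profile_correlation(flat), "zero-variance")
  # module co-members correlate above the background 95th percentile
  within <- r[1:6, 1:6][upper.tri(diag(6))]
  null_pairs <- r[1:6, 7:18]
  expect_gt(min(within), quantile(null_pairs, 0.95))
})

test_that("polarization identity links distance and correlation", {
  mp <- module_profiles()
  xn <- polarization_normalize(mp$profile)
  r <- profile_correlation(mp$profile)
  d2 <- as.matrix(dist(xn))^2
  expect_lt(max(abs(d2 - 2 * (1 - r))), 1e-10)
  # r = 1 and r = -1 extremes
  a <- rnorm(20)
  xy <- polarization_normalize(rbind(a, 2 * a + 3, -a))
  expect_lt(sum((xy[1, ] - xy[2, ])^2), 1e-20)
  expect_equal(sum((xy[1, ] - xy[3, ])^2), 4, tolerance = 1e-12)
  expect_error(polarization_normalize(rbind(a, rep(1, 20))), "constant")
})

test_that("density clustering recovers programmed modules", {
  mp <- module_profiles()
  D <- 1 - profile_correlation(mp$profile)
  cl <- cluster_items(D, min_cluster_size = 4, min_samples = 1,
                      selection_method = "eom")
  expect_gte(ari(cl$cluster, mp$truth), 0.9)
  # leaf selection (the gene-program convention) also recovers them
  cl2 <- cluster_items(D, min_cluster_size = 4, min_samples = 1,
                       selection_method = "leaf")
  expect_gte(ari(cl2$cluster, mp$truth), 0.9)
  # scaling profiles leaves the correlation metric unchanged
  Ds <- 1 - profile_correlation(mp$profile * 7)
  expect_equal(cluster_items(Ds, 4, 1, "eom")$cluster, cl$cluster)
  # identical profiles collapse to one cluster
  expect_equal(unique(cluster_items(matrix(0, 6, 6), 4, 1,
                                    "eom")$cluster), 0L)
  # fewer items than min_cluster_size: all noise
  expect_true(all(cluster_items(D[1:3, 1:3], 4, 1, "eom")$cluster == -1))
})

test_that("embedding preserves module structure and duplicates", {
  # modules larger than the neighborhood size so the kNN graph stays
  # module-pure
  mp <- module_profiles(n_per = 10, sep = 4)
  n <- length(mp$truth)
  xn <- polarization_normalize(mp$profile)
  emb <- embed_vectors(xn, dim = 2, seed = 3)
  co <- emb$coords
  within <- mean(unlist(lapply(split(seq_len(n), mp$truth), function(ix)
    mean(dist(co[ix, ])))))
  Dfull <- as.matrix(dist(co))
  between <- mean(Dfull[mp$truth == 1, mp$truth != 1])
  expect_lt(within, between)
  # far-separated modules are linearly separable in 2-D: nearest
  # centroid classifies perfectly
  cents <- do.call(rbind, lapply(split(seq_len(n), mp$truth),
                                 function(ix) colMeans(co[ix, ])))
  assign <- apply(co, 1, function(pt)
    which.min(colSums((t(cents) - pt)^2)))
  expect_gte(ari(assign, mp$truth), 0.9)
  # reproducibility and duplicate handling
  expect_identical(embed_vectors(xn, dim = 2, seed = 3)$coords, co)
  dup <- rbind(xn, xn[1, , drop = FALSE])
  co2 <- embed_vectors(dup, dim = 2, seed = 3)$coords
  expect_lt(sqrt(sum((co2[1, ] - co2[n + 1, ])^2)), 1e-3)
  expect_error(embed_vectors(xn[1:2, ], dim = 2), "dim must be smaller")
})

test_that("embedded distances track the correlation distance", {
  # a smooth one-factor continuum of profiles: distances should order
  # the same way as sqrt(2(1 - r))
  set.seed(2)
  n <- 25; G <- 60
  u <- rnorm(G); v <- rnorm(G)
  th <- seq(0, pi, length.out = n)
  P <- t(sapply(th, function(t) cos(t) * u + sin(t) * v +
                  rnorm(G, sd = 0.3)))
  xn <- polarization_normalize(P)
  for (d in c(2, 10)) {
    emb <- embed_vectors(xn, dim = d, seed = 2)
    de <- as.matrix(dist(emb$coords))
    dc <- sqrt(2 * (1 - cor(t(P))))
    ut <- upper.tri(de)
    expect_gte(cor(de[ut], dc[ut], method = "spearman"), 0.8)
  }
})

test_that("program scores standardize and rank programmed modules", {
  mp <- module_profiles()
  prof <- structure(list(profile = mp$profile,
                         n_cells = rep(50, 18),
                         features = colnames(mp$profile)),
                    class = "perturbation_profiles")
  colnames(prof$profile) <- sprintf("gene_%02d", 1:40)
  # singleton set: raw score equals the profile value
  sc <- program_score(prof, "gene_01")
  expect_equal(sc$raw_score, unname(prof$profile[, "gene_01"]))
  expect_equal(mean(sc$score), 0, tolerance = 1e-12)
  expect_equal(sd(sc$score), 1, tolerance = 1e-12)
  # a module programmed up in 5 perturbations tops the ranking
  prof2 <- prof
  prof2$profile[1:5, 1:8] <- prof2$profile[1:5, 1:8] + 10
  sc2 <- program_score(prof2, sprintf("gene_%02d", 1:8))
  top5 <- order(-sc2$score)[1:5]
  expect_setequal(top5, 1:5)
  expect_error(program_score(prof, "nope"), "empty")
})

test_that("genotype-phenotype matrix equals nested-loop averages", {
  mp <- module_profiles()
  prof <- structure(list(profile = mp$profile, n_cells = rep(50, 18),
                         features = colnames(mp$profile)),
                    class = "perturbation_profiles")
  pcl <- structure(list(cluster = mp$truth - 1L),
                   class = "cluster_assignment")
  gcl <- structure(list(cluster = rep(0:3, each = 10)),
                   class = "cluster_assignment")
  gp <- genotype_phenotype_matrix(prof, pcl, gcl)
  for (a in 0:2) for (b in 0:3) {
    manual <- mean(mp$profile[mp$truth - 1L == a,
                              rep(0:3, each = 10) == b])
    expect_equal(gp$matrix[paste0("P", a), paste0("G", b)], manual)
  }
  expect_identical(gp$strong, abs(gp$matrix) >= 2)
})

test_that("complex recall separates annotated from background links", {
  mp <- module_profiles()
  prof <- structure(list(profile = mp$profile, n_cells = rep(50, 18),
                         features = colnames(mp$profile)),
                    class = "perturbation_profiles")
  sets <- list(modA = rownames(mp$profile)[1:6],
               modB = rownames(mp$profile)[7:12],
               sparse = c(rownames(mp$profile)[13], "missing1",
                          "missing2"))
  cr <- complex_recall(prof, sets, coverage_floor = 2 / 3)
  expect_equal(cr$n_complexes, 2L)  # 1/3 coverage excluded
  expect_gt(cr$median_within, cr$median_background)
  expect_warning(
    complex_recall(prof, list(gone = c("x", "y", "z"))),
    "coverage")
})

test_that("localization variance contrasts divergent and uniform groups", {
  set.seed(8)
  n_genes <- 30
  common <- rnorm(n_genes)
  # group A: divergent responses on the feature subset; group B uniform
  pa <- do.call(rbind, lapply(1:5, function(i) common + rnorm(n_genes, sd = 2)))
  pb <- do.call(rbind, lapply(1:5, function(i) common + rnorm(n_genes, sd = 0.05)))
  P <- rbind(pa, pb)
  rownames(P) <- sprintf("p%02d", 1:10)
  colnames(P) <- sprintf("g%02d", 1:n_genes)
  prof <- structure(list(profile = P, n_cells = rep(50, 10),
                         features = colnames(P)),
                    class = "perturbation_profiles")
  loc <- setNames(rep(c("A", "B"), each = 5), rownames(P))
  lv <- localization_variance(prof, loc, colnames(P)[1:13],
                              n_boot = 500, seed = 1)
  expect_gt(lv$mean_variance[lv$localization == "A"],
            lv$mean_variance[lv$localization == "B"])
  expect_gt(lv$ci_lo[lv$localization == "A"],
            lv$ci_hi[lv$localization == "B"])
  # n_boot = 1 collapses the CI onto the estimate
  lv1 <- localization_variance(prof, loc, colnames(P)[1:13],
                               n_boot = 1, seed = 1)
  expect_equal(lv1$ci_lo, lv1$mean_variance)
  # identical profiles give zero variance
  Pid <- P; Pid[1:5, ] <- rep(P[1, ], each = 5)
  prof_id <- prof; prof_id$profile <- Pid
  lv0 <- localization_variance(prof_id, loc, colnames(P)[1:13],
                               n_boot = 1)
  expect_equal(lv0$mean_variance[lv0$localization == "A"], 0)
  # groups with < 2 members are skipped
  loc2 <- loc; loc2[1] <- "C"
  lvs <- localization_variance(prof, loc2, colnames(P)[1:13], n_boot = 1)
  expect_false("C" %in% lvs$localization)
})
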