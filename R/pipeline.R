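# Pipeline orchestration: configuration, stage sequencing, manifest.

#' Attach guide calls to an expression experiment
#'
#' Subsets the expression matrix to single-perturbation cells and fills
#' the \code{perturbation} / \code{is_control} cell metadata from the
#' calls; multiplets and unassigned cells are dropped.
#'
#' @param um expression experiment.
#' @param calls a \code{\link{call_cells}} result.
#' @return the filtered, labelled experiment.
#' @export
apply_guide_calls <- function(um, calls) {
  single <- calls[calls$category == "single_perturbation", ]
  common <- intersect(colnames(um), single$barcode)
  um <- um[, common]
  ix <- match(common, single$barcode)
  colData(um)$perturbation <- single$perturbation[ix]
  colData(um)$is_control <- single$is_control[ix]
  um
}

#' Pipeline configuration with study defaults
#'
#' Collects every stage threshold with the genome-scale defaults: guide
#' downsampling to 1000 reads/cell and 100 mixture restarts; core-control
#' DEG threshold 8; 2000 adjusted-UMI floor and 25\% mitochondrial
#' ceiling; z clip 10 and 20 PCs; 10,000 permutations against a
#' 5,000-cell control subsample; strength gates 50 DEGs / 25 cells / 30\%
#' knockdown; profile features from top-10 DEGs plus top-30\% variance at
#' 0.25 UMI/cell; CNV window 100 genes, 1.5 SD noise band, 0.8 length
#' fraction; one global seed with fixed per-stage offsets.
#'
#' @param ... overrides for any default field (unknown names rejected).
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    guide_target_reads = 1000L, guide_restarts = 100L,
    guide_posterior_cutoff = 0.5,
    core_deg_threshold = 8, min_adjusted_umi = 2000,
    max_mito_fraction = 0.25,
    pca_expr_floor = 0.5, clip = 10, k = 20L,
    n_perm = 10000L, control_subsample = 5000L,
    min_cells_mw = 10L,
    strength_min_degs = 50L, strength_max_degs_weak = 5L,
    strength_min_cells = 25L, strength_min_knockdown = 0.3,
    profile_top_n_deg = 10L, profile_expr_floor = 0.25,
    profile_var_quantile = 0.30,
    cluster_min_size = 4L, cluster_min_samples = 1L,
    cluster_selection = "eom",
    leverage_k = 20L, leverage_expr_floor = 0.25,
    cnv_window = 100L, cnv_noise_sd = 1.5, cnv_length_fraction = 0.8,
    cnv_min_cells = 25L,
    stages = c("guides", "normalize", "test", "cluster", "phenotypes",
               "leverage", "cin"),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

stage_seed <- function(cfg, stage) {
  offsets <- c(guides = 101L, normalize = 211L, test = 307L,
               cluster = 401L, phenotypes = 503L, leverage = 601L,
               cin = 701L)
  cfg$seed + unname(offsets[stage])
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes guides, normalize, test, cluster, phenotypes, leverage and
#' cin in order (any subset via \code{config$stages}), writing each
#' stage's tables under \code{out_dir} together with a JSON manifest
#' (package version, configuration, per-stage timing). Stage failures
#' halt with an error naming the stage.
#'
#' @param expression expression \code{SingleCellExperiment} (raw counts,
#'   gemgroups; perturbation labels may be absent when the guides stage
#'   runs).
#' @param guides guide \code{SingleCellExperiment}; required when the
#'   guides stage is enabled.
#' @param out_dir output directory.
#' @param config a \code{\link{pipeline_config}}.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(expression, guides = NULL, out_dir,
                         config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  timing <- list()
  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    out <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timing[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"),
                             3)
    out
  }

  res$guides <- run_stage("guides", function() {
    if (is.null(guides)) stop("guide matrix missing")
    gm <- downsample_guide_reads(guides, config$guide_target_reads,
                                 seed = stage_seed(config, "guides"))
    fits <- fit_all_guides(gm, n_restarts = config$guide_restarts,
                           seed = stage_seed(config, "guides"),
                           cutoff = config$guide_posterior_cutoff)
    calls <- call_cells(gm, fits)
    write_tsv(calls, file.path(out_dir, "guide_calls.tsv"))
    expression <<- apply_guide_calls(expression, calls)
    calls
  })

  res$normalize <- run_stage("normalize", function() {
    core <- select_core_controls(expression,
                                 deg_threshold = config$core_deg_threshold)
    factors <- compute_depth_factors(expression, core)
    expression <<- apply_qc_filters(expression, factors,
                                    config$min_adjusted_umi,
                                    config$max_mito_fraction)
    model <- fit_normalization(expression, core, factors)
    z <- z_transform(expression, model)
    long <- do.call(rbind, lapply(colnames(model$mu), function(g)
      data.frame(gemgroup = g, gene = rownames(model$mu),
                 mu = model$mu[, g], sigma = model$sigma[, g])))
    write_tsv(long, file.path(out_dir, "normalization_model.tsv"))
    list(core = core, factors = factors, model = model, z = z)
  })

  res$test <- run_stage("test", function() {
    z <- res$normalize$z
    pc <- pca_features(z, expr_floor = config$pca_expr_floor,
                       clip = config$clip, k = config$k,
                       seed = stage_seed(config, "test"))
    en <- energy_test_all(pc, n_control_subsample =
                            config$control_subsample,
                          n_perm = config$n_perm,
                          seed = stage_seed(config, "test"))
    de <- de_test_all(z, min_cells_mw = config$min_cells_mw)
    kd <- vapply(de$summary$perturbation, function(p)
      compute_knockdown(expression, res$normalize$factors, p)$knockdown,
      numeric(1))
    summ <- merge(en, de$summary[, c("perturbation", "n_degs")],
                  by = "perturbation")
    summ$knockdown <- kd[summ$perturbation]
    summ$strength <- classify_strength(
      summ$n_degs, summ$n_cells, summ$knockdown,
      config$strength_min_degs, config$strength_max_degs_weak,
      config$strength_min_cells, config$strength_min_knockdown)
    write_tsv(summ, file.path(out_dir, "perturbation_tests.tsv"))
    list(pc = pc, energy = en, de = de, summary = summ)
  })

  res$cluster <- run_stage("cluster", function() {
    z <- res$normalize$z
    summ <- res$test$summary
    strong <- summ$perturbation[summ$strength == "strong"]
    if (length(strong) < 2) {
      message("fewer than 2 strong perturbations; clustering skipped")
      return(NULL)
    }
    feats <- select_profile_features(z, res$test$de,
                                     config$profile_top_n_deg,
                                     config$profile_expr_floor,
                                     config$profile_var_quantile)
    prof <- build_profiles(z, strong, feats)
    r <- profile_correlation(prof)
    cl <- cluster_items(1 - r, config$cluster_min_size,
                        config$cluster_min_samples,
                        config$cluster_selection)
    xn <- polarization_normalize(prof)
    emb <- if (nrow(xn) > 3)
      embed_vectors(xn, dim = 2L, seed = stage_seed(config, "cluster"))
    else NULL
    write_tsv(data.frame(perturbation = rownames(prof$profile),
                         cluster = cl$cluster),
              file.path(out_dir, "perturbation_clusters.tsv"))
    write_tsv(data.frame(perturbation = rownames(prof$profile),
                         prof$profile, check.names = FALSE),
              file.path(out_dir, "perturbation_profiles.tsv"))
    if (!is.null(emb))
      write_tsv(data.frame(perturbation = rownames(prof$profile),
                           x = emb$coords[, 1], y = emb$coords[, 2]),
                file.path(out_dir, "perturbation_embedding.tsv"))
    list(features = feats, profiles = prof, correlation = r,
         clusters = cl, embedding = emb)
  })

  res$phenotypes <- run_stage("phenotypes", function() {
    tr <- total_rna(expression)
    mt <- fraction_mt(expression)
    te <- fraction_te(expression)
    cell <- tr$cell
    cell$fraction_mt <- mt[cell$barcode]
    if (!is.null(te)) cell$fraction_te <- te[cell$barcode]
    write_tsv(cell, file.path(out_dir, "composite_phenotypes_cells.tsv"))
    spl <- splicing_ratio(expression)
    if (!is.null(spl))
      write_tsv(data.frame(perturbation = rownames(spl$ratio),
                           spl$ratio, check.names = FALSE),
                file.path(out_dir, "splicing_ratio.tsv"))
    list(total_rna = tr, fraction_mt = mt, fraction_te = te,
         splicing = spl)
  })

  res$leverage <- run_stage("leverage", function() {
    lev <- leverage_scores(res$normalize$z, k = config$leverage_k,
                           expr_floor = config$leverage_expr_floor,
                           clip = config$clip,
                           seed = stage_seed(config, "leverage"))
    het <- heterogeneity_stats(lev)
    write_tsv(lev$cell, file.path(out_dir, "leverage_scores.tsv"))
    write_tsv(het, file.path(out_dir, "leverage_stats.tsv"))
    list(scores = lev, stats = het)
  })

  res$cin <- run_stage("cin", function() {
    prof <- infer_cnv(expression, window = config$cnv_window,
                      noise_sd_threshold = config$cnv_noise_sd)
    kar <- call_karyotype(prof, config$cnv_length_fraction)
    cin <- cin_score(prof, min_cells = config$cnv_min_cells)
    write_tsv(data.frame(barcode = prof$cell_meta$barcode,
                         call = kar$call),
              file.path(out_dir, "karyotype_calls.tsv"))
    write_tsv(cin, file.path(out_dir, "cin_scores.tsv"))
    list(profiles = prof, karyotype = kar, cin = cin)
  })

  manifest <- list(package = "perturbmap",
                   version = as.character(utils::packageVersion("perturbmap")),
                   seed = config$seed,
                   stages = config$stages,
                   config = unclass(config),
                   timing_seconds = timing)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
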