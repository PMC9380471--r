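#' Configuration for the synthetic Perturb-seq generator
#'
#' Defines the statistical structure of a simulated CRISPRi screen:
#' negative-binomial UMI counts over several gemgroups with programmed
#' sequencing-depth differences, non-targeting control constructs, targeting
#' perturbations with programmed on-target knockdown, optional effect-gene
#' sets (shifts expressed in control standard deviations), incomplete
#' penetrance, guide read counts as a Poisson background plus a high-count
#' lognormal true-guide component, lentiviral-recombination multiplets, and
#' chromosome-scale copy-number lesions.
#'
#' @param n_gemgroups number of gemgroups (droplet lanes).
#' @param cells_per_gemgroup cells per gemgroup.
#' @param n_genes number of nuclear genes (13 mitochondrial genes and
#'   \code{n_te_metagenes} TE metagenes are added on top).
#' @param n_perturbations number of targeting perturbations; each targets
#'   one nuclear gene.
#' @param frac_controls fraction of cells carrying non-targeting control
#'   constructs (default 0.05, mirroring the ~5\% non-targeting design).
#' @param n_control_constructs number of distinct non-targeting constructs
#'   the control cells are spread across.
#' @param depth_mean_per_gemgroup expected total UMIs per cell, one value
#'   per gemgroup (unequal values induce batch effects).
#' @param nb_dispersion negative-binomial dispersion (1/size), shared
#'   across genes.
#' @param knockdown_fraction on-target knockdown in affected cells, scalar
#'   or one value per perturbation (default 0.85).
#' @param effect_gene_sets named list: perturbation -> list(genes =
#'   character, shifts = numeric). Shifts are expressed in control-cell
#'   standard deviations of the gene's counts; the generator converts them
#'   to mean multipliers \code{1 + shift * sd/mean}.
#' @param penetrance fraction of a perturbation's cells that exhibit its
#'   programmed effects, scalar or per-perturbation.
#' @param guide_background_rate Poisson mean of background guide reads per
#'   construct per cell.
#' @param guide_signal_log_mean,guide_signal_log_sd natural-log location
#'   and scale of true-guide read counts (default exp(log_mean) = 100).
#' @param recombination_rate fraction of cells carrying a second guide
#'   targeting a different gene (lentiviral recombination / co-encapsulation).
#' @param cnv_lesions list of lesions, each
#'   \code{list(perturbation=, chrom=, copy_ratio=, fraction=)}: the means
#'   of all genes on \code{chrom} are multiplied by \code{copy_ratio} in
#'   \code{fraction} of that perturbation's cells.
#' @param n_chroms number of nuclear chromosomes genes are spread over.
#' @param n_te_metagenes number of TE metagene features (class "TE").
#' @param simulate_layers simulate spliced/unspliced layers?
#' @param unspliced_fraction mean per-gene unspliced read fraction.
#' @param splicing_effects named list perturbation -> multiplier on the
#'   unspliced odds in affected cells (genome-wide).
#' @param mt_fraction expected fraction of UMIs from the 13
#'   mitochondrial-class genes.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_gemgroups = 2L,
                       cells_per_gemgroup = 500L,
                       n_genes = 300L,
                       n_perturbations = 20L,
                       frac_controls = 0.05,
                       n_control_constructs = 2L,
                       depth_mean_per_gemgroup = NULL,
                       nb_dispersion = 0.2,
                       knockdown_fraction = 0.85,
                       effect_gene_sets = NULL,
                       penetrance = 1,
                       guide_background_rate = 0.5,
                       guide_signal_log_mean = log(100),
                       guide_signal_log_sd = 0.5,
                       recombination_rate = 0.05,
                       cnv_lesions = NULL,
                       n_chroms = 5L,
                       n_te_metagenes = 5L,
                       simulate_layers = FALSE,
                       unspliced_fraction = 0.25,
                       splicing_effects = NULL,
                       mt_fraction = 0.12,
                       seed = 1L) {
  if (is.null(depth_mean_per_gemgroup))
    depth_mean_per_gemgroup <- round(seq(5000, 6500,
                                         length.out = n_gemgroups))
  cfg <- list(n_gemgroups = as.integer(n_gemgroups),
              cells_per_gemgroup = as.integer(cells_per_gemgroup),
              n_genes = as.integer(n_genes),
              n_perturbations = as.integer(n_perturbations),
              frac_controls = frac_controls,
              n_control_constructs = as.integer(n_control_constructs),
              depth_mean_per_gemgroup = rep_len(depth_mean_per_gemgroup,
                                                n_gemgroups),
              nb_dispersion = nb_dispersion,
              knockdown_fraction = rep_len(knockdown_fraction,
                                           max(1L, n_perturbations)),
              effect_gene_sets = effect_gene_sets,
              penetrance = rep_len(penetrance, max(1L, n_perturbations)),
              guide_background_rate = guide_background_rate,
              guide_signal_log_mean = guide_signal_log_mean,
              guide_signal_log_sd = guide_signal_log_sd,
              recombination_rate = recombination_rate,
              cnv_lesions = cnv_lesions,
              n_chroms = as.integer(n_chroms),
              n_te_metagenes = as.integer(n_te_metagenes),
              simulate_layers = isTRUE(simulate_layers),
              unspliced_fraction = unspliced_fraction,
              splicing_effects = splicing_effects,
              mt_fraction = mt_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  frac_fields <- c("frac_controls", "recombination_rate",
                   "unspliced_fraction", "mt_fraction")
  for (f in frac_fields)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0, 1]")
  if (any(cfg$penetrance < 0 | cfg$penetrance > 1))
    stop("penetrance must lie in [0, 1]")
  if (any(cfg$knockdown_fraction < 0 | cfg$knockdown_fraction > 1))
    stop("knockdown_fraction must lie in [0, 1]")
  counts <- c("n_gemgroups", "cells_per_gemgroup", "n_genes",
              "n_chroms")
  for (f in counts)
    if (cfg[[f]] < 1) stop(f, " must be positive")
  if (cfg$n_perturbations < 0) stop("n_perturbations must be >= 0")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (any(cfg$depth_mean_per_gemgroup <= 0))
    stop("depth_mean_per_gemgroup must be positive")
  if (!is.null(cfg$cnv_lesions)) {
    for (les in cfg$cnv_lesions) {
      stopifnot(all(c("perturbation", "chrom", "copy_ratio", "fraction")
                    %in% names(les)))
      if (les$fraction < 0 || les$fraction > 1)
        stop("cnv lesion fraction must lie in [0, 1]")
    }
  }
  invisible(cfg)
}

# Deterministic gene universe: nuclear genes over n_chroms chromosomes,
# 13 mitochondrial-class genes on "MT", and TE metagene features.
sim_gene_table <- function(cfg) {
  n <- cfg$n_genes
  chrom <- paste0("chr", rep_len(seq_len(cfg$n_chroms), n))
  chrom <- sort(chrom)  # contiguous blocks per chromosome
  idx_in_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  nuclear <- data.frame(
    gene = sprintf("gene_%04d", seq_len(n)),
    chrom = chrom,
    start = idx_in_chrom * 10000L,
    end = idx_in_chrom * 10000L + 5000L,
    class = "nuclear",
    stringsAsFactors = FALSE)
  mt_names <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8",
                "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
                "MT-ND5", "MT-ND6", "MT-CYB")
  mt <- data.frame(gene = mt_names, chrom = "MT",
                   start = seq_along(mt_names) * 1000L,
                   end = seq_along(mt_names) * 1000L + 800L,
                   class = "mitochondrial", stringsAsFactors = FALSE)
  te <- if (cfg$n_te_metagenes > 0)
    data.frame(gene = sprintf("TE_%02d", seq_len(cfg$n_te_metagenes)),
               chrom = "TE", start = 0L, end = 0L, class = "TE",
               stringsAsFactors = FALSE)
  else NULL
  rbind(nuclear, mt, te)
}

#' Generate a synthetic UMI count experiment with known truth
#'
#' Counts are negative binomial with gene-specific lognormal baseline
#' means, gemgroup depth factors, programmed on-target knockdown (mean
#' multiplied by \code{1 - knockdown_fraction} in affected cells),
#' effect-gene shifts sized in control standard deviations, and
#' chromosome-scale copy-number lesions multiplying all gene means on the
#' lesioned chromosome.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{experiment} (a
#'   \code{SingleCellExperiment}) and \code{truth} (see Details). Truth
#'   holds per-cell labels (\code{cells}), per-perturbation effects
#'   (\code{effects}), the target map (\code{targets}) and the per-cell
#'   karyotype copy-ratio matrix (\code{karyotype}).
#' @export
generate_expression <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  genes <- sim_gene_table(config)
  n_feat <- nrow(genes)
  n_cells <- config$n_gemgroups * config$cells_per_gemgroup

  # lognormal baselines; MT genes rescaled to hit the target mt fraction
  base_mu <- rlnorm(n_feat, meanlog = -1.3, sdlog = 1.4)
  is_mt <- genes$class == "mitochondrial"
  is_te <- genes$class == "TE"
  if (any(is_te)) base_mu[is_te] <- base_mu[is_te] * 0.3
  nonmt_sum <- sum(base_mu[!is_mt])
  base_mu[is_mt] <- base_mu[is_mt] *
    (config$mt_fraction / (1 - config$mt_fraction)) *
    nonmt_sum / sum(base_mu[is_mt])

  # perturbation design: targets drawn from well-expressed nuclear genes
  nuc <- which(genes$class == "nuclear")
  expressed <- nuc[base_mu[nuc] > 0.5]
  if (length(expressed) < config$n_perturbations)
    expressed <- nuc[order(base_mu[nuc], decreasing = TRUE)]
  targets <- genes$gene[sort(sample(expressed, config$n_perturbations))]
  perturbations <- targets
  control_constructs <- sprintf("non-targeting_%02d",
                                seq_len(config$n_control_constructs))

  if (!is.null(config$effect_gene_sets)) {
    bad <- setdiff(unlist(lapply(config$effect_gene_sets, `[[`, "genes")),
                   genes$gene)
    if (length(bad))
      stop("effect genes not in gene universe: ", paste(bad, collapse = ", "))
    unknown <- setdiff(names(config$effect_gene_sets),
                       c(perturbations, control_constructs))
    if (length(unknown))
      stop("effect_gene_sets names unknown perturbations: ",
           paste(unknown, collapse = ", "))
  }

  # assign each cell a construct label
  gemgroup <- rep(paste0("gem", seq_len(config$n_gemgroups)),
                  each = config$cells_per_gemgroup)
  is_control <- runif(n_cells) < config$frac_controls
  label <- character(n_cells)
  label[is_control] <- sample(control_constructs, sum(is_control),
                              replace = TRUE)
  if (config$n_perturbations > 0) {
    label[!is_control] <- sample(perturbations, sum(!is_control),
                                 replace = TRUE)
  } else {
    is_control[] <- TRUE
    label[] <- sample(control_constructs, n_cells, replace = TRUE)
  }
  pert_index <- match(label, perturbations)  # NA for controls
  affected <- !is_control &
    runif(n_cells) < config$penetrance[pmax(pert_index, 1L)]
  affected[is.na(affected)] <- FALSE

  # per-gemgroup depth factors so expected totals hit the configured means
  depth_factor <- config$depth_mean_per_gemgroup / sum(base_mu)
  names(depth_factor) <- paste0("gem", seq_len(config$n_gemgroups))

  # mean matrix (features x cells)
  mu <- matrix(base_mu, nrow = n_feat, ncol = n_cells)
  mu <- sweep(mu, 2, depth_factor[gemgroup], `*`)

  # control-scale SDs used to convert z shifts to mean multipliers
  sd_scale <- function(m) sqrt(m + config$nb_dispersion * m^2)

  karyotype_chroms <- unique(genes$chrom[genes$class != "TE"])
  karyotype <- matrix(1, nrow = n_cells, ncol = length(karyotype_chroms),
                      dimnames = list(NULL, karyotype_chroms))
  effects <- list()
  for (p in seq_len(config$n_perturbations)) {
    cells_p <- which(affected & pert_index == p)
    if (length(cells_p)) {
      tg <- match(targets[p], genes$gene)
      mu[tg, cells_p] <- mu[tg, cells_p] * (1 - config$knockdown_fraction[p])
    }
    eff <- config$effect_gene_sets[[perturbations[p]]]
    if (!is.null(eff) && length(cells_p)) {
      gi <- match(eff$genes, genes$gene)
      shifts <- rep_len(eff$shifts, length(gi))
      for (j in seq_along(gi)) {
        g <- gi[j]
        mult <- pmax(0, 1 + shifts[j] * sd_scale(mu[g, cells_p]) /
                          mu[g, cells_p])
        mu[g, cells_p] <- mu[g, cells_p] * mult
      }
    }
    effects[[perturbations[p]]] <-
      list(target = targets[p],
           knockdown = config$knockdown_fraction[p],
           penetrance = config$penetrance[p],
           effect_genes = if (is.null(eff)) character(0) else eff$genes,
           shifts = if (is.null(eff)) numeric(0) else
             rep_len(eff$shifts, length(eff$genes)))
  }

  # effect sets may also be keyed by control constructs (e.g. to emulate
  # non-targeting guides that induce phenotypes by chance)
  ctl_eff <- intersect(names(config$effect_gene_sets), control_constructs)
  for (cc in ctl_eff) {
    cells_c <- which(label == cc)
    eff <- config$effect_gene_sets[[cc]]
    if (length(cells_c)) {
      gi <- match(eff$genes, genes$gene)
      shifts <- rep_len(eff$shifts, length(gi))
      for (j in seq_along(gi)) {
        g <- gi[j]
        mult <- pmax(0, 1 + shifts[j] * sd_scale(mu[g, cells_c]) /
                          mu[g, cells_c])
        mu[g, cells_c] <- mu[g, cells_c] * mult
      }
      affected[cells_c] <- TRUE
      effects[[cc]] <- list(target = NA_character_, knockdown = 0,
                            penetrance = 1, effect_genes = eff$genes,
                            shifts = shifts)
    }
  }

  if (!is.null(config$cnv_lesions)) {
    for (les in config$cnv_lesions) {
      cells_l <- which(label == les$perturbation)
      cells_l <- cells_l[runif(length(cells_l)) < les$fraction]
      gi <- which(genes$chrom == les$chrom)
      if (!length(gi)) stop("lesion names unknown chromosome: ", les$chrom)
      if (length(cells_l)) {
        mu[gi, cells_l] <- mu[gi, cells_l] * les$copy_ratio
        if (les$chrom %in% colnames(karyotype))
          karyotype[cells_l, les$chrom] <-
            karyotype[cells_l, les$chrom] * les$copy_ratio
      }
    }
  }

  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = 1 / config$nb_dispersion),
                   nrow = n_feat)

  layers <- list()
  if (config$simulate_layers) {
    p_uns <- pmin(0.95, pmax(0.02, rnorm(n_feat, config$unspliced_fraction,
                                         0.05)))
    p_uns[is_te] <- 0
    pm <- matrix(p_uns, nrow = n_feat, ncol = n_cells)
    if (!is.null(config$splicing_effects)) {
      for (p in names(config$splicing_effects)) {
        cells_p <- which(affected & label == p)
        if (length(cells_p)) {
          odds <- pm[, cells_p] / (1 - pm[, cells_p]) *
            config$splicing_effects[[p]]
          pm[, cells_p] <- odds / (1 + odds)
        }
      }
    }
    uns <- matrix(rbinom(length(counts), counts, as.vector(pm)),
                  nrow = n_feat)
    layers <- list(spliced = Matrix(counts - uns, sparse = TRUE),
                   unspliced = Matrix(uns, sparse = TRUE))
  }

  barcode <- sprintf("cell_%05d", seq_len(n_cells))
  perturbation <- label
  sce <- perturb_experiment(Matrix(counts, sparse = TRUE), genes, barcode,
                            gemgroup, perturbation = perturbation,
                            layers = layers)
  colData(sce)$is_control <- is_control

  truth <- list(
    cells = data.frame(barcode = barcode, gemgroup = gemgroup,
                       perturbation = perturbation,
                       is_control = is_control, affected = affected,
                       stringsAsFactors = FALSE),
    targets = setNames(targets, perturbations),
    control_constructs = control_constructs,
    effects = effects,
    karyotype = karyotype,
    depth_factor = depth_factor,
    base_mu = setNames(base_mu, genes$gene))
  list(experiment = sce, truth = truth)
}

#' Generate synthetic guide read counts
#'
#' Every cell receives Poisson background reads for every construct; its
#' true construct receives additional reads from a lognormal high-count
#' component. A \code{recombination_rate} fraction of cells carries a
#' second construct with a different target, emulating lentiviral
#' recombination or co-encapsulation.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth truth list from \code{\link{generate_expression}}.
#' @return list with \code{experiment} (guide
#'   \code{SingleCellExperiment}) and \code{truth} augmented with
#'   \code{guides} (long data.frame barcode/construct) and
#'   \code{recombinant} flag per cell.
#' @export
generate_guide_counts <- function(config, truth) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  cells <- truth$cells
  n_cells <- nrow(cells)
  constructs <- c(names(truth$targets), truth$control_constructs)
  target_of <- c(truth$targets,
                 setNames(rep("non-targeting",
                              length(truth$control_constructs)),
                          truth$control_constructs))
  n_con <- length(constructs)

  counts <- matrix(rpois(n_con * n_cells, config$guide_background_rate),
                   nrow = n_con, dimnames = list(constructs, cells$barcode))
  signal <- function(n) pmax(1, round(rlnorm(n, config$guide_signal_log_mean,
                                             config$guide_signal_log_sd)))
  primary <- match(cells$perturbation, constructs)
  counts[cbind(primary, seq_len(n_cells))] <-
    counts[cbind(primary, seq_len(n_cells))] + signal(n_cells)

  recomb <- runif(n_cells) < config$recombination_rate
  second <- rep(NA_integer_, n_cells)
  for (i in which(recomb)) {
    other <- which(target_of[constructs] != target_of[constructs[primary[i]]])
    if (!length(other)) { recomb[i] <- FALSE; next }
    second[i] <- sample(other, 1L)
    counts[second[i], i] <- counts[second[i], i] + signal(1L)
  }

  construct_meta <- data.frame(construct = constructs,
                               target = unname(target_of[constructs]),
                               tss = "P1", stringsAsFactors = FALSE)
  gm <- guide_experiment(Matrix(counts, sparse = TRUE), construct_meta,
                         cells$barcode, cells$gemgroup)
  guides <- data.frame(
    barcode = c(cells$barcode, cells$barcode[!is.na(second)]),
    construct = c(constructs[primary],
                  constructs[second[!is.na(second)]]),
    stringsAsFactors = FALSE)
  guides <- guides[order(guides$barcode, guides$construct), ]
  rownames(guides) <- NULL
  truth$guides <- guides
  truth$recombinant <- recomb
  list(experiment = gm, truth = truth)
}

#' Generate a complete synthetic dataset (expression + guides + truth)
#'
#' @param config a \code{\link{sim_config}}; its single seed drives both
#'   generators.
#' @return list with \code{expression}, \code{guides}
#'   (\code{SingleCellExperiment}s) and \code{truth}.
#' @export
generate_dataset <- function(config) {
  ex <- generate_expression(config)
  gd <- generate_guide_counts(config, ex$truth)
  list(expression = ex$experiment, guides = gd$experiment,
       truth = gd$truth)
}

#' Write a synthetic dataset to disk
#'
#' Expression and guide matrices are written in feature-barcode
#' MatrixMarket convention under \code{expression/} and \code{guides/};
#' truth tables as TSV; the configuration as a flat key-value file.
#'
#' @param ds output of \code{\link{generate_dataset}}.
#' @param config the \code{\link{sim_config}} used.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(ds, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_barcode(ds$expression, file.path(dir, "expression"))
  write_feature_barcode(ds$guides, file.path(dir, "guides"))
  write.table(ds$truth$cells, file.path(dir, "truth_cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ds$truth$guides, file.path(dir, "truth_guides.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  kar <- data.frame(barcode = ds$truth$cells$barcode, ds$truth$karyotype,
                    check.names = FALSE)
  write.table(kar, file.path(dir, "truth_karyotype.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  scalars <- config[!vapply(config, is.list, logical(1))]
  kv <- vapply(scalars, function(v) paste(v, collapse = ","), character(1))
  writeLines(paste0(names(kv), "=", kv), file.path(dir, "config.txt"))
  invisible(dir)
}
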