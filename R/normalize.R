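# Control-anchored, gemgroup-internal normalization: core-control
# selection, depth factors, QC filters, and the two-step z-normalization
# that yields "fraction of transcriptional effort" scores.

control_labels <- function(um) {
  cd <- colData(um)
  if (is.null(cd$is_control)) stop("experiment lacks an is_control column")
  unique(cd$perturbation[cd$is_control])
}

#' Select core non-targeting control constructs
#'
#' Some non-targeting guides induce detectable phenotypes by chance. A
#' minimal, mutually indistinguishable "core" set is built by: (i)
#' restricting control cells to genes with mean > 1 UMI/cell; (ii)
#' z-normalizing those genes across control cells; (iii) testing every
#' pair of control constructs per gene with the two-sample
#' Anderson-Darling test; (iv) BH adjustment over all tests; (v) counting
#' each construct's average number of differentially expressed genes
#' (q < 0.05) against all others; (vi) retaining constructs whose average
#' falls below \code{deg_threshold}.
#'
#' @param um expression \code{SingleCellExperiment} with per-cell
#'   \code{perturbation} and \code{is_control} columns.
#' @param controls control pseudo-perturbation labels (default: all
#'   labels flagged \code{is_control}).
#' @param deg_threshold average-DEG cutoff (8 for genome-scale depth, 30
#'   for deeper essential-scale libraries).
#' @param expr_floor gene mean UMI floor (default 1).
#' @return object of class \code{core_controls}: list with \code{core}
#'   (retained labels), \code{avg_degs} (named per-construct averages) and
#'   \code{deg_threshold}.
#' @export
select_core_controls <- function(um, controls = NULL, deg_threshold = 8,
                                 expr_floor = 1, seed = 1L) {
  if (is.null(controls)) controls <- control_labels(um)
  if (length(controls) < 2) stop("need at least 2 control constructs")
  cd <- colData(um)
  ctl_cells <- which(cd$perturbation %in% controls)
  n_per <- table(factor(cd$perturbation[ctl_cells], levels = controls))
  if (any(n_per < 10))
    stop("control constructs with < 10 cells: ",
         paste(names(n_per)[n_per < 10], collapse = ", "))
  counts <- assay(um, "counts")[, ctl_cells, drop = FALSE]
  keep_genes <- Matrix::rowMeans(counts) > expr_floor
  if (!any(keep_genes)) stop("no gene passes the expression filter")
  # scale cells to a common total first, so gemgroup depth differences do
  # not masquerade as construct-level expression differences
  totals <- pmax(Matrix::colSums(counts), 1)
  counts <- counts %*% Matrix::Diagonal(x = median(totals) / totals)
  x <- t(as.matrix(counts[keep_genes, , drop = FALSE]))  # cells x genes
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  lab <- cd$perturbation[ctl_cells]
  # tail p-values beyond the tabulated range matter here: with many
  # pairwise tests, BH needs p well below 1e-3 to call anything
  n_med <- round(median(n_per))
  grid <- ad_null_grid(n_med, n_med, n_mc = 20000L, seed = seed)
  pairs <- utils::combn(controls, 2)
  pvals <- matrix(NA_real_, ncol(pairs), ncol(x))
  for (pi in seq_len(ncol(pairs))) {
    a <- x[lab == pairs[1, pi], , drop = FALSE]
    b <- x[lab == pairs[2, pi], , drop = FALSE]
    for (g in seq_len(ncol(x)))
      pvals[pi, g] <- ad_test_gene(a[, g], b[, g], grid = grid)$p
  }
  q <- matrix(bh_adjust(as.vector(pvals)), nrow(pvals))
  degs_per_pair <- rowSums(q < 0.05, na.rm = TRUE)
  avg <- vapply(controls, function(cn) {
    mean(degs_per_pair[pairs[1, ] == cn | pairs[2, ] == cn])
  }, numeric(1))
  structure(list(core = controls[avg < deg_threshold], avg_degs = avg,
                 deg_threshold = deg_threshold),
            class = "core_controls")
}

#' @export
print.core_controls <- function(x, ...) {
  cat("Core controls:", length(x$core), "of", length(x$avg_degs),
      "constructs retained (avg DEGs <", x$deg_threshold, ")\n")
  invisible(x)
}

#' Compute per-gemgroup depth scale factors
#'
#' Factors equalize the mean total UMI counts of core-control cells
#' across gemgroups; applying a gemgroup's factor to all its cells gives
#' "adjusted UMI counts".
#'
#' @param um expression experiment.
#' @param core core control labels (a \code{core_controls} object or a
#'   character vector).
#' @return named numeric vector of factors, one per gemgroup.
#' @export
compute_depth_factors <- function(um, core) {
  if (inherits(core, "core_controls")) core <- core$core
  cd <- colData(um)
  gem <- unique(cd$gemgroup)
  totals <- total_umis(um)
  is_core <- cd$perturbation %in% core
  means <- vapply(gem, function(g) {
    sel <- is_core & cd$gemgroup == g
    if (!any(sel)) stop("gemgroup without core control cells: ", g)
    mean(totals[sel])
  }, numeric(1))
  target <- mean(means)
  setNames(target / means, gem)
}

#' Apply per-cell quality filters
#'
#' Removes cells whose depth-adjusted total UMI count falls below
#' \code{min_adjusted_umi} (cells exactly at the floor are retained) or
#' whose mitochondrial UMI fraction exceeds \code{max_mito_fraction}
#' (cells exactly at the ceiling are retained).
#'
#' @param um expression experiment.
#' @param factors depth factors from \code{\link{compute_depth_factors}}.
#' @param min_adjusted_umi adjusted-UMI floor (2000 genome-scale, 3000
#'   essential-scale).
#' @param max_mito_fraction mitochondrial-fraction ceiling (0.25
#'   genome-scale; 0.20 / 0.11 for the essential-scale libraries).
#' @return filtered experiment.
#' @export
apply_qc_filters <- function(um, factors, min_adjusted_umi = 2000,
                             max_mito_fraction = 0.25) {
  if (min_adjusted_umi <= 0) stop("min_adjusted_umi must be positive")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must lie in [0, 1]")
  totals <- total_umis(um)
  adj <- totals * factors[colData(um)$gemgroup]
  mt <- rowData(um)$class == "mitochondrial"
  mito_frac <- Matrix::colSums(assay(um, "counts")[mt, , drop = FALSE]) /
    pmax(totals, 1)
  keep <- adj >= min_adjusted_umi & mito_frac <= max_mito_fraction
  um[, keep]
}

#' Fit the control-anchored normalization model
#'
#' Two steps: (i) UMI count normalization, scaling every cell so its
#' total equals the median adjusted total of core-control cells; (ii) per
#' gemgroup, per gene, the mean and standard deviation of the normalized
#' expression over core-control cells. Genes whose control SD is zero in
#' a gemgroup are masked (NA) there rather than producing infinite
#' z-scores.
#'
#' @param um QC-filtered expression experiment.
#' @param core core control labels.
#' @param factors depth factors.
#' @return object of class \code{normalization_model}: \code{core},
#'   \code{factors}, \code{median_target}, and per-gemgroup \code{mu} /
#'   \code{sigma} matrices (genes x gemgroups).
#' @export
fit_normalization <- function(um, core, factors) {
  if (inherits(core, "core_controls")) core <- core$core
  if (!length(core)) stop("core control set is empty")
  cd <- colData(um)
  totals <- total_umis(um)
  is_core <- cd$perturbation %in% core
  if (!any(is_core)) stop("no core control cells present")
  m_target <- median(totals[is_core] * factors[cd$gemgroup[is_core]])
  norm <- normalize_totals(um, m_target)
  gems <- unique(cd$gemgroup)
  mu <- sigma <- matrix(NA_real_, nrow(um), length(gems),
                        dimnames = list(rownames(um), gems))
  for (g in gems) {
    sel <- is_core & cd$gemgroup == g
    if (!any(sel)) stop("gemgroup without core control cells: ", g)
    sub <- norm[, sel, drop = FALSE]
    mu[, g] <- Matrix::rowMeans(sub)
    ex2 <- Matrix::rowMeans(sub^2)
    n <- sum(sel)
    v <- pmax(0, (ex2 - mu[, g]^2) * n / (n - 1))
    sigma[, g] <- sqrt(v)
  }
  sigma[sigma == 0] <- NA_real_
  structure(list(core = core, factors = factors, median_target = m_target,
                 mu = mu, sigma = sigma),
            class = "normalization_model")
}

#' @export
print.normalization_model <- function(x, ...) {
  cat("Control-anchored normalization model\n")
  cat("  core controls:", length(x$core),
      "| gemgroups:", ncol(x$mu),
      "| median UMI target:", signif(x$median_target, 5), "\n")
  cat("  genes masked (zero control SD) in >=1 gemgroup:",
      sum(apply(is.na(x$sigma), 1, any)), "\n")
  invisible(x)
}

# scale every cell's counts so the total equals `target`
normalize_totals <- function(um, target) {
  counts <- assay(um, "counts")
  totals <- pmax(Matrix::colSums(counts), 1)
  counts %*% Matrix::Diagonal(x = target / totals)
}

#' Transform an experiment to control-anchored z-scores
#'
#' \code{z = (x - mu_control) / sigma_control} per gene within each
#' gemgroup, after scaling every cell's total UMI count to the core-
#' control median. Scores read as "fraction of transcriptional effort" in
#' units of control standard deviations: +2 means a gene expressed two
#' control SDs above the control mean.
#'
#' @param um QC-filtered expression experiment; must only contain
#'   gemgroups covered by the model.
#' @param model a \code{normalization_model}.
#' @return object of class \code{z_matrix}: list with dense \code{z}
#'   (genes x cells; NA where the gene is masked in the cell's gemgroup),
#'   \code{cell_meta}, \code{gene_meta}, \code{gene_mean_umi} (raw mean
#'   UMIs per cell, for downstream expression floors) and \code{model}.
#' @export
z_transform <- function(um, model) {
  cd <- colData(um)
  unknown <- setdiff(unique(cd$gemgroup), colnames(model$mu))
  if (length(unknown))
    stop("gemgroups not covered by model: ", paste(unknown, collapse = ", "))
  norm <- as.matrix(normalize_totals(um, model$median_target))
  gem <- cd$gemgroup
  z <- (norm - model$mu[, gem, drop = FALSE]) /
    model$sigma[, gem, drop = FALSE]
  dimnames(z) <- dimnames(um)
  structure(list(z = z,
                 cell_meta = as.data.frame(cd),
                 gene_meta = gene_table(um),
                 gene_mean_umi = gene_means(um),
                 model = model),
            class = "z_matrix")
}

#' @export
print.z_matrix <- function(x, ...) {
  cat("z-normalized expression:", nrow(x$z), "genes x", ncol(x$z),
      "cells;", sum(apply(is.na(x$z), 1, any)), "genes masked somewhere\n")
  invisible(x)
}

#' Measure on-target knockdown
#'
#' Ratio of mean depth-adjusted (unnormalized) expression of the target
#' gene in perturbed cells versus non-targeting control cells; knockdown
#' is one minus this ratio.
#'
#' @param um expression experiment.
#' @param factors depth factors.
#' @param perturbation perturbation label.
#' @param target target gene (defaults to the perturbation label itself).
#' @param controls control labels (default: cells flagged
#'   \code{is_control}).
#' @return list with \code{ratio} (remaining expression) and
#'   \code{knockdown}; both NA with \code{measured = FALSE} when the
#'   target is not in the matrix.
#' @export
compute_knockdown <- function(um, factors, perturbation, target = NULL,
                              controls = NULL) {
  if (is.null(target)) target <- perturbation
  if (!target %in% rownames(um))
    return(list(ratio = NA_real_, knockdown = NA_real_, measured = FALSE))
  cd <- colData(um)
  adj <- as.numeric(assay(um, "counts")[target, ]) * factors[cd$gemgroup]
  sel_p <- cd$perturbation == perturbation
  sel_c <- if (is.null(controls)) cd$is_control else
    cd$perturbation %in% controls
  if (!any(sel_p) || !any(sel_c))
    return(list(ratio = NA_real_, knockdown = NA_real_, measured = FALSE))
  ratio <- mean(adj[sel_p]) / mean(adj[sel_c])
  list(ratio = ratio, knockdown = 1 - ratio, measured = TRUE)
}

#' Expression change of a target's genomic neighbors
#'
#' For a perturbation's target gene, finds the nearest expressed gene
#' (mean > \code{expr_floor} UMI/cell) upstream and downstream on the
#' same chromosome and reports the fractional change in depth-adjusted
#' expression, (perturbed - control)/control; -1 means complete
#' knockdown. Targets at a chromosome end give a one-sided result.
#'
#' @param um expression experiment.
#' @param factors depth factors.
#' @param perturbation perturbation label (target gene symbol).
#' @param expr_floor neighbor expression floor (default 0.1 UMI/cell).
#' @return data.frame with one row per side (up/down): neighbor gene and
#'   fractional change; zero rows when no neighbor qualifies.
#' @export
neighbor_knockdown <- function(um, factors, perturbation,
                               expr_floor = 0.1) {
  gm <- gene_table(um)
  if (!perturbation %in% gm$gene) stop("target gene not annotated")
  tgt <- gm[gm$gene == perturbation, ]
  same <- gm[gm$chrom == tgt$chrom & gm$gene != perturbation, ]
  means <- gene_means(um)[same$gene]
  same <- same[means > expr_floor, , drop = FALSE]
  up <- same[same$start < tgt$start, , drop = FALSE]
  dn <- same[same$start > tgt$start, , drop = FALSE]
  pick <- rbind(
    if (nrow(up)) cbind(side = "upstream",
                        up[which.max(up$start), , drop = FALSE]),
    if (nrow(dn)) cbind(side = "downstream",
                        dn[which.min(dn$start), , drop = FALSE]))
  if (is.null(pick) || !nrow(pick))
    return(data.frame(side = character(0), neighbor = character(0),
                      fractional_change = numeric(0)))
  cd <- colData(um)
  sel_p <- cd$perturbation == perturbation
  sel_c <- cd$is_control
  fc <- vapply(pick$gene, function(g) {
    adj <- as.numeric(assay(um, "counts")[g, ]) * factors[cd$gemgroup]
    (mean(adj[sel_p]) - mean(adj[sel_c])) / mean(adj[sel_c])
  }, numeric(1))
  data.frame(side = pick$side, neighbor = pick$gene,
             fractional_change = unname(fc), stringsAsFactors = FALSE)
}
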