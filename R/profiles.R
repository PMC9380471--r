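# Pseudobulk perturbation profiles, correlation structure, program
# scores, genotype-phenotype summaries, complex recall and
# localization-variance analyses.

#' Select the highly-variable feature gene set for profiles
#'
#' Union of (i) the top \code{top_n_deg} differentially expressed genes
#' of every perturbation, ordered by the Anderson-Darling statistic among
#' genes significant at the DE alpha, and (ii) all genes with raw mean
#' expression above \code{expr_floor} UMIs/cell whose z-score variance is
#' in the top \code{var_quantile} fraction of the dataset.
#'
#' @param z a \code{\link{z_transform}} result.
#' @param de a \code{\link{de_test_all}} result.
#' @param top_n_deg DEGs taken per perturbation (default 10).
#' @param expr_floor mean-UMI floor for the variance arm (default 0.25).
#' @param var_quantile top variance fraction (default 0.30).
#' @return character vector of genes, in matrix row order.
#' @export
select_profile_features <- function(z, de, top_n_deg = 10L,
                                    expr_floor = 0.25,
                                    var_quantile = 0.30) {
  deg_genes <- unlist(lapply(de$genes, function(tb) {
    sig <- tb[!is.na(tb$ad_q) & tb$ad_q < de$deg_alpha, ]
    head(sig$gene[order(sig$ad_stat, decreasing = TRUE)], top_n_deg)
  }), use.names = FALSE)
  vz <- apply(z$z, 1, var, na.rm = TRUE)
  pass <- z$gene_mean_umi > expr_floor & !is.na(vz)
  hv <- character(0)
  if (var_quantile > 0 && any(pass)) {
    cut <- quantile(vz[pass], 1 - var_quantile, names = FALSE)
    hv <- rownames(z$z)[pass & vz >= cut]
  }
  feats <- rownames(z$z)[rownames(z$z) %in% union(deg_genes, hv)]
  if (!length(feats)) stop("empty feature set")
  feats
}

#' Build pseudobulk perturbation profiles
#'
#' Mean z-score over each perturbation's cells, restricted to the
#' feature genes. To keep the direct knockdown from dominating, the
#' target gene's value is set to 0 in its own perturbation's profile
#' (0 is the control mean by construction).
#'
#' @param z a \code{\link{z_transform}} result.
#' @param perturbations labels to profile (default: all non-control
#'   labels present).
#' @param features feature genes (default: all genes).
#' @param mask_targets zero out each perturbation's own target gene?
#' @param target_map named vector perturbation -> target gene (defaults
#'   to the labels themselves, the convention for CRISPRi target genes).
#' @return object of class \code{perturbation_profiles}: \code{profile}
#'   (perturbations x features), \code{n_cells}, \code{features}.
#' @export
build_profiles <- function(z, perturbations = NULL, features = NULL,
                           mask_targets = TRUE, target_map = NULL) {
  cm <- z$cell_meta
  if (is.null(perturbations))
    perturbations <- sort(unique(cm$perturbation[!cm$is_control]))
  if (is.null(features)) features <- rownames(z$z)
  if (is.null(target_map))
    target_map <- setNames(perturbations, perturbations)
  keep <- vapply(perturbations, function(p)
    sum(cm$perturbation == p) > 0, logical(1))
  perturbations <- perturbations[keep]
  prof <- matrix(NA_real_, length(perturbations), length(features),
                 dimnames = list(perturbations, features))
  n_cells <- integer(length(perturbations))
  for (i in seq_along(perturbations)) {
    sel <- cm$perturbation == perturbations[i]
    n_cells[i] <- sum(sel)
    prof[i, ] <- rowMeans(z$z[features, sel, drop = FALSE], na.rm = TRUE)
  }
  prof[is.nan(prof)] <- 0
  if (mask_targets) {
    for (i in seq_along(perturbations)) {
      tg <- target_map[perturbations[i]]
      if (!is.na(tg) && tg %in% features) prof[i, tg] <- 0
    }
  }
  structure(list(profile = prof, n_cells = setNames(n_cells,
                                                    perturbations),
                 features = features, masked = mask_targets),
            class = "perturbation_profiles")
}

#' @export
print.perturbation_profiles <- function(x, ...) {
  cat("Pseudobulk profiles:", nrow(x$profile), "perturbations x",
      ncol(x$profile), "genes\n")
  invisible(x)
}

#' Pairwise Pearson correlation of perturbation profiles
#'
#' Correlation is scale-invariant, so perturbations with related but
#' differently sized effects still pair up. Zero-variance profiles give
#' NaN rows and a warning.
#'
#' @param profiles a \code{perturbation_profiles} object or a plain
#'   matrix (rows = profiles).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
profile_correlation <- function(profiles) {
  m <- if (inherits(profiles, "perturbation_profiles")) profiles$profile
  else as.matrix(profiles)
  if (nrow(m) < 2) stop("need at least 2 profiles")
  sds <- apply(m, 1, sd)
  if (any(sds == 0))
    warning("zero-variance profiles: ",
            paste(rownames(m)[sds == 0], collapse = ", "))
  r <- suppressWarnings(cor(t(m)))
  diag(r) <- 1
  r
}

#' Center and normalize profiles so Euclidean distance encodes correlation
#'
#' Each profile is centered and scaled to unit Euclidean norm, giving
#' vectors that satisfy the polarization identity
#' \eqn{\|\hat x - \hat y\|^2 = 2(1 - corr(x, y))}; minimizing Euclidean
#' distances between normalized profiles is then equivalent to minimizing
#' correlation distances between the raw ones.
#'
#' @param profiles a \code{perturbation_profiles} object or matrix.
#' @return matrix of normalized profiles (rows centered, unit norm).
#' @export
polarization_normalize <- function(profiles) {
  m <- if (inherits(profiles, "perturbation_profiles")) profiles$profile
  else as.matrix(profiles)
  ctr <- m - rowMeans(m)
  nrm <- sqrt(rowSums(ctr^2))
  if (any(nrm == 0))
    stop("constant profiles cannot be normalized: ",
         paste(rownames(m)[nrm == 0], collapse = ", "))
  ctr / nrm
}

#' Score a gene expression program across perturbations
#'
#' Raw score = mean profile z over the program's genes; scores are then
#' standardized across the scored perturbation collection (mean 0, SD 1)
#' so programs of different sizes and dynamic ranges are comparable.
#'
#' @param profiles a \code{perturbation_profiles} object.
#' @param gene_set genes of the program (must intersect the profiled
#'   features).
#' @return data.frame: perturbation, raw_score, score (standardized).
#' @export
program_score <- function(profiles, gene_set) {
  gs <- intersect(gene_set, colnames(profiles$profile))
  if (!length(gs)) stop("empty or unprofiled gene set")
  raw <- rowMeans(profiles$profile[, gs, drop = FALSE])
  data.frame(perturbation = rownames(profiles$profile),
             raw_score = unname(raw),
             score = unname((raw - mean(raw)) / sd(raw)),
             stringsAsFactors = FALSE)
}

#' Genotype-phenotype cluster summary matrix
#'
#' Averages profile z-scores over each perturbation cluster (rows) and
#' each gene-program cluster (columns); entries with |mean| at or above
#' \code{strong_threshold} control SDs are flagged as strong links.
#'
#' @param profiles a \code{perturbation_profiles} object.
#' @param perturbation_clusters \code{cluster_assignment} over the
#'   profiled perturbations (noise items are dropped).
#' @param gene_clusters \code{cluster_assignment} over the feature genes.
#' @param strong_threshold strong-link threshold in SD units (default 2).
#' @return list with \code{matrix} (clusters x programs) and
#'   \code{strong} (logical matrix).
#' @export
genotype_phenotype_matrix <- function(profiles, perturbation_clusters,
                                      gene_clusters,
                                      strong_threshold = 2) {
  pc <- perturbation_clusters$cluster
  gc <- gene_clusters$cluster
  stopifnot(length(pc) == nrow(profiles$profile),
            length(gc) == ncol(profiles$profile))
  pids <- sort(unique(pc[pc >= 0]))
  gids <- sort(unique(gc[gc >= 0]))
  if (!length(pids) || !length(gids))
    stop("no non-noise clusters to summarize")
  m <- matrix(NA_real_, length(pids), length(gids),
              dimnames = list(paste0("P", pids), paste0("G", gids)))
  for (a in seq_along(pids)) for (b in seq_along(gids)) {
    m[a, b] <- mean(profiles$profile[pc == pids[a], gc == gids[b],
                                     drop = FALSE])
  }
  list(matrix = m, strong = abs(m) >= strong_threshold,
       strong_threshold = strong_threshold)
}

#' Recall of annotated complexes by profile correlation
#'
#' Complexes with at least \code{coverage_floor} of their subunits
#' profiled are expanded into all pairwise links; the distribution of
#' within-complex link correlations is compared with the background of
#' all pairwise links among profiled perturbations.
#'
#' @param profiles a \code{perturbation_profiles} object.
#' @param complex_sets named list of character vectors (complex members,
#'   by perturbation/gene label).
#' @param coverage_floor minimum profiled fraction (default 2/3).
#' @return list with \code{within} / \code{background} correlation
#'   vectors, their medians, and \code{n_complexes} retained.
#' @export
complex_recall <- function(profiles, complex_sets, coverage_floor = 2 / 3) {
  r <- profile_correlation(profiles)
  profiled <- rownames(r)
  keep <- vapply(complex_sets, function(s)
    mean(s %in% profiled) >= coverage_floor && sum(s %in% profiled) >= 2,
    logical(1))
  if (!any(keep)) {
    warning("no complex passes the coverage floor")
    return(list(within = numeric(0),
                background = r[upper.tri(r)],
                median_within = NA_real_,
                median_background = median(r[upper.tri(r)]),
                n_complexes = 0L))
  }
  within <- unlist(lapply(complex_sets[keep], function(s) {
    mem <- intersect(s, profiled)
    sub <- r[mem, mem, drop = FALSE]
    sub[upper.tri(sub)]
  }), use.names = FALSE)
  background <- r[upper.tri(r)]
  list(within = within, background = background,
       median_within = median(within),
       median_background = median(background),
       n_complexes = sum(keep))
}

#' Variance of feature-subset responses by protein localization
#'
#' For each feature gene (e.g. the 13 mitochondrially encoded genes),
#' computes the variance of mean profile values across all perturbations
#' sharing a localization, then averages across features, with a 95\%
#' bootstrap confidence interval over features. Dual-localized entries
#' must be excluded upstream (pass one localization per perturbation).
#'
#' @param profiles a \code{perturbation_profiles} object.
#' @param localization named character vector perturbation ->
#'   localization.
#' @param gene_subset feature genes over which variance is computed.
#' @param n_boot bootstrap replicates (default 1000; 1 collapses the CI
#'   to the point estimate).
#' @param seed integer seed.
#' @return data.frame: localization, n_perturbations, mean_variance,
#'   ci_lo, ci_hi. Groups with fewer than 2 perturbations are skipped.
#' @export
localization_variance <- function(profiles, localization, gene_subset,
                                  n_boot = 1000L, seed = 1L) {
  gs <- intersect(gene_subset, colnames(profiles$profile))
  if (!length(gs)) stop("gene subset not profiled")
  set.seed(seed)
  locs <- sort(unique(localization))
  rows <- lapply(locs, function(L) {
    perts <- intersect(names(localization)[localization == L],
                       rownames(profiles$profile))
    if (length(perts) < 2) return(NULL)
    v <- apply(profiles$profile[perts, gs, drop = FALSE], 2, var)
    boots <- vapply(seq_len(n_boot), function(b)
      mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
    ci <- if (n_boot > 1) quantile(boots, c(0.025, 0.975), names = FALSE)
    else rep(mean(v), 2)
    data.frame(localization = L, n_perturbations = length(perts),
               mean_variance = mean(v), ci_lo = ci[1], ci_hi = ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
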