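# Gene-level differential expression per perturbation and strength
# classification.

#' Gene-level differential expression for one perturbation
#'
#' For each gene, compares z-normalized expression in a perturbation's
#' cells against control cells with the two-sample Anderson-Darling test
#' (broadly sensitive to any distributional change) and the asymptotic
#' Mann-Whitney test (stochastic ordering); both are BH-adjusted across
#' genes.
#'
#' @param z a \code{\link{z_transform}} result.
#' @param perturbation perturbation label.
#' @param controls control labels (default: cells flagged
#'   \code{is_control}, excluding the tested label).
#' @param genes genes to test (default: all genes unmasked in every
#'   gemgroup present).
#' @param min_cells_mw Mann-Whitney minimum-cell gate (default 10).
#' @param grid optional \code{\link{ad_null_grid}} for tail p-values.
#' @return data.frame: gene, ad_stat, ad_p, ad_q, mw_p, mw_q.
#' @export
de_test_genes <- function(z, perturbation, controls = NULL, genes = NULL,
                          min_cells_mw = 10L, grid = NULL) {
  cm <- z$cell_meta
  sel_p <- cm$perturbation == perturbation
  sel_c <- if (is.null(controls)) cm$is_control & !sel_p else
    cm$perturbation %in% controls & !sel_p
  if (sum(sel_p) < 2 || sum(sel_c) < 2)
    stop("need >= 2 cells in each group")
  if (is.null(genes)) {
    ok <- !apply(is.na(z$z[, sel_p | sel_c, drop = FALSE]), 1, any)
    genes <- rownames(z$z)[ok]
  }
  zp <- z$z[genes, sel_p, drop = FALSE]
  zc <- z$z[genes, sel_c, drop = FALSE]
  ad_stat <- ad_p <- mw_p <- rep(NA_real_, length(genes))
  for (g in seq_along(genes)) {
    a <- zp[g, ]; b <- zc[g, ]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) next
    ad <- ad_test_gene(a, b, grid = grid)
    ad_stat[g] <- ad$statistic
    ad_p[g] <- ad$p
    mw_p[g] <- mw_test_gene(a, b, min_cells = min_cells_mw)$p
  }
  data.frame(gene = genes, ad_stat = ad_stat, ad_p = ad_p,
             ad_q = bh_adjust(ad_p), mw_p = mw_p, mw_q = bh_adjust(mw_p),
             stringsAsFactors = FALSE)
}

#' Differential expression for all perturbations
#'
#' Runs \code{\link{de_test_genes}} per perturbation and summarizes DEG
#' counts at \code{q < deg_alpha} by the Anderson-Darling test.
#'
#' @param z a \code{\link{z_transform}} result.
#' @param perturbations labels to test (default: all non-control labels).
#' @param deg_alpha DEG significance on the BH-adjusted AD p (default
#'   0.05).
#' @param extend_tails extend AD p-values beyond the tabulated floor of
#'   0.001 with a Monte-Carlo grid (\code{\link{ad_null_grid}}) sized at
#'   the median group sizes? Without this, BH across thousands of genes
#'   cannot call isolated strong effects (e.g. the knocked-down target
#'   itself).
#' @param grid_seed seed of the Monte-Carlo grid.
#' @param ... passed to \code{\link{de_test_genes}}.
#' @return object of class \code{de_results}: list with \code{summary}
#'   (perturbation, n_cells, n_degs) and \code{genes} (named list of
#'   per-gene tables).
#' @export
de_test_all <- function(z, perturbations = NULL, deg_alpha = 0.05,
                        extend_tails = TRUE, grid_seed = 1L, ...) {
  cm <- z$cell_meta
  if (is.null(perturbations))
    perturbations <- sort(unique(cm$perturbation[!cm$is_control]))
  grid <- NULL
  if (extend_tails) {
    n_p <- round(median(vapply(perturbations, function(p)
      sum(cm$perturbation == p), integer(1))))
    n_c <- sum(cm$is_control)
    grid <- ad_null_grid(min(max(n_p, 5L), 500L), min(n_c, 500L),
                         n_mc = 20000L, seed = grid_seed)
  }
  tables <- lapply(perturbations, function(p)
    de_test_genes(z, p, grid = grid, ...))
  names(tables) <- perturbations
  summary <- data.frame(
    perturbation = perturbations,
    n_cells = vapply(perturbations, function(p)
      sum(cm$perturbation == p), integer(1)),
    n_degs = vapply(tables, function(tb)
      sum(tb$ad_q < deg_alpha, na.rm = TRUE), integer(1)),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, genes = tables,
                 deg_alpha = deg_alpha),
            class = "de_results")
}

#' @export
print.de_results <- function(x, ...) {
  cat("Gene-level DE for", nrow(x$summary), "perturbations; median DEGs:",
      median(x$summary$n_degs), "\n")
  invisible(x)
}

#' Classify perturbation strength
#'
#' A perturbation is \code{strong} when it has at least
#' \code{min_degs_strong} differentially expressed genes (BH-adjusted AD
#' p < 0.05), at least \code{min_cells} quality-filtered cells, and an
#' on-target knockdown of at least \code{min_knockdown} when the target
#' was measured (an unmeasured target passes the gate). \code{weak}
#' perturbations meet the same cell/knockdown gates with fewer than
#' \code{max_degs_weak} DEGs; everything else is \code{other}.
#'
#' @param n_degs DEG count.
#' @param n_cells cell count.
#' @param knockdown measured knockdown fraction, or NA when not measured.
#' @param min_degs_strong,max_degs_weak,min_cells,min_knockdown gates
#'   (defaults 50, 5, 25, 0.3).
#' @return "strong", "weak" or "other" (vectorized).
#' @export
classify_strength <- function(n_degs, n_cells, knockdown,
                              min_degs_strong = 50L, max_degs_weak = 5L,
                              min_cells = 25L, min_knockdown = 0.3) {
  kd_ok <- is.na(knockdown) | knockdown >= min_knockdown
  gates <- n_cells >= min_cells & kd_ok
  ifelse(gates & n_degs >= min_degs_strong, "strong",
         ifelse(gates & n_degs < max_degs_weak, "weak", "other"))
}
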