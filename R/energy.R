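# Energy-distance two-sample testing on principal-component scores.

#' PCA feature matrix for energy-distance testing
#'
#' Keeps genes with raw mean expression above \code{expr_floor} UMIs per
#' cell, clips z-scores above \code{clip} down to \code{clip} (to dampen
#' a handful of strongly induced outlier genes), masks NAs to 0 (the
#' control mean), and projects cells onto the top \code{k} principal
#' components.
#'
#' @param z a \code{\link{z_transform}} result.
#' @param expr_floor gene mean UMI floor (default 0.5).
#' @param clip upper z clip (default 10).
#' @param k number of principal components (default 20).
#' @param seed seed for the randomized solver used on large inputs.
#' @return object of class \code{pc_features}: \code{scores} (cells x k),
#'   \code{cell_meta}, and provenance fields.
#' @export
pca_features <- function(z, expr_floor = 0.5, clip = 10, k = 20L,
                         seed = 1L) {
  keep <- z$gene_mean_umi > expr_floor
  x <- t(z$z[keep, , drop = FALSE])          # cells x genes
  x[is.na(x)] <- 0
  x[x > clip] <- clip
  if (k > min(dim(x))) stop("k exceeds matrix rank bound")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  if (min(dim(xc)) > 300 && k <= min(dim(xc)) / 3) {
    set.seed(seed)
    sv <- irlba::irlba(xc, nv = k)
    scores <- sv$u %*% diag(sv$d, k, k)
  } else {
    sv <- svd(xc, nu = k, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  }
  rownames(scores) <- rownames(x)
  structure(list(scores = scores, cell_meta = z$cell_meta,
                 expr_floor = expr_floor, clip = clip, k = k, seed = seed),
            class = "pc_features")
}

# pairwise Euclidean distances between rows of A and rows of B, by exact
# per-dimension differencing (the expanded dot-product form loses several
# digits through cancellation)
cross_dist <- function(A, B) {
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in seq_len(ncol(A)))
    d2 <- d2 + outer(A[, k], B[, k], `-`)^2
  sqrt(d2)
}

#' Energy-distance estimator between two samples
#'
#' The three-double-sum estimator
#' \deqn{2/(n_1 n_2)\sum\|x_i-y_j\| - 1/n_1^2\sum\|x_i-x_j\| -
#'   1/n_2^2\sum\|y_i-y_j\|,} symmetric in its arguments. The biased
#' variant can be slightly negative on finite same-distribution samples;
#' the permutation p-value, not the sign, carries the inference.
#'
#' @param X,Y sample matrices (rows = observations); vectors are treated
#'   as one-dimensional samples.
#' @return the estimator value.
#' @export
energy_distance <- function(X, Y) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  if (!nrow(X) || !nrow(Y)) stop("empty sample")
  2 * mean(cross_dist(X, Y)) - mean(cross_dist(X, X)) -
    mean(cross_dist(Y, Y))
}

# energy distance from a pooled distance matrix given the indices of the
# "perturbed" sample; s = rowSums(D), Tsum = sum(D)
energy_from_pool <- function(D, s, Tsum, idx, n) {
  n2 <- length(idx)
  n1 <- n - n2
  Syy <- sum(D[idx, idx])
  Sy <- sum(s[idx])
  Sxy <- Sy - Syy
  Sxx <- Tsum - 2 * Sxy - Syy
  2 * Sxy / (n1 * n2) - Sxx / n1^2 - Syy / n2^2
}

#' Permutation energy-distance test
#'
#' Compares perturbed cells against a control pool in PC space. Controls
#' larger than \code{n_control_subsample} are subsampled once with the
#' run seed. Significance comes from permuting the control/perturbed
#' labels; the p-value uses the add-one rule
#' \eqn{p = (1 + \#\{\epsilon_{perm} \ge \epsilon_{obs}\})/(1 + B)} so it
#' is never zero.
#'
#' @param perturbed,controls matrices of PC scores (rows = cells).
#' @param n_control_subsample maximum control cells used (default 5000).
#' @param n_perm number of permutations (default 10000; must be >= 1).
#' @param seed integer seed.
#' @return list with \code{energy}, \code{p}, \code{n_perm},
#'   \code{n_perturbed}, \code{n_controls}. Perturbations with fewer than
#'   2 cells return NA with \code{skipped = TRUE}.
#' @export
energy_test <- function(perturbed, controls, n_control_subsample = 5000L,
                        n_perm = 10000L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be positive")
  if (is.vector(perturbed)) perturbed <- matrix(perturbed, ncol = 1)
  if (is.vector(controls)) controls <- matrix(controls, ncol = 1)
  if (nrow(perturbed) < 2)
    return(list(energy = NA_real_, p = NA_real_, skipped = TRUE,
                n_perturbed = nrow(perturbed), n_controls = nrow(controls),
                n_perm = n_perm))
  set.seed(seed)
  if (nrow(controls) > n_control_subsample)
    controls <- controls[sample(nrow(controls), n_control_subsample), ,
                         drop = FALSE]
  pool <- rbind(controls, perturbed)
  n <- nrow(pool)
  n2 <- nrow(perturbed)
  D <- cross_dist(pool, pool)
  s <- rowSums(D)
  Tsum <- sum(s)
  idx_obs <- (n - n2 + 1):n
  obs <- energy_from_pool(D, s, Tsum, idx_obs, n)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, n2)
    if (energy_from_pool(D, s, Tsum, idx, n) >= obs) ge <- ge + 1L
  }
  list(energy = obs, p = (1 + ge) / (1 + n_perm), skipped = FALSE,
       n_perturbed = n2, n_controls = n - n2, n_perm = n_perm)
}

#' Energy-distance tests for every perturbation
#'
#' Runs \code{\link{energy_test}} for each non-control perturbation (and
#' optionally each control pseudo-perturbation) against the pooled
#' control cells.
#'
#' @param pc a \code{\link{pca_features}} result.
#' @param include_controls also test each control pseudo-perturbation
#'   against the remaining controls (their false-positive rate estimates
#'   the test's calibration)?
#' @param n_control_subsample,n_perm,seed see \code{\link{energy_test}}.
#' @return data.frame: perturbation, n_cells, energy, p.
#' @export
energy_test_all <- function(pc, include_controls = FALSE,
                            n_control_subsample = 5000L, n_perm = 10000L,
                            seed = 1L) {
  cm <- pc$cell_meta
  is_ctl <- cm$is_control
  perts <- sort(unique(cm$perturbation[!is_ctl]))
  if (include_controls)
    perts <- c(perts, sort(unique(cm$perturbation[is_ctl])))
  res <- lapply(seq_along(perts), function(i) {
    p <- perts[i]
    sel_p <- cm$perturbation == p
    sel_c <- is_ctl & !sel_p
    et <- energy_test(pc$scores[sel_p, , drop = FALSE],
                      pc$scores[sel_c, , drop = FALSE],
                      n_control_subsample = n_control_subsample,
                      n_perm = n_perm, seed = seed + i)
    data.frame(perturbation = p, n_cells = sum(sel_p),
               energy = et$energy, p = et$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
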