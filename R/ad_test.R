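# k-sample Anderson-Darling test (Scholz & Stephens 1987), midrank (tie-
# corrected) statistic, with the standard critical-value interpolation for
# p-values and an optional Monte-Carlo grid extension for far tails.

ad_variance <- function(n) {
  k <- length(n)
  N <- sum(n)
  H <- sum(1 / n)
  inv <- 1 / seq_len(N - 1)
  h <- sum(inv)
  # g = sum_{i=1}^{N-2} 1/(N-i) * sum_{j=i+1}^{N-1} 1/j, via cumulative sums
  cum <- cumsum(inv)                     # cum[i] = sum_{j<=i} 1/j
  i <- seq_len(N - 2)
  g <- sum((cum[N - 1] - cum[i]) / (N - i))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H -
    8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
    (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
}

# midrank (tie-corrected) k-sample AD statistic A2akN
ad_statistic_raw <- function(samples) {
  n <- lengths(samples)
  N <- sum(n)
  Z <- sort(unlist(samples, use.names = FALSE))
  Zstar <- unique(Z)
  L <- length(Zstar)
  if (L < 2) return(list(A2 = NA_real_, n = n, constant = TRUE))
  left <- findInterval(Zstar, Z, left.open = TRUE)   # count strictly below
  lj <- findInterval(Zstar, Z) - left                # multiplicity in pool
  Bj <- left + lj / 2
  A2 <- 0
  for (s in samples) {
    s <- sort(s)
    below <- findInterval(Zstar, s, left.open = TRUE)
    fij <- findInterval(Zstar, s) - below
    Mij <- below + fij / 2
    ni <- length(s)
    denom <- Bj * (N - Bj) - N * lj / 4
    ok <- denom > 0
    inner <- lj[ok] / N * (N * Mij[ok] - Bj[ok] * ni)^2 / denom[ok]
    A2 <- A2 + sum(inner) / ni
  }
  list(A2 = A2 * (N - 1) / N, n = n, constant = FALSE)
}

# standardized statistic Tk = (A2 - (k-1)) / sigma
ad_standardized <- function(samples) {
  raw <- ad_statistic_raw(samples)
  if (isTRUE(raw$constant)) return(list(tk = NA_real_, constant = TRUE))
  sigma2 <- ad_variance(raw$n)
  list(tk = (raw$A2 - (length(raw$n) - 1)) / sqrt(sigma2),
       A2 = raw$A2, constant = FALSE)
}

# tabulated critical values (levels 25%..0.1%) for m = k - 1
ad_critical <- function(k) {
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326, 2.573, 3.085)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822, 2.364, 3.615)
  b2 <- c(-0.105, -0.305, -0.481, -0.855, -1.527, -1.800, -2.300)
  m <- k - 1
  list(critical = b0 + b1 / sqrt(m) + b2 / m,
       p = c(0.25, 0.1, 0.05, 0.025, 0.01, 0.005, 0.001))
}

# p from the standardized statistic via quadratic fit of log p against the
# critical values; clipped to the tabulated range [0.001, 0.25] unless a
# Monte-Carlo grid is supplied for the tails
ad_pvalue <- function(tk, k = 2, grid = NULL) {
  if (is.na(tk)) return(NA_real_)
  cv <- ad_critical(k)
  if (!is.null(grid) && tk > max(cv$critical))
    return(ad_grid_pvalue(grid, tk))
  fit <- lm.fit(cbind(1, cv$critical, cv$critical^2), log(cv$p))
  p <- exp(sum(fit$coefficients * c(1, tk, tk^2)))
  min(max(p, 0.001), 0.25)
}

#' Monte-Carlo grid for Anderson-Darling tail p-values
#'
#' The tabulated critical values of the k-sample Anderson-Darling test
#' stop at p = 0.001. To report smaller p-values, a null reference
#' distribution of the standardized statistic is simulated once for given
#' sample sizes, p is precomputed on a grid of statistic values, and
#' intermediate values are obtained by monotone piecewise-linear
#' interpolation in log p.
#'
#' @param n1,n2 the two sample sizes.
#' @param n_mc number of Monte-Carlo null replicates.
#' @param seed integer seed.
#' @return object of class \code{ad_grid} for use in
#'   \code{\link{ad_test_gene}}.
#' @export
ad_null_grid <- function(n1, n2, n_mc = 20000L, seed = 1L) {
  set.seed(seed)
  tks <- vapply(seq_len(n_mc), function(i) {
    z <- rnorm(n1 + n2)
    ad_standardized(list(z[seq_len(n1)], z[-seq_len(n1)]))$tk
  }, numeric(1))
  tks <- sort(tks)
  # tail grid: p(t) = P(T >= t), log-linear between quantile knots
  probs <- c(seq(0.5, 0.99, by = 0.01), seq(0.991, 1 - 1 / n_mc, by = 0.001))
  knots <- quantile(tks, probs, names = FALSE, type = 1)
  keep <- !duplicated(knots)
  structure(list(t = knots[keep], logp = log(1 - probs[keep]),
                 t_max = max(tks), n_mc = n_mc),
            class = "ad_grid")
}

ad_grid_pvalue <- function(grid, tk) {
  if (tk <= grid$t[1]) return(exp(grid$logp[1]))
  if (tk >= max(grid$t)) {
    # log-linear extrapolation from the last two knots
    m <- length(grid$t)
    slope <- (grid$logp[m] - grid$logp[m - 1]) /
      (grid$t[m] - grid$t[m - 1])
    return(max(exp(grid$logp[m] + slope * (tk - grid$t[m])),
               .Machine$double.xmin))
  }
  exp(approx(grid$t, grid$logp, xout = tk, ties = "ordered")$y)
}

#' Two-sample Anderson-Darling test
#'
#' Tie-corrected (midrank) two-sample Anderson-Darling test, broadly
#' sensitive to any change in distribution. p-values within the tabulated
#' range come from interpolation of the published critical values; beyond
#' the table they can be extended with a precomputed Monte-Carlo grid
#' (\code{\link{ad_null_grid}}).
#'
#' @param perturbed_values,control_values numeric vectors (length >= 2).
#' @param grid optional \code{ad_grid} for tail p-values.
#' @return list with \code{statistic} (standardized Tk) and \code{p}.
#'   A constant pooled sample returns \code{p = 1} with NA statistic.
#' @export
ad_test_gene <- function(perturbed_values, control_values, grid = NULL) {
  stopifnot(length(perturbed_values) >= 2, length(control_values) >= 2)
  st <- ad_standardized(list(as.numeric(perturbed_values),
                             as.numeric(control_values)))
  if (isTRUE(st$constant)) return(list(statistic = NA_real_, p = 1))
  list(statistic = st$tk, p = ad_pvalue(st$tk, k = 2, grid = grid))
}

#' Two-sided Mann-Whitney test with a minimum-cell gate
#'
#' Asymptotic two-sided Mann-Whitney (Wilcoxon rank-sum) p-value, testing
#' whether one distribution is stochastically greater. Perturbations with
#' fewer than \code{min_cells} cells return an NA sentinel.
#'
#' @param perturbed_values,control_values numeric vectors.
#' @param min_cells minimum perturbed-group size (default 10).
#' @return list with \code{p} (NA when gated), \code{U} statistic.
#' @export
mw_test_gene <- function(perturbed_values, control_values, min_cells = 10L) {
  if (length(perturbed_values) < min_cells)
    return(list(p = NA_real_, U = NA_real_))
  if (length(unique(c(perturbed_values, control_values))) < 2)
    return(list(p = 1, U = NA_real_))
  wt <- suppressWarnings(wilcox.test(perturbed_values, control_values,
                                     exact = FALSE, correct = TRUE))
  list(p = wt$p.value, U = unname(wt$statistic))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement; NAs are propagated and
#' excluded from the ranking.
#'
#' @param pvals numeric vector of p-values in [0, 1] (NAs allowed).
#' @return adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  p.adjust(pvals, method = "BH")
}
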