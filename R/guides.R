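#' Downsample guide reads to a per-cell target
#'
#' Cells whose total guide reads exceed \code{per_cell_target} are
#' subsampled without replacement (multivariate hypergeometric across
#' constructs) down to the target; cells at or below the target are left
#' unchanged. This evens out read-depth differences across gemgroups
#' before mixture-model guide calling.
#'
#' @param gm guide \code{SingleCellExperiment}.
#' @param per_cell_target positive integer read target per cell.
#' @param seed integer seed.
#' @return the guide experiment with downsampled counts.
#' @export
downsample_guide_reads <- function(gm, per_cell_target, seed = 1L) {
  stopifnot(per_cell_target > 0)
  counts <- as.matrix(assay(gm, "counts"))
  if (any(counts != round(counts)))
    stop("guide counts must be integers")
  set.seed(seed)
  totals <- colSums(counts)
  for (i in which(totals > per_cell_target)) {
    ci <- counts[, i]
    nz <- which(ci > 0)
    remaining <- per_cell_target
    totrem <- totals[i]
    for (j in nz) {
      x <- rhyper(1, m = ci[j], n = totrem - ci[j], k = remaining)
      totrem <- totrem - ci[j]
      ci[j] <- x
      remaining <- remaining - x
      if (totrem == 0) break
    }
    counts[, i] <- ci
  }
  assay(gm, "counts") <- Matrix(counts, sparse = TRUE)
  gm
}

# log-density of counts under the background (Poisson) and signal
# (Gaussian on log2(count + 1)) components
guide_mixture_logdens <- function(y, lambda, mu, sigma) {
  cbind(bg = dpois(y, lambda, log = TRUE),
        sig = dnorm(log2(y + 1), mu, sigma, log = TRUE))
}

#' Fit a Poisson-Gaussian mixture to one construct's read counts
#'
#' Background reads are modelled as Poisson on the raw counts; true-guide
#' reads as Gaussian on log2(count + 1). The model is fit by EM with
#' random restarts (default 100), keeping the maximum-likelihood fit;
#' ties are broken by restart order. Cells with posterior signal
#' probability above \code{cutoff} are called positive.
#'
#' @param counts integer read-count vector over cells (length >= 20).
#' @param n_restarts number of random EM restarts.
#' @param seed integer seed.
#' @param cutoff posterior probability for a positive call (default 0.5).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return object of class \code{guide_mixture_fit}: list with
#'   \code{lambda} (background mean), \code{mu}, \code{sigma} (signal
#'   location/scale on log2 counts), \code{weight} (signal mixture
#'   weight), \code{loglik}, \code{posterior} (per-cell signal
#'   probability), \code{positive} (logical calls) and \code{flag}
#'   (\code{"ok"}, \code{"no_signal"}, or \code{"degenerate"}).
#' @export
fit_guide_mixture <- function(counts, n_restarts = 100L, seed = 1L,
                              cutoff = 0.5, max_iter = 200L, tol = 1e-8) {
  stopifnot(length(counts) >= 20, n_restarts >= 1)
  y <- as.numeric(counts)
  n <- length(y)
  if (all(y == 0)) {
    return(structure(list(lambda = 0, mu = NA_real_, sigma = NA_real_,
                          weight = 0, loglik = 0,
                          posterior = rep(0, n),
                          positive = rep(FALSE, n), flag = "no_signal"),
                     class = "guide_mixture_fit"))
  }
  set.seed(seed)
  # EM over the unique count values with multiplicities: the likelihood
  # only depends on the count histogram, and guide counts have few
  # distinct values, so restarts stay cheap on large cell numbers
  tab <- table(y)
  yu <- as.numeric(names(tab))
  wu <- as.numeric(tab)
  lyu <- log2(yu + 1)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    lambda <- runif(1, 0.05, max(1, quantile(y, 0.5)))
    mu <- runif(1, quantile(lyu, 0.5), max(lyu))
    sigma <- runif(1, 0.3, 2)
    w <- runif(1, 0.05, 0.6)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      ld <- guide_mixture_logdens(yu, lambda, mu, sigma)
      a <- cbind(log1p(-w) + ld[, 1], log(w) + ld[, 2])
      m <- pmax(a[, 1], a[, 2])
      ll <- sum(wu * (m + log(exp(a[, 1] - m) + exp(a[, 2] - m))))
      resp <- 1 / (1 + exp(a[, 1] - a[, 2]))  # P(signal | y)
      w <- sum(wu * resp) / n
      if (w < 1e-12 || w > 1 - 1e-12) break
      lambda <- max(1e-6, sum(wu * (1 - resp) * yu) / sum(wu * (1 - resp)))
      mu <- sum(wu * resp * lyu) / sum(wu * resp)
      sigma <- max(0.1, sqrt(sum(wu * resp * (lyu - mu)^2) /
                               sum(wu * resp)))
      if (is.finite(ll) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (is.finite(ll) && (is.null(best) || ll > best$loglik + 1e-12)) {
      best <- list(lambda = lambda, mu = mu, sigma = sigma, weight = w,
                   loglik = ll, posterior_u = resp)
    }
  }
  best$posterior <- best$posterior_u[match(y, yu)]
  best$posterior_u <- NULL
  flag <- "ok"
  if (best$weight < 1e-6 || best$weight > 1 - 1e-6) flag <- "degenerate"
  structure(c(best, list(positive = best$posterior > cutoff, flag = flag)),
            class = "guide_mixture_fit")
}

#' @export
print.guide_mixture_fit <- function(x, ...) {
  cat("Poisson-Gaussian guide mixture fit [", x$flag, "]\n", sep = "")
  cat(sprintf("  background mean %.3f | signal log2 mean %.2f (sd %.2f)\n",
              x$lambda, x$mu, x$sigma))
  cat(sprintf("  signal weight %.3f | loglik %.1f | %d positive cells\n",
              x$weight, x$loglik, sum(x$positive)))
  invisible(x)
}

#' Fit guide mixtures for all constructs
#'
#' @param gm guide \code{SingleCellExperiment}.
#' @param n_restarts,seed,cutoff passed to \code{\link{fit_guide_mixture}};
#'   each construct gets a distinct deterministic sub-seed.
#' @param min_nonzero_cells constructs with fewer nonzero cells are
#'   skipped (flag \code{"skipped"}).
#' @return named list of \code{guide_mixture_fit} objects.
#' @export
fit_all_guides <- function(gm, n_restarts = 100L, seed = 1L, cutoff = 0.5,
                           min_nonzero_cells = 10L) {
  counts <- as.matrix(assay(gm, "counts"))
  fits <- vector("list", nrow(counts))
  names(fits) <- rownames(counts)
  for (i in seq_len(nrow(counts))) {
    y <- counts[i, ]
    if (sum(y > 0) < min_nonzero_cells && any(y > 0)) {
      fits[[i]] <- structure(list(lambda = NA_real_, mu = NA_real_,
                                  sigma = NA_real_, weight = NA_real_,
                                  loglik = NA_real_,
                                  posterior = rep(0, length(y)),
                                  positive = rep(FALSE, length(y)),
                                  flag = "skipped"),
                             class = "guide_mixture_fit")
    } else {
      fits[[i]] <- fit_guide_mixture(y, n_restarts = n_restarts,
                                     seed = seed + i, cutoff = cutoff)
    }
  }
  fits
}

#' Categorize cells by their called guides
#'
#' Positive calls are aggregated per cell. A cell is a
#' \code{single_perturbation} when its called constructs target exactly
#' one gene (a single construct, or two constructs sharing a target); a
#' \code{multiplet} when its constructs target two or more distinct
#' genes; otherwise \code{unassigned}. Distinct non-targeting constructs
#' are treated as distinct targets, so each non-targeting guide defines
#' its own control pseudo-perturbation. Only single-perturbation cells
#' feed downstream analysis.
#'
#' @param gm guide \code{SingleCellExperiment}.
#' @param fits list from \code{\link{fit_all_guides}} covering all
#'   constructs.
#' @return object of class \code{guide_call}: data.frame with columns
#'   \code{barcode}, \code{gemgroup}, \code{constructs} (comma-joined),
#'   \code{n_positive}, \code{category}, \code{perturbation} (target gene,
#'   or the construct id for non-targeting guides; NA unless single) and
#'   \code{is_control}.
#' @export
call_cells <- function(gm, fits) {
  stopifnot(all(rownames(gm) %in% names(fits)))
  pos <- do.call(rbind, lapply(rownames(gm), function(cn)
    fits[[cn]]$positive))
  rownames(pos) <- rownames(gm)
  target <- rowData(gm)$target
  # effective per-construct label: gene for targeting guides, construct id
  # for non-targeting guides
  eff_target <- ifelse(target == "non-targeting", rownames(gm), target)
  n_cells <- ncol(gm)
  category <- character(n_cells)
  perturbation <- rep(NA_character_, n_cells)
  constructs <- character(n_cells)
  for (i in seq_len(n_cells)) {
    called <- which(pos[, i])
    constructs[i] <- paste(rownames(gm)[called], collapse = ",")
    tg <- unique(eff_target[called])
    if (length(called) == 0) {
      category[i] <- "unassigned"
    } else if (length(tg) == 1 && length(called) <= 2) {
      category[i] <- "single_perturbation"
      perturbation[i] <- tg
    } else {
      category[i] <- "multiplet"
    }
  }
  out <- data.frame(barcode = colnames(gm),
                    gemgroup = colData(gm)$gemgroup,
                    constructs = constructs,
                    n_positive = colSums(pos),
                    category = category,
                    perturbation = perturbation,
                    is_control = !is.na(perturbation) &
                      perturbation %in% rownames(gm)[target == "non-targeting"],
                    stringsAsFactors = FALSE)
  class(out) <- c("guide_call", "data.frame")
  out
}

#' @export
print.guide_call <- function(x, ...) {
  tab <- table(x$category)
  cat("Guide calls for", nrow(x), "cells:\n")
  for (k in names(tab)) cat(sprintf("  %-20s %d\n", k, tab[[k]]))
  invisible(x)
}
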