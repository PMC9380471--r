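# SVD leverage scores: a scalar per-cell measure of how outlying a
# transcriptome is, used for penetrance and heterogeneity ranking.

#' Per-cell SVD leverage scores
#'
#' Within each gemgroup, the expression matrix (genes above the raw-mean
#' floor, z-scores clipped at \code{clip}, NAs at the control mean) is
#' decomposed by truncated SVD and each cell's raw leverage score is the
#' squared norm of its row of the top-\code{k} left singular vectors.
#' Raw scores are normalized to sum to 1 within the gemgroup (the
#' leverage sampling distribution), then logged and z-scored against
#' control cells so that gemgroups can be pooled.
#'
#' @param z a \code{\link{z_transform}} result.
#' @param k number of singular vectors (default 20).
#' @param expr_floor raw mean-UMI feature floor (default 0.25).
#' @param clip upper z clip (default 10).
#' @param control_set labels defining the reference cells (default: the
#'   model's core controls).
#' @param seed seed for the iterative SVD on large gemgroups.
#' @return object of class \code{leverage_scores}: data.frame per cell
#'   (barcode, gemgroup, perturbation, raw_score, score) plus
#'   parameters. Gemgroups with fewer than \code{k + 1} cells are
#'   skipped (NA scores) with a message.
#' @export
leverage_scores <- function(z, k = 20L, expr_floor = 0.25, clip = 10,
                            control_set = NULL, seed = 1L) {
  cm <- z$cell_meta
  if (is.null(control_set)) control_set <- z$model$core
  keep <- z$gene_mean_umi > expr_floor
  xall <- t(z$z[keep, , drop = FALSE])
  xall[is.na(xall)] <- 0
  xall[xall > clip] <- clip
  raw <- rep(NA_real_, nrow(xall))
  set.seed(seed)
  for (g in unique(cm$gemgroup)) {
    sel <- which(cm$gemgroup == g)
    if (length(sel) < k) {
      message("gemgroup ", g, " has fewer than k cells; skipped")
      next
    }
    x <- xall[sel, , drop = FALSE]
    kk <- min(k, ncol(x))
    u <- if (min(dim(x)) > 200 && kk <= min(dim(x)) / 3)
      irlba::irlba(x, nv = kk)$u
    else svd(x, nu = kk, nv = 0)$u
    s <- rowSums(u[, seq_len(kk), drop = FALSE]^2)
    raw[sel] <- s / sum(s)
  }
  # log then z-normalize vs control cells; zero scores floored first
  score <- rep(NA_real_, length(raw))
  is_ctl <- cm$perturbation %in% control_set
  pos_min <- suppressWarnings(min(raw[raw > 0], na.rm = TRUE))
  lr <- log(pmax(raw, pos_min / 10))
  mu <- mean(lr[is_ctl], na.rm = TRUE)
  sg <- sd(lr[is_ctl], na.rm = TRUE)
  score <- (lr - mu) / sg
  structure(list(cell = data.frame(barcode = cm$barcode,
                                   gemgroup = cm$gemgroup,
                                   perturbation = cm$perturbation,
                                   raw_score = raw, score = score,
                                   stringsAsFactors = FALSE),
                 k = k, expr_floor = expr_floor, clip = clip,
                 control_set = control_set),
            class = "leverage_scores")
}

#' @export
print.leverage_scores <- function(x, ...) {
  cat("Leverage scores for", nrow(x$cell), "cells (k =", x$k, ")\n")
  invisible(x)
}

#' Per-perturbation leverage mean and variability
#'
#' The mean normalized leverage score tracks phenotype magnitude; its
#' standard deviation across a perturbation's cells is the variability /
#' penetrance metric (incompletely penetrant perturbations mix affected
#' and unaffected cells, inflating the SD).
#'
#' @param scores a \code{\link{leverage_scores}} result.
#' @return data.frame: perturbation, n_cells, mean_score, sd_score (NA
#'   for single-cell perturbations).
#' @export
heterogeneity_stats <- function(scores) {
  sp <- split(scores$cell$score, scores$cell$perturbation)
  data.frame(perturbation = names(sp),
             n_cells = lengths(sp),
             mean_score = vapply(sp, mean, numeric(1), USE.NAMES = FALSE),
             sd_score = vapply(sp, function(v)
               if (length(v) < 2) NA_real_ else sd(v), numeric(1),
               USE.NAMES = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank perturbations by excess leverage-score variability
#'
#' Locally weighted regression (lowess) of the leverage-score SD on the
#' log DEG count establishes the expected variability at a given effect
#' size; perturbations are ranked by their residual above the fit.
#'
#' @param stats output of \code{\link{heterogeneity_stats}}.
#' @param deg_counts named DEG counts per perturbation.
#' @param span lowess span (default 0.3).
#' @param top_n how many top outliers to flag.
#' @return data.frame sorted by residual (descending): perturbation,
#'   sd_score, log_degs, fitted, residual, outlier flag.
#' @export
variability_outliers <- function(stats, deg_counts, span = 0.3,
                                 top_n = 20L) {
  common <- intersect(stats$perturbation, names(deg_counts))
  df <- stats[match(common, stats$perturbation), ]
  df$log_degs <- log10(pmax(deg_counts[common], 1))
  df <- df[!is.na(df$sd_score), ]
  if (nrow(df) < 10) stop("need >= 10 perturbations for a stable fit")
  df <- df[order(df$perturbation), ]  # order-invariant ranking
  fit <- lowess(df$log_degs, df$sd_score, f = span)
  df$fitted <- approx(fit$x, fit$y, xout = df$log_degs, rule = 2,
                      ties = "ordered")$y
  df$residual <- df$sd_score - df$fitted
  df <- df[order(-df$residual, df$perturbation), ]
  df$outlier <- seq_len(nrow(df)) <= top_n
  rownames(df) <- NULL
  df[, c("perturbation", "n_cells", "sd_score", "log_degs", "fitted",
         "residual", "outlier")]
}
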