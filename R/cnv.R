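# Expression-based inference of chromosome-scale copy-number changes and
# chromosomal-instability scoring.

#' Infer per-cell copy-number profiles from expression
#'
#' Genes are filtered to a raw-mean floor, depth-normalized (counts per
#' million), log-scaled, and expressed as residuals against the control-
#' cell average. Residuals are clipped, ordered by genomic position, and
#' smoothed with a rolling mean of \code{window} genes that never spans
#' chromosome boundaries (chromosomes with fewer genes fall back to a
#' reduced window). After per-cell median centering, values within a
#' dynamic noise band of \code{noise_sd_threshold} control standard
#' deviations (computed per window position over control cells) are set
#' to zero, and a running-median filter removes isolated spikes.
#'
#' @param um expression experiment (gene coordinates required).
#' @param controls control labels (default: cells flagged
#'   \code{is_control}).
#' @param window rolling-window width in genes (default 100).
#' @param noise_sd_threshold dynamic threshold in control SDs
#'   (default 1.5).
#' @param expr_floor raw mean-UMI gene floor (default 0.05).
#' @param lfc_clip residual clip before smoothing (default 3).
#' @param median_filter running-median width, odd (default 5).
#' @return object of class \code{cnv_profiles}: \code{values} (cells x
#'   genes, thresholded CNV values), \code{gene_meta} (ordered),
#'   \code{control_sd} per position, parameters.
#' @export
infer_cnv <- function(um, controls = NULL, window = 100L,
                      noise_sd_threshold = 1.5, expr_floor = 0.05,
                      lfc_clip = 3, median_filter = 5L) {
  # nuclear chromosomes only: TE metagenes have no genomic position and
  # the mitochondrial contig is not a chromosome-scale CNV target
  gm <- gene_table(um)
  gm <- gm[gm$class == "nuclear", , drop = FALSE]
  if (any(is.na(gm$start) | is.na(gm$chrom)))
    stop("genes without coordinates: ",
         paste(gm$gene[is.na(gm$start) | is.na(gm$chrom)], collapse = ", "))
  cd <- colData(um)
  is_ctl <- if (is.null(controls)) cd$is_control else
    cd$perturbation %in% controls
  if (!any(is_ctl)) stop("no control cells for the reference baseline")
  counts <- assay(um, "counts")[gm$gene, , drop = FALSE]
  keep <- Matrix::rowMeans(counts) >= expr_floor
  gm <- gm[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  # order genes by chromosome then position (input order irrelevant)
  ord <- order(gm$chrom, gm$start)
  gm <- gm[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  # CPM + log
  cpm <- t(as.matrix(counts)) / pmax(Matrix::colSums(counts), 1) * 1e6
  lx <- log1p(cpm)                                # cells x genes
  ref <- colMeans(lx[is_ctl, , drop = FALSE])
  resid <- sweep(lx, 2, ref)
  resid[resid > lfc_clip] <- lfc_clip
  resid[resid < -lfc_clip] <- -lfc_clip
  # rolling mean within chromosomes
  sm <- matrix(0, nrow(resid), ncol(resid), dimnames = dimnames(resid))
  for (ch in unique(gm$chrom)) {
    ix <- which(gm$chrom == ch)
    w <- min(window, length(ix))
    sm[, ix] <- t(apply(resid[, ix, drop = FALSE], 1, roll_mean, w = w))
  }
  sm <- sm - apply(sm, 1, median)
  # robust control noise scale per window position: outlier control
  # cells would otherwise inflate the band and mask true lesions
  ctrl_sd <- apply(sm[is_ctl, , drop = FALSE], 2, mad)
  thr <- noise_sd_threshold * ctrl_sd
  vals <- sm
  vals[abs(sweep(sm, 2, thr, `/`)) < 1] <- 0
  if (median_filter > 1) {
    for (ch in unique(gm$chrom)) {
      ix <- which(gm$chrom == ch)
      kf <- min(median_filter, length(ix))
      if (kf %% 2 == 0) kf <- kf - 1
      if (kf >= 3)
        vals[, ix] <- t(apply(vals[, ix, drop = FALSE], 1, runmed,
                              k = kf, endrule = "constant"))
    }
  }
  structure(list(values = vals, gene_meta = gm, control_sd = ctrl_sd,
                 cell_meta = as.data.frame(cd), window = window,
                 noise_sd_threshold = noise_sd_threshold,
                 expr_floor = expr_floor),
            class = "cnv_profiles")
}

# centered rolling mean; near chromosome edges the window slides inward
# instead of shrinking, so every position averages the same number of
# genes and the noise level stays uniform along the chromosome
roll_mean <- function(v, w) {
  n <- length(v)
  full <- min(w, n)
  half <- floor(full / 2)
  cs <- cumsum(c(0, v))
  lo <- pmax(pmin(seq_len(n) - half, n - full + 1), 1)
  hi <- lo + full - 1
  (cs[hi + 1] - cs[lo]) / full
}

#' @export
print.cnv_profiles <- function(x, ...) {
  cat("CNV profiles:", nrow(x$values), "cells x", ncol(x$values),
      "genes; window", x$window, "| threshold",
      x$noise_sd_threshold, "SD\n")
  invisible(x)
}

#' Call per-cell karyotype stability
#'
#' A chromosome shows a copy-number change over the fraction of its
#' length (gene genomic extents as weights) with nonzero CNV values; a
#' cell is \code{unstable} when any chromosome exceeds
#' \code{length_fraction_threshold}. Direction is \code{gain} /
#' \code{loss} when at least 80\% of the nonzero weight carries one
#' sign, else \code{mixed}.
#'
#' @param profiles a \code{\link{infer_cnv}} result.
#' @param length_fraction_threshold chromosomal-length fraction above
#'   which a change calls the cell unstable (default 0.8).
#' @return list with \code{call} (per cell, "stable"/"unstable"),
#'   \code{fraction} (cells x chromosomes nonzero-length fractions) and
#'   \code{direction} (cells x chromosomes character matrix).
#' @export
call_karyotype <- function(profiles, length_fraction_threshold = 0.8) {
  gm <- profiles$gene_meta
  chroms <- unique(gm$chrom)
  v <- profiles$values
  wts <- pmax(gm$end - gm$start, 1)
  frac <- matrix(0, nrow(v), length(chroms),
                 dimnames = list(rownames(v), chroms))
  dir <- matrix("none", nrow(v), length(chroms),
                dimnames = list(rownames(v), chroms))
  for (ci in seq_along(chroms)) {
    ix <- which(gm$chrom == chroms[ci])
    w <- wts[ix]
    sub <- v[, ix, drop = FALSE]
    nz <- sub != 0
    frac[, ci] <- (nz %*% w) / sum(w)
    pos_w <- ((sub > 0) %*% w)
    neg_w <- ((sub < 0) %*% w)
    tot_w <- pos_w + neg_w
    dir[, ci] <- ifelse(tot_w == 0, "none",
                        ifelse(pos_w / pmax(tot_w, 1e-12) >= 0.8, "gain",
                               ifelse(neg_w / pmax(tot_w, 1e-12) >= 0.8,
                                      "loss", "mixed")))
  }
  unstable <- apply(frac > length_fraction_threshold, 1, any)
  list(call = ifelse(unstable, "unstable", "stable"),
       fraction = frac, direction = dir,
       threshold = length_fraction_threshold)
}

#' Chromosomal-instability score per perturbation
#'
#' Each cell's CNV score is the sum of its squared CNV values; each
#' perturbation's score is the mean over its cells, z-normalized against
#' the distribution of scores over non-targeting control
#' pseudo-perturbations (so controls center at 0).
#'
#' @param profiles a \code{\link{infer_cnv}} result.
#' @param min_cells minimum cells per scored perturbation (default 25;
#'   consistent with the strength gates).
#' @return data.frame: perturbation, n_cells, mean_score (raw),
#'   cin_score (z vs controls), is_control.
#' @export
cin_score <- function(profiles, min_cells = 25L) {
  cm <- profiles$cell_meta
  cell_score <- rowSums(profiles$values^2)
  sp <- split(seq_along(cell_score), cm$perturbation)
  n <- lengths(sp)
  means <- vapply(sp, function(ix) mean(cell_score[ix]), numeric(1))
  is_ctl <- vapply(sp, function(ix) all(cm$is_control[ix]), logical(1))
  keep <- n >= min_cells
  ctl_keep <- is_ctl & keep
  if (!any(ctl_keep)) {
    if (sum(is_ctl) < 2) stop("no control pseudo-perturbations to anchor")
    message("no control pseudo-perturbation meets min_cells; ",
            "anchoring on all control pseudo-perturbations")
    ctl_keep <- is_ctl
  }
  mu <- mean(means[ctl_keep])
  sg <- sd(means[ctl_keep])
  if (is.na(sg) || sg == 0) sg <- 1
  out <- data.frame(perturbation = names(sp), n_cells = n,
                    mean_score = unname(means),
                    cin_score = unname((means - mu) / sg),
                    is_control = unname(is_ctl),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[keep, ]
}
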