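# Composite phenotypes: transcriptome-integrating per-cell and
# per-perturbation measures.

#' Total RNA content, standardized against gemgroup controls
#'
#' Each cell's total UMI count is z-scored against the control cells of
#' its gemgroup (same standardization machinery as gene z-scores);
#' perturbation values are means over cells.
#'
#' @param um expression experiment (with perturbation/is_control
#'   metadata).
#' @param controls control labels used as the reference (default: cells
#'   flagged \code{is_control}).
#' @return list with \code{cell} (data.frame barcode, gemgroup,
#'   perturbation, total_umis, total_rna_z) and \code{perturbation}
#'   (mean z per label).
#' @export
total_rna <- function(um, controls = NULL) {
  cd <- colData(um)
  totals <- total_umis(um)
  is_ctl <- if (is.null(controls)) cd$is_control else
    cd$perturbation %in% controls
  z <- rep(NA_real_, length(totals))
  for (g in unique(cd$gemgroup)) {
    sel <- cd$gemgroup == g
    ref <- totals[sel & is_ctl]
    if (length(ref) < 2) stop("gemgroup without control cells: ", g)
    z[sel] <- (totals[sel] - mean(ref)) / sd(ref)
  }
  cell <- data.frame(barcode = cd$barcode, gemgroup = cd$gemgroup,
                     perturbation = cd$perturbation,
                     total_umis = totals, total_rna_z = z,
                     stringsAsFactors = FALSE)
  pert <- vapply(split(z, cd$perturbation), mean, numeric(1))
  list(cell = cell, perturbation = pert)
}

#' Fraction of mitochondrial RNA per cell
#'
#' Sum of UMIs over mitochondrial-class genes (the 13 mitochondrially
#' encoded protein-coding genes) divided by the cell's total UMI count.
#'
#' @param um expression experiment.
#' @return numeric vector per cell (NaN for zero-total cells); zero with
#'   a warning when no mitochondrial genes are annotated.
#' @export
fraction_mt <- function(um) {
  mt <- rowData(um)$class == "mitochondrial"
  totals <- total_umis(um)
  if (!any(mt)) {
    warning("no mitochondrial-class genes annotated; returning 0")
    return(setNames(rep(0, ncol(um)), colnames(um)))
  }
  setNames(as.numeric(Matrix::colSums(
    assay(um, "counts")[mt, , drop = FALSE]) / totals), colnames(um))
}

#' Fraction of transposable-element RNA per cell
#'
#' Sum of reads over the TE metagene features (a dedicated \code{"TE"}
#' assay when present, otherwise TE-class rows of the count matrix)
#' divided by the cell's total RNA content (raw totals).
#'
#' @param um expression experiment.
#' @return numeric vector per cell, or NULL with a message when no TE
#'   information is present.
#' @export
fraction_te <- function(um) {
  totals <- total_umis(um)
  if ("TE" %in% assayNames(um)) {
    te_sum <- Matrix::colSums(assay(um, "TE"))
  } else if (any(rowData(um)$class == "TE")) {
    te <- rowData(um)$class == "TE"
    te_sum <- Matrix::colSums(assay(um, "counts")[te, , drop = FALSE])
  } else {
    message("no TE layer or TE-class features; fraction TE disabled")
    return(NULL)
  }
  setNames(as.numeric(te_sum / totals), colnames(um))
}

#' Relative unspliced fraction per perturbation and gene
#'
#' Splicing is quantified at the pseudobulk level: per perturbation and
#' gene, the unspliced read fraction
#' unspliced/(unspliced + spliced) over the perturbation's cells,
#' divided by the mean of that gene's fraction across the non-targeting
#' control pseudo-perturbations (so the control pseudobulk sits at 1 by
#' construction). Genes with zero control unspliced reads are excluded,
#' and only genes quantifiable in every perturbation (the common gene
#' set) are reported.
#'
#' @param um expression experiment with \code{spliced} and
#'   \code{unspliced} assays.
#' @return list with \code{ratio} (perturbations x genes matrix),
#'   \code{control_fraction} (per-gene reference), or NULL with a
#'   message when the layers are absent.
#' @export
splicing_ratio <- function(um) {
  if (!all(c("spliced", "unspliced") %in% assayNames(um))) {
    message("spliced/unspliced layers absent; splicing ratio disabled")
    return(NULL)
  }
  cd <- colData(um)
  labs <- sort(unique(cd$perturbation))
  spl <- assay(um, "spliced"); uns <- assay(um, "unspliced")
  frac <- matrix(NA_real_, length(labs), nrow(um),
                 dimnames = list(labs, rownames(um)))
  for (i in seq_along(labs)) {
    sel <- cd$perturbation == labs[i]
    s <- Matrix::rowSums(spl[, sel, drop = FALSE])
    u <- Matrix::rowSums(uns[, sel, drop = FALSE])
    frac[i, ] <- ifelse(s + u > 0, u / (s + u), NA_real_)
  }
  ctl_labs <- unique(cd$perturbation[cd$is_control])
  ref <- colMeans(frac[ctl_labs, , drop = FALSE], na.rm = TRUE)
  keep <- !is.na(ref) & ref > 0 & colSums(is.na(frac)) == 0
  ratio <- sweep(frac[, keep, drop = FALSE], 2, ref[keep], `/`)
  list(ratio = ratio, control_fraction = ref[keep],
       control_labels = ctl_labs)
}

# even-odd ray casting point-in-polygon
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- poly$x[i]; yi <- poly$y[i]
    xj <- poly$x[j]; yj <- poly$y[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Cell-cycle phase assignment by gated 2-D embedding
#'
#' Cells are embedded in two dimensions using only a cell-cycle gene
#' subset (total-normalized, log-scaled expression, correlation-style
#' geometry via centered unit-norm rows, neighbor-preserving embedding),
#' then assigned to phases by point-in-polygon tests against user gates.
#' Cells outside every gate are \code{"unassigned"}.
#'
#' @param um expression experiment.
#' @param cc_genes cell-cycle gene list (e.g. canonical S and G2/M
#'   markers plus G1 markers).
#' @param gates named list of polygons (data.frames with \code{x},
#'   \code{y}) in embedding coordinates, e.g. names "G1/G0", "S",
#'   "G2/M"; an empty list leaves all cells unassigned with a warning.
#' @param n_neighbors,seed embedding parameters.
#' @return list with \code{embedding} (cells x 2), \code{phase} (per
#'   cell) and \code{occupancy} (per perturbation x phase fractions).
#' @export
cell_cycle_phases <- function(um, cc_genes, gates = list(),
                              n_neighbors = 30L, seed = 1L) {
  gs <- intersect(cc_genes, rownames(um))
  if (length(gs) < 3) stop("too few cell-cycle genes present")
  norm <- normalize_totals(um, 1e4)
  x <- t(as.matrix(log1p(norm[gs, , drop = FALSE])))
  keep <- apply(x, 1, sd) > 0
  xn <- x
  xn[keep, ] <- polarization_normalize(x[keep, , drop = FALSE])
  xn[!keep, ] <- 0
  emb <- embed_vectors(xn, dim = 2L, n_neighbors = n_neighbors,
                       seed = seed)
  co <- emb$coords
  phase <- rep("unassigned", nrow(co))
  if (!length(gates)) {
    warning("no gates supplied; all cells unassigned")
  } else {
    for (g in names(gates)) {
      hit <- point_in_polygon(co[, 1], co[, 2], gates[[g]]) &
        phase == "unassigned"
      phase[hit] <- g
    }
  }
  cd <- colData(um)
  occ <- do.call(rbind, lapply(split(seq_along(phase), cd$perturbation),
                               function(ix) {
    tab <- table(factor(phase[ix],
                        levels = unique(c(names(gates), "unassigned"))))
    tab / length(ix)
  }))
  list(embedding = co, phase = phase, occupancy = occ)
}
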