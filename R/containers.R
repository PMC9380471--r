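#' Construct a Perturb-seq expression experiment
#'
#' Wraps a genes x cells UMI count matrix and its metadata in a
#' \link[SingleCellExperiment]{SingleCellExperiment}. Rows are features
#' (genes, plus optional TE metagenes), columns are cells. Optional layers
#' (spliced, unspliced, TE) are stored as additional assays with the same
#' dimensions.
#'
#' @param counts genes x cells matrix of UMI counts (dense or sparse;
#'   coerced to \code{dgCMatrix}).
#' @param gene_meta data.frame with one row per gene: columns \code{gene},
#'   \code{chrom}, \code{start}, \code{end}, \code{class} (one of
#'   \code{"nuclear"}, \code{"mitochondrial"}, \code{"TE"}).
#' @param barcode character vector of cell barcodes.
#' @param gemgroup per-cell batch (gemgroup) labels.
#' @param perturbation optional per-cell perturbation label (NA when not
#'   yet assigned).
#' @param layers optional named list of additional genes x cells count
#'   matrices (e.g. \code{spliced}, \code{unspliced}).
#' @return A \code{SingleCellExperiment} with assay \code{"counts"}.
#' @export
perturb_experiment <- function(counts, gene_meta, barcode, gemgroup,
                               perturbation = NULL, layers = list()) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  stopifnot(nrow(counts) == nrow(gene_meta), ncol(counts) == length(barcode),
            length(gemgroup) == length(barcode))
  need <- c("gene", "chrom", "start", "end", "class")
  missing_cols <- setdiff(need, colnames(gene_meta))
  if (length(missing_cols))
    stop("gene_meta lacks columns: ", paste(missing_cols, collapse = ", "))
  rownames(counts) <- gene_meta$gene
  colnames(counts) <- barcode
  if (is.null(perturbation)) perturbation <- rep(NA_character_, length(barcode))
  assays <- c(list(counts = counts), layers)
  assays <- lapply(assays, function(m) {
    m <- as(as(m, "CsparseMatrix"), "dMatrix")
    dimnames(m) <- dimnames(counts)
    m
  })
  start <- pmax(gene_meta$start, 1)
  rr <- GenomicRanges::GRanges(
    seqnames = gene_meta$chrom,
    ranges = IRanges::IRanges(start = start,
                              end = pmax(gene_meta$end, start)),
    gene = gene_meta$gene, class = gene_meta$class)
  names(rr) <- gene_meta$gene
  SingleCellExperiment(
    assays = assays,
    rowRanges = rr,
    colData = DataFrame(barcode = barcode,
                        gemgroup = as.character(gemgroup),
                        perturbation = as.character(perturbation),
                        row.names = barcode))
}

#' Gene annotation table of an expression experiment
#'
#' @param x expression \code{SingleCellExperiment} built by
#'   \code{\link{perturb_experiment}}.
#' @return data.frame with columns gene, chrom, start, end, class.
#' @export
gene_table <- function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(gene = rowData(x)$gene,
             chrom = as.character(GenomicRanges::seqnames(rr)),
             start = GenomicRanges::start(rr),
             end = GenomicRanges::end(rr),
             class = rowData(x)$class,
             stringsAsFactors = FALSE, row.names = rowData(x)$gene)
}

#' Construct a guide (sgRNA) count experiment
#'
#' @param counts constructs x cells matrix of guide read counts.
#' @param construct_meta data.frame with columns \code{construct},
#'   \code{target} (gene symbol or \code{"non-targeting"}) and optionally
#'   \code{tss}.
#' @param barcode cell barcodes.
#' @param gemgroup per-cell gemgroup labels.
#' @return A \code{SingleCellExperiment} with assay \code{"counts"}.
#' @export
guide_experiment <- function(counts, construct_meta, barcode, gemgroup) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  stopifnot(nrow(counts) == nrow(construct_meta),
            ncol(counts) == length(barcode),
            all(c("construct", "target") %in% colnames(construct_meta)))
  if (is.null(construct_meta$tss)) construct_meta$tss <- "P1"
  rownames(counts) <- construct_meta$construct
  colnames(counts) <- barcode
  SingleCellExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(construct_meta, row.names = construct_meta$construct),
    colData = DataFrame(barcode = barcode,
                        gemgroup = as.character(gemgroup),
                        row.names = barcode))
}

#' Write an experiment in feature-barcode MatrixMarket convention
#'
#' Emits \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv} and a
#' \code{cells.tsv} with per-cell metadata into \code{dir}. Extra assays
#' are written as \code{<layer>.mtx}.
#'
#' @param x a \code{SingleCellExperiment} from \code{perturb_experiment}
#'   or \code{guide_experiment}.
#' @param dir output directory, created if absent.
#' @return \code{dir}, invisibly.
#' @export
write_feature_barcode <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(assay(x, "counts"), file.path(dir, "matrix.mtx"))
  for (layer in setdiff(assayNames(x), "counts"))
    Matrix::writeMM(assay(x, layer), file.path(dir, paste0(layer, ".mtx")))
  feats <- if ("gene" %in% colnames(rowData(x))) gene_table(x) else
    as.data.frame(rowData(x))
  write.table(feats, file.path(dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  write.table(as.data.frame(colData(x)), file.path(dir, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an experiment written by \code{write_feature_barcode}
#'
#' @param dir directory containing \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv}, \code{cells.tsv} and optional layer .mtx files.
#' @param kind \code{"expression"} or \code{"guides"}.
#' @return A \code{SingleCellExperiment}.
#' @export
read_feature_barcode <- function(dir, kind = c("expression", "guides")) {
  kind <- match.arg(kind)
  counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  feats <- read.delim(file.path(dir, "features.tsv"), stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  cells <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  layer_files <- setdiff(list.files(dir, pattern = "\\.mtx$"), "matrix.mtx")
  layers <- lapply(layer_files, function(f)
    as(Matrix::readMM(file.path(dir, f)), "CsparseMatrix"))
  names(layers) <- sub("\\.mtx$", "", layer_files)
  if (kind == "expression") {
    perturb_experiment(counts, feats, barcodes, cells$gemgroup,
                       perturbation = cells$perturbation, layers = layers)
  } else {
    guide_experiment(counts, feats, barcodes, cells$gemgroup)
  }
}

# Per-cell column sums of the counts assay (total UMIs).
total_umis <- function(x) Matrix::colSums(assay(x, "counts"))

# Mean expression per gene (UMIs per cell) over a column subset.
gene_means <- function(x, cells = NULL) {
  m <- assay(x, "counts")
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  Matrix::rowMeans(m)
}
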