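# Neighbor-preserving Euclidean embedding with spectral initialization:
# attractive penalties on k-nearest-neighbor pairs, repulsive penalties on
# sampled non-neighbor pairs, refined by deterministic gradient descent.

knn_pairs <- function(D, k) {
  n <- nrow(D)
  k <- min(k, n - 1)
  idx <- t(apply(D, 1, function(r) order(r)[2:(k + 1)]))
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(idx))
  keep <- i < j
  e <- unique(rbind(cbind(i[keep], j[keep]), cbind(j[!keep], i[!keep])))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

spectral_init <- function(D, k, dim) {
  n <- nrow(D)
  e <- knn_pairs(D, k)
  A <- matrix(0, n, n)
  A[e] <- 1; A[e[, c(2, 1)]] <- 1
  deg <- pmax(rowSums(A), 1)
  Lsym <- diag(n) - diag(1 / sqrt(deg)) %*% A %*% diag(1 / sqrt(deg))
  ev <- eigen(Lsym, symmetric = TRUE)
  ord <- order(ev$values)
  V <- ev$vectors[, ord[2:(dim + 1)], drop = FALSE]
  # fix sign for reproducibility
  for (j in seq_len(ncol(V)))
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  scale(V, center = TRUE, scale = FALSE)
}

#' Neighbor-preserving embedding of row vectors
#'
#' Embeds items into \code{dim} Euclidean dimensions so that near
#' neighbors stay near and non-neighbors are pushed apart:
#' initialization from the spectral layout of the k-nearest-neighbor
#' graph (principal components for large inputs), followed by gradient
#' descent on an attractive penalty over neighbor pairs and a repulsive
#' penalty over deterministically sampled non-neighbor pairs. Identical
#' input rows receive identical coordinates. Deterministic given the
#' seed.
#'
#' @param X items x features matrix (rows are embedded).
#' @param dim embedding dimension (2 for figures, 20 for the
#'   high-dimensional imputation embedding).
#' @param n_neighbors neighborhood size (default 7).
#' @param repulsive_fraction repulsive pairs per attractive pair
#'   (default 5).
#' @param n_iter gradient iterations.
#' @param seed integer seed.
#' @return object of class \code{embedding}: \code{coords} (items x
#'   dim), \code{objective} (mean neighbor distance at convergence).
#' @export
embed_vectors <- function(X, dim = 2L, n_neighbors = 7L,
                          repulsive_fraction = 5, n_iter = 200L,
                          seed = 1L) {
  X <- as.matrix(X)
  n_all <- nrow(X)
  if (dim >= n_all) stop("dim must be smaller than the number of items")
  key <- apply(X, 1, function(r) paste(signif(r, 12), collapse = ","))
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  U <- X[uniq, , drop = FALSE]
  n <- nrow(U)
  set.seed(seed)
  if (n <= dim) {
    co <- matrix(rnorm(n * dim, sd = 1e-4), n, dim)
  } else {
    D <- as.matrix(dist(U))
    e <- knn_pairs(D, n_neighbors)
    co <- if (n > 1500) {
      sv <- svd(scale(U, scale = FALSE), nu = dim, nv = 0)
      sv$u %*% diag(sv$d[seq_len(dim)], dim, dim) / sqrt(n)
    } else {
      spectral_init(D, n_neighbors, dim)
    }
    co <- co / max(sd(co), 1e-12)
    n_rep <- min(round(repulsive_fraction * nrow(e)), n * (n - 1) / 2)
    rep_pairs <- cbind(sample.int(n, n_rep, replace = TRUE),
                       sample.int(n, n_rep, replace = TRUE))
    rep_pairs <- rep_pairs[rep_pairs[, 1] != rep_pairs[, 2], , drop = FALSE]
    co <- refine_embedding(co, e, rep_pairs, n_iter, step = 0.05)
  }
  coords <- co[map, , drop = FALSE]
  rownames(coords) <- rownames(X)
  obj <- if (n > dim) {
    Dc <- sqrt(rowSums((coords[e[, 1], , drop = FALSE] -
                          coords[e[, 2], , drop = FALSE])^2))
    mean(Dc)
  } else 0
  structure(list(coords = coords, objective = obj, dim = dim,
                 n_neighbors = n_neighbors, seed = seed),
            class = "embedding")
}

# gradient refinement: attractive springs on neighbor pairs, inverse
# repulsion on sampled pairs
refine_embedding <- function(co, e, rep_pairs, n_iter, step) {
  n <- nrow(co)
  for (it in seq_len(n_iter)) {
    grad <- matrix(0, n, ncol(co))
    dv <- co[e[, 1], , drop = FALSE] - co[e[, 2], , drop = FALSE]
    acc <- function(g, idx) {
      out <- matrix(0, n, ncol(co))
      for (d_i in seq_len(ncol(co))) {
        s <- rowsum(g[, d_i], idx)
        out[as.integer(rownames(s)), d_i] <- s[, 1]
      }
      out
    }
    grad <- grad + acc(dv, e[, 1]) - acc(dv, e[, 2])
    dr <- co[rep_pairs[, 1], , drop = FALSE] -
      co[rep_pairs[, 2], , drop = FALSE]
    dn2 <- rowSums(dr^2) + 1e-3
    rg <- dr / dn2
    grad <- grad - (acc(rg, rep_pairs[, 1]) - acc(rg, rep_pairs[, 2]))
    lr <- step * (1 - (it - 1) / n_iter)
    co <- co - lr * grad / max(sqrt(mean(grad^2)), 1e-9)
  }
  co
}

#' @export
print.embedding <- function(x, ...) {
  cat("Embedding:", nrow(x$coords), "items in", x$dim,
      "dims; mean neighbor distance", signif(x$objective, 4), "\n")
  invisible(x)
}
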