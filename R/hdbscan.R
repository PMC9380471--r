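# Hierarchical density-based clustering with noise (HDBSCAN) from a
# precomputed distance matrix: mutual-reachability single-linkage tree,
# condensed tree at min_cluster_size, and excess-of-mass or leaf cluster
# selection. Written in-package because no installed R package provides
# the algorithm.

#' Density-based clustering of a precomputed distance matrix
#'
#' Implements the HDBSCAN procedure: core distances at
#' \code{min_samples}, mutual-reachability distances, a single-linkage
#' hierarchy, condensation at \code{min_cluster_size}, and cluster
#' selection by excess of mass (\code{"eom"}) or condensed-tree leaves
#' (\code{"leaf"}). The method is intrinsically conservative: points not
#' in any selected cluster are noise (cluster id -1). Perturbation
#' clustering uses (4, 1, eom) and gene-program clustering (10, 10,
#' leaf) by convention. When the hierarchy never splits into two
#' min-size children (e.g. all items identical), all items are returned
#' as one cluster.
#'
#' @param D symmetric distance matrix (e.g. 1 - correlation).
#' @param min_cluster_size smallest cluster size (>= 2).
#' @param min_samples core-distance neighborhood size (1 = plain
#'   single linkage).
#' @param selection_method "eom" or "leaf".
#' @return object of class \code{cluster_assignment}: list with
#'   \code{cluster} (integer per item, -1 noise, ids contiguous from 0),
#'   \code{members} (list per cluster) and the parameters.
#' @export
cluster_items <- function(D, min_cluster_size = 4L, min_samples = 1L,
                          selection_method = c("eom", "leaf")) {
  selection_method <- match.arg(selection_method)
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(min_cluster_size >= 2, min_samples >= 1)
  labels <- rep(-1L, n)
  if (n >= min_cluster_size) {
    core <- apply(D, 1, function(r) sort(r)[min_samples])
    M <- pmax(D, matrix(core, n, n), matrix(core, n, n, byrow = TRUE))
    diag(M) <- 0
    hc <- stats::hclust(stats::as.dist(M), method = "single")
    labels <- condensed_tree_labels(hc, n, min_cluster_size,
                                    selection_method)
  }
  ids <- sort(unique(labels[labels >= 0]))
  relab <- labels
  for (i in seq_along(ids)) relab[labels == ids[i]] <- i - 1L
  members <- split(seq_len(n), relab)
  members <- members[names(members) != "-1"]
  nm <- rownames(D)
  if (!is.null(nm)) {
    names(relab) <- nm
    members <- lapply(members, function(ix) nm[ix])
  }
  structure(list(cluster = relab, members = members,
                 min_cluster_size = min_cluster_size,
                 min_samples = min_samples,
                 selection_method = selection_method),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Density clustering:", length(x$members), "clusters,",
      sum(x$cluster == -1), "noise items of", length(x$cluster), "\n")
  invisible(x)
}

# condense the single-linkage tree and select clusters
condensed_tree_labels <- function(hc, n, m, selection) {
  merge <- hc$merge
  height <- hc$height
  # subtree sizes and point sets per internal node
  sizes <- integer(nrow(merge))
  pts <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    l <- merge[i, 1]; r <- merge[i, 2]
    pl <- if (l < 0) -l else pts[[l]]
    pr <- if (r < 0) -r else pts[[r]]
    pts[[i]] <- c(pl, pr)
    sizes[i] <- length(pts[[i]])
  }
  lam <- function(d) 1 / max(d, .Machine$double.eps)

  # condensed clusters
  cl_birth <- numeric(0); cl_parent <- integer(0)
  cl_children <- list(); cl_fell <- list(); cl_fell_lam <- list()
  cl_death <- numeric(0); cl_passed <- integer(0)
  new_cluster <- function(parent, birth) {
    id <- length(cl_birth) + 1L
    cl_birth[id] <<- birth; cl_parent[id] <<- parent
    cl_children[[id]] <<- integer(0)
    cl_fell[[id]] <<- integer(0); cl_fell_lam[[id]] <<- numeric(0)
    cl_death[id] <<- NA_real_; cl_passed[id] <<- 0L
    if (parent > 0) cl_children[[parent]] <<- c(cl_children[[parent]], id)
    id
  }
  root <- new_cluster(0L, 0)
  # iterative descent: stack of (node, cluster)
  stack <- list(list(node = nrow(merge), cl = root))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- fr$node; cl <- fr$cl
    repeat {
      l <- merge[node, 1]; r <- merge[node, 2]
      sl <- if (l < 0) 1L else sizes[l]
      sr <- if (r < 0) 1L else sizes[r]
      lambda <- lam(height[node])
      if (sl >= m && sr >= m) {
        cl_death[cl] <- lambda
        cl_passed[cl] <- sl + sr
        c1 <- new_cluster(cl, lambda)
        c2 <- new_cluster(cl, lambda)
        stack[[length(stack) + 1L]] <- list(node = l, cl = c1)
        stack[[length(stack) + 1L]] <- list(node = r, cl = c2)
        break
      } else if (sl >= m || sr >= m) {
        small <- if (sl >= m) r else l
        big <- if (sl >= m) l else r
        sp <- if (small < 0) -small else pts[[small]]
        cl_fell[[cl]] <- c(cl_fell[[cl]], sp)
        cl_fell_lam[[cl]] <- c(cl_fell_lam[[cl]], rep(lambda, length(sp)))
        node <- big
      } else {
        sp <- c(if (l < 0) -l else pts[[l]], if (r < 0) -r else pts[[r]])
        cl_fell[[cl]] <- c(cl_fell[[cl]], sp)
        cl_fell_lam[[cl]] <- c(cl_fell_lam[[cl]], rep(lambda, length(sp)))
        cl_death[cl] <- lambda
        break
      }
    }
  }
  n_cl <- length(cl_birth)
  if (n_cl == 1L) {
    # hierarchy never split into two min-size children: one cluster
    return(rep(0L, n))
  }
  stability <- vapply(seq_len(n_cl), function(c) {
    s <- sum(cl_fell_lam[[c]] - cl_birth[c])
    if (cl_passed[c] > 0 && !is.na(cl_death[c]))
      s <- s + cl_passed[c] * (cl_death[c] - cl_birth[c])
    s
  }, numeric(1))

  selected <- rep(FALSE, n_cl)
  if (selection == "leaf") {
    selected <- lengths(cl_children) == 0
    selected[root] <- FALSE
  } else {
    stab_hat <- stability
    for (c in rev(seq_len(n_cl))) {
      if (c == root) next
      ch <- cl_children[[c]]
      if (!length(ch)) { selected[c] <- TRUE; next }
      s_ch <- sum(stab_hat[ch])
      if (stability[c] >= s_ch) {
        selected[c] <- TRUE
        stab_hat[c] <- stability[c]
      } else {
        stab_hat[c] <- s_ch
      }
    }
  }
  # keep only topmost selected clusters (walk down from root)
  labels <- rep(-1L, n)
  assign_subtree <- function(c, lab) {
    labels[cl_fell[[c]]] <<- lab
    for (ch in cl_children[[c]]) assign_subtree(ch, lab)
  }
  next_lab <- 0L
  walk <- function(c) {
    if (c != root && selected[c]) {
      assign_subtree(c, next_lab)
      next_lab <<- next_lab + 1L
      return(invisible())
    }
    for (ch in cl_children[[c]]) walk(ch)
  }
  walk(root)
  labels
}
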