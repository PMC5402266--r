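# Markov Cluster algorithm (MCL), implemented from scratch on dense
# matrices. Flow simulation on the graph: alternate expansion (matrix
# power, random-walk spreading) and inflation (elementwise power + column
# renormalization, flow sharpening) until the flow matrix stops changing;
# clusters are read off the support of the limiting matrix.

# column-normalize a nonnegative matrix to column-stochastic form
.mcl_normalize <- function(M) {
  cs <- colSums(M)
  if (any(cs == 0)) stop_ts("column with all-zero flow; self-loops missing?")
  sweep(M, 2L, cs, `/`)
}

# one full MCL step: expansion, inflation, pruning, renormalization
.mcl_step <- function(M, expansion = 2L, inflation = 2, prune_below = 1e-5) {
  E <- M
  for (i in seq_len(expansion - 1L)) E <- E %*% M
  E <- E ^ inflation
  E[E < prune_below] <- 0
  cs <- colSums(E)
  dead <- which(cs == 0)
  for (j in dead) {            # pruning must not empty a column
    i <- which.max((M %*% M)[, j])
    E[i, j] <- 1
  }
  .mcl_normalize(E)
}

#' Cluster a network with the Markov Cluster algorithm
#'
#' Builds a column-stochastic flow matrix from the weighted adjacency of
#' the network (with self-loops), then iterates expansion (matrix power
#' `expansion`), inflation (elementwise power `inflation` followed by
#' column renormalization) and pruning of entries below `prune_below`
#' until the flow matrix changes by less than `tol` in any entry, or
#' `max_iter` iterations are reached (then a warning is emitted and the
#' current iterate is clustered, flagged via `converged = FALSE`).
#' Clusters are the connected components of the support of the limiting
#' flow matrix, which merges overlapping attractor systems. Higher
#' inflation yields finer clusters; disconnected components of the input
#' are never merged.
#'
#' @param network a `coexpression_network` from [build_network()], or a
#'   symmetric nonnegative weighted adjacency matrix with dimnames.
#' @param inflation inflation exponent (> 1 for nontrivial clustering);
#'   default 2.0.
#' @param expansion integer matrix-power exponent; default 2.
#' @param self_loop_weight `"max"` (each node's self-loop gets the maximum
#'   incident edge weight, 1 for isolated nodes) or a positive number used
#'   for every node.
#' @param prune_below entries of the flow matrix below this value are set
#'   to zero after inflation; keeps the iteration sparse-spirited.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the maximum absolute entry change.
#' @return object of class `mcl_clustering`: list with `membership` (named
#'   integer vector, cluster ids contiguous from 1 ordered by decreasing
#'   size), `sizes` (table of cluster sizes), `n_iterations`, `converged`,
#'   and the parameters used.
#' @examples
#' adj <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
#' adj[1:2, 1:2] <- 1; adj[3:4, 3:4] <- 1; diag(adj) <- 0
#' mcl_cluster(adj)$membership
#' @export
mcl_cluster <- function(network, inflation = 2.0, expansion = 2L,
                        self_loop_weight = "max", prune_below = 1e-5,
                        max_iter = 100L, tol = 1e-6) {
  A <- if (inherits(network, "coexpression_network")) {
    .network_adjacency(network)
  } else if (is.matrix(network)) {
    if (!isSymmetric(unname(network)) || any(network < 0))
      stop_ts("adjacency must be symmetric and nonnegative")
    if (is.null(rownames(network))) stop_ts("adjacency needs dimnames")
    A <- network; diag(A) <- 0; A
  } else stop_ts("network must be a coexpression_network or adjacency matrix")
  n <- nrow(A)
  if (n < 1L) stop_ts("network has no nodes")
  if (inflation <= 0) stop_ts("inflation must be > 0")
  expansion <- check_count(expansion, "expansion")

  loops <- if (identical(self_loop_weight, "max")) {
    mx <- apply(A, 2L, max)
    ifelse(mx > 0, mx, 1)
  } else {
    w <- check_fraction(self_loop_weight, "self_loop_weight", lo = 0, hi = Inf)
    rep(w, n)
  }
  diag(A) <- loops
  M <- .mcl_normalize(A)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    M_new <- .mcl_step(M, expansion, inflation, prune_below)
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; clustering the current iterate")

  # read off clusters: connected components of the limit-matrix support
  support <- (M > 0) | t(M > 0)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # renumber: cluster 1 = largest, ties by smallest first member index
  sizes <- tabulate(comp)
  first <- vapply(seq_along(sizes), function(k) min(which(comp == k)), integer(1L))
  new_id <- integer(length(sizes))
  new_id[order(-sizes, first)] <- seq_along(sizes)
  membership <- setNames(new_id[comp], rownames(A))
  structure(list(membership = membership,
                 sizes = table(membership, dnn = NULL),
                 n_iterations = iter,
                 converged = converged,
                 inflation = inflation, expansion = expansion,
                 prune_below = prune_below, tol = tol),
            class = "mcl_clustering")
}

#' @export
print.mcl_clustering <- function(x, ...) {
  cat(sprintf("MCL clustering: %d nodes in %d clusters (inflation %g, %d iterations%s)\n",
              length(x$membership), length(x$sizes), x$inflation, x$n_iterations,
              if (x$converged) "" else ", NOT converged"))
  cat("sizes:", paste(head(sort(as.integer(x$sizes), decreasing = TRUE), 10L),
                      collapse = " "), "\n")
  invisible(x)
}

#' Cluster sizes after dropping singleton (isolate) clusters
#'
#' Convenience accessor: sizes of all clusters with at least `min_size`
#' members, largest first.
#'
#' @param assignment an `mcl_clustering`.
#' @param min_size smallest cluster size to keep (default 2, i.e. drop
#'   isolates).
#' @return integer vector of cluster sizes, decreasing.
#' @export
cluster_sizes <- function(assignment, min_size = 2L) {
  sz <- as.integer(assignment$sizes)
  sort(sz[sz >= min_size], decreasing = TRUE)
}
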