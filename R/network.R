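# Coexpression network construction and import/export.

#' Pearson correlation matrix over a sample subset
#'
#' Computes the standard sample Pearson correlation between all pairs of
#' genes (rows) across the chosen samples. Genes with zero variance over
#' the subset carry no correlation signal and are dropped with a warning.
#'
#' @param m expression matrix (genes x samples). Correlation is computed on
#'   the values as given; apply a log transform first if desired (the
#'   pipeline log2-transforms intensities before this step).
#' @param samples sample ids to use (default: all columns); at least 3.
#' @return symmetric correlation matrix with unit diagonal, one row/column
#'   per retained gene.
#' @export
pearson_matrix <- function(m, samples = colnames(m)) {
  miss <- setdiff(samples, colnames(m))
  if (length(miss)) stop_ts("unknown sample(s): %s", paste(miss, collapse = ", "))
  if (length(samples) < 3L)
    stop_ts("need >= 3 samples for correlation, got %d", length(samples))
  x <- m[, samples, drop = FALSE]
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s): ",
            paste(head(rownames(x)[v == 0], 5L), collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop_ts("need >= 2 genes with nonzero variance")
  r <- cor(t(x))
  diag(r) <- 1
  r
}

#' Build a thresholded coexpression network
#'
#' Edges connect gene pairs whose Pearson correlation is greater than or
#' equal to `threshold` (signed, not absolute). Genes without any edge are
#' retained as isolated nodes.
#'
#' @param corr symmetric correlation matrix (see [pearson_matrix()]).
#' @param threshold minimum correlation for an edge; default 0.80.
#' @return object of class `coexpression_network`: a list with `nodes`
#'   (character), `edges` (data.frame `gene_a`, `gene_b`, `r`, deduplicated,
#'   `gene_a` < `gene_b` in node order), and `threshold`.
#' @export
build_network <- function(corr, threshold = 0.80) {
  if (!isSymmetric(unname(corr))) stop_ts("correlation matrix must be symmetric")
  if (threshold < -1 || threshold > 1) stop_ts("threshold must be in [-1, 1]")
  nodes <- rownames(corr)
  hit <- which(corr >= threshold & upper.tri(corr), arr.ind = TRUE)
  edges <- data.frame(gene_a = nodes[hit[, 1L]],
                      gene_b = nodes[hit[, 2L]],
                      r = corr[hit],
                      stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$gene_a, nodes), match(edges$gene_b, nodes)), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression network: %d nodes, %d edges (r >= %g)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

# dense weighted adjacency (no self-loops) from a network object
.network_adjacency <- function(network) {
  n <- length(network$nodes)
  A <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  if (nrow(network$edges)) {
    ia <- match(network$edges$gene_a, network$nodes)
    ib <- match(network$edges$gene_b, network$nodes)
    A[cbind(ia, ib)] <- network$edges$r
    A[cbind(ib, ia)] <- network$edges$r
  }
  A
}

#' Export a network to an edge list or GraphML
#'
#' The edge-list form is a TSV with columns `gene_a`, `gene_b`, `r` (one
#' line per edge; isolated nodes are not represented). The GraphML form
#' keeps every node and stores the correlation as edge attribute `r` and,
#' when a clustering is supplied, the cluster id as node attribute
#' `cluster`.
#'
#' @param network a `coexpression_network`.
#' @param path output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @param assignment optional [mcl_cluster()] result (or named membership
#'   vector) written as the `cluster` node attribute in GraphML.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("edgelist", "graphml"),
                           assignment = NULL) {
  if (!inherits(network, "coexpression_network")) stop_ts("not a coexpression_network")
  if (!is.character(format) || !all(format %in% c("edgelist", "graphml")))
    stop_ts("unknown format '%s'; supported: edgelist, graphml", paste(format, collapse = ","))
  format <- match.arg(format)
  if (format == "edgelist") {
    write.table(network$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(network$nodes), name = network$nodes)
    if (nrow(network$edges))
      g <- igraph::add_edges(g, rbind(match(network$edges$gene_a, network$nodes),
                                      match(network$edges$gene_b, network$nodes)),
                             r = network$edges$r)
    if (!is.null(assignment)) {
      memb <- if (inherits(assignment, "mcl_clustering")) assignment$membership else assignment
      igraph::V(g)$cluster <- as.integer(memb[network$nodes])
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network back from an edge list TSV
#'
#' @param path edge-list TSV written by [export_network()].
#' @param threshold threshold to record on the resulting network (default:
#'   the smallest edge weight present, or 0.80 for an empty list).
#' @return a `coexpression_network` whose nodes are the genes incident to
#'   at least one edge (the edge list does not carry isolated nodes).
#' @export
read_network_edgelist <- function(path, threshold = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "r")
  if (!all(need %in% colnames(df))) stop_ts("edge list '%s' lacks columns gene_a/gene_b/r", path)
  nodes <- unique(c(df$gene_a, df$gene_b))
  if (is.null(threshold)) threshold <- if (nrow(df)) min(df$r) else 0.80
  structure(list(nodes = nodes, edges = df[need], threshold = threshold),
            class = "coexpression_network")
}

#' Read a network (and clustering, if stored) from GraphML
#'
#' @param path GraphML file written by [export_network()].
#' @return a `coexpression_network`; when the file carries a `cluster` node
#'   attribute it is returned in the `membership` attribute.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  r <- if (igraph::ecount(g)) igraph::E(g)$r else numeric(0)
  edges <- data.frame(gene_a = as.character(el[, 1L]),
                      gene_b = as.character(el[, 2L]),
                      r = as.numeric(r), stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges,
                        threshold = if (nrow(edges)) min(edges$r) else 0.80),
                   class = "coexpression_network")
  if ("cluster" %in% igraph::vertex_attr_names(g))
    attr(net, "membership") <- setNames(as.integer(igraph::V(g)$cluster), nodes)
  net
}
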