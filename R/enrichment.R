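# Gene-set overrepresentation testing of the selected tissue-specific set.

#' Hypergeometric gene-set enrichment
#'
#' For each gene set, tests whether the overlap with the selected gene set
#' is larger than expected by chance when drawing `s = |selected|` genes
#' from the universe of `N` genes containing `K` set members: the p-value
#' is the hypergeometric upper tail `P(X >= k)`. Set members outside the
#' universe are ignored; sets with no member in the universe are skipped
#' with a warning. P-values are adjusted with [benjamini_hochberg()].
#'
#' @param selected character vector of selected gene ids; must be a subset
#'   of `universe`.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all genes the selection was drawn
#'   from (typically the rownames of the preprocessed matrix).
#' @return data.frame with one row per tested set, sorted by `p`
#'   ascending: `set`, `k` (overlap), `K` (set size in universe), `s`
#'   (selected size), `N` (universe size), `p`, `p_adj`.
#' @export
hypergeom_enrichment <- function(selected, gene_sets, universe) {
  universe <- unique(universe)
  selected <- unique(selected)
  out_of <- setdiff(selected, universe)
  if (length(out_of))
    stop_ts("selected gene(s) outside the universe: %s",
            paste(head(out_of, 5L), collapse = ", "))
  if (is.null(names(gene_sets))) stop_ts("gene_sets must be a named list")
  N <- length(universe)
  s <- length(selected)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(members)
    if (K == 0L) {
      warning("gene set '", nm, "' has no member in the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(members, selected))
    p <- stats::phyper(k - 1L, K, N - K, s, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, s = s, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop_ts("no gene set overlaps the universe")
  res$p_adj <- benjamini_hochberg(res$p)
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment: with m p-values
#' sorted ascending, `p_adj(i) = min_{j >= i} min(1, p(j) * m / j)`,
#' returned in the original input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same order as input.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_ts("p-values must be numeric in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  scaled <- pmin(1, p[ord] * m / seq_len(m))
  adj_sorted <- rev(cummin(rev(scaled)))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

#' Permutation-based enrichment p-value
#'
#' Empirical alternative to the hypergeometric test: draws `n_perm`
#' uniform subsets of the universe of the same size as the selection and
#' compares their overlap with the gene set to the observed overlap. The
#' p-value uses the add-one estimator
#' `(1 + #\{permuted overlap >= observed\}) / (n_perm + 1)`.
#'
#' @param selected character vector of selected gene ids (subset of
#'   `universe`).
#' @param gene_set character vector of set member ids.
#' @param universe character vector of all candidate genes.
#' @param n_perm number of permutations, at least 100.
#' @param seed integer seed for reproducibility.
#' @return list with `p`, `observed` overlap and `n_perm`.
#' @export
permutation_enrichment <- function(selected, gene_set, universe,
                                   n_perm = 1000L, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(setdiff(selected, universe)))
    stop_ts("selected genes must be a subset of the universe")
  members <- intersect(unique(gene_set), universe)
  observed <- length(intersect(members, selected))
  s <- length(selected)
  in_set <- universe %in% members
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    sum(in_set[sample.int(length(universe), s)]), integer(1L))
  list(p = (1 + sum(perm >= observed)) / (n_perm + 1),
       observed = observed, n_perm = n_perm)
}
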