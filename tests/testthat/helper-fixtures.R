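# Shared fixtures and small independent oracles, built in code.

# tiny config: fast everywhere a full-size bundle is not needed
small_gen_config <- function(seed = 1L, ...) {
  expression_gen_config(
    n_tissues = 6L, replicates_per_tissue = 2L,
    target_tissues = c("heart_1", "heart_2"),
    module_sizes = c(8L, 5L), n_background_genes = 20L,
    seed = seed, ...)
}

# the four-module, 316-gene design used by the clustering experiments:
# 10 target tissues x 2 replicates = 20 target samples, no background
module_gen_config <- function(seed = 17L, ...) {
  expression_gen_config(
    module_sizes = c(285L, 15L, 10L, 6L), n_background_genes = 0L,
    seed = seed, ...)
}

# correlation input as the pipeline prepares it: log2 intensities over the
# target-tissue samples
target_log2_matrix <- function(bundle, cfg) {
  samples <- bundle$samples$sample_id[bundle$samples$tissue %in% cfg$target_tissues]
  log2(bundle$expression[, samples, drop = FALSE] + 1)
}

# weighted adjacency matrix of k disjoint cliques (unit weights)
clique_adjacency <- function(sizes) {
  n <- sum(sizes)
  ids <- sprintf("n%02d", seq_len(n))
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  at <- 0L
  for (s in sizes) {
    idx <- at + seq_len(s)
    A[idx, idx] <- 1
    at <- at + s
  }
  diag(A) <- 0
  A
}

# exact hypergeometric upper tail by exhaustive enumeration over all
# subsets of size s (oracle; only for N <= 12)
enum_hyper_tail <- function(N, K, s, k) {
  stopifnot(N <= 12)
  draws <- utils::combn(N, s)
  hits <- colSums(draws <= K)   # elements 1..K are the "annotated" ones
  mean(hits >= k)
}

# naive term-by-term TSI (oracle)
naive_tsi <- function(x) {
  total <- 0
  for (xi in x) total <- total + (1 - xi / max(x))
  total / (length(x) - 1)
}

expect_same_file <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
}
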