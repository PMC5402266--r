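# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ts <- function(fmt, ..., call. = FALSE) {
  stop(sprintf(fmt, ...), call. = call.)
}

# scalar count >= min
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop_ts("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_ts("'%s' must be a single number", name)
  if ((lo_open && x <= lo) || (!lo_open && x < lo) || x > hi)
    stop_ts("'%s' must be in %s%g, %g]", name, if (lo_open) "(" else "[", lo, hi)
  as.numeric(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Returns 1 for identical partitions (up to label permutation) and is
#' approximately 0 for independent random partitions.
#'
#' @param a,b vectors of cluster labels of equal length (any atomic type).
#' @return a single number, at most 1.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")) # 1
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_ts("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
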