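# Tissue-specificity scoring and selection of tissue-restricted genes.

#' Tissue-specificity index (TSI)
#'
#' For a per-tissue expression vector `x` of length `n` with maximum
#' `exp_max`, the index is
#' \deqn{TSI = \frac{\sum_{i=1}^{n} (1 - x_i / exp_{max})}{n - 1}.}
#' It is 0 for a uniformly expressed (housekeeping) gene and 1 for a gene
#' expressed in a single tissue, and is invariant under positive scaling
#' of `x`.
#'
#' @param x numeric vector of per-tissue mean expression; length >= 2, all
#'   values >= 0, maximum > 0.
#' @return TSI in `[0, 1]`.
#' @examples
#' compute_tsi(c(5, 5, 5, 5, 5))  # 0
#' compute_tsi(c(7, 0, 0, 0, 0))  # 1
#' compute_tsi(c(8, 2, 0, 0))     # 0.91666...
#' @export
compute_tsi <- function(x) {
  n <- length(x)
  if (n < 2L) stop_ts("TSI needs >= 2 tissues, got %d", n)
  if (any(!is.finite(x)) || any(x < 0)) stop_ts("expression values must be finite and >= 0")
  mx <- max(x)
  if (mx == 0) stop_ts("TSI undefined for an all-zero profile")
  sum(1 - x / mx) / (n - 1)
}

#' Assign each gene its maximum-expression tissue
#'
#' @param profile genes x tissues matrix of per-tissue mean expression.
#' @return named character vector gene -> tissue. Exact ties are broken by
#'   tissue column order, with a warning listing the tied genes.
#' @export
assign_max_tissue <- function(profile) {
  if (ncol(profile) < 2L) stop_ts("profile needs >= 2 tissues")
  idx <- apply(profile, 1L, which.max)
  n_max <- apply(profile, 1L, function(r) sum(r == max(r)))
  if (any(n_max > 1L))
    warning("max-expression tie(s) broken by tissue order for gene(s): ",
            paste(rownames(profile)[n_max > 1L], collapse = ", "))
  setNames(colnames(profile)[idx], rownames(profile))
}

#' Score all genes of a tissue profile
#'
#' Computes TSI and the maximum-expression tissue for every gene, restricts
#' to genes whose maximum lies in the target tissue group, and flags the
#' top `fraction` of that pool by TSI as selected. Genes with an all-zero
#' profile have no defined TSI; they are dropped with a message.
#'
#' @param profile genes x tissues matrix (see [average_replicates()]).
#' @param target_tissues character vector of target tissue labels; must be
#'   a subset of the profile's columns.
#' @param fraction fraction of the target-maximal pool to select
#'   (default 0.2, the top 20 percent).
#' @return data.frame `gene_id`, `tsi`, `max_tissue`, `selected`, one row
#'   per scored gene, in profile order.
#' @export
specificity_table <- function(profile, target_tissues, fraction = 0.2) {
  fraction <- check_fraction(fraction, "fraction")
  bad <- setdiff(target_tissues, colnames(profile))
  if (length(bad))
    stop_ts("target tissue(s) not in profile: %s", paste(bad, collapse = ", "))
  zero <- rowSums(profile) == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " gene(s) with all-zero profile: ",
            paste(head(rownames(profile)[zero], 5L), collapse = ", "),
            if (sum(zero) > 5L) ", ...")
    profile <- profile[!zero, , drop = FALSE]
  }
  tab <- data.frame(
    gene_id = rownames(profile),
    tsi = apply(profile, 1L, compute_tsi),
    max_tissue = assign_max_tissue(profile),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  sel <- select_top_quantile(tab, fraction, target_tissues)
  tab$selected <- tab$gene_id %in% sel
  tab
}

#' Select the top TSI quantile among target-maximal genes
#'
#' Restricts the table to genes whose maximum-expression tissue belongs to
#' the target group (N genes), then returns the `floor(fraction * N)`
#' genes with the highest TSI. Ties are broken by TSI descending, then
#' gene id ascending.
#'
#' @param table data.frame with columns `gene_id`, `tsi`, `max_tissue`.
#' @param fraction selection fraction in `(0, 1]`.
#' @param target_tissues character vector defining the target group.
#' @return character vector of selected gene ids (in ranking order).
#' @export
select_top_quantile <- function(table, fraction, target_tissues) {
  fraction <- check_fraction(fraction, "fraction")
  pool <- table[table$max_tissue %in% target_tissues, , drop = FALSE]
  n <- nrow(pool)
  if (n == 0L) stop_ts("no gene has its expression maximum in the target tissue group")
  k <- floor(fraction * n)
  pool <- pool[order(-pool$tsi, pool$gene_id), , drop = FALSE]
  pool$gene_id[seq_len(k)]
}
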