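# Selective-constraint comparison: mean derived allele frequency (DAF) per
# gene set with bootstrap percentile confidence intervals. Persistently low
# DAF is the signature of purifying selection; the distributions are far
# from normal, hence the nonparametric bootstrap.

#' Mean derived allele frequency over a gene set
#'
#' @param variants data.frame `snp_id`, `gene_id`, `daf` (see
#'   [read_variants()]).
#' @param genes character vector of gene ids defining the set.
#' @param set_name label used in error messages.
#' @return list with `n` (number of SNPs mapped to the set) and `mean`.
#' @export
mean_daf <- function(variants, genes, set_name = "gene set") {
  daf <- variants$daf[variants$gene_id %in% genes]
  if (!length(daf)) stop_ts("no SNP maps to %s", set_name)
  list(n = length(daf), mean = mean(daf))
}

#' Bootstrap percentile confidence interval for a mean
#'
#' Resamples `values` with replacement `n_reps` times, takes the mean of
#' each replicate, and returns the empirical `(1 - level)/2` and
#' `1 - (1 - level)/2` quantiles. Constant input yields the degenerate
#' interval `(c, c)` with a warning.
#'
#' @param values numeric vector, length >= 2.
#' @param n_reps bootstrap replicates, at least 100 (default 500).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return named numeric vector `c(lo, hi)`; the replicate means are
#'   attached as the `"replicates"` attribute.
#' @export
bootstrap_ci <- function(values, n_reps = 500L, level = 0.95, seed = 1L) {
  n_reps <- check_count(n_reps, "n_reps", min = 100L)
  level <- check_fraction(level, "level")
  n <- length(values)
  if (n < 2L) stop_ts("need >= 2 values for a bootstrap CI")
  if (any(!is.finite(values))) stop_ts("values must be finite")
  if (max(values) == min(values)) {
    warning("constant input: degenerate CI")
    out <- c(lo = values[1L], hi = values[1L])
    attr(out, "replicates") <- rep(values[1L], n_reps)
    return(out)
  }
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_reps, replace = TRUE), nrow = n)
  means <- colMeans(matrix(values[idx], nrow = n))
  alpha <- (1 - level) / 2
  qs <- quantile(means, c(alpha, 1 - alpha), names = FALSE)
  out <- c(lo = qs[1L], hi = qs[2L])
  attr(out, "replicates") <- means
  out
}

#' Compare mean DAF between two gene sets with bootstrap CIs
#'
#' Computes the per-set mean DAF with a bootstrap percentile CI
#' (SNP-level resampling by default), declares the difference significant
#' when the two CIs are disjoint, and additionally reports a two-sided
#' bootstrap p-value for the difference in means (twice the smaller
#' fraction of replicate differences on either side of 0, add-one
#' smoothed). Overlapping gene sets are allowed with a warning; shared
#' SNPs count in both sets.
#'
#' @param variants data.frame `snp_id`, `gene_id`, `daf`.
#' @param set_a,set_b character vectors of gene ids.
#' @param n_reps bootstrap replicates (default 500).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @param names_ab labels for the two sets in the output.
#' @param resample `"snps"` (resample SNPs directly) or `"genes"`
#'   (resample genes with replacement and pool their SNPs).
#' @return object of class `daf_comparison`: per-set `n`, `mean`, `ci`;
#'   `difference` (mean_a - mean_b), `p_diff`, `significant` (disjoint
#'   CIs), `direction`, and the parameters `n_reps`, `level`, `seed`,
#'   `resample`.
#' @export
compare_daf <- function(variants, set_a, set_b, n_reps = 500L, level = 0.95,
                        seed = 1L, names_ab = c("set_a", "set_b"),
                        resample = c("snps", "genes")) {
  resample <- match.arg(resample)
  variants <- validate_variants(variants[c("snp_id", "gene_id", "daf")])
  shared <- intersect(intersect(set_a, set_b), variants$gene_id)
  if (length(shared))
    warning(length(shared), " gene(s) in both sets; their SNPs count in both")
  one_set <- function(genes, nm, seed_k) {
    sub <- variants[variants$gene_id %in% genes, , drop = FALSE]
    if (!nrow(sub)) stop_ts("no SNP maps to %s", nm)
    if (resample == "snps") {
      vals <- sub$daf
      ci <- bootstrap_ci(vals, n_reps, level, seed_k)
    } else {
      genes_in <- unique(sub$gene_id)
      by_gene <- split(sub$daf, sub$gene_id)[genes_in]
      set.seed(seed_k)
      means <- vapply(seq_len(n_reps), function(i) {
        picked <- sample.int(length(genes_in), replace = TRUE)
        mean(unlist(by_gene[picked], use.names = FALSE))
      }, numeric(1L))
      alpha <- (1 - level) / 2
      qs <- quantile(means, c(alpha, 1 - alpha), names = FALSE)
      ci <- c(lo = qs[1L], hi = qs[2L])
      attr(ci, "replicates") <- means
    }
    list(name = nm, n = nrow(sub), mean = mean(sub$daf),
         ci = ci[c("lo", "hi")], replicates = attr(ci, "replicates"))
  }
  a <- one_set(set_a, names_ab[1L], seed)
  b <- one_set(set_b, names_ab[2L], seed + 1L)
  diffs <- a$replicates - b$replicates
  p_diff <- min(1, 2 * min((1 + sum(diffs <= 0)) / (n_reps + 1),
                           (1 + sum(diffs >= 0)) / (n_reps + 1)))
  disjoint <- a$ci[["hi"]] < b$ci[["lo"]] || b$ci[["hi"]] < a$ci[["lo"]]
  direction <- if (a$mean < b$mean) sprintf("%s lower", names_ab[1L])
               else if (a$mean > b$mean) sprintf("%s lower", names_ab[2L])
               else "equal"
  a$replicates <- NULL; b$replicates <- NULL
  structure(list(sets = setNames(list(a, b), names_ab),
                 difference = a$mean - b$mean,
                 p_diff = p_diff,
                 significant = disjoint,
                 direction = direction,
                 n_reps = n_reps, level = level, seed = seed,
                 resample = resample),
            class = "daf_comparison")
}

#' @export
print.daf_comparison <- function(x, ...) {
  for (s in x$sets)
    cat(sprintf("%s: n = %d SNPs, mean DAF = %.4f, %d%% CI [%.4f, %.4f]\n",
                s$name, s$n, s$mean, round(100 * x$level), s$ci[["lo"]], s$ci[["hi"]]))
  cat(sprintf("difference = %.4f, bootstrap p = %.4g, %s (%s; %d reps)\n",
              x$difference, x$p_diff,
              if (x$significant) "significant (disjoint CIs)" else "not significant (CIs overlap)",
              x$direction, x$n_reps))
  invisible(x)
}
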