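# Preprocessing: between-array median scaling, transcript-to-gene
# collapsing, and replicate averaging into per-tissue profiles.

#' Scale arrays to a common median
#'
#' Each column (array) is multiplied by `reference / median(column)` where
#' the reference is the median of all column medians. Afterwards every
#' column median equals the reference (to 1e-9 relative). This is the
#' standard between-array "scale" normalization for single-channel
#' intensity data.
#'
#' @param m expression matrix (genes x samples, nonnegative, dimnames set).
#' @return matrix of the same shape with equalized column medians.
#' @export
median_scale <- function(m) {
  m <- validate_expression(m)
  meds <- apply(m, 2L, median)
  if (any(meds <= 0))
    stop_ts("degenerate array(s) with median 0: %s",
            paste(colnames(m)[meds <= 0], collapse = ", "))
  reference <- median(meds)
  sweep(m, 2L, reference / meds, `*`)
}

#' Collapse transcript rows to one row per gene
#'
#' For transcripts assigned to the same gene, the smallest transcript that
#' covers the coding sequence (CDS) is kept. When no transcript of a gene
#' covers the CDS, the overall smallest transcript is kept and the gene is
#' reported in a message. Equal-length candidates are broken by
#' lexicographically smallest transcript id, so builds are deterministic.
#'
#' @param m transcript-level expression matrix (rownames = transcript ids).
#' @param annotation data.frame as from [read_transcript_annotation()]:
#'   `transcript_id`, `gene_id`, `length`, `covers_cds`.
#' @return gene-level matrix; rownames are gene ids, rows in order of first
#'   appearance of each gene's kept transcript in `m`. The chosen
#'   transcript per gene is available in the `"kept_transcript"` attribute.
#' @export
collapse_transcripts <- function(m, annotation) {
  m <- validate_expression(m)
  unknown <- setdiff(rownames(m), annotation$transcript_id)
  if (length(unknown))
    stop_ts("unannotated transcript(s): %s", paste(unknown, collapse = ", "))
  ann <- annotation[match(rownames(m), annotation$transcript_id), ]
  keep <- character(0L)
  no_cds <- character(0L)
  for (g in unique(ann$gene_id)) {
    cand <- ann[ann$gene_id == g, ]
    pool <- cand[cand$covers_cds, ]
    if (nrow(pool) == 0L) {
      pool <- cand
      no_cds <- c(no_cds, g)
    }
    pool <- pool[order(pool$length, pool$transcript_id), ]
    keep[g] <- pool$transcript_id[1L]
  }
  if (length(no_cds))
    message("no CDS-covering transcript for gene(s), kept smallest overall: ",
            paste(no_cds, collapse = ", "))
  out <- m[keep, , drop = FALSE]
  # preserve the row order of the kept transcripts in the input matrix
  ord <- order(match(keep, rownames(m)))
  out <- out[ord, , drop = FALSE]
  kept <- keep[ord]
  rownames(out) <- names(kept)
  attr(out, "kept_transcript") <- kept
  out
}

#' Average replicate samples into per-tissue profiles
#'
#' Computes the mean expression per tissue for every gene. When the sample
#' annotation carries a `time_point` column (and `by_time_point = FALSE`,
#' the default), samples are first averaged within each (tissue, time
#' point) and those per-time-point means are then averaged per tissue, so
#' unbalanced time courses do not bias the tissue profile. With
#' `by_time_point = TRUE` the columns of the result are
#' `tissue@time_point` combinations instead.
#'
#' @param m expression matrix (genes x samples).
#' @param sample_annotation data.frame with `sample_id`, `tissue` and
#'   optionally `time_point`; every column of `m` must be annotated.
#' @param by_time_point keep (tissue, time point) profiles separate.
#' @return genes x tissues matrix of mean expression (the tissue profile).
#'   Tissue columns follow first appearance order in the annotation.
#' @export
average_replicates <- function(m, sample_annotation, by_time_point = FALSE) {
  m <- validate_expression(m)
  ann <- sample_annotation
  miss <- setdiff(colnames(m), ann$sample_id)
  if (length(miss))
    stop_ts("sample(s) without tissue annotation: %s", paste(miss, collapse = ", "))
  ann <- ann[match(colnames(m), ann$sample_id), ]
  if (any(is.na(ann$tissue) | !nzchar(ann$tissue)))
    stop_ts("sample(s) with empty tissue label: %s",
            paste(ann$sample_id[is.na(ann$tissue) | !nzchar(ann$tissue)], collapse = ", "))
  has_time <- "time_point" %in% colnames(ann) && !all(is.na(ann$time_point))
  group_mean <- function(groups) {
    lvls <- unique(groups)
    out <- vapply(lvls, function(g)
      rowMeans(m[, groups == g, drop = FALSE]), numeric(nrow(m)))
    matrix(out, nrow = nrow(m), dimnames = list(rownames(m), lvls))
  }
  if (!has_time) {
    prof <- group_mean(ann$tissue)
  } else {
    tt <- paste(ann$tissue, ann$time_point, sep = "@")
    prof_tt <- group_mean(tt)
    if (by_time_point) return(prof_tt)
    tissue_of <- sub("@.*$", "", colnames(prof_tt))
    lvls <- unique(ann$tissue)
    prof <- vapply(lvls, function(ti)
      rowMeans(prof_tt[, tissue_of == ti, drop = FALSE]), numeric(nrow(m)))
    prof <- matrix(prof, nrow = nrow(m), dimnames = list(rownames(m), lvls))
  }
  if (ncol(prof) < 2L)
    stop_ts("tissue profile needs >= 2 tissues, got %d", ncol(prof))
  prof
}
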