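# Readers and writers for the plain-text interchange formats used by the
# pipeline: expression TSV, sample/transcript annotation TSV, GMT gene sets,
# and the per-SNP variant table.

#' Read an expression matrix from TSV
#'
#' The expected dialect is: a header row of sample identifiers, one row per
#' gene (or transcript) whose first column is the row identifier, tab
#' separation, '.' decimal point. Values are linear-scale nonnegative
#' intensities (e.g. summarized microarray signal).
#'
#' @param path path to the TSV file.
#' @return numeric matrix with gene ids as rownames and sample ids as
#'   colnames, in file order.
#' @seealso [median_scale()], [average_replicates()]
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop_ts("expression file '%s' needs an id column plus >= 1 sample", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop_ts("duplicate row id(s) in '%s': %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop_ts("duplicate sample id(s) in '%s': %s", path,
            paste(unique(samples[duplicated(samples)]), collapse = ", "))
  suppressWarnings(vals <- vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df), dimnames = list(ids, samples))
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_ts("non-numeric or non-finite cell at row '%s', column '%s'",
            ids[bad[1L, 1L]], samples[bad[1L, 2L]])
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop_ts("negative expression value at row '%s', column '%s' (linear-scale intensities must be >= 0)",
            ids[neg[1L, 1L]], samples[neg[1L, 2L]])
  validate_expression(vals)
}

# Shared validation for in-memory expression matrices.
validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop_ts("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_ts("expression matrix must carry row (gene) and column (sample) names")
  if (anyDuplicated(rownames(m))) stop_ts("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(m))) stop_ts("duplicate sample ids in expression matrix")
  if (any(!is.finite(m))) stop_ts("expression matrix contains non-finite values")
  if (any(m < 0)) stop_ts("expression matrix contains negative values")
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: first column `gene_id`, then one column
#' per sample.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Requires columns `sample_id` and `tissue`; an optional `time_point`
#' column is preserved when present.
#'
#' @param path path to a TSV with a header.
#' @return data.frame with columns `sample_id`, `tissue` and, if present,
#'   `time_point`.
#' @export
read_sample_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop_ts("sample annotation '%s' lacks column(s): %s",
                            path, paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_ts("duplicate sample_id in '%s'", path)
  df
}

#' Read a transcript-to-gene annotation table
#'
#' Requires columns `transcript_id`, `gene_id`, `length` (transcript length
#' in bases, > 0) and `covers_cds` (logical: does the transcript span the
#' full coding sequence).
#'
#' @param path path to a TSV with a header.
#' @return data.frame with the four columns above, `covers_cds` coerced to
#'   logical.
#' @seealso [collapse_transcripts()]
#' @export
read_transcript_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "length", "covers_cds")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop_ts("transcript annotation '%s' lacks column(s): %s",
                            path, paste(miss, collapse = ", "))
  df$covers_cds <- as.logical(df$covers_cds)
  if (any(is.na(df$covers_cds))) stop_ts("covers_cds must be true/false in '%s'", path)
  if (anyDuplicated(df$transcript_id)) stop_ts("duplicate transcript_id in '%s'", path)
  if (any(!is.finite(df$length) | df$length <= 0)) stop_ts("transcript length must be > 0 in '%s'", path)
  df
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of gene ids; the `description`
#'   attribute of each element holds the second field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_ts("GMT file '%s' is empty", path)
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) stop_ts("malformed GMT line (need name and description): %s", ln)
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    attr(genes, "description") <- parts[2L]
    sets[[parts[1L]]] <- genes
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors; each element's
#'   `description` attribute, when present, becomes the second field.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_ts("all gene sets must be named")
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-SNP variant table
#'
#' Requires columns `snp_id`, `gene_id` and `daf` (derived allele frequency
#' in `[0, 1]`).
#'
#' @param path path to a TSV with a header.
#' @return data.frame with the three columns.
#' @seealso [compare_daf()]
#' @export
read_variants <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("snp_id", "gene_id", "daf")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop_ts("variant table '%s' lacks column(s): %s",
                            path, paste(miss, collapse = ", "))
  validate_variants(df[need])
}

validate_variants <- function(df) {
  if (anyDuplicated(df$snp_id)) stop_ts("duplicate snp_id in variant table")
  if (!is.numeric(df$daf) || any(!is.finite(df$daf)) || any(df$daf < 0 | df$daf > 1))
    stop_ts("daf must be numeric in [0, 1]")
  df
}
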