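# End-to-end driver: preprocess -> specificity -> network -> enrichment ->
# constraint, with a reproducible output manifest.

#' Assemble a pipeline configuration
#'
#' Defaults follow the analysis' standard settings: top 20% TSI selection,
#' correlation threshold 0.80, MCL inflation 2.0, 500 bootstrap replicates
#' at the 95% level.
#'
#' @param expression path to the expression TSV (see [read_expression()]).
#' @param samples path to the sample annotation TSV.
#' @param target_tissues character vector: the target tissue group.
#' @param outdir output directory for all stage results.
#' @param transcript_annotation optional path; when given, transcript rows
#'   are collapsed to genes before profiling.
#' @param gene_sets_gmt optional GMT path; when given, the enrichment stage
#'   runs over these sets.
#' @param variants optional variant TSV path; when given, the constraint
#'   stage compares the selected set against all genes.
#' @param fraction TSI selection fraction (default 0.2).
#' @param threshold correlation threshold for edges (default 0.80).
#' @param corr_samples `"target"` (correlate over target-tissue samples,
#'   where tissue-restricted co-regulation lives) or `"all"`.
#' @param corr_log2 log2-transform (with pseudocount 1) intensities before
#'   correlation (default `TRUE`; microarray coexpression is conventionally
#'   computed on the log scale).
#' @param mcl_inflation,mcl_expansion MCL parameters (defaults 2.0 and 2).
#' @param daf_n_reps,daf_level bootstrap settings (defaults 500 and 0.95).
#' @param seed integer master seed; stage seeds are derived as
#'   `seed + 100 * stage index` so stages are independently reproducible.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, samples, target_tissues, outdir,
                            transcript_annotation = NULL,
                            gene_sets_gmt = NULL, variants = NULL,
                            fraction = 0.2, threshold = 0.80,
                            corr_samples = "target", corr_log2 = TRUE,
                            mcl_inflation = 2.0, mcl_expansion = 2L,
                            daf_n_reps = 500L, daf_level = 0.95,
                            seed = 1L) {
  structure(list(expression = expression, samples = samples,
                 target_tissues = as.character(target_tissues),
                 outdir = outdir,
                 transcript_annotation = transcript_annotation,
                 gene_sets_gmt = gene_sets_gmt, variants = variants,
                 fraction = fraction, threshold = threshold,
                 corr_samples = corr_samples, corr_log2 = isTRUE(corr_log2),
                 mcl_inflation = mcl_inflation, mcl_expansion = mcl_expansion,
                 daf_n_reps = daf_n_reps, daf_level = daf_level,
                 seed = seed),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every constraint and reports all violations at once.
#'
#' @param config a [pipeline_config()].
#' @return character vector of error messages; empty when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  errs <- character(0L)
  add <- function(msg) errs <<- c(errs, msg)
  need_file <- function(path, what) {
    if (is.null(path)) return()
    if (!is.character(path) || length(path) != 1L || !file.exists(path))
      add(sprintf("%s file not found: %s", what, paste(path, collapse = ",")))
  }
  if (is.null(config$expression)) add("expression path is required")
  need_file(config$expression, "expression")
  if (is.null(config$samples)) add("sample annotation path is required")
  need_file(config$samples, "sample annotation")
  need_file(config$transcript_annotation, "transcript annotation")
  need_file(config$gene_sets_gmt, "gene sets GMT")
  need_file(config$variants, "variants")
  if (!length(config$target_tissues) || any(!nzchar(config$target_tissues)))
    add("target_tissues must be a nonempty set of labels")
  f <- config$fraction
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f > 1)
    add("fraction must be in (0, 1]")
  th <- config$threshold
  if (!is.numeric(th) || length(th) != 1L || is.na(th) || th < -1 || th > 1)
    add("correlation threshold must be in [-1, 1]")
  if (!identical(config$corr_samples, "target") && !identical(config$corr_samples, "all"))
    add("corr_samples must be 'target' or 'all'")
  if (!is.numeric(config$mcl_inflation) || config$mcl_inflation <= 0)
    add("mcl_inflation must be > 0")
  if (!is.numeric(config$daf_n_reps) || config$daf_n_reps < 100)
    add("daf_n_reps must be >= 100")
  lv <- config$daf_level
  if (!is.numeric(lv) || length(lv) != 1L || is.na(lv) || lv <= 0 || lv >= 1)
    add("daf_level must be in (0, 1)")
  if (!is.numeric(config$seed) || length(config$seed) != 1L || is.na(config$seed))
    add("seed must be a single integer")
  errs
}

.stage_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.2fs)", stage, paste0(...),
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes preprocess, specificity, network, and (when inputs are
#' configured) enrichment and constraint, writing every stage's outputs
#' under `config$outdir` plus a `manifest.json` recording parameters, file
#' checksums and shapes. Identical configuration and seed reproduce
#' identical output checksums.
#'
#' @param config a valid [pipeline_config()].
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) stop_ts("invalid configuration:\n- %s", paste(errs, collapse = "\n- "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0L)
  out_path <- function(name) {
    p <- file.path(config$outdir, name)
    outputs[[name]] <<- p
    p
  }
  stages <- list()

  # -- preprocess ------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  m <- tryCatch(read_expression(config$expression),
                error = function(e) stop_ts("stage preprocess failed on '%s': %s",
                                            config$expression, conditionMessage(e)))
  ann <- read_sample_annotation(config$samples)
  m <- median_scale(m)
  if (!is.null(config$transcript_annotation)) {
    tx <- read_transcript_annotation(config$transcript_annotation)
    m <- collapse_transcripts(m, tx)
  }
  profile <- average_replicates(m, ann)
  write_expression(m, out_path("expression_normalized.tsv"))
  write_expression(profile, out_path("tissue_profile.tsv"))
  stages$preprocess <- list(genes = nrow(m), samples = ncol(m),
                            tissues = ncol(profile))
  .stage_log("preprocess", t0, nrow(m), " genes x ", ncol(m), " samples -> ",
             ncol(profile), " tissues")

  # -- specificity -----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  miss <- setdiff(config$target_tissues, colnames(profile))
  if (length(miss))
    stop_ts("stage specificity failed: target tissue(s) absent from data: %s",
            paste(miss, collapse = ", "))
  spec <- specificity_table(profile, config$target_tissues, config$fraction)
  selected <- spec$gene_id[spec$selected]
  write.table(spec, out_path("specificity.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  sel_set <- list(tissue_specific = selected)
  attr(sel_set$tissue_specific, "description") <-
    sprintf("top %g%% TSI genes maximal in target group", 100 * config$fraction)
  write_gmt(sel_set, out_path("selected_genes.gmt"))
  stages$specificity <- list(pool = sum(spec$max_tissue %in% config$target_tissues),
                             selected = length(selected))
  .stage_log("specificity", t0, stages$specificity$pool, " target-maximal genes, ",
             length(selected), " selected")

  # -- network ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  use_samples <- if (config$corr_samples == "target")
    ann$sample_id[ann$tissue %in% config$target_tissues] else colnames(m)
  x <- m[selected, , drop = FALSE]
  if (config$corr_log2) x <- log2(x + 1)
  corr <- pearson_matrix(x, use_samples)
  net <- build_network(corr, config$threshold)
  clust <- mcl_cluster(net, inflation = config$mcl_inflation,
                       expansion = config$mcl_expansion)
  export_network(net, out_path("network_edges.tsv"), "edgelist")
  export_network(net, out_path("network.graphml"), "graphml", assignment = clust)
  write.table(data.frame(gene_id = names(clust$membership),
                         cluster = clust$membership),
              out_path("clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  stages$network <- list(nodes = length(net$nodes), edges = nrow(net$edges),
                         clusters = length(clust$sizes),
                         multi_gene_clusters = length(cluster_sizes(clust)),
                         converged = clust$converged)
  .stage_log("network", t0, length(net$nodes), " nodes, ", nrow(net$edges),
             " edges, ", length(clust$sizes), " clusters")

  # -- enrichment ------------------------------------------------------
  if (!is.null(config$gene_sets_gmt)) {
    t0 <- as.numeric(Sys.time())
    sets <- read_gmt(config$gene_sets_gmt)
    enr <- hypergeom_enrichment(selected, sets, universe = rownames(m))
    write.table(enr, out_path("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    stages$enrichment <- list(sets_tested = nrow(enr),
                              min_p = min(enr$p))
    .stage_log("enrichment", t0, nrow(enr), " sets tested")
  }

  # -- constraint ------------------------------------------------------
  if (!is.null(config$variants)) {
    t0 <- as.numeric(Sys.time())
    variants <- read_variants(config$variants)
    cmp <- compare_daf(variants, set_a = selected, set_b = rownames(m),
                       n_reps = config$daf_n_reps, level = config$daf_level,
                       seed = config$seed + 500L,
                       names_ab = c("tissue_specific", "all_genes"))
    daf_tab <- do.call(rbind, lapply(cmp$sets, function(s)
      data.frame(set = s$name, n_snps = s$n, mean_daf = s$mean,
                 ci_lo = s$ci[["lo"]], ci_hi = s$ci[["hi"]])))
    write.table(daf_tab, out_path("daf_comparison.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(sets = cmp$sets, difference = cmp$difference, p_diff = cmp$p_diff,
           significant = cmp$significant, direction = cmp$direction,
           n_reps = cmp$n_reps, level = cmp$level),
      out_path("daf_comparison.json"), auto_unbox = TRUE, digits = NA)
    stages$constraint <- list(significant = cmp$significant,
                              direction = cmp$direction)
    .stage_log("constraint", t0, "significant = ", cmp$significant)
  }

  manifest <- list(
    package = "tsnetwork",
    version = as.character(utils::packageVersion("tsnetwork")),
    seed = config$seed,
    parameters = unclass(config),
    stages = stages,
    files = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
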