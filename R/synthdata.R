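# Synthetic multi-tissue expression data with planted, tissue-restricted,
# co-regulated modules, plus matching gene sets and variant tables.
#
# Generative model (log scale, natural log):
#   log x_gs = baseline + boost * 1[gene in module, sample in target tissue]
#            + loading * F_{m(g), s} * 1[gene in module]
#            + eps_gs,   eps ~ N(0, noise_sd_log^2)
# with one standard-normal latent factor F_m per module per sample, shared by
# all genes of the module. Values are exponentiated to the linear scale.
# Under this one-factor model the population Pearson correlation between two
# genes of the same module on the log scale is loading^2 / (loading^2 +
# noise_sd_log^2) — an analytic handle used by the network-stage tests.

# Non-target fetal tissue labels used to fill the panel.
.default_other_tissues <- c("brain", "liver", "lung", "kidney", "muscle",
                            "skin", "thymus", "adrenal", "intestine",
                            "placenta", "spleen", "stomach", "testis",
                            "bladder", "pancreas")

#' Configuration for the synthetic expression generator
#'
#' Defaults describe the emulated data regime: a panel of 20 fetal tissues of
#' which 10 form the target ("heart") group, 2 replicate arrays per tissue,
#' four planted co-regulated modules totalling 316 genes, and enough flat
#' background genes (3160, calibrated once against the median-scaling step,
#' which nudges flat genes slightly away from the target group) that the
#' expected number of genes maximal in the target group is about 1580 —
#' so the top-20% selection retains essentially the planted set.
#'
#' @param n_tissues total number of tissues in the panel.
#' @param replicates_per_tissue replicate samples per tissue.
#' @param target_tissues labels of the target tissue group; must have at
#'   most `n_tissues` elements. Non-target labels are filled from a fixed
#'   fetal-tissue list.
#' @param module_sizes integer vector, genes per planted module.
#' @param n_background_genes number of flat (non-specific) background genes.
#' @param baseline_log_expression baseline of log expression (natural log;
#'   default 3, i.e. linear intensity around exp(3) ~ 20).
#' @param target_boost_log log-scale elevation of module genes in target
#'   tissues; default 3 (a ~20-fold induction).
#' @param factor_loading loading of the shared per-module latent factor.
#' @param noise_sd_log standard deviation of the i.i.d. log-scale noise.
#' @param factor_in_target_only if `TRUE`, the latent factor is applied only
#'   in target-tissue samples (module genes are then uncorrelated elsewhere).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a list of class `expression_gen_config`.
#' @export
expression_gen_config <- function(n_tissues = 20L,
                                  replicates_per_tissue = 2L,
                                  target_tissues = paste0("heart_", 1:10),
                                  module_sizes = c(285L, 15L, 10L, 6L),
                                  n_background_genes = 3160L,
                                  baseline_log_expression = 3,
                                  target_boost_log = 3,
                                  factor_loading = 1.0,
                                  noise_sd_log = 0.33,
                                  factor_in_target_only = FALSE,
                                  seed = 17L) {
  cfg <- list(n_tissues = check_count(n_tissues, "n_tissues"),
              replicates_per_tissue = check_count(replicates_per_tissue, "replicates_per_tissue"),
              target_tissues = as.character(target_tissues),
              module_sizes = vapply(module_sizes, check_count, integer(1L), name = "module_sizes"),
              n_background_genes = check_count(n_background_genes, "n_background_genes", min = 0L),
              baseline_log_expression = as.numeric(baseline_log_expression),
              target_boost_log = as.numeric(target_boost_log),
              factor_loading = as.numeric(factor_loading),
              noise_sd_log = as.numeric(noise_sd_log),
              factor_in_target_only = isTRUE(factor_in_target_only),
              seed = check_count(seed, "seed", min = 0L))
  if (!length(cfg$target_tissues)) stop_ts("target_tissues must be nonempty")
  if (length(cfg$target_tissues) > cfg$n_tissues)
    stop_ts("target_tissues has more labels (%d) than n_tissues (%d)",
            length(cfg$target_tissues), cfg$n_tissues)
  if (anyDuplicated(cfg$target_tissues)) stop_ts("duplicate target tissue labels")
  if (cfg$noise_sd_log <= 0) stop_ts("noise_sd_log must be > 0")
  if (sum(cfg$module_sizes) + cfg$n_background_genes == 0L)
    stop_ts("empty design: no module genes and no background genes")
  class(cfg) <- "expression_gen_config"
  cfg
}

# Tissue label panel: target labels first, then fixed non-target fillers.
.tissue_panel <- function(cfg) {
  n_other <- cfg$n_tissues - length(cfg$target_tissues)
  other <- .default_other_tissues[seq_len(min(n_other, length(.default_other_tissues)))]
  if (n_other > length(other))
    other <- c(other, sprintf("tissue_%02d", seq_len(n_other - length(other))))
  other <- setdiff(other, cfg$target_tissues)[seq_len(n_other)]
  c(cfg$target_tissues, other)
}

#' Generate a synthetic expression matrix with planted modules
#'
#' See the model description in [expression_gen_config()]. Module genes are
#' boosted in the target tissues and share a per-module latent factor;
#' background genes are flat apart from i.i.d. log-normal noise.
#'
#' @param config an [expression_gen_config()].
#' @return a list with elements
#'   * `expression`: genes x samples numeric matrix, linear scale, strictly
#'     positive;
#'   * `samples`: data.frame `sample_id`, `tissue`;
#'   * `truth`: data.frame `gene_id`, `module` (`"M1"`, ... or
#'     `"background"`), `specificity_class` (`"target_specific"` or
#'     `"background"`).
#' @examples
#' cfg <- expression_gen_config(n_tissues = 4, target_tissues = "heart_1",
#'                              module_sizes = 5, n_background_genes = 10,
#'                              seed = 1)
#' bundle <- generate_expression(cfg)
#' dim(bundle$expression)
#' @export
generate_expression <- function(config) {
  if (!inherits(config, "expression_gen_config"))
    stop_ts("config must come from expression_gen_config()")
  cfg <- config
  tissues <- .tissue_panel(cfg)
  n_samples <- cfg$n_tissues * cfg$replicates_per_tissue
  sample_tissue <- rep(tissues, each = cfg$replicates_per_tissue)
  sample_ids <- paste0(sample_tissue, "_r", rep(seq_len(cfg$replicates_per_tissue), cfg$n_tissues))
  in_target <- sample_tissue %in% cfg$target_tissues

  n_modules <- length(cfg$module_sizes)
  module_of <- rep(seq_len(n_modules), cfg$module_sizes)
  gene_ids <- c(sprintf("M%d_G%04d", module_of, unlist(lapply(cfg$module_sizes, seq_len))),
                if (cfg$n_background_genes > 0L)
                  sprintf("BG_G%05d", seq_len(cfg$n_background_genes)))
  n_genes <- length(gene_ids)

  set.seed(cfg$seed)
  # per-module, per-sample latent factors
  fac <- matrix(rnorm(n_modules * n_samples), nrow = n_modules)
  if (cfg$factor_in_target_only) fac[, !in_target] <- 0
  logm <- matrix(cfg$baseline_log_expression, nrow = n_genes, ncol = n_samples,
                 dimnames = list(gene_ids, sample_ids))
  n_mod_genes <- sum(cfg$module_sizes)
  if (n_mod_genes > 0L) {
    logm[seq_len(n_mod_genes), in_target] <-
      logm[seq_len(n_mod_genes), in_target] + cfg$target_boost_log
    logm[seq_len(n_mod_genes), ] <-
      logm[seq_len(n_mod_genes), ] + cfg$factor_loading * fac[module_of, , drop = FALSE]
  }
  logm <- logm + matrix(rnorm(n_genes * n_samples, sd = cfg$noise_sd_log),
                        nrow = n_genes)

  truth <- data.frame(
    gene_id = gene_ids,
    module = c(paste0("M", module_of),
               rep("background", cfg$n_background_genes)),
    specificity_class = c(rep("target_specific", n_mod_genes),
                          rep("background", cfg$n_background_genes)),
    stringsAsFactors = FALSE)

  list(expression = exp(logm),
       samples = data.frame(sample_id = sample_ids, tissue = sample_tissue,
                            stringsAsFactors = FALSE),
       truth = truth)
}

#' Configuration for the synthetic variant generator
#'
#' Each gene set draws its derived allele frequencies from its own Beta
#' distribution. Defaults plant purifying selection in the `constrained`
#' set: Beta(0.3, 3) (mean 0.091) against a Beta(0.5, 3) background (mean
#' 0.143), so a lower mean DAF in the constrained set is the ground truth.
#'
#' @param set_params named list; each element a numeric `c(alpha, beta)`
#'   with both entries > 0.
#' @param snps_per_gene SNPs generated per gene.
#' @param background_set name of the set (must be in `set_params`) used for
#'   genes that belong to no supplied set.
#' @param seed integer seed.
#' @return a list of class `variant_gen_config`.
#' @export
variant_gen_config <- function(set_params = list(constrained = c(0.3, 3.0),
                                                 background = c(0.5, 3.0)),
                               snps_per_gene = 5L,
                               background_set = "background",
                               seed = 17L) {
  if (is.null(names(set_params)) || any(!nzchar(names(set_params))))
    stop_ts("set_params must be a named list")
  for (nm in names(set_params)) {
    p <- set_params[[nm]]
    if (length(p) != 2L || any(!is.finite(p)) || any(p <= 0))
      stop_ts("set_params[['%s']] must be c(alpha, beta) with both > 0", nm)
  }
  if (!background_set %in% names(set_params))
    stop_ts("background_set '%s' has no entry in set_params", background_set)
  structure(list(set_params = lapply(set_params, as.numeric),
                 snps_per_gene = check_count(snps_per_gene, "snps_per_gene"),
                 background_set = background_set,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "variant_gen_config")
}

#' Generate a per-SNP variant table with set-specific DAF distributions
#'
#' Every gene receives `snps_per_gene` SNPs whose derived allele frequencies
#' are drawn from the Beta distribution of the first gene set containing the
#' gene (list order gives precedence); genes in no set fall back to the
#' configured background set.
#'
#' @param gene_sets named list of character vectors of gene ids. Set names
#'   with Beta parameters in `config$set_params` are used for drawing;
#'   others fall back to the background set.
#' @param config a [variant_gen_config()].
#' @return data.frame `snp_id`, `gene_id`, `daf` plus a `set_of` attribute
#'   mapping each gene to the set its DAF was drawn from.
#' @export
generate_variants <- function(gene_sets, config) {
  if (!inherits(config, "variant_gen_config"))
    stop_ts("config must come from variant_gen_config()")
  genes <- unique(unlist(gene_sets, use.names = FALSE))
  if (!length(genes)) stop_ts("gene_sets contain no genes")
  set_of <- setNames(rep(config$background_set, length(genes)), genes)
  for (nm in rev(names(gene_sets))) {    # earlier sets override later ones
    hit <- intersect(gene_sets[[nm]], genes)
    if (nm %in% names(config$set_params)) set_of[hit] <- nm
  }
  set.seed(config$seed)
  k <- config$snps_per_gene
  daf <- unlist(lapply(genes, function(g) {
    p <- config$set_params[[set_of[[g]]]]
    rbeta(k, p[1L], p[2L])
  }), use.names = FALSE)
  out <- data.frame(
    snp_id = paste0(rep(genes, each = k), "_snp", rep(seq_len(k), length(genes))),
    gene_id = rep(genes, each = k),
    daf = daf,
    stringsAsFactors = FALSE)
  attr(out, "set_of") <- set_of
  out
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Generates an expression bundle and a matching variant table and writes
#' five files into `outdir`: `expression.tsv`, `samples.tsv`,
#' `gene_sets.gmt` (planted module genes as `constrained`, the rest as
#' `background`), `variants.tsv`, and `truth.tsv` (per-gene module label,
#' specificity class and DAF Beta parameters). Re-running with the same
#' configurations reproduces byte-identical files.
#'
#' @param outdir output directory, created if missing.
#' @param expr_config an [expression_gen_config()].
#' @param variant_config a [variant_gen_config()].
#' @return named character vector of the five file paths, invisibly.
#' @export
write_fixture_bundle <- function(outdir,
                                 expr_config = expression_gen_config(),
                                 variant_config = variant_gen_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop_ts("cannot create output directory '%s'", outdir)
  bundle <- generate_expression(expr_config)
  specific <- bundle$truth$gene_id[bundle$truth$specificity_class == "target_specific"]
  background <- setdiff(bundle$truth$gene_id, specific)
  sets <- list(constrained = specific, background = background)
  if (!length(background)) sets$background <- NULL
  variants <- generate_variants(sets, variant_config)
  set_of <- attr(variants, "set_of")
  truth <- bundle$truth
  pars <- do.call(rbind, variant_config$set_params[set_of[truth$gene_id]])
  truth$daf_alpha <- pars[, 1L]
  truth$daf_beta <- pars[, 2L]

  paths <- c(expression = file.path(outdir, "expression.tsv"),
             samples = file.path(outdir, "samples.tsv"),
             gene_sets = file.path(outdir, "gene_sets.gmt"),
             variants = file.path(outdir, "variants.tsv"),
             truth = file.path(outdir, "truth.tsv"))
  write_expression(bundle$expression, paths[["expression"]])
  write.table(bundle$samples, paths[["samples"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gmt(sets, paths[["gene_sets"]])
  write.table(variants[c("snp_id", "gene_id", "daf")], paths[["variants"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
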