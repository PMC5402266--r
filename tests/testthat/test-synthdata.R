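test_that("generator validates its configuration", {
  expect_error(expression_gen_config(n_tissues = 0), "n_tissues")
  expect_error(expression_gen_config(target_tissues = character(0)), "nonempty")
  expect_error(expression_gen_config(n_tissues = 2,
                                     target_tissues = c("a", "b", "c")),
               "more labels")
  expect_error(expression_gen_config(noise_sd_log = 0), "noise_sd_log")
  expect_error(expression_gen_config(module_sizes = integer(0),
                                     n_background_genes = 0), "empty design")
})

test_that("generated bundle has the configured shape, positivity and determinism", {
  cfg <- small_gen_config(seed = 11)
  b1 <- generate_expression(cfg)
  b2 <- generate_expression(cfg)
  expect_identical(b1, b2)                       # fixed seed => identical
  expect_equal(dim(b1$expression), c(8 + 5 + 20, 6 * 2))
  expect_true(all(b1$expression > 0))
  expect_equal(nrow(b1$samples), 12)
  expect_equal(sort(unique(b1$truth$module)), sort(c("M1", "M2", "background")))
  expect_identical(b1$truth$gene_id, rownames(b1$expression))
  expect_false(identical(generate_expression(small_gen_config(seed = 12))$expression,
                         b1$expression))         # different seed differs
})

test_that("noise-free limit: replicates within a tissue are identical", {
  # factor off, noise -> 0: expression depends on (gene, tissue) only
  cfg <- expression_gen_config(n_tissues = 4, replicates_per_tissue = 3,
                               target_tissues = "heart_1",
                               module_sizes = 4, n_background_genes = 3,
                               factor_loading = 0, noise_sd_log = 1e-12,
                               seed = 5)
  b <- generate_expression(cfg)
  for (ti in unique(b$samples$tissue)) {
    cols <- b$samples$sample_id[b$samples$tissue == ti]
    within_var <- apply(b$expression[, cols], 1, var)
    expect_lt(max(within_var), 1e-15)
  }
})

test_that("one-factor model yields the analytic within-module correlation", {
  # population log-scale r = loading^2 / (loading^2 + sd^2) = 1/1.1089 ~ 0.902;
  # sample mean pairwise r over 20 target samples must sit in [0.85, 0.95]
  cfg <- expression_gen_config(module_sizes = 50L, n_background_genes = 0L,
                               seed = 23)
  b <- generate_expression(cfg)
  x <- target_log2_matrix(b, cfg)
  expect_equal(ncol(x), 20)
  r <- cor(t(x))
  mean_r <- mean(r[upper.tri(r)])
  expect_gt(mean_r, 0.85)
  expect_lt(mean_r, 0.95)
})

test_that("noise-free boosted gene hits the closed-form TSI", {
  # 11 tissues, one targeted, boost 3: profile (e^4, e^1 x10) after exp();
  # TSI = 10 * (1 - e^-3) / 10 = 1 - e^-3
  cfg <- expression_gen_config(n_tissues = 11, replicates_per_tissue = 1,
                               target_tissues = "heart_1",
                               module_sizes = 1, n_background_genes = 0,
                               baseline_log_expression = 1, target_boost_log = 3,
                               factor_loading = 0, noise_sd_log = 1e-9,
                               seed = 2)
  b <- generate_expression(cfg)
  prof <- b$expression[1, ]
  expect_equal(compute_tsi(prof), 1 - exp(-3), tolerance = 1e-6)
})

test_that("variant generator draws set-specific Beta DAFs", {
  sets <- list(constrained = sprintf("c%03d", 1:100),
               background = sprintf("b%03d", 1:100))
  cfg <- variant_gen_config(snps_per_gene = 5, seed = 7)
  v <- generate_variants(sets, cfg)
  expect_equal(nrow(v), 2 * 100 * 5)             # snps_per_gene x genes
  expect_false(anyDuplicated(v$snp_id) > 0)
  expect_true(all(v$daf >= 0 & v$daf <= 1))
  # Beta means: 0.3/3.3 ~ 0.0909 vs 0.5/3.5 ~ 0.1429, se ~ sd/sqrt(500)
  m_con <- mean(v$daf[grepl("^c", v$gene_id)])
  m_bg <- mean(v$daf[grepl("^b", v$gene_id)])
  expect_lt(m_con, m_bg)
  expect_equal(m_con, 0.3 / 3.3, tolerance = 0.2)
  expect_equal(m_bg, 0.5 / 3.5, tolerance = 0.2)
  expect_identical(generate_variants(sets, cfg), v)  # deterministic
})

test_that("uniform Beta(1,1) DAFs pool to mean ~ 0.5", {
  sets <- list(background = sprintf("g%03d", 1:200))
  cfg <- variant_gen_config(set_params = list(background = c(1, 1)),
                            snps_per_gene = 5, seed = 3)
  v <- generate_variants(sets, cfg)
  se <- sqrt(1 / 12 / nrow(v))
  expect_lt(abs(mean(v$daf) - 0.5), 3 * se)
})

test_that("genes outside every parameterized set fall back to the background Beta", {
  sets <- list(mystery = c("g1", "g2"), background = c("g3"))
  cfg <- variant_gen_config(set_params = list(background = c(5, 5)),
                            snps_per_gene = 2, background_set = "background",
                            seed = 9)
  v <- generate_variants(sets, cfg)
  expect_setequal(unique(v$gene_id), c("g1", "g2", "g3"))
  expect_equal(unname(attr(v, "set_of")[c("g1", "g3")]),
               c("background", "background"))
})

test_that("fixture bundle writes five reproducible files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ec <- small_gen_config(seed = 4)
  vc <- variant_gen_config(snps_per_gene = 2, seed = 4)
  p1 <- write_fixture_bundle(d1, ec, vc)
  p2 <- write_fixture_bundle(d2, ec, vc)
  expect_length(p1, 5)
  expect_true(all(file.exists(p1)))
  for (nm in names(p1)) expect_same_file(p1[[nm]], p2[[nm]])
  # different seed changes the expression values
  d3 <- withr::local_tempdir()
  p3 <- write_fixture_bundle(d3, small_gen_config(seed = 5), vc)
  expect_false(unname(tools::md5sum(p1[["expression"]])) ==
               unname(tools::md5sum(p3[["expression"]])))
  # round-trips through the readers
  m <- read_expression(p1[["expression"]])
  expect_equal(dim(m), c(33, 12))
  truth <- read.delim(p1[["truth"]])
  expect_equal(nrow(truth), 33)
  expect_false(anyDuplicated(truth$gene_id) > 0)
  sets <- read_gmt(p1[["gene_sets"]])
  expect_setequal(names(sets), c("constrained", "background"))
})
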