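test_that("pearson_matrix matches hand-computed correlations", {
  m <- rbind(g1 = c(1, 2, 3, 4),
             g2 = c(1, 3, 2, 4),
             g3 = c(6, 4, 2, 0))
  colnames(m) <- paste0("s", 1:4)
  r <- pearson_matrix(m)
  expect_equal(diag(r), setNames(rep(1, 3), rownames(m)))
  expect_equal(r["g1", "g2"], 0.8)             # hand: cov 1 / (sd^2 = 1.25)
  expect_equal(r["g1", "g3"], -1)              # perfect anticorrelation
  expect_true(isSymmetric(unname(r)))
  expect_error(pearson_matrix(m[, 1:2]), ">= 3 samples")
  expect_error(pearson_matrix(m, c("s1", "sX", "s3")), "sX")
  # zero-variance genes dropped with a warning
  m2 <- rbind(m, g4 = c(2, 2, 2, 2))
  expect_warning(r2 <- pearson_matrix(m2), "g4")
  expect_equal(rownames(r2), c("g1", "g2", "g3"))
})

test_that("build_network thresholds edges and keeps isolated nodes", {
  r <- diag(3)
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  r["a", "b"] <- r["b", "a"] <- 0.9
  r["a", "c"] <- r["c", "a"] <- 0.5
  r["b", "c"] <- r["c", "b"] <- 0.85
  net <- build_network(r, 0.80)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$gene_a, net$edges$gene_b),
                  c("a b", "b c"))
  expect_equal(net$nodes, c("a", "b", "c"))    # c isolated but retained
  # threshold 1.0 with no off-diagonal 1s: no edges
  expect_equal(nrow(build_network(r, 1.0)$edges), 0)
  # boundary is inclusive (>=)
  expect_equal(nrow(build_network(r, 0.85)$edges), 2)
  expect_error(build_network(r, 1.5), "threshold")
})

test_that("edge sets are nested across thresholds", {
  set.seed(19)
  x <- matrix(rnorm(20 * 10), 20, dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  r <- pearson_matrix(x)
  edge_key <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  thresholds <- c(0.0, 0.3, 0.6, 0.8)
  for (i in seq_along(thresholds)[-1]) {
    lo <- edge_key(build_network(r, thresholds[i - 1]))
    hi <- edge_key(build_network(r, thresholds[i]))
    expect_true(all(hi %in% lo))
  }
})

test_that("MCL separates disjoint cliques (component oracle)", {
  cl <- mcl_cluster(clique_adjacency(c(5, 5)))
  expect_equal(length(cl$sizes), 2)
  expect_equal(as.integer(cl$sizes), c(5, 5))
  expect_true(cl$converged)
  # a single clique is one cluster
  cl4 <- mcl_cluster(clique_adjacency(4))
  expect_equal(length(cl4$sizes), 1)
  expect_equal(as.integer(cl4$sizes), 4)
  # membership ids contiguous from 1, ordered by decreasing size
  cl3 <- mcl_cluster(clique_adjacency(c(2, 6, 3)))
  expect_equal(as.integer(cl3$sizes), c(6, 3, 2))
  expect_setequal(unique(cl3$membership), 1:3)
})

test_that("MCL clusters never span disconnected components", {
  set.seed(31)
  for (i in 1:5) {
    sizes <- sample(2:6, 3)
    A <- clique_adjacency(sizes)
    # random extra edges inside each clique block don't exist; perturb weights
    A[A > 0] <- runif(sum(A > 0), 0.5, 1)
    A <- (A + t(A)) / 2
    comp <- rep(seq_along(sizes), sizes)
    cl <- mcl_cluster(A)
    # each MCL cluster must sit inside one component
    split_comp <- split(comp, cl$membership)
    expect_true(all(vapply(split_comp, function(v) length(unique(v)) == 1, logical(1))))
  }
})

test_that("MCL iterates stay column-stochastic through the step operator", {
  set.seed(57)
  A <- clique_adjacency(c(4, 3))
  A[A > 0] <- runif(sum(A > 0), 0.3, 1)
  A <- (A + t(A)) / 2
  diag(A) <- apply(A, 2, max)
  M <- tsnetwork:::.mcl_normalize(A)
  for (i in 1:20) {
    M <- tsnetwork:::.mcl_step(M, expansion = 2L, inflation = 2, prune_below = 1e-5)
    expect_lt(max(abs(colSums(M) - 1)), 1e-9)
  }
})

test_that("raising inflation never decreases the cluster count", {
  cfg <- module_gen_config(seed = 29)
  b <- generate_expression(cfg)
  net <- build_network(pearson_matrix(target_log2_matrix(b, cfg)), 0.80)
  counts <- vapply(c(1.4, 2.0, 4.0), function(inf)
    length(mcl_cluster(net, inflation = inf)$sizes), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("MCL recovers the four planted modules from the synthetic bundle", {
  cfg <- module_gen_config(seed = 17)
  b <- generate_expression(cfg)
  x <- target_log2_matrix(b, cfg)
  net <- build_network(pearson_matrix(x), 0.80)
  # within-module edges dominate; between-module expected r ~ 0
  truth <- setNames(b$truth$module, b$truth$gene_id)
  same <- truth[net$edges$gene_a] == truth[net$edges$gene_b]
  expect_gt(mean(same), 0.999)
  cl <- mcl_cluster(net, inflation = 2.0)
  expect_equal(length(cluster_sizes(cl)), 4)
  expect_gte(adjusted_rand_index(cl$membership[names(truth)], truth), 0.99)
})

test_that("network export round-trips through both formats", {
  r <- diag(4)
  nodes <- c("a", "b", "c", "d")
  dimnames(r) <- list(nodes, nodes)
  r["a", "b"] <- r["b", "a"] <- 0.92
  r["c", "d"] <- r["d", "c"] <- 0.88
  net <- build_network(r, 0.80)
  cl <- mcl_cluster(net)

  edge_path <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, edge_path, "edgelist")
  expect_equal(length(readLines(edge_path)), 3)   # header + 2 edges
  back <- read_network_edgelist(edge_path)
  expect_setequal(back$nodes, nodes)
  expect_equal(back$edges, net$edges)

  gml_path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml_path, "graphml", assignment = cl)
  g_back <- read_network_graphml(gml_path)
  expect_setequal(g_back$nodes, net$nodes)
  expect_setequal(paste(g_back$edges$gene_a, g_back$edges$gene_b),
                  paste(net$edges$gene_a, net$edges$gene_b))
  memb <- attr(g_back, "membership")
  expect_equal(memb[nodes], cl$membership[nodes])

  expect_error(export_network(net, edge_path, "dot"), "edgelist, graphml")
})

test_that("an empty network exports validly in both formats", {
  r <- diag(2)
  dimnames(r) <- list(c("a", "b"), c("a", "b"))
  net <- build_network(r, 0.99)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, p1, "edgelist")
  expect_equal(readLines(p1), "gene_a\tgene_b\tr")
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, p2, "graphml")
  expect_setequal(read_network_graphml(p2)$nodes, c("a", "b"))
})
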