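test_that("ModCon follows the printed formula on an authored fixture", {
  genes <- sprintf("m%02d", 1:6)
  rho <- matrix(0, 6, 6, dimnames = list(genes, genes))
  w <- function(i, j, v) rho[i, j] <<- rho[j, i] <<- v
  w(1, 2, 0.9); w(1, 3, 0.8); w(2, 3, 0.7); w(3, 4, 0.6); w(4, 5, 0.5)
  net <- reduce_epg(toy_merged(rho), n_edges = 5)
  stats_tab <- data.frame(
    gene_id = genes,
    percentile_expression = c(80, 60, 90, 40, 70, 50),
    var_across = c(10, 20, 5, 30, 15, 25),
    var_within = c(0.5, 0.4, 0.6, 0.3, 0.2, 0.1))
  rk <- modcon_rank(genes, net, stats_tab)
  # spreadsheet-style oracle: connectivity from the retained edges
  conn <- c(m01 = 1.7, m02 = 1.6, m03 = 2.1, m04 = 1.1, m05 = 0.5, m06 = 0)
  oracle <- conn^2 * stats_tab$percentile_expression * stats_tab$var_within *
    (100 - stats_tab$var_across) / 100
  expect_equal(rk$modcon, sort(unname(oracle), decreasing = TRUE),
               tolerance = 1e-12)
  expect_equal(rk$gene_id[1], "m03")
  # zero intra-module edges -> connectivity 0 -> modcon 0
  expect_equal(rk$modcon[rk$gene_id == "m06"], 0)
  # connectivity only counts edges inside the module
  rk_sub <- modcon_rank(c("m04", "m05"), net, stats_tab)
  expect_equal(rk_sub$connectivity[rk_sub$gene_id == "m04"], 0.5)
})

test_that("squared connectivity gives a 4:1 modcon ratio for 2:1 connectivity", {
  genes <- c("a", "b", "c", "d")
  rho <- matrix(0, 4, 4, dimnames = list(genes, genes))
  rho["a", "b"] <- rho["b", "a"] <- 1
  rho["a", "c"] <- rho["c", "a"] <- 1
  rho["d", "b"] <- rho["b", "d"] <- 1
  net <- reduce_epg(toy_merged(rho), n_edges = 3)
  stats_tab <- data.frame(gene_id = genes, percentile_expression = 50,
                          var_across = 0, var_within = 0.5)
  rk <- modcon_rank(c("a", "b", "c", "d"), net, stats_tab)
  # a has connectivity 2, d has 1 (identical stats otherwise)
  expect_equal(rk$modcon[rk$gene_id == "a"] / rk$modcon[rk$gene_id == "d"], 4)
})

test_that("modcon ranking is invariant to gene order and deterministic on ties", {
  sim <- small_sim()
  per <- lapply(sim$datasets, function(d) dataset_spearman(d))
  net <- reduce_epg(merge_correlations(per, min_datasets = 3), n_edges = 3)
  stats_tab <- gene_meta_stats(sim$datasets)
  mod_genes <- names(sim$truth$assignment)[sim$truth$assignment == 1]
  r1 <- modcon_rank(mod_genes, net, stats_tab)
  r2 <- modcon_rank(rev(mod_genes), net, stats_tab)
  expect_identical(r1$gene_id, r2$gene_id)
})

test_that("MEV is the per-sample sum of population z-scores of top hub genes", {
  set.seed(13)
  vals <- matrix(rnorm(50, 8), 5, 10)
  ds <- make_ds(vals, id = "mev")
  rk <- data.frame(gene_id = ds$gene_ids, connectivity = 5:1, modcon = 5:1)
  # top_n = 1: MEV equals that single gene's z-score vector
  res1 <- compute_mev(ds, rk, top_n = 1)
  x <- vals[1, ]
  z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(unname(res1$mev), unname(z), tolerance = 1e-12)
  expect_identical(res1$genes_used, ds$gene_ids[1])
  # z-scores are centered: MEV sums to ~0 across samples
  res_all <- compute_mev(ds, rk, top_n = 5)
  expect_equal(sum(res_all$mev), 0, tolerance = 1e-9)
  expect_length(res_all$genes_used, 5)
})

test_that("zero-variance genes are skipped and replaced by the next-ranked gene", {
  vals <- rbind(rep(3, 6), rnorm(6), rnorm(6), rnorm(6))
  ds <- make_ds(vals, id = "zv")
  rk <- data.frame(gene_id = ds$gene_ids, connectivity = 4:1, modcon = 4:1)
  res <- compute_mev(ds, rk, top_n = 2)
  expect_identical(res$genes_used, ds$gene_ids[2:3])
})

test_that("MEV is invariant under positive affine transforms of expression", {
  set.seed(14)
  vals <- matrix(rnorm(60, 8), 6, 10)
  ds1 <- make_ds(vals, id = "aff")
  ds2 <- make_ds(vals * 2.5 + 7, id = "aff")
  rk <- data.frame(gene_id = ds1$gene_ids, connectivity = 6:1, modcon = 6:1)
  expect_equal(compute_mev(ds1, rk, 4)$mev, compute_mev(ds2, rk, 4)$mev,
               tolerance = 1e-9)
})

test_that("MEV tracks the planted latent module factor", {
  sim <- small_sim()
  per <- lapply(sim$datasets, function(d) dataset_spearman(d))
  net <- reduce_epg(merge_correlations(per, min_datasets = 3), n_edges = 3)
  stats_tab <- gene_meta_stats(sim$datasets)
  truth <- sim$truth$assignment
  rankings <- lapply(split(names(truth)[truth > 0], truth[truth > 0]),
                     modcon_rank, network = net, meta_stats = stats_tab)
  mev <- mev_matrix(sim$datasets[[1]], rankings, top_n = 25)
  expect_s3_class(mev, "mev_matrix")
  expect_true(all(lengths(mev$genes_used) == 25))
  for (k in 1:4) {
    f <- sim$truth$factors[[1]][, k]
    rho <- cor(mev$values[as.character(k), names(f)], f, method = "spearman")
    expect_gt(rho, 0.9)
  }
})

test_that("module correlations merge medians and zero non-significant pairs", {
  sim <- small_sim()
  per <- lapply(sim$datasets, function(d) dataset_spearman(d))
  net <- reduce_epg(merge_correlations(per, min_datasets = 3), n_edges = 3)
  stats_tab <- gene_meta_stats(sim$datasets)
  truth <- sim$truth$assignment
  rankings <- lapply(split(names(truth)[truth > 0], truth[truth > 0]),
                     modcon_rank, network = net, meta_stats = stats_tab)
  mevs <- lapply(sim$datasets, mev_matrix, rankings = rankings)
  mc <- module_correlation(mevs)
  expect_equal(unname(diag(mc$rho)), rep(1, 4))
  expect_equal(mc$rho, t(mc$rho))
  # independent planted factors: off-diagonal correlations are noise and
  # mostly zeroed by the p-filter
  off <- mc$rho[upper.tri(mc$rho)]
  expect_true(all(abs(off) < 0.5))
})
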