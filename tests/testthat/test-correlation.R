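test_that("variant-gene selection keeps the ceil(fraction * G) highest-variance genes", {
  vals <- rbind(c(1, 1, 1.1, 1), c(0, 10, 0, 10), c(5, 6, 7, 8),
                c(2, 2.5, 2, 2.5), c(0, 0, 0, 100))
  ds <- make_ds(vals, genes = c("gA", "gB", "gC", "gD", "gE"))
  # brute-force ranking by variance
  v <- apply(vals, 1, var)
  names(v) <- ds$gene_ids
  expect_setequal(select_variant_genes(ds, 0.8),
                  names(sort(v, decreasing = TRUE))[1:4])
  expect_setequal(select_variant_genes(ds, 1.0), ds$gene_ids)
  # 10 genes at 0.8 -> exactly 8
  ds10 <- make_ds(matrix(rnorm(40), 10, 4))
  expect_length(select_variant_genes(ds10, 0.8), 8)
  expect_error(select_variant_genes(ds10, 0), "fraction")
})

test_that("variant-gene ties break deterministically by gene id", {
  vals <- matrix(rep(c(0, 1), 3), nrow = 3, ncol = 2, byrow = TRUE)
  ds <- make_ds(vals, genes = c("gC", "gA", "gB"))
  expect_identical(select_variant_genes(ds, 2/3), c("gA", "gB"))
})

test_that("dataset Spearman matches rank-then-Pearson with cor.test p-values", {
  set.seed(7)
  vals <- matrix(rnorm(24), 4, 6)
  vals[2, ] <- vals[1, ] + rnorm(6, sd = 0.3)     # a correlated pair
  vals[3, 3] <- vals[3, 2]                         # introduce a tie
  ds <- make_ds(vals)
  sp <- suppressWarnings(dataset_spearman(ds))
  for (pair in list(c(1, 2), c(1, 3), c(2, 4))) {
    i <- ds$gene_ids[pair[1]]; j <- ds$gene_ids[pair[2]]
    oracle_rho <- cor(rank(vals[pair[1], ]), rank(vals[pair[2], ]))
    expect_equal(sp$rho[i, j], oracle_rho, tolerance = 1e-12)
    oracle_p <- suppressWarnings(
      cor.test(vals[pair[1], ], vals[pair[2], ], method = "spearman"))
    # t-approximation vs cor.test's AS89/exact: same scale, loose agreement
    expect_equal(sp$pval[i, j], oracle_p$p.value, tolerance = 0.15)
  }
  expect_equal(unname(diag(sp$rho)), rep(1, 4))
  expect_equal(sp$rho, t(sp$rho))
})

test_that("perfect anti-ranked vectors give rho -1 with p 0", {
  ds <- make_ds(rbind(1:5, 5:1), samples = sprintf("s%d", 1:5))
  sp <- suppressWarnings(dataset_spearman(ds))
  expect_equal(sp$rho[1, 2], -1)
  expect_equal(sp$pval[1, 2], 0)
})

test_that("zero-variance genes are recorded as missing", {
  ds <- make_ds(rbind(c(1, 1, 1, 1, 1), rnorm(5), rnorm(5)))
  sp <- suppressWarnings(dataset_spearman(ds))
  expect_true(all(is.na(sp$rho["g01", c("g02", "g03")])))
  expect_false(anyNA(sp$rho["g02", "g03"]))
})

test_that("merging takes per-pair medians over the datasets containing both genes", {
  mk <- function(genes, rho12) {
    rho <- diag(length(genes)); dimnames(rho) <- list(genes, genes)
    rho[1, 2] <- rho[2, 1] <- rho12
    pval <- matrix(0.001, length(genes), length(genes),
                   dimnames = dimnames(rho)); diag(pval) <- 0
    list(gene_ids = genes, rho = rho, pval = pval, n_samples = 30L)
  }
  per <- list(mk(c("gA", "gB"), 0.2), mk(c("gA", "gB"), 0.5),
              mk(c("gA", "gB"), 0.9))
  merged <- merge_correlations(per, min_datasets = 1)
  expect_equal(merged$rho["gA", "gB"], 0.5)      # odd-count median
  expect_equal(merged$n_datasets["gA", "gB"], 3)

  # pair present in only 2 of 3 datasets: median over those 2
  per2 <- list(mk(c("gA", "gB", "gC"), 0.4), mk(c("gA", "gB", "gC"), 0.8),
               mk(c("gA", "gC"), 0.99))
  merged2 <- merge_correlations(per2, min_datasets = 2)
  expect_equal(merged2$rho["gA", "gB"], 0.6)     # even-count midpoint
  expect_equal(merged2$n_datasets["gA", "gB"], 2)
  expect_equal(merged2$n_datasets["gA", "gC"], 3)

  # min_datasets drops rare genes entirely
  merged3 <- merge_correlations(per2, min_datasets = 3)
  expect_identical(merged3$gene_ids, c("gA", "gC"))
})

test_that("single-dataset merge equals that dataset with p > 0.05 zeroed", {
  genes <- c("gA", "gB", "gC")
  rho <- matrix(c(0, .7, .1, .7, 0, -.5, .1, -.5, 0), 3,
                dimnames = list(genes, genes)); diag(rho) <- 1
  pval <- matrix(c(0, .01, .5, .01, 0, .04, .5, .04, 0), 3,
                 dimnames = list(genes, genes))
  merged <- merge_correlations(
    list(list(gene_ids = genes, rho = rho, pval = pval, n_samples = 30L)),
    min_datasets = 1)
  expect_equal(merged$rho["gA", "gB"], 0.7)
  expect_equal(merged$rho["gB", "gC"], -0.5)
  expect_equal(merged$rho["gA", "gC"], 0)        # p = 0.5 zeroed
  expect_equal(unname(diag(merged$rho)), rep(0, 3))
})

test_that("merged matrices are symmetric, dataset-order invariant, and p-filtered", {
  sim <- small_sim()
  per <- lapply(sim$datasets[1:2], function(d)
    dataset_spearman(d, select_variant_genes(d, 0.5)))
  m1 <- merge_correlations(per, min_datasets = 1)
  m2 <- merge_correlations(rev(per), min_datasets = 1)
  expect_equal(m1$rho, m2$rho)
  expect_equal(m1$rho, t(m1$rho))
  expect_true(all(m1$pval[m1$rho != 0] <= 0.05))
  # block streaming is an implementation detail: tiny blocks agree
  m3 <- merge_correlations(per, min_datasets = 1, block_size = 7L)
  expect_equal(m1$rho, m3$rho)
  expect_equal(m1$n_datasets, m3$n_datasets)
})

test_that("planted within-module correlations exceed between-module ones", {
  sim <- small_sim()
  per <- lapply(sim$datasets, function(d) dataset_spearman(d))
  merged <- merge_correlations(per, min_datasets = 3)
  truth <- sim$truth$assignment[merged$gene_ids]
  same <- outer(truth, truth, "==") & truth > 0
  diag(same) <- NA
  within <- median(merged$rho[which(same)])
  between <- median(merged$rho[which(!same & outer(truth, truth, function(a, b) a > 0 & b > 0))])
  expect_gt(within, between + 0.3)
})
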