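test_that("binarization applies the strict frequency filter on the cohort", {
  samples <- sprintf("s%03d", 1:100)
  mk_tab <- function(gene, hit_samples)
    data.frame(gene_id = gene, sample_id = hit_samples,
               chromosome = "chr1", position = 100L)
  tab <- mutation_table(rbind(mk_tab("gSix", samples[1:6]),
                              mk_tab("gFive", samples[1:5])))
  mm <- binarize_mutations(tab, samples, min_freq = 0.05)
  expect_true("gSix" %in% rownames(mm$indicators))    # 0.06 > 0.05
  expect_false("gFive" %in% rownames(mm$indicators))  # 0.05 not > 0.05
  expect_equal(unname(mm$frequency["gSix"]), 0.06)
  expect_error(binarize_mutations(tab, c("other1", "other2"), 0.05),
               "no overlap")
})

test_that("indicator matrix matches hand construction on a toy table", {
  samples <- c("sA", "sB", "sC", "sD")
  tab <- mutation_table(data.frame(
    gene_id = c("g1", "g1", "g2", "g1"),
    sample_id = c("sA", "sC", "sB", "sA"),   # duplicate (g1, sA) collapses
    chromosome = "chr1", position = c(10L, 20L, 30L, 40L)))
  mm <- binarize_mutations(tab, samples, min_freq = 0)
  expect_equal(mm$indicators["g1", ], c(sA = 1L, sB = 0L, sC = 1L, sD = 0L))
  expect_equal(mm$indicators["g2", ], c(sA = 0L, sB = 1L, sC = 0L, sD = 0L))
})

test_that("positional splitting assigns inclusive windows and ignores strays", {
  samples <- sprintf("s%d", 1:6)
  tab <- mutation_table(data.frame(
    gene_id = "GATA3",
    sample_id = c("s1", "s2", "s3", "s4", "s5", "s5", "s6"),
    chromosome = "chr10",
    position = c(100L, 150L, 200L, 250L, 320L, 330L, 999L)))
  windows <- data.frame(chromosome = "chr10",
                        start = c(100L, 200L, 300L),
                        end = c(150L, 260L, 350L),
                        label = c("w1", "w2", "w3"))
  expect_message(mm <- split_by_position(tab, "GATA3", windows, samples),
                 "outside")
  # boundary coordinates are inclusive; counts match hand tally
  expect_equal(unname(rowSums(mm$indicators)), c(2, 2, 1))
  expect_equal(mm$indicators["w1", c("s1", "s2")], c(s1 = 1L, s2 = 1L))
  expect_equal(sum(mm$indicators["w3", ]), 1)  # s5's two hits collapse
  # empty window -> all-zero row
  w_empty <- data.frame(chromosome = "chr10", start = 500L, end = 600L,
                        label = "none")
  mm2 <- suppressMessages(split_by_position(tab, "GATA3", w_empty, samples))
  expect_equal(sum(mm2$indicators), 0)
  # overlapping windows are rejected
  w_bad <- data.frame(chromosome = "chr10", start = c(100L, 140L),
                      end = c(150L, 210L), label = c("a", "b"))
  expect_error(split_by_position(tab, "GATA3", w_bad, samples), "overlap")
})

test_that("association retains genes with a positive significant module correlation", {
  sim <- small_sim()
  per <- lapply(sim$datasets, function(d) dataset_spearman(d))
  net <- reduce_epg(merge_correlations(per, min_datasets = 3), n_edges = 3)
  stats_tab <- gene_meta_stats(sim$datasets)
  truth <- sim$truth$assignment
  rankings <- lapply(split(names(truth)[truth > 0], truth[truth > 0]),
                     modcon_rank, network = net, meta_stats = stats_tab)
  mev <- mev_matrix(sim$datasets[[1]], rankings)
  mut <- generate_mutations(sim$truth, effect_per_module = c(1.5, 0, 0, 0),
                            base_rate = 0.15)
  mm <- binarize_mutations(mut, sim$datasets[[1]]$sample_ids, min_freq = 0.05)
  am <- associate(mev, mm)
  expect_true("mut_M1" %in% am$retained)
  # the module-1 z is the row maximum for the module-1-driven gene
  expect_equal(colnames(am$z)[which.max(am$z["mut_M1", ])], "1")
  # z sign follows rho sign, magnitude from the two-sided p
  g <- am$retained[1]
  k <- which.max(am$z[g, ])
  expect_equal(sign(am$z[g, k]), sign(am$rho[g, colnames(am$z)[k]]))
})

test_that("null mutations are usually dropped; constant indicators give z 0", {
  sim <- small_sim()
  mev_vals <- matrix(rnorm(4 * 60), 4, 60,
                     dimnames = list(1:4, sim$datasets[[1]]$sample_ids))
  mev <- structure(list(values = mev_vals, genes_used = list(),
                        dataset_id = "x"), class = "mev_matrix")
  set.seed(55)
  dropped <- 0L
  for (i in 1:10) {
    ind <- matrix(rbinom(60, 1, 0.2), 1, 60,
                  dimnames = list("gNull", colnames(mev_vals)))
    mm <- structure(list(indicators = ind, frequency = rowMeans(ind)),
                    class = "mutation_matrix")
    am <- associate(mev, mm)
    dropped <- dropped + as.integer(!"gNull" %in% am$retained)
  }
  expect_gte(dropped, 7)  # ~0.815 retention-free probability per replicate
  const <- structure(list(indicators = matrix(1L, 1, 60,
                            dimnames = list("gAll", colnames(mev_vals))),
                          frequency = 1), class = "mutation_matrix")
  am2 <- associate(mev, const)
  expect_equal(unname(am2$rho["gAll", ]), rep(0, 4))
  expect_length(am2$retained, 0)
})

test_that("association is invariant to monotone transforms of the MEVs", {
  set.seed(66)
  samples <- sprintf("s%02d", 1:40)
  mev_vals <- matrix(rnorm(2 * 40), 2, 40, dimnames = list(1:2, samples))
  ind <- matrix(rbinom(40, 1, 0.3), 1, 40, dimnames = list("g", samples))
  mm <- structure(list(indicators = ind, frequency = rowMeans(ind)),
                  class = "mutation_matrix")
  mk <- function(v) structure(list(values = v, genes_used = list(),
                                   dataset_id = "x"), class = "mev_matrix")
  a1 <- associate(mk(mev_vals), mm)
  a2 <- associate(mk(exp(mev_vals)), mm)
  expect_equal(a1$rho, a2$rho, tolerance = 1e-12)
})

test_that("rank_by_mev sorts by MEV with deterministic tie-breaks", {
  mev_row <- c(s1 = 2, s2 = 5, s3 = 2, s4 = -1)
  mut_row <- c(s1 = 1, s2 = 1, s3 = 0, s4 = 0)
  tab <- rank_by_mev(mev_row, mut_row)
  expect_identical(tab$sample_id, c("s2", "s1", "s3", "s4"))  # tie s1 < s3
  expect_identical(tab$mutated, c(1L, 1L, 0L, 0L))
  # all mutations in the top half -> polarized indicator means
  top <- tab$mutated[1:2]; bottom <- tab$mutated[3:4]
  expect_gt(mean(top), mean(bottom))
  expect_gt(attr(tab, "z"), 0)
})
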