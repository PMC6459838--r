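test_that("hypergeometric enrichment matches closed forms and exact enumeration", {
  pop <- sprintf("g%02d", 1:20)
  mod <- pop[1:5]
  # module == signature: single-term tail, p = 1 / C(20, 5)
  res <- hypergeom_enrich(mod, mod, pop)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-14)
  expect_gt(res$z, 0)

  # population 50, signature 10, module 10, overlap 6: brute-force tail
  pop50 <- sprintf("h%02d", 1:50)
  sig <- pop50[1:10]
  mod10 <- c(pop50[1:6], pop50[21:24])
  res2 <- hypergeom_enrich(mod10, sig, pop50)
  oracle <- sum(sapply(6:10, function(k)
    choose(10, k) * choose(40, 10 - k) / choose(50, 10)))
  expect_equal(res2$overlap, 6)
  expect_equal(res2$p_value, oracle, tolerance = 1e-12)

  # zero overlap where overlap is expected: p ~ 1, depletion z <= 0
  res3 <- hypergeom_enrich(pop[1:10], pop[11:20], pop)
  expect_gt(res3$p_value, 0.9)
  expect_lte(res3$z, 0)

  # degenerate cases
  expect_equal(hypergeom_enrich(character(0), mod, pop)$p_value, 1)
  expect_equal(hypergeom_enrich(mod, "not_in_population", pop)$z, 0)
  expect_error(hypergeom_enrich(c(mod, "alien"), mod, pop), "subset")
})

test_that("hypergeometric p equals exact enumeration for all populations <= 30", {
  for (pop_n in c(5, 9, 14, 20, 27, 30)) {
    pop <- sprintf("p%02d", seq_len(pop_n))
    for (sig_n in unique(c(1, pop_n %/% 3, pop_n %/% 2))) {
      for (mod_n in unique(c(2, pop_n %/% 4 + 1, pop_n %/% 2))) {
        for (k in 0:min(sig_n, mod_n)) {
          mod <- c(pop[seq_len(k)],
                   if (mod_n > k) rev(pop)[seq_len(mod_n - k)])
          sig <- pop[seq_len(sig_n)]
          if (length(intersect(mod, sig)) != k) next
          res <- hypergeom_enrich(mod, sig, pop)
          expect_equal(res$p_value,
                       enum_hyper_upper(k, sig_n, mod_n, pop_n),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH adjustment reproduces hand-applied step-up", {
  expect_equal(bh_fdr(0.04), 0.04)
  # hand: 0.04*4/4=.04, 0.03*4/3=.04, 0.02*4/2=.04, 0.01*4/1=.04
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  # input order preserved
  p <- c(0.2, 0.001, 0.03)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"))
})

test_that("normalized entropy is 1 for even sizes and matches the formula for (99,1)", {
  expect_equal(normalized_entropy(rep(20, 5)), 1, tolerance = 1e-14)
  h_direct <- -(0.99 * log2(0.99) + 0.01 * log2(0.01)) / log2(2)
  expect_equal(normalized_entropy(c(99, 1)), h_direct, tolerance = 1e-12)
  expect_equal(h_direct, 0.0807931358959, tolerance = 1e-10)
  # base invariance: ln-based implementation equals an explicit log2 version
  sizes <- c(40, 25, 20, 15)
  p <- sizes / sum(sizes)
  expect_equal(normalized_entropy(sizes),
               -sum(p * log2(p)) / log2(length(p)), tolerance = 1e-12)
  expect_equal(normalized_entropy(100), 0)
})

test_that("MFC is 1 on a block-diagonal z matrix and < 1 with shared enrichment", {
  z <- matrix(0, 10, 4)
  z[cbind(1:10, rep(1:4, length.out = 10))] <- runif(10, 2, 8)
  expect_equal(median_fractional_contribution(z), 1)
  # every signature equally enriched in two modules -> MFC 0.5
  z2 <- matrix(0, 6, 4)
  z2[, 1] <- 3; z2[, 2] <- 3
  expect_equal(median_fractional_contribution(z2), 0.5)
  # depletion (negative z) entries do not enter the row sums
  z3 <- cbind(rep(4, 5), rep(-2, 5), 0, 0)
  expect_equal(median_fractional_contribution(z3), 1)
})

test_that("SCES multiplies ZScoreMS, MFC and entropy; scaling z scales SCES", {
  stats <- pgcna:::sces_matrix_stats
  z <- matrix(c(5, 0, 0, 4, 1, 0, 0, 3, 2), 3, byrow = TRUE)
  s1 <- stats(z)
  s2 <- stats(3 * z)
  expect_equal(s2$zscore_ms, 3 * s1$zscore_ms, tolerance = 1e-12)
  expect_equal(s2$mfc, s1$mfc, tolerance = 1e-12)
})

test_that("sces() filters, takes top-15 per module, and composes the report", {
  sim <- small_sim()
  sigs <- generate_signatures(sim$truth, n_per_module = 5, jitter = 0)
  truth <- sim$truth$assignment[sim$truth$assignment > 0]
  cl <- make_clustering(truth)
  rep <- sces(cl, sigs)
  expect_s3_class(rep, "sces_report")
  expect_equal(rep$sces, rep$zscore_ms * rep$mfc * rep$normalized_entropy)
  # pure module-aligned signatures are each enriched in exactly one module
  expect_equal(rep$mfc, 1, tolerance = 1e-10)
  # top-15 rule: global list size <= 15 * K before dedup
  expect_lte(nrow(rep$top_signatures), 15 * length(cl$module_sizes))
  expect_lte(max(table(rep$top_signatures$module)), 15)
  # z matrix covers the deduplicated global list
  expect_setequal(rownames(rep$z_matrix), unique(rep$top_signatures$signature))
})

test_that("sces() warns and returns 0 when nothing passes the filters", {
  cl <- make_clustering(stats::setNames(rep(1:2, each = 10), sprintf("g%02d", 1:20)))
  sigs <- signature_collection(list(tiny = c("g01", "g02")))  # below min size
  expect_warning(rep <- sces(cl, sigs), "SCES = 0")
  expect_equal(rep$sces, 0)
})

test_that("SCES ranking prefers the planted clustering over a degraded one", {
  sim <- small_sim()
  sigs <- generate_signatures(sim$truth, n_per_module = 5, jitter = 0.1)
  truth <- sim$truth$assignment[sim$truth$assignment > 0]
  good <- make_clustering(truth)
  # degrade: split module 1 arbitrarily in half
  bad_assign <- truth
  m1 <- names(bad_assign)[bad_assign == 1]
  bad_assign[m1[seq_len(length(m1) %/% 2)]] <- max(truth) + 1L
  # and merge modules 3 and 4
  bad_assign[bad_assign == 4] <- 3L
  bad <- make_clustering(bad_assign)
  rk <- rank_clusterings(list(bad, good), sigs)
  expect_equal(rk$order[1], 2)
  expect_gt(rk$scores[2], rk$scores[1])
  # permuting the list leaves the ranking (by identity) unchanged
  rk2 <- rank_clusterings(list(good, bad), sigs)
  expect_equal(rk2$order[1], 1)
  expect_equal(sort(rk$scores), sort(rk2$scores), tolerance = 1e-12)
})
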