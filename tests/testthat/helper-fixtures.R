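# Shared fixture builders. Everything is generated in code; no data files.

make_ds <- function(values, id = "ds1", genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  rownames(values) <- genes %||% sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  expression_dataset(values, id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built merged correlation object (significant wherever rho != 0).
toy_merged <- function(rho, pval = NULL) {
  rho <- as.matrix(rho)
  diag(rho) <- 0
  if (is.null(dimnames(rho)))
    dimnames(rho) <- list(sprintf("g%02d", seq_len(nrow(rho))),
                          sprintf("g%02d", seq_len(nrow(rho))))
  if (is.null(pval)) {
    pval <- matrix(1, nrow(rho), ncol(rho), dimnames = dimnames(rho))
    pval[rho != 0] <- 0.001
    diag(pval) <- 0
  }
  structure(list(gene_ids = rownames(rho), rho = rho, pval = pval,
                 n_datasets = matrix(1L, nrow(rho), ncol(rho),
                                     dimnames = dimnames(rho)),
                 p_cutoff = 0.05, min_datasets = 1L),
            class = "merged_correlation")
}

# Clustering object from a bare assignment (modularity left NA; fine for
# enrichment/SCES paths which never read it).
make_clustering <- function(assignment) {
  assignment <- pgcna:::relabel_assignment(assignment)
  structure(list(assignment = assignment, modularity = NA_real_,
                 run_seed = NA_integer_,
                 module_sizes = table(assignment)),
            class = "pgcna_clustering")
}

# Two disjoint weighted triangles a1-a2-a3 and b1-b2-b3 (unit weights).
two_triangles <- function() {
  rho <- matrix(0, 6, 6, dimnames = list(
    c("a1", "a2", "a3", "b1", "b2", "b3"),
    c("a1", "a2", "a3", "b1", "b2", "b3")))
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    rho[p[1], p[2]] <- 1; rho[p[2], p[1]] <- 1
  }
  reduce_epg(toy_merged(rho), n_edges = 5)
}

# Small planted-module study memoised per test session.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_expression(pgcna_sim_config(
        n_genes = 200, n_modules = 4, n_datasets = 3,
        samples_per_dataset = 60, seed = 11))
      cache <<- sim
    }
    cache
  }
})

# Exact hypergeometric upper-tail oracle by direct enumeration of the
# probability mass function with choose(); independent of phyper.
enum_hyper_upper <- function(k, white, draw, population) {
  if (k <= 0) return(1)
  kk <- k:min(white, draw)
  sum(choose(white, kk) * choose(population - white, draw - kk)) /
    choose(population, draw)
}
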