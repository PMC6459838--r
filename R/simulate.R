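#' Configuration for the synthetic multi-cohort generator
#'
#' The generator emulates the study design the pipeline targets: several
#' expression cohorts sharing the same planted co-expression modules, each
#' cohort re-drawing its own per-sample latent module factors (cohort
#' heterogeneity that the median merge must absorb), plus module-aligned
#' gene signatures, module-driven survival and module-correlated binary
#' mutations.
#'
#' Gene g in module k has expression `baseline_g + loading * f_k +
#' sqrt(1 - loading^2) * noise` on a log2-like scale, so the within-module
#' correlation target is `loading^2`. A fraction of genes belong to no
#' module (pure noise).
#'
#' @param n_genes total genes (default 1000).
#' @param n_modules planted modules (default 8).
#' @param n_datasets cohorts (default 4).
#' @param samples_per_dataset samples per cohort; scalar or vector
#'   (default 120).
#' @param loading latent-factor loading in (0,1) (default 0.75).
#' @param noise_sd residual sd (default `sqrt(1 - loading^2)`, keeping
#'   unit marginal variance).
#' @param null_fraction fraction of module-less genes (default 0.1).
#' @param baseline_range per-gene log2 abundance baselines drawn uniformly
#'   from this range and shared across cohorts (default c(4, 12)).
#' @param seed master seed.
#' @return a `pgcna_sim_config` list.
#' @export
pgcna_sim_config <- function(n_genes = 1000L, n_modules = 8L,
                             n_datasets = 4L, samples_per_dataset = 120L,
                             loading = 0.75,
                             noise_sd = sqrt(1 - loading^2),
                             null_fraction = 0.1,
                             baseline_range = c(4, 12), seed = 1L) {
  stopifnot(n_genes > 0, n_modules > 0, n_datasets > 0,
            all(samples_per_dataset > 0),
            loading > 0, loading < 1, null_fraction >= 0, null_fraction < 1)
  n_null <- round(null_fraction * n_genes)
  if (n_genes - n_null < n_modules)
    stop("module sizes exceed available genes")
  structure(list(n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 n_datasets = as.integer(n_datasets),
                 samples_per_dataset = rep_len(as.integer(samples_per_dataset),
                                               n_datasets),
                 loading = loading, noise_sd = noise_sd,
                 null_fraction = null_fraction,
                 baseline_range = baseline_range,
                 seed = as.integer(seed)),
            class = "pgcna_sim_config")
}

#' Generate synthetic expression cohorts with planted modules
#'
#' @param config a [pgcna_sim_config()].
#' @return list with `datasets` (list of [expression_dataset()]) and
#'   `truth`: `assignment` (gene -> module, 0 for null genes), `factors`
#'   (per cohort, samples x modules latent factor matrix), `baseline`,
#'   and the `config`.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "pgcna_sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  G <- config$n_genes; K <- config$n_modules
  genes <- sprintf("g%04d", seq_len(G))
  n_null <- round(config$null_fraction * G)
  module_of <- c(rep(0L, n_null),
                 rep_len(seq_len(K), G - n_null))
  # shuffle so module membership is not confounded with gene id order
  module_of <- sample(module_of)
  names(module_of) <- genes
  baseline <- stats::setNames(
    stats::runif(G, config$baseline_range[1], config$baseline_range[2]), genes)
  datasets <- vector("list", config$n_datasets)
  factors <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    n <- config$samples_per_dataset[d]
    samples <- sprintf("d%d_s%03d", d, seq_len(n))
    f <- matrix(stats::rnorm(n * K), n, K,
                dimnames = list(samples, paste0("M", seq_len(K))))
    eps <- matrix(stats::rnorm(G * n, sd = config$noise_sd), G, n)
    signal <- matrix(0, G, n)
    in_mod <- module_of > 0
    signal[in_mod, ] <- config$loading * t(f[, module_of[in_mod], drop = FALSE])
    vals <- baseline + signal + eps
    dimnames(vals) <- list(genes, samples)
    datasets[[d]] <- expression_dataset(vals, sprintf("synth%02d", d))
    factors[[d]] <- f
  }
  names(factors) <- vapply(datasets, `[[`, "", "dataset_id")
  list(datasets = datasets,
       truth = list(assignment = module_of, factors = factors,
                    baseline = baseline, config = config))
}

#' Generate module-aligned gene signatures
#'
#' Draws signatures from the planted modules with controlled contamination
#' so clustering-selection scores have a known ordering: a `jitter`
#' fraction of each signature's members is replaced by random genes.
#'
#' @param truth ground truth from [generate_expression()].
#' @param n_per_module signatures per module (default 5).
#' @param size genes per signature (default 20; capped at module size).
#' @param jitter contamination fraction in \[0, 1) (default 0.1).
#' @param seed RNG seed (default: derived from the generator config seed).
#' @return a `signature_collection`.
#' @export
generate_signatures <- function(truth, n_per_module = 5L, size = 20L,
                                jitter = 0.1,
                                seed = truth$config$seed + 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  genes <- names(truth$assignment)
  sigs <- list()
  for (k in seq_len(truth$config$n_modules)) {
    members <- genes[truth$assignment == k]
    for (i in seq_len(n_per_module)) {
      sz <- min(size, length(members))
      core <- sample(members, sz)
      n_swap <- floor(jitter * sz)
      if (n_swap > 0)
        core[seq_len(n_swap)] <- sample(setdiff(genes, core), n_swap)
      sigs[[sprintf("sig_M%d_%02d", k, i)]] <- unique(core)
    }
  }
  signature_collection(sigs, source_tag = "synthetic")
}

#' Generate right-censored survival tables driven by module factors
#'
#' Event times are exponential with log-hazard `log(base_hazard) +
#' sum_k beta_k * f_k` per sample; censoring times are independent
#' exponentials tuned to the requested censoring fraction.
#'
#' @param truth ground truth from [generate_expression()].
#' @param beta_per_module log-hazard coefficients, length `n_modules`
#'   (default all 0).
#' @param base_hazard baseline hazard (default 0.1).
#' @param censoring target censoring fraction in \[0, 1\] (default 0.3).
#' @param seed RNG seed.
#' @return named list of [survival_table()], one per cohort.
#' @export
generate_survival <- function(truth, beta_per_module = NULL,
                              base_hazard = 0.1, censoring = 0.3,
                              seed = truth$config$seed + 2L) {
  K <- truth$config$n_modules
  beta <- beta_per_module %||% rep(0, K)
  stopifnot(length(beta) == K)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  out <- list()
  for (id in names(truth$factors)) {
    f <- truth$factors[[id]]
    hazard <- base_hazard * exp(drop(f %*% beta))
    t_event <- stats::rexp(nrow(f), rate = hazard)
    if (censoring >= 1) {
      time <- stats::rexp(nrow(f), rate = base_hazard)
      event <- rep(0L, nrow(f))
    } else if (censoring <= 0) {
      time <- t_event; event <- rep(1L, nrow(f))
    } else {
      t_cens <- stats::rexp(nrow(f),
                            rate = base_hazard * censoring / (1 - censoring))
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    }
    out[[id]] <- survival_table(
      data.frame(sample_id = rownames(f), time = time, event = event,
                 stringsAsFactors = FALSE), id)
  }
  out
}

#' Generate module-correlated binary mutations
#'
#' For one cohort, synthetic mutated genes are created per module; a
#' sample carries a mutation in such a gene with probability
#' `plogis(qlogis(base_rate) + effect_k * f_k)`. Additional null mutated
#' genes mutate at the base rate independently of any factor. Coordinates
#' come from a toy genome map (one 10 kb locus per mutated gene on chr1).
#'
#' @param truth ground truth from [generate_expression()].
#' @param effect_per_module logit-scale effects, length `n_modules`
#'   (default all 0 = no association).
#' @param base_rate baseline mutation probability (default 0.1).
#' @param n_null_genes module-independent mutated genes (default 3).
#' @param dataset_index which cohort's samples to mutate (default 1).
#' @param seed RNG seed.
#' @return a [mutation_table()] data.frame; gene ids are `mut_M<k>` for
#'   module-driven genes and `mut_null<i>` for null genes.
#' @export
generate_mutations <- function(truth, effect_per_module = NULL,
                               base_rate = 0.1, n_null_genes = 3L,
                               dataset_index = 1L,
                               seed = truth$config$seed + 3L) {
  K <- truth$config$n_modules
  effect <- effect_per_module %||% rep(0, K)
  stopifnot(length(effect) == K)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  f <- truth$factors[[dataset_index]]
  samples <- rownames(f)
  mut_genes <- c(sprintf("mut_M%d", seq_len(K)),
                 if (n_null_genes > 0) sprintf("mut_null%d", seq_len(n_null_genes)))
  locus_start <- 1e6 * seq_along(mut_genes)
  rows <- list()
  if (base_rate > 0) {
    for (i in seq_along(mut_genes)) {
      g <- mut_genes[i]
      k <- if (i <= K) i else 0L
      logit <- stats::qlogis(base_rate) +
        if (k > 0) effect[k] * f[, k] else 0
      hit <- stats::runif(length(samples)) < stats::plogis(logit)
      if (any(hit))
        rows[[g]] <- data.frame(
          gene_id = g, sample_id = samples[hit], chromosome = "chr1",
          position = locus_start[i] +
            sample.int(10000L, sum(hit), replace = TRUE),
          stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), sample_id = character(0),
               chromosome = character(0), position = integer(0))
  rownames(tab) <- NULL
  mutation_table(tab)
}

#' Write a complete synthetic fixture directory
#'
#' Materialises a generated study as plain-text files: one expression TSV
#' per cohort, a GMT signature file, survival TSVs, a mutation TSV and a
#' JSON ground-truth manifest.
#'
#' @param config a [pgcna_sim_config()].
#' @param dir output directory (created).
#' @param ... passed to [generate_signatures()], [generate_survival()],
#'   [generate_mutations()] via their defaults.
#' @return the ground truth, invisibly.
#' @export
write_sim_fixture <- function(config, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_expression(config)
  for (ds in sim$datasets)
    write_expression_tsv(ds, file.path(dir, paste0(ds$dataset_id, ".tsv")))
  sigs <- generate_signatures(sim$truth)
  gmt <- vapply(names(sigs$signatures), function(nm)
    paste(c(nm, "synthetic", sigs$signatures[[nm]]), collapse = "\t"), "")
  writeLines(gmt, file.path(dir, "signatures.gmt"))
  surv <- generate_survival(sim$truth)
  for (id in names(surv))
    utils::write.table(surv[[id]], file.path(dir, paste0(id, "_survival.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  mut <- generate_mutations(sim$truth)
  utils::write.table(mut, file.path(dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(assignment = as.list(sim$truth$assignment),
         seed = config$seed, n_modules = config$n_modules),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(sim$truth)
}
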