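#' Fit a parsimonious gene correlation network model
#'
#' The full pipeline on one or more expression cohorts: (optional)
#' quantile normalisation; per-cohort Spearman correlation over each
#' cohort's most variant genes; median merge across cohorts with a
#' p-value noise filter; edge-per-gene (EPG) reduction to a sparse
#' network; repeated seeded Louvain modularity clustering; selection of
#' the best clustering by SCES when a signature collection is supplied
#' (by modularity otherwise); per-gene cross-cohort meta-statistics
#' (percentile expression, MAD, QCOD, and meta hazard ratios when
#' survival tables are given); ModCon hub ranking per module; and
#' per-cohort module expression values (MEVs) with a merged
#' module-module correlation map.
#'
#' @param datasets an [expression_dataset()] or list of them.
#' @param signatures optional `signature_collection` used for SCES-based
#'   clustering selection and module annotation.
#' @param survival_tables optional named list of [survival_table()]s
#'   (names = dataset ids) for the hazard-ratio meta-analysis.
#' @param epg edges retained per gene (default 3).
#' @param variant_fraction per-cohort fraction of most-variant genes
#'   correlated (default 0.8).
#' @param min_datasets minimum cohorts a gene must appear in to survive
#'   the merge; default `ceiling(D / 3)`, mirroring the reference
#'   analysis's roughly one-third rule.
#' @param p_noise_cutoff correlations with median p above this are zeroed
#'   (default 0.05).
#' @param n_runs,n_keep Louvain runs and runs retained (defaults 100 and
#'   `min(100, n_runs)`; the reference analysis used 10,000 and 100).
#' @param top_hub_genes ModCon genes summed per MEV (default 25).
#' @param normalize quantile-normalize the cohorts first (default TRUE).
#' @param seed base seed for the clustering runs.
#' @param ... passed to [sces()] (e.g. `fdr_cutoff`, `top_n`).
#' @return an object of class `pgcna`; see [print.pgcna()],
#'   [summary.pgcna()], [plot.pgcna()], [predict.pgcna()].
#' @examples
#' sim <- generate_expression(pgcna_sim_config(n_genes = 120, n_modules = 3,
#'                                             n_datasets = 2,
#'                                             samples_per_dataset = 40))
#' fit <- pgcna(sim$datasets, n_runs = 10, seed = 7)
#' fit
#' @export
pgcna <- function(datasets, signatures = NULL, survival_tables = NULL,
                  epg = 3L, variant_fraction = 0.8,
                  min_datasets = NULL, p_noise_cutoff = 0.05,
                  n_runs = 100L, n_keep = min(100L, n_runs),
                  top_hub_genes = 25L, normalize = TRUE, seed = 1L, ...) {
  if (inherits(datasets, "expression_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, TRUE, "expression_dataset")))
  D <- length(datasets)
  min_datasets <- min_datasets %||% max(1L, ceiling(D / 3))
  if (normalize) datasets <- lapply(datasets, quantile_normalize)
  per_dataset <- lapply(datasets, function(d)
    dataset_spearman(d, select_variant_genes(d, variant_fraction)))
  merged <- merge_correlations(per_dataset, min_datasets = min_datasets,
                               p_cutoff = p_noise_cutoff)
  network <- reduce_epg(merged, n_edges = epg)
  clusterings <- multi_run_cluster(network, n_runs = n_runs,
                                   n_keep = n_keep, base_seed = seed)
  if (!is.null(signatures)) {
    ranking <- rank_clusterings(clusterings, signatures, ...)
    best <- ranking$best
    best_sces <- ranking$best_report
    sces_scores <- ranking$scores
  } else {
    best <- clusterings[[1]]
    best_sces <- NULL
    sces_scores <- NULL
  }
  meta <- gene_meta_stats(datasets, survival_tables,
                          genes = merged$gene_ids)
  modules <- split(names(best$assignment), best$assignment)
  rankings <- lapply(modules, modcon_rank, network = network,
                     meta_stats = meta)
  mev <- lapply(datasets, mev_matrix, rankings = rankings,
                top_n = top_hub_genes)
  names(mev) <- vapply(datasets, `[[`, "", "dataset_id")
  module_cor <- if (length(modules) >= 2L) module_correlation(mev) else NULL
  structure(list(
    dataset_ids = vapply(datasets, `[[`, "", "dataset_id"),
    datasets = datasets,
    merged = merged, network = network,
    clusterings = clusterings, best = best,
    sces = best_sces, sces_scores = sces_scores,
    meta_stats = meta, modcon = rankings,
    mev = mev, module_cor = module_cor,
    params = list(epg = epg, variant_fraction = variant_fraction,
                  min_datasets = min_datasets,
                  p_noise_cutoff = p_noise_cutoff, n_runs = n_runs,
                  n_keep = n_keep, top_hub_genes = top_hub_genes,
                  normalize = normalize, seed = seed),
    call = match.call()),
    class = "pgcna")
}

#' @export
print.pgcna <- function(x, ...) {
  cat("Parsimonious gene correlation network\n")
  cat(sprintf("  cohorts: %d (%s)\n", length(x$dataset_ids),
              paste(x$dataset_ids, collapse = ", ")))
  cat(sprintf("  merged genes: %d; EPG%d network: %d edges (%d isolated genes)\n",
              length(x$merged$gene_ids), x$network$epg,
              nrow(x$network$edges), length(x$network$isolated)))
  cat(sprintf("  best clustering: %d modules, Q = %.4f",
              length(x$best$module_sizes), x$best$modularity))
  if (!is.null(x$sces))
    cat(sprintf(", SCES = %.2f", x$sces$sces))
  cat("\n")
  invisible(x)
}

#' Summarize a fitted PGCNA model
#'
#' @param object a `pgcna` fit.
#' @param ... unused.
#' @return a `summary.pgcna` with per-module size, hub gene, median ModCon
#'   and (when available) the top enriched signature.
#' @export
summary.pgcna <- function(object, ...) {
  mods <- names(object$modcon)
  tab <- data.frame(
    module = as.integer(mods),
    size = as.integer(object$best$module_sizes[mods]),
    hub_gene = vapply(object$modcon, function(r)
      if (nrow(r)) r$gene_id[1] else NA_character_, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(object$sces) && nrow(object$sces$top_signatures)) {
    top <- object$sces$top_signatures
    first <- top[!duplicated(top$module), ]
    tab$top_signature <- first$signature[match(tab$module, first$module)]
  }
  structure(list(modules = tab[order(tab$module), ],
                 modularity = object$best$modularity,
                 sces = object$sces, params = object$params,
                 n_genes = length(object$merged$gene_ids),
                 n_edges = nrow(object$network$edges)),
            class = "summary.pgcna")
}

#' @export
print.summary.pgcna <- function(x, ...) {
  cat(sprintf("PGCNA fit: %d genes, %d edges (EPG%d), %d modules, Q = %.4f\n",
              x$n_genes, x$n_edges, x$params$epg, nrow(x$modules),
              x$modularity))
  if (!is.null(x$sces))
    cat(sprintf("SCES = %.3f (ZScoreMS %.2f, MFC %.3f, entropy %.3f)\n",
                x$sces$sces, x$sces$zscore_ms, x$sces$mfc,
                x$sces$normalized_entropy))
  print(x$modules, row.names = FALSE)
  invisible(x)
}

#' Plot a fitted PGCNA model
#'
#' Two base-graphics panels: the log-log degree distribution with the
#' scale-free diagnostic fit, and module sizes of the selected clustering.
#'
#' @param x a `pgcna` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pgcna <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  st <- network_stats(x$network)
  tab <- table(st$degree[st$degree > 0])
  graphics::plot(log10(as.numeric(names(tab))), log10(as.numeric(tab)),
                 xlab = "log10 degree", ylab = "log10 frequency",
                 main = sprintf("Degree distribution (slope %.2f, R2 %.2f)",
                                st$scale_free$slope, st$scale_free$r_squared),
                 pch = 19, ...)
  if (!is.na(st$scale_free$slope))
    graphics::abline(st$scale_free$intercept, st$scale_free$slope, lty = 2)
  graphics::barplot(as.numeric(x$best$module_sizes),
                    names.arg = names(x$best$module_sizes),
                    xlab = "module", ylab = "genes",
                    main = sprintf("Module sizes (Q = %.3f)", x$best$modularity))
  invisible(x)
}

#' Module expression values for new cohorts
#'
#' Applies a fitted model's modules and ModCon hub rankings to unseen
#' expression data (the train-on-compendium / apply-to-new-cohort design):
#' returns the MEV matrix of the new cohort.
#'
#' @param object a `pgcna` fit.
#' @param newdata an [expression_dataset()] (or list of them).
#' @param normalize quantile-normalize the new data first (default TRUE).
#' @param ... unused.
#' @return a `mev_matrix`, or a named list of them for a list input.
#' @export
predict.pgcna <- function(object, newdata, normalize = TRUE, ...) {
  if (inherits(newdata, "expression_dataset")) {
    if (normalize) newdata <- quantile_normalize(newdata)
    return(mev_matrix(newdata, object$modcon,
                      top_n = object$params$top_hub_genes))
  }
  out <- lapply(newdata, predict.pgcna, object = object, normalize = normalize)
  names(out) <- vapply(newdata, `[[`, "", "dataset_id")
  out
}

# Stable module colors: palette index from a deterministic hash of the
# sorted member gene ids, so matched modules across runs share colors.
module_colors <- function(modules) {
  palette <- grDevices::hcl.colors(24, "Dark 3")
  vapply(modules, function(genes) {
    key <- paste(sort(genes), collapse = ",")
    h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% length(palette)
    palette[h + 1L]
  }, "")
}

#' Export a clustered network for external visualization
#'
#' Writes GraphML (Gephi-loadable) plus node/edge TSVs. Nodes carry module
#' label, a stable module color, degree, optional betweenness centrality
#' and any supplied per-gene meta-statistics.
#'
#' @param net a `sparse_network`, or a `pgcna` fit (in which case the
#'   network, best clustering and meta-stats are taken from the fit).
#' @param clustering optional `pgcna_clustering`.
#' @param meta_stats optional data.frame from [gene_meta_stats()].
#' @param dir output directory.
#' @param name file stem (default "network").
#' @param betweenness also compute betweenness centrality (default FALSE).
#' @return the GraphML path, invisibly.
#' @export
export_network <- function(net, clustering = NULL, meta_stats = NULL,
                           dir = ".", name = "network",
                           betweenness = FALSE) {
  if (inherits(net, "pgcna")) {
    clustering <- clustering %||% net$best
    meta_stats <- meta_stats %||% net$meta_stats
    net <- net$network
  }
  stopifnot(inherits(net, "sparse_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- as_igraph(net, include_isolated = TRUE)
  vnames <- igraph::V(g)$name
  igraph::V(g)$degree <- igraph::degree(g)
  if (!is.null(clustering)) {
    lab <- clustering$assignment[vnames]
    igraph::V(g)$module <- ifelse(is.na(lab), 0L, as.integer(lab))
    cols <- module_colors(split(names(clustering$assignment),
                                clustering$assignment))
    igraph::V(g)$color <- ifelse(is.na(lab), "#cccccc",
                                 cols[as.character(lab)])
  }
  if (betweenness)
    igraph::V(g)$betweenness <- igraph::betweenness(g, weights = NA)
  if (!is.null(meta_stats)) {
    idx <- match(vnames, meta_stats$gene_id)
    for (col in c("percentile_expression", "var_across", "var_within",
                  "meta_ln_hr")) {
      if (col %in% names(meta_stats)) {
        v <- meta_stats[[col]][idx]
        v[is.na(v)] <- -1
        g <- igraph::set_vertex_attr(g, col, value = v)
      }
    }
  }
  graphml <- file.path(dir, paste0(name, ".graphml"))
  igraph::write_graph(g, graphml, format = "graphml")
  write_network_tsv(net, file.path(dir, paste0(name, "_edges.tsv")),
                    file.path(dir, paste0(name, "_nodes.tsv")),
                    clustering = clustering, meta_stats = meta_stats)
  invisible(graphml)
}
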