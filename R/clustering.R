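#' Weighted Newman-Girvan modularity of a partition
#'
#' Direct evaluation of Q = sum_c [ w_in_c / m - (s_c / 2m)^2 ], where m is
#' the total edge weight, w_in_c the weight internal to community c and s_c
#' the summed strength (weighted degree) of its members. Only edges with
#' positive weight enter (modularity is undefined for negative weights).
#'
#' @param net a `sparse_network`.
#' @param assignment named vector mapping gene id -> module label; genes
#'   absent from it are ignored (their edges are dropped).
#' @return modularity Q.
#' @export
modularity_q <- function(net, assignment) {
  stopifnot(inherits(net, "sparse_network"))
  edges <- net$edges[net$edges$weight > 0, , drop = FALSE]
  li <- assignment[edges$gene_i]
  lj <- assignment[edges$gene_j]
  ok <- !is.na(li) & !is.na(lj)
  edges <- edges[ok, , drop = FALSE]
  li <- li[ok]; lj <- lj[ok]
  m <- sum(edges$weight)
  if (m <= 0) stop("network has no positive-weight edges among assigned genes")
  labels <- sort(unique(c(li, lj)))
  w_in <- vapply(labels, function(l) sum(edges$weight[li == l & lj == l]), 0)
  strength <- tapply(c(edges$weight, edges$weight), c(li, lj), sum)
  s_tot <- vapply(labels, function(l) strength[[as.character(l)]], 0)
  sum(w_in / m - (s_tot / (2 * m))^2)
}

# Canonical relabelling: modules numbered 1..K by decreasing size, ties by
# the lexicographically smallest member gene id.
relabel_assignment <- function(assignment) {
  assignment <- assignment[order(names(assignment))]
  groups <- split(names(assignment), assignment)
  first_member <- vapply(groups, function(g) min(g), "")
  ord <- order(-lengths(groups), first_member)
  new_label <- integer(length(groups))
  new_label[ord] <- seq_along(groups)
  out <- stats::setNames(new_label[match(assignment, names(groups))],
                         names(assignment))
  out
}

new_clustering <- function(assignment, net, seed) {
  assignment <- relabel_assignment(assignment)
  structure(list(assignment = assignment,
                 modularity = modularity_q(net, assignment),
                 run_seed = seed,
                 module_sizes = table(assignment)),
            class = "pgcna_clustering")
}

#' @export
print.pgcna_clustering <- function(x, ...) {
  cat(sprintf("<pgcna_clustering: %d genes in %d modules, Q = %.4f (seed %s)>\n",
              length(x$assignment), length(x$module_sizes), x$modularity,
              format(x$run_seed)))
  invisible(x)
}

#' Single seeded Louvain clustering of a sparse network
#'
#' One run of the two-phase greedy modularity optimisation (Louvain /
#' FastUnfold). Stochasticity between runs comes from a seeded random
#' permutation of the vertex processing order. Edges with non-positive
#' weight are dropped (with a message); isolated genes are excluded from
#' the partition. Module labels are canonical: 1..K by decreasing size,
#' ties by smallest member gene id.
#'
#' @param net a `sparse_network` with at least one positive-weight edge.
#' @param seed integer seed for this run.
#' @return a `pgcna_clustering`: named `assignment` (gene -> module),
#'   `modularity` (recomputed by [modularity_q()]), `run_seed`,
#'   `module_sizes`.
#' @export
louvain_cluster <- function(net, seed = 1L) {
  stopifnot(inherits(net, "sparse_network"))
  g <- suppressMessages(as_igraph(net, drop_negative = TRUE,
                                  include_isolated = FALSE))
  if (igraph::ecount(g) == 0L) stop("network has no positive-weight edges")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  perm <- sample.int(igraph::vcount(g))
  gp <- igraph::permute(g, perm)
  cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight)
  member <- igraph::membership(cl)
  new_clustering(stats::setNames(as.integer(member), names(member)), net, seed)
}

#' Repeated Louvain clustering, keeping the best runs
#'
#' Runs [louvain_cluster()] `n_runs` times with per-run seeds derived
#' deterministically from `base_seed`, and returns the `n_keep` runs with
#' the highest modularity, sorted descending. Per-run seeds are recorded on
#' each clustering so any single run can be replayed.
#'
#' @param net a `sparse_network`.
#' @param n_runs number of independent runs (the reference analysis used
#'   10,000; default 100).
#' @param n_keep number of top-modularity runs to retain (default
#'   `min(100, n_runs)`).
#' @param base_seed seed from which per-run seeds are spawned.
#' @return list of `pgcna_clustering`, sorted by decreasing modularity.
#' @export
multi_run_cluster <- function(net, n_runs = 100L, n_keep = min(100L, n_runs),
                              base_seed = 1L) {
  stopifnot(n_keep <= n_runs, n_runs >= 1L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(base_seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  runs <- lapply(run_seeds, function(s) louvain_cluster(net, seed = s))
  q <- vapply(runs, `[[`, 0, "modularity")
  runs[order(-q)][seq_len(n_keep)]
}

# Upper-tail hypergeometric p-value P(overlap >= k) for drawing `draw`
# genes from a population containing `white` marked genes. log-space safe.
hyper_upper_p <- function(k, white, draw, population) {
  if (k <= 0) return(1)
  exp(stats::phyper(k - 1, white, population - white, draw,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Module stability across clustering runs
#'
#' For each module of a reference clustering and each comparison run, the
#' maximum-overlap module in that run is found; the overlap count, overlap
#' fraction (of the reference module size) and the hypergeometric p-value
#' of the overlap are recorded. Per-gene stability is the percentage of
#' runs in which the gene lands in the module matched to its reference
#' module; per-module stability is the median overlap fraction.
#'
#' @param reference a `pgcna_clustering` used as the reference partition.
#' @param others list of `pgcna_clustering` over the same gene set.
#' @return a `stability_report`: `per_module` data.frame (module, size,
#'   median_overlap_fraction), `per_gene` named percentage vector, and
#'   `matches` data.frame with one row per (reference module, run).
#' @export
module_stability <- function(reference, others) {
  stopifnot(inherits(reference, "pgcna_clustering"), length(others) >= 1L)
  genes <- names(reference$assignment)
  pop <- length(genes)
  ref_mods <- split(genes, reference$assignment)
  gene_hits <- stats::setNames(numeric(length(genes)), genes)
  rows <- list()
  for (r in seq_along(others)) {
    run <- others[[r]]
    if (!setequal(names(run$assignment), genes))
      stop("clusterings must cover the same gene set")
    run_mods <- split(names(run$assignment), run$assignment)
    for (m in names(ref_mods)) {
      ov <- vapply(run_mods, function(g) length(intersect(g, ref_mods[[m]])), 0L)
      best <- names(ov)[order(-ov, as.integer(names(ov)))][1]
      k <- ov[[best]]
      matched <- intersect(run_mods[[best]], ref_mods[[m]])
      gene_hits[matched] <- gene_hits[matched] + 1
      rows[[length(rows) + 1L]] <- data.frame(
        module = as.integer(m), run = r, matched_module = as.integer(best),
        overlap = k,
        overlap_fraction = k / length(ref_mods[[m]]),
        p_value = hyper_upper_p(k, length(run_mods[[best]]),
                                length(ref_mods[[m]]), pop),
        stringsAsFactors = FALSE)
    }
  }
  matches <- do.call(rbind, rows)
  per_module <- do.call(rbind, lapply(split(matches, matches$module), function(d)
    data.frame(module = d$module[1],
               size = length(ref_mods[[as.character(d$module[1])]]),
               median_overlap_fraction = stats::median(d$overlap_fraction))))
  rownames(per_module) <- NULL
  structure(list(per_module = per_module,
                 per_gene = 100 * gene_hits / length(others),
                 matches = matches,
                 n_runs = length(others)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report: %d modules over %d runs, median gene stability %.1f%%>\n",
              nrow(x$per_module), x$n_runs, stats::median(x$per_gene)))
  invisible(x)
}

#' Write a clustering as TSV plus a JSON run manifest
#'
#' @param clustering a `pgcna_clustering`.
#' @param tsv_path two-column gene/module table destination.
#' @param manifest_path optional JSON manifest (seed, modularity, module
#'   sizes).
#' @export
write_clustering <- function(clustering, tsv_path, manifest_path = NULL) {
  stopifnot(inherits(clustering, "pgcna_clustering"))
  tab <- data.frame(gene_id = names(clustering$assignment),
                    module = unname(clustering$assignment))
  tab <- tab[order(tab$module, tab$gene_id), ]
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(manifest_path)) {
    manifest <- list(run_seed = clustering$run_seed,
                     modularity = clustering$modularity,
                     module_sizes = as.list(clustering$module_sizes))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}

#' Adjusted Rand index between two partitions
#'
#' Closed-form ARI from the contingency table; used to score recovery of
#' planted modules against ground truth.
#'
#' @param a,b partition label vectors (named vectors are matched by name).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
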