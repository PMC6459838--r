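#' Parsimonious edge-per-gene (EPG) reduction
#'
#' For every gene only its `n_edges` most correlated partners are retained
#' (ranked by signed correlation, descending; zeroed entries from the
#' p-value noise filter are never candidates). Retention is then
#' symmetrized as the union of nominations: an edge survives if either
#' endpoint nominated it. Edge weights are the merged correlation values,
#' unscaled. Genes with no significant correlation at all remain in the
#' node list as isolated nodes.
#'
#' @param merged a `merged_correlation` from [merge_correlations()].
#' @param n_edges edges retained per gene (EPG); 3 to 10 recommended.
#' @param rank_by `"signed"` (default) ranks partners by correlation value;
#'   `"absolute"` ranks by |correlation|.
#' @return a `sparse_network`: list with `gene_ids`, an `edges` data.frame
#'   (`gene_i`, `gene_j`, `weight`, with `gene_i < gene_j`), `epg`, and
#'   `isolated` (ids of genes with zero retained edges).
#' @export
reduce_epg <- function(merged, n_edges = 3L, rank_by = c("signed", "absolute")) {
  stopifnot(inherits(merged, "merged_correlation"))
  rank_by <- match.arg(rank_by)
  genes <- merged$gene_ids
  G <- length(genes)
  if (G < 2L) stop("merged correlation matrix is empty")
  n_edges <- as.integer(n_edges)
  if (n_edges < 1L) stop("n_edges must be >= 1")
  if (n_edges < 3L || n_edges > 10L)
    warning("EPG outside the recommended 3..10 range (", n_edges, ")")
  from <- integer(0); to <- integer(0)
  for (i in seq_len(G)) {
    row <- merged$rho[i, ]
    cand <- which(row != 0)
    cand <- cand[cand != i]
    if (length(cand) == 0L) next
    key <- if (rank_by == "signed") row[cand] else abs(row[cand])
    ord <- order(-key, genes[cand])
    keep <- cand[ord][seq_len(min(n_edges, length(cand)))]
    from <- c(from, rep.int(i, length(keep)))
    to <- c(to, keep)
  }
  if (length(from) == 0L) {
    edges <- data.frame(gene_i = character(0), gene_j = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  } else {
    # canonical orientation by gene id (not matrix index), so output is
    # independent of gene ordering
    na <- genes[from]; nb <- genes[to]
    gi <- pmin(na, nb); gj <- pmax(na, nb)
    w <- merged$rho[cbind(from, to)]
    dup <- duplicated(paste(gi, gj, sep = "\r"))
    gi <- gi[!dup]; gj <- gj[!dup]; w <- w[!dup]
    ord <- order(gi, gj)
    edges <- data.frame(gene_i = gi[ord], gene_j = gj[ord], weight = w[ord],
                        stringsAsFactors = FALSE)
  }
  connected <- unique(c(edges$gene_i, edges$gene_j))
  structure(list(gene_ids = genes, edges = edges, epg = n_edges,
                 rank_by = rank_by,
                 isolated = setdiff(genes, connected)),
            class = "sparse_network")
}

#' @export
print.sparse_network <- function(x, ...) {
  cat(sprintf("<sparse_network: EPG%d, %d genes, %d edges, %d isolated>\n",
              x$epg, length(x$gene_ids), nrow(x$edges), length(x$isolated)))
  invisible(x)
}

#' Convert a sparse network to an igraph graph
#'
#' @param net a `sparse_network`.
#' @param drop_negative drop edges with non-positive weight (required for
#'   modularity clustering); the number dropped is reported via a message.
#' @param include_isolated keep isolated genes as degree-0 vertices.
#' @return an igraph undirected weighted graph.
#' @export
as_igraph <- function(net, drop_negative = FALSE, include_isolated = TRUE) {
  stopifnot(inherits(net, "sparse_network"))
  edges <- net$edges
  if (drop_negative) {
    n_neg <- sum(edges$weight <= 0)
    if (n_neg > 0) {
      message(n_neg, " non-positive-weight edge(s) dropped before clustering")
      edges <- edges[edges$weight > 0, , drop = FALSE]
    }
  }
  verts <- if (include_isolated) net$gene_ids else
    unique(c(edges$gene_i, edges$gene_j))
  igraph::graph_from_data_frame(
    edges[, c("gene_i", "gene_j", "weight")],
    directed = FALSE, vertices = sort(verts))
}

# Least-squares fit of log10(count) on log10(degree) over distinct positive
# degrees: the scale-free diagnostic. Returns slope, intercept and R^2.
loglog_degree_fit <- function(degrees) {
  degrees <- degrees[degrees > 0]
  if (length(degrees) == 0L)
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_))
  tab <- table(degrees)
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  if (length(x) < 3L)
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_))
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Topology summary of a sparse network
#'
#' Per-node degree, connected-component count, fraction of genes with at
#' least one edge, and the scale-free diagnostic: a linear fit of
#' log10 frequency against log10 degree over the distinct positive degrees,
#' reported as slope and R-squared.
#'
#' @param net a `sparse_network`.
#' @return list with `degree` (named vector over all genes, 0 for isolated),
#'   `n_components` (among connected genes), `connected_fraction`, and
#'   `scale_free` (slope, intercept, r_squared).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "sparse_network"))
  if (length(net$gene_ids) == 0L) stop("empty network")
  g <- as_igraph(net, include_isolated = TRUE)
  deg <- igraph::degree(g)
  deg <- deg[net$gene_ids]
  connected <- names(deg)[deg > 0]
  n_comp <- if (length(connected) > 0)
    igraph::count_components(igraph::induced_subgraph(g, connected)) else 0L
  list(degree = deg,
       n_components = n_comp,
       connected_fraction = length(connected) / length(net$gene_ids),
       scale_free = loglog_degree_fit(deg))
}

#' Write a network as edge and node TSV files
#'
#' Gephi-compatible flat files: an edge list (`gene_i`, `gene_j`, `weight`)
#' and a node list (`gene_id`, `degree`, plus module labels and meta-stat
#' columns when supplied).
#'
#' @param net a `sparse_network`.
#' @param edge_path,node_path output paths.
#' @param clustering optional `pgcna_clustering` supplying module labels.
#' @param meta_stats optional data.frame from [gene_meta_stats()] merged in
#'   by `gene_id`.
#' @export
write_network_tsv <- function(net, edge_path, node_path,
                              clustering = NULL, meta_stats = NULL) {
  stopifnot(inherits(net, "sparse_network"))
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  deg <- network_stats(net)$degree
  nodes <- data.frame(gene_id = net$gene_ids,
                      degree = unname(deg[net$gene_ids]),
                      stringsAsFactors = FALSE)
  if (!is.null(clustering)) {
    stopifnot(inherits(clustering, "pgcna_clustering"))
    nodes$module <- unname(clustering$assignment[nodes$gene_id])
  }
  if (!is.null(meta_stats))
    nodes <- merge(nodes, meta_stats, by = "gene_id", all.x = TRUE, sort = FALSE)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(node_path)
}
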