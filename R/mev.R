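#' ModCon hub ranking of a module's genes
#'
#' ModCon = connectivity^2 * percentileExpression * VarWithin *
#' (100 - VarAcross) / 100, where connectivity is the sum of a gene's
#' retained intra-module edge weights (floored at 0 before squaring),
#' percentile expression is on a 0-100 scale, VarWithin is the median QCOD
#' (0-1) and VarAcross the MAD of per-dataset percentiles (0-100). The
#' score rewards well-connected genes that vary across patients but are
#' stable across datasets. Genes are returned sorted by decreasing ModCon,
#' ties broken by gene id.
#'
#' @param module_genes character vector of the module's genes.
#' @param network a `sparse_network` (connectivity sums its retained
#'   edges).
#' @param meta_stats data.frame from [gene_meta_stats()].
#' @return data.frame gene_id, connectivity, modcon, sorted by decreasing
#'   modcon.
#' @export
modcon_rank <- function(module_genes, network, meta_stats) {
  stopifnot(length(module_genes) >= 1L, inherits(network, "sparse_network"))
  known <- intersect(module_genes, meta_stats$gene_id)
  if (length(known) < length(module_genes))
    warning(length(module_genes) - length(known),
            " module gene(s) lack meta-stats and were excluded")
  edges <- network$edges
  intra <- edges$gene_i %in% known & edges$gene_j %in% known
  conn <- stats::setNames(numeric(length(known)), known)
  if (any(intra)) {
    e <- edges[intra, ]
    add <- tapply(c(e$weight, e$weight), c(e$gene_i, e$gene_j), sum)
    conn[names(add)] <- add
  }
  ms <- meta_stats[match(known, meta_stats$gene_id), ]
  conn_pos <- pmax(conn, 0)
  modcon <- conn_pos^2 * ms$percentile_expression * ms$var_within *
    (100 - ms$var_across) / 100
  out <- data.frame(gene_id = known, connectivity = unname(conn),
                    modcon = unname(modcon), stringsAsFactors = FALSE)
  out[order(-out$modcon, out$gene_id), , drop = FALSE]
}

#' Module expression value (MEV) of one module in one dataset
#'
#' Takes the `top_n` highest-ModCon genes of the module that are present
#' in the dataset, z-scores each gene's (quantile-normalized, log2)
#' expression across samples using the population standard deviation, and
#' sums the z-scores per sample. Zero-variance genes are skipped and
#' replaced by the next-ranked gene.
#'
#' @param dataset an [expression_dataset()].
#' @param module_ranking data.frame from [modcon_rank()].
#' @param top_n hub genes used (default 25).
#' @return list with `mev` (named vector over samples) and `genes_used`;
#'   NULL if no ranked gene is present in the dataset.
#' @export
compute_mev <- function(dataset, module_ranking, top_n = 25L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  candidates <- module_ranking$gene_id[module_ranking$gene_id %in% dataset$gene_ids]
  if (length(candidates) == 0L) return(NULL)
  used <- character(0)
  z_sum <- numeric(ncol(dataset$values))
  for (g in candidates) {
    if (length(used) >= top_n) break
    x <- dataset$values[g, ]
    mu <- mean(x, na.rm = TRUE)
    sdv <- sqrt(mean((x - mu)^2, na.rm = TRUE))  # population sd (ddof 0)
    if (is.na(sdv) || sdv == 0) next
    z <- (x - mu) / sdv
    z[is.na(z)] <- 0
    z_sum <- z_sum + z
    used <- c(used, g)
  }
  if (length(used) == 0L) return(NULL)
  list(mev = stats::setNames(z_sum, dataset$sample_ids), genes_used = used)
}

#' MEV matrix of all modules for one dataset
#'
#' @param dataset an [expression_dataset()].
#' @param rankings named list of [modcon_rank()] tables, one per module
#'   label.
#' @param top_n hub genes per module (default 25).
#' @return a `mev_matrix`: `values` (modules x samples), `genes_used`
#'   (per-module character vectors), `dataset_id`.
#' @export
mev_matrix <- function(dataset, rankings, top_n = 25L) {
  rows <- lapply(rankings, function(r) compute_mev(dataset, r, top_n))
  missing <- names(rankings)[vapply(rows, is.null, TRUE)]
  if (length(missing) > 0)
    message("module(s) with no usable genes in '", dataset$dataset_id,
            "': ", paste(missing, collapse = ", "))
  keep <- !vapply(rows, is.null, TRUE)
  vals <- do.call(rbind, lapply(rows[keep], `[[`, "mev"))
  rownames(vals) <- names(rankings)[keep]
  structure(list(values = vals,
                 genes_used = lapply(rows[keep], `[[`, "genes_used"),
                 dataset_id = dataset$dataset_id),
            class = "mev_matrix")
}

#' @export
print.mev_matrix <- function(x, ...) {
  cat(sprintf("<mev_matrix '%s': %d modules x %d samples>\n",
              x$dataset_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Merged module-module correlation map
#'
#' Spearman correlations between all module MEV pairs within each dataset,
#' merged across datasets as the median correlation and median p-value;
#' correlations with median p above `p_cutoff` are set to 0. The diagonal
#' is 1.
#'
#' @param mev_list list of `mev_matrix`, one per dataset.
#' @param p_cutoff noise filter (default 0.05).
#' @return list with `rho`, `pval` (module x module) and `n_datasets`.
#' @export
module_correlation <- function(mev_list, p_cutoff = 0.05) {
  stopifnot(length(mev_list) >= 1L)
  mods <- sort(unique(unlist(lapply(mev_list, function(m) rownames(m$values)))))
  K <- length(mods)
  D <- length(mev_list)
  rho_a <- array(NA_real_, c(K, K, D))
  p_a <- array(NA_real_, c(K, K, D))
  for (d in seq_len(D)) {
    v <- mev_list[[d]]$values
    present <- match(rownames(v), mods)
    if (nrow(v) < 2L) next
    sp <- spearman_matrix(v)
    rho_a[present, present, d] <- sp$rho
    p_a[present, present, d] <- sp$pval
  }
  rho <- apply(rho_a, c(1, 2), stats::median, na.rm = TRUE)
  pval <- apply(p_a, c(1, 2), stats::median, na.rm = TRUE)
  ndat <- apply(!is.na(rho_a), c(1, 2), sum)
  rho[is.na(rho)] <- 0
  pval[is.na(pval)] <- 1
  rho[pval > p_cutoff] <- 0
  diag(rho) <- 1
  diag(pval) <- 0
  dimnames(rho) <- dimnames(pval) <- dimnames(ndat) <- list(mods, mods)
  list(rho = rho, pval = pval, n_datasets = ndat)
}

#' Write an MEV matrix as TSV plus a gene manifest
#'
#' @param mev a `mev_matrix`.
#' @param tsv_path modules x samples table destination.
#' @param manifest_path optional JSON listing the genes used per module.
#' @export
write_mev <- function(mev, tsv_path, manifest_path = NULL) {
  stopifnot(inherits(mev, "mev_matrix"))
  tab <- data.frame(module = rownames(mev$values), mev$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(manifest_path))
    jsonlite::write_json(mev$genes_used, manifest_path, auto_unbox = FALSE)
  invisible(tsv_path)
}
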