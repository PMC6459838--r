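#' Select the most variant genes of a dataset
#'
#' Returns the `ceil(fraction * G)` genes with the highest per-gene variance
#' (computed over non-missing values). Ties are broken deterministically by
#' gene id, so the selection does not depend on row order.
#'
#' @param dataset an [expression_dataset()].
#' @param fraction fraction of genes to keep, in (0, 1]; default 0.8.
#' @return character vector of selected gene ids (sorted).
#' @export
select_variant_genes <- function(dataset, fraction = 0.8) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  g <- nrow(dataset$values)
  if (g == 0L) stop("empty dataset")
  v <- apply(dataset$values, 1, stats::var, na.rm = TRUE)
  n_keep <- ceiling(fraction * g)
  ord <- order(-v, names(v))
  sort(names(v)[ord][seq_len(n_keep)])
}

# Spearman rho and t-approximation p-values for all row pairs of a matrix.
# Ties receive average ranks; rows with zero variance get NA rho/p.
spearman_matrix <- function(values) {
  n <- ncol(values)
  rho <- stats::cor(t(values), method = "spearman", use = "everything")
  # t approximation: t = rho * sqrt((n-2)/(1-rho^2)), two-sided
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval[abs(r) >= 1 - 1e-15] <- 0
  diag(pval) <- 0
  list(rho = rho, pval = pval)
}

#' Spearman correlation matrices for one dataset
#'
#' Computes all-pairs Spearman rank correlations (average ranks for ties)
#' over the requested genes, with two-sided p-values from the
#' t-approximation to Spearman's statistic. Genes with zero variance have
#' undefined correlations and are recorded as missing.
#'
#' @param dataset an [expression_dataset()].
#' @param genes gene ids to correlate (default: all genes in the dataset);
#'   ids absent from the dataset are ignored.
#' @return list with `gene_ids`, symmetric matrices `rho` (unit diagonal)
#'   and `pval`, and `n_samples`.
#' @export
dataset_spearman <- function(dataset, genes = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  genes <- if (is.null(genes)) dataset$gene_ids else
    intersect(genes, dataset$gene_ids)
  genes <- sort(genes)
  if (length(genes) < 2L) stop("need >= 2 genes to correlate")
  n <- ncol(dataset$values)
  if (n < 5L)
    warning("dataset '", dataset$dataset_id, "' has ", n,
            " samples; Spearman p-values are unreliable below 5")
  vals <- dataset$values[genes, , drop = FALSE]
  sp <- spearman_matrix(vals)
  constant <- apply(vals, 1, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2L || stats::sd(v) == 0
  })
  if (any(constant)) {
    sp$rho[constant, ] <- NA_real_
    sp$rho[, constant] <- NA_real_
    sp$pval[constant, ] <- NA_real_
    sp$pval[, constant] <- NA_real_
  }
  diag(sp$rho) <- 1
  diag(sp$pval) <- 0
  dimnames(sp$rho) <- dimnames(sp$pval) <- list(genes, genes)
  list(gene_ids = genes, rho = sp$rho, pval = sp$pval, n_samples = n)
}

#' Merge per-dataset correlation matrices
#'
#' Combines per-dataset Spearman results into a single median correlation
#' and median p-value matrix: for every gene pair the median is taken
#' across the datasets containing both genes. Genes present in fewer than
#' `min_datasets` datasets are removed, and the noise filter then zeroes
#' every correlation whose median p-value exceeds `p_cutoff`.
#'
#' The merge streams over row blocks so peak memory stays at
#' O(block x G x D) rather than G x G x D.
#'
#' @param per_dataset list of results from [dataset_spearman()].
#' @param min_datasets minimum number of datasets a gene must appear in.
#' @param p_cutoff median p-value above which correlations are set to 0
#'   (default 0.05).
#' @param block_size rows per streamed block (default 256).
#' @return a `merged_correlation`: list with `gene_ids`, symmetric matrices
#'   `rho` (diagonal 0), `pval`, and integer matrix `n_datasets`.
#' @export
merge_correlations <- function(per_dataset, min_datasets = 1L,
                               p_cutoff = 0.05, block_size = 256L) {
  stopifnot(length(per_dataset) >= 1L, min_datasets >= 1L)
  gene_count <- table(unlist(lapply(per_dataset, `[[`, "gene_ids")))
  genes <- sort(names(gene_count)[gene_count >= min_datasets])
  if (length(genes) < 2L)
    stop("fewer than 2 genes present in >= ", min_datasets, " datasets")
  G <- length(genes)
  D <- length(per_dataset)
  rho <- matrix(0, G, G, dimnames = list(genes, genes))
  pval <- matrix(1, G, G, dimnames = list(genes, genes))
  ndat <- matrix(0L, G, G, dimnames = list(genes, genes))
  # per-dataset index of each merged gene (NA if absent)
  idx <- lapply(per_dataset, function(d) match(genes, d$gene_ids))
  for (start in seq(1L, G, by = block_size)) {
    rows <- start:min(start + block_size - 1L, G)
    nb <- length(rows)
    rho_stack <- array(NA_real_, c(nb, G, D))
    p_stack <- array(NA_real_, c(nb, G, D))
    for (d in seq_len(D)) {
      ri <- idx[[d]][rows]
      ci <- idx[[d]]
      ok_r <- !is.na(ri)
      ok_c <- !is.na(ci)
      if (!any(ok_r) || !any(ok_c)) next
      rho_stack[ok_r, ok_c, d] <- per_dataset[[d]]$rho[ri[ok_r], ci[ok_c]]
      p_stack[ok_r, ok_c, d] <- per_dataset[[d]]$pval[ri[ok_r], ci[ok_c]]
    }
    rho[rows, ] <- apply(rho_stack, c(1, 2), stats::median, na.rm = TRUE)
    pval[rows, ] <- apply(p_stack, c(1, 2), stats::median, na.rm = TRUE)
    ndat[rows, ] <- apply(!is.na(rho_stack), c(1, 2), sum)
  }
  rho[is.na(rho)] <- 0
  pval[is.na(pval)] <- 1
  rho[pval > p_cutoff] <- 0
  diag(rho) <- 0
  diag(pval) <- 0
  structure(list(gene_ids = genes, rho = rho, pval = pval,
                 n_datasets = ndat, p_cutoff = p_cutoff,
                 min_datasets = as.integer(min_datasets)),
            class = "merged_correlation")
}

#' @export
print.merged_correlation <- function(x, ...) {
  nz <- sum(x$rho[upper.tri(x$rho)] != 0)
  cat(sprintf("<merged_correlation: %d genes, %d significant pairs (p <= %g)>\n",
              length(x$gene_ids), nz, x$p_cutoff))
  invisible(x)
}

#' Export the upper triangle of a merged correlation matrix as TSV
#'
#' @param merged a `merged_correlation`.
#' @param path output path.
#' @param nonzero_only write only pairs surviving the noise filter
#'   (default TRUE).
#' @export
write_correlation_tsv <- function(merged, path, nonzero_only = TRUE) {
  ut <- upper.tri(merged$rho)
  keep <- if (nonzero_only) ut & merged$rho != 0 else ut
  ij <- which(keep, arr.ind = TRUE)
  tab <- data.frame(gene_i = merged$gene_ids[ij[, 1]],
                    gene_j = merged$gene_ids[ij[, 2]],
                    rho = merged$rho[keep],
                    pval = merged$pval[keep],
                    n_datasets = merged$n_datasets[keep])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
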