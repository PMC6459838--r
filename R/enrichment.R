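#' Hypergeometric enrichment of a gene set in a module
#'
#' One-sided upper-tail hypergeometric test: the draw is the module's
#' genes, the successes are the signature's genes, the population is the
#' genes on the platform. The tail is evaluated in log space so extreme
#' enrichments do not underflow. The z-score is the signed standard-normal
#' quantile of the one-sided enrichment p-value (positive for enrichment,
#' negative for depletion).
#'
#' @param module_genes character vector (must be a subset of the
#'   population).
#' @param signature_genes character vector; intersected with the population.
#' @param population_genes character vector: the gene universe.
#' @return list with `overlap`, `module_size`, `signature_size` (within the
#'   population), `population_size`, `p_value`, `z`.
#' @export
hypergeom_enrich <- function(module_genes, signature_genes, population_genes) {
  population_genes <- unique(population_genes)
  module_genes <- unique(module_genes)
  if (length(setdiff(module_genes, population_genes)) > 0)
    stop("module genes must be a subset of the population")
  sig <- intersect(unique(signature_genes), population_genes)
  k <- length(intersect(module_genes, sig))
  n_pop <- length(population_genes)
  n_mod <- length(module_genes)
  n_sig <- length(sig)
  if (n_mod == 0L || n_sig == 0L) {
    return(list(overlap = 0L, module_size = n_mod, signature_size = n_sig,
                population_size = n_pop, p_value = 1, z = 0))
  }
  log_p <- stats::phyper(k - 1, n_sig, n_pop - n_sig, n_mod,
                         lower.tail = FALSE, log.p = TRUE)
  z <- stats::qnorm(log_p, lower.tail = FALSE, log.p = TRUE)
  list(overlap = k, module_size = n_mod, signature_size = n_sig,
       population_size = n_pop, p_value = exp(log_p), z = z)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure with monotonicity enforcement; the input
#' order is preserved.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return vector of q-values in the same order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Normalized Shannon entropy of module sizes
#'
#' H_n(p) = -sum_i p_i log(p_i) / log(n) over the module-size proportions,
#' where n is the number of modules. Equals 1 for even module sizes and
#' falls towards 0 with increasing skew. The log base cancels; natural logs
#' are used. A single-module partition is defined to have entropy 0
#' (maximal skew).
#'
#' @param sizes positive module sizes (or proportions).
#' @return entropy in \[0, 1\].
#' @export
normalized_entropy <- function(sizes) {
  sizes <- sizes[sizes > 0]
  n <- length(sizes)
  if (n == 0L) stop("no non-empty modules")
  if (n == 1L) return(0)
  p <- sizes / sum(sizes)
  -sum(p * log(p)) / log(n)
}

#' Per-module signature enrichment table
#'
#' Tests every signature against every module of a clustering and applies
#' BH FDR within each module.
#'
#' @param clustering a `pgcna_clustering`.
#' @param signatures a `signature_collection`.
#' @param population gene universe (defaults to the clustered genes).
#' @param min_size,max_size signature size bounds (within the population);
#'   signatures outside \[5, 1000\] are not tested by default.
#' @return data.frame with columns module, signature, overlap,
#'   signature_size, module_size, population_size, p_value, fdr, z.
#' @export
module_enrichment <- function(clustering, signatures,
                              population = names(clustering$assignment),
                              min_size = 5L, max_size = 1000L) {
  stopifnot(inherits(clustering, "pgcna_clustering"),
            inherits(signatures, "signature_collection"))
  population <- unique(population)
  sig_in_pop <- lapply(signatures$signatures, intersect, population)
  keep <- lengths(sig_in_pop) >= min_size & lengths(sig_in_pop) <= max_size
  sig_in_pop <- sig_in_pop[keep]
  mods <- split(names(clustering$assignment), clustering$assignment)
  if (length(sig_in_pop) == 0L)
    return(data.frame(module = integer(0), signature = character(0),
                      overlap = integer(0), signature_size = integer(0),
                      module_size = integer(0), population_size = integer(0),
                      p_value = numeric(0), fdr = numeric(0), z = numeric(0),
                      stringsAsFactors = FALSE))
  rows <- list()
  for (m in names(mods)) {
    mg <- intersect(mods[[m]], population)
    res <- lapply(sig_in_pop, function(sg) hypergeom_enrich(mg, sg, population))
    p <- vapply(res, `[[`, 0, "p_value")
    rows[[m]] <- data.frame(
      module = as.integer(m),
      signature = names(sig_in_pop) %||% character(0),
      overlap = vapply(res, `[[`, 0L, "overlap"),
      signature_size = vapply(res, `[[`, 0L, "signature_size"),
      module_size = length(mg),
      population_size = length(population),
      p_value = p,
      fdr = bh_fdr(p),
      z = vapply(res, `[[`, 0, "z"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scaled cluster enrichment score (SCES) of a clustering
#'
#' Scores how well a clustering separates known biology. Per module,
#' enriched signatures (size within \[`min_size`, `max_size`\], FDR below
#' `fdr_cutoff`) are ranked by FDR and the top `top_n` enter a global
#' signature list. Over the deduplicated global list a signature x module
#' z-score matrix is built; each signature's fractional contribution is its
#' maximum z divided by its summed z (over modules with positive z), and
#' MFC is the median fractional contribution (1 = every signature enriched
#' in a single module). ZScoreMS is the summed per-signature maximum z.
#' Module-size evenness enters as the normalized Shannon entropy.
#'
#' SCES = ZScoreMS * MFC * normalized entropy.
#'
#' @param clustering a `pgcna_clustering`.
#' @param signatures a `signature_collection`.
#' @param population gene universe (defaults to the clustered genes).
#' @param fdr_cutoff FDR threshold for a signature to count (default 0.05).
#' @param top_n signatures added to the global list per module (default 15).
#' @param min_size,max_size signature size bounds (defaults 5 and 1000).
#' @return an `sces_report`: `sces`, `zscore_ms`, `mfc`,
#'   `normalized_entropy`, the z-score matrix `z_matrix` (global signatures
#'   x modules), the per-module top signature table `top_signatures`, and
#'   the full `enrichment` table.
#' @export
sces <- function(clustering, signatures,
                 population = names(clustering$assignment),
                 fdr_cutoff = 0.05, top_n = 15L,
                 min_size = 5L, max_size = 1000L) {
  enr <- module_enrichment(clustering, signatures, population,
                           min_size = min_size, max_size = max_size)
  ent <- normalized_entropy(as.numeric(clustering$module_sizes))
  hits <- enr[!is.na(enr$fdr) & enr$fdr < fdr_cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) {
    warning("no signature passed the size and FDR filters; SCES = 0")
    return(structure(list(sces = 0, zscore_ms = 0, mfc = NA_real_,
                          normalized_entropy = ent,
                          z_matrix = NULL, top_signatures = hits,
                          enrichment = enr),
                     class = "sces_report"))
  }
  top <- do.call(rbind, lapply(split(hits, hits$module), function(d) {
    d <- d[order(d$fdr, d$p_value, d$signature), , drop = FALSE]
    utils::head(d, top_n)
  }))
  global <- unique(top$signature)
  mods <- sort(unique(enr$module))
  zmat <- matrix(0, length(global), length(mods),
                 dimnames = list(global, as.character(mods)))
  sub <- enr[enr$signature %in% global, ]
  zmat[cbind(sub$signature, as.character(sub$module))] <- sub$z
  stats <- sces_matrix_stats(zmat)
  structure(list(sces = stats$zscore_ms * stats$mfc * ent,
                 zscore_ms = stats$zscore_ms, mfc = stats$mfc,
                 normalized_entropy = ent, z_matrix = zmat,
                 top_signatures = top, enrichment = enr),
            class = "sces_report")
}

# MFC and ZScoreMS from a signature x module z matrix. Fractional
# contributions use positive z entries only; rows without a positive entry
# are dropped from the MFC median.
sces_matrix_stats <- function(zmat) {
  pos <- pmax(zmat, 0)
  row_max <- apply(zmat, 1, max)
  row_pos_sum <- rowSums(pos)
  has_pos <- row_pos_sum > 0
  frac <- row_max[has_pos] / row_pos_sum[has_pos]
  list(zscore_ms = sum(row_max),
       mfc = if (any(has_pos)) stats::median(frac) else NA_real_,
       fractional_contribution = frac)
}

#' Median fractional contribution (MFC) of a z-score matrix
#'
#' Convenience wrapper exposing the MFC component of [sces()] for an
#' arbitrary signature x module z matrix.
#'
#' @param zmat numeric matrix, signatures in rows, modules in columns.
#' @return the median over signatures of max(z) / sum(positive z).
#' @export
median_fractional_contribution <- function(zmat) {
  sces_matrix_stats(as.matrix(zmat))$mfc
}

#' @export
print.sces_report <- function(x, ...) {
  cat(sprintf("<sces_report: SCES = %.3f (ZScoreMS %.2f, MFC %.3f, entropy %.3f)>\n",
              x$sces, x$zscore_ms, x$mfc, x$normalized_entropy))
  invisible(x)
}

#' Rank clusterings by SCES
#'
#' Scores each retained clustering with [sces()] and sorts descending; the
#' first element is the optimal clustering.
#'
#' @param clusterings list of `pgcna_clustering`.
#' @param signatures a `signature_collection`.
#' @param population gene universe.
#' @param ... passed to [sces()].
#' @return list with `order` (indices into the input, best first),
#'   `reports` (SCES reports in input order), `best` (the top clustering).
#' @export
rank_clusterings <- function(clusterings, signatures,
                             population = NULL, ...) {
  stopifnot(length(clusterings) >= 1L)
  reports <- lapply(clusterings, function(cl) {
    pop <- population %||% names(cl$assignment)
    suppressWarnings(sces(cl, signatures, population = pop, ...))
  })
  scores <- vapply(reports, `[[`, 0, "sces")
  ord <- order(-scores)
  list(order = ord, scores = scores, reports = reports,
       best = clusterings[[ord[1]]], best_report = reports[[ord[1]]])
}
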