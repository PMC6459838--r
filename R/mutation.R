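#' Binary mutation matrix over a sample cohort
#'
#' Builds gene x sample 0/1 indicators (1 if the sample carries at least
#' one SNV in the gene) over the intersection of the mutation table's
#' samples and the expression cohort, then drops genes whose mutation
#' frequency is not strictly above `min_freq`.
#'
#' @param table a [mutation_table()].
#' @param samples character vector: the expression cohort's sample ids.
#' @param min_freq frequency cut; genes with frequency <= `min_freq` are
#'   dropped (the reference analyses used 0.05 and 0.10).
#' @return a `mutation_matrix`: `indicators` (genes x samples, 0/1) and
#'   `frequency` (named row means).
#' @export
binarize_mutations <- function(table, samples, min_freq = 0.05) {
  cohort <- samples
  if (length(intersect(cohort, unique(table$sample_id))) == 0L)
    stop("no overlap between mutation samples and the expression cohort")
  tab <- table[table$sample_id %in% cohort, , drop = FALSE]
  genes <- sort(unique(tab$gene_id))
  ind <- matrix(0L, length(genes), length(cohort),
                dimnames = list(genes, cohort))
  ind[cbind(tab$gene_id, tab$sample_id)] <- 1L
  freq <- rowMeans(ind)
  keep <- freq > min_freq
  structure(list(indicators = ind[keep, , drop = FALSE],
                 frequency = freq[keep]),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("<mutation_matrix: %d mutated genes x %d samples>\n",
              nrow(x$indicators), ncol(x$indicators)))
  invisible(x)
}

#' Split one gene's mutations into coordinate windows
#'
#' Assigns a gene's mutations to labelled, non-overlapping 1-based
#' inclusive genomic windows (e.g. separating hotspot regions of a gene)
#' and returns one indicator row per window. Mutations falling outside all
#' windows are ignored with a message.
#'
#' @param table a [mutation_table()].
#' @param gene_id the gene whose mutations are split.
#' @param windows data.frame with columns `chromosome`, `start`, `end`,
#'   `label`.
#' @param samples cohort sample ids for the indicator columns.
#' @return a `mutation_matrix` whose rows are the window labels.
#' @export
split_by_position <- function(table, gene_id, windows, samples) {
  stopifnot(all(c("chromosome", "start", "end", "label") %in% names(windows)))
  for (chrom in unique(windows$chromosome)) {
    w <- windows[windows$chromosome == chrom, , drop = FALSE]
    if (nrow(w) > 1L) {
      w <- w[order(w$start), ]
      if (any(w$start[-1] <= w$end[-nrow(w)]))
        stop("windows overlap on ", chrom)
    }
  }
  tab <- table[table$gene_id == gene_id & table$sample_id %in% samples, ,
               drop = FALSE]
  ind <- matrix(0L, nrow(windows), length(samples),
                dimnames = list(windows$label, samples))
  assigned <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(windows))) {
    hit <- tab$chromosome == windows$chromosome[i] &
      tab$position >= windows$start[i] & tab$position <= windows$end[i]
    assigned <- assigned | hit
    if (any(hit)) ind[i, unique(tab$sample_id[hit])] <- 1L
  }
  if (any(!assigned))
    message(sum(!assigned), " mutation(s) of ", gene_id,
            " fall outside all windows and were ignored")
  structure(list(indicators = ind, frequency = rowMeans(ind)),
            class = "mutation_matrix")
}

# Spearman correlation of one numeric vector against the rows of a matrix,
# with two-sided t-approximation p-values.
spearman_vs_rows <- function(x, mat) {
  n <- length(x)
  rho <- apply(mat, 1, function(r) stats::cor(x, r, method = "spearman"))
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  list(rho = rho, pval = p)
}

#' Mutation-module association matrix
#'
#' Spearman rank correlation between each mutated gene's 0/1 indicator and
#' each module's MEV over the shared samples, converted to signed
#' z-scores: z = sign(rho) * qnorm(1 - p/2) from the two-sided p-value, so
#' the z carries both direction and significance. Genes with at least one
#' positive correlation at p below `p_cutoff` are retained; their full z
#' rows are reported.
#'
#' @param mev a `mev_matrix`.
#' @param mut a `mutation_matrix`.
#' @param p_cutoff significance threshold for retention (default 0.05).
#' @return an `association_matrix`: `z` (retained genes x modules), `rho`,
#'   `pval` (all genes), `retained` gene ids.
#' @export
associate <- function(mev, mut, p_cutoff = 0.05) {
  stopifnot(inherits(mev, "mev_matrix"), inherits(mut, "mutation_matrix"))
  samples <- intersect(colnames(mev$values), colnames(mut$indicators))
  if (length(samples) < 10L) stop("need >= 10 shared samples")
  M <- mev$values[, samples, drop = FALSE]
  X <- mut$indicators[, samples, drop = FALSE]
  genes <- rownames(X)
  mods <- rownames(M)
  rho <- pval <- matrix(NA_real_, length(genes), length(mods),
                        dimnames = list(genes, mods))
  for (g in genes) {
    ind <- X[g, ]
    if (stats::sd(ind) == 0) { rho[g, ] <- 0; pval[g, ] <- 1; next }
    sp <- spearman_vs_rows(ind, M)
    rho[g, ] <- sp$rho
    pval[g, ] <- sp$pval
  }
  p_clamped <- pmin(pmax(pval, 1e-320), 1 - 1e-16)
  z <- sign(rho) * stats::qnorm(1 - p_clamped / 2)
  z[rho == 0] <- 0
  retained <- genes[apply(rho > 0 & pval < p_cutoff, 1, any)]
  structure(list(z = z[retained, , drop = FALSE], rho = rho, pval = pval,
                 retained = retained, samples = samples),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("<association_matrix: %d of %d mutated genes retained, %d modules>\n",
              length(x$retained), nrow(x$rho), ncol(x$rho)))
  invisible(x)
}

#' Samples ranked by MEV with mutation status attached
#'
#' Pure ordering for export/display: samples sorted by one module's MEV
#' (descending, ties broken by sample id) with one mutated gene's 0/1
#' indicator and the association summary attached.
#'
#' @param mev_row named numeric vector (one module's MEVs).
#' @param mut_row named 0/1 vector (one gene's indicators).
#' @return data.frame (sample_id, mev, mutated) sorted by decreasing MEV,
#'   with attributes `z` and `neg_log10_p` summarising the association.
#' @export
rank_by_mev <- function(mev_row, mut_row) {
  samples <- intersect(names(mev_row), names(mut_row))
  stopifnot(length(samples) >= 2L)
  m <- mev_row[samples]; x <- mut_row[samples]
  out <- data.frame(sample_id = samples, mev = unname(m),
                    mutated = as.integer(unname(x)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mev, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  if (stats::sd(x) > 0) {
    sp <- spearman_vs_rows(as.numeric(x), matrix(m, nrow = 1))
    p <- pmin(pmax(sp$pval[1], 1e-320), 1 - 1e-16)
    attr(out, "z") <- sign(sp$rho[1]) * stats::qnorm(1 - p / 2)
    attr(out, "neg_log10_p") <- -log10(p)
  } else {
    attr(out, "z") <- 0
    attr(out, "neg_log10_p") <- 0
  }
  out
}
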