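#' Gene-level overlap of two module sets
#'
#' Pairwise upper-tail hypergeometric tests of module gene membership
#' between two clusterings (e.g. networks from two cancers), on the shared
#' gene universe. For each module of A the maximally significant partner
#' in B is flagged.
#'
#' @param mods_a,mods_b named lists of character vectors (module label ->
#'   member genes).
#' @param population gene universe; defaults to the intersection of the
#'   two module sets' gene unions (overlap is only observable on the
#'   shared universe).
#' @return an `overlap_matrix`: `neg_log10_p` and `counts`
#'   (modules_a x modules_b), `best_match` (named vector, per A module),
#'   `population_size`.
#' @export
module_overlap <- function(mods_a, mods_b, population = NULL) {
  if (is.null(population))
    population <- intersect(unique(unlist(mods_a)), unique(unlist(mods_b)))
  if (length(population) == 0L) stop("empty shared gene population")
  a <- lapply(mods_a, intersect, population)
  b <- lapply(mods_b, intersect, population)
  p <- counts <- matrix(NA_real_, length(a), length(b),
                        dimnames = list(names(a), names(b)))
  for (i in names(a)) for (j in names(b)) {
    k <- length(intersect(a[[i]], b[[j]]))
    counts[i, j] <- k
    p[i, j] <- hyper_upper_p(k, length(b[[j]]), length(a[[i]]),
                             length(population))
  }
  best <- apply(p, 1, function(row) colnames(p)[which.min(row)])
  structure(list(neg_log10_p = -log10(pmax(p, 1e-320)), p_value = p,
                 counts = counts, best_match = best,
                 population_size = length(population)),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix: %d x %d modules, population %d>\n",
              nrow(x$counts), ncol(x$counts), x$population_size))
  invisible(x)
}

#' Signature-level overlap of two module sets
#'
#' Compares modules by their significantly enriched signatures rather than
#' their genes: per analysis, each module's signature set is the
#' signatures passing a p-value pre-filter (default p < 0.001) with size
#' within \[5, 1000\]; the overlap of two modules' sets is tested
#' hypergeometrically against the union of all pre-filtered signatures
#' from either analysis.
#'
#' @param enrich_a,enrich_b enrichment tables from [module_enrichment()]
#'   computed on the same signature collection.
#' @param p_cutoff pre-filter threshold (default 0.001).
#' @param min_size,max_size signature size bounds (defaults 5, 1000).
#' @return an `overlap_matrix` over signature sets.
#' @export
signature_overlap <- function(enrich_a, enrich_b, p_cutoff = 0.001,
                              min_size = 5L, max_size = 1000L) {
  pick <- function(enr) {
    hits <- enr[enr$p_value < p_cutoff & enr$signature_size >= min_size &
                  enr$signature_size <= max_size, , drop = FALSE]
    split(hits$signature, hits$module)
  }
  sets_a <- pick(enrich_a)
  sets_b <- pick(enrich_b)
  population <- union(unique(unlist(sets_a)), unique(unlist(sets_b)))
  if (length(population) == 0L)
    stop("no signature passes the pre-filter in either analysis")
  module_overlap(sets_a, sets_b, population = population)
}

#' Write an overlap matrix as TSV files
#'
#' @param overlap an `overlap_matrix`.
#' @param neg_log10_path,counts_path output paths for the -log10 p and
#'   overlap-count matrices.
#' @export
write_overlap_tsv <- function(overlap, neg_log10_path, counts_path) {
  stopifnot(inherits(overlap, "overlap_matrix"))
  wr <- function(m, path) {
    tab <- data.frame(module = rownames(m), m, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(overlap$neg_log10_p, neg_log10_path)
  wr(overlap$counts, counts_path)
  invisible(neg_log10_path)
}
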