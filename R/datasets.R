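#' Construct an expression dataset
#'
#' A light container for one cohort's genes x samples matrix of log2
#' expression values, identified by a dataset id. Gene and sample
#' identifiers are taken from the matrix dimnames and must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimensions must carry unique names. Missing values are allowed.
#' @param dataset_id short string identifying the cohort.
#' @return an object of class `expression_dataset`: a list with elements
#'   `dataset_id`, `values`, `gene_ids`, `sample_ids`.
#' @export
expression_dataset <- function(values, dataset_id) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in dataset '", dataset_id, "'")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in dataset '", dataset_id, "'")
  storage.mode(values) <- "double"
  structure(
    list(dataset_id = as.character(dataset_id), values = values,
         gene_ids = rownames(values), sample_ids = colnames(values)),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s': %d genes x %d samples, %d missing values>\n",
              x$dataset_id, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Read an expression matrix from tab-delimited text
#'
#' Expects a header row of sample ids and a first column of gene (or probe)
#' identifiers.
#'
#' @param path file path.
#' @param dataset_id cohort identifier; defaults to the file name without
#'   extension.
#' @return an [expression_dataset()].
#' @export
read_expression_tsv <- function(path, dataset_id = NULL) {
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  expression_dataset(values, dataset_id)
}

#' Write an expression dataset as tab-delimited text
#'
#' @param dataset an [expression_dataset()].
#' @param path output path; first column `gene_id`, then one column per sample.
#' @export
write_expression_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  tab <- data.frame(gene_id = dataset$gene_ids, dataset$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize an expression dataset
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' mean of the column-wise sorted values (the standard limma reference).
#' Missing values keep their positions; ranking is performed within the
#' non-missing entries of each column.
#'
#' @param dataset an [expression_dataset()] with at least two samples.
#' @return the normalized [expression_dataset()].
#' @export
quantile_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (ncol(dataset$values) < 2)
    stop("quantile normalization needs >= 2 samples; dataset '",
         dataset$dataset_id, "' has ", ncol(dataset$values))
  if (any(is.infinite(dataset$values)))
    stop("expression values must be finite or missing")
  norm <- limma::normalizeQuantiles(dataset$values, ties = TRUE)
  dimnames(norm) <- dimnames(dataset$values)
  expression_dataset(norm, dataset$dataset_id)
}

#' Merge probe-level rows to gene level
#'
#' Probes mapping to the same gene are merged per sample: when the probes
#' agree (mean pairwise Pearson correlation at or above `corr_threshold`)
#' the per-sample median is taken; when they disagree (below threshold) the
#' per-sample maximum is taken, on the basis that discordant probes usually
#' include a failing one reporting background. Single-probe genes pass
#' through unchanged. The matrix is expected to be quantile-normalized.
#'
#' @param probe_dataset an [expression_dataset()] whose rows are probes.
#' @param probe_to_gene named character vector mapping probe id -> gene id;
#'   probes absent from the map are dropped.
#' @param corr_threshold Pearson correlation cut separating the median rule
#'   from the maximum rule (default 0.2).
#' @return an [expression_dataset()] with one row per mapped gene, rows
#'   ordered by gene id.
#' @export
merge_probes <- function(probe_dataset, probe_to_gene, corr_threshold = 0.2) {
  stopifnot(inherits(probe_dataset, "expression_dataset"))
  probes <- intersect(probe_dataset$gene_ids, names(probe_to_gene))
  if (length(probes) == 0L) stop("no probes covered by the probe-to-gene map")
  map <- probe_to_gene[probes]
  genes <- sort(unique(unname(map)))
  vals <- probe_dataset$values
  out <- matrix(NA_real_, length(genes), ncol(vals),
                dimnames = list(genes, colnames(vals)))
  for (g in genes) {
    pr <- probes[map == g]
    sub <- vals[pr, , drop = FALSE]
    if (length(pr) == 1L) {
      out[g, ] <- sub[1L, ]
      next
    }
    cc <- stats::cor(t(sub), use = "pairwise.complete.obs")
    mean_r <- mean(cc[upper.tri(cc)], na.rm = TRUE)
    out[g, ] <- if (!is.na(mean_r) && mean_r >= corr_threshold)
      apply(sub, 2, stats::median, na.rm = TRUE)
    else
      apply(sub, 2, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  }
  expression_dataset(out, probe_dataset$dataset_id)
}

#' Read a GMT gene-signature file
#'
#' Standard GMT: one signature per line, tab-separated name, description,
#' then member genes. Duplicate genes within a line are deduplicated;
#' malformed lines (fewer than three fields) are skipped with a warning.
#'
#' @param path GMT file path.
#' @param source_tag label recorded on the collection (defaults to the file
#'   name).
#' @return a `signature_collection`: list with `signatures` (named list of
#'   character vectors) and `source_tag`.
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- list()
  bad <- 0L
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) { bad <- bad + 1L; next }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) { bad <- bad + 1L; next }
    sigs[[fields[1]]] <- genes
  }
  if (bad > 0L) warning(bad, " malformed GMT line(s) skipped in ", path)
  signature_collection(sigs, source_tag)
}

#' Construct a signature collection
#'
#' @param signatures named list of character vectors of gene ids; names must
#'   be unique and sets non-empty.
#' @param source_tag provenance label.
#' @return a `signature_collection` object.
#' @export
signature_collection <- function(signatures, source_tag = "unknown") {
  if (length(signatures) > 0) {
    if (is.null(names(signatures)) || anyDuplicated(names(signatures)))
      stop("signature names must be present and unique")
    if (any(lengths(signatures) == 0L)) stop("signature gene sets must be non-empty")
  }
  structure(list(signatures = lapply(signatures, unique),
                 source_tag = source_tag),
            class = "signature_collection")
}

#' @export
print.signature_collection <- function(x, ...) {
  cat(sprintf("<signature_collection '%s': %d signatures, median size %s>\n",
              x$source_tag, length(x$signatures),
              if (length(x$signatures)) stats::median(lengths(x$signatures)) else NA))
  invisible(x)
}

#' Read a right-censored survival table
#'
#' Tab-delimited columns: sample id, time, event (0/1).
#'
#' @param path file path.
#' @param dataset_id cohort the table belongs to.
#' @return a data.frame with columns `sample_id`, `time`, `event` and
#'   attribute `dataset_id`.
#' @export
read_survival_tsv <- function(path, dataset_id = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("sample_id", "time", "event")
  survival_table(tab, dataset_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Validate a survival table
#' @param tab data.frame with columns sample_id, time, event.
#' @param dataset_id cohort id stored as an attribute.
#' @return the validated data.frame.
#' @export
survival_table <- function(tab, dataset_id) {
  stopifnot(all(c("sample_id", "time", "event") %in% names(tab)))
  if (any(tab$time < 0)) stop("survival times must be non-negative")
  if (!all(tab$event %in% c(0, 1))) stop("event indicator must be 0/1")
  tab$sample_id <- as.character(tab$sample_id)
  attr(tab, "dataset_id") <- dataset_id
  tab
}

#' Read a minimal mutation table
#'
#' Tab-delimited MAF-like subset with columns gene id, sample id,
#' chromosome, 1-based position.
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `sample_id`, `chromosome`,
#'   `position`.
#' @export
read_mutation_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:4] <- c("gene_id", "sample_id", "chromosome", "position")
  mutation_table(tab)
}

#' Validate a mutation table
#' @param tab data.frame with columns gene_id, sample_id, chromosome, position.
#' @return the validated data.frame.
#' @export
mutation_table <- function(tab) {
  stopifnot(all(c("gene_id", "sample_id", "chromosome", "position") %in% names(tab)))
  if (nrow(tab) > 0 && any(tab$position < 1 | tab$position != round(tab$position)))
    stop("positions must be positive 1-based integers")
  tab$gene_id <- as.character(tab$gene_id)
  tab$sample_id <- as.character(tab$sample_id)
  tab$chromosome <- as.character(tab$chromosome)
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' On-disk store for pipeline intermediates
#'
#' A directory-backed binary store holding one group per dataset plus named
#' pipeline objects (merged correlations, networks, clusterings). Objects
#' round-trip bit-identically.
#'
#' @param path directory; created if absent.
#' @return a `pgcna_store` handle.
#' @export
pgcna_store <- function(path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  structure(list(path = normalizePath(path)), class = "pgcna_store")
}

#' @rdname pgcna_store
#' @param store a `pgcna_store`.
#' @param name object name within the store.
#' @param object any R object (e.g. an [expression_dataset()]).
#' @export
store_write <- function(store, name, object) {
  stopifnot(inherits(store, "pgcna_store"))
  saveRDS(object, file.path(store$path, paste0(name, ".rds")))
  invisible(name)
}

#' @rdname pgcna_store
#' @export
store_read <- function(store, name) {
  stopifnot(inherits(store, "pgcna_store"))
  f <- file.path(store$path, paste0(name, ".rds"))
  if (!file.exists(f)) stop("no object '", name, "' in store ", store$path)
  readRDS(f)
}

#' @rdname pgcna_store
#' @export
store_list <- function(store) {
  sub("\\.rds$", "", list.files(store$path, pattern = "\\.rds$"))
}
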