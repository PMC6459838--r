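#' Per-gene percentile expression across datasets
#'
#' Within each dataset genes are ranked by their median expression over
#' samples and converted to a 0-100 percentile, (rank - 1) / (G - 1) * 100
#' with average ranks for ties; the reported value per gene is the median
#' percentile across the datasets containing it.
#'
#' @param datasets list of [expression_dataset()].
#' @return list with `median_percentile` (named vector over all genes) and
#'   `per_dataset` (gene x dataset matrix of percentiles, NA where absent).
#' @export
percentile_expression <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  genes <- sort(unique(unlist(lapply(datasets, `[[`, "gene_ids"))))
  per <- matrix(NA_real_, length(genes), length(datasets),
                dimnames = list(genes, vapply(datasets, `[[`, "", "dataset_id")))
  for (d in seq_along(datasets)) {
    vals <- datasets[[d]]$values
    med <- apply(vals, 1, stats::median, na.rm = TRUE)
    G <- length(med)
    pct <- if (G > 1) (rank(med, ties.method = "average") - 1) / (G - 1) * 100
           else rep(100, G)
    per[names(med), d] <- pct
  }
  list(median_percentile = apply(per, 1, stats::median, na.rm = TRUE),
       per_dataset = per)
}

#' Quartile coefficient of dispersion
#'
#' (Q3 - Q1) / (Q3 + Q1) with linear-interpolation (type 7) quartiles; a
#' scale-free within-dataset dispersion measure. Undefined when
#' Q1 + Q3 <= 0 (returned as NA).
#'
#' @param values numeric vector (>= 4 non-missing values).
#' @return QCOD, or NA if undefined.
#' @export
qcod <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) stop("qcod needs >= 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  if (sum(q) <= 0) return(NA_real_)
  (q[2] - q[1]) / (q[2] + q[1])
}

# Raw median absolute deviation (no normal-consistency constant): used
# only as a relative weight on the 0-100 percentile scale.
raw_mad <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(abs(x - stats::median(x)))
}

#' Per-gene univariate Cox models within one dataset
#'
#' Fits, for each requested gene, a Cox proportional-hazards model with the
#' z-scored expression of the gene as a continuous covariate against the
#' dataset's right-censored survival data.
#'
#' @param dataset an [expression_dataset()].
#' @param surv a [survival_table()] for the same cohort.
#' @param genes gene ids to fit (default all genes in the dataset).
#' @return data.frame with gene_id, ln_hr, se, n_samples (NA rows for genes
#'   that could not be fitted).
#' @export
dataset_cox <- function(dataset, surv, genes = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  genes <- if (is.null(genes)) dataset$gene_ids else
    intersect(genes, dataset$gene_ids)
  samples <- intersect(dataset$sample_ids, surv$sample_id)
  if (length(samples) < 10L)
    warning("dataset '", dataset$dataset_id,
            "' has <10 samples with survival data")
  sv <- surv[match(samples, surv$sample_id), ]
  if (sum(sv$event) == 0L) {
    return(data.frame(gene_id = genes, ln_hr = NA_real_, se = NA_real_,
                      n_samples = length(samples), stringsAsFactors = FALSE))
  }
  y <- survival::Surv(sv$time, sv$event)
  fit_one <- function(g) {
    x <- dataset$values[g, samples]
    ok <- !is.na(x)
    if (sum(ok) < 10L || stats::sd(x[ok]) == 0) return(c(NA_real_, NA_real_))
    z <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
    fit <- tryCatch(survival::coxph(y ~ z), error = function(e) NULL,
                    warning = function(w) suppressWarnings(survival::coxph(y ~ z)))
    if (is.null(fit)) return(c(NA_real_, NA_real_))
    c(unname(stats::coef(fit)[1]), sqrt(diag(stats::vcov(fit)))[1])
  }
  res <- t(vapply(genes, fit_one, numeric(2)))
  data.frame(gene_id = genes, ln_hr = res[, 1], se = res[, 2],
             n_samples = length(samples), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Size-weighted fixed-effect meta-analysis of hazard ratios
#'
#' Combines per-dataset log hazard ratios with weights equal to dataset
#' size (not inverse variance): beta = sum(w_i b_i) / sum(w_i), with
#' se^2 = sum(w_i^2 se_i^2) / (sum w_i)^2 and a two-sided normal p-value.
#'
#' @param ln_hr,se,n per-dataset log hazard ratios, standard errors and
#'   sample sizes (vectors of equal length; NA entries are dropped).
#' @return list with `ln_hr`, `se`, `p_value`, `n_datasets`.
#' @export
meta_hazard <- function(ln_hr, se, n) {
  stopifnot(length(ln_hr) == length(se), length(se) == length(n))
  ok <- !is.na(ln_hr) & !is.na(se) & se > 0
  if (!any(ok))
    return(list(ln_hr = NA_real_, se = NA_real_, p_value = NA_real_,
                n_datasets = 0L))
  b <- ln_hr[ok]; s <- se[ok]; w <- n[ok]
  beta <- sum(w * b) / sum(w)
  se_meta <- sqrt(sum(w^2 * s^2) / sum(w)^2)
  list(ln_hr = beta, se = se_meta,
       p_value = 2 * stats::pnorm(-abs(beta / se_meta)),
       n_datasets = sum(ok))
}

#' Cross-dataset per-gene meta-statistics
#'
#' Assembles the gene-level annotations used by ModCon and the network
#' overlays: median percentile expression across datasets, dispersion
#' across datasets (raw MAD of the per-dataset percentiles, 0-100 scale),
#' dispersion within datasets (median QCOD over samples, 0-1 scale), and,
#' when survival tables are supplied, the size-weighted fixed-effect meta
#' hazard ratio of each gene's z-scored expression.
#'
#' @param datasets list of [expression_dataset()].
#' @param survival_tables optional named list of [survival_table()], names
#'   matching dataset ids.
#' @param genes genes to annotate (default: union over datasets).
#' @return data.frame keyed by `gene_id` with columns
#'   `percentile_expression`, `var_across`, `var_within`, `meta_ln_hr`,
#'   `meta_ln_hr_se`, `meta_hr_p`.
#' @export
gene_meta_stats <- function(datasets, survival_tables = NULL, genes = NULL) {
  pct <- percentile_expression(datasets)
  genes <- genes %||% rownames(pct$per_dataset)
  per <- pct$per_dataset[genes, , drop = FALSE]
  var_across <- apply(per, 1, raw_mad)
  qc <- matrix(NA_real_, length(genes), length(datasets),
               dimnames = list(genes, colnames(per)))
  for (d in seq_along(datasets)) {
    common <- intersect(genes, datasets[[d]]$gene_ids)
    qc[common, d] <- apply(datasets[[d]]$values[common, , drop = FALSE], 1,
                           function(v) tryCatch(qcod(v), error = function(e) NA_real_))
  }
  var_within <- apply(qc, 1, function(v) stats::median(v, na.rm = TRUE))
  out <- data.frame(gene_id = genes,
                    percentile_expression = unname(pct$median_percentile[genes]),
                    var_across = unname(var_across),
                    var_within = unname(var_within),
                    meta_ln_hr = NA_real_, meta_ln_hr_se = NA_real_,
                    meta_hr_p = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(survival_tables) && length(survival_tables) > 0) {
    ids <- vapply(datasets, `[[`, "", "dataset_id")
    with_surv <- which(ids %in% names(survival_tables))
    cox <- lapply(with_surv, function(d)
      dataset_cox(datasets[[d]], survival_tables[[ids[d]]], genes = genes))
    for (i in seq_along(genes)) {
      g <- genes[i]
      rows <- lapply(cox, function(tab) tab[tab$gene_id == g, ])
      b <- vapply(rows, function(r) if (nrow(r)) r$ln_hr else NA_real_, 0)
      s <- vapply(rows, function(r) if (nrow(r)) r$se else NA_real_, 0)
      n <- vapply(rows, function(r) if (nrow(r)) r$n_samples else NA_real_, 0)
      mh <- meta_hazard(b, s, n)
      out$meta_ln_hr[i] <- mh$ln_hr
      out$meta_ln_hr_se[i] <- mh$se
      out$meta_hr_p[i] <- mh$p_value
    }
  }
  out
}
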