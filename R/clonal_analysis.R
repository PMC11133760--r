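# Downstream clonal analysis: sample/barcode QC filters, replicate
# handling, normalisation, abundance and diversity statistics, and
# clone-in-cluster enrichment.

#' Counts matrix with sample metadata
#'
#' The container passed between all downstream analysis functions: a
#' barcodes x samples counts matrix plus per-sample metadata, with a record
#' of the normalisation state.
#'
#' @param counts Numeric matrix, rownames barcodes, colnames samples,
#'   non-negative.
#' @param meta data.frame keyed by sample (rownames or a `sample` column
#'   matching `colnames(counts)`); defaults to an empty frame.
#' @param norm One of `"raw"`, `"cpm"`, `"percent"`, `"tmm"`.
#' @return List of class `annotated_counts` with elements `counts`, `meta`,
#'   `norm`.
#' @export
annotated_counts <- function(counts, meta = NULL, norm = "raw") {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (norm == "raw" && any(counts < 0)) stop("raw counts must be non-negative")
  if (is.null(meta)) {
    meta <- data.frame(sample = colnames(counts), stringsAsFactors = FALSE)
    rownames(meta) <- meta$sample
  }
  if (!is.null(meta$sample)) rownames(meta) <- meta$sample
  if (!setequal(rownames(meta), colnames(counts))) {
    stop("sample metadata must be keyed identically to matrix columns")
  }
  meta <- meta[colnames(counts), , drop = FALSE]
  structure(list(counts = counts, meta = meta, norm = norm),
            class = "annotated_counts")
}

#' @export
print.annotated_counts <- function(x, ...) {
  cat("annotated_counts:", nrow(x$counts), "barcodes x", ncol(x$counts),
      "samples (", x$norm, ")\n")
  invisible(x)
}

# Type-7 (linear interpolation) percentile, the R default.
percentile_value <- function(x, percentile) {
  stats::quantile(x, probs = percentile / 100, type = 7, names = FALSE)
}

#' Remove low-depth outlier samples
#'
#' The threshold is the given percentile (linear-interpolation convention)
#' of the per-sample total read counts; samples whose total falls below it
#' are removed.
#'
#' @param ac An [annotated_counts()].
#' @param percentile Percentile in (0, 100), e.g. 5 for a 5th-percentile
#'   outlier threshold.
#' @return Filtered `annotated_counts` with attribute `removed_samples`.
#' @export
filter_samples_by_depth <- function(ac, percentile = 5) {
  stopifnot(percentile > 0, percentile < 100)
  totals <- colSums(ac$counts)
  threshold <- percentile_value(totals, percentile)
  keep <- totals >= threshold
  if (!any(keep)) stop("depth filter removed every sample")
  out <- annotated_counts(ac$counts[, keep, drop = FALSE],
                          ac$meta[keep, , drop = FALSE], ac$norm)
  attr(out, "removed_samples") <- colnames(ac$counts)[!keep]
  out
}

#' Filter barcodes by absolute or relative count thresholds
#'
#' A barcode is kept iff its count (absolute) or within-sample proportion
#' (relative) reaches `threshold` in at least `min_samples` samples; both
#' comparisons are inclusive. Surviving counts are never altered.
#'
#' @param ac An [annotated_counts()].
#' @param threshold Count (absolute) or proportion (relative) threshold.
#' @param min_samples Minimum number of samples reaching the threshold.
#' @param type `"absolute"` or `"relative"`.
#' @return Filtered `annotated_counts` with attribute `removed_barcodes`.
#' @export
threshold_counts <- function(ac, threshold = 10, min_samples = 1,
                             type = c("absolute", "relative")) {
  type <- match.arg(type)
  stopifnot(threshold >= 0, min_samples >= 1, min_samples <= ncol(ac$counts))
  vals <- if (type == "absolute") {
    ac$counts
  } else {
    sweep(ac$counts, 2, colSums(ac$counts), "/")
  }
  keep <- rowSums(vals >= threshold) >= min_samples
  out <- annotated_counts(ac$counts[keep, , drop = FALSE], ac$meta, ac$norm)
  attr(out, "removed_barcodes") <- rownames(ac$counts)[!keep]
  out
}

#' Normalise a counts matrix
#'
#' `cpm`: counts per million of the column total; `percent`: percentage of
#' the column total; `tmm`: trimmed-mean-of-M-values scaling factors
#' computed per sample, then counts per million on the effective
#' (factor-scaled) library sizes.
#'
#' @param ac An [annotated_counts()] holding raw counts.
#' @param method `"cpm"`, `"percent"` or `"tmm"`.
#' @return `annotated_counts` with transformed values and updated `norm`.
#' @export
normalise_counts <- function(ac, method = c("cpm", "percent", "tmm")) {
  method <- match.arg(method)
  if (ac$norm != "raw") stop("normalise_counts expects raw counts")
  totals <- colSums(ac$counts)
  if (any(totals == 0)) {
    stop("zero total count in sample ", colnames(ac$counts)[totals == 0][1])
  }
  vals <- switch(method,
    cpm = sweep(ac$counts, 2, totals, "/") * 1e6,
    percent = sweep(ac$counts, 2, totals, "/") * 100,
    tmm = {
      f <- edgeR::calcNormFactors(ac$counts, method = "TMM")
      sweep(ac$counts, 2, totals * f, "/") * 1e6
    }
  )
  annotated_counts(vals, ac$meta, norm = if (method == "tmm") "tmm" else method)
}

#' TMM scaling factors
#'
#' Per-sample trimmed-mean-of-M-values factors, normalised to geometric
#' mean 1; proportional columns yield factors of 1.
#'
#' @param ac An [annotated_counts()] holding raw counts.
#' @return Named numeric vector of factors.
#' @export
tmm_factors <- function(ac) {
  stats::setNames(edgeR::calcNormFactors(ac$counts, method = "TMM"),
                  colnames(ac$counts))
}

#' Within-group replicate correlation
#'
#' Pairwise correlation between samples of each replicate group over the
#' full barcode universe (zeros included). Constant columns have undefined
#' correlation and report `NA`.
#'
#' @param ac An [annotated_counts()].
#' @param group_field Metadata column naming the replicate group.
#' @param method `"pearson"` or `"spearman"`.
#' @return data.frame with `group`, `sample1`, `sample2`, `correlation`.
#' @export
replicate_corr <- function(ac, group_field, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  groups <- ac$meta[[group_field]]
  if (is.null(groups)) stop("no metadata field '", group_field, "'")
  res <- list()
  for (g in unique(groups)) {
    members <- colnames(ac$counts)[groups == g]
    if (length(members) < 2L) next
    pairs <- utils::combn(members, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- ac$counts[, pairs[1, j]]
      b <- ac$counts[, pairs[2, j]]
      cc <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else {
        stats::cor(a, b, method = method)
      }
      res[[length(res) + 1L]] <- data.frame(
        group = g, sample1 = pairs[1, j], sample2 = pairs[2, j],
        correlation = cc, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(group = character(0), sample1 = character(0),
                      sample2 = character(0), correlation = numeric(0)))
  }
  do.call(rbind, res)
}

#' Collapse well-correlated replicates to their mean
#'
#' Replicate groups whose minimum pairwise correlation exceeds
#' `corr_threshold` are replaced by the element-wise mean column (the group
#' label becomes the sample name); groups failing the bar, singleton
#' groups, and groups with undefined correlation are left uncollapsed and
#' reported.
#'
#' @param ac An [annotated_counts()].
#' @param group_field Metadata column naming the replicate group.
#' @param corr_threshold Minimum pairwise correlation (default 0.9).
#' @param method Correlation method.
#' @param mean_type `"arithmetic"` (default) or `"geometric"`.
#' @return `annotated_counts` with attribute `uncollapsed_groups`.
#' @export
collapse_replicates <- function(ac, group_field, corr_threshold = 0.9,
                                method = c("pearson", "spearman"),
                                mean_type = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  mean_type <- match.arg(mean_type)
  groups <- ac$meta[[group_field]]
  if (is.null(groups)) stop("no metadata field '", group_field, "'")
  cors <- replicate_corr(ac, group_field, method)
  cols <- list()
  meta_rows <- list()
  uncollapsed <- character(0)
  for (g in unique(groups)) {
    members <- colnames(ac$counts)[groups == g]
    gc <- cors$correlation[cors$group == g]
    collapsible <- length(members) >= 2L && length(gc) > 0 &&
      !anyNA(gc) && min(gc) > corr_threshold
    if (collapsible) {
      sub <- ac$counts[, members, drop = FALSE]
      col <- if (mean_type == "arithmetic") rowMeans(sub) else {
        exp(rowMeans(log(sub + 1))) - 1
      }
      cols[[as.character(g)]] <- col
      meta_rows[[as.character(g)]] <-
        ac$meta[members[1], , drop = FALSE]
    } else {
      if (length(members) >= 2L) uncollapsed <- c(uncollapsed, as.character(g))
      for (m in members) {
        cols[[m]] <- ac$counts[, m]
        meta_rows[[m]] <- ac$meta[m, , drop = FALSE]
      }
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  meta <- do.call(rbind, meta_rows)
  meta$sample <- names(cols)
  rownames(meta) <- meta$sample
  out <- annotated_counts(m, meta, ac$norm)
  attr(out, "uncollapsed_groups") <- uncollapsed
  out
}

#' Number of barcodes comprising a cumulative abundance percentile
#'
#' Barcodes are ranked by count descending; the result is the smallest
#' number of top barcodes whose cumulative count reaches `percentile` of
#' the sample total (inclusive).
#'
#' @param sample_counts Numeric vector of barcode counts for one sample.
#' @param percentile Fraction in (0, 1], e.g. 0.95.
#' @return Integer.
#' @export
percentile_barcodes <- function(sample_counts, percentile = 0.95) {
  stopifnot(percentile > 0, percentile <= 1)
  total <- sum(sample_counts)
  if (total <= 0) stop("sample total must be positive")
  sorted <- sort(sample_counts[sample_counts > 0], decreasing = TRUE)
  which(cumsum(sorted) >= percentile * total)[1]
}

#' Clonal diversity indices
#'
#' Shannon (natural log), Simpson in complement form (1 - sum p_i^2),
#' inverse Simpson (1 / sum p_i^2) over barcodes with positive counts, and
#' the Gini index of inequality computed over the full barcode universe
#' including zeros: sum_ij |x_i - x_j| / (2 n^2 mu).
#'
#' @param sample_counts Numeric vector of barcode counts (total > 0).
#' @param metric One of `"shannon"`, `"simpson"`, `"invsimpson"`, `"gini"`.
#' @return Numeric.
#' @export
diversity_index <- function(sample_counts,
                            metric = c("shannon", "simpson", "invsimpson",
                                       "gini")) {
  metric <- match.arg(metric)
  if (sum(sample_counts) <= 0) stop("sample total must be positive")
  if (metric == "gini") {
    x <- as.numeric(sample_counts)
    n <- length(x)
    mu <- mean(x)
    return(sum(abs(outer(x, x, "-"))) / (2 * n^2 * mu))
  }
  pos <- sample_counts[sample_counts > 0]
  as.numeric(vegan::diversity(pos, index = metric))
}

#' Per-sample diversity of an annotated counts object
#'
#' @param ac An [annotated_counts()].
#' @param metric See [diversity_index()].
#' @return Named numeric vector, one value per sample.
#' @export
sample_diversity <- function(ac, metric = "shannon") {
  apply(ac$counts, 2, diversity_index, metric = metric)
}

#' Pairwise sample correlation matrix
#'
#' Correlation between all sample pairs over the shared barcode universe
#' (zeros included); symmetric with unit diagonal.
#'
#' @param ac An [annotated_counts()] with at least two samples.
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric numeric matrix.
#' @export
pairwise_sample_correlation <- function(ac, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(ncol(ac$counts) >= 2)
  m <- stats::cor(ac$counts, method = method)
  diag(m) <- 1
  m
}

#' Hypergeometric enrichment of a cell group across partitions
#'
#' For each partition (e.g. transcriptional cluster): with N labeled cells
#' in total, K of them in `target_group`, n in the partition and k in the
#' overlap, the upper-tail hypergeometric probability P(X >= k) tests
#' over-representation of the group in that partition. P values are
#' Benjamini-Hochberg adjusted across partitions.
#'
#' @param labels data.frame with columns `group` (e.g. clone) and
#'   `partition` (e.g. cluster), one row per cell.
#' @param target_group The group label to test.
#' @return data.frame with `partition`, `k`, `n`, `K`, `N`, `p_raw`,
#'   `p_adj`, `neg_log10_p`.
#' @export
cluster_enrichment <- function(labels, target_group) {
  stopifnot(all(c("group", "partition") %in% names(labels)))
  if (!target_group %in% labels$group) {
    stop("target_group '", target_group, "' not present in labels")
  }
  N <- nrow(labels)
  K <- sum(labels$group == target_group)
  parts <- sort(unique(labels$partition))
  res <- lapply(parts, function(p) {
    n <- sum(labels$partition == p)
    k <- sum(labels$partition == p & labels$group == target_group)
    p_raw <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(partition = p, k = k, n = n, K = K, N = N, p_raw = p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out$neg_log10_p <- -log10(out$p_raw)
  out
}

#' Clone-level summaries of a per-cell lineage table
#'
#' Cells-per-clone tallies (by dominant barcode), the barcodes-per-cell
#' histogram, optional per-clone quartile summaries of a per-cell numeric
#' metric, and detection rate (annotated / total cells) when the total is
#' supplied.
#'
#' @param table Per-cell table from [annotate_cells()].
#' @param per_cell_metric Optional named numeric vector (cell_id -> value).
#' @param total_cells Optional total number of cells assayed.
#' @return List with `cells_per_clone`, `barcodes_per_cell`, optional
#'   `metric_by_clone`, optional `detection_rate`.
#' @export
clone_summaries <- function(table, per_cell_metric = NULL, total_cells = NULL) {
  dom <- dominant_barcode(table)
  dom <- dom[!is.na(dom)]
  cells_per_clone <- sort(table(dom), decreasing = TRUE)
  barcodes_per_cell <- table(table$n_barcodes)
  out <- list(
    cells_per_clone = stats::setNames(as.integer(cells_per_clone),
                                      names(cells_per_clone)),
    barcodes_per_cell = stats::setNames(as.integer(barcodes_per_cell),
                                        names(barcodes_per_cell))
  )
  if (!is.null(per_cell_metric)) {
    sp <- split(per_cell_metric[names(dom)], dom)
    out$metric_by_clone <- do.call(rbind, lapply(names(sp), function(cl) {
      q <- stats::quantile(sp[[cl]], c(0.25, 0.5, 0.75), na.rm = TRUE,
                           names = FALSE)
      data.frame(clone = cl, n_cells = length(sp[[cl]]), q25 = q[1],
                 median = q[2], q75 = q[3], stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(total_cells)) {
    out$detection_rate <- nrow(table) / total_cells
  }
  out
}
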