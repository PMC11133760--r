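# End-to-end workflow drivers tying the modules together, plus the
# machine-readable QC report.

# Canonical stage order used to check that per-sample QC counters are
# non-increasing along the pipeline.
QC_STAGE_ORDER <- c("input", "merged", "quality_pass", "complexity_pass",
                    "cbumi_parsed", "whitelist_pass",
                    "constant_found", "length_pass", "assigned",
                    "cells_annotated")

new_qc <- function() {
  list(counters = list(), details = list())
}

qc_set <- function(qc, stage, value) {
  qc$counters[[stage]] <- as.numeric(value)
  qc
}

#' Validate and write a QC report as JSON
#'
#' Counters must be non-increasing along the pipeline stage order (a
#' violation indicates an internal inconsistency and is a hard error).
#'
#' @param qc QC structure produced by the workflow drivers: list with
#'   `counters` (named stage counts) and `details`.
#' @param path Output JSON path (NULL returns the report invisibly).
#' @param config Optional config list echoed into the report.
#' @return The report list, invisibly.
#' @export
emit_qc_report <- function(qc, path = NULL, config = NULL) {
  present <- QC_STAGE_ORDER[QC_STAGE_ORDER %in% names(qc$counters)]
  vals <- unlist(qc$counters[present])
  if (length(vals) >= 2L && any(diff(vals) > 0)) {
    bad <- present[which(diff(vals) > 0)[1] + 1L]
    stop("QC counter inconsistency: stage '", bad,
         "' exceeds its predecessor")
  }
  report <- list(
    tool = "barkit",
    version = as.character(utils::packageVersion("barkit")),
    counters = qc$counters,
    details = qc$details,
    config = config
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
  }
  invisible(report)
}

#' Run the population-level (bulk) workflow on reads in memory
#'
#' Merging (paired input), quality filtering, optional complexity
#' filtering, constant-region trimming with the length policy, then either
#' reference-based assignment or reference-free Levenshtein clustering.
#'
#' @param reads Reads data.frame (read 1 / single reads).
#' @param reads2 Optional mate reads data.frame; enables merging.
#' @param cfg An [extract_config()].
#' @param reference Optional `barcode_reference`; when given, reference
#'   mode is used.
#' @param align_cfg An [align_config()] (reference mode).
#' @param cluster_cfg A [cluster_config()] (reference-free mode).
#' @return List with `counts` (named numeric vector), `qc`, and
#'   `barcodes` (the surviving extracted sequences).
#' @export
run_bulk_workflow <- function(reads, reads2 = NULL, cfg = extract_config(),
                              reference = NULL,
                              align_cfg = align_config(),
                              cluster_cfg = cluster_config()) {
  qc <- new_qc()
  qc <- qc_set(qc, "input", nrow(reads))
  if (!is.null(reads2)) {
    merged <- vector("list", nrow(reads))
    for (i in seq_len(nrow(reads))) {
      merged[[i]] <- merge_pairs(reads[i, ], reads2[i, ],
                                 cfg$merge_min_overlap,
                                 cfg$merge_max_mismatch_density)
    }
    merged <- merged[!vapply(merged, is.null, logical(1))]
    reads <- if (length(merged)) do.call(rbind, merged) else reads[0, ]
    qc <- qc_set(qc, "merged", nrow(reads))
  }
  qpass <- vapply(reads$qual, quality_filter, logical(1),
                  minqual = cfg$minqual, pctqual = cfg$pctqual,
                  USE.NAMES = FALSE)
  reads <- reads[qpass, , drop = FALSE]
  qc <- qc_set(qc, "quality_pass", nrow(reads))
  if (cfg$complexity_threshold > 0) {
    cpass <- vapply(reads$seq, complexity_filter, logical(1),
                    threshold = cfg$complexity_threshold, USE.NAMES = FALSE)
    reads <- reads[cpass, , drop = FALSE]
  }
  qc <- qc_set(qc, "complexity_pass", nrow(reads))
  barcodes <- character(0)
  reject_reasons <- character(0)
  for (i in seq_len(nrow(reads))) {
    tr <- find_and_trim_constants(reads[i, ], cfg)
    if (is_trim_rejection(tr)) {
      reject_reasons <- c(reject_reasons, tr$reason)
    } else {
      barcodes <- c(barcodes, tr$barcode_seq)
    }
  }
  qc <- qc_set(qc, "constant_found",
               length(barcodes) + sum(reject_reasons %in%
                 c("too_short", "too_long", "wrong_length")))
  qc <- qc_set(qc, "length_pass", length(barcodes))
  qc$details$trim_rejections <- as.list(table(reject_reasons))
  if (!is.null(reference)) {
    asg <- assign_many(barcodes, reference, align_cfg)
    counts <- count_sample(asg)
    aq <- attr(asg, "qc")
    qc <- qc_set(qc, "assigned", aq[["aligned"]])
    qc$details$ambiguous <- unname(aq[["ambiguous"]])
    qc$details$unmapped <- unname(aq[["unmapped"]])
  } else {
    trimmed <- trim_to_common_length(barcodes, cfg)
    tallies <- count_sample(trimmed)
    counts <- cluster_reference_free(tallies, cluster_cfg)
    qc <- qc_set(qc, "assigned", sum(counts))
    qc$details$clustered_away <- length(tallies) - length(counts)
  }
  list(counts = counts, qc = qc, barcodes = barcodes)
}

#' Run the single-cell workflow
#'
#' From paired FASTQ (read 1 = cell barcode + UMI, read 2 = lineage
#' barcode amplicon) or from tagged alignment records: parse and whitelist
#' cell barcodes, quality/complexity filter and trim the lineage read,
#' assign (or cluster) lineage barcodes, remove PCR chimeras, collapse
#' UMIs, apply the per-cell filters and annotate cells.
#'
#' @param reads1 Reads data.frame for read 1, or `NULL` when `tagged` is
#'   given.
#' @param reads2 Reads data.frame for the lineage read.
#' @param tagged Optional data.frame from [read_tagged_alignments()]
#'   (columns `seq`, `qual`, `cell_id`, `umi`), replacing `reads1`/`reads2`.
#' @param cfg An [extract_config()] for the lineage read.
#' @param sc An [sc_config()].
#' @param reference Optional `barcode_reference` (reference mode).
#' @param align_cfg An [align_config()].
#' @param cluster_cfg A [cluster_config()] (reference-free mode).
#' @return List with `table` (per-cell annotation, filtered), `records`
#'   (chimera-removed molecule records) and `qc`.
#' @export
run_sc_workflow <- function(reads1 = NULL, reads2 = NULL, tagged = NULL,
                            cfg = extract_config(), sc = sc_config(),
                            reference = NULL,
                            align_cfg = align_config(),
                            cluster_cfg = cluster_config()) {
  qc <- new_qc()
  if (!is.null(tagged)) {
    df <- data.frame(cell_id = tagged$cell_id, umi = tagged$umi,
                     seq = tagged$seq, qual = tagged$qual,
                     stringsAsFactors = FALSE)
    qc <- qc_set(qc, "input", nrow(df))
    qc <- qc_set(qc, "cbumi_parsed", nrow(df))
  } else {
    stopifnot(nrow(reads1) == nrow(reads2))
    qc <- qc_set(qc, "input", nrow(reads1))
    cbumi <- parse_cb_umi(reads1$seq, sc$cb_umi_pattern)
    ok <- !is.na(cbumi$cell_id)
    df <- data.frame(cell_id = cbumi$cell_id[ok], umi = cbumi$umi[ok],
                     seq = reads2$seq[ok], qual = reads2$qual[ok],
                     stringsAsFactors = FALSE)
    qc <- qc_set(qc, "cbumi_parsed", nrow(df))
  }
  whitelist <- sc$whitelist
  if (is.null(whitelist)) {
    if (!is.null(sc$expected_cells)) {
      tal <- table(df$cell_id)
      whitelist <- call_cells_knee(stats::setNames(as.numeric(tal), names(tal)),
                                   sc$expected_cells)
    } else {
      whitelist <- unique(df$cell_id)
    }
  }
  corrected <- whitelist_filter(df$cell_id, whitelist, sc$correct_one_mismatch)
  df$cell_id <- corrected
  df <- df[!is.na(df$cell_id), , drop = FALSE]
  qc <- qc_set(qc, "whitelist_pass", nrow(df))
  qpass <- vapply(df$qual, quality_filter, logical(1),
                  minqual = cfg$minqual, pctqual = cfg$pctqual,
                  USE.NAMES = FALSE)
  df <- df[qpass, , drop = FALSE]
  if (cfg$complexity_threshold > 0) {
    cpass <- vapply(df$seq, complexity_filter, logical(1),
                    threshold = cfg$complexity_threshold, USE.NAMES = FALSE)
    df <- df[cpass, , drop = FALSE]
  }
  barcodes <- rep(NA_character_, nrow(df))
  for (i in seq_len(nrow(df))) {
    tr <- find_and_trim_constants(
      sequenced_reads("x", df$seq[i], df$qual[i]), cfg)
    if (!is_trim_rejection(tr)) barcodes[i] <- tr$barcode_seq
  }
  df$barcode_seq <- barcodes
  df <- df[!is.na(df$barcode_seq), , drop = FALSE]
  qc <- qc_set(qc, "constant_found", nrow(df))
  if (!is.null(reference)) {
    asg <- assign_many(df$barcode_seq, reference, align_cfg)
    df$lineage_barcode <- as.character(asg)
    df <- df[!is.na(df$lineage_barcode), , drop = FALSE]
  } else {
    tallies <- count_sample(df$barcode_seq)
    clustered <- greedy_sphere_cluster(tallies, cluster_cfg$distance,
                                       cluster_cfg$ratio)
    df$lineage_barcode <- clustered$centroid[match(df$barcode_seq,
                                                   clustered$seq)]
  }
  qc <- qc_set(qc, "assigned", nrow(df))
  # tally read support per (cell, UMI, lineage barcode)
  key <- paste(df$cell_id, df$umi, df$lineage_barcode, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  records <- data.frame(
    cell_id = vapply(parts, `[`, character(1), 1L),
    umi = vapply(parts, `[`, character(1), 2L),
    lineage_barcode = vapply(parts, `[`, character(1), 3L),
    read_support = as.integer(tab),
    stringsAsFactors = FALSE
  )
  records <- remove_chimeras(records)
  qc$details$chimeric_groups_removed <- attr(records, "n_chimeric_removed")
  table_out <- annotate_cells(records, umi_distance = sc$umi_distance)
  filtered <- filter_cell_barcodes(table_out, sc$umi_count_threshold,
                                   sc$dominant_fraction)
  qc <- qc_set(qc, "cells_annotated", nrow(filtered))
  qc$details$cells_dropped_by_filters <- attr(filtered, "n_cells_dropped")
  qc$details$barcodes_per_cell_histogram <-
    as.list(table(filtered$n_barcodes))
  list(table = filtered, records = records, qc = qc)
}

#' Run the spatial workflow
#'
#' The single-cell workflow applied to coordinate-labeled spots (the
#' spot/cell identifier encodes its x/y coordinate as `"x_y"`), followed by
#' aggregation of UMI counts to square bins. Optionally only the dominant
#' barcode per spot is retained before binning.
#'
#' @inheritParams run_sc_workflow
#' @param bin_size Spatial bin edge length (default 20).
#' @param dominant_only Keep only each spot's dominant barcode (default
#'   TRUE).
#' @return List as [run_sc_workflow()] plus `bins` (bins x barcodes counts
#'   matrix).
#' @export
run_spatial_workflow <- function(reads1 = NULL, reads2 = NULL, tagged = NULL,
                                 cfg = extract_config(), sc = sc_config(),
                                 reference = NULL,
                                 align_cfg = align_config(),
                                 cluster_cfg = cluster_config(),
                                 bin_size = 20, dominant_only = TRUE) {
  res <- run_sc_workflow(reads1, reads2, tagged, cfg, sc, reference,
                         align_cfg, cluster_cfg)
  long <- cell_table_long(res$table)
  if (dominant_only) {
    dom <- dominant_barcode(res$table)
    dom <- dom[!is.na(dom)]
    long <- long[paste(long$cell_id, long$lineage_barcode) %in%
                   paste(names(dom), dom), , drop = FALSE]
  }
  coords <- parse_spot_coords(long$cell_id)
  long$x <- coords$x
  long$y <- coords$y
  res$bins <- aggregate_to_bins(long, bin_size)
  res
}

# Decode "x_y" spot identifiers into integer coordinates.
parse_spot_coords <- function(cell_ids) {
  parts <- strsplit(cell_ids, "_", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) stop("spot identifier not of the form 'x_y': ", cell_ids[bad][1])
  data.frame(x = as.numeric(vapply(parts, `[`, character(1), 1L)),
             y = as.numeric(vapply(parts, `[`, character(1), 2L)))
}
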