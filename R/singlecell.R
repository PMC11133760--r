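# Single-cell and spatial subworkflow: cell-barcode/UMI parsing,
# whitelisting, knee cell calling, PCR-chimera removal, UMI collapsing,
# per-cell filtering and annotation, and spatial bin aggregation.

#' Configuration for the single-cell workflow
#'
#' @param cb_umi_pattern String over C and N describing read 1: C positions
#'   form the cell barcode, N positions the UMI; a C-block followed by an
#'   N-block (default 16 C + 10 N, the common droplet chemistry).
#' @param whitelist Optional character vector of accepted cell barcodes.
#' @param expected_cells Optional expected cell number for knee calling when
#'   no whitelist is given.
#' @param umi_distance Levenshtein radius for UMI collapsing (default 1).
#' @param umi_count_threshold Minimum UMIs per (cell, lineage barcode)
#'   retained by [filter_cell_barcodes()] (default 0 = off).
#' @param dominant_fraction Lineage barcodes below this fraction of the
#'   cell's most abundant barcode are dropped (default 0 = off).
#' @param correct_one_mismatch Rescue cell barcodes at Hamming distance 1
#'   from exactly one whitelist entry (default FALSE).
#' @return List of class `sc_config`.
#' @export
sc_config <- function(cb_umi_pattern = paste0(strrep("C", 16), strrep("N", 10)),
                      whitelist = NULL, expected_cells = NULL,
                      umi_distance = 1, umi_count_threshold = 0,
                      dominant_fraction = 0, correct_one_mismatch = FALSE) {
  if (!grepl("^C+N+$", cb_umi_pattern)) {
    stop("cb_umi_pattern must be a block of C followed by a block of N")
  }
  stopifnot(umi_distance >= 0, umi_count_threshold >= 0,
            dominant_fraction >= 0, dominant_fraction <= 1)
  structure(list(cb_umi_pattern = cb_umi_pattern, whitelist = whitelist,
                 expected_cells = expected_cells,
                 umi_distance = as.integer(umi_distance),
                 umi_count_threshold = umi_count_threshold,
                 dominant_fraction = dominant_fraction,
                 correct_one_mismatch = correct_one_mismatch),
            class = "sc_config")
}

#' Parse cell barcode and UMI from read 1
#'
#' @param seqs Character vector of read-1 sequences.
#' @param pattern C/N pattern string (see [sc_config()]).
#' @return data.frame with `cell_id` and `umi` (`NA` rows for reads shorter
#'   than the pattern, which are rejected and counted by callers); trailing
#'   read bases beyond the pattern are ignored.
#' @export
parse_cb_umi <- function(seqs, pattern) {
  cb_len <- sum(strsplit(pattern, "", fixed = TRUE)[[1]] == "C")
  pat_len <- nchar(pattern)
  ok <- nchar(seqs) >= pat_len
  data.frame(
    cell_id = ifelse(ok, substr(seqs, 1L, cb_len), NA_character_),
    umi = ifelse(ok, substr(seqs, cb_len + 1L, pat_len), NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Filter (and optionally correct) cell barcodes against a whitelist
#'
#' Exact whitelist members are kept. With `correct_one_mismatch`, a cell
#' barcode at Hamming distance 1 from exactly one whitelist entry is
#' rewritten to that entry; barcodes equidistant to two or more entries are
#' dropped.
#'
#' @param cell_ids Character vector of observed cell barcodes.
#' @param whitelist Character vector of accepted cell barcodes.
#' @param correct_one_mismatch Logical (default FALSE).
#' @return Character vector parallel to `cell_ids`: the (possibly
#'   corrected) barcode, or `NA` where dropped.
#' @export
whitelist_filter <- function(cell_ids, whitelist, correct_one_mismatch = FALSE) {
  stopifnot(length(whitelist) > 0)
  out <- ifelse(cell_ids %in% whitelist, cell_ids, NA_character_)
  if (correct_one_mismatch) {
    todo <- which(is.na(out) & !is.na(cell_ids))
    if (length(todo)) {
      wl_len <- nchar(whitelist)
      fixes <- vapply(unique(cell_ids[todo]), function(cb) {
        same <- whitelist[wl_len == nchar(cb)]
        if (!length(same)) return(NA_character_)
        d <- hamming_many(cb, same)
        hits <- same[d == 1L]
        if (length(hits) == 1L) hits else NA_character_
      }, character(1))
      out[todo] <- fixes[cell_ids[todo]]
    }
  }
  out
}

#' Call cells from ranked cell-barcode read counts
#'
#' Simple knee rule: the threshold is one tenth of the read count at the
#' 99th percentile of the top `expected_cells` barcodes (rank
#' `ceil(0.01 x expected_cells)` of the descending tallies); all cell
#' barcodes at or above the threshold are called.
#'
#' @param cb_tallies Named numeric vector, cell barcode -> reads.
#' @param expected_cells Expected number of real cells (>= 1).
#' @return Character vector of called cell barcodes (a whitelist).
#' @export
call_cells_knee <- function(cb_tallies, expected_cells) {
  stopifnot(expected_cells >= 1)
  if (length(cb_tallies) < expected_cells) {
    warning("fewer distinct cell barcodes (", length(cb_tallies),
            ") than expected cells (", expected_cells, "); using all")
    return(names(cb_tallies))
  }
  sorted <- sort(cb_tallies, decreasing = TRUE)
  rank99 <- ceiling(0.01 * expected_cells)
  threshold <- sorted[rank99] / 10
  names(cb_tallies)[cb_tallies >= threshold]
}

#' Remove PCR chimeras from molecule records
#'
#' A PCR chimera pairs a cell barcode and UMI with the wrong lineage
#' barcode. Per (cell, UMI) group, only the lineage barcode with strictly
#' maximal read support is kept; groups whose maximum is shared (ambiguous
#' ties) are removed entirely.
#'
#' @param records data.frame with columns `cell_id`, `umi`,
#'   `lineage_barcode`, `read_support` (one row per distinct combination).
#' @return The surviving records, with attribute `n_chimeric_removed` =
#'   number of (cell, UMI) groups dropped or pruned.
#' @export
remove_chimeras <- function(records) {
  if (nrow(records) == 0L) {
    attr(records, "n_chimeric_removed") <- 0L
    return(records)
  }
  grp <- paste(records$cell_id, records$umi, sep = "\r")
  # aggregate read support over duplicate rows of the same combination
  key <- paste(grp, records$lineage_barcode, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- rowsum(records$read_support, group = key, reorder = FALSE)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    records <- data.frame(
      cell_id = vapply(parts, `[`, character(1), 1L),
      umi = vapply(parts, `[`, character(1), 2L),
      lineage_barcode = vapply(parts, `[`, character(1), 3L),
      read_support = agg[, 1],
      stringsAsFactors = FALSE
    )
    grp <- paste(records$cell_id, records$umi, sep = "\r")
  }
  grp_max <- stats::ave(records$read_support, grp, FUN = max)
  at_max <- records$read_support == grp_max
  n_at_max <- stats::ave(at_max, grp, FUN = sum)
  keep <- at_max & n_at_max == 1L
  affected <- unique(grp[!keep])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_chimeric_removed") <- length(affected)
  out
}

#' Collapse UMIs within a Levenshtein radius
#'
#' Directional adjacency network, the standard UMI-deduplication rule: UMIs
#' are visited in read-count-descending order (ties lexicographic); each
#' unassigned UMI seeds a cluster that expands along directed edges from a
#' member `a` to an unassigned UMI `b` with `lev(a, b) <= d` and
#' `count(a) >= 2 * count(b) - 1`. Error variants are low-count offshoots
#' of a true molecule, so two variants of one UMI (up to `2d` apart) merge
#' through their parent, while two genuine molecules of similar abundance
#' are kept apart. The corrected molecule count is the number of clusters.
#'
#' @param umis Named numeric vector, UMI sequence -> read count.
#' @param d Levenshtein radius; `d = 0` keeps every distinct UMI.
#' @return Integer: deduplicated UMI count.
#' @export
collapse_umis <- function(umis, d = 1) {
  n <- length(umis)
  if (n <= 1L || d == 0L) return(n)
  ord <- order(-as.numeric(umis), names(umis))
  seqs <- names(umis)[ord]
  counts <- as.numeric(umis)[ord]
  assigned <- rep(FALSE, n)
  clusters <- 0L
  for (i in seq_len(n)) {
    if (assigned[i]) next
    clusters <- clusters + 1L
    assigned[i] <- TRUE
    queue <- i
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      cand <- which(!assigned)
      if (!length(cand)) break
      ok <- counts[cur] >= 2 * counts[cand] - 1
      if (any(ok)) {
        dd <- levenshtein(seqs[cur], seqs[cand[ok]])
        take <- cand[ok][dd <= d]
        if (length(take)) {
          assigned[take] <- TRUE
          queue <- c(queue, take)
        }
      }
    }
  }
  clusters
}

#' Build the per-cell lineage annotation table
#'
#' Records must already be chimera-removed; UMIs are collapsed per
#' (cell, lineage barcode) within `umi_distance`. Within each cell, lineage
#' barcodes are ordered by UMI count descending (ties lexicographic) and
#' collapsed to comma-separated lists.
#'
#' @param records data.frame with `cell_id`, `umi`, `lineage_barcode`,
#'   `read_support`.
#' @param umi_distance Levenshtein radius for UMI collapsing (default 1).
#' @return data.frame with `cell_id`, `barcodes`, `umi_counts` (both
#'   comma-separated) and `n_barcodes`.
#' @export
annotate_cells <- function(records, umi_distance = 1) {
  if (nrow(records) == 0L) {
    return(data.frame(cell_id = character(0), barcodes = character(0),
                      umi_counts = character(0), n_barcodes = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(records$cell_id, records$lineage_barcode, sep = "\r")
  split_idx <- split(seq_len(nrow(records)), key)
  umi_counts <- vapply(split_idx, function(ix) {
    collapse_umis(stats::setNames(records$read_support[ix], records$umi[ix]),
                  d = umi_distance)
  }, integer(1))
  parts <- strsplit(names(split_idx), "\r", fixed = TRUE)
  long <- data.frame(
    cell_id = vapply(parts, `[`, character(1), 1L),
    lineage_barcode = vapply(parts, `[`, character(1), 2L),
    umi_count = as.integer(umi_counts),
    stringsAsFactors = FALSE
  )
  cell_table_from_long(long)
}

# Collapse a long (cell_id, lineage_barcode, umi_count) frame into the
# comma-separated per-cell table, sorted by UMI count desc then barcode.
cell_table_from_long <- function(long) {
  ord <- order(long$cell_id, -long$umi_count, long$lineage_barcode)
  long <- long[ord, , drop = FALSE]
  sp <- split(seq_len(nrow(long)), long$cell_id)
  out <- data.frame(
    cell_id = names(sp),
    barcodes = vapply(sp, function(ix) paste(long$lineage_barcode[ix], collapse = ","),
                      character(1)),
    umi_counts = vapply(sp, function(ix) paste(long$umi_count[ix], collapse = ","),
                        character(1)),
    n_barcodes = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Expand the comma-separated per-cell table back to long form.
cell_table_long <- function(table) {
  if (nrow(table) == 0L) {
    return(data.frame(cell_id = character(0), lineage_barcode = character(0),
                      umi_count = integer(0), stringsAsFactors = FALSE))
  }
  bcs <- strsplit(table$barcodes, ",", fixed = TRUE)
  cts <- strsplit(table$umi_counts, ",", fixed = TRUE)
  data.frame(
    cell_id = rep(table$cell_id, lengths(bcs)),
    lineage_barcode = unlist(bcs),
    umi_count = as.integer(unlist(cts)),
    stringsAsFactors = FALSE
  )
}

#' Filter per-cell lineage annotations
#'
#' Per cell: drop lineage barcodes below the UMI count threshold, then drop
#' those below `dominant_fraction` times the cell's maximum UMI count
#' (inclusive boundary: a barcode exactly at the fraction is kept). Cells
#' with no surviving barcodes are removed (and counted).
#'
#' @param table Per-cell table from [annotate_cells()].
#' @param umi_count_threshold Minimum UMI count (inclusive).
#' @param dominant_fraction Fraction of the cell's top barcode (0-1).
#' @return Filtered table with attribute `n_cells_dropped`.
#' @export
filter_cell_barcodes <- function(table, umi_count_threshold = 0,
                                 dominant_fraction = 0) {
  long <- cell_table_long(table)
  long <- long[long$umi_count >= umi_count_threshold, , drop = FALSE]
  if (nrow(long) && dominant_fraction > 0) {
    cellmax <- stats::ave(long$umi_count, long$cell_id, FUN = max)
    long <- long[long$umi_count >= dominant_fraction * cellmax, , drop = FALSE]
  }
  out <- cell_table_from_long(long)
  attr(out, "n_cells_dropped") <- length(setdiff(table$cell_id, out$cell_id))
  out
}

#' Dominant lineage barcode per cell
#'
#' The lineage barcode with the most UMIs in each cell; cells whose top two
#' barcodes tie in UMI count get no call.
#'
#' @param table Per-cell table from [annotate_cells()].
#' @return Named character vector, cell_id -> barcode (`NA` = no call).
#' @export
dominant_barcode <- function(table) {
  long <- cell_table_long(table)
  sp <- split(seq_len(nrow(long)), long$cell_id)
  out <- vapply(sp, function(ix) {
    cnt <- long$umi_count[ix]
    top <- max(cnt)
    if (sum(cnt == top) > 1L) return(NA_character_)
    long$lineage_barcode[ix][which.max(cnt)]
  }, character(1))
  out
}

#' Aggregate spatial barcode records to square bins
#'
#' Bin id = (floor(x / bin_size), floor(y / bin_size)); UMI counts are
#' summed per (bin, barcode), conserving total mass.
#'
#' @param records data.frame with `x`, `y`, `lineage_barcode`, `umi_count`.
#' @param bin_size Bin edge length (>= 1); 1 is identity binning.
#' @return Counts matrix, rows = bins (named `"bx_by"`), columns = barcodes.
#' @export
aggregate_to_bins <- function(records, bin_size = 20) {
  stopifnot(bin_size >= 1, all(records$x >= 0), all(records$y >= 0))
  bx <- floor(records$x / bin_size)
  by <- floor(records$y / bin_size)
  bin_id <- paste(bx, by, sep = "_")
  bins <- sort(unique(bin_id))
  bcs <- sort(unique(records$lineage_barcode))
  m <- matrix(0, nrow = length(bins), ncol = length(bcs),
              dimnames = list(bins, bcs))
  agg <- rowsum(as.numeric(records$umi_count),
                group = paste(bin_id, records$lineage_barcode, sep = "\r"))
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  for (i in seq_len(nrow(agg))) {
    m[parts[[i]][1], parts[[i]][2]] <- agg[i, 1]
  }
  m
}
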