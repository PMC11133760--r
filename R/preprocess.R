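# Read-level front end: pair merging, quality and complexity filtering,
# constant-region detection/trimming and the barcode length policy.

#' Configuration for barcode extraction from raw reads
#'
#' Parameter names mirror the conventions of barcode pre-processing
#' pipelines so published settings transcribe directly.
#'
#' @param upconstant Constant sequence 5' of the barcode ("").
#' @param downconstant Constant sequence 3' of the barcode ("").
#' @param constants_mode Which constant regions are required: `"up"`,
#'   `"down"`, `"both"`, `"up_optional_down"` (up required, down trimmed if
#'   found) or `"any"` (at least one).
#' @param constant_error_rate Allowed mismatch fraction within an aligned
#'   constant region, inclusive (default 0.1).
#' @param up_coverage Minimum bases of `upconstant` that must be present when
#'   it is only partially contained at the read start (default: full length).
#' @param down_coverage Same for `downconstant` at the read end.
#' @param minqual Phred threshold for the quality filter (default 20).
#' @param pctqual Percentage of bases that must reach `minqual` (default 80).
#' @param complexity_threshold Minimum sequence complexity in percent
#'   (fraction of adjacent base pairs that differ); 0 disables.
#' @param min_readlength Minimum extracted barcode length in bp (default 1).
#' @param barcode_length Expected barcode length; enforced only when both
#'   flanking constants were found (NULL disables).
#' @param barcode_length_max Maximum allowed barcode length (NULL disables).
#' @param merge_min_overlap Minimum overlap for read-pair merging (default 10).
#' @param merge_max_mismatch_density Maximum mismatch fraction within the
#'   overlap when merging pairs (default 0.25).
#' @return A list of class `extract_config`.
#' @export
extract_config <- function(upconstant = "", downconstant = "",
                           constants_mode = c("up", "down", "both",
                                              "up_optional_down", "any"),
                           constant_error_rate = 0.1,
                           up_coverage = NULL, down_coverage = NULL,
                           minqual = 20, pctqual = 80,
                           complexity_threshold = 0,
                           min_readlength = 1,
                           barcode_length = NULL,
                           barcode_length_max = NULL,
                           merge_min_overlap = 10,
                           merge_max_mismatch_density = 0.25) {
  constants_mode <- match.arg(constants_mode)
  upconstant <- toupper(upconstant)
  downconstant <- toupper(downconstant)
  if (is.null(up_coverage)) up_coverage <- nchar(upconstant)
  if (is.null(down_coverage)) down_coverage <- nchar(downconstant)
  stopifnot(constant_error_rate >= 0, constant_error_rate <= 1,
            up_coverage <= max(nchar(upconstant), 0),
            down_coverage <= max(nchar(downconstant), 0),
            min_readlength >= 1)
  need_up <- constants_mode %in% c("up", "both", "up_optional_down")
  need_down <- constants_mode %in% c("down", "both")
  if (need_up && !nzchar(upconstant)) stop("constants_mode requires upconstant")
  if (need_down && !nzchar(downconstant)) stop("constants_mode requires downconstant")
  if (constants_mode == "any" && !nzchar(upconstant) && !nzchar(downconstant)) {
    stop("constants_mode 'any' requires at least one constant sequence")
  }
  structure(list(
    upconstant = upconstant, downconstant = downconstant,
    constants_mode = constants_mode,
    constant_error_rate = constant_error_rate,
    up_coverage = up_coverage, down_coverage = down_coverage,
    minqual = minqual, pctqual = pctqual,
    complexity_threshold = complexity_threshold,
    min_readlength = min_readlength,
    barcode_length = barcode_length,
    barcode_length_max = barcode_length_max,
    merge_min_overlap = merge_min_overlap,
    merge_max_mismatch_density = merge_max_mismatch_density
  ), class = "extract_config")
}

#' Merge an overlapping read pair into a single consensus read
#'
#' Read 2 is reverse-complemented, candidate overlaps are scored from the
#' longest down to `min_overlap` by mismatch density (N never counts as a
#' match), and the lowest-density overlap at or below
#' `max_mismatch_density` wins, ties broken toward the longer overlap.
#' The consensus takes the higher-quality base at each overlapping position
#' (read 1 on quality ties) and the maximum of the two qualities.
#'
#' @param r1,r2 Single-row reads data.frames (or lists with `seq`, `qual`,
#'   `read_id`); `r2` is the opposite-strand mate.
#' @param min_overlap Minimum overlap length in bp.
#' @param max_mismatch_density Maximum mismatches / overlap length, inclusive.
#' @return A one-row reads data.frame for the merged read, or `NULL` when no
#'   qualifying overlap exists (the pair is rejected, not an error).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10, max_mismatch_density = 0.25) {
  stopifnot(min_overlap >= 1)
  s1 <- toupper(r1$seq[1]); q1 <- phred_to_int(r1$qual[1])
  s2 <- revcomp(toupper(r2$seq[1]))
  q2 <- rev(phred_to_int(r2$qual[1]))
  n1 <- nchar(s1); n2 <- nchar(s2)
  c1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  best <- NULL
  for (o in seq(min(n1, n2), min_overlap)) {
    a <- c1[(n1 - o + 1):n1]
    b <- c2[1:o]
    mm <- sum(a != b | a == "N" | b == "N")
    dens <- mm / o
    if (dens <= max_mismatch_density &&
        (is.null(best) || dens < best$dens)) {
      best <- list(o = o, dens = dens)
    }
  }
  if (is.null(best)) return(NULL)
  o <- best$o
  ov1 <- (n1 - o + 1):n1
  ov2 <- 1:o
  take1 <- q1[ov1] >= q2[ov2]
  cons <- ifelse(take1, c1[ov1], c2[ov2])
  consq <- pmax(q1[ov1], q2[ov2])
  merged_seq <- paste(c(c1[seq_len(n1 - o)], cons, c2[seq(o + 1, length.out = n2 - o)]),
                      collapse = "")
  merged_q <- c(q1[seq_len(n1 - o)], consq, q2[seq(o + 1, length.out = n2 - o)])
  sequenced_reads(r1$read_id[1], merged_seq, int_to_phred(merged_q))
}

#' Phred quality filter
#'
#' A read passes when at least `pctqual` percent of its bases have quality
#' `minqual` or better; the boundary is inclusive.
#'
#' @param r One-row reads data.frame, or a Phred+33 quality string.
#' @param minqual Phred threshold.
#' @param pctqual Required percentage of bases at or above `minqual`.
#' @return Logical.
#' @export
quality_filter <- function(r, minqual = 20, pctqual = 80) {
  qual <- if (is.character(r)) r else r$qual[1]
  q <- phred_to_int(qual)
  if (length(q) == 0L) return(FALSE)
  100 * sum(q >= minqual) / length(q) >= pctqual
}

#' Sequence complexity score
#'
#' Percentage of bases that differ from their next base:
#' 100 x |{i : seq[i] != seq[i+1]}| / (L - 1). Homopolymers score 0, a
#' sequence with no adjacent repeats scores 100.
#'
#' @param seq Character scalar, length >= 2.
#' @return Numeric percent; `NA` for sequences shorter than 2 bases.
#' @export
complexity_score <- function(seq) {
  n <- nchar(seq)
  if (n < 2L) return(NA_real_)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  100 * sum(ch[-n] != ch[-1]) / (n - 1)
}

#' Complexity filter
#'
#' @param seq Character scalar.
#' @param threshold Minimum complexity percent, inclusive.
#' @return Logical; sequences shorter than 2 bases fail.
#' @export
complexity_filter <- function(seq, threshold) {
  sc <- complexity_score(seq)
  !is.na(sc) && sc >= threshold
}

# Enumerate acceptable placements of one constant in a read and pick the
# winner: fewest mismatches, then longest aligned length, then leftmost (up)
# or rightmost (down). Substitution-only; N always counts as a mismatch.
# Returns list(start, end, mismatches, aligned_len) of the occupied read
# span, or NULL.
find_constant <- function(read_chars, constant, side, coverage, error_rate) {
  L <- length(read_chars)
  K <- nchar(constant)
  if (K == 0L) return(NULL)
  kc <- strsplit(constant, "", fixed = TRUE)[[1]]
  cand <- list()
  mism <- function(a, b) sum(a != b | a == "N" | b == "N")
  # full internal placements
  if (L >= K) {
    for (p in 1:(L - K + 1L)) {
      mm <- mism(read_chars[p:(p + K - 1L)], kc)
      if (mm / K <= error_rate) {
        cand[[length(cand) + 1L]] <- list(start = p, end = p + K - 1L,
                                          mismatches = mm, aligned_len = K)
      }
    }
  }
  # partial placements: constant suffix at read start (up) / prefix at read
  # end (down), covering >= coverage bases
  cmax <- min(K - 1L, L)
  if (coverage >= 1L && cmax >= coverage) {
    for (cv in coverage:cmax) {
      if (side == "up") {
        mm <- mism(read_chars[1:cv], kc[(K - cv + 1L):K])
        pos <- list(start = 1L, end = cv)
      } else {
        mm <- mism(read_chars[(L - cv + 1L):L], kc[1:cv])
        pos <- list(start = L - cv + 1L, end = L)
      }
      if (mm / cv <= error_rate) {
        cand[[length(cand) + 1L]] <- c(pos, list(mismatches = mm, aligned_len = cv))
      }
    }
  }
  if (!length(cand)) return(NULL)
  mms <- vapply(cand, `[[`, numeric(1), "mismatches")
  lens <- vapply(cand, `[[`, numeric(1), "aligned_len")
  starts <- vapply(cand, `[[`, numeric(1), "start")
  pos_key <- if (side == "up") starts else -starts
  ord <- order(mms, -lens, pos_key)
  cand[[ord[1]]]
}

#' Locate and trim constant regions, extracting the variable barcode
#'
#' Constants are matched substitution-only, either as full internal matches
#' or as partial anchors (the tail of the upstream constant at the read
#' start, the head of the downstream constant at the read end) covering at
#' least `up_coverage`/`down_coverage` bases. A placement is acceptable when
#' its mismatch fraction is at most `constant_error_rate`; ties resolve to
#' fewest mismatches, then longest aligned length, then leftmost (up) or
#' rightmost (down). The barcode is the read segment strictly between the
#' trimmed regions, then subjected to the length policy (`min_readlength`,
#' `barcode_length_max`, and exact `barcode_length` when both flanks were
#' found).
#'
#' @param r One-row reads data.frame.
#' @param cfg An [extract_config()].
#' @return A list with `barcode_seq`, `found_up`, `found_down` and
#'   `trimmed_read` (one-row reads data.frame); or, when the read fails, a
#'   `trim_rejection` object whose `$reason` is one of `constant`,
#'   `conflict`, `too_short`, `too_long`, `wrong_length` (rejections are
#'   counted in QC, never errors).
#' @export
find_and_trim_constants <- function(r, cfg) {
  s <- toupper(r$seq[1])
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(ch)
  reject <- function(reason) structure(list(rejected = TRUE, reason = reason),
                                       class = "trim_rejection")
  search_up <- nzchar(cfg$upconstant) &&
    cfg$constants_mode %in% c("up", "both", "up_optional_down", "any")
  search_down <- nzchar(cfg$downconstant) &&
    cfg$constants_mode %in% c("down", "both", "up_optional_down", "any")
  up <- if (search_up) {
    find_constant(ch, cfg$upconstant, "up", cfg$up_coverage, cfg$constant_error_rate)
  } else NULL
  down <- if (search_down) {
    find_constant(ch, cfg$downconstant, "down", cfg$down_coverage, cfg$constant_error_rate)
  } else NULL
  found_up <- !is.null(up)
  found_down <- !is.null(down)
  ok <- switch(cfg$constants_mode,
    up = found_up,
    down = found_down,
    both = found_up && found_down,
    up_optional_down = found_up,
    any = found_up || found_down
  )
  if (!ok) return(reject("constant"))
  from <- if (found_up) up$end + 1L else 1L
  to <- if (found_down) down$start - 1L else L
  if (found_up && found_down && down$start <= up$end) return(reject("conflict"))
  bc_len <- max(0L, to - from + 1L)
  barcode <- if (bc_len > 0L) substr(s, from, to) else ""
  if (bc_len < cfg$min_readlength) return(reject("too_short"))
  if (!is.null(cfg$barcode_length_max) && bc_len > cfg$barcode_length_max) {
    return(reject("too_long"))
  }
  if (!is.null(cfg$barcode_length) && found_up && found_down &&
      bc_len != cfg$barcode_length) {
    return(reject("wrong_length"))
  }
  trimmed <- sequenced_reads(r$read_id[1], barcode,
                             substr(r$qual[1], from, to))
  list(barcode_seq = barcode, found_up = found_up, found_down = found_down,
       trimmed_read = trimmed)
}

# TRUE when find_and_trim_constants returned a rejection marker.
is_trim_rejection <- function(x) inherits(x, "trim_rejection")

#' Trim extracted barcodes to a common length
#'
#' Reference-free path only: unless both flanking constants were trimmed
#' (in which case full-length variable barcodes are retained), all barcodes
#' are truncated from the 3' end to the shortest observed length, so that
#' clustering compares like with like.
#'
#' @param barcodes Character vector of extracted barcode sequences.
#' @param cfg An [extract_config()]; only `constants_mode` is consulted.
#' @return Character vector.
#' @export
trim_to_common_length <- function(barcodes, cfg) {
  if (length(barcodes) == 0L) return(barcodes)
  if (cfg$constants_mode == "both") return(barcodes)
  substr(barcodes, 1L, min(nchar(barcodes)))
}

#' Barcode length bounds implied by the construct geometry
#'
#' For a construct read of fixed length containing a stagger, a UMI, a
#' primer region and a downstream constant anchor, the longest extractable
#' barcode is `read_len - stagger_min - umi_len - primer_len -
#' down_anchor_len`. The lower bound is not derivable from the geometry and
#' is a user-supplied floor (default 1).
#'
#' @param read_len Sequenced read length in bp.
#' @param stagger_min,stagger_max Stagger length range in bp.
#' @param umi_len UMI length in bp.
#' @param primer_len Primer region length in bp.
#' @param down_anchor_len Downstream constant anchor length in bp.
#' @param min_floor User-supplied minimum barcode length (default 1).
#' @return List with `min_possible` and `max_possible` (bp).
#' @export
barcode_length_bounds <- function(read_len, stagger_min = 0, stagger_max = 6,
                                  umi_len = 0, primer_len = 0,
                                  down_anchor_len = 0, min_floor = 1) {
  stopifnot(read_len > 0, stagger_min >= 0, stagger_max >= stagger_min,
            umi_len >= 0, primer_len >= 0, down_anchor_len >= 0)
  max_possible <- read_len - stagger_min - umi_len - primer_len - down_anchor_len
  if (max_possible <= 0) {
    stop("fixed regions leave no room for a barcode (max_possible <= 0)")
  }
  list(min_possible = min_floor, max_possible = max_possible)
}

#' Accepted barcode length window for cluster-distance-bounded extraction
#'
#' Tools that restrict accepted barcode lengths to the nominal length plus
#' or minus the Levenshtein clustering distance accept the window
#' `[nominal - distance, nominal + distance]`.
#'
#' @param nominal_length Nominal barcode length in bp.
#' @param cluster_distance Levenshtein clustering radius.
#' @return List with `lower` and `upper` (bp).
#' @export
accepted_length_window <- function(nominal_length, cluster_distance) {
  stopifnot(nominal_length >= 1, cluster_distance >= 0)
  list(lower = nominal_length - cluster_distance,
       upper = nominal_length + cluster_distance)
}
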