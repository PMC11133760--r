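# Quantification: reference-based assignment of extracted barcodes and
# reference-free Levenshtein clustering, plus counts-matrix assembly.

#' Configuration for reference-based barcode assignment
#'
#' @param max_mismatches Maximum Hamming mismatches allowed (0-3).
#' @return List of class `align_config`.
#' @export
align_config <- function(max_mismatches = 1) {
  stopifnot(max_mismatches >= 0, max_mismatches <= 3)
  structure(list(max_mismatches = as.integer(max_mismatches)),
            class = "align_config")
}

#' Configuration for reference-free barcode clustering
#'
#' @param distance Levenshtein clustering radius (default 3).
#' @param ratio Merge ratio: a sequence is absorbed by a centroid only when
#'   the centroid's own tally is at least `ratio` times the sequence's
#'   (default 5).
#' @return List of class `cluster_config`.
#' @export
cluster_config <- function(distance = 3, ratio = 5) {
  stopifnot(distance >= 0, ratio >= 1)
  structure(list(distance = as.integer(distance), ratio = ratio),
            class = "cluster_config")
}

#' Assign one extracted barcode to a reference library
#'
#' Full-length barcodes are compared to each entry by Hamming distance.
#' Shorter barcodes are anchored: they are compared against the length-
#' matched prefix and suffix of each (longer) entry only, reflecting reads
#' that cover only the start or end of a fixed-length barcode. The best
#' distance within `max_mismatches` wins; two or more entries tied at the
#' best distance is ambiguous and yields no assignment.
#'
#' @param b Barcode sequence (non-empty).
#' @param ref A `barcode_reference`.
#' @param cfg An [align_config()].
#' @return The winning barcode name, or `NA_character_` with attribute
#'   `reason` = `"ambiguous"` or `"unmapped"` when no single hit exists.
#' @export
assign_to_reference <- function(b, ref, cfg = align_config()) {
  stopifnot(nzchar(b))
  b <- toupper(b)
  entries <- ref$entries
  lens <- nchar(entries)
  nb <- nchar(b)
  dists <- rep(NA_integer_, length(entries))
  eq <- lens == nb
  if (any(eq)) dists[eq] <- hamming_many(b, entries[eq])
  longer <- lens > nb
  if (any(longer)) {
    pre <- hamming_many(b, substr(entries[longer], 1L, nb))
    suf <- hamming_many(b, substr(entries[longer], lens[longer] - nb + 1L,
                                  lens[longer]))
    dists[longer] <- pmin(pre, suf)
  }
  unassigned <- function(reason) structure(NA_character_, reason = reason)
  if (all(is.na(dists))) return(unassigned("unmapped"))
  best <- min(dists, na.rm = TRUE)
  if (best > cfg$max_mismatches) return(unassigned("unmapped"))
  hits <- which(!is.na(dists) & dists == best)
  if (length(hits) > 1L) return(unassigned("ambiguous"))
  names(entries)[hits]
}

#' Assign many barcodes to a reference library
#'
#' Vectorised wrapper around [assign_to_reference()] that memoises repeated
#' sequences (error-free data collapses to few distinct queries).
#'
#' @param barcodes Character vector of extracted barcode sequences.
#' @inheritParams assign_to_reference
#' @return Character vector of names (`NA` where unassigned) with attribute
#'   `qc` = counts of `aligned`, `ambiguous`, `unmapped`.
#' @export
assign_many <- function(barcodes, ref, cfg = align_config()) {
  uniq <- unique(barcodes)
  res <- vapply(uniq, function(b) {
    a <- assign_to_reference(b, ref, cfg)
    if (is.na(a)) paste0(".", attr(a, "reason")) else a
  }, character(1))
  full <- res[match(barcodes, uniq)]
  out <- ifelse(startsWith(full, "."), NA_character_, full)
  attr(out, "qc") <- c(aligned = sum(!is.na(out)),
                       ambiguous = sum(full == ".ambiguous"),
                       unmapped = sum(full == ".unmapped"))
  out
}

# Greedy sphere clustering shared by barcode clustering and UMI collapse.
# Sequences are visited by count descending (ties lexicographic); each
# becomes a new centroid unless an existing centroid lies within `distance`
# AND its canonical (original) tally is at least `ratio` times the
# sequence's tally. Among several admissible centroids the nearest wins,
# then the higher canonical tally, then lexicographic order.
# Returns a data.frame(seq, count, centroid).
greedy_sphere_cluster <- function(tallies, distance, ratio) {
  if (length(tallies) == 0L) {
    return(data.frame(seq = character(0), count = numeric(0),
                      centroid = character(0), stringsAsFactors = FALSE))
  }
  seqs <- names(tallies)
  counts <- as.numeric(tallies)
  ord <- order(-counts, seqs)
  seqs <- seqs[ord]; counts <- counts[ord]
  cent_seq <- character(0)
  cent_canon <- numeric(0)
  assigned <- character(length(seqs))
  for (i in seq_along(seqs)) {
    target <- NA_integer_
    if (length(cent_seq)) {
      admissible <- which(cent_canon >= ratio * counts[i])
      if (length(admissible)) {
        dd <- levenshtein(seqs[i], cent_seq[admissible])
        ok <- dd <= distance
        if (any(ok)) {
          cand <- admissible[ok]
          dcand <- dd[ok]
          sel <- order(dcand, -cent_canon[cand], cent_seq[cand])[1]
          target <- cand[sel]
        }
      }
    }
    if (is.na(target)) {
      cent_seq <- c(cent_seq, seqs[i])
      cent_canon <- c(cent_canon, counts[i])
      assigned[i] <- seqs[i]
    } else {
      assigned[i] <- cent_seq[target]
    }
  }
  data.frame(seq = seqs, count = counts, centroid = assigned,
             stringsAsFactors = FALSE)
}

#' Reference-free clustering of barcode tallies
#'
#' Greedy sphere absorption: sequences are visited in count-descending
#' order (ties lexicographic); each either joins an existing centroid
#' within the Levenshtein `distance` whose original tally is at least
#' `ratio` times its own, or founds a new centroid. Total count mass is
#' conserved exactly.
#'
#' @param tallies Named numeric vector (sequence -> count, all counts > 0).
#' @param cfg A [cluster_config()].
#' @return Named numeric vector, centroid sequence -> merged count.
#' @export
cluster_reference_free <- function(tallies, cfg = cluster_config()) {
  if (length(tallies) == 0L) return(stats::setNames(numeric(0), character(0)))
  stopifnot(all(tallies > 0))
  asg <- greedy_sphere_cluster(tallies, cfg$distance, cfg$ratio)
  agg <- rowsum(asg$count, group = asg$centroid, reorder = FALSE)
  stats::setNames(agg[, 1], rownames(agg))
}

#' Tally assigned barcode names for one sample
#'
#' @param assignments Character vector of barcode names or centroid
#'   sequences; `NA`s (unassigned reads) are dropped.
#' @return Named numeric vector of counts.
#' @export
count_sample <- function(assignments) {
  assignments <- assignments[!is.na(assignments)]
  if (length(assignments) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(assignments)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Combine per-sample tallies into a counts matrix
#'
#' Unions barcode names over samples and fills zeros; column sums equal the
#' per-sample assigned-read totals. Duplicate sample names are an error.
#'
#' @param per_sample Named list of named numeric vectors.
#' @return Numeric matrix (barcodes x samples).
#' @export
combine_samples <- function(per_sample) {
  counts_from_tallies(per_sample)
}

#' Keep barcodes present in both PCR replicates and average their counts
#'
#' A barcode survives only when it reaches `min_reads` in both replicates;
#' its value is the arithmetic mean of the two replicate counts.
#'
#' @param rep1,rep2 Named numeric vectors for the two PCR replicates of one
#'   biological sample.
#' @param min_reads Minimum count required in each replicate (default 5).
#' @return Named numeric vector of mean counts.
#' @export
replicate_intersection_filter <- function(rep1, rep2, min_reads = 5) {
  shared <- intersect(names(rep1), names(rep2))
  keep <- shared[rep1[shared] >= min_reads & rep2[shared] >= min_reads]
  stats::setNames((rep1[keep] + rep2[keep]) / 2, keep)
}
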