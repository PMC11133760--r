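# Low-level sequence helpers shared across modules.

PHRED_OFFSET <- 33L

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual Character scalar, one ASCII character per base.
#' @return Integer vector of Phred scores (0-93).
#' @export
phred_to_int <- function(qual) {
  if (!nzchar(qual)) return(integer(0))
  as.integer(charToRaw(qual)) - PHRED_OFFSET
}

#' Encode integer Phred scores as a Phred+33 quality string
#'
#' @param q Integer vector of Phred scores (0-93).
#' @return Character scalar.
#' @export
int_to_phred <- function(q) {
  stopifnot(all(q >= 0L), all(q <= 93L))
  rawToChar(as.raw(q + PHRED_OFFSET))
}

#' Reverse complement of a DNA sequence
#'
#' N maps to N; input restricted to A, C, G, T, N.
#' @param seq Character scalar.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  if (!nzchar(seq)) return(seq)
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Hamming distance between equal-length strings. N counts as a mismatch
# against anything, including another N (conservative).
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (!nzchar(a)) return(0L)
  av <- charToRaw(a)
  bv <- charToRaw(b)
  n_raw <- charToRaw("N")
  sum(av != bv | av == n_raw | bv == n_raw)
}

# Vectorised Hamming distance of one query against many equal-length subjects.
hamming_many <- function(query, subjects) {
  vapply(subjects, function(s) hamming(query, s), integer(1), USE.NAMES = FALSE)
}

#' Levenshtein distance between sequences
#'
#' Unit-cost edit distance (substitution, insertion, deletion), used for
#' reference-free barcode clustering and UMI collapsing.
#'
#' @param a Character scalar.
#' @param b Character vector.
#' @return Integer vector of distances, one per element of `b`.
#' @export
levenshtein <- function(a, b) {
  as.integer(utils::adist(a, b))
}

# Expand an IUPAC pattern string into a list of per-position alphabets.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_alphabets <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  IUPAC_CODES[chars]
}

# Does `seq` match an IUPAC pattern exactly (same length, every position in
# the allowed alphabet)?
matches_iupac <- function(seq, pattern) {
  alph <- iupac_alphabets(pattern)
  if (nchar(seq) != length(alph)) return(FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  all(mapply(function(ch, al) ch %in% al, chars, alph))
}

# Random DNA of given length under the current RNG state.
random_dna <- function(n_bases) {
  if (n_bases == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}
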