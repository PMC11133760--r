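# Readers and writers for the external formats the pipeline touches:
# FASTQ (plain or gzip), FASTA barcode references, tagged SAM/BAM records,
# per-sample and combined counts tables, sample sheets and whitelists.

#' Construct a table of sequenced reads
#'
#' The in-memory form of a FASTQ file: one row per read with the identifier,
#' sequence and Phred+33-encoded quality string. Sequence and quality must
#' have equal length per read and sequences must be non-empty.
#'
#' @param read_id Character vector of read identifiers.
#' @param seq Character vector of sequences over A, C, G, T, N.
#' @param qual Character vector of Phred+33 quality strings.
#' @return A data.frame with columns `read_id`, `seq`, `qual`.
#' @export
sequenced_reads <- function(read_id, seq, qual) {
  stopifnot(length(read_id) == length(seq), length(seq) == length(qual))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("sequence/quality length mismatch at record ", bad[1])
  }
  if (any(!nzchar(seq))) stop("empty sequence at record ", which(!nzchar(seq))[1])
  data.frame(read_id = as.character(read_id), seq = toupper(seq),
             qual = qual, stringsAsFactors = FALSE)
}

read_lines_auto <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

#' Read a FASTQ file (optionally a pair of files)
#'
#' Four-line records, Phred+33 qualities; gzip is autodetected from the
#' `.gz` suffix. With `paired_path`, both mates are read and must contain
#' the same number of records.
#'
#' @param path FASTQ file for read 1 (or the only read).
#' @param paired_path Optional FASTQ file for read 2.
#' @return A reads data.frame (see [sequenced_reads()]); for pairs, a list
#'   with elements `r1` and `r2`.
#' @export
read_fastq <- function(path, paired_path = NULL) {
  parse_one <- function(p) {
    lines <- read_lines_auto(p)
    if (length(lines) && !nzchar(lines[length(lines)])) {
      lines <- lines[-length(lines)]
    }
    if (length(lines) %% 4L != 0L) {
      stop("truncated FASTQ record at record ", length(lines) %/% 4L + 1L,
           " in ", p)
    }
    n <- length(lines) %/% 4L
    if (n == 0L) {
      return(data.frame(read_id = character(0), seq = character(0),
                        qual = character(0), stringsAsFactors = FALSE))
    }
    idx <- seq_len(n)
    hdr <- lines[4L * idx - 3L]
    seqs <- lines[4L * idx - 2L]
    plus <- lines[4L * idx - 1L]
    quals <- lines[4L * idx]
    bad_hdr <- which(substr(hdr, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")
    if (length(bad_hdr)) stop("malformed FASTQ record at record ", bad_hdr[1], " in ", p)
    bad_len <- which(nchar(seqs) != nchar(quals))
    if (length(bad_len)) {
      stop("sequence/quality length mismatch at record ", bad_len[1], " in ", p)
    }
    ids <- sub("^@", "", hdr)
    ids <- sub("[ /].*$", "", ids)
    sequenced_reads(ids, seqs, quals)
  }
  r1 <- parse_one(path)
  if (is.null(paired_path)) return(r1)
  r2 <- parse_one(paired_path)
  if (nrow(r1) != nrow(r2)) {
    stop("mate count mismatch: ", nrow(r1), " vs ", nrow(r2), " records")
  }
  list(r1 = r1, r2 = r2)
}

#' Write reads to a FASTQ file
#'
#' @param reads A reads data.frame (see [sequenced_reads()]).
#' @param path Output path; `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(reads)) {
    out <- rbind(paste0("@", reads$read_id), reads$seq, "+", reads$qual)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

#' Read a reference library of known barcodes from FASTA
#'
#' Headers name the barcodes; sequences are uppercased. Duplicate names or
#' duplicate sequences make the reference ambiguous and are an error.
#'
#' @param path FASTA file.
#' @return A `barcode_reference`: list with `entries` (named character vector
#'   of sequences) and `fixed_length` (TRUE iff all sequences share a length).
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  barcode_reference(stats::setNames(toupper(as.character(ss)), names(ss)))
}

#' Construct a barcode reference from a named vector of sequences
#'
#' @param entries Named character vector; names are barcode identifiers.
#' @return A `barcode_reference` object.
#' @export
barcode_reference <- function(entries) {
  if (length(entries) == 0L) stop("empty barcode reference")
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("all reference entries must be named")
  }
  if (anyDuplicated(names(entries))) {
    stop("duplicate barcode name in reference: ",
         names(entries)[duplicated(names(entries))][1])
  }
  entries <- stats::setNames(toupper(as.character(entries)), names(entries))
  if (any(!nzchar(entries))) stop("empty sequence in reference")
  if (anyDuplicated(entries)) {
    stop("duplicate barcode sequence in reference: ",
         entries[duplicated(entries)][1])
  }
  structure(
    list(entries = entries,
         fixed_length = length(unique(nchar(entries))) == 1L),
    class = "barcode_reference"
  )
}

#' @export
print.barcode_reference <- function(x, ...) {
  cat("barcode_reference:", length(x$entries), "barcodes,",
      if (x$fixed_length) paste0("fixed length ", nchar(x$entries[1]), " bp")
      else "variable length", "\n")
  invisible(x)
}

#' Write a barcode reference to FASTA
#'
#' @param ref A `barcode_reference`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(ref$entries)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read cell-barcode/UMI tagged alignment records from SAM or BAM
#'
#' Extracts reads carrying cell-barcode and UMI tags, the route used when
#' lineage-barcode reads are fished out of a single-cell alignment. The
#' corrected scheme reads tags CB/UB, the raw scheme CR/UR. Records lacking
#' the requested tags are skipped and counted.
#'
#' @param path SAM (plain text) or BAM file. SAM input is converted on the
#'   fly.
#' @param tag_scheme `"corrected"` (CB/UB tags) or `"raw"` (CR/UR).
#' @param unmapped_only Keep only records with the unmapped flag set.
#' @return A data.frame with columns `read_id`, `seq`, `qual`, `cell_id`,
#'   `umi`; the number of records skipped for missing tags is attached as
#'   attribute `n_skipped`. Zero yielded records produces a warning.
#' @export
read_tagged_alignments <- function(path, tag_scheme = c("corrected", "raw"),
                                   unmapped_only = FALSE) {
  tag_scheme <- match.arg(tag_scheme)
  tags <- if (tag_scheme == "corrected") c("CB", "UB") else c("CR", "UR")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "seq", "qual", "flag"),
    tag = tags,
    flag = if (unmapped_only) {
      Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)
    } else {
      Rsamtools::scanBamFlag()
    }
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  cell <- res$tag[[tags[1]]]
  umi <- res$tag[[tags[2]]]
  n <- length(res$qname)
  if (is.null(cell)) cell <- rep(NA_character_, n)
  if (is.null(umi)) umi <- rep(NA_character_, n)
  keep <- !is.na(cell) & !is.na(umi)
  out <- data.frame(
    read_id = res$qname[keep],
    seq = as.character(res$seq)[keep],
    qual = as.character(res$qual)[keep],
    cell_id = cell[keep],
    umi = umi[keep],
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) {
    warning("no records with ", paste(tags, collapse = "/"),
            " tags yielded from ", path)
  }
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Assemble a counts matrix from per-sample tallies
#'
#' Takes a named list of per-sample counts (each a named numeric vector,
#' barcode -> count) and returns the barcodes x samples matrix with the
#' union of barcodes as rows and zeros where a barcode was not observed.
#'
#' @param tallies Named list of named non-negative numeric vectors.
#' @return Numeric matrix, rownames barcodes, colnames samples.
#' @export
counts_from_tallies <- function(tallies) {
  if (anyDuplicated(names(tallies))) {
    stop("duplicate sample names: ",
         names(tallies)[duplicated(names(tallies))][1])
  }
  all_bc <- unique(unlist(lapply(tallies, names), use.names = FALSE))
  m <- matrix(0, nrow = length(all_bc), ncol = length(tallies),
              dimnames = list(all_bc, names(tallies)))
  for (s in names(tallies)) {
    v <- tallies[[s]]
    if (length(v)) m[names(v), s] <- as.numeric(v)
  }
  if (any(m < 0)) stop("negative count in tallies")
  m
}

#' Write a counts matrix as TSV
#'
#' Header row `barcode<TAB>sample...`; counts written as integers where
#' integral so that a write/read round trip is exact.
#'
#' @param m Counts matrix (rownames barcodes, colnames samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  fmt <- function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           format(x, digits = 17, scientific = FALSE, trim = TRUE))
  }
  lines <- c(
    paste(c("barcode", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

# Read one counts file: either a two-column per-sample TSV (barcode, count;
# header optional) or a combined matrix TSV with a header row. Duplicate
# barcode rows are summed with a warning.
read_counts_file <- function(path, sample_id = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts file needs at least two columns: ", path)
  # Headerless two-column files surface the first data row as a header;
  # detect a numeric second column name and re-read.
  if (ncol(df) == 2L && !is.na(suppressWarnings(as.numeric(names(df)[2])))) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("barcode", if (is.null(sample_id)) "count" else sample_id)
  }
  bc <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(is.na(vals))) stop("non-numeric count in ", path)
  if (any(vals < 0)) stop("negative count in ", path)
  if (anyDuplicated(bc)) {
    warning("duplicate barcode rows summed in ", path)
    vals <- rowsum(vals, group = bc, reorder = FALSE)
    bc <- rownames(vals)
  }
  rownames(vals) <- bc
  vals
}

#' Read a sample sheet
#'
#' CSV with mandatory columns `sample` and `counts_path` plus arbitrary
#' metadata columns. Relative counts paths are resolved against the sheet's
#' directory.
#'
#' @param path CSV file.
#' @return data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "counts_path")
  miss <- setdiff(req, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample)) {
    stop("duplicate sample_id in sheet: ", sheet$sample[duplicated(sheet$sample)][1])
  }
  rel <- !file.exists(sheet$counts_path)
  sheet$counts_path[rel] <- file.path(dirname(path), sheet$counts_path[rel])
  sheet
}

#' Read counts for all samples of a sample sheet
#'
#' Loads each sample's counts file, unions the barcode sets across samples
#' (zero-filling unobserved barcodes) and attaches the sheet's metadata.
#'
#' @param sheet data.frame from [read_sample_sheet()] (or equivalent).
#' @return An `annotated_counts` object (see [annotated_counts()]).
#' @export
read_counts <- function(sheet) {
  missing_file <- !file.exists(sheet$counts_path)
  if (any(missing_file)) {
    stop("counts file not found for sample ", sheet$sample[missing_file][1],
         ": ", sheet$counts_path[missing_file][1])
  }
  tallies <- list()
  for (i in seq_len(nrow(sheet))) {
    vals <- read_counts_file(sheet$counts_path[i], sample_id = sheet$sample[i])
    if (ncol(vals) == 1L) {
      tallies[[sheet$sample[i]]] <- stats::setNames(vals[, 1], rownames(vals))
    } else {
      if (!sheet$sample[i] %in% colnames(vals)) {
        stop("sample ", sheet$sample[i], " not found in matrix file ",
             sheet$counts_path[i])
      }
      tallies[[sheet$sample[i]]] <- stats::setNames(vals[, sheet$sample[i]],
                                                    rownames(vals))
    }
  }
  meta <- sheet[, setdiff(names(sheet), "counts_path"), drop = FALSE]
  rownames(meta) <- meta$sample
  annotated_counts(counts_from_tallies(tallies), meta)
}

#' Read a cell-barcode whitelist
#'
#' Plain text, one accepted cell barcode per line.
#'
#' @param path Text file.
#' @return Character vector.
#' @export
read_whitelist <- function(path) {
  wl <- read_lines_auto(path)
  wl <- wl[nzchar(wl)]
  unique(wl)
}

#' Write a per-cell lineage annotation table as TSV
#'
#' Columns `cell_id`, `barcodes` (comma-separated, UMI-count descending) and
#' `umi_counts` (parallel comma-separated integers).
#'
#' @param table data.frame from [annotate_cells()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  utils::write.table(table[, c("cell_id", "barcodes", "umi_counts")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell lineage annotation table written by [write_cell_table()]
#'
#' @param path TSV path.
#' @return data.frame with columns `cell_id`, `barcodes`, `umi_counts`.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df
}
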