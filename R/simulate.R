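# Seeded synthetic-data generator: barcode libraries, bulk barcode-seq
# reads, and single-cell/spatial barcode amplicon reads with known ground
# truth (clone abundances, cell-clone assignments, planted chimeras).

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate a semi-random lineage barcode library (20 repeats of
#' the IUPAC triplet "WSN", 60 bp) flanked by short constant regions, with
#' a 0-6 bp stagger, log-normal clone abundances and a two-point Phred
#' model (high-quality bases Q37, error-prone bases Q14).
#'
#' @param n_barcodes Library size (default 50).
#' @param barcode_pattern IUPAC pattern, e.g. `strrep("WSN", 20)`.
#' @param clone_abundance Either `list(meanlog=, sdlog=)` for log-normal
#'   abundances or an explicit numeric vector of length `n_barcodes`.
#' @param upconstant,downconstant Flanking constant sequences.
#' @param stagger_range Integer pair, inclusive stagger length range.
#' @param read_len Read length in bp (default 100).
#' @param sub_error_rate Per-base substitution probability (default 0).
#' @param phred_high,phred_low Two-point quality model (default 37 / 14).
#' @param n_reads Bulk reads to emit (default 10000).
#' @param paired Emit overlapping paired-end mates (default FALSE).
#' @param fragment_extra Extra fragment length beyond `read_len` in
#'   paired mode, controlling the mate overlap (default 20).
#' @param n_cells Single-cell: number of cells (default 100).
#' @param barcodes_per_cell Lineage barcodes per cell (default 1).
#' @param cb_len,umi_len Cell-barcode and UMI lengths (default 16 / 10).
#' @param umis_per_molecule_lambda Poisson rate for molecules (UMIs) per
#'   (cell, barcode), shifted by +1 (default 10).
#' @param reads_per_umi_lambda Poisson rate for reads per molecule, shifted
#'   by +2 so every molecule has at least two supporting reads (default 2).
#' @param chimera_rate Per-molecule probability of planting a PCR chimera
#'   reusing the (cell, UMI) with a different lineage barcode at strictly
#'   lower read support (default 0).
#' @param chimera_ties Plant chimeras at equal read support instead, to
#'   exercise ambiguous-tie removal (default FALSE).
#' @param umi_error_rate Per-read probability of a one-base UMI
#'   substitution (default 0).
#' @param seed Integer seed fixing all randomness.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_barcodes = 50,
                       barcode_pattern = strrep("WSN", 20),
                       clone_abundance = list(meanlog = 0, sdlog = 1),
                       upconstant = "CGATTGACTA",
                       downconstant = "TGCTAATGCG",
                       stagger_range = c(0, 6),
                       read_len = 100,
                       sub_error_rate = 0,
                       phred_high = 37, phred_low = 14,
                       n_reads = 10000,
                       paired = FALSE,
                       fragment_extra = 20,
                       n_cells = 100,
                       barcodes_per_cell = 1,
                       cb_len = 16, umi_len = 10,
                       umis_per_molecule_lambda = 10,
                       reads_per_umi_lambda = 2,
                       chimera_rate = 0,
                       chimera_ties = FALSE,
                       umi_error_rate = 0,
                       seed = 1) {
  stopifnot(n_barcodes >= 1, sub_error_rate >= 0, sub_error_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            umi_error_rate >= 0, umi_error_rate <= 1,
            stagger_range[1] >= 0, stagger_range[2] >= stagger_range[1])
  structure(as.list(environment()), class = "sim_config")
}

# Substitute each base independently with probability `rate`, always to a
# different base. Returns list(seq, errored = logical per position).
apply_substitutions <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  list(seq = paste(ch, collapse = ""), errored = hit)
}

two_point_qual <- function(errored, high, low) {
  int_to_phred(ifelse(errored, low, high))
}

#' Generate a lineage barcode library
#'
#' Sequences are sampled position-wise from the IUPAC pattern; uniqueness
#' is enforced by rejection. Deterministic under the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A `barcode_reference` with entries named `BC_1 ... BC_n`.
#' @export
generate_library <- function(cfg) {
  alph <- iupac_alphabets(cfg$barcode_pattern)
  space <- prod(vapply(alph, length, integer(1)))
  if (cfg$n_barcodes > space) {
    stop("n_barcodes (", cfg$n_barcodes, ") exceeds pattern space (", space, ")")
  }
  set.seed(cfg$seed)
  seqs <- character(0)
  while (length(seqs) < cfg$n_barcodes) {
    need <- cfg$n_barcodes - length(seqs)
    new <- vapply(seq_len(need), function(i) {
      paste(vapply(alph, function(a) if (length(a) == 1L) a else sample(a, 1),
                   character(1)), collapse = "")
    }, character(1))
    seqs <- unique(c(seqs, new))
  }
  barcode_reference(stats::setNames(seqs, paste0("BC_", seq_along(seqs))))
}

# Draw realized clone abundance probabilities for a library.
clone_probs <- function(cfg, n) {
  if (is.numeric(cfg$clone_abundance)) {
    stopifnot(length(cfg$clone_abundance) == n)
    ab <- cfg$clone_abundance
  } else {
    ab <- stats::rlnorm(n, cfg$clone_abundance$meanlog, cfg$clone_abundance$sdlog)
  }
  ab / sum(ab)
}

#' Simulate a bulk barcode-seq sample
#'
#' Each read is stagger + upconstant + barcode + downconstant + random pad,
#' truncated to `read_len`, with i.i.d. substitution errors; substituted
#' positions carry the low Phred value, all others the high one. In paired
#' mode two overlapping mates of a longer fragment are emitted. Truth
#' counts are the realized reads per barcode (they sum to `n_reads`).
#'
#' @param cfg A [sim_config()].
#' @param library A `barcode_reference` (e.g. from [generate_library()]).
#' @param dir Optional directory; when given, FASTQ, the library FASTA, and
#'   truth TSV/JSON are written there.
#' @param sample_id Sample name used in file names (default `"sim"`).
#' @return List with `reads` (and `reads2` when paired), `truth` (named
#'   numeric vector, barcode name -> true read count), `library`, and file
#'   `paths` when `dir` was given.
#' @export
simulate_bulk <- function(cfg, library = generate_library(cfg), dir = NULL,
                          sample_id = "sim") {
  set.seed(cfg$seed + 1L)
  entries <- library$entries
  probs <- clone_probs(cfg, length(entries))
  min_len <- cfg$stagger_range[2] + nchar(cfg$upconstant) +
    max(nchar(entries)) + nchar(cfg$downconstant)
  if (cfg$read_len < min_len && !cfg$paired) {
    stop("read_len must cover stagger + constants + barcode (", min_len, " bp)")
  }
  draws <- sample(names(entries), cfg$n_reads, replace = TRUE, prob = probs)
  truth <- stats::setNames(numeric(length(entries)), names(entries))
  tab <- table(draws)
  truth[names(tab)] <- as.numeric(tab)
  ids <- sprintf("read_%06d", seq_len(cfg$n_reads))
  frag_len <- if (cfg$paired) cfg$read_len + cfg$fragment_extra else cfg$read_len
  seqs <- character(cfg$n_reads)
  quals <- character(cfg$n_reads)
  seqs2 <- character(cfg$n_reads)
  quals2 <- character(cfg$n_reads)
  for (i in seq_len(cfg$n_reads)) {
    stag <- sample(cfg$stagger_range[1]:cfg$stagger_range[2], 1)
    core <- paste0(random_dna(stag), cfg$upconstant, entries[draws[i]],
                   cfg$downconstant)
    pad <- max(0L, frag_len - nchar(core))
    frag <- substr(paste0(core, random_dna(pad)), 1L, frag_len)
    r1 <- apply_substitutions(substr(frag, 1L, cfg$read_len), cfg$sub_error_rate)
    seqs[i] <- r1$seq
    quals[i] <- two_point_qual(r1$errored, cfg$phred_high, cfg$phred_low)
    if (cfg$paired) {
      mate <- revcomp(substr(frag, frag_len - cfg$read_len + 1L, frag_len))
      r2 <- apply_substitutions(mate, cfg$sub_error_rate)
      seqs2[i] <- r2$seq
      quals2[i] <- two_point_qual(r2$errored, cfg$phred_high, cfg$phred_low)
    }
  }
  out <- list(reads = sequenced_reads(ids, seqs, quals),
              truth = truth, library = library)
  if (cfg$paired) out$reads2 <- sequenced_reads(ids, seqs2, quals2)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fastq = file.path(dir, paste0(sample_id, "_R1.fastq")),
      reference = file.path(dir, "library.fasta"),
      truth = file.path(dir, paste0(sample_id, "_truth.tsv"))
    )
    write_fastq(out$reads, paths$fastq)
    if (cfg$paired) {
      paths$fastq2 <- file.path(dir, paste0(sample_id, "_R2.fastq"))
      write_fastq(out$reads2, paths$fastq2)
    }
    write_reference_fasta(library, paths$reference)
    utils::write.table(
      data.frame(barcode = names(truth), count = as.integer(truth)),
      paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Simulate a single-cell lineage barcode amplicon library
#'
#' Each cell carries `barcodes_per_cell` lineage barcodes; every
#' (cell, barcode) gets a Poisson number of molecules, each with a unique
#' UMI and a Poisson read support of at least two. Read 1 is cell barcode +
#' UMI, read 2 is upconstant + lineage barcode + downconstant + pad. With
#' probability `chimera_rate` a molecule additionally emits a chimeric
#' record reusing its (cell, UMI) with a different lineage barcode at
#' strictly lower (or, with `chimera_ties`, equal) read support. UMI errors
#' substitute one UMI base per read at `umi_error_rate`.
#'
#' @param cfg A [sim_config()].
#' @param library A `barcode_reference`.
#' @param dir Optional output directory for FASTQ/whitelist/truth files.
#' @param sam Also write a tagged SAM file (unmapped records with CB/UB
#'   tags carrying the truth cell barcode and UMI) when `dir` is given.
#' @return List with `reads1`, `reads2`, `whitelist`, `truth` (data.frame
#'   `cell_id`, `barcode`, `n_molecules`), `chimeras` (data.frame of
#'   planted chimeric records), `library`, and `paths` when `dir` given.
#' @export
simulate_sc <- function(cfg, library = generate_library(cfg), dir = NULL,
                        sam = FALSE) {
  set.seed(cfg$seed + 2L)
  entries <- library$entries
  probs <- clone_probs(cfg, length(entries))
  # unique cell barcodes
  cells <- character(0)
  while (length(cells) < cfg$n_cells) {
    cells <- unique(c(cells, vapply(seq_len(cfg$n_cells - length(cells)),
                                    function(i) random_dna(cfg$cb_len),
                                    character(1))))
  }
  truth <- list(); chims <- list()
  r1_seq <- character(0); r2_seq <- character(0); rid <- character(0)
  r1_cell <- character(0); r1_umi <- character(0)
  read_n <- 0L
  for (ci in seq_along(cells)) {
    cell <- cells[ci]
    bcs <- sample(names(entries), cfg$barcodes_per_cell, replace = FALSE,
                  prob = probs)
    umis_used <- character(0)
    for (bc in bcs) {
      n_mol <- stats::rpois(1, cfg$umis_per_molecule_lambda) + 1L
      truth[[length(truth) + 1L]] <- data.frame(
        cell_id = cell, barcode = bc, n_molecules = n_mol,
        stringsAsFactors = FALSE)
      for (m in seq_len(n_mol)) {
        repeat {
          umi <- random_dna(cfg$umi_len)
          if (!umi %in% umis_used) break
        }
        umis_used <- c(umis_used, umi)
        support <- stats::rpois(1, cfg$reads_per_umi_lambda) + 2L
        emit <- function(lineage_bc, n_copies) {
          for (r in seq_len(n_copies)) {
            read_n <<- read_n + 1L
            u <- umi
            if (stats::runif(1) < cfg$umi_error_rate) {
              pos <- sample(cfg$umi_len, 1)
              base <- substr(u, pos, pos)
              substr(u, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                                    base), 1)
            }
            rid <<- c(rid, sprintf("scread_%07d", read_n))
            r1_seq <<- c(r1_seq, paste0(cell, u))
            pad <- cfg$read_len - nchar(cfg$upconstant) -
              nchar(entries[lineage_bc]) - nchar(cfg$downconstant)
            r2_seq <<- c(r2_seq, paste0(cfg$upconstant, entries[lineage_bc],
                                        cfg$downconstant,
                                        random_dna(max(0L, pad))))
            r1_cell <<- c(r1_cell, cell)
            r1_umi <<- c(r1_umi, u)
          }
        }
        emit(bc, support)
        if (stats::runif(1) < cfg$chimera_rate) {
          other <- sample(setdiff(names(entries), bc), 1)
          chi_support <- if (cfg$chimera_ties) support else support - 1L
          emit(other, chi_support)
          chims[[length(chims) + 1L]] <- data.frame(
            cell_id = cell, umi = umi, true_barcode = bc,
            chimera_barcode = other, true_support = support,
            chimera_support = chi_support, stringsAsFactors = FALSE)
        }
      }
    }
  }
  hi <- cfg$phred_high
  out <- list(
    reads1 = sequenced_reads(rid, r1_seq,
                             vapply(nchar(r1_seq), function(n)
                               int_to_phred(rep(hi, n)), character(1))),
    reads2 = sequenced_reads(rid, r2_seq,
                             vapply(nchar(r2_seq), function(n)
                               int_to_phred(rep(hi, n)), character(1))),
    whitelist = cells,
    truth = do.call(rbind, truth),
    chimeras = if (length(chims)) do.call(rbind, chims) else
      data.frame(cell_id = character(0), umi = character(0),
                 true_barcode = character(0), chimera_barcode = character(0),
                 true_support = integer(0), chimera_support = integer(0)),
    library = library
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fastq1 = file.path(dir, "sc_R1.fastq"),
      fastq2 = file.path(dir, "sc_R2.fastq"),
      whitelist = file.path(dir, "whitelist.txt"),
      reference = file.path(dir, "library.fasta"),
      truth = file.path(dir, "sc_truth.tsv")
    )
    write_fastq(out$reads1, paths$fastq1)
    write_fastq(out$reads2, paths$fastq2)
    writeLines(out$whitelist, paths$whitelist)
    write_reference_fasta(library, paths$reference)
    utils::write.table(out$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (sam) {
      paths$sam <- file.path(dir, "sc_tagged.sam")
      write_tagged_sam(out$reads2, r1_cell, r1_umi, paths$sam)
    }
    out$paths <- paths
  }
  out
}

#' Write reads as unmapped SAM records with cell-barcode and UMI tags
#'
#' Emits one unmapped record per read with CB/UB (and matching CR/UR) tags,
#' the form produced by extracting barcode reads from a single-cell
#' alignment.
#'
#' @param reads Reads data.frame (sequence source).
#' @param cell_ids,umis Character vectors parallel to `reads`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_tagged_sam <- function(reads, cell_ids, umis, path) {
  stopifnot(nrow(reads) == length(cell_ids), nrow(reads) == length(umis))
  header <- "@HD\tVN:1.6\tSO:unsorted"
  body <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s\tCB:Z:%s\tUB:Z:%s\tCR:Z:%s\tUR:Z:%s",
                  reads$read_id, reads$seq, reads$qual,
                  cell_ids, umis, cell_ids, umis)
  writeLines(c(header, body), path)
  invisible(path)
}
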