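test_that("merge_pairs reconstructs a planted fragment and rejects non-overlaps", {
  set.seed(101)
  frag <- rand_dna(14)
  r1 <- make_read(substr(frag, 1, 10))
  r2 <- make_read(revcomp(substr(frag, 5, 14)), id = "r1")
  merged <- merge_pairs(r1, r2, min_overlap = 4, max_mismatch_density = 0)
  expect_equal(merged$seq, frag)
  expect_equal(nchar(merged$seq), 14L)

  # identity case: full-length overlap
  s <- rand_dna(10)
  m2 <- merge_pairs(make_read(s), make_read(revcomp(s)), min_overlap = 4,
                    max_mismatch_density = 0.1)
  expect_equal(m2$seq, s)

  # incompatible homopolymers: every overlap is 100% mismatch
  rej <- merge_pairs(make_read("AAAAAAAAAA"), make_read("GGGGGGGGGG"),
                     min_overlap = 4, max_mismatch_density = 0.1)
  expect_null(rej)
})

test_that("merge_pairs consensus takes the higher-quality base and max quality", {
  # full-length overlap with one disagreement where r2 has higher quality
  r1 <- sequenced_reads("r", "AAAA", int_to_phred(c(10, 30, 30, 30)))
  rc2 <- "CAAA"; q2 <- c(35, 20, 20, 20)
  r2 <- sequenced_reads("r", revcomp(rc2), int_to_phred(rev(q2)))
  m <- merge_pairs(r1, r2, min_overlap = 4, max_mismatch_density = 0.25)
  expect_equal(m$seq, "CAAA")  # q35 beats q10 at the disagreement
  expect_equal(phred_to_int(m$qual), c(35, 30, 30, 30))
})

test_that("merge_pairs agrees with the exhaustive overlap oracle", {
  set.seed(77)
  for (i in 1:60) {
    flen <- sample(12:30, 1)
    l1 <- sample(8:flen, 1); l2 <- sample(8:flen, 1)
    frag <- rand_dna(flen)
    s1 <- substr(frag, 1, l1)
    s2rc <- substr(frag, flen - l2 + 1, flen)
    # sprinkle substitutions into mate 2
    if (runif(1) < 0.5) {
      pos <- sample(l2, 1)
      substr(s2rc, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
    }
    r1 <- make_read(s1)
    r2 <- make_read(revcomp(s2rc), id = "r1")
    got <- merge_pairs(r1, r2, min_overlap = 5, max_mismatch_density = 0.2)
    want_o <- oracle_best_overlap(s1, s2rc, 5, 0.2)
    if (is.na(want_o)) {
      expect_null(got)
    } else {
      expect_equal(nchar(got$seq), l1 + l2 - want_o)
    }
  }
})

test_that("quality filter is inclusive at the boundary and monotone in pctqual", {
  expect_true(quality_filter(int_to_phred(rep(30, 20)), 20, 80))
  q7of10 <- int_to_phred(c(rep(25, 7), rep(10, 3)))
  expect_false(quality_filter(q7of10, 20, 80))
  q8of10 <- int_to_phred(c(rep(25, 8), rep(10, 2)))
  expect_true(quality_filter(q8of10, 20, 80))  # exactly 80% passes

  set.seed(5)
  for (i in 1:50) {
    q <- int_to_phred(sample(0:40, 12, replace = TRUE))
    pcts <- sort(runif(2, 0, 100))
    lo <- quality_filter(q, 20, pcts[1])
    hi <- quality_filter(q, 20, pcts[2])
    expect_true(lo || !hi)  # raising pctqual never converts fail to pass
  }
})

test_that("complexity score matches adjacent-difference definition", {
  expect_equal(complexity_score("AAAA"), 0)
  expect_false(complexity_filter("AAAA", 65))
  expect_equal(complexity_score("ACGT"), 100)
  expect_true(complexity_filter("ACGT", 65))
  expect_equal(complexity_score("AACC"), 100 / 3, tolerance = 1e-12)
  expect_false(complexity_filter("A", 0))  # too short

  # invariance under complementation and reversal
  set.seed(8)
  for (i in 1:50) {
    s <- rand_dna(sample(5:40, 1))
    sc <- complexity_score(s)
    expect_equal(complexity_score(chartr("ACGT", "TGCA", s)), sc)
    expect_equal(complexity_score(paste(rev(strsplit(s, "")[[1]]), collapse = "")), sc)
  }
})

test_that("constant trimming recovers planted barcodes with errors and partial anchors", {
  up <- "CGATTGACTACGATTGACTA"  # 20 bp
  down <- "TGCTAATGCGTGCTAATGCG"
  set.seed(21)
  bc <- rand_dna(60)

  up_err <- up
  substr(up_err, 3, 3) <- "T"; substr(up_err, 11, 11) <- "G"
  stopifnot(sum(strsplit(up_err, "")[[1]] != strsplit(up, "")[[1]]) == 2)
  cfg <- extract_config(upconstant = up, downconstant = down,
                        constants_mode = "both", constant_error_rate = 0.1)
  r <- make_read(paste0(up_err, bc, down))
  tr <- find_and_trim_constants(r, cfg)  # 2/20 = 0.1, inclusive
  expect_equal(tr$barcode_seq, bc)
  expect_true(tr$found_up && tr$found_down)

  # partial downstream anchor: first 12 bp of downconstant at read end
  cfg2 <- extract_config(downconstant = down, constants_mode = "down",
                         down_coverage = 10)
  r2 <- make_read(paste0(bc, substr(down, 1, 12)))
  tr2 <- find_and_trim_constants(r2, cfg2)
  expect_equal(tr2$barcode_seq, bc)
  expect_false(tr2$found_up)
  expect_true(tr2$found_down)

  # neither constant, mode any: rejected
  cfg3 <- extract_config(upconstant = up, downconstant = down,
                         constants_mode = "any", constant_error_rate = 0)
  r3 <- make_read(rand_dna(80))
  expect_true(barkit:::is_trim_rejection(find_and_trim_constants(r3, cfg3)))
})

test_that("planted-read recovery holds for random barcodes and staggers", {
  up <- "CGATTGACTA"; down <- "TGCTAATGCG"
  cfg <- extract_config(upconstant = up, downconstant = down,
                        constants_mode = "both", constant_error_rate = 0)
  set.seed(31)
  for (i in 1:1000) {
    bc <- rand_dna(sample(20:60, 1))
    stagger <- rand_dna(sample(0:6, 1))
    r <- make_read(paste0(stagger, up, bc, down))
    tr <- find_and_trim_constants(r, cfg)
    expect_false(barkit:::is_trim_rejection(tr))
    expect_identical(tr$barcode_seq, bc)
  }
})

test_that("length policy rejects out-of-range barcodes", {
  up <- "CGATTGACTA"; down <- "TGCTAATGCG"
  bc <- strrep("AC", 30)
  r <- make_read(paste0(up, bc, down))
  cfg_len <- extract_config(upconstant = up, downconstant = down,
                            constants_mode = "both", barcode_length = 58)
  expect_equal(find_and_trim_constants(r, cfg_len)$reason, "wrong_length")
  cfg_min <- extract_config(upconstant = up, downconstant = down,
                            constants_mode = "both", min_readlength = 61)
  expect_equal(find_and_trim_constants(r, cfg_min)$reason, "too_short")
  cfg_max <- extract_config(upconstant = up, downconstant = down,
                            constants_mode = "both", barcode_length_max = 59)
  expect_equal(find_and_trim_constants(r, cfg_max)$reason, "too_long")
})

test_that("trim_to_common_length truncates except when both constants trimmed", {
  cfg_up <- extract_config(upconstant = "ACGT", constants_mode = "up")
  seqs <- c(strrep("A", 60), strrep("C", 58), strrep("G", 59))
  expect_equal(nchar(trim_to_common_length(seqs, cfg_up)), rep(58L, 3))

  cfg_both <- extract_config(upconstant = "ACGT", downconstant = "TGCA",
                             constants_mode = "both")
  expect_equal(trim_to_common_length(seqs, cfg_both), seqs)
  expect_equal(trim_to_common_length(seqs[1], cfg_up), seqs[1])
  expect_equal(trim_to_common_length(character(0), cfg_up), character(0))
})

test_that("construct geometry bounds match the published arithmetic", {
  b <- barcode_length_bounds(read_len = 150, stagger_min = 0, stagger_max = 6,
                             umi_len = 6, primer_len = 22,
                             down_anchor_len = 15, min_floor = 40)
  expect_equal(b$max_possible, 107)
  expect_equal(b$min_possible, 40)

  w <- accepted_length_window(nominal_length = 100, cluster_distance = 8)
  expect_equal(w$lower, 92)
  expect_equal(w$upper, 108)

  expect_equal(barcode_length_bounds(100)$max_possible, 100)
  expect_error(barcode_length_bounds(20, umi_len = 10, primer_len = 10),
               "max_possible")
})
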