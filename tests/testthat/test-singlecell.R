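test_that("cell barcode and UMI parse from the C/N pattern", {
  pat <- paste0(strrep("C", 16), strrep("N", 10))
  r26 <- paste0(strrep("A", 16), strrep("G", 10))
  got <- parse_cb_umi(r26, pat)
  expect_equal(got$cell_id, strrep("A", 16))
  expect_equal(got$umi, strrep("G", 10))

  r30 <- paste0(r26, "TTTT")
  expect_equal(parse_cb_umi(r30, pat), got)  # trailing bases ignored

  expect_true(is.na(parse_cb_umi(strrep("A", 20), pat)$cell_id))
})

test_that("whitelist filter keeps members and corrects unique 1-mismatch neighbors", {
  wl <- c("AAAA", "CCCC", "AATA")
  expect_equal(whitelist_filter("AAAA", wl), "AAAA")
  expect_true(is.na(whitelist_filter("AAAC", wl)))  # correction off

  # AAAG: distance 1 to AAAA only -> corrected
  expect_equal(whitelist_filter("AAAG", wl, correct_one_mismatch = TRUE), "AAAA")
  # AAYA-type ambiguity: ACTA? distance-1 enumeration: AACA is 1 from AAAA? no (2);
  # pick a query equidistant to AAAA and AATA: "AAGA" is 1 from both -> dropped
  expect_equal(oracle_levenshtein("AAGA", "AAAA"), 1)
  expect_equal(oracle_levenshtein("AAGA", "AATA"), 1)
  expect_true(is.na(whitelist_filter("AAGA", wl, correct_one_mismatch = TRUE)))
})

test_that("knee calling separates cells from ambient noise by the rank rule", {
  tal <- c(stats::setNames(rep(1000, 100), paste0("CELL", 1:100)),
           stats::setNames(rep(5, 1000), paste0("NOISE", 1:1000)))
  called <- call_cells_knee(tal, expected_cells = 100)
  expect_setequal(called, paste0("CELL", 1:100))  # threshold 1000/10 = 100

  eq <- stats::setNames(rep(7, 20), paste0("C", 1:20))
  expect_setequal(call_cells_knee(eq, 20), names(eq))
  expect_equal(call_cells_knee(c(only = 42), 1), "only")
  expect_warning(call_cells_knee(c(a = 1, b = 2), 5), "fewer distinct")
})

test_that("chimera removal keeps the strict maximum and drops ties", {
  rec <- data.frame(
    cell_id = c("CB1", "CB1", "CB1", "CB1", "CB2"),
    umi = c("U1", "U1", "U2", "U2", "U3"),
    lineage_barcode = c("BC_A", "BC_B", "BC_A", "BC_B", "BC_C"),
    read_support = c(5L, 2L, 3L, 3L, 4L),
    stringsAsFactors = FALSE
  )
  out <- remove_chimeras(rec)
  # (CB1,U1): BC_A wins; (CB1,U2): tie removed; (CB2,U3): single kept
  expect_equal(nrow(out), 2L)
  expect_setequal(paste(out$cell_id, out$umi, out$lineage_barcode),
                  c("CB1 U1 BC_A", "CB2 U3 BC_C"))
  expect_equal(attr(out, "n_chimeric_removed"), 2L)
})

test_that("UMI collapse merges error offshoots but not distant UMIs", {
  expect_equal(collapse_umis(c(AAAAAAAAAA = 10, AAAAAAAAAT = 1), d = 1), 1L)
  expect_equal(collapse_umis(c(AAAAAAAAAA = 5, TTTTTTTTTT = 5), d = 1), 2L)
  expect_equal(collapse_umis(c(AAAA = 3, CCCC = 2, GGGG = 1), d = 0), 3L)
  # two variants of one parent, 2d apart, merge through the parent
  expect_equal(collapse_umis(c(AAAAAAAAAA = 6, CAAAAAAAAA = 1, AAAAAAAAAG = 1),
                             d = 1), 1L)
  # similar-abundance true molecules stay apart
  expect_equal(collapse_umis(c(AAAAAAAAAA = 5, AAAAAAAAAT = 4), d = 1), 2L)

  set.seed(17)
  for (i in 1:40) {
    n <- sample(1:12, 1)
    umis <- stats::setNames(sample(1:20, n, replace = TRUE),
                            unique(replicate(n, rand_dna(8))))
    umis <- umis[seq_along(unique(names(umis)))]
    d <- sample(0:2, 1)
    got <- collapse_umis(umis, d)
    expect_lte(got, length(umis))  # never increases
    expect_gte(got, 1L)
    expect_equal(collapse_umis(umis, 0), length(umis))
  }
})

test_that("per-cell filters apply UMI threshold then dominant fraction inclusively", {
  tab <- barkit:::cell_table_from_long(data.frame(
    cell_id = c("C1", "C1", "C2", "C2", "C3", "C3"),
    lineage_barcode = c("BC_A", "BC_B", "BC_A", "BC_B", "BC_A", "BC_B"),
    umi_count = c(20L, 1L, 20L, 3L, 20L, 4L),
    stringsAsFactors = FALSE
  ))
  f1 <- filter_cell_barcodes(tab[tab$cell_id == "C1", ], umi_count_threshold = 5)
  expect_equal(f1$barcodes, "BC_A")

  f2 <- filter_cell_barcodes(tab[tab$cell_id == "C2", ], 0, dominant_fraction = 0.2)
  expect_equal(f2$barcodes, "BC_A")  # 3 < 0.2 x 20

  f3 <- filter_cell_barcodes(tab[tab$cell_id == "C3", ], 0, dominant_fraction = 0.2)
  expect_equal(f3$barcodes, "BC_A,BC_B")  # 4 >= 4 inclusive

  all_dropped <- filter_cell_barcodes(tab, umi_count_threshold = 100)
  expect_equal(nrow(all_dropped), 0L)
  expect_equal(attr(all_dropped, "n_cells_dropped"), 3L)
})

test_that("cell annotation orders barcodes and calls dominants with tie guard", {
  rec <- data.frame(
    cell_id = rep("C1", 3),
    umi = c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG"),
    lineage_barcode = c("BC_A", "BC_A", "BC_B"),
    read_support = c(4L, 3L, 5L),
    stringsAsFactors = FALSE
  )
  tab <- annotate_cells(rec, umi_distance = 1)
  expect_equal(tab$barcodes, "BC_A,BC_B")
  expect_equal(tab$umi_counts, "2,1")
  expect_equal(unname(dominant_barcode(tab)), "BC_A")

  tie <- barkit:::cell_table_from_long(data.frame(
    cell_id = "C9", lineage_barcode = c("BC_A", "BC_B"),
    umi_count = c(5L, 5L), stringsAsFactors = FALSE))
  expect_true(is.na(dominant_barcode(tie)))
})

test_that("spatial binning floors coordinates and conserves mass", {
  rec <- data.frame(x = c(39, 41, 42), y = c(41, 45, 47),
                    lineage_barcode = c("BC_A", "BC_B", "BC_B"),
                    umi_count = c(7, 2, 3), stringsAsFactors = FALSE)
  m <- aggregate_to_bins(rec, 20)
  expect_equal(m["1_2", "BC_A"], 7)
  expect_equal(m["2_2", "BC_B"], 5)  # two spots in one bin sum
  expect_equal(sum(m), sum(rec$umi_count))

  m1 <- aggregate_to_bins(rec, 1)
  expect_equal(nrow(m1), 3L)  # identity binning
  set.seed(3)
  for (bs in c(2, 5, 10, 50)) {
    r <- data.frame(x = sample(0:99, 30, TRUE), y = sample(0:99, 30, TRUE),
                    lineage_barcode = sample(c("A", "B", "C"), 30, TRUE),
                    umi_count = sample(1:9, 30, TRUE))
    expect_equal(sum(aggregate_to_bins(r, bs)), sum(r$umi_count))
  }
})
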