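make_ac <- function(m) {
  annotated_counts(m)
}

test_that("depth filter removes samples below the percentile threshold", {
  m <- matrix(0, nrow = 2, ncol = 10,
              dimnames = list(c("A", "B"), paste0("S", 1:10)))
  m[1, ] <- c(rep(100, 9), 1)
  got <- filter_samples_by_depth(make_ac(m), 5)
  expect_equal(attr(got, "removed_samples"), "S10")
  expect_equal(ncol(got$counts), 9L)

  eq <- matrix(50, 2, 4, dimnames = list(c("A", "B"), paste0("S", 1:4)))
  expect_equal(ncol(filter_samples_by_depth(make_ac(eq), 5)$counts), 4L)

  # tied minimum: interpolated threshold equals the minimum, nothing removed
  m2 <- m; m2[1, 9:10] <- 1  # totals: 100 x 8, then 1, 1
  tiny <- filter_samples_by_depth(make_ac(m2), 0.0001)
  expect_equal(ncol(tiny$counts), 10L)
})

test_that("threshold_counts is inclusive and supports relative mode", {
  m <- matrix(9, nrow = 2, ncol = 8,
              dimnames = list(c("keep", "drop"), paste0("S", 1:8)))
  m["keep", 1:4] <- 10
  got <- threshold_counts(make_ac(m), threshold = 10, min_samples = 4)
  expect_equal(rownames(got$counts), "keep")
  expect_equal(attr(got, "removed_barcodes"), "drop")
  # surviving counts unchanged
  expect_equal(got$counts["keep", ], m["keep", ])

  rel <- matrix(c(2, 98, 2, 98), 2, 2,
                dimnames = list(c("lo", "hi"), c("S1", "S2")))
  gotr <- threshold_counts(make_ac(rel), threshold = 0.01, min_samples = 2,
                           type = "relative")
  expect_setequal(rownames(gotr$counts), c("lo", "hi"))  # 0.02 >= 0.01
  gotr2 <- threshold_counts(make_ac(rel), threshold = 0.05, min_samples = 2,
                            type = "relative")
  expect_equal(rownames(gotr2$counts), "hi")
})

test_that("normalisation: cpm and percent column sums, tmm factors of 1", {
  m <- matrix(c(1, 1, 30, 10), 2, 2,
              dimnames = list(c("A", "B"), c("S1", "S2")))
  cpm <- normalise_counts(make_ac(m), "cpm")
  expect_equal(unname(colSums(cpm$counts)), c(1e6, 1e6), tolerance = 1e-9)
  expect_equal(unname(cpm$counts[, "S1"]), c(5e5, 5e5))

  pct <- normalise_counts(make_ac(m), "percent")
  expect_equal(unname(colSums(pct$counts)), c(100, 100), tolerance = 1e-9)

  set.seed(2)
  base <- matrix(rpois(40, 50) + 1, 10, 4,
                 dimnames = list(paste0("B", 1:10), paste0("S", 1:4)))
  ident <- base; ident[, ] <- base[, 1]
  expect_equal(unname(tmm_factors(make_ac(ident))), rep(1, 4), tolerance = 1e-9)

  prop <- cbind(S1 = base[, 1], S2 = 2 * base[, 1])
  rownames(prop) <- rownames(base)
  expect_equal(unname(tmm_factors(make_ac(prop))), c(1, 1), tolerance = 1e-9)

  zero <- base; zero[, 2] <- 0
  expect_error(normalise_counts(make_ac(zero), "cpm"), "S2")
})

test_that("replicate correlation and collapse behave on closed-form cases", {
  x <- c(10, 20, 30, 40)
  m <- cbind(A_1 = x, A_2 = x, B_1 = x, B_2 = 2 * x, C_1 = c(1, 2, 3, 4),
             C_2 = c(3, 2, 1, 4))
  rownames(m) <- paste0("BC", 1:4)
  meta <- data.frame(sample = colnames(m),
                     group = sub("_[12]$", "", colnames(m)),
                     stringsAsFactors = FALSE)
  ac <- annotated_counts(m, meta)
  cors <- replicate_corr(ac, "group")
  expect_equal(cors$correlation[cors$group == "A"], 1)
  expect_equal(cors$correlation[cors$group == "B"], 1)  # (x, 2x) linear

  # 3-point closed form: (1,2,3) vs (3,2,1) has Pearson -1
  m3 <- cbind(D_1 = c(1, 2, 3), D_2 = c(3, 2, 1))
  rownames(m3) <- paste0("BC", 1:3)
  ac3 <- annotated_counts(m3, data.frame(sample = colnames(m3),
                                         group = c("D", "D")))
  expect_equal(replicate_corr(ac3, "group")$correlation, -1)
  col3 <- collapse_replicates(ac3, "group", 0.9)
  expect_equal(attr(col3, "uncollapsed_groups"), "D")
  expect_equal(ncol(col3$counts), 2L)

  col <- collapse_replicates(ac, "group", 0.9)
  expect_true(all(c("A", "B") %in% colnames(col$counts)))
  expect_equal(unname(col$counts[, "A"]), x)
  expect_equal(unname(col$counts[, "B"]), 1.5 * x)  # mean of x and 2x
  expect_true("C" %in% attr(col, "uncollapsed_groups"))

  const <- cbind(E_1 = rep(5, 4), E_2 = c(1, 2, 3, 4))
  rownames(const) <- paste0("BC", 1:4)
  ace <- annotated_counts(const, data.frame(sample = colnames(const),
                                            group = c("E", "E")))
  expect_true(is.na(replicate_corr(ace, "group")$correlation))
  expect_equal(attr(collapse_replicates(ace, "group", 0.9),
                    "uncollapsed_groups"), "E")
})

test_that("percentile_barcodes counts top clones to the cumulative cutoff", {
  expect_equal(percentile_barcodes(c(50, 30, 15, 4, 1), 0.95), 3L)
  expect_equal(percentile_barcodes(c(42), 0.5), 1L)
  expect_equal(percentile_barcodes(rep(1, 100), 0.95), 95L)

  set.seed(4)
  for (i in 1:20) {
    x <- sample(1:100, sample(3:30, 1), replace = TRUE)
    ps <- sort(runif(2, 0.05, 1))
    expect_lte(percentile_barcodes(x, ps[1]), percentile_barcodes(x, ps[2]))
  }
})

test_that("diversity indices match closed forms", {
  u10 <- rep(10, 10)
  expect_equal(diversity_index(u10, "shannon"), log(10), tolerance = 1e-12)
  expect_equal(diversity_index(u10, "simpson"), 0.9, tolerance = 1e-12)
  expect_equal(diversity_index(u10, "invsimpson"), 10, tolerance = 1e-12)
  expect_equal(diversity_index(u10, "gini"), 0, tolerance = 1e-12)

  expect_equal(diversity_index(7, "shannon"), 0)
  expect_equal(diversity_index(7, "simpson"), 0)
  expect_equal(diversity_index(7, "invsimpson"), 1)

  expect_equal(diversity_index(c(0, 0, 0, 4), "gini"), 0.75, tolerance = 1e-12)

  # shannon and invsimpson are maximal at uniformity over fixed support
  set.seed(19)
  for (i in 1:30) {
    n <- sample(3:20, 1)
    pert <- rep(100, n) + sample(c(-1, 1), n, TRUE) * sample(1:50, n, TRUE)
    pert <- pmax(pert, 1)
    if (length(unique(pert)) == 1L) pert[1] <- pert[1] + 1
    expect_lt(diversity_index(pert, "shannon"), log(n))
    expect_lt(diversity_index(pert, "invsimpson"), n)
    expect_gt(diversity_index(pert, "gini"), 0)
  }
})

test_that("pairwise sample correlation is symmetric with unit diagonal", {
  m <- cbind(S1 = c(5, 0, 2, 0), S2 = c(5, 0, 2, 0), S3 = c(0, 4, 0, 7))
  rownames(m) <- paste0("BC", 1:4)
  pc <- pairwise_sample_correlation(make_ac(m))
  expect_equal(pc, t(pc))
  expect_equal(unname(diag(pc)), rep(1, 3))
  expect_equal(pc["S1", "S2"], 1)
  expect_lt(pc["S1", "S3"], 0)  # disjoint supports anti-correlate
})

test_that("cluster enrichment matches the exact hypergeometric tail", {
  labels <- data.frame(
    group = c(rep("cloneX", 5), rep("other", 15)),
    partition = c(rep("P1", 4), "P2", rep("P2", 15)),
    stringsAsFactors = FALSE
  )
  got <- cluster_enrichment(labels, "cloneX")
  p1 <- got[got$partition == "P1", ]
  expect_equal(p1$k, 4); expect_equal(p1$n, 4)
  expect_equal(p1$K, 5); expect_equal(p1$N, 20)
  expect_equal(p1$p_raw, 5 / 4845, tolerance = 1e-12)

  # k = 0 and the all-cells partition are certain events
  l2 <- data.frame(group = c("g", "x", "x", "x"), partition = rep("all", 4))
  e2 <- cluster_enrichment(l2, "g")
  expect_equal(e2$p_raw, 1)

  set.seed(23)
  for (i in 1:40) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    labs <- data.frame(
      group = sample(rep(c("t", "o"), c(K, N - K))),
      partition = sample(c("P1", "P2", "P3"), N, TRUE))
    res <- cluster_enrichment(labs, "t")
    for (j in seq_len(nrow(res))) {
      expect_equal(res$p_raw[j],
                   oracle_hyper_upper(res$N[j], res$K[j], res$n[j], res$k[j]),
                   tolerance = 1e-12)
    }
    expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  }
})

test_that("clone summaries tally cells per clone and barcodes per cell", {
  tab <- barkit:::cell_table_from_long(data.frame(
    cell_id = c("c1", "c2", "c3", "c4", "c4"),
    lineage_barcode = c("A", "A", "A", "B", "C"),
    umi_count = c(3L, 2L, 4L, 6L, 1L), stringsAsFactors = FALSE))
  s <- clone_summaries(tab, total_cells = 8)
  expect_equal(s$cells_per_clone[["A"]], 3L)
  expect_equal(s$cells_per_clone[["B"]], 1L)
  expect_equal(s$barcodes_per_cell[["1"]], 3L)
  expect_equal(s$barcodes_per_cell[["2"]], 1L)
  expect_equal(s$detection_rate, 0.5)

  metric <- stats::setNames(c(1, 2, 3, 4), c("c1", "c2", "c3", "c4"))
  s2 <- clone_summaries(tab, per_cell_metric = metric)
  expect_equal(s2$metric_by_clone$median[s2$metric_by_clone$clone == "A"], 2)
})
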