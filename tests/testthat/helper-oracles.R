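# Independent oracles used to verify the implementation: plain-R dynamic
# programming, exhaustive enumeration and closed forms, written without
# reference to the package internals.

# Wagner-Fischer edit distance, pure R.
oracle_levenshtein <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca); m <- length(cb)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, rep(0L, m))
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (ca[i] != cb[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

# Brute-force greedy sphere clustering: full all-pairs distance matrix via
# oracle_levenshtein, then the count-descending greedy absorption rule
# (nearest admissible centroid; ties to higher canonical count, then
# lexicographic).
oracle_cluster <- function(tallies, d, r) {
  seqs <- names(tallies)
  counts <- as.numeric(tallies)
  ord <- order(-counts, seqs)
  seqs <- seqs[ord]; counts <- counts[ord]
  n <- length(seqs)
  dist <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dist[i, j] <- oracle_levenshtein(seqs[i], seqs[j])
  }
  centroid_of <- integer(0)   # index into seqs for each centroid
  result <- numeric(0)
  for (i in seq_len(n)) {
    best <- NA_integer_
    if (length(centroid_of)) {
      adm <- centroid_of[counts[centroid_of] >= r * counts[i]]
      adm <- adm[dist[adm, i] <= d]
      if (length(adm)) {
        o <- order(dist[adm, i], -counts[adm], seqs[adm])
        best <- adm[o[1]]
      }
    }
    if (is.na(best)) {
      centroid_of <- c(centroid_of, i)
      result[seqs[i]] <- counts[i]
    } else {
      result[seqs[best]] <- result[seqs[best]] + counts[i]
    }
  }
  result
}

# Exhaustive overlap scan for read-pair merging: enumerate every overlap
# length, score by mismatch density (N is never a match), return the best
# qualifying overlap length or NA.
oracle_best_overlap <- function(s1, s2rc, min_overlap, max_density) {
  n1 <- nchar(s1); n2 <- nchar(s2rc)
  best_o <- NA_integer_; best_d <- Inf
  for (o in min_overlap:min(n1, n2)) {
    a <- strsplit(substr(s1, n1 - o + 1, n1), "")[[1]]
    b <- strsplit(substr(s2rc, 1, o), "")[[1]]
    dens <- sum(a != b | a == "N" | b == "N") / o
    if (dens <= max_density && (dens < best_d ||
                                (dens == best_d && o > best_o))) {
      best_d <- dens; best_o <- o
    }
  }
  best_o
}

# Upper-tail hypergeometric probability by direct summation of the pmf.
oracle_hyper_upper <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# One-row reads data.frame with uniform quality.
make_read <- function(seq, q = 37, id = "r1") {
  sequenced_reads(id, seq, int_to_phred(rep(q, nchar(seq))))
}
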