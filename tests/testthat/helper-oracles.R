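# independent oracles used to cross-check the implementation paths

# per-window duplex scan via repeated score_duplex calls over an explicit
# enumeration of ungapped windows and single-gap variants
oracle_scan <- function(mirna, tx, cutoff, allow_gap = TRUE) {
  tx <- chartr("Tt", "Uu", toupper(tx))
  L <- nchar(mirna)
  n <- nchar(tx)
  hits <- list()
  for (s in seq_len(n - L + 1L)) {
    best <- score_duplex(mirna, substr(tx, s, s + L - 1L),
                         target_start = s, target_end = s + L - 1L)
    if (allow_gap && L >= 3L) {
      seg <- substr(tx, s, s + L - 2L)
      for (g in 2:(L - 1L)) {
        frag <- paste0(substr(seg, 1L, g - 1L), "-", substr(seg, g, L - 1L))
        d <- score_duplex(mirna, frag, target_start = s, target_end = s + L - 2L)
        if (d$expectation < best$expectation) best <- d
      }
    }
    if (best$expectation <= cutoff) hits[[length(hits) + 1L]] <- best
  }
  e <- vapply(hits, `[[`, numeric(1), "expectation")
  st <- vapply(hits, `[[`, integer(1), "target_start")
  hits[order(e, st)]
}

# hypergeometric upper tail by direct combinatorial summation
oracle_hyper_tail <- function(k, N, K, n) {
  kk <- max(k, 0):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Benjamini-Hochberg step-up written out long-hand
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# textbook product-moment correlation
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# small random alignment-free helpers
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

published_duplexes <- function() {
  read.delim(system.file("extdata", "published_duplexes.tsv",
                         package = "crossoil"),
             sep = "\t", stringsAsFactors = FALSE)
}
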