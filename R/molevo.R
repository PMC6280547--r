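# molecular evolution: Poisson-corrected distances, neighbor joining with
# bootstrap, Nei-Gojobori (1986) counting Ka/Ks, and branch-model LRTs.

GAP_CHARS <- c("-", "?", "X", ".")

#' Proportion of differing sites between two aligned rows
#'
#' @param row_a,row_b aligned sequences (strings or character vectors) of
#'   equal length.
#' @param pairwise_deletion drop columns where either row has a gap or
#'   missing character (`-`, `?`, `X`, `.`); default TRUE. When FALSE, such
#'   columns must not be present.
#' @return fraction of differing comparable sites.
#' @export
p_distance <- function(row_a, row_b, pairwise_deletion = TRUE) {
  a <- if (length(row_a) == 1L) strsplit(toupper(row_a), "")[[1]] else toupper(row_a)
  b <- if (length(row_b) == 1L) strsplit(toupper(row_b), "")[[1]] else toupper(row_b)
  stop_if(length(a) != length(b), "rows differ in length")
  gap <- a %in% GAP_CHARS | b %in% GAP_CHARS
  if (pairwise_deletion) {
    a <- a[!gap]; b <- b[!gap]
  } else {
    stop_if(any(gap), "gap characters present; use pairwise_deletion = TRUE")
  }
  stop_if(length(a) == 0L, "no comparable sites after gap deletion")
  mean(a != b)
}

#' Poisson-corrected distance
#'
#' Corrects an observed proportion of differences for multiple hits under
#' the Poisson model of amino-acid substitution: d = -ln(1 - p).
#'
#' @param p observed proportion, in \[0, 1).
#' @return corrected distance, >= p with equality only at 0.
#' @export
poisson_distance <- function(p) {
  stop_if(any(p < 0 | p >= 1), "p must lie in [0, 1)")
  -log(1 - p)
}

#' Poisson-corrected pairwise distance matrix of an alignment
#'
#' @param aln named character vector of aligned sequences (equal lengths),
#'   or a character matrix (taxa x sites).
#' @param pairwise_deletion passed to [p_distance()].
#' @return symmetric numeric matrix with taxa dimnames.
#' @export
poisson_dist_matrix <- function(aln, pairwise_deletion = TRUE) {
  m <- alignment_matrix(aln)
  k <- nrow(m)
  d <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d[i, j] <- d[j, i] <- poisson_distance(
      p_distance(m[i, ], m[j, ], pairwise_deletion))
  }
  d
}

alignment_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  stop_if(is.null(names(aln)), "alignment sequences must be named")
  lens <- nchar(aln)
  stop_if(length(unique(lens)) != 1L, "aligned rows differ in length")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion agglomeration (via `ape::nj`), returning an
#' unrooted tree. Negative branch lengths — an artifact NJ can produce on
#' non-additive matrices — are clamped to zero for display, with the
#' negative remainder transferred to the sibling branch so that path
#' lengths are preserved as closely as possible; the raw lengths are kept
#' in the `"raw_edge_lengths"` attribute.
#'
#' @param d symmetric numeric matrix (zero diagonal, >= 3 taxa) or `dist`.
#' @return an `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stop_if(!is.matrix(d) || nrow(d) != ncol(d), "d must be square")
  stop_if(nrow(d) < 3L, "need at least 3 taxa")
  stop_if(any(abs(d - t(d)) > 1e-8), "distance matrix must be symmetric")
  stop_if(any(diag(d) != 0), "distance matrix must have a zero diagonal")
  tr <- ape::nj(as.dist(d))
  raw <- tr$edge.length
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs) > 0) {
      sib <- sibs[which.max(tr$edge.length[sibs])]
      tr$edge.length[sib] <- tr$edge.length[sib] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  attr(tr, "raw_edge_lengths") <- raw
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-corrected NJ tree per replicate, and reports for each internal
#' bipartition the percentage of replicates containing it (0-100), stored
#' in `node.label`.
#'
#' @param aln alignment (named character vector or taxa x sites matrix).
#' @param n_reps number of bootstrap replicates; 1000 is the conventional
#'   choice, smaller values are fine for exploration.
#' @param seed RNG seed; same seed gives identical supports.
#' @param pairwise_deletion passed to the distance computation.
#' @return the NJ tree on the full alignment with `node.label` set to
#'   integer percentage supports.
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L,
                              pairwise_deletion = TRUE) {
  stop_if(!is_count(n_reps, 1L), "n_reps must be a positive integer")
  m <- alignment_matrix(aln)
  build <- function(x) neighbor_joining(poisson_dist_matrix(x, pairwise_deletion))
  tr <- build(m)
  counts <- with_seed(seed,
    ape::boot.phylo(tr, m, build, B = n_reps, quiet = TRUE, rooted = FALSE))
  tr$node.label <- as.integer(round(100 * counts / n_reps))
  tr
}

# --- Nei-Gojobori (1986) counting -------------------------------------------

ng86_env <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(ng86_env$codons)) return(ng86_env)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  aa <- unname(code)
  nts <- c("A", "C", "G", "T")
  syn_sites <- numeric(length(codons))
  names(syn_sites) <- codons
  for (ci in seq_along(codons)) {
    if (aa[ci] == "*") next
    chars <- strsplit(codons[ci], "")[[1]]
    s <- 0
    for (pos in 1:3) for (alt in setdiff(nts, chars[pos])) {
      mut <- chars; mut[pos] <- alt
      mut_aa <- code[[paste(mut, collapse = "")]]
      if (mut_aa == "*") next  # mutations to stops are disregarded
      if (mut_aa == aa[ci]) s <- s + 1 / 3
    }
    syn_sites[ci] <- s
  }
  ng86_env$codons <- codons
  ng86_env$aa <- setNames(aa, codons)
  ng86_env$syn_sites <- syn_sites
  ng86_env
}

split_codons <- function(cds) {
  s <- toupper(chartr("Uu", "Tt", cds))
  stop_if(nchar(s) %% 3 != 0, "CDS length must be a multiple of 3")
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

# average syn/nonsyn substitution counts over all orderings of the
# differing positions, skipping pathways that pass through a stop codon
ng86_codon_diffs <- function(c1, c2, tab) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- perm_rows(k)
  tot_s <- 0; tot_n <- 0; n_ok <- 0L
  for (r in seq_len(nrow(paths))) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    s <- 0; n <- 0; ok <- TRUE
    for (step in paths[r, seq_len(k)]) {
      prev <- paste(cur, collapse = "")
      cur[pos[step]] <- tgt[pos[step]]
      nxt <- paste(cur, collapse = "")
      if (tab$aa[[nxt]] == "*") { ok <- FALSE; break }
      if (tab$aa[[prev]] == tab$aa[[nxt]]) s <- s + 1 else n <- n + 1
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = tot_s / n_ok, nd = tot_n / n_ok)
}

#' Nei-Gojobori counting estimate of Ka, Ks and omega
#'
#' The 1986 unweighted-pathway method: synonymous and nonsynonymous site
#' counts are averaged between the two sequences (mutations to stop codons
#' disregarded), codons differing at several positions are averaged over
#' all substitution orderings that avoid stops, and proportions are
#' corrected for multiple hits with the Jukes-Cantor formula
#' d = -3/4 ln(1 - 4/3 p). omega = Ka/Ks measures selective pressure:
#' < 1 purifying, ~ 1 neutral, > 1 positive selection. This counting
#' estimator is the desk-scale stand-in for codon-model maximum-likelihood
#' omega fitting.
#'
#' @param cds_a,cds_b in-frame coding sequences of equal length (multiple
#'   of 3, no internal stops; DNA or RNA alphabet).
#' @return object of class `selection_estimate`: list with `ka`, `ks`,
#'   `omega` (`NA` and flagged when Ks = 0), site and difference counts.
#' @export
ng86_ka_ks <- function(cds_a, cds_b) {
  tab <- ng86_tables()
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  stop_if(length(ca) != length(cb), "sequences differ in length")
  internal <- seq_len(length(ca) - 1L)
  stop_if(any(tab$aa[ca[internal]] == "*") || any(tab$aa[cb[internal]] == "*"),
          "internal stop codon")
  # drop a terminal stop if both sequences end in one
  if (tab$aa[[ca[length(ca)]]] == "*" && tab$aa[[cb[length(cb)]]] == "*") {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }

  S <- mean(c(sum(tab$syn_sites[ca]), sum(tab$syn_sites[cb])))
  N <- 3 * length(ca) - S

  diffs <- vapply(seq_along(ca), function(i)
    ng86_codon_diffs(ca[i], cb[i], tab), numeric(2))
  sd_tot <- sum(diffs["sd", ], na.rm = TRUE)
  nd_tot <- sum(diffs["nd", ], na.rm = TRUE)

  ps <- sd_tot / S
  pn <- nd_tot / N
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)  # saturated
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(ps)
  ka <- jc(pn)
  omega <- if (!is.na(ks) && ks > 0 && !is.na(ka)) ka / ks else NA_real_
  structure(list(ka = ka, ks = ks, omega = omega,
                 syn_sites = S, nonsyn_sites = N,
                 syn_diffs = sd_tot, nonsyn_diffs = nd_tot,
                 n_codons = length(ca),
                 omega_defined = !is.na(omega)),
            class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf("<selection_estimate> Ka = %.4f, Ks = %.4f, omega = %s (%d codons)\n",
              x$ka, x$ks,
              if (x$omega_defined) sprintf("%.4f", x$omega) else "undefined",
              x$n_codons))
  invisible(x)
}

#' Likelihood-ratio test between nested branch models
#'
#' statistic = 2 |lnL_alt - lnL_null|, compared against the chi-square
#' upper tail with `df` degrees of freedom (the difference in free
#' parameters, e.g. df = 6 when a two-ratio model adds six branch rates to
#' a one-ratio null). The absolute value makes the test robust to the two
#' log-likelihood labels being swapped in the input; when the alternative
#' fits worse than the null (`lnl_alt < lnl_null`, impossible for a
#' correctly maximized nested pair) the result carries
#' `label_swap_suspected = TRUE` rather than silently relabeling.
#'
#' @param lnl_null,lnl_alt log-likelihoods of the null and alternative
#'   model fits.
#' @param df positive integer degrees of freedom.
#' @return object of class `lrt_result` with `statistic`, `p_value`, the
#'   inputs, and `label_swap_suspected`.
#' @examples
#' branch_lrt(-2343.655, -2361.163, df = 6)  # statistic 35.016
#' @export
branch_lrt <- function(lnl_null, lnl_alt, df) {
  stop_if(!is_count(df, 1L), "df must be a positive integer")
  stat <- 2 * abs(lnl_alt - lnl_null)
  structure(list(lnl_null = lnl_null, lnl_alt = lnl_alt, df = as.integer(df),
                 statistic = stat,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 label_swap_suspected = lnl_alt < lnl_null),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt_result> 2|dlnL| = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (x$label_swap_suspected)
    cat("  note: alternative lnL < null lnL; model labels may be swapped\n")
  invisible(x)
}
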