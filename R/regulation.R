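# miRNA target prediction: duplex expectation scoring, transcript scanning,
# inhibition-mode calls, and regulator joins.
#
# The expectation score penalizes departures from perfect antiparallel
# complementarity, position by position from the miRNA 5' end:
#   match 0, G:U wobble 0.5, mismatch 1, target gap 2,
# with non-gap penalties doubled in the seed region (miRNA positions 2-7).
# Lower totals mean stronger predicted targeting; a perfect reverse
# complement scores 0.

DUPLEX_ALPHABET <- c("A", "C", "G", "U")
RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

as_rna_chars <- function(s, what, allow_gap = FALSE) {
  ch <- strsplit(chartr("Tt", "Uu", toupper(s)), "")[[1]]
  ok <- ch %in% c(DUPLEX_ALPHABET, if (allow_gap) "-")
  stop_if(any(!ok), sprintf("%s contains non-nucleotide characters: %s",
                            what, paste(unique(ch[!ok]), collapse = "")))
  ch
}

#' Score an miRNA:target duplex
#'
#' Aligns the miRNA (5' to 3') antiparallel against a target fragment
#' (given 5' to 3', possibly containing a single `-` where a miRNA base is
#' unpaired) and totals per-position penalties: match 0, G:U wobble 0.5,
#' mismatch 1, gap 2; non-gap penalties are doubled at miRNA positions 2-7
#' (the seed). T and U are equivalent, so DNA transcripts score identically
#' to their RNA transcriptions.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param target_fragment target-site fragment, 5' to 3'; must have the
#'   same number of alignment columns as the miRNA (a `-` occupies one).
#' @param mirna_id,target_id optional sequence labels.
#' @param target_start,target_end optional 1-based coordinates of the
#'   fragment on its transcript.
#' @return object of class `duplex_alignment` with fields `expectation`,
#'   `pair_states` (per miRNA position: match/wobble/mismatch/gap),
#'   `inhibition` (see [call_inhibition()]), fragments, ids and
#'   coordinates. `upe` (site accessibility energy) is a pass-through slot,
#'   `NA` unless supplied by an external tool.
#' @examples
#' score_duplex("CAGCCAAGGAUGACUUGCCG", "AGGCAAGCCAAACUUGGCUG")$expectation # 4
#' @export
score_duplex <- function(mirna, target_fragment, mirna_id = "miRNA",
                         target_id = "target", target_start = NA_integer_,
                         target_end = NA_integer_) {
  m <- as_rna_chars(mirna, "miRNA")
  t5 <- as_rna_chars(target_fragment, "target fragment", allow_gap = TRUE)
  stop_if(length(m) != length(t5),
          "miRNA and target fragment must span the same alignment length")
  stop_if(sum(t5 == "-") > 1L, "at most one gap per duplex")
  t3 <- rev(t5)  # miRNA position i pairs the i-th base from the target 3' end

  states <- character(length(m))
  pen <- numeric(length(m))
  for (i in seq_along(m)) {
    if (t3[i] == "-") {
      states[i] <- "gap"; pen[i] <- 2
    } else if (RNA_COMPLEMENT[[m[i]]] == t3[i]) {
      states[i] <- "match"; pen[i] <- 0
    } else if ((m[i] == "G" && t3[i] == "U") ||
               (m[i] == "U" && t3[i] == "G")) {
      states[i] <- "wobble"; pen[i] <- 0.5
    } else {
      states[i] <- "mismatch"; pen[i] <- 1
    }
    if (i >= 2L && i <= 7L && states[i] != "gap") pen[i] <- pen[i] * 2
  }

  d <- structure(list(
    mirna_id = mirna_id, target_id = target_id,
    mirna_fragment = paste(m, collapse = ""),
    target_fragment = paste(t5, collapse = ""),
    pair_states = states, position_penalties = pen,
    expectation = sum(pen), upe = NA_real_,
    mirna_start = 1L, mirna_end = length(m),
    target_start = as.integer(target_start),
    target_end = as.integer(target_end),
    inhibition = NA_character_
  ), class = "duplex_alignment")
  d$inhibition <- call_inhibition(d)
  d
}

#' Call the predicted inhibition mode of a duplex
#'
#' Cleavage requires intact pairing at the duplex center: the call is
#' `"Translation"` if any of miRNA positions 9-11 is a mismatch or gap,
#' otherwise `"Cleavage"`.
#'
#' @param d a `duplex_alignment` from [score_duplex()].
#' @return `"Cleavage"` or `"Translation"`.
#' @export
call_inhibition <- function(d) {
  states <- d$pair_states
  centre <- states[9:11]
  centre <- centre[!is.na(centre)]
  if (any(centre %in% c("mismatch", "gap"))) "Translation" else "Cleavage"
}

#' @export
print.duplex_alignment <- function(x, ...) {
  mark <- vapply(x$pair_states, switch, "", match = "|", wobble = "o",
                 mismatch = " ", gap = "-")
  cat(sprintf("<duplex_alignment> %s -> %s  e = %g%s  [%s]\n",
              x$mirna_id, x$target_id, x$expectation,
              if (is.na(x$upe)) "" else sprintf(", UPE = %g", x$upe),
              x$inhibition))
  if (!is.na(x$target_start))
    cat(sprintf("  target %d..%d\n", x$target_start, x$target_end))
  cat(sprintf("  miRNA  5' %s 3'\n            %s\n  target 3' %s 5'\n",
              x$mirna_fragment, paste(mark, collapse = ""),
              paste(rev(strsplit(x$target_fragment, "")[[1]]), collapse = "")))
  invisible(x)
}

#' Scan a transcript for miRNA target sites
#'
#' Evaluates every window of the transcript against the miRNA: ungapped
#' windows of the miRNA length, plus (when `allow_gap`) variants with a
#' single gap at each interior alignment column, which shorten the target
#' side by one base. For each target start position the best-scoring
#' variant is kept, and sites with expectation <= `max_expectation` are
#' returned sorted by expectation then start coordinate.
#'
#' @param mirna miRNA sequence, 5' to 3' (RNA or DNA alphabet).
#' @param transcript transcript sequence, 5' to 3' (RNA or DNA alphabet).
#' @param max_expectation score cutoff; default 3, the conventional
#'   stringent setting for plant miRNA target prediction.
#' @param allow_gap also consider single-gap duplexes; default TRUE.
#' @param mirna_id,transcript_id labels carried into the hits.
#' @return list of `duplex_alignment` hits (possibly empty), each with
#'   1-based inclusive `target_start`/`target_end`.
#' @export
scan_transcript <- function(mirna, transcript, max_expectation = 3,
                            allow_gap = TRUE, mirna_id = "miRNA",
                            transcript_id = "transcript") {
  stop_if(!is.numeric(max_expectation) || max_expectation < 0,
          "max_expectation must be non-negative")
  m <- as_rna_chars(mirna, "miRNA")
  tx <- as_rna_chars(transcript, "transcript")
  L <- length(m)
  n <- length(tx)
  if (n < L) return(list())
  n_win <- n - L + 1L

  # per-position penalty lookup: pen[miRNA base, target base], doubled in
  # the seed (positions 2-7); precomputing it lets every window be scored
  # with indexing instead of per-duplex string work
  base_pen <- matrix(1, 4, 4, dimnames = list(DUPLEX_ALPHABET, DUPLEX_ALPHABET))
  for (b in DUPLEX_ALPHABET) base_pen[b, RNA_COMPLEMENT[[b]]] <- 0
  base_pen["G", "U"] <- base_pen["U", "G"] <- 0.5
  seed_mult <- ifelse(seq_len(L) >= 2L & seq_len(L) <= 7L, 2, 1)

  # A[i, s]: penalty of miRNA pos i against tx[s + L - i] (ungapped pairing);
  # B[i, s]: against tx[s + L - 1 - i] (pairing downstream of a target gap)
  idx_a <- outer(seq_len(L), seq_len(n_win), function(i, s) s + L - i)
  A <- matrix(base_pen[cbind(rep(m, n_win), tx[idx_a])], L) * seed_mult
  score0 <- colSums(A)

  best_e <- score0
  best_g <- rep(0L, n_win)  # 0 = ungapped; else gap at fragment position g
  if (allow_gap && L >= 3L) {
    idx_b <- idx_a - 1L
    idx_b[idx_b < 1L] <- 1L  # miRNA pos L never sits after the gap; dummy
    B <- matrix(base_pen[cbind(rep(m, n_win), tx[idx_b])], L) * seed_mult
    # fragment gap at position g unpairs miRNA position L + 1 - g; miRNA
    # positions above that pair as in A, those below shift onto B
    csumA <- apply(A, 2L, cumsum)   # csumA[i, s] = sum A[1..i, s]
    csumB <- apply(B, 2L, cumsum)
    for (g in 2:(L - 1L)) {
      ig <- L + 1L - g
      e_g <- (score0 - csumA[ig, ]) + 2 + csumB[ig - 1L, ]
      upd <- e_g < best_e
      best_e[upd] <- e_g[upd]
      best_g[upd] <- g
    }
  }

  keep <- which(best_e <= max_expectation)
  hits <- lapply(keep, function(s) {
    g <- best_g[s]
    if (g == 0L) {
      frag <- paste(tx[s:(s + L - 1L)], collapse = "")
      tend <- s + L - 1L
    } else {
      seg <- tx[s:(s + L - 2L)]  # the L - 1 real bases of a gapped site
      frag <- paste(c(seg[seq_len(g - 1L)], "-", seg[g:(L - 1L)]),
                    collapse = "")
      tend <- s + L - 2L
    }
    score_duplex(paste(m, collapse = ""), frag, mirna_id = mirna_id,
                 target_id = transcript_id, target_start = s,
                 target_end = tend)
  })
  e <- vapply(hits, `[[`, numeric(1), "expectation")
  st <- vapply(hits, `[[`, integer(1), "target_start")
  hits[order(e, st)]
}

#' Turn a list of scan hits into a table
#'
#' @param hits list of `duplex_alignment` objects.
#' @return data.frame mirroring the conventional target-prediction report
#'   columns (accessions, expectation, UPE, coordinates, aligned fragments,
#'   inhibition).
#' @export
duplex_table <- function(hits) {
  if (length(hits) == 0L) {
    return(data.frame(mirna_acc = character(), target_acc = character(),
                      expectation = numeric(), upe = numeric(),
                      mirna_start = integer(), mirna_end = integer(),
                      target_start = integer(), target_end = integer(),
                      mirna_fragment = character(),
                      target_fragment = character(),
                      inhibition = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    mirna_acc = vapply(hits, `[[`, "", "mirna_id"),
    target_acc = vapply(hits, `[[`, "", "target_id"),
    expectation = vapply(hits, `[[`, numeric(1), "expectation"),
    upe = vapply(hits, `[[`, numeric(1), "upe"),
    mirna_start = vapply(hits, `[[`, integer(1), "mirna_start"),
    mirna_end = vapply(hits, `[[`, integer(1), "mirna_end"),
    target_start = vapply(hits, `[[`, integer(1), "target_start"),
    target_end = vapply(hits, `[[`, integer(1), "target_end"),
    mirna_fragment = vapply(hits, `[[`, "", "mirna_fragment"),
    target_fragment = vapply(hits, `[[`, "", "target_fragment"),
    inhibition = vapply(hits, `[[`, "", "inhibition"),
    stringsAsFactors = FALSE
  )
}

#' Join TF- and miRNA-target evidence onto a candidate gene set
#'
#' @param candidates character vector of candidate gene ids.
#' @param tf_pairs data.frame with columns `tf_id`, `target_id` (may be
#'   NULL).
#' @param mirna_hits data.frame from [duplex_table()] (may be NULL).
#' @return data.frame of de-duplicated links: `regulator_id`,
#'   `target_gene`, `kind` (`"tf"` or `"mirna"`), `evidence`.
#' @export
join_regulators <- function(candidates, tf_pairs = NULL, mirna_hits = NULL) {
  links <- list()
  if (!is.null(tf_pairs) && nrow(tf_pairs) > 0L) {
    keep <- tf_pairs$target_id %in% candidates
    links$tf <- data.frame(regulator_id = tf_pairs$tf_id[keep],
                           target_gene = tf_pairs$target_id[keep],
                           kind = rep("tf", sum(keep)),
                           evidence = rep("tf_target_table", sum(keep)),
                           stringsAsFactors = FALSE)
  }
  if (!is.null(mirna_hits) && nrow(mirna_hits) > 0L) {
    keep <- mirna_hits$target_acc %in% candidates
    links$mirna <- data.frame(
      regulator_id = mirna_hits$mirna_acc[keep],
      target_gene = mirna_hits$target_acc[keep],
      kind = rep("mirna", sum(keep)),
      evidence = sprintf("e=%g;%s", mirna_hits$expectation[keep],
                         mirna_hits$inhibition[keep]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(links))
  if (is.null(out)) {
    out <- data.frame(regulator_id = character(), target_gene = character(),
                      kind = character(), evidence = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[!duplicated(out[c("regulator_id", "target_gene", "kind")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
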