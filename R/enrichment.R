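#' Pathway enrichment by the hypergeometric (one-sided Fisher) test
#'
#' For each annotation term, tests whether the input gene set contains more
#' term members than expected by chance given the annotated universe:
#' p = P(X >= k) with X ~ Hypergeometric(N, K, n), where N is the universe
#' size, K the term's background count, n the input size and k the overlap.
#' Terms with background count below `small_term_cutoff` are excluded.
#' Benjamini-Hochberg adjusted p-values are appended and results are sorted
#' by ascending raw p.
#'
#' @param input_set character vector of gene ids (intersected with the
#'   universe).
#' @param annotations named list of character vectors, one per term (see
#'   [read_gmt()]).
#' @param universe background gene universe; default: all genes with at
#'   least one annotation.
#' @param small_term_cutoff minimum background count; default 5.
#' @return data.frame with columns `term_id`, `name`, `input_count`,
#'   `background_count`, `input_size`, `universe_size`, `p_value`,
#'   `corrected_p`.
#' @export
fisher_enrichment <- function(input_set, annotations, universe = NULL,
                              small_term_cutoff = 5L) {
  term_names <- attr(annotations, "term_names") %||%
    setNames(names(annotations), names(annotations))
  if (is.null(universe)) universe <- unique(unlist(annotations))
  stop_if(length(universe) == 0L, "empty annotation universe")
  universe <- unique(universe)
  input_set <- intersect(unique(input_set), universe)

  N <- length(universe)
  n <- length(input_set)
  rows <- lapply(names(annotations), function(id) {
    bg <- intersect(annotations[[id]], universe)
    K <- length(bg)
    if (K < small_term_cutoff) return(NULL)
    k <- length(intersect(input_set, bg))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, name = unname(term_names[id]),
               input_count = k, background_count = K,
               input_size = n, universe_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(), name = character(),
                      input_count = integer(), background_count = integer(),
                      input_size = integer(), universe_size = integer(),
                      p_value = numeric(), corrected_p = numeric())
    return(out)
  }
  out$corrected_p <- bh_adjust(out$p_value)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over the standard step-up procedure
#' (`stats::p.adjust(..., method = "BH")`).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, each >= the raw value and capped at 1.
#' @export
bh_adjust <- function(p) {
  stop_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Top-ranked enrichment terms
#'
#' @param results data.frame from [fisher_enrichment()].
#' @param k number of terms to keep (ascending corrected p, ties broken by
#'   term id).
#' @return the first `k` rows after ranking.
#' @export
top_terms <- function(results, k = 10L) {
  stop_if(!is_count(k), "k must be a non-negative integer")
  ord <- order(results$corrected_p, results$term_id)
  head(results[ord, , drop = FALSE], k)
}
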