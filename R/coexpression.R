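#' Pearson product-moment correlation of two series
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  stop_if(length(x) != length(y), "x and y differ in length")
  stop_if(length(x) < 3L, "need at least 3 observations")
  stop_if(sd(x) == 0 || sd(y) == 0, "undefined correlation: constant vector")
  cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the t transform t = r * sqrt((n-2) / (1-r^2)) on n-2 degrees of
#' freedom. With only n = 4 samples (df = 2) this reduces to the closed
#' form 1 - t/sqrt(2 + t^2); at r = 0.9 that gives p ~ 0.10, i.e. with
#' 4-stage series the conjunction of |r| >= 0.9 and p <= 0.05 implies an
#' effective |r| cutoff above 0.9.
#'
#' @param r correlation, |r| < 1.
#' @param n sample count, >= 3.
#' @return two-sided p-value.
#' @export
corr_pvalue <- function(r, n) {
  stop_if(any(n < 3), "need n >= 3")
  stop_if(any(abs(r) >= 1), "|r| must be < 1 (p -> 0 as |r| -> 1)")
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Co-expression neighborhood of a focal gene
#'
#' Finds all genes whose expression series satisfies both criteria
#' |r| >= `r_min` and p <= `alpha` against the focal gene. Constant series
#' (undefined correlation) are skipped.
#'
#' @param target focal gene id (must be a row of `m`).
#' @param m expression matrix, genes x samples (RPKM-like scale; the
#'   correlation is computed on the values as given).
#' @param r_min absolute-correlation threshold; default 0.9.
#' @param alpha p-value threshold; default 0.05.
#' @return data.frame of edges: `gene_a` (the target), `gene_b`, `r`, `p`,
#'   `n`.
#' @export
coexpr_neighbors <- function(target, m, r_min = 0.9, alpha = 0.05) {
  stop_if(!target %in% rownames(m), sprintf("target %s not in matrix", target))
  x <- m[target, ]
  stop_if(sd(x) == 0, "target series is constant")
  others <- setdiff(rownames(m), target)
  o <- m[others, , drop = FALSE]
  ok <- apply(o, 1L, sd) > 0
  r <- as.vector(cor(x, t(o[ok, , drop = FALSE])))
  n <- length(x)
  p <- ifelse(abs(r) >= 1, 0, corr_pvalue(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15), n))
  keep <- abs(r) >= r_min & p <= alpha
  data.frame(gene_a = target, gene_b = others[ok][keep],
             r = r[keep], p = p[keep], n = n, stringsAsFactors = FALSE)
}

#' Compare two species' co-expression neighborhoods through orthology
#'
#' Pairs of neighbors (one per species) that belong to the same orthologous
#' group are the conserved part of the two networks; the remaining genes
#' are species-specific and are typically passed on to pathway enrichment.
#'
#' @param nbrs_a,nbrs_b edge data.frames from [coexpr_neighbors()] for
#'   species A and B.
#' @param og_table long-format OG membership table covering both gene sets.
#' @return list with `shared` (data.frame `gene_a`, `gene_b`, `og_id`),
#'   `specific_a` and `specific_b` (character vectors).
#' @export
compare_networks <- function(nbrs_a, nbrs_b, og_table) {
  og_of <- setNames(og_table$og_id, og_table$gene_id)
  ga <- unique(nbrs_a$gene_b)
  gb <- unique(nbrs_b$gene_b)
  oa <- og_of[ga]
  ob <- og_of[gb]
  shared_og <- intersect(oa[!is.na(oa)], ob[!is.na(ob)])

  shared <- do.call(rbind, lapply(shared_og, function(og) {
    expand.grid(gene_a = ga[!is.na(oa) & oa == og],
                gene_b = gb[!is.na(ob) & ob == og],
                stringsAsFactors = FALSE)
  }))
  if (is.null(shared)) {
    shared <- data.frame(gene_a = character(), gene_b = character(),
                         og_id = character(), stringsAsFactors = FALSE)
  } else {
    shared$og_id <- unname(og_of[shared$gene_a])
  }
  list(shared = shared,
       specific_a = sort(setdiff(ga, shared$gene_a)),
       specific_b = sort(setdiff(gb, shared$gene_b)))
}
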