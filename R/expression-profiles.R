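#' Relative expression content
#'
#' Divides each value by the mean expression of all genes at that stage, so
#' profiles become comparable between species with different overall
#' expression levels. The per-stage mean of the output is exactly 1.
#'
#' @param m non-negative numeric matrix, genes x stages.
#' @return matrix of the same shape.
#' @export
relative_expression <- function(m) {
  stop_if(!is.matrix(m) || !is.numeric(m), "m must be a numeric matrix")
  stop_if(any(m < 0), "expression values must be non-negative")
  mu <- colMeans(m)
  stop_if(any(mu == 0), "degenerate stage: all genes zero at some stage")
  sweep(m, 2L, mu, "/")
}

#' Log-ratio transform of a stage series
#'
#' Transforms an expression series (v0, v1, ..., vn) to
#' (0, log2(v1/v0), ..., log2(vn/v0)), the representation used for short
#' time-series profile clustering. The transform is invariant to positive
#' scaling of the series, so absolute expression level drops out and only
#' the temporal shape remains.
#'
#' @param v numeric vector of positive values; `v[1]` must be > 0.
#' @return numeric vector of the same length, first element 0.
#' @export
log_normalize <- function(v) {
  stop_if(!is.numeric(v) || length(v) < 2L, "v must be a numeric series")
  stop_if(v[1] <= 0, "first-stage value must be positive (gene should be filtered)")
  log2(v / v[1])
}

#' Log-ratio transform of a whole matrix
#'
#' Applies [log_normalize()] row-wise. Genes whose first-stage value is 0
#' (or that contain non-finite values) cannot be transformed and are
#' excluded rather than pseudocounted; their ids are returned in the
#' `"excluded"` attribute.
#'
#' @param m non-negative numeric matrix, genes x stages.
#' @return transformed matrix of the kept genes, with attribute `excluded`.
#' @export
log_normalize_matrix <- function(m) {
  keep <- m[, 1] > 0 & apply(is.finite(m), 1L, all)
  if (!any(keep)) {
    out <- matrix(numeric(0), 0L, ncol(m), dimnames = list(NULL, colnames(m)))
  } else {
    out <- t(apply(m[keep, , drop = FALSE], 1L, log_normalize))
    colnames(out) <- colnames(m)
  }
  attr(out, "excluded") <- rownames(m)[!keep]
  out
}

#' Minimum absolute expression change filter
#'
#' Keeps a transformed series only if it moves by at least `threshold` on
#' the log2-ratio scale at some stage, removing near-flat genes before
#' profile assignment.
#'
#' @param transformed numeric vector (from [log_normalize()]) or matrix
#'   (rows filtered).
#' @param threshold non-negative log2-change threshold; default 2.
#' @return logical scalar (vector input) or logical vector (matrix input).
#' @export
min_change_filter <- function(transformed, threshold = 2) {
  stop_if(!is.numeric(threshold) || threshold < 0,
          "threshold must be non-negative")
  if (is.matrix(transformed)) {
    apply(abs(transformed), 1L, max) >= threshold
  } else {
    max(abs(transformed)) >= threshold
  }
}

#' Generate model temporal profiles
#'
#' Enumerates every temporal shape that starts at 0 and changes by an
#' integer number of units in `-c..c` between consecutive stages (there are
#' `(2c+1)^(n_stages-1)` of them), then picks `m` representatives by greedy
#' max-min Euclidean distance, seeded with the all-flat profile. The greedy
#' choice is deterministic: ties are broken by enumeration order.
#'
#' @param n_stages number of stages (>= 2).
#' @param c maximum per-step unit change (positive integer).
#' @param m number of profiles to select; default 20, the configuration
#'   used for a 4-stage seed developmental series.
#' @param seed kept for interface stability; selection is deterministic.
#' @return object of class `model_profiles`: an `m x n_stages` numeric
#'   matrix of shapes, row ids `1..m` in selection order (profile 1 is the
#'   flat profile).
#' @export
generate_model_profiles <- function(n_stages = 4L, c = 1L, m = 20L, seed = 1L) {
  stop_if(!is_count(n_stages, 2L), "n_stages must be an integer >= 2")
  stop_if(!is_count(c, 1L), "c must be a positive integer")
  n_cand <- (2 * c + 1)^(n_stages - 1)
  stop_if(!is_count(m, 1L) || m > n_cand,
          sprintf("m must be an integer in 1..%d", n_cand))

  steps <- expand.grid(rep(list(seq(-c, c)), n_stages - 1L))
  shapes <- cbind(0, t(apply(steps, 1L, cumsum)))
  dimnames(shapes) <- NULL

  flat <- which(rowSums(abs(shapes)) == 0)[1]
  selected <- flat
  # squared distance of every candidate to its nearest selected profile
  mind <- rowSums(sweep(shapes, 2L, shapes[flat, ], "-")^2)
  while (length(selected) < m) {
    nxt <- which.max(mind)           # ties -> first in enumeration order
    selected <- c(selected, nxt)
    d <- rowSums(sweep(shapes, 2L, shapes[nxt, ], "-")^2)
    mind <- pmin(mind, d)
  }
  out <- shapes[selected, , drop = FALSE]
  rownames(out) <- seq_len(m)
  colnames(out) <- paste0("t", seq_len(n_stages))
  structure(out, class = c("model_profiles", "matrix"),
            c = as.integer(c), n_candidates = n_cand)
}

#' @export
print.model_profiles <- function(x, ...) {
  cat(sprintf("<model_profiles> %d profiles over %d stages (c = %d, %d candidates)\n",
              nrow(x), ncol(x), attr(x, "c"), attr(x, "n_candidates")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Assign genes to the best-correlated model profile
#'
#' Each transformed gene series is assigned to the profile with the highest
#' Pearson correlation to its shape. Because correlation is invariant to
#' positive affine transforms, assignment depends only on the temporal
#' shape, not on its amplitude. Zero-variance (flat) gene series have no
#' defined correlation and are left unassigned; flat model profiles can
#' never win for the same reason. Ties go to the lowest profile id.
#'
#' @param transformed matrix from [log_normalize_matrix()] (genes x stages).
#' @param profiles [generate_model_profiles()] output.
#' @return object of class `profile_assignment`: data.frame with columns
#'   `gene`, `profile` (integer, NA when unassigned), `corr`.
#' @export
assign_genes <- function(transformed, profiles) {
  stop_if(is.null(profiles) || nrow(profiles) == 0L, "empty profile list")
  stop_if(ncol(transformed) != ncol(profiles),
          "stage counts of genes and profiles differ")
  if (nrow(transformed) == 0L) {
    return(structure(data.frame(gene = character(), profile = integer(),
                                corr = numeric(), stringsAsFactors = FALSE),
                     class = c("profile_assignment", "data.frame"),
                     n_profiles = nrow(profiles)))
  }
  genes <- rownames(transformed) %||% as.character(seq_len(nrow(transformed)))

  gene_sd <- apply(transformed, 1L, sd)
  prof_sd <- apply(profiles, 1L, sd)
  cc <- suppressWarnings(cor(t(transformed), t(unclass(profiles))))
  cc[gene_sd == 0, ] <- NA_real_
  cc[, prof_sd == 0] <- NA_real_

  pick <- function(row) {
    if (all(is.na(row))) return(c(NA_integer_, NA_real_))
    j <- which.max(row)  # which.max returns the first (lowest id) maximum
    c(j, row[j])
  }
  res <- t(apply(cc, 1L, pick))
  out <- data.frame(gene = genes, profile = as.integer(res[, 1]),
                    corr = res[, 2], stringsAsFactors = FALSE)
  structure(out, class = c("profile_assignment", "data.frame"),
            n_profiles = nrow(profiles))
}

#' Permutation significance of profile cluster sizes
#'
#' For each model profile, the expected cluster size is the number of
#' assigned genes times the mean fraction of genes assigned to that profile
#' when the stage order is permuted (all `n_stages!` permutations when
#' `n_stages <= 5`, otherwise `n_perm` random permutations). The p-value is
#' the upper tail of Binomial(total assigned, expected/total) at the
#' observed size, and a profile is significant when p < `alpha`. No
#' multiplicity correction is applied by default (set `bonferroni = TRUE`
#' to divide `alpha` by the number of profiles).
#'
#' @param assignment [assign_genes()] output on the observed stage order.
#' @param transformed the matrix that produced `assignment`.
#' @param profiles the model profiles used.
#' @param alpha significance level; default 0.05.
#' @param n_perm random permutations when exhaustive enumeration is not
#'   feasible (`n_stages > 5`).
#' @param seed RNG seed for the random-permutation fallback.
#' @param bonferroni divide alpha by the number of profiles.
#' @return data.frame with columns `profile`, `observed`, `expected`,
#'   `p_value`, `significant`.
#' @export
profile_significance <- function(assignment, transformed, profiles,
                                 alpha = 0.05, n_perm = 1000L, seed = 1L,
                                 bonferroni = FALSE) {
  n_prof <- nrow(profiles)
  n_stage <- ncol(profiles)
  observed <- tabulate(assignment$profile[!is.na(assignment$profile)], n_prof)
  total <- sum(observed)

  if (total == 0L || nrow(transformed) == 0L) {
    return(data.frame(profile = seq_len(n_prof), observed = observed,
                      expected = 0, p_value = 1, significant = FALSE))
  }

  if (n_stage <= 5L) {
    perms <- perm_rows(n_stage)
  } else {
    perms <- with_seed(seed, t(replicate(n_perm, sample.int(n_stage))))
  }

  frac <- matrix(0, nrow(perms), n_prof)
  for (k in seq_len(nrow(perms))) {
    # permuting stages of the transformed matrix is equivalent to permuting
    # the raw series and re-log-normalizing: the transforms differ by a
    # constant shift per gene, to which Pearson correlation is invariant
    a <- assign_genes(transformed[, perms[k, ], drop = FALSE], profiles)
    cnt <- tabulate(a$profile[!is.na(a$profile)], n_prof)
    if (sum(cnt) > 0) frac[k, ] <- cnt / sum(cnt)
  }
  expected <- total * colMeans(frac)

  p <- vapply(seq_len(n_prof), function(j) {
    pr <- min(max(expected[j] / total, 0), 1)
    pbinom(observed[j] - 1L, total, pr, lower.tail = FALSE)
  }, numeric(1))

  cut <- if (bonferroni) alpha / n_prof else alpha
  data.frame(profile = seq_len(n_prof), observed = observed,
             expected = expected, p_value = p, significant = p < cut)
}

#' Classify the temporal trend of a profile over a stage window
#'
#' The default window (stages 2 to 3) is the period of rapid seed-oil
#' accumulation in a 4-stage developmental series: profiles rising across
#' it are "up", falling ones "down", flat ones "other".
#'
#' @param profiles [generate_model_profiles()] output (or a shape matrix).
#' @param window integer pair `(i, j)` of stage indices, `i < j`.
#' @return character vector (one per profile) in `{"up", "down", "other"}`.
#' @export
classify_trend <- function(profiles, window = c(2L, 3L)) {
  stop_if(length(window) != 2L || window[1] >= window[2] ||
            window[1] < 1L || window[2] > ncol(profiles),
          "window must be stage indices (i, j) with i < j in range")
  d <- profiles[, window[2]] - profiles[, window[1]]
  ifelse(d > 0, "up", ifelse(d < 0, "down", "other"))
}

#' Combine copy-number and expression-trend evidence into candidate genes
#'
#' Restricted to the query OGs (the gene families of interest), a gene is a
#' candidate when its family is copy-number divergent, or when it is
#' assigned to a significant up- or down-trending profile — by default the
#' union of the two rules (`combine = "intersect"` requires both).
#'
#' @param og_table long-format OG membership table.
#' @param query_og_ids OG ids of the families of interest.
#' @param divergent_og_ids OG ids flagged by [divergent_ogs()].
#' @param assignment [assign_genes()] output for the genes of one or both
#'   species (rbind multiple species first if needed).
#' @param significance [profile_significance()] output matching `assignment`.
#' @param trends [classify_trend()] output for the same profiles.
#' @param combine `"union"` (default) or `"intersect"`.
#' @return sorted character vector of candidate gene ids.
#' @export
candidate_genes <- function(og_table, query_og_ids, divergent_og_ids,
                            assignment, significance, trends,
                            combine = c("union", "intersect")) {
  combine <- match.arg(combine)
  in_query <- og_table$og_id %in% query_og_ids

  cnv_genes <- og_table$gene_id[in_query &
                                  og_table$og_id %in% divergent_og_ids]

  good_prof <- significance$profile[significance$significant &
                                      trends %in% c("up", "down")]
  trend_all <- assignment$gene[!is.na(assignment$profile) &
                                 assignment$profile %in% good_prof]
  trend_genes <- intersect(trend_all, og_table$gene_id[in_query])

  out <- if (combine == "union") union(cnv_genes, trend_genes)
         else intersect(cnv_genes, trend_genes)
  sort(unique(out))
}
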