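#' Describe a species by name and ploidy
#'
#' Ploidy is the genome copy multiplicity used to put gene-family copy
#' counts of species with different polyploidy histories on a common scale
#' (e.g. a diploid soybean-like species has ploidy 2, a tetraploid
#' rapeseed-like species ploidy 4).
#'
#' @param name species label, matching the `species` column of the OG table.
#' @param ploidy integer >= 1.
#' @return an object of class `species_info`.
#' @export
species_info <- function(name, ploidy) {
  stop_if(!is.character(name) || length(name) != 1L || !nzchar(name),
          "species name must be a non-empty string")
  stop_if(!is_count(ploidy, min = 1L), "ploidy must be an integer >= 1")
  structure(list(name = name, ploidy = as.integer(ploidy)),
            class = "species_info")
}

#' @export
print.species_info <- function(x, ...) {
  cat(sprintf("<species_info> %s (ploidy %d)\n", x$name, x$ploidy))
  invisible(x)
}

#' Relative copy number of a gene family
#'
#' The family copy count divided by the species ploidy. Dividing by ploidy
#' makes counts comparable across species with different polyploidy levels:
#' a family with 41 copies in a diploid (41/2 = 20.5) is larger, per genome
#' complement, than one with 31 copies in a tetraploid (31/4 = 7.75).
#'
#' @param count non-negative integer copy count (vectorized).
#' @param ploidy integer >= 1 (vectorized or scalar).
#' @return `count / ploidy` as a numeric vector.
#' @examples
#' relative_copy_number(41, 2)  # 20.5
#' relative_copy_number(105, 4) # 26.25
#' @export
relative_copy_number <- function(count, ploidy) {
  stop_if(any(!is.finite(count)) || any(count < 0) || any(count != floor(count)),
          "count must be a non-negative integer")
  stop_if(any(!is.finite(ploidy)) || any(ploidy < 1) ||
            any(ploidy != floor(ploidy)),
          "ploidy must be an integer >= 1")
  count / ploidy
}

#' Classify an orthologous group by its two copy counts
#'
#' @param count_a,count_b non-negative integer copy counts in species A and
#'   B (vectorized).
#' @return character vector with levels `specific_A`, `specific_B`,
#'   `one_to_one`, `one_to_many`, `many_to_one`, `many_to_many`.
#' @export
classify_og <- function(count_a, count_b) {
  stop_if(length(count_a) != length(count_b), "count vectors differ in length")
  stop_if(any(count_a < 0) || any(count_b < 0), "counts must be non-negative")
  stop_if(any(count_a == 0 & count_b == 0),
          "invalid OG: both species have zero copies")
  out <- character(length(count_a))
  out[count_a > 0 & count_b == 0] <- "specific_A"
  out[count_a == 0 & count_b > 0] <- "specific_B"
  out[count_a == 1 & count_b == 1] <- "one_to_one"
  out[count_a == 1 & count_b > 1] <- "one_to_many"
  out[count_a > 1 & count_b == 1] <- "many_to_one"
  out[count_a > 1 & count_b > 1] <- "many_to_many"
  out
}

#' Summarize orthologous groups for a species pair
#'
#' Builds one row per OG with per-species copy counts, relative copy
#' numbers and the OG class. OGs with zero members in both species (absent
#' from the table for this pair) are dropped.
#'
#' @param og_table long-format data.frame with columns `og_id`, `species`,
#'   `gene_id` (see [read_og_table()]).
#' @param a,b [species_info()] objects for species A and B.
#' @return data.frame with columns `og_id`, `count_a`, `count_b`, `rcn_a`,
#'   `rcn_b`, `class`.
#' @export
og_summary <- function(og_table, a, b) {
  stop_if(!inherits(a, "species_info") || !inherits(b, "species_info"),
          "a and b must be species_info objects")
  og_ids <- sort(unique(og_table$og_id))
  cnt <- function(sp) {
    tab <- table(factor(og_table$og_id[og_table$species == sp],
                        levels = og_ids))
    as.integer(tab)
  }
  count_a <- cnt(a$name)
  count_b <- cnt(b$name)
  keep <- count_a > 0 | count_b > 0
  data.frame(
    og_id = og_ids[keep],
    count_a = count_a[keep],
    count_b = count_b[keep],
    rcn_a = relative_copy_number(count_a[keep], a$ploidy),
    rcn_b = relative_copy_number(count_b[keep], b$ploidy),
    class = classify_og(count_a[keep], count_b[keep]),
    stringsAsFactors = FALSE
  )
}

#' Flag copy-number-divergent orthologous groups
#'
#' An OG is divergent when the ratio of its two relative copy numbers
#' (larger over smaller) is at least `fold`, or when one species has no
#' copy at all while the other does (species-specific presence, the
#' strongest form of divergence; the ratio is undefined there).
#'
#' @param summary data.frame from [og_summary()].
#' @param fold ratio threshold >= 1; default 2.
#' @return the input data.frame with an added logical column `divergent`.
#' @export
divergent_ogs <- function(summary, fold = 2) {
  stop_if(!is.numeric(fold) || length(fold) != 1L || fold < 1,
          "fold must be a single number >= 1")
  if (nrow(summary) == 0L) {
    summary$divergent <- logical(0)
    return(summary)
  }
  lo <- pmin(summary$rcn_a, summary$rcn_b)
  hi <- pmax(summary$rcn_a, summary$rcn_b)
  summary$divergent <- ifelse(lo == 0, hi > 0, hi / lo >= fold)
  summary
}

#' Restrict orthologous groups to those containing query genes
#'
#' Mirrors the study design in which lipid-biosynthesis and carbon-
#' metabolism genes of a reference species are used as queries to pull out
#' the gene families of interest.
#'
#' @param query_gene_ids character vector of query gene ids.
#' @param og_table long-format OG membership table.
#' @return character vector of OG ids containing at least one query gene.
#' @export
select_query_ogs <- function(query_gene_ids, og_table) {
  stop_if(length(query_gene_ids) == 0L, "query gene set is empty")
  sort(unique(og_table$og_id[og_table$gene_id %in% query_gene_ids]))
}
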