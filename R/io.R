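#' Read an orthologous-group membership table
#'
#' The long-format table has one row per gene with columns `og_id`,
#' `species` and `gene_id` (tab-separated, with a header line), as produced
#' by orthology inference tools after reshaping, or by [simulate_study()].
#'
#' @param path path to a tab-separated file.
#' @return a data.frame with character columns `og_id`, `species`, `gene_id`.
#' @export
read_og_table <- function(path) {
  df <- read_tsv(path)
  need <- c("og_id", "species", "gene_id")
  stop_if(!all(need %in% names(df)),
          sprintf("og table %s must have columns: %s", path,
                  paste(need, collapse = ", ")))
  df[need] <- lapply(df[need], as.character)
  df[need]
}

#' Read a gene-by-stage expression matrix
#'
#' Expects a tab-separated file whose first column (`gene`) holds gene ids
#' and remaining columns hold non-negative RPKM-like values for ordered
#' developmental stages (`t1`, `t2`, ...).
#'
#' @param path path to a tab-separated file.
#' @return a numeric matrix, genes in rows (rownames), stages in columns.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv(path)
  stop_if(names(df)[1] != "gene",
          sprintf("expression table %s must start with a 'gene' column", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df$gene)
  stop_if(any(m < 0, na.rm = TRUE), "expression values must be non-negative")
  m
}

#' Read gene sets in GMT format
#'
#' One term per line: `term_id<TAB>name<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors (names are term ids); the
#'   human-readable term name is kept in the `"term_names"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  stop_if(any(bad), sprintf("GMT %s: lines with fewer than 3 fields", path))
  ids <- vapply(parts, `[[`, "", 1L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "term_names") <- setNames(vapply(parts, `[[`, "", 2L), ids)
  sets
}

#' Read sequences from a FASTA file
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return a named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stop_if(is.null(names(seqs)) || any(!nzchar(names(seqs))),
          "sequences must be named")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

# expression matrix -> "gene t1..tn" TSV
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
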