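#' Configuration for an end-to-end pipeline run
#'
#' Collects the input paths and thresholds of every stage. Optional inputs
#' (GMT annotations, miRNA/transcript FASTA, TF-target pairs, a network
#' focal gene) switch their stages on when supplied.
#'
#' @param species_a,species_b [species_info()] objects.
#' @param og_table path to the long-format OG membership TSV.
#' @param expr_a,expr_b paths to the per-species expression TSVs.
#' @param query_genes optional character vector (or file of one id per
#'   line) restricting candidates to families containing these genes;
#'   default: all OGs are query OGs.
#' @param gmt,mirna_fasta,transcripts_fasta,tf_pairs optional input paths.
#' @param network_target_a,network_target_b optional focal gene ids for
#'   the co-expression stage.
#' @param fold copy-number divergence fold threshold (>= 1).
#' @param min_change minimum absolute log2 expression change.
#' @param alpha profile significance level.
#' @param r_min,coexpr_alpha co-expression thresholds.
#' @param max_expectation duplex score cutoff.
#' @param fdr,small_term_cutoff,top_k enrichment parameters.
#' @param n_profiles,c model-profile parameters.
#' @param trend_window stage window for the trend call.
#' @param combine how copy-number and trend evidence combine
#'   (`"union"`/`"intersect"`).
#' @param seed RNG seed for any stochastic step.
#' @return an object of class `run_config`.
#' @export
run_config <- function(species_a, species_b, og_table, expr_a, expr_b,
                       query_genes = NULL, gmt = NULL, mirna_fasta = NULL,
                       transcripts_fasta = NULL, tf_pairs = NULL,
                       network_target_a = NULL, network_target_b = NULL,
                       fold = 2, min_change = 2, alpha = 0.05,
                       r_min = 0.9, coexpr_alpha = 0.05,
                       max_expectation = 3, fdr = 0.05,
                       small_term_cutoff = 5L, top_k = 10L,
                       n_profiles = 20L, c = 1L, trend_window = c(2L, 3L),
                       combine = "union", seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' @param cfg a [run_config()].
#' @return character vector of problems, empty when the config is runnable.
#' @export
validate_config <- function(cfg) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)

  for (sp in c("species_a", "species_b")) {
    s <- cfg[[sp]]
    if (!inherits(s, "species_info")) add(sprintf("%s: not a species_info", sp))
    else if (s$ploidy < 1) add(sprintf("%s: ploidy must be >= 1", sp))
  }
  for (f in c("og_table", "expr_a", "expr_b")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      add(sprintf("%s: missing input file (%s)", f, cfg[[f]] %||% "NULL"))
  }
  for (f in c("gmt", "mirna_fasta", "transcripts_fasta", "tf_pairs")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      add(sprintf("%s: file not found (%s)", f, cfg[[f]]))
  }
  chk_range <- function(field, lo, hi) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || v < lo || v > hi)
      add(sprintf("%s: must lie in [%g, %g]", field, lo, hi))
  }
  chk_range("fold", 1, Inf)
  chk_range("min_change", 0, Inf)
  chk_range("alpha", 0, 1)
  chk_range("coexpr_alpha", 0, 1)
  chk_range("fdr", 0, 1)
  chk_range("r_min", 0, 1)
  chk_range("max_expectation", 0, Inf)
  if (!is_count(cfg$small_term_cutoff)) add("small_term_cutoff: must be a non-negative integer")
  if (!is_count(cfg$top_k)) add("top_k: must be a non-negative integer")
  if (!is_count(cfg$n_profiles, 1L)) add("n_profiles: must be a positive integer")
  if (!is_count(cfg$c, 1L)) add("c: must be a positive integer")
  if (!cfg$combine %in% c("union", "intersect"))
    add("combine: must be 'union' or 'intersect'")
  issues
}

#' Run the full candidate-prioritization pipeline
#'
#' Executes the stages in dependency order — OG copy-number divergence,
#' expression profile clustering and significance, candidate combination,
#' optional pathway enrichment, optional co-expression network comparison,
#' optional miRNA/TF regulatory overlay — writes intermediate TSVs and a
#' per-gene candidate report to `out_dir`, and returns the report. The run
#' is deterministic given the seed.
#'
#' @param cfg a validated [run_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) the candidate report data.frame.
#' @export
run_pipeline <- function(cfg, out_dir) {
  issues <- validate_config(cfg)
  stop_if(length(issues) > 0,
          paste0("invalid configuration:\n  ", paste(issues, collapse = "\n  ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_rows <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(code)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = name, seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  # -- orthology --------------------------------------------------------
  og_table <- read_og_table(cfg$og_table)
  osum <- stage("orthology", {
    divergent_ogs(og_summary(og_table, cfg$species_a, cfg$species_b),
                  fold = cfg$fold)
  })
  write_tsv(osum, file.path(out_dir, "divergent_ogs.tsv"))

  query_genes <- cfg$query_genes
  if (is.character(query_genes) && length(query_genes) == 1L &&
      file.exists(query_genes)) {
    query_genes <- readLines(query_genes, warn = FALSE)
  }
  query_ogs <- if (is.null(query_genes)) unique(og_table$og_id)
               else select_query_ogs(query_genes, og_table)

  # -- expression profiles ----------------------------------------------
  profiles <- generate_model_profiles(
    n_stages = ncol(read_expression_matrix(cfg$expr_a)),
    c = cfg$c, m = cfg$n_profiles, seed = cfg$seed)
  trends <- classify_trend(profiles, cfg$trend_window)
  write_tsv(data.frame(profile = rownames(profiles),
                       shape = apply(profiles, 1L, paste, collapse = ","),
                       trend = trends),
            file.path(out_dir, "profiles.tsv"))

  run_species <- function(expr_path, tag) {
    stage(paste0("profiles_", tag), {
      m <- read_expression_matrix(expr_path)
      rel <- relative_expression(m)
      write_expression_matrix(round(rel, 6),
                              file.path(out_dir, sprintf("rel_expr_%s.tsv", tag)))
      tv <- log_normalize_matrix(m)
      keep <- min_change_filter(tv, cfg$min_change)
      tv_kept <- tv[keep, , drop = FALSE]
      asg <- assign_genes(tv_kept, profiles)
      sig <- profile_significance(asg, tv_kept, profiles, alpha = cfg$alpha,
                                  seed = cfg$seed)
      write_tsv(asg, file.path(out_dir, sprintf("assignments_%s.tsv", tag)))
      write_tsv(sig, file.path(out_dir, sprintf("significance_%s.tsv", tag)))
      list(m = m, assignment = asg, significance = sig)
    })
  }
  pa <- run_species(cfg$expr_a, cfg$species_a$name)
  pb <- run_species(cfg$expr_b, cfg$species_b$name)

  # -- candidates -------------------------------------------------------
  divergent_ids <- osum$og_id[osum$divergent]
  asg_all <- rbind(pa$assignment, pb$assignment)
  sig_union <- data.frame(
    profile = seq_len(nrow(profiles)),
    significant = pa$significance$significant | pb$significance$significant)
  cands <- stage("candidates", {
    candidate_genes(og_table, query_ogs, divergent_ids, asg_all,
                    sig_union, trends, combine = cfg$combine)
  })
  writeLines(cands, file.path(out_dir, "candidates.txt"))

  # -- enrichment (optional) --------------------------------------------
  enr <- NULL
  if (!is.null(cfg$gmt)) {
    enr <- stage("enrichment", {
      ann <- read_gmt(cfg$gmt)
      res <- fisher_enrichment(cands, ann,
                               small_term_cutoff = cfg$small_term_cutoff)
      top_terms(res, cfg$top_k)
    })
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  }

  # -- co-expression networks (optional) --------------------------------
  net <- NULL
  if (!is.null(cfg$network_target_a) && !is.null(cfg$network_target_b)) {
    net <- stage("coexpression", {
      na <- coexpr_neighbors(cfg$network_target_a, pa$m, cfg$r_min,
                             cfg$coexpr_alpha)
      nb <- coexpr_neighbors(cfg$network_target_b, pb$m, cfg$r_min,
                             cfg$coexpr_alpha)
      write_tsv(rbind(na, nb), file.path(out_dir, "edges.tsv"))
      compare_networks(na, nb, og_table)
    })
    write_tsv(net$shared, file.path(out_dir, "comparison.tsv"))
  }

  # -- regulation (optional) --------------------------------------------
  reg <- NULL
  if (!is.null(cfg$mirna_fasta) && !is.null(cfg$transcripts_fasta)) {
    reg <- stage("regulation", {
      mirnas <- read_fasta(cfg$mirna_fasta)
      txs <- read_fasta(cfg$transcripts_fasta)
      hits <- list()
      for (mi in names(mirnas)) for (tx in names(txs)) {
        hits <- c(hits, scan_transcript(mirnas[[mi]], txs[[tx]],
                                        max_expectation = cfg$max_expectation,
                                        mirna_id = mi, transcript_id = tx))
      }
      tf <- if (!is.null(cfg$tf_pairs)) read_tsv(cfg$tf_pairs) else NULL
      ht <- duplex_table(hits)
      write_tsv(ht, file.path(out_dir, "targets.tsv"))
      join_regulators(cands, tf_pairs = tf, mirna_hits = ht)
    })
    write_tsv(reg, file.path(out_dir, "regulators.tsv"))
  }

  # -- report -----------------------------------------------------------
  report <- stage("report", {
    rows <- og_table[og_table$gene_id %in% cands, , drop = FALSE]
    m <- match(rows$og_id, osum$og_id)
    asg_idx <- match(rows$gene_id, asg_all$gene)
    prof <- asg_all$profile[asg_idx]
    sig_by_prof <- setNames(sig_union$significant, sig_union$profile)
    regulators <- vapply(rows$gene_id, function(g) {
      if (is.null(reg)) return("")
      paste(sort(unique(reg$regulator_id[reg$target_gene == g])),
            collapse = ";")
    }, "")
    data.frame(
      gene = rows$gene_id, species = rows$species, og_id = rows$og_id,
      og_class = osum$class[m],
      rcn_a = osum$rcn_a[m], rcn_b = osum$rcn_b[m],
      divergent = osum$divergent[m],
      profile = prof,
      trend = ifelse(is.na(prof), NA_character_, trends[prof]),
      profile_significant = ifelse(is.na(prof), FALSE,
                                   unname(sig_by_prof[as.character(prof)])),
      stringsAsFactors = FALSE)
  })
  report <- report[order(report$species, report$gene), , drop = FALSE]
  rownames(report) <- NULL
  write_tsv(report, file.path(out_dir, "report.tsv"))
  write_tsv(do.call(rbind, log_rows), file.path(out_dir, "run_log.tsv"))
  invisible(report)
}
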