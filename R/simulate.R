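# synthetic two-species study generator with known ground truth.
#
# The defaults emulate the study design the package targets: a diploid
# low-oil species and a tetraploid high-oil species profiled over four
# matched seed developmental stages, RPKM-like non-negative expression with
# planted temporal profiles, planted copy-number-divergent families,
# planted miRNA target sites, and planted branch-wise selection regimes.

#' Configuration for the synthetic two-species study
#'
#' @param seed integer RNG seed; identical configs give byte-identical
#'   outputs.
#' @param n_ogs number of orthologous groups (>= 10).
#' @param species_a,species_b species labels.
#' @param ploidy_a,ploidy_b ploidies (defaults 2 and 4, a diploid vs a
#'   tetraploid).
#' @param frac_divergent fraction of OGs planted as copy-number divergent.
#' @param n_stages number of developmental stages (>= 3; default 4).
#' @param noise_sd Gaussian noise SD on the log2 scale for expression.
#' @param genes_per_profile genes planted per model profile per species.
#' @param n_planted_targets number of planted miRNA target sites.
#' @param site_mutations,site_wobbles mismatches / G:U wobbles introduced
#'   into each planted site.
#' @param transcript_length length of simulated transcripts (nt).
#' @param n_codons codons per simulated coding sequence.
#' @param c maximum per-step unit change of the planted model profiles.
#' @param n_profiles number of model profiles planted (includes the flat
#'   profile, which carries no signal and is skipped when planting).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_ogs = 100L,
                       species_a = "glyma", species_b = "bna",
                       ploidy_a = 2L, ploidy_b = 4L,
                       frac_divergent = 0.2, n_stages = 4L,
                       noise_sd = 0.2, genes_per_profile = 100L,
                       n_planted_targets = 5L, site_mutations = 0L,
                       site_wobbles = 0L, transcript_length = 500L,
                       n_codons = 500L, c = 1L, n_profiles = 20L) {
  stop_if(!is_count(seed), "seed must be a non-negative integer")
  stop_if(!is_count(n_ogs, 10L), "n_ogs must be an integer >= 10")
  stop_if(!is_count(ploidy_a, 1L) || !is_count(ploidy_b, 1L),
          "ploidies must be integers >= 1")
  stop_if(!is.numeric(frac_divergent) || frac_divergent < 0 ||
            frac_divergent > 1, "frac_divergent must lie in [0, 1]")
  stop_if(!is_count(n_stages, 3L), "n_stages must be an integer >= 3")
  stop_if(!is.numeric(noise_sd) || noise_sd < 0,
          "noise_sd must be non-negative")
  stop_if(!is_count(n_planted_targets, 1L),
          "n_planted_targets must be >= 1")
  stop_if(!is_count(c, 1L), "c must be a positive integer")
  structure(list(seed = as.integer(seed), n_ogs = as.integer(n_ogs),
                 species_a = species_a, species_b = species_b,
                 ploidy_a = as.integer(ploidy_a),
                 ploidy_b = as.integer(ploidy_b),
                 frac_divergent = frac_divergent,
                 n_stages = as.integer(n_stages), noise_sd = noise_sd,
                 genes_per_profile = as.integer(genes_per_profile),
                 n_planted_targets = as.integer(n_planted_targets),
                 site_mutations = as.integer(site_mutations),
                 site_wobbles = as.integer(site_wobbles),
                 transcript_length = as.integer(transcript_length),
                 n_codons = as.integer(n_codons), c = as.integer(c),
                 n_profiles = as.integer(n_profiles)),
            class = "sim_config")
}

# zero-truncated geometric, mean 1/p (p = 0.5 -> mean 2 copies per haploid
# genome complement)
rztgeom <- function(n, p = 0.5) rgeom(n, p) + 1L

#' Simulate a two-species orthologous-group table
#'
#' Each OG receives a base per-haploid copy number from a zero-truncated
#' geometric (mean 2), multiplied by each species' ploidy so that
#' non-divergent OGs have exactly equal relative copy numbers. A planted
#' fraction is made divergent: one species' count is doubled (rcn ratio
#' exactly 2) or zeroed (species-specific presence). Copy counts carry no
#' noise, so the 2-fold rule recovers the planted set exactly.
#'
#' @param cfg a [sim_config()].
#' @return list with `og_table` (long-format data.frame), `gene_tables`
#'   (per-species data.frames of `gene_id`, `og_id`), and `truth` (list
#'   with `divergent_og_ids`).
#' @export
simulate_species_pair <- function(cfg) {
  stop_if(!inherits(cfg, "sim_config"), "cfg must be a sim_config")
  with_seed(cfg$seed + 101L, {
    og_ids <- sprintf("OG%04d", seq_len(cfg$n_ogs))
    base <- rztgeom(cfg$n_ogs)
    count_a <- base * cfg$ploidy_a
    count_b <- base * cfg$ploidy_b

    n_div <- round(cfg$n_ogs * cfg$frac_divergent)
    div_idx <- if (n_div > 0) sort(sample.int(cfg$n_ogs, n_div)) else integer(0)
    for (i in div_idx) {
      mode <- sample(c("expand_a", "expand_b", "lose_a", "lose_b"), 1L,
                     prob = c(0.4, 0.4, 0.1, 0.1))
      switch(mode,
             expand_a = { count_a[i] <- 2L * count_a[i] },
             expand_b = { count_b[i] <- 2L * count_b[i] },
             lose_a   = { count_a[i] <- 0L },
             lose_b   = { count_b[i] <- 0L })
    }

    mk_genes <- function(sp, counts) {
      do.call(rbind, lapply(seq_along(og_ids), function(i) {
        if (counts[i] == 0L) return(NULL)
        data.frame(og_id = og_ids[i], species = sp,
                   gene_id = sprintf("%s_%s_g%02d", sp, og_ids[i],
                                     seq_len(counts[i])),
                   stringsAsFactors = FALSE)
      }))
    }
    og_table <- rbind(mk_genes(cfg$species_a, count_a),
                      mk_genes(cfg$species_b, count_b))
    rownames(og_table) <- NULL
    list(og_table = og_table,
         gene_tables = split(og_table[c("gene_id", "og_id")],
                             og_table$species),
         truth = list(divergent_og_ids = og_ids[div_idx]))
  })
}

#' Simulate stage-series expression with planted temporal profiles
#'
#' Every gene is assigned one of the supplied model profiles (cycling
#' through the non-flat ones) and its series is generated as
#' `baseline * 2^(shape + N(0, noise_sd))` with a per-gene positive
#' baseline, so all values are positive and, at `noise_sd = 0`,
#' [log_normalize()] returns the planted shape exactly.
#'
#' @param cfg a [sim_config()] (`noise_sd`, `n_stages`, `seed`,
#'   `genes_per_profile` are used).
#' @param profiles [generate_model_profiles()] output; flat (all-zero)
#'   shapes are never planted since they carry no recoverable signal.
#' @param gene_ids optional gene ids to use (e.g. one species' genes from
#'   [simulate_species_pair()]); default: `genes_per_profile` genes per
#'   planted profile.
#' @param seed_offset internal stream separator so the two species of one
#'   study draw different noise.
#' @return list with `expr` (genes x stages matrix, columns `t1..tn`) and
#'   `profile_labels` (named integer vector, the ground truth).
#' @export
simulate_expression <- function(cfg, profiles, gene_ids = NULL,
                                seed_offset = 0L) {
  stop_if(!inherits(cfg, "sim_config"), "cfg must be a sim_config")
  stop_if(ncol(profiles) != cfg$n_stages,
          "profiles and cfg disagree on n_stages")
  plantable <- which(apply(profiles, 1L, function(s) any(s != 0)))
  stop_if(length(plantable) == 0L, "no non-flat profile to plant")

  if (is.null(gene_ids)) {
    n_genes <- cfg$genes_per_profile * length(plantable)
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
  }
  n_genes <- length(gene_ids)
  labels <- plantable[(seq_len(n_genes) - 1L) %% length(plantable) + 1L]

  with_seed(cfg$seed + 211L + seed_offset, {
    baseline <- 2^runif(n_genes, 1, 7)
    noise <- matrix(rnorm(n_genes * cfg$n_stages, 0, cfg$noise_sd),
                    n_genes, cfg$n_stages)
    expr <- baseline * 2^(unclass(profiles)[labels, , drop = FALSE] + noise)
    dimnames(expr) <- list(gene_ids, paste0("t", seq_len(cfg$n_stages)))
    list(expr = expr, profile_labels = setNames(labels, gene_ids))
  })
}

random_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mutate one planted site: mismatches replace a base with a non-pairing
# one; wobbles convert a C (pairing miRNA G) to U or an A (pairing miRNA
# U) to G on the target strand
mutate_site <- function(site_rna, mirna_rna, n_mm, n_wob, avoid = integer(0)) {
  s <- strsplit(site_rna, "")[[1]]
  L <- length(s)
  m <- strsplit(mirna_rna, "")[[1]]
  # target fragment position j pairs miRNA position L - j + 1
  usable <- setdiff(seq_len(L), avoid)
  wobble_ok <- usable[m[L - usable + 1L] %in% c("G", "U")]
  stop_if(length(wobble_ok) < n_wob,
          "not enough G/U miRNA positions outside the protected regions")
  wob <- if (n_wob > 0) sample(wobble_ok, n_wob) else integer(0)
  mm_ok <- setdiff(usable, wob)
  stop_if(length(mm_ok) < n_mm, "not enough mutable site positions")
  mm <- if (n_mm > 0) sample(mm_ok, n_mm) else integer(0)
  for (j in mm) {
    mi <- m[L - j + 1L]
    s[j] <- setdiff(c("A", "C", "G", "U"),
                    c(s[j], switch(mi, G = "U", U = "G", character(0))))[1]
  }
  for (j in wob) {
    mi <- m[L - j + 1L]
    s[j] <- if (mi == "G") "U" else "G"
  }
  paste(s, collapse = "")
}

#' Simulate miRNAs and transcripts with planted target sites
#'
#' Generates RNA miRNAs and DNA transcripts; each planted site is the
#' reverse complement of its miRNA inserted at a random position, with
#' `cfg$site_mutations` mismatches and `cfg$site_wobbles` G:U wobbles
#' introduced (at positions pairing miRNA positions outside 2-7 and 9-11,
#' so the seed penalty doubling and the inhibition call stay predictable).
#' Flanking sequence is random.
#'
#' @param cfg a [sim_config()].
#' @return list with `mirnas` (named RNA strings), `transcripts` (named DNA
#'   strings) and `truth$true_target_sites` (data.frame `mirna_id`,
#'   `transcript_id`, `start`, `end`, 1-based inclusive).
#' @export
simulate_mirna_targets <- function(cfg) {
  stop_if(!inherits(cfg, "sim_config"), "cfg must be a sim_config")
  with_seed(cfg$seed + 307L, {
    n <- cfg$n_planted_targets
    L <- 21L
    mirnas <- setNames(
      vapply(seq_len(n), function(i) random_seq(L, c("A", "C", "G", "U")), ""),
      sprintf("sim-miR%03d", seq_len(n)))
    transcripts <- character(n)
    sites <- vector("list", n)
    # fragment positions pairing miRNA 2-7 and 9-11 are kept intact
    avoid <- c(L - (2:7) + 1L, L - (9:11) + 1L)
    for (i in seq_len(n)) {
      tx <- random_seq(cfg$transcript_length, c("A", "C", "G", "T"))
      site_rna <- as.character(Biostrings::reverseComplement(
        Biostrings::RNAString(mirnas[i])))
      if (cfg$site_mutations + cfg$site_wobbles > 0) {
        site_rna <- mutate_site(site_rna, mirnas[i], cfg$site_mutations,
                                cfg$site_wobbles, avoid)
      }
      site_dna <- chartr("U", "T", site_rna)
      start <- sample.int(cfg$transcript_length - L + 1L, 1L)
      substr(tx, start, start + L - 1L) <- site_dna
      transcripts[i] <- tx
      sites[[i]] <- data.frame(mirna_id = names(mirnas)[i],
                               transcript_id = sprintf("tx%03d", i),
                               start = start, end = start + L - 1L,
                               stringsAsFactors = FALSE)
    }
    names(transcripts) <- sprintf("tx%03d", seq_len(n))
    list(mirnas = mirnas, transcripts = transcripts,
         truth = list(true_target_sites = do.call(rbind, sites)))
  })
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate a codon alignment under branch-wise selection regimes
#'
#' Evolves an ancestral in-frame coding sequence down a tree. On each
#' branch, mutation events are drawn at rate `branch length` per
#' nucleotide site; each event proposes a random single-base change, stops
#' are always rejected, synonymous changes are accepted with probability
#' min(1, 1/omega) and nonsynonymous ones with probability min(1, omega) —
#' so the realized Ka/Ks ratio of a branch approximates its planted omega.
#' No indels are introduced, so the leaf sequences are aligned as emitted.
#'
#' @param cfg a [sim_config()] (`n_codons` and `seed` are used).
#' @param tree an `ape::phylo` tree or newick string with branch lengths
#'   (>= 3 taxa for a general tree; a 2-taxon pair is accepted for
#'   pairwise-rate studies).
#' @param omega_by_branch either a single omega applied to every branch,
#'   or a named numeric vector keyed by the tip/node label of each edge's
#'   child node (missing entries default to 1).
#' @return named character vector of aligned leaf CDS (DNA), with the
#'   ancestral sequence in the `"root_seq"` attribute.
#' @export
simulate_codon_alignment <- function(cfg, tree, omega_by_branch = 1) {
  stop_if(!inherits(cfg, "sim_config"), "cfg must be a sim_config")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stop_if(!inherits(tree, "phylo"), "tree must be a phylo or newick text")
  stop_if(is.null(tree$edge.length), "tree must have branch lengths")
  stop_if(any(unlist(omega_by_branch) <= 0), "omega values must be > 0")

  tab <- ng86_tables()
  sense <- tab$codons[tab$aa != "*"]
  n_tip <- length(tree$tip.label)
  node_label <- function(v) {
    if (v <= n_tip) tree$tip.label[v]
    else if (!is.null(tree$node.label) && nzchar(tree$node.label[v - n_tip]))
      tree$node.label[v - n_tip] else as.character(v)
  }
  omega_of <- function(v) {
    if (length(omega_by_branch) == 1L && is.null(names(omega_by_branch)))
      return(as.numeric(omega_by_branch))
    w <- omega_by_branch[[node_label(v)]]
    if (is.null(w) || is.na(w)) 1 else as.numeric(w)
  }

  tree <- ape::reorder.phylo(tree, "cladewise")  # edges in preorder
  with_seed(cfg$seed + 401L, {
    root <- sample(sense, cfg$n_codons, replace = TRUE)
    seqs <- vector("list", max(tree$edge))
    root_node <- n_tip + 1L
    seqs[[root_node]] <- root
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      len <- tree$edge.length[e]
      omega <- omega_of(child)
      s <- seqs[[parent]]
      n_events <- rpois(1L, len * 3 * cfg$n_codons)
      for (k in seq_len(n_events)) {
        ci <- sample.int(cfg$n_codons, 1L)
        pos <- sample.int(3L, 1L)
        old <- strsplit(s[ci], "")[[1]]
        alt <- sample(setdiff(c("A", "C", "G", "T"), old[pos]), 1L)
        new <- old; new[pos] <- alt
        new_codon <- paste(new, collapse = "")
        if (new_codon %in% STOP_CODONS) next
        syn <- tab$aa[[s[ci]]] == tab$aa[[new_codon]]
        p_acc <- if (syn) min(1, 1 / omega) else min(1, omega)
        if (runif(1L) <= p_acc) s[ci] <- new_codon
      }
      seqs[[child]] <- s
    }
    out <- setNames(vapply(seq_len(n_tip),
                           function(v) paste(seqs[[v]], collapse = ""), ""),
                    tree$tip.label)
    attr(out, "root_seq") <- paste(root, collapse = "")
    out
  })
}

#' Write a complete synthetic study to disk
#'
#' Runs all generators under one configuration and writes the fixture
#' files every downstream stage reads: `og_table.tsv`,
#' `expr_<species>.tsv`, `mirna.fasta`, `transcripts.fasta`, `tree.nwk`,
#' `codon_aln.fasta` and `truth.json`. Identical configurations give
#' byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if missing).
#' @param tree newick text for the codon simulation; default a balanced
#'   four-taxon tree.
#' @param omega_by_branch passed to [simulate_codon_alignment()].
#' @return (invisibly) a list with the file paths and the combined ground
#'   truth.
#' @export
simulate_study <- function(cfg, dir,
                           tree = "((A:0.05,B:0.05):0.02,(C:0.05,D:0.05):0.02);",
                           omega_by_branch = 1) {
  stop_if(!inherits(cfg, "sim_config"), "cfg must be a sim_config")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  pair <- simulate_species_pair(cfg)
  profiles <- generate_model_profiles(cfg$n_stages, cfg$c, cfg$n_profiles)
  ex_a <- simulate_expression(cfg, profiles,
                              gene_ids = pair$gene_tables[[cfg$species_a]]$gene_id,
                              seed_offset = 0L)
  ex_b <- simulate_expression(cfg, profiles,
                              gene_ids = pair$gene_tables[[cfg$species_b]]$gene_id,
                              seed_offset = 1L)
  mir <- simulate_mirna_targets(cfg)
  aln <- simulate_codon_alignment(cfg, tree, omega_by_branch)

  paths <- list(
    og_table = file.path(dir, "og_table.tsv"),
    expr_a = file.path(dir, sprintf("expr_%s.tsv", cfg$species_a)),
    expr_b = file.path(dir, sprintf("expr_%s.tsv", cfg$species_b)),
    mirna = file.path(dir, "mirna.fasta"),
    transcripts = file.path(dir, "transcripts.fasta"),
    tree = file.path(dir, "tree.nwk"),
    codon_aln = file.path(dir, "codon_aln.fasta"),
    truth = file.path(dir, "truth.json"))

  write_tsv(pair$og_table, paths$og_table)
  write_expression_matrix(round(ex_a$expr, 6), paths$expr_a)
  write_expression_matrix(round(ex_b$expr, 6), paths$expr_b)
  write_fasta(mir$mirnas, paths$mirna)
  write_fasta(mir$transcripts, paths$transcripts)
  writeLines(if (is.character(tree)) tree else ape::write.tree(tree),
             paths$tree)
  write_fasta(aln, paths$codon_aln)

  truth <- list(
    divergent_og_ids = pair$truth$divergent_og_ids,
    gene_profile_labels = as.list(c(ex_a$profile_labels, ex_b$profile_labels)),
    true_target_sites = mir$truth$true_target_sites,
    branch_omega_labels = as.list(
      if (is.null(names(omega_by_branch)))
        setNames(rep(as.numeric(omega_by_branch), 1), "all")
      else omega_by_branch))
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paths$truth)
  invisible(list(paths = paths, truth = truth, profiles = profiles))
}
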