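test_that("expectation scoring reproduces every published duplex exactly", {
  pub <- published_duplexes()
  for (i in seq_len(nrow(pub))) {
    d <- score_duplex(pub$mirna_fragment[i], pub$target_fragment[i],
                      mirna_id = pub$mirna_acc[i],
                      target_id = pub$target_acc[i])
    expect_equal(d$expectation, pub$expectation[i],
                 label = sprintf("%s expectation", pub$mirna_acc[i]))
    expect_equal(d$inhibition, pub$inhibition[i],
                 label = sprintf("%s inhibition", pub$mirna_acc[i]))
  }
})

test_that("score components follow the penalty scheme position by position", {
  # miR169-family duplex: mismatches at 9, 10, 13, 20, all outside the seed
  d <- score_duplex("CAGCCAAGGAUGACUUGCCG", "AGGCAAGCCAAACUUGGCUG")
  expect_equal(which(d$pair_states == "mismatch"), c(9L, 10L, 13L, 20L))
  expect_equal(d$expectation, 4)
  # variant with a position-1 G:U wobble instead of the terminal mismatch
  d2 <- score_duplex("UAGCCAAGGAUGACUUGCCU", "AGGCAAGCCAAACUUGGCUG")
  expect_equal(d2$pair_states[1], "wobble")
  expect_equal(d2$expectation, 3.5)
  # gapped duplex: doubled seed wobble at position 2 plus an undoubled gap
  # at position 7
  d3 <- score_duplex("CGAGCCGAAUCAAUAUCACU", "AGUGAUAUUGAUU-GGCUUG")
  expect_equal(d3$pair_states[2], "wobble")
  expect_equal(d3$pair_states[7], "gap")
  expect_equal(d3$position_penalties[2], 1)   # 0.5 doubled in the seed
  expect_equal(d3$position_penalties[7], 2)   # gaps are not doubled
  expect_equal(d3$expectation, 3)

  # expectation is the sum of the per-position penalties
  expect_equal(d$expectation, sum(d$position_penalties))
  expect_equal(d3$expectation, sum(d3$position_penalties))
})

test_that("a perfect reverse complement is the unique zero score", {
  set.seed(14)
  for (rep in 1:5) {
    mir <- random_rna(21)
    site <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(mir)))
    expect_equal(score_duplex(mir, site)$expectation, 0)
    expect_equal(score_duplex(mir, site)$inhibition, "Cleavage")
    # any single substitution raises the score
    pos <- sample(21, 1)
    ch <- substr(site, pos, pos)
    mut <- site
    substr(mut, pos, pos) <- setdiff(c("A", "C", "G", "U"), ch)[1]
    expect_gt(score_duplex(mir, mut)$expectation, 0)
  }
})

test_that("DNA targets score identically to their RNA transcription", {
  mir <- "CAGCCAAGGAUGACUUGCCG"
  rna <- "AGGCAAGCCAAACUUGGCUG"
  dna <- chartr("U", "T", rna)
  expect_equal(score_duplex(mir, dna)$expectation,
               score_duplex(mir, rna)$expectation)
  expect_error(score_duplex(mir, "AGGCAAGCCAAACUXGGCUG"), "non-nucleotide")
})

test_that("central mispairing at positions 9-11 switches the inhibition call", {
  mir <- random_rna(21)
  site <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(mir)))
  base <- score_duplex(mir, site)
  expect_equal(base$inhibition, "Cleavage")
  # break pairing at miRNA position 10 (target fragment position 21 - 10 + 1)
  j <- 21 - 10 + 1
  mut <- site
  ch <- substr(site, j, j)
  mi10 <- substr(mir, 10, 10)
  bad <- setdiff(c("A", "C", "G", "U"),
                 c(ch, switch(mi10, G = "U", U = "G", character(0))))[1]
  substr(mut, j, j) <- bad
  d <- score_duplex(mir, mut)
  expect_equal(d$pair_states[10], "mismatch")
  expect_equal(d$inhibition, "Translation")
})

test_that("transcript scanning equals the brute-force window enumeration", {
  set.seed(15)
  for (rep in 1:3) {
    mir <- random_rna(sample(19:22, 1))
    tx <- random_dna(300)
    fast <- scan_transcript(mir, tx, max_expectation = 13)
    slow <- oracle_scan(mir, tx, 13)
    expect_equal(length(fast), length(slow))
    for (i in seq_along(fast)) {
      expect_equal(fast[[i]]$expectation, slow[[i]]$expectation)
      expect_equal(fast[[i]]$target_start, slow[[i]]$target_start)
      expect_equal(fast[[i]]$target_fragment, slow[[i]]$target_fragment)
    }
  }
})

test_that("planted sites are recovered at their exact coordinates", {
  cfg <- sim_config(seed = 3, n_planted_targets = 4)
  mt <- simulate_mirna_targets(cfg)
  truth <- mt$truth$true_target_sites
  for (i in seq_len(nrow(truth))) {
    hits <- scan_transcript(mt$mirnas[[truth$mirna_id[i]]],
                            mt$transcripts[[truth$transcript_id[i]]],
                            max_expectation = 3)
    expect_gte(length(hits), 1)
    expect_equal(hits[[1]]$expectation, 0)
    expect_equal(hits[[1]]$target_start, truth$start[i])
    expect_equal(hits[[1]]$target_end, truth$end[i])
  }

  # one planted wobble outside seed and centre -> best score exactly 0.5
  cfgw <- sim_config(seed = 3, n_planted_targets = 2, site_wobbles = 1)
  mtw <- simulate_mirna_targets(cfgw)
  hits <- scan_transcript(mtw$mirnas[[1]], mtw$transcripts[[1]],
                          max_expectation = 3)
  expect_equal(hits[[1]]$expectation, 0.5)

  # cutoff below the best score -> no hits
  none <- scan_transcript(mtw$mirnas[[1]], mtw$transcripts[[1]],
                          max_expectation = 0.4)
  expect_equal(length(none), 0)
})

test_that("regulator join keeps only candidate targets, de-duplicated", {
  tf <- data.frame(tf_id = c("TF1", "TF1", "TF2", "TF3"),
                   target_id = c("g1", "g1", "g1", "g9"),
                   stringsAsFactors = FALSE)
  hits <- data.frame(mirna_acc = c("miR1", "miR2"),
                     target_acc = c("g1", "g7"),
                     expectation = c(2, 1), inhibition = c("Cleavage", "Cleavage"),
                     stringsAsFactors = FALSE)
  out <- join_regulators(c("g1", "g2"), tf, hits)
  expect_equal(nrow(out), 3)  # TF1-g1 (deduped), TF2-g1, miR1-g1
  expect_setequal(out$regulator_id, c("TF1", "TF2", "miR1"))
  expect_true(all(out$target_gene == "g1"))

  expect_equal(nrow(join_regulators(character(0), tf, hits)), 0)
  # brute-force join oracle on a random fixture
  set.seed(16)
  cand <- paste0("g", sample(1:20, 8))
  tf2 <- data.frame(tf_id = paste0("TF", sample(1:5, 30, TRUE)),
                    target_id = paste0("g", sample(1:20, 30, TRUE)),
                    stringsAsFactors = FALSE)
  out2 <- join_regulators(cand, tf2, NULL)
  brute <- unique(tf2[tf2$target_id %in% cand, ])
  expect_equal(nrow(out2), nrow(brute))
  expect_setequal(paste(out2$regulator_id, out2$target_gene),
                  paste(brute$tf_id, brute$target_id))
})
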