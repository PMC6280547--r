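test_that("p-distance handles gaps by pairwise deletion", {
  expect_equal(p_distance("AAAA", "AAAA"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_equal(p_distance("AA-A", "AATA"), 0)  # gap column dropped: 0/3
  expect_equal(p_distance("AC-A", "GCTA"), 1 / 3)
  expect_error(p_distance("--", "AA"), "no comparable sites")
  expect_error(p_distance("AAA", "AA"), "length")
})

test_that("Poisson correction follows its closed form and dominates p", {
  expect_equal(poisson_distance(0), 0)
  expect_equal(poisson_distance(0.1), -log(0.9))
  expect_equal(poisson_distance(0.1), 0.10536, tolerance = 1e-4)
  p <- seq(0, 0.9, by = 0.1)
  d <- poisson_distance(p)
  expect_true(all(diff(d) > 0))           # monotone
  expect_true(all(d[-1] > p[-1]))         # d >= p, equality only at 0
  expect_error(poisson_distance(1), "\\[0, 1\\)")
})

test_that("three-taxon NJ solves the three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  tip_len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(tip_len[["A"]], (3 + 4 - 5) / 2)  # 1
  expect_equal(tip_len[["B"]], (3 + 5 - 4) / 2)  # 2
  expect_equal(tip_len[["C"]], (4 + 5 - 3) / 2)  # 3
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "square|3 taxa")
  dd <- d; dd[1, 2] <- 7
  expect_error(neighbor_joining(dd), "symmetric")
})

test_that("NJ reconstructs additive matrices exactly for 4 to 8 taxa", {
  set.seed(17)
  for (k in 4:8) {
    tr0 <- ape::rtree(k)
    d0 <- cophenetic(tr0)
    tr <- neighbor_joining(d0)
    d1 <- cophenetic(tr)[rownames(d0), colnames(d0)]
    expect_lt(max(abs(d1 - d0)), 1e-8)
  }
})

test_that("an ultrametric balanced quartet yields the correct sister pairs", {
  # ((A,B),(C,D)) with within-pair distance 2, across 6
  d <- matrix(6, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  tr <- neighbor_joining(d)
  parts <- ape::prop.part(tr)
  tips <- attr(parts, "labels")
  clades <- lapply(parts, function(i) sort(tips[i]))
  expect_true(list(c("A", "B")) %in% clades || list(c("C", "D")) %in% clades)
})

test_that("bootstrap supports are deterministic and saturate on clean splits", {
  cfg <- sim_config(seed = 2, n_codons = 400)
  tree <- "(((A:0.03,B:0.03):0.08,(C:0.03,D:0.03):0.08):0.2,((E:0.03,F:0.03):0.08,(G:0.03,H:0.03):0.08):0.2);"
  aln <- simulate_codon_alignment(cfg, tree, 1)
  tr1 <- bootstrap_support(aln, n_reps = 30, seed = 5)
  tr2 <- bootstrap_support(aln, n_reps = 30, seed = 5)
  expect_identical(tr1$node.label, tr2$node.label)
  # the root "bipartition" is not a real split; ape reports it as NA
  supports <- tr1$node.label[-1]
  expect_true(all(supports >= 0 & supports <= 100))
  # deep, clean splits on a long alignment: high support everywhere
  expect_true(all(tr1$node.label[-1] >= 95))

  # single replicate: supports can only be 0 or 100
  tr3 <- bootstrap_support(aln, n_reps = 1, seed = 9)
  expect_true(all(tr3$node.label[-1] %in% c(0L, 100L)))

  # invariance to taxon order
  perm <- sample(names(aln))
  tr4 <- bootstrap_support(aln[perm], n_reps = 30, seed = 5)
  expect_setequal(tr4$node.label[-1], tr1$node.label[-1])
})

test_that("NG86 counting matches a reference implementation and code degeneracy", {
  ident <- paste(rep("ATGGCTAGC", 10), collapse = "")
  e0 <- ng86_ka_ks(ident, ident)
  expect_equal(e0$ka, 0)
  expect_equal(e0$ks, 0)
  expect_false(e0$omega_defined)

  # one synonymous third-position change in 300 codons: ka = 0, ks > 0
  a <- paste(rep("GGT", 300), collapse = "")
  b <- paste0("GGC", paste(rep("GGT", 299), collapse = ""))
  e1 <- ng86_ka_ks(a, b)
  expect_equal(e1$ka, 0)
  expect_gt(e1$ks, 0)

  # frozen reference values computed independently with an established
  # NG86 implementation for this exact 36-codon pair
  base <- paste(rep("ATGGCTAGCAAAGGGTTTCCCGATGAACTTATTGCA", 3), collapse = "")
  alt <- paste0("ATGGCCAGCAGAGGATTTCCAGACGAGCTGACTGCA",
                substr(base, 37, nchar(base)))
  e2 <- ng86_ka_ks(base, alt)
  expect_equal(e2$ka, 0.0237643643, tolerance = 1e-9)
  expect_equal(e2$ks, 0.3295249948, tolerance = 1e-9)
  expect_equal(e2$omega, 0.0721170311, tolerance = 1e-8)

  expect_error(ng86_ka_ks("ATGTAAGGT", "ATGTAAGGT"), "stop")
  expect_error(ng86_ka_ks("ATGA", "ATGA"), "multiple of 3")
})

test_that("simulated selection regimes order the estimated omega correctly", {
  cfg <- sim_config(seed = 1, n_codons = 800)
  neutral <- simulate_codon_alignment(cfg, "(A:0.05,B:0.05);", 1)
  purified <- simulate_codon_alignment(cfg, "(A:0.05,B:0.05);", 0.1)
  w1 <- ng86_ka_ks(neutral[["A"]], neutral[["B"]])$omega
  w2 <- ng86_ka_ks(purified[["A"]], purified[["B"]])$omega
  expect_gt(w1, w2)
  expect_lt(w2, 0.5)

  # zero branch lengths: no substitutions at all
  frozen <- simulate_codon_alignment(cfg, "(A:0,B:0);", 1)
  expect_identical(frozen[["A"]], frozen[["B"]])
})

test_that("branch-model LRT reproduces the published PEPC comparison", {
  res <- branch_lrt(-2343.655, -2361.163, df = 6)
  expect_equal(res$statistic, 35.016, tolerance = 1e-12)
  expect_equal(res$p_value, 4.278e-06, tolerance = 0.01)
  expect_true(res$label_swap_suspected)

  expect_equal(branch_lrt(-100, -100, 3)$statistic, 0)
  expect_equal(branch_lrt(-100, -100, 3)$p_value, 1)
  # df = 2 closed form: p = exp(-stat / 2)
  r2 <- branch_lrt(-50, -47.3, 2)
  expect_equal(r2$p_value, exp(-r2$statistic / 2), tolerance = 1e-12)
  expect_error(branch_lrt(-1, -2, 0), "df")
})

test_that("chi-square tail at df = 6 matches the series closed form", {
  # 1 - F(x; 6) = exp(-x/2) * (1 + x/2 + (x/2)^2 / 2)
  for (x in c(1, 5, 12.59, 35.016, 60)) {
    series <- exp(-x / 2) * (1 + x / 2 + (x / 2)^2 / 2)
    expect_equal(pchisq(x, 6, lower.tail = FALSE), series, tolerance = 1e-9)
  }
})
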