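test_that("log-ratio transform matches its closed form and is scale invariant", {
  expect_equal(log_normalize(c(2, 4, 8, 16)), c(0, 1, 2, 3))
  expect_equal(log_normalize(c(5, 5, 5, 5)), c(0, 0, 0, 0))
  set.seed(1)
  v <- runif(5, 0.5, 20)
  for (k in c(0.1, 3, 100)) {
    expect_equal(log_normalize(k * v), log_normalize(v))
  }
  expect_error(log_normalize(c(0, 1, 2)), "positive")

  m <- rbind(a = c(2, 4, 8, 16), b = c(0, 1, 1, 1), c = c(1, 2, 4, 8))
  tv <- log_normalize_matrix(m)
  expect_equal(rownames(tv), c("a", "c"))
  expect_equal(attr(tv, "excluded"), "b")
  expect_equal(unname(tv["a", ]), c(0, 1, 2, 3))
})

test_that("relative expression content has unit per-stage mean and matches the ratio oracle", {
  set.seed(2)
  m <- matrix(runif(20, 0.1, 50), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("t", 1:4)))
  rel <- relative_expression(m)
  expect_equal(unname(colMeans(rel)), rep(1, 4), tolerance = 1e-9)
  for (g in 1:5) for (s in 1:4) {
    expect_equal(rel[g, s], m[g, s] / mean(m[, s]))
  }
  # gene at the stage mean -> exactly 1
  m2 <- matrix(c(5, 5, 10, 20), 2, 2)
  expect_equal(relative_expression(m2)[1, 2], 10 / 15)
  expect_error(relative_expression(cbind(c(0, 0), c(1, 2))), "degenerate")
})

test_that("minimum-change filter keeps only series moving past the threshold", {
  expect_true(min_change_filter(c(0, 1, 2, 3), 2))
  expect_false(min_change_filter(c(0, 0.5, 1, 1.5), 2))
  expect_true(min_change_filter(c(0, 0, 0), 0))
  m <- rbind(c(0, 1, 2, 3), c(0, -0.5, -1, -1.5), c(0, -2, 0, 0))
  expect_equal(min_change_filter(m, 2), c(TRUE, FALSE, TRUE))
})

test_that("model profile generation enumerates and selects deterministically", {
  p <- generate_model_profiles(n_stages = 4, c = 1, m = 20)
  expect_equal(attr(p, "n_candidates"), 27)  # 3^3 step combinations
  expect_equal(nrow(p), 20)
  expect_equal(unname(unclass(p)[, 1]), rep(0, 20))
  expect_equal(anyDuplicated(apply(p, 1, paste, collapse = ",")), 0L)
  expect_equal(unname(unclass(p)[1, ]), rep(0, 4))  # seeded with the flat shape
  # steps bounded by c
  expect_true(all(abs(diff(t(unclass(p)))) <= 1))

  # m = full enumeration returns every candidate
  full <- generate_model_profiles(n_stages = 3, c = 1, m = 9)
  expect_equal(nrow(full), 9)
  expect_equal(anyDuplicated(apply(full, 1, paste, collapse = ",")), 0L)

  expect_identical(unclass(generate_model_profiles(4, 1, 20)),
                   unclass(generate_model_profiles(4, 1, 20)))
  expect_error(generate_model_profiles(4, 1, m = 28), "m must be")
})

test_that("assignment maximizes Pearson correlation with deterministic ties", {
  p <- generate_model_profiles(4, 1, 20)
  shp <- unclass(p)

  # a gene exactly on a profile shape is assigned there with r = 1
  nonflat <- which(apply(shp != 0, 1, any))
  tv <- shp[nonflat, , drop = FALSE]
  rownames(tv) <- paste0("g", nonflat)
  a <- assign_genes(tv, p)
  expect_equal(a$profile, unname(nonflat))
  expect_equal(a$corr, rep(1, length(nonflat)), tolerance = 1e-12)

  # constant transformed vector -> unassigned
  tv2 <- rbind(flat = c(0, 0, 0, 0), up = c(0, 1, 2, 3))
  a2 <- assign_genes(tv2, p)
  expect_true(is.na(a2$profile[1]))
  expect_false(is.na(a2$profile[2]))

  # affine invariance: a*x + b with a > 0 gives identical assignments
  set.seed(4)
  tv3 <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(paste0("g", 1:50), NULL))
  a3 <- assign_genes(tv3, p)
  a4 <- assign_genes(tv3 * 2.5 + 7, p)
  expect_equal(a3$profile, a4$profile)

  # brute-force argmax oracle
  brute <- vapply(1:50, function(g) {
    rs <- vapply(seq_len(nrow(shp)), function(j) {
      if (sd(shp[j, ]) == 0) return(-Inf)
      oracle_pearson(tv3[g, ], shp[j, ])
    }, numeric(1))
    which.max(rs)
  }, integer(1))
  expect_equal(a3$profile, brute)

  expect_error(assign_genes(tv3, p[0, , drop = FALSE]), "empty")
})

test_that("permutation significance flags planted concentration and behaves at the null", {
  p <- generate_model_profiles(4, 1, 20)
  shp <- unclass(p)
  target <- which(apply(shp, 1, function(s) all(s == c(0, 1, 2, 3))))

  # 20 genes all shaped like one profile: observed far above the
  # 24-permutation expectation
  tv <- matrix(rep(c(0, 1, 2, 3), 20), 20, 4, byrow = TRUE)
  rownames(tv) <- paste0("g", 1:20)
  asg <- assign_genes(tv, p)
  sig <- profile_significance(asg, tv, p)
  expect_equal(sig$observed[target], 20)
  expect_lt(sig$p_value[target], 0.05)
  expect_true(sig$significant[target])
  expect_gt(sig$observed[target], sig$expected[target])

  # empty input: all p = 1
  tv0 <- matrix(numeric(0), 0, 4)
  sig0 <- profile_significance(assign_genes(tv0, p), tv0, p)
  expect_equal(sig0$p_value, rep(1, 20))
  expect_false(any(sig0$significant))

  # label-free random data: significant-profile rate stays near nominal
  set.seed(1)
  tvr <- matrix(rnorm(1000 * 4), 1000, 4,
                dimnames = list(paste0("g", 1:1000), NULL))
  asgr <- assign_genes(tvr, p)
  sigr <- profile_significance(asgr, tvr, p)
  expect_lte(sum(sigr$significant), 4)  # ~1 of 20 expected at alpha 0.05
})

test_that("trend classification reads the profile over the oil-accumulation window", {
  shp <- rbind(c(0, 1, 2, 3), c(0, 0, 0, 0), c(0, -1, -2, -2), c(0, 1, 1, 2))
  expect_equal(classify_trend(shp, c(2, 3)), c("up", "other", "down", "other"))
  expect_equal(classify_trend(shp, c(1, 4)), c("up", "other", "down", "up"))
  expect_error(classify_trend(shp, c(3, 2)), "window")
})

test_that("candidate combination equals brute-force set algebra", {
  set.seed(9)
  n_og <- 30
  tab <- do.call(rbind, lapply(seq_len(n_og), function(i) {
    data.frame(og_id = paste0("OG", i), species = sample(c("a", "b"), 1),
               gene_id = paste0("g", i, "_", 1:2), stringsAsFactors = FALSE)
  }))
  query <- paste0("OG", 1:20)
  divergent <- paste0("OG", sample(1:30, 8))
  genes <- unique(tab$gene_id)
  asg <- data.frame(gene = genes,
                    profile = sample(c(NA, 1:6), length(genes), TRUE),
                    corr = 0.9, stringsAsFactors = FALSE)
  sig <- data.frame(profile = 1:6,
                    significant = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  trends <- c("up", "down", "up", "other", "down", "other")

  got_u <- candidate_genes(tab, query, divergent, asg, sig, trends, "union")
  got_i <- candidate_genes(tab, query, divergent, asg, sig, trends, "intersect")

  good_prof <- c(1, 2)  # significant AND up/down
  brute_cnv <- tab$gene_id[tab$og_id %in% intersect(query, divergent)]
  brute_trend <- intersect(asg$gene[!is.na(asg$profile) & asg$profile %in% good_prof],
                           tab$gene_id[tab$og_id %in% query])
  expect_equal(got_u, sort(unique(union(brute_cnv, brute_trend))))
  expect_equal(got_i, sort(unique(intersect(brute_cnv, brute_trend))))

  expect_equal(candidate_genes(tab, character(0), character(0), asg,
                               sig[0, ], character(0)), character(0))
})
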