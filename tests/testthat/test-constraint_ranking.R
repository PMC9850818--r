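test_that("Mann-Whitney p-values match hand enumeration on small cases", {
  expect_equal(mwu_compare(c(-0.1, 0, 0.1), c(1.0, 1.1)), 0.2)
  expect_equal(mwu_compare(c(1, 1, 1), c(1, 1)), 1.0)
  expect_equal(mwu_compare(c(0.8, 0.9, 1.0, 1.1, 1.2), c(1.05, 1.15)),
               4 / 7)
  expect_error(mwu_compare(numeric(), c(1)), "non-empty")
})

test_that("exact mode equals brute-force enumeration of assignments", {
  set.seed(31)
  for (trial in 1:60) {
    n1 <- sample(2:8, 1)
    n2 <- sample(1:4, 1)
    repeat {
      x <- round(rnorm(n1), 4)
      y <- round(rnorm(n2), 4)
      if (!anyDuplicated(c(x, y))) break
    }
    expect_equal(mwu_compare(x, y), brute_mwu(x, y), tolerance = 1e-12)
  }
})

test_that("the rank test is invariant under common monotone transforms", {
  set.seed(32)
  for (trial in 1:20) {
    x <- rlnorm(sample(5:60, 1))
    y <- rlnorm(sample(3:10, 1))
    expect_equal(mwu_compare(x, y), mwu_compare(log2(x), log2(y)))
    expect_equal(mwu_compare(x, y), mwu_compare(x^3, y^3))
  }
})

test_that("approximate mode agrees with the corrected normal reference", {
  # large tie-free samples: compare against wilcox.test's corrected
  # normal approximation as an independent reference
  set.seed(33)
  x <- rnorm(60)
  y <- rnorm(40, 0.3)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(mwu_compare(x, y), ref, tolerance = 1e-10)
  # with ties, the tie-corrected variance is used
  xt <- rep(1:5, each = 6)
  yt <- rep(3:7, each = 4)
  reft <- suppressWarnings(wilcox.test(xt, yt, exact = FALSE,
                                       correct = TRUE)$p.value)
  expect_equal(mwu_compare(xt, yt), reft, tolerance = 1e-10)
})

test_that("rank_by_mwu sorts ascending with lexicographic tie-break", {
  prof <- build_population_profiles(
    make_table(matrix(c(100L, 50L, 30L), 3, 60) + 0L,
               matrix(100L, 3, 60),
               genes = c("gb", "ga", "gc")),
    min_samples = 10)
  # hybrid shifted far for gc, none for others
  rec <- build_interspecies_records(
    make_table(rbind(c(100, 100), c(50, 50), c(240, 240)),
               rbind(c(100, 100), c(50, 50), c(30, 30)),
               genes = c("gb", "ga", "gc")))
  rl <- rank_by_mwu(prof, rec)
  expect_identical(rl$rank, 1:3)
  expect_equal(rl$gene_id[1], "gc")
  # ga and gb have identical inputs hence identical p: lexicographic
  expect_identical(rl$gene_id[2:3], c("ga", "gb"))
})

test_that("signed scores combine significance and direction", {
  expect_equal(signed_score(0.01, 2.3), 2)
  expect_equal(signed_score(0.01, -2.3), -2)
  expect_equal(signed_score(1.0, 5), 0)
  # antisymmetry in the sign of the fold change
  set.seed(34)
  p <- runif(50, 1e-8, 1)
  fc <- rnorm(50)
  expect_equal(signed_score(p, fc), -signed_score(p, -fc))
  expect_error(signed_score(0, 1), "\\(0, 1\\]")
})

test_that("difference-in-ranks puts constraint-revealed genes on top", {
  mwu <- make_ranked(paste0("g", 1:3), c(0.001, 0.01, 0.1))
  de_rev <- structure(data.frame(gene_id = paste0("g", 3:1),
                                 score = c(0.01, 0.05, 0.9),
                                 mwu_p = NA_real_, rank = 1:3,
                                 stringsAsFactors = FALSE),
                      class = c("ranked_gene_list", "data.frame"),
                      ranking_kind = "de_fdr")
  d <- diff_in_ranks(mwu, de_rev)
  # reversal of a 3-gene list: scores +2, 0, -2
  expect_equal(d$score, c(2, 0, -2))
  expect_identical(d$gene_id, c("g1", "g2", "g3"))
  # identical rankings give all-zero scores
  de_same <- structure(data.frame(gene_id = paste0("g", 1:3),
                                  score = 1:3, mwu_p = NA_real_,
                                  rank = 1:3, stringsAsFactors = FALSE),
                       class = c("ranked_gene_list", "data.frame"),
                       ranking_kind = "de_fdr")
  expect_true(all(diff_in_ranks(mwu, de_same)$score == 0))
  # universe mismatch is an error naming the difference
  de_bad <- structure(data.frame(gene_id = c("g1", "g2", "gX"),
                                 score = 1:3, mwu_p = NA_real_,
                                 rank = 1:3, stringsAsFactors = FALSE),
                      class = c("ranked_gene_list", "data.frame"),
                      ranking_kind = "de_fdr")
  expect_error(diff_in_ranks(mwu, de_bad), "gX")
})

test_that("a large positive rank difference rises to the top", {
  n <- 600
  genes <- sprintf("g%03d", 1:n)
  mwu <- make_ranked(genes, seq(0.001, 1, length.out = n))
  de_ranked <- c(genes[500], genes[-c(10, 500)], genes[10])
  de <- structure(data.frame(gene_id = de_ranked, score = seq_len(n),
                             mwu_p = NA_real_, rank = seq_len(n),
                             stringsAsFactors = FALSE),
                  class = c("ranked_gene_list", "data.frame"),
                  ranking_kind = "de_fdr")
  d <- diff_in_ranks(mwu, de)
  i <- match(genes[10], d$gene_id)
  expect_equal(d$score[i], 600 - 10)  # mwu rank 10, de rank 600
  expect_lte(i, 2L)
})
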