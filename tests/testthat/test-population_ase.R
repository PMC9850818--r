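test_that("ASE ratio applies the pseudocount per allele", {
  expect_equal(compute_ase_ratio(9, 19), 0.5)
  expect_equal(compute_ase_ratio(0, 0), 1.0)
  expect_equal(compute_ase_ratio(99, 49), 2.0)
  expect_error(compute_ase_ratio(-1, 5), "non-negative")
  expect_error(compute_ase_ratio(1, 5, pseudocount = 0), "positive")
})

test_that("coverage filter is per gene and keeps the >= boundary", {
  tab <- make_table(rbind(c(10, 10, 5), c(3, 100, 40)),
                    rbind(c(10, 9, 100), c(50, 100, 40)))
  m10 <- filter_low_coverage(tab, 10)
  expect_identical(unname(m10[1, ]), c(TRUE, FALSE, FALSE))
  expect_identical(unname(m10[2, ]), c(FALSE, TRUE, TRUE))
  # (5, 100) removed at 10 but retained at 5
  m5 <- filter_low_coverage(tab, 5)
  expect_true(m5[1, 3])
  # min_reads 0 keeps everything
  expect_true(all(filter_low_coverage(tab, 0)))
  # NA cells never pass
  tab$counts1[1, 1] <- NA
  expect_false(filter_low_coverage(tab, 0)[1, 1])
})

test_that("median normalization fixes the median at 1", {
  expect_equal(normalize_median(c(2, 4, 8)), c(0.5, 1, 2))
  expect_equal(normalize_median(c(1, 3)), c(0.5, 1.5))
  expect_equal(normalize_median(c(1, 1, 1)), c(1, 1, 1))
  expect_error(normalize_median(numeric()), "empty")
  expect_error(normalize_median(c(1, -2)), "positive")

  # property: median is 1 after normalization (odd exactly, even to 1e-12)
  set.seed(21)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    r <- normalize_median(rlnorm(n))
    tol <- if (n %% 2 == 1) 0 else 1e-12
    expect_equal(median(r), 1, tolerance = tol)
  }
})

test_that("population profiles apply filters in order and compute variance", {
  # 60 samples, one gene loses 11 -> 49 retained -> excluded at min 50
  set.seed(3)
  c1 <- matrix(50L, 2, 60)
  c2 <- matrix(50L, 2, 60)
  c1[1, 1:11] <- 2L
  tab <- make_table(c1, c2)
  prof <- build_population_profiles(tab, min_reads = 10, min_samples = 50)
  expect_identical(prof$gene_id, "g2")
  # all retained ratios equal -> zero variance
  expect_equal(unname(prof$ase_variance["g2"]), 0)
  expect_equal(unname(prof$n_samples["g2"]), 60L)
  # the retained median is 1 (normalization happens after filtering)
  expect_equal(median(prof$ratios[["g2"]]), 1)

  expect_warning(build_population_profiles(tab, min_samples = 1000),
                 "no genes")
})

test_that("profile variance is invariant to sample relabeling", {
  set.seed(4)
  cfg <- simulation_config(n_genes = 20, n_samples = 80, alpha = 10,
                           seed = 4)
  tab <- generate_population(cfg)
  prof <- build_population_profiles(tab, min_samples = 20)
  perm <- sample(ncol(tab$counts1))
  prof2 <- build_population_profiles(tab[, perm], min_samples = 20)
  expect_equal(prof$ase_variance, prof2$ase_variance)
})

test_that("measured ASE variance matches a Monte-Carlo oracle", {
  # one beta-binomial gene at 500 samples vs an independent simulation
  # of the same ratio distribution at 10x the sample size
  alpha <- 20
  depth <- 300
  cfg <- simulation_config(n_genes = 1, n_samples = 500, depth_mean = depth,
                           depth_sdlog = 0, alpha = alpha, seed = 99)
  prof <- build_population_profiles(generate_population(cfg),
                                    min_samples = 50)
  set.seed(123)
  n_mc <- 5000
  f <- rbeta(n_mc, alpha, alpha)
  tot <- rpois(n_mc, depth)
  a1 <- rbinom(n_mc, tot, f)
  keep <- pmin(a1, tot - a1) >= 10
  r <- (a1[keep] + 1) / (tot[keep] - a1[keep] + 1)
  oracle_var <- var(r / median(r))
  expect_lt(abs(prof$ase_variance[[1]] - oracle_var) / oracle_var, 0.15)
})

test_that("lower generator dispersion gives stochastically lower variance", {
  set.seed(5)
  n <- 250
  alpha <- exp(runif(n, log(2), log(500)))
  cfg <- simulation_config(n_genes = n, n_samples = 120, depth_mean = 200,
                           depth_sdlog = 0.2, alpha = alpha, seed = 5)
  prof <- build_population_profiles(generate_population(cfg),
                                    min_samples = 50)
  a <- alpha[match(prof$gene_id, cfg$gene_id)]
  ct <- suppressWarnings(cor.test(prof$ase_variance, a,
                                  method = "spearman"))
  expect_true(length(prof) >= 200)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("allele flip rebuilds reciprocal renormalized profiles", {
  prof <- build_population_profiles(
    make_table(rbind(c(49L, 99L, 199L)), rbind(c(99L, 99L, 99L))),
    min_reads = 10, min_samples = 3)
  flipped <- flip_allele_orientation(prof)
  r <- prof$ratios[[1]]
  expect_equal(r, c(0.5, 1, 2))
  expect_equal(flipped$ratios[[1]], normalize_median(1 / r))
  # this ratio set is closed under reciprocals, so flipping permutes it
  expect_equal(sort(flipped$ratios[[1]]), sort(r))
  # flipping equals swapping the count matrices and rebuilding
  swapped <- build_population_profiles(
    make_table(rbind(c(99L, 99L, 99L)), rbind(c(49L, 99L, 199L))),
    min_reads = 10, min_samples = 3)
  expect_equal(flipped$ratios, swapped$ratios)
  expect_equal(flipped$ase_variance, swapped$ase_variance)
})
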