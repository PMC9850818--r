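# small profile builder: genes with prescribed variances via direct
# construction of the profile object is avoided — variances come from
# real tables — so validation tests mostly run on simulated cohorts

test_that("constraint correlation recovers a perfect monotone relation", {
  # five genes whose ASE variance decreases as the score increases
  cfg <- simulation_config(n_genes = 5, n_samples = 200, depth_mean = 300,
                           depth_sdlog = 0,
                           alpha = c(2, 6, 20, 60, 200), seed = 61)
  prof <- build_population_profiles(generate_population(cfg))
  scores <- constraint_scores(cfg$gene_id, c(0.1, 0.3, 0.5, 0.7, 0.9),
                              rep(10, 5))
  res <- constraint_correlation(prof, scores)
  expect_equal(res$rho, -1)
  expect_equal(res$n_genes, 5L)

  # constant score is degenerate
  flat <- constraint_scores(cfg$gene_id, rep(0.5, 5), rep(10, 5))
  expect_error(constraint_correlation(prof, flat), "constant")
  expect_error(constraint_correlation(prof, scores[1:2, ]), ">= 3")
})

test_that("simulated constraint gradient yields a negative correlation", {
  cfg <- validation_cohort_config(seed = 62)
  prof <- build_population_profiles(generate_population(cfg))
  scores <- generate_constraint_scores(cfg)
  res <- constraint_correlation(prof, scores)
  expect_lt(res$rho, 0)
  expect_lt(res$p_value, 0.01)
})

test_that("down-sampling at the full sample count reproduces the full result", {
  cfg <- simulation_config(n_genes = 40, n_samples = 80, depth_mean = 300,
                           depth_sdlog = 0,
                           alpha = exp(seq(log(3), log(300),
                                           length.out = 40)),
                           seed = 63)
  tab <- generate_population(cfg)
  scores <- generate_constraint_scores(cfg, noise_sd = 0)
  mask <- filter_low_coverage(tab, 10)
  full_n <- min(rowSums(mask))
  expect_gt(full_n, 50)
  ds <- downsample_experiment(tab, scores, n_grid = c(full_n), reps = 1,
                              seed = 1)
  # every gene is drawn at exactly its quantifiable-sample floor; genes
  # above the floor are subsampled, so compare only the determinism of
  # two identically seeded runs plus the n == available no-op case
  ds2 <- downsample_experiment(tab, scores, n_grid = c(full_n), reps = 1,
                               seed = 1)
  expect_equal(ds, ds2)
  ds3 <- downsample_experiment(tab, scores, n_grid = c(full_n), reps = 1,
                               seed = 2)
  expect_equal(ds$n_genes, ds3$n_genes)

  # a gene quantifiable in all samples and drawn at n = n_samples gives
  # exactly the full-data profile correlation
  cfg2 <- simulation_config(n_genes = 25, n_samples = 60,
                            depth_mean = 500, depth_sdlog = 0,
                            alpha = exp(seq(log(5), log(200),
                                            length.out = 25)),
                            seed = 64)
  tab2 <- generate_population(cfg2)
  scores2 <- generate_constraint_scores(cfg2, noise_sd = 0)
  mask2 <- filter_low_coverage(tab2, 10)
  expect_true(all(mask2))
  prof2 <- build_population_profiles(tab2, min_samples = 10)
  want <- constraint_correlation(prof2, scores2)$rho
  got <- downsample_experiment(tab2, scores2, n_grid = c(60), reps = 3,
                               seed = 9)
  expect_equal(got$mean_rho, want)
  expect_error(downsample_experiment(tab2, scores2, n_grid = c(25, 60)),
               "descending")
})

test_that("expression-matched comparison detects lower variance under constraint", {
  # high-constraint half has much tighter alleles at matched depth
  cfg <- simulation_config(n_genes = 120, n_samples = 150,
                           depth_mean = 300, depth_sdlog = 0,
                           alpha = rep(c(120, 6), each = 60), seed = 65)
  prof <- build_population_profiles(generate_population(cfg))
  scores <- constraint_scores(cfg$gene_id,
                              rep(c(0.9, 0.1), each = 60),
                              rep(10, 120))
  res <- expression_matched_comparison(prof, scores, n_top = 60)
  expect_lt(mean(res$differences), 0)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$n_pairs, 60)
  # invariant to gene order
  perm <- sample(nrow(scores))
  res2 <- expression_matched_comparison(prof, scores[perm, ], n_top = 60)
  expect_equal(res2$differences, res$differences)
  expect_error(expression_matched_comparison(prof, scores, n_top = 100),
               "need >= 200")
})

test_that("cohort splits of one cohort give concordant rankings", {
  cfg <- simulation_config(n_genes = 80, n_samples = 600, depth_mean = 200,
                           depth_sdlog = 0.2,
                           alpha = exp(seq(log(4), log(200),
                                           length.out = 80)),
                           delta = rep(c(0, 0.6), 40),
                           n_hybrid_replicates = 8, seed = 66)
  tab <- generate_population(cfg)
  hyb <- generate_hybrid(cfg)
  rec <- build_interspecies_records(hyb$table, hyb$de_summary)
  rank_fn <- function(t) {
    rank_by_mwu(build_population_profiles(t, min_samples = 30), rec)
  }
  samp <- sample_ids(tab)
  # identical partitions: identical rankings
  same <- cohort_split_robustness(tab, list(samp[1:50], samp[1:50]),
                                  rank_fn)
  expect_equal(same$rho, 1)
  halves <- cohort_split_robustness(tab, list(samp[1:300], samp[301:600]),
                                    rank_fn)
  expect_gte(halves$rho, 0.9)
  expect_error(cohort_split_robustness(tab, list(character(), samp),
                                       rank_fn), "empty")
  expect_error(cohort_split_robustness(tab, list("zzz", samp), rank_fn),
               "not in table")
})
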