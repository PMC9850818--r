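test_that("direction counts follow the sign of the mean fold change", {
  rec <- make_records(paste0("g", 1:4), c(1, 0.2, -0.5, 0))
  expect_equal(unname(count_directions(paste0("g", 1:3), rec)), c(2L, 1L))
  # zero fold changes are excluded from both counts
  expect_equal(unname(count_directions(c("g4", "g1"), rec)), c(1L, 0L))
  # six genes all one way
  rec6 <- make_records(paste0("h", 1:6), rep(0.8, 6))
  expect_equal(unname(count_directions(paste0("h", 1:6), rec6)), c(6L, 0L))
  expect_error(count_directions("nope", rec), "nope")
})

test_that("binomial sign test matches closed forms and the pmf oracle", {
  expect_equal(binomial_sign_test(6, 6), 0.03125)
  expect_equal(binomial_sign_test(8, 11), 232 / 1024)
  expect_equal(binomial_sign_test(5, 10), 1.0)
  for (n in 1:20) {
    for (k in 0:n) {
      expect_equal(binomial_sign_test(k, n), brute_binom(k, n),
                   tolerance = 1e-12)
      # symmetry
      expect_equal(binomial_sign_test(k, n), binomial_sign_test(n - k, n))
    }
  }
  expect_error(binomial_sign_test(5, 4), "k <= n")
  expect_error(binomial_sign_test(-1, 4), "k <= n")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  set.seed(51)
  for (trial in 1:20) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p))
    expect_true(all(q >= p & q <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_enrichment <- function(set_name, fdr_q, leading_edge) {
  out <- data.frame(set_name = set_name, es = 0.5, nes = 1.5,
                    nominal_p = 0.01, fdr_q = fdr_q,
                    peak_rank = lengths(leading_edge),
                    set_size_used = lengths(leading_edge),
                    stringsAsFactors = FALSE)
  out$leading_edge <- leading_edge
  structure(out, class = c("enrichment_results", "data.frame"))
}

test_that("sign test applies eligibility, dedupe, and BH rules", {
  genes <- paste0("g", 1:20)
  rec <- make_records(genes, c(rep(1, 14), rep(-1, 6)))
  enr1 <- make_enrichment(
    c("allpos", "edge5", "weak"),
    c(0.10, 0.05, 0.50),
    list(genes[1:8], genes[1:5], genes[1:10]))
  enr2 <- make_enrichment(
    c("allpos", "mixed"),
    c(0.20, 0.01),
    list(genes[1:8], genes[9:20]))
  res <- run_sign_test(list(day50 = enr1, day100 = enr2), rec)
  # 'edge5' has exactly 5 driving genes: excluded (needs > 5)
  expect_false("edge5" %in% res$set_name)
  # 'weak' fails the 0.25 eligibility FDR
  expect_false("weak" %in% res$set_name)
  # 'allpos' appears at both time points: tested once, at the lower FDR
  expect_equal(sum(res$set_name == "allpos"), 1L)
  expect_identical(res$timepoint[res$set_name == "allpos"], "day50")
  a <- res[res$set_name == "allpos", ]
  expect_equal(a$k_species1, 8L)
  expect_equal(a$n_total, 8L)
  expect_identical(a$direction, "species1-biased")
  expect_equal(a$binom_p, binomial_sign_test(8, 8))
  m <- res[res$set_name == "mixed", ]
  expect_equal(m$k_species1, 6L)
  expect_equal(m$n_total, 12L)
  expect_identical(m$direction, "balanced")
  expect_equal(res$bh_q, bh_adjust(res$binom_p))
})

test_that("ties in the lowest FDR pick the earliest time point", {
  genes <- paste0("g", 1:10)
  rec <- make_records(genes, rep(1, 10))
  e <- make_enrichment("s", 0.1, list(genes[1:7]))
  res <- run_sign_test(list(early = e, late = e), rec)
  expect_identical(res$timepoint, "early")
})

test_that("no candidates gives an empty result with a warning", {
  genes <- paste0("g", 1:10)
  rec <- make_records(genes, rep(1, 10))
  e <- make_enrichment("s", 0.9, list(genes[1:7]))
  expect_warning(res <- run_sign_test(e, rec), "no gene set")
  expect_equal(nrow(res), 0L)
})

test_that("an injected one-directional set attains the smallest binomial p", {
  # synthetic hybrid with one strongly species-1-biased 8-gene set among
  # neutral genes; the full enrichment + sign-test path must single it out
  sets <- c(list(list(name = "driven", size = 8, direction = "+",
                      delta = 1.2)),
            lapply(1:20, function(i) {
              list(name = sprintf("neutral%02d", i), size = 14,
                   direction = "none", delta = 0)
            }))
  cfg <- simulation_config(n_genes = 300, n_samples = 60,
                           depth_mean = 200, depth_sdlog = 0.2,
                           alpha = 40, delta = 0,
                           n_hybrid_replicates = 8,
                           gene_sets = sets, seed = 52)
  pop <- generate_population(cfg)
  hyb <- generate_hybrid(cfg)
  prof <- build_population_profiles(pop)
  rec <- filter_expressed(build_interspecies_records(hyb$table,
                                                     hyb$de_summary))
  signed <- rank_by_signed(prof, rec)
  enr <- gsea_preranked(signed, generate_gene_sets(cfg), n_perm = 500,
                        seed = 6, min_size = 5)
  res <- run_sign_test(enr, rec)
  expect_true("driven" %in% res$set_name)
  expect_equal(res$set_name[which.min(res$binom_p)], "driven")
  expect_identical(res$direction[res$set_name == "driven"],
                   "species1-biased")
})
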