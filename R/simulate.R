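# Synthetic data with the statistical structure the method assumes.
#
# Allelic imbalance follows a beta-binomial: per gene g and sample s the
# allele-1 fraction is Beta-distributed with per-gene concentration
# (large concentration = tightly balanced alleles = constrained
# cis-regulation), and allele-1 reads are binomial at that fraction.
# Sequencing depth is log-normal across genes (median `depth_mean`) and
# Poisson across samples.  Hybrid experiments shift the allele-1
# fraction to 2^delta / (1 + 2^delta) per gene (delta in log2 units)
# with the same beta dispersion across replicates.

#' Simulation configuration
#'
#' @param n_genes Number of genes.
#' @param n_samples Population cohort size (columns of the population
#'   table).
#' @param depth_mean Median per-gene mean depth (reads per gene-sample).
#' @param depth_sdlog Log-normal sd of per-gene mean depth.
#' @param alpha Per-gene symmetric Beta concentration (recycled); large
#'   alpha = constrained gene.  The Beta for the allele-1 fraction has
#'   both shapes `alpha` in the population, giving concentration
#'   `2 * alpha`.
#' @param delta Per-gene interspecies shift in log2 units (recycled);
#'   0 = no cis divergence.
#' @param n_hybrid_replicates Replicates of the hybrid experiment.
#' @param gene_sets Optional list describing gene sets; each element a
#'   list with `name`, `size`, `direction` (`"+"`, `"-"` or `"none"`)
#'   and `delta` (the |shift| injected into member genes for
#'   directional sets; ignored for `"none"`).  Members are assigned at
#'   construction (directional sets are disjoint) and directional
#'   members get their `delta` overridden to `sign * delta`.
#' @param seed Integer seed; all generators derive their streams from
#'   it, so every table is bit-reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 100, n_samples = 500,
                              depth_mean = 100, depth_sdlog = 0.5,
                              alpha = 50, delta = 0,
                              n_hybrid_replicates = 8,
                              gene_sets = NULL, seed = 1) {
  if (n_genes < 1 || n_samples < 1 || n_hybrid_replicates < 1) {
    stopf("n_genes, n_samples and n_hybrid_replicates must be >= 1")
  }
  alpha <- rep_len(alpha, n_genes)
  delta <- rep_len(delta, n_genes)
  if (any(alpha <= 0)) stopf("alpha must be positive")
  if (depth_mean <= 0 || depth_sdlog < 0) stopf("invalid depth model")
  gene_id <- sprintf("g%04d", seq_len(n_genes))
  collection <- NULL
  if (!is.null(gene_sets)) {
    resolved <- with_seed(seed + 4L, {
      pool <- gene_id  # directional sets draw disjointly from this pool
      sets <- list()
      for (spec in gene_sets) {
        if (spec$size > n_genes) stopf("gene set '%s' larger than n_genes",
                                       spec$name)
        if (identical(spec$direction, "none")) {
          members <- sample(gene_id, spec$size)
        } else {
          if (spec$size > length(pool)) {
            stopf("not enough unassigned genes for directional set '%s'",
                  spec$name)
          }
          members <- sample(pool, spec$size)
          pool <- setdiff(pool, members)
          sgn <- if (identical(spec$direction, "+")) 1 else -1
          delta[match(members, gene_id)] <- sgn * abs(spec$delta)
        }
        sets[[spec$name]] <- members
      }
      list(sets = sets, delta = delta)
    })
    delta <- resolved$delta
    collection <- gene_set_collection(resolved$sets,
                                      source = "synthetic")
  }
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 depth_mean = depth_mean, depth_sdlog = depth_sdlog,
                 alpha = alpha, delta = delta,
                 n_hybrid_replicates = n_hybrid_replicates,
                 gene_id = gene_id, collection = collection, seed = seed),
            class = "simulation_config")
}

# per-gene mean depths; first draw of the population stream so that
# generate_constraint_scores can reproduce them for its expression column
.sim_gene_depths <- function(config) {
  stats::rlnorm(config$n_genes, log(config$depth_mean), config$depth_sdlog)
}

#' Generate a synthetic population allele-count table
#'
#' @param config A [simulation_config()].
#' @return An [allele_count_table()] (`n_genes` x `n_samples`);
#'   deterministic given `config$seed`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 1L, {
    G <- config$n_genes
    S <- config$n_samples
    m <- .sim_gene_depths(config)
    depth <- matrix(stats::rpois(G * S, rep(m, S)), G, S)
    f <- matrix(stats::rbeta(G * S, rep(config$alpha, S),
                             rep(config$alpha, S)), G, S)
    c1 <- matrix(stats::rbinom(G * S, depth, f), G, S)
    dimnames(c1) <- list(config$gene_id,
                         sprintf("s%04d", seq_len(S)))
    c2 <- depth - c1
    dimnames(c2) <- dimnames(c1)
    allele_count_table(c1, c2,
                       sample_meta = data.frame(
                         individual = colnames(c1),
                         stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic hybrid experiment with a DE-summary surrogate
#'
#' Per gene, the species-1 allele fraction is centered at
#' `2^delta / (1 + 2^delta)` and perturbed per replicate by the gene's
#' beta dispersion (Beta with mean at the shifted fraction and the same
#' concentration `2 * alpha` as in the population).  The DE summary
#' surrogate takes `mean_log2fc` as the mean replicate log2 ratio and
#' `de_fdr` as the BH-adjusted one-sample t-test p-value of the
#' replicate log2 ratios against 0 (standing in for a DESeq2 fit, which
#' is an external input in real use).
#'
#' @param config A [simulation_config()].
#' @return List with `table` (an [allele_count_table()], columns =
#'   replicates) and `de_summary` (`data.frame` with `gene_id`,
#'   `mean_log2fc`, `de_fdr`).
#' @export
generate_hybrid <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 2L, {
    G <- config$n_genes
    R <- config$n_hybrid_replicates
    m <- .sim_gene_depths(config)
    p <- 2^config$delta / (1 + 2^config$delta)
    conc <- 2 * config$alpha
    depth <- matrix(stats::rpois(G * R, rep(m, R)), G, R)
    f <- matrix(stats::rbeta(G * R, rep(conc * p, R),
                             rep(conc * (1 - p), R)), G, R)
    c1 <- matrix(stats::rbinom(G * R, depth, f), G, R)
    dimnames(c1) <- list(config$gene_id, sprintf("rep%02d", seq_len(R)))
    c2 <- depth - c1
    dimnames(c2) <- dimnames(c1)
    table <- allele_count_table(c1, c2)
    l2r <- log2((c1 + 1) / (c2 + 1))
    mean_fc <- rowMeans(l2r)
    pvals <- apply(l2r, 1L, function(v) {
      if (stats::sd(v) < 1e-12) {
        if (abs(mean(v)) < 1e-12) 1 else 2.2e-16
      } else {
        stats::t.test(v, mu = 0)$p.value
      }
    })
    de <- data.frame(gene_id = config$gene_id, mean_log2fc = mean_fc,
                     de_fdr = bh_adjust(pvals), stringsAsFactors = FALSE,
                     row.names = NULL)
    list(table = table, de_summary = de)
  })
}

#' Generate synthetic constraint scores and expression summaries
#'
#' Constraint scores are a monotone increasing function of the gene's
#' beta concentration (i.e. decreasing in allelic dispersion) with
#' optional rank-scale noise, mapped to (0, 1); the expression summary
#' is the gene's mean depth from the population depth model, so genes
#' quantified deeper also score as more expressed.
#'
#' @param config A [simulation_config()].
#' @param noise_sd Noise on the latent log-concentration scale, as a
#'   fraction of its spread (default 0.25; 0 gives a perfect monotone
#'   map from concentration to score).
#' @return A [constraint_scores()] table.
#' @export
generate_constraint_scores <- function(config, noise_sd = 0.25) {
  stopifnot(inherits(config, "simulation_config"))
  expr <- with_seed(config$seed + 1L, .sim_gene_depths(config))
  with_seed(config$seed + 3L, {
    latent <- log(config$alpha)
    spread <- stats::sd(latent)
    if (noise_sd > 0 && spread > 0) {
      latent <- latent + stats::rnorm(config$n_genes, 0, noise_sd * spread)
    }
    score <- (rank(latent, ties.method = "first") - 0.5) / config$n_genes
    constraint_scores(config$gene_id, score, expr)
  })
}

#' Gene-set collection of a simulation
#'
#' Returns the sets resolved at configuration time (injected directional
#' and neutral sets), optionally extended with additional random sets
#' drawn from all genes.
#'
#' @param config A [simulation_config()].
#' @param n_random Number of extra random sets (default 0).
#' @param size_range Size range for the random sets (default 10-30).
#' @return A [gene_set_collection()].
#' @export
generate_gene_sets <- function(config, n_random = 0,
                               size_range = c(10, 30)) {
  stopifnot(inherits(config, "simulation_config"))
  sets <- if (is.null(config$collection)) list() else config$collection$sets
  if (n_random > 0) {
    rand <- with_seed(config$seed + 5L, {
      lapply(seq_len(n_random), function(i) {
        k <- sample(seq(size_range[1L], size_range[2L]), 1L)
        sample(config$gene_id, min(k, config$n_genes))
      })
    })
    names(rand) <- sprintf("random_set_%03d", seq_len(n_random))
    sets <- c(sets, rand)
  }
  if (length(sets) == 0L) stopf("no gene sets defined in the configuration")
  gene_set_collection(sets, source = "synthetic")
}

#' Default constrained-vs-unconstrained study cohort
#'
#' The reference synthetic cohort used throughout the package's checks:
#' 100 genes, all with the same interspecies shift of 0.5 log2 units —
#' 50 tightly constrained (beta concentration 300) and 50 weakly
#' constrained (concentration 8) — a population of 500 samples at median
#' depth 100, and 8 hybrid replicates.  A useful ranking must place the
#' constrained shifted genes above the unconstrained shifted ones even
#' though their fold changes are identical in expectation.
#'
#' @param seed Integer seed.
#' @return A [simulation_config()]; genes `g0001`-`g0050` are the
#'   constrained class, `g0051`-`g0100` the unconstrained class.
#' @export
default_cohort_config <- function(seed = 1) {
  simulation_config(n_genes = 100, n_samples = 500, depth_mean = 100,
                    depth_sdlog = 0.3,
                    alpha = rep(c(150, 4), each = 50),
                    delta = 0.5, n_hybrid_replicates = 8, seed = seed)
}

#' Validation cohort with a continuous constraint gradient
#'
#' A cohort for the validation procedures: 250 genes whose beta
#' concentrations span 3-300 log-uniformly (a continuous constraint
#' gradient rather than two classes), 600 samples, median depth 300 with
#' small depth spread so the coverage filter rarely truncates genes, no
#' interspecies shift.
#'
#' @param seed Integer seed.
#' @return A [simulation_config()].
#' @export
validation_cohort_config <- function(seed = 1) {
  alpha <- with_seed(seed + 7L,
                     exp(stats::runif(250, log(3), log(300))))
  simulation_config(n_genes = 250, n_samples = 600, depth_mean = 300,
                    depth_sdlog = 0.2, alpha = alpha, delta = 0,
                    n_hybrid_replicates = 8, seed = seed)
}
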