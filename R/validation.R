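# Validation procedures: does population ASE variance behave like a
# constraint proxy?  Correlation with an external dosage-sensitivity
# score, robustness of that correlation to sample-size down-sampling,
# an expression-matched paired comparison, and cohort-split robustness
# of the final ranking.

#' Constraint-score table
#'
#' @param gene_id Character vector of gene ids (unique).
#' @param constraint Constraint scores in `[0, 1]` (pHI-like; high =
#'   dosage sensitive).
#' @param expression Non-negative expression summaries (e.g. mean of
#'   within-tissue median TPM).
#' @return A `data.frame` of class `constraint_scores`.
#' @export
constraint_scores <- function(gene_id, constraint, expression) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stopf("gene ids must be unique")
  if (any(constraint < 0 | constraint > 1, na.rm = TRUE)) {
    stopf("constraint scores must lie in [0, 1]")
  }
  if (any(expression < 0, na.rm = TRUE)) {
    stopf("expression summaries must be >= 0")
  }
  structure(data.frame(gene_id = gene_id, constraint = constraint,
                       expression = expression, stringsAsFactors = FALSE),
            class = c("constraint_scores", "data.frame"))
}

#' Read a constraint-score table (TSV: gene_id, constraint, expression)
#' @param path TSV path.
#' @return A [constraint_scores()] table.
#' @export
read_constraint_scores <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("gene_id", "constraint", "expression")
  if (!all(need %in% names(df))) {
    stopf("'%s' must have columns %s", path, paste(need, collapse = ", "))
  }
  constraint_scores(df$gene_id, df$constraint, df$expression)
}

#' Spearman correlation between ASE variance and a constraint score
#'
#' Under the constraint interpretation of population ASE variance, the
#' correlation with a dosage-sensitivity score should be negative:
#' dosage-sensitive genes tolerate less allelic imbalance.
#'
#' @param profiles A `population_profiles` object.
#' @param scores A [constraint_scores()] table.
#' @return List with `rho`, `p_value`, `n_genes` over the gene
#'   intersection (at least 3 genes; constant inputs are an error).
#' @export
constraint_correlation <- function(profiles, scores) {
  stopifnot(inherits(profiles, "population_profiles"))
  common <- intersect(profiles$gene_id, scores$gene_id)
  if (length(common) < 3L) {
    stopf("need >= 3 overlapping genes, got %d", length(common))
  }
  v <- unname(profiles$ase_variance[common])
  s <- scores$constraint[match(common, scores$gene_id)]
  if (stats::sd(v) == 0 || stats::sd(s) == 0) {
    stopf("correlation undefined: ASE variance or constraint score is constant")
  }
  ct <- suppressWarnings(stats::cor.test(v, s, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_genes = length(common))
}

#' Down-sampling experiment on the constraint correlation
#'
#' How many samples per gene does the population ASE distribution need?
#' Genes are restricted to those with at least `max(n_grid)`
#' quantifiable samples (passing the per-allele coverage filter), so
#' every gene contributes the same `n` in every condition.  For each `n`
#' in the grid and each of `reps` replicates, `n` quantifiable samples
#' are drawn per gene without replacement, profiles are rebuilt, and the
#' Spearman correlation with the constraint score is recorded; the mean
#' over replicates is reported.
#'
#' @param table An [allele_count_table()] for the population cohort.
#' @param scores A [constraint_scores()] table.
#' @param n_grid Integer sample sizes, sorted descending (default the
#'   GTEx-scale grid 5000 ... 10).
#' @param reps Draws per grid point (default 100).
#' @param seed RNG seed.
#' @param min_reads,pseudocount As in [build_population_profiles()].
#' @param scale Variance scale, `"ratio"` or `"log2"`.
#' @return Data frame with one row per `n`: `n`, `mean_rho`,
#'   `mean_abs_rho`, `n_genes`.
#' @export
downsample_experiment <- function(table, scores,
                                  n_grid = c(5000, 4000, 3000, 2000, 1000,
                                             500, 250, 100, 50, 25, 10),
                                  reps = 100, seed = NULL, min_reads = 10,
                                  pseudocount = 1,
                                  scale = c("ratio", "log2")) {
  stopifnot(inherits(table, "allele_count_table"))
  scale <- match.arg(scale)
  if (is.unsorted(rev(n_grid), strictly = TRUE)) {
    stopf("n_grid must be sorted in descending order")
  }
  if (reps < 1) stopf("reps must be >= 1")
  mask <- filter_low_coverage(table, min_reads)
  avail <- rowSums(mask)
  elig <- which(avail >= max(n_grid))
  elig <- elig[gene_ids(table)[elig] %in% scores$gene_id]
  if (length(elig) == 0L) {
    stopf("no gene has >= %d quantifiable samples and a constraint score",
          max(n_grid))
  }
  cc_log("down-sampling: %d genes with >= %d quantifiable samples",
         length(elig), max(n_grid))
  idx_by_gene <- lapply(elig, function(g) which(mask[g, ]))
  sc <- scores$constraint[match(gene_ids(table)[elig], scores$gene_id)]
  c1 <- table$counts1
  c2 <- table$counts2

  gene_var <- function(g, idx) {
    r <- normalize_median(compute_ase_ratio(c1[g, idx], c2[g, idx],
                                            pseudocount))
    if (scale == "ratio") stats::var(r) else stats::var(log2(r))
  }
  with_seed(seed, {
    res <- lapply(n_grid, function(n) {
      rhos <- vapply(seq_len(reps), function(rep) {
        vars <- vapply(seq_along(elig), function(i) {
          idx <- idx_by_gene[[i]]
          gene_var(elig[i], if (n < length(idx)) sample(idx, n) else idx)
        }, 0)
        spearman_rho(vars, sc)
      }, 0)
      data.frame(n = n, mean_rho = mean(rhos),
                 mean_abs_rho = mean(abs(rhos)), n_genes = length(elig))
    })
    do.call(rbind, res)
  })
}

#' Expression-matched paired comparison of ASE variance
#'
#' Controls for expression level when comparing ASE variance between
#' high- and low-constraint genes: the `n_top` highest- and `n_top`
#' lowest-constraint genes are each ranked by their expression summary,
#' paired by expression rank, and the per-pair variance difference
#' (high minus low constraint) is tested with a classical two-sided
#' paired t-test.  A negative mean difference says high-constraint genes
#' have lower ASE variance at matched expression.
#'
#' @param profiles A `population_profiles` object.
#' @param scores A [constraint_scores()] table.
#' @param n_top Genes per constraint tail (default 2500).
#' @return List with `differences` (length `n_top`), `t_statistic`,
#'   `p_value`, `n_pairs`.
#' @export
expression_matched_comparison <- function(profiles, scores, n_top = 2500) {
  stopifnot(inherits(profiles, "population_profiles"))
  common <- intersect(profiles$gene_id, scores$gene_id)
  if (length(common) < 2L * n_top) {
    stopf("need >= %d genes with both variance and scores, got %d",
          2L * n_top, length(common))
  }
  s <- scores[match(common, scores$gene_id), ]
  v <- unname(profiles$ase_variance[common])
  ord <- order(-s$constraint, common)  # deterministic tail selection
  hi <- ord[seq_len(n_top)]
  lo <- ord[seq(length(ord) - n_top + 1L, length(ord))]
  rank_by_expr <- function(i) i[order(s$expression[i], common[i])]
  hi <- rank_by_expr(hi)
  lo <- rank_by_expr(lo)
  d <- v[hi] - v[lo]
  tt <- stats::t.test(d)
  list(differences = d, t_statistic = unname(tt$statistic),
       p_value = tt$p.value, n_pairs = n_top)
}

#' Cohort-split robustness of a gene ranking
#'
#' Runs a full ranking pipeline independently on two disjoint sample
#' partitions of a cohort and reports the Spearman correlation of the
#' resulting gene ranks on the shared gene set.  High correlation means
#' the ranking is not driven by any one subgroup of the cohort.
#'
#' @param table An [allele_count_table()].
#' @param split List of two character vectors of sample ids.
#' @param ranking_fn Function taking an `allele_count_table` and
#'   returning a `ranked_gene_list` (typically wrapping
#'   [build_population_profiles()] + [rank_by_mwu()]).
#' @return List with `rho`, `n_genes`.
#' @export
cohort_split_robustness <- function(table, split, ranking_fn) {
  stopifnot(inherits(table, "allele_count_table"), length(split) == 2L)
  for (part in split) {
    if (length(part) == 0L) stopf("a partition is empty")
    missing <- setdiff(part, sample_ids(table))
    if (length(missing) > 0L) {
      stopf("partition sample '%s' not in table", missing[1L])
    }
  }
  r1 <- ranking_fn(table[, split[[1L]]])
  r2 <- ranking_fn(table[, split[[2L]]])
  common <- intersect(r1$gene_id, r2$gene_id)
  if (length(common) == 0L) {
    stopf("no genes shared between the two partition rankings")
  }
  rho <- spearman_rho(r1$rank[match(common, r1$gene_id)],
                      r2$rank[match(common, r2$gene_id)])
  list(rho = rho, n_genes = length(common))
}
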