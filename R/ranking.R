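# Constraint-aware gene rankings.
#
# The core statistic: for each gene, a two-sided Mann-Whitney U test
# compares the hybrid (between-species) log2 ASE ratios to the gene's
# within-population log2 ASE distribution.  A small p-value means the
# interspecies shift exceeds what the population tolerates for that gene
# — divergence judged against the gene's own cis-regulatory constraint —
# so genes are ranked by this p-value rather than by fold change alone.

.new_ranked_gene_list <- function(gene_id, score, mwu_p, kind,
                                  decreasing = FALSE) {
  ord <- order(if (decreasing) -score else score, gene_id)
  out <- data.frame(gene_id = gene_id[ord], score = score[ord],
                    mwu_p = mwu_p[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_gene_list", "data.frame"),
            ranking_kind = kind)
}

#' @export
print.ranked_gene_list <- function(x, ...) {
  cat(sprintf("ranked_gene_list (%s): %d genes\n",
              attr(x, "ranking_kind"), nrow(x)))
  print.data.frame(utils::head(x, 5L))
  if (nrow(x) > 5L) cat(sprintf("  ... %d more\n", nrow(x) - 5L))
  invisible(x)
}

#' Two-sided Mann-Whitney U test between two ASE distributions
#'
#' Compares the location of two samples with the rank-sum (Mann-Whitney
#' U) test.  When the product of sample sizes is at most 400 and the
#' pooled values are tie-free, the exact null distribution of U is used;
#' otherwise the normal approximation with tie correction and continuity
#' correction.  With zero rank variance (all pooled values equal) the
#' p-value is 1.
#'
#' Being a rank test, the result is invariant under any common strictly
#' monotone transform of both inputs, so ratio and log2-ratio inputs give
#' identical p-values.
#'
#' @param population_log2_ratios,hybrid_log2_ratios Non-empty numeric
#'   vectors (any common monotone scale).
#' @return Two-sided p-value in (0, 1].
#' @export
mwu_compare <- function(population_log2_ratios, hybrid_log2_ratios) {
  x <- population_log2_ratios
  y <- hybrid_log2_ratios
  if (length(x) == 0L || length(y) == 0L) {
    stopf("both input vectors must be non-empty")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stopf("inputs must be finite")
  }
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n1 * n2 <= 400) {
    p <- 2 * min(stats::pwilcox(u1, n1, n2),
                 1 - stats::pwilcox(u1 - 1, n1, n2))
    return(min(1, p))
  }
  n <- n1 + n2
  tab <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  mu <- n1 * n2 / 2
  d <- u1 - mu
  z <- (d - sign(d) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Rank genes by the population-vs-interspecies Mann-Whitney p-value
#'
#' For every gene present in both inputs, runs [mwu_compare()] on the
#' population log2 ratios versus the hybrid log2 ratios and ranks genes
#' by ascending p-value (rank 1 = most divergent relative to its
#' within-species constraint).  Ties are broken lexicographically by
#' gene id so ranks are deterministic.
#'
#' @param profiles A `population_profiles` object.
#' @param records An `interspecies_records` object.
#' @return A `ranked_gene_list` (kind `"mwu"`) with `score = mwu_p`.
#' @export
rank_by_mwu <- function(profiles, records) {
  stopifnot(inherits(profiles, "population_profiles"),
            inherits(records, "interspecies_records"))
  common <- intersect(profiles$gene_id, records$gene_id)
  if (length(common) == 0L) {
    stopf("no genes shared between population profiles and interspecies records")
  }
  dropped <- length(profiles$gene_id) + length(records$gene_id) -
    2L * length(common)
  if (dropped > 0L) {
    cc_log("mwu ranking: %d genes absent from one input excluded", dropped)
  }
  p <- vapply(common, function(g) {
    mwu_compare(profiles$log2_ratios[[g]], records$hybrid_log2_ratios[[g]])
  }, 0)
  .new_ranked_gene_list(common, p, p, "mwu", decreasing = FALSE)
}

#' Signed ranking score
#'
#' `-log10(p) * sign(mean_log2fc)`: the Mann-Whitney significance signed
#' by the direction of the interspecies fold change, so one ordered list
#' reads species-1-biased divergent genes at the top and
#' species-2-biased divergent genes at the bottom.  The p-value is
#' floored at 1e-300 before the log.
#'
#' @param mwu_p p-value in (0, 1].
#' @param mean_log2fc Mean differential-expression log2 fold change;
#'   `sign(0)` gives score 0.
#' @return Real score (vectorized).
#' @export
signed_score <- function(mwu_p, mean_log2fc) {
  if (any(mwu_p <= 0 | mwu_p > 1, na.rm = TRUE)) {
    stopf("mwu_p must be in (0, 1]")
  }
  -log10(pmax(mwu_p, 1e-300)) * sign(mean_log2fc)
}

#' Rank genes by the signed Mann-Whitney score
#'
#' Computes [rank_by_mwu()] p-values and signs them with each gene's
#' `mean_log2fc` ([signed_score()]); genes without a fold-change summary
#' are excluded (and counted in the log).  Descending order: rank 1 is
#' the most significant species-1-biased gene.
#'
#' @inheritParams rank_by_mwu
#' @return A `ranked_gene_list` (kind `"signed"`).
#' @export
rank_by_signed <- function(profiles, records) {
  mwu <- rank_by_mwu(profiles, records)
  fc <- records$mean_log2fc[mwu$gene_id]
  keep <- !is.na(fc)
  if (any(!keep)) {
    cc_log("signed ranking: %d genes without mean_log2fc excluded",
           sum(!keep))
  }
  if (!any(keep)) stopf("no genes with a mean_log2fc available")
  .new_ranked_gene_list(mwu$gene_id[keep],
                        signed_score(mwu$mwu_p[keep], unname(fc[keep])),
                        mwu$mwu_p[keep], "signed", decreasing = TRUE)
}

#' Rank genes by differential-expression FDR
#'
#' The "traditional" ranking the constraint-aware ranking is contrasted
#' with: ascending DE FDR, ties broken lexicographically by gene id
#' (many genes share FDR 1, so the tie rule matters for determinism).
#'
#' @param records An `interspecies_records` object with `de_fdr` values.
#' @return A `ranked_gene_list` (kind `"de_fdr"`).
#' @export
rank_by_de_fdr <- function(records) {
  stopifnot(inherits(records, "interspecies_records"))
  keep <- which(!is.na(records$de_fdr))
  if (length(keep) == 0L) stopf("no genes with a de_fdr available")
  if (length(keep) < length(records$gene_id)) {
    cc_log("de_fdr ranking: %d genes without de_fdr excluded",
           length(records$gene_id) - length(keep))
  }
  .new_ranked_gene_list(records$gene_id[keep],
                        unname(records$de_fdr)[keep],
                        rep(NA_real_, length(keep)),
                        "de_fdr", decreasing = FALSE)
}

#' Difference-in-ranks gene list
#'
#' `score(g) = de_rank(g) - mwu_rank(g)`, sorted descending.  A gene
#' ranked high by the constraint-aware Mann-Whitney comparison (small
#' `mwu_rank`) but low by the traditional DE-FDR ranking (large
#' `de_rank`) gets a large positive score and sits at the top: these are
#' genes with modest fold changes whose expression is nonetheless tightly
#' constrained within the population.
#'
#' @param mwu_list A `ranked_gene_list` of kind `"mwu"`.
#' @param de_list A `ranked_gene_list` of kind `"de_fdr"` over the same
#'   gene universe.
#' @return A `ranked_gene_list` (kind `"diff_in_ranks"`).
#' @export
diff_in_ranks <- function(mwu_list, de_list) {
  stopifnot(inherits(mwu_list, "ranked_gene_list"),
            inherits(de_list, "ranked_gene_list"))
  if (!setequal(mwu_list$gene_id, de_list$gene_id)) {
    diff <- c(setdiff(mwu_list$gene_id, de_list$gene_id),
              setdiff(de_list$gene_id, mwu_list$gene_id))
    stopf("gene universes differ (%d genes in one list only, e.g. %s)",
          length(diff), paste(utils::head(diff, 3L), collapse = ", "))
  }
  mwu_rank <- stats::setNames(mwu_list$rank, mwu_list$gene_id)
  de_rank <- stats::setNames(de_list$rank, de_list$gene_id)
  genes <- mwu_list$gene_id
  score <- unname(de_rank[genes]) - unname(mwu_rank[genes])
  mwu_p <- stats::setNames(mwu_list$mwu_p, mwu_list$gene_id)
  .new_ranked_gene_list(genes, score, unname(mwu_p[genes]),
                        "diff_in_ranks", decreasing = TRUE)
}
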