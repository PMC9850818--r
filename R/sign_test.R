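# Binomial sign test for lineage-specific selection.
#
# In a hybrid, the cis-regulatory divergence of different genes rests on
# independent mutations, so under neutrality the direction of each
# gene's allelic bias is a fair coin flip.  If the genes driving an
# enrichment are skewed toward one species' allele far beyond chance,
# that is evidence of polygenic lineage-specific selection on the gene
# set.  The test: count species-1-biased vs species-2-biased genes in
# the leading edge and apply the exact two-sided binomial test at
# p = 0.5, then Benjamini-Hochberg across all tested sets.

#' Count direction of allelic bias among leading-edge genes
#'
#' @param leading_edge Character vector of gene ids (the set members
#'   before the enrichment peak).
#' @param records An `interspecies_records` object supplying each gene's
#'   `mean_log2fc`; every leading-edge gene must have one.
#' @return Named integer vector `c(k_species1, k_species2)`: genes with
#'   positive and negative `mean_log2fc`.  Genes with `mean_log2fc` of
#'   exactly 0 are excluded from both counts.
#' @export
count_directions <- function(leading_edge, records) {
  stopifnot(inherits(records, "interspecies_records"))
  fc <- records$mean_log2fc[leading_edge]
  bad <- leading_edge[is.na(fc)]
  if (length(bad) > 0L) {
    stopf("no mean_log2fc for leading-edge gene '%s'", bad[1L])
  }
  zero <- sum(fc == 0)
  if (zero > 0L) {
    cc_log("count_directions: %d gene(s) with mean_log2fc == 0 excluded",
           zero)
  }
  c(k_species1 = sum(fc > 0), k_species2 = sum(fc < 0))
}

#' Exact two-sided binomial sign test
#'
#' Two-sided exact binomial test of `k` successes in `n` trials at
#' success probability 0.5; by symmetry this equals
#' `2 * P(X >= max(k, n - k))` capped at 1.
#'
#' @param k Number of species-1-biased genes, `0 <= k <= n`.
#' @param n Total directional genes, `n >= 1`.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' binomial_sign_test(6, 6)   # 0.03125
#' binomial_sign_test(8, 11)  # 0.2266
#' @export
binomial_sign_test <- function(k, n) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != floor(k) || n != floor(n)) {
    stopf("need integers 0 <= k <= n with n >= 1 (got k = %s, n = %s)",
          format(k), format(n))
  }
  stats::binom.test(k, n, p = 0.5)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR control; a thin validating wrapper around
#' `stats::p.adjust(method = "BH")` returning q-values in input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the lineage-specific-selection sign test over enrichment results
#'
#' Candidate sets are those nominally enriched (GSEA `fdr_q <
#' gsea_fdr`) with more than `min_driving_genes` leading-edge genes.
#' A set enriched at several time points is tested once, at the time
#' point with the lowest GSEA FDR (ties broken by the earliest time
#' point in `enrichments`).  For each candidate, leading-edge direction
#' counts ([count_directions()]) feed the exact binomial test, and
#' Benjamini-Hochberg correction is applied across all tested sets.
#'
#' @param enrichments A single `enrichment_results` object or a named
#'   list of them, one per time point (list order = time order).
#' @param records An `interspecies_records` object, or a list parallel
#'   to `enrichments`, supplying `mean_log2fc` per gene.
#' @param gsea_fdr GSEA FDR eligibility cutoff (default 0.25).
#' @param min_driving_genes Leading edges must be strictly larger than
#'   this (default 5).
#' @param bh_threshold Sets with `bh_q` below this are flagged
#'   significant (default 0.1).
#' @return Data frame with one row per tested set: `set_name`,
#'   `timepoint`, `k_species1`, `n_total`, `direction`, `binom_p`,
#'   `bh_q`, `significant`.  Empty (with a warning) if no candidate.
#' @export
run_sign_test <- function(enrichments, records, gsea_fdr = 0.25,
                          min_driving_genes = 5, bh_threshold = 0.1) {
  if (inherits(enrichments, "enrichment_results")) {
    enrichments <- list(t1 = enrichments)
  }
  if (length(enrichments) == 0L) stopf("need at least one time point")
  if (is.null(names(enrichments))) {
    names(enrichments) <- paste0("t", seq_along(enrichments))
  }
  if (inherits(records, "interspecies_records")) {
    records <- stats::setNames(rep(list(records), length(enrichments)),
                               names(enrichments))
  }
  tps <- names(enrichments)
  all_sets <- unique(unlist(lapply(enrichments, `[[`, "set_name")))

  rows <- list()
  for (set in all_sets) {
    fdrs <- vapply(tps, function(tp) {
      e <- enrichments[[tp]]
      i <- match(set, e$set_name)
      if (is.na(i)) NA_real_ else e$fdr_q[i]
    }, 0)
    if (all(is.na(fdrs))) next
    sel <- which.min(fdrs)  # first minimum = earliest time point on ties
    e <- enrichments[[sel]]
    i <- match(set, e$set_name)
    le <- e$leading_edge[[i]]
    if (is.na(fdrs[sel]) || fdrs[sel] >= gsea_fdr) next
    if (length(le) <= min_driving_genes) next
    ks <- count_directions(le, records[[sel]])
    k1 <- ks[["k_species1"]]
    n <- k1 + ks[["k_species2"]]
    if (n < 1L) next
    rows[[length(rows) + 1L]] <- data.frame(
      set_name = set, timepoint = tps[sel], k_species1 = k1, n_total = n,
      direction = if (k1 > n - k1) "species1-biased"
                  else if (k1 < n - k1) "species2-biased" else "balanced",
      binom_p = binomial_sign_test(k1, n), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    warning("no gene set passes the enrichment eligibility filters")
    return(data.frame(set_name = character(), timepoint = character(),
                      k_species1 = integer(), n_total = integer(),
                      direction = character(), binom_p = numeric(),
                      bh_q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$bh_q <- bh_adjust(out$binom_p)
  out$significant <- out$bh_q < bh_threshold
  cc_log("sign test: %d sets tested, %d significant at BH q < %g",
         nrow(out), sum(out$significant), bh_threshold)
  out
}
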