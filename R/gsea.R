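# Self-contained preranked gene-set enrichment.
#
# Weighted Kolmogorov-Smirnov running-sum statistic: walking down the
# ranked list, the running sum gains |score|^weight / sum(|score|^weight
# over set members) at each set member and loses 1/(N - N_hits) at each
# non-member; the enrichment score (ES) is the signed maximum-magnitude
# deviation.  Significance comes from a gene-permutation null: set labels
# are reassigned to random list positions, ES is renormalized within each
# sign to give the NES, and FDR is computed from the pooled positive and
# negative null NES distributions.

#' Weighted running-sum enrichment score
#'
#' @param ranked A `ranked_gene_list` (or any data frame with `gene_id`
#'   and `score`, already in rank order).
#' @param gene_set Character vector of gene ids; at least one must occur
#'   in the ranked list.
#' @param weight Exponent on `|score|` for the hit increments (default 1,
#'   the standard GSEA weighting; 0 gives the classical unweighted KS
#'   statistic).  If all set members have score 0 the unweighted
#'   increments are used.
#' @return List with `es` (in `[-1, 1]`), `peak_rank` (position of the
#'   maximum `|running sum|`), `leading_edge` (set members at ranks `<=
#'   peak_rank` for positive ES, `>= peak_rank` for negative ES) and
#'   `running_sum` (length-N numeric).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  genes <- ranked$gene_id
  scores <- ranked$score
  N <- length(genes)
  if (N == 0L) stopf("ranked list is empty")
  hit <- genes %in% gene_set
  k <- sum(hit)
  if (k == 0L) stopf("no gene of the set occurs in the ranked list")
  if (k == N) stopf("gene set covers the whole ranked list")
  w <- abs(scores)^weight
  sw <- sum(w[hit])
  incr <- numeric(N)
  if (sw == 0) {
    incr[hit] <- 1 / k
  } else {
    incr[hit] <- w[hit] / sw
  }
  incr[!hit] <- -1 / (N - k)
  running <- cumsum(incr)
  peak <- which.max(abs(running))
  es <- running[peak]
  le <- if (es >= 0) genes[hit & seq_len(N) <= peak]
        else genes[hit & seq_len(N) >= peak]
  list(es = es, peak_rank = peak, leading_edge = le, running_sum = running)
}

# ES from sorted hit positions only, O(k): the running sum is linear
# between hits, so its extremes occur at a hit (maximum) or just before
# one (minimum); both candidate sets are evaluated directly.  Used for
# the permutation null, where only the ES value is needed.
.es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  pos <- sort.int(pos)
  wh <- w[pos]
  sw <- sum(wh)
  if (sw == 0) {
    ph <- seq_len(k) / k
  } else {
    ph <- cumsum(wh) / sw
  }
  miss <- (pos - seq_len(k)) / (N - k)
  cand <- c(ph - miss, c(0, ph[-k]) - miss)
  cand[which.max(abs(cand))]
}

#' Preranked gene-set enrichment analysis
#'
#' Runs the weighted KS enrichment score over every eligible set of a
#' collection and assesses significance with a gene-permutation null:
#' `n_perm` random draws of set-sized position subsets of the ranked
#' list.  The normalized enrichment score (NES) divides ES by the mean
#' magnitude of same-sign null ES values for that set; the nominal
#' p-value is the same-sign null exceedance fraction (floored at
#' `1/n_perm`); the FDR q-value follows the positive/negative-pool
#' procedure of the published GSEA method on the normalized null.
#' Results are deterministic given `seed`.
#'
#' @param ranked A `ranked_gene_list`.
#' @param collection A [gene_set_collection()].
#' @param n_perm Number of gene-label permutations (default 1000).
#' @param seed RNG seed for the permutations (default 6).
#' @param min_size,max_size Bounds on `|set` \eqn{\cap}` list|` for a set
#'   to be tested (defaults 10 and 300).
#' @param weight ES weight exponent (default 1).
#' @return An `enrichment_results` data frame with one row per tested
#'   set: `set_name`, `es`, `nes`, `nominal_p`, `fdr_q`, `peak_rank`,
#'   `set_size_used`, and list column `leading_edge`.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000, seed = 6,
                           min_size = 10, max_size = 300, weight = 1) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (n_perm < 1) stopf("n_perm must be >= 1")
  genes <- ranked$gene_id
  N <- length(genes)
  sizes <- vapply(collection$sets, function(s) sum(s %in% genes), 0L)
  skipped <- names(sizes)[sizes == 0L]
  if (length(skipped) > 0L) {
    warning(sprintf("%d set(s) with no gene in the ranked list skipped (e.g. '%s')",
                    length(skipped), skipped[1L]))
  }
  eligible <- names(sizes)[sizes >= min_size & sizes <= max_size &
                             sizes < N]
  cc_log("gsea: %d of %d sets eligible (size %d-%d in list)",
         length(eligible), length(collection$sets), min_size, max_size)
  if (length(eligible) == 0L) {
    return(.new_enrichment_results(character(), numeric(), numeric(),
                                   numeric(), numeric(), integer(),
                                   integer(), list()))
  }
  w <- abs(ranked$score)^weight
  obs <- lapply(eligible, function(nm) {
    enrichment_score(ranked, collection$sets[[nm]], weight)
  })
  es <- vapply(obs, `[[`, 0, "es")

  # one null ES matrix column per set; permutations share the RNG stream
  # under `seed` so the whole analysis is reproducible
  null_es <- with_seed(seed, {
    vapply(eligible, function(nm) {
      k <- sizes[[nm]]
      vapply(seq_len(n_perm), function(i) {
        .es_from_positions(sample.int(N, k), w, N)
      }, 0)
    }, numeric(n_perm))
  })
  null_es <- matrix(null_es, nrow = n_perm)

  nes <- numeric(length(eligible))
  nominal_p <- numeric(length(eligible))
  null_nes <- matrix(NA_real_, n_perm, length(eligible))
  for (j in seq_along(eligible)) {
    nul <- null_es[, j]
    pos <- nul[nul >= 0]
    neg <- nul[nul < 0]
    mpos <- if (length(pos)) mean(pos) else NA_real_
    mneg <- if (length(neg)) mean(abs(neg)) else NA_real_
    same <- if (es[j] >= 0) pos else neg
    denom <- if (es[j] >= 0) mpos else mneg
    nes[j] <- if (!is.na(denom) && denom > 0) es[j] / denom else NA_real_
    nominal_p[j] <- if (length(same)) {
      max(mean(abs(same) >= abs(es[j])), 1 / n_perm)
    } else 1 / n_perm
    scaled <- nul
    if (!is.na(mpos) && mpos > 0) scaled[nul >= 0] <- nul[nul >= 0] / mpos
    if (!is.na(mneg) && mneg > 0) scaled[nul < 0] <- nul[nul < 0] / mneg
    null_nes[, j] <- scaled
  }

  fdr_q <- .gsea_fdr(nes, null_nes)
  .new_enrichment_results(eligible, es, nes, nominal_p, fdr_q,
                          vapply(obs, `[[`, 0L, "peak_rank"),
                          unname(sizes[eligible]),
                          lapply(obs, `[[`, "leading_edge"))
}

# Positive/negative-pool FDR on normalized scores: for NES* >= 0,
# q = P(null NES >= NES* | null NES >= 0) / P(obs NES >= NES* | obs >= 0),
# and symmetrically for negative NES; capped at 1.
.gsea_fdr <- function(nes, null_nes) {
  pool <- as.vector(null_nes)
  pool <- pool[is.finite(pool)]
  pool_pos <- pool[pool >= 0]
  pool_neg <- pool[pool < 0]
  obs_pos <- nes[!is.na(nes) & nes >= 0]
  obs_neg <- nes[!is.na(nes) & nes < 0]
  vapply(nes, function(v) {
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      num <- if (length(pool_pos)) mean(pool_pos >= v) else 0
      den <- if (length(obs_pos)) mean(obs_pos >= v) else 1
    } else {
      num <- if (length(pool_neg)) mean(pool_neg <= v) else 0
      den <- if (length(obs_neg)) mean(obs_neg <= v) else 1
    }
    min(1, num / max(den, .Machine$double.eps))
  }, 0)
}

.new_enrichment_results <- function(set_name, es, nes, nominal_p, fdr_q,
                                    peak_rank, set_size_used,
                                    leading_edge) {
  out <- data.frame(set_name = set_name, es = es, nes = nes,
                    nominal_p = nominal_p, fdr_q = fdr_q,
                    peak_rank = as.integer(peak_rank),
                    set_size_used = as.integer(set_size_used),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$leading_edge <- unname(leading_edge)
  structure(out, class = c("enrichment_results", "data.frame"))
}

#' @export
print.enrichment_results <- function(x, ...) {
  cat(sprintf("enrichment_results: %d sets tested\n", nrow(x)))
  if (nrow(x)) {
    show <- as.data.frame(x)[, c("set_name", "es", "nes", "nominal_p",
                                 "fdr_q", "set_size_used")]
    print.data.frame(utils::head(show[order(show$fdr_q), ], 5L),
                     row.names = FALSE)
  }
  invisible(x)
}
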