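# Small in-code fixtures and independent oracles shared across tests.

make_table <- function(c1, c2, genes = NULL, samples = NULL) {
  c1 <- as.matrix(c1)
  c2 <- as.matrix(c2)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(c1)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(c1)))
  dimnames(c1) <- dimnames(c2) <- list(genes, samples)
  allele_count_table(c1, c2)
}

make_ranked <- function(genes, scores) {
  structure(data.frame(gene_id = genes, score = scores, mwu_p = NA_real_,
                       rank = seq_along(genes), stringsAsFactors = FALSE),
            class = c("ranked_gene_list", "data.frame"),
            ranking_kind = "mwu")
}

# records with given per-gene fold changes and large counts (passes the
# expression filter); log2 ratios are a single replicate at the fc
make_records <- function(genes, mean_log2fc, de_fdr = rep(0.5, length(genes))) {
  c1 <- matrix(round(100 * 2^mean_log2fc), ncol = 1,
               dimnames = list(genes, "rep01"))
  c2 <- matrix(100, nrow = length(genes), ncol = 1,
               dimnames = list(genes, "rep01"))
  build_interspecies_records(
    allele_count_table(c1, c2),
    data.frame(gene_id = genes, mean_log2fc = mean_log2fc,
               de_fdr = de_fdr, stringsAsFactors = FALSE))
}

# --- independent oracles -------------------------------------------------

# exact two-sided Mann-Whitney p by enumerating all choose(n1+n2, n2)
# assignments of the pooled values to the second group
brute_mwu <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  u_of <- function(first) {
    r <- rank(pooled)
    sum(r[first]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(idx, 2L, function(first) {
    r <- rank(pooled)
    sum(r[first]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# direct position-by-position running-sum ES evaluation
brute_es <- function(genes, scores, set, weight = 1) {
  N <- length(genes)
  hit <- genes %in% set
  k <- sum(hit)
  w <- abs(scores)^weight
  sw <- sum(w[hit])
  best <- 0
  run <- 0
  peak <- 1L
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + if (sw == 0) 1 / k else w[i] / sw
    } else {
      run <- run - 1 / (N - k)
    }
    if (abs(run) > abs(best)) {
      best <- run
      peak <- i
    }
  }
  list(es = best, peak_rank = peak)
}

# two-sided binomial p at 0.5 by summing the pmf tails
brute_binom <- function(k, n) {
  m <- max(k, n - k)
  min(1, 2 * sum(stats::dbinom(m:n, n, 0.5)))
}

# step-up BH by definition
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  q
}
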