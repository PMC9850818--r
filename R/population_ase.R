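# Population ASE distributions.
#
# For each gene, the allele-specific expression ratio is computed per
# sample with a pseudocount, low-coverage samples are removed, and the
# retained ratios are normalized so their median is 1.  The spread of the
# normalized ratios across the cohort is the gene's population ASE
# variance, used downstream as a proxy for cis-regulatory constraint:
# genes under stabilizing selection on expression tolerate little allelic
# imbalance in the population and have low variance.

#' Allele-specific expression ratio with pseudocount
#'
#' `(count1 + pseudocount) / (count2 + pseudocount)`.  The pseudocount
#' (default 1 per allele) prevents division by zero; with both counts zero
#' the ratio is 1.
#'
#' @param count1,count2 Non-negative integer counts (vectorized).
#' @param pseudocount Positive value added to each allele's count.
#' @return Positive ratio(s).
#' @examples
#' compute_ase_ratio(9, 19)   # 0.5
#' compute_ase_ratio(0, 0)    # 1
#' @export
compute_ase_ratio <- function(count1, count2, pseudocount = 1) {
  if (pseudocount <= 0) stopf("pseudocount must be positive")
  if (any(count1 < 0, na.rm = TRUE) || any(count2 < 0, na.rm = TRUE)) {
    stopf("counts must be non-negative")
  }
  (count1 + pseudocount) / (count2 + pseudocount)
}

#' Per-gene low-coverage sample mask
#'
#' A sample is retained for a gene only if it has at least `min_reads`
#' raw counts (pseudocount not included) from *each* allele.  The mask is
#' per gene: the same sample can pass for one gene and fail for another.
#' `NA` counts never pass (gene absent in that sample).
#'
#' @param table An [allele_count_table()].
#' @param min_reads Minimum reads per allele (default 10).
#' @return Logical gene-by-sample matrix, `TRUE` where retained.
#' @export
filter_low_coverage <- function(table, min_reads = 10) {
  stopifnot(inherits(table, "allele_count_table"))
  if (min_reads < 0) stopf("min_reads must be >= 0")
  m <- !is.na(table$counts1) & !is.na(table$counts2) &
    table$counts1 >= min_reads & table$counts2 >= min_reads
  dimnames(m) <- dimnames(table$counts1)
  m
}

#' Median-normalize a vector of ASE ratios
#'
#' Divides by the median so that the normalized median is 1, removing any
#' consistent expression bias of one allele and leaving only the spread of
#' allelic imbalance.  Even-length medians are the mean of the two middle
#' order statistics.
#'
#' @param ratios Positive numeric vector, length >= 1.
#' @return `ratios / median(ratios)`.
#' @export
normalize_median <- function(ratios) {
  if (length(ratios) == 0L) stopf("cannot normalize an empty ratio vector")
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stopf("ratios must be positive and finite")
  }
  ratios / stats::median(ratios)
}

#' Build per-gene population ASE profiles
#'
#' Per gene: drop low-coverage samples ([filter_low_coverage()]), compute
#' pseudocounted ASE ratios on the retained samples, median-normalize,
#' and record the sample variance (denominator n - 1) of the normalized
#' ratios.  Genes retained in fewer than `min_samples` samples are
#' excluded.
#'
#' @param table An [allele_count_table()] for the population cohort.
#' @param min_reads Per-allele coverage threshold (default 10).
#' @param min_samples Minimum retained samples per gene (default 50).
#' @param pseudocount Pseudocount per allele (default 1).
#' @param scale Scale on which `ase_variance` is computed: `"ratio"`
#'   (default, variance of the normalized ratios) or `"log2"` (variance
#'   of their log2).
#' @return An object of class `population_profiles`: parallel per-gene
#'   vectors/lists `gene_id`, `ratios`, `log2_ratios`, `n_samples`,
#'   `ase_variance`.  Empty (with a warning) if no gene survives.
#' @export
build_population_profiles <- function(table, min_reads = 10,
                                      min_samples = 50, pseudocount = 1,
                                      scale = c("ratio", "log2")) {
  stopifnot(inherits(table, "allele_count_table"))
  scale <- match.arg(scale)
  mask <- filter_low_coverage(table, min_reads)
  genes <- gene_ids(table)
  keep <- which(rowSums(mask) >= max(min_samples, 1L))
  if (length(keep) == 0L) {
    warning("no genes survive the coverage and sample-count filters")
    return(.new_population_profiles(character(), list(), list(),
                                    integer(), numeric(), scale))
  }
  ratios <- vector("list", length(keep))
  log2r <- vector("list", length(keep))
  nn <- integer(length(keep))
  vv <- numeric(length(keep))
  for (k in seq_along(keep)) {
    g <- keep[k]
    idx <- which(mask[g, ])
    r <- compute_ase_ratio(table$counts1[g, idx], table$counts2[g, idx],
                           pseudocount)
    r <- normalize_median(unname(r))
    l <- log2(r)
    ratios[[k]] <- r
    log2r[[k]] <- l
    nn[k] <- length(r)
    vv[k] <- if (length(r) > 1L) {
      if (scale == "ratio") stats::var(r) else stats::var(l)
    } else 0
  }
  cc_log("population profiles: %d of %d genes retained (>= %d samples)",
         length(keep), length(genes), min_samples)
  .new_population_profiles(genes[keep], ratios, log2r, nn, vv, scale)
}

.new_population_profiles <- function(gene_id, ratios, log2_ratios,
                                     n_samples, ase_variance, scale) {
  names(ratios) <- names(log2_ratios) <- gene_id
  names(n_samples) <- names(ase_variance) <- gene_id
  structure(list(gene_id = gene_id, ratios = ratios,
                 log2_ratios = log2_ratios, n_samples = n_samples,
                 ase_variance = ase_variance, scale = scale),
            class = "population_profiles")
}

#' @export
print.population_profiles <- function(x, ...) {
  cat(sprintf("population_profiles: %d genes (variance scale: %s)\n",
              length(x$gene_id), x$scale))
  if (length(x$gene_id)) {
    cat(sprintf("  samples per gene: %d-%d; median ASE variance %.4g\n",
                min(x$n_samples), max(x$n_samples),
                stats::median(x$ase_variance)))
  }
  invisible(x)
}

#' @export
length.population_profiles <- function(x) length(x$gene_id)

#' @export
as.data.frame.population_profiles <- function(x, ...) {
  data.frame(gene_id = x$gene_id, n_samples = unname(x$n_samples),
             ase_variance = unname(x$ase_variance),
             stringsAsFactors = FALSE)
}

#' Swap the allele orientation of population profiles
#'
#' Rebuilds each gene's profile with the allele roles exchanged: ratios
#' become reciprocals and are re-normalized to median 1.  Since a common
#' scale factor cancels in the median normalization, this is identical to
#' swapping the two count matrices and rebuilding.  Used to check that
#' downstream rankings are robust to the arbitrary labelling of alleles.
#'
#' @param profiles A `population_profiles` object.
#' @return A `population_profiles` object with flipped orientation.
#' @export
flip_allele_orientation <- function(profiles) {
  stopifnot(inherits(profiles, "population_profiles"))
  ratios <- lapply(profiles$ratios, function(r) normalize_median(1 / r))
  log2r <- lapply(ratios, log2)
  vv <- vapply(seq_along(ratios), function(i) {
    r <- ratios[[i]]
    if (length(r) > 1L) {
      if (profiles$scale == "ratio") stats::var(r) else stats::var(log2r[[i]])
    } else 0
  }, 0)
  .new_population_profiles(profiles$gene_id, ratios, log2r,
                           unname(profiles$n_samples), vv, profiles$scale)
}
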