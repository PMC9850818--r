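#' Biallelic read-count table
#'
#' Container for allele-resolved read counts: two gene-by-sample integer
#' matrices, one per allele.  For a population cohort, allele 1 is the
#' reference allele and allele 2 the alternative allele; for an
#' interspecies hybrid experiment, allele 1 is the species-1 (e.g. human)
#' allele and allele 2 the species-2 (e.g. chimpanzee) allele.
#'
#' Counts must be non-negative integers.  `NA` means the gene was not
#' quantifiable in that sample (no phased variant covered, for instance)
#' and is treated as sample-absent, not as zero: a zero count is
#' informative about allelic imbalance, a missing one is not.
#'
#' @param counts1 Gene-by-sample matrix of reads supporting allele 1, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param counts2 Same-shape matrix of reads supporting allele 2.
#' @param sample_meta Optional `data.frame` of per-sample attributes
#'   (individual id, tissue, sex, ...) with one row per sample.
#' @return An object of class `allele_count_table`.
#' @examples
#' c1 <- matrix(c(10L, 20L, 30L, 40L), 2, 2,
#'              dimnames = list(c("gA", "gB"), c("s1", "s2")))
#' tab <- allele_count_table(c1, c1 + 5L)
#' @export
allele_count_table <- function(counts1, counts2, sample_meta = NULL) {
  counts1 <- as.matrix(counts1)
  counts2 <- as.matrix(counts2)
  if (!identical(dim(counts1), dim(counts2))) {
    stopf("counts1 (%d x %d) and counts2 (%d x %d) differ in shape",
          nrow(counts1), ncol(counts1), nrow(counts2), ncol(counts2))
  }
  gene_ids <- rownames(counts1)
  sample_ids <- colnames(counts1)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stopf("counts1 must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(gene_ids)) {
    stopf("duplicate gene id: '%s'", gene_ids[duplicated(gene_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample id: '%s'", sample_ids[duplicated(sample_ids)][1L])
  }
  .check_count_matrix(counts1, "counts1")
  .check_count_matrix(counts2, "counts2")
  dimnames(counts2) <- dimnames(counts1)
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (nrow(sample_meta) != length(sample_ids)) {
      stopf("sample_meta has %d rows for %d samples",
            nrow(sample_meta), length(sample_ids))
    }
  }
  structure(
    list(counts1 = counts1, counts2 = counts2, sample_meta = sample_meta),
    class = "allele_count_table"
  )
}

.check_count_matrix <- function(m, what) {
  if (!is.numeric(m)) stopf("%s must be numeric", what)
  v <- m[!is.na(m)]
  if (any(v < 0)) stopf("%s contains a negative count", what)
  if (any(v != floor(v))) stopf("%s contains a non-integer count", what)
}

#' @export
print.allele_count_table <- function(x, ...) {
  cat(sprintf("allele_count_table: %d genes x %d samples\n",
              nrow(x$counts1), ncol(x$counts1)))
  na_frac <- mean(is.na(x$counts1))
  if (na_frac > 0) cat(sprintf("  %.1f%% gene-sample cells absent (NA)\n",
                               100 * na_frac))
  invisible(x)
}

#' @export
dim.allele_count_table <- function(x) dim(x$counts1)

#' Gene and sample identifiers of an allele-count table
#' @param x An `allele_count_table`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$counts1)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$counts1)

#' Subset an allele-count table
#'
#' @param x An `allele_count_table`.
#' @param i Gene index (integer, logical, or gene ids).
#' @param j Sample index (integer, logical, or sample ids).
#' @param ... Unused.
#' @return An `allele_count_table` over the selected genes and samples.
#' @export
`[.allele_count_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts1))
  if (missing(j)) j <- seq_len(ncol(x$counts1))
  meta <- x$sample_meta
  if (!is.null(meta)) {
    jj <- seq_len(ncol(x$counts1))
    names(jj) <- colnames(x$counts1)
    meta <- meta[if (is.character(j)) jj[j] else jj[j], , drop = FALSE]
  }
  allele_count_table(x$counts1[i, j, drop = FALSE],
                     x$counts2[i, j, drop = FALSE],
                     sample_meta = meta)
}

#' Pool allele counts across samples of the same individual
#'
#' Sums the per-allele read counts over all samples belonging to one
#' individual, yielding one column per individual.  Appropriate when the
#' samples of an individual are technical or cell-type fractions of the
#' same tissue (e.g. neuron / progenitor / cortical-wall fractions of a
#' fetal cortex donor), so that the downstream population distribution
#' has one value per independent individual.
#'
#' Cells that are `NA` in every pooled sample stay `NA`; otherwise `NA`
#' cells are treated as absent and the remaining counts are summed.
#'
#' @param table An [allele_count_table()].
#' @param individual_map Named character vector mapping sample id to
#'   individual id; every sample in `table` must be mapped.
#' @return An `allele_count_table` with one column per individual, in
#'   order of first appearance among the samples.
#' @export
pool_counts_by_individual <- function(table, individual_map) {
  stopifnot(inherits(table, "allele_count_table"))
  samp <- sample_ids(table)
  ind <- individual_map[samp]
  if (any(is.na(ind))) {
    stopf("unmapped sample: '%s'", samp[is.na(ind)][1L])
  }
  inds <- unique(unname(ind))
  pool_one <- function(m) {
    out <- vapply(inds, function(u) {
      sub <- m[, ind == u, drop = FALSE]
      s <- rowSums(sub, na.rm = TRUE)
      s[rowSums(!is.na(sub)) == 0L] <- NA_real_
      s
    }, numeric(nrow(m)))
    out <- matrix(out, nrow = nrow(m),
                  dimnames = list(rownames(m), inds))
    out
  }
  allele_count_table(pool_one(table$counts1), pool_one(table$counts2))
}
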