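# Interspecies (hybrid) ASE distributions.
#
# In an interspecies hybrid, both parental genomes share one trans
# environment, so the allelic ratio isolates cis-regulatory divergence.
# Unlike the population pipeline, no per-replicate coverage filter is
# applied (large interspecies expression differences are expected and
# informative) and medians are NOT normalized to 1 (a consistent bias
# toward one species' allele is the signal, not a nuisance).

#' Build per-gene interspecies ASE records
#'
#' Per gene and replicate, computes `log2((count1 + pc) / (count2 + pc))`
#' where allele 1 is the species-1 (e.g. human) allele.  Every replicate
#' with counts is kept.  Externally supplied differential-expression
#' summaries (mean log2 fold change and DE FDR, e.g. from DESeq2 fits of
#' the same experiment) are attached by gene id; genes without a summary
#' carry `NA`.
#'
#' @param table An [allele_count_table()] of the hybrid experiment
#'   (columns = replicates).
#' @param de_summary Optional `data.frame` with columns `gene_id`,
#'   `mean_log2fc`, `de_fdr` (see [read_de_summary()]).
#' @param pseudocount Pseudocount per allele (default 1).
#' @return An object of class `interspecies_records` with parallel
#'   per-gene fields `gene_id`, `hybrid_log2_ratios` (list),
#'   `mean_log2fc`, `de_fdr`, `mean_count1`, `mean_count2`.
#' @export
build_interspecies_records <- function(table, de_summary = NULL,
                                       pseudocount = 1) {
  stopifnot(inherits(table, "allele_count_table"))
  genes <- gene_ids(table)
  present <- !is.na(table$counts1) & !is.na(table$counts2)
  keep <- which(rowSums(present) >= 1L)
  if (length(keep) < length(genes)) {
    cc_log("interspecies records: %d genes with no quantified replicate dropped",
           length(genes) - length(keep))
  }
  l2r <- lapply(keep, function(g) {
    idx <- which(present[g, ])
    unname(log2(compute_ase_ratio(table$counts1[g, idx],
                                  table$counts2[g, idx], pseudocount)))
  })
  mc1 <- vapply(keep, function(g) mean(table$counts1[g, ], na.rm = TRUE), 0)
  mc2 <- vapply(keep, function(g) mean(table$counts2[g, ], na.rm = TRUE), 0)
  fc <- rep(NA_real_, length(keep))
  fdr <- rep(NA_real_, length(keep))
  if (!is.null(de_summary)) {
    i <- match(genes[keep], de_summary$gene_id)
    fc <- de_summary$mean_log2fc[i]
    fdr <- de_summary$de_fdr[i]
    if (any(fdr < 0 | fdr > 1, na.rm = TRUE)) {
      stopf("de_fdr outside [0, 1]")
    }
  }
  .new_interspecies_records(genes[keep], l2r, fc, fdr, mc1, mc2)
}

.new_interspecies_records <- function(gene_id, hybrid_log2_ratios,
                                      mean_log2fc, de_fdr,
                                      mean_count1, mean_count2) {
  names(hybrid_log2_ratios) <- gene_id
  names(mean_log2fc) <- names(de_fdr) <- gene_id
  names(mean_count1) <- names(mean_count2) <- gene_id
  structure(list(gene_id = gene_id,
                 hybrid_log2_ratios = hybrid_log2_ratios,
                 mean_log2fc = mean_log2fc, de_fdr = de_fdr,
                 mean_count1 = mean_count1, mean_count2 = mean_count2),
            class = "interspecies_records")
}

#' @export
print.interspecies_records <- function(x, ...) {
  cat(sprintf("interspecies_records: %d genes, %s replicates each\n",
              length(x$gene_id),
              if (length(x$gene_id))
                paste(range(lengths(x$hybrid_log2_ratios)), collapse = "-")
              else "-"))
  invisible(x)
}

#' @export
length.interspecies_records <- function(x) length(x$gene_id)

#' Subset interspecies records
#' @param x An `interspecies_records` object.
#' @param i Gene index or gene ids.
#' @param ... Unused.
#' @export
`[.interspecies_records` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$gene_id)
  .new_interspecies_records(x$gene_id[i],
                            x$hybrid_log2_ratios[i],
                            unname(x$mean_log2fc)[i],
                            unname(x$de_fdr)[i],
                            unname(x$mean_count1)[i],
                            unname(x$mean_count2)[i])
}

#' @export
as.data.frame.interspecies_records <- function(x, ...) {
  data.frame(gene_id = x$gene_id,
             n_replicates = unname(lengths(x$hybrid_log2_ratios)),
             mean_hybrid_log2_ratio =
               vapply(x$hybrid_log2_ratios, mean, 0),
             mean_log2fc = unname(x$mean_log2fc),
             de_fdr = unname(x$de_fdr),
             mean_count1 = unname(x$mean_count1),
             mean_count2 = unname(x$mean_count2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove lowly expressed genes from interspecies records
#'
#' A gene is removed only when the mean read count across replicates is
#' below `min_mean_count` for *both* alleles; one adequately covered
#' allele suffices to keep the gene (an allele silenced in one species is
#' itself an interspecies signal).
#'
#' @param records An `interspecies_records` object.
#' @param min_mean_count Threshold on the per-allele mean count
#'   (default 25).
#' @return The retained `interspecies_records`.
#' @export
filter_expressed <- function(records, min_mean_count = 25) {
  stopifnot(inherits(records, "interspecies_records"))
  if (min_mean_count < 0) stopf("min_mean_count must be >= 0")
  keep <- which(records$mean_count1 >= min_mean_count |
                  records$mean_count2 >= min_mean_count)
  cc_log("expression filter: %d of %d genes retained (mean count >= %g on >= 1 allele)",
         length(keep), length(records$gene_id), min_mean_count)
  records[keep]
}

#' Remove genes on an exclusion list
#'
#' Intended for genes with known mapping bias or residing in regions with
#' structural artefacts (e.g. culture-acquired duplications); such genes
#' are removed wholesale rather than modelled.
#'
#' @param records An `interspecies_records` object.
#' @param excluded Character vector of gene ids to drop.
#' @return The retained `interspecies_records`; excluded ids not present
#'   in the records trigger a warning and are otherwise ignored.
#' @export
apply_exclusion_list <- function(records, excluded) {
  stopifnot(inherits(records, "interspecies_records"))
  excluded <- unique(as.character(excluded))
  absent <- setdiff(excluded, records$gene_id)
  if (length(absent) > 0L) {
    warning(sprintf("%d excluded gene id(s) not found in records (e.g. '%s')",
                    length(absent), absent[1L]))
  }
  keep <- which(!(records$gene_id %in% excluded))
  cc_log("exclusion list: %d genes removed, %d remain",
         length(records$gene_id) - length(keep), length(keep))
  records[keep]
}
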