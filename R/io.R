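# Readers and writers for the plain-text formats the pipeline consumes and
# produces: allele-count TSVs (two dialects), GMT gene sets, DE summaries,
# exclusion lists, and the ranking / enrichment / sign-test result tables.

.parse_count_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) stopf("empty file: '%s'", path)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stopf("parse error at line %d of '%s': %d fields where %d expected",
          bad, path, nf[bad], nf[1L])
  }
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  gene <- df[[1L]]
  if (anyDuplicated(gene)) {
    stopf("duplicate gene id '%s' in '%s'", gene[duplicated(gene)][1L], path)
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  raw[raw == ""] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw),
                                 dimnames = list(gene, colnames(raw))))
  bad <- which((is.na(num) & !is.na(raw)) |
                 (!is.na(num) & (num < 0 | num != floor(num))),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("parse error at line %d of '%s': '%s' is not a non-negative integer",
          bad[1L, 1L] + 1L, path, raw[bad[1L, , drop = FALSE]])
  }
  num
}

#' Read an allele-count table
#'
#' Two TSV dialects are supported.  `"two-file"` expects two files of
#' identical layout (header of sample ids, first column gene id), one per
#' allele, as produced by splitting a combined ASE release into per-allele
#' count files.  `"paired-column"` expects one file whose count columns
#' come in pairs `<sample>_1`, `<sample>_2` holding the allele-1 and
#' allele-2 counts of each sample.
#'
#' Empty cells are read as `NA` (gene not quantifiable in that sample).
#' Malformed rows and negative or non-integer counts are reported with
#' their line number.
#'
#' @param path File path; a length-2 vector (allele-1 file, allele-2 file)
#'   for the `"two-file"` dialect.
#' @param dialect `"two-file"` or `"paired-column"`; inferred from
#'   `length(path)` when omitted.
#' @return An [allele_count_table()] with row/column order as in the file.
#' @export
read_allele_counts <- function(path,
                               dialect = if (length(path) == 2L) "two-file"
                                         else "paired-column") {
  dialect <- match.arg(dialect, c("two-file", "paired-column"))
  if (dialect == "two-file") {
    if (length(path) != 2L) {
      stopf("'two-file' dialect needs two paths (allele 1, allele 2)")
    }
    m1 <- .parse_count_matrix(path[1L])
    m2 <- .parse_count_matrix(path[2L])
    if (!identical(dimnames(m1), dimnames(m2))) {
      stopf("allele files '%s' and '%s' disagree in gene/sample ids",
            path[1L], path[2L])
    }
    return(allele_count_table(m1, m2))
  }
  m <- .parse_count_matrix(path)
  cn <- colnames(m)
  if (ncol(m) %% 2L != 0L) {
    stopf("'paired-column' dialect needs an even number of count columns")
  }
  i1 <- seq(1L, ncol(m), by = 2L)
  i2 <- i1 + 1L
  base1 <- sub("_1$", "", cn[i1])
  base2 <- sub("_2$", "", cn[i2])
  ok <- grepl("_1$", cn[i1]) & grepl("_2$", cn[i2]) & base1 == base2
  if (!all(ok)) {
    stopf("columns '%s'/'%s' are not a '<sample>_1'/'<sample>_2' pair",
          cn[i1][!ok][1L], cn[i2][!ok][1L])
  }
  m1 <- m[, i1, drop = FALSE]
  m2 <- m[, i2, drop = FALSE]
  colnames(m1) <- colnames(m2) <- base1
  allele_count_table(m1, m2)
}

#' Write an allele-count table
#'
#' @param table An [allele_count_table()].
#' @param path Output path; length 2 for the `"two-file"` dialect.
#' @param dialect See [read_allele_counts()].
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(table, path,
                                dialect = if (length(path) == 2L) "two-file"
                                          else "paired-column") {
  stopifnot(inherits(table, "allele_count_table"))
  dialect <- match.arg(dialect, c("two-file", "paired-column"))
  write_one <- function(m, p) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (dialect == "two-file") {
    if (length(path) != 2L) stopf("'two-file' dialect needs two paths")
    write_one(table$counts1, path[1L])
    write_one(table$counts2, path[2L])
  } else {
    g <- nrow(table$counts1)
    s <- ncol(table$counts1)
    m <- matrix(NA_real_, g, 2L * s)
    m[, seq(1L, 2L * s, 2L)] <- table$counts1
    m[, seq(2L, 2L * s, 2L)] <- table$counts2
    cn <- character(2L * s)
    cn[seq(1L, 2L * s, 2L)] <- paste0(sample_ids(table), "_1")
    cn[seq(2L, 2L * s, 2L)] <- paste0(sample_ids(table), "_2")
    dimnames(m) <- list(gene_ids(table), cn)
    write_one(m, path)
  }
  invisible(path)
}

#' Gene-set collection
#'
#' @param sets Named list of character vectors (set name -> gene ids);
#'   duplicates within a set are removed, empty sets are not allowed.
#' @param source Optional character vector of source-ontology labels, one
#'   per set (recycled if length 1).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stopf("set names must be present and unique")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    stopf("empty gene set: '%s'", names(sets)[lengths(sets) == 0L][1L])
  }
  if (is.null(source)) source <- rep("", length(sets))
  source <- rep_len(as.character(source), length(sets))
  names(source) <- names(sets)
  structure(list(sets = sets, source = source), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %s\n", length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-")
              else "-"))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.  Duplicate
#' genes within a set are dropped; the description field is retained as
#' the set's source label.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()]; empty file gives an empty collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(structure(list(sets = stats::setNames(list(), character()),
                          source = character()),
                     class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stopf("parse error at line %d of '%s': fewer than 3 tab-separated fields",
          short[1L], path)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stopf("duplicate set name '%s' in '%s'", nm[duplicated(nm)][1L], path)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, source = vapply(fields, `[[`, "", 2L))
}

#' Write a gene-set collection as GMT
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$source[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression summary
#'
#' TSV with columns `gene_id`, `mean_log2fc`, `de_fdr` — the externally
#' computed per-gene mean log2 fold change (species 1 over species 2) and
#' its differential-expression FDR.
#'
#' @param path TSV path.
#' @return `data.frame` with those three columns.
#' @export
read_de_summary <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("gene_id", "mean_log2fc", "de_fdr")
  if (!all(need %in% names(df))) {
    stopf("DE summary '%s' must have columns %s", path,
          paste(need, collapse = ", "))
  }
  fdr <- df$de_fdr[!is.na(df$de_fdr)]
  if (any(fdr < 0 | fdr > 1)) stopf("de_fdr outside [0, 1] in '%s'", path)
  df[, need]
}

#' Read a gene exclusion list (one gene id per line)
#' @param path Text file path.
#' @return Character vector of gene ids.
#' @export
read_exclusion_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Write / read a ranked gene list as TSV
#'
#' Columns `gene_id`, `mwu_p`, `score`, `rank`; the ranking kind is kept
#' in a `# ranking_kind:` header comment so the file round-trips.
#'
#' @param ranked A `ranked_gene_list`.
#' @param path Output path.
#' @return `path` (writer) or a `ranked_gene_list` (reader).
#' @export
write_ranked_list <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ranking_kind: %s", attr(ranked, "ranking_kind")), con)
  utils::write.table(as.data.frame(ranked)[, c("gene_id", "mwu_p", "score",
                                               "rank")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- sub("^# ranking_kind: *", "", first)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  out <- data.frame(gene_id = as.character(df$gene_id), score = df$score,
                    mwu_p = df$mwu_p, rank = as.integer(df$rank),
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_gene_list", "data.frame"),
            ranking_kind = kind)
}

#' Write enrichment results as TSV
#'
#' @param results An `enrichment_results` data frame from
#'   [gsea_preranked()]; leading-edge genes are comma-joined.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_results <- function(results, path) {
  df <- as.data.frame(results)
  df$leading_edge <- vapply(results$leading_edge, paste, "", collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sign-test results as TSV
#' @param results Data frame from [run_sign_test()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sign_test_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
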