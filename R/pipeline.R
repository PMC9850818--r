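# End-to-end orchestration: simulate (or read) inputs, build population
# profiles and interspecies records, rank, run enrichment, run the sign
# test, and write every result as TSV plus a JSON run manifest.

#' Pipeline configuration
#'
#' Collects every stage threshold with its default.  Defaults follow the
#' reference analysis: per-allele coverage 10, at least 50 population
#' samples per gene, pseudocount 1, per-allele mean-count filter 25,
#' 1000 permutations with GSEA seed 6, set sizes 10-300, GSEA
#' eligibility FDR 0.25, more than 5 driving genes, BH threshold 0.1.
#'
#' @param min_reads,min_samples,pseudocount Population-profile stage.
#' @param min_mean_count Interspecies expression filter.
#' @param n_perm,gsea_seed,min_size,max_size,weight Enrichment stage.
#' @param gsea_fdr,min_driving_genes,bh_threshold Sign-test stage.
#' @param scale Variance scale for population profiles.
#' @param seed Global seed; stage seeds derive from it by fixed offsets.
#' @param inputs Optional named list of input paths (`population`,
#'   `hybrid`, `de_summary`, `gmt`, and optionally `exclude`,
#'   `scores`); when `NULL` the synthetic module supplies all inputs.
#' @param sim Optional [simulation_config()] used when `inputs` is
#'   `NULL` (default [default_cohort_config()] under `seed`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_reads = 10, min_samples = 50,
                            pseudocount = 1, min_mean_count = 25,
                            n_perm = 1000, gsea_seed = 6, min_size = 10,
                            max_size = 300, weight = 1, gsea_fdr = 0.25,
                            min_driving_genes = 5, bh_threshold = 0.1,
                            scale = "ratio", seed = 1, inputs = NULL,
                            sim = NULL) {
  structure(list(min_reads = min_reads, min_samples = min_samples,
                 pseudocount = pseudocount,
                 min_mean_count = min_mean_count, n_perm = n_perm,
                 gsea_seed = gsea_seed, min_size = min_size,
                 max_size = max_size, weight = weight,
                 gsea_fdr = gsea_fdr,
                 min_driving_genes = min_driving_genes,
                 bh_threshold = bh_threshold, scale = scale, seed = seed,
                 inputs = inputs, sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field of [pipeline_config()] may appear in the file; missing
#' fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stopf("unknown config field '%s' in '%s'", unknown[1L], path)
  }
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (or read) inputs; population profiles;
#' interspecies records with expression and exclusion filters; MWU,
#' DE-FDR, difference-in-ranks and signed rankings; preranked enrichment
#' on the signed ranking; binomial sign test.  Every stage logs its
#' gene counts (with `options(cisconstraint.verbose = TRUE)`), results
#' are written as TSVs under `out_dir`, and `manifest.json` records the
#' configuration, seed and package version.  A failing stage raises an
#' error naming the stage.  Re-running with an identical configuration
#' reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and the output
#'   paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  paths <- list()

  inputs <- stage("inputs", {
    if (is.null(config$inputs)) {
      sim <- config$sim
      if (is.null(sim)) sim <- default_cohort_config(config$seed)
      pop <- generate_population(sim)
      hyb <- generate_hybrid(sim)
      sets <- if (is.null(sim$collection)) {
        generate_gene_sets(sim, n_random = 20)
      } else generate_gene_sets(sim)
      scores <- generate_constraint_scores(sim)
      paths$population <- file.path(out_dir, "population_counts.tsv")
      paths$hybrid <- file.path(out_dir, "hybrid_counts.tsv")
      paths$de_summary <- file.path(out_dir, "de_summary.tsv")
      paths$gmt <- file.path(out_dir, "gene_sets.gmt")
      paths$scores <- file.path(out_dir, "constraint_scores.tsv")
      write_allele_counts(pop, paths$population)
      write_allele_counts(hyb$table, paths$hybrid)
      utils::write.table(hyb$de_summary, paths$de_summary, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_gmt(sets, paths$gmt)
      utils::write.table(as.data.frame(scores), paths$scores, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(population = pop, hybrid = hyb$table,
           de_summary = hyb$de_summary, sets = sets, exclude = character())
    } else {
      inp <- config$inputs
      for (need in c("population", "hybrid", "de_summary", "gmt")) {
        if (is.null(inp[[need]])) stopf("input '%s' missing", need)
        if (!all(file.exists(inp[[need]]))) {
          stopf("input file not found: '%s'", inp[[need]][1L])
        }
      }
      list(population = read_allele_counts(inp$population),
           hybrid = read_allele_counts(inp$hybrid),
           de_summary = read_de_summary(inp$de_summary),
           sets = read_gmt(inp$gmt),
           exclude = if (is.null(inp$exclude)) character()
                     else read_exclusion_list(inp$exclude))
    }
  })

  profiles <- stage("population-dist", {
    p <- build_population_profiles(inputs$population,
                                   min_reads = config$min_reads,
                                   min_samples = config$min_samples,
                                   pseudocount = config$pseudocount,
                                   scale = config$scale)
    paths$profiles <- file.path(out_dir, "population_profiles.tsv")
    utils::write.table(as.data.frame(p), paths$profiles, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p
  })

  records <- stage("hybrid-ase", {
    r <- build_interspecies_records(inputs$hybrid, inputs$de_summary,
                                    pseudocount = config$pseudocount)
    r <- filter_expressed(r, config$min_mean_count)
    if (length(inputs$exclude) > 0L) {
      r <- apply_exclusion_list(r, inputs$exclude)
    }
    paths$records <- file.path(out_dir, "interspecies_records.tsv")
    utils::write.table(as.data.frame(r), paths$records, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    r
  })

  rankings <- stage("rank", {
    mwu <- rank_by_mwu(profiles, records)
    de <- rank_by_de_fdr(records[mwu$gene_id])
    diffr <- diff_in_ranks(mwu, de)
    signed <- rank_by_signed(profiles, records)
    for (nm in c("mwu", "de", "diffr", "signed")) {
      fn <- file.path(out_dir, sprintf("ranking_%s.tsv",
                                       c(mwu = "mwu", de = "de_fdr",
                                         diffr = "diff_in_ranks",
                                         signed = "signed")[[nm]]))
      paths[[paste0("ranking_", nm)]] <- fn
      write_ranked_list(get(nm), fn)
    }
    list(mwu = mwu, de = de, diff = diffr, signed = signed)
  })

  enrichment <- stage("gsea", {
    e <- gsea_preranked(rankings$signed, inputs$sets,
                        n_perm = config$n_perm, seed = config$gsea_seed,
                        min_size = config$min_size,
                        max_size = config$max_size,
                        weight = config$weight)
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
    write_enrichment_results(e, paths$enrichment)
    e
  })

  signtest <- stage("signtest", {
    s <- run_sign_test(enrichment, records, gsea_fdr = config$gsea_fdr,
                       min_driving_genes = config$min_driving_genes,
                       bh_threshold = config$bh_threshold)
    paths$signtest <- file.path(out_dir, "sign_test.tsv")
    write_sign_test_results(s, paths$signtest)
    s
  })

  stage("manifest", {
    paths$manifest <- file.path(out_dir, "manifest.json")
    manifest <- list(
      package = "cisconstraint",
      version = as.character(utils::packageVersion("cisconstraint")),
      seed = config$seed,
      config = config[setdiff(names(config), c("inputs", "sim"))],
      outputs = lapply(paths, basename))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  })

  invisible(list(profiles = profiles, records = records,
                 rankings = rankings, enrichment = enrichment,
                 sign_test = signtest, paths = paths))
}
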