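#' Pipeline configuration
#'
#' Collects input paths and analysis parameters for [run_pipeline()]. Can
#' also be loaded from a YAML file with [read_pipeline_config()].
#'
#' @param ranked_lists Path to the ranked-lists TSV (see
#'   [read_ranked_lists()]).
#' @param comparisons Path to the comparison-records TSV.
#' @param out_dir Output directory (created if absent).
#' @param pools Named character vector of gene-pool file paths (may be
#'   empty).
#' @param annotations Optional path to a hallmark-annotation TSV.
#' @param registry Disease registry (default [disease_registry()]).
#' @param rank_cap Per-disease list depth used in aggregation (default 100).
#' @param top_k Aggregated-list cut for classification and downstream
#'   analysis (default 100).
#' @param threshold Consistency threshold (default 0.60).
#' @param min_classes Dual-purpose minimum class count (default 2).
#' @param var_equal Use the Student instead of the Welch t-test?
#' @param background_size Enrichment background `N` (default 5626).
#' @param stamp Stamp outputs with a timestamp provenance line? Default
#'   `FALSE` so reruns on identical inputs are byte-identical.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ranked_lists, comparisons, out_dir,
                            pools = character(), annotations = NULL,
                            registry = disease_registry(),
                            rank_cap = 100L, top_k = 100L,
                            threshold = 0.60, min_classes = 2L,
                            var_equal = FALSE, background_size = 5626L,
                            stamp = FALSE) {
  cfg <- list(ranked_lists = ranked_lists, comparisons = comparisons,
              out_dir = out_dir, pools = pools, annotations = annotations,
              registry = registry, rank_cap = as.integer(rank_cap),
              top_k = as.integer(top_k), threshold = threshold,
              min_classes = as.integer(min_classes), var_equal = var_equal,
              background_size = as.integer(background_size), stamp = stamp)
  if (cfg$rank_cap < 1L || cfg$top_k < 1L)
    stop("rank_cap and top_k must be >= 1")
  if (cfg$threshold <= 0.5 || cfg$threshold > 1)
    stop("threshold must be in (0.5, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML map directly onto [pipeline_config()]
#' arguments; `pools` is a named map of pool name to file path.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  pools <- if (!is.null(y$pools)) unlist(y$pools) else character()
  args <- y[setdiff(names(y), "pools")]
  do.call(pipeline_config, c(args, list(pools = pools)))
}

#' Run the full analysis on in-memory tables
#'
#' The computational core of [run_pipeline()], free of file IO: aggregation
#' per category, top-k selection, AAD/common classification, expression
#' consistency and the dual-purpose filter on the AAD top list, enrichment
#' against each pool, hallmark summary and candidate selection when
#' annotations are given.
#'
#' Aggregation, classification and everything downstream run once per
#' novelty setting present in `ranked`.
#'
#' @param ranked Ranked-list data.frame (columns `disease`, `novelty`,
#'   `gene`, `rank`) covering both categories.
#' @param comparisons Comparison records.
#' @param registry Disease registry mapping each disease to its category.
#' @param pools List of [gene_pool()] objects (possibly empty).
#' @param annotations Optional hallmark annotation table.
#' @inheritParams pipeline_config
#' @return A named list (one element per novelty) of stage-result lists:
#'   `aggregated_aad`, `aggregated_naad`, `aad_top`, `naad_top`,
#'   `classification`, `profiles`, `dual_calls`, `enrichment`,
#'   `hallmark_summary`, `candidates`.
#' @export
run_analysis <- function(ranked, comparisons, registry = disease_registry(),
                         pools = list(), annotations = NULL,
                         rank_cap = 100L, top_k = 100L, threshold = 0.60,
                         min_classes = 2L, var_equal = FALSE) {
  validate_disease_registry(registry)
  unknown <- setdiff(unique(ranked$disease), registry$disease)
  if (length(unknown))
    stop("ranked lists mention unknown disease(s): ",
         paste(unknown, collapse = ", "))
  cat_of <- stats::setNames(registry$category, registry$disease)
  results <- list()
  for (nov in intersect(NOVELTY_LEVELS, unique(ranked$novelty))) {
    rl <- ranked[ranked$novelty == nov, , drop = FALSE]
    agg_aad <- combine_lists(rl[cat_of[rl$disease] == "AAD", , drop = FALSE],
                             rank_cap = rank_cap)
    agg_naad <- combine_lists(rl[cat_of[rl$disease] == "NAAD", , drop = FALSE],
                              rank_cap = rank_cap)
    aad_top <- select_top(agg_aad, top_k)
    naad_top <- select_top(agg_naad, top_k)
    cls <- classify_targets(aad_top, naad_top)
    profiles <- consistency_profiles(comparisons, genes = aad_top,
                                     threshold = threshold)
    dual <- dual_purpose_filter(profiles, min_classes = min_classes)
    enrich <- lapply(pools, function(p) overlap_and_test(aad_top, p))
    hs <- if (!is.null(annotations)) summarize_hallmarks(annotations, aad_top)
    cand <- if (!is.null(annotations))
      select_candidates(annotations, dual, aad_top)
    results[[nov]] <- list(aggregated_aad = agg_aad,
                           aggregated_naad = agg_naad,
                           aad_top = aad_top, naad_top = naad_top,
                           classification = cls, profiles = profiles,
                           dual_calls = dual, enrichment = enrich,
                           hallmark_summary = hs, candidates = cand)
  }
  if (!length(results)) stop("no recognized novelty setting in ranked lists")
  results
}

#' Run the file-based analysis pipeline
#'
#' Reads every input named in the config, runs [run_analysis()], writes each
#' stage's table as TSV under `out_dir` (per novelty setting), and writes a
#' machine-readable JSON run report with stage counts, parameters and input
#' MD5 hashes. With `stamp = FALSE` (the default) a rerun on identical
#' inputs reproduces every output byte for byte, including the report hash.
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly (a list; also written as
#'   `run_report.json` with its MD5 in `run_report.md5`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ranked <- read_ranked_lists(config$ranked_lists)
  comparisons <- read_comparisons(config$comparisons,
                                  registry = config$registry)
  pools <- lapply(stats::setNames(nm = names(config$pools)), function(nm)
    read_gene_pool(config$pools[[nm]], name = nm,
                   background_size = config$background_size))
  annotations <- if (!is.null(config$annotations))
    read_hallmark_annotations(config$annotations)
  res <- run_analysis(ranked, comparisons, registry = config$registry,
                      pools = pools, annotations = annotations,
                      rank_cap = config$rank_cap, top_k = config$top_k,
                      threshold = config$threshold,
                      min_classes = config$min_classes,
                      var_equal = config$var_equal)
  report <- list(
    parameters = config[c("rank_cap", "top_k", "threshold", "min_classes",
                          "var_equal", "background_size")],
    inputs = c(list(ranked_lists = unname(tools::md5sum(config$ranked_lists)),
                    comparisons = unname(tools::md5sum(config$comparisons))),
               lapply(as.list(config$pools),
                      function(p) unname(tools::md5sum(p))),
               if (!is.null(config$annotations))
                 list(annotations = unname(tools::md5sum(config$annotations)))),
    n_rejected_logfc = attr(comparisons, "n_rejected"),
    stages = list())
  for (nov in names(res)) {
    r <- res[[nov]]
    sub <- file.path(config$out_dir, nov)
    dir.create(sub, showWarnings = FALSE)
    write_tsv(as.data.frame(r$aggregated_aad),
              file.path(sub, "aggregated_AAD.tsv"), stamp = config$stamp)
    write_tsv(as.data.frame(r$aggregated_naad),
              file.path(sub, "aggregated_NAAD.tsv"), stamp = config$stamp)
    write_tsv(as.data.frame(r$classification),
              file.path(sub, "classification.tsv"), stamp = config$stamp)
    write_tsv(r$profiles, file.path(sub, "consistency_profiles.tsv"),
              stamp = config$stamp)
    write_tsv(r$dual_calls, file.path(sub, "dual_purpose.tsv"),
              stamp = config$stamp)
    if (length(r$enrichment)) {
      enr <- do.call(rbind, lapply(names(r$enrichment), function(nm) {
        df <- as.data.frame(r$enrichment[[nm]])
        cbind(pool = nm, df)
      }))
      write_tsv(enr, file.path(sub, "enrichment.tsv"), stamp = config$stamp)
    }
    if (!is.null(r$candidates))
      write_tsv(r$candidates, file.path(sub, "candidates.tsv"),
                stamp = config$stamp)
    report$stages[[nov]] <- list(
      n_aggregated_aad = nrow(r$aggregated_aad),
      n_aggregated_naad = nrow(r$aggregated_naad),
      n_aad_top = length(r$aad_top),
      n_aad_specific = length(r$classification$aad_specific),
      n_common = length(r$classification$common),
      n_naad_specific = length(r$classification$naad_specific),
      n_profiles = nrow(r$profiles),
      n_dual_purpose = length(unique(r$dual_calls$gene)),
      n_candidates = if (!is.null(r$candidates))
        length(unique(r$candidates$gene)) else NA_integer_,
      enrichment = lapply(r$enrichment, function(e)
        list(N = e$N, K = e$K, n = e$n, r = e$r, expected = e$expected,
             fold = e$fold, p_value = e$p_value)))
  }
  report_path <- file.path(config$out_dir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(unname(tools::md5sum(report_path)),
             file.path(config$out_dir, "run_report.md5"))
  invisible(report)
}

#' Write a simulation to disk as pipeline-ready input files
#'
#' Emits the ranked-list TSV, comparison TSV, ground-truth TSV and a config
#' echo (JSON) into `out_dir`; the two data files are readable by
#' [read_ranked_lists()] and [read_comparisons()] with zero rejections.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param stamp Stamp a timestamp provenance line? Default `FALSE` so a
#'   fixed seed gives byte-identical files.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(config, out_dir, stamp = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- gen_ranked_lists(config)
  rec <- gen_comparisons(config, sim$truth)
  paths <- c(ranked_lists = file.path(out_dir, "ranked_lists.tsv"),
             comparisons = file.path(out_dir, "comparisons.tsv"),
             truth = file.path(out_dir, "ground_truth.tsv"),
             config = file.path(out_dir, "sim_config.json"))
  write_tsv(sim$ranked, paths[["ranked_lists"]], stamp = stamp)
  write_tsv(rec[, c("gene", "comparison_id", "disease", "logfc")],
            paths[["comparisons"]], stamp = stamp)
  truth_df <- rbind(
    cbind(sim$truth$planted_aad, set = "planted_aad"),
    cbind(sim$truth$planted_common, set = "planted_common"),
    data.frame(gene = sim$truth$null_genes, direction = 0L, set = "null"))
  write_tsv(truth_df, paths[["truth"]], stamp = stamp)
  cfg <- unclass(config)
  cfg$diseases <- NULL
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Planted-signal recovery on one simulated dataset
#'
#' Chains the analysis stages on a fresh simulation from `config`:
#' aggregate both categories, select top-k, classify, profile consistency
#' and apply the dual-purpose filter on the AAD-specific set. Recovery
#' is judged against the simulation's planted ground truth, and the
#' recovered AAD top list is tested for enrichment in a pool built from the
#' planted genes plus random null fillers.
#'
#' @param config A [sim_config()].
#' @param top_k Aggregated-list cut (default 100).
#' @param threshold,min_classes Consistency-filter settings.
#' @param pool_fillers Number of random null genes padded into the
#'   planted-gene pool for the enrichment check (default 40).
#' @return A one-row data.frame: `seed`, `sensitivity` (planted AAD genes
#'   recovered in the AAD-specific dual-purpose set, as a fraction),
#'   `fpr` (null genes so recovered, over all null genes), `fold` and
#'   `p_value` of the planted-pool enrichment, plus the raw counts.
#' @export
recover_planted <- function(config, top_k = 100L, threshold = 0.60,
                            min_classes = 2L, pool_fillers = 40L) {
  sim <- gen_ranked_lists(config)
  rec <- gen_comparisons(config, sim$truth)
  cat_of <- stats::setNames(config$diseases$category,
                            config$diseases$disease)
  rl <- sim$ranked
  aad_top <- select_top(
    combine_lists(rl[cat_of[rl$disease] == "AAD", , drop = FALSE],
                  rank_cap = config$list_depth), top_k)
  naad_top <- select_top(
    combine_lists(rl[cat_of[rl$disease] == "NAAD", , drop = FALSE],
                  rank_cap = config$list_depth), top_k)
  cls <- classify_targets(aad_top, naad_top)
  profiles <- consistency_profiles(rec, genes = cls$aad_specific,
                                   threshold = threshold)
  dual <- dual_purpose_filter(profiles, min_classes = min_classes)
  recovered <- intersect(cls$aad_specific, dual$gene)
  planted <- sim$truth$planted_aad$gene
  nulls <- sim$truth$null_genes
  with_substream(config$seed, "pool-fillers", {
    fillers <- sample(nulls, min(pool_fillers, length(nulls)))
  })
  pool <- gene_pool("planted", c(planted, sim$truth$planted_common$gene,
                                 fillers),
                    background_size = config$n_genes)
  enr <- overlap_and_test(aad_top, pool)
  data.frame(seed = config$seed,
             sensitivity = length(intersect(recovered, planted)) /
               length(planted),
             fpr = length(intersect(recovered, nulls)) / length(nulls),
             n_recovered = length(recovered),
             n_aad_specific = length(cls$aad_specific),
             fold = enr$fold, p_value = enr$p_value)
}

#' Multi-seed recovery benchmark
#'
#' Runs [recover_planted()] over several seeds of the same configuration and
#' averages sensitivity and false-positive rate.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param ... Arguments forwarded to [sim_config()] (other than `seed`).
#' @return A list with the per-seed data.frame `runs` and scalar summaries
#'   `mean_sensitivity`, `mean_fpr`, `frac_enriched` (fraction of seeds with
#'   fold > 1 and p < 0.01).
#' @export
run_recovery <- function(seeds, ...) {
  runs <- do.call(rbind, lapply(seeds, function(s)
    recover_planted(sim_config(seed = s, ...))))
  list(runs = runs,
       mean_sensitivity = mean(runs$sensitivity),
       mean_fpr = mean(runs$fpr),
       frac_enriched = mean(runs$fold > 1 & runs$p_value < 0.01))
}
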