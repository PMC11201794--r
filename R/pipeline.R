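# Umbrella orchestration: simulate/read -> preprocess -> per-cohort DE ->
# meta-analysis -> signature -> validation scoring -> enrichment, with a JSON
# run manifest.

#' Pipeline configuration
#'
#' @param fixture_dir directory holding a multi-cohort fixture as written by
#'   [write_fixture()] (`*_expression.tsv`, `*_phenotype.tsv`,
#'   `probe_map.tsv`). Ignored when `simulate` is given.
#' @param simulate optional [synthetic_config()]; when given, cohorts are
#'   generated in memory instead of read from `fixture_dir`.
#' @param out_dir output directory for all stage TSVs and the run manifest
#'   (created if missing).
#' @param gmt_path,hierarchy_path optional pathway catalog files for the
#'   enrichment stage; enrichment is skipped when `gmt_path` is `NULL`.
#' @param es_min,fdr_max,min_cohorts signature-selection thresholds (see
#'   [select_signature()]); `min_cohorts` is also the measurement filter for
#'   [run_meta()] and the shared-DEG threshold is `min(min_cohorts - 1,
#'   n cohorts)` unless `shared_min` is given.
#' @param shared_min minimum cohorts for [count_shared_degs()] (default 4).
#' @param deg_mode DEG threshold mode (see [call_degs()]).
#' @param offset pseudo-count for [ensure_log2()].
#' @param seed integer seed recorded in the manifest (and used for
#'   simulation).
#'
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(fixture_dir = NULL, simulate = NULL, out_dir,
                            gmt_path = NULL, hierarchy_path = NULL,
                            es_min = 1, fdr_max = 0.05, min_cohorts = 5L,
                            shared_min = 4L, deg_mode = "auto", offset = 1,
                            seed = 1L) {
  if (is.null(fixture_dir) && is.null(simulate))
    stop_field("fixture_dir", "either fixture_dir or simulate must be given")
  if (!is_number(fdr_max) || fdr_max <= 0 || fdr_max > 1)
    stop_field("fdr_max", "must be in (0, 1]")
  if (!is_number(es_min) || es_min < 0) stop_field("es_min", "must be >= 0")
  if (!is_count(min_cohorts)) stop_field("min_cohorts", "must be >= 1")
  if (!is_count(shared_min)) stop_field("shared_min", "must be >= 1")
  deg_mode <- match.arg(deg_mode, c("auto", "stringent", "relaxed", "fc_only"))
  structure(list(fixture_dir = fixture_dir, simulate = simulate,
                 out_dir = out_dir, gmt_path = gmt_path,
                 hierarchy_path = hierarchy_path, es_min = es_min,
                 fdr_max = fdr_max, min_cohorts = as.integer(min_cohorts),
                 shared_min = as.integer(shared_min), deg_mode = deg_mode,
                 offset = offset, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @noRd
load_fixture_cohorts <- function(dir) {
  expr_files <- sort(list.files(dir, pattern = "_expression\\.tsv$",
                                full.names = TRUE))
  if (!length(expr_files))
    stop(sprintf("no *_expression.tsv files found in %s", dir), call. = FALSE)
  cohorts <- lapply(expr_files, function(ep) {
    cid <- sub("_expression\\.tsv$", "", basename(ep))
    pp <- file.path(dir, sprintf("%s_phenotype.tsv", cid))
    read_cohort(ep, pp, cid)
  })
  probe_map <- read_probe_map(file.path(dir, "probe_map.tsv"))
  list(cohorts = cohorts, probe_map = probe_map)
}

#' Run the full multi-cohort pipeline
#'
#' Stages, in order: load or simulate cohorts; per-cohort preprocessing
#' (log2, quantile normalization, probe collapsing) and PCA QC; per-cohort
#' differential expression; shared-DEG counting; cross-cohort meta-analysis
#' over the cohorts with at least 2 samples per arm; signature selection;
#' geometric-mean signature scoring of every cohort (including those not
#' eligible for meta-analysis); optional pathway over-representation of the
#' signature with ancestor roll-up and per-cohort DEG enrichment counts.
#' Each stage writes a TSV under `out_dir`; a JSON manifest records the seed,
#' thresholds and per-stage row counts. A stage failure aborts with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  stage <- "load"
  manifest <- list(seed = config$seed,
                   thresholds = list(es_min = config$es_min,
                                     fdr_max = config$fdr_max,
                                     min_cohorts = config$min_cohorts,
                                     shared_min = config$shared_min,
                                     deg_mode = config$deg_mode),
                   stages = list(), files = list())
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  loaded <- run_stage("load", {
    if (!is.null(config$simulate)) {
      sim <- generate_multicohort(config$simulate)
      list(cohorts = sim$cohorts, probe_map = sim$probe_map)
    } else load_fixture_cohorts(config$fixture_dir)
  })
  cohorts <- loaded$cohorts
  manifest$stages$load <- list(n_cohorts = length(cohorts),
                               n_probes = nrow(cohorts[[1]]$matrix))

  prepped <- run_stage("preprocess", lapply(cohorts, preprocess_cohort,
                                            probe_map = loaded$probe_map,
                                            offset = config$offset))
  pca <- run_stage("preprocess", do.call(rbind, lapply(prepped, function(cd) {
    n_comp <- min(2L, ncol(cd$matrix) - 1L)
    fr <- pca_explained(cd$matrix, n_comp)
    data.frame(cohort_id = cd$cohort_id, pc1 = fr[1],
               pc2 = if (n_comp > 1L) fr[2] else NA_real_,
               pc12_pct = 100 * sum(fr), stringsAsFactors = FALSE)
  })))
  write_tsv(pca, out("pca_explained.tsv"))
  manifest$stages$preprocess <- list(n_genes = nrow(prepped[[1]]$matrix))
  manifest$files$pca <- out("pca_explained.tsv")

  de_tables <- run_stage("de", {
    tabs <- lapply(prepped, cohort_de, mode = config$deg_mode)
    names(tabs) <- vapply(prepped, `[[`, "", "cohort_id")
    for (cid in names(tabs))
      write_tsv(tabs[[cid]], out(sprintf("de_%s.tsv", cid)))
    tabs
  })
  manifest$stages$de <- lapply(de_tables, function(d)
    list(n_degs = sum(d$deg_call != "none"), mode = d$threshold_mode[1]))

  shared <- run_stage("shared_degs", count_shared_degs(
    de_tables, min_cohorts = min(config$shared_min, length(de_tables))))
  write_tsv(shared, out("shared_degs.tsv"))
  manifest$stages$shared_degs <- list(n_genes = nrow(shared))
  manifest$files$shared_degs <- out("shared_degs.tsv")

  eligible <- vapply(prepped, function(cd)
    sum(cd$groups == "treated") >= 2L && sum(cd$groups == "control") >= 2L, TRUE)
  meta <- run_stage("meta", {
    if (sum(eligible) < config$min_cohorts)
      stop(sprintf("only %d cohort(s) eligible but min_cohorts = %d",
                   sum(eligible), config$min_cohorts))
    run_meta(prepped[eligible], min_cohorts_measured = config$min_cohorts)
  })
  write_tsv(meta, out("meta.tsv"))
  manifest$stages$meta <- list(n_genes = nrow(meta),
                               n_cohorts = sum(eligible))
  manifest$files$meta <- out("meta.tsv")

  signature <- run_stage("signature", select_signature(
    meta, es_min = config$es_min, fdr_max = config$fdr_max,
    min_cohorts = config$min_cohorts))
  write_tsv(as.data.frame(signature), out("signature.tsv"))
  manifest$stages$signature <- list(n_genes = nrow(signature))
  manifest$files$signature <- out("signature.tsv")

  scores <- run_stage("score", {
    if (nrow(signature)) {
      do.call(rbind, lapply(prepped, score_summary, signature = signature))
    } else data.frame()
  })
  write_tsv(scores, out("signature_scores.tsv"))
  manifest$stages$score <- list(n_cohorts = nrow(scores))
  manifest$files$scores <- out("signature_scores.tsv")

  if (!is.null(config$gmt_path)) {
    enr <- run_stage("enrich", {
      hierarchy <- if (!is.null(config$hierarchy_path))
        read_hierarchy(config$hierarchy_path) else NULL
      catalog <- read_gmt(config$gmt_path, hierarchy)
      universe <- meta$gene
      sig_res <- if (nrow(signature))
        hypergeom_ora(intersect(signature$gene, universe), catalog, universe)
      else NULL
      empty_ora <- data.frame(pathway_id = character(), p_adj = numeric(),
                              stringsAsFactors = FALSE)
      per_cohort <- lapply(de_tables[eligible], function(d) {
        degs <- intersect(d$gene[d$deg_call != "none"], universe)
        if (length(degs)) hypergeom_ora(degs, catalog, universe) else empty_ora
      })
      counts <- cross_cohort_pathway_counts(per_cohort, fdr_max = config$fdr_max)
      list(signature = sig_res, counts = counts,
           rollup = if (!is.null(hierarchy) && !is.null(sig_res) && nrow(sig_res))
             rollup_ancestors(sig_res, catalog) else NULL)
    })
    if (!is.null(enr$signature)) {
      write_tsv(enr$signature, out("enrichment_signature.tsv"))
      manifest$files$enrichment <- out("enrichment_signature.tsv")
    }
    write_tsv(enr$counts, out("pathway_cohort_counts.tsv"))
    manifest$files$pathway_counts <- out("pathway_cohort_counts.tsv")
    if (!is.null(enr$rollup)) {
      write_tsv(enr$rollup, out("ancestor_rollup.tsv"))
      manifest$files$rollup <- out("ancestor_rollup.tsv")
    }
    manifest$stages$enrich <- list(
      n_signature_pathways = if (is.null(enr$signature)) 0L else nrow(enr$signature),
      n_counted_pathways = nrow(enr$counts))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
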