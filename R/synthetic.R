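#' Configuration for the synthetic multi-cohort generator
#'
#' Describes a simulated collection of two-arm (control vs treated) expression
#' cohorts with a planted set of up-regulated signature genes. The generator
#' emulates log2-scale microarray intensity matrices: per-gene Gaussian
#' baselines, per-gene/per-cohort sample noise with a heavy-ish spread of
#' variances (so variance moderation is non-trivial), multiple probes per gene
#' with independent probe-level noise, and standardized planted effects with
#' optional between-cohort heterogeneity.
#'
#' @param n_cohorts number of cohorts to simulate.
#' @param per_cohort_n list of `c(n_control, n_treated)` integer pairs, one per
#'   cohort; both entries must be >= 1.
#' @param n_genes number of genes.
#' @param n_signature number of planted (up-regulated) signature genes;
#'   must not exceed `n_genes`.
#' @param delta planted standardized mean shift, in units of the within-cohort
#'   per-sample standard deviation.
#' @param tau2 between-cohort variance of the planted standardized effect
#'   (each cohort draws its own effect from `Normal(delta, tau2)`).
#' @param probes_per_gene number of probes measuring each gene (scalar, or a
#'   length-`n_genes` vector).
#' @param baseline_mean,baseline_sd location and spread of per-gene baseline
#'   log2 intensities.
#' @param probe_noise_sd standard deviation of independent probe-level noise
#'   added on top of the latent gene value (log2 scale).
#' @param mixed_directions if `TRUE`, each signature gene is planted with a
#'   random sign instead of up-only.
#' @param probe_dropout fraction of genes whose probes are dropped per cohort
#'   (cohort-specific probe subsets, exercising missing-gene handling).
#' @param seed integer seed; the generator is bit-reproducible given the
#'   config.
#'
#' @return an object of class `synthetic_config`.
#' @seealso [generate_multicohort()]
#' @export
synthetic_config <- function(n_cohorts = 5L,
                             per_cohort_n = rep(list(c(4L, 4L)), n_cohorts),
                             n_genes = 1000L,
                             n_signature = 50L,
                             delta = 2,
                             tau2 = 0,
                             probes_per_gene = 3L,
                             baseline_mean = 7.5,
                             baseline_sd = 1.5,
                             probe_noise_sd = 0.1,
                             mixed_directions = FALSE,
                             probe_dropout = 0,
                             seed = 1L) {
  if (!is_count(n_cohorts)) stop_field("n_cohorts", "must be a positive integer")
  if (!is.list(per_cohort_n) || length(per_cohort_n) != n_cohorts)
    stop_field("per_cohort_n", sprintf("must be a list of %d (n_control, n_treated) pairs", n_cohorts))
  for (p in per_cohort_n) {
    if (length(p) != 2L || !all(vapply(p, is_count, TRUE)))
      stop_field("per_cohort_n", "every pair must have both entries >= 1")
  }
  if (!is_count(n_genes)) stop_field("n_genes", "must be a positive integer")
  if (!is_count(n_signature, min = 0L)) stop_field("n_signature", "must be a non-negative integer")
  if (n_signature > n_genes) stop_field("n_signature", "must not exceed n_genes")
  if (!is_number(delta)) stop_field("delta", "must be a finite real")
  if (!is_number(tau2) || tau2 < 0) stop_field("tau2", "must be a non-negative real")
  if (length(probes_per_gene) == 1L) probes_per_gene <- rep(as.integer(probes_per_gene), n_genes)
  if (length(probes_per_gene) != n_genes || !all(vapply(probes_per_gene, is_count, TRUE)))
    stop_field("probes_per_gene", "must be a positive integer or a length-n_genes vector of them")
  if (!is_number(baseline_mean)) stop_field("baseline_mean", "must be a finite real")
  if (!is_number(baseline_sd) || baseline_sd <= 0) stop_field("baseline_sd", "must be > 0")
  if (!is_number(probe_noise_sd) || probe_noise_sd < 0) stop_field("probe_noise_sd", "must be >= 0")
  if (!is_number(probe_dropout) || probe_dropout < 0 || probe_dropout >= 1)
    stop_field("probe_dropout", "must be in [0, 1)")
  if (!is_count(seed, min = -.Machine$integer.max)) stop_field("seed", "must be an integer")

  structure(
    list(n_cohorts = as.integer(n_cohorts),
         per_cohort_n = lapply(per_cohort_n, as.integer),
         n_genes = as.integer(n_genes),
         n_signature = as.integer(n_signature),
         delta = delta, tau2 = tau2,
         probes_per_gene = as.integer(probes_per_gene),
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         probe_noise_sd = probe_noise_sd,
         mixed_directions = isTRUE(mixed_directions),
         probe_dropout = probe_dropout,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Bundle an expression matrix with its group labels
#'
#' @param matrix numeric matrix, features x samples, with dimnames.
#' @param groups named character vector mapping every sample (column) to
#'   `"control"` or `"treated"`.
#' @param cohort_id cohort identifier.
#' @param scale `"log2"` or `"raw"`; stored as an attribute on the matrix.
#'
#' @return an object of class `cohort_dataset` with elements `matrix`,
#'   `groups`, `cohort_id`.
#' @export
cohort_dataset <- function(matrix, groups, cohort_id, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (is.null(colnames(matrix)) || is.null(rownames(matrix)))
    stop_field("matrix", "must carry feature and sample dimnames")
  if (anyDuplicated(colnames(matrix))) stop_field("matrix", "duplicated sample ids")
  if (anyDuplicated(rownames(matrix))) stop_field("matrix", "duplicated feature ids")
  missing <- setdiff(colnames(matrix), names(groups))
  if (length(missing))
    stop_field("groups", paste0("no group label for sample(s): ",
                                paste(missing, collapse = ", ")))
  groups <- groups[colnames(matrix)]
  if (!all(groups %in% c("control", "treated")))
    stop_field("groups", "labels must be 'control' or 'treated'")
  if (!all(c("control", "treated") %in% groups))
    stop_field("groups", "need at least 1 sample per group")
  attr(matrix, "scale") <- scale
  structure(list(matrix = matrix, groups = groups, cohort_id = cohort_id),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %s: %d features x %d samples (%d control / %d treated), %s scale\n",
              x$cohort_id, nrow(x$matrix), ncol(x$matrix),
              sum(x$groups == "control"), sum(x$groups == "treated"),
              attr(x$matrix, "scale") %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic multi-cohort expression collection with known truth
#'
#' Simulates `n_cohorts` probe-level log2 expression matrices. Each gene g has
#' a baseline `Normal(baseline_mean, baseline_sd^2)`; per cohort, a per-sample
#' noise variance is drawn from a scaled inverse chi-squared spread; signature
#' genes shift the treated arm by `delta_gk * sigma` with
#' `delta_gk ~ Normal(delta, tau2)`. Each gene is expanded into
#' `probes_per_gene` probe rows with independent `Normal(0, probe_noise_sd^2)`
#' probe noise.
#'
#' @param config a [synthetic_config()].
#'
#' @return a list with elements:
#'   * `cohorts`: list of [cohort_dataset()] objects (probe-level, log2 scale);
#'     each also carries the latent gene-level matrix in `$latent` for
#'     validation against the generator truth.
#'   * `truth`: list with `signature_genes` (character) and
#'     `per_cohort_effects` (`data.frame(gene_symbol, cohort_id, true_effect)`
#'     over signature genes; non-signature genes have effect exactly 0).
#'   * `probe_map`: `data.frame(probe_id, gene_symbol)`.
#' @export
generate_multicohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  with_seed(config$seed, {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    sig_idx <- if (config$n_signature > 0L)
      sort(sample.int(config$n_genes, config$n_signature)) else integer(0)
    sig_genes <- genes[sig_idx]
    sig_sign <- if (config$mixed_directions)
      sample(c(-1, 1), length(sig_idx), replace = TRUE) else rep(1, length(sig_idx))

    baseline <- rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)

    probe_id <- unlist(lapply(seq_len(config$n_genes), function(i)
      sprintf("%s_p%02d", genes[i], seq_len(config$probes_per_gene[i]))),
      use.names = FALSE)
    probe_gene <- rep(genes, times = config$probes_per_gene)
    probe_map <- data.frame(probe_id = probe_id, gene_symbol = probe_gene,
                            stringsAsFactors = FALSE)

    # per-sample noise SD: sigma_g^2 ~ s0^2 * d0 / chi^2_d0 (scaled inverse
    # chi-squared), giving a realistic spread of gene-wise variances
    d0 <- 10; s0 <- 0.5

    truth_rows <- vector("list", config$n_cohorts)
    cohorts <- vector("list", config$n_cohorts)
    for (k in seq_len(config$n_cohorts)) {
      cid <- sprintf("C%02d", k)
      nc <- config$per_cohort_n[[k]][1]
      nt <- config$per_cohort_n[[k]][2]
      sigma <- s0 * sqrt(d0 / rchisq(config$n_genes, df = d0))

      delta_k <- numeric(config$n_genes)
      if (length(sig_idx)) {
        delta_k[sig_idx] <- sig_sign *
          rnorm(length(sig_idx), mean = config$delta, sd = sqrt(config$tau2))
      }

      n <- nc + nt
      noise <- matrix(rnorm(config$n_genes * n), config$n_genes, n) * sigma
      latent <- baseline + noise
      latent[, (nc + 1):n] <- latent[, (nc + 1):n] + delta_k * sigma

      samples <- c(sprintf("%s_ctrl%02d", cid, seq_len(nc)),
                   sprintf("%s_trt%02d", cid, seq_len(nt)))
      dimnames(latent) <- list(genes, samples)

      expr <- latent[probe_gene, , drop = FALSE] +
        matrix(rnorm(length(probe_id) * n, sd = config$probe_noise_sd),
               length(probe_id), n)
      dimnames(expr) <- list(probe_id, samples)

      if (config$probe_dropout > 0) {
        drop_genes <- sample(genes, floor(config$probe_dropout * config$n_genes))
        keep <- !(probe_gene %in% drop_genes)
        expr <- expr[keep, , drop = FALSE]
      }

      groups <- setNames(rep(c("control", "treated"), c(nc, nt)), samples)
      cd <- cohort_dataset(expr, groups, cid, scale = "log2")
      cd$latent <- latent
      cohorts[[k]] <- cd

      truth_rows[[k]] <- data.frame(
        gene_symbol = sig_genes, cohort_id = rep(cid, length(sig_genes)),
        true_effect = delta_k[sig_idx], stringsAsFactors = FALSE)
    }

    truth <- list(
      signature_genes = sig_genes,
      per_cohort_effects = do.call(rbind, truth_rows) %||%
        data.frame(gene_symbol = character(), cohort_id = character(),
                   true_effect = numeric()))
    list(cohorts = cohorts, truth = truth, probe_map = probe_map,
         config = config)
  })
}

#' Write a synthetic multi-cohort fixture to disk
#'
#' Emits, per cohort, an expression TSV (probes x samples, first column
#' `probe_id`) and a phenotype TSV (`sample_id`, `group`), plus one shared
#' probe map TSV and one ground-truth TSV. Files round-trip losslessly
#' through [read_expression()] and friends.
#'
#' @param sim result of [generate_multicohort()].
#' @param directory output directory; must exist unless `create = TRUE`.
#' @param create create the directory if missing.
#'
#' @return named list (manifest) of written file paths: `expression` and
#'   `phenotype` (one per cohort), `probe_map`, `ground_truth`.
#' @export
write_fixture <- function(sim, directory, create = FALSE) {
  if (!dir.exists(directory)) {
    if (!create) stop(sprintf("directory does not exist: %s", directory), call. = FALSE)
    dir.create(directory, recursive = TRUE)
  }
  expr_paths <- character(0)
  pheno_paths <- character(0)
  for (cd in sim$cohorts) {
    ep <- file.path(directory, sprintf("%s_expression.tsv", cd$cohort_id))
    pp <- file.path(directory, sprintf("%s_phenotype.tsv", cd$cohort_id))
    write_expression(cd$matrix, ep)
    write_tsv(data.frame(sample_id = names(cd$groups), group = unname(cd$groups),
                         stringsAsFactors = FALSE), pp)
    expr_paths <- c(expr_paths, setNames(ep, cd$cohort_id))
    pheno_paths <- c(pheno_paths, setNames(pp, cd$cohort_id))
  }
  map_path <- file.path(directory, "probe_map.tsv")
  write_tsv(sim$probe_map, map_path)
  truth_path <- file.path(directory, "ground_truth.tsv")
  write_tsv(sim$truth$per_cohort_effects, truth_path)
  list(expression = expr_paths, phenotype = pheno_paths,
       probe_map = map_path, ground_truth = truth_path)
}

#' Build a toy pathway catalog around a synthetic simulation
#'
#' Constructs a small [pathway_catalog()] in which one pathway contains the
#' simulation's planted signature genes and the remaining pathways are random
#' draws from the null genes, plus a two-level hierarchy mapping every pathway
#' to one of two top-level ancestors. Intended for end-to-end enrichment
#' checks with known truth.
#'
#' @param sim result of [generate_multicohort()] (must have planted genes).
#' @param n_null_sets number of random null pathways.
#' @param set_size size of each null pathway.
#' @param seed RNG seed for the null draws.
#'
#' @return a `pathway_catalog` whose first set, `PW_SIGNATURE`, is the planted
#'   gene set.
#' @export
synthetic_pathway_catalog <- function(sim, n_null_sets = 10L, set_size = 25L,
                                      seed = 1L) {
  sig <- sim$truth$signature_genes
  if (!length(sig)) stop("simulation has no planted signature genes", call. = FALSE)
  all_genes <- unique(sim$probe_map$gene_symbol)
  null_pool <- setdiff(all_genes, sig)
  with_seed(seed, {
    sets <- c(list(PW_SIGNATURE = sig),
              setNames(lapply(seq_len(n_null_sets), function(i)
                sample(null_pool, min(set_size, length(null_pool)))),
                sprintf("PW_NULL%02d", seq_len(n_null_sets))))
    descriptions <- setNames(c("planted signature pathway",
                               sprintf("random null pathway %d", seq_len(n_null_sets))),
                             names(sets))
    hierarchy <- data.frame(
      child_id = names(sets),
      parent_id = c("ROOT_A", rep(c("ROOT_A", "ROOT_B"),
                                  length.out = n_null_sets)),
      stringsAsFactors = FALSE)
    pathway_catalog(sets, descriptions, hierarchy)
  })
}
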