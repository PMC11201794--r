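# Per-gene cross-cohort meta-analysis: Hedges' adjusted g, DerSimonian-Laird
# random-effects pooling, Cochran's Q, directional Fisher sum-of-logs
# combination, signature selection and geometric-mean validation scoring.

#' Hedges' adjusted g for one gene in one cohort
#'
#' Standardized mean difference `d = (mean_t - mean_c) / s_p` with the
#' df-weighted pooled standard deviation (`df = n_t + n_c - 2`), corrected by
#' the small-sample factor `J = 1 - 3 / (4*df - 1)`, so `g = J * d`. Sampling
#' variance uses the common large-sample form
#' `var_g = (n_t + n_c)/(n_t*n_c) + g^2 / (2*(n_t + n_c))`.
#'
#' @param treated,control numeric vectors of log2 expression values, at least
#'   2 per arm.
#' @return one-row `data.frame(g, var_g, n_t, n_c)`.
#' @export
hedges_g <- function(treated, control) {
  n_t <- length(treated); n_c <- length(control)
  if (n_t < 2L || n_c < 2L) stop("need at least 2 values per arm", call. = FALSE)
  df <- n_t + n_c - 2L
  sp2 <- ((n_t - 1) * var(treated) + (n_c - 1) * var(control)) / df
  if (sp2 <= 0)
    stop(errorCondition("zero pooled variance: effect size undefined",
                        class = "metacohort_zero_variance"))
  d <- (mean(treated) - mean(control)) / sqrt(sp2)
  J <- 1 - 3 / (4 * df - 1)
  g <- J * d
  var_g <- (n_t + n_c) / (n_t * n_c) + g^2 / (2 * (n_t + n_c))
  data.frame(g = g, var_g = var_g, n_t = n_t, n_c = n_c)
}

#' DerSimonian-Laird random-effects pooling of one gene's effects
#'
#' Fixed-effect weights `w_i = 1/var_i` give Cochran's
#' `Q = sum w_i (g_i - g_bar_w)^2`; the between-study variance is
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random-effects
#' weights `1/(var_i + tau2)` then give the pooled effect and its SE.
#'
#' @param g numeric vector of per-cohort effect sizes.
#' @param var_g numeric vector of their sampling variances (all > 0).
#'
#' @return `list(es_pooled, se_pooled, tau2, q_stat, k)`. A single effect
#'   (k = 1) is passed through with `tau2 = 0` and `q_stat = 0`, flagged by a
#'   warning.
#' @export
dl_pool <- function(g, var_g) {
  if (length(g) != length(var_g)) stop("g and var_g lengths differ", call. = FALSE)
  if (any(var_g <= 0)) stop("all sampling variances must be > 0", call. = FALSE)
  k <- length(g)
  if (k == 1L) {
    warning("single-cohort gene: pooled effect is the lone effect (tau2 = 0)")
    return(list(es_pooled = g, se_pooled = sqrt(var_g), tau2 = 0, q_stat = 0, k = 1L))
  }
  w <- 1 / var_g
  gw <- sum(w * g) / sum(w)
  q <- sum(w * (g - gw)^2)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (k - 1)) / c_dl)
  ws <- 1 / (var_g + tau2)
  list(es_pooled = sum(ws * g) / sum(ws),
       se_pooled = 1 / sqrt(sum(ws)),
       tau2 = tau2, q_stat = q, k = k)
}

#' Cochran's Q heterogeneity test for one gene
#'
#' @inheritParams dl_pool
#' @return `list(q_stat, q_pvalue)` with the p-value from the upper tail of
#'   chi-squared with k - 1 degrees of freedom.
#' @export
cochran_q <- function(g, var_g) {
  if (length(g) < 2L) stop("need at least 2 cohorts for a heterogeneity test",
                           call. = FALSE)
  pool <- dl_pool(g, var_g)
  list(q_stat = pool$q_stat,
       q_pvalue = pchisq(pool$q_stat, df = length(g) - 1L, lower.tail = FALSE))
}

#' One-sided p-values of a standardized effect
#'
#' Normal approximation `z = g / sqrt(var_g)`: `p_up = 1 - Phi(z)`,
#' `p_down = Phi(z)`; the two always sum to 1.
#'
#' @inheritParams dl_pool
#' @return `data.frame(p_up, p_down)` (vectorized over the inputs).
#' @export
one_sided_pvalues <- function(g, var_g) {
  if (any(var_g <= 0)) stop("var_g must be > 0", call. = FALSE)
  z <- g / sqrt(var_g)
  data.frame(p_up = pnorm(z, lower.tail = FALSE), p_down = pnorm(z))
}

#' Fisher's sum-of-logs combination of p-values
#'
#' `X = -2 * sum(log p_i)` referred to the upper tail of chi-squared with
#' `2k` degrees of freedom. Zero p-values are clamped to `p_floor` with a
#' warning.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @param p_floor positive floor applied to zero inputs (default 1e-300).
#' @return `list(fisher_stat, combined_p)`.
#' @export
fisher_combine <- function(p_values, p_floor = 1e-300) {
  if (!length(p_values)) stop("need at least one p-value", call. = FALSE)
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]", call. = FALSE)
  if (any(p_values == 0)) {
    warning(sprintf("zero p-value(s) clamped to %g", p_floor))
    p_values <- pmax(p_values, p_floor)
  }
  x <- -2 * sum(log(p_values))
  list(fisher_stat = x,
       combined_p = pchisq(x, df = 2 * length(p_values), lower.tail = FALSE))
}

#' Cross-cohort random-effects meta-analysis of all genes
#'
#' For every gene measured in at least `min_cohorts_measured` cohorts:
#' per-cohort Hedges' adjusted g, DerSimonian-Laird pooling, Cochran's Q,
#' and directional Fisher combination of the per-cohort one-sided normal
#' p-values, with BH FDR applied separately to the up- and down-direction
#' Fisher p-value families across genes.
#'
#' Genes are matched across cohorts case-insensitively. Genes with zero
#' pooled variance in a cohort are dropped from that cohort's effects (and
#' counted in a message). The per-(gene, cohort) effects are attached as
#' attribute `"effects"` for [forest_data()].
#'
#' @param cohorts list of gene-level [cohort_dataset()]s, each with >= 2
#'   samples per arm.
#' @param min_cohorts_measured minimum number of cohorts a gene must be
#'   measured in to enter the meta-analysis.
#' @param p_floor floor for zero one-sided p-values (see [fisher_combine()]).
#'
#' @return a `MetaResult` data.frame: `gene, k, es_pooled, se_pooled, tau2,
#'   q_stat, q_pvalue, fisher_stat_up, fisher_p_up, fisher_fdr_up,
#'   fisher_stat_down, fisher_p_down, fisher_fdr_down`. Empty (with a
#'   warning) if no gene passes the measurement filter.
#' @export
run_meta <- function(cohorts, min_cohorts_measured = 5L, p_floor = 1e-300) {
  stopifnot(length(cohorts) >= 1L)
  for (cd in cohorts) {
    tr <- cd$groups == "treated"
    if (sum(tr) < 2L || sum(!tr) < 2L)
      stop(sprintf("cohort %s has fewer than 2 samples in an arm", cd$cohort_id),
           call. = FALSE)
  }
  if (!is_count(min_cohorts_measured)) stop_field("min_cohorts_measured",
                                                  "must be a positive integer")
  ids <- vapply(cohorts, function(cd) as.character(cd$cohort_id), "")

  # per-cohort gene-wise g and var_g (vectorized Hedges' g; identical to
  # hedges_g() per gene, asserted in the test suite)
  eff <- lapply(cohorts, function(cd) {
    x <- cd$matrix
    tr <- cd$groups == "treated"
    n_t <- sum(tr); n_c <- sum(!tr); df <- n_t + n_c - 2L
    xt <- x[, tr, drop = FALSE]; xc <- x[, !tr, drop = FALSE]
    mt <- rowMeans(xt); mc <- rowMeans(xc)
    sp2 <- (rowSums((xt - mt)^2) + rowSums((xc - mc)^2)) / df
    J <- 1 - 3 / (4 * df - 1)
    g <- ifelse(sp2 > 0, J * (mt - mc) / sqrt(sp2), NA_real_)
    n_zero <- sum(sp2 <= 0)
    if (n_zero > 0L)
      message(sprintf("run_meta: %d gene(s) with zero pooled variance dropped in cohort %s",
                      n_zero, cd$cohort_id))
    var_g <- (n_t + n_c) / (n_t * n_c) + g^2 / (2 * (n_t + n_c))
    data.frame(key = gene_key(rownames(x)), gene = rownames(x),
               g = g, var_g = var_g, n_t = n_t, n_c = n_c,
               stringsAsFactors = FALSE)
  })

  keys <- unique(unlist(lapply(eff, `[[`, "key")))
  display <- character(0)
  G <- V <- matrix(NA_real_, length(keys), length(cohorts),
                   dimnames = list(keys, ids))
  for (j in seq_along(eff)) {
    e <- eff[[j]]
    G[e$key, j] <- e$g
    V[e$key, j] <- e$var_g
    new <- setdiff(e$key, names(display))
    display <- c(display, setNames(e$gene[match(new, e$key)], new))
  }

  k_measured <- rowSums(!is.na(G))
  keep <- k_measured >= min_cohorts_measured
  if (!any(keep)) {
    warning("no gene measured in enough cohorts; empty meta-analysis result")
    empty <- data.frame(gene = character(), k = integer(), es_pooled = numeric(),
                        se_pooled = numeric(), tau2 = numeric(), q_stat = numeric(),
                        q_pvalue = numeric(), fisher_stat_up = numeric(),
                        fisher_p_up = numeric(), fisher_fdr_up = numeric(),
                        fisher_stat_down = numeric(), fisher_p_down = numeric(),
                        fisher_fdr_down = numeric(), stringsAsFactors = FALSE)
    return(empty)
  }
  G <- G[keep, , drop = FALSE]; V <- V[keep, , drop = FALSE]
  k <- k_measured[keep]

  # DerSimonian-Laird, vectorized across genes
  W <- 1 / V
  sw <- rowSums(W, na.rm = TRUE)
  gw <- rowSums(W * G, na.rm = TRUE) / sw
  Q <- rowSums(W * (G - gw)^2, na.rm = TRUE)
  c_dl <- sw - rowSums(W^2, na.rm = TRUE) / sw
  tau2 <- ifelse(k > 1, pmax(0, (Q - (k - 1)) / c_dl), 0)
  Ws <- 1 / (V + tau2)
  es <- rowSums(Ws * G, na.rm = TRUE) / rowSums(Ws, na.rm = TRUE)
  se <- 1 / sqrt(rowSums(Ws, na.rm = TRUE))
  q_p <- ifelse(k > 1, pchisq(Q, df = k - 1, lower.tail = FALSE), NA_real_)

  # directional Fisher combination
  Z <- G / sqrt(V)
  P_up <- pmax(pnorm(Z, lower.tail = FALSE), p_floor)
  P_dn <- pmax(pnorm(Z), p_floor)
  X_up <- -2 * rowSums(log(P_up), na.rm = TRUE)
  X_dn <- -2 * rowSums(log(P_dn), na.rm = TRUE)
  p_up <- pchisq(X_up, df = 2 * k, lower.tail = FALSE)
  p_dn <- pchisq(X_dn, df = 2 * k, lower.tail = FALSE)

  out <- data.frame(gene = unname(display[rownames(G)]), k = as.integer(k),
                    es_pooled = es, se_pooled = se, tau2 = tau2,
                    q_stat = Q, q_pvalue = q_p,
                    fisher_stat_up = X_up, fisher_p_up = p_up,
                    fisher_fdr_up = bh_adjust(p_up),
                    fisher_stat_down = X_dn, fisher_p_down = p_dn,
                    fisher_fdr_down = bh_adjust(p_dn),
                    row.names = NULL, stringsAsFactors = FALSE)

  effects <- do.call(rbind, lapply(seq_along(eff), function(j) {
    e <- eff[[j]]
    e <- e[e$key %in% rownames(G) & !is.na(e$g), , drop = FALSE]
    data.frame(gene = unname(display[e$key]), cohort = ids[j],
               g = e$g, var_g = e$var_g, n_t = e$n_t, n_c = e$n_c,
               stringsAsFactors = FALSE)
  }))
  attr(out, "effects") <- effects
  out
}

#' Select a cross-cohort gene signature
#'
#' Up-direction members satisfy `es_pooled >= es_min`,
#' `fisher_fdr_up <= fdr_max` and `k >= min_cohorts`; down-direction members
#' symmetrically (`es_pooled <= -es_min`, `fisher_fdr_down <= fdr_max`).
#' Members are ordered by directional Fisher FDR, then by decreasing
#' absolute pooled effect.
#'
#' @param meta a `MetaResult` data.frame from [run_meta()].
#' @param es_min minimum absolute pooled effect size (default 1).
#' @param fdr_max maximum directional Fisher FDR (default 0.05).
#' @param min_cohorts minimum number of cohorts the gene is measured in
#'   (default 5).
#'
#' @return data.frame `gene, direction, es_pooled, se_pooled, fisher_fdr, k`
#'   with the thresholds in attribute `"thresholds"`. Empty is valid.
#' @export
select_signature <- function(meta, es_min = 1, fdr_max = 0.05, min_cohorts = 5L) {
  up <- meta$es_pooled >= es_min & meta$fisher_fdr_up <= fdr_max & meta$k >= min_cohorts
  dn <- meta$es_pooled <= -es_min & meta$fisher_fdr_down <= fdr_max & meta$k >= min_cohorts
  rows <- rbind(
    data.frame(gene = meta$gene[up], direction = rep("up", sum(up)),
               es_pooled = meta$es_pooled[up], se_pooled = meta$se_pooled[up],
               fisher_fdr = meta$fisher_fdr_up[up], k = meta$k[up],
               stringsAsFactors = FALSE),
    data.frame(gene = meta$gene[dn], direction = rep("down", sum(dn)),
               es_pooled = meta$es_pooled[dn], se_pooled = meta$se_pooled[dn],
               fisher_fdr = meta$fisher_fdr_down[dn], k = meta$k[dn],
               stringsAsFactors = FALSE))
  rows <- rows[order(rows$fisher_fdr, -abs(rows$es_pooled)), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "thresholds") <- list(es_min = es_min, fdr_max = fdr_max,
                                   min_cohorts = min_cohorts)
  class(rows) <- c("signature_gene_set", "data.frame")
  rows
}

#' Per-sample geometric-mean signature score
#'
#' On log2 data the geometric mean of linear-scale values is the arithmetic
#' mean of the log2 values, so each sample's score is the mean over the
#' signature genes present in the matrix.
#'
#' @param matrix gene-level log2 expression matrix.
#' @param signature a [select_signature()] result, or a character vector of
#'   gene symbols.
#'
#' @return `data.frame(sample_id, score)` with attribute `n_genes_used`
#'   (signature genes found in the matrix, matched case-insensitively).
#' @export
geometric_mean_score <- function(matrix, signature) {
  genes <- if (is.character(signature)) signature else signature$gene
  hit <- match(gene_key(genes), gene_key(rownames(matrix)))
  hit <- hit[!is.na(hit)]
  if (!length(hit)) stop("no signature gene present in the matrix", call. = FALSE)
  score <- colMeans(matrix[hit, , drop = FALSE])
  out <- data.frame(sample_id = colnames(matrix), score = unname(score),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_genes_used") <- length(hit)
  out
}

#' Compare signature scores between arms of a cohort
#'
#' @param cohort a gene-level [cohort_dataset()].
#' @inheritParams geometric_mean_score
#' @return one-row data.frame `cohort_id, control_mean, treated_mean, diff,
#'   n_genes_used`.
#' @export
score_summary <- function(cohort, signature) {
  sc <- geometric_mean_score(cohort$matrix, signature)
  grp <- cohort$groups[sc$sample_id]
  data.frame(cohort_id = cohort$cohort_id,
             control_mean = mean(sc$score[grp == "control"]),
             treated_mean = mean(sc$score[grp == "treated"]),
             diff = mean(sc$score[grp == "treated"]) - mean(sc$score[grp == "control"]),
             n_genes_used = attr(sc, "n_genes_used"),
             stringsAsFactors = FALSE)
}

#' Forest-plot data for one gene
#'
#' @param gene gene symbol.
#' @param effects per-(gene, cohort) effects table with columns `gene,
#'   cohort, g, var_g` (e.g. `attr(run_meta(...), "effects")`).
#' @param pooled the gene's `MetaResult` row from [run_meta()].
#'
#' @return data.frame with one row per cohort (`cohort, g, ci_low, ci_high,
#'   weight`), 95% CIs `g +/- 1.96*sqrt(var_g)`, normalized random-effects
#'   weights summing to 1, plus a `"pooled"` summary row using
#'   `es_pooled +/- 1.96*se_pooled`.
#' @export
forest_data <- function(gene, effects, pooled) {
  e <- effects[gene_key(effects$gene) == gene_key(gene), , drop = FALSE]
  if (!nrow(e)) stop(sprintf("no effects for gene %s", gene), call. = FALSE)
  p <- pooled[gene_key(pooled$gene) == gene_key(gene), , drop = FALSE]
  if (nrow(p) != 1L)
    stop(sprintf("pooled result does not match gene %s", gene), call. = FALSE)
  if (nrow(e) != p$k)
    stop("effects and pooled result disagree on the number of cohorts", call. = FALSE)
  w <- 1 / (e$var_g + p$tau2)
  w <- w / sum(w)
  rbind(
    data.frame(cohort = e$cohort, g = e$g,
               ci_low = e$g - 1.96 * sqrt(e$var_g),
               ci_high = e$g + 1.96 * sqrt(e$var_g),
               weight = w, stringsAsFactors = FALSE),
    data.frame(cohort = "pooled", g = p$es_pooled,
               ci_low = p$es_pooled - 1.96 * p$se_pooled,
               ci_high = p$es_pooled + 1.96 * p$se_pooled,
               weight = 1, stringsAsFactors = FALSE))
}
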