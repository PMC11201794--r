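# Single-cohort two-group differential expression: moderated t with
# empirical-Bayes variance shrinkage, BH correction, two-tier DEG thresholds,
# and cross-cohort shared-DEG counting.

#' Moderated two-sample t statistics for one cohort
#'
#' Per gene: `log2fc` is the treated minus control mean on log2 scale; the
#' pooled residual variance s^2 (df = n_t + n_c - 2) is shrunk toward a
#' scaled inverse chi-squared prior, `s_tilde^2 = (d0*s0^2 + df*s^2)/(d0 + df)`,
#' with the prior (d0, s0^2) fitted across genes by method of moments on
#' log s^2; `t = log2fc / (s_tilde * sqrt(1/n_t + 1/n_c))` is referred to a t
#' distribution with `df + d0` degrees of freedom.
#'
#' Genes with zero variance in both arms get `t = NA`, `p = 1` when the
#' shrunken variance is also zero; their `log2fc` is still reported.
#'
#' @param cohort a gene-level [cohort_dataset()] (log2 scale).
#' @param moderation set `FALSE` to disable shrinkage, giving the ordinary
#'   pooled two-sample t statistic.
#'
#' @return `data.frame(gene, log2fc, t, p_raw, df_residual)` with the fitted
#'   prior in attributes `d0` and `s0_sq`.
#' @export
moderated_t <- function(cohort, moderation = TRUE) {
  x <- cohort$matrix
  tr <- cohort$groups == "treated"
  n_t <- sum(tr); n_c <- sum(!tr)
  if (n_t < 2L || n_c < 2L)
    stop(errorCondition("fewer than 2 samples in a group: use fc_only mode",
                        class = "metacohort_small_n"))
  xt <- x[, tr, drop = FALSE]; xc <- x[, !tr, drop = FALSE]
  mt <- rowMeans(xt); mc <- rowMeans(xc)
  log2fc <- mt - mc
  df <- n_t + n_c - 2L
  s2 <- (rowSums((xt - mt)^2) + rowSums((xc - mc)^2)) / df

  if (moderation) {
    prior <- fit_variance_prior(s2, df)
    d0 <- prior$d0; s0_sq <- prior$s0_sq
    s2_shrunk <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
      (d0 * s0_sq + df * s2) / (d0 + df)
    df_total <- df + d0
  } else {
    d0 <- 0; s0_sq <- NA_real_
    s2_shrunk <- s2
    df_total <- df
  }

  se <- sqrt(s2_shrunk * (1 / n_t + 1 / n_c))
  t_stat <- ifelse(se > 0, log2fc / se, ifelse(log2fc == 0, 0, NA_real_))
  p <- ifelse(is.na(t_stat), 1,
              2 * pt(-abs(t_stat), df = min(df_total, .Machine$double.xmax)))
  out <- data.frame(gene = rownames(x), log2fc = log2fc, t = t_stat,
                    p_raw = p, df_residual = df, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

# Method-of-moments fit of the scaled inverse chi-squared variance prior on
# log s^2 (zero-variance genes are excluded from the fit).
#' @noRd
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(d0 = Inf, s0_sq = max(mean(s2), .Machine$double.eps)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- var(e)
  excess <- ev - trigamma(df / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper around the standard step-up procedure.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NA allowed;
#'   propagated).
#' @return adjusted values in input order.
#' @export
bh_adjust <- function(p_values) {
  bad <- !is.na(p_values) & (p_values < 0 | p_values > 1)
  if (any(bad))
    stop(sprintf("p-values outside [0, 1] at position(s) %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes under two-tier thresholds
#'
#' Threshold modes: `stringent` requires adjusted p <= `alpha` and
#' |log2FC| >= `lfc_min`; `relaxed` uses the raw p instead of the adjusted
#' one; `fc_only` uses the fold change alone (for cohorts with one sample per
#' group where no test is possible). `auto` applies `stringent`, falls back
#' to `relaxed` if no gene passes, and to `fc_only` when p-values are
#' unavailable.
#'
#' @param stats data.frame with columns `gene`, `log2fc` and (unless
#'   `fc_only`) `p_raw`, as returned by [moderated_t()].
#' @param mode one of `"auto"`, `"stringent"`, `"relaxed"`, `"fc_only"`.
#' @param lfc_min absolute log2 fold-change threshold (default 1).
#' @param alpha significance threshold on the (adjusted or raw) p (default
#'   0.05).
#'
#' @return a `DeTable`: `data.frame(gene, log2fc, t, p_raw, p_adj, deg_call,
#'   threshold_mode)` where `deg_call` is `"up"`, `"down"` or `"none"`.
#' @export
call_degs <- function(stats, mode = c("auto", "stringent", "relaxed", "fc_only"),
                      lfc_min = 1, alpha = 0.05) {
  mode <- match.arg(mode)
  have_p <- "p_raw" %in% names(stats) && any(!is.na(stats$p_raw))
  if (!have_p && mode %in% c("stringent", "relaxed"))
    stop("no p-values available; use mode 'fc_only' (or 'auto')", call. = FALSE)
  if (!have_p) mode <- "fc_only"

  out <- data.frame(gene = stats$gene, log2fc = stats$log2fc,
                    t = if ("t" %in% names(stats)) stats$t else NA_real_,
                    p_raw = if (have_p) stats$p_raw else NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$p_adj <- if (have_p) bh_adjust(out$p_raw) else NA_real_

  decide <- function(m) {
    pass <- switch(m,
      stringent = !is.na(out$p_adj) & out$p_adj <= alpha & abs(out$log2fc) >= lfc_min,
      relaxed   = !is.na(out$p_raw) & out$p_raw <= alpha & abs(out$log2fc) >= lfc_min,
      fc_only   = abs(out$log2fc) >= lfc_min)
    ifelse(pass, ifelse(out$log2fc > 0, "up", "down"), "none")
  }

  if (mode == "auto") {
    call <- decide("stringent"); used <- "stringent"
    if (!any(call != "none")) { call <- decide("relaxed"); used <- "relaxed" }
  } else {
    call <- decide(mode); used <- mode
  }
  out$deg_call <- call
  out$threshold_mode <- used
  out
}

#' Differential expression for one cohort
#'
#' Convenience wrapper: runs [moderated_t()] and [call_degs()], switching to
#' fold-change-only calling when a group has a single sample.
#'
#' @inheritParams moderated_t
#' @inheritParams call_degs
#' @return a `DeTable` (see [call_degs()]).
#' @export
cohort_de <- function(cohort, mode = "auto", lfc_min = 1, alpha = 0.05,
                      moderation = TRUE) {
  tr <- cohort$groups == "treated"
  if (sum(tr) < 2L || sum(!tr) < 2L) {
    x <- cohort$matrix
    log2fc <- rowMeans(x[, tr, drop = FALSE]) - rowMeans(x[, !tr, drop = FALSE])
    stats <- data.frame(gene = rownames(x), log2fc = log2fc,
                        row.names = NULL, stringsAsFactors = FALSE)
    return(call_degs(stats, mode = "fc_only", lfc_min = lfc_min, alpha = alpha))
  }
  stats <- moderated_t(cohort, moderation = moderation)
  call_degs(stats, mode = mode, lfc_min = lfc_min, alpha = alpha)
}

#' Count genes deregulated in multiple cohorts
#'
#' @param deg_tables named list of `DeTable`s (one per cohort), genes matched
#'   by symbol (case-insensitive).
#' @param min_cohorts minimum number of cohorts in which a gene must be
#'   called a DEG (in either direction) to be reported.
#'
#' @return data.frame with one row per gene passing the filter: `gene`,
#'   `n_deregulated`, `n_up`, `n_down`, then one call column per cohort;
#'   sorted by descending `n_deregulated`. Mixed directions are preserved.
#' @export
count_shared_degs <- function(deg_tables, min_cohorts) {
  if (length(deg_tables) < 2L) stop("need at least 2 DEG tables", call. = FALSE)
  if (!is_count(min_cohorts)) stop_field("min_cohorts", "must be a positive integer")
  if (min_cohorts > length(deg_tables))
    stop(sprintf("min_cohorts (%d) exceeds the number of cohorts (%d)",
                 min_cohorts, length(deg_tables)), call. = FALSE)
  ids <- names(deg_tables) %||% sprintf("cohort%d", seq_along(deg_tables))

  keys <- unique(unlist(lapply(deg_tables, function(d) gene_key(d$gene))))
  display <- character(0)
  calls <- matrix("absent", length(keys), length(deg_tables),
                  dimnames = list(keys, ids))
  for (j in seq_along(deg_tables)) {
    d <- deg_tables[[j]]
    k <- gene_key(d$gene)
    calls[k, j] <- d$deg_call
    new <- setdiff(k, names(display))
    display <- c(display, setNames(d$gene[match(new, k)], new))
  }
  n_up <- rowSums(calls == "up")
  n_down <- rowSums(calls == "down")
  n_dereg <- n_up + n_down
  keep <- n_dereg >= min_cohorts
  out <- data.frame(gene = unname(display[keys[keep]]),
                    n_deregulated = n_dereg[keep],
                    n_up = n_up[keep], n_down = n_down[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(calls[keep, , drop = FALSE],
                                  stringsAsFactors = FALSE), row.names = NULL)
  out[order(-out$n_deregulated, out$gene), , drop = FALSE]
}
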