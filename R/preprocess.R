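# Per-cohort preprocessing: log2 handling, quantile normalization,
# probe -> gene collapsing, PCA-based exploratory QC.

#' Ensure a matrix is on log2 scale
#'
#' Applies `log2(x + offset)` if the matrix is on raw intensity scale and
#' returns it untouched if already log2. The scale is read from the matrix's
#' `"scale"` attribute when present; otherwise a standard heuristic is used:
#' a maximum above 50 is taken as raw intensity, anything else as already
#' log2-transformed.
#'
#' @param matrix numeric features x samples matrix.
#' @param offset non-negative pseudo-count added before the log (default 1).
#'
#' @return the matrix on log2 scale, with `attr(, "scale") == "log2"`.
#' @export
ensure_log2 <- function(matrix, offset = 1) {
  if (!is_number(offset) || offset < 0) stop_field("offset", "must be >= 0")
  scale <- attr(matrix, "scale")
  if (is.null(scale)) scale <- if (max(matrix, na.rm = TRUE) > 50) "raw" else "log2"
  if (scale == "log2") {
    attr(matrix, "scale") <- "log2"
    return(matrix)
  }
  if (any(matrix < 0, na.rm = TRUE))
    stop("raw-scale matrix contains negative values; cannot log2-transform",
         call. = FALSE)
  out <- log2(matrix + offset)
  attr(out, "scale") <- "log2"
  out
}

#' Quantile-normalize the columns of an expression matrix
#'
#' Forces every column onto the common reference distribution given by the
#' across-column mean of order statistics. Ties within a column receive the
#' mean of the reference values at their tied ranks.
#'
#' @param matrix numeric features x samples matrix with no missing values.
#'
#' @return the normalized matrix; a single-sample matrix is returned
#'   unchanged with a warning (there is nothing to normalize against).
#' @export
quantile_normalize <- function(matrix) {
  if (ncol(matrix) < 2L) {
    warning("single-sample matrix: quantile normalization skipped")
    return(matrix)
  }
  if (anyNA(matrix)) stop("missing values not supported by quantile normalization",
                          call. = FALSE)
  ref <- rowMeans(apply(matrix, 2L, sort, method = "radix"))
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    col <- matrix[, j]
    v <- numeric(length(col))
    v[order(col, method = "radix")] <- ref
    # equal input values share the mean of their assigned reference values
    out[, j] <- ave(v, col, FUN = mean)
  }
  attributes(out) <- attributes(matrix)
  out
}

#' Collapse probe-level rows to gene level
#'
#' Each gene's row becomes the arithmetic mean (on log2 scale) of its probes'
#' rows. Probes absent from the map are dropped and counted in a message.
#'
#' @param matrix probe-level features x samples matrix.
#' @param probe_map `data.frame(probe_id, gene_symbol)`; many probes may map
#'   to one gene.
#'
#' @return gene-level matrix whose rownames are the unique mapped gene
#'   symbols, carrying the input's `"scale"` attribute.
#' @export
collapse_probes <- function(matrix, probe_map) {
  if (!all(c("probe_id", "gene_symbol") %in% names(probe_map)))
    stop_field("probe_map", "must have columns probe_id, gene_symbol")
  map <- setNames(probe_map$gene_symbol, probe_map$probe_id)
  mapped <- rownames(matrix) %in% names(map)
  if (!any(mapped))
    stop("no probe in the matrix is covered by the probe map", call. = FALSE)
  n_dropped <- sum(!mapped)
  if (n_dropped > 0L)
    message(sprintf("collapse_probes: dropped %d unmapped probe(s)", n_dropped))
  x <- matrix[mapped, , drop = FALSE]
  genes <- map[rownames(x)]
  sums <- rowsum(x, group = genes, reorder = TRUE)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  attr(out, "scale") <- attr(matrix, "scale")
  out
}

#' Explained-variance fractions of the leading principal components
#'
#' Samples are the observations and genes the variables; the matrix is
#' centered (per gene) and not scaled before the decomposition.
#'
#' @param matrix features x samples matrix on log2 scale.
#' @param n_components number of leading components requested; must not
#'   exceed `min(n_samples - 1, n_features)`.
#'
#' @return numeric vector of the first `n_components` fractions of total
#'   variance (non-increasing, each in `[0, 1]`, summing to at most 1).
#' @export
pca_explained <- function(matrix, n_components = 2L) {
  n <- ncol(matrix)
  if (n < 2L) stop("need at least 2 samples for PCA", call. = FALSE)
  max_comp <- min(n - 1L, nrow(matrix))
  if (!is_count(n_components) || n_components > max_comp)
    stop(sprintf("n_components must be in 1..%d", max_comp), call. = FALSE)
  pc <- prcomp(t(matrix), center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  frac[seq_len(n_components)]
}

#' Standard preprocessing for one cohort
#'
#' Runs the per-cohort pipeline: log2 transform (if needed), quantile
#' normalization, probe-to-gene collapsing.
#'
#' @param cohort a [cohort_dataset()] with probe-level features.
#' @param probe_map `data.frame(probe_id, gene_symbol)`.
#' @param offset pseudo-count for [ensure_log2()].
#'
#' @return a `cohort_dataset` whose matrix is gene-level, normalized, log2.
#' @export
preprocess_cohort <- function(cohort, probe_map, offset = 1) {
  x <- ensure_log2(cohort$matrix, offset = offset)
  x <- quantile_normalize(x)
  x <- collapse_probes(x, probe_map)
  out <- cohort_dataset(x, cohort$groups, cohort$cohort_id, scale = "log2")
  out$latent <- cohort$latent
  out
}
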