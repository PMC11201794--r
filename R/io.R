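# Readers and writers for every on-disk format the pipeline touches.
# All files are TSV, UTF-8, '.' decimal separator; writes round-trip through
# the matching readers within 1e-9.

#' @noRd
check_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  path
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' First column holds feature (probe or gene) ids, remaining columns one
#' sample each; values are reals. Duplicated sample or feature ids are
#' rejected.
#'
#' @param path file path.
#' @param scale `"log2"`, `"raw"`, or `NULL` to leave detection to
#'   [ensure_log2()]'s heuristic.
#' @return numeric features x samples matrix with a `"scale"` attribute when
#'   given.
#' @export
read_expression <- function(path, scale = NULL) {
  check_file(path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop(sprintf("%s: expected a feature-id column plus >= 1 sample column", path),
         call. = FALSE)
  feat <- as.character(df[[1]])
  if (anyDuplicated(feat))
    stop(sprintf("%s: duplicated feature id(s): %s", path,
                 paste(utils::head(unique(feat[duplicated(feat)]), 3L), collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(names(df)[-1]))
    stop(sprintf("%s: duplicated sample id(s)", path), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(sprintf("%s: non-numeric expression values", path),
                           call. = FALSE)
  rownames(m) <- feat
  if (!is.null(scale)) attr(m, "scale") <- match.arg(scale, c("log2", "raw"))
  m
}

#' Write an expression matrix TSV
#'
#' @param matrix numeric features x samples matrix with dimnames.
#' @param path output path.
#' @param id_column header name for the feature-id column.
#' @export
write_expression <- function(matrix, path, id_column = "probe_id") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write_tsv(df, path)
}

#' Read a phenotype table
#'
#' Columns `sample_id` and `group` (values `control` / `treated`).
#'
#' @param path file path.
#' @return named character vector `sample_id -> group`.
#' @export
read_phenotype <- function(path) {
  check_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop(sprintf("%s: phenotype file needs columns sample_id, group", path),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop(sprintf("%s: duplicated sample_id", path), call. = FALSE)
  bad <- setdiff(unique(df$group), c("control", "treated"))
  if (length(bad))
    stop(sprintf("%s: unknown group label(s): %s", path, paste(bad, collapse = ", ")),
         call. = FALSE)
  setNames(df$group, df$sample_id)
}

#' Read a probe-to-gene mapping table
#'
#' Columns `probe_id`, `gene_symbol`; many-to-one allowed, duplicated probe
#' ids are not.
#'
#' @param path file path.
#' @return `data.frame(probe_id, gene_symbol)`.
#' @export
read_probe_map <- function(path) {
  check_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(df)))
    stop(sprintf("%s: probe map needs columns probe_id, gene_symbol", path),
         call. = FALSE)
  if (anyDuplicated(df$probe_id))
    stop(sprintf("%s: duplicated probe_id", path), call. = FALSE)
  df[, c("probe_id", "gene_symbol")]
}

#' Read gene sets in GMT format
#'
#' Standard tab-separated gene-set lines: set id, description, then one gene
#' per field. Lines with fewer than 3 fields are rejected with their line
#' number.
#'
#' @param path file path.
#' @param hierarchy optional `data.frame(child_id, parent_id)` to attach (see
#'   [read_hierarchy()]).
#' @return a [pathway_catalog()].
#' @export
read_gmt <- function(path, hierarchy = NULL) {
  check_file(path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); descriptions <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop(sprintf("%s: line %d has fewer than 3 fields (id, description, genes...)",
                   path, i), call. = FALSE)
    sets[[f[1]]] <- unique(f[-(1:2)])
    descriptions[f[1]] <- f[2]
  }
  pathway_catalog(sets, descriptions, hierarchy)
}

#' Write gene sets in GMT format
#'
#' @param catalog a [pathway_catalog()].
#' @param path output path.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog$sets), function(id)
    paste(c(id, catalog$descriptions[id], catalog$sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a pathway child-to-parent hierarchy table
#'
#' Columns `child_id`, `parent_id` (one edge per row, as in pathway-relation
#' dump files).
#'
#' @param path file path.
#' @return `data.frame(child_id, parent_id)`.
#' @export
read_hierarchy <- function(path) {
  check_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("child_id", "parent_id") %in% names(df)))
    stop(sprintf("%s: hierarchy needs columns child_id, parent_id", path),
         call. = FALSE)
  df[, c("child_id", "parent_id")]
}

#' Read one cohort (expression + phenotype) from disk
#'
#' @param expression_path expression TSV (see [read_expression()]).
#' @param phenotype_path phenotype TSV (see [read_phenotype()]).
#' @param cohort_id identifier for the cohort.
#' @return a [cohort_dataset()]. Every matrix sample must appear in the
#'   phenotype table; the offending sample is named otherwise.
#' @export
read_cohort <- function(expression_path, phenotype_path, cohort_id) {
  m <- read_expression(expression_path)
  groups <- read_phenotype(phenotype_path)
  missing <- setdiff(colnames(m), names(groups))
  if (length(missing))
    stop(sprintf("%s: no phenotype entry for sample(s): %s",
                 phenotype_path, paste(missing, collapse = ", ")), call. = FALSE)
  scale <- if (max(m, na.rm = TRUE) > 50) "raw" else "log2"
  cohort_dataset(m, groups, cohort_id, scale = scale)
}
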