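# Hypergeometric over-representation against a pathway catalog, with
# hierarchical top-level-ancestor aggregation and cross-cohort frequency
# tables.

#' Pathway catalog: gene sets plus an optional hierarchy
#'
#' @param sets named list of character vectors (pathway id -> member genes);
#'   member sets must be non-empty.
#' @param descriptions optional named character vector of pathway names.
#' @param hierarchy optional `data.frame(child_id, parent_id)` of edges; must
#'   form a forest or DAG with at least one root.
#'
#' @return an object of class `pathway_catalog`.
#' @export
pathway_catalog <- function(sets, descriptions = NULL, hierarchy = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_field("sets", "must be a non-empty named list")
  if (any(lengths(sets) == 0L)) stop_field("sets", "member sets must be non-empty")
  if (is.null(descriptions)) descriptions <- setNames(names(sets), names(sets))
  if (!is.null(hierarchy)) {
    if (!all(c("child_id", "parent_id") %in% names(hierarchy)))
      stop_field("hierarchy", "must have columns child_id, parent_id")
    nodes <- unique(c(hierarchy$child_id, hierarchy$parent_id))
    roots <- setdiff(nodes, hierarchy$child_id)
    if (!length(roots)) stop_field("hierarchy", "has no root (cycle?)")
  }
  structure(list(sets = sets, descriptions = descriptions, hierarchy = hierarchy),
            class = "pathway_catalog")
}

#' @export
print.pathway_catalog <- function(x, ...) {
  cat(sprintf("<pathway_catalog> %d set(s), sizes %d-%d%s\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              if (is.null(x$hierarchy)) "" else
                sprintf(", hierarchy with %d edge(s)", nrow(x$hierarchy))))
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway with at least one overlap with the query, computes the
#' inclusive upper-tail hypergeometric p-value
#' `P(X >= overlap | universe_size, set_size, query_size)`, where the
#' pathway's member set is first intersected with the universe. BH adjustment
#' is applied across the tested pathways; results are sorted by adjusted p.
#'
#' @param query character vector of genes of interest; must be a subset of
#'   `universe`.
#' @param catalog a [pathway_catalog()].
#' @param universe character vector of all measured genes.
#'
#' @return data.frame `pathway_id, name, overlap_count, set_size, query_size,
#'   universe_size, p_raw, p_adj, overlap_genes` (comma-separated).
#' @export
hypergeom_ora <- function(query, catalog, universe) {
  query <- unique(query); universe <- unique(universe)
  if (!length(query)) stop("empty query gene set", call. = FALSE)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  out_of_universe <- setdiff(query, universe)
  if (length(out_of_universe))
    stop(sprintf("query gene(s) outside the universe: %s",
                 paste(utils::head(out_of_universe, 5L), collapse = ", ")),
         call. = FALSE)
  rows <- lapply(names(catalog$sets), function(id) {
    members <- intersect(catalog$sets[[id]], universe)
    ov <- intersect(query, members)
    if (!length(ov)) return(NULL)
    m <- length(members); q <- length(query); N <- length(universe)
    p <- phyper(length(ov) - 1L, m, N - m, q, lower.tail = FALSE)
    data.frame(pathway_id = id, name = unname(catalog$descriptions[id]),
               overlap_count = length(ov), set_size = m, query_size = q,
               universe_size = N, p_raw = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(pathway_id = character(), name = character(),
                      overlap_count = integer(), set_size = integer(),
                      query_size = integer(), universe_size = integer(),
                      p_raw = numeric(), p_adj = numeric(),
                      overlap_genes = character(), stringsAsFactors = FALSE))
  rows$p_adj <- bh_adjust(rows$p_raw)
  rows <- rows[order(rows$p_adj, rows$p_raw, rows$pathway_id), , drop = FALSE]
  rows <- rows[, c("pathway_id", "name", "overlap_count", "set_size",
                   "query_size", "universe_size", "p_raw", "p_adj",
                   "overlap_genes")]
  rownames(rows) <- NULL
  rows
}

# All root ancestors of a node by upward traversal (memoized per call).
#' @noRd
root_ancestors <- function(node, parents_of, cache) {
  if (!is.null(cache[[node]])) return(cache[[node]])
  seen <- character(0)
  frontier <- node
  roots <- character(0)
  while (length(frontier)) {
    cur <- frontier[1]; frontier <- frontier[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    p <- parents_of[[cur]]
    if (is.null(p) || !length(p)) roots <- c(roots, cur)
    else frontier <- c(frontier, p)
  }
  cache[[node]] <- unique(roots)
  cache[[node]]
}

#' Aggregate enriched pathways to their top-level ancestors
#'
#' Maps each enriched pathway to all root ancestors reachable by upward
#' traversal of the catalog hierarchy; a pathway under multiple roots is
#' counted once per root. Pathways absent from the hierarchy go to the
#' reserved root `"unclassified"` with a warning.
#'
#' @param results an [hypergeom_ora()] result (or any data.frame with a
#'   `pathway_id` column).
#' @param catalog a [pathway_catalog()] with a hierarchy.
#'
#' @return data.frame `ancestor_id, n_pathways, pathways` (comma-separated),
#'   sorted by descending count.
#' @export
rollup_ancestors <- function(results, catalog) {
  if (is.null(catalog$hierarchy))
    stop("catalog has no hierarchy to roll up", call. = FALSE)
  h <- catalog$hierarchy
  parents_of <- split(h$parent_id, h$child_id)
  known <- unique(c(h$child_id, h$parent_id))
  cache <- new.env(parent = emptyenv())
  assign_rows <- lapply(unique(results$pathway_id), function(id) {
    if (!(id %in% known)) {
      warning(sprintf("pathway %s absent from hierarchy: assigned to 'unclassified'", id))
      return(data.frame(ancestor_id = "unclassified", pathway_id = id,
                        stringsAsFactors = FALSE))
    }
    data.frame(ancestor_id = root_ancestors(id, parents_of, cache),
               pathway_id = id, stringsAsFactors = FALSE)
  })
  a <- do.call(rbind, assign_rows)
  agg <- lapply(split(a$pathway_id, a$ancestor_id), function(p) {
    data.frame(n_pathways = length(p), pathways = paste(sort(p), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- cbind(data.frame(ancestor_id = names(agg), stringsAsFactors = FALSE),
               do.call(rbind, unname(agg)))
  out <- out[order(-out$n_pathways, out$ancestor_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count cohorts in which each pathway is significantly enriched
#'
#' @param per_cohort_results named list (cohort id -> [hypergeom_ora()]
#'   result); at least 2 cohorts.
#' @param fdr_max adjusted-p threshold for calling a pathway significant in a
#'   cohort (default 0.05).
#'
#' @return data.frame `pathway_id, n_cohorts_significant`, covering every
#'   pathway appearing in any cohort's results, sorted by descending count.
#' @export
cross_cohort_pathway_counts <- function(per_cohort_results, fdr_max = 0.05) {
  if (length(per_cohort_results) < 2L)
    stop("need results from at least 2 cohorts", call. = FALSE)
  all_ids <- unique(unlist(lapply(per_cohort_results, `[[`, "pathway_id")))
  counts <- setNames(integer(length(all_ids)), all_ids)
  for (res in per_cohort_results) {
    sig <- res$pathway_id[!is.na(res$p_adj) & res$p_adj <= fdr_max]
    counts[sig] <- counts[sig] + 1L
  }
  out <- data.frame(pathway_id = names(counts),
                    n_cohorts_significant = unname(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_cohorts_significant, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
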