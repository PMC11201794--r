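toy_catalog <- function() {
  pathway_catalog(
    sets = list(PW1 = c("a", "b", "c", "d", "e"),
                PW2 = c("f", "g", "h"),
                PW3 = letters[1:10]),
    hierarchy = data.frame(child_id = c("PW1", "PW2", "PW3", "MID"),
                           parent_id = c("MID", "ROOT2", "ROOT1", "ROOT1")))
}

test_that("catalog construction validates sets and hierarchy", {
  expect_error(pathway_catalog(list()), "sets")
  expect_error(pathway_catalog(list(A = character(0))), "non-empty")
  expect_error(pathway_catalog(list(A = "x"),
                               hierarchy = data.frame(child_id = c("A", "B"),
                                                      parent_id = c("B", "A"))),
               "root")
})

test_that("the fully-overlapping pathway attains the exact combinatorial p-value", {
  # universe of 10, pathway of 5, query of 5, overlap 5 -> 1 / C(10,5)
  uni <- letters[1:10]
  cat <- pathway_catalog(list(PW = letters[1:5]))
  res <- hypergeom_ora(letters[1:5], cat, uni)
  expect_equal(res$p_raw, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$overlap_count, 5)
})

test_that("a pathway equal to the universe is never enriched", {
  uni <- letters[1:8]
  cat <- pathway_catalog(list(ALL = uni))
  res <- hypergeom_ora(c("a", "b"), cat, uni)
  expect_equal(res$p_raw, 1)
})

test_that("zero-overlap pathways are excluded and empty inputs are errors", {
  uni <- letters[1:10]
  cat <- pathway_catalog(list(PW = c("x", "y", "a")))
  res <- hypergeom_ora(c("b", "c"), cat, uni)
  expect_equal(nrow(res), 0)
  expect_error(hypergeom_ora(character(0), cat, uni), "empty query")
  expect_error(hypergeom_ora("zzz", cat, uni), "outside the universe")
})

test_that("upper-tail p-values equal exact enumeration on small universes", {
  set.seed(30)
  for (i in 1:25) {
    N <- sample(5:12, 1)
    uni <- sprintf("u%02d", seq_len(N))
    set <- sample(uni, sample(2:(N - 1), 1))
    query <- sample(uni, sample(2:(N - 1), 1))
    cat <- pathway_catalog(setNames(list(set), "PW"))
    ov <- length(intersect(set, query))
    res <- hypergeom_ora(query, cat, uni)
    if (ov == 0) {
      expect_equal(nrow(res), 0)
    } else {
      expect_equal(res$p_raw, hyper_tail_oracle(ov, length(set), length(query), N),
                   tolerance = 1e-12)
    }
  }
})

test_that("adding a member gene to the query never increases the pathway's p-value", {
  uni <- sprintf("u%02d", 1:40)
  set <- uni[1:12]
  cat <- pathway_catalog(list(PW = set))
  query <- uni[c(1:4, 20:27)]
  p0 <- hypergeom_ora(query, cat, uni)$p_raw
  p1 <- hypergeom_ora(c(query, uni[5]), cat, uni)$p_raw
  expect_lte(p1, p0)
})

test_that("ancestor roll-up follows chains, DAG multi-roots, and unclassified fallback", {
  cat <- toy_catalog()
  res <- data.frame(pathway_id = c("PW1", "PW2"), p_adj = c(0.01, 0.02))
  roll <- rollup_ancestors(res, cat)
  expect_equal(roll$n_pathways[roll$ancestor_id == "ROOT1"], 1)  # PW1 via MID
  expect_equal(roll$n_pathways[roll$ancestor_id == "ROOT2"], 1)  # PW2
  # a pathway with two parents counts under both roots
  dag <- pathway_catalog(list(P = "x"),
                         hierarchy = data.frame(child_id = c("P", "P", "M"),
                                                parent_id = c("R1", "M", "R2")))
  roll2 <- rollup_ancestors(data.frame(pathway_id = "P"), dag)
  expect_setequal(roll2$ancestor_id, c("R1", "R2"))
  expect_warning(roll3 <- rollup_ancestors(data.frame(pathway_id = "GHOST"), cat),
                 "unclassified")
  expect_identical(roll3$ancestor_id, "unclassified")
})

test_that("roll-up counts match a brute-force transitive-closure oracle on a random forest", {
  set.seed(31)
  n <- 50
  nodes <- sprintf("N%02d", 1:n)
  parent <- c(NA, nodes[unlist(lapply(2:n, function(i) sample(i - 1, 1)))])
  edges <- data.frame(child_id = nodes[-1], parent_id = parent[-1])
  leaves <- sample(nodes, 10)
  cat <- pathway_catalog(setNames(as.list(leaves), leaves), hierarchy = edges)
  roll <- rollup_ancestors(data.frame(pathway_id = leaves), cat)
  # oracle: walk each leaf to its root directly
  up <- setNames(parent, nodes)
  root_of <- function(x) { while (!is.na(up[x])) x <- up[x]; x }
  oracle <- table(vapply(leaves, root_of, ""))
  expect_equal(sum(roll$n_pathways), length(leaves))  # tree: conservation exact
  for (r in names(oracle))
    expect_equal(roll$n_pathways[roll$ancestor_id == r], unname(oracle[r]),
                 ignore_attr = TRUE)
})

test_that("cross-cohort pathway counts respect the FDR threshold", {
  mk <- function(p) data.frame(pathway_id = c("PW1", "PW2"), p_adj = p)
  res <- list(A = mk(c(0.01, 0.2)), B = mk(c(0.02, 0.9)),
              C = mk(c(0.04, 0.01)), D = mk(c(0.5, 0.6)))
  cc <- cross_cohort_pathway_counts(res, fdr_max = 0.05)
  expect_equal(cc$n_cohorts_significant[cc$pathway_id == "PW1"], 3)
  expect_equal(cc$n_cohorts_significant[cc$pathway_id == "PW2"], 1)
  zero <- cross_cohort_pathway_counts(res, fdr_max = 0)
  expect_true(all(zero$n_cohorts_significant == 0))
  expect_error(cross_cohort_pathway_counts(res["A"]), "at least 2")
})

test_that("planted-pathway enrichment dominates end to end", {
  sim <- generate_multicohort(synthetic_config(seed = 32))
  catalog <- synthetic_pathway_catalog(sim)
  pre <- collapse_only(sim)
  meta <- run_meta(pre, 5)
  sig <- select_signature(meta)
  res <- hypergeom_ora(intersect(sig$gene, meta$gene), catalog, meta$gene)
  expect_identical(res$pathway_id[1], "PW_SIGNATURE")
  expect_lt(res$p_adj[1], 1e-10)
  per_cohort <- lapply(pre, function(cd) {
    d <- cohort_de(cd)
    hypergeom_ora(intersect(d$gene[d$deg_call != "none"], meta$gene),
                  catalog, meta$gene)
  })
  names(per_cohort) <- sprintf("C%02d", seq_along(per_cohort))
  cc <- cross_cohort_pathway_counts(per_cohort, 0.05)
  expect_identical(cc$pathway_id[1], "PW_SIGNATURE")
  expect_equal(cc$n_cohorts_significant[1], 5)
  roll <- rollup_ancestors(res, catalog)
  expect_true("ROOT_A" %in% roll$ancestor_id)
})

test_that("the bundled toy catalog loads and supports the full enrichment path", {
  gmt <- system.file("extdata", "toy_pathways.gmt", package = "metacohort")
  hier <- system.file("extdata", "toy_hierarchy.tsv", package = "metacohort")
  catalog <- read_gmt(gmt, hierarchy = read_hierarchy(hier))
  expect_length(catalog$sets, 6)
  expect_identical(catalog$descriptions[["R-TOY-01"]], "Toll-like receptor cascades")
  universe <- unique(c(unlist(catalog$sets), sprintf("FILLER%02d", 1:40)))
  res <- hypergeom_ora(c("MYD88", "IRAK1", "IRAK4", "TRAF6", "JUN"),
                       catalog, universe)
  # all 5 query genes sit inside the 8-member TLR cascade: C(8,5)/C(66,5)
  # narrowly beats the fully-hit 4-member MyD88 set, C(62,1)/C(66,5)
  expect_setequal(res$pathway_id[1:2], c("R-TOY-01", "R-TOY-02"))
  expect_equal(res$p_raw[res$pathway_id == "R-TOY-01"],
               choose(8, 5) / choose(66, 5), tolerance = 1e-12)
  roll <- rollup_ancestors(res, catalog)
  expect_true("IMMUNE_SYSTEM" %in% roll$ancestor_id)
  # the MyD88 sub-pathway rolls up through the TLR cascade to the immune root
  imm <- roll$pathways[roll$ancestor_id == "IMMUNE_SYSTEM"]
  expect_match(imm, "R-TOY-02")
})
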