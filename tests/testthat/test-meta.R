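test_that("Hedges' g reproduces the hand-computed formula chain", {
  # treated [2,2,3,3] vs control [0,0,1,1]: d = 2/sqrt(1/3), J = 1 - 3/23
  e <- hedges_g(c(2, 2, 3, 3), c(0, 0, 1, 1))
  d <- 2 / sqrt(1 / 3)
  J <- 1 - 3 / 23
  expect_equal(e$g, J * d, tolerance = 1e-10)
  expect_equal(e$var_g, 8 / 16 + (J * d)^2 / 16, tolerance = 1e-10)
  expect_equal(e$g, 3.0123, tolerance = 1e-4)
  expect_equal(e$var_g, 1.0671, tolerance = 1e-4)
})

test_that("Hedges' g is antisymmetric and zero for equal means", {
  a <- hedges_g(c(2, 2, 3, 3), c(0, 0, 1, 1))
  b <- hedges_g(c(0, 0, 1, 1), c(2, 2, 3, 3))
  expect_equal(a$g, -b$g)
  expect_equal(a$var_g, b$var_g)
  z <- hedges_g(c(1, 2, 3), c(3, 2, 1))
  expect_equal(z$g, 0)
  expect_equal(z$var_g, 6 / 9)
  expect_error(hedges_g(c(1), c(1, 2)), "at least 2")
  expect_error(hedges_g(c(1, 1), c(2, 2)), class = "metacohort_zero_variance")
})

test_that("DerSimonian-Laird pooling matches hand computation and limits", {
  # homogeneous case
  h <- dl_pool(rep(1.2, 4), rep(0.3, 4))
  expect_equal(h$q_stat, 0)
  expect_equal(h$tau2, 0)
  expect_equal(h$es_pooled, 1.2)
  expect_equal(h$se_pooled, sqrt(0.3 / 4))
  # hand oracle: g = [1, 2], var = [0.5, 0.5]
  p <- dl_pool(c(1, 2), c(0.5, 0.5))
  expect_equal(p$q_stat, 1.0, tolerance = 1e-12)
  expect_equal(p$tau2, 0)
  expect_equal(p$es_pooled, 1.5, tolerance = 1e-12)
  # weight monotonicity: a huge-variance cohort barely contributes
  lim <- dl_pool(c(0, 5), c(0.1, 1e8))
  expect_lt(abs(lim$es_pooled), 0.01)
  expect_error(dl_pool(c(1, 2), c(0.5, 0)), "> 0")
})

test_that("k = 1 passes the single effect through flagged", {
  expect_warning(p <- dl_pool(1.3, 0.4), "single-cohort")
  expect_equal(p$es_pooled, 1.3)
  expect_equal(p$tau2, 0)
})

test_that("dl_pool agrees with metafor's DL estimator", {
  skip_if_not_installed("metafor")
  set.seed(20)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    g <- rnorm(k, 1, 1)
    v <- runif(k, 0.2, 1.5)
    mine <- dl_pool(g, v)
    ref <- metafor::rma(yi = g, vi = v, method = "DL")
    expect_equal(mine$es_pooled, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(mine$se_pooled, ref$se, tolerance = 1e-10)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(mine$q_stat, ref$QE, tolerance = 1e-10)
  }
})

test_that("with tau2 = 0 pooling reduces to the fixed-effects mean and is order-invariant", {
  g <- c(1.0, 1.1, 0.9); v <- c(0.5, 0.4, 0.6)   # Q < k-1 here
  p <- dl_pool(g, v)
  expect_equal(p$tau2, 0)
  w <- 1 / v
  expect_equal(p$es_pooled, sum(w * g) / sum(w), tolerance = 1e-12)
  perm <- sample(3)
  q <- dl_pool(g[perm], v[perm])
  expect_equal(p$es_pooled, q$es_pooled, tolerance = 1e-12)
  expect_equal(p$tau2, q$tau2, tolerance = 1e-12)
})

test_that("Cochran's Q and its chi-squared p-value behave as specified", {
  h <- cochran_q(rep(2, 3), rep(0.4, 3))
  expect_equal(h$q_stat, 0)
  expect_equal(h$q_pvalue, 1)
  q1 <- cochran_q(c(1, 2), c(0.5, 0.5))
  expect_equal(q1$q_stat, 1.0, tolerance = 1e-12)
  expect_equal(q1$q_pvalue, pchisq(1, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(q1$q_pvalue, 0.3173, tolerance = 1e-4)
  # a duplicated cohort sitting exactly at the fixed-effects mean adds zero
  w <- 1 / c(0.5, 0.5); gw <- sum(w * c(1, 2)) / sum(w)
  q2 <- cochran_q(c(1, 2, gw), c(0.5, 0.5, 0.5))
  expect_equal(q2$q_stat, q1$q_stat, tolerance = 1e-12)
  expect_error(cochran_q(1, 0.5), "at least 2")
})

test_that("one-sided p-values are symmetric and match the normal tail", {
  p0 <- one_sided_pvalues(0, 0.5)
  expect_equal(p0$p_up, 0.5)
  expect_equal(p0$p_down, 0.5)
  p1 <- one_sided_pvalues(1.96, 1)
  expect_equal(p1$p_up, pnorm(1.96, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(p1$p_up, 0.0250, tolerance = 1e-4)
  pn <- one_sided_pvalues(-1.96, 1)
  expect_equal(pn$p_up, p1$p_down)
  expect_equal(pn$p_down, p1$p_up)
  set.seed(21)
  g <- rnorm(20); v <- runif(20, 0.1, 2)
  ps <- one_sided_pvalues(g, v)
  expect_equal(ps$p_up + ps$p_down, rep(1, 20))
})

test_that("Fisher's sum of logs matches the chi-squared oracle and is monotone", {
  f1 <- fisher_combine(c(1, 1, 1))
  expect_equal(f1$fisher_stat, 0)
  expect_equal(f1$combined_p, 1)
  f2 <- fisher_combine(c(0.05, 0.05))
  expect_equal(f2$fisher_stat, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(f2$fisher_stat, 11.983, tolerance = 1e-3)
  expect_equal(f2$combined_p, pchisq(-4 * log(0.05), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(f2$combined_p, 0.01747866, tolerance = 1e-6)
  f3 <- fisher_combine(c(0.01, 0.05))
  expect_gt(f3$fisher_stat, f2$fisher_stat)
  expect_lt(f3$combined_p, f2$combined_p)
  expect_warning(fz <- fisher_combine(c(0, 0.5)), "clamped")
  expect_true(is.finite(fz$fisher_stat))
})

test_that("run_meta equals the scalar operations gene by gene", {
  sim <- generate_multicohort(synthetic_config(n_genes = 60, n_signature = 10,
                                               seed = 22))
  pre <- collapse_only(sim)
  meta <- run_meta(pre, 5)
  eff <- attr(meta, "effects")
  for (gn in meta$gene[c(1, 25, 60)]) {
    gs <- vs <- numeric(0)
    for (cd in pre) {
      tr <- cd$groups == "treated"
      e <- hedges_g(cd$matrix[gn, tr], cd$matrix[gn, !tr])
      gs <- c(gs, e$g); vs <- c(vs, e$var_g)
    }
    p <- dl_pool(gs, vs)
    q <- cochran_q(gs, vs)
    row <- meta[meta$gene == gn, ]
    expect_equal(row$es_pooled, p$es_pooled, tolerance = 1e-12)
    expect_equal(row$se_pooled, p$se_pooled, tolerance = 1e-12)
    expect_equal(row$tau2, p$tau2, tolerance = 1e-12)
    expect_equal(row$q_stat, q$q_stat, tolerance = 1e-12)
    expect_equal(row$q_pvalue, q$q_pvalue, tolerance = 1e-12)
    os <- one_sided_pvalues(gs, vs)
    fu <- fisher_combine(os$p_up)
    expect_equal(row$fisher_stat_up, fu$fisher_stat, tolerance = 1e-12)
    expect_equal(row$fisher_p_up, fu$combined_p, tolerance = 1e-12)
    # effects attribute carries exactly these per-cohort effects
    er <- eff[eff$gene == gn, ]
    expect_equal(sort(er$g), sort(gs), tolerance = 1e-12)
  }
})

test_that("meta results respect their structural invariants", {
  sim <- generate_multicohort(synthetic_config(n_genes = 300, n_signature = 50,
                                               seed = 23))
  meta <- run_meta(collapse_only(sim), 5)
  eff <- attr(meta, "effects")
  rng <- do.call(rbind, lapply(split(eff$g, eff$gene), range))
  rng <- rng[meta$gene, ]
  expect_true(all(meta$es_pooled >= rng[, 1] - 1e-12))
  expect_true(all(meta$es_pooled <= rng[, 2] + 1e-12))
  expect_true(all(meta$tau2[meta$q_stat <= meta$k - 1] == 0))
  expect_true(all(meta$fisher_fdr_up >= meta$fisher_p_up - 1e-15))
  expect_true(all(meta$fisher_fdr_down >= meta$fisher_p_down - 1e-15))
})

test_that("genes measured in too few cohorts are excluded", {
  sim <- generate_multicohort(synthetic_config(n_genes = 100, n_signature = 0,
                                               probe_dropout = 0.4, seed = 24))
  pre <- collapse_only(sim)
  meta <- run_meta(pre, 5)
  per_cohort <- lapply(pre, function(cd) rownames(cd$matrix))
  counts <- table(unlist(per_cohort))
  expect_true(all(counts[meta$gene] == 5))
  expect_false(any(names(counts)[counts < 5] %in% meta$gene))
  expect_warning(empty <- run_meta(pre, 6), "no gene")
  expect_equal(nrow(empty), 0)
})

test_that("signature selection applies the joint effect/FDR/cohort thresholds", {
  meta <- data.frame(
    gene = c("a", "b", "c", "d"),
    k = c(5, 5, 5, 4),
    es_pooled = c(1.5, 0.9, -1.4, 2.0),
    se_pooled = 0.3, tau2 = 0, q_stat = 0, q_pvalue = 1,
    fisher_stat_up = 10, fisher_p_up = c(0.001, 1e-6, 0.9, 0.001),
    fisher_fdr_up = c(0.001, 1e-6, 0.9, 0.001),
    fisher_stat_down = 1, fisher_p_down = c(0.9, 0.9, 0.001, 0.9),
    fisher_fdr_down = c(0.9, 0.9, 0.001, 0.9))
  sig <- select_signature(meta, es_min = 1, fdr_max = 0.05, min_cohorts = 5)
  expect_setequal(sig$gene, c("a", "c"))
  expect_identical(sig$direction[sig$gene == "c"], "down")
  # b fails the effect-size floor despite a tiny FDR; d fails min_cohorts
  expect_false("b" %in% sig$gene)
  expect_false("d" %in% sig$gene)
})

test_that("planted genes are selected and nulls excluded at study scale", {
  sim <- generate_multicohort(synthetic_config(seed = 25))
  meta <- run_meta(collapse_only(sim), 5)
  sig <- select_signature(meta)
  truth <- sim$truth$signature_genes
  expect_gte(mean(truth %in% sig$gene), 0.9)
  expect_lte(sum(!(sig$gene %in% truth)), 3)
  expect_true(all(sig$direction[sig$gene %in% truth] == "up"))
})

test_that("geometric-mean scores follow the closed form", {
  m <- matrix(log2(c(1, 4, 2, 8)), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  sc <- geometric_mean_score(m, c("gA", "gB"))
  expect_equal(sc$score, c(1, 2))      # log2 geometric means of (1,4), (2,8)
  one <- geometric_mean_score(m, "gB")
  expect_equal(one$score, unname(m["gB", ]))
  expect_error(geometric_mean_score(m, "missing"), "no signature gene")
  expect_equal(attr(sc, "n_genes_used"), 2)
})

test_that("forest data reproduces normalized random-effects weights", {
  eff <- data.frame(gene = "g1", cohort = c("A", "B", "C", "D"),
                    g = 1.2, var_g = 0.5)
  pooled <- data.frame(gene = "g1", k = 4, es_pooled = 1.2,
                       se_pooled = sqrt(0.5 / 4), tau2 = 0)
  fd <- forest_data("g1", eff, pooled)
  expect_equal(fd$weight[1:4], rep(0.25, 4))
  expect_equal(fd$ci_low[1], 1.2 - 1.96 * sqrt(0.5))
  expect_identical(fd$cohort[5], "pooled")
  # brute-force weight recomputation on a heterogeneous gene
  set.seed(26)
  g <- rnorm(5, 1); v <- runif(5, 0.3, 1)
  p <- dl_pool(g, v)
  eff2 <- data.frame(gene = "g2", cohort = LETTERS[1:5], g = g, var_g = v)
  pooled2 <- data.frame(gene = "g2", k = 5, es_pooled = p$es_pooled,
                        se_pooled = p$se_pooled, tau2 = p$tau2)
  fd2 <- forest_data("g2", eff2, pooled2)
  w <- 1 / (v + p$tau2)
  expect_equal(fd2$weight[1:5], w / sum(w), tolerance = 1e-10)
  expect_error(forest_data("g3", eff2, pooled2), "no effects")
  expect_error(forest_data("g2", eff2, pooled2[0, ]), "does not match")
})

test_that("single-cohort forest rows carry full weight and equal the summary", {
  eff <- data.frame(gene = "g1", cohort = "A", g = 0.8, var_g = 0.2)
  pooled <- data.frame(gene = "g1", k = 1, es_pooled = 0.8,
                       se_pooled = sqrt(0.2), tau2 = 0)
  fd <- forest_data("g1", eff, pooled)
  expect_equal(fd$weight[1], 1)
  expect_equal(fd$g[1], fd$g[2])
  expect_equal(fd$ci_low[1], fd$ci_low[2])
})

test_that("directional Fisher statistics cannot be jointly extreme under one sign", {
  sim <- generate_multicohort(synthetic_config(n_genes = 200, n_signature = 40,
                                               delta = 2, seed = 27))
  meta <- run_meta(collapse_only(sim), 5)
  bound <- 0.5 * 0.5^meta$k
  expect_false(any(meta$fisher_p_up < bound & meta$fisher_p_down < bound))
})

test_that("heterogeneity p-values are approximately uniform under homogeneity", {
  # Q with estimated sampling variances at 4+4 samples is mildly
  # over-dispersed relative to chi-squared(k-1); approximate uniformity is
  # asserted at KS < 0.08 (see the methods vignette)
  sim <- generate_multicohort(synthetic_config(n_genes = 2000, n_signature = 0,
                                               seed = 28))
  meta <- run_meta(collapse_only(sim), 5)
  ks <- suppressWarnings(ks.test(meta$q_pvalue, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})
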