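# Shared fixture builders: everything is generated in code at test time.

# Collapse probe-level synthetic cohorts to gene level without quantile
# normalization (the generator draws all columns from one distribution, so
# there is no technical column effect to remove; see the methods vignette).
collapse_only <- function(sim) {
  suppressMessages(lapply(sim$cohorts, function(cd)
    cohort_dataset(collapse_probes(cd$matrix, sim$probe_map),
                   cd$groups, cd$cohort_id)))
}

# A tiny deterministic two-arm cohort built from explicit values.
tiny_cohort <- function(values, n_control, n_treated, genes = NULL,
                        cohort_id = "T1") {
  n <- n_control + n_treated
  m <- matrix(values, ncol = n)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  samples <- sprintf("s%02d", seq_len(n))
  dimnames(m) <- list(genes, samples)
  groups <- setNames(rep(c("control", "treated"), c(n_control, n_treated)),
                     samples)
  cohort_dataset(m, groups, cohort_id)
}

# Independent brute-force BH step-up (the oracle for bh_adjust).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- min(prev, 1)
  }
  q
}

# Exact hypergeometric upper tail by enumeration over all draws (universe
# small enough for choose() arithmetic to be exact).
hyper_tail_oracle <- function(overlap, set_size, query_size, universe_size) {
  kmax <- min(set_size, query_size)
  sum(vapply(overlap:kmax, function(k)
    choose(set_size, k) * choose(universe_size - set_size, query_size - k), 0)) /
    choose(universe_size, query_size)
}
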