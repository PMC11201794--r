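# Shared study configuration for the analysis scripts (sourced by 01-05).
#
# Eight synthetic cohorts emulate the sample-size spread of a typical
# multi-cohort microarray collection: arm sizes range from 1 to 16, so five
# cohorts meet the >= 2 samples/arm eligibility bar for meta-analysis and
# three do not (those are used for held-out signature validation, and the
# 1+1 cohort exercises fold-change-only DEG calling).

suppressMessages(library(metacohort))

args <- commandArgs(trailingOnly = TRUE)
i <- match("--seed", args)
STUDY_SEED <- if (!is.na(i) && i < length(args)) as.integer(args[i + 1]) else 1L

STUDY_CONFIG <- synthetic_config(
  n_cohorts = 8L,
  per_cohort_n = list(c(6L, 6L), c(7L, 8L), c(3L, 3L), c(16L, 16L),
                      c(1L, 2L), c(1L, 1L), c(1L, 1L), c(3L, 4L)),
  n_genes = 1000L,
  n_signature = 50L,
  delta = 2,
  tau2 = 0,
  probes_per_gene = 3L,
  seed = STUDY_SEED)

MIN_COHORTS <- 5L    # meta-analysis measurement + selection threshold
SHARED_MIN <- 4L     # shared-DEG reporting threshold
FDR_MAX <- 0.05
ES_MIN <- 1

FIXTURE_DIR <- "results/fixture"
RESULTS_DIR <- "results"
dir.create(FIXTURE_DIR, recursive = TRUE, showWarnings = FALSE)

eligible_ids <- function(cohorts) {
  vapply(cohorts, function(cd)
    sum(cd$groups == "treated") >= 2 && sum(cd$groups == "control") >= 2, TRUE)
}
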