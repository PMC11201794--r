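#!/usr/bin/env Rscript
# Stage 1: generate the eight-cohort synthetic study with 50 planted
# up-regulated genes (delta = 2 within-cohort SDs) and write it to disk as
# TSV fixtures, together with a toy pathway catalog whose first pathway is
# exactly the planted gene set.

source("analysis/00_config.R")

sim <- generate_multicohort(STUDY_CONFIG)
manifest <- write_fixture(sim, FIXTURE_DIR, create = TRUE)

catalog <- synthetic_pathway_catalog(sim, seed = STUDY_SEED)
write_gmt(catalog, file.path(FIXTURE_DIR, "toy_pathways.gmt"))
write.table(catalog$hierarchy, file.path(FIXTURE_DIR, "toy_hierarchy.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sizes <- vapply(sim$cohorts, function(cd)
  sprintf("%s: %d control + %d treated", cd$cohort_id,
          sum(cd$groups == "control"), sum(cd$groups == "treated")), "")
cat("simulated cohorts:\n ", paste(sizes, collapse = "\n  "), "\n")
cat(sprintf("planted signature: %d of %d genes, delta = %g, tau2 = %g\n",
            STUDY_CONFIG$n_signature, STUDY_CONFIG$n_genes,
            STUDY_CONFIG$delta, STUDY_CONFIG$tau2))
cat(sprintf("fixture written to %s (%d files)\n", FIXTURE_DIR,
            length(unlist(manifest)) + 2L))
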