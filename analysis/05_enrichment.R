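#!/usr/bin/env Rscript
# Stage 5: hypergeometric over-representation of the meta-analysis signature
# against the toy pathway catalog (universe = all genes measured in the
# meta-analysis), top-level-ancestor roll-up, and per-cohort DEG enrichment
# counted across cohorts.

source("analysis/00_config.R")

catalog <- read_gmt(file.path(FIXTURE_DIR, "toy_pathways.gmt"),
                    hierarchy = read_hierarchy(file.path(FIXTURE_DIR,
                                                         "toy_hierarchy.tsv")))
meta <- read.delim(file.path(RESULTS_DIR, "meta.tsv"))
signature <- read.delim(file.path(RESULTS_DIR, "signature.tsv"))
universe <- meta$gene

ora <- hypergeom_ora(intersect(signature$gene, universe), catalog, universe)
write.table(ora, file.path(RESULTS_DIR, "enrichment_signature.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("signature over-representation (top 3):\n")
print(ora[1:min(3, nrow(ora)), c("pathway_id", "overlap_count", "set_size",
                                 "p_raw", "p_adj")], row.names = FALSE)

roll <- rollup_ancestors(ora, catalog)
write.table(roll, file.path(RESULTS_DIR, "ancestor_rollup.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\ntop-level ancestor roll-up:\n")
print(roll, row.names = FALSE)

# per-cohort DEG enrichment over the meta-eligible cohorts
de_files <- list.files(RESULTS_DIR, pattern = "^de_C[0-9]+\\.tsv$",
                       full.names = TRUE)
per_cohort <- list()
for (df in de_files) {
  cid <- sub("^de_(C[0-9]+)\\.tsv$", "\\1", basename(df))
  d <- read.delim(df)
  degs <- intersect(d$gene[d$deg_call != "none"], universe)
  if (length(degs) >= 1)
    per_cohort[[cid]] <- hypergeom_ora(degs, catalog, universe)
}
counts <- cross_cohort_pathway_counts(per_cohort, fdr_max = FDR_MAX)
write.table(counts, file.path(RESULTS_DIR, "pathway_cohort_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("\npathways significant (FDR <= %.2f) per cohort, out of %d:\n",
            FDR_MAX, length(per_cohort)))
print(utils::head(counts, 5), row.names = FALSE)
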