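#!/usr/bin/env Rscript
# Stage 3: single-cohort differential expression under the two-tier
# thresholds (adjusted p <= 0.05 & |log2FC| >= 1, relaxing to raw p when
# nothing passes, and to fold-change-only for 1-sample arms), then
# cross-cohort shared-DEG counting.

source("analysis/00_config.R")

gene_files <- sort(list.files(FIXTURE_DIR, pattern = "_genes\\.tsv$",
                              full.names = TRUE))
stopifnot(length(gene_files) > 0)

de_tables <- list()
for (gp in gene_files) {
  cid <- sub("_genes\\.tsv$", "", basename(gp))
  cohort <- read_cohort(gp, file.path(FIXTURE_DIR, paste0(cid, "_phenotype.tsv")), cid)
  de <- cohort_de(cohort, mode = "auto", lfc_min = ES_MIN, alpha = FDR_MAX)
  write.table(de, file.path(RESULTS_DIR, paste0("de_", cid, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  de_tables[[cid]] <- de
  cat(sprintf("%s: %4d DEGs (%d up / %d down) under %s thresholds\n", cid,
              sum(de$deg_call != "none"), sum(de$deg_call == "up"),
              sum(de$deg_call == "down"), de$threshold_mode[1]))
}
cat(sprintf("mean DEGs per cohort: %.0f\n",
            mean(vapply(de_tables, function(d) sum(d$deg_call != "none"), 0))))

shared <- count_shared_degs(de_tables, min_cohorts = SHARED_MIN)
write.table(shared, file.path(RESULTS_DIR, "shared_degs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\n%d genes deregulated in at least %d of %d cohorts\n",
            nrow(shared), SHARED_MIN, length(de_tables)))
print(utils::head(shared[, c("gene", "n_deregulated", "n_up", "n_down")], 10),
      row.names = FALSE)
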