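#!/usr/bin/env Rscript
# Stage 2: per-cohort preprocessing (log2 check, quantile normalization,
# probe -> gene collapsing) and PCA-based exploratory QC. Writes the
# explained-variance table; cohorts with < 3 samples carry only the first
# component.

source("analysis/00_config.R")

probe_map <- read_probe_map(file.path(FIXTURE_DIR, "probe_map.tsv"))
expr_files <- sort(list.files(FIXTURE_DIR, pattern = "_expression\\.tsv$",
                              full.names = TRUE))
qc <- list()
for (ep in expr_files) {
  cid <- sub("_expression\\.tsv$", "", basename(ep))
  cohort <- read_cohort(ep, file.path(FIXTURE_DIR, paste0(cid, "_phenotype.tsv")), cid)
  pre <- suppressWarnings(preprocess_cohort(cohort, probe_map))
  write_expression(pre$matrix, file.path(FIXTURE_DIR, paste0(cid, "_genes.tsv")),
                   id_column = "gene_symbol")
  n_comp <- min(2L, ncol(pre$matrix) - 1L)
  fr <- pca_explained(pre$matrix, n_comp)
  qc[[cid]] <- data.frame(cohort_id = cid, n_samples = ncol(pre$matrix),
                          n_genes = nrow(pre$matrix),
                          pc1_pct = 100 * fr[1],
                          pc2_pct = if (n_comp > 1) 100 * fr[2] else NA,
                          pc12_pct = 100 * sum(fr))
}
qc <- do.call(rbind, qc)
write.table(qc, file.path(RESULTS_DIR, "pca_explained.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("per-cohort PCA explained variance (%):\n")
print(qc, row.names = FALSE, digits = 3)
cat(sprintf("\nPC1+PC2 range across cohorts with >= 2 components: %.1f-%.1f%%\n",
            min(qc$pc12_pct[!is.na(qc$pc2_pct)]),
            max(qc$pc12_pct[!is.na(qc$pc2_pct)])))
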