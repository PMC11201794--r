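#!/usr/bin/env Rscript
# Stage 4: random-effects meta-analysis over the meta-eligible cohorts
# (Hedges' g -> DerSimonian-Laird pooling, Cochran's Q, directional Fisher
# combination with BH FDR), signature selection (|ES| >= 1, Fisher FDR <=
# 0.05, measured in >= 5 cohorts), forest-plot data for the top genes, and
# geometric-mean validation scoring of the cohorts not eligible for
# meta-analysis.

source("analysis/00_config.R")

gene_files <- sort(list.files(FIXTURE_DIR, pattern = "_genes\\.tsv$",
                              full.names = TRUE))
cohorts <- lapply(gene_files, function(gp) {
  cid <- sub("_genes\\.tsv$", "", basename(gp))
  read_cohort(gp, file.path(FIXTURE_DIR, paste0(cid, "_phenotype.tsv")), cid)
})
elig <- eligible_ids(cohorts)
cat(sprintf("%d of %d cohorts eligible for meta-analysis (>= 2 samples/arm)\n",
            sum(elig), length(cohorts)))

meta <- run_meta(cohorts[elig], min_cohorts_measured = MIN_COHORTS)
write.table(meta, file.path(RESULTS_DIR, "meta.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

signature <- select_signature(meta, es_min = ES_MIN, fdr_max = FDR_MAX,
                              min_cohorts = MIN_COHORTS)
write.table(as.data.frame(signature), file.path(RESULTS_DIR, "signature.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
truth <- read.delim(file.path(FIXTURE_DIR, "ground_truth.tsv"))
planted <- unique(truth$gene_symbol)
cat(sprintf("signature: %d genes (%d up / %d down); recovers %.0f%% of the %d plants, %d false\n",
            nrow(signature), sum(signature$direction == "up"),
            sum(signature$direction == "down"),
            100 * mean(planted %in% signature$gene), length(planted),
            sum(!(signature$gene %in% planted))))
pl <- meta[meta$gene %in% planted, ]
cat(sprintf("planted genes: mean pooled ES %.2f (target %g), mean tau2 %.3f\n",
            mean(pl$es_pooled), STUDY_CONFIG$delta, mean(pl$tau2)))

# forest data for the five most significant up-regulated signature genes
effects <- attr(meta, "effects")
top <- utils::head(signature$gene[signature$direction == "up"], 5)
forest_dir <- file.path(RESULTS_DIR, "forests")
dir.create(forest_dir, showWarnings = FALSE)
for (gn in top) {
  fd <- forest_data(gn, effects, meta)
  write.table(fd, file.path(forest_dir, paste0(gn, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
cat(sprintf("forest-plot tables written for: %s\n", paste(top, collapse = ", ")))

# validation scoring: all cohorts, flagging the non-eligible ones
scores <- do.call(rbind, lapply(cohorts, score_summary, signature = signature))
scores$meta_eligible <- elig
write.table(scores, file.path(RESULTS_DIR, "signature_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
held_out <- scores[!scores$meta_eligible, ]
cat(sprintf("held-out cohorts with treated > control signature score: %d of %d\n",
            sum(held_out$diff > 0), nrow(held_out)))
print(scores[, c("cohort_id", "control_mean", "treated_mean", "diff",
                 "meta_eligible")], row.names = FALSE, digits = 3)
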