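#!/usr/bin/env Rscript
# Stage 5: chromatin-accessibility similarity. Selects the top 1% most
# variable peaks across the pooled patient + model matrix, computes
# Spearman similarity of every model to every metastatic patient, then
# summarizes per subtype and compares the two best models per subtype
# with the paired signed-rank test.

library(pcfidelity)

dir <- "results/data"
out <- "results/atac"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
wt <- function(x, f) write.table(x, file.path(out, f), sep = "\t",
                                 quote = FALSE, row.names = FALSE)

atac <- read_peak_counts(file.path(dir, "atac_counts.tsv"))
ann <- read.delim(file.path(dir, "annotations.tsv"),
                  stringsAsFactors = FALSE)
truth <- jsonlite::read_json(file.path(dir, "truth_ledger.json"))
subtype <- unlist(truth$subtype)
models <- intersect(ann$sample[ann$cohort == "cell_line"], colnames(atac))
patients <- intersect(ann$sample[ann$cohort == "metastatic"],
                      colnames(atac))

panel <- select_variable_peaks(atac)
cat(sprintf("Variable-peak panel: %d of %d peaks\n",
            length(panel$peaks), nrow(atac)))
sim <- atac_similarity(atac, panel, models, patients)
summ <- atac_subtype_summary(sim, subtype[patients])
cat("Median model-patient similarity per subtype:\n")
print(round(summ, 3))
wt(data.frame(model = rownames(sim), sim, check.names = FALSE),
   "atac_similarity.tsv")
wt(data.frame(model = rownames(summ), summ, check.names = FALSE),
   "atac_subtype_summary.tsv")

cmp <- lapply(colnames(summ), function(st) {
  pts <- patients[subtype[patients] == st]
  ord <- order(-summ[, st])
  top <- rownames(summ)[ord[1]]; second <- rownames(summ)[ord[2]]
  pc <- paired_compare(sim[top, pts], sim[second, pts])
  cat(sprintf("%s: %s vs %s over %d patients -> signed-rank p = %.4g (%s)\n",
              st, top, second, length(pts), pc$p, pc$method))
  data.frame(subtype = st, top_model = top, runner_up = second,
             n_patients = length(pts), p = pc$p, method = pc$method)
})
wt(do.call(rbind, cmp), "paired_comparisons.tsv")
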