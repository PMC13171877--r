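#!/usr/bin/env Rscript
# Stage 2: genomic concordance. Builds the mutation panel (site-wise
# Fisher screen + high-frequency rule), ranks cell lines by panel
# mutations and by the burden-normalized ratio, catalogues hotspot
# variants and their presence in cell lines, classifies hypermutated
# samples from the burden gap, validates the cutoff against MMR genes,
# and screens gene-level CNV for metastatic shifts.

library(pcfidelity)

dir <- "results/data"
out <- "results/genomics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
wt <- function(x, f) write.table(x, file.path(out, f), sep = "\t",
                                 quote = FALSE, row.names = FALSE)

maf <- read_maf(file.path(dir, "mutations.maf"))
ann <- read.delim(file.path(dir, "annotations.tsv"),
                  stringsAsFactors = FALSE)
records <- maf$records
met <- ann$sample[ann$cohort == "metastatic"]
cl <- ann$sample[ann$cohort == "cell_line"]

mat <- mutation_matrix(records, ann)
diff <- select_diff_genes(mat, ann)
high <- select_high_genes(mat, ann)
panel <- gene_panel(diff$diff_genes, high)
cat(sprintf("Panel: %d differential + %d highly mutated -> %d unique genes\n",
            length(panel$diff_genes), length(panel$high_genes),
            length(panel$union)))
wt(diff$per_site, "fisher_per_site.tsv")
wt(data.frame(gene = panel$union,
              in_diff = panel$union %in% panel$diff_genes,
              in_high = panel$union %in% panel$high_genes), "panel.tsv")

panel_rank <- rank_by_panel(mat, panel, cl)
burden <- mutation_burden(records, samples = ann$sample)
bu <- setNames(burden$burden, burden$sample)
ratio <- normalized_ratio(panel_rank$panel_count, bu[panel_rank$model])
ratio_rank <- rank_models(setNames(ratio, panel_rank$model))
names(ratio_rank)[2] <- "normalized_ratio"
cat("Top models by panel count:",
    paste(head(panel_rank$model, 3), collapse = ", "), "\n")
cat("Top models by normalized ratio:",
    paste(head(ratio_rank$model, 3), collapse = ", "), "\n")
wt(panel_rank, "panel_rank.tsv")
wt(ratio_rank, "ratio_rank.tsv")

hs <- find_hotspots(records, met)
pres <- hotspot_presence(hs, records[records$sample %in% cl, ], cl)
cat(sprintf("Hotspots: %d recurrent variants; %d carried by >=1 cell line\n",
            nrow(hs), sum(rowSums(pres) > 0)))
wt(as.data.frame(hs), "hotspots.tsv")
wt(data.frame(hotspot = rownames(pres), pres, check.names = FALSE),
   "hotspot_presence.tsv")

hy <- hypermutation_cutoff(bu)
cat(sprintf("Hypermutation: %d samples above the gap (%.2f log10 units, cutoff burden %g); bimodality separation %.1f\n",
            length(hy$hypermutated), hy$gap, hy$cutoff_burden,
            hy$bimodality$separation))
mmr <- mmr_comparison(mat, c("MLH1", "MSH2", "MSH6", "PMS2"),
                      hy$hypermutated,
                      setdiff(colnames(mat), hy$hypermutated))
cat(sprintf("MMR validation: mean mutated MMR genes %.2f (hyper) vs %.3f (other), rank-sum p = %.3g\n",
            mmr$mean_hyper, mmr$mean_other, mmr$p))
jsonlite::write_json(list(hypermutated = hy$hypermutated,
                          cutoff_burden = hy$cutoff_burden, gap = hy$gap,
                          mmr_p = mmr$p),
                     file.path(out, "hypermutation.json"),
                     auto_unbox = TRUE, digits = NA)

seg <- read_seg(file.path(dir, "cnv.seg"))
gm <- read.delim(file.path(dir, "gene_models.tsv"), stringsAsFactors = FALSE)
gene_cnv <- segments_to_gene_cnv(seg, gm)
cnv <- differential_cnv(gene_cnv, ann)
sig <- cnv[which(cnv$significant), ]
cat(sprintf("CNV: %d genes beyond |delta| > 0.3 at adjusted p < 0.05; AR delta = %.2f\n",
            nrow(sig), cnv$delta[cnv$gene == "AR"]))
wt(cnv, "cnv_differential.tsv")
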