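#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-omics cohort that stands in for
# the consortium datasets (primary cohort, three metastatic sites, a
# cell-line panel, single cells, CNV segments, ATAC peaks) and write it
# to results/data in the standard formats, together with the planted
# truth ledger.

library(pcfidelity)

seed <- 1L
cfg <- sim_config(seed = seed)
cohort <- simulate_cohort(cfg)
dir <- "results/data"
write_cohort(cohort, dir)

ann <- cohort$annotations
cat("Cohort written to", dir, "\n")
cat(sprintf("  samples: %d primary, %d metastatic (%s), %d cell lines\n",
            sum(ann$cohort == "primary"), sum(ann$cohort == "metastatic"),
            paste(names(cfg$n_met_per_site), cfg$n_met_per_site,
                  collapse = ", "),
            sum(ann$cohort == "cell_line")))
cat(sprintf("  %d genes, %d mutation records, %d ATAC peaks\n",
            nrow(cohort$bulk), nrow(cohort$records), nrow(cohort$atac)))
cat(sprintf("  planted: %d differential genes, %d hypermutators, %d hotspots\n",
            length(cohort$truth$diff_genes),
            length(cohort$truth$hypermutated_samples),
            nrow(cohort$truth$hotspots)))
cat(sprintf("  matched models: %s\n",
            paste(names(cohort$truth$matched_models),
                  cohort$truth$matched_models, sep = "->", collapse = ", ")))
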