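# Small in-code fixtures shared across test files.

toy_records <- function() {
  data.frame(
    gene = c("TP53", "TP53", "AR", "AR", "SPOP", "SPOP", "MUC16"),
    sample = c("S1", "S2", "S2", "S3", "S1", "S4", "S3"),
    variant_class = c("Missense_Mutation", "Missense_Mutation",
                      "Missense_Mutation", "Silent", "Nonsense_Mutation",
                      "Frame_Shift_Del", "Missense_Mutation"),
    protein_change = c("p.R175H", "p.R175H", "p.T878A", "", "p.F133V",
                       "p.K16fs", "p.A100T"),
    stringsAsFactors = FALSE)
}

toy_annotations <- function() {
  data.frame(
    sample = c("S1", "S2", "S3", "S4"),
    cohort = c("primary", "metastatic", "metastatic", "cell_line"),
    site = c("primary", "bone", "liver", "none"),
    stringsAsFactors = FALSE)
}

# A tiny expression matrix with named genes and controlled variances.
toy_expression <- function() {
  set.seed(42)
  genes <- c("AR", "SYP", "CD44", "CD8A", "CD8B", "GZMA", "GZMB", "PRF1",
             paste0("G", 1:12))
  m <- matrix(stats::runif(length(genes) * 6, 1, 5), nrow = length(genes),
              dimnames = list(genes, paste0("X", 1:6)))
  m
}

# Fast small simulation config for generator-heavy tests.
small_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed, n_primary = 60L,
    n_met_per_site = c(bone = 20L, liver = 15L, lymph_node = 15L),
    n_cell_lines = 6L, n_genes = 300L, n_diff_genes = 10L,
    n_hotspots = 4L, n_peaks = 400L, n_cells_per_sample = 5L,
    n_sc_per_subtype = 2L, n_normal_cells_per_type = 10L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
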