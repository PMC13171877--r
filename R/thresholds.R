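#' Analysis thresholds
#'
#' Bundles every cutoff used across the pipeline so stages share one
#' configuration object. Defaults follow the published analysis protocol:
#' BH-adjusted significance at 0.05, site replication at 2, the strict 5%
#' high-mutation rule, hotspot recurrence at 3 samples, +/-0.3 copy-number
#' delta, |log2FC| > 1 for differential expression, 1000 highly variable
#' genes, 5000 lineage genes, the top 1% of variable peaks, the top-quartile
#' MSPC rule, and 200 / 1000 top PC1 features for genes / peaks.
#'
#' @param alpha_adj adjusted p-value cutoff.
#' @param min_sites_sig minimum number of metastatic sites in which a gene
#'   must qualify (significance or frequency rule).
#' @param high_mut_freq per-site mutation frequency that must be strictly
#'   exceeded for the "highly mutated" list.
#' @param hotspot_min_samples minimum distinct metastatic carriers for a
#'   hotspot variant.
#' @param cnv_delta absolute difference of median gene-level copy number
#'   (log-ratio scale) required to call a CNV shift.
#' @param de_abs_log2fc absolute log2 fold-change cutoff for DE calls.
#' @param n_hvg size of the highly-variable-gene panel.
#' @param n_lineage_genes size of the lineage gene panel.
#' @param peak_top_frac fraction of most-variable ATAC peaks retained.
#' @param mspc_quantile quantile defining the "top quartile" MSPC rule
#'   (scores at or above the 1 - mspc_quantile quantile qualify).
#' @param n_pc1_genes,n_pc1_peaks number of top positive PC1 loadings
#'   extracted for genes and peaks respectively.
#' @param gap_top_frac fraction of top burden ranks searched for the
#'   hypermutation gap.
#' @param gap_min minimum gap (log10 units) accepted as a natural cutoff.
#'
#' @return A named list of class \code{"pcf_thresholds"}.
#' @export
default_thresholds <- function(alpha_adj = 0.05,
                               min_sites_sig = 2L,
                               high_mut_freq = 0.05,
                               hotspot_min_samples = 3L,
                               cnv_delta = 0.3,
                               de_abs_log2fc = 1.0,
                               n_hvg = 1000L,
                               n_lineage_genes = 5000L,
                               peak_top_frac = 0.01,
                               mspc_quantile = 0.25,
                               n_pc1_genes = 200L,
                               n_pc1_peaks = 1000L,
                               gap_top_frac = 0.20,
                               gap_min = 0.5) {
  th <- list(alpha_adj = alpha_adj, min_sites_sig = as.integer(min_sites_sig),
             high_mut_freq = high_mut_freq,
             hotspot_min_samples = as.integer(hotspot_min_samples),
             cnv_delta = cnv_delta, de_abs_log2fc = de_abs_log2fc,
             n_hvg = as.integer(n_hvg),
             n_lineage_genes = as.integer(n_lineage_genes),
             peak_top_frac = peak_top_frac, mspc_quantile = mspc_quantile,
             n_pc1_genes = as.integer(n_pc1_genes),
             n_pc1_peaks = as.integer(n_pc1_peaks),
             gap_top_frac = gap_top_frac, gap_min = gap_min)
  num <- unlist(th)
  if (any(num <= 0)) stop("all thresholds must be positive")
  fr <- c(th$high_mut_freq, th$peak_top_frac, th$mspc_quantile, th$gap_top_frac)
  if (any(fr <= 0 | fr >= 1)) stop("fractional thresholds must lie in (0, 1)")
  class(th) <- "pcf_thresholds"
  th
}

#' MAF variant classes treated as silent / non-coding
#'
#' Everything outside this list counts as non-synonymous. The list is
#' configurable wherever it is consumed.
#'
#' @return Character vector of Variant_Classification values.
#' @export
silent_classes <- function() {
  c("Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
    "RNA", "IGR", "Splice_Region")
}

#' Known MAF variant classification vocabulary
#'
#' @return Character vector: non-synonymous classes followed by the silent
#'   classes from \code{\link{silent_classes}}.
#' @export
variant_vocabulary <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site", silent_classes())
}
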