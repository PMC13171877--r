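# Recovery benchmarking: run the full analysis stack on seeded synthetic
# cohorts and score how well each stage recovers the planted ground truth.
# This is the package's primary evidence that the procedures do what they
# claim under the emulated study conditions.

#' Ground-truth recovery benchmark over seeded cohorts
#'
#' For each seed: simulates a default cohort, runs every analysis stage,
#' and scores it against the truth ledger — exact recovery of the
#' hypermutator set, sensitivity/false-discovery proportion of the
#' differential mutation screen, whether each designated matched cell line
#' ranks first in the transcriptomic correlation ranking against its
#' subtype's metastatic references, single-cell lineage accuracy, balanced
#' accuracy of the MSPC quartile rule, recovery of the planted AR
#' amplification, the cytotoxicity-score contrast in hypermutated
#' primaries, and (optionally) whether each matched model tops the ATAC
#' similarity within its subtype.
#'
#' @param seeds integer vector of simulation seeds.
#' @param config_fun function(seed) returning a \code{\link{sim_config}}.
#' @param thresholds see \code{\link{default_thresholds}}.
#' @param include_atac also score chromatin-accessibility recovery.
#' @return data.frame with one row per seed.
#' @export
recovery_benchmark <- function(seeds = 1:20, config_fun = sim_config,
                               thresholds = default_thresholds(),
                               include_atac = TRUE) {
  rows <- lapply(seeds, function(s) {
    cfg <- config_fun(s)
    co <- simulate_cohort(cfg)
    ann <- co$annotations
    cl <- ann$sample[ann$cohort == "cell_line"]
    met <- ann$sample[ann$cohort == "metastatic"]
    pri <- ann$sample[ann$cohort == "primary"]
    truth <- co$truth

    mat <- mutation_matrix(co$records, ann)
    burden <- stats::setNames(co$burden$burden, co$burden$sample)
    hy <- hypermutation_cutoff(burden, thresholds)
    hyper_exact <- identical(hy$hypermutated, truth$hypermutated_samples)

    diff <- select_diff_genes(mat, ann, thresholds)
    sens <- mean(truth$diff_genes %in% diff$diff_genes)
    fdp <- if (length(diff$diff_genes))
      mean(!(diff$diff_genes %in% truth$diff_genes)) else 0

    gene_cnv <- segments_to_gene_cnv(co$segments, co$gene_models)
    cnv <- differential_cnv(gene_cnv, ann, thresholds)
    ar <- cnv[cnv$gene == "AR", ]
    cnv_ar <- isTRUE(ar$significant) && abs(ar$delta) > thresholds$cnv_delta

    hvg <- select_hvg(co$bulk[, cl, drop = FALSE], thresholds$n_hvg)
    sim_tab <- similarity_table(co$bulk[, cl, drop = FALSE],
                                co$bulk[, met, drop = FALSE], hvg)
    tc_top1 <- all(vapply(names(truth$matched_models), function(st) {
      refs <- met[truth$subtype[met] == st]
      r <- rank_models(sim_tab[, refs, drop = FALSE])
      r$rank[r$model == truth$matched_models[[st]]] == 1L
    }, logical(1)))

    ref <- build_lineage_reference(co$normal_sc, co$normal_meta$cell_type,
                                   thresholds$n_lineage_genes)
    lin <- suppressWarnings(assign_lineage(co$sc, ref))
    lineage_acc <- mean(lin$lineage == truth$cell_lineage[lin$cell])

    scores <- ssgsea(co$bulk[, met, drop = FALSE], co$gene_sets)
    st_truth <- truth$subtype[met]
    label_map <- st_truth[st_truth %in% c("ARPC", "NEPC")]
    calls <- call_mspc(scores, label_map, thresholds = thresholds)
    is_mspc <- calls$subtype == "MSPC"
    truth_mspc <- st_truth[calls$sample] == "MSPC"
    sens_m <- if (any(truth_mspc)) mean(is_mspc[truth_mspc]) else NA
    spec_m <- if (any(!truth_mspc)) mean(!is_mspc[!truth_mspc]) else NA
    mspc_ba <- mean(c(sens_m, spec_m))

    ctl <- ctl_score(co$bulk, pri)
    hp <- intersect(truth$hypermutated_samples, pri)
    ctl_pos <- length(hp) > 0 &&
      mean(ctl[hp]) > mean(ctl[setdiff(pri, hp)])

    atac_top1 <- NA
    if (include_atac) {
      panel <- select_variable_peaks(co$atac, thresholds$peak_top_frac)
      a_models <- intersect(cl, colnames(co$atac))
      a_pat <- intersect(met, colnames(co$atac))
      a_sim <- atac_similarity(co$atac, panel, a_models, a_pat)
      a_sum <- atac_subtype_summary(a_sim, truth$subtype[a_pat])
      atac_top1 <- all(vapply(names(truth$matched_models), function(st)
        rownames(a_sum)[which.max(a_sum[, st])] ==
          truth$matched_models[[st]], logical(1)))
    }

    data.frame(seed = s, hyper_exact = hyper_exact, diff_sens = sens,
               diff_fdp = fdp, cnv_ar = cnv_ar, tc_top1 = tc_top1,
               lineage_acc = lineage_acc, mspc_ba = mspc_ba,
               ctl_pos = ctl_pos, atac_top1 = atac_top1)
  })
  do.call(rbind, rows)
}

#' Null-cohort control benchmark
#'
#' Runs the screening stages on cohorts with every planted effect removed
#' (\code{\link{null_sim_config}}) and records the false-positive count of
#' the differential-mutation screen, the size of its tested universe,
#' whether the hypermutation gap search correctly reports no natural
#' cutoff, and which model happens to win the transcriptomic ranking —
#' under the null the winner should be exchangeable across models.
#'
#' @param seeds integer vector of simulation seeds.
#' @param thresholds see \code{\link{default_thresholds}}.
#' @return data.frame with one row per seed.
#' @export
null_benchmark <- function(seeds = 1:20,
                           thresholds = default_thresholds()) {
  rows <- lapply(seeds, function(s) {
    cfg <- null_sim_config(s)
    design <- sim_design(cfg)
    mut <- simulate_mutations(cfg, design)
    expr <- simulate_expression(cfg, mut$truth, design)
    ann <- mut$annotations
    cl <- ann$sample[ann$cohort == "cell_line"]
    met <- ann$sample[ann$cohort == "metastatic"]
    mat <- mutation_matrix(mut$records, ann)
    diff <- select_diff_genes(mat, ann, thresholds)
    burden <- stats::setNames(mut$burden$burden, mut$burden$sample)
    hy <- hypermutation_cutoff(burden, thresholds)
    hvg <- select_hvg(expr$bulk[, cl, drop = FALSE], thresholds$n_hvg)
    sim_tab <- similarity_table(expr$bulk[, cl, drop = FALSE],
                                expr$bulk[, met, drop = FALSE], hvg)
    r <- rank_models(sim_tab)
    data.frame(seed = s, fp = length(diff$diff_genes),
               genes_tested = length(unique(diff$per_site$gene)),
               no_cutoff = hy$no_cutoff, winner = r$model[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
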