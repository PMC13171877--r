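# End-to-end orchestration: runs the genomic, transcriptomic, subtype,
# lineage and ATAC stages on a (typically synthetic) cohort and distils a
# per-model fidelity report. Every stage logs counts in/out for its
# filters, since the analysis's headline numbers are exactly such counts.

stage_requirements <- list(
  genomics = c("records", "annotations", "burden", "segments", "gene_models"),
  tc = c("bulk", "annotations"),
  subtype = c("bulk", "gene_sets", "annotations", "sc"),
  lineage = c("normal_sc", "normal_meta", "sc"),
  atac = c("atac", "annotations"))

#' Run the full fidelity pipeline
#'
#' Stages run in dependency order on a synthetic cohort (default) or any
#' cohort-shaped list of inputs; a pre-flight check rejects the run before
#' any computation when a requested stage lacks its inputs. All
#' non-simulation stages are pure functions of inputs + thresholds, so a
#' rerun with identical configuration is byte-identical. When
#' \code{out_dir} is given, stage tables, the fidelity report and a
#' manifest (seed, thresholds, input sizes) are written there.
#'
#' @param cohort a \code{\link{simulate_cohort}} result, or NULL to
#'   simulate from \code{sim}.
#' @param sim a \code{\link{sim_config}} used when \code{cohort} is NULL.
#' @param stages subset of c("genomics", "tc", "subtype", "lineage",
#'   "atac").
#' @param thresholds see \code{\link{default_thresholds}}.
#' @param label_map named sample -> "ARPC"/"NEPC" map used by the MSPC
#'   quartile rule; for synthetic cohorts it defaults to the planted
#'   ARPC/NEPC labels of metastatic samples (standing in for the source
#'   annotations real data provide).
#' @param out_dir optional output directory.
#' @return list with one element per stage plus \code{report} (the
#'   per-model fidelity table) and \code{log} (filter counts).
#' @export
run_pipeline <- function(cohort = NULL, sim = sim_config(),
                         stages = c("genomics", "tc", "subtype", "lineage",
                                    "atac"),
                         thresholds = default_thresholds(),
                         label_map = NULL, out_dir = NULL) {
  stages <- match.arg(stages, names(stage_requirements), several.ok = TRUE)
  if (is.null(cohort)) cohort <- simulate_cohort(sim)
  missing_in <- unlist(lapply(stages, function(s)
    setdiff(stage_requirements[[s]], names(cohort)[!vapply(cohort, is.null,
                                                           logical(1))])))
  if (length(missing_in))
    stop_fmt("pre-flight: missing input(s) for requested stage(s): %s",
             paste(unique(missing_in), collapse = ", "))
  ann <- cohort$annotations
  cl <- ann$sample[ann$cohort == "cell_line"]
  met <- ann$sample[ann$cohort == "metastatic"]
  pri <- ann$sample[ann$cohort == "primary"]
  res <- list()
  log <- list()

  if ("genomics" %in% stages) {
    mat <- mutation_matrix(cohort$records, ann)
    diff <- select_diff_genes(mat, ann, thresholds)
    high <- select_high_genes(mat, ann, thresholds)
    panel <- gene_panel(diff$diff_genes, high)
    panel_rank <- rank_by_panel(mat, panel, cl)
    burden <- stats::setNames(cohort$burden$burden, cohort$burden$sample)
    ratio <- normalized_ratio(panel_rank$panel_count,
                              burden[panel_rank$model])
    ratio_rank <- rank_models(stats::setNames(ratio, panel_rank$model))
    names(ratio_rank)[2] <- "normalized_ratio"
    hotspots <- find_hotspots(cohort$records, met, thresholds)
    presence <- hotspot_presence(
      hotspots, cohort$records[cohort$records$sample %in% cl, ], cl)
    hyper <- hypermutation_cutoff(burden, thresholds)
    mmr <- if (length(hyper$hypermutated) >= 2L)
      mmr_comparison(mat, mmr_genes(), hyper$hypermutated,
                     setdiff(colnames(mat), hyper$hypermutated)) else NULL
    gene_cnv <- segments_to_gene_cnv(cohort$segments, cohort$gene_models)
    cnv <- differential_cnv(gene_cnv, ann, thresholds)
    res$genomics <- list(matrix = mat, diff = diff, high_genes = high,
                         panel = panel, panel_rank = panel_rank,
                         ratio_rank = ratio_rank, hotspots = hotspots,
                         presence = presence, hypermutation = hyper,
                         mmr = mmr, gene_cnv = gene_cnv, cnv = cnv)
    log$genomics <- c(genes_tested = nrow(mat),
                      diff_genes = length(diff$diff_genes),
                      high_genes = length(high),
                      panel_size = length(panel$union),
                      hotspots = nrow(hotspots),
                      hypermutated = length(hyper$hypermutated),
                      cnv_significant = sum(cnv$significant, na.rm = TRUE))
  }

  if ("tc" %in% stages) {
    hvg <- select_hvg(cohort$bulk[, cl, drop = FALSE], thresholds$n_hvg)
    sim_tab <- similarity_table(cohort$bulk[, cl, drop = FALSE],
                                cohort$bulk[, met, drop = FALSE], hvg)
    ranking <- rank_models(sim_tab)
    sites <- sort(unique(ann$site[ann$cohort == "metastatic"]))
    by_site <- lapply(sites, function(s) {
      ss <- ann$sample[ann$cohort == "metastatic" & ann$site == s]
      rank_models(sim_tab[, ss, drop = FALSE])
    })
    names(by_site) <- sites
    consistency <- site_consistency(by_site)
    ctl <- ctl_score(cohort$bulk, pri)
    res$tc <- list(hvg = hvg, similarity = sim_tab, ranking = ranking,
                   by_site = by_site, site_consistency = consistency,
                   ctl = ctl)
    log$tc <- c(hvg = length(hvg$genes), models = length(cl),
                references = length(met))
  }

  if ("subtype" %in% stages) {
    scores <- ssgsea(cohort$bulk[, met, drop = FALSE], cohort$gene_sets)
    if (is.null(label_map) && !is.null(cohort$truth)) {
      st <- cohort$truth$subtype[met]
      label_map <- st[st %in% c("ARPC", "NEPC")]
    }
    calls <- call_mspc(scores, label_map %||% character(),
                       thresholds = thresholds)
    pos_group <- if (!is.null(cohort$truth))
      intersect(cl, names(cohort$truth$subtype)[
        cohort$truth$subtype == "MSPC"]) else NULL
    pca <- pc1_top_loadings(cohort$bulk[, cl, drop = FALSE],
                            thresholds$n_pc1_genes,
                            positive_group = pos_group)
    ora <- ora_hypergeometric(pca$features, cohort$gene_sets,
                              rownames(cohort$bulk))
    cell_calls <- call_subtype_markers(cohort$sc)
    model_calls <- call_subtype_markers(cohort$bulk[, cl, drop = FALSE])
    res$subtype <- list(scores = scores, calls = calls, pca = pca,
                        ora = ora, cell_calls = cell_calls,
                        model_calls = model_calls)
    log$subtype <- c(samples_scored = nrow(scores),
                     mspc_called = sum(calls$subtype == "MSPC"),
                     cells_called = nrow(cell_calls))
  }

  if ("lineage" %in% stages) {
    ref <- build_lineage_reference(cohort$normal_sc,
                                   cohort$normal_meta$cell_type,
                                   thresholds$n_lineage_genes)
    cells <- assign_lineage(cohort$sc, ref)
    res$lineage <- list(reference = ref, cells = cells)
    log$lineage <- c(panel = length(ref$panel), cells = nrow(cells))
  }

  if ("atac" %in% stages) {
    atac_samples <- colnames(cohort$atac)
    a_models <- intersect(cl, atac_samples)
    a_patients <- intersect(met, atac_samples)
    panel <- select_variable_peaks(cohort$atac, thresholds$peak_top_frac)
    sim_tab <- atac_similarity(cohort$atac, panel, a_models, a_patients)
    st_map <- if (!is.null(cohort$truth))
      cohort$truth$subtype[a_patients] else
      stats::setNames(ann$site[match(a_patients, ann$sample)], a_patients)
    summary <- atac_subtype_summary(sim_tab, st_map)
    res$atac <- list(panel = panel, similarity = sim_tab,
                     subtype_summary = summary)
    log$atac <- c(peaks = nrow(cohort$atac), panel = length(panel$peaks),
                  models = length(a_models), patients = length(a_patients))
  }

  res$report <- build_fidelity_report(res, cl)
  res$log <- log
  if (!is.null(out_dir)) write_pipeline_outputs(res, cohort, thresholds,
                                                out_dir)
  res
}

# Consolidate stage tables into one row per model.
build_fidelity_report <- function(res, cell_lines) {
  rep <- data.frame(model = cell_lines, stringsAsFactors = FALSE)
  if (!is.null(res$genomics)) {
    g <- res$genomics
    i <- match(rep$model, g$panel_rank$model)
    rep$panel_count <- g$panel_rank$panel_count[i]
    rep$panel_rank <- g$panel_rank$rank[i]
    j <- match(rep$model, g$ratio_rank$model)
    rep$normalized_ratio <- g$ratio_rank$normalized_ratio[j]
    rep$ratio_rank <- g$ratio_rank$rank[j]
    rep$hotspots_carried <- colSums(g$presence)[rep$model]
    rep$hypermutated <- rep$model %in% g$hypermutation$hypermutated
  }
  if (!is.null(res$tc)) {
    i <- match(rep$model, res$tc$ranking$model)
    rep$tc_similarity <- res$tc$ranking$similarity[i]
    rep$tc_rank <- res$tc$ranking$rank[i]
  }
  if (!is.null(res$subtype)) {
    i <- match(rep$model, res$subtype$model_calls$cell)
    rep$subtype_call <- res$subtype$model_calls$subtype[i]
  }
  if (!is.null(res$atac)) {
    s <- res$atac$subtype_summary
    i <- match(rep$model, rownames(s))
    for (st in colnames(s)) rep[[paste0("atac_", st)]] <- s[i, st]
  }
  rep
}

write_pipeline_outputs <- function(res, cohort, thresholds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$genomics)) {
    g <- res$genomics
    wt(data.frame(gene = g$panel$union,
                  in_diff = g$panel$union %in% g$panel$diff_genes,
                  in_high = g$panel$union %in% g$panel$high_genes), "panel.tsv")
    wt(g$panel_rank, "panel_rank.tsv")
    wt(g$ratio_rank, "ratio_rank.tsv")
    wt(as.data.frame(g$hotspots), "hotspots.tsv")
    wt(g$cnv, "cnv_differential.tsv")
    jsonlite::write_json(
      list(cutoff_burden = g$hypermutation$cutoff_burden,
           gap = g$hypermutation$gap,
           no_cutoff = g$hypermutation$no_cutoff,
           hypermutated = g$hypermutation$hypermutated,
           bimodality_separation = g$hypermutation$bimodality$separation),
      file.path(out_dir, "hypermutation.json"), auto_unbox = TRUE,
      digits = NA)
  }
  if (!is.null(res$tc)) wt(res$tc$ranking, "tc_ranking.tsv")
  if (!is.null(res$subtype)) wt(res$subtype$calls, "subtype_calls.tsv")
  if (!is.null(res$lineage)) wt(res$lineage$cells, "lineage_calls.tsv")
  if (!is.null(res$atac))
    wt(data.frame(model = rownames(res$atac$subtype_summary),
                  res$atac$subtype_summary, check.names = FALSE),
       "atac_subtype_summary.tsv")
  wt(res$report, "fidelity_report.tsv")
  manifest <- list(seed = cohort$config$seed %||% NA,
                   thresholds = unclass(thresholds),
                   stages = names(res$log),
                   log = lapply(res$log, as.list),
                   n_samples = nrow(cohort$annotations),
                   n_genes = if (!is.null(cohort$bulk)) nrow(cohort$bulk)
                             else NA)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Consolidated report over written pipeline outputs
#'
#' Reads the stage tables written by \code{\link{run_pipeline}}, verifies
#' that the fidelity report's ranks reproduce the stage rankings, and
#' writes a human-readable summary with explicit markers for stages that
#' were not run.
#'
#' @param out_dir directory produced by \code{\link{run_pipeline}}.
#' @return list(report, summary_lines), invisibly writes summary.txt.
#' @export
fidelity_report <- function(out_dir) {
  fr_path <- file.path(out_dir, "fidelity_report.tsv")
  if (!file.exists(fr_path))
    stop_fmt("no fidelity_report.tsv in '%s'", out_dir)
  rep <- utils::read.delim(fr_path, stringsAsFactors = FALSE)
  lines <- c("Model fidelity summary", "======================")
  tc_path <- file.path(out_dir, "tc_ranking.tsv")
  if (file.exists(tc_path) && "tc_rank" %in% names(rep)) {
    tc <- utils::read.delim(tc_path, stringsAsFactors = FALSE)
    if (!identical(rep$tc_rank[match(tc$model, rep$model)], tc$rank))
      stop_fmt("fidelity report ranks inconsistent with tc_ranking.tsv")
    lines <- c(lines, sprintf("Top transcriptomic model: %s (rho = %.3f)",
                              tc$model[1], tc$similarity[1]))
  } else lines <- c(lines, "[transcriptomic stage not run]")
  hy_path <- file.path(out_dir, "hypermutation.json")
  if (file.exists(hy_path)) {
    hy <- jsonlite::read_json(hy_path)
    lines <- c(lines, sprintf("Hypermutated samples: %d (gap %.2f log10)",
                              length(hy$hypermutated),
                              as.numeric(hy$gap %||% NA)))
  } else lines <- c(lines, "[genomic stage not run]")
  for (i in seq_len(nrow(rep)))
    lines <- c(lines, paste(names(rep), rep[i, ], sep = "=",
                            collapse = " "))
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(list(report = rep, summary_lines = lines))
}
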