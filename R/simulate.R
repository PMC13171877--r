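# Seeded synthetic multi-omics cohort generator. Emulates the statistical
# structure the downstream analyses assume: a large primary cohort, three
# metastatic sites, a small cell-line panel, bimodal mutation burden driven
# by a hypermutator subpopulation, subtype expression programs
# (ARPC/NEPC/MSPC), normal epithelial lineage references, and
# subtype-linked ATAC peak blocks. Every planted entity is recorded in a
# truth ledger for recovery benchmarking.

lineage_markers <- function() {
  list(luminal = c("AR", "KLK2", "KLK3", "KLK4", "ACPP"),
       basal = c("KRT5", "TP63", "KRT17", "KRT15"),
       neuroendocrine = c("ASCL1", "FOXA2", "MYCN", "POU3F2", "SIAH2",
                          "NCAM1", "CHGA", "CHGB", "SYP", "ENO2"))
}

immune_genes <- function() {
  c("CD3D", "CD3E", "CD8A", "CD8B", "GZMA", "GZMB", "PRF1", "PDCD1", "CTLA4")
}

mmr_genes <- function() c("MLH1", "MSH2", "MSH6", "PMS2")

mspc_markers <- function() c("CD44", "VIM", "TP63", "KRT5", "KRT17", "KRT15")

#' Configuration of the synthetic multi-omics cohort
#'
#' Defaults define the study conditions emulated throughout: 300 primary
#' samples, metastatic samples from three sites (bone 60, liver 40,
#' lymph node 40), 12 cell-line models, 2000 genes including the named
#' marker, immune and mismatch-repair genes, 40 genes with metastatic
#' mutation probability elevated by \code{diff_delta}, 3% hypermutators
#' with 30-fold burden scaling, 10 planted hotspot variants, an
#' ARPC/NEPC/MSPC mix of 0.55/0.20/0.25, and 10000 ATAC peaks with 5%
#' subtype-specific accessible blocks. A single root seed drives
#' independent sub-streams per data modality, so changing one modality's
#' parameters does not perturb the others.
#'
#' @param seed root random seed (integer).
#' @param n_primary number of primary samples.
#' @param n_met_per_site named counts for bone, liver, lymph_node.
#' @param n_cell_lines number of cell-line models.
#' @param n_genes total genes (>= 150; includes the named genes).
#' @param n_diff_genes planted differentially mutated genes.
#' @param diff_delta added metastatic mutation probability for those genes.
#' @param hyper_frac fraction of hypermutated samples.
#' @param hyper_multiplier per-gene probability scaling in hypermutators
#'   (capped at 0.95).
#' @param mmr_hyper_prob mutation probability of MMR genes in
#'   hypermutators (NA leaves them at baseline).
#' @param n_hotspots planted recurrent protein changes.
#' @param subtype_mix ARPC/NEPC/MSPC proportions among metastatic samples
#'   and cell lines (must sum to 1).
#' @param expr_noise_sd bulk expression noise, log2 units.
#' @param sc_noise_sd single-cell (overdispersed) noise, log2 units.
#' @param n_cells_per_sample malignant cells simulated per profiled sample.
#' @param n_sc_per_subtype metastatic samples profiled at single-cell
#'   level per subtype.
#' @param n_normal_cells_per_type normal epithelial cells per lineage.
#' @param marker_shift log2 elevation of subtype/lineage marker genes.
#' @param program_shift log2 elevation of the EMT/stemness program genes
#'   in MSPC.
#' @param imm_delta log2 elevation of immune genes in hypermutated
#'   primaries.
#' @param model_offset_sd per-line systematic offset sd for non-designated
#'   models.
#' @param silent_rate_factor silent-variant rate relative to the
#'   non-synonymous rate.
#' @param n_peaks number of ATAC peaks.
#' @param peak_frac_per_subtype fraction of peaks elevated per subtype.
#' @param atac_shift log2 elevation of subtype peak blocks.
#' @param atac_noise_sd ATAC noise, log2 units.
#' @param plant_matched designate one best-model cell line per subtype
#'   sharing that subtype's centroid exactly.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_primary = 300L,
                       n_met_per_site = c(bone = 60L, liver = 40L,
                                          lymph_node = 40L),
                       n_cell_lines = 12L,
                       n_genes = 2000L,
                       n_diff_genes = 40L,
                       diff_delta = 0.10,
                       hyper_frac = 0.03,
                       hyper_multiplier = 30,
                       mmr_hyper_prob = 0.4,
                       n_hotspots = 10L,
                       subtype_mix = c(ARPC = 0.55, NEPC = 0.20,
                                       MSPC = 0.25),
                       expr_noise_sd = 0.4,
                       sc_noise_sd = 0.8,
                       n_cells_per_sample = 20L,
                       n_sc_per_subtype = 4L,
                       n_normal_cells_per_type = 50L,
                       marker_shift = 3,
                       program_shift = 2,
                       imm_delta = 1.5,
                       model_offset_sd = 1.0,
                       silent_rate_factor = 0.3,
                       n_peaks = 10000L,
                       peak_frac_per_subtype = 0.05,
                       atac_shift = 2,
                       atac_noise_sd = 0.3,
                       plant_matched = TRUE) {
  cfg <- as.list(environment())
  if (abs(sum(subtype_mix) - 1) > 1e-8)
    stop_fmt("subtype_mix must sum to 1")
  if (hyper_multiplier < 1) stop_fmt("hyper_multiplier must be >= 1")
  counts <- c(n_primary, n_met_per_site, n_cell_lines, n_genes,
              n_diff_genes, n_hotspots, n_cells_per_sample, n_peaks)
  if (any(counts <= 0)) stop_fmt("all counts must be positive")
  if (n_genes < 150L) stop_fmt("n_genes must be at least 150")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  cfg$mod_seeds <- stats::setNames(
    sample.int(.Machine$integer.max - 1L, 5),
    c("design", "mut", "expr", "cnv", "atac"))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  class(cfg) <- "sim_config"
  cfg
}

#' Null configuration: all planted effects removed
#'
#' Same cohort layout as \code{\link{sim_config}} but with zero
#' differential-mutation delta, no hypermutator scaling, no MMR
#' enrichment, no immune shift, flat expression/ATAC centroids, and no
#' designated matched model — so every analysis faces pure noise.
#'
#' @param seed root random seed.
#' @param ... overrides passed to \code{\link{sim_config}}.
#' @return a \code{"sim_config"}.
#' @export
null_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, diff_delta = 0, hyper_multiplier = 1,
             mmr_hyper_prob = NA_real_, imm_delta = 0, marker_shift = 0,
             program_shift = 0, atac_shift = 0, plant_matched = FALSE, ...)
}

# Gene universe: named marker/immune/MMR genes first, then the EMT and
# stemness program genes, then anonymous filler genes.
sim_genes <- function(config) {
  named <- unique(c(unlist(lineage_markers()), mspc_markers(),
                    immune_genes(), mmr_genes()))
  emt_prog <- sprintf("EMTSIG%02d", 1:30)
  stem_prog <- sprintf("STEMSIG%02d", 1:30)
  filler <- sprintf("G%04d", seq_len(config$n_genes - length(named) - 60L))
  list(all = c(named, emt_prog, stem_prog, filler),
       named = named, emt_prog = emt_prog, stem_prog = stem_prog,
       filler = filler,
       emt_set = c("VIM", "CD44", emt_prog),
       stem_set = c("CD44", stem_prog))
}

# Cohort design: sample table, subtype truth, hypermutators, planted gene
# lists, matched models. Deterministic under the design sub-seed.
sim_design <- function(config) {
  set.seed(config$mod_seeds[["design"]])
  g <- sim_genes(config)
  primary <- sprintf("P%04d", seq_len(config$n_primary))
  met <- unlist(lapply(names(config$n_met_per_site), function(s)
    sprintf("M_%s_%03d", s, seq_len(config$n_met_per_site[[s]]))))
  met_site <- rep(names(config$n_met_per_site), config$n_met_per_site)
  if (config$plant_matched) {
    designated <- paste0("CL_", names(config$subtype_mix))
    extra <- if (config$n_cell_lines > 3L)
      sprintf("CL%02d", seq(4L, config$n_cell_lines)) else character()
    cl <- c(designated, extra)
    matched <- stats::setNames(designated, names(config$subtype_mix))
  } else {
    cl <- sprintf("CL%02d", seq_len(config$n_cell_lines))
    matched <- character()
  }
  ann <- data.frame(
    sample = c(primary, met, cl),
    cohort = c(rep("primary", length(primary)),
               rep("metastatic", length(met)),
               rep("cell_line", length(cl))),
    site = c(rep("primary", length(primary)), met_site,
             rep("none", length(cl))),
    stringsAsFactors = FALSE)
  draw_mix <- function(n) {
    k <- floor(n * config$subtype_mix)
    rest <- n - sum(k)
    pool <- c(rep(names(config$subtype_mix), k),
              sample(names(config$subtype_mix), rest, replace = TRUE,
                     prob = config$subtype_mix))
    sample(pool)
  }
  subtype <- stats::setNames(rep("ARPC", nrow(ann)), ann$sample)
  subtype[met] <- draw_mix(length(met))
  if (config$plant_matched) {
    subtype[matched] <- names(matched)
    extra_cl <- setdiff(cl, matched)
    if (length(extra_cl)) subtype[extra_cl] <- draw_mix(length(extra_cl))
  } else {
    subtype[cl] <- draw_mix(length(cl))
  }
  n_hyper <- round(config$hyper_frac * nrow(ann))
  hypermutated <- sort(sample(ann$sample, n_hyper))
  diff_genes <- sort(sample(g$filler, config$n_diff_genes))
  hotspot_genes <- sample(setdiff(g$filler, diff_genes), config$n_hotspots)
  list(genes = g, annotations = ann, subtype = subtype,
       hypermutated = hypermutated, diff_genes = diff_genes,
       hotspot_genes = hotspot_genes, matched_models = matched,
       primary = primary, met = met, cell_lines = cl)
}

#' Simulate somatic mutations
#'
#' Baseline per-gene non-synonymous mutation probability ~ Beta(0.5, 60);
#' planted differential genes add \code{diff_delta} in metastatic samples;
#' hypermutators scale every probability by \code{hyper_multiplier}
#' (capped at 0.95) and carry MMR-gene mutations at
#' \code{mmr_hyper_prob}; silent variants are drawn independently at
#' \code{silent_rate_factor} times the non-synonymous rate so the planted
#' rates refer to qualifying mutations. Hotspot variants are identical
#' protein changes given to 3-6 random metastatic carriers; the first two
#' are also planted in the first cell line for presence checks.
#'
#' @param config a \code{\link{sim_config}}.
#' @param design internal cohort design (recomputed if omitted).
#' @return list(records, annotations, burden, truth).
#' @export
simulate_mutations <- function(config, design = sim_design(config)) {
  set.seed(config$mod_seeds[["mut"]])
  g <- design$genes
  ann <- design$annotations
  genes <- g$all
  samples <- ann$sample
  base_p <- stats::rbeta(length(genes), 0.5, 60)
  names(base_p) <- genes
  p <- matrix(base_p, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  is_met <- ann$cohort == "metastatic"
  p[design$diff_genes, is_met] <- p[design$diff_genes, is_met] +
    config$diff_delta
  is_hyper <- samples %in% design$hypermutated
  p[, is_hyper] <- pmin(p[, is_hyper] * config$hyper_multiplier, 0.95)
  if (is.finite(config$mmr_hyper_prob))
    p[mmr_genes(), is_hyper] <- config$mmr_hyper_prob
  hit <- matrix(stats::runif(length(p)) < p, nrow = nrow(p),
                dimnames = dimnames(p))
  idx <- which(hit, arr.ind = TRUE)
  nonsyn <- setdiff(variant_vocabulary(), silent_classes())
  aa <- c("A", "R", "N", "D", "C", "E", "G", "H", "K", "L", "P", "T")
  n_rec <- nrow(idx)
  records <- data.frame(
    gene = genes[idx[, 1]], sample = samples[idx[, 2]],
    variant_class = sample(nonsyn, n_rec, replace = TRUE,
                           prob = c(0.62, 0.10, 0.01, 0.09, 0.05, 0.03,
                                    0.03, 0.05, 0.02)),
    protein_change = sprintf("p.%s%d%s", sample(aa, n_rec, TRUE),
                             sample.int(900L, n_rec, TRUE),
                             sample(aa, n_rec, TRUE)),
    stringsAsFactors = FALSE)
  hit_s <- matrix(stats::runif(length(p)) < config$silent_rate_factor * p,
                  nrow = nrow(p), dimnames = dimnames(p))
  idx_s <- which(hit_s, arr.ind = TRUE)
  silent_rec <- data.frame(
    gene = genes[idx_s[, 1]], sample = samples[idx_s[, 2]],
    variant_class = sample(silent_classes(), nrow(idx_s), replace = TRUE),
    protein_change = "", stringsAsFactors = FALSE)
  hs <- lapply(seq_along(design$hotspot_genes), function(h) {
    carriers <- sample(design$met, sample(3:6, 1))
    data.frame(gene = design$hotspot_genes[h], sample = carriers,
               variant_class = "Missense_Mutation",
               protein_change = sprintf("p.H%dR", 100L + h),
               stringsAsFactors = FALSE)
  })
  hs_rec <- do.call(rbind, hs)
  cl_hs <- hs_rec[!duplicated(hs_rec$gene), , drop = FALSE]
  cl_hs <- cl_hs[seq_len(min(2L, nrow(cl_hs))), , drop = FALSE]
  cl_hs$sample <- design$cell_lines[1]
  records <- rbind(records, hs_rec, cl_hs, silent_rec)
  records <- records[order(records$sample, records$gene,
                           records$protein_change), , drop = FALSE]
  rownames(records) <- NULL
  burden <- mutation_burden(records, samples = samples)
  hotspots <- data.frame(
    gene = design$hotspot_genes,
    protein_change = sprintf("p.H%dR", 100L + seq_along(design$hotspot_genes)),
    n_carriers = vapply(hs, function(x) length(unique(x$sample)), integer(1)),
    stringsAsFactors = FALSE)
  high_true <- genes[base_p + config$diff_delta *
                       (genes %in% design$diff_genes) > 0.05]
  truth <- list(diff_genes = design$diff_genes,
                high_mut_genes = sort(high_true),
                hypermutated_samples = design$hypermutated,
                hotspots = hotspots,
                cell_line_hotspots = cl_hs[, c("gene", "protein_change",
                                               "sample")],
                subtype = design$subtype,
                matched_models = design$matched_models)
  list(records = records, annotations = design$annotations,
       burden = burden, truth = truth)
}

# Subtype and lineage centroids on the log2 scale.
sim_centroids <- function(config, g) {
  mu <- stats::runif(length(g$all), 2, 8)
  names(mu) <- g$all
  lm <- lineage_markers()
  shift <- function(genes, by) {
    v <- mu
    v[genes] <- v[genes] + by
    v
  }
  arpc <- shift(lm$luminal, config$marker_shift)
  nepc <- shift(lm$neuroendocrine, config$marker_shift)
  mspc <- shift(mspc_markers(), config$marker_shift)
  mspc[c(g$emt_prog, g$stem_prog)] <-
    mspc[c(g$emt_prog, g$stem_prog)] + config$program_shift
  cbind(ARPC = arpc, NEPC = nepc, MSPC = mspc,
        luminal = shift(lm$luminal, config$marker_shift),
        basal = shift(lm$basal, config$marker_shift),
        neuroendocrine = shift(lm$neuroendocrine, config$marker_shift))
}

#' Simulate bulk and single-cell expression
#'
#' Bulk sample profile = subtype centroid + N(0, expr_noise_sd) on the log2
#' scale, clipped at 0. Hypermutated primary samples gain \code{imm_delta}
#' on the immune genes. One designated cell line per subtype shares that
#' subtype's centroid exactly; other models add a per-line systematic
#' offset. Malignant single cells draw from their sample's subtype
#' centroid with overdispersed noise; normal epithelial cells draw from
#' the luminal/basal/neuroendocrine centroids.
#'
#' @param config a \code{\link{sim_config}}.
#' @param ledger truth from \code{\link{simulate_mutations}} (supplies the
#'   hypermutator set); may be NULL for expression-only use.
#' @param design internal cohort design (recomputed if omitted).
#' @return list(bulk, sc, cell_meta, normal_sc, normal_meta, centroids,
#'   gene_sets, truth).
#' @export
simulate_expression <- function(config, ledger = NULL,
                                design = sim_design(config)) {
  set.seed(config$mod_seeds[["expr"]])
  g <- design$genes
  cen <- sim_centroids(config, g)
  ann <- design$annotations
  hyper <- ledger$hypermutated_samples %||% design$hypermutated
  n_genes <- nrow(cen)
  noise <- function(n, sd) matrix(stats::rnorm(n_genes * n, 0, sd),
                                  nrow = n_genes)
  bulk <- cen[, design$subtype[ann$sample]] +
    noise(nrow(ann), config$expr_noise_sd)
  colnames(bulk) <- ann$sample
  non_designated <- setdiff(design$cell_lines, design$matched_models)
  for (m in non_designated)
    bulk[, m] <- bulk[, m] + stats::rnorm(n_genes, 0, config$model_offset_sd)
  hyper_primary <- intersect(hyper, design$primary)
  bulk[immune_genes(), hyper_primary] <-
    bulk[immune_genes(), hyper_primary] + config$imm_delta
  bulk <- pmax(bulk, 0)
  rownames(bulk) <- g$all
  sc_samples <- unlist(lapply(names(config$subtype_mix), function(st) {
    pool <- design$met[design$subtype[design$met] == st]
    sample(pool, min(config$n_sc_per_subtype, length(pool)))
  }))
  cell_meta <- data.frame(
    cell = sprintf("%s_c%02d", rep(sc_samples, each = config$n_cells_per_sample),
                   seq_len(config$n_cells_per_sample)),
    sample = rep(sc_samples, each = config$n_cells_per_sample),
    stringsAsFactors = FALSE)
  cell_meta$subtype <- design$subtype[cell_meta$sample]
  lin_of <- c(ARPC = "luminal", NEPC = "neuroendocrine", MSPC = "basal")
  cell_meta$lineage <- unname(lin_of[cell_meta$subtype])
  sc <- cen[, cell_meta$subtype] + noise(nrow(cell_meta), config$sc_noise_sd)
  sc <- pmax(sc, 0)
  dimnames(sc) <- list(g$all, cell_meta$cell)
  types <- rep(c("luminal", "basal", "neuroendocrine"),
               each = config$n_normal_cells_per_type)
  normal <- cen[, types] + noise(length(types), config$sc_noise_sd)
  normal <- pmax(normal, 0)
  dimnames(normal) <- list(g$all, sprintf("N_%s_%02d", types,
                                          seq_len(length(types))))
  gene_sets <- list(EMT = g$emt_set, stemness = g$stem_set)
  truth <- list(cell_subtype = stats::setNames(cell_meta$subtype,
                                               cell_meta$cell),
                cell_lineage = stats::setNames(cell_meta$lineage,
                                               cell_meta$cell),
                sc_samples = sc_samples)
  list(bulk = bulk, sc = sc, cell_meta = cell_meta, normal_sc = normal,
       normal_meta = data.frame(cell = colnames(normal), cell_type = types,
                                stringsAsFactors = FALSE),
       centroids = cen, gene_sets = gene_sets, truth = truth)
}

#' Simulate copy-number segments
#'
#' Genes are laid out on 20 synthetic chromosomes; each sample receives one
#' segment per 20-gene block with value ~ N(0, 0.1), and the block covering
#' AR gains +0.8 in metastatic samples and cell lines (a planted
#' amplification).
#'
#' @param config a \code{\link{sim_config}}.
#' @param ledger unused placeholder for interface symmetry.
#' @param design internal cohort design (recomputed if omitted).
#' @return list(segments, gene_models, truth).
#' @export
simulate_cnv <- function(config, ledger = NULL, design = sim_design(config)) {
  set.seed(config$mod_seeds[["cnv"]])
  g <- design$genes
  n <- length(g$all)
  per_chrom <- ceiling(n / 20)
  chrom <- sprintf("chr%d", (seq_len(n) - 1L) %/% per_chrom + 1L)
  pos_in <- (seq_len(n) - 1L) %% per_chrom
  gene_models <- data.frame(gene = g$all, chrom = chrom,
                            start = pos_in * 10000, end = pos_in * 10000 + 5000,
                            stringsAsFactors = FALSE)
  block <- pos_in %/% 20L
  blocks <- unique(data.frame(chrom = chrom, block = block,
                              stringsAsFactors = FALSE))
  blocks$start <- blocks$block * 200000
  blocks$end <- blocks$start + 200000
  ann <- design$annotations
  seg <- merge(data.frame(sample = ann$sample, stringsAsFactors = FALSE),
               blocks, by = NULL)
  seg$value <- stats::rnorm(nrow(seg), 0, 0.1)
  ar_chrom <- chrom[g$all == "AR"]
  ar_block <- block[g$all == "AR"]
  amp <- ann$sample[ann$cohort %in% c("metastatic", "cell_line")]
  bump <- seg$sample %in% amp & seg$chrom == ar_chrom & seg$block == ar_block
  seg$value[bump] <- seg$value[bump] + 0.8
  seg <- seg[order(seg$sample, seg$chrom, seg$start),
             c("sample", "chrom", "start", "end", "value")]
  rownames(seg) <- NULL
  amp_genes <- g$all[chrom == ar_chrom & block == ar_block]
  list(segments = seg, gene_models = gene_models,
       truth = list(amplified_gene = "AR", amplified_block = amp_genes,
                    amplified_samples = amp, amp_delta = 0.8))
}

#' Simulate an ATAC peak-count matrix
#'
#' Per-peak baseline accessibility ~ N(4, 1) on the log2 scale; 5% of peaks
#' per subtype are elevated by \code{atac_shift} log2 units in that
#' subtype's metastatic samples and in the matched (designated) cell line.
#' Counts = 2^(baseline + shift + noise), i.e. lognormal-type normalized
#' read counts over the metastatic samples and all cell lines.
#'
#' @param config a \code{\link{sim_config}}.
#' @param ledger unused placeholder for interface symmetry.
#' @param design internal cohort design (recomputed if omitted).
#' @return list(counts, truth) where truth records the per-subtype elevated
#'   peak blocks.
#' @export
simulate_atac <- function(config, ledger = NULL, design = sim_design(config)) {
  set.seed(config$mod_seeds[["atac"]])
  n <- config$n_peaks
  labels <- sprintf("chr%d:%d-%d", (seq_len(n) - 1L) %% 20L + 1L,
                    ((seq_len(n) - 1L) %/% 20L) * 1000L,
                    ((seq_len(n) - 1L) %/% 20L) * 1000L + 500L)
  samples <- c(design$met, design$cell_lines)
  base <- stats::rnorm(n, 4, 1)
  k <- round(config$peak_frac_per_subtype * n)
  blocks <- list(ARPC = seq_len(k), NEPC = seq_len(k) + k,
                 MSPC = seq_len(k) + 2L * k)
  lvl <- matrix(base, nrow = n, ncol = length(samples),
                dimnames = list(labels, samples))
  for (st in names(blocks)) {
    carriers <- intersect(design$met,
                          names(design$subtype)[design$subtype == st])
    if (st %in% names(design$matched_models))
      carriers <- c(carriers, design$matched_models[[st]])
    lvl[blocks[[st]], carriers] <- lvl[blocks[[st]], carriers] +
      config$atac_shift
  }
  counts <- 2^(lvl + matrix(stats::rnorm(length(lvl), 0,
                                         config$atac_noise_sd),
                            nrow = n))
  list(counts = counts,
       truth = list(blocks = lapply(blocks, function(i) labels[i])))
}

#' Simulate the full coupled multi-omics cohort
#'
#' Runs every modality under one root seed and assembles the complete
#' truth ledger. Identical seeds give byte-identical outputs.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{"synthetic_cohort"}: annotations, records,
#'   burden, bulk, sc, cell_meta, normal_sc, normal_meta, segments,
#'   gene_models, atac, gene_sets, centroids, truth.
#' @export
simulate_cohort <- function(config = sim_config()) {
  design <- sim_design(config)
  mut <- simulate_mutations(config, design)
  expr <- simulate_expression(config, mut$truth, design)
  cnv <- simulate_cnv(config, mut$truth, design)
  atac <- simulate_atac(config, mut$truth, design)
  truth <- c(mut$truth, expr$truth, cnv$truth["amplified_gene"],
             cnv$truth["amplified_samples"],
             list(atac_blocks = atac$truth$blocks))
  out <- list(config = config, annotations = mut$annotations,
              records = mut$records, burden = mut$burden,
              bulk = expr$bulk, sc = expr$sc, cell_meta = expr$cell_meta,
              normal_sc = expr$normal_sc, normal_meta = expr$normal_meta,
              segments = cnv$segments, gene_models = cnv$gene_models,
              atac = atac$counts, gene_sets = expr$gene_sets,
              centroids = expr$centroids, truth = truth)
  class(out) <- "synthetic_cohort"
  out
}

#' Write a synthetic cohort to standard formats
#'
#' Emits MAF, SEG, expression / peak-count TSVs, a GMT of the EMT and
#' stemness signatures, a sample annotation TSV and a JSON truth ledger.
#'
#' @param cohort from \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- cohort$annotations
  ann$subtype_truth <- cohort$truth$subtype[ann$sample]
  write_maf(cohort$records, file.path(dir, "mutations.maf"), ann)
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_seg(cohort$segments, file.path(dir, "cnv.seg"))
  utils::write.table(cohort$gene_models, file.path(dir, "gene_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression(round(cohort$bulk, 4), file.path(dir, "expression_bulk.tsv"))
  write_expression(round(cohort$sc, 4), file.path(dir, "expression_sc.tsv"))
  write_expression(round(cohort$normal_sc, 4),
                   file.path(dir, "expression_normal_sc.tsv"))
  utils::write.table(cohort$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$normal_meta, file.path(dir, "normal_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_peak_counts(round(cohort$atac, 3), file.path(dir, "atac_counts.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "signatures.gmt"))
  truth <- cohort$truth
  truth$subtype <- as.list(truth$subtype)
  truth$cell_subtype <- as.list(truth$cell_subtype)
  truth$cell_lineage <- as.list(truth$cell_lineage)
  jsonlite::write_json(truth, file.path(dir, "truth_ledger.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
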