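#' Binary gene-by-sample mutation matrix
#'
#' Collapses mutation records to presence/absence: a cell is 1 when the
#' sample carries at least one qualifying mutation in the gene. Silent and
#' non-coding classes (see \code{\link{silent_classes}}) are excluded when
#' \code{exclude_silent} is set, mirroring the filtering applied before all
#' mutation-frequency analyses; multiple variants of one gene in one sample
#' are deliberately binarized.
#'
#' @param records mutation records (gene, sample, variant_class, ...).
#' @param annotations sample annotations; every record's sample must appear.
#' @param exclude_silent drop silent-class variants first (default TRUE).
#' @param silent variant classes treated as silent.
#' @return integer matrix genes x samples, entries in \{0, 1\}; columns cover
#'   all annotated samples (all-zero columns for unmutated samples).
#' @export
mutation_matrix <- function(records, annotations, exclude_silent = TRUE,
                            silent = silent_classes()) {
  unknown <- setdiff(unique(records$sample), annotations$sample)
  if (length(unknown))
    stop_fmt("records contain sample(s) missing from annotations: %s",
             paste(unknown, collapse = ", "))
  keep <- if (exclude_silent) !(records$variant_class %in% silent)
          else rep(TRUE, nrow(records))
  rec <- records[keep, , drop = FALSE]
  genes <- sort(unique(records$gene))
  samples <- annotations$sample
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  if (nrow(rec))
    m[cbind(match(rec$gene, genes), match(rec$sample, samples))] <- 1L
  m
}

#' Per-sample mutation burden
#'
#' Burden is the count of all mutation records per sample — silent variants
#' included, matching a "total mutation burden" definition; set
#' \code{nonsynonymous_only} to restrict to qualifying classes.
#'
#' @param records mutation records.
#' @param samples sample universe (samples without records get burden 0).
#' @param nonsynonymous_only drop silent classes first.
#' @param silent variant classes treated as silent.
#' @return data.frame(sample, burden).
#' @export
mutation_burden <- function(records, samples = unique(records$sample),
                            nonsynonymous_only = FALSE,
                            silent = silent_classes()) {
  rec <- if (nonsynonymous_only)
    records[!(records$variant_class %in% silent), , drop = FALSE] else records
  tab <- table(factor(rec$sample, levels = samples))
  data.frame(sample = samples, burden = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Fisher's exact test for one gene between two sample groups
#'
#' Two-sided exact test on the 2x2 table (mutated / unmutated x group).
#'
#' @param matrix binary mutation matrix.
#' @param group_a,group_b disjoint, non-empty sample sets (column names).
#' @param gene gene to test.
#' @return two-sided p-value.
#' @export
fisher_gene_test <- function(matrix, group_a, group_b, gene) {
  if (!length(group_a) || !length(group_b))
    stop_fmt("both groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop_fmt("groups must be disjoint")
  if (!gene %in% rownames(matrix))
    stop_fmt("gene '%s' absent from the mutation matrix", gene)
  a <- sum(matrix[gene, group_a])
  b <- sum(matrix[gene, group_b])
  tab <- rbind(c(a, length(group_a) - a), c(b, length(group_b) - b))
  stats::fisher.test(tab)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (thin wrapper over
#' \code{stats::p.adjust}), kept as a named surface so every stage adjusts
#' identically.
#'
#' @param p_values numeric vector of p-values.
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(p_values) stats::p.adjust(p_values, method = "BH")

# Two-sided Fisher p for vectors of counts a (mutated in group of size na)
# vs b (mutated in group of size nb), deduplicating identical tables.
fisher_vec <- function(a, na, b, nb) {
  key <- paste(a, b)
  u <- !duplicated(key)
  pu <- vapply(which(u), function(i) {
    tab <- rbind(c(a[i], na - a[i]), c(b[i], nb - b[i]))
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  pu[match(key, key[u])]
}

#' Differentially mutated genes, site by site
#'
#' For each metastatic site separately, each gene's mutation frequency is
#' compared against the full primary cohort with a two-sided Fisher exact
#' test; BH adjustment is applied within site over the genes carrying at
#' least one mutation in that site + primary cohort. Genes significant
#' (adjusted p < alpha) in at least \code{min_sites_sig} sites are retained.
#'
#' @param matrix binary mutation matrix (silent already excluded).
#' @param annotations sample annotations with cohort and site.
#' @param thresholds see \code{\link{default_thresholds}}.
#' @return list: \code{per_site} (data.frame gene, site, freq_site,
#'   freq_primary, p, p_adj), \code{n_sig_sites} (named integer),
#'   \code{diff_genes} (character).
#' @export
select_diff_genes <- function(matrix, annotations,
                              thresholds = default_thresholds()) {
  primary <- annotations$sample[annotations$cohort == "primary"]
  met <- annotations[annotations$cohort == "metastatic", , drop = FALSE]
  sites <- sort(unique(met$site))
  if (length(sites) < 2L)
    stop_fmt("need metastatic samples from at least two sites, got %d",
             length(sites))
  if (!length(primary)) stop_fmt("no primary samples in annotations")
  b_all <- rowSums(matrix[, primary, drop = FALSE])
  per_site <- lapply(sites, function(s) {
    ss <- met$sample[met$site == s]
    a <- rowSums(matrix[, ss, drop = FALSE])
    tested <- which(a + b_all > 0)
    p <- fisher_vec(a[tested], length(ss), b_all[tested], length(primary))
    data.frame(gene = rownames(matrix)[tested], site = s,
               freq_site = a[tested] / length(ss),
               freq_primary = b_all[tested] / length(primary),
               p = p, p_adj = bh_adjust(p),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  per_site <- do.call(rbind, per_site)
  sig <- per_site[per_site$p_adj < thresholds$alpha_adj, , drop = FALSE]
  n_sig <- table(factor(sig$gene, levels = rownames(matrix)))
  diff_genes <- names(n_sig)[n_sig >= thresholds$min_sites_sig]
  list(per_site = per_site,
       n_sig_sites = stats::setNames(as.integer(n_sig), names(n_sig)),
       diff_genes = diff_genes)
}

#' Highly mutated genes
#'
#' Genes whose per-site mutation frequency strictly exceeds
#' \code{high_mut_freq} in at least \code{min_sites_sig} metastatic sites.
#'
#' @inheritParams select_diff_genes
#' @return character vector of gene symbols.
#' @export
select_high_genes <- function(matrix, annotations,
                              thresholds = default_thresholds()) {
  met <- annotations[annotations$cohort == "metastatic", , drop = FALSE]
  sites <- sort(unique(met$site))
  n_over <- rep(0L, nrow(matrix))
  for (s in sites) {
    ss <- met$sample[met$site == s]
    freq <- rowSums(matrix[, ss, drop = FALSE]) / length(ss)
    n_over <- n_over + (freq > thresholds$high_mut_freq)
  }
  rownames(matrix)[n_over >= thresholds$min_sites_sig]
}

#' Combine differential and highly mutated genes into a panel
#'
#' @param diff_genes,high_genes character vectors.
#' @return list(diff_genes, high_genes, union) with the union ordered
#'   alphabetically.
#' @export
gene_panel <- function(diff_genes, high_genes) {
  list(diff_genes = diff_genes, high_genes = high_genes,
       union = sort(unique(c(diff_genes, high_genes))))
}

#' Rank models by mutated panel-gene count
#'
#' Descending count, competition (min) ranks; ties listed alphabetically.
#'
#' @param matrix binary mutation matrix.
#' @param panel character vector of panel genes (or a \code{gene_panel}).
#' @param cell_lines model sample names (matrix columns).
#' @return data.frame(model, panel_count, rank), ordered by rank then name.
#' @export
rank_by_panel <- function(matrix, panel, cell_lines) {
  if (is.list(panel)) panel <- panel$union
  genes <- intersect(panel, rownames(matrix))
  counts <- colSums(matrix[genes, cell_lines, drop = FALSE])
  r <- min_rank_desc(counts)
  out <- data.frame(model = cell_lines, panel_count = as.integer(counts),
                    rank = r[cell_lines], stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(out$rank, out$model), , drop = FALSE]
}

#' Burden-normalized panel concordance ratio
#'
#' Panel-gene mutation count divided by total mutation burden; corrects the
#' raw count for hypermutation. Samples with zero burden are returned as
#' \code{NA} with a warning.
#'
#' @param panel_count integer vector (recycled against burden).
#' @param burden matching total mutation burdens.
#' @return numeric ratios.
#' @export
normalized_ratio <- function(panel_count, burden) {
  out <- ifelse(burden > 0, panel_count / burden, NA_real_)
  if (anyNA(out))
    warning(sprintf("%d sample(s) with zero burden excluded (ratio undefined)",
                    sum(is.na(out))))
  out
}

#' Catalogue hotspot mutations
#'
#' A hotspot is an identical non-synonymous protein change carried by at
#' least \code{hotspot_min_samples} distinct metastatic samples. Records
#' with silent classes or empty protein change are excluded first.
#'
#' @param records mutation records.
#' @param metastatic_samples samples defining the discovery cohort.
#' @param thresholds see \code{\link{default_thresholds}}.
#' @param silent variant classes treated as silent.
#' @return data.frame(gene, protein_change, n_carriers, carriers) of class
#'   \code{"hotspot_catalog"}; \code{carriers} is comma-collapsed.
#' @export
find_hotspots <- function(records, metastatic_samples,
                          thresholds = default_thresholds(),
                          silent = silent_classes()) {
  rec <- records[records$sample %in% metastatic_samples &
                 !(records$variant_class %in% silent) &
                 nzchar(records$protein_change), , drop = FALSE]
  if (!nrow(rec)) {
    out <- data.frame(gene = character(), protein_change = character(),
                      n_carriers = integer(), carriers = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("hotspot_catalog", class(out))
    return(out)
  }
  key <- paste(rec$gene, rec$protein_change, sep = "\r")
  carriers <- lapply(split(rec$sample, key), unique)
  n <- lengths(carriers)
  keep <- names(carriers)[n >= thresholds$hotspot_min_samples]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[`, character(1), 1),
    protein_change = vapply(parts, `[`, character(1), 2),
    n_carriers = as.integer(n[keep]),
    carriers = vapply(carriers[keep], function(x)
      paste(sort(x), collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$n_carriers, out$gene, out$protein_change), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hotspot_catalog", class(out))
  out
}

#' Hotspot presence across cell lines
#'
#' Exact (gene, protein_change) string match between a hotspot catalog and
#' model mutation records.
#'
#' @param catalog from \code{\link{find_hotspots}}.
#' @param cell_line_records mutation records of the models.
#' @param cell_lines model names; defaults to the samples in the records.
#' @return logical matrix, hotspots ("gene protein_change") x cell lines.
#' @export
hotspot_presence <- function(catalog, cell_line_records,
                             cell_lines = unique(cell_line_records$sample)) {
  labels <- paste(catalog$gene, catalog$protein_change)
  m <- matrix(FALSE, nrow = nrow(catalog), ncol = length(cell_lines),
              dimnames = list(labels, cell_lines))
  if (!nrow(catalog) || !nrow(cell_line_records)) return(m)
  key_rec <- paste(cell_line_records$gene, cell_line_records$protein_change)
  hit <- key_rec %in% labels & cell_line_records$sample %in% cell_lines
  rec <- cell_line_records[hit, , drop = FALSE]
  if (nrow(rec))
    m[cbind(match(paste(rec$gene, rec$protein_change), labels),
            match(rec$sample, cell_lines))] <- TRUE
  m
}

#' Gap-based hypermutation classification
#'
#' Samples are ranked by total burden; adjacent gaps on the
#' log10(burden + 1) scale are searched within the upper \code{gap_top_frac}
#' of ranks, and the cutoff is placed at the largest gap provided it exceeds
#' \code{gap_min} log10 units — otherwise the call is returned empty with a
#' "no natural cutoff" flag. A two-component Gaussian mixture on
#' log10(burden + 1) supplies a bimodality support statistic
#' (|mu1 - mu2| / pooled sigma).
#'
#' @param burdens named numeric vector of per-sample burdens.
#' @param thresholds see \code{\link{default_thresholds}} (uses
#'   \code{gap_top_frac}, \code{gap_min}).
#' @return list of class \code{"hypermutation_call"}: \code{cutoff_burden}
#'   (highest non-hypermutated burden; hypermutated samples strictly exceed
#'   it), \code{gap_index} (rank position above the gap), \code{gap} (log10
#'   units), \code{hypermutated} (character), \code{no_cutoff} (flag),
#'   \code{bimodality} (means, sds, weights, separation).
#' @importFrom mclust Mclust mclustBIC
#' @export
hypermutation_cutoff <- function(burdens, thresholds = default_thresholds()) {
  if (is.null(names(burdens))) stop_fmt("burdens must be named by sample")
  if (sum(burdens > 0) < 20L)
    stop_fmt("need at least 20 samples with positive burden")
  ord <- order(-burdens, names(burdens))
  b <- burdens[ord]
  l <- log10(b + 1)
  n <- length(b)
  k <- max(1L, floor(thresholds$gap_top_frac * n))
  gaps <- l[seq_len(min(k, n - 1L))] - l[seq_len(min(k, n - 1L)) + 1L]
  gi <- unname(which.max(gaps))
  fit <- if (length(unique(l)) >= 3L)
    suppressWarnings(try(
      mclust::Mclust(l, G = 2, verbose = FALSE, modelNames = c("E", "V")),
      silent = TRUE)) else NULL
  if (inherits(fit, "try-error")) fit <- NULL
  bim <- if (!is.null(fit)) {
    mu <- fit$parameters$mean
    sg <- sqrt(if (length(fit$parameters$variance$sigmasq) == 1L)
      rep(fit$parameters$variance$sigmasq, 2) else
      fit$parameters$variance$sigmasq)
    w <- fit$parameters$pro
    list(means = unname(mu), sds = unname(sg), weights = unname(w),
         separation = abs(diff(mu)) / sqrt(sum(w * sg^2)))
  } else list(means = NA_real_, sds = NA_real_, weights = NA_real_,
              separation = NA_real_)
  if (!length(gaps) || gaps[gi] < thresholds$gap_min) {
    out <- list(cutoff_burden = NA_real_, gap_index = NA_integer_,
                gap = if (length(gaps)) unname(gaps[gi]) else NA_real_,
                hypermutated = character(), no_cutoff = TRUE,
                bimodality = bim)
  } else {
    out <- list(cutoff_burden = unname(b[gi + 1L]),
                gap_index = gi, gap = unname(gaps[gi]),
                hypermutated = sort(names(b)[seq_len(gi)]),
                no_cutoff = FALSE, bimodality = bim)
  }
  class(out) <- "hypermutation_call"
  out
}

#' Mismatch-repair mutation comparison
#'
#' Per-sample count of mutated MMR genes, compared between hypermutated and
#' non-hypermutated samples with a two-sided Wilcoxon rank-sum test.
#'
#' @param matrix binary mutation matrix.
#' @param mmr_genes MMR gene symbols (e.g. MLH1, MSH2, MSH6, PMS2).
#' @param hypermutated,others disjoint sample sets.
#' @return list(counts = named per-sample counts, p = p-value,
#'   mean_hyper, mean_other).
#' @export
mmr_comparison <- function(matrix, mmr_genes, hypermutated, others) {
  if (!length(mmr_genes)) stop_fmt("empty MMR gene list")
  genes <- intersect(mmr_genes, rownames(matrix))
  if (!length(genes))
    stop_fmt("none of the MMR genes are present in the matrix")
  counts <- colSums(matrix[genes, , drop = FALSE])
  ch <- counts[hypermutated]; co <- counts[others]
  p <- if (length(unique(c(ch, co))) < 2L) 1 else
    suppressWarnings(stats::wilcox.test(ch, co, exact = FALSE)$p.value)
  list(counts = counts, p = p,
       mean_hyper = mean(ch), mean_other = mean(co))
}

#' Map copy-number segments to gene-level values
#'
#' Gene value = overlap-length-weighted mean of overlapping segment values,
#' per sample; genes untouched by any segment are \code{NA}.
#'
#' @param segments data.frame(sample, chrom, start, end, value), 0-based
#'   half-open (as from \code{\link{read_seg}}).
#' @param gene_models data.frame(gene, chrom, start, end), same convention.
#' @return numeric matrix genes x samples.
#' @export
segments_to_gene_cnv <- function(segments, gene_models) {
  samples <- sort(unique(segments$sample))
  genes_gr <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(gene_models$start + 1, gene_models$end))
  out <- matrix(NA_real_, nrow = nrow(gene_models), ncol = length(samples),
                dimnames = list(gene_models$gene, samples))
  for (s in samples) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    seg_gr <- GenomicRanges::GRanges(
      seg$chrom, IRanges::IRanges(seg$start + 1, seg$end))
    hits <- GenomicRanges::findOverlaps(genes_gr, seg_gr)
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(genes_gr)[qi], IRanges::ranges(seg_gr)[si]))
    num <- tapply(w * seg$value[si], qi, sum)
    den <- tapply(w, qi, sum)
    out[as.integer(names(num)), s] <- num / den
  }
  out
}

#' Differential gene-level copy number
#'
#' Per gene: two-sided Wilcoxon rank-sum test between metastatic and primary
#' samples, BH adjustment across tested genes, and the difference of cohort
#' medians (metastatic - primary). A gene is significant iff
#' |delta| > cnv_delta and adjusted p < alpha.
#'
#' @param gene_cnv gene x sample CNV matrix (log-ratio scale).
#' @param annotations sample annotations with cohort.
#' @param thresholds see \code{\link{default_thresholds}}.
#' @return data.frame(gene, median_met, median_primary, delta, p, p_adj,
#'   significant).
#' @export
differential_cnv <- function(gene_cnv, annotations,
                             thresholds = default_thresholds()) {
  met <- intersect(colnames(gene_cnv),
                   annotations$sample[annotations$cohort == "metastatic"])
  pri <- intersect(colnames(gene_cnv),
                   annotations$sample[annotations$cohort == "primary"])
  if (!length(met) || !length(pri))
    stop_fmt("need both metastatic and primary samples with CNV values")
  res <- lapply(rownames(gene_cnv), function(g) {
    x <- gene_cnv[g, met]; y <- gene_cnv[g, pri]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    c(stats::median(x), stats::median(y), stats::median(x) - stats::median(y), p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(gene = rownames(gene_cnv),
                    median_met = res[, 1], median_primary = res[, 2],
                    delta = res[, 3], p = res[, 4],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_adj <- NA_real_
  tested <- !is.na(out$p)
  out$p_adj[tested] <- bh_adjust(out$p[tested])
  out$significant <- !is.na(out$p_adj) &
    abs(out$delta) > thresholds$cnv_delta &
    out$p_adj < thresholds$alpha_adj
  out
}
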