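#' Select highly variable genes
#'
#' Genes are ranked by the variance of their log2 expression across the
#' model panel columns; the top \code{n_hvg} are retained. Ties break
#' deterministically by gene symbol.
#'
#' @param expression genes x samples matrix (log2 scale), typically the
#'   model panel from which the gene list is recomputed.
#' @param n_hvg panel size (default 1000).
#' @return list(genes, variance) of class \code{"hvg_panel"}; \code{genes}
#'   has length \code{min(n_hvg, available genes)}.
#' @export
select_hvg <- function(expression, n_hvg = default_thresholds()$n_hvg) {
  v <- row_vars(expression)
  if (n_hvg > nrow(expression)) {
    warning(sprintf("n_hvg (%d) exceeds available genes (%d); using all",
                    n_hvg, nrow(expression)))
    n_hvg <- nrow(expression)
  }
  ord <- order(-v, rownames(expression))
  sel <- ord[seq_len(n_hvg)]
  out <- list(genes = rownames(expression)[sel], variance = v[sel])
  class(out) <- "hvg_panel"
  out
}

#' Transcriptomic similarity of one model to a reference set
#'
#' Spearman rank correlation (average-rank ties) between the model profile
#' and each reference over the highly-variable-gene panel; the model's
#' similarity is the median of the per-reference correlations. Genes absent
#' from either side are dropped pairwise, with a warning when coverage falls
#' below 90% of the panel.
#'
#' @param model_profile named expression vector.
#' @param reference_profiles genes x references matrix.
#' @param hvg character vector of panel genes (or an \code{hvg_panel}).
#' @return list(similarity = median rho, per_reference = named rho vector,
#'   n_genes = genes used). A model constant on the panel yields \code{NA}
#'   similarity.
#' @export
tc_similarity <- function(model_profile, reference_profiles, hvg) {
  if (is.list(hvg)) hvg <- hvg$genes
  common <- intersect(hvg, intersect(names(model_profile),
                                     rownames(reference_profiles)))
  if (length(common) < 0.9 * length(hvg))
    warning(sprintf("only %d/%d panel genes shared by model and references",
                    length(common), length(hvg)))
  if (length(common) < 3L) stop_fmt("fewer than 3 shared panel genes")
  rho <- spearman_vs_cols(model_profile[common],
                          reference_profiles[common, , drop = FALSE])
  names(rho) <- colnames(reference_profiles)
  list(similarity = stats::median(rho), per_reference = rho,
       n_genes = length(common))
}

#' Model x reference Spearman similarity table
#'
#' @param models genes x models matrix.
#' @param references genes x references matrix.
#' @param hvg panel genes (or an \code{hvg_panel}).
#' @return numeric matrix models x references of Spearman rho.
#' @export
similarity_table <- function(models, references, hvg) {
  if (is.list(hvg)) hvg <- hvg$genes
  common <- intersect(hvg, intersect(rownames(models), rownames(references)))
  if (length(common) < 0.9 * length(hvg))
    warning(sprintf("only %d/%d panel genes shared by models and references",
                    length(common), length(hvg)))
  if (length(common) < 3L) stop_fmt("fewer than 3 shared panel genes")
  stats::cor(models[common, , drop = FALSE],
             references[common, , drop = FALSE], method = "spearman")
}

#' Rank models by median similarity
#'
#' Descending median Spearman rho, competition (min) ranks.
#'
#' @param similarities a models x references similarity matrix, or a named
#'   vector of per-model similarities.
#' @return data.frame(model, similarity, rank), ordered by rank then model.
#' @export
rank_models <- function(similarities) {
  sim <- if (is.matrix(similarities)) apply(similarities, 1, stats::median)
         else similarities
  r <- min_rank_desc(sim)
  out <- data.frame(model = names(sim), similarity = unname(sim),
                    rank = unname(r), stringsAsFactors = FALSE)
  out[order(out$rank, out$model), , drop = FALSE]
}

#' Consistency of model rankings across metastatic sites
#'
#' Pairwise Spearman correlation of the per-site model similarity vectors.
#'
#' @param site_rankings named list of \code{\link{rank_models}} results (or
#'   named similarity vectors), one per site, over the same models.
#' @return symmetric matrix of pairwise Spearman rho.
#' @export
site_consistency <- function(site_rankings) {
  vecs <- lapply(site_rankings, function(r) {
    if (is.data.frame(r)) stats::setNames(r$similarity, r$model) else r
  })
  models <- Reduce(intersect, lapply(vecs, names))
  if (length(models) < 3L) stop_fmt("fewer than 3 shared models across sites")
  m <- sapply(vecs, function(v) v[models])
  stats::cor(m, method = "spearman")
}

#' Cytotoxic CD8+ T-cell infiltration score
#'
#' Mean expression of CD8A, CD8B, GZMA, GZMB and PRF1 per sample (the TIDE
#' cytotoxic score).
#'
#' @param expression genes x samples matrix (log2 scale).
#' @param samples columns to score (default: all).
#' @param markers the five cytotoxicity marker genes.
#' @return named numeric vector of scores.
#' @export
ctl_score <- function(expression, samples = colnames(expression),
                      markers = c("CD8A", "CD8B", "GZMA", "GZMB", "PRF1")) {
  miss <- setdiff(markers, rownames(expression))
  if (length(miss))
    stop_fmt("cytotoxicity marker(s) missing from expression: %s",
             paste(miss, collapse = ", "))
  colMeans(expression[markers, samples, drop = FALSE])
}

#' Rank-sum differential expression
#'
#' Per gene: two-sided Wilcoxon rank-sum p between the groups, BH adjustment
#' across tested genes, and log2 fold change as the difference of group
#' means on the log2 scale. A gene is called iff adjusted p < alpha and
#' |log2FC| > the fold-change cutoff.
#'
#' @param expression genes x samples matrix (log2 scale).
#' @param group_a,group_b disjoint sample sets; log2FC is A minus B.
#' @param thresholds see \code{\link{default_thresholds}}.
#' @return data.frame(gene, log2fc, p, p_adj, call) with call in
#'   \{"up", "down", "none"\}.
#' @export
rank_sum_de <- function(expression, group_a, group_b,
                        thresholds = default_thresholds()) {
  if (length(intersect(group_a, group_b))) stop_fmt("groups must be disjoint")
  a <- expression[, group_a, drop = FALSE]
  b <- expression[, group_b, drop = FALSE]
  p <- vapply(seq_len(nrow(expression)), function(i)
    suppressWarnings(stats::wilcox.test(a[i, ], b[i, ], exact = FALSE)$p.value),
    numeric(1))
  lfc <- rowMeans(a) - rowMeans(b)
  p_adj <- bh_adjust(p)
  call <- ifelse(!is.na(p_adj) & p_adj < thresholds$alpha_adj &
                   abs(lfc) > thresholds$de_abs_log2fc,
                 ifelse(lfc > 0, "up", "down"), "none")
  data.frame(gene = rownames(expression), log2fc = unname(lfc), p = p,
             p_adj = p_adj, call = call, stringsAsFactors = FALSE,
             row.names = NULL)
}
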