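#' Single-sample gene set enrichment (ssGSEA)
#'
#' For each sample, genes are ordered by decreasing expression (average-rank
#' ties, deterministic label tie-break) and a weighted running sum is
#' accumulated: in-set genes contribute their |expression rank|^alpha
#' (normalized over the set), out-of-set genes contribute the unweighted
#' fraction. The score is the sum over all positions of the gap
#' P_in(i) - P_out(i). With alpha = 0 this reduces to the unweighted
#' Kolmogorov-Smirnov-style running-sum statistic. Scores are not
#' normalized across samples.
#'
#' @param expression genes x samples matrix (log2 scale).
#' @param gene_sets named list of character vectors.
#' @param alpha rank-weight exponent (default 0.25).
#' @param min_size minimum set size after intersecting with the matrix genes.
#' @return samples x sets numeric matrix with \code{alpha} attribute.
#' @export
ssgsea <- function(expression, gene_sets, alpha = 0.25, min_size = 5L) {
  genes <- rownames(expression)
  member <- lapply(names(gene_sets), function(nm) {
    inset <- genes %in% gene_sets[[nm]]
    if (sum(inset) < min_size)
      stop_fmt("gene set '%s' has %d gene(s) after intersection (< %d)",
               nm, sum(inset), min_size)
    inset
  })
  names(member) <- names(gene_sets)
  n <- length(genes)
  scores <- matrix(NA_real_, nrow = ncol(expression),
                   ncol = length(gene_sets),
                   dimnames = list(colnames(expression), names(gene_sets)))
  for (j in seq_len(ncol(expression))) {
    x <- expression[, j]
    ord <- order(-x, genes)
    r <- rank(x, ties.method = "average")[ord]
    w <- abs(r)^alpha
    for (nm in names(gene_sets)) {
      inset <- member[[nm]][ord]
      wi <- ifelse(inset, w, 0)
      p_in <- cumsum(wi) / sum(wi)
      n_out <- n - sum(inset)
      p_out <- if (n_out > 0) cumsum(!inset) / n_out else rep(0, n)
      scores[j, nm] <- sum(p_in - p_out)
    }
  }
  attr(scores, "alpha") <- alpha
  scores
}

#' ARPC/NEPC/MSPC assignment for bulk samples
#'
#' Externally annotated samples are assigned first through
#' \code{label_map} (AR+/NE- -> ARPC, AR-/NE+ -> NEPC in the source
#' annotations). Among the remaining samples, those whose EMT and stemness
#' ssGSEA scores both sit in the top quartile — quartiles computed over the
#' full cohort, threshold inclusive — are designated MSPC; the rest stay
#' unassigned.
#'
#' @param ssgsea_scores samples x sets matrix from \code{\link{ssgsea}}.
#' @param label_map named character vector (sample -> "ARPC"/"NEPC"),
#'   possibly empty.
#' @param emt,stem column names of the EMT and stemness scores.
#' @param thresholds see \code{\link{default_thresholds}} (uses
#'   \code{mspc_quantile}).
#' @return data.frame(sample, subtype, provenance) with provenance in
#'   \{"label_map", "quartile_rule", "none"\}.
#' @export
call_mspc <- function(ssgsea_scores, label_map = character(),
                      emt = "EMT", stem = "stemness",
                      thresholds = default_thresholds()) {
  samples <- rownames(ssgsea_scores)
  subtype <- stats::setNames(rep("unassigned", length(samples)), samples)
  prov <- stats::setNames(rep("none", length(samples)), samples)
  mapped <- intersect(names(label_map), samples)
  subtype[mapped] <- label_map[mapped]
  prov[mapped] <- "label_map"
  q <- 1 - thresholds$mspc_quantile
  cut_emt <- stats::quantile(ssgsea_scores[, emt], q, names = FALSE)
  cut_stem <- stats::quantile(ssgsea_scores[, stem], q, names = FALSE)
  free <- setdiff(samples, mapped)
  hit <- free[ssgsea_scores[free, emt] >= cut_emt &
              ssgsea_scores[free, stem] >= cut_stem]
  subtype[hit] <- "MSPC"
  prov[hit] <- "quartile_rule"
  data.frame(sample = samples, subtype = unname(subtype),
             provenance = unname(prov), stringsAsFactors = FALSE)
}

#' Marker-based subtype assignment for single cells
#'
#' Each subtype marker (AR for ARPC, SYP for NEPC, CD44 for MSPC) is
#' z-scored across cells; a cell takes the subtype of its highest marker
#' z-score, or stays unassigned when every marker z is negative.
#'
#' @param cell_expression genes x cells matrix (log2 scale).
#' @param markers named character vector subtype -> marker gene.
#' @return data.frame(cell, subtype) plus the marker z-scores.
#' @export
call_subtype_markers <- function(cell_expression,
                                 markers = c(ARPC = "AR", NEPC = "SYP",
                                             MSPC = "CD44")) {
  miss <- setdiff(markers, rownames(cell_expression))
  if (length(miss))
    stop_fmt("marker gene(s) missing from expression: %s",
             paste(miss, collapse = ", "))
  z <- t(apply(cell_expression[markers, , drop = FALSE], 1, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  rownames(z) <- names(markers)
  best <- apply(z, 2, which.max)
  call <- names(markers)[best]
  call[apply(z, 2, max) < 0] <- "unassigned"
  out <- data.frame(cell = colnames(cell_expression), subtype = call,
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(t(z)))
}

#' Build the normal-epithelium lineage reference
#'
#' Pseudo-bulk = mean log2 expression per labeled epithelial cell type
#' (luminal, basal, neuroendocrine); the lineage gene panel is the top
#' \code{n_genes} by variance across the pseudo-bulk columns, constant
#' genes excluded.
#'
#' @param normal_expression genes x cells matrix of normal epithelial cells.
#' @param cell_type_labels character vector per cell.
#' @param n_genes panel size (default 5000; capped at available
#'   non-constant genes).
#' @return list(pseudo_bulk = genes x types matrix, panel = character,
#'   variance = named numeric) of class \code{"lineage_reference"}.
#' @export
build_lineage_reference <- function(normal_expression, cell_type_labels,
                                    n_genes =
                                      default_thresholds()$n_lineage_genes) {
  types <- unique(cell_type_labels)
  pb <- sapply(types, function(t)
    rowMeans(normal_expression[, cell_type_labels == t, drop = FALSE]))
  v <- row_vars(pb)
  varying <- which(v > 0)
  k <- min(n_genes, length(varying))
  if (k < n_genes)
    warning(sprintf("lineage panel truncated to %d varying genes", k))
  ord <- varying[order(-v[varying], rownames(pb)[varying])]
  sel <- ord[seq_len(k)]
  out <- list(pseudo_bulk = pb, panel = rownames(pb)[sel], variance = v[sel])
  class(out) <- "lineage_reference"
  out
}

#' Assign cells to epithelial lineages
#'
#' Spearman correlation of each cell with each pseudo-bulk over the lineage
#' gene panel; the cell takes the lineage with the highest correlation.
#' Exact ties resolve in the reference's column order and are flagged.
#'
#' @param profiles named expression vector, or genes x cells matrix.
#' @param reference a \code{\link{build_lineage_reference}} result.
#' @return data.frame(cell, lineage, tie) plus one rho column per lineage.
#' @export
assign_lineage <- function(profiles, reference) {
  if (is.null(dim(profiles)))
    profiles <- matrix(profiles, ncol = 1,
                       dimnames = list(names(profiles), "cell"))
  panel <- intersect(reference$panel, rownames(profiles))
  sub <- profiles[panel, , drop = FALSE]
  const <- apply(sub, 2, function(x) length(unique(x)) < 2L)
  if (any(const))
    stop_fmt("cell(s) constant on the lineage panel (undefined correlation): %s",
             paste(colnames(sub)[const], collapse = ", "))
  rho <- stats::cor(sub, reference$pseudo_bulk[panel, , drop = FALSE],
                    method = "spearman")
  best <- apply(rho, 1, which.max)
  tie <- apply(rho, 1, function(r) sum(r == max(r)) > 1L)
  out <- data.frame(cell = colnames(profiles),
                    lineage = colnames(rho)[best], tie = unname(tie),
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(rho, row.names = seq_len(nrow(rho))))
}

#' Top positive PC1 loadings
#'
#' Features (genes or peaks) are centered across columns and decomposed by
#' SVD; PC1 is oriented so that the designated contrast group has positive
#' scores (or, absent one, so that the loading distribution skews
#' positive — the SVD sign being arbitrary), and the \code{n_top} features
#' with the largest positive loadings are returned.
#'
#' @param mat features x samples matrix (>= 3 columns).
#' @param n_top number of features to return.
#' @param positive_group optional column names whose mean PC1 score fixes
#'   the sign.
#' @return list(features, loadings = full named vector, scores = per-sample
#'   PC1 scores, var_share, flipped).
#' @export
pc1_top_loadings <- function(mat, n_top, positive_group = NULL) {
  if (ncol(mat) < 3L) stop_fmt("PCA needs at least 3 columns")
  if (n_top > nrow(mat)) {
    warning(sprintf("n_top (%d) exceeds features (%d); returning all",
                    n_top, nrow(mat)))
    n_top <- nrow(mat)
  }
  x <- mat - rowMeans(mat)
  s <- svd(x)
  loadings <- stats::setNames(s$u[, 1], rownames(mat))
  scores <- stats::setNames(s$d[1] * s$v[, 1], colnames(mat))
  flip <- if (!is.null(positive_group)) mean(scores[positive_group]) < 0
          else mean((loadings - mean(loadings))^3) < 0
  if (flip) { loadings <- -loadings; scores <- -scores }
  ord <- order(-loadings, names(loadings))
  list(features = names(loadings)[ord[seq_len(n_top)]],
       loadings = loadings, scores = scores,
       var_share = s$d[1]^2 / sum(s$d^2), flipped = flip)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric tail probability of the overlap between a
#' feature list and each gene set, within a stated universe; BH adjustment
#' across sets.
#'
#' @param feature_list character vector (e.g. top PC1 genes).
#' @param gene_sets named list of character vectors.
#' @param universe the background feature universe.
#' @return data.frame(set, overlap, set_size, list_size, p, p_adj).
#' @export
ora_hypergeometric <- function(feature_list, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_fmt("empty universe")
  lst <- unique(intersect(feature_list, universe))
  res <- lapply(names(gene_sets), function(nm) {
    set <- unique(intersect(gene_sets[[nm]], universe))
    k <- length(intersect(set, lst))
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(lst), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set),
               list_size = length(lst), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out
}
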