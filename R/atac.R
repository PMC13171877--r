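#' Select the most variable ATAC peaks
#'
#' Peaks are ranked by count variance across all pooled samples (patients
#' and models together) and the top \code{frac} fraction is retained
#' (\code{ceiling(frac * n_peaks)} peaks). Ties break deterministically by
#' peak coordinate label.
#'
#' @param peak_counts peaks x samples matrix of normalized counts.
#' @param frac fraction retained (default 0.01).
#' @return list(peaks, variance) of class \code{"peak_panel"}.
#' @export
select_variable_peaks <- function(peak_counts,
                                  frac = default_thresholds()$peak_top_frac) {
  if (frac <= 0 || frac > 1) stop_fmt("frac must lie in (0, 1]")
  v <- row_vars(peak_counts)
  k <- min(nrow(peak_counts), ceiling(frac * nrow(peak_counts)))
  ord <- order(-v, rownames(peak_counts))
  sel <- ord[seq_len(k)]
  out <- list(peaks = rownames(peak_counts)[sel], variance = v[sel])
  class(out) <- "peak_panel"
  out
}

#' Chromatin-accessibility similarity table
#'
#' Spearman rank correlation (average-rank ties) between every model and
#' every patient sample over the variable-peak panel. Being rank-based, the
#' similarity is invariant to any monotone renormalization of the counts.
#'
#' @param peak_counts peaks x samples matrix.
#' @param panel peak labels (or a \code{peak_panel}).
#' @param models,patients column name sets.
#' @return numeric matrix models x patients of Spearman rho.
#' @export
atac_similarity <- function(peak_counts, panel, models, patients) {
  if (is.list(panel)) panel <- panel$peaks
  panel <- intersect(panel, rownames(peak_counts))
  if (length(panel) < 3L) stop_fmt("fewer than 3 panel peaks in the matrix")
  stats::cor(peak_counts[panel, models, drop = FALSE],
             peak_counts[panel, patients, drop = FALSE],
             method = "spearman")
}

#' Per-subtype similarity summary
#'
#' Median model-patient similarity within each patient subtype; the medians
#' preserve the ranking structure of the underlying table.
#'
#' @param similarity models x patients matrix from
#'   \code{\link{atac_similarity}}.
#' @param patient_subtypes named character vector (patient -> subtype).
#' @return models x subtypes matrix of median rho.
#' @export
atac_subtype_summary <- function(similarity, patient_subtypes) {
  subtypes <- sort(unique(patient_subtypes[colnames(similarity)]))
  sapply(subtypes, function(st) {
    cols <- colnames(similarity)[patient_subtypes[colnames(similarity)] == st]
    apply(similarity[, cols, drop = FALSE], 1, stats::median)
  })
}

# Exact null distribution of the positive-rank sum W+ over ranks r
# (half-integer average ranks handled by doubling), via convolution.
signed_rank_exact_p <- function(w, r) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1L)  # f[s + 1] = number of sign patterns with 2*W+ = s
  f[1] <- 1
  for (x in r2) {
    g <- f
    g[(x + 1L):(total + 1L)] <- g[(x + 1L):(total + 1L)] + f[1:(total + 1L - x)]
    f <- g
  }
  f <- f / 2^length(r2)
  w2 <- round(2 * w)
  p_le <- sum(f[seq_len(min(total, w2) + 1L)])
  p_ge <- sum(f[(max(0, w2) + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Paired Wilcoxon signed-rank comparison of two similarity vectors
#'
#' Two-sided signed-rank test for paired similarity values of two models
#' over the same patient set. Zero differences are handled by the Pratt
#' method: they enter the ranking of |differences| and are then discarded,
#' so heavy zero-inflation is not silently dropped from the ranks. The
#' exact null distribution (convolution over the retained ranks) is used
#' for n <= \code{exact_max} pairs; beyond that, a normal approximation
#' with continuity correction.
#'
#' @param sim_a,sim_b similarity values of models A and B over the same
#'   patients, equal length >= 5.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return list(statistic = positive-rank sum, p = two-sided p, n_nonzero,
#'   method).
#' @export
paired_compare <- function(sim_a, sim_b, exact_max = 25L) {
  if (length(sim_a) != length(sim_b))
    stop_fmt("paired vectors must have equal length")
  if (length(sim_a) < 5L)
    stop_fmt("need at least 5 pairs, got %d", length(sim_a))
  d <- sim_a - sim_b
  r_all <- rank(abs(d), ties.method = "average")
  nz <- d != 0
  r <- r_all[nz]
  w <- sum(r[d[nz] > 0])
  if (!length(r))
    return(list(statistic = 0, p = 1, n_nonzero = 0L, method = "degenerate"))
  if (length(sim_a) <= exact_max) {
    p <- signed_rank_exact_p(w, r)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sg <- sqrt(sum(r^2) / 4)
    z <- (w - mu - 0.5 * sign(w - mu)) / sg
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, p = p, n_nonzero = length(r), method = method)
}
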