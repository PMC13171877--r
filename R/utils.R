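# Internal helpers shared across stages.

# Row variances of a numeric matrix (denominator n - 1).
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(stats::setNames(rep(NA_real_, nrow(x)), rownames(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1L)
}

# Competition ("min") ranks on descending values: largest value gets rank 1,
# ties share the smallest rank of their block.
min_rank_desc <- function(x) {
  r <- rank(-x, ties.method = "min")
  stats::setNames(as.integer(r), names(x))
}

# Spearman rho between a vector and each column of a matrix, average-rank ties.
spearman_vs_cols <- function(v, m) {
  if (length(unique(v)) < 2L) return(stats::setNames(rep(NA_real_, ncol(m)), colnames(m)))
  drop(stats::cor(v, m, method = "spearman"))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
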