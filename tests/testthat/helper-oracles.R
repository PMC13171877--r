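# Independent brute-force oracles used to verify the statistical
# primitives. Each one is a literal transcription of the defining formula,
# kept deliberately separate from the package implementation.

# Two-sided Fisher exact p by enumerating every table with fixed margins:
# sum the hypergeometric probabilities of all tables at most as probable
# as the observed one (with the customary relative tolerance).
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total (group A size)
  n <- c + d          # row 2 total
  k <- a + c          # mutated total
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up by the textbook definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Spearman rho with average ranks, via the Pearson formula on ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact two-sided signed-rank p (Pratt zeros) by enumerating all 2^n sign
# patterns over the non-zero differences.
signed_rank_enum_oracle <- function(d) {
  r_all <- rank(abs(d), ties.method = "average")
  nz <- d != 0
  r <- r_all[nz]
  if (!length(r)) return(1)
  w_obs <- sum(r[d[nz] > 0])
  n <- length(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Literal running-sum ssGSEA for one sample and one set.
ssgsea_oracle <- function(x, set, alpha) {
  genes <- names(x)
  ord <- order(-x, genes)
  r <- rank(x, ties.method = "average")[ord]
  inset <- genes[ord] %in% set
  num <- denom_in <- 0
  denom_in <- sum(abs(r[inset])^alpha)
  n_out <- sum(!inset)
  p_in <- p_out <- 0
  score <- 0
  for (i in seq_along(ord)) {
    if (inset[i]) p_in <- p_in + abs(r[i])^alpha / denom_in
    else if (n_out > 0) p_out <- p_out + 1 / n_out
    score <- score + (p_in - p_out)
  }
  unname(score)
}

# One-sided hypergeometric tail by summing the pmf.
hyper_enum_oracle <- function(k, set_size, universe, list_size) {
  support <- k:min(set_size, list_size)
  sum(vapply(support, function(x)
    exp(lchoose(set_size, x) + lchoose(universe - set_size, list_size - x) -
          lchoose(universe, list_size)), numeric(1)))
}
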