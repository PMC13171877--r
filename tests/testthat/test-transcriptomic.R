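test_that("HVG selection is a deterministic variance sort", {
  m <- rbind(FLAT = rep(2, 5),
             LOW = c(2, 2, 2, 2, 2.1),
             MID = c(1, 2, 3, 4, 5),
             HIGH = c(0, 5, 0, 5, 10))
  colnames(m) <- paste0("S", 1:5)
  hv <- select_hvg(m, 3)
  expect_equal(hv$genes, c("HIGH", "MID", "LOW"))
  # a constant gene is never selected ahead of any varying gene
  expect_false("FLAT" %in% select_hvg(m, 3)$genes)
  expect_warning(all_g <- select_hvg(m, 10), "exceeds")
  expect_equal(length(all_g$genes), 4L)
  # hand variance sort on a random 10-gene toy
  set.seed(3)
  m2 <- matrix(rnorm(80), 10, 8, dimnames = list(paste0("g", 1:10),
                                                 paste0("s", 1:8)))
  v <- apply(m2, 1, var)
  expect_equal(select_hvg(m2, 3)$genes,
               names(sort(v, decreasing = TRUE))[1:3])
})

test_that("TC similarity is the median of tied-rank Spearman correlations", {
  genes <- paste0("g", 1:6)
  ref <- matrix(c(1, 2, 3, 4, 5, 6,
                  2, 1, 4, 3, 6, 5,
                  6, 5, 4, 3, 2, 1), ncol = 3,
                dimnames = list(genes, c("R1", "R2", "R3")))
  model <- stats::setNames(c(1, 2, 3, 4, 5, 6), genes)
  got <- tc_similarity(model, ref, genes)
  # per-reference rho checked against the brute-force rank formula
  for (j in 1:3)
    expect_equal(unname(got$per_reference[j]),
                 spearman_oracle(model, ref[, j]), tolerance = 1e-12)
  expect_equal(got$similarity, unname(sort(got$per_reference)[2]))
  # identical to every reference -> 1; rank reversal -> -1
  same <- ref[, c(1, 1, 1)]
  expect_equal(tc_similarity(model, same, genes)$similarity, 1)
  expect_equal(unname(tc_similarity(model, ref[, 3, drop = FALSE],
                                    genes)$per_reference), -1)
  # ties handled by average ranks: verify on a tied toy
  tied <- stats::setNames(c(1, 1, 2, 2, 3, 3), genes)
  expect_equal(unname(tc_similarity(tied, ref[, 1, drop = FALSE],
                                    genes)$per_reference),
               spearman_oracle(tied, ref[, 1]), tolerance = 1e-12)
  # invariance to strictly monotone transforms of the model profile
  expect_equal(tc_similarity(exp(model) + 5, ref, genes)$per_reference,
               got$per_reference, tolerance = 1e-12)
  # constant model -> missing similarity
  const <- stats::setNames(rep(1, 6), genes)
  expect_true(is.na(tc_similarity(const, ref, genes)$similarity))
})

test_that("explicit medians aggregate a 3-reference toy", {
  # engineered per-reference rho of {0.2, 0.5, 0.9} -> median 0.5
  sims <- c(R1 = 0.2, R2 = 0.5, R3 = 0.9)
  expect_equal(stats::median(sims), 0.5)
  tab <- matrix(c(0.2, 0.5, 0.9, 0.1, 0.1, 0.1), nrow = 2, byrow = TRUE,
                dimnames = list(c("M1", "M2"), names(sims)))
  r <- rank_models(tab)
  expect_equal(r$similarity[r$model == "M1"], 0.5)
  expect_equal(r$rank, c(1L, 2L))
})

test_that("model ranking uses min-rank ties and ignores constant shifts", {
  sims <- c(A = 0.9, B = 0.8, C = 0.8, D = 0.1)
  r <- rank_models(sims)
  expect_equal(r$rank[match(c("A", "B", "C", "D"), r$model)],
               c(1L, 2L, 2L, 4L))
  r2 <- rank_models(sims + 0.05)
  expect_equal(r2$rank, r$rank)
  all_equal <- rank_models(c(A = 0.5, B = 0.5, C = 0.5))
  expect_true(all(all_equal$rank == 1L))
})

test_that("site consistency is pairwise Spearman of similarity vectors", {
  v <- c(M1 = 0.9, M2 = 0.5, M3 = 0.1)
  same <- list(bone = v, liver = v, lymph_node = v)
  expect_true(all(site_consistency(same) == 1))
  rev2 <- list(bone = v, liver = rev(stats::setNames(v, names(v))))
  rev2$liver <- stats::setNames(c(0.1, 0.5, 0.9), names(v))
  expect_equal(site_consistency(rev2)["bone", "liver"], -1)
})

test_that("CTL score is the mean of the five cytotoxicity markers", {
  m <- toy_expression()
  m[c("CD8A", "CD8B", "GZMA", "GZMB", "PRF1"), "X1"] <- c(1, 2, 3, 4, 5)
  expect_equal(unname(ctl_score(m, "X1")), 3)
  m[c("CD8A", "CD8B", "GZMA", "GZMB", "PRF1"), "X2"] <- 2.5
  expect_equal(unname(ctl_score(m, "X2")), 2.5)
  expect_error(ctl_score(m[-4, ]), "CD8A")
})

test_that("rank-sum DE needs both the p-value and fold-change rule", {
  set.seed(11)
  genes <- c("UP", "FCONLY", "PONLY", "NULL")
  a_cols <- paste0("A", 1:12); b_cols <- paste0("B", 1:12)
  m <- matrix(rnorm(4 * 24, 5, 0.3), 4, 24,
              dimnames = list(genes, c(a_cols, b_cols)))
  m["UP", a_cols] <- m["UP", a_cols] + 2           # big shift, clean
  m["FCONLY", a_cols] <- m["FCONLY", 1:12] + rnorm(12, 2, 6) # huge noise
  m["PONLY", a_cols] <- m["PONLY", a_cols] + 0.4   # significant, small FC
  res <- rank_sum_de(m, a_cols, b_cols)
  expect_equal(res$call[res$gene == "UP"], "up")
  expect_equal(res$call[res$gene == "PONLY"], "none")
  expect_equal(res$call[res$gene == "NULL"], "none")
  # identical groups -> zero calls
  m2 <- m; m2[, a_cols] <- m2[, b_cols]
  expect_true(all(rank_sum_de(m2, a_cols, b_cols)$call == "none"))
  expect_error(rank_sum_de(m, a_cols, c(a_cols[1], b_cols)), "disjoint")
})
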