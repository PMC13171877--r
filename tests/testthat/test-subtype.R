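test_that("ssGSEA matches the literal running-sum oracle", {
  # 4-gene toy, expressions {4,3,2,1}, set = top 2: hand trace with alpha=1.
  # Ranks (ascending) are {4,3,2,1}; in-set weights 4 and 3 (sum 7);
  # out fraction steps 1/2. Running gaps: 4/7, 1, 1/2, 0 -> score 57/28.
  x <- stats::setNames(c(4, 3, 2, 1), c("a", "b", "c", "d"))
  m <- matrix(x, ncol = 1, dimnames = list(names(x), "S1"))
  sc <- ssgsea(m, list(top = c("a", "b")), alpha = 1, min_size = 2)
  expect_equal(unname(sc["S1", "top"]), 4 / 7 + 1 + 1 / 2 + 0)
  expect_equal(unname(sc["S1", "top"]),
               ssgsea_oracle(x, c("a", "b"), alpha = 1))

  # alpha = 0 reduces to the unweighted KS-style running sum
  sc0 <- ssgsea(m, list(top = c("a", "b")), alpha = 0, min_size = 2)
  expect_equal(unname(sc0["S1", "top"]),
               ssgsea_oracle(x, c("a", "b"), alpha = 0))
  expect_equal(unname(sc0["S1", "top"]), 1 / 2 + 1 + 1 / 2 + 0)

  # set = all genes: out-of-set ECDF vanishes; closed form sum of P_in
  scall <- ssgsea(m, list(all = names(x)), alpha = 0, min_size = 2)
  expect_equal(unname(scall["S1", "all"]), sum((1:4) / 4))

  # 100 random 50-gene instances against the oracle to 1e-8
  set.seed(99)
  for (i in 1:100) {
    genes <- paste0("g", 1:50)
    x <- stats::setNames(round(rexp(50, 0.3), 2), genes)  # includes ties
    set <- sample(genes, sample(5:20, 1))
    mm <- matrix(x, ncol = 1, dimnames = list(genes, "S"))
    expect_equal(unname(ssgsea(mm, list(s = set), alpha = 0.25)["S", "s"]),
                 ssgsea_oracle(x, set, 0.25), tolerance = 1e-8)
  }

  # permuting gene input order leaves scores identical
  big <- toy_expression()
  perm <- sample(nrow(big))
  s1 <- ssgsea(big, list(s = c("AR", "SYP", "CD44", "CD8A", "G1")), 0.25)
  s2 <- ssgsea(big[perm, ], list(s = c("AR", "SYP", "CD44", "CD8A", "G1")),
               0.25)
  expect_equal(s1, s2)
  expect_error(ssgsea(big, list(tiny = c("AR", "SYP"))), "tiny")
})

test_that("MSPC calling: label map first, then the double-quartile rule", {
  set.seed(2)
  n <- 40
  scores <- cbind(EMT = rnorm(n), stemness = rnorm(n))
  rownames(scores) <- paste0("S", 1:n)
  # force known quantile positions
  scores["S1", ] <- c(10, 10)     # both top -> MSPC
  scores["S2", ] <- c(10, 0)      # EMT high only -> not MSPC
  label_map <- c(S3 = "ARPC", S4 = "NEPC", S1 = "ARPC")
  calls <- call_mspc(scores, label_map)
  got <- stats::setNames(calls$subtype, calls$sample)
  expect_equal(unname(got["S1"]), "ARPC")   # label map takes precedence
  expect_equal(unname(got["S2"]), "unassigned")
  expect_equal(unname(got["S3"]), "ARPC")
  expect_equal(unname(got["S4"]), "NEPC")
  # exactly one label per sample
  expect_equal(nrow(calls), n)
  expect_false(any(duplicated(calls$sample)))
  # without the label map S1 is MSPC by the quartile rule
  calls2 <- call_mspc(scores)
  expect_equal(calls2$subtype[calls2$sample == "S1"], "MSPC")
  expect_equal(calls2$provenance[calls2$sample == "S1"], "quartile_rule")
})

test_that("marker z-score rule assigns cells and leaves cold cells out", {
  genes <- c("AR", "SYP", "CD44", "G1")
  m <- matrix(3, 4, 5, dimnames = list(genes, paste0("c", 1:5)))
  m["AR", "c1"] <- 8       # AR high -> ARPC
  m["SYP", "c2"] <- 8      # SYP high -> NEPC
  m["CD44", "c3"] <- 8     # CD44 high -> MSPC
  m["AR", "c5"] <- 1       # below mean on AR, flat elsewhere
  calls <- call_subtype_markers(m)
  got <- stats::setNames(calls$subtype, calls$cell)
  expect_equal(unname(got[c("c1", "c2", "c3")]), c("ARPC", "NEPC", "MSPC"))
  # c4: all three markers at/below their means -> unassigned
  expect_equal(unname(got["c4"]), "unassigned")
  expect_error(call_subtype_markers(m[c("AR", "G1"), ]), "SYP")
})

test_that("lineage reference is a pseudo-bulk variance sort", {
  genes <- paste0("g", 1:10)
  cells <- matrix(0, 10, 6, dimnames = list(genes, paste0("c", 1:6)))
  labels <- rep(c("luminal", "basal", "neuroendocrine"), each = 2)
  cells[, 1:2] <- c(1:10, 3:12)
  cells[, 3:4] <- c(10:1, 12:3)
  cells[, 5:6] <- 5
  ref <- build_lineage_reference(cells, labels, n_genes = 3)
  pb_manual <- sapply(unique(labels), function(t)
    rowMeans(cells[, labels == t, drop = FALSE]))
  expect_equal(ref$pseudo_bulk, pb_manual)
  v <- apply(pb_manual, 1, var)
  expect_equal(ref$panel, names(sort(-v))[1:3])
  # one cell per type -> pseudo-bulk equals that cell
  ref1 <- build_lineage_reference(cells[, c(1, 3, 5)],
                                  c("luminal", "basal", "neuroendocrine"),
                                  n_genes = 5)
  expect_equal(unname(ref1$pseudo_bulk[, "luminal"]), unname(cells[, 1]))
  # constant gene excluded before any varying gene
  cells2 <- rbind(cells, FLAT = 0)
  expect_warning(
    ref2 <- build_lineage_reference(cells2, labels, n_genes = 11),
    "truncated")
  expect_false("FLAT" %in% ref2$panel)
})

test_that("lineage assignment takes the argmax correlation", {
  genes <- paste0("g", 1:20)
  set.seed(8)
  pb <- matrix(rnorm(60), 20, 3,
               dimnames = list(genes, c("luminal", "basal",
                                        "neuroendocrine")))
  cells <- matrix(rnorm(60), 20, 3, dimnames = list(genes, c("x", "y", "z")))
  ref <- build_lineage_reference(pb, colnames(pb), n_genes = 20)
  cells[, "x"] <- pb[, "basal"]
  got <- assign_lineage(cells, ref)
  expect_equal(got$lineage[got$cell == "x"], "basal")
  expect_equal(got$basal[got$cell == "x"], 1)
  # monotone transform of the profile changes nothing (rank-based)
  got2 <- assign_lineage(exp(cells / 2), ref)
  expect_equal(got2$lineage, got$lineage)
  expect_error(assign_lineage(matrix(1, 20, 1,
                                     dimnames = list(genes, "flat")), ref),
               "constant")
})

test_that("PC1 loadings recover planted separating features", {
  set.seed(21)
  n_feat <- 50
  feats <- paste0("f", 1:n_feat)
  grp <- rep(c("A", "B"), each = 6)
  m <- matrix(rnorm(n_feat * 12, 0, 0.1), n_feat, 12,
              dimnames = list(feats, paste0("s", 1:12)))
  planted <- paste0("f", 1:10)
  m[planted, grp == "B"] <- m[planted, grp == "B"] + 3
  top <- pc1_top_loadings(m, 10, positive_group = paste0("s", 7:12))
  expect_setequal(top$features, planted)
  # orientation: the designated group has positive scores
  expect_gt(mean(top$scores[paste0("s", 7:12)]), 0)
  # duplicated distinct profiles keep the rank-1 variance share
  two <- cbind(a = c(rep(1, 25), rep(0, 25)), b = c(rep(0, 25), rep(1, 25)))
  rownames(two) <- feats
  dup3 <- two[, c(1, 1, 1, 2, 2, 2)]
  dup5 <- two[, c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2)]
  expect_equal(pc1_top_loadings(dup3, 5)$var_share, 1, tolerance = 1e-12)
  expect_equal(pc1_top_loadings(dup5, 5)$var_share, 1, tolerance = 1e-12)
  expect_warning(allf <- pc1_top_loadings(m, 100), "exceeds")
  expect_length(allf$features, n_feat)
  expect_error(pc1_top_loadings(m[, 1:2], 5), "at least 3")
})

test_that("hypergeometric ORA matches enumeration", {
  universe <- paste0("u", 1:20)
  sets <- list(hit = universe[1:5], off = paste0("x", 1:5))
  res <- ora_hypergeometric(universe[1:5], sets, universe)
  expect_equal(res$p[res$set == "hit"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p[res$set == "off"], 1, tolerance = 1e-12)
  # random instances with margins <= 20 vs the tail-sum oracle
  set.seed(13)
  for (i in 1:50) {
    N <- sample(5:20, 1)
    uni <- paste0("u", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    set <- sample(uni, K); lst <- sample(uni, n)
    k <- length(intersect(set, lst))
    got <- ora_hypergeometric(lst, list(s = set), uni)
    expect_equal(got$p, hyper_enum_oracle(k, K, N, n), tolerance = 1e-10)
  }
  expect_error(ora_hypergeometric(universe[1:2], sets, character()),
               "empty universe")
})
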