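test_that("mutation matrix binarizes and honours the silent filter", {
  rec <- toy_records()
  ann <- toy_annotations()
  m <- mutation_matrix(rec, ann, exclude_silent = TRUE)
  # S3 carries only a Silent AR variant -> 0 with the filter on
  expect_equal(m["AR", "S3"], 0L)
  m2 <- mutation_matrix(rec, ann, exclude_silent = FALSE)
  expect_equal(m2["AR", "S3"], 1L)
  # two TP53 records in S1/S2 stay binary
  expect_true(all(m %in% 0:1))
  # no records -> all-zero matrix over annotated samples
  m0 <- mutation_matrix(rec[0, ], ann)
  expect_equal(sum(m0), 0L)
  expect_equal(ncol(m0), 4L)
  # unknown sample is an error listing it
  bad <- rec; bad$sample[1] <- "GHOST"
  expect_error(mutation_matrix(bad, ann), "GHOST")
})

test_that("Fisher gene test matches full-margin enumeration", {
  # identical margins -> p = 1
  ann <- data.frame(sample = paste0("S", 1:110),
                    cohort = rep(c("primary", "metastatic"), c(50, 60)),
                    stringsAsFactors = FALSE)
  m <- matrix(0L, 1, 110, dimnames = list("G", ann$sample))
  expect_equal(fisher_gene_test(m, ann$sample[1:50], ann$sample[51:110], "G"),
               1.0)

  # all 2x2 tables with n <= 12 against the enumeration oracle
  for (n in 2:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      na <- a + b; nb <- cc + d
      if (na == 0 || nb == 0) next
      samples <- paste0("S", seq_len(n))
      mm <- matrix(0L, 1, n, dimnames = list("G", samples))
      ga <- samples[seq_len(na)]; gb <- samples[na + seq_len(nb)]
      if (a > 0) mm[1, ga[seq_len(a)]] <- 1L
      if (cc > 0) mm[1, gb[seq_len(cc)]] <- 1L
      expect_equal(fisher_gene_test(mm, ga, gb, "G"),
                   fisher_enum_oracle(a, b, cc, d), tolerance = 1e-10)
    }
  }
  expect_error(fisher_gene_test(m, ann$sample[1:50], ann$sample[51:110],
                                "NOPE"), "absent")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(7)
  p <- runif(50)
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  # order preserving; idempotent on a flat already-adjusted vector
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
})

test_that("differential gene selection applies the two-site rule", {
  # deterministic toy: gene DIFF mutated in most bone+liver mets, absent in
  # primaries; gene ONESITE only separates in bone
  set.seed(1)
  n_pri <- 60
  ann <- data.frame(
    sample = c(paste0("P", 1:n_pri), paste0("B", 1:15), paste0("L", 1:15)),
    cohort = rep(c("primary", "metastatic"), c(n_pri, 30)),
    site = rep(c("primary", "bone", "liver"), c(n_pri, 15, 15)),
    stringsAsFactors = FALSE)
  m <- matrix(0L, 3, nrow(ann), dimnames = list(c("DIFF", "ONESITE", "NULL"),
                                                ann$sample))
  m["DIFF", c(paste0("B", 1:12), paste0("L", 1:12))] <- 1L
  m["ONESITE", paste0("B", 1:12)] <- 1L
  m["NULL", c("P1", "B1", "L1")] <- 1L
  res <- select_diff_genes(m, ann)
  expect_true("DIFF" %in% res$diff_genes)
  expect_false("ONESITE" %in% res$diff_genes)
  expect_false("NULL" %in% res$diff_genes)
  expect_equal(unname(res$n_sig_sites["ONESITE"]), 1L)
  # per-site table covers only genes with >= 1 mutation in site + primary
  expect_true(all(res$per_site$freq_site + res$per_site$freq_primary > 0))
})

test_that("high-mutation selection strictly exceeds 5% in two sites", {
  ann <- data.frame(
    sample = c(paste0("B", 1:20), paste0("L", 1:20), paste0("Y", 1:20)),
    cohort = "metastatic",
    site = rep(c("bone", "liver", "lymph_node"), each = 20),
    stringsAsFactors = FALSE)
  m <- matrix(0L, 3, 60, dimnames = list(c("TWO", "ONE", "EDGE"), ann$sample))
  m["TWO", c("B1", "B2", "L1", "L2")] <- 1L     # 10% in two sites
  m["ONE", c("B1", "B2")] <- 1L                 # 10% in one site
  m["EDGE", c("B1", "L1", "Y1")] <- 1L          # exactly 5% everywhere
  got <- select_high_genes(m, ann)
  expect_equal(got, "TWO")
})

test_that("panel ranking uses min-rank ties and the ratio reorders them", {
  counts <- c(A = 8, B = 3, C = 3, D = 1, E = 0)
  samples <- names(counts)
  genes <- paste0("G", 1:8)
  m <- matrix(0L, 8, 5, dimnames = list(genes, samples))
  for (s in samples) if (counts[s] > 0) m[seq_len(counts[s]), s] <- 1L
  r <- rank_by_panel(m, genes, samples)
  expect_equal(r$rank[match(c("A", "B", "C", "D", "E"), r$model)],
               c(1L, 2L, 2L, 4L, 5L))
  # zero panel mutations -> last
  expect_equal(r$model[r$rank == 5L], "E")

  # burden normalization: same counts, 10x burden spread flips the order
  burden <- c(A = 400, B = 10, C = 40, D = 5, E = 10)
  ratio <- normalized_ratio(counts, burden)
  expect_equal(unname(ratio["B"]), 0.3)
  expect_equal(unname(ratio["A"]), 0.02)
  expect_false(identical(order(-counts), order(-ratio)))
  expect_equal(unname(normalized_ratio(10, 200)), 0.05)
  expect_equal(unname(normalized_ratio(0, 50)), 0)
  expect_warning(z <- normalized_ratio(3, 0), "zero burden")
  expect_true(is.na(z))
})

test_that("hotspot catalogue needs three non-silent carriers", {
  rec <- data.frame(
    gene = c(rep("TP53", 3), rep("AR", 2), rep("RPL22", 5)),
    sample = c("M1", "M2", "M3", "M1", "M2", paste0("M", 1:5)),
    variant_class = c(rep("Missense_Mutation", 5), rep("Silent", 5)),
    protein_change = c(rep("p.R175H", 3), rep("p.T878A", 2),
                       rep("p.K16fs", 5)),
    stringsAsFactors = FALSE)
  mets <- paste0("M", 1:5)
  cat <- find_hotspots(rec, mets)
  expect_equal(cat$gene, "TP53")          # AR: 2 carriers; RPL22: silent
  expect_equal(cat$n_carriers, 3L)

  # duplicate records in one sample count once
  rec2 <- rbind(rec, data.frame(gene = "TP53", sample = "M1",
                                variant_class = "Missense_Mutation",
                                protein_change = "p.R175H"))
  expect_equal(find_hotspots(rec2, mets)$n_carriers, 3L)

  # presence: exact gene + protein-change match only
  cl_rec <- data.frame(
    gene = c("TP53", "TP53"), sample = c("LNCaP", "PC3"),
    variant_class = "Missense_Mutation",
    protein_change = c("p.R175H", "p.R273C"), stringsAsFactors = FALSE)
  pres <- hotspot_presence(cat, cl_rec, c("LNCaP", "PC3", "DU145"))
  expect_true(pres["TP53 p.R175H", "LNCaP"])
  expect_false(pres["TP53 p.R175H", "PC3"])
  expect_false(any(pres[, "DU145"]))
  empty <- find_hotspots(rec[0, ], mets)
  expect_equal(dim(hotspot_presence(empty, cl_rec)), c(0L, 2L))
})

test_that("hypermutation cutoff finds the largest upper-tail log gap", {
  b <- c(5000, 4800, 4500, 100, 90, 85, 80, 78, 76, 74, 72, 70, 68, 66,
         64, 62, 60, 58, 56, 54, 52, 50)
  names(b) <- paste0("S", seq_along(b))
  call <- hypermutation_cutoff(b, default_thresholds(gap_top_frac = 0.5))
  expect_equal(call$gap_index, 3L)
  expect_equal(sort(call$hypermutated), c("S1", "S2", "S3"))
  expect_equal(call$cutoff_burden, 100)
  expect_false(call$no_cutoff)
  expect_gt(call$bimodality$separation, 2)

  # scale equivariance of the classification
  call10 <- hypermutation_cutoff(b * 10, default_thresholds(gap_top_frac = 0.5))
  expect_equal(call10$hypermutated, call$hypermutated)

  # equal burdens: no gap, flag raised
  flat <- stats::setNames(rep(50, 25), paste0("S", 1:25))
  call0 <- hypermutation_cutoff(flat)
  expect_true(call0$no_cutoff)
  expect_length(call0$hypermutated, 0)

  expect_error(hypermutation_cutoff(stats::setNames(1:5, paste0("S", 1:5))),
               "at least 20")
})

test_that("MMR comparison contrasts per-sample mutated-gene counts", {
  genes <- c("MLH1", "MSH2", "MSH6", "PMS2", "OTHER")
  samples <- paste0("S", 1:20)
  m <- matrix(0L, 5, 20, dimnames = list(genes, samples))
  hyper <- samples[1:6]; rest <- samples[7:20]
  m[1:3, hyper] <- 1L
  res <- mmr_comparison(m, genes[1:4], hyper, rest)
  expect_lt(res$p, 0.001)
  expect_equal(res$mean_hyper, 3)
  expect_equal(res$mean_other, 0)
  # identical groups -> p = 1 (up to tie handling)
  m[] <- 1L
  res2 <- mmr_comparison(m, genes[1:4], hyper, rest)
  expect_equal(res2$p, 1, tolerance = 1e-8)
  expect_error(mmr_comparison(m, character(), hyper, rest), "empty")
  expect_error(mmr_comparison(m, c("NOT1", "NOT2"), hyper, rest), "none")
})

test_that("segment-to-gene mapping is overlap-weighted", {
  gm <- data.frame(gene = c("A", "B", "C"), chrom = "chr1",
                   start = c(100, 1000, 5000), end = c(200, 2000, 5100),
                   stringsAsFactors = FALSE)
  seg <- data.frame(sample = "S1", chrom = "chr1",
                    start = c(0, 1500), end = c(1500, 3000),
                    value = c(0.8, 0), stringsAsFactors = FALSE)
  cnv <- segments_to_gene_cnv(seg, gm)
  expect_equal(cnv["A", "S1"], 0.8)          # fully inside the 0.8 segment
  expect_equal(cnv["B", "S1"], 0.4)          # half in 0.8, half in 0
  expect_true(is.na(cnv["C", "S1"]))         # no overlap

  # weighted mean with unequal split: 25% in 1.0, 75% in 0
  seg2 <- data.frame(sample = "S1", chrom = "chr1",
                     start = c(1000, 1250), end = c(1250, 2000),
                     value = c(1, 0), stringsAsFactors = FALSE)
  cnv2 <- segments_to_gene_cnv(seg2, gm)
  expect_equal(cnv2["B", "S1"], 0.25)
})

test_that("differential CNV requires both the delta and the p-value rule", {
  set.seed(5)
  ann <- data.frame(sample = paste0("S", 1:40),
                    cohort = rep(c("metastatic", "primary"), each = 20),
                    stringsAsFactors = FALSE)
  met <- ann$sample[1:20]; pri <- ann$sample[21:40]
  cnv <- rbind(
    BIG = c(rnorm(20, 0.8, 0.05), rnorm(20, 0, 0.05)),   # clear shift
    SMALL = c(rnorm(20, 0.15, 0.05), rnorm(20, 0, 0.05)),# sig p, tiny delta
    NOISY = c(rnorm(20, 0, 0.5), rnorm(20, 0, 0.5)))     # nothing
  colnames(cnv) <- ann$sample
  res <- differential_cnv(cnv, ann)
  expect_true(res$significant[res$gene == "BIG"])
  expect_false(res$significant[res$gene == "SMALL"])   # |delta| <= 0.3
  expect_false(res$significant[res$gene == "NOISY"])
  # identical cohorts -> nothing significant
  same <- cnv; same[, met] <- same[, pri]
  expect_false(any(differential_cnv(same, ann)$significant))
})
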