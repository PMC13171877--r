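test_that("identical seeds give byte-identical cohorts", {
  a <- simulate_cohort(small_config(seed = 7))
  b <- simulate_cohort(small_config(seed = 7))
  expect_identical(a[setdiff(names(a), "config")],
                   b[setdiff(names(b), "config")])
  c2 <- simulate_cohort(small_config(seed = 8))
  expect_false(identical(a$records, c2$records))
})

test_that("hypermutator planting follows the configured fraction and rates", {
  cfg <- small_config(seed = 3)
  mut <- simulate_mutations(cfg)
  n_total <- nrow(mut$annotations)
  expect_length(mut$truth$hypermutated_samples,
                round(cfg$hyper_frac * n_total))
  # burden ratio between hypermutators and the rest, across seeds
  ratios <- vapply(1:10, function(s) {
    m <- simulate_mutations(small_config(seed = s))
    bu <- stats::setNames(m$burden$burden, m$burden$sample)
    hy <- m$truth$hypermutated_samples
    mean(bu[hy]) / mean(bu[setdiff(names(bu), hy)])
  }, numeric(1))
  expect_true(all(ratios >= 10 & ratios <= 60))
  # with multiplier 1 the burden distribution has no planted gap
  m1 <- simulate_mutations(small_config(seed = 3, hyper_multiplier = 1,
                                        mmr_hyper_prob = NA_real_))
  bu <- stats::setNames(m1$burden$burden, m1$burden$sample)
  call <- hypermutation_cutoff(bu)
  expect_true(call$no_cutoff)
})

test_that("planted hotspots and MMR enrichment are recoverable", {
  cfg <- small_config(seed = 5)
  mut <- simulate_mutations(cfg)
  met <- mut$annotations$sample[mut$annotations$cohort == "metastatic"]
  cat <- find_hotspots(mut$records, met)
  key <- paste(cat$gene, cat$protein_change)
  truth_key <- paste(mut$truth$hotspots$gene,
                     mut$truth$hotspots$protein_change)
  expect_true(all(truth_key %in% key))
  # the planted cell-line carriage shows up in the presence matrix
  cl <- mut$annotations$sample[mut$annotations$cohort == "cell_line"]
  pres <- hotspot_presence(cat, mut$records[mut$records$sample %in% cl, ], cl)
  clh <- mut$truth$cell_line_hotspots
  for (i in seq_len(nrow(clh)))
    expect_true(pres[paste(clh$gene[i], clh$protein_change[i]), clh$sample[i]])
  # MMR genes enriched in hypermutators
  mat <- mutation_matrix(mut$records, mut$annotations)
  hy <- mut$truth$hypermutated_samples
  res <- mmr_comparison(mat, c("MLH1", "MSH2", "MSH6", "PMS2"), hy,
                        setdiff(colnames(mat), hy))
  expect_gt(res$mean_hyper, res$mean_other)
})

test_that("noise-free expression collapses onto the subtype centroids", {
  cfg <- small_config(seed = 2, expr_noise_sd = 1e-12)
  co <- simulate_cohort(cfg)
  arpc <- names(co$truth$subtype)[co$truth$subtype == "ARPC"]
  arpc <- intersect(arpc, colnames(co$bulk))
  ref <- co$centroids[, "ARPC"]
  for (s in arpc[1:3])
    expect_equal(unname(co$bulk[, s]), unname(pmax(ref, 0)),
                 tolerance = 1e-6)
  # the designated matched line sits exactly on its centroid
  cl <- co$truth$matched_models[["ARPC"]]
  expect_equal(stats::cor(co$bulk[, cl], co$centroids[, "ARPC"],
                          method = "spearman"), 1, tolerance = 1e-8)
})

test_that("immune shift in hypermutated primaries matches the plant", {
  diffs <- vapply(1:5, function(s) {
    co <- simulate_cohort(small_config(seed = s))
    ann <- co$annotations
    pri <- ann$sample[ann$cohort == "primary"]
    hp <- intersect(co$truth$hypermutated_samples, pri)
    if (!length(hp)) return(NA_real_)
    imm <- c("CD3D", "CD3E", "CD8A", "CD8B", "GZMA", "GZMB", "PRF1",
             "PDCD1", "CTLA4")
    mean(co$bulk[imm, hp]) - mean(co$bulk[imm, setdiff(pri, hp)])
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  # planted delta of 1.5 log2 units, within Monte-Carlo error
  expect_lt(abs(mean(diffs) - 1.5), 0.3)
})

test_that("CNV plant is confined to the AR block in metastatic samples", {
  co <- simulate_cohort(small_config(seed = 4))
  cnv <- segments_to_gene_cnv(co$segments, co$gene_models)
  ann <- co$annotations
  pri <- ann$sample[ann$cohort == "primary"]
  met <- ann$sample[ann$cohort == "metastatic"]
  # background-only samples: gene values near zero
  expect_lt(max(abs(cnv[, pri[1:5]])), 0.6)
  expect_lt(abs(mean(cnv[, pri])), 0.05)
  # planted amplification: median difference close to the 0.8 plant
  d <- stats::median(cnv["AR", met]) - stats::median(cnv["AR", pri])
  expect_lt(abs(d - 0.8), 0.15)
})

test_that("ATAC blocks make within-subtype samples more alike", {
  co <- simulate_cohort(small_config(seed = 6))
  met <- co$annotations$sample[co$annotations$cohort == "metastatic"]
  panel <- select_variable_peaks(co$atac, 0.05)
  st <- co$truth$subtype[met]
  arpc <- met[st == "ARPC"][1:4]; nepc <- met[st == "NEPC"][1:4]
  sub <- co$atac[panel$peaks, c(arpc, nepc)]
  rho <- stats::cor(sub, method = "spearman")
  within <- c(rho[arpc, arpc][upper.tri(diag(4))],
              rho[nepc, nepc][upper.tri(diag(4))])
  across <- as.vector(rho[arpc, nepc])
  expect_gt(mean(within), mean(across))
  # peak count honoured
  expect_equal(nrow(simulate_atac(small_config(seed = 1, n_peaks = 100L))$counts),
               100L)
})

test_that("cohort export round-trips through the standard formats", {
  co <- simulate_cohort(small_config(seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  maf <- read_maf(file.path(dir, "mutations.maf"))
  expect_equal(nrow(maf$records), nrow(co$records))
  seg <- read_seg(file.path(dir, "cnv.seg"))
  expect_equal(seg$start, co$segments$start)
  expect_equal(seg$value, co$segments$value, tolerance = 1e-9)
  bulk <- read_expression(file.path(dir, "expression_bulk.tsv"))
  expect_equal(bulk, round(co$bulk, 4), tolerance = 1e-9)
  peaks <- read_peak_counts(file.path(dir, "atac_counts.tsv"))
  expect_equal(dim(peaks), dim(co$atac))
  gmt <- read_gmt(file.path(dir, "signatures.gmt"))
  expect_equal(gmt$EMT, co$gene_sets$EMT)
  truth <- jsonlite::read_json(file.path(dir, "truth_ledger.json"))
  expect_equal(sort(unlist(truth$hypermutated_samples)),
               co$truth$hypermutated_samples)
})
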