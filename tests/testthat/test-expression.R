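toy_samples <- function(n) data.frame(
  sample_id = sprintf("s%d", seq_len(n)),
  tissue = rep(c("mPFC", "striatum"), length.out = n),
  age = rep(c(7, 14, 56), length.out = n),
  replicate = seq_len(n), sex = "F")

test_that("CPM normalization scales every sample to one million", {
  m <- count_matrix(matrix(c(4, 2e6 - 4, 10, 90), ncol = 2,
                          dimnames = list(c("a", "b"), NULL)),
                    toy_samples(2))
  n <- normalize_library_size(m)
  expect_equal(n$counts["a", 1], 2)       # 4 reads in 2e6 -> 2 CPM
  expect_equal(unname(colSums(n$counts)), c(1e6, 1e6))
  set.seed(8)
  r <- count_matrix(matrix(rpois(60, 40), nrow = 10), toy_samples(6))
  expect_equal(unname(colSums(normalize_library_size(r)$counts)),
               rep(1e6, 6))
  z <- count_matrix(matrix(0, 2, 2), toy_samples(2))
  expect_error(normalize_library_size(z), "s1")
})

test_that("detection filter boundary is inclusive and matches brute force", {
  counts <- rbind(
    kept_exact = c(10, 10, 10, 0, 0, 0),
    removed = c(9, 100, 100, 0, 0, 0),
    kept_rich = c(50, 50, 50, 50, 0, 0))
  m <- count_matrix(counts, toy_samples(6))
  expect_setequal(detection_filter(m), c("kept_exact", "kept_rich"))
  set.seed(14)
  rm_counts <- matrix(rpois(200, 8), nrow = 20,
                      dimnames = list(sprintf("f%02d", 1:20), NULL))
  m2 <- count_matrix(rm_counts, toy_samples(10))
  brute <- rownames(rm_counts)[vapply(seq_len(20), function(i)
    sum(rm_counts[i, ] >= 10) >= 3, logical(1))]
  expect_setequal(detection_filter(m2), brute)
  # monotonicity: adding reads never removes a kept feature
  kept_before <- detection_filter(m2)
  m3 <- m2
  m3$counts <- m3$counts + 5L
  expect_true(all(kept_before %in% detection_filter(m3)))
})

test_that("antisense:total ratio follows its definition", {
  sm <- count_matrix(matrix(c(30, 30), nrow = 1,
                            dimnames = list("g1", NULL)), toy_samples(2))
  am <- count_matrix(matrix(c(20, 20), nrow = 1,
                            dimnames = list("c1", NULL)),
                     toy_samples(2), "antisense_contig")
  cmap <- data.frame(contig_id = "c1", gene_id = "g1")
  r <- antisense_total_ratio(sm, am, cmap)
  expect_equal(r$ratio, 0.4)  # 40 / (60 + 40)
  r0 <- antisense_total_ratio(sm, am, cmap[0, ])
  expect_equal(r0$ratio, 0)
  expect_error(antisense_total_ratio(sm, am, cmap, gene_ids = "nope"),
               "unknown gene")
})

test_that("designed ratios are recovered from NB counts", {
  cfg <- sim_config(seed = 1L, dispersion = 0.05)
  samples <- sim_samples(cfg)[1:12, ]
  design <- list(
    genes = data.table::data.table(gene_id = sprintf("g%02d", 1:20),
                                   baseline = 400, sense_slope = 0),
    contigs = data.table::data.table(
      contig_id = sprintf("c%02d", 1:20), gene_id = sprintf("g%02d", 1:20),
      type = "real", ratio = 0.38, anti_slope = 0, anti_mpfc_factor = 1,
      designed_class = "positive"))
  mats <- simulate_count_matrices(cfg, design, samples)
  libs <- library_sizes(mats$sense, mats$antisense)
  r <- antisense_total_ratio(normalize_library_size(mats$sense, libs),
                             normalize_library_size(mats$antisense, libs),
                             design$contigs)
  # the cohort-level estimate is tight; single genes wobble with the
  # NB dispersion (sd ~0.02 here), so allow the occasional 2-sigma gene
  expect_lt(abs(mean(r$ratio) - 0.38), 0.05)
  expect_true(all(abs(r$ratio - 0.38) < 0.1))
})

test_that("TSS matches hand evaluation and its symmetries", {
  expect_equal(tissue_specificity_score(10, 100, 10, 100), 0)
  expect_equal(tissue_specificity_score(20, 100, 0, 100), 200)
  set.seed(23)
  for (i in 1:50) {
    mo <- runif(1, 0, 50); mt <- mo + runif(1, 1, 100)
    so <- runif(1, 0, 50); st <- so + runif(1, 1, 100)
    tss <- tissue_specificity_score(mo, mt, so, st)
    # antisymmetry under tissue swap
    expect_equal(tissue_specificity_score(so, st, mo, mt), -tss)
    # invariance under common rescaling
    k <- runif(1, 0.1, 10)
    expect_equal(tissue_specificity_score(k * mo, k * mt, k * so, k * st),
                 tss)
    # sign equals the sign of the antisense-proportion difference
    expect_equal(sign(tss), sign(mo / mt - so / st))
  }
  # undefined cases
  expect_true(is.na(tissue_specificity_score(0, 100, 0, 100)))
  expect_true(is.na(tissue_specificity_score(5, 0, 5, 100)))
})

test_that("the per-gene TSS report aggregates tissues correctly", {
  counts_s <- matrix(c(80, 80, 100, 100), nrow = 1,
                     dimnames = list("g1", NULL))
  counts_a <- matrix(c(20, 20, 0, 0), nrow = 1,
                     dimnames = list("c1", NULL))
  samples <- data.frame(sample_id = sprintf("s%d", 1:4),
                        tissue = c("mPFC", "mPFC", "striatum", "striatum"),
                        age = c(7, 14, 7, 14), replicate = c(1, 2, 1, 2),
                        sex = "F")
  sm <- count_matrix(counts_s, samples)
  am <- count_matrix(counts_a, samples, "antisense_contig")
  tt <- tss_table(sm, am, data.frame(contig_id = "c1", gene_id = "g1"))
  expect_equal(tt$mPFC_OppReads, 40)
  expect_equal(tt$mPFC_Total, 200)
  expect_equal(tt$Str_Total, 200)
  expect_equal(tt$TSS, tissue_specificity_score(40, 200, 0, 200))
})
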