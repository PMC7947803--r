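test_that("SAM parsing honours flags, CIGAR arithmetic and NH tags", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6", "@SQ\tSN:chrT\tLN:50000",
    "r1\t16\tchrT\t101\t255\t50M\t*\t0\t0\t*\t*",
    "r2\t0\tchrT\t201\t255\t30M2D18M\t*\t0\t0\t*\t*\tNH:i:3",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",          # unmapped
    "r4\t256\tchrT\t301\t0\t20M\t*\t0\t0\t*\t*", # secondary
    "r5\t0\tchrT\t401\t255\tBADCIGAR\t*\t0\t0\t*\t*"), sam)
  expect_warning(recs <- parse_sam(sam), "1 record")
  expect_equal(recs$qname, c("r1", "r2"))
  expect_true(recs$is_reverse[1])
  expect_false(recs$is_reverse[2])
  expect_equal(recs$pos, c(100L, 200L))      # 0-based leftmost
  expect_equal(recs$aln_len, c(50L, 50L))    # 30M2D18M spans 50 ref bases
  expect_equal(recs$nh, c(NA_integer_, 3L))
  expect_error(parse_sam(withr::local_tempfile(fileext = ".sam")),
               "not found")
})

test_that("synthetic records round-trip through SAM text", {
  set.seed(5)
  n <- 100
  recs <- data.table::data.table(
    qname = sprintf("q%03d", 1:n),
    pos = sample.int(40000L, n),
    aln_len = sample(30:150, n, replace = TRUE),
    is_reverse = sample(c(TRUE, FALSE), n, replace = TRUE),
    is_read1 = rep(c(TRUE, FALSE), length.out = n),
    mapq = sample(0:255, n, replace = TRUE),
    nh = sample(1:4, n, replace = TRUE))
  recs$is_read2 <- !recs$is_read1
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_lines(recs, sam)
  back <- parse_sam(sam)
  for (col in c("qname", "pos", "aln_len", "is_reverse", "is_read1",
                "is_read2", "mapq", "nh"))
    expect_equal(back[[col]], recs[[col]], label = col)
})

test_that("fragment strand matches the enumerated protocol truth table", {
  # hand-enumerated: RF means read1 aligns antisense to the transcript
  truth <- data.frame(
    protocol = rep(c("RF", "FR"), each = 4),
    is_read1 = rep(c(TRUE, TRUE, FALSE, FALSE), 2),
    is_reverse = rep(c(FALSE, TRUE), 4),
    expected = c("-", "+", "+", "-",   # RF
                 "+", "-", "-", "+"))  # FR
  for (i in seq_len(nrow(truth)))
    expect_equal(
      fragment_strand(truth$is_reverse[i], truth$is_read1[i],
                      !truth$is_read1[i], protocol = truth$protocol[i]),
      truth$expected[i],
      label = paste(truth$protocol[i], "read1:", truth$is_read1[i],
                    "rev:", truth$is_reverse[i]))
  # single-end records behave as read1
  expect_equal(fragment_strand(FALSE, FALSE, FALSE, "RF"), "-")
})

test_that("unique mapping uses NH when present, MAPQ otherwise", {
  expect_true(is_uniquely_mapped(1L, 0L, 30L))
  expect_false(is_uniquely_mapped(2L, 255L, 30L))
  expect_false(is_uniquely_mapped(NA_integer_, 3L, 30L))
  expect_true(is_uniquely_mapped(NA_integer_, 30L, 30L))
})

test_that("single-record classification distinguishes zone membership", {
  annot <- genome_annotation(data.frame(
    gene_id = c("X", "Y"), seq_id = "chrT",
    start = c(101L, 401L), end = c(1000L, 600L), strand = c("+", "-")))
  gene <- gene_span(annot, "X")
  zone <- compute_overlap_free_zone(annot, "X")
  rec <- function(pos, rev, r1 = TRUE)
    list(seq_id = "chrT", pos = pos, aln_len = 50L, is_reverse = rev,
         is_read1 = r1, is_read2 = !r1)
  # antisense fragment ("-" strand = read1 forward under RF) in the zone
  expect_equal(classify_fragment(rec(150L, FALSE), gene, zone), "antisense")
  # same strand but inside the opposite-strand blocker: outside_zone
  expect_equal(classify_fragment(rec(450L, FALSE), gene, zone),
               "outside_zone")
  # sense fragment anywhere in the span
  expect_equal(classify_fragment(rec(450L, TRUE), gene, zone), "sense")
  # off the span entirely
  expect_equal(classify_fragment(rec(5000L, TRUE), gene, zone), "ambiguous")
})

test_that("classification is invariant under mate swap", {
  annot <- genome_annotation(data.frame(
    gene_id = "X", seq_id = "chrT", start = 101L, end = 1000L,
    strand = "+"))
  gene <- gene_span(annot, "X")
  zone <- compute_overlap_free_zone(annot, "X")
  set.seed(9)
  for (i in 1:50) {
    pos <- sample(50:1050, 1)
    rev <- sample(c(TRUE, FALSE), 1)
    # the mate aligns opposite, at the same locus
    m1 <- list(seq_id = "chrT", pos = pos, aln_len = 60L,
               is_reverse = rev, is_read1 = TRUE, is_read2 = FALSE)
    m2 <- list(seq_id = "chrT", pos = pos, aln_len = 60L,
               is_reverse = !rev, is_read1 = FALSE, is_read2 = TRUE)
    expect_equal(classify_fragment(m1, gene, zone),
                 classify_fragment(m2, gene, zone))
  }
})

test_that("counting deduplicates mates and handles empty input", {
  annot <- genome_annotation(data.frame(
    gene_id = "X", seq_id = "chrT", start = 101L, end = 1000L,
    strand = "+"))
  contigs <- list(contig_record("c1", "X", "chrT", "-", 201L, 400L))
  # two mates of one sense fragment, both on gene X
  recs <- data.table::data.table(
    qname = "f1", seq_id = "chrT", pos = c(150L, 300L),
    aln_len = 80L, is_reverse = c(FALSE, TRUE),
    is_read1 = c(FALSE, TRUE), is_read2 = c(TRUE, FALSE),
    mapq = 255L, nh = 1L)
  cts <- count_fragments(recs, annot, contigs)
  expect_equal(unname(cts$sense["X"]), 1L)
  expect_equal(unname(cts$antisense["c1"]), 0L)
  # empty stream
  cts0 <- count_fragments(recs[0], annot, contigs)
  expect_equal(sum(cts0$sense) + sum(cts0$antisense), 0L)
})

test_that("simulated counts are recovered exactly without misassignment", {
  cfg <- small_cfg(misassignment_rate = 0, multimap_rate = 0)
  sim <- simulate_annotation(cfg)
  csim <- simulate_contigs(sim, cfg)
  design <- simulate_design(cfg, sim$truth$gene_id, csim$contig_map)
  samples <- sim_samples(cfg)[1:2, ]
  frag <- simulate_fragments(sim, csim, design, cfg, samples)
  for (sid in samples$sample_id) {
    sam <- withr::local_tempfile(fileext = ".sam")
    writeLines(frag$sam[[sid]], sam)
    cts <- count_fragments(parse_sam(sam), sim$annot, csim$contigs,
                           csim$zones)
    tr <- frag$truth[sample_id == sid]
    truth_sense <- table(tr[orientation_true == "sense"]$gene_id)
    for (g in names(cts$sense))
      expect_equal(unname(cts$sense[g]),
                   if (g %in% names(truth_sense))
                     as.integer(truth_sense[[g]]) else 0L,
                   label = paste("sense", g))
    truth_anti <- table(tr[orientation_true == "antisense"]$contig_id)
    for (ct in names(cts$antisense))
      expect_equal(unname(cts$antisense[ct]),
                   if (ct %in% names(truth_anti))
                     as.integer(truth_anti[[ct]]) else 0L,
                   label = paste("antisense", ct))
  }
})
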