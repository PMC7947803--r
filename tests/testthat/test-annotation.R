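test_that("GTF loading takes the union extent of a gene's features", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_lines(data.frame(
    seq_id = "chrT", type = "exon", start = c(101L, 301L),
    end = c(200L, 400L), strand = "+", gene_id = "gA",
    transcript_id = "gA.t1"), gtf)
  annot <- load_annotation(gtf)
  sp <- gene_span(annot, "gA")
  expect_equal(BiocGenerics::start(sp), 101)
  expect_equal(BiocGenerics::end(sp), 400)
  expect_equal(as.character(BiocGenerics::strand(sp)), "+")
})

test_that("empty and malformed GTF inputs are handled", {
  empty <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_warning(annot <- load_annotation(empty), "empty")
  expect_equal(length(annot$genes), 0L)

  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("# comment", "chrT\tonly\tthree"), bad)
  expect_error(load_annotation(bad), "line 2")

  nostrand <- withr::local_tempfile(fileext = ".gtf")
  writeLines(
    'chrT\tt\texon\t10\t90\t.\t.\t.\tgene_id "gX"; transcript_id "gX.t";',
    nostrand)
  expect_error(load_annotation(nostrand), "gX")
})

test_that("random annotations round-trip through GTF", {
  set.seed(11)
  genes <- random_gene_table(50)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_lines(cbind(genes, type = "exon",
                        transcript_id = paste0(genes$gene_id, ".t")), gtf)
  annot <- load_annotation(gtf)
  expect_setequal(annot$genes$gene_id, genes$gene_id)
  got <- as.data.frame(annot$genes)
  got <- got[match(genes$gene_id, annot$genes$gene_id), ]
  expect_equal(got$start, genes$start)
  expect_equal(got$end, genes$end)
  expect_equal(as.character(got$strand), genes$strand)
})

test_that("overlap-free zone equals set subtraction of opposite strand", {
  annot <- genome_annotation(data.frame(
    gene_id = c("X", "Y"), seq_id = "chrT",
    start = c(101L, 401L), end = c(1000L, 600L),
    strand = c("+", "-")))
  z <- compute_overlap_free_zone(annot, "X")
  expect_equal(BiocGenerics::start(z), c(101, 601))
  expect_equal(BiocGenerics::end(z), c(400, 1000))
  # the blocker itself is fully covered by X on its opposite strand
  expect_length(compute_overlap_free_zone(annot, "Y"), 0L)
  # no opposite-strand overlap: zone is the whole span
  solo <- genome_annotation(data.frame(
    gene_id = c("X", "Z"), seq_id = "chrT",
    start = c(101L, 2000L), end = c(1000L, 2500L),
    strand = c("+", "+")))
  z2 <- compute_overlap_free_zone(solo, "X")
  expect_equal(zone_positions(z2), 101:1000)
  expect_error(compute_overlap_free_zone(solo, "nope"), "not in annotation")
})

test_that("zones match the per-base oracle and are idempotent", {
  set.seed(21)
  for (i in 1:25) {
    genes <- random_gene_table(sample(2:10, 1))
    annot <- genome_annotation(genes)
    zones <- overlap_free_zones(annot)
    for (g in genes$gene_id) {
      expect_identical(zone_positions(zones[[g]]),
                       oracle_zone_mask(genes, g))
    }
    # idempotence: subtracting the blockers from the zones again is a no-op
    for (g in genes$gene_id) {
      z <- zones[[g]]
      opp <- genes[genes$gene_id != g &
                     genes$strand != genes$strand[genes$gene_id == g], ]
      if (!nrow(opp) || !length(z)) next
      again <- IRanges::setdiff(IRanges::ranges(z),
                                IRanges::IRanges(opp$start, opp$end))
      expect_identical(as.data.frame(again),
                       as.data.frame(IRanges::reduce(IRanges::ranges(z))))
    }
    # zone length never exceeds span; equality iff no opposite overlap
    spans <- annot$genes
    for (g in genes$gene_id) {
      zl <- sum(BiocGenerics::width(zones[[g]]))
      sp <- spans[spans$gene_id == g]
      has_opp <- length(oracle_zone_mask(genes, g)) <
        BiocGenerics::width(sp)
      expect_lte(zl, BiocGenerics::width(sp))
      expect_identical(zl == BiocGenerics::width(sp), !has_opp)
    }
  }
})

test_that("interval index agrees with a linear scan", {
  set.seed(31)
  genes <- random_gene_table(10)
  annot <- genome_annotation(genes)
  for (i in 1:50) {
    qs <- sample.int(11000L, 1)
    qe <- qs + sample.int(3000L, 1)
    scan <- genes$gene_id[genes$start <= qe & genes$end >= qs]
    expect_setequal(query_genes(annot, "chrT", qs, qe), scan)
  }
})

test_that("blocker biotype restriction is honoured", {
  annot <- genome_annotation(data.frame(
    gene_id = c("X", "Y"), seq_id = "chrT",
    start = c(101L, 401L), end = c(1000L, 600L),
    strand = c("+", "-"), biotype = c("protein_coding", "lncRNA")))
  z_all <- compute_overlap_free_zone(annot, "X")
  expect_length(z_all, 2L)
  z_pc <- compute_overlap_free_zone(annot, "X",
                                    blocker_biotypes = "protein_coding")
  expect_equal(zone_positions(z_pc), 101:1000)
})

test_that("contig GTF writing and reloading preserves segments", {
  ct1 <- contig_record("c1", "gA", "chrT", "-",
                       seg_starts = c(11L, 71L), seg_ends = c(50L, 90L))
  ct2 <- contig_record("c2", "gB", "chrT", "+",
                       seg_starts = 200L, seg_ends = 380L)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_contig_gtf(list(ct1, ct2), gtf)
  lines <- readLines(gtf)
  exons <- grep("\texon\t", lines, value = TRUE)
  expect_length(exons, 3L)
  expect_match(exons[1], "\t11\t50\t\\.\t-")
  expect_match(exons[2], "\t71\t90\t\\.\t-")
  back <- read_contig_gtf(gtf)
  expect_equal(vapply(back, `[[`, character(1), "contig_id"), c("c1", "c2"))
  expect_equal(as.data.frame(back[[1]]$segments),
               as.data.frame(ct1$segments))
  expect_equal(back[[1]]$gene_id, "gA")
  expect_equal(back[[2]]$strand, "+")
})

test_that("segments outside the cognate gene span warn but are written", {
  annot <- genome_annotation(data.frame(
    gene_id = "gA", seq_id = "chrT", start = 100L, end = 200L,
    strand = "+"))
  ct <- contig_record("c1", "gA", "chrT", "-",
                      seg_starts = 150L, seg_ends = 400L)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  expect_warning(write_contig_gtf(list(ct), gtf, annot = annot),
                 "outside cognate gene span")
  expect_length(read_contig_gtf(gtf), 1L)
})
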