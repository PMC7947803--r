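make_blast_file <- function(rows, path) {
  write_blast_tab(rows, path)
  path
}

test_that("outfmt-6 parsing normalizes coordinates and finds qlen", {
  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "q1\ts1\t99.5\t480\t2\t0\t1\t480\t1000\t1479\t1e-100\t800\t480",
    # minus-strand hit: subject coordinates reversed
    "q2\ts1\t98.0\t100\t2\t0\t5\t104\t2000\t1901\t1e-50\t150\t200"), tab)
  hits <- parse_blast_tab(tab, "column")
  expect_equal(nrow(hits), 2L)
  expect_equal(hits[qid == "q1"]$qlen, 480L)
  h2 <- hits[qid == "q2"]
  expect_equal(h2$sstrand, "-")
  expect_lte(h2$sstart, h2$send)

  tab12 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t99.5\t480\t2\t0\t1\t480\t1000\t1479\t1e-100\t800",
             tab12)
  expect_error(parse_blast_tab(tab12, "column"), "only 12 columns")
})

test_that("query lengths can come from a FASTA", {
  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t99.5\t90\t0\t0\t1\t90\t100\t189\t1e-40\t150", tab)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">q1 some description", strrep("A", 120)), fa)
  hits <- parse_blast_tab(tab, "fasta", query_fasta = fa)
  expect_equal(hits$qlen, 120L)
  fa2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">other", "ACGT"), fa2)
  expect_error(parse_blast_tab(tab, "fasta", query_fasta = fa2), "q1")
})

test_that("query coverage uses interval union, not HSP sums", {
  h <- function(qs, qe, qlen = 100)
    data.frame(qstart = qs, qend = qe, qlen = qlen,
               pident = 99, length = qe - qs + 1)
  expect_equal(query_coverage(h(1, 95)), 95)
  expect_equal(query_coverage(h(c(1, 40), c(50, 100))), 100)
  expect_equal(query_coverage(h(c(1, 61), c(30, 90))), 60)
  expect_equal(query_coverage(NULL), 0)
})

test_that("coverage equals the per-position mask oracle on random HSPs", {
  set.seed(77)
  for (i in 1:100) {
    hits <- random_hsp_set()
    expect_equal(query_coverage(hits), oracle_coverage(hits))
  }
})

test_that("weighted identity is the length-weighted mean", {
  h <- data.frame(pident = c(100, 98), length = c(100, 100))
  expect_equal(weighted_identity(h), 99)
  expect_equal(weighted_identity(data.frame(pident = 99.2, length = 10)),
               99.2)
  empty <- weighted_identity(NULL)
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "empty"))
  set.seed(78)
  for (i in 1:20) {
    hits <- random_hsp_set()
    expect_equal(weighted_identity(hits),
                 sum(hits$pident * hits$length) / sum(hits$length))
  }
})

test_that("self-validation thresholds are inclusive", {
  cts <- list(
    contig_record("pass_exact", "g1", "chrT", "-", 1L, 480L, length = 100),
    contig_record("fail_ident", "g2", "chrT", "-", 1L, 480L, length = 100),
    contig_record("no_hits", "g3", "chrT", "-", 1L, 480L, length = 100))
  hits <- data.table::rbindlist(list(
    # identity 99.0 and coverage 95.0 exactly: kept (inclusive)
    data.table::data.table(qid = "pass_exact", sid = "chr1", pident = 99.0,
                           length = 95L, qstart = 1L, qend = 95L,
                           sstart = 1L, send = 95L, sstrand = "+",
                           evalue = 0, bitscore = 100, qlen = 100L),
    # identity 98.9, full coverage: removed
    data.table::data.table(qid = "fail_ident", sid = "chr1", pident = 98.9,
                           length = 100L, qstart = 1L, qend = 100L,
                           sstart = 1L, send = 100L, sstrand = "+",
                           evalue = 0, bitscore = 100, qlen = 100L)))
  sv <- self_validate(cts, hits)
  expect_equal(sv$kept, c(TRUE, FALSE, FALSE))
  expect_equal(sv$reason, c("", "low_identity", "no_hits"))
  # fixed point: re-filtering the kept set removes nothing
  kept <- cts[sv$kept]
  sv2 <- self_validate(kept, hits)
  expect_true(all(sv2$kept))
})

test_that("lncRNA mapping requires strictly more than 95% coverage", {
  cts <- list(contig_record("c1", "g1", "chrT", "-", 1L, 100L,
                            length = 100))
  mk <- function(qend) data.table::data.table(
    qid = "c1", sid = "lncA", pident = 99.5, length = qend,
    qstart = 1L, qend = qend, sstart = 1L, send = qend, sstrand = "+",
    evalue = 0, bitscore = 100, qlen = 100L)
  expect_equal(nrow(map_known_lncrna(cts, mk(95L))), 0L)  # exactly 95.0
  m <- map_known_lncrna(cts, mk(96L))
  expect_equal(m$lncrna_id, "lncA")
})

test_that("the 3% low-pass filter uses a strict inequality", {
  expect_false(spurious_filter(30, 970))   # 0.03 exactly
  expect_true(spurious_filter(31, 969))    # 0.031
  expect_false(spurious_filter(0, 0))      # zero denominator
  expect_false(spurious_filter(0, 100))
  expect_error(spurious_filter(-1, 10), "nonnegative")
  # idempotence: filtering the kept set again removes nothing
  a <- c(50, 31, 10, 3)
  s <- c(500, 969, 990, 997)
  keep <- spurious_filter(a, s)
  expect_identical(spurious_filter(a[keep], s[keep]), rep(TRUE, sum(keep)))
})

test_that("planted validation outcomes are recovered exactly", {
  cfg <- small_cfg(seed = 3L)
  sim <- simulate_annotation(cfg)
  csim <- simulate_contigs(sim, cfg)
  ids <- csim$contig_map$contig_id
  planted <- ids[seq_along(ids) %% 2L == 0L]
  hits <- simulate_blast_hits(csim$contigs, cfg, planted_valid = planted,
                              planted_conserved = character(0))
  sv <- self_validate(csim$contigs, hits$self)
  expect_setequal(sv$contig_id[sv$kept], planted)
})
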