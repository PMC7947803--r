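# shared fixture builders; everything is generated in code at test time

# small, fast simulation configuration for module tests
small_cfg <- function(seed = 42L, ...) {
  sim_config(seed = seed, n_genes = 10L, baseline_mean = 40,
             replicates = c(1L, 2L, 2L), ...)
}

# random gene table on one sequence, arbitrary overlaps allowed
random_gene_table <- function(n_genes, max_coord = 10000L) {
  starts <- sample.int(max_coord - 400L, n_genes, replace = TRUE)
  widths <- sample(100:2000, n_genes, replace = TRUE)
  data.frame(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    seq_id = "chrT",
    start = starts,
    end = pmin(starts + widths, max_coord),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    biotype = sample(c("protein_coding", "lncRNA"), n_genes,
                     replace = TRUE),
    stringsAsFactors = FALSE)
}

# per-base oracle for the overlap-free zone: a base is kept iff it lies
# inside the gene span and inside no OTHER opposite-strand gene span
oracle_zone_mask <- function(genes, gene_id, max_coord = 12000L) {
  g <- genes[genes$gene_id == gene_id, ]
  mask <- logical(max_coord)
  mask[g$start:g$end] <- TRUE
  opp <- genes[genes$gene_id != gene_id & genes$strand != g$strand, ]
  for (i in seq_len(nrow(opp))) mask[opp$start[i]:opp$end[i]] <- FALSE
  which(mask)
}

# zone GRanges -> covered base positions
zone_positions <- function(zone) {
  if (!length(zone)) return(integer(0))
  sort(unlist(Map(seq.int, BiocGenerics::start(zone),
                  BiocGenerics::end(zone))))
}

# independent GTF writer (deliberately not write_annotation_gtf): one
# exon feature line per row of `feats`
write_gtf_lines <- function(feats, path) {
  writeLines(sprintf(
    '%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    feats$seq_id, feats$type, feats$start, feats$end, feats$strand,
    feats$gene_id, feats$transcript_id), path)
}

# independent SAM writer for round-trip tests
write_sam_lines <- function(recs, path, seq_id = "chrT", seq_len = 50000L) {
  flag <- 1L +
    ifelse(recs$is_reverse, 16L, 0L) +
    ifelse(recs$is_read1, 64L, 0L) +
    ifelse(recs$is_read2, 128L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t0\t*\t*\tNH:i:%d",
                   recs$qname, flag, seq_id, recs$pos + 1L, recs$mapq,
                   recs$aln_len, recs$pos + 1L, recs$nh)
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", seq_id, seq_len), lines), path)
}

# random HSP table for one query in parse_blast_tab layout
random_hsp_set <- function(qid = "q1", qlen = NULL, n = NULL) {
  if (is.null(qlen)) qlen <- sample(50:500, 1)
  if (is.null(n)) n <- sample(1:6, 1)
  qs <- sample.int(qlen, n, replace = TRUE)
  qe <- pmin(qs + sample.int(200, n, replace = TRUE), qlen)
  data.table::data.table(
    qid = qid, sid = "s1", pident = round(runif(n, 80, 100), 2),
    length = qe - qs + 1L, qstart = qs, qend = qe,
    sstart = qs, send = qe, sstrand = "+",
    evalue = 1e-10, bitscore = 100, qlen = qlen)
}

# per-position coverage oracle
oracle_coverage <- function(hits) {
  if (!nrow(hits)) return(0)
  mask <- logical(hits$qlen[1])
  for (i in seq_len(nrow(hits))) mask[hits$qstart[i]:hits$qend[i]] <- TRUE
  100 * sum(mask) / hits$qlen[1]
}

# minimal pipeline config for a directory written by simulate_dataset
sim_pipeline_config <- function(dir, out_dir) {
  pipeline_config(paths = list(
    annotation = file.path(dir, "annotation.gtf"),
    contigs = file.path(dir, "contigs.gtf"),
    sample_sheet = file.path(dir, "sample_sheet.tsv"),
    self_blast = file.path(dir, "self_blast.tsv"),
    human_blast = file.path(dir, "human_blast.tsv"),
    lncrna_blast = file.path(dir, "lncrna_blast.tsv"),
    gene_list = file.path(dir, "gene_list.txt"),
    out_dir = out_dir))
}
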