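#' Load a gene annotation from GTF
#'
#' Reads a GTF file (tab-separated, 1-based closed coordinates) and builds a
#' strand-aware gene-level annotation.  Each gene's span is the union extent
#' (minimum start to maximum end) of all of its annotated features, so UTRs
#' annotated as separate features are automatically included.  All raw
#' features are retained alongside the gene spans so transcript/exon
#' structure written by [write_contig_gtf()] round-trips.
#'
#' Genes whose features carry no usable strand (anything other than
#' \code{+} or \code{-}) are rejected with an error naming the gene, and
#' structurally malformed lines (fewer than 9 tab-separated fields) raise a
#' parse error naming the line number.  An empty file yields an empty
#' annotation with a warning.
#'
#' @param gtf_path path to a GTF file.
#' @return a \code{genome_annotation}: a list with elements
#'   \describe{
#'     \item{genes}{a [GenomicRanges::GRanges] of UTR-inclusive gene spans,
#'       named by \code{gene_id}, with metadata columns \code{gene_id} and
#'       \code{biotype}.}
#'     \item{features}{a \code{GRanges} of all imported features with their
#'       \code{type}, \code{gene_id} and \code{transcript_id}.}
#'   }
#' @seealso [compute_overlap_free_zone()], [write_contig_gtf()]
#' @export
load_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) ns_stop("annotation file not found: %s", gtf_path)
  raw <- readLines(gtf_path, warn = FALSE)
  body_idx <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(body_idx)) {
    ns_warn("empty GTF file: %s", gtf_path)
    return(empty_annotation())
  }
  nfields <- lengths(strsplit(raw[body_idx], "\t", fixed = TRUE))
  bad <- body_idx[nfields < 9]
  if (length(bad))
    ns_stop("malformed GTF line %d in %s: expected 9 tab-separated fields",
            bad[1], gtf_path)

  feats <- rtracklayer::import(gtf_path, format = "gtf")
  if (!length(feats)) {
    ns_warn("GTF file contains no features: %s", gtf_path)
    return(empty_annotation())
  }
  if (is.null(feats$gene_id) || anyNA(feats$gene_id))
    ns_stop("GTF features without a gene_id attribute in %s", gtf_path)
  bad_strand <- as.character(BiocGenerics::strand(feats)) %in% c("+", "-")
  if (!all(bad_strand))
    ns_stop("gene(s) with unknown strand rejected: %s",
            paste(unique(feats$gene_id[!bad_strand]), collapse = ", "))
  build_annotation(feats)
}

#' Build a genome annotation from a gene table
#'
#' In-memory constructor equivalent to loading a GTF with one feature per
#' gene: useful for simulations and tests.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{seq_id},
#'   \code{start}, \code{end} (1-based closed), \code{strand} and
#'   optionally \code{biotype}.
#' @return a \code{genome_annotation}.
#' @export
genome_annotation <- function(genes) {
  genes <- as.data.frame(genes)
  if (!nrow(genes)) return(empty_annotation())
  if (!all(genes$strand %in% c("+", "-")))
    ns_stop("gene(s) with unknown strand rejected: %s",
            paste(genes$gene_id[!genes$strand %in% c("+", "-")],
                  collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    ns_stop("duplicate gene_id: %s",
            genes$gene_id[duplicated(genes$gene_id)][1])
  if (is.unsorted(genes$gene_id)) genes <- genes[order(genes$gene_id), ]
  bt <- if ("biotype" %in% names(genes)) genes$biotype else "unknown"
  # one GRanges serves as both feature table and span index (the span of
  # a single-feature gene is the feature)
  spans <- GenomicRanges::GRanges(
    genes$seq_id, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, gene_id = genes$gene_id, biotype = bt)
  names(spans) <- genes$gene_id
  structure(list(genes = spans, features = spans),
            class = "genome_annotation")
}

empty_annotation <- function() {
  g <- GenomicRanges::GRanges()
  g$gene_id <- character(0)
  g$biotype <- character(0)
  structure(list(genes = g, features = GenomicRanges::GRanges()),
            class = "genome_annotation")
}

# gene spans = union extent of each gene's features (UTR-inclusive).
# Aggregation is done on plain vectors: annotations are rebuilt in tight
# simulation loops, where per-gene S4 splitting dominates runtime.
build_annotation <- function(feats) {
  if (is.null(feats$transcript_id)) feats$transcript_id <- NA_character_
  gid <- as.character(feats$gene_id)
  if (!anyDuplicated(gid)) {
    # one feature per gene: the spans ARE the features
    o <- order(gid)
    spans <- feats[o]
    bt <- spans$gene_biotype
    S4Vectors::mcols(spans) <- S4Vectors::DataFrame(
      gene_id = gid[o],
      biotype = if (is.null(bt)) "unknown" else
        ifelse(is.na(bt), "unknown", as.character(bt)))
    names(spans) <- gid[o]
    return(structure(list(genes = spans, features = feats),
                     class = "genome_annotation"))
  }
  ids <- sort(unique(gid))
  f <- factor(gid, levels = ids)
  seqn <- as.character(GenomeInfoDb::seqnames(feats))
  str <- as.character(BiocGenerics::strand(feats))
  loc_key <- paste(seqn, str)
  uk <- unique(data.frame(gid = gid, key = loc_key))
  multi <- unique(uk$gid[duplicated(uk$gid)])
  if (length(multi))
    ns_stop("gene(s) with features on multiple sequences or strands: %s",
            paste(multi, collapse = ", "))
  first <- match(ids, gid)
  span_start <- vapply(split(BiocGenerics::start(feats), f), min,
                       numeric(1))
  span_end <- vapply(split(BiocGenerics::end(feats), f), max, numeric(1))
  bt <- feats$gene_biotype
  biotype <- if (is.null(bt)) rep("unknown", length(ids)) else {
    b <- as.character(bt)[first]
    ifelse(is.na(b), "unknown", b)
  }
  spans <- GenomicRanges::GRanges(
    seqn[first], IRanges::IRanges(unname(span_start), unname(span_end)),
    strand = str[first], gene_id = ids, biotype = biotype)
  names(spans) <- ids
  structure(list(genes = spans, features = feats),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d sequence(s)\n",
              length(x$genes),
              length(GenomeInfoDb::seqlevelsInUse(x$genes))))
  invisible(x)
}

#' Look up genes whose spans intersect an interval
#'
#' Interval-index query backed by [GenomicRanges::findOverlaps()];
#' equivalent to (and tested against) a linear scan over all gene spans.
#'
#' @param annot a \code{genome_annotation}.
#' @param seq_id sequence name.
#' @param start,end 1-based closed query interval.
#' @return character vector of gene ids.
#' @export
query_genes <- function(annot, seq_id, start, end) {
  q <- GenomicRanges::GRanges(seq_id, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, annot$genes, ignore.strand = TRUE)
  annot$genes$gene_id[S4Vectors::subjectHits(hits)]
}

#' Gene span accessor
#'
#' @param annot a \code{genome_annotation}.
#' @param gene_id gene identifier.
#' @return a length-1 \code{GRanges} with the UTR-inclusive span.
#' @export
gene_span <- function(annot, gene_id) {
  i <- match(gene_id, annot$genes$gene_id)
  if (is.na(i)) ns_stop("gene not in annotation: %s", gene_id)
  annot$genes[i]
}

#' Compute a gene's overlap-free zone
#'
#' The overlap-free zone of a gene is the part of its UTR-inclusive span not
#' covered by any \emph{other} annotated gene on the \emph{opposite} strand.
#' Only antisense fragments falling in this zone are unambiguously
#' attributable to antisense transcription of the gene rather than to sense
#' transcription of an overlapping opposite-strand feature, so downstream
#' antisense read extraction is restricted to it.  Same-strand overlaps do
#' not shrink the zone; ambiguity between same-strand genes is resolved at
#' the read level by unique mapping instead.
#'
#' @param annot a \code{genome_annotation}.
#' @param gene_id gene whose zone to compute (must be in \code{annot}).
#' @param blocker_biotypes optional character vector; when given, only
#'   opposite-strand genes of these biotypes are subtracted.  Default
#'   \code{NULL} treats every annotated gene as real strand occupancy.
#' @param min_zone_length drop zone pieces shorter than this many bp
#'   (default 1, i.e. keep all).
#' @return a \code{GRanges} of disjoint, sorted intervals within the gene
#'   span (possibly empty) carrying the gene's strand.
#' @export
compute_overlap_free_zone <- function(annot, gene_id,
                                      blocker_biotypes = NULL,
                                      min_zone_length = 1L) {
  span <- gene_span(annot, gene_id)
  g <- annot$genes
  opp <- g[g$gene_id != gene_id &
             as.character(BiocGenerics::strand(g)) !=
               as.character(BiocGenerics::strand(span))]
  if (!is.null(blocker_biotypes))
    opp <- opp[opp$biotype %in% blocker_biotypes]
  opp <- opp[GenomicRanges::countOverlaps(opp, span, ignore.strand = TRUE) > 0]
  zones <- GenomicRanges::setdiff(unstrand_keep(span), unstrand_keep(opp))
  zones <- zones[BiocGenerics::width(zones) >= min_zone_length]
  if (length(zones)) {
    BiocGenerics::strand(zones) <- BiocGenerics::strand(span)
    zones$gene_id <- gene_id
  } else {
    zones$gene_id <- character(0)
  }
  sort(zones)
}

# drop strand but keep seqlevels aligned for set operations
unstrand_keep <- function(gr) {
  BiocGenerics::strand(gr) <- "*"
  gr
}

#' Overlap-free zones for every gene
#'
#' Vectorized equivalent of calling [compute_overlap_free_zone()] per
#' gene (and tested to agree with it).
#'
#' @inheritParams compute_overlap_free_zone
#' @return a named [GenomicRanges::GRangesList], one element per gene.
#' @export
overlap_free_zones <- function(annot, blocker_biotypes = NULL,
                               min_zone_length = 1L) {
  g <- annot$genes
  n <- length(g)
  ids <- g$gene_id
  if (!n) return(GenomicRanges::GRangesList())
  zt <- zone_core(annot, blocker_biotypes, min_zone_length)
  str <- as.character(BiocGenerics::strand(g))
  ul <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(g))[zt$gene_idx],
    IRanges::IRanges(zt$start, zt$end), strand = str[zt$gene_idx],
    gene_id = ids[zt$gene_idx], seqinfo = GenomeInfoDb::seqinfo(g))
  part <- IRanges::PartitioningByEnd(
    cumsum(tabulate(zt$gene_idx, nbins = n)), names = ids)
  IRanges::relist(ul, part)
}

#' Overlap-free zones as a plain table
#'
#' Same computation as [overlap_free_zones()], returned as a data.frame —
#' the form the pipeline's zone report uses, and a cheap entry point for
#' verifying zone geometry on many small annotations.
#'
#' @inheritParams compute_overlap_free_zone
#' @return data.frame with columns \code{gene_id}, \code{seq_id},
#'   \code{start}, \code{end}, \code{strand}; zero rows for genes whose
#'   zone is empty.
#' @export
overlap_free_zone_table <- function(annot, blocker_biotypes = NULL,
                                    min_zone_length = 1L) {
  g <- annot$genes
  if (!length(g))
    return(data.frame(gene_id = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  zt <- zone_core(annot, blocker_biotypes, min_zone_length)
  data.frame(
    gene_id = g$gene_id[zt$gene_idx],
    seq_id = as.character(GenomeInfoDb::seqnames(g))[zt$gene_idx],
    start = zt$start, end = zt$end,
    strand = as.character(BiocGenerics::strand(g))[zt$gene_idx],
    stringsAsFactors = FALSE)
}

# zone computation on plain integer vectors: subtract the merged union
# of opposite-strand blocker spans from each gene span.  S4 per-gene set
# operations dominate runtime in simulation loops, so the interval sweep
# is done in base R; compute_overlap_free_zone() is the independent
# per-gene reference implementation the result is tested against.
zone_core <- function(annot, blocker_biotypes = NULL,
                      min_zone_length = 1L) {
  g <- annot$genes
  n <- length(g)
  gs <- BiocGenerics::start(g)
  ge <- BiocGenerics::end(g)
  str <- as.character(BiocGenerics::strand(g))
  seqn <- as.character(GenomeInfoDb::seqnames(g))
  allowed <- if (is.null(blocker_biotypes)) rep(TRUE, n)
             else g$biotype %in% blocker_biotypes
  # candidate blocker pairs (qh = gene, sh = opposite-strand overlapper)
  if (n <= 400L) {
    qh <- rep(seq_len(n), each = n)
    sh <- rep.int(seq_len(n), n)
    keep <- qh != sh & seqn[qh] == seqn[sh] & str[qh] != str[sh] &
      gs[sh] <= ge[qh] & ge[sh] >= gs[qh] & allowed[sh]
    qh <- qh[keep]
    sh <- sh[keep]
  } else {
    ov <- GenomicRanges::findOverlaps(g, g, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    keep <- qh != sh & str[qh] != str[sh] & allowed[sh]
    qh <- qh[keep]
    sh <- sh[keep]
  }
  zone_s <- as.list(gs)
  zone_e <- as.list(ge)
  if (length(qh)) {
    bs0 <- pmax(gs[sh], gs[qh])
    be0 <- pmin(ge[sh], ge[qh])
    o <- order(qh, bs0)
    qh <- qh[o]
    bs <- bs0[o]
    be <- be0[o]
    for (gi in unique(qh)) {
      sel <- qh == gi
      s <- bs[sel]
      e <- be[sel]
      # merge overlapping/adjacent blocker intervals
      cme <- cummax(e)
      new_blk <- c(TRUE, s[-1L] > cme[-length(s)] + 1L)
      grp <- cumsum(new_blk)
      ms <- s[new_blk]
      me <- as.vector(tapply(e, grp, max))
      # complement within the span
      zs <- c(gs[gi], me + 1L)
      ze <- c(ms - 1L, ge[gi])
      ok <- zs <= ze
      zone_s[[gi]] <- zs[ok]
      zone_e[[gi]] <- ze[ok]
    }
  }
  counts <- lengths(zone_s)
  all_s <- unlist(zone_s, use.names = FALSE)
  all_e <- unlist(zone_e, use.names = FALSE)
  gene_idx <- rep(seq_len(n), counts)
  ok <- (all_e - all_s + 1) >= min_zone_length
  list(gene_idx = gene_idx[ok], start = as.integer(all_s[ok]),
       end = as.integer(all_e[ok]))
}

#' Construct a de novo antisense contig record
#'
#' A contig is an assembled antisense transcript fragment mapped inside a
#' cognate gene; discontinuously mapped pieces are kept as separate
#' exon-like segments.  The contig lies on the strand opposite its cognate
#' gene.
#'
#' @param contig_id contig identifier.
#' @param gene_id cognate (sense) gene identifier.
#' @param seq_id sequence name.
#' @param strand contig strand, \code{"+"} or \code{"-"}.
#' @param seg_starts,seg_ends parallel vectors of 1-based closed genomic
#'   segment coordinates.
#' @param length contig length in bp; defaults to the summed segment
#'   widths.
#' @param antisense_reads summed unique antisense read count (default 0).
#' @param known_lncrna_ids character vector of known lncRNAs this contig
#'   maps to (default none).
#' @return an object of class \code{contig_record}.
#' @export
contig_record <- function(contig_id, gene_id, seq_id, strand,
                          seg_starts, seg_ends,
                          length = NULL, antisense_reads = 0,
                          known_lncrna_ids = character(0)) {
  if (length(seg_starts) != length(seg_ends) || !length(seg_starts))
    ns_stop("contig %s: need >= 1 segment with matching starts/ends",
            contig_id)
  if (any(seg_ends < seg_starts))
    ns_stop("contig %s: segment end before start", contig_id)
  if (!strand %in% c("+", "-"))
    ns_stop("contig %s: strand must be + or -", contig_id)
  o <- order(seg_starts)
  segs <- IRanges::IRanges(seg_starts[o], seg_ends[o])
  len <- if (is.null(length)) sum(IRanges::width(segs)) else length
  if (len <= 0) ns_stop("contig %s: length must be > 0", contig_id)
  if (antisense_reads < 0)
    ns_stop("contig %s: antisense_reads must be >= 0", contig_id)
  structure(list(contig_id = contig_id, gene_id = gene_id, seq_id = seq_id,
                 strand = strand, segments = segs, length = len,
                 antisense_reads = antisense_reads,
                 known_lncrna_ids = known_lncrna_ids),
            class = "contig_record")
}

#' @export
print.contig_record <- function(x, ...) {
  cat(sprintf("contig %s (%s%s) on gene %s: %d segment(s), %d bp\n",
              x$contig_id, x$seq_id, x$strand, x$gene_id,
              length(x$segments), x$length))
  invisible(x)
}

# contig segments as a GRanges (one range per segment, mcols contig_id,
# gene_id), used by fragment-to-contig assignment
contig_segment_granges <- function(contigs) {
  if (!length(contigs)) return(GenomicRanges::GRanges())
  grl <- lapply(contigs, function(ct) {
    gr <- GenomicRanges::GRanges(ct$seq_id, ct$segments, strand = ct$strand)
    gr$contig_id <- ct$contig_id
    gr$gene_id <- ct$gene_id
    gr
  })
  do.call(c, grl)
}

#' Write antisense contigs as GTF
#'
#' Each contig is emitted as one \code{transcript} feature plus one
#' \code{exon} feature per mapped segment, on the contig's own strand
#' (opposite to its cognate gene).  The output is re-loadable with
#' [load_annotation()], which reconstructs the segment sets exactly.
#' Segments lying outside the cognate gene span raise a warning but are
#' still written.
#'
#' @param contigs list of [contig_record()] objects.
#' @param out_path output GTF path.
#' @param annot optional \code{genome_annotation} used to check that
#'   segments fall within their cognate gene spans.
#' @return the output path, invisibly.
#' @export
write_contig_gtf <- function(contigs, out_path, annot = NULL) {
  lines <- character(0)
  for (ct in contigs) {
    if (!is.null(annot) && ct$gene_id %in% annot$genes$gene_id) {
      sp <- gene_span(annot, ct$gene_id)
      outside <- IRanges::start(ct$segments) < BiocGenerics::start(sp) |
        IRanges::end(ct$segments) > BiocGenerics::end(sp)
      if (any(outside))
        ns_warn("contig %s: %d segment(s) outside cognate gene span of %s",
                ct$contig_id, sum(outside), ct$gene_id)
    }
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; cognate_gene_id "%s";',
      ct$contig_id, ct$contig_id, ct$gene_id)
    tx <- sprintf("%s\tnatscan\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                  ct$seq_id, min(IRanges::start(ct$segments)),
                  max(IRanges::end(ct$segments)), ct$strand, attrs)
    ex <- sprintf("%s\tnatscan\texon\t%d\t%d\t.\t%s\t.\t%s",
                  ct$seq_id, IRanges::start(ct$segments),
                  IRanges::end(ct$segments), ct$strand, attrs)
    lines <- c(lines, tx, ex)
  }
  writeLines(lines, out_path)
  invisible(out_path)
}
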