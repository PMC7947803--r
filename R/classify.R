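#' Classify one alignment record against one gene
#'
#' A fragment is \emph{sense} to a gene when its inferred strand equals the
#' gene strand and its aligned interval intersects the gene span;
#' \emph{antisense} when its strand is opposite and it intersects the
#' gene's overlap-free zone; \emph{outside_zone} when it is opposite-strand
#' and inside the span but misses the zone (i.e. it lies over an
#' opposite-strand blocker and cannot be attributed unambiguously); and
#' \emph{ambiguous} otherwise.
#'
#' @param rec a single alignment record: list or one-row data.frame with
#'   \code{seq_id}, \code{pos} (0-based), \code{aln_len}, \code{is_reverse},
#'   \code{is_read1}, \code{is_read2}.
#' @param gene a length-1 \code{GRanges} gene span (see [gene_span()]).
#' @param zone the gene's overlap-free zone \code{GRanges}
#'   (see [compute_overlap_free_zone()]).
#' @param protocol strandedness protocol, \code{"RF"} (default) or
#'   \code{"FR"}.
#' @return one of \code{"sense"}, \code{"antisense"}, \code{"outside_zone"},
#'   \code{"ambiguous"}.
#' @export
classify_fragment <- function(rec, gene, zone, protocol = "RF") {
  if (rec$seq_id != as.character(GenomeInfoDb::seqnames(gene)))
    return("ambiguous")
  fs <- fragment_strand(rec$is_reverse, rec$is_read1, rec$is_read2,
                        protocol = protocol)
  frag <- IRanges::IRanges(rec$pos + 1L, rec$pos + rec$aln_len)
  in_span <- IRanges::overlapsAny(frag, IRanges::ranges(gene))
  gstrand <- as.character(BiocGenerics::strand(gene))
  if (fs == gstrand) {
    if (in_span) return("sense") else return("ambiguous")
  }
  in_zone <- length(zone) > 0 &&
    IRanges::overlapsAny(frag, IRanges::ranges(zone))
  if (in_zone) return("antisense")
  if (in_span) return("outside_zone")
  "ambiguous"
}

# fragment GRanges from a record table (1-based closed intervals)
records_granges <- function(records) {
  GenomicRanges::GRanges(
    records$seq_id,
    IRanges::IRanges(records$pos + 1L, records$pos + records$aln_len))
}

#' Fragment-level sense/antisense assignments for one sample
#'
#' Classifies every mapped primary record against every gene whose span it
#' intersects, then aggregates mates to fragment level by \code{qname}:
#' within a (fragment, gene) pair, sense or antisense from either mate wins
#' over \code{outside_zone}, which wins over \code{ambiguous}.  A fragment
#' is flagged unique when all of its records are uniquely mapped
#' (see [is_uniquely_mapped()]).
#'
#' @param records record table from [parse_sam()].
#' @param annot a \code{genome_annotation}.
#' @param zones overlap-free zones from [overlap_free_zones()]; computed
#'   when \code{NULL}.
#' @param protocol strandedness protocol (default \code{"RF"}).
#' @param min_mapq MAPQ fallback threshold for unique mapping.
#' @return a \code{data.table} with one row per (fragment, gene):
#'   \code{qname}, \code{gene_id}, \code{orientation}, \code{unique}.
#' @export
fragment_assignments <- function(records, annot, zones = NULL,
                                 protocol = "RF", min_mapq = 30L) {
  if (is.null(zones)) zones <- overlap_free_zones(annot)
  empty <- data.table::data.table(qname = character(0),
                                  gene_id = character(0),
                                  orientation = character(0),
                                  unique = logical(0))
  if (!nrow(records)) return(empty)
  frag_gr <- records_granges(records)
  ov <- GenomicRanges::findOverlaps(frag_gr, annot$genes,
                                    ignore.strand = TRUE)
  if (!length(ov)) return(empty)

  ri <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  fs <- fragment_strand(records$is_reverse, records$is_read1,
                        records$is_read2, protocol = protocol)
  uniq <- is_uniquely_mapped(records$nh, records$mapq, min_mapq)
  pairs <- data.table::data.table(
    rec = ri,
    qname = records$qname[ri],
    gene_id = annot$genes$gene_id[gi],
    gstrand = as.character(BiocGenerics::strand(annot$genes))[gi],
    fs = fs[ri],
    unique = uniq[ri])

  zone_gr <- unlist(zones, use.names = FALSE)
  in_zone_key <- character(0)
  if (length(zone_gr)) {
    zov <- GenomicRanges::findOverlaps(frag_gr, zone_gr,
                                       ignore.strand = TRUE)
    in_zone_key <- unique(paste(S4Vectors::queryHits(zov),
                                zone_gr$gene_id[S4Vectors::subjectHits(zov)]))
  }
  pairs[, in_zone := paste(rec, gene_id) %in% in_zone_key]
  pairs[, orientation := data.table::fifelse(
    fs == gstrand, "sense",
    data.table::fifelse(in_zone, "antisense", "outside_zone"))]

  # aggregate mates: sense/antisense beat outside_zone beat ambiguous
  o_rank <- c(sense = 1L, antisense = 1L, outside_zone = 2L, ambiguous = 3L)
  pairs[, r := o_rank[orientation]]
  out <- pairs[, .(orientation = orientation[which.min(r)],
                   unique = all(unique)),
               by = .(qname, gene_id)]
  out[]
}

#' Count unique fragments per gene (sense) and per contig (antisense)
#'
#' Only uniquely mapped fragments contribute; a fragment counts once per
#' feature (mates deduplicated by \code{qname}).  An antisense fragment is
#' assigned to a contig iff it is antisense to the contig's cognate gene
#' and at least one of its records intersects one of the contig's mapped
#' segments.  A fragment matching several contigs of one gene counts for
#' each of them (contigs are alternative assemblies, not a partition); it
#' never counts for more than one gene per contig.
#'
#' @param records record table from [parse_sam()].
#' @param annot a \code{genome_annotation}.
#' @param contigs list of [contig_record()] objects.
#' @param zones optional precomputed [overlap_free_zones()].
#' @param protocol,min_mapq see [fragment_assignments()].
#' @return list with \code{sense} (named integer vector over all genes),
#'   \code{antisense} (named integer vector over all contigs) and
#'   \code{assignments} (the fragment-level table).
#' @export
count_fragments <- function(records, annot, contigs, zones = NULL,
                            protocol = "RF", min_mapq = 30L) {
  if (is.null(zones)) zones <- overlap_free_zones(annot)
  asn <- fragment_assignments(records, annot, zones, protocol, min_mapq)
  gene_ids <- annot$genes$gene_id
  contig_ids <- vapply(contigs, `[[`, character(1), "contig_id")

  sense <- setNames(integer(length(gene_ids)), gene_ids)
  s <- asn[orientation == "sense" & unique == TRUE,
           .N, by = gene_id]
  sense[s$gene_id] <- s$N

  antisense <- setNames(integer(length(contig_ids)), contig_ids)
  anti <- asn[orientation == "antisense" & unique == TRUE]
  if (nrow(anti) && length(contigs)) {
    seg_gr <- contig_segment_granges(contigs)
    frag_gr <- records_granges(records)
    sov <- GenomicRanges::findOverlaps(frag_gr, seg_gr,
                                       ignore.strand = TRUE)
    hits <- data.table::data.table(
      qname = records$qname[S4Vectors::queryHits(sov)],
      contig_id = seg_gr$contig_id[S4Vectors::subjectHits(sov)],
      gene_id = seg_gr$gene_id[S4Vectors::subjectHits(sov)])
    hits <- unique(hits)
    hits <- merge(hits, anti[, .(qname, gene_id)],
                  by = c("qname", "gene_id"))
    if (nrow(hits)) {
      multi <- hits[, .(n = data.table::uniqueN(contig_id)),
                    by = .(qname, gene_id)][n > 1L]
      if (nrow(multi))
        message(sprintf(
          "%d fragment(s) matched multiple contigs of one gene and were counted for each",
          nrow(multi)))
      a <- hits[, .(N = data.table::uniqueN(qname)), by = contig_id]
      antisense[a$contig_id] <- a$N
    }
  }
  list(sense = sense, antisense = antisense, assignments = asn)
}

#' Build sense and antisense count matrices from per-sample SAM files
#'
#' Runs [count_fragments()] for every sample in the sample sheet and
#' assembles the per-gene sense matrix and per-contig antisense matrix.
#'
#' @param sample_sheet data.frame with columns \code{sample_id},
#'   \code{tissue}, \code{age}, \code{replicate}, \code{sex},
#'   \code{sam_path}.
#' @param annot a \code{genome_annotation}.
#' @param contigs list of [contig_record()] objects.
#' @param zones optional precomputed zones.
#' @param protocol,min_mapq see [fragment_assignments()].
#' @return list with two [count_matrix()] objects, \code{sense} and
#'   \code{antisense}.
#' @export
build_count_matrices <- function(sample_sheet, annot, contigs,
                                 zones = NULL, protocol = "RF",
                                 min_mapq = 30L) {
  sample_sheet <- as.data.frame(sample_sheet)
  if (is.null(zones)) zones <- overlap_free_zones(annot)
  gene_ids <- annot$genes$gene_id
  contig_ids <- vapply(contigs, `[[`, character(1), "contig_id")
  ns <- nrow(sample_sheet)
  sm <- matrix(0L, length(gene_ids), ns,
               dimnames = list(gene_ids, sample_sheet$sample_id))
  am <- matrix(0L, length(contig_ids), ns,
               dimnames = list(contig_ids, sample_sheet$sample_id))
  for (i in seq_len(ns)) {
    recs <- parse_sam(sample_sheet$sam_path[i])
    cts <- count_fragments(recs, annot, contigs, zones, protocol, min_mapq)
    sm[, i] <- cts$sense
    am[, i] <- cts$antisense
  }
  meta <- sample_sheet[, c("sample_id", "tissue", "age", "replicate", "sex")]
  list(sense = count_matrix(sm, meta, stratum = "sense_gene"),
       antisense = count_matrix(am, meta, stratum = "antisense_contig"))
}
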