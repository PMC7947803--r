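#' Self-validate contigs against the source genome
#'
#' A de novo contig is kept when its BLAST hits against the genome it was
#' assembled from reach at least the configured weighted identity
#' (default 99%) \emph{and} at least the configured union query coverage
#' (default 95%) — both thresholds inclusive.  Contigs with no hits are
#' removed and counted.
#'
#' @param contigs list of [contig_record()] objects.
#' @param hits contig-vs-genome hit table from [parse_blast_tab()].
#' @param cfg a [filter_config()].
#' @param subject_mode \code{"pooled"} (default; HSPs merged across
#'   subjects, appropriate for a whole-genome subject split into
#'   chromosomes) or \code{"per_subject"} (best single subject).
#' @return a \code{data.table} with one row per contig: \code{contig_id},
#'   \code{coverage}, \code{identity}, \code{kept}, \code{reason}
#'   (\code{""}, \code{"no_hits"}, \code{"low_identity"},
#'   \code{"low_coverage"}).
#' @export
self_validate <- function(contigs, hits, cfg = filter_config(),
                          subject_mode = "pooled") {
  ids <- vapply(contigs, `[[`, character(1), "contig_id")
  sm <- hit_summary(hits, subject_mode)
  out <- data.table::data.table(contig_id = ids)
  out <- merge(out, sm, by.x = "contig_id", by.y = "qid",
               all.x = TRUE, sort = FALSE)
  no_hit <- is.na(out$coverage)
  out[no_hit, c("coverage", "identity") := .(0, 0)]
  out[, kept := identity >= cfg$self_id_min & coverage >= cfg$self_cov_min]
  out[, reason := data.table::fifelse(
    kept, "",
    data.table::fifelse(no_hit, "no_hits",
      data.table::fifelse(identity < cfg$self_id_min, "low_identity",
                          "low_coverage")))]
  out[]
}

#' Map contigs to known lncRNAs
#'
#' Records a contig-to-lncRNA mapping for every (contig, lncRNA) pair with
#' query coverage \emph{strictly} greater than the configured cutoff
#' (default > 95%) and identity at least the configured minimum (default
#' 99%).  Coverage and identity are computed per subject, since each known
#' lncRNA is a distinct subject sequence; one contig may map to several
#' lncRNAs.
#'
#' @param contigs list of [contig_record()] objects.
#' @param hits contig-vs-lncRNA hit table from [parse_blast_tab()].
#' @param cfg a [filter_config()].
#' @return a \code{data.table} of mapped pairs: \code{contig_id},
#'   \code{lncrna_id}, \code{coverage}, \code{identity}.
#' @export
map_known_lncrna <- function(contigs, hits, cfg = filter_config()) {
  ids <- vapply(contigs, `[[`, character(1), "contig_id")
  empty <- data.table::data.table(contig_id = character(0),
                                  lncrna_id = character(0),
                                  coverage = numeric(0),
                                  identity = numeric(0))
  if (!nrow(hits)) return(empty)
  per <- hits[qid %in% ids,
              .(coverage = query_coverage(.SD),
                identity = as.numeric(weighted_identity(.SD))),
              by = .(qid, sid)]
  per <- per[coverage > cfg$lnc_cov_min & identity >= cfg$lnc_id_min]
  if (!nrow(per)) return(empty)
  data.table::setnames(per, c("qid", "sid"), c("contig_id", "lncrna_id"))
  data.table::setorder(per, contig_id, lncrna_id)
  per[]
}

#' Low-pass filter for spurious antisense contigs
#'
#' Stranded dUTP libraries misassign the strand of up to ~3% of fragments,
#' so a weakly covered "antisense" contig under a highly expressed gene is
#' likely an artifact of its cognate gene's own sense reads.  A contig is
#' kept only when its antisense reads are \emph{strictly} more than
#' \code{cfg$spurious_frac} (default 3%) of the combined sense-plus-
#' antisense reads of its locus:
#' \deqn{a / (s + a) > 0.03}
#' where \eqn{a} is the contig's summed unique antisense count and \eqn{s}
#' the cognate gene's summed unique sense count.  A zero denominator
#' removes the contig.
#'
#' @param antisense_reads contig antisense unique-read totals (vector).
#' @param gene_sense_reads cognate gene sense unique-read totals, recycled
#'   against \code{antisense_reads}.
#' @param cfg a [filter_config()].
#' @return logical vector: keep?
#' @examples
#' spurious_filter(c(30, 31, 0), c(970, 969, 0))  # FALSE TRUE FALSE
#' @export
spurious_filter <- function(antisense_reads, gene_sense_reads,
                            cfg = filter_config()) {
  if (any(antisense_reads < 0) || any(gene_sense_reads < 0))
    ns_stop("read counts must be nonnegative")
  denom <- gene_sense_reads + antisense_reads
  ifelse(denom > 0, antisense_reads / denom > cfg$spurious_frac, FALSE)
}

#' Run the full contig QC cascade
#'
#' Applies, in order, genome self-validation then the spurious low-pass
#' filter, and reports one removal reason per removed contig.
#'
#' @param contigs list of [contig_record()] objects (with
#'   \code{antisense_reads} populated).
#' @param self_hits contig-vs-genome hit table.
#' @param gene_sense_reads named vector of summed unique sense counts per
#'   gene.
#' @param cfg a [filter_config()].
#' @return a \code{data.table} per contig: \code{contig_id},
#'   \code{gene_id}, \code{coverage}, \code{identity},
#'   \code{antisense_reads}, \code{sense_reads}, \code{kept},
#'   \code{reason}.
#' @export
contig_qc <- function(contigs, self_hits, gene_sense_reads,
                      cfg = filter_config()) {
  sv <- self_validate(contigs, self_hits, cfg)
  info <- data.table::data.table(
    contig_id = vapply(contigs, `[[`, character(1), "contig_id"),
    gene_id = vapply(contigs, `[[`, character(1), "gene_id"),
    antisense_reads = vapply(contigs, `[[`, numeric(1), "antisense_reads"))
  out <- merge(info, sv, by = "contig_id", sort = FALSE)
  out[, sense_reads := ifelse(gene_id %in% names(gene_sense_reads),
                              gene_sense_reads[gene_id], 0)]
  keep_sp <- spurious_filter(out$antisense_reads, out$sense_reads, cfg)
  out[, reason := data.table::fifelse(!kept, reason,
        data.table::fifelse(keep_sp, "", "spurious_low_pass"))]
  out[, kept := kept & keep_sp]
  out[]
}
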