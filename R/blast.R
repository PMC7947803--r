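#' Parse a BLAST tabular (outfmt 6) hit table
#'
#' Reads the 12 standard columns (\code{qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore}), optionally
#' followed by a 13th \code{qlen} column.  Query coordinates are
#' normalized so \code{qstart <= qend}; minus-strand hits (reversed
#' subject coordinates) are retained with \code{sstrand == "-"}.
#'
#' @param path path to the tab-separated hit table.
#' @param qlen_source where query lengths come from: \code{"column"}
#'   (13th column required) or \code{"fasta"} (lengths read from
#'   \code{query_fasta}).
#' @param query_fasta FASTA file of query sequences, required when
#'   \code{qlen_source = "fasta"}.
#' @return a \code{data.table} with columns \code{qid}, \code{sid},
#'   \code{pident}, \code{length}, \code{qstart}, \code{qend},
#'   \code{sstart}, \code{send}, \code{sstrand}, \code{evalue},
#'   \code{bitscore}, \code{qlen}, keyed by \code{qid}.
#' @export
parse_blast_tab <- function(path, qlen_source = c("column", "fasta"),
                            query_fasta = NULL) {
  qlen_source <- match.arg(qlen_source)
  if (!file.exists(path)) ns_stop("BLAST table not found: %s", path)
  cols <- c("qid", "sid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (!nrow(dt)) {
    out <- data.table::data.table(
      qid = character(0), sid = character(0), pident = numeric(0),
      length = integer(0), qstart = integer(0), qend = integer(0),
      sstart = integer(0), send = integer(0), sstrand = character(0),
      evalue = numeric(0), bitscore = numeric(0), qlen = integer(0))
    data.table::setkey(out, qid)
    return(out)
  }
  if (ncol(dt) < 12L)
    ns_stop("expected >= 12 tab-separated columns in %s, found %d",
            path, ncol(dt))
  has_qlen_col <- ncol(dt) >= 13L
  if (qlen_source == "column" && !has_qlen_col)
    ns_stop("qlen_source = \"column\" but %s has only 12 columns", path)
  data.table::setnames(dt, seq_along(cols), cols)

  if (qlen_source == "column") {
    qlen <- as.integer(dt[[13L]])
  } else {
    if (is.null(query_fasta))
      ns_stop("qlen_source = \"fasta\" requires query_fasta")
    seqs <- Biostrings::readDNAStringSet(query_fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    missing <- setdiff(unique(dt$qid), names(seqs))
    if (length(missing))
      ns_stop("query id(s) absent from FASTA %s: %s", query_fasta,
              paste(missing, collapse = ", "))
    widths <- setNames(Biostrings::width(seqs), names(seqs))
    qlen <- unname(widths[dt$qid])
  }
  out <- dt[, .(qid = as.character(qid), sid = as.character(sid),
                pident = as.numeric(pident), length = as.integer(length),
                qstart = as.integer(qstart), qend = as.integer(qend),
                sstart = as.integer(sstart), send = as.integer(send),
                evalue = as.numeric(evalue), bitscore = as.numeric(bitscore))]
  out[, sstrand := data.table::fifelse(send < sstart, "-", "+")]
  # normalize coordinates so start <= end on both axes
  out[qend < qstart, c("qstart", "qend") := .(qend, qstart)]
  out[send < sstart, c("sstart", "send") := .(send, sstart)]
  out[, qlen := qlen]
  if (any(out$qlen <= 0L, na.rm = TRUE) || anyNA(out$qlen))
    ns_stop("non-positive or missing query length in %s", path)
  data.table::setcolorder(out, c("qid", "sid", "pident", "length",
                                 "qstart", "qend", "sstart", "send",
                                 "sstrand", "evalue", "bitscore", "qlen"))
  data.table::setkey(out, qid)
  out[]
}

#' Query coverage of a set of HSPs
#'
#' Percent of the query covered by the \emph{union} of the HSP query
#' intervals — overlapping or nested HSPs are not double-counted.
#'
#' @param hits hit rows for one query (all sharing \code{qid} and
#'   \code{qlen}), as produced by [parse_blast_tab()].
#' @return coverage percent in \code{[0, 100]}; 0 for an empty hit set.
#' @examples
#' h <- data.frame(qstart = c(1, 40), qend = c(50, 100), qlen = 100)
#' query_coverage(h)  # 100: union of [1,50] and [40,100]
#' @export
query_coverage <- function(hits) {
  if (is.null(hits) || !nrow(hits)) return(0)
  qlen <- hits$qlen[1]
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(hits$qstart, hits$qend))))
  100 * covered / qlen
}

#' Alignment-length-weighted mean identity of a set of HSPs
#'
#' @param hits hit rows for one query; needs columns \code{pident} and
#'   \code{length}.
#' @return weighted mean percent identity; 0 (with attribute
#'   \code{empty = TRUE}) for an empty hit set.
#' @export
weighted_identity <- function(hits) {
  if (is.null(hits) || !nrow(hits))
    return(structure(0, empty = TRUE))
  sum(hits$pident * hits$length) / sum(hits$length)
}

# per-query coverage/identity summary table; subject_mode "pooled" merges
# HSPs across subjects (whole-genome searches), "per_subject" keeps the
# best subject by coverage then identity
hit_summary <- function(hits, subject_mode = c("pooled", "per_subject")) {
  subject_mode <- match.arg(subject_mode)
  if (!nrow(hits))
    return(data.table::data.table(qid = character(0), coverage = numeric(0),
                                  identity = numeric(0)))
  if (subject_mode == "pooled") {
    out <- hits[, .(coverage = query_coverage(.SD),
                    identity = as.numeric(weighted_identity(.SD))),
                by = qid]
  } else {
    per <- hits[, .(coverage = query_coverage(.SD),
                    identity = as.numeric(weighted_identity(.SD))),
                by = .(qid, sid)]
    data.table::setorder(per, qid, -coverage, -identity)
    out <- per[, .SD[1L], by = qid][, .(qid, coverage, identity)]
  }
  out[]
}
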