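#' Parse a SAM text file into alignment records
#'
#' Reads the plain-text SAM subset this pipeline consumes: header lines are
#' required (and skipped), unmapped, secondary and supplementary records
#' are tolerated and dropped, and the optional \code{NH:i} tag (number of
#' reported alignments for the read) is captured when present.  Records
#' whose CIGAR cannot be parsed are skipped; the number of skipped records
#' is reported in one warning and in the \code{n_skipped} attribute.
#'
#' @param path path to a SAM text file.
#' @return a [data.table::data.table] of mapped primary records with
#'   columns \code{qname}, \code{seq_id}, \code{pos} (0-based leftmost),
#'   \code{aln_len} (aligned reference length from CIGAR M/D/N/=/X ops),
#'   \code{is_reverse}, \code{is_read1}, \code{is_read2}, \code{mapq} and
#'   \code{nh} (\code{NA} when the tag is absent).
#' @export
parse_sam <- function(path) {
  if (!file.exists(path)) ns_stop("SAM file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "@"))
    ns_stop("SAM header required in %s", path)
  lines <- lines[!startsWith(lines, "@")]
  empty <- sam_empty()
  if (!length(lines)) return(empty)

  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:6)
  flag <- as.integer(f[[2]])
  keep <- bitwAnd(flag, 0x4L) == 0L &    # mapped
    bitwAnd(flag, 0x100L) == 0L &        # primary
    bitwAnd(flag, 0x800L) == 0L          # not supplementary
  aln_len <- cigar_ref_len(f[[6]])
  bad_cigar <- keep & is.na(aln_len)
  if (any(bad_cigar))
    ns_warn("%d record(s) with unparsable CIGAR skipped in %s",
            sum(bad_cigar), path)
  keep <- keep & !is.na(aln_len)

  nh <- rep(NA_integer_, length(lines))
  m <- regexpr("\tNH:i:[0-9]+", lines)
  hit <- m > 0L
  nh[hit] <- as.integer(substring(lines[hit], m[hit] + 6L,
                                  m[hit] + attr(m, "match.length")[hit] - 1L))

  out <- data.table::data.table(
    qname = f[[1]][keep],
    seq_id = f[[3]][keep],
    pos = as.integer(f[[4]][keep]) - 1L,
    aln_len = aln_len[keep],
    is_reverse = bitwAnd(flag[keep], 0x10L) != 0L,
    is_read1 = bitwAnd(flag[keep], 0x40L) != 0L,
    is_read2 = bitwAnd(flag[keep], 0x80L) != 0L,
    mapq = as.integer(f[[5]][keep]),
    nh = nh[keep])
  data.table::setattr(out, "n_skipped", sum(bad_cigar))
  out
}

sam_empty <- function() {
  data.table::data.table(
    qname = character(0), seq_id = character(0), pos = integer(0),
    aln_len = integer(0), is_reverse = logical(0), is_read1 = logical(0),
    is_read2 = logical(0), mapq = integer(0), nh = integer(0))
}

# aligned reference length from CIGAR: sum of M/D/N/=/X op lengths.
# NA for "*" or strings containing anything but [0-9MIDNSHP=X].
cigar_ref_len <- function(cigar) {
  out <- rep(NA_integer_, length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)   # fast path: single match op
  out[simple] <- as.integer(sub("M", "", cigar[simple], fixed = TRUE))
  ok <- !simple & grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(ok)) {
    ops <- regmatches(cigar[ok], gregexpr("[0-9]+[MIDNSHP=X]", cigar[ok]))
    out[ok] <- vapply(ops, function(o) {
      n <- as.integer(sub("[MIDNSHP=X]$", "", o))
      op <- sub("^[0-9]+", "", o)
      sum(n[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
  }
  out[!is.na(out) & out <= 0L] <- NA_integer_
  out
}

#' Infer the transcribed strand of a fragment
#'
#' Under a stranded dUTP-type library (the \code{"RF"} protocol, the
#' default here), read 1 aligns antisense to the source transcript: the
#' fragment's strand is the opposite of read 1's alignment strand and
#' equal to read 2's alignment strand.  \code{"FR"} is the mirror
#' convention.  Single-end records (neither mate flag set) are treated as
#' read 1.
#'
#' @param is_reverse logical, record aligned to the reverse strand.
#' @param is_read1,is_read2 logical mate flags (vectors recycled).
#' @param protocol \code{"RF"} (dUTP, default) or \code{"FR"}.
#' @return character vector of \code{"+"}/\code{"-"} fragment strands.
#' @examples
#' fragment_strand(FALSE, TRUE, FALSE)          # RF, read1 forward -> "-"
#' fragment_strand(FALSE, FALSE, TRUE)          # RF, read2 forward -> "+"
#' @export
fragment_strand <- function(is_reverse, is_read1, is_read2 = !is_read1,
                            protocol = c("RF", "FR")) {
  protocol <- match.arg(protocol)
  n <- max(length(is_reverse), length(is_read1), length(is_read2))
  is_reverse <- rep_len(is_reverse, n)
  read1_like <- rep_len(is_read1, n) | !(rep_len(is_read1, n) |
                                           rep_len(is_read2, n))
  aln <- ifelse(is_reverse, "-", "+")
  flip <- if (protocol == "RF") read1_like else !read1_like
  ifelse(flip, ifelse(aln == "+", "-", "+"), aln)
}

#' Is a record uniquely mapped?
#'
#' The \code{NH} tag is authoritative when present (\code{NH == 1});
#' otherwise a MAPQ threshold is used as fallback.
#'
#' @param nh integer NH tag values (\code{NA} when absent).
#' @param mapq integer mapping qualities.
#' @param min_mapq MAPQ fallback threshold (default 30).
#' @return logical vector.
#' @export
is_uniquely_mapped <- function(nh, mapq, min_mapq = 30L) {
  ifelse(!is.na(nh), nh == 1L, mapq >= min_mapq)
}
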