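#' Filter thresholds for the NAT pipeline
#'
#' Bundles every threshold used by the contig validation, detection,
#' spurious-read and conservation filters.  Defaults follow the published
#' analysis protocol this pipeline implements:
#' contig self-validation against the source genome at >= 99% identity and
#' >= 95% query coverage (inclusive); known-lncRNA cross-mapping at > 95%
#' coverage (strict) and >= 99% identity; the spurious-antisense low-pass
#' filter keeping contigs whose antisense reads exceed 3% of sense plus
#' antisense reads (strict); cross-species conservation at > 90% coverage
#' and > 90% identity (both strict); and the detection filter requiring at
#' least 10 uniquely mapped reads in at least 3 samples.
#'
#' The two BLAST filters deliberately differ at the boundary: the
#' self-validation thresholds are inclusive while the lncRNA coverage and
#' both conservation thresholds are strict.
#'
#' @param self_id_min minimum weighted percent identity for contig
#'   self-validation (inclusive), default 99.
#' @param self_cov_min minimum percent query coverage for self-validation
#'   (inclusive), default 95.
#' @param lnc_id_min minimum percent identity for known-lncRNA mapping
#'   (inclusive), default 99.
#' @param lnc_cov_min percent query coverage for lncRNA mapping; a contig
#'   maps only when coverage is strictly greater, default 95.
#' @param spurious_frac antisense read fraction that a contig must strictly
#'   exceed to survive the low-pass filter, default 0.03.
#' @param human_id_min percent identity that a contig must strictly exceed
#'   to be called conserved in the second genome, default 90.
#' @param human_cov_min percent coverage that a contig must strictly exceed
#'   to be called conserved, default 90.
#' @param detect_min_reads minimum raw unique-read count per qualifying
#'   sample (inclusive), default 10.
#' @param detect_min_samples minimum number of qualifying samples
#'   (inclusive), default 3.
#' @param f_test_alpha significance level for the developmental linear
#'   model F-test, default 0.05.
#' @return an object of class \code{filter_config} (a named list).
#' @examples
#' cfg <- filter_config()
#' cfg$spurious_frac
#' @export
filter_config <- function(self_id_min = 99, self_cov_min = 95,
                          lnc_id_min = 99, lnc_cov_min = 95,
                          spurious_frac = 0.03,
                          human_id_min = 90, human_cov_min = 90,
                          detect_min_reads = 10, detect_min_samples = 3,
                          f_test_alpha = 0.05) {
  pct <- c(self_id_min = self_id_min, self_cov_min = self_cov_min,
           lnc_id_min = lnc_id_min, lnc_cov_min = lnc_cov_min,
           human_id_min = human_id_min, human_cov_min = human_cov_min)
  bad <- pct[!(pct > 0 & pct <= 100)]
  if (length(bad))
    ns_stop("percentage thresholds must lie in (0, 100]: %s",
            paste(names(bad), collapse = ", "))
  if (!(spurious_frac > 0 && spurious_frac < 1))
    ns_stop("spurious_frac must lie in (0, 1)")
  if (!(f_test_alpha > 0 && f_test_alpha < 1))
    ns_stop("f_test_alpha must lie in (0, 1)")
  if (detect_min_reads < 1 || detect_min_samples < 1)
    ns_stop("detection thresholds must be >= 1")
  structure(list(self_id_min = self_id_min, self_cov_min = self_cov_min,
                 lnc_id_min = lnc_id_min, lnc_cov_min = lnc_cov_min,
                 spurious_frac = spurious_frac,
                 human_id_min = human_id_min, human_cov_min = human_cov_min,
                 detect_min_reads = detect_min_reads,
                 detect_min_samples = detect_min_samples,
                 f_test_alpha = f_test_alpha),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("NAT pipeline filter configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
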