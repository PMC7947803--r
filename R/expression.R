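#' Construct a count matrix with sample metadata
#'
#' Features (genes or antisense contigs) in rows, samples in columns, with
#' a sample sheet carrying tissue, age, replicate and sex.
#'
#' @param counts numeric matrix, features x samples, nonnegative.
#' @param samples data.frame with columns \code{sample_id}, \code{tissue},
#'   \code{age}, \code{replicate} and optionally \code{sex}; one row per
#'   column of \code{counts}, (tissue, age, replicate) unique.
#' @param stratum \code{"sense_gene"} or \code{"antisense_contig"}.
#' @return an object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, samples,
                         stratum = c("sense_gene", "antisense_contig")) {
  stratum <- match.arg(stratum)
  counts <- as.matrix(counts)
  samples <- as.data.frame(samples)
  if (ncol(counts) != nrow(samples))
    ns_stop("count_matrix: %d columns but %d sample rows",
            ncol(counts), nrow(samples))
  if (any(counts < 0)) ns_stop("count_matrix: negative counts")
  need <- c("sample_id", "tissue", "age", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    ns_stop("sample sheet missing column(s): %s", paste(miss, collapse = ", "))
  key <- paste(samples$tissue, samples$age, samples$replicate)
  if (anyDuplicated(key))
    ns_stop("duplicate (tissue, age, replicate) in sample sheet")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  structure(list(counts = counts, samples = samples, stratum = stratum),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d features x %d samples\n",
              x$stratum, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Per-sample library sizes across both strata
#'
#' The library size of a sample is its total unique-read count over the
#' sense (gene) stratum plus the antisense (contig) stratum, so sense and
#' antisense abundances stay on one common scale after normalization.
#'
#' @param sense,antisense [count_matrix()] objects over the same samples.
#' @return named numeric vector of library sizes.
#' @export
library_sizes <- function(sense, antisense) {
  if (!identical(sense$samples$sample_id, antisense$samples$sample_id))
    ns_stop("sense and antisense matrices cover different samples")
  colSums(sense$counts) + colSums(antisense$counts)
}

#' Normalize a count matrix by library size (CPM)
#'
#' Scales each sample to counts per million.  By default the library size
#' is the matrix's own column total; pass the cross-stratum
#' [library_sizes()] to normalize sense and antisense matrices jointly.
#'
#' @param m a [count_matrix()].
#' @param lib_sizes optional per-sample library sizes (named or in column
#'   order); default \code{colSums(m$counts)}.
#' @return a \code{count_matrix} of normalized counts.
#' @export
normalize_library_size <- function(m, lib_sizes = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(m$counts)
  if (length(lib_sizes) != ncol(m$counts))
    ns_stop("need one library size per sample")
  zero <- lib_sizes <= 0
  if (any(zero))
    ns_stop("zero library size for sample(s): %s",
            paste(m$samples$sample_id[zero], collapse = ", "))
  m$counts <- sweep(m$counts, 2, lib_sizes, "/") * 1e6
  m
}

#' Detection filter
#'
#' A feature is detected when it has at least \code{cfg$detect_min_reads}
#' raw uniquely mapped reads (default 10) in at least
#' \code{cfg$detect_min_samples} different samples (default 3); both
#' boundaries inclusive.
#'
#' @param m a raw-count [count_matrix()].
#' @param cfg a [filter_config()].
#' @return character vector of retained feature ids.
#' @export
detection_filter <- function(m, cfg = filter_config()) {
  qualifying <- rowSums(m$counts >= cfg$detect_min_reads)
  rownames(m$counts)[qualifying >= cfg$detect_min_samples]
}

#' Antisense:total expression ratio per gene
#'
#' For each gene, sums the normalized counts over every sample for the
#' gene itself and for all of its cognate antisense contigs, and reports
#' \eqn{ratio = antisense / (sense + antisense)}.  Genes with zero
#' denominator are flagged (\code{defined = FALSE}, ratio \code{NA});
#' genes with no contigs have ratio 0.
#'
#' @param sense_norm,anti_norm normalized [count_matrix()] objects (see
#'   [normalize_library_size()]).
#' @param contig_map data.frame mapping \code{contig_id} to its cognate
#'   \code{gene_id}.
#' @param gene_ids genes to report; default all rows of \code{sense_norm}.
#' @return a \code{data.table}: \code{gene_id}, \code{sense_sum},
#'   \code{antisense_sum}, \code{ratio}, \code{defined}.
#' @export
antisense_total_ratio <- function(sense_norm, anti_norm, contig_map,
                                  gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- rownames(sense_norm$counts)
  unknown <- setdiff(gene_ids, rownames(sense_norm$counts))
  if (length(unknown))
    ns_stop("unknown gene(s): %s", paste(unknown, collapse = ", "))
  contig_map <- as.data.frame(contig_map)
  sense_sum <- rowSums(sense_norm$counts)[gene_ids]
  anti_by_contig <- rowSums(anti_norm$counts)
  anti_sum <- vapply(gene_ids, function(g) {
    cts <- contig_map$contig_id[contig_map$gene_id == g]
    cts <- intersect(cts, names(anti_by_contig))
    if (length(cts)) sum(anti_by_contig[cts]) else 0
  }, numeric(1))
  denom <- sense_sum + anti_sum
  data.table::data.table(
    gene_id = gene_ids,
    sense_sum = unname(sense_sum),
    antisense_sum = unname(anti_sum),
    ratio = ifelse(denom > 0, anti_sum / denom,
                   ifelse(anti_sum == 0 & denom == 0, NA_real_, NA_real_)),
    defined = denom > 0)
}

#' Tissue specificity score (TSS)
#'
#' Contrasts a gene's antisense read proportion between the two profiled
#' brain regions, normalized by the pooled antisense proportion:
#' \deqn{TSS = 100 \times \frac{\frac{Opp_{mPFC}}{Total_{mPFC}} -
#'   \frac{Opp_{Str}}{Total_{Str}}}
#'   {\frac{Opp_{mPFC} + Opp_{Str}}{Total_{mPFC} + Total_{Str}}}}
#' where \eqn{Opp} are library-size-normalized antisense (opposite-strand)
#' counts summed over the samples of one tissue and \eqn{Total} the
#' corresponding sense-plus-antisense totals.  Positive scores indicate
#' mPFC enrichment of antisense expression, negative scores striatum
#' enrichment.  The score is antisymmetric under tissue exchange and
#' invariant to a common rescaling of all counts.
#'
#' Undefined when either tissue total is zero or no antisense reads exist
#' at all; such genes get \code{NA} and should be excluded from TSS
#' reports.
#'
#' @param mpfc_opp,mpfc_total,str_opp,str_total normalized antisense and
#'   total counts per tissue (vectors recycled to common length).
#' @return numeric TSS values (\code{NA} where undefined).
#' @examples
#' tissue_specificity_score(20, 100, 0, 100)   # 200
#' tissue_specificity_score(10, 100, 10, 100)  # 0
#' @export
tissue_specificity_score <- function(mpfc_opp, mpfc_total,
                                     str_opp, str_total) {
  total <- mpfc_total + str_total
  pooled <- (mpfc_opp + str_opp) / total
  ok <- mpfc_total > 0 & str_total > 0 & (mpfc_opp + str_opp) > 0 &
    mpfc_opp <= mpfc_total & str_opp <= str_total
  out <- rep(NA_real_, length(pooled))
  out[ok] <- 100 * ((mpfc_opp / mpfc_total) -
                      (str_opp / str_total))[ok] / pooled[ok]
  out
}

#' Per-gene tissue specificity report
#'
#' Aggregates normalized counts per tissue and applies
#' [tissue_specificity_score()] to every gene.
#'
#' @inheritParams antisense_total_ratio
#' @return a \code{data.table}: \code{gene_id}, \code{mPFC_OppReads},
#'   \code{mPFC_Total}, \code{Str_OppReads}, \code{Str_Total}, \code{TSS},
#'   \code{defined}.
#' @export
tss_table <- function(sense_norm, anti_norm, contig_map, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- rownames(sense_norm$counts)
  contig_map <- as.data.frame(contig_map)
  tiss <- sense_norm$samples$tissue
  sum_by_tissue <- function(mat, tn)
    if (any(tiss == tn)) rowSums(mat[, tiss == tn, drop = FALSE])
    else setNames(numeric(nrow(mat)), rownames(mat))
  s_m <- sum_by_tissue(sense_norm$counts, "mPFC")[gene_ids]
  s_s <- sum_by_tissue(sense_norm$counts, "striatum")[gene_ids]
  a_by_contig_m <- sum_by_tissue(anti_norm$counts, "mPFC")
  a_by_contig_s <- sum_by_tissue(anti_norm$counts, "striatum")
  gene_anti <- function(v) vapply(gene_ids, function(g) {
    cts <- intersect(contig_map$contig_id[contig_map$gene_id == g], names(v))
    if (length(cts)) sum(v[cts]) else 0
  }, numeric(1))
  a_m <- gene_anti(a_by_contig_m)
  a_s <- gene_anti(a_by_contig_s)
  out <- data.table::data.table(
    gene_id = gene_ids,
    mPFC_OppReads = unname(a_m),
    mPFC_Total = unname(s_m + a_m),
    Str_OppReads = unname(a_s),
    Str_Total = unname(s_s + a_s),
    TSS = tissue_specificity_score(a_m, s_m + a_m, a_s, s_s + a_s))
  out[, defined := !is.na(TSS)]
  out[]
}
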