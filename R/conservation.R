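#' Cross-species conservation filter
#'
#' Calls a contig conserved in a second genome when its BLAST hits reach
#' \emph{strictly} more than the configured coverage and identity
#' thresholds (default > 90% union query coverage and > 90%
#' length-weighted identity).  Coverage/identity aggregation reuses the
#' same operators as contig self-validation ([query_coverage()],
#' [weighted_identity()]).  Contigs without hits are reported with
#' coverage 0 and \code{conserved = FALSE}.
#'
#' @param contigs list of [contig_record()] objects.
#' @param hits contig-vs-second-genome hit table from [parse_blast_tab()].
#' @param cfg a [filter_config()].
#' @param subject_mode \code{"pooled"} (default) or \code{"per_subject"};
#'   see [self_validate()].
#' @return a \code{data.table}: \code{contig_id}, \code{gene_id}
#'   (cognate), \code{coverage}, \code{identity}, \code{conserved}.
#' @export
conservation_filter <- function(contigs, hits, cfg = filter_config(),
                                subject_mode = "pooled") {
  out <- data.table::data.table(
    contig_id = vapply(contigs, `[[`, character(1), "contig_id"),
    gene_id = vapply(contigs, `[[`, character(1), "gene_id"))
  sm <- hit_summary(hits, subject_mode)
  out <- merge(out, sm, by.x = "contig_id", by.y = "qid",
               all.x = TRUE, sort = FALSE)
  out[is.na(coverage), c("coverage", "identity") := .(0, 0)]
  out[, conserved := coverage > cfg$human_cov_min &
        identity > cfg$human_id_min]
  out[]
}

#' Cross-reference conservation calls against a gene list
#'
#' Joins conservation calls to a list of genes of interest (e.g. ASD risk
#' genes, already given as source-species symbols) and reports, per listed
#' gene, how many cognate contigs exist and how many are conserved.
#' Listed genes absent from the annotation are flagged.
#'
#' @param calls output of [conservation_filter()].
#' @param gene_list character vector of gene identifiers of interest.
#' @param annot optional \code{genome_annotation} used to flag listed
#'   genes that are absent from the annotation.
#' @return a \code{data.table} with one row per listed gene:
#'   \code{gene_id}, \code{n_contigs}, \code{n_conserved},
#'   \code{conserved_contigs} (comma-separated ids),
#'   \code{in_annotation}.
#' @export
cross_reference_genes <- function(calls, gene_list, annot = NULL) {
  if (!length(gene_list)) ns_stop("gene list is empty")
  calls <- data.table::as.data.table(calls)
  out <- data.table::data.table(gene_id = unique(gene_list))
  per_gene <- calls[, .(
    n_contigs = .N,
    n_conserved = sum(conserved),
    conserved_contigs = paste(sort(contig_id[conserved]), collapse = ",")),
    by = gene_id]
  out <- merge(out, per_gene, by = "gene_id", all.x = TRUE, sort = FALSE)
  out[is.na(n_contigs), c("n_contigs", "n_conserved") := .(0L, 0L)]
  out[is.na(conserved_contigs), conserved_contigs := ""]
  out[, in_annotation := if (is.null(annot)) NA else
    gene_id %in% annot$genes$gene_id]
  data.table::setorder(out, gene_id)
  out[]
}

#' Read a gene list file
#'
#' Plain text, one gene symbol per line; blank lines and \code{#} comments
#' ignored.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) ns_stop("gene list not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
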