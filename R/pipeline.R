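#' Read contigs back from a contig GTF
#'
#' Inverse of [write_contig_gtf()]: reconstructs one [contig_record()] per
#' transcript from its exon features.
#'
#' @param path contig GTF path.
#' @return list of \code{contig_record} objects.
#' @export
read_contig_gtf <- function(path) {
  ca <- load_annotation(path)
  f <- ca$features
  ex <- f[f$type == "exon"]
  if (!length(ex)) return(list())
  ids <- unique(ex$transcript_id)
  lapply(ids, function(ct) {
    e <- ex[ex$transcript_id == ct]
    cg <- if (!is.null(e$cognate_gene_id)) as.character(e$cognate_gene_id[1])
          else NA_character_
    contig_record(
      contig_id = ct, gene_id = cg,
      seq_id = as.character(GenomeInfoDb::seqnames(e))[1],
      strand = as.character(BiocGenerics::strand(e))[1],
      seg_starts = BiocGenerics::start(e), seg_ends = BiocGenerics::end(e))
  })
}

#' Read a sample sheet TSV
#'
#' Columns: \code{sample_id}, \code{tissue}, \code{age}, \code{replicate},
#' \code{sex}, \code{sam_path}.
#'
#' @param path TSV path.
#' @param base_dir optional directory against which relative
#'   \code{sam_path} entries are resolved.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path, base_dir = NULL) {
  sheet <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("sample_id", "tissue", "age", "replicate", "sex", "sam_path")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    ns_stop("sample sheet missing column(s): %s",
            paste(miss, collapse = ", "))
  if (!is.null(base_dir)) {
    rel <- !grepl("^(/|[A-Za-z]:)", sheet$sam_path)
    sheet$sam_path[rel] <- file.path(base_dir, sheet$sam_path[rel])
  }
  sheet
}

#' Assemble and validate a pipeline configuration
#'
#' @param paths named list of input paths: \code{annotation},
#'   \code{contigs}, \code{sample_sheet}, \code{self_blast},
#'   \code{human_blast}, optionally \code{lncrna_blast}, and
#'   \code{gene_list}; plus \code{out_dir}.
#' @param filters a [filter_config()].
#' @param protocol strandedness protocol, default \code{"RF"}.
#' @param min_mapq MAPQ fallback for unique mapping, default 30.
#' @param blocker_biotypes see [compute_overlap_free_zone()].
#' @param min_zone_length see [compute_overlap_free_zone()].
#' @param json_path alternatively, read everything from a JSON config
#'   file with keys \code{paths} and (optionally) \code{filters},
#'   \code{protocol}, \code{min_mapq}.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(paths = NULL, filters = filter_config(),
                            protocol = "RF", min_mapq = 30L,
                            blocker_biotypes = NULL,
                            min_zone_length = 1L, json_path = NULL) {
  if (!is.null(json_path)) {
    js <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    paths <- as.list(js$paths)
    if (!is.null(js$filters)) filters <- do.call(filter_config, js$filters)
    if (!is.null(js$protocol)) protocol <- js$protocol
    if (!is.null(js$min_mapq)) min_mapq <- as.integer(js$min_mapq)
    if (!is.null(js$blocker_biotypes)) blocker_biotypes <- js$blocker_biotypes
    if (!is.null(js$min_zone_length))
      min_zone_length <- as.integer(js$min_zone_length)
  }
  need <- c("annotation", "contigs", "sample_sheet", "self_blast",
            "human_blast", "gene_list", "out_dir")
  miss <- setdiff(need, names(paths))
  if (length(miss))
    ns_stop("pipeline config missing path(s): %s",
            paste(miss, collapse = ", "))
  for (nm in setdiff(need, "out_dir"))
    if (!file.exists(paths[[nm]]))
      ns_stop("config path %s does not exist: %s", nm, paths[[nm]])
  if (!inherits(filters, "filter_config"))
    ns_stop("filters must be a filter_config")
  structure(list(paths = paths, filters = filters, protocol = protocol,
                 min_mapq = min_mapq, blocker_biotypes = blocker_biotypes,
                 min_zone_length = min_zone_length),
            class = "pipeline_config")
}

#' Run the NAT identification pipeline end-to-end
#'
#' Stages: annotation loading and overlap-free-zone computation;
#' strand-aware fragment extraction and unique-read counting from the
#' per-sample SAM files; contig QC (genome self-validation, then the 3%
#' spurious low-pass filter) and known-lncRNA cross-mapping; expression
#' summaries (detection filter, CPM normalization, antisense:total
#' ratios, tissue specificity scores); per-tissue sense-antisense
#' developmental slope classification; and cross-species conservation
#' with gene-list cross-referencing.  All reports are written as TSV
#' under \code{out_dir} plus a machine-readable \code{run_report.json};
#' outputs are byte-deterministic for a fixed input set.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the run report, invisibly (a named list mirroring
#'   \code{run_report.json}).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (!inherits(cfg, "pipeline_config"))
    ns_stop("cfg must be a pipeline_config")
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  fc <- cfg$filters

  stage <- "annotation"
  report <- list(tool = "natscan",
                 version = as.character(utils::packageVersion("natscan")),
                 config = list(protocol = cfg$protocol,
                               min_mapq = cfg$min_mapq,
                               filters = unclass(fc)))
  res <- try({
    say("[annotation] loading %s", cfg$paths$annotation)
    annot <- load_annotation(cfg$paths$annotation)
    zones <- overlap_free_zones(annot, cfg$blocker_biotypes,
                                cfg$min_zone_length)
    contigs <- read_contig_gtf(cfg$paths$contigs)
    report$annotation <- list(
      n_genes = length(annot$genes),
      n_contigs_input = length(contigs))

    stage <- "extract"
    say("[extract] counting fragments for %d contig(s)", length(contigs))
    sheet <- read_sample_sheet(cfg$paths$sample_sheet)
    mats <- build_count_matrices(sheet, annot, contigs, zones,
                                 cfg$protocol, cfg$min_mapq)
    write_report_tsv(cbind(feature_id = rownames(mats$sense$counts),
                           as.data.frame(mats$sense$counts)),
                     file.path(out_dir, "sense_counts.tsv"))
    write_report_tsv(cbind(feature_id = rownames(mats$antisense$counts),
                           as.data.frame(mats$antisense$counts)),
                     file.path(out_dir, "antisense_counts.tsv"))

    stage <- "qc"
    gene_sense_tot <- rowSums(mats$sense$counts)
    anti_tot <- rowSums(mats$antisense$counts)
    for (i in seq_along(contigs))
      contigs[[i]]$antisense_reads <-
        unname(anti_tot[contigs[[i]]$contig_id])
    self_hits <- parse_blast_tab(cfg$paths$self_blast, "column")
    qc <- contig_qc(contigs, self_hits, gene_sense_tot, fc)
    write_report_tsv(qc, file.path(out_dir, "contig_qc.tsv"))
    kept_ids <- qc$contig_id[qc$kept]
    kept <- contigs[vapply(contigs, function(ct)
      ct$contig_id %in% kept_ids, logical(1))]
    report$qc <- list(
      n_contigs_input = length(contigs),
      n_self_valid = sum(qc$reason != "no_hits" &
                           qc$reason != "low_identity" &
                           qc$reason != "low_coverage"),
      n_after_spurious = length(kept))
    if (!is.null(cfg$paths$lncrna_blast) &&
        file.exists(cfg$paths$lncrna_blast)) {
      lnc_hits <- parse_blast_tab(cfg$paths$lncrna_blast, "column")
      lnc_map <- map_known_lncrna(kept, lnc_hits, fc)
      write_report_tsv(lnc_map, file.path(out_dir, "lncrna_map.tsv"))
      report$qc$n_lncrna_mapped <- length(unique(lnc_map$contig_id))
    }

    stage <- "expression"
    say("[expression] %d contig(s) after QC", length(kept))
    kept_anti <- mats$antisense
    kept_anti$counts <- kept_anti$counts[kept_ids, , drop = FALSE]
    detected_genes <- detection_filter(mats$sense, fc)
    detected_contigs <- detection_filter(kept_anti, fc)
    libs <- library_sizes(mats$sense, kept_anti)
    sense_n <- normalize_library_size(mats$sense, libs)
    anti_n <- normalize_library_size(kept_anti, libs)
    cmap <- data.table::data.table(
      contig_id = vapply(kept, `[[`, character(1), "contig_id"),
      gene_id = vapply(kept, `[[`, character(1), "gene_id"))
    ratios <- antisense_total_ratio(sense_n, anti_n, cmap)
    tss <- tss_table(sense_n, anti_n, cmap)
    write_report_tsv(ratios, file.path(out_dir, "antisense_ratio.tsv"))
    write_report_tsv(tss, file.path(out_dir, "tss.tsv"))
    report$expression <- list(
      n_genes_detected = length(detected_genes),
      n_contigs_detected = length(detected_contigs),
      n_tss_defined = sum(tss$defined))

    stage <- "devcorr"
    dmap <- cmap[contig_id %in% detected_contigs &
                   gene_id %in% detected_genes]
    pairs <- fit_pairs(sense_n, anti_n, dmap, alpha = fc$f_test_alpha)
    quad <- summarize_quadrants(pairs)
    write_report_tsv(pairs, file.path(out_dir, "pairs.tsv"))
    write_report_tsv(quad, file.path(out_dir, "quadrants.tsv"))
    report$devcorr <- list(
      n_pairs = nrow(pairs),
      quadrants = lapply(seq_len(nrow(quad)), function(i)
        as.list(quad[i])))

    stage <- "conservation"
    human_hits <- parse_blast_tab(cfg$paths$human_blast, "column")
    calls <- conservation_filter(kept, human_hits, fc)
    genes_of_interest <- read_gene_list(cfg$paths$gene_list)
    xref <- cross_reference_genes(calls, genes_of_interest, annot)
    write_report_tsv(calls, file.path(out_dir, "conservation.tsv"))
    write_report_tsv(xref, file.path(out_dir, "gene_xref.tsv"))
    report$conservation <- list(
      n_conserved = sum(calls$conserved),
      n_listed_genes = length(genes_of_interest),
      n_listed_with_contig = sum(xref$n_contigs > 0),
      n_listed_with_conserved = sum(xref$n_conserved > 0))
    NULL
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    ns_stop("pipeline failed at stage '%s': %s", stage,
            conditionMessage(attr(res, "condition")))

  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  say("[done] reports under %s", out_dir)
  invisible(report)
}
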