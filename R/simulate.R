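#' Simulation configuration
#'
#' The stated world the generator emulates: a small genome with
#' deliberately overlapping opposite-strand genes, dUTP-protocol stranded
#' paired-end fragments from sense mRNAs and embedded antisense
#' transcripts, negative-binomial count matrices over a 2-tissue x 3-age
#' design, and BLAST-style hit tables with controlled identity and
#' coverage.
#'
#' Defaults mirror the study design this pipeline targets: ages P7, P14
#' and P56 with 2, 5 and 5 animals respectively (both brain regions
#' sampled from each animal, so 12 samples per tissue), and a strand
#' misassignment rate of 3%, the upper bound reported for dUTP
#' libraries.  Sequencing depth is scaled down to desk size: the per-gene
#' baseline is a mean count, not a genome-wide read total.
#'
#' @param seed integer random seed; every generator derives its stream
#'   deterministically from it.
#' @param n_genes number of focal (sense) genes, default 50.
#' @param overlap_fraction fraction of focal genes given a nested
#'   opposite-strand blocker gene, default 0.3.
#' @param tissues profiled tissues.
#' @param ages ages in postnatal days.
#' @param replicates animals per age (recycled over tissues).
#' @param baseline_mean mean unique sense fragment count per gene and
#'   sample at the age midpoint, default 100.
#' @param dispersion negative-binomial dispersion (variance =
#'   \eqn{\mu + dispersion \mu^2}); 0 gives Poisson counts. Default 0.1.
#' @param antisense_frac fraction of focal genes with a real antisense
#'   contig, default 0.7.
#' @param artifact_frac fraction of focal genes given a spurious
#'   "strand-misassignment artifact" contig with antisense fraction well
#'   below the 3% low-pass threshold, default 0.15.
#' @param ratio_range range of designed antisense:total ratios for real
#'   contigs, default \code{c(0.05, 0.45)}.
#' @param enrich_frac fraction of real contigs with designed
#'   tissue-specific antisense enrichment, default 0.2.
#' @param enrich_factor fold enrichment of antisense expression in the
#'   favoured tissue, default 3.
#' @param negative_pair_frac fraction of real sense-antisense pairs with
#'   designed opposite slope signs, default 1/6.
#' @param fold_change designed expression fold change from P7 to P56,
#'   default 4.
#' @param misassignment_rate fraction of fragments with flipped mate
#'   orientation, default 0.03.
#' @param multimap_rate fraction of fragments reported with NH = 2,
#'   default 0.05.
#' @param read_len,frag_len read and fragment lengths in bp.
#' @param seq_id name of the simulated sequence.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_genes = 50L, overlap_fraction = 0.3,
                       tissues = c("mPFC", "striatum"),
                       ages = c(7, 14, 56), replicates = c(2L, 5L, 5L),
                       baseline_mean = 100, dispersion = 0.1,
                       antisense_frac = 0.7, artifact_frac = 0.15,
                       ratio_range = c(0.05, 0.45),
                       enrich_frac = 0.2, enrich_factor = 3,
                       negative_pair_frac = 1 / 6, fold_change = 4,
                       misassignment_rate = 0.03, multimap_rate = 0.05,
                       read_len = 80L, frag_len = 200L,
                       seq_id = "chr1") {
  cfg <- mget(names(formals()))
  stopifnot(n_genes >= 1, length(ages) == length(replicates),
            all(replicates >= 1))
  rates <- c(overlap_fraction = overlap_fraction,
             antisense_frac = antisense_frac,
             artifact_frac = artifact_frac,
             misassignment_rate = misassignment_rate,
             multimap_rate = multimap_rate)
  bad <- rates[rates < 0 | rates > 1]
  if (length(bad))
    ns_stop("rates must lie in [0, 1]: %s", paste(names(bad), collapse = ", "))
  structure(cfg, class = "sim_config")
}

# deterministic per-stage seed derivation (kept < 2^31)
stage_seed <- function(cfg, offset) {
  (as.integer(cfg$seed) %% 1000000L) * 1000L + offset
}

#' Sample sheet for the simulated design
#'
#' @param cfg a [sim_config()].
#' @return data.frame: \code{sample_id}, \code{tissue}, \code{age},
#'   \code{replicate}, \code{sex}.
#' @export
sim_samples <- function(cfg) {
  rows <- list()
  for (tn in cfg$tissues)
    for (i in seq_along(cfg$ages))
      for (r in seq_len(cfg$replicates[i]))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_P%d_r%d", tn, cfg$ages[i], r),
          tissue = tn, age = cfg$ages[i], replicate = r,
          sex = if (r %% 2L == 1L) "F" else "M",
          stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Simulate a gene annotation with opposite-strand overlaps
#'
#' Places \code{n_genes} focal genes along one sequence with random
#' lengths and gaps; a designed fraction of them receive a nested
#' opposite-strand blocker gene (biotype \code{lncRNA}), so their
#' overlap-free zones are strictly smaller than their spans.
#'
#' @param cfg a [sim_config()].
#' @return list with \code{annot} (a \code{genome_annotation}) and
#'   \code{truth} (data.table: \code{gene_id}, \code{role},
#'   \code{strand}, \code{overlapped}, \code{blocker_id}).
#' @export
simulate_annotation <- function(cfg) {
  set.seed(stage_seed(cfg, 101L))
  n <- cfg$n_genes
  widths <- as.integer(round(runif(n, 1500, 3500)))
  gaps <- as.integer(round(runif(n, 300, 800)))
  starts <- cumsum(c(1000L, head(widths + gaps, -1L)))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  n_over <- as.integer(round(cfg$overlap_fraction * n))
  overlapped <- rep(FALSE, n)
  if (n_over > 0) overlapped[sample.int(n, n_over)] <- TRUE

  gene_ids <- sprintf("gene%03d", seq_len(n))
  rows <- data.frame(
    seq_id = cfg$seq_id, start = starts, end = starts + widths - 1L,
    strand = strands, gene_id = gene_ids, biotype = "protein_coding",
    role = "focal", stringsAsFactors = FALSE)
  blk <- rows[overlapped, , drop = FALSE]
  blocker_id <- rep(NA_character_, n)
  if (nrow(blk)) {
    w <- blk$end - blk$start + 1L
    b_start <- blk$start + as.integer(round(w * runif(nrow(blk), 0.25, 0.4)))
    b_width <- as.integer(round(w * runif(nrow(blk), 0.15, 0.3)))
    b <- data.frame(
      seq_id = cfg$seq_id, start = b_start,
      end = pmin(b_start + b_width - 1L, blk$end - 50L),
      strand = ifelse(blk$strand == "+", "-", "+"),
      gene_id = sprintf("blk%03d", which(overlapped)),
      biotype = "lncRNA", role = "blocker", stringsAsFactors = FALSE)
    blocker_id[overlapped] <- b$gene_id
    rows <- rbind(rows, b)
  }
  feats <- GenomicRanges::GRanges(
    rows$seq_id, IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand, type = "gene", gene_id = rows$gene_id,
    gene_biotype = rows$biotype, transcript_id = NA_character_)
  truth <- data.table::data.table(
    gene_id = rows$gene_id, role = rows$role,
    strand = rows$strand,
    overlapped = c(overlapped, rep(NA, nrow(rows) - n)),
    blocker_id = c(blocker_id, rep(NA_character_, nrow(rows) - n)))
  list(annot = build_annotation(feats), truth = truth)
}

#' Simulate antisense contigs within overlap-free zones
#'
#' Gives a designed fraction of focal genes a real antisense contig (1-2
#' segments inside the gene's overlap-free zone, on the opposite strand)
#' and a further fraction a spurious artifact contig emulating strand
#' misassignment (very low designed antisense fraction).
#'
#' @param sim output of [simulate_annotation()].
#' @param cfg a [sim_config()].
#' @return list with \code{contigs} (list of [contig_record()]),
#'   \code{contig_map} (data.table \code{contig_id}, \code{gene_id},
#'   \code{type}) and \code{zones} (precomputed [overlap_free_zones()]).
#' @export
simulate_contigs <- function(sim, cfg) {
  set.seed(stage_seed(cfg, 202L))
  annot <- sim$annot
  focal <- sim$truth[role == "focal"]$gene_id
  zones <- overlap_free_zones(annot)
  n_real <- as.integer(round(cfg$antisense_frac * length(focal)))
  n_art <- as.integer(round(cfg$artifact_frac * length(focal)))
  pick <- sample(focal, min(length(focal), n_real + n_art))
  types <- rep(c("real", "artifact"), c(n_real, n_art))[seq_along(pick)]

  contigs <- list()
  map_rows <- list()
  for (i in seq_along(pick)) {
    g <- pick[i]
    z <- zones[[g]]
    if (!length(z)) next
    zi <- which.max(BiocGenerics::width(z))
    zs <- BiocGenerics::start(z)[zi]
    ze <- BiocGenerics::end(z)[zi]
    zw <- ze - zs + 1L
    n_seg <- if (zw > 1200L && runif(1) < 0.4) 2L else 1L
    seg_w <- as.integer(round(runif(n_seg, 250, max(300, zw / 3))))
    seg_w <- pmin(seg_w, as.integer(floor(zw / (2L * n_seg))))
    seg_w <- pmax(seg_w, 150L)
    if (n_seg == 2L) {
      s1 <- zs + as.integer(round(runif(1, 0, zw * 0.1)))
      s2 <- s1 + seg_w[1] + as.integer(round(runif(1, 50, 200)))
      starts <- c(s1, s2)
    } else {
      starts <- zs + as.integer(round(runif(1, 0, max(0, zw - seg_w[1] - 1))))
    }
    ends <- pmin(starts + seg_w - 1L, ze)
    if (any(ends < starts)) next
    gs <- as.character(BiocGenerics::strand(gene_span(annot, g)))
    ct_id <- sprintf("ctg_%s", g)
    contigs[[length(contigs) + 1L]] <- contig_record(
      contig_id = ct_id, gene_id = g, seq_id = cfg$seq_id,
      strand = if (gs == "+") "-" else "+",
      seg_starts = starts, seg_ends = ends)
    map_rows[[length(map_rows) + 1L]] <- data.table::data.table(
      contig_id = ct_id, gene_id = g, type = types[i])
  }
  list(contigs = contigs,
       contig_map = if (length(map_rows)) data.table::rbindlist(map_rows)
                    else data.table::data.table(contig_id = character(0),
                                                gene_id = character(0),
                                                type = character(0)),
       zones = zones)
}

#' Simulate the per-gene expression design
#'
#' Draws, per focal gene, a baseline mean and a designed developmental
#' slope sign, and per contig a designed antisense:total ratio, slope
#' sign (concordant with the gene except for a designed fraction of
#' negative pairs) and tissue enrichment factor.  Artifact contigs get
#' antisense fractions of 0.5-1.5%, emulating strand misassignment and
#' designed to fall under the 3% low-pass filter.
#'
#' @param cfg a [sim_config()].
#' @param gene_ids focal gene identifiers.
#' @param contig_map data.table with \code{contig_id}, \code{gene_id},
#'   \code{type} (\code{"real"}/\code{"artifact"}).
#' @return list of two data.tables, \code{genes} (\code{gene_id},
#'   \code{baseline}, \code{sense_slope}) and \code{contigs}
#'   (\code{contig_id}, \code{gene_id}, \code{type}, \code{ratio},
#'   \code{anti_slope}, \code{anti_mpfc_factor}, \code{designed_class}).
#' @export
simulate_design <- function(cfg, gene_ids, contig_map) {
  set.seed(stage_seed(cfg, 303L))
  beta <- log(cfg$fold_change) / (max(cfg$ages) - min(cfg$ages))
  genes <- data.table::data.table(
    gene_id = gene_ids,
    baseline = cfg$baseline_mean * exp(stats::rnorm(length(gene_ids), 0, 0.4)),
    sense_slope = sample(c(-1, 1), length(gene_ids), replace = TRUE) * beta)
  cm <- data.table::as.data.table(contig_map)
  n <- nrow(cm)
  if (!n)
    return(list(genes = genes,
                contigs = data.table::data.table(
                  contig_id = character(0), gene_id = character(0),
                  type = character(0), ratio = numeric(0),
                  anti_slope = numeric(0), anti_mpfc_factor = numeric(0),
                  designed_class = character(0))))
  gidx <- match(cm$gene_id, genes$gene_id)
  real <- cm$type == "real"
  ratio <- numeric(n)
  ratio[real] <- runif(sum(real), cfg$ratio_range[1], cfg$ratio_range[2])
  ratio[!real] <- runif(sum(!real), 0.005, 0.015)
  concord <- runif(n) >= cfg$negative_pair_frac
  anti_slope <- ifelse(concord, 1, -1) * sign(genes$sense_slope[gidx]) * beta
  enriched <- real & runif(n) < cfg$enrich_frac
  mpfc_side <- runif(n) < 0.5
  anti_mpfc_factor <- ifelse(enriched,
                             ifelse(mpfc_side, cfg$enrich_factor,
                                    1 / cfg$enrich_factor), 1)
  contigs <- data.table::data.table(
    contig_id = cm$contig_id, gene_id = cm$gene_id, type = cm$type,
    ratio = ratio, anti_slope = anti_slope,
    anti_mpfc_factor = anti_mpfc_factor,
    designed_class = ifelse(concord, "positive", "negative"))
  list(genes = genes, contigs = contigs)
}

# expected mean matrices (genes x samples, contigs x samples) under the
# log-linear design; exported for tests via truth
design_means <- function(design, samples, cfg) {
  age_c <- mean(cfg$ages)
  ages <- as.numeric(samples$age)
  g <- design$genes
  mu_s <- outer(seq_len(nrow(g)), seq_len(nrow(samples)),
                function(i, j) g$baseline[i] *
                  exp(g$sense_slope[i] * (ages[j] - age_c)))
  dimnames(mu_s) <- list(g$gene_id, samples$sample_id)
  ct <- design$contigs
  mu_a <- matrix(0, nrow(ct), nrow(samples),
                 dimnames = list(ct$contig_id, samples$sample_id))
  if (nrow(ct)) {
    gidx <- match(ct$gene_id, g$gene_id)
    for (i in seq_len(nrow(ct))) {
      tf <- ifelse(samples$tissue == "mPFC", ct$anti_mpfc_factor[i], 1)
      mu_a[i, ] <- g$baseline[gidx[i]] *
        ct$ratio[i] / (1 - ct$ratio[i]) * tf *
        exp(ct$anti_slope[i] * (ages - age_c))
    }
  }
  list(sense = mu_s, antisense = mu_a)
}

#' Simulate negative-binomial count matrices
#'
#' Draws unique-read counts for every (feature, sample) from a negative
#' binomial with the design's log-linear mean structure and the
#' configured dispersion (Poisson when dispersion is 0).  Cognate contig
#' means are \eqn{r/(1-r)} times the gene mean so that the expected
#' antisense:total ratio equals the designed ratio \eqn{r}.
#'
#' @param cfg a [sim_config()].
#' @param design output of [simulate_design()].
#' @param samples sample sheet from [sim_samples()]; default derived from
#'   \code{cfg}.
#' @return list with \code{sense} and \code{antisense}
#'   [count_matrix()] objects and \code{means} (the designed mean
#'   matrices).
#' @export
simulate_count_matrices <- function(cfg, design, samples = NULL) {
  if (is.null(samples)) samples <- sim_samples(cfg)
  set.seed(stage_seed(cfg, 404L))
  mu <- design_means(design, samples, cfg)
  draw <- function(m) {
    x <- if (cfg$dispersion <= 0) stats::rpois(length(m), lambda = m)
         else rnbinom(length(m), mu = m, size = 1 / cfg$dispersion)
    matrix(as.integer(x), nrow(m), ncol(m), dimnames = dimnames(m))
  }
  list(sense = count_matrix(draw(mu$sense), samples, "sense_gene"),
       antisense = count_matrix(draw(mu$antisense), samples,
                                "antisense_contig"),
       means = mu)
}

#' Simulate stranded paired-end SAM files with ground truth
#'
#' For every sample, draws per-feature fragment counts from the design
#' and emits dUTP-protocol (RF) read pairs: sense fragments uniformly
#' within the gene span on the gene strand, antisense fragments within
#' contig segments on the opposite strand.  A configured fraction of
#' fragments have both mate orientations flipped (strand misassignment,
#' the failure mode of dUTP chemistry) and a further fraction carry
#' \code{NH:i:2} (multi-mappers, excluded from unique counting).
#'
#' @param sim output of [simulate_annotation()].
#' @param contig_sim output of [simulate_contigs()].
#' @param design output of [simulate_design()].
#' @param cfg a [sim_config()].
#' @param samples sample sheet; default [sim_samples()].
#' @return list with \code{sam} (named list of character vectors, the SAM
#'   lines per sample) and \code{truth} (data.table per fragment:
#'   \code{qname}, \code{sample_id}, \code{gene_id}, \code{contig_id},
#'   \code{orientation_true}, \code{misassigned}, \code{unique}).
#' @export
simulate_fragments <- function(sim, contig_sim, design, cfg,
                               samples = NULL) {
  if (is.null(samples)) samples <- sim_samples(cfg)
  annot <- sim$annot
  mu <- design_means(design, samples, cfg)
  spans <- annot$genes
  seq_len_total <- max(BiocGenerics::end(spans)) + 1000L
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", cfg$seq_id, seq_len_total))
  seg_by_contig <- lapply(contig_sim$contigs, function(ct) ct$segments)
  names(seg_by_contig) <- vapply(contig_sim$contigs, `[[`, character(1),
                                 "contig_id")
  gene_strand <- setNames(as.character(BiocGenerics::strand(spans)),
                          spans$gene_id)
  gene_start <- setNames(BiocGenerics::start(spans), spans$gene_id)
  gene_end <- setNames(BiocGenerics::end(spans), spans$gene_id)

  sams <- list()
  truths <- list()
  for (si in seq_len(nrow(samples))) {
    set.seed(stage_seed(cfg, 505L) + si)
    sid <- samples$sample_id[si]
    frags <- list()
    # sense fragments per focal gene
    for (g in design$genes$gene_id) {
      n_f <- draw_count(mu$sense[g, sid], cfg$dispersion)
      if (n_f > 0)
        frags[[length(frags) + 1L]] <- place_fragments(
          n_f, gene_start[g], gene_end[g], cfg$frag_len,
          gene_id = g, contig_id = NA_character_,
          strand = gene_strand[g], orientation = "sense")
    }
    # antisense fragments within contig segments
    for (i in seq_len(nrow(design$contigs))) {
      ct <- design$contigs$contig_id[i]
      g <- design$contigs$gene_id[i]
      segs <- seg_by_contig[[ct]]
      if (is.null(segs)) next
      n_f <- draw_count(mu$antisense[ct, sid], cfg$dispersion)
      if (n_f <= 0) next
      wts <- IRanges::width(segs)
      pick <- sample.int(length(segs), n_f, replace = TRUE,
                         prob = wts / sum(wts))
      anti_strand <- if (gene_strand[g] == "+") "-" else "+"
      for (k in seq_along(segs)) {
        nk <- sum(pick == k)
        if (nk > 0)
          frags[[length(frags) + 1L]] <- place_fragments(
            nk, IRanges::start(segs)[k], IRanges::end(segs)[k],
            cfg$frag_len, gene_id = g, contig_id = ct,
            strand = anti_strand, orientation = "antisense")
      }
    }
    fr <- data.table::rbindlist(frags)
    if (!nrow(fr)) {
      sams[[sid]] <- header
      next
    }
    fr[, qname := sprintf("frag_%s_%06d", sid, seq_len(.N))]
    fr[, misassigned := runif(.N) < cfg$misassignment_rate]
    fr[, nh := data.table::fifelse(runif(.N) < cfg$multimap_rate, 2L, 1L)]
    fr[, emitted_strand := data.table::fifelse(
      misassigned, data.table::fifelse(strand == "+", "-", "+"), strand)]
    sams[[sid]] <- c(header, sam_pair_lines(fr, cfg))
    fr[, sample_id := sid]
    truths[[sid]] <- fr[, .(qname, sample_id, gene_id, contig_id,
                            orientation_true = orientation,
                            misassigned, unique = nh == 1L)]
  }
  list(sam = sams,
       truth = if (length(truths)) data.table::rbindlist(truths)
               else data.table::data.table())
}

draw_count <- function(mu, dispersion) {
  if (dispersion <= 0) stats::rpois(1L, mu)
  else rnbinom(1L, mu = mu, size = 1 / dispersion)
}

# uniform fragment placement within [lo, hi]; fragments clipped to fit
place_fragments <- function(n, lo, hi, frag_len, gene_id, contig_id,
                            strand, orientation) {
  w <- hi - lo + 1L
  fl <- min(frag_len, w)
  starts <- lo + as.integer(floor(runif(n, 0, max(1, w - fl + 1)) ))
  data.table::data.table(
    gene_id = gene_id, contig_id = contig_id,
    f_start = starts, f_end = starts + fl - 1L,
    strand = strand, orientation = orientation)
}

# emit two SAM lines per fragment under the RF protocol:
# forward-aligned mate at the left end, reverse-aligned mate at the
# right end; for a "+" fragment the forward mate is read2, for "-" read1.
sam_pair_lines <- function(fr, cfg) {
  rl <- cfg$read_len
  left_pos <- fr$f_start
  right_pos <- pmax(fr$f_end - rl + 1L, fr$f_start)
  len_left <- pmin(rl, fr$f_end - fr$f_start + 1L)
  plus <- fr$emitted_strand == "+"
  # FLAG bits: 1 paired, 2 proper, 16 self reverse, 32 mate reverse,
  # 64 read1, 128 read2
  fwd_flag <- 1L + 2L + 32L + ifelse(plus, 128L, 64L)
  rev_flag <- 1L + 2L + 16L + ifelse(plus, 64L, 128L)
  cig <- sprintf("%dM", len_left)
  tag <- sprintf("NH:i:%d", fr$nh)
  tlen <- fr$f_end - fr$f_start + 1L
  l1 <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t=\t%d\t%d\t*\t*\t%s",
                fr$qname, fwd_flag, cfg$seq_id, left_pos, cig,
                right_pos, tlen, tag)
  l2 <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t=\t%d\t%d\t*\t*\t%s",
                fr$qname, rev_flag, cfg$seq_id, right_pos, cig,
                left_pos, -tlen, tag)
  as.vector(rbind(l1, l2))
}

#' Simulate BLAST hit tables with planted outcomes
#'
#' Builds outfmt-6-style hit tables in which planted-valid contigs
#' receive HSP sets with union query coverage >= 96% at identity >= 99%,
#' planted-conserved contigs receive > 90%/> 90% hits against the second
#' genome, and everything else receives sub-threshold hits, including
#' near-boundary decoys at exactly 90.0% coverage and 90.0% identity
#' (which must never be called conserved under the strict thresholds).
#' Planted lncRNA mappings get > 95% coverage at >= 99% identity, with a
#' decoy at exactly 95.0% coverage.
#'
#' @param contigs list of [contig_record()] objects.
#' @param cfg a [sim_config()].
#' @param planted_valid contig ids that must pass [self_validate()].
#' @param planted_conserved contig ids that must pass
#'   [conservation_filter()].
#' @param planted_lncrna named character vector: names are contig ids,
#'   values known-lncRNA ids they must map to.
#' @return list of data.tables \code{self}, \code{second_genome} and
#'   \code{lncrna}, each in [parse_blast_tab()] layout, plus
#'   \code{truth} (per contig: planted flags).
#' @export
simulate_blast_hits <- function(contigs, cfg, planted_valid,
                                planted_conserved,
                                planted_lncrna = character(0)) {
  set.seed(stage_seed(cfg, 606L))
  ids <- vapply(contigs, `[[`, character(1), "contig_id")
  qlen <- setNames(vapply(contigs, `[[`, numeric(1), "length"), ids)

  self_rows <- list()
  for (ct in ids) {
    ql <- as.integer(qlen[ct])
    if (ct %in% planted_valid) {
      cov <- runif(1, 96, 100)
      idn <- runif(1, 99.0, 100)
      self_rows[[ct]] <- make_hsps(ct, cfg$seq_id, ql, cov, idn,
                                   split = runif(1) < 0.5)
    } else if (runif(1) < 0.5) {
      cov <- runif(1, 40, 90)
      idn <- runif(1, 99, 100)
      self_rows[[ct]] <- make_hsps(ct, cfg$seq_id, ql, cov, idn)
    } else {
      cov <- runif(1, 96, 100)
      idn <- runif(1, 90, 98.5)
      self_rows[[ct]] <- make_hsps(ct, cfg$seq_id, ql, cov, idn)
    }
  }
  human_rows <- list()
  decoys <- setdiff(ids, planted_conserved)
  exact_decoys <- head(decoys, 2L)
  for (ct in ids) {
    ql <- as.integer(qlen[ct])
    if (ct %in% planted_conserved) {
      cov <- runif(1, 91, 99)
      idn <- runif(1, 91, 99)
      human_rows[[ct]] <- make_hsps(ct, "hchr1", ql, cov, idn,
                                    split = runif(1) < 0.5)
    } else if (ct %in% exact_decoys) {
      # boundary decoy: exactly 90.0 coverage and 90.0 identity
      human_rows[[ct]] <- make_hsps(ct, "hchr1", ql, 90, 90, exact = TRUE)
    } else if (runif(1) < 0.7) {
      cov <- runif(1, 30, 89.9)
      idn <- runif(1, 70, 95)
      human_rows[[ct]] <- make_hsps(ct, "hchr1", ql, cov, idn)
    }
  }
  lnc_rows <- list()
  for (ct in names(planted_lncrna)) {
    ql <- as.integer(qlen[ct])
    lnc_rows[[ct]] <- make_hsps(ct, planted_lncrna[[ct]], ql,
                                runif(1, 96, 99.5), runif(1, 99, 100))
  }
  if (length(ids) && length(planted_lncrna) < length(ids)) {
    ct <- setdiff(ids, names(planted_lncrna))[1L]
    # decoy at exactly 95.0 coverage: must NOT map (strict > 95)
    lnc_rows[[paste0(ct, "_decoy")]] <-
      make_hsps(ct, "lnc_decoy", as.integer(qlen[ct]), 95, 99.5,
                exact = TRUE)
  }
  truth <- data.table::data.table(
    contig_id = ids,
    planted_valid = ids %in% planted_valid,
    planted_conserved = ids %in% planted_conserved)
  list(self = bind_hits(self_rows), second_genome = bind_hits(human_rows),
       lncrna = bind_hits(lnc_rows), truth = truth)
}

# build 1-2 HSP rows on one subject reaching the target union coverage
# and weighted identity.  Coverage is floored to whole bases so a decoy
# targeted at a strict-threshold boundary (exact = TRUE) can never land
# above its stated percent.
make_hsps <- function(qid, sid, qlen, cov_pct, ident, split = FALSE,
                      exact = FALSE) {
  covered <- max(1L, as.integer(floor(qlen * cov_pct / 100)))
  covered <- min(covered, qlen)
  mk <- function(qs, qe, idn) {
    len <- qe - qs + 1L
    ss <- as.integer(round(runif(1, 1e4, 9e5)))
    rev <- runif(1) < 0.3
    data.table::data.table(
      qid = qid, sid = sid, pident = round(idn, 2), length = len,
      qstart = qs, qend = qe,
      sstart = if (rev) ss + len - 1L else ss,
      send = if (rev) ss else ss + len - 1L,
      sstrand = if (rev) "-" else "+",
      evalue = 1e-30, bitscore = round(2 * len + runif(1, 0, 10), 1),
      qlen = qlen)
  }
  if (!split || covered < 60L) {
    rows <- mk(1L, covered, ident)
  } else {
    # two overlapping HSPs whose union is [1, covered]
    cut <- as.integer(floor(covered * runif(1, 0.4, 0.6)))
    ovl <- as.integer(floor(min(cut, covered - cut) * runif(1, 0.1, 0.5)))
    rows <- rbind(mk(1L, cut, ident), mk(cut - ovl + 1L, covered, ident))
  }
  rows
}

bind_hits <- function(rows) {
  if (!length(rows)) {
    out <- data.table::data.table(
      qid = character(0), sid = character(0), pident = numeric(0),
      length = integer(0), qstart = integer(0), qend = integer(0),
      sstart = integer(0), send = integer(0), sstrand = character(0),
      evalue = numeric(0), bitscore = numeric(0), qlen = integer(0))
  } else out <- data.table::rbindlist(rows)
  data.table::setkey(out, qid)
  out[]
}

#' Write a hit table as BLAST outfmt 6 text (13 columns incl. qlen)
#'
#' @param hits hit table in [parse_blast_tab()] layout.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  hits <- data.table::as.data.table(hits)
  out <- hits[, .(qid, sid, pident, length, mismatch = 0L, gapopen = 0L,
                  qstart, qend,
                  sstart = data.table::fifelse(sstrand == "-", send, sstart),
                  send = data.table::fifelse(sstrand == "-", sstart, send),
                  evalue, bitscore, qlen)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write an annotation as GTF
#'
#' One \code{gene} feature line per gene; 1-based closed coordinates.
#'
#' @param annot a \code{genome_annotation}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_annotation_gtf <- function(annot, path) {
  g <- annot$genes
  lines <- sprintf(
    "%s\tnatscan\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
    as.character(GenomeInfoDb::seqnames(g)), BiocGenerics::start(g),
    BiocGenerics::end(g), as.character(BiocGenerics::strand(g)),
    g$gene_id, g$biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs every generator with one configuration and writes all pipeline
#' inputs under one directory: \code{annotation.gtf},
#' \code{contigs.gtf}, \code{sample_sheet.tsv}, per-sample SAM files
#' under \code{sam/}, \code{self_blast.tsv}, \code{human_blast.tsv},
#' \code{lncrna_blast.tsv}, \code{gene_list.txt} and truth tables under
#' \code{truth/}.  All outputs are deterministic in \code{cfg$seed}.
#'
#' Planted outcomes: all real contigs are planted valid (genome
#' self-validation) and a deterministic half of them planted conserved;
#' artifact contigs are planted invalid for conservation and carry
#' designed antisense fractions below the low-pass threshold.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible list with all in-memory objects (\code{annot},
#'   \code{contigs}, \code{contig_map}, \code{design}, \code{samples},
#'   \code{truth}, \code{hits}, \code{paths}).
#' @export
simulate_dataset <- function(cfg, out_dir) {
  dir.create(file.path(out_dir, "sam"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  sim <- simulate_annotation(cfg)
  csim <- simulate_contigs(sim, cfg)
  focal <- sim$truth[role == "focal"]$gene_id
  # blocker genes are expressed too: their sense reads are exactly the
  # opposite-strand signal the overlap-free zones must shield against
  design <- simulate_design(cfg, sim$truth$gene_id, csim$contig_map)
  samples <- sim_samples(cfg)
  frag <- simulate_fragments(sim, csim, design, cfg, samples)

  real_ids <- csim$contig_map[type == "real"]$contig_id
  planted_conserved <- real_ids[seq_along(real_ids) %% 2L == 1L]
  lnc_targets <- real_ids[seq_along(real_ids) %% 3L == 1L]
  planted_lncrna <- setNames(sprintf("lnc_%03d", seq_along(lnc_targets)),
                             lnc_targets)
  hits <- simulate_blast_hits(csim$contigs, cfg,
                              planted_valid = csim$contig_map$contig_id,
                              planted_conserved = planted_conserved,
                              planted_lncrna = planted_lncrna)

  p <- list(
    annotation = file.path(out_dir, "annotation.gtf"),
    contigs = file.path(out_dir, "contigs.gtf"),
    sample_sheet = file.path(out_dir, "sample_sheet.tsv"),
    self_blast = file.path(out_dir, "self_blast.tsv"),
    human_blast = file.path(out_dir, "human_blast.tsv"),
    lncrna_blast = file.path(out_dir, "lncrna_blast.tsv"),
    gene_list = file.path(out_dir, "gene_list.txt"))
  write_annotation_gtf(sim$annot, p$annotation)
  write_contig_gtf(csim$contigs, p$contigs, annot = sim$annot)
  sheet <- samples
  sheet$sam_path <- file.path(out_dir, "sam",
                              paste0(sheet$sample_id, ".sam"))
  for (sid in names(frag$sam))
    writeLines(frag$sam[[sid]],
               file.path(out_dir, "sam", paste0(sid, ".sam")))
  data.table::fwrite(sheet, p$sample_sheet, sep = "\t", quote = FALSE)
  write_blast_tab(hits$self, p$self_blast)
  write_blast_tab(hits$second_genome, p$human_blast)
  write_blast_tab(hits$lncrna, p$lncrna_blast)
  # gene list of interest: every focal gene with a contig plus a few
  # without, mimicking a curated risk-gene list
  with_ct <- unique(csim$contig_map$gene_id)
  without <- setdiff(focal, with_ct)
  writeLines(sort(c(with_ct, head(without, 5L))), p$gene_list)
  data.table::fwrite(frag$truth, file.path(out_dir, "truth",
                                           "fragments.tsv"), sep = "\t")
  data.table::fwrite(csim$contig_map, file.path(out_dir, "truth",
                                                "contigs.tsv"), sep = "\t")
  data.table::fwrite(hits$truth, file.path(out_dir, "truth",
                                           "blast.tsv"), sep = "\t")
  write_report_tsv(design$genes, file.path(out_dir, "truth",
                                           "design_genes.tsv"))
  write_report_tsv(design$contigs, file.path(out_dir, "truth",
                                             "design_contigs.tsv"))
  invisible(list(annot = sim$annot, annot_truth = sim$truth,
                 contigs = csim$contigs, contig_map = csim$contig_map,
                 zones = csim$zones, design = design, samples = samples,
                 truth = frag$truth, hits = hits, paths = p))
}
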