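#' Fit a developmental linear model for one feature
#'
#' Ordinary least squares of normalized expression on age in days, with
#' the model F-test deciding significance (for simple regression this
#' equals the slope t-test).  The fit is first attempted on all three ages
#' (P7, P14, P56); when that F-test fails at \code{alpha}, a fallback fit
#' using only the two later ages is attempted — early postnatal samples
#' often break an otherwise clean later-age linear trend.  The slope is
#' taken from whichever fit was final; \code{fit_ok} is \code{TRUE} iff
#' the final F-test p-value is below \code{alpha}.
#'
#' Degenerate inputs (all values identical, fewer than 2 distinct ages,
#' fewer than 3 points) yield an unfit result with an undefined p-value.
#'
#' @param values normalized counts, one per sample.
#' @param ages ages in days, parallel to \code{values}.
#' @param alpha F-test significance level (default 0.05).
#' @param fallback_ages ages retained for the fallback fit
#'   (default \code{c(14, 56)}); \code{NULL} disables the fallback, which
#'   is what calibration studies of the plain F-test should use.
#' @param feature_id,tissue optional labels carried into the result.
#' @return an object of class \code{linear_fit}: \code{feature_id},
#'   \code{tissue}, \code{slope} (normalized counts per day),
#'   \code{intercept}, \code{f_pvalue}, \code{n_points},
#'   \code{used_fallback}, \code{fit_ok}.
#' @export
fit_linear_model <- function(values, ages, alpha = 0.05,
                             fallback_ages = c(14, 56),
                             feature_id = NA_character_,
                             tissue = NA_character_) {
  if (length(values) != length(ages))
    ns_stop("values and ages must have equal length")
  res <- ols_ftest(values, ages)
  used_fallback <- FALSE
  if (!is.null(fallback_ages) && !isTRUE(res$f_pvalue < alpha) &&
      length(unique(ages)) > length(unique(fallback_ages))) {
    keep <- ages %in% fallback_ages
    fb <- ols_ftest(values[keep], ages[keep])
    if (fb$valid) {
      res <- fb
      used_fallback <- TRUE
    }
  }
  structure(list(feature_id = feature_id, tissue = tissue,
                 slope = res$slope, intercept = res$intercept,
                 f_pvalue = res$f_pvalue, n_points = res$n,
                 used_fallback = used_fallback,
                 fit_ok = isTRUE(res$f_pvalue < alpha)),
            class = "linear_fit")
}

# OLS of y on x with model F-test p; valid FALSE when the design is
# degenerate (<3 points, <2 distinct ages, or zero variance in y)
ols_ftest <- function(y, x) {
  n <- length(y)
  if (n < 3L || length(unique(x)) < 2L)
    return(list(slope = NA_real_, intercept = NA_real_,
                f_pvalue = NA_real_, n = n, valid = FALSE))
  if (length(unique(y)) == 1L)
    return(list(slope = 0, intercept = y[1], f_pvalue = NA_real_,
                n = n, valid = FALSE))
  fit <- lm(y ~ x)
  # a perfect fit makes summary.lm warn about unreliability; the F
  # statistic still degenerates to the right limit (p -> 0)
  fs <- suppressWarnings(summary(fit))$fstatistic
  p <- if (is.null(fs)) NA_real_ else
    unname(pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
  co <- coef(fit)
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       f_pvalue = p, n = n, valid = TRUE)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "linear_fit %s [%s]: slope %.4g, F p %.3g, n %d%s -> %s\n",
    x$feature_id, x$tissue, x$slope, x$f_pvalue, x$n_points,
    if (x$used_fallback) " (fallback)" else "",
    if (x$fit_ok) "fit_ok" else "unfit"))
  invisible(x)
}

#' Classify a sense-antisense pair by slope sign
#'
#' A pair is \code{positive} when the developmental slopes of the gene and
#' its antisense contig have the same sign (both rising or both falling),
#' \code{negative} when the signs differ, \code{flat} when either slope is
#' exactly zero, and \code{unfit} when either linear model failed its
#' F-test.
#'
#' @param gene_fit,contig_fit [fit_linear_model()] results from the same
#'   tissue.
#' @return one of \code{"positive"}, \code{"negative"}, \code{"flat"},
#'   \code{"unfit"}.
#' @export
classify_pair <- function(gene_fit, contig_fit) {
  if (!is.na(gene_fit$tissue) && !is.na(contig_fit$tissue) &&
      gene_fit$tissue != contig_fit$tissue)
    ns_stop("classify_pair: tissue mismatch (%s vs %s)",
            gene_fit$tissue, contig_fit$tissue)
  if (!gene_fit$fit_ok || !contig_fit$fit_ok) return("unfit")
  if (gene_fit$slope == 0 || contig_fit$slope == 0) return("flat")
  if (sign(gene_fit$slope) == sign(contig_fit$slope)) "positive"
  else "negative"
}

#' Fit and classify all sense-antisense pairs per tissue
#'
#' For every (gene, cognate contig) pair and every tissue, fits the gene
#' and the contig developmental models independently (each with its own
#' fallback) on library-size-normalized counts and classifies the pair by
#' slope-sign concordance.
#'
#' @param sense_norm,anti_norm normalized [count_matrix()] objects.
#' @param contig_map data.frame with \code{contig_id}, \code{gene_id}.
#' @param alpha F-test significance level.
#' @param fallback_ages see [fit_linear_model()].
#' @return a \code{data.table}: \code{gene_id}, \code{contig_id},
#'   \code{tissue}, \code{gene_slope}, \code{contig_slope}, \code{gene_p},
#'   \code{contig_p}, \code{gene_fallback}, \code{contig_fallback},
#'   \code{klass}.
#' @export
fit_pairs <- function(sense_norm, anti_norm, contig_map, alpha = 0.05,
                      fallback_ages = c(14, 56)) {
  contig_map <- as.data.frame(contig_map)
  contig_map <- contig_map[contig_map$contig_id %in%
                             rownames(anti_norm$counts) &
                           contig_map$gene_id %in%
                             rownames(sense_norm$counts), , drop = FALSE]
  tissues <- unique(sense_norm$samples$tissue)
  rows <- list()
  fit_cache <- new.env(parent = emptyenv())
  get_fit <- function(mat, meta, fid, tn) {
    key <- paste(fid, tn, sep = "\r")
    if (!is.null(fit_cache[[key]])) return(fit_cache[[key]])
    sel <- meta$tissue == tn
    ft <- fit_linear_model(mat[fid, sel], as.numeric(meta$age[sel]),
                           alpha = alpha, fallback_ages = fallback_ages,
                           feature_id = fid, tissue = tn)
    fit_cache[[key]] <- ft
    ft
  }
  for (tn in tissues) {
    for (i in seq_len(nrow(contig_map))) {
      g <- contig_map$gene_id[i]
      ct <- contig_map$contig_id[i]
      gf <- get_fit(sense_norm$counts, sense_norm$samples, g, tn)
      cf <- get_fit(anti_norm$counts, anti_norm$samples, ct, tn)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene_id = g, contig_id = ct, tissue = tn,
        gene_slope = gf$slope, contig_slope = cf$slope,
        gene_p = gf$f_pvalue, contig_p = cf$f_pvalue,
        gene_fallback = gf$used_fallback,
        contig_fallback = cf$used_fallback,
        klass = classify_pair(gf, cf))
    }
  }
  if (!length(rows))
    return(data.table::data.table(
      gene_id = character(0), contig_id = character(0),
      tissue = character(0), gene_slope = numeric(0),
      contig_slope = numeric(0), gene_p = numeric(0),
      contig_p = numeric(0), gene_fallback = logical(0),
      contig_fallback = logical(0), klass = character(0)))
  data.table::rbindlist(rows)
}

#' Tally pair classifications per tissue
#'
#' @param pairs output of [fit_pairs()] (or any table with \code{tissue}
#'   and \code{klass}).
#' @return a \code{data.table} with one row per tissue and columns
#'   \code{positive}, \code{negative}, \code{flat}, \code{unfit};
#'   rows sum to the number of input pairs per tissue.
#' @export
summarize_quadrants <- function(pairs) {
  classes <- c("positive", "negative", "flat", "unfit")
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) {
    out <- data.table::data.table(tissue = character(0))
    for (k in classes) out[, (k) := integer(0)]
    return(out[])
  }
  tab <- table(factor(pairs$tissue),
               factor(pairs$klass, levels = classes))
  out <- data.table::data.table(tissue = rownames(tab))
  for (k in classes) out[, (k) := as.integer(tab[, k])]
  out[]
}
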