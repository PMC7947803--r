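#' @importFrom data.table data.table fread fwrite setDT setnames := .N .SD
#' @importFrom stats rnbinom runif rbinom lm pf coef setNames anova
#' @importFrom utils head tail
NULL

# internal: stop with a consistent prefix so callers can grep stage errors
ns_stop <- function(...) stop(sprintf(...), call. = FALSE)

ns_warn <- function(...) warning(sprintf(...), call. = FALSE)

# format a numeric column deterministically for report files (criterion:
# byte-identical reruns).  15 significant digits round-trips doubles while
# avoiding platform-dependent trailing noise.
ns_num <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  out[is.na(x)] <- "NA"
  out
}

# write a data.frame as TSV with deterministic formatting
write_report_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- ns_num(df[[j]])
  }
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA",
                     eol = "\n")
  invisible(path)
}
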