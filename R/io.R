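#' @name io-tables
#' @title Readers and writers for the pipeline's TSV schemas
#'
#' @description All interchange is plain UTF-8 TSV with a header row and
#' decimal points. Residual concentrations written as "ND" (below
#' detection) are parsed as 0 with the nitrogen detection limit (1.9 mg
#' N/l) attached as the attribute `detection_limit_N`. Every writer output
#' re-parses under its own reader (format closure).
#'
#' Schemas:
#' * feed: `condition`, `decanoate_g_per_l`, `nh4cl_g_per_l`
#' * steady state: `condition`, (`replicate`,) `D_per_h`, `cdw_g_per_l`,
#'   `cdw_sd`, `pha_pct_cdw`, `pha_sd`, `resid_C_g_per_l`,
#'   `resid_N_g_per_l`, `molpct_C6`, `molpct_C8`, `molpct_C10`
#' * trace: `time_h`, `od600`, `dO2_pct`, `co2_frac`, `o2_frac`
#' * metabolite peaks: `sample_id`, `rt_min`, `area`, `spectrum`
#'   (semicolon-joined `mz:intensity` pairs)
#' * alkane ladder: `n`, `rt_min`
NULL

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("%s (%s): missing column(s) %s", what, path,
          paste(missing, collapse = ", "))
  df
}

#' @rdname io-tables
#' @param path file path.
#' @return `read_feed_table`: data frame with the feed schema.
#' @export
read_feed_table <- function(path) {
  df <- read_tsv_checked(path, c("condition", "decanoate_g_per_l",
                                 "nh4cl_g_per_l"), "feed table")
  if (any(df$decanoate_g_per_l < 0) || any(df$nh4cl_g_per_l < 0))
    stopf("feed table (%s): concentrations must be >= 0", path)
  df
}

#' @rdname io-tables
#' @param df data frame to write.
#' @export
write_feed_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_nd <- function(x, path, col) {
  if (is.numeric(x)) return(x)
  nd <- toupper(trimws(x)) %in% c("ND", "N.D.", "NA")
  out <- suppressWarnings(as.numeric(x))
  out[nd] <- 0
  bad <- which(is.na(out))
  if (length(bad))
    stopf("steady-state table (%s): non-numeric value '%s' in column %s, line %d",
          path, x[bad[1]], col, bad[1] + 1)
  out
}

#' @rdname io-tables
#' @return `read_steadystate_table`: data frame with numeric residual
#'   columns ("ND" parsed as 0) and attribute `detection_limit_N` (g N/l).
#' @export
read_steadystate_table <- function(path) {
  req <- c("condition", "D_per_h", "cdw_g_per_l", "pha_pct_cdw",
           "resid_C_g_per_l", "resid_N_g_per_l",
           "molpct_C6", "molpct_C8", "molpct_C10")
  df <- read_tsv_checked(path, req, "steady-state table")
  df$resid_C_g_per_l <- parse_nd(df$resid_C_g_per_l, path, "resid_C_g_per_l")
  df$resid_N_g_per_l <- parse_nd(df$resid_N_g_per_l, path, "resid_N_g_per_l")
  attr(df, "detection_limit_N") <- N_DETECTION_LIMIT
  df
}

#' @rdname io-tables
#' @export
write_steadystate_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io-tables
#' @param gas_flow,culture_volume reactor metadata attached to the trace.
#' @export
read_trace_table <- function(path, gas_flow = 1, culture_volume = 0.8) {
  df <- read_tsv_checked(path, c("time_h", "od600", "dO2_pct", "co2_frac",
                                 "o2_frac"), "trace table")
  chemostat_trace(df$time_h, df$od600, df$dO2_pct, df$co2_frac, df$o2_frac,
                  gas_flow = gas_flow, culture_volume = culture_volume)
}

#' @rdname io-tables
#' @param trace a [chemostat_trace()].
#' @export
write_trace_table <- function(trace, path) {
  df <- data.frame(time_h = trace$time_h, od600 = trace$od600,
                   dO2_pct = trace$dissolved_o2, co2_frac = trace$co2_frac,
                   o2_frac = trace$o2_frac)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse / format a centroided spectrum string
#'
#' Spectra travel in TSV cells as semicolon-joined `mz:intensity` pairs.
#'
#' @param s spectrum string.
#' @return `parse_spectrum`: named numeric vector (names = m/z).
#' @export
parse_spectrum <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- which(vapply(kv, length, integer(1)) != 2)
  if (length(bad))
    stopf("malformed spectrum entry '%s' (pair %d)", parts[bad[1]], bad[1])
  mz <- vapply(kv, `[[`, character(1), 1)
  inten <- suppressWarnings(as.numeric(vapply(kv, `[[`, character(1), 2)))
  if (anyNA(inten)) stopf("non-numeric spectrum intensity in '%s'", s)
  stats::setNames(inten, mz)
}

#' @rdname parse_spectrum
#' @param spec named numeric vector.
#' @export
format_spectrum <- function(spec) {
  paste(sprintf("%s:%.6g", names(spec), unname(spec)), collapse = ";")
}

#' @rdname io-tables
#' @export
read_metabolite_peaks <- function(path) {
  read_tsv_checked(path, c("sample_id", "rt_min", "area", "spectrum"),
                   "metabolite peak table")
}

#' @rdname io-tables
#' @export
read_alkane_ladder <- function(path) {
  df <- read_tsv_checked(path, c("n", "rt_min"), "alkane ladder")
  alkane_ladder(df$n, df$rt_min)
}

#' @rdname io-tables
#' @export
read_array_table <- function(path) {
  read_tsv_checked(path, c("probe", "locus_tag", "array_id", "role", "fg",
                           "bg"), "array table")
}

#' @rdname io-tables
#' @export
read_spot_table <- function(path) {
  read_tsv_checked(path, c("spot_id", "locus_tag", "gel_id", "group",
                           "volume"), "spot table")
}

#' Write every table of a simulated study to a directory
#'
#' Materializes a [simulate_study()] result as the TSV inputs of the
#' pipeline plus `truth.json`.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_feed_table(study$feed, p("feed.tsv"))
  write_steadystate_table(study$steadystate, p("steadystate.tsv"))
  for (cond in names(study$traces))
    write_trace_table(study$traces[[cond]], p(sprintf("trace_%s.tsv", cond)))
  utils::write.table(study$arrays$n_vs_c$arrays, p("arrays_n_vs_c.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$arrays$cn_vs_c$arrays, p("arrays_cn_vs_c.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$spots$volumes, p("spots.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$metabolites$peaks, p("peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$metabolites$ladder, p("ladder.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- study$truth
  truth$borders <- unclass(truth$borders)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
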