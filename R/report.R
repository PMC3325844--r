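#' Physiology summary across a set of chemostat conditions
#'
#' Reduces feed and (replicate) steady-state tables to the standard
#' culture-summary shape: molar feed ratio, yield coefficients on elemental
#' carbon and nitrogen, the per-condition dual-limitation boundary, the
#' study-level borders (the smallest and largest per-condition boundary),
#' specific rates, PHA content, monomer composition and the classified
#' growth regime. Replicate rows per condition are averaged before the
#' yield arithmetic, mirroring how replicate chemostat measurements are
#' reported.
#'
#' @param feed feed table (schema of [read_feed_table()]).
#' @param state steady-state table (schema of [read_steadystate_table()]).
#' @param mu_max maximum specific growth rate used for validation, 1/h.
#' @return data frame, one row per condition, with columns `condition`,
#'   `c0_n0`, `y_xc`, `y_xn`, `boundary`, `cdw_g_per_l`, `pha_pct_cdw`,
#'   `q_c`, `q_pha`, `molpct_C6`, `molpct_C8`, `molpct_C10`, `regime`;
#'   attribute `borders` carries the [regime_boundaries()].
#' @export
#' @examples
#' study <- simulate_study(seed = 1)
#' physiology_summary(study$feed, study$steadystate)
physiology_summary <- function(feed, state, mu_max = 0.53) {
  conds <- feed$condition
  rows <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    cnd <- conds[i]
    st <- state[state$condition == cnd, , drop = FALSE]
    if (nrow(st) == 0) stopf("no steady-state rows for condition '%s'", cnd)
    fm <- feed_medium(feed$decanoate_g_per_l[i], feed$nh4cl_g_per_l[i],
                      condition = cnd)
    rec <- steady_state_record(
      cnd, mean(st$D_per_h), mean(st$cdw_g_per_l),
      mean(st$pha_pct_cdw) / 100,
      mean(st$resid_C_g_per_l), mean(st$resid_N_g_per_l),
      c(C6 = mean(st$molpct_C6), C8 = mean(st$molpct_C8),
        C10 = mean(st$molpct_C10)),
      mu_max = mu_max)
    ys <- yield_coefficients(fm, rec)
    rates <- specific_rates(rec, fm)
    rows[[i]] <- data.frame(
      condition = cnd, c0_n0 = fm$c0_n0_ratio,
      y_xc = ys$y_xc, y_xn = ys$y_xn, boundary = regime_boundary(ys),
      cdw_g_per_l = rec$cdw, pha_pct_cdw = 100 * rec$pha_fraction,
      q_c = rates$q_c, q_pha = rates$q_pha,
      molpct_C6 = rec$monomer_molpercent[["C6"]],
      molpct_C8 = rec$monomer_molpercent[["C8"]],
      molpct_C10 = rec$monomer_molpercent[["C10"]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  borders <- regime_boundaries(min(out$boundary), max(out$boundary))
  out$regime <- classify_regime(out$c0_n0, borders)
  attr(out, "borders") <- borders
  out
}

#' Assemble the study-level report
#'
#' Combines whichever stage outputs are available into one report object:
#' the physiology summary, a differential-expression summary (counts per
#' comparison plus the shared-locus overlap) and the metabolite
#' level-change table. Missing stages leave explicit NULL gaps rather than
#' failing.
#'
#' @param physiology output of [physiology_summary()], or NULL.
#' @param de_n,de_cn called transcript tables ([call_transcript_de()]), or
#'   NULL.
#' @param protein_calls called protein table ([call_protein_de()]), or NULL.
#' @param level_changes output of [level_change_calls()], or NULL.
#' @return list of class `pha_report` with elements `physiology`,
#'   `de_summary`, `overlap`, `level_changes`.
#' @export
build_report <- function(physiology = NULL, de_n = NULL, de_cn = NULL,
                         protein_calls = NULL, level_changes = NULL) {
  de_summary <- NULL
  overlap <- NULL
  summarize <- function(d, label) {
    s <- attr(d, "summary")
    if (is.null(s)) s <- c(n_up = sum(d$call == "up"),
                           n_down = sum(d$call == "down"),
                           n_de = sum(d$call != "ns"))
    data.frame(comparison = label, n_up = s[["n_up"]], n_down = s[["n_down"]],
               n_de = s[["n_de"]], stringsAsFactors = FALSE)
  }
  tabs <- list()
  if (!is.null(de_n)) tabs <- c(tabs, list(summarize(de_n, "N_vs_C")))
  if (!is.null(de_cn)) tabs <- c(tabs, list(summarize(de_cn, "CN_vs_C")))
  if (length(tabs)) de_summary <- do.call(rbind, tabs)
  if (!is.null(de_n) && !is.null(de_cn))
    overlap <- overlap_and_concordance(de_n, de_cn, protein_calls)
  structure(list(physiology = physiology, de_summary = de_summary,
                 overlap = overlap, level_changes = level_changes),
            class = "pha_report")
}

#' @export
print.pha_report <- function(x, ...) {
  cat("== Chemostat study report ==\n")
  if (is.null(x$physiology)) {
    cat("[physiology stage missing]\n")
  } else {
    cat("\nPhysiology (borders:",
        sprintf("%.2f / %.2f mol/mol)\n",
                attr(x$physiology, "borders")$lower_border,
                attr(x$physiology, "borders")$upper_border))
    print(x$physiology, digits = 4)
  }
  if (!is.null(x$de_summary)) {
    cat("\nDifferential expression:\n")
    print(x$de_summary)
    if (!is.null(x$overlap))
      cat(sprintf("shared DE loci across comparisons: %d; transcript-protein concordant: %s\n",
                  x$overlap$n_shared, x$overlap$n_concordant))
  }
  if (!is.null(x$level_changes)) {
    cat("\nMetabolite level changes:\n")
    print(x$level_changes)
  }
  invisible(x)
}
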