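#' n-Alkane retention-index ladder
#'
#' The retention-time calibration series: n-alkanes with known carbon
#' numbers (conventionally C10 to C36), each defining retention index
#' 100 * n at its retention time.
#'
#' @param n alkane carbon numbers, strictly increasing.
#' @param rt_min retention times, minutes, strictly increasing.
#' @return data frame of class `alkane_ladder`.
#' @export
alkane_ladder <- function(n, rt_min) {
  if (length(n) < 2) stopf("ladder needs at least 2 alkanes")
  if (length(n) != length(rt_min)) stopf("n and rt_min lengths differ")
  if (any(diff(n) <= 0) || any(diff(rt_min) <= 0))
    stopf("ladder must be strictly increasing in carbon number and retention time")
  out <- data.frame(n = n, rt_min = rt_min)
  class(out) <- c("alkane_ladder", "data.frame")
  out
}

#' Kovats retention index (temperature-programmed, linear form)
#'
#' Piecewise-linear interpolation of retention time onto the alkane scale:
#' within a bracketing alkane pair, RI = 100 * (n_i + (n_{i+1} - n_i) *
#' (rt - t_i) / (t_{i+1} - t_i)). Exact on ladder points (RI = 100 n) and
#' monotone in retention time.
#'
#' @param rt_min retention times to convert (vectorized), minutes.
#' @param ladder an [alkane_ladder()].
#' @param extrapolate allow linear extrapolation beyond the ladder span
#'   (default FALSE: out-of-span times are an error).
#' @return retention indices.
#' @export
#' @examples
#' lad <- alkane_ladder(10:12, c(5, 7, 10))
#' retention_index(c(5, 6, 10), lad)  # 1000, 1050, 1200
retention_index <- function(rt_min, ladder, extrapolate = FALSE) {
  lo <- ladder$rt_min[1]; hi <- ladder$rt_min[nrow(ladder)]
  out_of_span <- rt_min < lo | rt_min > hi
  if (any(out_of_span) && !extrapolate)
    stopf("retention time outside ladder span [%.3f, %.3f] min; set extrapolate = TRUE to allow",
          lo, hi)
  ri <- stats::approx(ladder$rt_min, 100 * ladder$n, xout = rt_min,
                      rule = 1)$y
  if (extrapolate && any(out_of_span)) {
    k <- nrow(ladder)
    slope_lo <- 100 * (ladder$n[2] - ladder$n[1]) / (ladder$rt_min[2] - lo)
    slope_hi <- 100 * (ladder$n[k] - ladder$n[k - 1]) /
      (hi - ladder$rt_min[k - 1])
    low <- rt_min < lo
    ri[low] <- 100 * ladder$n[1] + slope_lo * (rt_min[low] - lo)
    high <- rt_min > hi
    ri[high] <- 100 * ladder$n[k] + slope_hi * (rt_min[high] - hi)
  }
  ri
}

#' Retention time for a target retention index (ladder inverse)
#'
#' Inverse of [retention_index()]: piecewise-linear interpolation of the
#' retention-index scale back onto retention time. Used by the synthetic
#' generator to place peaks at planted indices.
#'
#' @param ri retention indices (within the ladder span).
#' @param ladder an [alkane_ladder()].
#' @return retention times, minutes.
#' @export
rt_from_ri <- function(ri, ladder) {
  if (any(ri < 100 * ladder$n[1] | ri > 100 * ladder$n[nrow(ladder)]))
    stopf("retention index outside ladder span")
  stats::approx(100 * ladder$n, ladder$rt_min, xout = ri, rule = 1)$y
}

#' Mass-spectral match factor
#'
#' Cosine similarity between two centroided spectra over the union of their
#' integer m/z bins, on square-root-scaled intensities. Symmetric, scale
#' invariant and bounded in [0, 1].
#'
#' @param spec_a,spec_b named numeric vectors: names are integer m/z values,
#'   entries non-negative intensities with at least one positive entry.
#' @return match factor in [0, 1].
#' @export
#' @examples
#' match_factor(c(`100` = 1, `101` = 1), c(`100` = 1))  # 1/sqrt(2)
match_factor <- function(spec_a, spec_b) {
  if (all(spec_a <= 0) || all(spec_b <= 0))
    stopf("spectra must contain at least one positive intensity")
  if (any(spec_a < 0) || any(spec_b < 0)) stopf("intensities must be >= 0")
  mz <- union(names(spec_a), names(spec_b))
  a <- sqrt(unname(spec_a[mz])); a[is.na(a)] <- 0
  b <- sqrt(unname(spec_b[mz])); b[is.na(b)] <- 0
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Annotate a peak against a reference library
#'
#' Candidates are the library entries within `ri_window` retention-index
#' units of the peak; the hit is the candidate with the highest spectral
#' match factor, accepted when the factor reaches `min_match` (inclusive).
#' Ties break to the smaller RI distance, then to library order.
#'
#' @param peak list with `retention_index` and `spectrum` (named numeric).
#' @param library list of entries, each a list with `name`,
#'   `retention_index` and `spectrum`.
#' @param ri_window RI tolerance, +- units (default 5).
#' @param min_match minimum acceptable match factor (default 0.75).
#' @return list with `name`, `match_factor`, `delta_ri`, or NULL when no
#'   candidate qualifies.
#' @export
annotate_peak <- function(peak, library, ri_window = 5, min_match = 0.75) {
  best <- NULL
  for (entry in library) {
    d <- abs(peak$retention_index - entry$retention_index)
    if (d > ri_window) next
    mf <- match_factor(peak$spectrum, entry$spectrum)
    if (mf < min_match) next
    if (is.null(best) || mf > best$match_factor ||
        (mf == best$match_factor && d < best$delta_ri)) {
      best <- list(name = entry$name, match_factor = mf, delta_ri = d)
    }
  }
  best
}

#' Internal-standard / biomass normalized abundance
#'
#' area / IS area / g CDW: removes injection and extraction variability via
#' the ribitol internal standard and expresses the result per gram of cell
#' dry weight.
#'
#' @param area metabolite peak area (vectorized).
#' @param is_area internal-standard peak area (> 0).
#' @param cdw_g cell dry weight of the extracted sample, g (> 0).
#' @return normalized abundance, a.u. per (IS area x g CDW).
#' @export
normalize_abundance <- function(area, is_area, cdw_g) {
  if (any(is_area <= 0)) stopf("internal-standard area must be > 0")
  if (any(cdw_g <= 0)) stopf("cell dry weight must be > 0")
  area / is_area / cdw_g
}

#' Reproducibility and cross-condition correlation metrics
#'
#' Per metabolite and condition the relative standard deviation (sample sd
#' over mean, in percent) is computed within each replicate class; the
#' class-wise mean RSD summarizes technical (same fermentor) and biological
#' (independent cultivation) reproducibility. Metabolites whose biological
#' RSD exceeds `rsd_ceiling` in a condition are flagged excluded there.
#' Pearson correlations between condition mean profiles are computed on
#' log10 abundances.
#'
#' @param values data frame with columns `metabolite`, `condition`,
#'   `replicate_class` ("technical"/"biological") and `value` (>= 0).
#' @param rsd_ceiling biological-RSD exclusion ceiling, percent
#'   (default 50).
#' @return list with `rsd` (per metabolite x condition x class), `mean_rsd`
#'   (per class), `excluded` (metabolite/condition pairs over the ceiling)
#'   and `pearson` (condition-pair correlation matrix on log10 means).
#' @export
qc_metrics <- function(values, rsd_ceiling = 50) {
  need <- c("metabolite", "condition", "replicate_class", "value")
  if (!all(need %in% names(values)))
    stopf("values needs columns %s", paste(need, collapse = ", "))
  grp <- interaction(values$metabolite, values$condition,
                     values$replicate_class, drop = TRUE)
  rsd_one <- function(v) {
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m == 0) stopf("RSD undefined: group mean is zero")
    100 * stats::sd(v) / m
  }
  parts <- do.call(rbind, strsplit(levels(grp), ".", fixed = TRUE))
  rsd <- data.frame(metabolite = parts[, 1], condition = parts[, 2],
                    replicate_class = parts[, 3],
                    rsd = as.numeric(tapply(values$value, grp, rsd_one)),
                    stringsAsFactors = FALSE)
  mean_rsd <- tapply(rsd$rsd, rsd$replicate_class, mean, na.rm = TRUE)
  bio <- rsd[rsd$replicate_class == "biological" & !is.na(rsd$rsd), ]
  excluded <- bio[bio$rsd > rsd_ceiling, c("metabolite", "condition")]
  # condition mean profiles on the common metabolite set
  mm <- tapply(values$value, list(values$metabolite, values$condition), mean)
  pearson <- NULL
  if (!is.null(dim(mm)) && ncol(mm) >= 2) {
    lg <- log10(mm + .Machine$double.eps)
    pearson <- stats::cor(lg, use = "pairwise.complete.obs")
  }
  list(rsd = rsd, mean_rsd = mean_rsd, excluded = excluded, pearson = pearson)
}

#' Metabolite level-change calls against a reference condition
#'
#' A metabolite is called up (down) in a condition when the ratio of its
#' mean normalized abundance to the reference condition exceeds `min_fold`
#' (falls below 1/`min_fold`) and it passes the biological-RSD QC gate in
#' both conditions; metabolites absent or excluded by QC are reported n.d.,
#' and in-between ratios as no change ("nc").
#'
#' @param values data frame as in [qc_metrics()].
#' @param reference reference condition label.
#' @param min_fold fold-change threshold (default 1.5).
#' @param rsd_ceiling biological-RSD exclusion ceiling, percent.
#' @return data frame metabolite x comparison with columns `metabolite`,
#'   `condition`, `ratio`, `call` in {"up", "down", "nc", "nd"}.
#' @export
level_change_calls <- function(values, reference, min_fold = 1.5,
                               rsd_ceiling = 50) {
  if (!reference %in% values$condition)
    stopf("reference condition '%s' not present", reference)
  qc <- qc_metrics(values, rsd_ceiling = rsd_ceiling)
  excl_key <- paste(qc$excluded$metabolite, qc$excluded$condition)
  mm <- tapply(values$value, list(values$metabolite, values$condition), mean)
  conds <- setdiff(colnames(mm), reference)
  out <- expand.grid(metabolite = rownames(mm), condition = conds,
                     stringsAsFactors = FALSE)
  out$ratio <- mapply(function(m, c) mm[m, c] / mm[m, reference],
                      out$metabolite, out$condition)
  excluded <- paste(out$metabolite, out$condition) %in% excl_key |
    paste(out$metabolite, reference) %in% excl_key |
    is.na(out$ratio)
  out$call <- ifelse(excluded, "nd",
                     ifelse(out$ratio > min_fold, "up",
                            ifelse(out$ratio < 1 / min_fold, "down", "nc")))
  out
}
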