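#' Background-correct, log-ratio and median-center a two-channel array set
#'
#' For each array the foreground minus background intensity is floored at
#' half the smallest positive corrected value on that array/channel (so no
#' probe produces a non-finite ratio), the per-probe log2(test/reference)
#' ratio is taken, and each array is median-centered. This deliberately
#' simple normalization stands in for model-based background correction and
#' variance stabilization; it preserves planted fold changes and keeps the
#' null centered.
#'
#' @param arrays data frame in long layout with columns `probe`,
#'   `locus_tag`, `array_id`, `role` ("test"/"ref"), `fg`, `bg`. Every probe
#'   must appear once per array and role.
#' @return numeric matrix of log2 ratios, probes x arrays, rownames = locus
#'   tags (or probes when no tag is mapped).
#' @export
normalize_and_logratio <- function(arrays) {
  need <- c("probe", "locus_tag", "array_id", "role", "fg", "bg")
  if (!all(need %in% names(arrays)))
    stopf("arrays needs columns %s", paste(need, collapse = ", "))
  if (any(arrays$fg < 0) || any(arrays$bg < 0))
    stopf("intensities must be >= 0")
  ids <- unique(arrays$array_id)
  probes <- unique(arrays$probe)
  out <- matrix(NA_real_, length(probes), length(ids),
                dimnames = list(probes, as.character(ids)))
  for (a in ids) {
    chan <- list()
    for (r in c("test", "ref")) {
      sub <- arrays[arrays$array_id == a & arrays$role == r, , drop = FALSE]
      if (nrow(sub) != length(probes))
        stopf("array %s/%s: expected %d probes, found %d", a, r,
              length(probes), nrow(sub))
      corr <- sub$fg - sub$bg
      pos <- corr[corr > 0]
      if (length(pos) == 0) stopf("array %s/%s has no positive corrected intensity", a, r)
      corr <- pmax(corr, min(pos) / 2)
      chan[[r]] <- corr[match(probes, sub$probe)]
    }
    lr <- log2(chan$test / chan$ref)
    out[, as.character(a)] <- lr - stats::median(lr)
  }
  tag <- arrays$locus_tag[match(probes, arrays$probe)]
  rownames(out) <- ifelse(is.na(tag) | tag == "", probes, tag)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: for p-values sorted ascending,
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1, returned in the
#' original order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stopf("p must be numeric")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1] and contain no NA")
  stats::p.adjust(p, method = "BH")
}

#' Signed fold change from a log2 value
#'
#' Display convention of differential-expression tables: a 6.7-fold
#' decrease is written -6.7, so the magnitude is always >= 1 and the sign
#' carries the direction. Odd-symmetric in the log2 argument.
#'
#' @param log2fc log2 fold changes (vectorized).
#' @return signed fold changes.
#' @export
signed_fold <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Per-feature differential-expression statistics from replicate log ratios
#'
#' Mean log2 ratio, signed fold change and a one-sample t-test against zero
#' across replicate arrays, followed by Benjamini-Hochberg adjustment.
#'
#' @param ratios matrix of log2 ratios, features x replicates (>= 2
#'   replicates), rownames = locus tags.
#' @return data frame with `locus_tag`, `log2_fold_change`,
#'   `fold_change_signed`, `p_value`, `adj_p_value`.
#' @export
de_test <- function(ratios) {
  if (is.null(dim(ratios)) || ncol(ratios) < 2)
    stopf("at least 2 replicate arrays are required for p-values")
  n <- ncol(ratios)
  m <- rowMeans(ratios)
  sd <- sqrt(rowSums((ratios - m)^2) / (n - 1))
  t <- m / (sd / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  p[sd == 0] <- ifelse(m[sd == 0] == 0, 1, 0)  # degenerate: identical replicates
  data.frame(
    locus_tag = rownames(ratios),
    log2_fold_change = m,
    fold_change_signed = signed_fold(m),
    p_value = p,
    adj_p_value = bh_adjust(p),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Transcript-level differential-expression calls
#'
#' A gene is called up when its fold change strictly exceeds the threshold
#' and the adjusted p-value is below `alpha`; down when it falls strictly
#' below the reciprocal (signed fold below -threshold); otherwise ns.
#'
#' @param results data frame from [de_test()] (needs `fold_change_signed`
#'   and `adj_p_value`).
#' @param fc_threshold fold-change threshold (strict, in either direction).
#' @param alpha FDR level on the adjusted p-values.
#' @return `results` with a `call` column plus attribute `summary`
#'   (n_up, n_down, n_de).
#' @export
call_transcript_de <- function(results, fc_threshold = 2, alpha = 0.05) {
  sig <- results$adj_p_value < alpha
  up <- sig & results$fold_change_signed > fc_threshold
  down <- sig & results$fold_change_signed < -fc_threshold
  results$call <- ifelse(up, "up", ifelse(down, "down", "ns"))
  attr(results, "summary") <- c(n_up = sum(up), n_down = sum(down),
                                n_de = sum(up | down))
  results
}

#' Strict-cutoff filter on raw p-values
#'
#' Retains features whose fold change strictly exceeds `fc_threshold` in
#' either direction at a raw p-value below `p_threshold` - the stringent
#' secondary filter used to isolate the strongest responders between two
#' closely related conditions.
#'
#' @param results data frame with `fold_change_signed` and `p_value`.
#' @param fc_threshold strict fold-change bound (default 3.5).
#' @param p_threshold raw p-value bound (default 0.03).
#' @return the retained subset of `results`.
#' @export
strict_cutoff_filter <- function(results, fc_threshold = 3.5, p_threshold = 0.03) {
  keep <- abs(results$fold_change_signed) > fc_threshold &
    results$p_value < p_threshold
  results[keep, , drop = FALSE]
}

#' Welch t statistics for 2-D gel spots
#'
#' Computes, per spot, the mean expression ratio (test over reference) and a
#' Welch t-test p-value on log-transformed spot volumes across replicate
#' gels.
#'
#' @param volumes data frame with columns `spot_id`, `locus_tag`, `gel_id`,
#'   `group` ("test"/"ref") and `volume` (> 0).
#' @return data frame with `spot_id`, `locus_tag`, `ratio`, `p_value`,
#'   `only_in_test`, `only_in_ref` (flags set when a spot has volume in one
#'   group only).
#' @export
protein_spot_stats <- function(volumes) {
  need <- c("spot_id", "locus_tag", "gel_id", "group", "volume")
  if (!all(need %in% names(volumes)))
    stopf("volumes needs columns %s", paste(need, collapse = ", "))
  if (any(volumes$volume < 0)) stopf("spot volumes must be >= 0")
  out <- lapply(split(volumes, volumes$spot_id), function(s) {
    vt <- s$volume[s$group == "test"]
    vr <- s$volume[s$group == "ref"]
    only_t <- all(vr == 0) && any(vt > 0)
    only_r <- all(vt == 0) && any(vr > 0)
    ratio <- p <- NA_real_
    if (!only_t && !only_r && length(vt) && length(vr)) {
      ratio <- mean(vt) / mean(vr)
      if (length(vt) >= 2 && length(vr) >= 2 &&
          (stats::sd(log(vt)) > 0 || stats::sd(log(vr)) > 0)) {
        p <- stats::t.test(log(vt), log(vr))$p.value
      }
    }
    data.frame(spot_id = s$spot_id[1], locus_tag = s$locus_tag[1],
               ratio = ratio, p_value = p,
               only_in_test = only_t, only_in_ref = only_r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Protein-level differential-expression calls
#'
#' A spot is up when its mean ratio is at least `ratio_hi` (inclusive) and
#' the p-value is below `alpha`; down when the ratio is at most `ratio_lo`;
#' presence/absence spots pass through as "only_in_test" /
#' "only_in_reference" calls.
#'
#' @param spots data frame from [protein_spot_stats()] (or with the same
#'   columns).
#' @param ratio_hi up-regulation ratio bound, inclusive (default 2).
#' @param ratio_lo down-regulation ratio bound, inclusive (default 0.5).
#' @param alpha p-value bound (default 0.05).
#' @return `spots` with a `call` column in
#'   {"up", "down", "ns", "only_in_test", "only_in_reference"}.
#' @export
call_protein_de <- function(spots, ratio_hi = 2, ratio_lo = 0.5, alpha = 0.05) {
  call <- rep("ns", nrow(spots))
  sig <- !is.na(spots$p_value) & spots$p_value < alpha
  call[sig & spots$ratio >= ratio_hi] <- "up"
  call[sig & spots$ratio <= ratio_lo] <- "down"
  call[spots$only_in_test] <- "only_in_test"
  call[spots$only_in_ref] <- "only_in_reference"
  spots$call <- call
  spots
}

#' Overlap between two DE comparisons and transcript-protein concordance
#'
#' The shared set contains locus tags differentially expressed (call other
#' than "ns") in both transcript comparisons. Concordance pairs each
#' protein-level call with the transcript call for the same locus:
#' concordant when both are the same non-ns direction (presence in the test
#' condition counts as up, presence only in the reference as down).
#'
#' @param de_a,de_b called transcript results ([call_transcript_de()]).
#' @param protein_calls called protein results ([call_protein_de()]); may be
#'   NULL to skip concordance.
#' @param transcript_for_concordance which transcript table to pair protein
#'   calls with ("a" or "b").
#' @return list with `shared` (locus tags), `n_shared`, `concordance`
#'   (per-locus table) and `n_concordant`.
#' @export
overlap_and_concordance <- function(de_a, de_b, protein_calls = NULL,
                                    transcript_for_concordance = "a") {
  de_set <- function(d) d$locus_tag[d$call != "ns"]
  shared <- intersect(de_set(de_a), de_set(de_b))
  conc <- NULL
  n_conc <- NA_integer_
  if (!is.null(protein_calls)) {
    tr <- if (identical(transcript_for_concordance, "a")) de_a else de_b
    idx <- match(protein_calls$locus_tag, tr$locus_tag)
    pdir <- protein_calls$call
    pdir[pdir == "only_in_test"] <- "up"
    pdir[pdir == "only_in_reference"] <- "down"
    tdir <- ifelse(is.na(idx), NA_character_, tr$call[idx])
    conc <- data.frame(
      locus_tag = protein_calls$locus_tag,
      protein_call = pdir,
      transcript_call = tdir,
      concordant = !is.na(tdir) & pdir %in% c("up", "down") & pdir == tdir,
      stringsAsFactors = FALSE
    )
    n_conc <- sum(conc$concordant)
  }
  list(shared = shared, n_shared = length(shared),
       concordance = conc, n_concordant = n_conc)
}
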