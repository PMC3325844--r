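#' Default synthetic study conditions
#'
#' The three-regime chemostat design the generator emulates: a carbon-, a
#' dual carbon/nitrogen- and a nitrogen-limited culture at D = 0.1 1/h with
#' ammonium chloride held at 1 g/l and the decanoate feed set by the molar
#' C0/N0 ratio. Planted steady states (CDW, PHA fraction, residuals,
#' monomer composition) follow the published physiology of PHA-producing
#' *P. putida* on decanoate, so a default run produces a realistically
#' scaled study.
#'
#' @return data frame with one row per condition: `condition`, `c0_n0`,
#'   `cdw`, `pha_fraction`, `residual_carbon`, `residual_nitrogen`,
#'   `molpct_C6`, `molpct_C8`, `molpct_C10`.
#' @export
default_study_conditions <- function() {
  data.frame(
    condition = c("carbon", "dual", "nitrogen"),
    c0_n0 = c(5.83, 16.56, 26.97),
    cdw = c(1.46, 4.35, 4.63),
    pha_fraction = c(0.2578, 0.6194, 0.8058),
    residual_carbon = c(0, 0, 1.53),
    residual_nitrogen = c(0.112, 0, 0),
    molpct_C6 = c(3.3, 4.8, 4.3),
    molpct_C8 = c(53.4, 42.8, 40.2),
    molpct_C10 = c(43.3, 52.4, 55.5),
    stringsAsFactors = FALSE
  )
}

#' Default noise magnitudes of the generator
#'
#' Relative standard deviations applied as unit-mean multiplicative
#' lognormal noise. Physiology channels carry the few-percent measurement
#' errors typical of CDW/PHA determinations; online trace channels the
#' sub-percent stability of OD probes and gas analyzers; metabolite
#' abundances the study-scale 22% technical and 28-49% biological RSDs;
#' two-channel arrays a replicate log2-ratio standard deviation of 0.08.
#'
#' @return named list of noise parameters.
#' @export
default_noise <- function() {
  list(
    cdw_rsd = 0.03,
    pha_rsd = 0.03,
    residual_rsd = 0.05,
    trace_rsd = 0.005,
    gc_area_rsd = 0.02,
    metab_technical_rsd = 0.22,
    metab_biological_rsd = c(carbon = 0.32, dual = 0.28, nitrogen = 0.49),
    array_ratio_sd = 0.08,
    spot_rsd = 0.15
  )
}

# internal: zero out every noise magnitude (exact planted values)
noise_free <- function() {
  n <- default_noise()
  n[] <- lapply(n, function(x) x * 0)
  n
}

# internal: decanoate feed (g/l acid equivalents) hitting a target molar
# C0/N0 ratio at a given NH4Cl concentration
decanoate_for_ratio <- function(c0_n0, nh4cl_g_per_l = 1) {
  k <- elemental_constants()
  mol_n <- nh4cl_g_per_l / k$mm_NH4Cl
  c0_n0 * mol_n * k$mm_decanoic_acid / k$carbons_per_decanoate
}

# internal: steady-state CO2 evolution rate closing the carbon balance
closing_cer <- function(feed, cond, D) {
  k <- elemental_constants()
  consumed <- (feed$carbon_elemental - cond$residual_carbon) / k$mm_C
  to_bio <- cond$cdw * (1 - cond$pha_fraction) / k$biomass_g_per_cmol
  comp <- composition_from_molpercent(
    c(C6 = cond$molpct_C6, C8 = cond$molpct_C8, C10 = cond$molpct_C10))
  to_pha <- pha_carbon(comp, cond$cdw * cond$pha_fraction)
  cer <- D * (consumed - to_bio - to_pha)
  if (cer < 0)
    stopf("condition '%s' cannot close its carbon balance (negative CO2 share)",
          cond$condition)
  cer
}

#' Simulate a chemostat wash-in trace
#'
#' All monitored channels approach their steady-state level with the
#' first-order wash-in x(t) = x_ss (1 - e^(-D t)) (dissolved O2 and off-gas
#' O2 approach from their initial air-saturated levels), sampled at a fixed
#' interval and overlaid with multiplicative sensor noise. At the default
#' 5% drift tolerance the trace first sustains a full 4-residence-time
#' steady window between 5 and 8 residence times after inoculation.
#'
#' @param od_ss steady-state optical density.
#' @param D dilution rate, 1/h.
#' @param duration trace length, h (>= 8 residence times recommended).
#' @param cer steady-state CO2 evolution rate, C-mol/(l h), used to place
#'   the off-gas CO2 plateau.
#' @param dO2_ss steady-state dissolved oxygen, % saturation.
#' @param noise_rsd relative sensor noise (default 0.005).
#' @param dt sampling interval, h.
#' @param gas_flow aeration rate, l/min.
#' @param culture_volume working volume, l.
#' @param inlet_co2 inlet CO2 mole fraction.
#' @return a [chemostat_trace()].
#' @export
simulate_trace <- function(od_ss, D, duration = 8 / D, cer = 0.01,
                           dO2_ss = 40, noise_rsd = 0.005, dt = 0.25,
                           gas_flow = 1, culture_volume = 0.8,
                           inlet_co2 = 4e-4) {
  if (duration < 8 / D)
    warning("trace shorter than 8 residence times; steady state may not be reached",
            call. = FALSE)
  k <- elemental_constants()
  t <- seq(0, duration, by = dt)
  rise <- 1 - exp(-D * t)
  y_ss <- inlet_co2 + cer * k$molar_volume_gas * culture_volume / (60 * gas_flow)
  n <- length(t)
  od <- od_ss * rise * rlnorm_rsd(n, noise_rsd)
  dO2 <- (100 - (100 - dO2_ss) * rise) * rlnorm_rsd(n, noise_rsd)
  co2 <- (inlet_co2 + (y_ss - inlet_co2) * rise) * rlnorm_rsd(n, noise_rsd)
  o2 <- (0.2095 - (0.2095 - (0.2095 - 5 * (y_ss - inlet_co2))) * rise) *
    rlnorm_rsd(n, noise_rsd)
  # x(0) = 0 for OD by construction; clamp gas fractions to [0, 1]
  chemostat_trace(t, od, dO2, pmin(pmax(co2, 0), 1), pmin(pmax(o2, 0), 1),
                  gas_flow = gas_flow, culture_volume = culture_volume)
}

#' Simulate a two-channel array experiment with planted effects
#'
#' Probe baselines are lognormal; a chosen fraction of features receives a
#' symmetric up/down log2 effect split across the two dye channels; each
#' channel then gets lognormal intensity noise (so the replicate log2-ratio
#' standard deviation equals `ratio_sd`) and an additive background whose
#' measured estimate differs from the true spot background.
#'
#' @param n_features number of probes.
#' @param frac_de fraction of features with a planted effect.
#' @param effect_log2 absolute planted log2 fold change.
#' @param n_reps number of replicate arrays.
#' @param ratio_sd replicate standard deviation of the log2 ratio.
#' @param baseline_meanlog,baseline_sdlog lognormal baseline parameters.
#' @param bg_mean,bg_sd additive background level and its error.
#' @return list with `arrays` (long-format data frame ready for
#'   [normalize_and_logratio()]) and `truth` (`locus_tag`, `effect_log2`,
#'   `de` in -1/0/1).
#' @export
simulate_arrays <- function(n_features = 10000, frac_de = 0.05,
                            effect_log2 = 2, n_reps = 3, ratio_sd = 0.08,
                            baseline_meanlog = log(2000),
                            baseline_sdlog = 0.8,
                            bg_mean = 40, bg_sd = 4) {
  if (frac_de < 0 || frac_de > 1) stopf("frac_de must lie in [0, 1]")
  tags <- sprintf("PP_%04d", seq_len(n_features))
  n_de <- round(frac_de * n_features)
  de <- integer(n_features)
  if (n_de > 0) {
    idx <- sample.int(n_features, n_de)
    de[idx] <- rep_len(c(1L, -1L), n_de)
  }
  effect <- de * effect_log2
  baseline <- stats::rlnorm(n_features, baseline_meanlog, baseline_sdlog)
  sd_chan <- ratio_sd / sqrt(2)          # per-channel log2 noise
  rows <- vector("list", 2 * n_reps)
  ri <- 0
  for (r in seq_len(n_reps)) {
    for (role in c("test", "ref")) {
      sgn <- if (role == "test") 0.5 else -0.5
      signal <- baseline * 2^(sgn * effect + stats::rnorm(n_features, 0, sd_chan))
      bg_true <- pmax(stats::rnorm(n_features, bg_mean, bg_sd), 0)
      bg_meas <- pmax(stats::rnorm(n_features, bg_mean, bg_sd), 0)
      ri <- ri + 1
      rows[[ri]] <- data.frame(
        probe = tags, locus_tag = tags,
        array_id = sprintf("A%d", r), role = role,
        fg = signal + bg_true, bg = bg_meas,
        stringsAsFactors = FALSE
      )
    }
  }
  list(arrays = do.call(rbind, rows),
       truth = data.frame(locus_tag = tags, effect_log2 = effect, de = de,
                          stringsAsFactors = FALSE))
}

#' Built-in synthetic metabolite library
#'
#' A small reference library for the central-carbon/amino-acid panel the
#' metabolomics stage annotates. Retention indices are literature-scale
#' values for methoxyamine/TMS derivatives; the spectra are synthetic -
#' deterministic sparse fragment patterns in m/z 40-460 sharing the common
#' silylation fragments (73, 147) plus compound-unique fragments - suitable
#' for exercising annotation, not for matching real instrument data.
#'
#' @return list of library entries (`name`, `retention_index`, `spectrum`).
#' @export
default_metabolite_library <- function() {
  ri <- c(
    valine = 1220, isoleucine = 1295, glycine = 1305, succinate = 1316,
    fumarate = 1351, serine = 1362, threonine = 1388, malate = 1494,
    aspartate = 1523, cysteine = 1559, `2-ketoglutarate` = 1586,
    glutamate = 1622, ornithine = 1660, ribitol = 1733, glutamine = 1772,
    `3-phosphoglycerate` = 1805, citrate = 1817, glucose = 1887,
    tyrosine = 1940, `2-keto-3-deoxy-6-phosphogluconate` = 2250
  )
  lapply(seq_along(ri), function(i) {
    mz <- sort(unique(c(73, 147, 40 + (i * 37 + (1:10) * 53) %% 421)))
    inten <- c(999, 500, ((i * 13 + seq_len(length(mz) - 2) * 7) %% 90) + 10)
    list(name = names(ri)[i], retention_index = unname(ri[i]),
         spectrum = stats::setNames(inten, mz))
  })
}

#' Planted metabolite level-change pattern
#'
#' Ground-truth direction of each library metabolite in the dual- and
#' nitrogen-limited conditions relative to carbon limitation: "up"/"down"
#' plant a two-fold change, "nd" removes the metabolite from that
#' condition's samples (emulating compounds excluded by biological
#' variability).
#'
#' @return data frame `metabolite`, `dual`, `nitrogen`.
#' @export
default_metabolite_pattern <- function() {
  p <- rbind(
    c("glucose", "up", "up"),
    c("2-keto-3-deoxy-6-phosphogluconate", "up", "nd"),
    c("3-phosphoglycerate", "up", "nd"),
    c("citrate", "up", "up"),
    c("2-ketoglutarate", "down", "down"),
    c("succinate", "up", "down"),
    c("fumarate", "up", "down"),
    c("malate", "up", "down"),
    c("aspartate", "down", "down"),
    c("cysteine", "up", "nd"),
    c("glutamate", "down", "down"),
    c("glutamine", "up", "up"),
    c("glycine", "up", "up"),
    c("isoleucine", "up", "nd"),
    c("ornithine", "nd", "down"),
    c("serine", "nd", "up"),
    c("threonine", "nd", "up"),
    c("tyrosine", "up", "down"),
    c("valine", "up", "up")
  )
  data.frame(metabolite = p[, 1], dual = p[, 2], nitrogen = p[, 3],
             stringsAsFactors = FALSE)
}

#' Simulate GC-MS metabolite peaks from planted abundances
#'
#' Places each planted metabolite at the retention time corresponding to
#' its library retention index (ladder inverse interpolation), scales the
#' library spectrum, injects the ribitol internal-standard peak into every
#' sample and applies multiplicative area noise. Peak areas are
#' `abundance * IS area * CDW`, so [normalize_abundance()] recovers the
#' planted abundances.
#'
#' @param library metabolite library ([default_metabolite_library()]).
#' @param abundances data frame `sample_id`, `metabolite`, `abundance`.
#' @param ladder an [alkane_ladder()].
#' @param cdw data frame `sample_id`, `cdw_g` (sample biomass, g).
#' @param noise_rsd relative area noise (default 0).
#' @param is_area nominal internal-standard peak area.
#' @return data frame `sample_id`, `rt_min`, `area`, `spectrum`
#'   (semicolon-joined mz:intensity pairs).
#' @export
simulate_metabolite_peaks <- function(library, abundances, ladder, cdw,
                                      noise_rsd = 0, is_area = 1e5) {
  lib_ri <- vapply(library, `[[`, numeric(1), "retention_index")
  lib_names <- vapply(library, `[[`, character(1), "name")
  if (!all(abundances$metabolite %in% lib_names))
    stopf("abundance table contains metabolites missing from the library")
  samples <- unique(abundances$sample_id)
  cdw_g <- stats::setNames(cdw$cdw_g, cdw$sample_id)[samples]
  if (anyNA(cdw_g)) stopf("missing CDW for some samples")
  rows <- list()
  for (s in samples) {
    sub <- abundances[abundances$sample_id == s, , drop = FALSE]
    # ribitol internal standard first
    items <- rbind(data.frame(metabolite = "ribitol",
                              area = is_area * rlnorm_rsd(1, noise_rsd),
                              stringsAsFactors = FALSE),
                   data.frame(metabolite = sub$metabolite,
                              area = sub$abundance * is_area * cdw_g[[s]] *
                                rlnorm_rsd(nrow(sub), noise_rsd),
                              stringsAsFactors = FALSE))
    i <- match(items$metabolite, lib_names)
    spec <- vapply(seq_len(nrow(items)), function(j) {
      sp <- library[[i[j]]]$spectrum * items$area[j] / sum(library[[i[j]]]$spectrum)
      paste(sprintf("%s:%.6g", names(sp), unname(sp)), collapse = ";")
    }, character(1))
    rows[[s]] <- data.frame(sample_id = s,
                            rt_min = rt_from_ri(lib_ri[i], ladder),
                            area = items$area, spectrum = spec,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic chemostat multi-omics study
#'
#' Generates every input the pipeline consumes - feed table, replicate
#' steady-state measurements, wash-in monitoring traces, GC peak tables for
#' PHA quantification, two two-channel array comparisons with planted
#' differential expression, 2-D gel spot volumes, and GC-MS metabolite
#' peaks with an alkane ladder - together with the ground truth. Steady
#' states are constructed to close the carbon balance exactly before noise
#' is applied, and the three conditions fall into the three growth regimes
#' of the planted boundary model. Deterministic for a fixed seed.
#'
#' @param conditions condition table ([default_study_conditions()]).
#' @param n_replicates biological replicates per condition.
#' @param noise noise magnitudes ([default_noise()]; use zeros for exact
#'   planted values).
#' @param seed integer random seed.
#' @param D dilution rate, 1/h.
#' @param nh4cl_g_per_l feed ammonium chloride, g/l.
#' @param n_features array features per comparison.
#' @param frac_de fraction of array features with planted effects.
#' @param effect_log2 planted absolute log2 effect.
#' @param n_spots number of 2-D gel spots.
#' @return list with elements `feed`, `steadystate`, `traces`, `gc`,
#'   `arrays` (comparisons `n_vs_c`, `cn_vs_c`), `spots`, `metabolites`
#'   (`peaks`, `values`, `ladder`, `library`, `pattern`) and `truth`.
#' @export
simulate_study <- function(conditions = default_study_conditions(),
                           n_replicates = 3, noise = default_noise(),
                           seed = 1, D = 0.1, nh4cl_g_per_l = 1,
                           n_features = 2000, frac_de = 0.05,
                           effect_log2 = 2, n_spots = 150) {
  set.seed(seed)
  k <- elemental_constants()

  ## ---- physiology ----
  feed_df <- data.frame(
    condition = conditions$condition,
    decanoate_g_per_l = decanoate_for_ratio(conditions$c0_n0, nh4cl_g_per_l),
    nh4cl_g_per_l = nh4cl_g_per_l,
    stringsAsFactors = FALSE
  )
  truth_conditions <- conditions
  truth_conditions$decanoate_g_per_l <- feed_df$decanoate_g_per_l
  truth_conditions$D <- D
  truth_conditions$y_xc <- truth_conditions$y_xn <- truth_conditions$cer <-
    truth_conditions$boundary <- NA_real_
  ss_rows <- list(); traces <- list(); gc <- list()
  for (i in seq_len(nrow(conditions))) {
    cond <- conditions[i, ]
    feed <- feed_medium(feed_df$decanoate_g_per_l[i], nh4cl_g_per_l,
                        condition = cond$condition)
    st <- steady_state_record(cond$condition, D, cond$cdw, cond$pha_fraction,
                              cond$residual_carbon, cond$residual_nitrogen,
                              c(C6 = cond$molpct_C6, C8 = cond$molpct_C8,
                                C10 = cond$molpct_C10))
    ys <- yield_coefficients(feed, st)
    cer <- closing_cer(feed, cond, D)
    truth_conditions$y_xc[i] <- ys$y_xc
    truth_conditions$y_xn[i] <- ys$y_xn
    truth_conditions$cer[i] <- cer
    truth_conditions$boundary[i] <- regime_boundary(ys)

    for (r in seq_len(n_replicates)) {
      f_noisy <- min(cond$pha_fraction * rlnorm_rsd(1, noise$pha_rsd), 0.99)
      ss_rows[[length(ss_rows) + 1]] <- data.frame(
        condition = cond$condition, replicate = r, D_per_h = D,
        cdw_g_per_l = cond$cdw * rlnorm_rsd(1, noise$cdw_rsd),
        cdw_sd = cond$cdw * noise$cdw_rsd,
        pha_pct_cdw = 100 * f_noisy,
        pha_sd = 100 * cond$pha_fraction * noise$pha_rsd,
        resid_C_g_per_l = cond$residual_carbon * rlnorm_rsd(1, noise$residual_rsd),
        resid_N_g_per_l = cond$residual_nitrogen * rlnorm_rsd(1, noise$residual_rsd),
        molpct_C6 = cond$molpct_C6, molpct_C8 = cond$molpct_C8,
        molpct_C10 = cond$molpct_C10,
        stringsAsFactors = FALSE
      )
    }
    traces[[cond$condition]] <- simulate_trace(
      od_ss = 2.5 * cond$cdw, D = D, cer = cer,
      noise_rsd = noise$trace_rsd)
    # GC runs: one methanolysis per biological replicate, 8 mg dry sample
    ru <- pha_repeat_units()
    comp <- composition_from_molpercent(
      c(C6 = cond$molpct_C6, C8 = cond$molpct_C8, C10 = cond$molpct_C10))
    frac_mol <- comp$molpercent / 100
    mass_frac <- frac_mol * ru$repeat_mass / sum(frac_mol * ru$repeat_mass)
    for (r in seq_len(n_replicates)) {
      sample_mg <- 8
      pha_mg <- sample_mg * cond$pha_fraction
      masses <- pha_mg * mass_frac
      is_mass <- 0.5
      areas <- masses / is_mass * 1000 * rlnorm_rsd(3, noise$gc_area_rsd)
      gc[[paste(cond$condition, r, sep = ".")]] <- gc_peak_table(
        data.frame(monomer = c(ru$monomer, "IS"), area = c(areas, 1000),
                   stringsAsFactors = FALSE),
        internal_standard_mass_mg = is_mass, sample_dry_mass_mg = sample_mg)
    }
  }
  steadystate <- do.call(rbind, ss_rows)
  if (min(truth_conditions$boundary) < max(truth_conditions$boundary)) {
    planted_regimes <- classify_regime(
      conditions$c0_n0,
      regime_boundaries(min(truth_conditions$boundary),
                        max(truth_conditions$boundary)))
    if (length(unique(planted_regimes)) == 1)
      warning("all simulated conditions fall into one growth regime",
              call. = FALSE)
  }

  ## ---- transcriptome: two comparisons sharing a locus universe ----
  arr_n <- simulate_arrays(n_features, frac_de, effect_log2,
                           n_reps = n_replicates, ratio_sd = noise$array_ratio_sd)
  arr_cn <- simulate_arrays(n_features, frac_de, effect_log2,
                            n_reps = n_replicates, ratio_sd = noise$array_ratio_sd)

  ## ---- proteome spots linked to the transcript truth ----
  spots <- simulate_spots(arr_n$truth, n_spots = n_spots,
                          spot_rsd = noise$spot_rsd)

  ## ---- metabolome ----
  library <- default_metabolite_library()
  ladder <- alkane_ladder(10:36, 4 + (10:36 - 10) * 1.05)
  pattern <- default_metabolite_pattern()
  fold_of <- function(call) c(up = 2, down = 0.5, nd = NA_real_)[call]
  base_level <- stats::setNames(2 * (seq_len(nrow(pattern)) %% 5 + 1),
                                pattern$metabolite)
  val_rows <- list(); ab_rows <- list(); cdw_rows <- list()
  cond_fold <- list(carbon = rep(1, nrow(pattern)),
                    dual = fold_of(pattern$dual),
                    nitrogen = fold_of(pattern$nitrogen))
  for (cnd in c("carbon", "dual", "nitrogen")) {
    folds <- cond_fold[[cnd]]
    bio_rsd <- noise$metab_biological_rsd[[cnd]]
    for (r in seq_len(n_replicates)) {
      keep <- !is.na(folds)
      bio_draw <- rlnorm_rsd(sum(keep), bio_rsd)
      level <- base_level[pattern$metabolite[keep]] * folds[keep] * bio_draw
      sid <- paste(cnd, r, sep = ".")
      value <- level * rlnorm_rsd(sum(keep), noise$metab_technical_rsd)
      val_rows[[sid]] <- data.frame(
        metabolite = pattern$metabolite[keep], condition = cnd,
        replicate = r, replicate_class = "biological", value = value,
        stringsAsFactors = FALSE)
      ab_rows[[sid]] <- data.frame(sample_id = sid,
                                   metabolite = pattern$metabolite[keep],
                                   abundance = value,
                                   stringsAsFactors = FALSE)
      cdw_rows[[sid]] <- data.frame(
        sample_id = sid,
        cdw_g = conditions$cdw[conditions$condition == cnd] / 1000 * 5,
        stringsAsFactors = FALSE)  # 5 ml culture sampled
      # technical replicates of the first fermentor
      if (r == 1) {
        for (tr in 1:n_replicates) {
          val_rows[[paste(sid, "t", tr)]] <- data.frame(
            metabolite = pattern$metabolite[keep], condition = cnd,
            replicate = tr, replicate_class = "technical",
            value = level * rlnorm_rsd(sum(keep), noise$metab_technical_rsd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  values <- do.call(rbind, val_rows); rownames(values) <- NULL
  abund <- do.call(rbind, ab_rows)
  cdw_tbl <- do.call(rbind, cdw_rows)
  peaks <- simulate_metabolite_peaks(library, abund, ladder, cdw_tbl,
                                     noise_rsd = 0)

  list(
    feed = feed_df,
    steadystate = steadystate,
    traces = traces,
    gc = gc,
    arrays = list(n_vs_c = arr_n, cn_vs_c = arr_cn),
    spots = spots,
    metabolites = list(peaks = peaks, values = values, ladder = ladder,
                       library = library, pattern = pattern,
                       cdw = cdw_tbl),
    truth = list(conditions = truth_conditions,
                 borders = regime_boundaries(min(truth_conditions$boundary),
                                             max(truth_conditions$boundary)),
                 seed = seed)
  )
}

#' Simulate 2-D gel spot volumes linked to a transcript truth table
#'
#' Samples spot loci from the array universe, plants protein-level changes
#' (a subset concordant with the transcript truth, a subset protein-only),
#' adds presence/absence spots and replicate lognormal volume noise on
#' triplicate gels per group.
#'
#' @param transcript_truth truth table from [simulate_arrays()].
#' @param n_spots number of spots.
#' @param n_gels gels per group.
#' @param spot_rsd replicate volume RSD.
#' @param ratio_up,ratio_down planted protein ratios.
#' @return list with `volumes` (long data frame for
#'   [protein_spot_stats()]) and `truth` (`spot_id`, `locus_tag`,
#'   `protein_de` in {"up","down","ns","only_in_test","only_in_reference"},
#'   `transcript_de`).
#' @export
simulate_spots <- function(transcript_truth, n_spots = 150, n_gels = 3,
                           spot_rsd = 0.15, ratio_up = 4, ratio_down = 0.25) {
  de_loci <- transcript_truth$locus_tag[transcript_truth$de != 0]
  ns_loci <- transcript_truth$locus_tag[transcript_truth$de == 0]
  n_conc <- min(10, length(de_loci))
  chosen_de <- sample(de_loci, n_conc)
  chosen_ns <- sample(ns_loci, n_spots - n_conc)
  loci <- c(chosen_de, chosen_ns)
  tdir <- transcript_truth$de[match(loci, transcript_truth$locus_tag)]
  pdir <- rep("ns", n_spots)
  # concordant spots follow the transcript direction
  pdir[seq_len(n_conc)] <- ifelse(tdir[seq_len(n_conc)] > 0, "up", "down")
  # some protein-only changes and presence/absence spots on transcript-ns loci
  extra <- n_conc + seq_len(min(20, n_spots - n_conc))
  pdir[extra] <- rep_len(c("up", "down", "only_in_test", "only_in_reference"),
                         length(extra))
  rows <- list()
  for (i in seq_len(n_spots)) {
    ref_mean <- stats::rlnorm(1, log(1000), 0.3)
    ratio <- switch(pdir[i], up = ratio_up, down = ratio_down,
                    only_in_test = NA, only_in_reference = NA, ns = 1)
    vt <- if (identical(pdir[i], "only_in_reference")) rep(0, n_gels)
          else ref_mean * (if (is.na(ratio)) 1 else ratio) *
            rlnorm_rsd(n_gels, spot_rsd)
    vr <- if (identical(pdir[i], "only_in_test")) rep(0, n_gels)
          else ref_mean * rlnorm_rsd(n_gels, spot_rsd)
    rows[[i]] <- data.frame(
      spot_id = sprintf("S%03d", i), locus_tag = loci[i],
      gel_id = rep(sprintf("G%d", seq_len(2 * n_gels)), times = 1),
      group = rep(c("test", "ref"), each = n_gels),
      volume = c(vt, vr), stringsAsFactors = FALSE)
  }
  list(
    volumes = do.call(rbind, rows),
    truth = data.frame(spot_id = sprintf("S%03d", seq_len(n_spots)),
                       locus_tag = loci, protein_de = pdir,
                       transcript_de = tdir, stringsAsFactors = FALSE)
  )
}
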