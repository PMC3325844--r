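#' Feed medium with derived elemental content
#'
#' Builds a feed-medium description from the decanoate and ammonium chloride
#' concentrations of the inflowing medium and derives its elemental carbon
#' and nitrogen content and the molar C0/N0 ratio. The decanoate mass is
#' interpreted as decanoic-acid equivalents (MW 172.26 g/mol, 10 C atoms):
#' this is the convention under which the feed ratios, the yield
#' coefficients and the cell dry weights of a dual-limitation chemostat
#' experiment are mutually consistent.
#'
#' @param decanoate_g_per_l decanoate concentration, g/l (acid equivalents).
#' @param nh4cl_g_per_l ammonium chloride concentration, g/l.
#' @param condition optional condition label carried through reports.
#' @return An object of class `feed_medium`: a list with the two input
#'   concentrations plus `carbon_elemental` (g C/l), `nitrogen_elemental`
#'   (g N/l) and `c0_n0_ratio` (mol C / mol N).
#' @export
#' @examples
#' f <- feed_medium(8.686, 1.0)
#' f$c0_n0_ratio  # ~27 mol C per mol N
feed_medium <- function(decanoate_g_per_l, nh4cl_g_per_l, condition = NA_character_) {
  if (!is.numeric(decanoate_g_per_l) || !is.numeric(nh4cl_g_per_l))
    stopf("feed concentrations must be numeric")
  if (decanoate_g_per_l < 0 || nh4cl_g_per_l < 0)
    stopf("feed concentrations must be >= 0 (got decanoate %g, NH4Cl %g)",
          decanoate_g_per_l, nh4cl_g_per_l)
  k <- elemental_constants()
  carbon <- decanoate_g_per_l * k$carbons_per_decanoate * k$mm_C / k$mm_decanoic_acid
  nitrogen <- nh4cl_g_per_l * k$mm_N / k$mm_NH4Cl
  if (nitrogen == 0)
    stopf("C0/N0 ratio is undefined: feed contains no nitrogen (NH4Cl = 0)")
  ratio <- (carbon / k$mm_C) / (nitrogen / k$mm_N)
  structure(
    list(
      condition = condition,
      decanoate_conc = decanoate_g_per_l,
      nh4cl_conc = nh4cl_g_per_l,
      carbon_elemental = carbon,
      nitrogen_elemental = nitrogen,
      c0_n0_ratio = ratio
    ),
    class = "feed_medium"
  )
}

#' @export
print.feed_medium <- function(x, ...) {
  cat(sprintf(
    "Feed medium%s: %.3f g/l decanoate, %.3f g/l NH4Cl\n  %.4f g C/l, %.4f g N/l, C0/N0 = %.2f mol/mol\n",
    if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
    x$decanoate_conc, x$nh4cl_conc,
    x$carbon_elemental, x$nitrogen_elemental, x$c0_n0_ratio))
  invisible(x)
}

#' One steady-state chemostat measurement
#'
#' Bundles the measured state of one chemostat culture at steady state:
#' dilution rate, cell dry weight (CDW, PHA included), PHA fraction of CDW,
#' residual elemental carbon and nitrogen in the broth, and the monomer
#' composition of the accumulated polyester. Residuals reported below the
#' detection limit ("N.D.") enter as 0 with the nitrogen detection limit
#' (1.9 mg N/l) retained as an uncertainty bound.
#'
#' @param condition condition label (e.g. "carbon", "dual", "nitrogen").
#' @param D dilution rate, 1/h; must satisfy 0 < D < `mu_max`.
#' @param cdw cell dry weight, g/l (total, PHA included).
#' @param pha_fraction PHA fraction of CDW, dimensionless in [0, 1).
#' @param residual_carbon residual elemental carbon in the broth, g C/l.
#' @param residual_nitrogen residual elemental nitrogen, g N/l.
#' @param monomer_molpercent named numeric (C6, C8, C10) mol%, summing to
#'   100 +- 0.5; may be NULL when no composition was measured.
#' @param cdw_sd,pha_sd optional measurement standard deviations.
#' @param mu_max maximum specific growth rate used for validation (1/h).
#' @return An object of class `steady_state_record`.
#' @export
steady_state_record <- function(condition, D, cdw, pha_fraction,
                                residual_carbon = 0, residual_nitrogen = 0,
                                monomer_molpercent = NULL,
                                cdw_sd = NA_real_, pha_sd = NA_real_,
                                mu_max = 0.53) {
  if (D <= 0 || D >= mu_max)
    stopf("dilution rate must satisfy 0 < D < mu_max = %g (got %g)", mu_max, D)
  if (cdw < 0) stopf("CDW must be >= 0")
  if (pha_fraction < 0 || pha_fraction >= 1)
    stopf("PHA fraction must be in [0, 1) (got %g)", pha_fraction)
  if (residual_carbon < 0 || residual_nitrogen < 0)
    stopf("residual concentrations must be >= 0")
  if (!is.null(monomer_molpercent)) {
    if (!all(c("C6", "C8", "C10") %in% names(monomer_molpercent)))
      stopf("monomer_molpercent needs named entries C6, C8, C10")
    s <- sum(monomer_molpercent)
    if (abs(s - 100) > 0.5)
      stopf("monomer mol%% must sum to 100 +- 0.5 (got %.2f)", s)
  }
  structure(
    list(
      condition = condition, D = D, cdw = cdw, cdw_sd = cdw_sd,
      pha_fraction = pha_fraction, pha_sd = pha_sd,
      residual_carbon = residual_carbon,
      residual_nitrogen = residual_nitrogen,
      monomer_molpercent = monomer_molpercent
    ),
    class = "steady_state_record"
  )
}

#' PHA-free (residual) biomass concentration
#'
#' The catalytically active biomass: CDW minus the stored polyester. This is
#' the denominator of all specific rates.
#'
#' @param state a [steady_state_record()].
#' @return residual biomass, g/l.
#' @export
residual_biomass <- function(state) {
  state$cdw * (1 - state$pha_fraction)
}

#' Biomass yield coefficients on elemental carbon and nitrogen
#'
#' Y_X/C = dX/dC and Y_X/N = dX/dN in g biomass per g element consumed,
#' where dX is the total CDW produced (PHA included) and consumption is
#' feed elemental content minus the residual measured in the broth.
#'
#' @param feed a [feed_medium()].
#' @param state a [steady_state_record()].
#' @return An object of class `yield_set`: list with `y_xc`, `y_xn`,
#'   `delta_x` (g/l), `delta_c` (g C/l), `delta_n` (g N/l).
#' @export
#' @examples
#' f <- feed_medium(8.686, 1.0)
#' s <- steady_state_record("nitrogen", 0.1, 4.63, 0.8058,
#'                          residual_carbon = 1.53)
#' yield_coefficients(f, s)
yield_coefficients <- function(feed, state) {
  dc <- feed$carbon_elemental - state$residual_carbon
  dn <- feed$nitrogen_elemental - state$residual_nitrogen
  if (dc <= 0)
    stopf("non-positive carbon consumption (%.4g g C/l): residual carbon exceeds the feed content", dc)
  if (dn <= 0)
    stopf("non-positive nitrogen consumption (%.4g g N/l): residual nitrogen exceeds the feed content", dn)
  structure(
    list(y_xc = state$cdw / dc, y_xn = state$cdw / dn,
         delta_x = state$cdw, delta_c = dc, delta_n = dn),
    class = "yield_set"
  )
}

#' @export
print.yield_set <- function(x, ...) {
  cat(sprintf("Yields: Y_X/C = %.3f g/g, Y_X/N = %.3f g/g (dX %.3f, dC %.4f, dN %.4f g/l)\n",
              x$y_xc, x$y_xn, x$delta_x, x$delta_c, x$delta_n))
  invisible(x)
}

#' Specific carbon-uptake and PHA-production rates
#'
#' q_C = dC * D / X_PHA-free and q_PHA = PHA * D / X_PHA-free, both in
#' g per g residual biomass per hour; at steady state the specific growth
#' rate equals the dilution rate D.
#'
#' @param state a [steady_state_record()].
#' @param feed a [feed_medium()]; needed for the carbon-uptake rate. May be
#'   NULL, in which case `q_c` is returned as NA.
#' @return list with `q_c` (g C/(g h)), `q_pha` (g/(g h)), and
#'   `x_residual` (g/l).
#' @export
specific_rates <- function(state, feed = NULL) {
  xr <- residual_biomass(state)
  if (xr <= 0)
    stopf("residual (PHA-free) biomass is zero: specific rates are undefined at PHA fraction %g",
          state$pha_fraction)
  pha <- state$cdw * state$pha_fraction
  q_c <- NA_real_
  if (!is.null(feed)) {
    dc <- feed$carbon_elemental - state$residual_carbon
    q_c <- dc * state$D / xr
  }
  list(q_c = q_c, q_pha = pha * state$D / xr, x_residual = xr)
}

#' Dual-limitation regime boundary from a pair of yield coefficients
#'
#' The critical molar feed ratio at which a culture with yields Y_X/C and
#' Y_X/N exhausts carbon and nitrogen simultaneously:
#' C0/N0 = (Y_X/N * 14) / (Y_X/C * 12). The integer masses 12 and 14 are
#' used here by convention; elsewhere the package uses 12.011/14.007.
#'
#' @param yields a `yield_set` or a list/vector with elements `y_xc`, `y_xn`.
#' @return boundary feed ratio, mol C / mol N.
#' @export
#' @examples
#' regime_boundary(list(y_xc = 1.11, y_xn = 9.80))   # ~10.30
#' regime_boundary(list(y_xc = 1.01, y_xn = 17.74))  # ~20.49
regime_boundary <- function(yields) {
  y_xc <- yields[["y_xc"]]; y_xn <- yields[["y_xn"]]
  if (is.null(y_xc) || is.null(y_xn)) stopf("yields must provide y_xc and y_xn")
  if (y_xc <= 0) stopf("Y_X/C must be > 0")
  if (y_xn <= 0) stopf("Y_X/N must be > 0")
  k <- elemental_constants()
  (y_xn * k$mm_N_boundary) / (y_xc * k$mm_C_boundary)
}

#' Pair of dual-limitation regime borders
#'
#' @param lower carbon-side border (mol C / mol N).
#' @param upper nitrogen-side border (mol C / mol N).
#' @return object of class `regime_boundaries`.
#' @export
regime_boundaries <- function(lower, upper) {
  if (!(is.finite(lower) && is.finite(upper)) || lower <= 0 || lower >= upper)
    stopf("invalid borders: need 0 < lower < upper (got %g, %g)", lower, upper)
  structure(list(lower_border = lower, upper_border = upper),
            class = "regime_boundaries")
}

#' Classify a feed ratio into a growth regime
#'
#' Below the lower border growth is carbon-limited, above the upper border
#' strictly nitrogen-limited; ratios on or between the borders fall in the
#' dual carbon-nitrogen-limited regime (borders belong to the dual region).
#'
#' @param c0_n0 feed ratio, mol C / mol N (vectorized).
#' @param borders a [regime_boundaries()].
#' @return character vector in {"carbon", "dual", "nitrogen"}.
#' @export
#' @examples
#' b <- regime_boundaries(10.40, 20.50)
#' classify_regime(c(5.83, 16.56, 26.97), b)
classify_regime <- function(c0_n0, borders) {
  if (!inherits(borders, "regime_boundaries"))
    borders <- regime_boundaries(borders[["lower_border"]], borders[["upper_border"]])
  if (any(c0_n0 < 0)) stopf("feed ratio must be >= 0")
  ifelse(c0_n0 < borders$lower_border, "carbon",
         ifelse(c0_n0 > borders$upper_border, "nitrogen", "dual"))
}

#' Chemostat monitoring trace
#'
#' Online time series of the monitored culture channels: optical density,
#' dissolved oxygen and off-gas CO2/O2 mole fractions, together with the
#' aeration rate and working volume of the vessel.
#'
#' @param time_h sampling times, h, strictly increasing.
#' @param od600 optical density (a.u.).
#' @param dissolved_o2 dissolved oxygen, % air saturation.
#' @param co2_frac off-gas CO2 mole fraction in [0, 1].
#' @param o2_frac off-gas O2 mole fraction in [0, 1].
#' @param gas_flow aeration rate, l/min.
#' @param culture_volume working volume, l.
#' @return data frame of class `chemostat_trace` with attributes
#'   `gas_flow` and `culture_volume`.
#' @export
chemostat_trace <- function(time_h, od600, dissolved_o2, co2_frac, o2_frac,
                            gas_flow = 1, culture_volume = 0.8) {
  n <- length(time_h)
  if (n < 2 || any(diff(time_h) <= 0)) stopf("time must be strictly increasing")
  if (any(co2_frac < 0 | co2_frac > 1) || any(o2_frac < 0 | o2_frac > 1))
    stopf("gas mole fractions must lie in [0, 1]")
  if (gas_flow <= 0 || culture_volume <= 0)
    stopf("gas flow and culture volume must be > 0")
  out <- data.frame(time_h = time_h, od600 = od600,
                    dissolved_o2 = dissolved_o2,
                    co2_frac = co2_frac, o2_frac = o2_frac)
  attr(out, "gas_flow") <- gas_flow
  attr(out, "culture_volume") <- culture_volume
  class(out) <- c("chemostat_trace", "data.frame")
  out
}

#' Study-level configuration
#'
#' @param mu_max maximum specific growth rate on the carbon source, 1/h.
#' @param steady_state_tolerance maximum relative drift of a monitored
#'   channel from its window mean still counted as constant.
#' @param steady_state_window steadiness window length in residence times.
#' @return list of class `study_config`.
#' @export
study_config <- function(mu_max = 0.53, steady_state_tolerance = 0.05,
                         steady_state_window = 4) {
  if (mu_max <= 0) stopf("mu_max must be > 0")
  if (steady_state_tolerance <= 0 || steady_state_tolerance >= 0.5)
    stopf("steady_state_tolerance must lie in (0, 0.5)")
  if (steady_state_window < 1) stopf("steady_state_window must be >= 1")
  structure(list(mu_max = mu_max,
                 steady_state_tolerance = steady_state_tolerance,
                 steady_state_window = steady_state_window),
            class = "study_config")
}

#' Carbon dioxide evolution rate from the off-gas trace
#'
#' CER = F * 60 * (y_out - y_in) / V_m / V_culture in C-mol/(l h), where F
#' is the aeration rate (l/min), y the CO2 mole fractions and V_m the molar
#' volume at 25 degC, 1 atm (24.45 l/mol). The off-gas fraction is averaged
#' over the requested window (default: the whole trace). Negative net CO2 is
#' clipped to zero with a warning.
#'
#' @param trace a [chemostat_trace()].
#' @param inlet_co2 CO2 mole fraction of the inlet air (ambient default).
#' @param window optional `c(t_start, t_end)` in hours over which to average.
#' @return CO2 evolution rate, C-mol/(l h).
#' @export
co2_evolution <- function(trace, inlet_co2 = 4e-4, window = NULL) {
  k <- elemental_constants()
  y <- trace$co2_frac
  if (!is.null(window)) {
    sel <- trace$time_h >= window[1] & trace$time_h <= window[2]
    if (!any(sel)) stopf("no trace points inside the requested window")
    y <- y[sel]
  }
  dy <- mean(y) - inlet_co2
  if (dy < 0) {
    if (dy < -1e-6)
      warning("off-gas CO2 below inlet level; CER clipped to 0", call. = FALSE)
    dy <- 0
  }
  attr(trace, "gas_flow") * 60 * dy / k$molar_volume_gas / attr(trace, "culture_volume")
}

#' Carbon mass balance over one steady-state condition
#'
#' Distributes the consumed carbon over PHA-free biomass (27 g per C-mol),
#' polyester (via the monomer composition) and CO2 (CER / D at steady
#' state), and reports the closure (outputs over inputs) plus percentage
#' shares.
#'
#' @param feed a [feed_medium()].
#' @param state a [steady_state_record()] carrying the monomer composition.
#' @param cer CO2 evolution rate, C-mol/(l h) (e.g. from [co2_evolution()]).
#' @return list of class `carbon_balance`: `consumed`, `to_biomass`,
#'   `to_pha`, `to_co2` (C-mol/l), `closure`, and `shares` (% of consumed).
#' @export
carbon_balance <- function(feed, state, cer) {
  k <- elemental_constants()
  consumed <- (feed$carbon_elemental - state$residual_carbon) / k$mm_C
  if (consumed <= 0) stopf("non-positive carbon consumption")
  to_biomass <- residual_biomass(state) / k$biomass_g_per_cmol
  pha_mass <- state$cdw * state$pha_fraction
  to_pha <- if (pha_mass > 0) {
    if (is.null(state$monomer_molpercent))
      stopf("monomer composition required to convert PHA mass to C-mol")
    comp <- composition_from_molpercent(state$monomer_molpercent)
    pha_carbon(comp, pha_mass)
  } else 0
  to_co2 <- cer / state$D
  closure <- (to_biomass + to_pha + to_co2) / consumed
  if (closure > 1.05)
    warning(sprintf("carbon balance over-closure: %.3f", closure), call. = FALSE)
  structure(
    list(consumed = consumed, to_biomass = to_biomass, to_pha = to_pha,
         to_co2 = to_co2, closure = closure,
         shares = 100 * c(biomass = to_biomass, pha = to_pha,
                          co2 = to_co2) / consumed),
    class = "carbon_balance"
  )
}

#' @export
print.carbon_balance <- function(x, ...) {
  cat(sprintf(
    "Carbon balance: consumed %.4f C-mol/l -> biomass %.1f%%, PHA %.1f%%, CO2 %.1f%% (closure %.3f)\n",
    x$consumed, x$shares[["biomass"]], x$shares[["pha"]], x$shares[["co2"]],
    x$closure))
  invisible(x)
}

#' Detect steady state in a chemostat trace
#'
#' A culture is steady over a window of `steady_state_window` residence
#' times when every monitored channel (OD, dissolved O2, off-gas CO2) stays
#' within `steady_state_tolerance` relative deviation of its window mean.
#' The detector scans every sampled window start, reports the earliest
#' steady window, and additionally evaluates the trailing window of the
#' trace (the criterion applied before sampling a running culture).
#'
#' @param trace a [chemostat_trace()].
#' @param D dilution rate, 1/h (residence time is 1/D).
#' @param cfg a [study_config()].
#' @return list with `is_steady` (trailing window steady?), `window`
#'   (trailing window `c(start, end)` in h), `steady_from` (start time of
#'   the earliest steady window, NA if none) and `steady_at` (time at which
#'   steadiness over a full window is first established, i.e.
#'   `steady_from` + window length).
#' @export
detect_steady_state <- function(trace, D, cfg = study_config()) {
  len <- cfg$steady_state_window / D
  t <- trace$time_h
  span <- t[length(t)] - t[1]
  if (span < len)
    stopf("trace spans %.1f h but %.1f h (%g residence times at D = %g) are required",
          span, len, cfg$steady_state_window, D)
  ch <- cbind(od600 = trace$od600, dissolved_o2 = trace$dissolved_o2,
              co2_frac = trace$co2_frac)
  tol <- cfg$steady_state_tolerance
  window_steady <- function(i, j) {
    for (c in seq_len(ncol(ch))) {
      x <- ch[i:j, c]
      m <- mean(x)
      if (m <= 0 || max(abs(x - m)) / m > tol) return(FALSE)
    }
    TRUE
  }
  ends <- findInterval(t + len, t)      # last index inside [t_i, t_i + len]
  starts <- which(t + len <= t[length(t)] + 1e-9)
  steady_from <- NA_real_
  for (i in starts) {
    if (window_steady(i, ends[i])) { steady_from <- t[i]; break }
  }
  trail_i <- findInterval(t[length(t)] - len, t)
  if (t[trail_i] < t[length(t)] - len) trail_i <- trail_i + 1
  list(
    is_steady = window_steady(trail_i, length(t)),
    window = c(t[length(t)] - len, t[length(t)]),
    steady_from = steady_from,
    steady_at = if (is.na(steady_from)) NA_real_ else steady_from + len
  )
}
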