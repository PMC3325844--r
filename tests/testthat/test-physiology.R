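test_that("elemental feed content and molar ratio follow the element masses", {
  f <- feed_medium(8.70, 1.0)
  expect_equal(f$carbon_elemental, 8.70 * 10 * 12.011 / 172.26)
  expect_equal(f$nitrogen_elemental, 14.007 / 53.49)
  # printed high-carbon feed lands at the printed molar ratio within 0.3%
  expect_lt(abs(f$c0_n0_ratio - 26.97) / 26.97, 0.003)

  # hand-derived nitrogen content of 1 g/l NH4Cl
  expect_equal(feed_medium(5, 1)$nitrogen_elemental, 0.2618, tolerance = 1e-3)

  # zero carbon feed: zero elemental carbon and zero ratio
  f0 <- feed_medium(0, 1.0)
  expect_equal(f0$carbon_elemental, 0)
  expect_equal(f0$c0_n0_ratio, 0)

  expect_error(feed_medium(-1, 1), ">= 0")
  expect_error(feed_medium(1, 0), "undefined")
})

test_that("yield coefficients reproduce the printed culture table", {
  ref <- table1_reference()
  feed <- read_feed_table(extdata("chemostat_feed.tsv"))
  state <- read_steadystate_table(extdata("chemostat_steadystate.tsv"))
  for (i in seq_along(ref$conditions)) {
    fm <- feed_medium(feed$decanoate_g_per_l[i], feed$nh4cl_g_per_l[i])
    st <- steady_state_record(ref$conditions[i], 0.1, state$cdw_g_per_l[i],
                              state$pha_pct_cdw[i] / 100,
                              state$resid_C_g_per_l[i],
                              state$resid_N_g_per_l[i])
    ys <- yield_coefficients(fm, st)
    expect_lt(abs(ys$y_xc - ref$y_xc[i]) / ref$y_xc[i], 0.02)
    expect_lt(abs(ys$y_xn - ref$y_xn[i]) / ref$y_xn[i], 0.02)
    # internal consistency: y = delta_x / delta
    expect_equal(ys$y_xc, ys$delta_x / ys$delta_c, tolerance = 1e-12)
    expect_equal(ys$y_xn, ys$delta_x / ys$delta_n, tolerance = 1e-12)
  }
  # trivial ratio
  fm <- feed_medium(1.8775, 1)
  st <- steady_state_record("x", 0.1, 2.0, 0)
  expect_equal(yield_coefficients(fm, st)$y_xc,
               2.0 / fm$carbon_elemental)
  # residual exceeding the feed is an error naming the nutrient
  st_bad <- steady_state_record("x", 0.1, 2.0, 0, residual_carbon = 5)
  expect_error(yield_coefficients(fm, st_bad), "carbon")
})

test_that("specific rates use the PHA-free biomass denominator", {
  s <- steady_state_record("n", 0.1, 4.63, 0.8058)
  r <- specific_rates(s)
  expect_equal(r$q_pha, 4.63 * 0.8058 * 0.1 / (4.63 * (1 - 0.8058)))
  expect_equal(r$x_residual, 0.899, tolerance = 1e-3)

  # hand arithmetic: 0.1 * 0.6194 / 0.3806
  s2 <- steady_state_record("d", 0.1, 4.35, 0.6194)
  expect_equal(specific_rates(s2)$q_pha, 0.1 * 0.6194 / 0.3806,
               tolerance = 1e-9)
  expect_equal(specific_rates(s2)$q_pha, 0.163, tolerance = 5e-3)

  expect_equal(specific_rates(steady_state_record("c", 0.1, 2, 0))$q_pha, 0)
  expect_error(steady_state_record("bad", 0.1, 1, 1), "\\[0, 1\\)")

  expect_equal(residual_biomass(steady_state_record("c", 0.1, 1.46, 0.2578)),
               1.084, tolerance = 1e-3)
})

test_that("regime boundary quotient uses the integer element masses", {
  expect_equal(regime_boundary(list(y_xc = 1.11, y_xn = 9.80)),
               9.80 * 14 / (1.11 * 12))
  expect_lt(abs(regime_boundary(list(y_xc = 1.11, y_xn = 9.80)) - 10.40) / 10.40,
            0.01)
  expect_lt(abs(regime_boundary(list(y_xc = 1.01, y_xn = 17.74)) - 20.50) / 20.50,
            0.001)
  # symmetry: y_xn = y_xc * 12/14 gives a boundary of exactly 1
  expect_equal(regime_boundary(list(y_xc = 7, y_xn = 7 * 12 / 14)), 1)
  expect_error(regime_boundary(list(y_xc = 0, y_xn = 1)), "> 0")
})

test_that("regime classification brackets the borders with a closed dual interval", {
  b <- regime_boundaries(10.40, 20.50)
  expect_equal(classify_regime(c(5.83, 16.56, 26.97), b),
               c("carbon", "dual", "nitrogen"))
  # boundary values belong to the dual regime
  expect_equal(classify_regime(c(10.40, 20.50), b), c("dual", "dual"))
  expect_equal(classify_regime(10.40 - 1e-9, b), "carbon")
  expect_equal(classify_regime(20.50 + 1e-9, b), "nitrogen")
  expect_error(regime_boundaries(20, 10), "lower < upper")
})

test_that("boundary is monotone in the yields and epsilon-consistent with classification", {
  set.seed(7)
  for (i in 1:25) {
    y_xc <- runif(1, 0.5, 2); y_xn <- runif(1, 5, 25)
    bd <- regime_boundary(list(y_xc = y_xc, y_xn = y_xn))
    expect_gt(regime_boundary(list(y_xc = y_xc, y_xn = y_xn * 1.1)), bd)
    expect_lt(regime_boundary(list(y_xc = y_xc * 1.1, y_xn = y_xn)), bd)
    b <- regime_boundaries(bd, bd * 1.5)
    expect_equal(classify_regime(bd - 1e-6, b), "carbon")
    expect_equal(classify_regime(bd + 1e-6, b), "dual")
  }
})

test_that("zero-residual yields reproduce the feed ratio through the boundary quotient", {
  # closed-form limit: with no residuals, y_xn/y_xc * 14/12 = C0/N0 computed
  # with the integer masses
  set.seed(11)
  for (i in 1:10) {
    dec <- runif(1, 1, 10); cdw <- runif(1, 0.5, 5)
    fm <- feed_medium(dec, 1)
    st <- steady_state_record("x", 0.1, cdw, 0)
    ys <- yield_coefficients(fm, st)
    ratio_integer_masses <- (fm$carbon_elemental / 12) /
      (fm$nitrogen_elemental / 14)
    expect_equal(regime_boundary(ys), ratio_integer_masses, tolerance = 1e-12)
  }
})

test_that("CO2 evolution rate converts off-gas fractions at the gas molar volume", {
  tr <- chemostat_trace(0:10, rep(1, 11), rep(40, 11), rep(0.01, 11),
                        rep(0.2, 11), gas_flow = 1, culture_volume = 0.8)
  expect_equal(co2_evolution(tr, inlet_co2 = 0), 60 * 0.01 / 24.45 / 0.8,
               tolerance = 1e-12)
  # linear in gas flow
  tr2 <- chemostat_trace(0:10, rep(1, 11), rep(40, 11), rep(0.01, 11),
                         rep(0.2, 11), gas_flow = 2, culture_volume = 0.8)
  expect_equal(co2_evolution(tr2, inlet_co2 = 0),
               2 * co2_evolution(tr, inlet_co2 = 0))
  # outlet equal to inlet: zero
  expect_equal(co2_evolution(tr, inlet_co2 = 0.01), 0)
  # below inlet beyond tolerance: clipped with warning
  expect_warning(v <- co2_evolution(tr, inlet_co2 = 0.02), "clipped")
  expect_equal(v, 0)
})

test_that("carbon balance distributes consumed carbon and reports closure", {
  # hand-built case: consumed 0.1 C-mol/l, residual biomass 0.54 g/l, no PHA,
  # to_co2 0.06 -> shares 20/0/60, closure 0.8
  fm <- feed_medium(0.1 * 12.011 / (10 * 12.011 / 172.26), 1)
  st <- steady_state_record("x", 0.1, 0.54, 0)
  cb <- carbon_balance(fm, st, cer = 0.006)
  expect_equal(cb$consumed, 0.1, tolerance = 1e-12)
  expect_equal(cb$to_biomass, 0.02, tolerance = 1e-12)
  expect_equal(cb$to_pha, 0)
  expect_equal(unname(cb$shares), c(20, 0, 60), tolerance = 1e-9)
  expect_equal(cb$closure, 0.8, tolerance = 1e-12)

  # zero biomass: closure is the CO2 share alone
  st0 <- steady_state_record("x", 0.1, 0, 0)
  cb0 <- carbon_balance(fm, st0, cer = 0.006)
  expect_equal(cb0$closure, cb0$to_co2 / cb0$consumed)

  # over-closure warns but does not fail
  expect_warning(carbon_balance(fm, st, cer = 0.02), "over-closure")
})

test_that("steady-state detection matches the exhaustive window-scan oracle", {
  set.seed(101)
  D <- 0.1
  for (i in 1:40) {
    n <- sample(180:300, 1)
    t <- seq(0, by = 0.25, length.out = n)
    kind <- sample(c("washin", "const", "drift"), 1)
    base <- switch(kind,
      washin = 1 - exp(-D * t),
      const = rep(1, n),
      drift = 1 + 0.002 * t)
    noise <- runif(1, 0, 0.03)
    tr <- chemostat_trace(
      t,
      5 * base * exp(rnorm(n, 0, noise)),
      40 * (2 - base) * exp(rnorm(n, 0, noise)),
      pmin(0.01 * base * exp(rnorm(n, 0, noise)), 1),
      rep(0.2, n))
    got <- detect_steady_state(tr, D)
    want <- oracle_steady_scan(tr, D)
    expect_identical(got$is_steady, want$is_steady)
    expect_equal(got$steady_from, want$steady_from)
  }
})

test_that("steady-state detection enforces the required trace span", {
  tr <- chemostat_trace(seq(0, 10, 0.5), rep(1, 21), rep(40, 21),
                        rep(0.01, 21), rep(0.2, 21))
  expect_error(detect_steady_state(tr, 0.1), "40.0 h")
  # constant trace is steady over any window
  tr2 <- chemostat_trace(seq(0, 50, 0.5), rep(1, 101), rep(40, 101),
                         rep(0.01, 101), rep(0.2, 101))
  det <- detect_steady_state(tr2, 0.1)
  expect_true(det$is_steady)
  expect_equal(det$steady_from, 0)
})
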