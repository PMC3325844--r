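test_that("retention index is exact on ladder points and matches the oracle", {
  lad <- alkane_ladder(10:36, 4 + (10:36 - 10) * 1.05)
  expect_equal(retention_index(lad$rt_min, lad), 100 * lad$n)
  # midway between C10 and C11 is 1050
  lad2 <- alkane_ladder(10:12, c(5, 7, 10))
  expect_equal(retention_index(6, lad2), 1050)
  # irregular ladder vs brute-force piecewise interpolation
  set.seed(21)
  irregular <- alkane_ladder(c(10, 12, 13, 17, 20),
                             cumsum(runif(5, 0.5, 3)))
  rt <- runif(40, min(irregular$rt_min), max(irregular$rt_min))
  expect_equal(retention_index(rt, irregular), oracle_ri(rt, irregular),
               tolerance = 1e-12)
  # monotone in retention time
  expect_true(all(diff(retention_index(sort(rt), irregular)) >= 0))
  # out of span errors unless extrapolation is enabled
  expect_error(retention_index(100, irregular), "outside ladder span")
  expect_gt(retention_index(max(irregular$rt_min) + 1, irregular,
                            extrapolate = TRUE), 2000)
})

test_that("ladder inverse round-trips planted retention indices", {
  lad <- alkane_ladder(10:36, 4 + (10:36 - 10) * 1.05)
  ri <- c(1000, 1234.5, 1733, 2250, 3600)
  expect_equal(retention_index(rt_from_ri(ri, lad), lad), ri,
               tolerance = 1e-9)
})

test_that("match factor is a sqrt-scaled cosine: bounded, symmetric, scale-free", {
  a <- c(`100` = 1, `101` = 1); b <- c(`100` = 1)
  expect_equal(match_factor(a, b), 1 / sqrt(2))
  expect_equal(match_factor(a, a), 1)
  expect_equal(match_factor(c(`50` = 3), c(`60` = 2)), 0)  # disjoint support
  set.seed(33)
  for (i in 1:20) {
    s1 <- setNames(runif(8, 0, 100), sample(40:460, 8))
    s2 <- setNames(runif(8, 0, 100), sample(40:460, 8))
    mf <- match_factor(s1, s2)
    expect_equal(mf, oracle_cosine(s1, s2), tolerance = 1e-12)
    expect_equal(mf, match_factor(s2, s1))
    expect_equal(mf, match_factor(s1 * 7.3, s2 * 0.2))
    expect_true(mf >= 0 && mf <= 1)
  }
  expect_error(match_factor(c(`50` = 0), b), "positive intensity")
})

test_that("annotation applies the RI window and the inclusive 0.75 rule", {
  lib <- default_metabolite_library()
  entry <- lib[[5]]
  peak <- list(retention_index = entry$retention_index,
               spectrum = entry$spectrum)
  hit <- annotate_peak(peak, lib)
  expect_equal(hit$name, entry$name)
  expect_equal(hit$match_factor, 1.0)
  # candidate outside the RI window is never matched
  far <- list(retention_index = entry$retention_index + 50,
              spectrum = entry$spectrum)
  miss <- annotate_peak(far, lib[5])
  expect_null(miss)
  # a match factor just below 0.75 is rejected, exactly 0.75 accepted
  two_thirds <- list(retention_index = 1000,
                     spectrum = c(`50` = 1, `51` = 1, `52` = 1, `53` = 1))
  ref_half <- list(name = "half", retention_index = 1000,
                   spectrum = c(`50` = 1, `51` = 1))
  mf <- match_factor(two_thirds$spectrum, ref_half$spectrum)
  expect_equal(mf, sqrt(1 / 2), tolerance = 1e-9)
  expect_equal(annotate_peak(two_thirds, list(ref_half),
                             min_match = mf)$name, "half")
  expect_null(annotate_peak(two_thirds, list(ref_half),
                            min_match = mf + 1e-9))
  # best-scoring candidate wins
  alt <- list(name = "alt", retention_index = 1000,
              spectrum = c(`50` = 1, `51` = 1, `52` = 1, `53` = 1))
  expect_equal(annotate_peak(two_thirds, list(ref_half, alt))$name, "alt")
})

test_that("normalization divides by IS area and biomass", {
  expect_equal(normalize_abundance(1000, 500, 2), 1.0)
  expect_equal(normalize_abundance(880, 400, 1.1), 2.0)
  expect_equal(normalize_abundance(2 * 880, 400, 1.1), 4.0)  # linear
  expect_error(normalize_abundance(1, 0, 1), "> 0")
  expect_error(normalize_abundance(1, 1, 0), "> 0")
})

test_that("QC metrics compute RSD per group and Pearson across conditions", {
  vals <- data.frame(
    metabolite = rep(c("m1", "m2"), each = 6),
    condition = rep(rep(c("carbon", "dual"), each = 3), 2),
    replicate_class = "biological",
    value = c(9, 10, 11, 18, 20, 22, 5, 5, 5, 10, 10, 10))
  qc <- qc_metrics(vals)
  r <- qc$rsd
  expect_equal(r$rsd[r$metabolite == "m1" & r$condition == "carbon"], 10)
  expect_equal(r$rsd[r$metabolite == "m2" & r$condition == "dual"], 0)
  # identical profiles give Pearson 1
  expect_equal(qc$pearson["carbon", "dual"], 1.0)
  expect_equal(nrow(qc$excluded), 0)
  # zero mean is an error
  vals0 <- data.frame(metabolite = "m", condition = "c",
                      replicate_class = "biological", value = c(0, 0))
  expect_error(qc_metrics(vals0), "mean is zero")
})

test_that("level-change calls gate on fold threshold and QC exclusion", {
  set.seed(55)
  vals <- rbind(
    data.frame(metabolite = "cit", condition = "carbon",
               replicate_class = "biological", value = c(10, 10.5, 9.5)),
    data.frame(metabolite = "cit", condition = "dual",
               replicate_class = "biological", value = c(21, 20, 22)),
    data.frame(metabolite = "flat", condition = "carbon",
               replicate_class = "biological", value = c(5, 5.2, 4.8)),
    data.frame(metabolite = "flat", condition = "dual",
               replicate_class = "biological", value = c(5.1, 5, 4.9)),
    data.frame(metabolite = "wild", condition = "carbon",
               replicate_class = "biological", value = c(1, 30, 2)),
    data.frame(metabolite = "wild", condition = "dual",
               replicate_class = "biological", value = c(8, 8, 8)))
  calls <- level_change_calls(vals, reference = "carbon")
  get <- function(m) calls$call[calls$metabolite == m]
  expect_equal(get("cit"), "up")
  expect_equal(get("flat"), "nc")     # ratio 1: neither up nor down
  expect_equal(get("wild"), "nd")     # excluded by the biological-RSD ceiling
  expect_error(level_change_calls(vals, reference = "absent"), "not present")
})

test_that("the generated metabolome round-trips: annotation and level calls", {
  study <- simulate_study(noise = phaomics:::noise_free(), seed = 6)
  met <- study$metabolites
  lib_names <- vapply(met$library, `[[`, character(1), "name")
  # annotate every generated peak; identity recovery must be complete
  peaks <- met$peaks
  hits <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    pk <- list(retention_index = retention_index(peaks$rt_min[i], met$ladder),
               spectrum = parse_spectrum(peaks$spectrum[i]))
    h <- annotate_peak(pk, met$library)
    hits[i] <- if (is.null(h)) NA_character_ else h$name
  }
  expect_false(anyNA(hits))
  expect_true(all(hits %in% lib_names))
  # planted two-fold changes are recovered as up/down; planted absences as nd
  calls <- level_change_calls(met$values, reference = "carbon")
  pattern <- met$pattern
  for (j in seq_len(nrow(pattern))) {
    for (cond in c("dual", "nitrogen")) {
      want <- pattern[[cond]][j]
      got <- calls$call[calls$metabolite == pattern$metabolite[j] &
                          calls$condition == cond]
      expect_equal(got, want,
                   label = paste(pattern$metabolite[j], cond, got),
                   expected.label = want)
    }
  }
})
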