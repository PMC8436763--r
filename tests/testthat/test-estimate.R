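test_that("basal estimate is the photon-weighted mean of the pre-spike window", {
  tl <- make_flat_timeline(30)
  expect_equal(estimate_basal(tl, ap_time_ms = 510), 30)

  # photon weighting: double the counts on half the window
  tl2 <- make_flat_timeline(30)
  pre <- tl2$time_ms < 510 & tl2$time_ms >= 10
  tl2$ca_nM[pre][1:35] <- 40
  tl2$photons[pre][1:35] <- 2e4
  manual <- weighted.mean(tl2$ca_nM[pre], tl2$photons[pre])
  expect_equal(estimate_basal(tl2, ap_time_ms = 510), manual)

  # window overlapping the start of the recording / the stimulus
  expect_error(estimate_basal(tl, ap_time_ms = 100, window_ms = 500),
               class = "flimca_qc_error")
  # insufficient unflagged bins
  tl3 <- make_flat_timeline(30)
  tl3$flag[tl3$time_ms < 510] <- "low_signal"
  expect_error(estimate_basal(tl3, ap_time_ms = 510),
               class = "flimca_qc_error")
})

test_that("saturated fluorescence follows the printed saturation relation", {
  m <- fx_model
  expect_equal(estimate_fmax(1, 0, m), 6)            # gamma * f_rest
  expect_equal(estimate_fmax(2.5, 1e9, m), 2.5, tolerance = 1e-6)
  expect_equal(estimate_fmax(1, 31, m), 271 / 71)    # = 3.8169...
  expect_error(estimate_fmax(0, 31, m), class = "flimca_domain_error")
  expect_error(estimate_fmax(1, -3, m), class = "flimca_domain_error")
})

test_that("peak inversion is the exact inverse of the saturation law", {
  m <- fx_model
  scale <- 123.4  # arbitrary intensity units
  for (ca in c(0.5, 10, 100, 240, 900, 2399)) {
    f_ca <- scale * saturation_fluorescence(ca, m)
    f_max <- scale * 1  # F(infinity) in the same units
    expect_equal(estimate_peak(f_ca, f_max, m), ca,
                 tolerance = 1e-9)
  }
  # identity with estimate_fmax: no transient returns ca0 exactly
  ca0 <- 40
  f_rest <- scale * saturation_fluorescence(ca0, m)
  f_max <- estimate_fmax(f_rest, ca0, m)
  expect_equal(estimate_peak(f_rest, f_max, m), ca0, tolerance = 1e-9)

  # midpoint between floor and ceiling maps to kd, checked against a
  # brute-force root-finding inversion of F(ca) = f_peak
  f_mid <- f_max * (1 + 1 / m$gamma) / 2
  ca_mid <- estimate_peak(f_mid, f_max, m)
  expect_equal(ca_mid, m$kd, tolerance = 1e-9)
  root <- stats::uniroot(function(ca)
    f_max * saturation_fluorescence(ca, m) - f_mid, c(1, 5000),
    tol = 1e-10)$root
  expect_equal(ca_mid, root, tolerance = 1e-6)

  # pole behaviour: saturation guard refuses divergent estimates
  expect_error(estimate_peak(f_max * 0.999, f_max, m),
               class = "flimca_saturation_error")
  expect_error(estimate_peak(f_max / m$gamma, f_max, m),
               class = "flimca_floor_error")

  # gamma -> infinity limit: classic single-site form kd * F / (Fmax - F)
  m_inf <- indicator_model(gamma = 1e6)
  f <- 0.6
  expect_equal(estimate_peak(f, 1, m_inf),
               m_inf$kd * f / (1 - f), tolerance = 1e-4)
})

test_that("evoked-entry estimate recovers the transient and is scale-free", {
  sc <- ca_scenario(ca0 = 40, delta_ca = 160, photon_rate = 14286)
  cube <- simulate_trial(sc, fx_model, n_pixels = 2, duration_ms = 560,
                         seed = 77)
  tl <- decode_timeline(cube, fx_curve)
  tr <- intensity_trace(cube)
  est <- estimate_delta(tl, tr, ap_time_ms = 510, model = fx_model)
  expect_identical(est$flag, "ok")
  expect_equal(est$delta_nM, 160, tolerance = 0.15)
  expect_equal(est$ca0_nM, 40, tolerance = 0.10)

  # exact scale invariance: both relations are ratios of fluorescence
  tr_scaled <- dplyr::mutate(tr, intensity = intensity * 7.3)
  est_s <- estimate_delta(tl, tr_scaled, ap_time_ms = 510, model = fx_model)
  expect_equal(est_s$delta_nM, est$delta_nM, tolerance = 1e-12)
  expect_equal(est_s$ca_peak_nM, est$ca_peak_nM, tolerance = 1e-12)

  # the conventional max-based peak search also works on a real transient
  est_m <- estimate_delta(tl, tr, ap_time_ms = 510, model = fx_model,
                          peak_method = "max")
  expect_equal(est_m$delta_nM, 160, tolerance = 0.15)

  # a saturating transient is flagged, not reported as a divergent level
  sc_sat <- ca_scenario(ca0 = 40, delta_ca = 30000, photon_rate = 14286)
  cube_sat <- simulate_trial(sc_sat, fx_model, n_pixels = 2,
                             duration_ms = 560, seed = 78)
  est_sat <- estimate_delta(decode_timeline(cube_sat, fx_curve),
                            intensity_trace(cube_sat), 510, fx_model)
  expect_identical(est_sat$flag, "saturated")
  expect_true(is.na(est_sat$delta_nM))
})

test_that("trial-stability QC computes the CV and applies the ~20% rule", {
  r1 <- qc_trial_stability(c(100, 100, 100))
  expect_equal(r1$cv, 0); expect_true(r1$pass)

  r2 <- qc_trial_stability(c(100, 160))
  expect_equal(r2$cv, sd(c(100, 160)) / 130)   # 0.3264
  expect_equal(r2$cv, 0.3264, tolerance = 1e-3)
  expect_false(r2$pass)

  r3 <- qc_trial_stability(c(100, 105, 95))
  expect_equal(r3$cv, 0.05, tolerance = 1e-12)
  expect_true(r3$pass)

  r4 <- qc_trial_stability(42)
  expect_true(r4$pass)
  expect_identical(r4$flag, "single_trial")
})

test_that("lifetime and intensity decays cross-validate on shared truth", {
  sc <- ca_scenario(ca0 = 30, delta_ca = 80, decay_tau_ms = 300,
                    photon_rate = 14286)
  cube <- simulate_trial(sc, fx_model, n_pixels = 2, duration_ms = 900,
                         seed = 55)
  tl <- decode_timeline(cube, fx_curve)
  tr <- intensity_trace(cube)
  cv <- crossvalidate_decay(tl, tr, ap_time_ms = 510)
  expect_identical(cv$flag, "ok")
  expect_lt(cv$score, 0.3)
  expect_true(cv$pass)

  # amplitude rescaling leaves the score untouched
  cv_s <- crossvalidate_decay(tl, dplyr::mutate(tr, intensity = intensity * 40),
                              ap_time_ms = 510)
  expect_equal(cv_s$score, cv$score, tolerance = 1e-12)

  # a constant trace cannot match the decoded decay
  cv_c <- crossvalidate_decay(tl, dplyr::mutate(tr, intensity = 1000),
                              ap_time_ms = 510)
  expect_false(isTRUE(cv_c$pass))

  # no in-range segment -> not applicable
  cv_na <- crossvalidate_decay(tl, tr, ap_time_ms = 510, linear_range_nM = 1)
  expect_identical(cv_na$flag, "not_applicable")
})
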