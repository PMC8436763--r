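test_that("decay density has the correct zero-Ca and saturation limits", {
  tt <- seq(0, 12.5, by = 0.01)
  W <- fx_model$rep_window

  # ca = 0: pure truncated exponential with tau_free
  expect_equal(bound_weight(0, fx_model), 0)
  ref_free <- exp(-tt / 0.7) / (0.7 * (1 - exp(-W / 0.7)))
  expect_equal(decay_density(tt, 0, fx_model), ref_free, tolerance = 1e-12)

  # ca -> infinity: pure tau_bound
  expect_equal(bound_weight(1e12, fx_model), 1, tolerance = 1e-9)
  ref_bound <- exp(-tt / 3.7) / (3.7 * (1 - exp(-W / 3.7)))
  expect_equal(decay_density(tt, 1e12, fx_model), ref_bound, tolerance = 1e-9)

  expect_error(decay_density(tt, -5, fx_model), class = "flimca_domain_error")
})

test_that("mixture weight at ca = kd matches direct arithmetic and the density", {
  # gamma * f / (gamma * f + 1 - f) with f = 1/2
  expect_equal(bound_weight(240, fx_model), 6 / 7)

  # recover the weight from the density itself by solving a 2x2 linear
  # system at two time points (independent of the weight formula)
  comp <- function(tau, t) exp(-t / tau) / (tau * (1 - exp(-12.5 / tau)))
  t1 <- 0.5; t2 <- 6
  A <- matrix(c(comp(3.7, t1), comp(0.7, t1),
                comp(3.7, t2), comp(0.7, t2)), 2, byrow = TRUE)
  y <- c(decay_density(t1, 240, fx_model), decay_density(t2, 240, fx_model))
  w <- solve(A, y)
  expect_equal(w[1], 6 / 7, tolerance = 1e-10)
  expect_equal(sum(w), 1, tolerance = 1e-10)
})

test_that("decay density integrates to one and slows monotonically with Ca", {
  for (ca in c(0, 5, 50, 240, 1000)) {
    q <- stats::integrate(decay_density, 0, 12.5, ca = ca, model = fx_model,
                          rel.tol = 1e-10)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
  # mean photon arrival time strictly increasing in ca
  grid <- seq(0, 1000, by = 50)
  mean_t <- vapply(grid, function(ca) {
    stats::integrate(function(t) t * decay_density(t, ca, fx_model), 0, 12.5,
                     rel.tol = 1e-10)$value
  }, numeric(1))
  expect_true(all(diff(mean_t) > 0))
})

test_that("simulated decay histograms are seeded, Poisson, and recover tau_free", {
  h1 <- simulate_decay(100, fx_model, 1e5, fx_binning, seed = 42)
  h2 <- simulate_decay(100, fx_model, 1e5, fx_binning, seed = 42)
  expect_identical(h1$counts, h2$counts)
  h3 <- simulate_decay(100, fx_model, 1e5, fx_binning, seed = 43)
  expect_false(identical(h1$counts, h3$counts))

  # Poisson moments: mean of total counts over 500 draws
  totals <- vapply(1:500, function(s)
    sum(simulate_decay(50, fx_model, 1000, fx_binning, seed = s)$counts),
    numeric(1))
  expect_lt(abs(mean(totals) - 1000), 3 * sqrt(1000 / 500))

  # ML monoexponential fit at ca = 0 recovers tau_free within 2%
  h0 <- simulate_decay(0, fx_model, 1e6, fx_binning, seed = 7)
  tau_hat <- fit_monoexp_tau(h0)
  expect_lt(abs(tau_hat - fx_model$tau_free) / fx_model$tau_free, 0.02)

  expect_error(simulate_decay(100, fx_model, 0, fx_binning),
               class = "flimca_config_error")
  expect_error(decay_binning(n_bins = 5), class = "flimca_config_error")
})

test_that("trial simulator obeys the shared saturation law", {
  # intensity peak/rest ratio equals F(ca0 + delta) / F(ca0)
  sc <- ca_scenario(ca0 = 40, delta_ca = 160, decay_tau_ms = 400,
                    ap_time_ms = 510, photon_rate = 30000)
  cube <- simulate_trial(sc, fx_model, n_pixels = 2, duration_ms = 600,
                         seed = 5)
  tr <- intensity_trace(cube)
  rest <- mean(tr$intensity[tr$time_ms < 510])
  peak <- mean(tr$intensity[tr$time_ms > 513 & tr$time_ms < 518])
  expected_ratio <- saturation_fluorescence(200, fx_model) /
    saturation_fluorescence(40, fx_model)
  expect_equal(peak / rest, expected_ratio, tolerance = 0.02)

  # two seeds differ but share expected totals within 4 SD
  sc0 <- ca_scenario(ca0 = 40, delta_ca = 0, photon_rate = 1000)
  c1 <- simulate_trial(sc0, fx_model, duration_ms = 560, seed = 1)
  c2 <- simulate_trial(sc0, fx_model, duration_ms = 560, seed = 2)
  expect_false(identical(c1$counts, c2$counts))
  expected_total <- 1000 * 560
  for (tot in c(sum(c1$counts), sum(c2$counts))) {
    expect_lt(abs(tot - expected_total), 4 * sqrt(expected_total))
  }

  expect_error(simulate_trial(sc, fx_model, duration_ms = 100),
               class = "flimca_config_error")
  expect_error(ca_scenario(ap_time_ms = 200), class = "flimca_config_error")
  expect_error(ca_scenario(ca0 = -1), class = "flimca_domain_error")
})

test_that("population generator honours nesting, effects, and determinism", {
  # degenerate variances: all boutons of one order/condition identical
  d0 <- population_design(n_cells = 6, boutons_per_cell = 3,
                          cell_sd = 0, bouton_sd = 0, seed = 2)
  pop0 <- simulate_population(d0)
  per_group <- dplyr::summarise(
    pop0, sd_ca0 = sd(true_ca0_nM), sd_delta = sd(true_delta_nM),
    .by = c("branch_order", "condition"))
  expect_true(all(per_group$sd_ca0 == 0 & per_group$sd_delta == 0))

  # multiplicative condition effect on delta: population mean ratio ~ 0.31
  d1 <- population_design(
    n_cells = 300, boutons_per_cell = 2, cell_sd = 0,
    bouton_sd = c(ca0 = 3, delta = 5),
    condition_effects = list(control = c(ca0 = 1, delta = 1),
                             tboa = c(ca0 = 1, delta = 0.31)),
    seed = 9)
  pop1 <- simulate_population(d1)
  means <- dplyr::summarise(pop1, m = mean(true_delta_nM), .by = "condition")
  ratio <- means$m[means$condition == "tboa"] /
    means$m[means$condition == "control"]
  expect_equal(ratio, 0.31, tolerance = 0.05)

  # paired structure: same boutons in both conditions
  expect_setequal(pop1$bouton_id[pop1$condition == "tboa"],
                  pop1$bouton_id[pop1$condition == "control"])

  # determinism
  expect_identical(simulate_population(d1), simulate_population(d1))

  expect_error(population_design(n_cells = 0), class = "flimca_config_error")
})

test_that("a blurred instrument response stays normalized and decodable", {
  b <- fx_binning
  p0 <- flimca:::decay_bin_probs(100, fx_model, b)
  pb <- flimca:::decay_bin_probs(100, fx_model, b, irf_sigma_ns = 0.1)
  expect_equal(sum(pb), 1, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(p0, pb)))
  # peak shifts off the first bin but NTC stays monotone in Ca
  h <- expected_decay(100, fx_model, 1e6, b, irf_sigma_ns = 0.1)
  expect_gt(which.max(h$counts), 1)
  ntc <- vapply(c(0, 30, 100, 300, 1000), function(ca)
    compute_ntc(expected_decay(ca, fx_model, 1, b, irf_sigma_ns = 0.1)),
    numeric(1))
  expect_true(all(diff(ntc) > 0))
  # decoding against a blur-matched calibration still recovers the level
  ladder <- c(1, 17, 38, 100, 150, 300, 602)
  cal <- purrr::map_dfr(ladder, function(ca) tibble::tibble(
    ca_nM = ca,
    ntc = compute_ntc(expected_decay(ca, fx_model, 1, b, irf_sigma_ns = 0.1))))
  curve_b <- fit_calibration(cal, b)
  hh <- simulate_decay(60, fx_model, 1e6, b, seed = 3, irf_sigma_ns = 0.1)
  expect_equal(invert_calibration(curve_b, compute_ntc(hh))$ca_nM, 60,
               tolerance = 0.05)
})
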