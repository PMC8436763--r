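# Shared fixtures, built once per test run (everything is generated in code;
# no stored data).

fx_model <- indicator_model()
fx_binning <- decay_binning()

# Reference (noiseless) calibration implied by the generative model.
fx_truth <- calibration_truth(fx_model, fx_binning)

# A realistic noisy calibration: 1e6-photon histograms on the standard
# clamped-solution ladder.
fx_ladder <- c(0, 17, 38, 100, 150, 300, 602)
fx_cal_data <- purrr::map_dfr(seq_along(fx_ladder), function(i) {
  h <- simulate_decay(fx_ladder[i], fx_model, 1e6, fx_binning, seed = 400 + i)
  tibble::tibble(ca_nM = fx_ladder[i], ntc = compute_ntc(h))
})
fx_curve <- fit_calibration(fx_cal_data, fx_binning)

# Hand-built flat timeline for estimator unit tests (no simulation noise).
make_flat_timeline <- function(ca, n_bins = 100, bin_ms = 7,
                               photons = 1e4) {
  tl <- tibble::tibble(
    time_ms = (seq_len(n_bins) - 0.5) * bin_ms,
    n_cycles = bin_ms,
    photons = photons,
    ntc = NA_real_,
    ca_nM = ca,
    ca_sd_nM = 1,
    flag = "ok"
  )
  structure(tl, class = c("ca_timeline", class(tl)),
            cycle_period_ms = 1, metadata = list())
}

# Maximum-likelihood monoexponential lifetime fit on a binned histogram
# (independent oracle for the simulator's zero-Ca limit).
fit_monoexp_tau <- function(hist) {
  edges <- hist$binning$bin_edges
  W <- max(edges)
  nll <- function(tau) {
    p <- diff(1 - exp(-edges / tau)) / (1 - exp(-W / tau))
    -sum(hist$counts * log(p))
  }
  stats::optimize(nll, c(0.1, 10))$minimum
}
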