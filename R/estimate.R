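#' Resting [Ca2+] from a decoded timeline
#'
#' Photon-count-weighted mean of the decoded Ca2+ over an averaging window
#' (default ~500 ms) immediately preceding the action potential.
#'
#' @param timeline A `ca_timeline` from [decode_timeline()].
#' @param ap_time_ms Stimulus onset, ms; the window is
#'   `[ap_time_ms - window_ms, ap_time_ms)` and must lie inside the
#'   recording.
#' @param window_ms Basal averaging window, ms. Default 500.
#' @param min_bins Minimum number of unflagged bins required. Default 10.
#' @return Resting Ca2+, nM (scalar).
#' @export
estimate_basal <- function(timeline, ap_time_ms, window_ms = 500,
                           min_bins = 10) {
  tl <- tibble::as_tibble(timeline)
  if (ap_time_ms - window_ms < min(tl$time_ms) - attr_bin_width(tl)) {
    abort("Basal window extends beyond the recording start (overlaps the stimulus setup).",
          class = "flimca_qc_error")
  }
  basal <- dplyr::filter(
    tl, .data$time_ms >= ap_time_ms - window_ms, .data$time_ms < ap_time_ms,
    .data$flag == "ok")
  if (nrow(basal) < min_bins) {
    abort(sprintf("Only %d unflagged bins in the basal window (need >= %d).",
                  nrow(basal), min_bins),
          class = "flimca_qc_error")
  }
  weighted.mean(basal$ca_nM, basal$photons)
}

attr_bin_width <- function(tl) {
  if (nrow(tl) > 1) diff(tl$time_ms[1:2]) / 2 else 0
}

#' Saturated indicator fluorescence from the resting state
#'
#' With the resting level known from the lifetime readout, the saturation
#' ceiling of a single-wavelength indicator follows from its affinity and
#' dynamic range alone:
#' \deqn{F_{max} = F_{rest}\,\frac{[Ca^{2+}]_0 + K_d}{[Ca^{2+}]_0 + K_d/\gamma}}
#'
#' @param f_rest Resting fluorescence, any consistent intensity unit (> 0).
#' @param ca0 Resting Ca2+, nM (from [estimate_basal()]).
#' @param model An [indicator_model()].
#' @return `F_max` in the units of `f_rest`.
#' @export
estimate_fmax <- function(f_rest, ca0, model) {
  if (any(f_rest <= 0)) {
    abort("`f_rest` must be positive.", class = "flimca_domain_error")
  }
  check_ca(ca0)
  f_rest * (ca0 + model$kd) / (ca0 + model$kd / model$gamma)
}

#' Peak [Ca2+] from peak fluorescence via the saturation law
#'
#' Inverts the single-wavelength saturation curve:
#' \deqn{[Ca^{2+}]_{peak} = K_d\,\frac{F_{peak} - F_{max}/\gamma}
#'   {F_{max} - F_{peak}}}
#' Composing with [estimate_fmax()] makes this the exact inverse of the
#' fluorescence law `F(ca)`, so `f_peak = F(ca0)` returns `ca0` identically.
#'
#' @param f_peak Peak fluorescence, same units as `f_max`. Must lie strictly
#'   between `f_max / gamma` (the Ca-free floor) and `sat_guard * f_max`;
#'   approaching `f_max` the estimate diverges, so values above the guard
#'   raise a saturation error rather than report a divergent level.
#' @param f_max Saturated fluorescence from [estimate_fmax()].
#' @param model An [indicator_model()].
#' @param sat_guard Saturation guard as a fraction of `f_max`. Default 0.95.
#' @return Peak Ca2+, nM.
#' @export
estimate_peak <- function(f_peak, f_max, model, sat_guard = 0.95) {
  if (any(f_peak >= sat_guard * f_max)) {
    abort("`f_peak` at or beyond the saturation guard: indicator saturated.",
          class = "flimca_saturation_error")
  }
  if (any(f_peak <= f_max / model$gamma)) {
    abort("`f_peak` at or below the Ca-free fluorescence floor.",
          class = "flimca_floor_error")
  }
  model$kd * (f_peak - f_max / model$gamma) / (f_max - f_peak)
}

#' Spike-evoked Ca2+ entry from lifetime + intensity readouts
#'
#' The evoked increment `delta = ca_peak - ca0`. The rapid rise of the
#' transient (1-2 ms) is faster than the lifetime averaging step (~7 ms), so
#' the peak is taken from the per-cycle intensity trace: `f_rest` is the
#' trace mean over the basal window and `f_peak` is located within
#' `search_ms` after the stimulus. Both printed relations are ratios of
#' fluorescence, so the result is invariant to any overall rescaling of the
#' trace.
#'
#' Two peak estimators are available. `"window"` (default) averages the
#' trace over a short fixed window after diffusion equilibration
#' (`ap + equil_ms` to `ap + equil_ms + peak_avg_ms`); it is unbiased when
#' no transient occurred. `"max"` takes the maximum of the (optionally
#' 2-cycle smoothed) trace in the search window; it is the conventional
#' low-SNR choice but positively biased under the null, since the maximum
#' of pure noise exceeds its mean.
#'
#' @param timeline A `ca_timeline` (provides the resting level).
#' @param trace An intensity trace tibble (`time_ms`, `intensity`) from
#'   [intensity_trace()].
#' @param ap_time_ms Stimulus onset, ms.
#' @param model An [indicator_model()].
#' @param search_ms Peak search window after the stimulus, ms. Default 20.
#' @param basal_window_ms Basal averaging window, ms. Default 500.
#' @param peak_method `"window"` or `"max"` (see above).
#' @param equil_ms Diffusion-equilibration delay before the peak window, ms.
#'   Default 3.
#' @param peak_avg_ms Width of the fixed peak window, ms. Default 5.
#' @param smooth_cycles Smoothing span (cycles) for `peak_method = "max"`.
#'   Default 2.
#' @return A tibble with one row: `ca0_nM`, `ca_peak_nM`, `delta_nM`,
#'   `f_rest`, `f_peak`, `f_max`, `flag` (`"ok"`, `"saturated"`,
#'   `"below_floor"`; failures leave `delta_nM` missing, not fabricated).
#' @export
estimate_delta <- function(timeline, trace, ap_time_ms, model,
                           search_ms = 20, basal_window_ms = 500,
                           peak_method = c("window", "max"),
                           equil_ms = 3, peak_avg_ms = 5,
                           smooth_cycles = 2) {
  peak_method <- match.arg(peak_method)
  ca0 <- estimate_basal(timeline, ap_time_ms, window_ms = basal_window_ms)
  if (max(trace$time_ms) < ap_time_ms + search_ms) {
    abort("Intensity trace does not cover the peak search window.",
          class = "flimca_config_error")
  }
  rest <- dplyr::filter(trace, .data$time_ms >= ap_time_ms - basal_window_ms,
                        .data$time_ms < ap_time_ms)
  f_rest <- mean(rest$intensity)

  if (peak_method == "window") {
    win <- dplyr::filter(trace, .data$time_ms >= ap_time_ms + equil_ms,
                         .data$time_ms < ap_time_ms + equil_ms + peak_avg_ms)
    f_peak <- mean(win$intensity)
  } else {
    win <- dplyr::filter(trace, .data$time_ms >= ap_time_ms,
                         .data$time_ms < ap_time_ms + search_ms)
    y <- win$intensity
    if (smooth_cycles > 1) {
      y <- as.numeric(stats::filter(y, rep(1 / smooth_cycles, smooth_cycles),
                                    sides = 2))
    }
    f_peak <- max(y, na.rm = TRUE)
  }

  f_max <- estimate_fmax(f_rest, ca0, model)
  res <- tryCatch(
    list(ca_peak = estimate_peak(f_peak, f_max, model), flag = "ok"),
    flimca_saturation_error = function(e) list(ca_peak = NA_real_,
                                               flag = "saturated"),
    flimca_floor_error = function(e) list(ca_peak = NA_real_,
                                          flag = "below_floor")
  )
  tibble::tibble(
    ca0_nM = ca0, ca_peak_nM = res$ca_peak,
    delta_nM = res$ca_peak - ca0,
    f_rest = f_rest, f_peak = f_peak, f_max = f_max, flag = res$flag
  )
}

#' Trial-to-trial stability QC
#'
#' Boutons whose baseline or evoked Ca2+ fluctuates by more than ~20%
#' between trials are discarded. The criterion is the coefficient of
#' variation (sample SD / mean) across trials.
#'
#' @param values Per-trial estimates (basal or evoked Ca2+), length >= 1.
#' @param max_cv Failure threshold. Default 0.20.
#' @return A tibble with `cv`, `pass`, `n_trials`, `flag` (`"ok"` or
#'   `"single_trial"` when only one trial exists -- pass by default, flagged).
#' @export
qc_trial_stability <- function(values, max_cv = 0.20) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    return(tibble::tibble(cv = NA_real_, pass = TRUE,
                          n_trials = length(values), flag = "single_trial"))
  }
  cv <- sd(values) / mean(values)
  tibble::tibble(cv = cv, pass = cv <= max_cv, n_trials = length(values),
                 flag = "ok")
}

#' Cross-validate the lifetime decay against the intensity decay
#'
#' Within the indicator's linear range the intensity trace and the decoded
#' lifetime readout must relax along the same time course after a spike.
#' Both post-stimulus decays are amplitude-normalized (rest level mapped to
#' 0, segment peak to 1) on the timeline's time grid, and the score is their
#' root-mean-square difference: 0 for identical shapes, larger for
#' mismatch, and invariant to any rescaling of the trace.
#'
#' @param timeline A `ca_timeline`.
#' @param trace An intensity trace tibble (`time_ms`, `intensity`).
#' @param ap_time_ms Stimulus onset, ms.
#' @param linear_range_nM Upper bound of the linear range; only bins whose
#'   decoded Ca2+ is at or below it enter the comparison. Default `kd / 2`
#'   with the standard OGB-1 affinity, i.e. 120 nM.
#' @param basal_window_ms Basal window used for the rest levels, ms.
#' @param cutoff Score above which the trial is flagged as mismatched.
#'   Default 0.3.
#' @param min_bins Minimum in-range bins; fewer gives a not-applicable
#'   result. Default 5.
#' @return A tibble with `score`, `pass`, `n_bins`, `flag` (`"ok"` or
#'   `"not_applicable"`).
#' @export
crossvalidate_decay <- function(timeline, trace, ap_time_ms,
                                linear_range_nM = 120,
                                basal_window_ms = 500, cutoff = 0.3,
                                min_bins = 5) {
  tl <- tibble::as_tibble(timeline)
  bw <- if (nrow(tl) > 1) diff(tl$time_ms[1:2]) else 7
  # intensity averaged onto the timeline's bins
  tr_bin <- trace |>
    dplyr::mutate(bin = floor((.data$time_ms - 1e-9) / bw)) |>
    dplyr::summarise(intensity = mean(.data$intensity), .by = "bin") |>
    dplyr::mutate(time_ms = (.data$bin + 0.5) * bw)
  joined <- dplyr::inner_join(tl, tr_bin[c("time_ms", "intensity")],
                              by = "time_ms")

  seg <- dplyr::filter(joined, .data$time_ms >= ap_time_ms,
                       .data$flag == "ok",
                       .data$ca_nM <= linear_range_nM)
  if (nrow(seg) < min_bins) {
    return(tibble::tibble(score = NA_real_, pass = NA, n_bins = nrow(seg),
                          flag = "not_applicable"))
  }
  basal <- dplyr::filter(joined, .data$time_ms >= ap_time_ms - basal_window_ms,
                         .data$time_ms < ap_time_ms, .data$flag == "ok")
  norm01 <- function(x, rest) {
    rng <- max(x) - rest
    if (rng <= 0) return(rep(Inf, length(x)))
    (x - rest) / rng
  }
  s_flim <- norm01(seg$ca_nM, mean(basal$ca_nM))
  s_int <- norm01(seg$intensity, mean(basal$intensity))
  score <- if (any(!is.finite(s_flim)) || any(!is.finite(s_int))) {
    Inf
  } else {
    sqrt(mean((s_flim - s_int)^2))
  }
  tibble::tibble(score = score, pass = score <= cutoff, n_bins = nrow(seg),
                 flag = "ok")
}
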