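#' Single-trial Ca2+ transient scenario
#'
#' Ground-truth description of one tornado-scan trial: a resting level, an
#' action-potential-evoked step that equilibrates across the bouton within a
#' few ms, and a slow exponential relaxation back to rest.
#'
#' @param ca0 Resting free Ca2+, nM.
#' @param delta_ca Evoked increment, nM (0 gives a null trial).
#' @param rise_ms Equilibration time of the evoked step, ms (<= 3; diffusion
#'   equilibrates a ~1 um bouton in 2-3 ms). Default 2.
#' @param decay_tau_ms Decay constant of the transient, ms. Default 400.
#' @param ap_time_ms Stimulus onset, ms. Must be >= 500 so a full basal
#'   averaging window precedes the spike. Default 510.
#' @param photon_rate Expected photons per scan cycle at the resting level.
#'   Default 2000 (a bright, superficial bouton).
#' @return An object of class `ca_scenario`.
#' @export
ca_scenario <- function(ca0 = 40, delta_ca = 160, rise_ms = 2,
                        decay_tau_ms = 400, ap_time_ms = 510,
                        photon_rate = 2000) {
  if (ca0 < 0 || delta_ca < 0) {
    abort("`ca0` and `delta_ca` must be >= 0.", class = "flimca_domain_error")
  }
  if (rise_ms > 3 || rise_ms <= 0) {
    abort("`rise_ms` must be in (0, 3] ms.", class = "flimca_domain_error")
  }
  if (ap_time_ms < 500) {
    abort("`ap_time_ms` must be >= 500 ms so a full basal window exists.",
          class = "flimca_config_error")
  }
  if (decay_tau_ms <= 0 || photon_rate < 0) {
    abort("`decay_tau_ms` must be > 0 and `photon_rate` >= 0.",
          class = "flimca_config_error")
  }
  structure(
    list(ca0 = ca0, delta_ca = delta_ca, rise_ms = rise_ms,
         decay_tau_ms = decay_tau_ms, ap_time_ms = ap_time_ms,
         photon_rate = photon_rate),
    class = "ca_scenario"
  )
}

#' True Ca2+ time course of a scenario
#'
#' @param scenario A [ca_scenario()].
#' @param t_ms Times, ms (vectorised).
#' @return Free Ca2+ in nM at each time.
#' @export
scenario_ca <- function(scenario, t_ms) {
  s <- scenario
  ca <- rep(s$ca0, length(t_ms))
  rising <- t_ms >= s$ap_time_ms & t_ms < s$ap_time_ms + s$rise_ms
  ca[rising] <- s$ca0 + s$delta_ca * (t_ms[rising] - s$ap_time_ms) / s$rise_ms
  after <- t_ms >= s$ap_time_ms + s$rise_ms
  ca[after] <- s$ca0 +
    s$delta_ca * exp(-(t_ms[after] - s$ap_time_ms - s$rise_ms) / s$decay_tau_ms)
  ca
}

#' Construct a tornado-scan photon-count cube
#'
#' The raw-data unit of the pipeline: photon counts indexed
#' (t: ns decay bin, x, y: scan pixels, T: scan-cycle index). The spiral
#' trajectory is abstracted to `n_x` pixels of equal dwell (all spatial
#' information is discarded before analysis anyway).
#'
#' @param counts 4-d non-negative array, dims (t, x, y, T).
#' @param binning The [decay_binning()] of the t axis.
#' @param cycle_period_ms Duration of one spiral scan cycle, ms (typically
#'   1-1.5 ms).
#' @param metadata Named list; by convention `bouton_id`, `cell_id`,
#'   `trial`, `ap_time_ms`.
#' @return An object of class `scan_cube`.
#' @export
scan_cube <- function(counts, binning, cycle_period_ms, metadata = list()) {
  if (length(dim(counts)) != 4L) {
    abort("`counts` must be a 4-d (t, x, y, T) array.",
          class = "flimca_config_error")
  }
  if (dim(counts)[1] != binning$n_bins) {
    abort("t dimension must match the binning.", class = "flimca_config_error")
  }
  if (any(counts < 0)) {
    abort("Counts must be non-negative.", class = "flimca_domain_error")
  }
  structure(
    list(counts = counts, binning = binning,
         cycle_period_ms = cycle_period_ms, metadata = metadata),
    class = "scan_cube"
  )
}

#' @export
print.scan_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<scan_cube> t:%d x:%d y:%d T:%d, cycle %g ms (%g ms total), %g photons\n",
    d[1], d[2], d[3], d[4], x$cycle_period_ms, d[4] * x$cycle_period_ms,
    sum(x$counts)))
  invisible(x)
}

#' Simulate one tornado-scan FLIM trial
#'
#' Generates a photon-count cube whose per-cycle expected flux follows the
#' indicator saturation law `F(ca(t))` (normalized so the basal flux equals
#' the scenario's `photon_rate`), and whose decay-bin distribution at each
#' cycle follows [decay_density()] at the instantaneous Ca2+ level. Counts
#' are independent Poisson draws per (bin, pixel, cycle) cell.
#'
#' @param scenario A [ca_scenario()].
#' @param model An [indicator_model()].
#' @param n_pixels Pixels per scan cycle (equal dwell). Default 4.
#' @param duration_ms Trial duration, ms; must cover the stimulus and its
#'   rise. Default 700.
#' @param cycle_period_ms Scan-cycle period, ms. Default 1.
#' @param binning A [decay_binning()].
#' @param seed Integer seed.
#' @param metadata Passed to [scan_cube()]; `ap_time_ms` is always recorded.
#' @return A [scan_cube()].
#' @export
simulate_trial <- function(scenario, model, n_pixels = 4, duration_ms = 700,
                           cycle_period_ms = 1, binning = decay_binning(),
                           seed = 1L, metadata = list()) {
  if (cycle_period_ms <= 0 || duration_ms <= 0 || n_pixels < 1) {
    abort("Geometry parameters must be positive.",
          class = "flimca_config_error")
  }
  if (duration_ms < scenario$ap_time_ms + scenario$rise_ms) {
    abort("`duration_ms` must cover the stimulus and its rise.",
          class = "flimca_config_error")
  }
  n_cycles <- floor(duration_ms / cycle_period_ms)
  t_mid <- (seq_len(n_cycles) - 0.5) * cycle_period_ms
  ca_t <- scenario_ca(scenario, t_mid)
  flux <- scenario$photon_rate *
    saturation_fluorescence(ca_t, model) / saturation_fluorescence(scenario$ca0, model)

  # expected counts per (t-bin, cycle); bin probabilities only need computing
  # once per distinct ca value (the whole pre-stimulus epoch shares one)
  uca <- unique(ca_t)
  pmat <- vapply(uca, decay_bin_probs, numeric(binning$n_bins),
                 model = model, binning = binning)
  lambda <- pmat[, match(ca_t, uca), drop = FALSE] *
    rep(flux / n_pixels, each = binning$n_bins)

  counts <- withr::with_seed(seed, {
    arr <- array(0L, dim = c(binning$n_bins, n_pixels, 1L, n_cycles))
    for (px in seq_len(n_pixels)) {
      arr[, px, 1L, ] <- rpois(length(lambda), lambda)
    }
    arr
  })
  md <- utils::modifyList(list(ap_time_ms = scenario$ap_time_ms), metadata)
  scan_cube(counts, binning, cycle_period_ms, md)
}

#' Per-cycle fluorescence intensity trace of a cube
#'
#' Total photon counts per scan cycle (all decay bins and pixels summed) --
#' the analogue-integration readout that accompanies every FLIM recording
#' and feeds the peak-fluorescence side of the evoked-Ca2+ estimator.
#'
#' @param cube A [scan_cube()].
#' @return A tibble with `time_ms` (cycle midpoints) and `intensity`.
#' @export
intensity_trace <- function(cube) {
  n_cycles <- dim(cube$counts)[4]
  tibble::tibble(
    time_ms = (seq_len(n_cycles) - 0.5) * cube$cycle_period_ms,
    intensity = as.numeric(apply(cube$counts, 4, sum))
  )
}

#' Write / read a scan cube as a JSON container
#'
#' Plain-text hierarchical container with datasets `counts` (flattened, with
#' `dims`), `bin_edges`, `cycle_period_ms` and a `metadata` attribute block.
#'
#' @param cube A [scan_cube()].
#' @param path File path (`.json`).
#' @return `write_scan_cube()` returns `path` invisibly; `read_scan_cube()`
#'   returns a [scan_cube()].
#' @export
write_scan_cube <- function(cube, path) {
  obj <- list(
    format = "flimca_scan_cube_v1",
    dims = dim(cube$counts),
    counts = as.integer(cube$counts),
    bin_edges = cube$binning$bin_edges,
    cycle_period_ms = cube$cycle_period_ms,
    metadata = cube$metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scan_cube
#' @export
read_scan_cube <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "flimca_scan_cube_v1")) {
    abort("Not a flimca scan-cube container.", class = "flimca_io_error")
  }
  bw <- diff(obj$bin_edges)[1]
  binning <- decay_binning(length(obj$bin_edges) - 1L, bw)
  scan_cube(array(obj$counts, dim = obj$dims), binning,
            obj$cycle_period_ms, as.list(obj$metadata))
}
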