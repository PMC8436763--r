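#' Normalized Total Count (NTC) of a decay histogram
#'
#' The lifetime summary statistic used throughout the pipeline: photon counts
#' integrated over a fixed window after the excitation pulse, divided by the
#' histogram's peak value. Slower decays (higher Ca2+) spread the same peak
#' over more bins, so NTC increases monotonically with Ca2+.
#'
#' The pulse origin is taken as the argmax of the histogram after a 3-bin
#' moving-average smooth (shot noise makes the raw argmax unstable at low
#' counts); the peak value used for normalization is the smoothed maximum by
#' default, with `smooth = FALSE` giving the raw maximum.
#'
#' @param hist A [decay_histogram()].
#' @param window_ns Integration window after the origin, ns (default 9).
#' @param smooth Use the 3-bin smoothed histogram for origin detection and
#'   peak normalization (default `TRUE`).
#' @param min_peak_counts Minimum acceptable peak value; below it a
#'   low-signal error (`flimca_low_signal`) is thrown. Default 0 (off).
#' @return A single unitless number.
#' @examples
#' m <- indicator_model()
#' h <- simulate_decay(100, m, 1e5, seed = 7)
#' compute_ntc(h)
#' @export
compute_ntc <- function(hist, window_ns = 9, smooth = TRUE,
                        min_peak_counts = 0) {
  counts <- hist$counts
  if (sum(counts) == 0) {
    abort("All-zero histogram: NTC undefined.", class = "flimca_low_signal")
  }
  bw <- hist$binning$bin_width_ns
  sm <- smooth3(counts)
  origin <- hist$origin %||% which.max(sm)
  peak <- if (smooth) max(sm) else max(counts)
  if (peak < min_peak_counts) {
    abort(sprintf("Peak count %.1f below min_peak_counts = %g.", peak,
                  min_peak_counts),
          class = "flimca_low_signal")
  }
  n_window <- round(window_ns / bw)
  last <- origin + n_window - 1L
  if (last > length(counts)) {
    abort("Integration window extends past the acquisition span.",
          class = "flimca_config_error")
  }
  sum(counts[origin:last]) / peak
}

# NTC plus a Poisson delta-method variance. The peak bins are part of the
# window sum, so for NTC = S / P with P the k-bin smoothed peak (expected
# bin counts ~ k P), first-order propagation of the ratio gives
#   var(NTC) / NTC^2 ~ var(S)/S^2 + var(P)/P^2 - 2 cov(S,P)/(S P)
#                    = 1/S + 1/(k P) - 2/S = 1/(k P) - 1/S.
ntc_stats <- function(hist, window_ns = 9, smooth = TRUE) {
  ntc <- compute_ntc(hist, window_ns = window_ns, smooth = smooth)
  counts <- hist$counts
  sm <- smooth3(counts)
  origin <- hist$origin %||% which.max(sm)
  peak <- if (smooth) max(sm) else max(counts)
  k <- if (smooth) 3 else 1
  n_window <- round(window_ns / hist$binning$bin_width_ns)
  wsum <- sum(counts[origin:(origin + n_window - 1L)])
  relvar <- max(1 / (k * max(peak, 1)) - 1 / max(wsum, 1), 1e-12)
  list(ntc = ntc, window_sum = wsum, peak = peak,
       ntc_sd = ntc * sqrt(relvar))
}

# 3-bin moving average with shrunk edges (mean of available neighbours)
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  mid <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  c((x[1] + x[2]) / 2, mid, (x[n - 1] + x[n]) / 2)
}

#' Collapse a scan cube into per-time-bin decay histograms
#'
#' Discards all spatial information: counts are summed over every pixel and
#' over the scan cycles falling in each analysis time bin, boosting photon
#' counts per histogram exactly as the tornado-scan readout does. Total
#' photon number is preserved exactly.
#'
#' @param cube A [scan_cube()].
#' @param time_bin_ms Width of the analysis time bins, ms (default 7). Must
#'   be at least one scan-cycle period.
#' @return A tibble with one row per time bin: `time_ms` (bin midpoint),
#'   `n_cycles`, `photons`, and a list-column `hist` of [decay_histogram()]s.
#' @export
collapse_cube <- function(cube, time_bin_ms = 7) {
  if (time_bin_ms < cube$cycle_period_ms) {
    abort("`time_bin_ms` must be >= the scan-cycle period.",
          class = "flimca_config_error")
  }
  dims <- dim(cube$counts)
  n_t <- dims[1]; n_cycles <- dims[4]
  if (n_cycles == 0 || sum(dims[2:3]) == 0) {
    abort("Empty cube.", class = "flimca_config_error")
  }
  # sum over x and y -> t x T matrix
  flat <- apply(cube$counts, c(1, 4), sum)
  cycle_mid <- (seq_len(n_cycles) - 0.5) * cube$cycle_period_ms
  bin_id <- floor((cycle_mid - 1e-9) / time_bin_ms)
  ids <- sort(unique(bin_id))
  rows <- purrr::map(ids, function(b) {
    cols <- which(bin_id == b)
    counts <- if (length(cols) == 1L) flat[, cols] else rowSums(flat[, cols, drop = FALSE])
    tibble::tibble(
      time_ms = (b + 0.5) * time_bin_ms,
      n_cycles = length(cols),
      photons = sum(counts),
      hist = list(decay_histogram(counts, cube$binning, origin = 1L))
    )
  })
  dplyr::bind_rows(rows)
}
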