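#' Fluorescence decay density at a given Ca2+ concentration
#'
#' Two-state mixture model of the indicator's nanosecond decay: a fast
#' monoexponential from the Ca-free state (`tau_free`) and a slow one from
#' the Ca-bound state (`tau_bound`), each truncated to the inter-pulse window
#' and mixed by the brightness-weighted bound fraction [bound_weight()].
#' Excitation is treated as a delta at t = 0 (the source pulse is two orders
#' of magnitude shorter than the lifetimes).
#'
#' @param t Time after the excitation pulse, ns (vectorised).
#' @param ca Free Ca2+ concentration, nM (scalar, >= 0).
#' @param model An [indicator_model()].
#' @return `p(t)`, a proper density on `[0, rep_window]` (zero outside).
#' @examples
#' m <- indicator_model()
#' tt <- seq(0, 12.5, by = 0.05)
#' plot(tt, decay_density(tt, 100, m), type = "l")
#' @export
decay_density <- function(t, ca, model) {
  check_ca(ca)
  stopifnot(length(ca) == 1L)
  w <- bound_weight(ca, model)
  W <- model$rep_window
  dens1 <- function(tau) {
    d <- exp(-t / tau) / (tau * (1 - exp(-W / tau)))
    d[t < 0 | t > W] <- 0
    d
  }
  w * dens1(model$tau_bound) + (1 - w) * dens1(model$tau_free)
}

# Exact per-bin probabilities of the decay density (analytic integrals of the
# truncated-exponential mixture); the workhorse for both simulation and
# noiseless oracles. `irf_sigma_ns > 0` convolves with a Gaussian instrument
# response (robustness testing; the default delta response reflects a source
# pulse two orders of magnitude shorter than the bins).
decay_bin_probs <- function(ca, model, binning, irf_sigma_ns = 0) {
  check_ca(ca)
  w <- bound_weight(ca, model)
  W <- model$rep_window
  edges <- binning$bin_edges
  cdf1 <- function(tau) (1 - exp(-pmin(edges, W) / tau)) / (1 - exp(-W / tau))
  p <- w * diff(cdf1(model$tau_bound)) + (1 - w) * diff(cdf1(model$tau_free))
  if (irf_sigma_ns > 0) {
    bw <- binning$bin_width_ns
    half <- ceiling(4 * irf_sigma_ns / bw)
    kern <- stats::dnorm(seq(-half, half) * bw, 0, irf_sigma_ns)
    kern <- kern / sum(kern)
    padded <- c(numeric(half), p, numeric(half))
    p <- vapply(seq_along(p), function(i)
      sum(padded[i:(i + 2 * half)] * rev(kern)), numeric(1))
    p <- pmax(p, 0)
  }
  # renormalize over the binned span (span may be shorter than rep_window)
  p / sum(p)
}

#' Construct a TCSPC decay histogram
#'
#' @param counts Non-negative photon counts per bin (numeric allowed so that
#'   noiseless expected histograms can flow through the same code path).
#' @param binning The [decay_binning()] the counts were histogrammed on.
#' @param origin Optional index of the excitation-pulse peak bin; detected
#'   from the data by [compute_ntc()] when `NULL`.
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(counts, binning, origin = NULL) {
  if (length(counts) != binning$n_bins) {
    abort("`counts` length must equal the number of bins.",
          class = "flimca_config_error")
  }
  if (any(counts < 0)) {
    abort("Counts must be non-negative.", class = "flimca_domain_error")
  }
  structure(
    list(counts = as.numeric(counts), binning = binning, origin = origin),
    class = "decay_histogram"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %d bins x %g ns, %g photons\n",
              x$binning$n_bins, x$binning$bin_width_ns, sum(x$counts)))
  invisible(x)
}

#' @export
autoplot.decay_histogram <- function(object, log_counts = TRUE, ...) {
  df <- tibble::tibble(
    time_ns = object$binning$bin_edges[-1] - object$binning$bin_width_ns / 2,
    counts = object$counts
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ns, .data$counts)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time after pulse (ns)", y = "photon counts")
  if (log_counts) p <- p + ggplot2::scale_y_log10()
  p
}

#' Simulate a clamped-Ca2+ calibration decay histogram
#'
#' Draws independent Poisson counts per bin whose expectations are
#' `n_photons` times the exact bin integrals of [decay_density()], emulating
#' a TCSPC acquisition in a solution clamped at a known free-Ca2+ level.
#' The total count is then Poisson(`n_photons`).
#'
#' @inheritParams decay_density
#' @param n_photons Expected total photon count (> 0).
#' @param binning A [decay_binning()].
#' @param seed Integer seed; every stochastic operation in flimca takes one
#'   explicitly. The caller's RNG state is left untouched.
#' @param irf_sigma_ns Gaussian instrument-response width, ns; 0 (default)
#'   treats excitation as a delta at the origin bin.
#' @return A [decay_histogram()] with `origin = 1`.
#' @export
simulate_decay <- function(ca, model, n_photons, binning = decay_binning(),
                           seed = 1L, irf_sigma_ns = 0) {
  if (n_photons <= 0) {
    abort("`n_photons` must be positive.", class = "flimca_config_error")
  }
  p <- decay_bin_probs(ca, model, binning, irf_sigma_ns)
  counts <- withr::with_seed(seed, rpois(binning$n_bins, n_photons * p))
  # with a delta response the pulse peak is the first bin; a blurred
  # response shifts it, so leave the origin to be detected from the data
  origin <- if (irf_sigma_ns == 0) 1L else NULL
  decay_histogram(counts, binning, origin = origin)
}

#' Noiseless expected decay histogram
#'
#' The infinite-photon limit of [simulate_decay()]: expected counts per bin.
#' Useful as an oracle and for building reference calibrations.
#'
#' @inheritParams simulate_decay
#' @return A [decay_histogram()] with non-integer counts.
#' @export
expected_decay <- function(ca, model, n_photons = 1, binning = decay_binning(),
                           irf_sigma_ns = 0) {
  decay_histogram(n_photons * decay_bin_probs(ca, model, binning, irf_sigma_ns),
                  binning,
                  origin = if (irf_sigma_ns == 0) 1L else NULL)
}
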