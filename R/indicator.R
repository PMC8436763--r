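#' Photophysical model of a single-wavelength Ca2+ indicator
#'
#' Bundles the parameters shared by the simulator and the estimators: the
#' indicator's Ca2+ affinity and dynamic range, the fluorescence lifetimes of
#' its Ca-free and Ca-bound states, and the laser inter-pulse window that
#' bounds every decay histogram.
#'
#' Defaults describe OGB-1 (Oregon Green BAPTA-1): `kd = 240` nM and
#' `gamma = 6` (ratio of saturated to Ca-free fluorescence). The two state
#' lifetimes are simulator parameters chosen to give a monotone NTC
#' calibration with its midpoint in the tens-of-nM range; they are not
#' literature values and both are configurable. The 12.5 ns window matches an
#' 80 MHz pulsed Ti:Sapphire source.
#'
#' @param kd Dissociation constant, nM.
#' @param gamma Dynamic range, unitless ratio F_max / F_min; must exceed 1.
#' @param tau_free Lifetime of the Ca-free state, ns.
#' @param tau_bound Lifetime of the Ca-bound state, ns; must exceed
#'   `tau_free` (binding slows the decay).
#' @param rep_window Laser inter-pulse window, ns.
#'
#' @return An object of class `indicator_model`.
#' @examples
#' m <- indicator_model()
#' saturation_fluorescence(c(0, 40, 240, 1e6), m)
#' @export
indicator_model <- function(kd = 240, gamma = 6, tau_free = 0.7,
                            tau_bound = 3.7, rep_window = 12.5) {
  if (!is.numeric(kd) || length(kd) != 1L || kd <= 0) {
    abort("`kd` must be a single positive number (nM).", class = "flimca_domain_error")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 1) {
    abort("`gamma` must be a single number > 1.", class = "flimca_domain_error")
  }
  if (!(tau_free > 0 && tau_bound > tau_free && rep_window > tau_bound)) {
    abort("Lifetimes must satisfy 0 < tau_free < tau_bound < rep_window.",
          class = "flimca_domain_error")
  }
  structure(
    list(kd = kd, gamma = gamma, tau_free = tau_free,
         tau_bound = tau_bound, rep_window = rep_window),
    class = "indicator_model"
  )
}

#' @export
print.indicator_model <- function(x, ...) {
  cat("<indicator_model>\n")
  cat(sprintf("  kd = %g nM, gamma = %g\n", x$kd, x$gamma))
  cat(sprintf("  tau_free = %g ns, tau_bound = %g ns, rep_window = %g ns\n",
              x$tau_free, x$tau_bound, x$rep_window))
  invisible(x)
}

#' Equilibrium bound fraction of the indicator
#'
#' Single-site binding: `f = ca / (ca + kd)`.
#'
#' @param ca Free Ca2+ concentration, nM (vectorised, >= 0).
#' @param model An [indicator_model()].
#' @return Numeric vector in `[0, 1)`.
#' @export
bound_fraction <- function(ca, model) {
  check_ca(ca)
  ca / (ca + model$kd)
}

#' Relative total fluorescence of the indicator
#'
#' The single-wavelength saturation law
#' `F(ca) = (ca + kd / gamma) / (ca + kd)` (one global scale factor left
#' free). It is the same law the simulator uses to set photon flux and the
#' peak estimator inverts, so simulated and estimated quantities share one
#' saturation model.
#'
#' @inheritParams bound_fraction
#' @return Numeric vector; `1/gamma` at zero Ca2+, tending to 1 at saturation.
#' @export
saturation_fluorescence <- function(ca, model) {
  check_ca(ca)
  (ca + model$kd / model$gamma) / (ca + model$kd)
}

#' Brightness-weighted probability that a photon came from the bound state
#'
#' The Ca-bound state is `gamma`-fold brighter, so a detected photon comes
#' from the bound state with probability
#' `w = gamma f / (gamma f + (1 - f))`, `f = ca / (ca + kd)`.
#'
#' @inheritParams bound_fraction
#' @return Numeric vector in `[0, 1)`.
#' @export
bound_weight <- function(ca, model) {
  f <- bound_fraction(ca, model)
  model$gamma * f / (model$gamma * f + (1 - f))
}

check_ca <- function(ca) {
  if (!is.numeric(ca) || any(!is.finite(ca) & !is.infinite(ca)) || any(ca < 0)) {
    abort("`ca` must be non-negative (nM).", class = "flimca_domain_error")
  }
  invisible(ca)
}

#' TCSPC decay-histogram binning
#'
#' The time base shared by calibration and experiment. NTC is bin-width
#' dependent, so the same binning object must be used to build a calibration
#' and to decode data against it; serialized calibrations carry a hash of
#' their binning to prevent mismatched reuse.
#'
#' @param n_bins Number of uniform bins (default 250).
#' @param bin_width_ns Bin width, ns (default 0.05; 250 x 0.05 = 12.5 ns
#'   covers an 80 MHz inter-pulse window).
#' @return An object of class `decay_binning` with `bin_edges` (length
#'   `n_bins + 1`, ns).
#' @export
decay_binning <- function(n_bins = 250, bin_width_ns = 0.05) {
  if (n_bins < 10) {
    abort("Need at least 10 bins to resolve a decay.",
          class = "flimca_config_error")
  }
  if (bin_width_ns <= 0) {
    abort("`bin_width_ns` must be positive.", class = "flimca_config_error")
  }
  structure(
    list(n_bins = as.integer(n_bins), bin_width_ns = bin_width_ns,
         bin_edges = seq(0, n_bins * bin_width_ns, by = bin_width_ns)),
    class = "decay_binning"
  )
}

#' @export
print.decay_binning <- function(x, ...) {
  cat(sprintf("<decay_binning> %d bins x %g ns = %g ns span\n",
              x$n_bins, x$bin_width_ns, x$n_bins * x$bin_width_ns))
  invisible(x)
}

binning_span_ns <- function(binning) binning$n_bins * binning$bin_width_ns

#' Stable fingerprint of a binning
#'
#' Used when serializing calibrations so a curve is never applied to data
#' histogrammed on a different time base.
#'
#' @param binning A [decay_binning()].
#' @return A character scalar.
#' @export
binning_hash <- function(binning) {
  sprintf("bins%d_width%.6gns", binning$n_bins, binning$bin_width_ns)
}
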