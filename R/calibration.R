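#' Fit a logistic NTC-vs-log[Ca2+] calibration
#'
#' Least-squares fit of the 4-parameter logistic
#' \deqn{NTC(ca) = ntc_{low} + \frac{ntc_{high} - ntc_{low}}
#'   {1 + 10^{\,hill\,(\log_{10} E_{50} - \log_{10} ca)}}}
#' to measured (Ca2+ level, NTC) pairs from clamped-solution decay
#' histograms. `E50` is the free-Ca2+ level at the curve midpoint. Nominally
#' zero-Ca solutions are mapped to a 1 nM floor so the fit can work on
#' log10[Ca2+].
#'
#' @param data Data frame with columns `ca_nM` and `ntc`; optional column
#'   `weight` for weighted least squares.
#' @param binning The [decay_binning()] the NTC values were computed on
#'   (recorded with the curve; NTC is bin-width dependent).
#' @param window_ns NTC integration window used, ns (recorded).
#' @param ca_floor_nM Floor applied to nominally zero levels. Default 1.
#' @return An object of class `flim_calibration` with fields `ntc_low`,
#'   `ntc_high`, `e50`, `hill`, `fit_cov`, `valid_range` (range of the
#'   calibrated levels, nM), `binning_hash`, plus the fitted model.
#' @examples
#' m <- indicator_model()
#' ladder <- c(0, 17, 38, 100, 150, 300, 602)
#' cal <- tibble::tibble(
#'   ca_nM = ladder,
#'   ntc = vapply(ladder, function(ca)
#'     compute_ntc(simulate_decay(ca, m, 1e6, seed = ca + 1)), 1)
#' )
#' fit_calibration(cal)
#' @export
fit_calibration <- function(data, binning = decay_binning(), window_ns = 9,
                            ca_floor_nM = 1) {
  if (!all(c("ca_nM", "ntc") %in% names(data))) {
    abort("`data` needs columns `ca_nM` and `ntc`.",
          class = "flimca_config_error")
  }
  df <- tibble::as_tibble(data)
  if (any(df$ca_nM < 0)) {
    abort("Calibration levels must be >= 0 nM.", class = "flimca_domain_error")
  }
  df$ca_nM <- pmax(df$ca_nM, ca_floor_nM)
  if (dplyr::n_distinct(df$ca_nM) < 5) {
    abort("Need >= 5 distinct Ca2+ levels spanning the sigmoid.",
          class = "flimca_fit_error")
  }
  df <- dplyr::arrange(df, .data$ca_nM)
  w <- if ("weight" %in% names(df)) df$weight else rep(1, nrow(df))

  lo <- min(df$ntc); hi <- max(df$ntc)
  mid <- (lo + hi) / 2
  e50_start <- 10^stats::approx(df$ntc, log10(df$ca_nM), xout = mid,
                                ties = mean, rule = 2)$y
  start <- list(ntc_low = lo, ntc_high = hi, log_e50 = log10(e50_start),
                hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ntc ~ ntc_low + (ntc_high - ntc_low) /
        (1 + 10^(hill * (log_e50 - log10(ca_nM)))),
      data = df, start = start, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(paste0("Calibration fit did not converge: ", conditionMessage(e)),
            class = "flimca_fit_error")
    }
  )
  cf <- coef(fit)
  if (cf[["hill"]] * (cf[["ntc_high"]] - cf[["ntc_low"]]) <= 0) {
    abort("Fitted calibration is non-monotone over the calibrated range.",
          class = "flimca_fit_error")
  }
  structure(
    list(
      ntc_low = unname(cf["ntc_low"]), ntc_high = unname(cf["ntc_high"]),
      e50 = unname(10^cf["log_e50"]), hill = unname(cf["hill"]),
      fit_cov = vcov(fit), valid_range = range(df$ca_nM),
      window_ns = window_ns, binning_hash = binning_hash(binning),
      data = df, fit = fit
    ),
    class = "flim_calibration"
  )
}

#' @export
print.flim_calibration <- function(x, ...) {
  cat("<flim_calibration> 4-parameter logistic on log10[Ca2+]\n")
  cat(sprintf("  NTC %.2f -> %.2f, E50 = %.1f nM, hill = %.2f\n",
              x$ntc_low, x$ntc_high, x$e50, x$hill))
  cat(sprintf("  valid range %.3g-%.3g nM (%s)\n",
              x$valid_range[1], x$valid_range[2], x$binning_hash))
  invisible(x)
}

#' Evaluate a calibration curve
#'
#' @param object A `flim_calibration`.
#' @param ca_nM Ca2+ levels, nM.
#' @param ... Unused.
#' @return Predicted NTC values.
#' @export
predict.flim_calibration <- function(object, ca_nM, ...) {
  object$ntc_low + (object$ntc_high - object$ntc_low) /
    (1 + 10^(object$hill * (log10(object$e50) - log10(ca_nM))))
}

#' @export
tidy.flim_calibration <- function(x, ...) {
  est <- c(ntc_low = x$ntc_low, ntc_high = x$ntc_high,
           log_e50 = log10(x$e50), hill = x$hill)
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = sqrt(diag(x$fit_cov))[names(est)]
  )
}

#' @export
glance.flim_calibration <- function(x, ...) {
  r <- stats::resid(x$fit)
  tibble::tibble(
    e50_nM = x$e50, hill = x$hill, ntc_low = x$ntc_low, ntc_high = x$ntc_high,
    sigma = sqrt(mean(r^2)), n_levels = nrow(x$data)
  )
}

#' @export
autoplot.flim_calibration <- function(object, ...) {
  grid <- tibble::tibble(
    ca_nM = 10^seq(log10(object$valid_range[1]), log10(object$valid_range[2]),
                   length.out = 200)
  )
  grid$ntc <- predict(object, grid$ca_nM)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$ca_nM, .data$ntc)) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::geom_line(data = grid) +
    ggplot2::scale_x_log10() +
    ggplot2::annotation_logticks(sides = "b") +
    ggplot2::labs(x = expression("[Ca"^"2+"*"] (nM)"),
                  y = "normalized total count (NTC)",
                  subtitle = sprintf("E50 = %.1f nM", object$e50))
}

#' Invert a calibration curve: NTC -> [Ca2+]
#'
#' Closed-form logistic inverse with a delta-method uncertainty from an
#' optional NTC standard deviation. NTC values outside the open interval
#' between the asymptotes cannot be inverted; they are flagged out-of-range
#' (`NA` with `flag = "out_of_range"`), never extrapolated.
#'
#' @param curve A `flim_calibration`.
#' @param ntc NTC values (vectorised).
#' @param ntc_sd Optional NTC standard deviations for uncertainty
#'   propagation.
#' @return A tibble with `ntc`, `ca_nM`, `ca_sd_nM`, `flag` (`"ok"`,
#'   `"out_of_range"`).
#' @export
invert_calibration <- function(curve, ntc, ntc_sd = NULL) {
  lo <- min(curve$ntc_low, curve$ntc_high)
  hi <- max(curve$ntc_low, curve$ntc_high)
  ok <- is.finite(ntc) & ntc > lo & ntc < hi
  ca <- rep(NA_real_, length(ntc))
  ratio <- (curve$ntc_high - ntc[ok]) / (ntc[ok] - curve$ntc_low)
  ca[ok] <- 10^(log10(curve$e50) - log10(ratio) / curve$hill)

  sd_ca <- rep(NA_real_, length(ntc))
  if (!is.null(ntc_sd)) {
    # d ca / d ntc from the closed-form inverse
    dca <- ca[ok] / curve$hill *
      (1 / (curve$ntc_high - ntc[ok]) + 1 / (ntc[ok] - curve$ntc_low))
    sd_ca[ok] <- abs(dca) * ntc_sd[ok]
  }
  tibble::tibble(
    ntc = ntc, ca_nM = ca, ca_sd_nM = sd_ca,
    flag = ifelse(ok, "ok", "out_of_range")
  )
}

#' Reference calibration from the generative model
#'
#' Builds the noiseless NTC curve implied by an [indicator_model()] on a
#' dense Ca2+ grid (expected histograms, no photon noise) and fits the same
#' logistic to it. Its `e50` is the generator's ground-truth E50 against
#' which noisy calibrations can be benchmarked.
#'
#' @param model An [indicator_model()].
#' @param binning A [decay_binning()].
#' @param window_ns NTC window, ns.
#' @param ca_grid_nM Ca2+ grid; default 60 log-spaced levels over 1-3000 nM.
#' @return A `flim_calibration`.
#' @export
calibration_truth <- function(model, binning = decay_binning(), window_ns = 9,
                              ca_grid_nM = 10^seq(0, log10(3000),
                                                  length.out = 60)) {
  ntc <- vapply(
    ca_grid_nM,
    function(ca) compute_ntc(expected_decay(ca, model, 1, binning),
                             window_ns = window_ns),
    numeric(1)
  )
  fit_calibration(tibble::tibble(ca_nM = ca_grid_nM, ntc = ntc),
                  binning = binning, window_ns = window_ns)
}

#' Serialize / load a calibration curve
#'
#' JSON with parameters, covariance, NTC window and the binning fingerprint;
#' [read_calibration()] refuses nothing but callers should check
#' `binning_hash` against their data's binning before reuse.
#'
#' @param curve A `flim_calibration`.
#' @param path File path (`.json`).
#' @export
write_calibration <- function(curve, path) {
  obj <- list(
    format = "flimca_calibration_v1",
    ntc_low = curve$ntc_low, ntc_high = curve$ntc_high,
    e50 = curve$e50, hill = curve$hill,
    fit_cov = as.vector(curve$fit_cov),
    cov_names = colnames(curve$fit_cov),
    valid_range = curve$valid_range,
    window_ns = curve$window_ns, binning_hash = curve$binning_hash,
    data = curve$data[c("ca_nM", "ntc")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "flimca_calibration_v1")) {
    abort("Not a flimca calibration file.", class = "flimca_io_error")
  }
  k <- length(obj$cov_names)
  cov <- matrix(obj$fit_cov, k, k, dimnames = list(obj$cov_names, obj$cov_names))
  structure(
    list(ntc_low = obj$ntc_low, ntc_high = obj$ntc_high, e50 = obj$e50,
         hill = obj$hill, fit_cov = cov, valid_range = obj$valid_range,
         window_ns = obj$window_ns, binning_hash = obj$binning_hash,
         data = tibble::as_tibble(obj$data), fit = NULL),
    class = "flim_calibration"
  )
}
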