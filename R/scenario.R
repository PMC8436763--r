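#' Configuration for an end-to-end simulated experiment
#'
#' One object that fixes everything a scenario run needs: the indicator
#' model, the TCSPC binning, the calibration ladder, the population design,
#' the per-trial acquisition settings, and the seed that all randomness
#' flows from. The default condition protocol mirrors the pharmacology /
#' somatic-voltage structure the statistics expect: a control condition, a
#' glutamate-transporter-block condition depressing evoked entry, an
#' mGluR-block condition depressing both measures, and a subthreshold
#' depolarization condition with no true effect (a built-in null).
#'
#' @param model An [indicator_model()].
#' @param binning A [decay_binning()].
#' @param calibration_levels_nM Clamped-solution ladder, nM (0 allowed; it
#'   is floored for log-domain fitting).
#' @param calibration_photons Photons per calibration histogram.
#' @param design A [population_design()].
#' @param photon_rate Photons per scan cycle at rest for bouton trials.
#' @param duration_ms,cycle_period_ms,n_pixels Trial acquisition geometry.
#' @param ap_time_ms Stimulus onset, ms (>= 500).
#' @param time_bin_ms Analysis bin, ms.
#' @param window_ns NTC window, ns.
#' @param n_trials Trials per bouton (cube-level averaging combines them).
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(
    model = indicator_model(),
    binning = decay_binning(),
    calibration_levels_nM = c(0, 17, 38, 100, 150, 300, 602),
    calibration_photons = 1e6,
    design = population_design(
      n_cells = 8,
      condition_effects = list(
        control = c(ca0 = 1, delta = 1),
        transporter_block = c(ca0 = 28 / 30, delta = 0.31),
        mGluR_block = c(ca0 = 23 / 31, delta = 66 / 140),
        depolarized = c(ca0 = 1, delta = 1))),
    photon_rate = 2000,
    duration_ms = 700, cycle_period_ms = 1, n_pixels = 4,
    ap_time_ms = 510, time_bin_ms = 7, window_ns = 9,
    n_trials = 1,
    seed = 1L) {
  cfg <- structure(
    list(model = model, binning = binning,
         calibration_levels_nM = calibration_levels_nM,
         calibration_photons = calibration_photons,
         design = design, photon_rate = photon_rate,
         duration_ms = duration_ms, cycle_period_ms = cycle_period_ms,
         n_pixels = n_pixels, ap_time_ms = ap_time_ms,
         time_bin_ms = time_bin_ms, window_ns = window_ns,
         n_trials = n_trials, seed = as.integer(seed)),
    class = "scenario_config"
  )
  validate_scenario_config(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Cross-checks the sub-configurations against their own invariants and the
#' couplings between them (stimulus inside the trial, analysis bin at least
#' one cycle, enough calibration levels).
#'
#' @param config A `scenario_config`.
#' @return `config`, invisibly; aborts with `flimca_config_error` otherwise.
#' @export
validate_scenario_config <- function(config) {
  c_ <- config
  if (!inherits(c_$model, "indicator_model") ||
      !inherits(c_$binning, "decay_binning") ||
      !inherits(c_$design, "population_design")) {
    abort("model/binning/design must be flimca objects.",
          class = "flimca_config_error")
  }
  if (length(unique(pmax(c_$calibration_levels_nM, 1))) < 5) {
    abort("Calibration ladder needs >= 5 distinct levels.",
          class = "flimca_config_error")
  }
  if (c_$ap_time_ms < 500) {
    abort("`ap_time_ms` must leave a full 500 ms basal window.",
          class = "flimca_config_error")
  }
  if (c_$duration_ms < c_$ap_time_ms + 30) {
    abort("`duration_ms` must cover the stimulus and the peak search window.",
          class = "flimca_config_error")
  }
  if (c_$time_bin_ms < c_$cycle_period_ms) {
    abort("`time_bin_ms` must be >= the cycle period.",
          class = "flimca_config_error")
  }
  if (c_$photon_rate <= 0 || c_$calibration_photons <= 0) {
    abort("Photon rates must be positive.", class = "flimca_low_signal")
  }
  invisible(config)
}

#' Read / write a scenario configuration as YAML
#'
#' Flat YAML mirror of [scenario_config()]; round-trips through
#' [validate_scenario_config()] on read.
#'
#' @param config A `scenario_config`.
#' @param path YAML file path.
#' @export
write_scenario_config <- function(config, path) {
  obj <- list(
    model = unclass(config$model),
    binning = list(n_bins = config$binning$n_bins,
                   bin_width_ns = config$binning$bin_width_ns),
    calibration_levels_nM = config$calibration_levels_nM,
    calibration_photons = config$calibration_photons,
    design = list(
      n_cells = config$design$n_cells,
      boutons_per_cell = config$design$boutons_per_cell,
      branch_order_means = as.list(config$design$branch_order_means),
      cell_sd = as.list(config$design$cell_sd),
      bouton_sd = as.list(config$design$bouton_sd),
      condition_effects = lapply(config$design$condition_effects, as.list),
      distance_range_um = config$design$distance_range_um,
      seed = config$design$seed),
    photon_rate = config$photon_rate,
    duration_ms = config$duration_ms,
    cycle_period_ms = config$cycle_period_ms,
    n_pixels = config$n_pixels, ap_time_ms = config$ap_time_ms,
    time_bin_ms = config$time_bin_ms, window_ns = config$window_ns,
    n_trials = config$n_trials, seed = config$seed
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  o <- yaml::read_yaml(path)
  scenario_config(
    model = do.call(indicator_model, o$model),
    binning = decay_binning(o$binning$n_bins, o$binning$bin_width_ns),
    calibration_levels_nM = unlist(o$calibration_levels_nM),
    calibration_photons = o$calibration_photons,
    design = population_design(
      n_cells = o$design$n_cells,
      boutons_per_cell = unlist(o$design$boutons_per_cell),
      branch_order_means = tibble::as_tibble(o$design$branch_order_means),
      cell_sd = unlist(o$design$cell_sd),
      bouton_sd = unlist(o$design$bouton_sd),
      condition_effects = lapply(o$design$condition_effects, unlist),
      distance_range_um = unlist(o$design$distance_range_um),
      seed = o$design$seed),
    photon_rate = o$photon_rate, duration_ms = o$duration_ms,
    cycle_period_ms = o$cycle_period_ms, n_pixels = o$n_pixels,
    ap_time_ms = o$ap_time_ms, time_bin_ms = o$time_bin_ms,
    window_ns = o$window_ns, n_trials = o$n_trials, seed = o$seed
  )
}

#' Run a full simulated experiment
#'
#' Chains every stage of the pipeline: simulate the calibration ladder and
#' fit the logistic curve; simulate the nested bouton population and one (or
#' several, cube-averaged) tornado-scan trials per bouton x condition;
#' decode each trial and estimate resting and evoked Ca2+; assemble the
#' bouton record table; and run the branch-order and paired-condition
#' statistics. Deterministic given the config seed; every intermediate can
#' be written to `out_dir`.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory (created); `NULL` skips writing.
#' @param write_cubes Also serialize every simulated cube (large). Default
#'   `FALSE`.
#' @param quiet Suppress per-stage progress messages. Default `TRUE`.
#' @return A list with `curve`, `population`, `records` (tibble of per
#'   bouton x condition estimates and QC flags), `branch_order`
#'   (`flim_stats` for both responses, control condition),
#'   `paired` (per non-control condition and response), `percent_changes`,
#'   `log`.
#' @export
run_scenario <- function(config, out_dir = NULL, write_cubes = FALSE,
                         quiet = TRUE) {
  validate_scenario_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  log <- list(seed = config$seed, started = format(Sys.time()),
              package_version = as.character(utils::packageVersion("flimca")))

  # -- stage 1: calibration ---------------------------------------------
  say("stage 1/4: calibration (%d levels)", length(config$calibration_levels_nM))
  cal_tbl <- purrr::imap_dfr(config$calibration_levels_nM, function(ca, i) {
    h <- simulate_decay(ca, config$model, config$calibration_photons,
                        config$binning, seed = config$seed * 1000L + i)
    tibble::tibble(ca_nM = ca,
                   ntc = compute_ntc(h, window_ns = config$window_ns))
  })
  curve <- fit_calibration(cal_tbl, binning = config$binning,
                           window_ns = config$window_ns)

  # -- stage 2: population ----------------------------------------------
  design <- config$design
  design$seed <- config$seed
  population <- simulate_population(design) |>
    population_scenarios(photon_rate = config$photon_rate,
                         ap_time_ms = config$ap_time_ms)
  say("stage 2/4: population (%d records)", nrow(population))

  # -- stage 3: per-bouton trials ---------------------------------------
  records <- purrr::map_dfr(seq_len(nrow(population)), function(i) {
    row <- population[i, ]
    sc <- row$scenario[[1]]
    cubes <- purrr::map(seq_len(config$n_trials), function(k) {
      simulate_trial(sc, config$model, n_pixels = config$n_pixels,
                     duration_ms = config$duration_ms,
                     cycle_period_ms = config$cycle_period_ms,
                     binning = config$binning,
                     seed = (config$seed * 7919L + i * 101L + k) %% .Machine$integer.max,
                     metadata = list(bouton_id = row$bouton_id,
                                     cell_id = row$cell_id,
                                     condition = row$condition, trial = k))
    })
    cube <- if (length(cubes) == 1L) cubes[[1]] else average_cubes(cubes)
    if (write_cubes && !is.null(out_dir)) {
      write_scan_cube(cube, file.path(
        out_dir, sprintf("cube_%s_%s.json", row$bouton_id, row$condition)))
    }
    tl <- decode_timeline(cube, curve, window_ns = config$window_ns,
                          time_bin_ms = config$time_bin_ms)
    est <- tryCatch(
      estimate_delta(tl, intensity_trace(cube), config$ap_time_ms,
                     config$model),
      flimca_qc_error = function(e) tibble::tibble(
        ca0_nM = NA_real_, ca_peak_nM = NA_real_, delta_nM = NA_real_,
        f_rest = NA_real_, f_peak = NA_real_, f_max = NA_real_,
        flag = "qc_failed")
    )
    dplyr::bind_cols(
      row[c("bouton_id", "cell_id", "animal_id", "branch_order",
            "distance_um", "condition", "true_ca0_nM", "true_delta_nM")],
      est)
  })
  say("stage 3/4: trials decoded (%d dropped by QC)",
      sum(records$flag != "ok"))
  log$qc_dropped <- sum(records$flag != "ok")

  # -- stage 4: statistics ----------------------------------------------
  control <- dplyr::filter(records, .data$condition == names(
    config$design$condition_effects)[1])
  branch_order <- list(
    ca0 = branch_order_analysis(control, "ca0"),
    delta = branch_order_analysis(control, "delta"))

  other <- setdiff(unique(records$condition), control$condition[1])
  paired <- purrr::map(setNames(other, other), function(cond) {
    after <- dplyr::filter(records, .data$condition == cond)
    purrr::map(c(ca0 = "ca0", delta = "delta"), function(resp) {
      paired_condition_test(control, after, response = resp)
    })
  })
  percent_changes <- purrr::imap_dfr(paired, function(tests, cond) {
    purrr::imap_dfr(tests, function(t, resp) {
      tibble::tibble(condition = cond, response = resp,
                     pct_change = percent_change(t$mean_before, t$mean_after),
                     p_value = t$p_value, method = t$method)
    })
  })
  say("stage 4/4: statistics done")
  log$finished <- format(Sys.time())

  result <- list(curve = curve, population = population, records = records,
                 branch_order = branch_order, paired = paired,
                 percent_changes = percent_changes, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_calibration(curve, file.path(out_dir, "calibration.json"))
    write_population(population, file.path(out_dir, "population.csv"))
    readr::write_csv(records, file.path(out_dir, "records.csv"))
    readr::write_csv(
      dplyr::bind_rows(ca0 = branch_order$ca0, delta = branch_order$delta,
                       .id = "response"),
      file.path(out_dir, "branch_order_stats.csv"))
    readr::write_csv(percent_changes, file.path(out_dir, "percent_changes.csv"))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE)
  }
  result
}

#' Average several trial cubes of one bouton
#'
#' Cube-level pooling for deeper, dimmer boutons where one trial has too few
#' photons: counts are summed cell-wise (equivalent to one acquisition of
#' the combined duration), preserving Poisson statistics.
#'
#' @param cubes List of [scan_cube()]s with identical geometry.
#' @return A [scan_cube()].
#' @export
average_cubes <- function(cubes) {
  if (!length(cubes)) abort("Empty cube list.", class = "flimca_config_error")
  dims <- dim(cubes[[1]]$counts)
  total <- Reduce(`+`, purrr::map(cubes, function(cb) {
    if (!identical(dim(cb$counts), dims)) {
      abort("Cubes must share geometry to be pooled.",
            class = "flimca_config_error")
    }
    cb$counts
  }))
  scan_cube(total, cubes[[1]]$binning, cubes[[1]]$cycle_period_ms,
            cubes[[1]]$metadata)
}
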