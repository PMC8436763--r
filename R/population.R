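#' Design of a nested synthetic bouton population
#'
#' Describes the sampling structure the branch-order statistics assume:
#' boutons nested in cells (1-4 boutons per cell, 1-2 cells per animal),
#' branch orders 1-3 with order-specific mean resting and evoked Ca2+, a
#' between-cell random effect, within-cell bouton noise, and multiplicative
#' condition effects (e.g. a transporter-block condition scaling evoked
#' entry).
#'
#' Default means are the control-condition group means of the system this
#' generator emulates: resting Ca2+ (31, 45, 34) nM and evoked entry
#' (42, 76, 101) nM for branch orders 1-3.
#'
#' @param n_cells Number of cells. Default 25.
#' @param boutons_per_cell Either a single count or a vector of candidate
#'   counts sampled per cell. Default `1:4`.
#' @param branch_order_means Tibble with columns `branch_order`, `ca0`,
#'   `delta` (nM).
#' @param cell_sd Between-cell random-effect SD, nM; named vector
#'   `c(ca0 = , delta = )` or a scalar applied to both. Default
#'   `c(ca0 = 8, delta = 25)`.
#' @param bouton_sd Within-cell bouton SD, nM; same convention. Default
#'   `c(ca0 = 10, delta = 30)`.
#' @param condition_effects Named list of multiplicative effects per
#'   condition label, each a vector `c(ca0 = , delta = )`. Default a single
#'   `control` condition with no effect.
#' @param distance_range_um Range of bouton distances from the soma, um.
#' @param seed Integer seed.
#' @return An object of class `population_design`.
#' @export
population_design <- function(
    n_cells = 25,
    boutons_per_cell = 1:4,
    branch_order_means = tibble::tibble(
      branch_order = 1:3,
      ca0 = c(31, 45, 34),
      delta = c(42, 76, 101)),
    cell_sd = c(ca0 = 8, delta = 25),
    bouton_sd = c(ca0 = 10, delta = 30),
    condition_effects = list(control = c(ca0 = 1, delta = 1)),
    distance_range_um = c(20, 300),
    seed = 1L) {
  if (n_cells < 1 || all(boutons_per_cell < 1)) {
    abort("Design needs at least one cell and one bouton per cell.",
          class = "flimca_config_error")
  }
  cell_sd <- expand_sd(cell_sd); bouton_sd <- expand_sd(bouton_sd)
  if (any(c(cell_sd, bouton_sd) < 0)) {
    abort("SDs must be >= 0.", class = "flimca_config_error")
  }
  if (!all(branch_order_means$branch_order %in% 1:3)) {
    abort("Branch orders must be in {1, 2, 3}.", class = "flimca_config_error")
  }
  structure(
    list(n_cells = n_cells, boutons_per_cell = boutons_per_cell,
         branch_order_means = branch_order_means, cell_sd = cell_sd,
         bouton_sd = bouton_sd, condition_effects = condition_effects,
         distance_range_um = distance_range_um, seed = seed),
    class = "population_design"
  )
}

expand_sd <- function(x) {
  if (length(x) == 1L && is.null(names(x))) x <- c(ca0 = x, delta = x)
  x[c("ca0", "delta")]
}

#' Simulate a nested bouton population
#'
#' Draws the ground-truth table the statistics module consumes: one row per
#' bouton x condition, with
#' `true value = branch-order mean x condition effect + cell effect + bouton noise`,
#' truncated at 0. Cell and bouton effects are drawn once per bouton and
#' shared across conditions, so condition contrasts are paired within
#' boutons, and cell identity is recorded for the two-factor analysis.
#'
#' @param design A [population_design()].
#' @return A tibble with columns `bouton_id`, `cell_id`, `animal_id`,
#'   `branch_order`, `distance_um`, `condition`, `true_ca0_nM`,
#'   `true_delta_nM`, `seed`.
#' @export
simulate_population <- function(design) {
  d <- design
  withr::with_seed(d$seed, {
    n_b <- if (length(d$boutons_per_cell) == 1L) {
      rep(d$boutons_per_cell, d$n_cells)
    } else {
      sample(d$boutons_per_cell, d$n_cells, replace = TRUE)
    }
    cells <- tibble::tibble(
      cell_id = sprintf("c%02d", seq_len(d$n_cells)),
      animal_id = sprintf("a%02d", ceiling(seq_len(d$n_cells) / 2)),
      cell_eff_ca0 = rnorm(d$n_cells, 0, d$cell_sd["ca0"]),
      cell_eff_delta = rnorm(d$n_cells, 0, d$cell_sd["delta"]),
      n_boutons = n_b
    )
    boutons <- cells |>
      dplyr::reframe(
        bouton = seq_len(.data$n_boutons),
        .by = c("cell_id", "animal_id", "cell_eff_ca0", "cell_eff_delta")) |>
      dplyr::mutate(
        bouton_id = sprintf("%s_b%d", .data$cell_id, .data$bouton),
        branch_order = sample(d$branch_order_means$branch_order,
                              dplyr::n(), replace = TRUE),
        distance_um = runif(dplyr::n(), d$distance_range_um[1],
                            d$distance_range_um[2]),
        noise_ca0 = rnorm(dplyr::n(), 0, d$bouton_sd["ca0"]),
        noise_delta = rnorm(dplyr::n(), 0, d$bouton_sd["delta"])
      ) |>
      dplyr::left_join(d$branch_order_means, by = "branch_order")

    conds <- purrr::imap(d$condition_effects, function(eff, label) {
      boutons |>
        dplyr::mutate(
          condition = label,
          true_ca0_nM = pmax(0, .data$ca0 * eff[["ca0"]] +
                               .data$cell_eff_ca0 + .data$noise_ca0),
          true_delta_nM = pmax(0, .data$delta * eff[["delta"]] +
                                 .data$cell_eff_delta + .data$noise_delta)
        )
    })
    dplyr::bind_rows(conds) |>
      dplyr::mutate(seed = d$seed) |>
      dplyr::select("bouton_id", "cell_id", "animal_id", "branch_order",
                    "distance_um", "condition", "true_ca0_nM",
                    "true_delta_nM", "seed")
  })
}

#' Per-bouton trial scenarios from a population table
#'
#' Attaches a [ca_scenario()] (as a list-column) to every row of a
#' population table so each bouton x condition can be pushed through the
#' full simulate -> decode -> estimate pipeline.
#'
#' @param population Output of [simulate_population()].
#' @param photon_rate Expected photons per scan cycle at rest.
#' @param ap_time_ms Stimulus onset, ms.
#' @param decay_tau_ms Transient decay constant, ms.
#' @param rise_ms Equilibration time, ms.
#' @return The table with an added list-column `scenario`.
#' @export
population_scenarios <- function(population, photon_rate = 2000,
                                 ap_time_ms = 510, decay_tau_ms = 400,
                                 rise_ms = 2) {
  population$scenario <- purrr::map2(
    population$true_ca0_nM, population$true_delta_nM,
    function(ca0, delta) {
      ca_scenario(ca0 = ca0, delta_ca = delta, rise_ms = rise_ms,
                  decay_tau_ms = decay_tau_ms, ap_time_ms = ap_time_ms,
                  photon_rate = photon_rate)
    })
  population
}

#' Write a population ground-truth table to CSV
#'
#' @param population Output of [simulate_population()].
#' @param path Output path.
#' @export
write_population <- function(population, path) {
  readr::write_csv(
    dplyr::select(population, -dplyr::any_of("scenario")), path)
  invisible(path)
}
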