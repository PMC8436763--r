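#' Branch-order analysis of a bouton table
#'
#' The two complementary tests applied to each response in the nested
#' design: (1) the conservative non-parametric Kruskal-Wallis ANOVA with
#' branch order as the single factor, and (2) a two-way ANOVA with branch
#' order and cell identity as two factors (no interaction; Type II sums of
#' squares, appropriate for the unbalanced 1-4 boutons/cell design). A
#' Shapiro-Wilk test on the within-group residuals is recorded alongside,
#' documenting why the rank-based test is carried.
#'
#' @param records Data frame with columns `branch_order`, `cell_id`, and the
#'   response (`ca0_nM` or `delta_nM`; `true_ca0_nM`/`true_delta_nM` also
#'   accepted).
#' @param response `"ca0"` or `"delta"`.
#' @param drop_sparse_levels Drop branch orders with fewer than 2
#'   observations (with a warning). Default `TRUE`.
#' @return A tibble (class `flim_stats`) with one row per test: `method`,
#'   `term`, `statistic`, `df`, `df_resid`, `p_value`, `n`,
#'   `normality_gate`.
#' @export
branch_order_analysis <- function(records, response = c("ca0", "delta"),
                                  drop_sparse_levels = TRUE) {
  response <- match.arg(response)
  col <- resolve_response(records, response)
  df <- tibble::as_tibble(records)
  df$y <- df[[col]]
  df <- dplyr::filter(df, is.finite(.data$y))
  df$branch_order <- factor(df$branch_order)
  df$cell_id <- factor(df$cell_id)

  tab <- table(df$branch_order)
  if (any(tab < 2)) {
    sparse <- names(tab)[tab < 2]
    if (drop_sparse_levels) {
      warn(sprintf("Dropping branch order(s) with < 2 boutons: %s",
                   paste(sparse, collapse = ", ")))
      df <- dplyr::filter(df, !(.data$branch_order %in% sparse))
      df$branch_order <- droplevels(df$branch_order)
    }
  }
  if (nlevels(df$branch_order) < 2) {
    abort("Need >= 2 branch orders with data.", class = "flimca_config_error")
  }

  # fully tied response: every rank statistic is 0 and carries no evidence
  # (ties policy: H = 0, p = 1); the parametric fit is undefined
  if (dplyr::n_distinct(df$y) == 1L) {
    out <- tibble::tibble(
      method = c("kruskal_wallis", "two_way_anova", "two_way_anova"),
      term = c("branch_order", "branch_order", "cell_id"),
      statistic = c(0, NA_real_, NA_real_),
      df = c(nlevels(df$branch_order) - 1, NA_real_, NA_real_),
      df_resid = NA_real_,
      p_value = c(1, NA_real_, NA_real_),
      n = nrow(df), normality_gate = "degenerate")
    return(structure(out, class = c("flim_stats", class(out)),
                     response = response))
  }

  # normality of within-group residuals motivates carrying the rank test
  resid_within <- df$y - stats::ave(df$y, df$branch_order)
  sw_p <- tryCatch(shapiro.test(resid_within)$p.value,
                   error = function(e) NA_real_)
  gate <- if (is.na(sw_p)) {
    "shapiro_na"
  } else if (sw_p < 0.05) {
    "shapiro_rejected"
  } else {
    "shapiro_not_rejected"
  }

  kw <- kruskal.test(y ~ branch_order, data = df)
  fit <- lm(y ~ branch_order + cell_id, data = df)
  a2 <- car::Anova(fit, type = 2)
  terms <- rownames(a2)
  bo_row <- which(terms == "branch_order")
  cell_row <- which(terms == "cell_id")
  res_row <- which(terms == "Residuals")

  out <- tibble::tibble(
    method = c("kruskal_wallis", "two_way_anova", "two_way_anova"),
    term = c("branch_order", "branch_order", "cell_id"),
    statistic = c(unname(kw$statistic),
                  a2[bo_row, "F value"], a2[cell_row, "F value"]),
    df = c(unname(kw$parameter), a2[bo_row, "Df"], a2[cell_row, "Df"]),
    df_resid = c(NA_real_, a2[res_row, "Df"], a2[res_row, "Df"]),
    p_value = c(kw$p.value, a2[bo_row, "Pr(>F)"], a2[cell_row, "Pr(>F)"]),
    n = nrow(df),
    normality_gate = gate
  )
  structure(out, class = c("flim_stats", class(out)), response = response)
}

resolve_response <- function(records, response) {
  cands <- paste0(response, c("_nM", "")) |>
    c(paste0("true_", response, "_nM"))
  hit <- cands[cands %in% names(records)]
  if (!length(hit)) {
    abort(sprintf("No %s column found (looked for %s).", response,
                  paste(cands, collapse = ", ")),
          class = "flimca_config_error")
  }
  hit[[1]]
}

#' Paired baseline-vs-effect comparison with a normality gate
#'
#' The paired test used for ligand and voltage manipulations where each
#' bouton is its own control. A Shapiro-Wilk test on the paired differences
#' decides the branch: normality rejected at `alpha_gate` gives the
#' non-parametric Wilcoxon signed-rank test (Pratt handling of
#' zero differences, normal approximation), otherwise the paired t-test.
#' The gate decision is part of the result.
#'
#' @param records_before,records_after Data frames with a shared id column
#'   and the response column; rows are matched by id, and unmatched ids are
#'   an error.
#' @param response `"ca0"` or `"delta"`.
#' @param id Name of the id column. Default `"bouton_id"`.
#' @param alpha_gate Normality-gate level. Default 0.05.
#' @return A one-row tibble (class `flim_stats`): `method`, `statistic`,
#'   `df`, `p_value`, `n`, `normality_gate`, `mean_before`, `mean_after`.
#' @export
paired_condition_test <- function(records_before, records_after,
                                  response = c("ca0", "delta"),
                                  id = "bouton_id", alpha_gate = 0.05) {
  response <- match.arg(response)
  col_b <- resolve_response(records_before, response)
  col_a <- resolve_response(records_after, response)
  b <- tibble::tibble(id = records_before[[id]],
                      before = records_before[[col_b]])
  a <- tibble::tibble(id = records_after[[id]],
                      after = records_after[[col_a]])
  if (!setequal(b$id, a$id) || anyDuplicated(b$id) || anyDuplicated(a$id)) {
    abort("Bouton ids do not pair one-to-one across conditions.",
          class = "flimca_pairing_error")
  }
  m <- dplyr::inner_join(b, a, by = "id") |>
    dplyr::filter(is.finite(.data$before), is.finite(.data$after))
  if (nrow(m) < 5) {
    abort("Need >= 5 matched pairs.", class = "flimca_config_error")
  }
  d <- m$after - m$before

  if (all(d == 0)) {
    out <- tibble::tibble(
      method = "no_effect_all_ties", statistic = NA_real_, df = NA_real_,
      p_value = 1, n = nrow(m), normality_gate = "degenerate",
      mean_before = mean(m$before), mean_after = mean(m$after))
    return(structure(out, class = c("flim_stats", class(out))))
  }

  sw_p <- tryCatch(shapiro.test(d)$p.value, error = function(e) NA_real_)
  use_wilcoxon <- is.na(sw_p) || sw_p < alpha_gate
  if (use_wilcoxon) {
    wt <- wilcoxon_signed_rank_pratt(d)
    out <- tibble::tibble(
      method = "wilcoxon_signed_rank", statistic = wt$statistic,
      df = NA_real_, p_value = wt$p_value, n = nrow(m),
      normality_gate = sprintf("shapiro_p=%.3g_rejected", sw_p))
  } else {
    tt <- t.test(m$after, m$before, paired = TRUE)
    out <- tibble::tibble(
      method = "paired_t", statistic = unname(tt$statistic),
      df = unname(tt$parameter), p_value = tt$p.value, n = nrow(m),
      normality_gate = sprintf("shapiro_p=%.3g_not_rejected", sw_p))
  }
  out$mean_before <- mean(m$before)
  out$mean_after <- mean(m$after)
  structure(out, class = c("flim_stats", class(out)))
}

# Wilcoxon signed-rank with Pratt handling of zero differences: zeros are
# ranked with the rest, then their ranks are discarded from the statistic.
# Normal approximation with tie and zero corrections and continuity
# correction; coincides with the standard test when no zeros are present.
wilcoxon_signed_rank_pratt <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  z <- sum(d == 0)
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4 - z * (z + 1) / 4
  ties <- table(r[d != 0])
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - z * (z + 1) * (2 * z + 1) / 24 -
    sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    return(list(statistic = w_pos, p_value = 1))
  }
  zstat <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
  list(statistic = w_pos, p_value = 2 * pnorm(-abs(zstat)))
}

#' Percent change between two group means
#'
#' `100 * (1 - mean_after / mean_before)`: the drop (in percent) of the
#' treated mean relative to baseline.
#'
#' @param mean_before Baseline mean (> 0).
#' @param mean_after Post-manipulation mean.
#' @return Percent change (positive for a decrease).
#' @export
percent_change <- function(mean_before, mean_after) {
  if (any(mean_before <= 0)) {
    abort("`mean_before` must be positive.", class = "flimca_domain_error")
  }
  100 * (1 - mean_after / mean_before)
}

#' @export
tidy.flim_stats <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.flim_stats <- function(x, ...) {
  tibble::tibble(n_tests = nrow(x), min_p = min(x$p_value, na.rm = TRUE))
}

#' Simulate a paired pharmacology experiment
#'
#' Lognormal bouton-level baselines with a given coefficient of variation,
#' multiplied by a condition effect and independent lognormal measurement
#' noise in each condition. Used for power / type-I studies of
#' [paired_condition_test()].
#'
#' @param n Number of boutons.
#' @param mean_before Baseline population mean, nM.
#' @param effect Multiplicative condition effect (1 = null).
#' @param cv Lognormal coefficient of variation of both the bouton levels
#'   and each measurement. Default 0.5.
#' @param seed Integer seed.
#' @return A list of two tibbles, `before` and `after`, each with
#'   `bouton_id` and `delta_nM`.
#' @export
simulate_paired_condition <- function(n, mean_before = 99, effect = 0.31,
                                      cv = 0.5, seed = 1L) {
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(seed, {
    level <- rlnorm(n, log(mean_before) - sdlog^2 / 2, sdlog)
    noise_b <- rlnorm(n, -sdlog^2 / 2, sdlog)
    noise_a <- rlnorm(n, -sdlog^2 / 2, sdlog)
    list(
      before = tibble::tibble(bouton_id = sprintf("b%03d", seq_len(n)),
                              delta_nM = level * noise_b),
      after = tibble::tibble(bouton_id = sprintf("b%03d", seq_len(n)),
                             delta_nM = level * effect * noise_a)
    )
  })
}
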