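make_records <- function(means = c(42, 76, 101), n_per_order = 20, sd = 30,
                         n_cells = 20, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      branch_order = rep(1:3, each = n_per_order),
      cell_id = sample(sprintf("c%02d", seq_len(n_cells)), 3 * n_per_order,
                       replace = TRUE),
      delta_nM = pmax(0, rep(means, each = n_per_order) +
                        rnorm(3 * n_per_order, 0, sd))
    )
  })
}

test_that("branch-order analysis runs both tests with the right structure", {
  rec <- make_records(seed = 3)
  res <- branch_order_analysis(rec, "delta")
  expect_s3_class(res, "flim_stats")
  expect_identical(res$method, c("kruskal_wallis", "two_way_anova",
                                 "two_way_anova"))
  kw <- res[res$method == "kruskal_wallis", ]
  expect_equal(kw$df, 2)                       # three orders
  cell <- res[res$term == "cell_id", ]
  expect_equal(cell$df, length(unique(rec$cell_id)) - 1)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  expect_lt(kw$p_value, 0.05)                      # large true effect

  # degenerate constant response: H = 0, evidence-free
  rec0 <- dplyr::mutate(rec, delta_nM = 7)
  res0 <- branch_order_analysis(rec0, "delta")
  expect_identical(res0$statistic[1], 0)
  expect_identical(res0$p_value[1], 1)

  # sparse level dropped with a warning
  rec_sparse <- dplyr::bind_rows(
    dplyr::filter(rec, branch_order != 3),
    dplyr::slice(dplyr::filter(rec, branch_order == 3), 1))
  expect_warning(branch_order_analysis(rec_sparse, "delta"),
                 "Dropping branch order")
})

test_that("the rank-based branch-order test is invariant to monotone transforms", {
  rec <- make_records(seed = 11)
  r1 <- branch_order_analysis(rec, "delta")
  rec_t <- dplyr::mutate(rec, delta_nM = log1p(delta_nM)^3)
  r2 <- branch_order_analysis(rec_t, "delta")
  kw1 <- r1[r1$method == "kruskal_wallis", ]
  kw2 <- r2[r2$method == "kruskal_wallis", ]
  expect_equal(kw1$statistic, kw2$statistic, tolerance = 1e-12)
  expect_equal(kw1$p_value, kw2$p_value, tolerance = 1e-12)
})

test_that("paired comparison gates on normality and honours pairing", {
  sim <- simulate_paired_condition(n = 12, mean_before = 99, effect = 0.31,
                                   cv = 0.5, seed = 5)
  res <- paired_condition_test(sim$before, sim$after, response = "delta")
  expect_true(res$method %in% c("paired_t", "wilcoxon_signed_rank"))
  expect_lt(res$p_value, 0.05)
  expect_match(res$normality_gate, "shapiro")

  # additive shift of both conditions changes nothing
  shift <- function(df) dplyr::mutate(df, delta_nM = delta_nM + 55)
  res_s <- paired_condition_test(shift(sim$before), shift(sim$after),
                                 response = "delta")
  expect_equal(res_s$p_value, res$p_value, tolerance = 1e-12)
  expect_identical(res_s$method, res$method)

  # all ties -> explicit no-effect result
  res_t <- paired_condition_test(sim$before, sim$before, response = "delta")
  expect_identical(res_t$method, "no_effect_all_ties")
  expect_identical(res_t$p_value, 1)

  # unmatched ids are a pairing error
  bad <- dplyr::mutate(sim$after,
                       bouton_id = paste0(bouton_id, "x"))
  expect_error(paired_condition_test(sim$before, bad, response = "delta"),
               class = "flimca_pairing_error")

  # gate reproducibility: the tests are deterministic given the table
  expect_identical(
    tidy(paired_condition_test(sim$before, sim$after, response = "delta")),
    tidy(res))
})

test_that("Pratt signed-rank agrees with the standard test when no zeros exist", {
  withr::with_seed(17, {
    for (i in 1:5) {
      d <- round(rnorm(15, 0.4), 2)
      d <- d[d != 0]
      ours <- wilcoxon_signed_rank_pratt(d)
      ref <- suppressWarnings(
        wilcox.test(d, exact = FALSE, correct = TRUE))
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
  # zeros participate in ranking but not in the statistic
  with_zeros <- wilcoxon_signed_rank_pratt(c(0, 0, 1, 2, 3, 4, -1))
  expect_true(with_zeros$p_value > 0 && with_zeros$p_value <= 1)
})

test_that("percent change is exact arithmetic on group means", {
  expect_equal(percent_change(99, 31), 100 * (1 - 31 / 99))
  expect_equal(percent_change(99, 31), 68.687, tolerance = 1e-4)
  expect_equal(percent_change(140, 66), 52.857, tolerance = 1e-4)
  expect_equal(percent_change(31, 23), 25.806, tolerance = 1e-4)
  expect_equal(percent_change(12, 12), 0)
  expect_error(percent_change(0, 5), class = "flimca_domain_error")
})
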