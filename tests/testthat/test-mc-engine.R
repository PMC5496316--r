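test_that("scenario results do honest replication bookkeeping", {
  scn <- scenario(100, 100, 0.5, 5, 3, 13, seed = 71L)
  res <- run_scenario(scn, 1, items = "studied_only")
  expect_true(res$power %in% c(0, 1))
  expect_lte(res$n_converged, 1L)
  res5 <- run_scenario(scn, 5, items = "all")
  expect_lte(res5$n_converged, 5L)
  expect_true(res5$power >= 0 && res5$power <= 1)
  expect_true(res5$type1_error >= 0 && res5$type1_error <= 1)
  expect_true(all(!is.na(unlist(res5$mean_fit_indices))))
})

test_that("identical seeds reproduce scenario results exactly", {
  scn <- scenario(100, 100, 0.5, 5, 3, 13, seed = 72L)
  r1 <- run_scenario(scn, 10, items = "all")
  r2 <- run_scenario(scn, 10, items = "all")
  expect_identical(r1$power, r2$power)
  expect_identical(r1$type1_error, r2$type1_error)
  expect_identical(r1$mean_fit_indices, r2$mean_fit_indices)
})

test_that("grids enumerate the factorial design and rerun deterministically", {
  g <- scenario_grid()
  expect_equal(nrow(g), 780L)
  expect_equal(nrow(unique(g)), 780L)
  # restricted grid: condition 13, severe DIF, 5 items
  g13 <- scenario_grid(deltas = 1.0, n_items = 5L, conditions = 13L)
  expect_equal(nrow(g13), 15L)
  # subset reruns reproduce the same rows as the full run
  full <- run_grid(g13[1:4, ], n_reps = 3, base_seed = 99L,
                   items = "studied_only")
  again <- run_grid(g13[3:4, ], n_reps = 3, base_seed = 99L,
                    items = "studied_only")
  expect_equal(full[3:4, ], again, ignore_attr = TRUE)
})

test_that("rejection of the studied item is monotone in the DIF magnitude", {
  # matched seeds across deltas: common random numbers for bank and traits
  rates <- vapply(c(0, 0.25, 0.5, 1.0), function(delta) {
    scn <- scenario(100, 100, delta, 5, 3, 13, seed = 73L)
    run_scenario(scn, 300, items = "studied_only")$power
  }, numeric(1))
  se <- sqrt(pmax(rates * (1 - rates), 0.002) / 300)
  # nondecreasing within two Monte-Carlo standard errors of slack
  for (i in 1:3) {
    expect_gte(rates[i + 1], rates[i] - 2 * (se[i] + se[i + 1]))
  }
  # and the span is scientifically meaningful: null near alpha, severe near 1
  expect_lt(rates[1], 0.1)
  expect_gt(rates[4], 0.9)
})

test_that("aggregation groups by design factors and reports pairwise contrasts", {
  # synthetic results table with known structure
  res <- data.frame(n_ref = rep(c(100, 500), each = 3),
                    n_focal = 100,
                    delta = rep(c(0.5, 1.0, 0.5), 2),
                    n_items = 5, n_categories = rep(c(3, 5, 7), 2),
                    condition_id = c(13, 1, 2, 13, 3, 4),
                    reps = 10, n_converged = 10,
                    power = c(0.6, 0.99, 0.7, 0.8, 0.9, 0.75),
                    type1_error = c(0.05, 0.06, 0.07, 0.05, 0.06, 0.08))
  agg <- aggregate_contrast(res, "distribution_class")
  expect_equal(agg$level, c("normal", "moderate", "high"))
  expect_equal(agg$mean_power[agg$level == "normal"], 0.7)
  expect_equal(agg$mean_power[agg$level == "moderate"], 0.945)
  pw <- attr(agg, "pairwise")
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$power_diff_pp[pw$level_a == "normal" & pw$level_b == "moderate"],
               100 * (0.7 - 0.945))
  agg_d <- aggregate_contrast(res, "delta")
  expect_equal(sort(agg_d$level), c("0.5", "1"))
  agg_r <- aggregate_contrast(res, "ratio")
  expect_equal(sort(agg_r$level), c("R100/F100", "R500/F100"))
  one <- aggregate_contrast(res[1, ], "delta")
  expect_equal(one$mean_power, 0.6)
  expect_error(aggregate_contrast(res, "unknown"))
})
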