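test_that("drawn banks respect the parameter distributions", {
  set.seed(5)
  bank <- draw_item_bank(5, 3)
  expect_equal(bank$n_items, 5L)
  expect_equal(bank$n_categories, 3L)
  expect_true(all(bank$discriminations >= 1.5 & bank$discriminations <= 2))
  expect_true(all(apply(bank$thresholds, 1, diff) > 0))
  expect_equal(ncol(bank$thresholds), 2L)

  # moments over many draws: U(1.5, 2) mean and the expected order
  # statistics of two standard normal draws, checked against a brute-force
  # simulation oracle
  set.seed(6)
  a_all <- replicate(2000, draw_item_bank(5, 3)$discriminations)
  expect_lt(abs(mean(a_all) - 1.75), 0.01)
  set.seed(7)
  th <- do.call(rbind, replicate(2000, draw_item_bank(5, 3)$thresholds,
                                 simplify = FALSE))
  set.seed(8)
  brute <- t(apply(matrix(rnorm(2e5), ncol = 2), 1, sort))
  expect_lt(abs(mean(th[, 1]) - mean(brute[, 1])), 0.02)
  expect_lt(abs(mean(th[, 1]) - (-1 / sqrt(pi))), 0.02)
  expect_lt(abs(mean(th[, 2]) - 1 / sqrt(pi)), 0.02)

  expect_error(draw_item_bank(1, 3), ">= 2")
  expect_error(draw_item_bank(5, 1), ">= 2")
})

test_that("uniform DIF shifts only the studied item's thresholds and is invertible", {
  bank <- item_bank(c(1.6, 1.8, 1.7), rbind(c(-1, 0, 1), c(-0.5, 0.2, 0.9),
                                            c(-2, -1, 0)))
  shifted <- apply_uniform_dif(bank, 1, 0.5)
  expect_equal(shifted$thresholds[1, ], c(-0.5, 0.5, 1.5))
  expect_equal(shifted$thresholds[2:3, ], bank$thresholds[2:3, ])
  expect_equal(shifted$discriminations, bank$discriminations)
  # identity and exact inverse
  expect_identical(apply_uniform_dif(bank, 2, 0), bank)
  expect_identical(apply_uniform_dif(shifted, 1, -0.5), bank)
  two <- item_bank(1.5, matrix(c(-1, 1), 1))
  expect_equal(apply_uniform_dif(two, 1, 1)$thresholds[1, ], c(0, 2))
  expect_error(apply_uniform_dif(bank, 4, 0.5), "valid item")
})

test_that("GRM category probabilities match direct evaluation and normalize", {
  p <- grm_category_probs(0, 2, c(-1, 1))
  expect_equal(p, c(0.1192029, 0.7615942, 0.1192029), tolerance = 1e-6)
  expect_equal(p[1], p[3])   # symmetric thresholds at theta = 0
  expect_equal(sum(p), 1)
  # logistic limit: all mass on the top category
  expect_equal(grm_category_probs(60, 1.5, c(-1, 0, 1)), c(0, 0, 0, 1),
               tolerance = 1e-12)
  expect_error(grm_category_probs(0, 2, c(1, -1)), "ascending")

  # normalization and nonnegativity over a wide parameter sweep
  set.seed(9)
  for (i in 1:200) {
    theta <- runif(1, -6, 6)
    a <- runif(1, 1.5, 2)
    J <- sample(2:7, 1)
    th <- sort(rnorm(J - 1))
    p <- grm_category_probs(theta, a, th)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("sampled category frequencies agree with the probability oracle", {
  set.seed(10)
  n <- 1e6
  for (theta in c(-1, 0.5)) {
    a <- 1.8; th <- c(-0.8, 0.1, 1.2)
    y <- mimicsim:::grm_sample_item(rep(theta, n), a, th)
    p <- grm_category_probs(theta, a, th)
    emp <- tabulate(y, nbins = 4) / n
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(emp - p) <= 4 * pmax(se, 1e-9)))
  }
})
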