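test_that("standardized Beta moments match numerical integration of the density", {
  # independent oracle: numerical integration of the Beta density
  num_moments <- function(a, b) {
    m <- integrate(function(x) x * dbeta(x, a, b), 0, 1)$value
    v <- integrate(function(x) (x - m)^2 * dbeta(x, a, b), 0, 1)$value
    list(mean = m, sd = sqrt(v))
  }
  for (sh in list(c(1, 4), c(0.5, 4), c(4, 1), c(4, 0.5))) {
    got <- standardized_beta_params(sh[1], sh[2])
    ora <- num_moments(sh[1], sh[2])
    # quadrature tolerance dominated by the integrable x^(a-1) endpoint
    # singularity when a = 1/2
    expect_equal(got$mean, ora$mean, tolerance = 1e-5)
    expect_equal(got$sd, ora$sd, tolerance = 1e-5)
  }
  # frozen closed-form values
  expect_equal(standardized_beta_params(1, 4)$mean, 0.2)
  expect_equal(standardized_beta_params(1, 4)$sd, 0.1632993, tolerance = 1e-6)
  expect_equal(standardized_beta_params(0.5, 4)$mean, 0.1111111, tolerance = 1e-6)
  expect_equal(standardized_beta_params(0.5, 4)$sd, 0.1340050, tolerance = 1e-6)
  # mirror symmetry
  expect_equal(standardized_beta_params(4, 1)$mean, 0.8)
  expect_equal(standardized_beta_params(4, 1)$sd, standardized_beta_params(1, 4)$sd)
  expect_error(standardized_beta_params(-1, 4), "positive")
  expect_error(standardized_beta_params(1, 0), "positive")
})

test_that("standardized Beta samples have mean 0, variance 1 and the Beta skewness", {
  set.seed(11)
  n <- 1e6
  beta_skew <- function(a, b) 2 * (b - a) * sqrt(a + b + 1) /
    ((a + b + 2) * sqrt(a * b))
  for (sh in list(c(1, 4), c(0.5, 4), c(4, 1), c(4, 0.5))) {
    x <- sample_latent(latent_trait_spec("beta", sh[1], sh[2]), n)
    # 4 Monte-Carlo standard errors around the target moments
    expect_lt(abs(mean(x)), 4 / sqrt(n))
    se_var <- sd(x^2) / sqrt(n)
    expect_lt(abs(var(x) - 1), 4 * se_var)
    skew <- mean(x^3)   # affine standardization leaves skewness invariant
    expect_lt(abs(skew - beta_skew(sh[1], sh[2])), 0.05)
  }
  z <- sample_latent(latent_trait_spec("normal"), 1e5)
  expect_lt(abs(mean(z)), 3 / sqrt(1e5))
  expect_lt(abs(sd(z) - 1), 0.02)
})

test_that("condition table maps ids to the correct group distributions", {
  c13 <- trait_condition(13)
  expect_equal(c13$reference$family, "normal")
  expect_equal(c13$focal$family, "normal")
  c2 <- trait_condition(2)
  expect_equal(c2$reference$family, "normal")
  expect_equal(c(c2$focal$shape1, c2$focal$shape2), c(0.5, 4))
  c9 <- trait_condition(9)
  expect_equal(c(c9$reference$shape1, c9$reference$shape2), c(1, 4))
  expect_equal(c(c9$focal$shape1, c9$focal$shape2), c(4, 1))
  expect_error(trait_condition(14), "1..13")
  expect_equal(distribution_class(c(13, 1, 2, 11, 12)),
               c("normal", "moderate", "high", "moderate", "high"))
})
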