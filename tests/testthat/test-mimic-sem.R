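test_that("implied moments obey the path-tracing rules and match a simulation oracle", {
  spec <- mimic_spec(5, 1)
  k <- 5
  lambda <- c(1.1, 1, 0.8, 1.2, 0.9)   # marker is item 2 (item 1 studied)
  tau <- c(2, 2.2, 1.8, 2.1, 2)
  psi <- c(0.5, 0.4, 0.6, 0.5, 0.45)
  gamma <- -0.4; beta <- -0.3; psi_zeta <- 1
  par <- c(lambda[-2], tau, psi, gamma, beta, psi_zeta)
  p_focal <- 1 / 3
  vx <- p_focal * (1 - p_focal)

  imp <- implied_moments(par, spec, vx, p_focal)
  # no latent signal: zero loadings cannot be expressed (marker fixed at 1),
  # but zero latent variance and zero structural paths give a diagonal item
  # block and zero item-covariate covariance
  imp0 <- implied_moments(c(lambda[-2], tau, psi, 0, 0, 0), spec, vx, p_focal)
  expect_equal(imp0$cov[1:k, 1:k], diag(psi))
  expect_equal(imp0$cov[1:k, k + 1], rep(0, k))
  expect_equal(imp0$mean[1:k], tau)

  # path-tracing: cov(item_i, x) = (lambda_i gamma + beta [i = s]) Var(x)
  b <- gamma * lambda; b[1] <- b[1] + beta
  expect_equal(imp$cov[1:k, k + 1], b * vx)
  expect_equal(imp$cov[k + 1, k + 1], vx)

  # simulation oracle: empirical moments of the structural equations
  set.seed(21)
  sim <- sim_linear_mimic(2e5, lambda, gamma, beta, 1, tau, psi, psi_zeta,
                          p_focal)
  Z <- cbind(sim$responses, x = sim$group)
  expect_equal(unname(colMeans(Z)), unname(imp$mean), tolerance = 0.02)
  expect_equal(unname(cov(Z)), unname(imp$cov), tolerance = 0.02)

  expect_error(implied_moments(par[-1], spec, vx, p_focal), "3k")
})

test_that("the ML discrepancy is zero at equality, positive elsewhere, hand-checkable", {
  # scalar hand evaluation: log 2 + 1/2 - 0 - 1
  expect_equal(
    fml_discrepancy(0, matrix(1), 0, matrix(2)),
    log(2) + 0.5 - 1, tolerance = 1e-12)
  # zero iff moments match
  set.seed(22)
  A <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  m <- rnorm(5)
  expect_equal(fml_discrepancy(m, A, m, A), 0, tolerance = 1e-10)
  # nonnegativity on random admissible instances
  for (i in 1:50) {
    S <- crossprod(matrix(rnorm(16), 4)) + diag(4)
    Sg <- crossprod(matrix(rnorm(16), 4)) + diag(4)
    expect_gte(fml_discrepancy(rnorm(4), S, rnorm(4), Sg), 0)
  }
  expect_error(fml_discrepancy(0, matrix(1), 0, matrix(-1)), "positive definite")
})

test_that("analytic gradients match finite differences", {
  set.seed(23)
  d <- generate_dataset(scenario(200, 100, 0.5, 5, 3, 13, seed = 8L))
  spec <- mimic_spec(5, 1)
  stats <- mimicsim:::.mimic_stats(d$responses, d$group)
  obj <- mimicsim:::.mimic_objective(stats, spec)
  k <- 5
  start <- c(rep(1, k - 1), stats$mbar[1:k], log(diag(stats$S)[1:k] / 2),
             0, 0, log(diag(stats$S)[2] / 2))
  fd <- function(f, x, h = 1e-6) {
    vapply(seq_along(x), function(i) {
      xp <- x; xm <- x; xp[i] <- x[i] + h; xm[i] <- x[i] - h
      (f(xp) - f(xm)) / (2 * h)
    }, numeric(1))
  }
  for (rep in 1:5) {
    pt <- start + rnorm(length(start), 0, 0.15)
    g <- obj$gr(pt)
    gn <- fd(obj$fn, pt)
    expect_lt(max(abs(g - gn) / pmax(abs(gn), 1)), 1e-5)
  }
})

test_that("parameters are recovered without bias on correctly specified data", {
  set.seed(24)
  sim <- gen_linear(50000)
  fit <- fit_mimic(sim)
  expect_true(fit$converged)
  expect_false(fit$heywood)
  # bias below 0.02 for loadings and structural paths at n = 50,000
  expect_lt(max(abs(fit$loadings - linear_truth$lambda)), 0.02)
  expect_lt(abs(fit$gamma - linear_truth$gamma), 0.02)
  expect_lt(abs(fit$beta - linear_truth$beta), 0.02)
  # and estimates within 3 reported standard errors of truth
  expect_lt(abs(fit$beta - linear_truth$beta), 3 * fit$se_beta)
  expect_lt(abs(fit$gamma - linear_truth$gamma), 3 * fit$se_gamma)
  expect_lt(max(abs(fit$residual_variances - linear_truth$psi)), 0.03)
  expect_lt(abs(fit$zeta_variance - linear_truth$psi_zeta), 0.05)
  # the saturated-means structure reproduces the item means
  expect_equal(fit$df, 8)
})

test_that("repeated fits of the same data are bit-identical", {
  d <- generate_dataset(scenario(150, 100, 0.5, 5, 3, 13, seed = 5L))
  f1 <- fit_mimic(d)
  f2 <- fit_mimic(d)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$loadings, f2$loadings)
  expect_identical(f1$se, f2$se)
  expect_identical(f1$fml, f2$fml)
})

test_that("reported standard errors calibrate against the sampling distribution", {
  set.seed(25)
  reps <- 500
  betas <- ses <- numeric(reps)
  for (i in seq_len(reps)) {
    fit <- fit_mimic(gen_linear(600, beta = 0))
    betas[i] <- fit$beta
    ses[i] <- fit$se_beta
  }
  expect_lt(abs(mean(ses) / sd(betas) - 1), 0.10)
})

test_that("the Wald DIF test rejects at the nominal rate under the null", {
  scn <- scenario(500, 500, 0, 5, 3, 13, seed = 314L)
  res <- run_scenario(scn, 1000, items = "studied_only")
  expect_gte(res$n_converged, 990L)
  expect_gte(res$power, 0.035)
  expect_lte(res$power, 0.065)
})

test_that("wald_dif_test computes the two-sided normal test", {
  expect_equal(wald_dif_test(0, 1), list(z = 0, p_value = 1))
  w <- wald_dif_test(0.5, 0.25)
  expect_equal(w$z, 2)
  expect_equal(w$p_value, 2 * pnorm(-2), tolerance = 1e-12)
  expect_equal(w$p_value, 0.0455, tolerance = 1e-3)
  expect_equal(wald_dif_test(-0.5, 0.25)$p_value, w$p_value)
  expect_error(wald_dif_test(0.5, 0), "positive")
})

test_that("fit indices follow their defining formulas and limits", {
  S <- diag(3); Sg <- diag(3)
  # hand evaluation of RMSEA
  fi <- fit_indices(50, 25, 400, 30, 101, S, Sg)
  expect_equal(fi$rmsea, 0.1)
  # perfect-fit limit
  fi2 <- fit_indices(25, 25, 400, 30, 101, S, Sg)
  expect_equal(fi2$rmsea, 0)
  expect_equal(fi2$cfi, 1)
  # implied = sample: zero residuals, GFI 1
  expect_equal(fi$rmr, 0)
  expect_equal(fi$gfi, 1)
  resid_case <- fit_indices(50, 25, 400, 30, 101, S + 0.1, Sg)
  expect_gt(resid_case$rmr, 0)
  expect_lt(resid_case$gfi, 1)
  # saturated convention
  expect_equal(fit_indices(0, 0, 400, 30, 101, S, Sg)$rmsea, 0)
})
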