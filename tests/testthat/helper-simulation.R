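# Shared fixtures, all generated in code.

# Simulate directly from the linear MIMIC structural equations (not the GRM):
# the oracle generating process under which the fitted model is exactly
# correct, used for parameter-recovery and standard-error calibration checks.
sim_linear_mimic <- function(n, lambda, gamma, beta, studied_item,
                             tau, psi, psi_zeta, p_focal = 0.5) {
  k <- length(lambda)
  x <- stats::rbinom(n, 1, p_focal)
  theta <- gamma * x + stats::rnorm(n, 0, sqrt(psi_zeta))
  Y <- vapply(seq_len(k), function(i) {
    tau[i] + lambda[i] * theta + stats::rnorm(n, 0, sqrt(psi[i]))
  }, numeric(n))
  Y[, studied_item] <- Y[, studied_item] + beta * x
  colnames(Y) <- paste0("item_", seq_len(k))
  list(responses = Y, group = x)
}

# Canonical truth used by several mimic_sem tests.
linear_truth <- list(
  lambda = c(1, 1, 0.8, 1.2, 0.9),
  gamma = -0.4, beta = -0.3, studied_item = 1L,
  tau = c(2, 2.2, 1.8, 2.1, 2), psi = c(0.5, 0.4, 0.6, 0.5, 0.45),
  psi_zeta = 1
)

gen_linear <- function(n, beta = linear_truth$beta, gamma = linear_truth$gamma,
                       p_focal = 0.5) {
  sim_linear_mimic(n, linear_truth$lambda, gamma, beta,
                   linear_truth$studied_item, linear_truth$tau,
                   linear_truth$psi, linear_truth$psi_zeta, p_focal)
}
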