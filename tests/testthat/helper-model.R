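# Shared fixtures, built in code. The reference trajectory used by the PINN
# tests is memoized so several test files can reuse one solve.

.cache <- new.env(parent = emptyenv())

table1 <- function() ad_preset("table1")
chaos <- function() ad_preset("chaos")

# clean sigma = 0.9 reference over 200 days at h = 0.05 (stable step for the
# fastest clearance rate), reused by PINN and acceptance tests
reference_09 <- function() {
  if (is.null(.cache$ref09)) {
    pr <- table1()
    .cache$ref09 <- fde_solve(pr$params, pr$init, 0.9, 200, 4000)
  }
  .cache$ref09
}

linear_decay_rhs <- function(t, u, z) -u

# rebuild params from a plain list (independent of internal coercers)
as_ad_params_test <- function(q) {
  do.call(ad_params, q[names(formals(ad_params))])
}

# admissible random parameter draw (positive rates on plausible scales)
random_params <- function() {
  ad_params(Pi_N = runif(1, 0.1, 10), rho = runif(1, 0.001, 0.5),
            alpha = runif(1, 0.001, 0.5), phi1 = runif(1, 0.001, 0.5),
            beta1 = runif(1, 0.001, 0.5), gamma = runif(1, 1e-5, 0.1),
            phi2 = runif(1, 1e-5, 0.1), beta2 = runif(1, 1e-4, 0.1),
            d_beta = runif(1, 0.5, 20), kappa = runif(1, 0.001, 0.5),
            beta3 = runif(1, 1e-4, 0.1), d_mu = runif(1, 0.01, 1),
            phi3 = runif(1, 0.001, 0.1))
}
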