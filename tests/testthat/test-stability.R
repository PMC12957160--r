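test_that("disease-free equilibrium follows Pi_N / phi1 and annihilates the flow", {
  eq <- disease_free_equilibrium(ad_params(Pi_N = 1, phi1 = 0.02))
  expect_equal(unname(eq$state["F_N"]), 50)
  expect_equal(unname(eq$state[2:5]), rep(0, 4))
  expect_lte(eq$residual_norm, 1e-10 * (1 + max(abs(eq$state))))
  ch <- chaos()
  expect_equal(unname(disease_free_equilibrium(ch$params)$state["F_N"]),
               700 / 3e-5, tolerance = 1e-12)
})

test_that("endemic construction reproduces the closed-form component ratios", {
  p <- table1()$params
  eq <- endemic_equilibrium(p, I_N_star = 1)
  expect_equal(unname(eq$state["A_beta"]), 0.00017 / 9.535, tolerance = 1e-10)
  expect_equal(unname(eq$state["A_beta"]), 1.78290e-5, tolerance = 1e-5)
  expect_equal(unname(eq$state["T_mu"]),
               0.025 * 0.00017 / (0.302 * 9.535), tolerance = 1e-10)
  expect_equal(unname(eq$state["T_mu"]), 1.47591e-6, tolerance = 1e-5)
  # the constrained equations are exactly satisfied
  expect_lte(eq$residual_norm, 1e-10 * (1 + max(abs(eq$state))))
  # I_N* = 0 reduces to the disease-free point
  eq0 <- endemic_equilibrium(p, I_N_star = 0)
  expect_equal(eq0$state, disease_free_equilibrium(p)$state)
  expect_error(endemic_equilibrium(p, I_N_star = -1), "non-negative")
  # baseline parameters have R0 < 1: no admissible endemic state
  expect_error(endemic_equilibrium(p), "no admissible endemic")
})

test_that("self-consistent endemic equilibrium satisfies the full flow when R0 > 1", {
  p <- ad_params(alpha = 0.08 * 30)   # push R0 above threshold
  expect_gt(ngm_matrices(p)$R0, 1)
  eq <- endemic_equilibrium(p)
  expect_lte(eq$full_residual, 1e-10 * (1 + max(abs(eq$state))))
  expect_gt(unname(eq$state["I_N"]), 0)
})

test_that("closed-form R0 equals the NGM spectral radius", {
  p <- table1()$params
  ngm <- ngm_matrices(p)
  expect_equal(ngm$R0, 0.4451, tolerance = 1e-4)
  expect_equal(ngm$R0, ngm$R0_numeric, tolerance = 1e-12)
  expect_true(all(diag(ngm$V) > 0))
  expect_true(all(ngm$V[upper.tri(ngm$V) | lower.tri(ngm$V)] == 0))
  # no new infections without the amyloid cascade
  expect_equal(ngm_matrices(ad_params(alpha = 0))$R0, 0)
  set.seed(7)
  for (i in 1:100) {
    q <- random_params()
    n <- ngm_matrices(q)
    expect_equal(n$R0, n$R0_numeric, tolerance = 1e-12)
  }
})

test_that("R0 = 1 is the threshold for instability of the infected subsystem", {
  p <- table1()$params
  alpha_crit <- p$alpha / ngm_matrices(p)$R0^2   # R0 ~ sqrt(alpha)
  dominant <- function(alpha) {
    q <- ad_params(alpha = alpha)
    n <- ngm_matrices(q)
    max(Re(eigen(n$F - n$V, only.values = TRUE)$values))
  }
  expect_lt(dominant(alpha_crit * 0.9), 0)
  expect_gt(dominant(alpha_crit * 1.1), 0)
  q_at <- ad_params(alpha = alpha_crit)
  expect_equal(ngm_matrices(q_at)$R0, 1, tolerance = 1e-10)
})

test_that("R0 surface is consistent, monotone in alpha, and masks the threshold", {
  p <- table1()$params
  s <- r0_surface(p, c("alpha", "gamma"),
                  list(c(0.01, 0.2), c(1e-5, 1e-3)), grid_n = 21)
  # grid point equal to the base parameters reproduces ngm R0
  i <- which.min(abs(s$x - p$alpha))
  j <- which.min(abs(s$y - p$gamma))
  q <- unclass(p)
  q$alpha <- s$x[i]; q$gamma <- s$y[j]
  expect_equal(s$R0[i, j], ngm_matrices(as_ad_params_test(q))$R0)
  # monotone along the alpha axis
  expect_true(all(apply(s$R0, 2, function(col) all(diff(col) > 0))))
  expect_false(any(s$contour_mask))   # all R0 < 1 on this range
  s2 <- r0_surface(p, c("alpha", "Pi_N"), list(c(0.01, 2), c(0.5, 20)),
                   grid_n = 15)
  expect_true(any(s2$R0 > 1) && any(s2$R0 < 1))
  expect_true(any(s2$contour_mask))
  expect_error(r0_surface(p, c("alpha", "beta1"), list(c(0, 1), c(0, 1))),
               "entering R0")
})

test_that("DFE Jacobian matches its printed structure and a numeric audit", {
  p <- table1()$params
  J <- jacobian_dfe(p)
  expect_equal(J[1, 1], -0.02)
  expect_equal(J[2, 3] + J[1, 3], 0)   # sign symmetry of alpha*Pi_N/phi1
  expect_equal(J[3, 2], p$gamma)
  expect_equal(J[4, 3], p$kappa)
  # centered finite-difference Jacobian of the full rhs at the DFE,
  # restricted to the four non-microglial states; any mismatch is reported
  dfe <- disease_free_equilibrium(p)$state
  num <- matrix(0, 4, 4)
  for (j in 1:4) {
    e <- rep(0, 5)
    hh <- 1e-6 * max(1, abs(dfe[j]))
    e[j] <- hh
    num[, j] <- ((model_rhs(dfe + e, p) - model_rhs(dfe - e, p)) /
                   (2 * hh))[1:4]
  }
  discrepancy <- max(abs(unname(J) - num))
  expect_lt(discrepancy, 1e-6)
  # gains subtract on the diagonal only; a fifth gain is accepted and unused
  Jg <- jacobian_dfe(p, c(1, 2, 3, 4, 5))
  expect_equal(diag(Jg), diag(J) - c(1, 2, 3, 4))
  expect_equal(Jg - diag(diag(Jg)), J - diag(diag(J)))
  expect_error(jacobian_dfe(p, c(-1, 0, 0, 0)), "non-negative")
})

test_that("gain-augmented chaos Jacobian reproduces the two structural roots", {
  ch <- chaos()
  J <- jacobian_dfe(ch$params, c(1, 2, 3, 4))
  expect_equal(J[1, 1], -1.00003)
  expect_equal(J[4, 4], -4.302)
  st <- eigen_stability(J)
  expect_equal(Re(st$eigenvalues[1]), -1.00003, tolerance = 1e-12)
  expect_equal(Re(st$eigenvalues[2]), -4.302, tolerance = 1e-12)
  # the published four-root list is inconsistent with this matrix: the
  # audit must flag it (trace identity), not reproduce it
  aud <- audit_reported_spectrum(J, c(-1.00003, -4.302,
                                      -25.8118817160782, -11.3265217160782))
  expect_false(aud$consistent)
  expect_gt(aud$gap, 1)
  expect_true(all(aud$matched[1:2]))
  expect_false(all(aud$matched))
  # this matrix is actually unstable: one positive real eigenvalue
  expect_false(st$stable)
  expect_gt(max(Re(st$eigenvalues)), 0)
})

test_that("eigenvalue reports are deterministic and satisfy the trace identity", {
  st <- eigen_stability(diag(c(-1, -2)))
  expect_equal(st$eigenvalues, as.complex(c(-1, -2)))
  expect_true(st$stable)
  expect_error(eigen_stability(matrix(1, 2, 3)), "square")
  set.seed(11)
  for (i in 1:100) {
    m <- matrix(rnorm(16), 4, 4)
    st <- eigen_stability(m)
    expect_equal(sum(st$eigenvalues), as.complex(sum(diag(m))),
                 tolerance = 1e-8)
    expect_true(all(diff(Mod(st$eigenvalues)) >= -1e-12))
  }
})

test_that("analysis report serializes to JSON with matrices and eigenpairs", {
  rep <- analyze_model(chaos()$params, c(1, 2, 3, 4))
  path <- tempfile(fileext = ".json")
  write_analysis(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$R0, rep$R0, tolerance = 1e-12)
  expect_length(back$eigenvalues, 4)
  expect_equal(back$eigenvalues[[1]]$re, -1.00003, tolerance = 1e-10)
  expect_length(back$jacobian, 4)
  expect_false(back$stable)
})
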