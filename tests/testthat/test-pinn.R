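test_that("network builder is deterministic, 7-armed and bounds its controls", {
  cfg <- pinn_config(seed = 5, hidden_layers = 2, width = 16, horizon = 100)
  net1 <- build_network(cfg)
  net2 <- build_network(cfg)
  probe <- seq(0, 100, length.out = 50)
  expect_identical(net1(probe), net2(probe))
  out <- net1(probe)
  expect_equal(dim(out), c(50, 7))
  expect_equal(colnames(out), c("F_N", "I_N", "A_beta", "T_mu", "M_rho",
                                "z1", "z2"))
  set.seed(3)
  out2 <- net1(runif(1000, 0, 100))
  expect_true(all(out2[, 6:7] >= 0 & out2[, 6:7] <= 1))
  # a different seed gives a different function
  net3 <- build_network(pinn_config(seed = 6, hidden_layers = 2, width = 16,
                                    horizon = 100))
  expect_false(identical(net1(probe), net3(probe)))
})

test_that("fractional residual vanishes for constants and collapses at sigma = 1", {
  zero_rhs <- function(t, u, z) 0 * u
  states <- matrix(2, 11, 3)
  r <- fractional_residual(states, 0.7, 0.1, zero_rhs)
  expect_equal(max(abs(r)), 0)
  # sigma = 1: exactly the backward-difference defect
  set.seed(8)
  U <- matrix(cumsum(rnorm(12)), 12, 1)
  h <- 0.25
  r1 <- fractional_residual(U, 1, h, linear_decay_rhs)
  defect <- (U[-1, 1] - U[-12, 1]) / h - (-U[-1, 1])
  expect_equal(as.numeric(r1), defect, tolerance = 1e-12)
})

test_that("the GL solver's own trajectory drives the residual to zero at ~O(h)", {
  sg <- 0.9
  res_max <- vapply(c(0.02, 0.01, 0.005), function(h) {
    U <- gl_integrate(linear_decay_rhs, 1, sg, 2, round(2 / h))
    max(abs(fractional_residual(matrix(U, ncol = 1), sg, h,
                                linear_decay_rhs)))
  }, numeric(1))
  expect_true(all(diff(res_max) < 0))
  ratios <- res_max[-1] / res_max[-3]
  expect_true(all(abs(ratios - 0.5) < 0.15))
})

test_that("loss breakdown follows the additive data + lambda * physics form", {
  lb <- total_loss(matrix(c(1.5, 2.5)), matrix(c(1.0, 2.0)),
                   residuals = NULL, lambda_phys = 0)
  expect_equal(lb$data_loss, 0.25)
  expect_equal(lb$total, lb$data_loss)
  R <- matrix(c(0.1, -0.2, 0.3), 3, 1)
  lb2 <- total_loss(matrix(0, 3, 1), matrix(0, 3, 1), R, lambda_phys = 2)
  expect_equal(lb2$physics_loss, mean(R^2))
  expect_equal(lb2$total, lb2$data_loss + 2 * lb2$physics_loss,
               tolerance = 1e-10)
  lb3 <- total_loss(matrix(1, 2, 2), matrix(1, 2, 2), NULL, 1)
  expect_equal(lb3$total, 0)
  expect_error(total_loss(matrix(0, 2, 2), matrix(0, 3, 2), NULL, 1),
               "alignment")
})

test_that("observation noise is seeded, anchored to the per-state amplitude, and leaves the input intact", {
  pr <- table1()
  tr <- fde_solve(pr$params, pr$init, 1, 10, 100)
  expect_identical(add_noise(tr, 0, seed = 1), tr)
  n1 <- add_noise(tr, 0.1, seed = 7)
  n2 <- add_noise(tr, 0.1, seed = 7)
  expect_identical(n1$states, n2$states)
  expect_false(identical(n1$states, add_noise(tr, 0.1, seed = 8)$states))
  expect_error(add_noise(tr, -0.1), ">= 0")
  # constant-1 series of length 1e4: empirical sd within 5% of the level
  const <- ad_trajectory(seq(0, 1, length.out = 1e4),
                         matrix(1, 1e4, 5))
  noisy <- add_noise(const, 0.1, seed = 3)
  sds <- apply(noisy$states - 1, 2, sd)
  expect_true(all(abs(sds - 0.1) / 0.1 < 0.05))
})

test_that("training gradients agree with central finite differences", {
  pr <- table1()
  ref <- fde_solve(pr$params, pr$init, 0.9, 10, 100)
  N <- 20
  h <- 10 / N
  w <- gl_weights(0.9, N)
  Wr <- fracAD:::gl_conv_matrix(w)[-1, , drop = FALSE]
  idx <- seq(1, 101, by = 5)
  sub <- ref$states[idx, ]
  scale <- apply(abs(sub), 2, max)
  scale[scale == 0] <- 1
  env <- list(x = matrix(seq(0, 1, length.out = N + 1), ncol = 1),
              di = seq(1, N + 1, by = 2),
              Yobs = sweep(sub[seq(1, N + 1, by = 2), ], 2, scale, "/") + 0.01,
              lambda = 1, params = pr$params, scale = scale,
              hs_inv = h^-0.9, Wr = Wr, rs = rowSums(Wr),
              use_controls = TRUE)
  net <- fracAD:::nn_init(c(1, 8, 8, 7), 11)
  lg <- fracAD:::pinn_loss_grad(net, env)
  eps <- 1e-6
  for (l in seq_along(net$W)) {
    for (ij in list(c(1, 1), c(min(2, nrow(net$W[[l]])), min(5, ncol(net$W[[l]]))))) {
      np <- net; np$W[[l]][ij[1], ij[2]] <- np$W[[l]][ij[1], ij[2]] + eps
      nm <- net; nm$W[[l]][ij[1], ij[2]] <- nm$W[[l]][ij[1], ij[2]] - eps
      fd <- (fracAD:::pinn_loss_grad(np, env)$total -
               fracAD:::pinn_loss_grad(nm, env)$total) / (2 * eps)
      expect_equal(lg$grads$W[[l]][ij[1], ij[2]], fd, tolerance = 1e-5)
    }
    np <- net; np$b[[l]][1] <- np$b[[l]][1] + eps
    nm <- net; nm$b[[l]][1] <- nm$b[[l]][1] - eps
    fd <- (fracAD:::pinn_loss_grad(np, env)$total -
             fracAD:::pinn_loss_grad(nm, env)$total) / (2 * eps)
    expect_equal(lg$grads$b[[l]][1], fd, tolerance = 1e-5)
  }
})

test_that("the three variants train as configured on the scaled-down profile", {
  pr <- table1()
  ref <- reference_09()
  cfg <- pinn_config(sigma = 0.9, hidden_layers = 3, width = 32,
                     learning_rate = 2e-3, iterations = 600, horizon = 200,
                     n_collocation = 100, seed = 1)
  fit <- train_variant("fractional", cfg, ref, pr$params, 0, seed = 2)
  expect_s3_class(fit, "ad_pinn")
  expect_length(fit$history, 600)
  expect_equal(fit$final$total, tail(fit$history, 1))
  expect_equal(fit$final$total,
               fit$final$data_loss + fit$lambda_phys * fit$final$physics_loss,
               tolerance = 1e-10)
  expect_true(all(fit$final$per_state_mse >= 0))
  # reproducibility: same seed, same fit
  fit2 <- train_variant("fractional", cfg, ref, pr$params, 0, seed = 2)
  expect_identical(fit$history, fit2$history)
  # integer variant records effective order one
  fitI <- train_variant("integer", cfg, ref, pr$params, 0, seed = 2)
  expect_equal(fitI$sigma_effective, 1)
  # baseline drops physics entirely and ignores the model parameters
  fitB <- train_variant("baseline", cfg, ref, pr$params, 0, seed = 2)
  expect_equal(fitB$lambda_phys, 0)
  expect_equal(fitB$final$total, fitB$final$data_loss)
  perturbed <- ad_params(alpha = 0.9, d_beta = 1)
  fitB2 <- train_variant("baseline", cfg, ref, perturbed, 0, seed = 2)
  expect_identical(fitB$history, fitB2$history)
  expect_identical(fitB$trajectory$states, fitB2$trajectory$states)
  # predictions evaluate anywhere on [0, T]
  pred <- predict(fit, c(0, 50.5, 199))
  expect_equal(dim(pred), c(3, 8))
})

test_that("baseline interpolates noiseless data below 1e-3 and the fractional PINN tracks F_N within 5%", {
  pr <- table1()
  ref <- reference_09()
  cfgB <- pinn_config(sigma = 0.9, hidden_layers = 3, width = 32,
                      learning_rate = 2e-3, iterations = 4000, horizon = 200,
                      n_collocation = 100, seed = 1)
  fitB <- train_variant("baseline", cfgB, ref, pr$params, 0, seed = 1)
  expect_lt(fitB$final$data_loss, 1e-3)
  # fractional variant on the 0.5-day collocation grid, 2000 iterations
  cfgF <- pinn_config(sigma = 0.9, iterations = 2000, horizon = 200,
                      n_collocation = 400, data_stride = 4, seed = 1)
  fitF <- train_variant("fractional", cfgF, ref, pr$params, 0, seed = 1)
  truth <- ref$states[seq(1, 4001, by = 10), "F_N"]
  rel_l2 <- sqrt(sum((fitF$trajectory$states[, "F_N"] - truth)^2) /
                   sum(truth^2))
  expect_lt(rel_l2, 0.05)
})

test_that("benchmark aggregation is seeded and its robustness ratio behaves", {
  pr <- table1()
  ref <- fde_solve(pr$params, pr$init, 0.9, 20, 400)
  cfg <- pinn_config(sigma = 0.9, hidden_layers = 2, width = 8,
                     iterations = 50, horizon = 20, n_collocation = 40,
                     seed = 1)
  b <- noise_benchmark(cfg, ref, pr$params, levels = c(0, 0.2),
                       replicates = 2, seed = 3,
                       variants = c("fractional", "baseline"))
  expect_s3_class(b, "ad_benchmark")
  expect_equal(nrow(b$table), 4)    # 2 variants x 2 levels
  expect_named(b$robustness, c("fractional", "baseline"))
  expect_true(all(b$table$min <= b$table$mean & b$table$mean <= b$table$max))
  expect_length(b$runs, 8)
  # identical base seed reproduces the whole benchmark
  b2 <- noise_benchmark(cfg, ref, pr$params, levels = c(0, 0.2),
                        replicates = 2, seed = 3,
                        variants = c("fractional", "baseline"))
  expect_equal(b$robustness, b2$robustness)
  expect_error(noise_benchmark(cfg, ref, pr$params, levels = c(0.1, 0.2),
                               replicates = 1, seed = 1), "include 0")
  paths <- write_benchmark(b, tempfile("benchdir"))
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[2])
  expect_length(js$runs, 8)
})
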