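#' Configuration for the physics-informed neural network
#'
#' All three learning variants (fractional PINN, integer-order PINN,
#' data-only baseline) share one architecture: a dense tanh network mapping
#' normalized time t/T to seven outputs, the five states (linear, in
#' normalized units) plus the two controls (squashed into [0, 1] by a
#' sigmoid). The loss is
#' \deqn{L = L_{data} + \lambda_{phys} L_{phys},}
#' with \eqn{L_{data}} the mean squared prediction-observation discrepancy
#' over the data grid and \eqn{L_{phys}} the mean squared GL-discretized
#' Caputo residual over the collocation grid.
#'
#' @param sigma fractional order for the physics residual (the integer
#'   variant forces 1 at training time).
#' @param hidden_layers number of hidden layers (default 4).
#' @param width hidden layer width (default 64).
#' @param lambda_phys physics weight, >= 0; 0 defines the baseline variant.
#' @param learning_rate Adam step size.
#' @param iterations training iterations.
#' @param seed RNG seed for initialization (noise uses a derived seed).
#' @param horizon time horizon T (days).
#' @param n_collocation number of collocation steps (grid has
#'   \code{n_collocation + 1} uniform nodes on [0, T]; the GL convolution
#'   requires the full uniform grid).
#' @param data_stride data grid = every \code{data_stride}-th collocation
#'   node (t = 0 is always a data node, which is how initial conditions are
#'   softly enforced).
#' @param use_controls should the physics residual use the controlled
#'   right-hand side with the network's own control outputs (default TRUE;
#'   the baseline never supervises or uses controls).
#' @return A list of class \code{"pinn_config"}.
#' @export
pinn_config <- function(sigma = 0.9, hidden_layers = 4, width = 64,
                        lambda_phys = 1, learning_rate = 1e-3,
                        iterations = 2000, seed = 1, horizon = 200,
                        n_collocation = 100, data_stride = 1,
                        use_controls = TRUE) {
  check_sigma(sigma)
  if (lambda_phys < 0) stop("lambda_phys must be >= 0")
  if (hidden_layers < 1 || width < 1) stop("invalid architecture")
  if (iterations < 1) stop("iterations must be >= 1")
  if (n_collocation < 2) stop("n_collocation must be >= 2")
  if (data_stride < 1 || data_stride > n_collocation)
    stop("data_stride must lie in [1, n_collocation]")
  structure(list(sigma = sigma, hidden_layers = hidden_layers, width = width,
                 lambda_phys = lambda_phys, learning_rate = learning_rate,
                 iterations = iterations, seed = seed, horizon = horizon,
                 n_collocation = n_collocation, data_stride = data_stride,
                 use_controls = use_controls),
            class = "pinn_config")
}

#' Build the (untrained) network approximator
#'
#' Deterministic given the config seed. The returned object is callable:
#' \code{net(times)} evaluates the network at raw times (normalized
#' internally by the horizon) and returns a matrix with columns
#' (F_N, I_N, A_beta, T_mu, M_rho, z1, z2); state outputs are in normalized
#' units, control outputs are squashed into [0, 1].
#'
#' @param config a \code{\link{pinn_config}}.
#' @return A function of class \code{"ad_network"}.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "pinn_config"))
  sizes <- c(1, rep(config$width, config$hidden_layers), 7)
  net <- nn_init(sizes, config$seed)
  f <- function(times) {
    x <- matrix(times / config$horizon, ncol = 1)
    out <- nn_forward(net, x)$out
    out[, 6:7] <- plogis(out[, 6:7])
    colnames(out) <- c(.ad_state_names, "z1", "z2")
    out
  }
  attr(f, "net") <- net
  attr(f, "config") <- config
  class(f) <- c("ad_network", "function")
  f
}

#' GL-discretized Caputo residual of a predicted trajectory
#'
#' For predictions \eqn{u} on the full uniform grid \eqn{t_0, \dots, t_N},
#' the residual at node \eqn{n \ge 1} is
#' \deqn{r_n = h^{-\sigma} \sum_{k=0}^{n} w_k\,(u_{n-k} - u_0)
#'       - f(t_n, u_n),}
#' the defect of the Caputo-GL derivative against the model flow. At
#' \eqn{\sigma = 1} this collapses to the backward-difference defect
#' \eqn{(u_n - u_{n-1})/h - f(t_n, u_n)}. Node 0 carries no derivative
#' information and is excluded.
#'
#' @param states matrix of predictions, one row per node (full uniform grid,
#'   row 1 = t = 0), any number of components.
#' @param sigma fractional order in (0, 1].
#' @param h uniform grid spacing; supply the grid's actual spacing (a
#'   non-uniform grid is an error upstream since the convolution assumes
#'   uniform spacing).
#' @param rhs flow field \code{f(t, u, z)}.
#' @param controls optional matrix of per-node control values (same rows as
#'   \code{states}).
#' @return Matrix of residuals with one row per node \eqn{1..N}.
#' @export
fractional_residual <- function(states, sigma, h, rhs, controls = NULL) {
  check_sigma(sigma)
  states <- as.matrix(states)
  N <- nrow(states) - 1
  if (N < 1) stop("need at least two nodes")
  if (!is.null(controls)) {
    controls <- as.matrix(controls)
    if (nrow(controls) != N + 1) stop("controls must match states rows")
  }
  w <- gl_weights(sigma, N)
  u0 <- states[1, ]
  du <- sweep(states, 2, u0, "-")
  Wr <- gl_conv_matrix(w)[-1, , drop = FALSE]
  conv <- (Wr %*% du) / h^sigma
  Fm <- t(vapply(seq_len(N), function(n) {
    z <- if (is.null(controls)) NULL else controls[n + 1, ]
    as.numeric(rhs(n * h, states[n + 1, ], z))
  }, numeric(ncol(states))))
  if (ncol(states) == 1) Fm <- matrix(Fm, ncol = 1)
  conv - Fm
}

# dense lower-triangular Toeplitz convolution matrix from GL weights
gl_conv_matrix <- function(w) {
  N1 <- length(w)
  M <- matrix(0, N1, N1)
  for (i in seq_len(N1)) M[i, 1:i] <- rev(w[1:i])
  M
}

#' Loss breakdown of predictions against observations and residuals
#'
#' \code{data_loss} is the mean squared norm of the prediction-observation
#' discrepancy over data nodes; \code{physics_loss} the mean squared norm of
#' the residual rows; \code{total = data_loss + lambda_phys * physics_loss}.
#'
#' @param predictions matrix of predictions on the data grid.
#' @param observations matrix of observations, same shape.
#' @param residuals matrix of collocation residuals (or NULL for none).
#' @param lambda_phys physics weight.
#' @return List of class \code{"ad_loss"} with \code{data_loss},
#'   \code{physics_loss}, \code{total} and \code{per_state_mse}.
#' @export
total_loss <- function(predictions, observations, residuals, lambda_phys) {
  predictions <- as.matrix(predictions)
  observations <- as.matrix(observations)
  if (!all(dim(predictions) == dim(observations)))
    stop("alignment error: prediction and observation grids differ")
  D <- predictions - observations
  data_loss <- sum(D^2) / nrow(D)
  physics_loss <- if (is.null(residuals)) 0 else
    sum(as.matrix(residuals)^2) / nrow(as.matrix(residuals))
  structure(list(data_loss = data_loss, physics_loss = physics_loss,
                 total = data_loss + lambda_phys * physics_loss,
                 lambda_phys = lambda_phys,
                 per_state_mse = colMeans(D^2)),
            class = "ad_loss")
}

#' Add seeded observation noise to a trajectory
#'
#' Independent zero-mean Gaussian noise per state variable with standard
#' deviation \code{level} times the maximum absolute value of that
#' variable's clean series (the per-variable max-amplitude anchor). The
#' input trajectory is untouched; controls, if present, are not perturbed.
#'
#' @param traj a clean \code{\link{ad_trajectory}}.
#' @param level noise intensity as a fraction (e.g. 0.2 for 20 percent).
#' @param seed RNG seed (restored afterwards).
#' @return A new \code{ad_trajectory} with noisy states.
#' @export
add_noise <- function(traj, level, seed = 1) {
  stopifnot(inherits(traj, "ad_trajectory"))
  if (!is.finite(level) || level < 0) stop("noise level must be >= 0")
  if (level == 0) return(traj)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  S <- traj$states
  for (j in seq_len(ncol(S))) {
    anchor <- max(abs(S[, j]))
    S[, j] <- S[, j] + rnorm(nrow(S), 0, level * anchor)
  }
  ad_trajectory(traj$time, S, controls = traj$controls, sigma = traj$sigma)
}

# vectorized model rhs over many nodes (rows); U raw units, z vectors
vec_rhs <- function(U, p, z1, z2) {
  F_N <- U[, 1]; I_N <- U[, 2]; A_b <- U[, 3]; T_m <- U[, 4]; M_r <- U[, 5]
  infect <- (1 - z2) * p$alpha * F_N * A_b
  cbind(p$Pi_N + p$rho * T_m - infect - p$phi1 * F_N,
        infect - p$beta1 * I_N * M_r - (p$gamma + p$phi2) * I_N,
        (1 - z1) * p$gamma * I_N - p$beta2 * A_b * M_r -
          (p$d_beta + p$kappa) * A_b,
        p$kappa * A_b - p$beta3 * T_m * M_r - (p$d_mu + p$rho) * T_m,
        (p$beta1 * I_N + p$beta2 * A_b + p$beta3 * T_m) * M_r - p$phi3 * M_r)
}

# Objective + analytic gradient for one training step, in normalized units.
# env carries precomputed constants; returns loss pieces and dL/d(out).
pinn_loss_grad <- function(net, env) {
  fwd <- nn_forward(net, env$x)
  out <- fwd$out
  Y <- out[, 1:5, drop = FALSE]
  data_D <- Y[env$di, , drop = FALSE] - env$Yobs
  data_loss <- sum(data_D^2) / length(env$di)
  GY <- matrix(0, nrow(out), 5)
  GY[env$di, ] <- (2 / length(env$di)) * data_D
  GZraw <- matrix(0, nrow(out), 2)
  phys_loss <- 0
  if (env$lambda > 0) {
    p <- env$params
    sc <- env$scale
    if (env$use_controls) {
      Z <- plogis(out[, 6:7, drop = FALSE])
      z1 <- Z[-1, 1]; z2 <- Z[-1, 2]
    } else {
      z1 <- z2 <- numeric(nrow(out) - 1)
    }
    U <- sweep(Y, 2, sc, "*")[-1, , drop = FALSE]   # raw units, nodes 1..N
    N <- nrow(U)
    conv <- env$hs_inv * (env$Wr %*% Y - outer(env$rs, Y[1, ]))
    G <- sweep(vec_rhs(U, p, z1, z2), 2, sc, "/")
    R <- conv - G
    phys_loss <- sum(R^2) / N
    lam <- env$lambda
    # convolution part of the gradient
    GY <- GY + lam * (2 / N) * env$hs_inv * crossprod(env$Wr, R)
    GY[1, ] <- GY[1, ] - lam * (2 / N) * env$hs_inv * colSums(env$rs * R)
    # flow-field part: E[, l] = scale_l * sum_j (R_j / scale_j) * df_j/du_l
    Rs <- sweep(R, 2, sc, "/")
    F_N <- U[, 1]; I_N <- U[, 2]; A_b <- U[, 3]; T_m <- U[, 4]; M_r <- U[, 5]
    a2 <- (1 - z2) * p$alpha
    burden <- p$beta1 * I_N + p$beta2 * A_b + p$beta3 * T_m
    E <- cbind(
      Rs[, 1] * (-a2 * A_b - p$phi1) + Rs[, 2] * (a2 * A_b),
      Rs[, 2] * (-p$beta1 * M_r - p$gamma - p$phi2) +
        Rs[, 3] * ((1 - z1) * p$gamma) + Rs[, 5] * (p$beta1 * M_r),
      Rs[, 1] * (-a2 * F_N) + Rs[, 2] * (a2 * F_N) +
        Rs[, 3] * (-p$beta2 * M_r - p$d_beta - p$kappa) + Rs[, 4] * p$kappa +
        Rs[, 5] * (p$beta2 * M_r),
      Rs[, 1] * p$rho + Rs[, 4] * (-p$beta3 * M_r - p$d_mu - p$rho) +
        Rs[, 5] * (p$beta3 * M_r),
      Rs[, 2] * (-p$beta1 * I_N) + Rs[, 3] * (-p$beta2 * A_b) +
        Rs[, 4] * (-p$beta3 * T_m) + Rs[, 5] * (burden - p$phi3))
    E <- sweep(E, 2, sc, "*")
    GY[-1, ] <- GY[-1, ] - lam * (2 / N) * E
    if (env$use_controls) {
      FA <- p$alpha * F_N * A_b
      dz1 <- lam * (2 / N) * (Rs[, 3] * p$gamma * I_N)
      dz2 <- lam * (-2 / N) * (Rs[, 1] - Rs[, 2]) * FA
      GZ <- cbind(dz1, dz2) * Z[-1, , drop = FALSE] *
        (1 - Z[-1, , drop = FALSE])
      GZraw[-1, ] <- GZ
    }
  }
  dout <- cbind(GY, GZraw)
  list(data_loss = data_loss, phys_loss = phys_loss,
       total = data_loss + env$lambda * phys_loss,
       grads = nn_backward(net, fwd, dout), out = out)
}

#' Train one learning variant on a reference trajectory
#'
#' The three variants share the architecture and optimizer and differ only
#' in the loss: the \code{"fractional"} PINN penalizes the GL-discretized
#' Caputo residual at the configured order, the \code{"integer"} PINN forces
#' order 1, and the \code{"baseline"} drops the physics term entirely
#' (\code{lambda_phys = 0}) and neither supervises nor uses the control
#' outputs. Observation noise, when requested, is injected into the
#' (subsampled) reference by \code{\link{add_noise}} with a seed derived
#' from \code{seed}; the network is initialized from \code{seed} itself.
#' States are trained in normalized units (each state divided by the max
#' absolute value of its clean series) so that no compartment dominates the
#' objective by scale alone; the physics residual is non-dimensionalized the
#' same way.
#'
#' @param variant one of \code{"fractional"}, \code{"integer"},
#'   \code{"baseline"}.
#' @param config a \code{\link{pinn_config}}.
#' @param reference clean GL-solver reference \code{\link{ad_trajectory}}
#'   whose grid contains the collocation grid (node count minus one must be
#'   a multiple of \code{n_collocation}).
#' @param params model parameters used in the physics residual.
#' @param noise_level observation-noise fraction (0 = clean).
#' @param seed seed for initialization (noise seed = seed + 10007).
#' @return An object of class \code{"ad_pinn"}.
#' @export
train_variant <- function(variant = c("fractional", "integer", "baseline"),
                          config, reference, params = ad_params(),
                          noise_level = 0, seed = config$seed) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "pinn_config"),
            inherits(reference, "ad_trajectory"))
  t0 <- proc.time()[["elapsed"]]
  N <- config$n_collocation
  M <- length(reference$time) - 1
  if (M %% N != 0)
    stop("reference grid must contain the collocation grid (steps divisible)")
  if (abs(max(reference$time) - config$horizon) > 1e-9 * config$horizon)
    stop("reference horizon does not match config horizon")
  idx <- seq(1, M + 1, by = M / N)
  sub <- ad_trajectory(reference$time[idx],
                       reference$states[idx, , drop = FALSE],
                       sigma = reference$sigma)
  obs <- add_noise(sub, noise_level, seed = seed + 10007L)

  sigma_eff <- switch(variant, fractional = config$sigma, integer = 1,
                      baseline = config$sigma)
  lambda <- if (variant == "baseline") 0 else config$lambda_phys
  use_controls <- config$use_controls && variant != "baseline"

  h <- config$horizon / N
  scale <- apply(abs(sub$states), 2, max)
  scale[scale == 0] <- 1
  di <- sort(unique(c(1, seq(1, N + 1, by = config$data_stride))))
  w <- gl_weights(sigma_eff, N)
  Wr <- gl_conv_matrix(w)[-1, , drop = FALSE]
  env <- list(
    x = matrix(seq(0, 1, length.out = N + 1), ncol = 1),
    di = di,
    Yobs = sweep(obs$states[di, , drop = FALSE], 2, scale, "/"),
    lambda = lambda, params = params, scale = scale,
    hs_inv = h^(-sigma_eff), Wr = Wr, rs = rowSums(Wr),
    use_controls = use_controls)

  net <- nn_init(c(1, rep(config$width, config$hidden_layers), 7), seed)
  opt <- adam_init(net)
  history <- numeric(config$iterations)
  lg <- NULL
  for (it in seq_len(config$iterations)) {
    lg <- pinn_loss_grad(net, env)
    if (!is.finite(lg$total))
      stop(sprintf("training failure: non-finite loss at iteration %d", it))
    history[it] <- lg$total
    step <- adam_step(net, lg$grads, opt, config$learning_rate)
    net <- step$net
    opt <- step$state
  }
  # final evaluation with the trained weights
  lg <- pinn_loss_grad(net, env)
  history[config$iterations] <- lg$total
  out <- lg$out
  pred_raw <- sweep(out[, 1:5, drop = FALSE], 2, scale, "*")
  controls <- if (use_controls) plogis(qlogis(pmin(pmax(out[, 6:7], 1e-12),
                                                   1 - 1e-12))) else NULL
  if (use_controls) colnames(controls) <- c("z1", "z2")
  final <- structure(list(
    data_loss = lg$data_loss,
    physics_loss = lg$phys_loss,
    total = lg$data_loss + lambda * lg$phys_loss,
    lambda_phys = lambda,
    per_state_mse = colMeans((pred_raw[di, , drop = FALSE] -
                                obs$states[di, , drop = FALSE])^2)),
    class = "ad_loss")
  structure(list(
    variant = variant,
    config = config,
    params = params,
    sigma_effective = if (variant == "integer") 1 else sigma_eff,
    lambda_phys = lambda,
    seed = seed,
    scale = scale,
    history = history,
    final = final,
    trajectory = ad_trajectory(sub$time, pred_raw, controls = controls,
                               sigma = if (lambda > 0) sigma_eff else NA),
    observations = obs,
    noise_level = noise_level,
    net = net,
    wall_time = proc.time()[["elapsed"]] - t0),
    class = "ad_pinn")
}

#' @export
print.ad_pinn <- function(x, ...) {
  cat(sprintf("%s network fit (sigma = %s, lambda_phys = %g)\n",
              x$variant,
              if (is.na(x$sigma_effective)) "-" else
                format(x$sigma_effective), x$lambda_phys))
  cat(sprintf("  iterations: %d, final loss: %.4g (data %.4g, physics %.4g)\n",
              length(x$history), x$final$total, x$final$data_loss,
              x$final$physics_loss))
  cat(sprintf("  noise level: %g, seed: %d, wall time: %.1f s\n",
              x$noise_level, x$seed, x$wall_time))
  invisible(x)
}

#' @export
summary.ad_pinn <- function(object, ...) {
  print(object)
  cat("Per-state MSE on the data grid (raw units):\n")
  print(object$final$per_state_mse)
  invisible(object)
}

#' @export
predict.ad_pinn <- function(object, times = object$trajectory$time, ...) {
  x <- matrix(times / object$config$horizon, ncol = 1)
  out <- nn_forward(object$net, x)$out
  states <- sweep(out[, 1:5, drop = FALSE], 2, object$scale, "*")
  colnames(states) <- .ad_state_names
  z <- plogis(out[, 6:7, drop = FALSE])
  colnames(z) <- c("z1", "z2")
  cbind(time = times, states, z)
}

#' @export
residuals.ad_pinn <- function(object, ...) {
  h <- object$config$horizon / object$config$n_collocation
  prm <- object$params
  fractional_residual(
    object$trajectory$states,
    sigma = object$sigma_effective, h = h,
    rhs = function(t, u, z) {
      if (is.null(z)) controlled_rhs(u, prm, 0, 0, .validate = FALSE)
      else controlled_rhs(u, prm, z[[1]], z[[2]], .validate = FALSE)
    },
    controls = object$trajectory$controls)
}

#' @export
plot.ad_pinn <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l", log = "y",
                 xlab = "iteration", ylab = "total loss",
                 main = sprintf("%s variant", x$variant), ...)
  invisible(x)
}

#' Noise-robustness benchmark across learning variants
#'
#' Trains every requested variant at every noise level for several seeded
#' replicates and aggregates final-loss and per-state-MSE statistics
#' (sample standard deviation with the n-1 denominator). The robustness
#' ratio per variant is
#' \deqn{\mathrm{robustness} = \frac{\overline{L}_{\mathrm{final}}
#'  (\mathrm{highest\ level})}{\overline{L}_{\mathrm{final}}(0)},}
#' smaller meaning more noise-robust; it is an error if the zero-noise mean
#' loss is exactly 0. Individual replicate failures are recorded, not fatal;
#' a fully failed variant-level cell is an error.
#'
#' @param config a \code{\link{pinn_config}}.
#' @param reference clean GL reference trajectory.
#' @param params model parameters for the physics residual.
#' @param levels noise levels (fractions); must include 0.
#' @param replicates replicates per cell (>= 1).
#' @param seed base seed; run seeds are \code{seed + 97 * level_index +
#'   replicate} and are recorded.
#' @param variants subset of the three variants.
#' @return Object of class \code{"ad_benchmark"}: \code{table} (per
#'   variant/level stats), \code{robustness} (named ratios), \code{runs}
#'   (per-run records), \code{failures}.
#' @export
noise_benchmark <- function(config, reference, params = ad_params(),
                            levels = c(0, 0.05, 0.10, 0.15, 0.20),
                            replicates = 3, seed = 1,
                            variants = c("fractional", "integer",
                                         "baseline")) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (!0 %in% levels) stop("levels must include 0 for the robustness ratio")
  levels <- sort(levels)
  runs <- list()
  failures <- list()
  for (v in variants) for (li in seq_along(levels)) {
    cell_ok <- 0
    for (r in seq_len(replicates)) {
      run_seed <- as.integer(seed + 97 * li + r)
      fit <- tryCatch(
        train_variant(v, config, reference, params,
                      noise_level = levels[li], seed = run_seed),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures[[length(failures) + 1]] <-
          list(variant = v, level = levels[li], replicate = r,
               seed = run_seed, message = conditionMessage(fit))
      } else {
        cell_ok <- cell_ok + 1
        runs[[length(runs) + 1]] <-
          list(variant = v, level = levels[li], replicate = r,
               seed = run_seed, final_loss = fit$final$total,
               data_loss = fit$final$data_loss,
               physics_loss = fit$final$physics_loss,
               per_state_mse = fit$final$per_state_mse,
               wall_time = fit$wall_time)
      }
    }
    if (cell_ok == 0)
      stop(sprintf("benchmark cell fully failed: variant %s, level %g",
                   v, levels[li]))
  }
  df <- do.call(rbind, lapply(runs, function(r)
    data.frame(variant = r$variant, level = r$level, replicate = r$replicate,
               seed = r$seed, final_loss = r$final_loss,
               t(r$per_state_mse), check.names = FALSE)))
  agg <- do.call(rbind, lapply(split(df, list(df$variant, df$level),
                                     drop = TRUE), function(g) {
    data.frame(variant = g$variant[1], level = g$level[1], n = nrow(g),
               mean = mean(g$final_loss),
               sd = if (nrow(g) > 1) sd(g$final_loss) else 0,
               min = min(g$final_loss), max = max(g$final_loss))
  }))
  rownames(agg) <- NULL
  top <- max(levels)
  robustness <- vapply(variants, function(v) {
    num <- mean(df$final_loss[df$variant == v & df$level == top])
    den <- mean(df$final_loss[df$variant == v & df$level == 0])
    if (den == 0) stop(sprintf(
      "robustness ratio undefined for variant %s: zero-noise loss is 0", v))
    num / den
  }, numeric(1))
  structure(list(table = agg, robustness = robustness, runs = runs,
                 failures = failures, levels = levels,
                 replicates = replicates, seed = seed, config = config),
            class = "ad_benchmark")
}

#' @export
print.ad_benchmark <- function(x, ...) {
  cat("Noise-robustness benchmark\n")
  print(x$table, row.names = FALSE)
  cat("Robustness ratio (loss at highest level / loss at 0):\n")
  print(x$robustness)
  if (length(x$failures))
    cat(sprintf("%d replicate failure(s) recorded\n", length(x$failures)))
  invisible(x)
}

#' Write a benchmark report (JSON + CSV)
#'
#' The CSV mirrors the summary-table layout (model, mean, sd, min, max per
#' metric); the JSON carries the full per-run records and seeds.
#'
#' @param bench an \code{"ad_benchmark"}.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "benchmark_summary.csv")
  utils::write.csv(bench$table, csv, row.names = FALSE)
  js <- file.path(dir, "benchmark.json")
  jsonlite::write_json(
    list(summary = bench$table,
         robustness = as.list(bench$robustness),
         levels = bench$levels, replicates = bench$replicates,
         seed = bench$seed,
         runs = bench$runs, failures = bench$failures),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
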