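#' Therapeutic control schedules
#'
#' A schedule assigns per-node intensities (z1, z2) on the solver grid,
#' each bounded in [0, 1]. \code{constant_schedule} fills both series with
#' fixed values; \code{window_schedule} maps a coefficient matrix (one row
#' per window, columns z1, z2, raw real values squashed by the logistic
#' function) onto equal time windows - the low-dimensional basis used by the
#' optimizer.
#'
#' @param n_steps number of solver steps (grid has n_steps + 1 nodes).
#' @param z1,z2 constant intensities in [0, 1].
#' @return Matrix with columns z1, z2 and one row per node.
#' @export
constant_schedule <- function(n_steps, z1 = 0, z2 = 0) {
  ad_controls(z1, z2)
  cbind(z1 = rep(z1, n_steps + 1), z2 = rep(z2, n_steps + 1))
}

#' @rdname constant_schedule
#' @param coef numeric matrix, windows x 2, of unconstrained basis
#'   coefficients; \code{plogis(coef)} gives the per-window intensities.
#' @export
window_schedule <- function(n_steps, coef) {
  coef <- as.matrix(coef)
  if (ncol(coef) != 2) stop("coef must have two columns (z1, z2)")
  B <- nrow(coef)
  win <- pmin(floor(seq(0, n_steps, length.out = n_steps + 1) /
                      ((n_steps + 1) / B)) + 1, B)
  Z <- plogis(coef[win, , drop = FALSE])
  colnames(Z) <- c("z1", "z2")
  Z
}

#' Simulate the model under a control schedule
#'
#' GL-integrates the controlled dynamics with the per-node intensities and
#' records the controls in the returned trajectory.
#'
#' @param params an \code{\link{ad_params}} object.
#' @param init initial state.
#' @param sigma fractional order.
#' @param horizon final time (days).
#' @param n_steps number of steps; the schedule must have
#'   \code{n_steps + 1} rows.
#' @param schedule control matrix (columns z1, z2).
#' @return An \code{\link{ad_trajectory}} with controls.
#' @export
simulate_with_control <- function(params, init, sigma, horizon, n_steps,
                                  schedule) {
  schedule <- as.matrix(schedule)
  if (nrow(schedule) != n_steps + 1)
    stop("schedule grid does not match solver grid")
  fde_solve(params, init, sigma, horizon, n_steps, controls = schedule)
}

#' Control objective (running cost)
#'
#' Quadratic-effort objective integrated over the horizon by the trapezoid
#' rule:
#' \deqn{J = \int_0^T \big( w_I I_N + w_A A_\beta + w_T T_\mu
#'     + c_1 z_1^2 + c_2 z_2^2 \big)\,dt.}
#' The default weights put unit cost on the g/ml pathological burdens and a
#' small quadratic effort penalty on the dimensionless interventions, so
#' that intervention is worthwhile where it measurably reduces burden.
#'
#' @param w_I,w_A,w_T burden weights on infected neurons, amyloid, tau.
#' @param c1,c2 effort weights on z1^2, z2^2.
#' @return List of class \code{"ad_objective"}.
#' @export
ad_objective <- function(w_I = 1, w_A = 1, w_T = 1, c1 = 1e-6, c2 = 1e-6) {
  w <- c(w_I, w_A, w_T, c1, c2)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be >= 0")
  structure(list(w_I = w_I, w_A = w_A, w_T = w_T, c1 = c1, c2 = c2),
            class = "ad_objective")
}

#' Evaluate the control objective on a trajectory
#'
#' @param traj an \code{\link{ad_trajectory}} carrying controls.
#' @param objective an \code{\link{ad_objective}}.
#' @return Scalar cost (trapezoidal quadrature).
#' @export
evaluate_objective <- function(traj, objective = ad_objective()) {
  stopifnot(inherits(traj, "ad_trajectory"))
  if (is.null(traj$controls)) stop("trajectory has no controls")
  S <- traj$states
  Z <- traj$controls
  integrand <- objective$w_I * S[, "I_N"] + objective$w_A * S[, "A_beta"] +
    objective$w_T * S[, "T_mu"] + objective$c1 * Z[, "z1"]^2 +
    objective$c2 * Z[, "z2"]^2
  trapz_quad(traj$time, integrand)
}

trapz_quad <- function(t, y) {
  n <- length(t)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

#' Optimize a windowed control schedule
#'
#' Direct parameterized-control optimization: the two intensities are
#' piecewise constant on \code{n_windows} equal windows, squashed into
#' [0, 1], and the objective is minimized by a seeded (1+1) random-search
#' descent starting from the constant mid-level schedule z1 = z2 = 0.5.
#' Only improving proposals are accepted, so the accepted-cost history is
#' non-increasing by construction, and the constant(0.5, 0.5) schedule is
#' the first feasible iterate (its cost bounds the optimum from above).
#'
#' @inheritParams simulate_with_control
#' @param objective an \code{\link{ad_objective}}.
#' @param n_windows number of control windows (basis size, >= 1).
#' @param iterations number of proposals.
#' @param seed RNG seed (restored afterwards).
#' @return List with the optimized \code{schedule}, accepted \code{cost}
#'   and non-increasing \code{cost_history}, plus the coefficient matrix.
#' @export
optimize_control <- function(params, init, sigma, horizon, n_steps,
                             objective = ad_objective(), n_windows = 10,
                             iterations = 300, seed = 1) {
  if (n_windows < 1) stop("basis size must be >= 1")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  cost_of <- function(coef) {
    sched <- window_schedule(n_steps, coef)
    traj <- simulate_with_control(params, init, sigma, horizon, n_steps,
                                  sched)
    cost <- evaluate_objective(traj, objective)
    if (!is.finite(cost)) stop("non-finite cost for a proposed schedule")
    cost
  }
  coef <- matrix(0, n_windows, 2)          # plogis(0) = 0.5 everywhere
  best <- cost_of(coef)
  history <- best
  step <- 1.0
  for (it in seq_len(iterations)) {
    prop <- coef + matrix(rnorm(2 * n_windows, 0, step), n_windows, 2)
    cost <- cost_of(prop)
    if (cost < best) {
      coef <- prop
      best <- cost
      step <- min(step * 1.2, 4)
    } else {
      step <- max(step * 0.95, 0.05)
    }
    history <- c(history, best)
  }
  list(schedule = window_schedule(n_steps, coef), coef = coef,
       cost = best, cost_history = history, seed = seed)
}

#' Compare no-control, constant-control and optimized-control strategies
#'
#' Simulates the three intervention strategies on the same grid and reports
#' per-strategy trajectories, terminal functional-neuron level, integrated
#' pathological burdens and objective costs.
#'
#' @inheritParams optimize_control
#' @param constant_z intensities of the constant strategy (default 0.5).
#' @return Object of class \code{"ad_strategies"}: named list of strategies
#'   (each with trajectory, cost, terminal_F_N, burden integrals) plus a
#'   summary data frame.
#' @export
compare_strategies <- function(params, init, sigma, horizon, n_steps,
                               objective = ad_objective(),
                               constant_z = c(0.5, 0.5), n_windows = 10,
                               iterations = 300, seed = 1) {
  run <- function(sched) {
    traj <- simulate_with_control(params, init, sigma, horizon, n_steps,
                                  sched)
    list(trajectory = traj,
         cost = evaluate_objective(traj, objective),
         terminal_F_N = traj$states[nrow(traj$states), "F_N"],
         burden = c(
           I_N = trapz_quad(traj$time, traj$states[, "I_N"]),
           A_beta = trapz_quad(traj$time, traj$states[, "A_beta"]),
           T_mu = trapz_quad(traj$time, traj$states[, "T_mu"])))
  }
  none <- run(constant_schedule(n_steps, 0, 0))
  const <- run(constant_schedule(n_steps, constant_z[1], constant_z[2]))
  opt <- optimize_control(params, init, sigma, horizon, n_steps, objective,
                          n_windows, iterations, seed)
  optimal <- run(opt$schedule)
  optimal$cost_history <- opt$cost_history
  strategies <- list(none = none, constant = const, optimal = optimal)
  summary <- data.frame(
    strategy = names(strategies),
    cost = vapply(strategies, `[[`, numeric(1), "cost"),
    terminal_F_N = vapply(strategies, `[[`, numeric(1), "terminal_F_N"),
    A_beta_burden = vapply(strategies, function(s) s$burden[["A_beta"]],
                           numeric(1)),
    row.names = NULL)
  structure(list(strategies = strategies, summary = summary,
                 objective = objective, sigma = sigma, seed = seed),
            class = "ad_strategies")
}

#' @export
print.ad_strategies <- function(x, ...) {
  cat("Therapeutic strategy comparison\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Serialize a strategy comparison to JSON (+ trajectory CSVs)
#'
#' @param comp an \code{"ad_strategies"} object.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_strategies <- function(comp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(comp$strategies)) {
    path <- file.path(dir, sprintf("strategy_%s.csv", nm))
    write_trajectory(comp$strategies[[nm]]$trajectory, path)
    paths <- c(paths, path)
  }
  js <- file.path(dir, "strategies.json")
  jsonlite::write_json(
    list(summary = comp$summary,
         burdens = lapply(comp$strategies, function(s) as.list(s$burden)),
         objective = unclass(comp$objective), sigma = comp$sigma,
         seed = comp$seed),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, js))
}
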