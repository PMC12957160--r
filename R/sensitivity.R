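#' Logarithmic sensitivity (elasticity) statistic
#'
#' Centered two-run elasticity
#' \deqn{S_{\log}(t) = \frac{\ln y_+(t) - \ln y_-(t)}{2 \ln(1+\delta)},}
#' where \eqn{y_\pm} are the outputs with the parameter perturbed to
#' \eqn{p(1\pm\delta)}. Nodes where either output is non-positive are flagged
#' undefined (NA), never silently zeroed; a curve undefined everywhere is an
#' error. For a pure power law \eqn{y = C p^k} the statistic returns exactly
#' \eqn{k} (up to the symmetric-log discretization of the exponent).
#'
#' @param y_plus,y_minus outputs at p(1+delta) and p(1-delta) (same length).
#' @param delta relative perturbation in (0, 0.5].
#' @return Numeric vector of elasticities, NA at undefined nodes.
#' @export
log_sensitivity_values <- function(y_plus, y_minus, delta = 0.1) {
  if (!is.finite(delta) || delta <= 0 || delta > 0.5)
    stop("delta must lie in (0, 0.5]")
  if (length(y_plus) != length(y_minus))
    stop("y_plus and y_minus must have equal length")
  ok <- is.finite(y_plus) & is.finite(y_minus) & y_plus > 0 & y_minus > 0
  if (!any(ok)) stop("sensitivity curve undefined at every node")
  s <- rep(NA_real_, length(y_plus))
  s[ok] <- (log(y_plus[ok]) - log(y_minus[ok])) / (2 * log1p(delta))
  s
}

#' Time-resolved logarithmic sensitivity of a model output
#'
#' Runs the GL solver twice, at \eqn{p(1+\delta)} and \eqn{p(1-\delta)} with
#' everything else fixed, and applies \code{\link{log_sensitivity_values}}
#' to the chosen output series. \code{parameter} may name a rate constant or
#' an initial-state component (e.g. \code{"T_mu"} to perturb the initial tau
#' burden multiplicatively).
#'
#' @param params an \code{\link{ad_params}} object.
#' @param init initial state vector.
#' @param sigma fractional order in (0, 1].
#' @param horizon final time (days).
#' @param n_steps number of time steps.
#' @param parameter name of a parameter (or initial-state component).
#' @param output name of the state output, one of F_N, I_N, A_beta, T_mu,
#'   M_rho.
#' @param delta relative perturbation, default 0.1 (10 percent).
#' @return An object of class \code{"ad_sensitivity"}: list with \code{time},
#'   \code{values} (elasticity per node, NA where undefined), and metadata.
#' @export
log_sensitivity <- function(params, init, sigma, horizon, n_steps,
                            parameter, output, delta = 0.1) {
  stopifnot(inherits(params, "ad_params"))
  output <- match.arg(output, .ad_state_names)
  run <- function(fac) {
    if (parameter %in% names(params)) {
      q <- unclass(params)
      q[[parameter]] <- q[[parameter]] * fac
      fde_solve(as_ad_params(q), init, sigma, horizon, n_steps)
    } else if (parameter %in% .ad_state_names) {
      init2 <- init
      init2[[parameter]] <- init2[[parameter]] * fac
      fde_solve(params, init2, sigma, horizon, n_steps)
    } else {
      stop("unknown parameter: ", parameter)
    }
  }
  tp <- run(1 + delta)
  tm <- run(1 - delta)
  vals <- log_sensitivity_values(tp$states[, output], tm$states[, output],
                                 delta)
  structure(list(time = tp$time, values = vals, parameter = parameter,
                 output = output, delta = delta, sigma = sigma),
            class = "ad_sensitivity")
}

#' @export
print.ad_sensitivity <- function(x, ...) {
  fin <- x$values[is.finite(x$values)]
  cat(sprintf(
    "Log-sensitivity S_log(%s; %s), delta = %g: %d/%d nodes defined\n",
    x$output, x$parameter, x$delta, length(fin), length(x$values)))
  if (length(fin))
    cat(sprintf("  range [%.4g, %.4g], final %.4g\n",
                min(fin), max(fin), x$values[length(x$values)]))
  invisible(x)
}

#' @export
plot.ad_sensitivity <- function(x, ...) {
  graphics::plot(x$time, x$values, type = "l",
                 xlab = "time (days)",
                 ylab = sprintf("S_log(%s; %s)", x$output, x$parameter), ...)
  invisible(x)
}

#' Plus/minus parameter perturbation sweep
#'
#' For each named parameter, returns the nominal, +delta and -delta
#' trajectories of all five states (the design behind time-course
#' perturbation panels).
#'
#' @inheritParams log_sensitivity
#' @param parameters nonempty character vector of parameter (or
#'   initial-state) names.
#' @return A named list, one element per parameter, each a list with
#'   trajectories \code{nominal}, \code{plus}, \code{minus}.
#' @export
parameter_sweep <- function(params, init, sigma, horizon, n_steps,
                            parameters, delta = 0.1) {
  if (!length(parameters)) stop("parameters must be a nonempty list")
  nominal <- fde_solve(params, init, sigma, horizon, n_steps)
  out <- lapply(parameters, function(pn) {
    perturb <- function(fac) {
      if (pn %in% names(params)) {
        q <- unclass(params)
        q[[pn]] <- q[[pn]] * fac
        fde_solve(as_ad_params(q), init, sigma, horizon, n_steps)
      } else if (pn %in% .ad_state_names) {
        init2 <- init
        init2[[pn]] <- init2[[pn]] * fac
        fde_solve(params, init2, sigma, horizon, n_steps)
      } else stop(sprintf("sweep failure for parameter '%s': unknown name", pn))
    }
    tryCatch(
      list(nominal = nominal, plus = perturb(1 + delta),
           minus = perturb(1 - delta)),
      error = function(e)
        stop(sprintf("sweep failure for parameter '%s': %s", pn,
                     conditionMessage(e)), call. = FALSE))
  })
  names(out) <- parameters
  out
}

#' Write a sweep bundle as CSV files
#'
#' One file per parameter and arm, in the canonical trajectory dialect,
#' named \code{sweep_<param>_<arm>.csv}.
#'
#' @param bundle output of \code{\link{parameter_sweep}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_sweep <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (pn in names(bundle)) for (arm in c("nominal", "plus", "minus")) {
    path <- file.path(dir, sprintf("sweep_%s_%s.csv", pn, arm))
    write_trajectory(bundle[[pn]][[arm]], path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Append sensitivity curves to a trajectory data frame
#'
#' Adds one column per curve, named \code{S_<parameter>_<output>}, to the
#' trajectory's CSV representation.
#'
#' @param traj an \code{\link{ad_trajectory}} on the same grid as the curves.
#' @param curves list of \code{"ad_sensitivity"} objects.
#' @return A data frame ready for \code{write.csv}.
#' @export
sensitivity_frame <- function(traj, curves) {
  df <- as.data.frame(traj)
  for (cu in curves) {
    if (length(cu$time) != nrow(df))
      stop("curve grid does not match trajectory grid")
    df[[sprintf("S_%s_%s", cu$parameter, cu$output)]] <- cu$values
  }
  df
}
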