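#' Trajectory container
#'
#' Holds a uniform time grid, the five state series, and (optionally) the two
#' control series. The canonical CSV dialect has header exactly
#' \code{time,F_N,I_N,A_beta,T_mu,M_rho} plus \code{,z1,z2} when controls are
#' present, one row per node, full double precision.
#'
#' @param time numeric vector of uniformly spaced nodes starting at 0.
#' @param states matrix with one row per node and five columns in state order.
#' @param controls optional matrix with columns z1, z2.
#' @param sigma fractional order used to generate the trajectory (metadata).
#' @return An object of class \code{"ad_trajectory"}.
#' @export
ad_trajectory <- function(time, states, controls = NULL, sigma = NA_real_) {
  states <- as.matrix(states)
  attr(states, "time") <- NULL
  if (nrow(states) != length(time))
    stop("states must have one row per time node")
  if (ncol(states) != 5) stop("expected five state columns")
  colnames(states) <- .ad_state_names
  h <- diff(time)
  if (length(h) && max(abs(h - h[1])) > 1e-9 * max(abs(h)))
    stop("time grid must be uniform")
  if (!is.null(controls)) {
    controls <- as.matrix(controls)
    if (nrow(controls) != length(time))
      stop("controls must have one row per time node")
    colnames(controls) <- c("z1", "z2")
  }
  structure(list(time = time, states = states, controls = controls,
                 sigma = sigma),
            class = "ad_trajectory")
}

#' @export
print.ad_trajectory <- function(x, ...) {
  cat(sprintf("Alzheimer's model trajectory: %d nodes over [0, %g] days%s\n",
              length(x$time), max(x$time),
              if (is.na(x$sigma)) "" else sprintf(" (sigma = %g)", x$sigma)))
  cat(sprintf("  with controls: %s\n", !is.null(x$controls)))
  cat("Final state:\n")
  print(x$states[nrow(x$states), ])
  invisible(x)
}

#' @export
as.data.frame.ad_trajectory <- function(x, ...) {
  df <- data.frame(time = x$time, x$states, check.names = FALSE)
  if (!is.null(x$controls)) df <- cbind(df, x$controls)
  df
}

#' @export
plot.ad_trajectory <- function(x, which = .ad_state_names, log = "", ...) {
  cols <- match(which, .ad_state_names)
  matplot(x$time, x$states[, cols, drop = FALSE], type = "l", lty = 1,
          xlab = "time (days)", ylab = "concentration (g/ml)", log = log, ...)
  legend("topleft", legend = which, lty = 1, col = seq_along(cols), bty = "n")
  invisible(x)
}

#' Write a trajectory in the canonical CSV dialect
#'
#' Values are rendered with 17 significant digits so that a write/read round
#' trip is bit-exact for doubles.
#'
#' @param traj an \code{\link{ad_trajectory}}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ad_trajectory"))
  df <- as.data.frame(traj)
  header <- paste(colnames(df), collapse = ",")
  body <- do.call(paste, c(lapply(df, function(col) sprintf("%.17g", col)),
                           sep = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a trajectory from the canonical CSV dialect
#'
#' The header is validated strictly: columns must be exactly
#' \code{time,F_N,I_N,A_beta,T_mu,M_rho} optionally followed by
#' \code{z1,z2}, in that order.
#'
#' @param path input file path.
#' @return An \code{\link{ad_trajectory}}.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "numeric")
  want <- c("time", .ad_state_names)
  have <- colnames(df)
  full <- c(want, "z1", "z2")
  if (!(identical(have, want) || identical(have, full))) {
    bad <- if (length(have) >= 1) {
      cmp <- full[seq_along(have)]
      mism <- which(is.na(cmp) | have != cmp)
      if (length(mism)) have[mism[1]] else have[length(have)]
    } else "<empty>"
    stop(sprintf("trajectory format error: unexpected column '%s' (header must be %s[,z1,z2])",
                 bad, paste(want, collapse = ",")))
  }
  controls <- if (identical(have, full)) as.matrix(df[, c("z1", "z2")]) else NULL
  ad_trajectory(df$time, as.matrix(df[, .ad_state_names]), controls = controls)
}
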