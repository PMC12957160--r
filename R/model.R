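#' Right-hand side of the fractional Alzheimer's model
#'
#' Evaluates the five coupled rate equations
#' \deqn{D^\sigma F_N = \Pi_N + \rho T_\mu - \alpha F_N A_\beta - \phi_1 F_N}
#' \deqn{D^\sigma I_N = \alpha F_N A_\beta - \beta_1 I_N M_\rho - (\gamma+\phi_2) I_N}
#' \deqn{D^\sigma A_\beta = \gamma I_N - \beta_2 A_\beta M_\rho - (d_\beta+\kappa) A_\beta}
#' \deqn{D^\sigma T_\mu = \kappa A_\beta - \beta_3 T_\mu M_\rho - (d_\mu+\rho) T_\mu}
#' \deqn{D^\sigma M_\rho = (\beta_1 I_N + \beta_2 A_\beta + \beta_3 T_\mu) M_\rho - \phi_3 M_\rho}
#' The Caputo order \eqn{\sigma} lives in the integrator, not here: this is
#' the instantaneous flow field shared by all fractional orders.
#'
#' @param state named or unnamed numeric state vector, ordered
#'   (F_N, I_N, A_beta, T_mu, M_rho).
#' @param params an \code{\link{ad_params}} object.
#' @return Numeric vector of the five derivatives, in state order.
#' @export
model_rhs <- function(state, params) {
  if (length(state) != 5 || !all(is.finite(state)))
    stop("invalid state: expected 5 finite components")
  controlled_rhs(state, params, z1 = 0, z2 = 0, .validate = FALSE)
}

#' Right-hand side with therapeutic controls
#'
#' Two intervention intensities modulate the disease pathways: \code{z1}
#' scales the amyloid production term \eqn{\gamma I_N} by \eqn{(1-z_1)}
#' (anti-amyloid therapy), and \code{z2} scales the infection term
#' \eqn{\alpha F_N A_\beta} by \eqn{(1-z_2)} in both the functional- and
#' infected-neuron equations (anti-neurodegeneration therapy). With
#' \code{z1 = z2 = 0} this reduces exactly to \code{\link{model_rhs}}.
#'
#' @inheritParams model_rhs
#' @param z1,z2 control intensities in [0, 1].
#' @param .validate internal flag to skip input checks.
#' @return Numeric vector of the five derivatives, in state order.
#' @export
controlled_rhs <- function(state, params, z1 = 0, z2 = 0, .validate = TRUE) {
  if (.validate) {
    if (length(state) != 5 || !all(is.finite(state)))
      stop("invalid state: expected 5 finite components")
    if (!all(is.finite(c(z1, z2))) || z1 < 0 || z1 > 1 || z2 < 0 || z2 > 1)
      stop("controls must lie in [0, 1]")
  }
  p <- params
  F_N <- state[[1]]; I_N <- state[[2]]; A_b <- state[[3]]
  T_m <- state[[4]]; M_r <- state[[5]]
  infect <- (1 - z2) * p$alpha * F_N * A_b
  c(p$Pi_N + p$rho * T_m - infect - p$phi1 * F_N,
    infect - p$beta1 * I_N * M_r - (p$gamma + p$phi2) * I_N,
    (1 - z1) * p$gamma * I_N - p$beta2 * A_b * M_r - (p$d_beta + p$kappa) * A_b,
    p$kappa * A_b - p$beta3 * T_m * M_r - (p$d_mu + p$rho) * T_m,
    (p$beta1 * I_N + p$beta2 * A_b + p$beta3 * T_m) * M_r - p$phi3 * M_r)
}

#' Analytic Jacobian of the (controlled) right-hand side
#'
#' @inheritParams controlled_rhs
#' @return 5 x 5 matrix of partial derivatives d f_i / d u_j.
#' @export
rhs_jacobian <- function(state, params, z1 = 0, z2 = 0) {
  p <- params
  F_N <- state[[1]]; I_N <- state[[2]]; A_b <- state[[3]]
  T_m <- state[[4]]; M_r <- state[[5]]
  a2 <- (1 - z2) * p$alpha
  J <- matrix(0, 5, 5, dimnames = list(.ad_state_names, .ad_state_names))
  J[1, ] <- c(-a2 * A_b - p$phi1, 0, -a2 * F_N, p$rho, 0)
  J[2, ] <- c(a2 * A_b, -p$beta1 * M_r - (p$gamma + p$phi2), a2 * F_N, 0,
              -p$beta1 * I_N)
  J[3, ] <- c(0, (1 - z1) * p$gamma, -p$beta2 * M_r - (p$d_beta + p$kappa), 0,
              -p$beta2 * A_b)
  J[4, ] <- c(0, 0, p$kappa, -p$beta3 * M_r - (p$d_mu + p$rho),
              -p$beta3 * T_m)
  J[5, ] <- c(0, p$beta1 * M_r, p$beta2 * M_r, p$beta3 * M_r,
              p$beta1 * I_N + p$beta2 * A_b + p$beta3 * T_m - p$phi3)
  J
}

# partials of the controlled rhs w.r.t. the two controls (5 x 2)
rhs_control_jacobian <- function(state, params) {
  p <- params
  F_N <- state[[1]]; I_N <- state[[2]]; A_b <- state[[3]]
  dz1 <- c(0, 0, -p$gamma * I_N, 0, 0)
  dz2 <- c(p$alpha * F_N * A_b, -p$alpha * F_N * A_b, 0, 0, 0)
  cbind(z1 = dz1, z2 = dz2)
}
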