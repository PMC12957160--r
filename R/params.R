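#' Model parameters for the Alzheimer's compartmental model
#'
#' Constructs and validates the full rate-constant set of the five-compartment
#' model. All rates are per day; concentrations are in g/ml. Defaults are the
#' baseline literature values (the "table1" preset). The natural neuron death
#' rate \code{phi1} is treated as per-day throughout, consistent with the
#' day-scale simulation horizons.
#'
#' @param Pi_N neuron production rate (amount/day).
#' @param rho tau-driven neurodegeneration rate (1/day).
#' @param alpha amyloid-beta cascade (infection) rate (1/day).
#' @param phi1 natural neuron death rate (1/day); must be positive.
#' @param beta1 microglial killing rate of infected neurons (1/day).
#' @param gamma amyloid production rate by infected neurons (1/day).
#' @param phi2 infected-neuron death rate (1/day).
#' @param beta2 microglial amyloid clearance rate (1/day).
#' @param d_beta proteolytic amyloid degradation rate (1/day).
#' @param kappa amyloid-to-tau initiation rate (1/day).
#' @param beta3 microglial tau clearance rate (1/day).
#' @param d_mu natural tau degradation rate (1/day).
#' @param phi3 microglial death rate (1/day).
#' @return An object of class \code{"ad_params"} (a named list).
#' @examples
#' p <- ad_params()
#' p$alpha
#' @export
ad_params <- function(Pi_N = 1, rho = 0.025, alpha = 0.08, phi1 = 0.02,
                      beta1 = 0.06, gamma = 0.00017, phi2 = 0.00019,
                      beta2 = 0.002, d_beta = 9.51, kappa = 0.025,
                      beta3 = 0.001, d_mu = 0.277, phi3 = 0.015) {
  p <- list(Pi_N = Pi_N, rho = rho, alpha = alpha, phi1 = phi1,
            beta1 = beta1, gamma = gamma, phi2 = phi2, beta2 = beta2,
            d_beta = d_beta, kappa = kappa, beta3 = beta3, d_mu = d_mu,
            phi3 = phi3)
  vals <- unlist(p)
  if (!all(is.finite(vals))) stop("all parameters must be finite")
  if (any(vals < 0)) stop("all parameters must be non-negative")
  if (phi1 <= 0) stop("phi1 must be strictly positive")
  if (d_beta + kappa <= 0) stop("d_beta + kappa must be strictly positive")
  if (d_mu + rho <= 0) stop("d_mu + rho must be strictly positive")
  structure(p, class = "ad_params")
}

#' Named presets for parameters and initial state
#'
#' \code{"table1"} is the baseline parameterization with initial state
#' (F_N, I_N, A_beta, T_mu, M_rho) = (0.14, 0, 1e-6, 1e-6, 0.02).
#' \code{"chaos"} is the alternative set used for the gain-stabilization
#' worked example (large neuron production, near-zero natural death rate);
#' the microglial rates it does not specify are completed from the baseline.
#'
#' @param name preset name, \code{"table1"} or \code{"chaos"}.
#' @return A list with elements \code{params} (\code{ad_params}) and
#'   \code{init} (named state vector).
#' @export
ad_preset <- function(name = c("table1", "chaos")) {
  name <- match.arg(name)
  init <- ad_state(F_N = 0.14, I_N = 0, A_beta = 1e-6, T_mu = 1e-6,
                   M_rho = 0.02)
  params <- switch(name,
    table1 = ad_params(),
    chaos = ad_params(Pi_N = 700, rho = 0.025, alpha = 0.08, phi1 = 0.00003,
                      gamma = 0.00017, phi2 = 0.00019, d_beta = 9.51,
                      kappa = 0.025, d_mu = 0.277))
  list(name = name, params = params, init = init)
}

#' Construct a validated state vector
#'
#' States are always ordered (F_N, I_N, A_beta, T_mu, M_rho): functional
#' neurons, infected neurons, amyloid-beta, tau protein, microglia (g/ml).
#'
#' @param F_N,I_N,A_beta,T_mu,M_rho state components (g/ml).
#' @return A named numeric vector of length 5.
#' @export
ad_state <- function(F_N, I_N, A_beta, T_mu, M_rho) {
  s <- c(F_N = F_N, I_N = I_N, A_beta = A_beta, T_mu = T_mu, M_rho = M_rho)
  if (length(s) != 5 || !all(is.finite(s)))
    stop("invalid state: all five components must be finite")
  s
}

#' Construct a validated therapeutic control pair
#'
#' \code{z1} targets amyloid accumulation (scales the amyloid source by
#' \code{1 - z1}); \code{z2} targets neurodegeneration (scales the infection
#' term by \code{1 - z2}). Both are dimensionless intervention intensities
#' in [0, 1].
#'
#' @param z1,z2 control intensities in [0, 1].
#' @return A named numeric vector \code{c(z1, z2)}.
#' @export
ad_controls <- function(z1 = 0, z2 = 0) {
  if (!all(is.finite(c(z1, z2))) || z1 < 0 || z1 > 1 || z2 < 0 || z2 > 1)
    stop("controls must lie in [0, 1]")
  c(z1 = z1, z2 = z2)
}

#' @export
print.ad_params <- function(x, ...) {
  cat("Alzheimer's model parameters (rates per day):\n")
  print(unlist(x))
  invisible(x)
}

# coerce a list/vector with exactly the right names into ad_params
as_ad_params <- function(x) {
  if (inherits(x, "ad_params")) return(x)
  x <- as.list(x)
  missing <- setdiff(.ad_param_names, names(x))
  if (length(missing))
    stop("missing parameter fields: ", paste(missing, collapse = ", "))
  do.call(ad_params, x[.ad_param_names])
}
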