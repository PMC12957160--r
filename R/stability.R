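#' Disease-free equilibrium
#'
#' The disease-free state has no infected neurons, amyloid or tau and no
#' activated microglia: \eqn{E_0 = (\Pi_N/\phi_1, 0, 0, 0, 0)}. The microglia
#' component is fixed at 0, the completion consistent with the four-state
#' linearization used for the stability analysis.
#'
#' @param params an \code{\link{ad_params}} object.
#' @return An object of class \code{"ad_equilibrium"} with fields
#'   \code{kind}, \code{state}, \code{residual_norm}.
#' @export
disease_free_equilibrium <- function(params) {
  stopifnot(inherits(params, "ad_params"))
  if (params$phi1 <= 0) stop("degenerate parameter: phi1 must be positive")
  state <- ad_state(F_N = params$Pi_N / params$phi1, I_N = 0, A_beta = 0,
                    T_mu = 0, M_rho = 0)
  new_equilibrium("disease-free", state, params)
}

new_equilibrium <- function(kind, state, params, note = NULL) {
  res <- max(abs(model_rhs(state, params)))
  structure(list(kind = kind, state = state, residual_norm = res,
                 note = note),
            class = "ad_equilibrium")
}

#' @export
print.ad_equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium (max |rhs| = %.3g)\n", x$kind, x$residual_norm))
  print(x$state)
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Endemic equilibrium
#'
#' With microglia at rest (\eqn{M_\rho^* = 0}) the amyloid and tau components
#' follow the infected-neuron level in closed form:
#' \eqn{A_\beta^* = \gamma I_N^*/(d_\beta+\kappa)},
#' \eqn{T_\mu^* = \kappa\gamma I_N^*/((d_\mu+\rho)(d_\beta+\kappa))}, and
#' \eqn{F_N^*} solves the functional-neuron balance directly:
#' \eqn{F_N^* = (\Pi_N + \rho T_\mu^*)/(\alpha A_\beta^* + \phi_1)}.
#'
#' By default (\code{I_N_star = NULL}) the self-consistent infected-neuron
#' level is solved from the infected-neuron balance
#' \eqn{\alpha F_N^* A_\beta^* = (\gamma+\phi_2) I_N^*}; a positive solution
#' exists only when the reproduction number exceeds 1, and the function
#' errors with a diagnostic otherwise. If \code{I_N_star} is supplied, the
#' construction above is returned as-is; its residual is then zero on the
#' F_N, A_beta, T_mu and M_rho equations but generally nonzero on the I_N
#' equation, and \code{residual_norm} reports the max residual over the
#' constrained equations only (the full residual is in \code{full_residual}).
#'
#' @param params an \code{\link{ad_params}} object.
#' @param I_N_star optional fixed infected-neuron level (>= 0).
#' @return An \code{"ad_equilibrium"} object.
#' @export
endemic_equilibrium <- function(params, I_N_star = NULL) {
  stopifnot(inherits(params, "ad_params"))
  p <- params
  a <- p$gamma / (p$d_beta + p$kappa)                       # A* / I*
  b <- p$kappa * p$gamma / ((p$d_mu + p$rho) * (p$d_beta + p$kappa)) # T* / I*
  build <- function(I) {
    A <- a * I
    Tm <- b * I
    Fn <- (p$Pi_N + p$rho * Tm) / (p$alpha * A + p$phi1)
    ad_state(F_N = Fn, I_N = I, A_beta = A, T_mu = Tm, M_rho = 0)
  }
  if (is.null(I_N_star)) {
    # self-consistent I*: alpha * F*(I) * a = gamma + phi2  (nontrivial branch)
    if (p$alpha == 0 || p$gamma == 0)
      stop("no endemic equilibrium: alpha and gamma must be positive")
    Fstar <- (p$gamma + p$phi2) * (p$d_beta + p$kappa) / (p$alpha * p$gamma)
    denom <- p$rho * b - Fstar * p$alpha * a
    I <- (Fstar * p$phi1 - p$Pi_N) / denom
    if (!is.finite(I) || I <= 0)
      stop(sprintf(
        "no admissible endemic equilibrium: self-consistent I_N* = %.4g <= 0 (R0 = %.4g)",
        I, ngm_matrices(params)$R0))
    eq <- new_equilibrium("endemic", build(I), params)
    eq$full_residual <- eq$residual_norm
    return(eq)
  }
  if (!is.finite(I_N_star) || I_N_star < 0)
    stop("I_N_star must be non-negative")
  state <- build(I_N_star)
  full <- model_rhs(state, params)
  eq <- new_equilibrium(if (I_N_star == 0) "disease-free" else "endemic",
                        state, params,
                        note = "I_N* supplied; I_N equation not enforced")
  eq$residual_norm <- max(abs(full[-2]))
  eq$full_residual <- max(abs(full))
  eq
}

# closed-form reproduction number
r0_closed_form <- function(p) {
  sqrt((p$alpha * p$gamma * p$Pi_N) /
         ((p$d_beta + p$kappa) * (p$gamma + p$phi2) * p$phi1))
}

#' Next-generation matrices and the basic reproduction number
#'
#' Linearizes the infected subsystem \eqn{X = (I_N, A_\beta, T_\mu)} at the
#' disease-free equilibrium into new-infection and transition parts,
#' \eqn{D^\sigma X = (F - V) X}, with
#' \deqn{F = \begin{pmatrix} 0 & \alpha \Pi_N/\phi_1 & 0 \\ \gamma & 0 & 0 \\
#'   0 & \kappa & 0 \end{pmatrix}, \quad
#'   V = \mathrm{diag}(\gamma+\phi_2,\; d_\beta+\kappa,\; d_\mu+\rho).}
#' The reproduction number is the spectral radius of \eqn{K = F V^{-1}}:
#' \deqn{R_0 = \sqrt{\frac{\alpha\,\gamma\,\Pi_N}
#'   {(d_\beta+\kappa)(\gamma+\phi_2)\,\phi_1}}.}
#'
#' @param params an \code{\link{ad_params}} object.
#' @return An object of class \code{"ad_ngm"}: list with \code{F}, \code{V},
#'   \code{K}, \code{R0} (closed form) and \code{R0_numeric} (spectral radius
#'   of K).
#' @export
ngm_matrices <- function(params) {
  stopifnot(inherits(params, "ad_params"))
  p <- params
  dens <- c(`gamma+phi2` = p$gamma + p$phi2,
            `d_beta+kappa` = p$d_beta + p$kappa,
            `d_mu+rho` = p$d_mu + p$rho, phi1 = p$phi1)
  if (any(dens <= 0))
    stop("degenerate parameter: ",
         paste(names(dens)[dens <= 0], collapse = ", "), " must be positive")
  inf_names <- c("I_N", "A_beta", "T_mu")
  F <- matrix(0, 3, 3, dimnames = list(inf_names, inf_names))
  F[1, 2] <- p$alpha * p$Pi_N / p$phi1
  F[2, 1] <- p$gamma
  F[3, 2] <- p$kappa
  V <- diag(dens[1:3])
  dimnames(V) <- list(inf_names, inf_names)
  K <- F %*% diag(1 / dens[1:3])
  dimnames(K) <- list(inf_names, inf_names)
  structure(list(F = F, V = V, K = K,
                 R0 = r0_closed_form(p),
                 R0_numeric = max(Mod(eigen(K, only.values = TRUE)$values))),
            class = "ad_ngm")
}

#' @export
print.ad_ngm <- function(x, ...) {
  cat(sprintf("Next-generation analysis: R0 = %.6g (spectral radius %.6g)\n",
              x$R0, x$R0_numeric))
  cat("K = F V^-1:\n")
  print(x$K)
  invisible(x)
}

#' Reproduction-number surface over a parameter pair
#'
#' Evaluates \eqn{R_0} on a rectangular grid of two parameters (all other
#' parameters held fixed) and marks the cells straddling the epidemic
#' threshold \eqn{R_0 = 1}.
#'
#' @param params baseline \code{\link{ad_params}}.
#' @param param_pair character vector of two parameter names entering R0.
#' @param ranges list of two numeric ranges \code{c(lo, hi)}.
#' @param grid_n grid resolution per axis.
#' @return List with axis vectors \code{x}, \code{y}, matrix \code{R0}
#'   (rows = x) and logical \code{contour_mask} marking cells adjacent to the
#'   R0 = 1 level.
#' @export
r0_surface <- function(params, param_pair, ranges, grid_n = 50) {
  stopifnot(inherits(params, "ad_params"))
  enter <- c("alpha", "gamma", "Pi_N", "phi1", "d_beta", "kappa", "phi2")
  if (length(param_pair) != 2 || !all(param_pair %in% enter))
    stop("param_pair must name two parameters entering R0: ",
         paste(enter, collapse = ", "))
  x <- seq(ranges[[1]][1], ranges[[1]][2], length.out = grid_n)
  y <- seq(ranges[[2]][1], ranges[[2]][2], length.out = grid_n)
  R0 <- matrix(NA_real_, grid_n, grid_n)
  bad <- character(0)
  for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
    q <- unclass(params)
    q[[param_pair[1]]] <- x[i]
    q[[param_pair[2]]] <- y[j]
    den <- c(q$d_beta + q$kappa, q$gamma + q$phi2, q$phi1)
    if (any(den <= 0)) {
      bad <- c(bad, sprintf("(%d,%d)", i, j))
    } else {
      R0[i, j] <- r0_closed_form(q)
    }
  }
  if (length(bad))
    stop("degenerate R0 denominator at grid cells: ",
         paste(head(bad, 10), collapse = " "))
  mask <- matrix(FALSE, grid_n, grid_n)
  above <- R0 >= 1
  for (i in seq_len(grid_n - 1)) for (j in seq_len(grid_n - 1)) {
    cell <- above[i:(i + 1), j:(j + 1)]
    if (any(cell) && !all(cell)) mask[i, j] <- TRUE
  }
  list(x = x, y = y, R0 = R0, contour_mask = mask, param_pair = param_pair)
}

#' Jacobian of the model at the disease-free equilibrium
#'
#' Four-state Jacobian in the ordering (F_N, I_N, A_beta, T_mu), with
#' optional stabilizing output gains \eqn{\omega_1..\omega_4} subtracted on
#' the diagonal:
#' \deqn{J = \begin{pmatrix}
#'  -\phi_1-\omega_1 & 0 & -\alpha\Pi_N/\phi_1 & \rho \\
#'  0 & -\gamma-\phi_2-\omega_2 & \alpha\Pi_N/\phi_1 & 0 \\
#'  0 & \gamma & -d_\beta-\kappa-\omega_3 & 0 \\
#'  0 & 0 & \kappa & -d_\mu-\rho-\omega_4 \end{pmatrix}}
#' With zero gains this is the linearization of \code{\link{model_rhs}} at
#' the disease-free state restricted to the four non-microglial components
#' (the microglial row/column decouples there since \eqn{M_\rho^* = 0}).
#' A fifth gain, if supplied, is accepted and ignored: the microglial state
#' does not enter this reduced Jacobian.
#'
#' @param params an \code{\link{ad_params}} object.
#' @param gains numeric vector of 4 (or 5) non-negative control gains.
#' @return 4 x 4 matrix.
#' @export
jacobian_dfe <- function(params, gains = c(0, 0, 0, 0)) {
  stopifnot(inherits(params, "ad_params"))
  if (params$phi1 <= 0) stop("degenerate parameter: phi1 must be positive")
  if (!length(gains) %in% c(4, 5) || any(!is.finite(gains)) || any(gains < 0))
    stop("gains must be 4 (or 5) non-negative values")
  g <- gains[1:4]
  p <- params
  aP <- p$alpha * p$Pi_N / p$phi1
  nm <- .ad_state_names[1:4]
  matrix(c(-p$phi1 - g[1], 0, -aP, p$rho,
           0, -p$gamma - p$phi2 - g[2], aP, 0,
           0, p$gamma, -p$d_beta - p$kappa - g[3], 0,
           0, 0, p$kappa, -p$d_mu - p$rho - g[4]),
         4, 4, byrow = TRUE, dimnames = list(nm, nm))
}

#' Eigenvalue stability classification
#'
#' Eigenvalues are reported sorted by ascending magnitude, ties broken by
#' ascending real part, for deterministic comparison with tabulated spectra.
#' The matrix is locally asymptotically stable when all real parts are
#' negative.
#'
#' @param m square real matrix.
#' @return An object of class \code{"ad_stability"}: list with
#'   \code{matrix}, complex \code{eigenvalues}, logical \code{stable}, and
#'   \code{trace} (for the sum-of-eigenvalues identity).
#' @export
eigen_stability <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  ev <- eigen(m, only.values = TRUE)$values
  ev <- as.complex(ev)
  ord <- order(Mod(ev), Re(ev))
  ev <- ev[ord]
  structure(list(matrix = m, eigenvalues = ev,
                 stable = all(Re(ev) < 0), trace = sum(diag(m))),
            class = "ad_stability")
}

#' @export
print.ad_stability <- function(x, ...) {
  cat(sprintf("Eigenvalue stability report (%dx%d): %s\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$stable) "stable (all Re < 0)" else "NOT stable"))
  for (ev in x$eigenvalues)
    cat(sprintf("  %.10g %+.10gi  (|.| = %.6g)\n", Re(ev), Im(ev), Mod(ev)))
  invisible(x)
}

#' Audit a reported spectrum against a matrix
#'
#' Compares an externally tabulated eigenvalue list with the matrix it is
#' claimed to belong to, using the trace identity (the eigenvalues of a
#' matrix sum to its trace) and the element-wise match to the computed
#' spectrum. Useful for flagging transcription errors in published spectra.
#'
#' @param m square real matrix.
#' @param reported numeric/complex vector of claimed eigenvalues.
#' @return List with \code{trace}, \code{reported_sum}, \code{gap}
#'   (|trace - sum|), logical \code{consistent} (gap below tolerance),
#'   \code{computed} (sorted spectrum) and per-entry \code{matched} flags.
#' @export
audit_reported_spectrum <- function(m, reported) {
  rep_sorted <- reported[order(Mod(reported), Re(reported))]
  st <- eigen_stability(m)
  gap <- abs(st$trace - sum(reported))
  tol_tr <- 1e-8 * max(1, abs(st$trace))
  matched <- vapply(rep_sorted, function(r)
    any(Mod(st$eigenvalues - r) <= 1e-6 * max(1, Mod(r))), logical(1))
  list(trace = st$trace, reported_sum = Re(sum(reported)), gap = gap,
       consistent = gap <= tol_tr, computed = st$eigenvalues,
       reported = rep_sorted, matched = matched)
}

#' Full stability analysis report
#'
#' Bundles equilibria, the reproduction number, the (optionally
#' gain-augmented) Jacobian at the disease-free state and its eigenvalue
#' classification into one JSON-serializable report.
#'
#' @param params an \code{\link{ad_params}} object.
#' @param gains optional stabilizing gains (see \code{\link{jacobian_dfe}}).
#' @return A list; serialize with \code{\link{write_analysis}}.
#' @export
analyze_model <- function(params, gains = c(0, 0, 0, 0)) {
  dfe <- disease_free_equilibrium(params)
  ngm <- ngm_matrices(params)
  J <- jacobian_dfe(params, gains)
  st <- eigen_stability(J)
  endemic <- tryCatch(endemic_equilibrium(params),
                      error = function(e) conditionMessage(e))
  list(
    params = unclass(params),
    gains = gains,
    disease_free = list(state = as.list(dfe$state),
                        residual_norm = dfe$residual_norm),
    endemic = if (inherits(endemic, "ad_equilibrium"))
      list(state = as.list(endemic$state),
           residual_norm = endemic$residual_norm) else endemic,
    R0 = ngm$R0,
    R0_spectral = ngm$R0_numeric,
    K = ngm$K,
    jacobian = J,
    eigenvalues = data.frame(re = Re(st$eigenvalues),
                             im = Im(st$eigenvalues)),
    stable = st$stable,
    trace = st$trace)
}

#' Serialize an analysis report to JSON
#'
#' Matrices are written row-major; eigenvalues as (re, im) pairs.
#'
#' @param report output of \code{\link{analyze_model}}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_analysis <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", dataframe = "rows")
  invisible(path)
}
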