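#' Initial osmotic swelling of a layer
#'
#' The mesh geometry is prescribed in the swollen reference configuration:
#' each layer is pre-swollen from its (virtual) zero-energy state by an
#' isotropic stretch \code{J0^(1/3)} such that the reference state
#' \code{F = I} is self-equilibrated with the surrounding fluid bath at zero
#' chemical potential. At \code{F = I} the fluid pressure is then
#' \code{p = Delta_pi(1) = beta0} and the (isotropic) matrix stress must
#' balance it:
#' \deqn{\phi_s^{ref} \mu_0 m_1 e^{q g_m(J_0)} (J_0^{2/3} - J_0^{-2 m_2})
#'   = \beta_0}
#' with \code{g_m(J0) = m1 (3 J0^(2/3) - 3) + (m1/m2)(J0^(-2 m2) - 1)}.
#' Fibers are referred to the swollen reference (stretch 1 at F = I), so
#' they contribute no pre-stress and the balance is exactly isotropic; the
#' left-hand side grows monotonically from 0 at \code{J0 = 1}, so the root
#' is unique. Because each layer is meshed in its own swollen state,
#' different \code{J0} across layers induce no residual stress or bending at
#' rest.
#'
#' @param params a \code{\link{layer_params}}.
#' @param J0_max upper bracket bound for the root search (expanded from 3
#'   geometrically up to this limit).
#' @param tol root tolerance on J0.
#' @return object of class \code{SwellingState}: list with \code{J0},
#'   \code{b0} (the 3x3 tensor \code{J0^(2/3) I}) and \code{residual}, the
#'   norm of the total Cauchy stress at \code{F = I} with \code{p = beta0}
#'   (MPa).
#' @export
solve_initial_swelling <- function(params, J0_max = 1e6, tol = 1e-12) {
  if (params$beta0 < 0) stop("solve_initial_swelling: beta0 must be >= 0")
  matrix_stress_iso <- function(J0) {
    gm <- params$m1 * (3 * J0^(2 / 3) - 3) +
      params$m1 / params$m2 * (J0^(-2 * params$m2) - 1)
    params$phi_s_ref * params$mu0 * params$m1 * exp(params$q * gm) *
      (J0^(2 / 3) - J0^(-2 * params$m2))
  }
  if (params$beta0 == 0) {
    J0 <- 1
  } else {
    f <- function(J0) matrix_stress_iso(J0) - params$beta0
    hi <- 3
    while (f(hi) < 0 && hi < J0_max) hi <- hi * 2
    if (f(hi) < 0)
      stop("solve_initial_swelling: no equilibrium swelling ratio in (1, ",
           J0_max, "); beta0 too large for this solid")
    J0 <- stats::uniroot(f, c(1, hi), tol = tol)$root
  }
  fib <- make_fiber_set(params$theta, 16L)
  sig <- solid_stress(diag(3), params, fib, J0 = J0) -
    osmotic_pressure(1, params) * diag(3)
  structure(list(J0 = J0, b0 = J0^(2 / 3) * diag(3),
                 residual = max(abs(sig))),
            class = "SwellingState")
}

#' @export
print.SwellingState <- function(x, ...) {
  cat(sprintf("<SwellingState> J0 = %.10f  equilibrium residual = %.3e MPa\n",
              x$J0, x$residual))
  invisible(x)
}
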