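# Material point constitutive model of one biphasic skin layer.
#
# Solid: exponential (Rubin-Bodner type) strain energy
#   Psi_s = phi_s_ref * mu0/(2q) * (exp(q g) - 1),  g = g_m + g_fe + g_fd
# with isotropic matrix term g_m (referred to the zero-energy state through
# the isotropic swelling pre-deformation b0 = J0^(2/3) I), an elastic fiber
# term g_fe and a dissipative fiber term g_fd, both tension-only through
# Macaulay brackets. Fluid: chemical potential mu_F = p - Delta_pi with
# constitutive osmotic pressure Delta_pi(J) and Darcy flux with
# deformation-dependent isotropic permeability k(J).
#
# All quantities in mm-N-s-MPa.

macaulay <- function(x) ifelse(x > 0, x, 0)

#' Osmotic pressure as a function of volume ratio
#'
#' \code{Delta_pi(J) = beta0 * ((1 - phi_s_ref)/(J - phi_s_ref))^beta1},
#' strictly decreasing in J and equal to \code{beta0} at J = 1.
#'
#' @param J volume ratio(s), must exceed \code{phi_s_ref}.
#' @param params a \code{\link{layer_params}} object.
#' @return osmotic pressure in MPa (vectorized over \code{J}).
#' @export
osmotic_pressure <- function(J, params) {
  if (any(J <= params$phi_s_ref))
    stop("osmotic_pressure: J must exceed phi_s_ref (pore space vanished)")
  params$beta0 * ((1 - params$phi_s_ref) / (J - params$phi_s_ref))^params$beta1
}

#' Deformation-dependent Darcy permeability
#'
#' \code{k(J) = k0 * ((J - phi_s_ref)/(1 - phi_s_ref))^kappa}; the isotropic
#' spatial permeability tensor is \code{k(J) I}.
#'
#' @inheritParams osmotic_pressure
#' @return scalar permeability in mm^4 N^-1 s^-1 (vectorized over \code{J}).
#' @export
permeability <- function(J, params) {
  if (any(J <= params$phi_s_ref))
    stop("permeability: J must exceed phi_s_ref (pore space vanished)")
  params$k0 * ((J - params$phi_s_ref) / (1 - params$phi_s_ref))^params$kappa
}

#' Darcy flux from a chemical potential gradient
#'
#' \code{q = -k grad(mu_F)}: fluid flows down the chemical potential
#' gradient.
#'
#' @param grad_mu_F spatial gradient of the fluid chemical potential
#'   (MPa/mm), any length.
#' @param k scalar permeability (mm^4 N^-1 s^-1).
#' @return flux vector (mm/s).
#' @export
darcy_flux <- function(grad_mu_F, k) -k * grad_mu_F

# g-terms of the strain energy. lambda_r are the relaxed stretches of the
# dissipative branch (internal variables); lambda_fd = lambda_f / lambda_r.
g_terms <- function(F, J0, lambda_r, params, dirs) {
  J <- det(F)
  if (J * J0 <= 0) stop("g_terms: nonpositive J*J0")
  gm <- params$m1 * (J0^(2 / 3) * sum(F * F) - 3) +
    params$m1 / params$m2 * ((J * J0)^(-2 * params$m2) - 1)
  gfe <- 0
  gfd <- 0
  if (params$m_fe > 0 || params$m_fd > 0) {
    lf <- fiber_stretch(F, dirs)
    if (params$m_fe > 0)
      gfe <- params$m_fe / params$m_4e *
        mean(macaulay(lf - 1)^(2 * params$m_4e))
    if (params$m_fd > 0) {
      lfd <- lf / lambda_r
      gfd <- params$m_fd / params$m_4d *
        mean(macaulay(lfd - 1)^(2 * params$m_4d))
    }
  }
  list(g_m = gm, g_fe = gfe, g_fd = gfd, g = gm + gfe + gfd, J = J)
}

#' Solid strain energy density
#'
#' Evaluates \code{Psi_s} and its three contributions for a given
#' deformation gradient (measured from the swollen reference), swelling
#' ratio \code{J0} and dissipative-branch relaxed stretches.
#'
#' @param F 3x3 deformation gradient.
#' @param params a \code{\link{layer_params}}.
#' @param fibers a \code{\link{make_fiber_set}} object.
#' @param J0 initial swelling volume ratio (from
#'   \code{\link{solve_initial_swelling}}).
#' @param lambda_r relaxed stretches of the dissipative fiber branch, length
#'   N (default 1: fully relaxed reference).
#' @return list with \code{Psi_s} (MPa) and the contributions \code{g_m},
#'   \code{g_fe}, \code{g_fd}.
#' @export
strain_energy <- function(F, params, fibers, J0 = 1,
                          lambda_r = rep(1, fibers$N)) {
  gt <- g_terms(F, J0, lambda_r, params, fibers$directions)
  c(list(Psi_s = params$phi_s_ref * params$mu0 / (2 * params$q) *
           (exp(params$q * gt$g) - 1)), gt[c("g_m", "g_fe", "g_fd")])
}

#' Cauchy stress of the solid phase
#'
#' Analytic push-forward of the strain energy derivative. The total stress
#' of the mixture is \code{solid_stress(...) - p I} with fluid pressure
#' \code{p = mu_F + Delta_pi(J)}.
#'
#' @inheritParams strain_energy
#' @return symmetric 3x3 Cauchy stress (MPa) of the solid contribution.
#' @export
solid_stress <- function(F, params, fibers, J0 = 1,
                         lambda_r = rep(1, fibers$N)) {
  dirs <- fibers$directions
  gt <- g_terms(F, J0, lambda_r, params, dirs)
  J <- gt$J
  b <- F %*% t(F)
  S <- 2 * params$m1 * J0^(2 / 3) * b -
    2 * params$m1 * (J * J0)^(-2 * params$m2) * diag(3)
  if (params$m_fe > 0 || params$m_fd > 0) {
    La <- dirs %*% t(F)                       # rows (F a_i)^T
    lf <- sqrt(rowSums(La * La))
    w <- numeric(fibers$N)
    if (params$m_fe > 0)
      w <- w + 2 * params$m_fe / fibers$N *
        macaulay(lf - 1)^(2 * params$m_4e - 1) / lf
    if (params$m_fd > 0) {
      lfd <- lf / lambda_r
      w <- w + 2 * params$m_fd / fibers$N *
        macaulay(lfd - 1)^(2 * params$m_4d - 1) / (lambda_r * lf)
    }
    S <- S + t(La) %*% (w * La)
  }
  pref <- params$phi_s_ref * params$mu0 / 2 * exp(params$q * gt$g) / J
  pref * S
}

#' Thermodynamic force on the dissipative fiber branch
#'
#' \code{f_fd^i = dPsi_s/dlambda_fd^i >= 0} (zero when the branch stretch is
#' not tensile); drives the relaxation of the internal variables.
#'
#' @keywords internal
fiber_force_fd <- function(lf, lambda_r, g, params, N) {
  lfd <- lf / lambda_r
  params$phi_s_ref * params$mu0 / 2 * exp(params$q * g) *
    2 * params$m_fd / N * macaulay(lfd - 1)^(2 * params$m_4d - 1)
}

#' Advance the dissipative fiber internal variables over one time step
#'
#' The dissipative branch stretch is the multiplicative remainder
#' \code{lambda_fd = lambda_f / lambda_r} with relaxed stretch
#' \code{lambda_r} evolving by the rate law
#' \code{d(lambda_r)/dt = k_fd * f_fd * lambda_r}, where \code{f_fd =
#' dPsi_s/dlambda_fd >= 0} is the thermodynamic force on the branch.
#' With \code{k_fd = 0} the branch is purely elastic
#' (\code{lambda_r = 1} forever); under a fixed-stretch hold
#' \code{lambda_r} grows monotonically towards \code{lambda_f}, so the
#' branch relaxes completely. Integrated per direction by backward Euler
#' (bisection-safe scalar solve) with outer sweeps for the energy coupling
#' across directions.
#'
#' @param F 3x3 deformation gradient at the end of the step.
#' @param lambda_r_n relaxed stretches at the start of the step (length N).
#' @param params,fibers,J0 as in \code{\link{strain_energy}}.
#' @param dt time step (s), > 0.
#' @return updated \code{lambda_r} vector.
#' @export
evolve_dissipative_fibers <- function(F, lambda_r_n, params, fibers, J0, dt) {
  if (dt <= 0) stop("evolve_dissipative_fibers: dt must be > 0")
  if (params$k_fd <= 0 || params$m_fd <= 0) return(lambda_r_n)
  dirs <- fibers$directions
  lf <- fiber_stretch(F, dirs)
  lr <- lambda_r_n
  for (sweep in 1:25) {
    g <- g_terms(F, J0, lr, params, dirs)$g
    lr_new <- lr
    for (i in seq_along(lr)) {
      if (lf[i] <= lambda_r_n[i]) next     # branch not tensile: no evolution
      h <- function(x) {
        f <- fiber_force_fd(lf[i], x, g, params, fibers$N)
        x - lambda_r_n[i] - dt * params$k_fd * f * x
      }
      lo <- lambda_r_n[i]; hi <- lf[i]
      if (h(lo) >= 0) { lr_new[i] <- lo; next }
      for (bis in 1:60) {
        mid <- 0.5 * (lo + hi)
        if (h(mid) < 0) lo <- mid else hi <- mid
      }
      lr_new[i] <- 0.5 * (lo + hi)
    }
    if (max(abs(lr_new - lr)) < 1e-13) { lr <- lr_new; break }
    lr <- lr_new
  }
  lr
}
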