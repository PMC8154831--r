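# Homogeneous material-point driver: uniaxial tension / relaxation of one
# layer with traction-free lateral faces, drained or undrained fluid.
#
# Deformation F = diag(lambda1, lambda2, lambda3) from the swollen
# reference; e1 is the loading direction in the tissue plane, e3 the
# out-of-plane axis, so lambda2 (in-plane lateral) and lambda3
# (out-of-plane) differ. Drained: the fluid is equilibrated at every
# instant, mu_F = 0, p = Delta_pi(J). Undrained: no flux, the fluid is
# trapped, J is frozen and p is an unknown reaction.

point_total_stress <- function(l1, l2, l3, p, params, fibers, J0, lambda_r) {
  F <- diag(c(l1, l2, l3))
  cpp_solid_stress(F, unclass(params), fibers$directions, J0, lambda_r) -
    p * diag(3)
}

point_evolve <- function(F, lr_n, params, fibers, J0, dt) {
  if (params$k_fd <= 0 || params$m_fd <= 0) return(lr_n)
  cpp_evolve_lr(F, lr_n, unclass(params), fibers$directions, J0, dt)
}

# Solve lateral equilibrium at prescribed lambda1. Returns converged state.
point_solve_step <- function(l1, y0, state_n, params, fibers, J0, dt,
                             drained = TRUE, J_fix = NULL, tol = 1e-11) {
  # y = (l2, l3) drained;  y = (l2, p) undrained (l3 = J_fix/(l1 l2))
  resid <- function(y) {
    if (drained) {
      l2 <- y[1]; l3 <- y[2]
      J <- l1 * l2 * l3
      if (J <= params$phi_s_ref) return(c(1e6, 1e6))
      p <- osmotic_pressure(J, params)
    } else {
      l2 <- y[1]; p <- y[2]
      l3 <- J_fix / (l1 * l2)
    }
    F <- diag(c(l1, l2, l3))
    lr <- point_evolve(F, state_n$lambda_r, params, fibers, J0, dt)
    sig <- point_total_stress(l1, l2, l3, p, params, fibers, J0, lr)
    c(sig[2, 2], sig[3, 3])
  }
  y <- y0
  for (it in 1:60) {
    r <- resid(y)
    if (max(abs(r)) < tol * max(params$mu0 * params$phi_s_ref, 1e-6)) break
    h <- pmax(1e-7, 1e-7 * abs(y))
    Jm <- matrix(0, 2, 2)
    for (j in 1:2) {
      yp <- y; yp[j] <- yp[j] + h[j]
      Jm[, j] <- (resid(yp) - r) / h[j]
    }
    dy <- tryCatch(solve(Jm, -r), error = function(e) NULL)
    if (is.null(dy)) stop("point_solve_step: singular lateral Jacobian")
    # damp large steps
    sc <- min(1, 0.2 / max(abs(dy) / pmax(abs(y), 0.2)))
    y <- y + sc * dy
    if (it == 60) stop("point_solve_step: lateral Newton did not converge")
  }
  if (drained) {
    l2 <- y[1]; l3 <- y[2]
    J <- l1 * l2 * l3
    p <- osmotic_pressure(J, params)
  } else {
    l2 <- y[1]; p <- y[2]
    l3 <- J_fix / (l1 * l2)
    J <- J_fix
  }
  F <- diag(c(l1, l2, l3))
  lr <- point_evolve(F, state_n$lambda_r, params, fibers, J0, dt)
  sig <- point_total_stress(l1, l2, l3, p, params, fibers, J0, lr)
  dpi <- osmotic_pressure(J, params)
  list(y = y, l1 = l1, l2 = l2, l3 = l3, J = J, p = p,
       delta_pi = dpi, mu_F = p - dpi, lambda_r = lr,
       sigma11 = sig[1, 1])
}

#' Integrate a homogeneous uniaxial loading program at one material point
#'
#' Drives a single layer through a stretch-controlled uniaxial history with
#' traction-free lateral faces, advancing the dissipative fiber internal
#' variables, and records the response curve. Nominal tension per unit
#' width is \code{T = P11 * thickness} with first Piola stress
#' \code{P11 = J sigma11 / lambda1} (units N/mm).
#'
#' @param params a \code{\link{layer_params}}.
#' @param fibers a \code{\link{make_fiber_set}}; default built from
#'   \code{params$theta}.
#' @param rate nominal strain rate (1/s), > 0 unless \code{lambda_max = 1}.
#' @param lambda_max target axial stretch.
#' @param hold hold duration at \code{lambda_max} (s).
#' @param dt time step (s); default resolves stretch increments of 0.0025.
#' @param drainage \code{"drained"} (fluid equilibrated, \code{mu_F = 0}) or
#'   \code{"undrained"} (no flux, J frozen at its pre-step value).
#' @param thickness reference thickness used for the tension (mm); defaults
#'   to \code{params$thickness}.
#' @return a \code{ResponseCurve}: data frame with columns \code{t,
#'   lambda1, lambda2, lambda3, J, T, p, delta_pi, mu_F}.
#' @export
run_point <- function(params, fibers = NULL, rate = 1e-3, lambda_max = 1.25,
                      hold = 0, dt = NULL, drainage = c("drained",
                      "undrained"), thickness = params$thickness) {
  drainage <- match.arg(drainage)
  if (is.null(fibers)) fibers <- make_fiber_set(params$theta, 16L)
  if (rate < 0) stop("run_point: rate must be >= 0")
  if (is.null(dt)) dt <- if (rate > 0) 0.0025 / rate else 1
  sw <- solve_initial_swelling(params)
  J0 <- sw$J0
  t_ramp <- if (rate > 0) (lambda_max - 1) / rate else 0
  times <- if (t_ramp > 0) seq(0, t_ramp, by = dt) else 0
  if (hold > 0) {
    # geometric spacing during the hold resolves the fast early decay
    th <- unique(c(t_ramp + cumsum(pmin(dt * 1.25^(0:200),
                                        hold / 10))))
    th <- th[th <= t_ramp + hold]
    if (!length(th) || max(th) < t_ramp + hold)
      th <- c(th, t_ramp + hold)
    times <- c(times, th)
  }
  state <- list(lambda_r = rep(1, fibers$N))
  y <- c(1, 1)
  J_prev <- 1
  out <- vector("list", length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    l1 <- 1 + rate * min(t, t_ramp)
    dtk <- if (k == 1) max(dt, 1e-9) else times[k] - times[k - 1]
    drained <- drainage == "drained"
    st <- point_solve_step(l1, if (drained) y else c(y[1],
                             osmotic_pressure(J_prev, params)),
                           state, params, fibers, J0, dtk,
                           drained = drained, J_fix = J_prev)
    if (drained) y <- st$y else y <- c(st$l2, st$l3)
    if (drained) J_prev <- st$J
    state$lambda_r <- st$lambda_r
    P11 <- st$J * st$sigma11 / st$l1
    out[[k]] <- data.frame(t = t, lambda1 = st$l1, lambda2 = st$l2,
                           lambda3 = st$l3, J = st$J,
                           T = P11 * thickness, p = st$p,
                           delta_pi = st$delta_pi, mu_F = st$mu_F)
  }
  curve <- do.call(rbind, out)
  class(curve) <- c("ResponseCurve", "data.frame")
  attr(curve, "thickness") <- thickness
  attr(curve, "J0") <- J0
  curve
}

#' Uniaxial relaxation program at one material point
#'
#' Stretch ramp at the given nominal strain rate until the nominal tension
#' reaches \code{peak_tension}, then the length is held fixed and the decay
#' is recorded (dissipative fiber relaxation; the drained point model keeps
#' the fluid equilibrated).
#'
#' @inheritParams run_point
#' @param peak_tension target nominal tension (N/mm).
#' @param lambda_bound abort if the ramp reaches this stretch without
#'   attaining the peak tension.
#' @return a \code{ResponseCurve} (see \code{\link{run_point}}).
#' @export
run_relaxation <- function(params, fibers = NULL, rate = 0.05,
                           peak_tension = 0.2, hold = 300, dt = NULL,
                           thickness = params$thickness,
                           lambda_bound = 2) {
  if (is.null(fibers)) fibers <- make_fiber_set(params$theta, 16L)
  if (is.null(dt)) dt <- 0.0025 / rate
  sw <- solve_initial_swelling(params)
  J0 <- sw$J0
  state <- list(lambda_r = rep(1, fibers$N))
  y <- c(1, 1)
  rows <- list()
  t <- 0; l1 <- 1
  repeat {
    st <- point_solve_step(l1, y, state, params, fibers, J0, max(dt, 1e-9),
                           drained = TRUE)
    y <- st$y; state$lambda_r <- st$lambda_r
    T <- st$J * st$sigma11 / st$l1 * thickness
    rows[[length(rows) + 1]] <- data.frame(t = t, lambda1 = st$l1,
      lambda2 = st$l2, lambda3 = st$l3, J = st$J, T = T, p = st$p,
      delta_pi = st$delta_pi, mu_F = st$mu_F)
    if (T >= peak_tension) break
    if (l1 >= lambda_bound)
      stop("run_relaxation: peak tension not reached before lambda bound")
    t <- t + dt; l1 <- l1 + rate * dt
  }
  if (hold > 0) {
    t_peak <- t
    dth <- cumsum(pmin(dt * 1.25^(0:400), hold / 10))
    dth <- dth[dth <= hold]
    if (!length(dth) || max(dth) < hold) dth <- c(dth, hold)
    t_prev <- t_peak
    for (th in t_peak + dth) {
      st <- point_solve_step(l1, y, state, params, fibers, J0, th - t_prev,
                             drained = TRUE)
      y <- st$y; state$lambda_r <- st$lambda_r
      T <- st$J * st$sigma11 / st$l1 * thickness
      rows[[length(rows) + 1]] <- data.frame(t = th, lambda1 = st$l1,
        lambda2 = st$l2, lambda3 = st$l3, J = st$J, T = T, p = st$p,
        delta_pi = st$delta_pi, mu_F = st$mu_F)
      t_prev <- th
    }
  }
  curve <- do.call(rbind, rows)
  class(curve) <- c("ResponseCurve", "data.frame")
  attr(curve, "thickness") <- thickness
  attr(curve, "J0") <- J0
  curve
}

#' Tangent stiffness from a tension-stretch curve
#'
#' Thickness-normalized linearization \code{E = (1/t) dT/dlambda},
#' evaluated by a central finite difference of window \code{window} on the
#' interpolated curve. If the window would leave the curve range at the
#' lower end it is shifted up (one-sided difference), which is how the
#' small-strain anchor near lambda = 1 is handled (tension-only fibers make
#' T non-smooth exactly at 1; the anchor is evaluated at 1.005 with the
#' window [1, 1.01]).
#'
#' @param curve a \code{ResponseCurve}, or any data frame with columns
#'   \code{lambda1} and \code{T} (monotone loading branch).
#' @param lambda_eval stretch at which to linearize.
#' @param thickness reference thickness t (mm); default from the curve
#'   attribute.
#' @param window finite-difference window on lambda.
#' @return tangent stiffness in MPa.
#' @export
tangent_stiffness <- function(curve, lambda_eval,
                              thickness = attr(curve, "thickness"),
                              window = 0.01) {
  lam <- curve$lambda1 %||% curve$lambda
  T <- curve$T
  keep <- !duplicated(lam)
  lam <- lam[keep]; T <- T[keep]
  if (lambda_eval < min(lam) || lambda_eval > max(lam))
    stop("tangent_stiffness: lambda_eval outside curve range")
  lo <- lambda_eval - window / 2
  hi <- lambda_eval + window / 2
  if (lo < min(lam)) { hi <- hi + (min(lam) - lo); lo <- min(lam) }
  if (hi > max(lam)) { lo <- lo - (hi - max(lam)); hi <- max(lam) }
  Tf <- stats::approx(lam, T, xout = c(lo, hi))$y
  (Tf[2] - Tf[1]) / (hi - lo) / thickness
}
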