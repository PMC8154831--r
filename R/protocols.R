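# Protocol runners: end-to-end orchestration of the named experiments on
# the finite-element solver, plus curve fitting on synthetic targets.

new_protocol_result <- function(protocol, config, ...) {
  structure(c(list(protocol = protocol, config = config), list(...)),
            class = "ProtocolResult")
}

#' @export
print.ProtocolResult <- function(x, ...) {
  cat("<ProtocolResult>", x$protocol, "\n")
  if (!is.null(x$moduli)) {
    cat("  tangent moduli (kPa):\n")
    print(round(x$moduli * 1000, 1))
  }
  if (!is.null(x$summary)) {
    cat("  summary:\n")
    for (nm in names(x$summary))
      cat(sprintf("    %-28s %g\n", nm, x$summary[[nm]]))
  }
  invisible(x)
}

uniaxial_bcs <- function(mesh, ramp) {
  list(
    u = list(bc_dirichlet(mesh$sets$xmin, 1, 0),
             bc_dirichlet(mesh$sets$xmax, 1, ramp),
             bc_dirichlet(mesh$sets$ymin, 2, 0),
             bc_dirichlet(mesh$sets$origin, 3, 0)),
    mu = intersect(mesh$mu_node_ids,
                   union(mesh$sets$ymax, mesh$sets$zmin)))
}

#' Monotonic uniaxial tension protocol (finite-element)
#'
#' Runs the multilayer uniaxial simulation: quarter-symmetric
#' \code{1 x 2.5 x Lz} mm domain stretched along x at a nominal strain
#' rate, drained at the free lateral face and the bottom, impermeable top
#' (stratum corneum) and loaded cross-section. Reports per-layer nominal
#' tensions, tangent moduli at the small/intermediate/large stretch
#' anchors, apparent lateral stretches and the out-of-plane deflection
#' metric.
#'
#' @param stack a \code{\link{layer_stack}}; default the 2 mm ex vivo skin
#'   sample (Epi 0.1 / PD 0.2 / RD 1.7 mm).
#' @param rate nominal strain rate (1/s).
#' @param lambda_max final axial stretch.
#' @param dl_step stretch increment per time step.
#' @param anchors stretches at which tangent moduli are evaluated.
#' @param nx,ny,nz_layers mesh resolution (defaults give 252 elements).
#' @param fiber_n fiber directions per set.
#' @param verbose print Newton convergence.
#' @return a \code{ProtocolResult} with elements \code{history},
#'   \code{tensions} (per-layer data frames), \code{moduli} (layers x
#'   anchors, MPa), \code{apparent}, \code{deflection}, \code{summary}.
#' @export
run_uniaxial_monotonic <- function(stack = skin_stack(2), rate = 1e-3,
                                   lambda_max = 1.25, dl_step = 0.005,
                                   anchors = c(1.005, 1.10, 1.20),
                                   nx = 6, ny = 6, nz_layers = NULL,
                                   fiber_n = 16L, verbose = FALSE) {
  mesh <- build_uniaxial_mesh(stack, nx = nx, ny = ny,
                              nz_layers = nz_layers)
  Lx <- mesh$meta$Lx
  bcs <- uniaxial_bcs(mesh, function(t) rate * t * Lx)
  t_end <- (lambda_max - 1) / rate
  times <- seq(dl_step / rate, t_end, by = dl_step / rate)
  h <- solve_transient(mesh, stack, bcs, times, fiber_n = fiber_n,
                       verbose = verbose)
  tensions <- lapply(stats::setNames(nm = names(stack$layers)),
                     function(nm) layer_tension(h, nm))
  th <- vapply(stack$layers, `[[`, 0, "thickness")
  moduli <- t(vapply(names(stack$layers), function(nm)
    vapply(anchors, function(l)
      tangent_stiffness(tensions[[nm]], l, thickness = th[nm]), 0),
    numeric(length(anchors))))
  colnames(moduli) <- paste0("lambda_", anchors)
  app <- apparent_stretches(h)
  defl <- deflection_metric(h)
  new_protocol_result(
    "uniaxial_monotonic",
    list(rate = rate, lambda_max = lambda_max, dl_step = dl_step,
         anchors = anchors, nx = nx, ny = ny, fiber_n = fiber_n,
         stack = stack),
    history = h, tensions = tensions, moduli = moduli, apparent = app,
    deflection = defl,
    summary = list(
      lambda2a_end = app$lambda2a[nrow(app)],
      lambda3a_end = app$lambda3a[nrow(app)],
      deflection_end_mm = defl$w[nrow(defl)]))
}

#' Uniaxial relaxation protocol (finite-element)
#'
#' Stretch ramp at the given rate until the total nominal tension reaches
#' \code{peak_tension} (N per mm width, the specimen peak force mapped to
#' the modelled cross-section), then the sample length is held fixed and
#' the tension decay is recorded over the hold.
#'
#' @inheritParams run_uniaxial_monotonic
#' @param peak_tension nominal tension target (N/mm).
#' @param hold hold duration (s).
#' @param dl_step ramp stretch increment per step.
#' @return a \code{ProtocolResult} with \code{history}, \code{decay}
#'   (data frame t, lambda, T) and \code{summary}.
#' @export
run_uniaxial_relaxation <- function(stack = skin_stack(2), rate = 0.05,
                                    peak_tension = 0.2, hold = 300,
                                    dl_step = 0.005, nx = 6, ny = 6,
                                    nz_layers = NULL, fiber_n = 16L,
                                    verbose = FALSE, lambda_bound = 1.6) {
  mesh <- build_uniaxial_mesh(stack, nx = nx, ny = ny,
                              nz_layers = nz_layers)
  Lx <- mesh$meta$Lx
  W0 <- mesh$meta$Ly
  ramp <- function(t) rate * t * Lx
  bcs <- uniaxial_bcs(mesh, ramp)
  dt <- dl_step / rate
  n_bound <- ceiling((lambda_bound - 1) / dl_step)
  # ramp step by step (continuation) until the reaction tension crosses
  # the peak target
  state <- NULL
  h1 <- NULL
  t_peak <- NA
  for (k in seq_len(n_bound)) {
    hk <- solve_transient(mesh, stack, bcs, times = k * dt,
                          fiber_n = fiber_n, verbose = verbose,
                          init = state)
    state <- hk$state
    if (is.null(h1)) h1 <- hk
    else {
      h1$times <- c(h1$times, hk$times)
      for (f in c("U", "MU", "Jgp", "Pgp", "Ru", "Ugp", "Gmu", "Kgp"))
        h1[[f]] <- c(h1[[f]], hk[[f]])
      h1$newton <- c(h1$newton, hk$newton)
      h1$state <- hk$state
    }
    Tx <- sum(hk$Ru[[1]][3 * (mesh$sets$xmax - 1) + 1]) / W0
    if (Tx >= peak_tension) { t_peak <- k * dt; break }
  }
  if (is.na(t_peak))
    stop("run_uniaxial_relaxation: peak tension not reached before the ",
         "stretch bound")
  u_hold <- ramp(t_peak)
  bcs_hold <- uniaxial_bcs(mesh, function(t) u_hold)
  dth <- cumsum(pmin(dt * 1.3^(0:200), hold / 8))
  dth <- dth[dth <= hold]
  if (!length(dth) || max(dth) < hold) dth <- c(dth, hold)
  h2 <- solve_transient(mesh, stack, bcs_hold, times = t_peak + dth,
                        fiber_n = fiber_n, verbose = verbose,
                        init = h1$state)
  tt <- c(h1$times, h2$times)
  TT <- c(reaction_force(h1, mesh$sets$xmax, 1),
          reaction_force(h2, mesh$sets$xmax, 1)) / W0
  lam <- 1 + c(vapply(h1$U, function(U) mean(U[mesh$sets$xmax, 1]), 0),
               vapply(h2$U, function(U) mean(U[mesh$sets$xmax, 1]), 0)) / Lx
  decay <- data.frame(t = tt, lambda = lam, T = TT)
  new_protocol_result(
    "uniaxial_relaxation",
    list(rate = rate, peak_tension = peak_tension, hold = hold,
         dl_step = dl_step, stack = stack),
    history = h2, ramp_history = h1, decay = decay,
    summary = list(
      t_peak = t_peak, lambda_peak = 1 + rate * t_peak,
      T_peak = TT[length(h1$times)],
      T_end = TT[length(TT)],
      decay_fraction = 1 - TT[length(TT)] / TT[length(h1$times)]))
}

#' Default layer stacks for the suction protocols
#'
#' 2 mm probe: Epi 0.1 / PD 0.2 / RD 1.1 mm over 3 mm hypodermis.
#' 8 mm probe: additionally a 2 mm stiff muscle layer at the bottom.
#' 10 mm probe: the thicker forearm skin stack Epi 0.1 / PD 0.2 /
#' RD 1.7 mm over 3 mm hypodermis.
#'
#' @param opening probe opening diameter (mm): 2, 8 or 10.
#' @return a \code{\link{layer_stack}}.
#' @export
suction_stack <- function(opening) {
  tab <- builtin_table1()
  if (opening == 10) {
    tab$RD$thickness <- 1.7
    layer_stack(tab[c("Epi", "PD", "RD", "Hypo")])
  } else {
    tab$RD$thickness <- 1.1
    if (opening == 8) layer_stack(tab[c("Epi", "PD", "RD", "Hypo",
                                        "Muscle")])
    else layer_stack(tab[c("Epi", "PD", "RD", "Hypo")])
  }
}

suction_bcs <- function(mesh, pressure_fn) {
  list(
    u = list(bc_dirichlet(mesh$sets$axis, 1, 0),
             bc_dirichlet(mesh$sets$outer, 1, 0),
             bc_dirichlet(mesh$sets$outer, 2, 0),
             bc_dirichlet(mesh$sets$bottom, 1, 0),
             bc_dirichlet(mesh$sets$bottom, 2, 0),
             bc_dirichlet(setdiff(mesh$sets$top_probe, mesh$sets$outer),
                          2, 0)),
    mu = intersect(mesh$mu_node_ids,
                   union(mesh$sets$bottom, mesh$sets$outer)),
    pressure = list(edges = mesh$edge_sets$opening, value = pressure_fn))
}

#' Suction protocol (axisymmetric finite-element)
#'
#' Simulates probe aspiration of the layered skin: the probe face is a
#' closed frictionless contact (zero vertical displacement, free radial
#' slip) outside the opening, and the opening is loaded by a follower
#' pressure on the deformed surface. The top surface is impermeable; all
#' other boundaries are drained. Protocols: \describe{
#'   \item{linear}{pressure ramps to \code{p_max} over \code{t_ramp}, holds
#'     \code{t_hold}, ramps back, and recovers for \code{t_recover}.}
#'   \item{instantaneous}{pressure jumps (1 s ramp) to \code{p_max}, holds,
#'     jumps back, recovers.}
#'   \item{mri}{pressure ramps at \code{p_rate} until the apex elevation
#'     reaches \code{apex_target} (the probe's maximum tissue elevation).}
#' }
#' The suction magnitudes are configuration inputs; the defaults are
#' package assumptions in the typical range of such devices, not reported
#' values.
#'
#' @param opening probe opening diameter (mm).
#' @param protocol \code{"linear"}, \code{"instantaneous"} or \code{"mri"}.
#' @param stack layer stack; default \code{\link{suction_stack}(opening)}.
#' @param p_max peak suction (MPa, positive number; applied as negative
#'   pressure). Defaults are package assumptions within typical instrument
#'   operating ranges: 0.02 for the 2 mm probe, 0.008 for the 8 mm probe
#'   (apex magnitudes then come out at the reported scale); for
#'   \code{"mri"} it only bounds the ramp (0.06).
#' @param t_ramp,t_hold,t_recover phase durations (s).
#' @param apex_target apex elevation target for \code{"mri"} (mm).
#' @param p_rate pressure ramp rate for \code{"mri"} (MPa/s).
#' @param radius domain radius (mm); defaults: 8 for the 2 mm opening, 16
#'   for 8 mm, 12 for 10 mm, else 3.2 openings.
#' @param dt base time step (s).
#' @param h_edge,refine,nz_layers mesh controls
#'   (\code{\link{build_suction_mesh}}).
#' @param fiber_n fiber directions per set.
#' @param verbose print Newton convergence.
#' @return a \code{ProtocolResult} with \code{history}, \code{apex} (data
#'   frame), \code{thickness} (from
#'   \code{\link{layer_thickness_change}}), \code{summary}.
#' @export
run_suction <- function(opening = 8,
                        protocol = c("linear", "instantaneous", "mri"),
                        stack = NULL, p_max = NULL, t_ramp = 20,
                        t_hold = 20, t_recover = 40, apex_target = 2.5,
                        p_rate = 5e-4, radius = NULL, dt = 1,
                        h_edge = 0.35, refine = 1, nz_layers = NULL,
                        fiber_n = 16L, verbose = FALSE) {
  protocol <- match.arg(protocol)
  if (is.null(stack)) stack <- suction_stack(opening)
  if (is.null(p_max))
    p_max <- switch(as.character(opening), "2" = 0.02, "8" = 0.008, 0.06)
  if (is.null(radius))
    radius <- switch(as.character(opening), "2" = 8, "8" = 16, "10" = 12,
                     3.2 * opening)
  mesh <- build_suction_mesh(stack, opening, radius = radius,
                             nz_layers = nz_layers, h_edge = h_edge,
                             refine = refine)
  apex <- mesh$sets$apex
  if (protocol == "mri") {
    pfun <- function(t) -p_rate * t
    t_end <- 1.2 * p_max / p_rate      # generous bound; run stops on target
    times <- seq(dt, t_end, by = dt)
    h <- solve_transient(mesh, stack, suction_bcs(mesh, pfun), times,
                         fiber_n = fiber_n, verbose = verbose,
                         stop_when = function(s) s$U[apex, 2] >=
                           apex_target)
  } else {
    tr <- if (protocol == "instantaneous") 1 else t_ramp
    pfun <- function(t) {
      if (t <= tr) return(-p_max * t / tr)
      if (t <= tr + t_hold) return(-p_max)
      if (t <= 2 * tr + t_hold)
        return(-p_max * (1 - (t - tr - t_hold) / tr))
      0
    }
    t_end <- 2 * tr + t_hold + t_recover
    dts <- if (protocol == "instantaneous") {
      # fine steps across the jumps, coarser elsewhere
      c(seq(0.2, tr, by = 0.2), seq(tr + dt, tr + t_hold, by = dt),
        seq(tr + t_hold + 0.2, 2 * tr + t_hold, by = 0.2),
        seq(2 * tr + t_hold + dt, t_end, by = dt))
    } else {
      seq(dt, t_end, by = dt)
    }
    h <- solve_transient(mesh, stack, suction_bcs(mesh, pfun),
                         unique(round(dts, 10)), fiber_n = fiber_n,
                         verbose = verbose)
  }
  ap <- apex_displacement(h)
  thc <- layer_thickness_change(h)
  k_end <- nrow(ap)
  res <- new_protocol_result(
    paste0("suction_", protocol),
    list(opening = opening, radius = radius, p_max = p_max,
         t_ramp = t_ramp, t_hold = t_hold, t_recover = t_recover,
         apex_target = apex_target, p_rate = p_rate, dt = dt,
         h_edge = h_edge, refine = refine, stack = stack),
    history = h, apex = ap, thickness = thc,
    summary = list(
      apex_peak_mm = max(ap$apex),
      apex_end_mm = ap$apex[k_end],
      skin_thickness_ratio_end = thc$skin[k_end],
      skin_thickness_change_pct = 100 * (thc$skin[k_end] - 1)))
  if (protocol == "mri") {
    # interpolate the crossing of the apex target
    i <- which(ap$apex >= apex_target)[1]
    if (!is.na(i) && i > 1) {
      w <- (apex_target - ap$apex[i - 1]) / (ap$apex[i] - ap$apex[i - 1])
      sk <- thc$skin[i - 1] + w * (thc$skin[i] - thc$skin[i - 1])
      res$summary$skin_thickness_ratio_at_target <- sk
      res$summary$skin_thickness_reduction_pct <- 100 * (1 - sk)
      res$summary$pressure_at_target_MPa <-
        -(h$times[i - 1] + w * (h$times[i] - h$times[i - 1])) * p_rate
    } else if (!is.na(i)) {
      res$summary$skin_thickness_ratio_at_target <- thc$skin[i]
      res$summary$skin_thickness_reduction_pct <- 100 * (1 - thc$skin[i])
    } else {
      warning("run_suction: apex target not reached; increase p_max bound")
    }
  }
  res
}

#' Synthetic tension-stretch target curves
#'
#' Generates model tension-stretch curves from the material-point driver
#' with optional additive Gaussian noise; reproducible via \code{seed}.
#' Used as fitting fixtures.
#'
#' @param params a \code{\link{layer_params}}.
#' @param noise_sd standard deviation of the additive tension noise
#'   (N/mm).
#' @param seed RNG seed.
#' @param rate,lambda_max loading program.
#' @param n number of sample points on the stretch grid.
#' @return data frame with \code{lambda} and \code{T}.
#' @export
generate_fixture_curves <- function(params, noise_sd = 0, seed = 1,
                                    rate = 1e-3, lambda_max = 1.25,
                                    n = 50) {
  if (noise_sd < 0) stop("generate_fixture_curves: noise_sd must be >= 0")
  cv <- run_point(params, rate = rate, lambda_max = lambda_max)
  grid <- seq(1, lambda_max, length.out = n)
  T0 <- stats::approx(cv$lambda1, cv$T, xout = grid)$y
  if (noise_sd > 0) {
    set.seed(seed)
    T0 <- T0 + stats::rnorm(n, sd = noise_sd)
  }
  data.frame(lambda = grid, T = T0)
}

#' Least-squares fit of layer parameters to tension-stretch curves
#'
#' Bounded Levenberg-Marquardt least squares (via minpack.lm) of selected
#' material parameters against one or more target tension-stretch curves,
#' using the material-point driver as the forward model. The inverse
#' problem of the full multi-experiment calibration is out of scope; this
#' is the local refinement step with synthetic-data recovery tests.
#'
#' @param target data frame with \code{lambda} and \code{T} (or a list of
#'   such data frames, summed in one residual).
#' @param params starting \code{\link{layer_params}}.
#' @param free character vector of parameter names to fit.
#' @param lower,upper named bounds (defaults: positive multiples of the
#'   start).
#' @param rate loading rate of the forward model.
#' @return list with \code{params} (fitted), \code{estimate} (named
#'   vector), \code{residual_norm}, \code{convergence} (minpack.lm info),
#'   \code{sensitivity} (relative residual change for a 1 percent bump of
#'   each fitted parameter).
#' @export
fit_parameters <- function(target, params, free = c("mu0", "m_fe"),
                           lower = NULL, upper = NULL, rate = 1e-3) {
  if (is.data.frame(target)) target <- list(target)
  if (!length(target) || !nrow(target[[1]]))
    stop("fit_parameters: empty target")
  lmax <- max(vapply(target, function(d) max(d$lambda), 0))
  start <- vapply(free, function(f) params[[f]], 0)
  if (is.null(lower)) lower <- start * 0.05
  if (is.null(upper)) upper <- start * 20
  fwd <- function(x) {
    p <- params
    for (i in seq_along(free)) p[[free[i]]] <- x[i]
    run_point(p, rate = rate, lambda_max = lmax + 0.01)
  }
  resid_fn <- function(x) {
    cv <- try(fwd(x), silent = TRUE)
    if (inherits(cv, "try-error"))
      return(rep(1e3, sum(vapply(target, nrow, 0L))))
    unlist(lapply(target, function(d)
      stats::approx(cv$lambda1, cv$T, xout = d$lambda)$y - d$T))
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-12, ptol = 1e-12))
  est <- stats::setNames(as.numeric(fit$par), free)
  pfit <- params
  for (f in free) pfit[[f]] <- est[[f]]
  rn <- sqrt(sum(resid_fn(fit$par)^2))
  sens <- vapply(seq_along(free), function(i) {
    x <- fit$par; x[i] <- x[i] * 1.01
    sqrt(sum(resid_fn(x)^2)) - rn
  }, 0)
  list(params = pfit, estimate = est, residual_norm = rn,
       convergence = fit$info,
       sensitivity = stats::setNames(sens, free))
}
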