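# Coupled poroelastic finite-element solver: momentum balance of the
# mixture div(sigma_s - p I) = 0 and fluid mass balance linking the solid
# volume rate to the Darcy flux, discretized with quadratic displacement /
# linear chemical potential elements, backward Euler in time and Newton
# iteration on the monolithic residual.

#' Dirichlet displacement boundary condition
#'
#' @param nodes node ids.
#' @param dof displacement component (1..3 for 3-D x/y/z, 1..2 for
#'   axisymmetric r/z).
#' @param value prescribed value (mm): a scalar or a function of time.
#' @return a BC entry for \code{\link{solve_transient}}.
#' @export
bc_dirichlet <- function(nodes, dof, value = 0) {
  list(nodes = nodes, dof = dof,
       value = if (is.function(value)) value else function(t) value)
}

default_fibers <- function(stack, N = 16L)
  lapply(stack$layers, function(p) make_fiber_set(p$theta, N))

# external force vector from a follower pressure on deformed quadratic
# edges (axisymmetric). P < 0 sucks the surface outward.
axi_pressure_force <- function(mesh, U, edges, P) {
  f <- numeric(nrow(mesh$nodes) * 2)
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5, 8, 5) / 9
  for (e in seq_len(nrow(edges))) {
    ids <- edges[e, ]
    xr <- mesh$nodes[ids, 1] + U[ids, 1]
    xz <- mesh$nodes[ids, 2] + U[ids, 2]
    for (g in 1:3) {
      xi <- gp[g]
      N <- c(0.5 * xi * (xi - 1), 1 - xi^2, 0.5 * xi * (xi + 1))
      dN <- c(xi - 0.5, -2 * xi, xi + 0.5)
      r <- sum(N * xr)
      tr <- sum(dN * xr); tz <- sum(dN * xz)
      # outward normal times |tangent|: (-tz, tr)
      tvec <- -P * c(-tz, tr) * 2 * pi * r * gw[g]
      for (a in 1:3) {
        n <- ids[a]
        f[2 * n - 1] <- f[2 * n - 1] + N[a] * tvec[1]
        f[2 * n] <- f[2 * n] + N[a] * tvec[2]
      }
    }
  }
  f
}

# finite-difference load stiffness of the follower pressure: triplets of
# d f_ext / d u restricted to the edge dofs
axi_pressure_stiffness <- function(mesh, U, edges, P, h = 1e-7) {
  ti <- tj <- integer(0); tv <- numeric(0)
  f0 <- axi_pressure_force(mesh, U, edges, P)
  nodes <- sort(unique(as.vector(edges)))
  for (n in nodes) {
    for (d in 1:2) {
      Up <- U; Up[n, d] <- Up[n, d] + h
      fp <- axi_pressure_force(mesh, Up, edges, P)
      dcol <- (fp - f0) / h
      nz <- which(abs(dcol) > 0)
      ti <- c(ti, nz); tj <- c(tj, rep(2L * (n - 1L) + d, length(nz)))
      tv <- c(tv, dcol[nz])
    }
  }
  list(ti = ti, tj = tj, tv = tv)
}

#' Solve a transient coupled poroelastic boundary-value problem
#'
#' Backward-Euler time stepping with full Newton iteration on the coupled
#' residual; the step is bisected on non-convergence (down to
#' \code{dt_min}). Layers are pre-swollen: each layer's equilibrium
#' swelling ratio is solved first, so the unloaded mesh with zero chemical
#' potential is an exact equilibrium state.
#'
#' @param mesh a \code{PoroMesh} from \code{\link{build_uniaxial_mesh}} or
#'   \code{\link{build_suction_mesh}}.
#' @param stack the \code{\link{layer_stack}} the mesh was built from.
#' @param bcs list with entries \code{u} (list of
#'   \code{\link{bc_dirichlet}}), \code{mu} (node ids held at zero
#'   chemical potential) and optionally \code{pressure} (list with
#'   \code{edges} matrix and \code{value} function of time; axisymmetric
#'   only).
#' @param times increasing output times (s), starting after 0.
#' @param fiber_n fiber directions per set.
#' @param rtol relative Newton tolerance on the residual norms.
#' @param dt_min smallest admissible substep (s).
#' @param max_iter Newton iteration cap per step.
#' @param verbose print per-step convergence info.
#' @param keep_fields store per-step Gauss-point fields (needed by the
#'   post-processors; disable to save memory).
#' @param stop_when optional function(state) evaluated after each output
#'   time; returning TRUE ends the run early.
#' @param init optional \code{$state} of a previous \code{FieldHistory} to
#'   continue from; \code{times} then start after \code{init$t}.
#' @return a \code{FieldHistory}: times, nodal displacement and chemical
#'   potential histories, per-Gauss-point volume ratio and total first
#'   Piola stress, internal force vectors (for reactions), mesh and stack;
#'   \code{$state} holds the final solver state for continuation runs.
#' @export
solve_transient <- function(mesh, stack, bcs, times, fiber_n = 16L,
                            rtol = 1e-8, dt_min = 1e-3, max_iter = 30L,
                            verbose = FALSE, keep_fields = TRUE,
                            stop_when = NULL, init = NULL) {
  stopifnot(inherits(mesh, "PoroMesh"), inherits(stack, "LayerStack"))
  ndim <- if (mesh$dim == 3) 3L else 2L
  nn <- nrow(mesh$nodes)
  nmu <- length(mesh$mu_node_ids)
  ndofU <- ndim * nn
  ndof <- ndofU + nmu
  ngp <- if (ndim == 3) 27L else 9L
  nel <- nrow(mesh$elems)

  params <- lapply(stack$layers, unclass)
  sw <- lapply(stack$layers, solve_initial_swelling)
  J0s <- vapply(sw, `[[`, 0, "J0")
  fdirs <- lapply(default_fibers(stack, fiber_n), `[[`, "directions")
  Nfib <- as.integer(fiber_n)

  connU <- mesh$elems; storage.mode(connU) <- "integer"
  connM <- mesh$connM; storage.mode(connM) <- "integer"
  X <- mesh$nodes
  assemble <- function(U, MU, lr, Jn, dt, want_tangent) {
    if (ndim == 3)
      cpp_assemble_hex(X, connU, connM, U, MU, params, fdirs, J0s,
                       mesh$layer, lr, Jn, dt, want_tangent)
    else
      cpp_assemble_axi(X, connU, connM, U, MU, params, fdirs, J0s,
                       mesh$layer, lr, Jn, dt, want_tangent)
  }

  # resolve BC values
  ubc <- bcs$u %||% list()
  mu_fixed_nodes <- bcs$mu %||% integer(0)
  mu_fixed <- ndofU + match(mu_fixed_nodes, mesh$mu_node_ids)
  if (anyNA(mu_fixed))
    stop("solve_transient: mu BC on nodes that carry no mu dof ",
         "(must be corner nodes)")
  u_fixed_dofs <- unlist(lapply(ubc, function(b)
    ndim * (b$nodes - 1L) + b$dof))
  fixed <- unique(c(u_fixed_dofs, mu_fixed))
  free <- setdiff(seq_len(ndof), fixed)
  dofmap <- integer(ndof); dofmap[free] <- seq_along(free)

  set_prescribed <- function(U, MU, t) {
    for (b in ubc) U[cbind(b$nodes, b$dof)] <- b$value(t)
    MU[match(mu_fixed_nodes, mesh$mu_node_ids)] <- 0
    list(U = U, MU = MU)
  }

  if (is.null(init)) {
    U <- matrix(0, nn, ndim)
    MU <- numeric(nmu)
    lr <- matrix(1, nel * ngp, Nfib)
    Jn <- rep(1, nel * ngp)
    t_start <- 0
  } else {
    U <- init$U; MU <- init$MU; lr <- init$lr; Jn <- init$Jn
    t_start <- init$t
  }

  hist <- list(times = numeric(0), U = list(), MU = list(), Jgp = list(),
               Pgp = list(), Ru = list(), Ugp = list(), Gmu = list(),
               Kgp = list(), newton = integer(0))
  dVgp <- NULL

  do_step <- function(t0, t1, U, MU, lr, Jn, depth = 0,
                      guessU = NULL, guessMU = NULL) {
    dt <- t1 - t0
    ps <- set_prescribed(guessU %||% U, guessMU %||% MU, t1)
    Utry <- ps$U; MUtry <- ps$MU
    Pext <- NULL
    r0u <- r0m <- NULL
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      want_t <- TRUE
      as <- tryCatch(assemble(Utry, MUtry, lr, Jn, dt, want_t),
                     error = function(e) NULL)
      if (is.null(as)) break   # invalid state (e.g. J too small): bisect
      Ru <- as$Ru; Rm <- as$Rm
      Kload <- NULL
      if (!is.null(bcs$pressure)) {
        Pt <- bcs$pressure$value(t1)
        fext <- axi_pressure_force(mesh, Utry, bcs$pressure$edges, Pt)
        Ru <- Ru - fext
        if (Pt != 0)
          Kload <- axi_pressure_stiffness(mesh, Utry, bcs$pressure$edges,
                                          Pt)
      }
      R <- c(Ru, Rm)
      rnu <- sqrt(sum(R[intersect(free, seq_len(ndofU))]^2))
      rnm <- sqrt(sum(R[setdiff(free, seq_len(ndofU))]^2))
      if (is.null(r0u)) { r0u <- max(rnu, 1e-12); r0m <- max(rnm, 1e-12) }
      if (verbose)
        message(sprintf("  t=%.4g it=%d |Ru|=%.3e |Rm|=%.3e",
                        t1, it, rnu, rnm))
      if ((rnu < max(rtol * r0u, 1e-11) || rnu < 1e-12) &&
          (rnm < max(rtol * r0m, 1e-12) || rnm < 1e-13)) {
        ok <- TRUE
        final <- as
        break
      }
      if (!is.finite(rnu) || !is.finite(rnm) ||
          rnu > 1e6 * r0u + 1e3) break
      ati <- as$ti; atj <- as$tj; atv <- as$tv
      if (!is.null(Kload)) {
        # R_u includes -f_ext, so the tangent gets -df_ext/du
        ati <- c(ati, Kload$ti); atj <- c(atj, Kload$tj)
        atv <- c(atv, -Kload$tv)
      }
      fi <- dofmap[ati]; fj <- dofmap[atj]
      sel <- fi > 0L & fj > 0L
      dx <- tryCatch(
        cpp_sparse_solve(fi[sel], fj[sel], atv[sel], length(free),
                         -R[free]),
        error = function(e) NULL)
      if (is.null(dx)) break
      Uv <- as.vector(t(Utry))
      Uv[free[free <= ndofU]] <- Uv[free[free <= ndofU]] +
        dx[seq_len(sum(free <= ndofU))]
      Utry <- matrix(Uv, nn, ndim, byrow = TRUE)
      mid <- free[free > ndofU] - ndofU
      MUtry[mid] <- MUtry[mid] + dx[(sum(free <= ndofU) + 1):length(dx)]
    }
    if (!ok) {
      if (dt / 2 < dt_min)
        stop("solve_transient: Newton failed at t = ", t1,
             " with dt = ", dt, " (dt_min reached)")
      mid <- (t0 + t1) / 2
      gU <- guessU %||% U; gMU <- guessMU %||% MU
      s1 <- do_step(t0, mid, U, MU, lr, Jn, depth + 1,
                    guessU = U + (gU - U) * 0.5,
                    guessMU = MU + (gMU - MU) * 0.5)
      s2 <- do_step(mid, t1, s1$U, s1$MU, s1$lr, s1$Jn, depth + 1)
      s2$newton <- s1$newton + s2$newton
      return(s2)
    }
    list(U = Utry, MU = MUtry, lr = final$lr_new, Jn = final$Jgp,
         final = final, newton = it)
  }

  t_prev <- t_start
  U_prev <- NULL; MU_prev <- NULL; dt_prev <- NA
  for (tk in times) {
    dtk <- tk - t_prev
    if (!is.null(U_prev) && is.finite(dt_prev) && dt_prev > 0) {
      fac <- min(dtk / dt_prev, 2)
      Ug <- U + (U - U_prev) * fac
      MUg <- MU + (MU - MU_prev) * fac
    } else { Ug <- U; MUg <- MU }
    U_prev <- U; MU_prev <- MU; dt_prev <- dtk
    st <- do_step(t_prev, tk, U, MU, lr, Jn, guessU = Ug, guessMU = MUg)
    U <- st$U; MU <- st$MU; lr <- st$lr; Jn <- st$Jn
    if (is.null(dVgp)) { dVgp <- st$final$dVgp; hist$Xgp0 <- st$final$Xgp }
    hist$times <- c(hist$times, tk)
    hist$newton <- c(hist$newton, st$newton)
    hist$U[[length(hist$U) + 1]] <- U
    hist$MU[[length(hist$MU) + 1]] <- MU
    hist$Ru[[length(hist$Ru) + 1]] <- st$final$Ru
    if (keep_fields) {
      hist$Jgp[[length(hist$Jgp) + 1]] <- st$final$Jgp
      hist$Pgp[[length(hist$Pgp) + 1]] <- st$final$Pgp
      hist$Ugp[[length(hist$Ugp) + 1]] <- st$final$Ugp
      hist$Gmu[[length(hist$Gmu) + 1]] <- st$final$Gmu
      hist$Kgp[[length(hist$Kgp) + 1]] <- st$final$Kgp
    }
    t_prev <- tk
    if (!is.null(stop_when) &&
        isTRUE(stop_when(list(t = tk, U = U, MU = MU)))) break
  }
  hist$dVgp <- dVgp
  hist$mesh <- mesh
  hist$stack <- stack
  hist$J0s <- J0s
  hist$state <- list(U = U, MU = MU, lr = lr, Jn = Jn, t = t_prev)
  structure(hist, class = "FieldHistory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.FieldHistory <- function(x, ...) {
  cat("<FieldHistory>", length(x$times), "stored times, ",
      nrow(x$mesh$nodes), "nodes\n")
  invisible(x)
}

#' Total fluid-filled volume over time
#'
#' Integral of J over the reference domain; constant in a run with
#' impermeable boundaries (fluid mass conservation).
#'
#' @param history a \code{FieldHistory}.
#' @return numeric vector (mm^3) along \code{history$times}.
#' @export
fluid_volume <- function(history) {
  vapply(history$Jgp, function(J) sum(J * history$dVgp), 0)
}

#' Per-layer nominal tension in a uniaxial run
#'
#' Nominal tension (force per unit reference width) carried by one layer:
#' the volume average of the axial first Piola stress over the layer,
#' times the layer reference thickness -- equivalently
#' \code{integral(P11 dV) / (L0 W0)}. By discrete equilibrium the sum over
#' layers equals the total applied tension.
#'
#' @param history a \code{FieldHistory} from a uniaxial run.
#' @param layer layer name.
#' @return data frame with \code{t}, \code{lambda} (axial stretch of the
#'   domain) and \code{T} (N/mm).
#' @export
layer_tension <- function(history, layer) {
  mesh <- history$mesh
  il <- match(layer, mesh$layer_names)
  if (is.na(il)) stop("layer_tension: no layer named '", layer, "'")
  ngp <- if (mesh$dim == 3) 27L else 9L
  qsel <- rep(mesh$layer == il, each = ngp)
  A0 <- mesh$meta$Lx * mesh$meta$Ly
  T <- vapply(seq_along(history$times), function(k)
    sum(history$Pgp[[k]][qsel, 1] * history$dVgp[qsel]) / A0, 0)
  lam <- attr(history, "lambda") %||% lambda_from_bc(history)
  data.frame(t = history$times, lambda = lam, T = T)
}

lambda_from_bc <- function(history) {
  # axial stretch from the mean x-displacement of the loaded face
  mesh <- history$mesh
  xm <- mesh$sets$xmax
  1 + vapply(history$U, function(U) mean(U[xm, 1]), 0) / mesh$meta$Lx
}

#' Apparent lateral and thickness stretches of a uniaxial run
#'
#' Apparent width stretch \code{lambda2a = W_def / W0} from the lateral
#' extent of the mid-specimen cross-section, and apparent thickness
#' stretch \code{lambda3a = T_def / T0} measured over the lower part
#' (default lower half) of the deepest layer, consistent with how the
#' deformed cross-section is gauged experimentally.
#'
#' @param history a \code{FieldHistory} from a uniaxial run.
#' @param lower_fraction fraction of the bottom layer used for
#'   \code{lambda3a}.
#' @return data frame with \code{t, lambda, lambda2a, lambda3a}.
#' @export
apparent_stretches <- function(history, lower_fraction = 0.5) {
  mesh <- history$mesh
  nds <- mesh$nodes
  tolg <- 1e-9
  # cross-section at x = 0 (symmetry plane)
  face <- which(abs(nds[, 1]) < tolg)
  W0 <- max(nds[face, 2]) - min(nds[face, 2])
  # thickness gauge: column of nodes at (x, y) = (0, 0), lower part of the
  # bottom layer
  zt <- mesh$meta$th
  z_top_gauge <- rev(zt)[1] * lower_fraction       # bottom layer thickness
  col <- which(abs(nds[, 1]) < tolg & abs(nds[, 2]) < tolg)
  nlo <- col[which.min(abs(nds[col, 3] - 0))]
  nhi <- col[which.min(abs(nds[col, 3] - z_top_gauge))]
  T0 <- nds[nhi, 3] - nds[nlo, 3]
  lam <- attr(history, "lambda") %||% lambda_from_bc(history)
  l2 <- vapply(history$U, function(U)
    (max(nds[face, 2] + U[face, 2]) - min(nds[face, 2] + U[face, 2])) /
      W0, 0)
  l3 <- vapply(history$U, function(U)
    ((nds[nhi, 3] + U[nhi, 3]) - (nds[nlo, 3] + U[nlo, 3])) / T0, 0)
  data.frame(t = history$times, lambda = lam, lambda2a = l2,
             lambda3a = l3)
}

#' Out-of-plane deflection metric of the top surface
#'
#' Difference between the out-of-plane displacement of the center of the
#' top surface and at reference distance \code{dist} (mm) from the center
#' across the specimen width (the traction-free direction, where
#' differential lateral contraction of the layers curls the surface; with
#' the half-width model the center is the symmetry plane y = 0). The
#' modelled slice is uniform along the loading axis, so the width
#' direction is the one in which a deflection profile can develop. If the
#' modelled half-width is smaller than \code{dist} the gauge distance is
#' scaled down proportionally (with a message).
#'
#' @param history a \code{FieldHistory} from a uniaxial run.
#' @param dist gauge distance across the width (mm).
#' @return data frame with \code{t, lambda, w} (mm).
#' @export
deflection_metric <- function(history, dist = 2) {
  mesh <- history$mesh
  nds <- mesh$nodes
  tolg <- 1e-9
  Ly <- mesh$meta$Ly
  if (dist > Ly) {
    dist <- 0.8 * Ly
    message("deflection_metric: domain narrower than the gauge distance; ",
            "using ", dist, " mm")
  }
  Lz <- mesh$meta$Lz
  top <- which(abs(nds[, 3] - Lz) < tolg & abs(nds[, 1]) < tolg)
  n_c <- top[which.min(abs(nds[top, 2]))]
  n_d <- top[which.min(abs(nds[top, 2] - dist))]
  lam <- attr(history, "lambda") %||% lambda_from_bc(history)
  w <- vapply(history$U, function(U) U[n_c, 3] - U[n_d, 3], 0)
  data.frame(t = history$times, lambda = lam, w = w)
}

#' Layer thickness ratios on the symmetry axis of a suction run
#'
#' Deformed over reference thickness of each layer, measured along the
#' axis r = 0.
#'
#' @param history a \code{FieldHistory} from a suction run.
#' @return data frame with \code{t}, one column per layer, and
#'   \code{skin} (the combined Epi+PD+RD ratio if those layers exist,
#'   otherwise all layers combined).
#' @export
layer_thickness_change <- function(history) {
  mesh <- history$mesh
  stopifnot(mesh$dim == 2)
  nds <- mesh$nodes
  axis <- which(abs(nds[, 1]) < 1e-9)
  th <- mesh$meta$th
  H <- mesh$meta$H
  # interface z-coordinates top -> bottom
  zi <- H - cumsum(c(0, th))
  iface_nodes <- vapply(zi, function(z)
    axis[which.min(abs(nds[axis, 2] - z))], 0L)
  out <- data.frame(t = history$times)
  zdef <- function(U, n) nds[n, 2] + U[n, 2]
  for (l in seq_along(th)) {
    r <- vapply(history$U, function(U)
      (zdef(U, iface_nodes[l]) - zdef(U, iface_nodes[l + 1])) / th[l], 0)
    out[[mesh$layer_names[l]]] <- r
  }
  skin_layers <- intersect(c("Epi", "PD", "RD"), mesh$layer_names)
  if (!length(skin_layers)) skin_layers <- mesh$layer_names
  i0 <- match(skin_layers[1], mesh$layer_names)
  i1 <- match(skin_layers[length(skin_layers)], mesh$layer_names)
  T0 <- sum(th[i0:i1])
  out$skin <- vapply(history$U, function(U)
    (zdef(U, iface_nodes[i0]) - zdef(U, iface_nodes[i1 + 1])) / T0, 0)
  out
}

#' Apex displacement history of a suction run
#'
#' @param history a \code{FieldHistory} from a suction run.
#' @return data frame with \code{t} and \code{apex} (mm, positive up).
#' @export
apex_displacement <- function(history) {
  n <- history$mesh$sets$apex
  data.frame(t = history$times,
             apex = vapply(history$U, function(U) U[n, 2], 0))
}

#' Global reaction force on a node set
#'
#' Sums the converged internal nodal forces over a Dirichlet node set;
#' by equilibrium this balances the load transmitted through that
#' boundary.
#'
#' @param history a \code{FieldHistory}.
#' @param nodes node ids (typically one of \code{mesh$sets}).
#' @param dof force component.
#' @return numeric vector along \code{history$times} (N).
#' @export
reaction_force <- function(history, nodes, dof) {
  ndim <- if (history$mesh$dim == 3) 3L else 2L
  idx <- ndim * (nodes - 1L) + dof
  vapply(history$Ru, function(r) sum(r[idx]), 0)
}
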