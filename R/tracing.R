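#' Trace fluid particles through a transient run
#'
#' Fluid particles move with the solid and with the interstitial flux:
#' \deqn{x_f(t + \Delta t) = x_f(t) + v_s \Delta t +
#'   \frac{1}{\varphi_f} q \Delta t}
#' with solid velocity \code{v_s} (from displacement increments), Darcy
#' flux \code{q = -k grad(mu_F)} and current fluid fraction
#' \code{phi_f = 1 - phi_s_ref / J} (incompressible solid constituent).
#' Fields are sampled piecewise-constant at the nearest Gauss point in the
#' deformed configuration. Paths are reported both in the spatial frame
#' and pulled back to the material (undeformed) frame via the displacement
#' of the co-located solid point. Particles that leave the domain are
#' truncated and flagged.
#'
#' @param history a \code{FieldHistory} stored with fields
#'   (\code{keep_fields = TRUE}).
#' @param seed_points matrix of starting positions (reference = spatial at
#'   t = 0), one row per particle; columns (x, y, z) for 3-D or (r, z) for
#'   axisymmetric.
#' @return data frame with \code{particle, t}, spatial coordinates
#'   \code{x1, x2[, x3]}, material coordinates \code{X1, X2[, X3]} and
#'   \code{inside}.
#' @export
trace_fluid_particles <- function(history, seed_points) {
  mesh <- history$mesh
  ndim <- if (mesh$dim == 3) 3L else 2L
  seed_points <- as.matrix(seed_points)
  if (ncol(seed_points) != ndim)
    stop("trace_fluid_particles: seed_points must have ", ndim, " columns")
  if (!length(history$Ugp))
    stop("trace_fluid_particles: history was run with keep_fields = FALSE")
  phis <- vapply(history$stack$layers, `[[`, 0, "phi_s_ref")
  ngp <- if (ndim == 3) 27L else 9L
  phis_gp <- rep(phis[mesh$layer], each = ngp)
  X0 <- history$Xgp0
  bounds <- apply(mesh$nodes, 2, range)
  np <- nrow(seed_points)
  x <- seed_points
  alive <- rep(TRUE, np)
  out <- vector("list", length(history$times) + 1L)
  matpos <- function(xp, k) {
    xs <- X0 + history$Ugp[[k]]
    i <- which.min(colSums((t(xs) - xp)^2))
    xp - history$Ugp[[k]][i, ]
  }
  rec <- function(tt, k) {
    Xm <- t(vapply(seq_len(np), function(i)
      if (k == 0) x[i, ] else matpos(x[i, ], k), numeric(ndim)))
    data.frame(particle = seq_len(np), t = tt, x = I(x), X = I(Xm),
               inside = alive)
  }
  out[[1]] <- rec(0, 0)
  t_prev <- 0
  for (k in seq_along(history$times)) {
    dt <- history$times[k] - t_prev
    xs <- X0 + history$Ugp[[k]]
    vs <- if (k == 1) history$Ugp[[k]] / dt
          else (history$Ugp[[k]] - history$Ugp[[k - 1]]) / dt
    qf <- -history$Kgp[[k]] * history$Gmu[[k]]
    phif <- 1 - phis_gp / history$Jgp[[k]]
    for (i in seq_len(np)) {
      if (!alive[i]) next
      d2 <- colSums((t(xs) - x[i, ])^2)
      g <- which.min(d2)
      x[i, ] <- x[i, ] + vs[g, ] * dt + qf[g, ] / phif[g] * dt
      if (any(x[i, ] < bounds[1, ] - 1e-6) ||
          any(x[i, ] > bounds[2, ] + 1e-6)) alive[i] <- FALSE
    }
    out[[k + 1L]] <- rec(history$times[k], k)
    t_prev <- history$times[k]
  }
  res <- do.call(rbind, out)
  xm <- as.matrix(res$x); Xm <- as.matrix(res$X)
  res$x <- NULL; res$X <- NULL
  for (d in seq_len(ndim)) res[[paste0("x", d)]] <- xm[, d]
  for (d in seq_len(ndim)) res[[paste0("X", d)]] <- Xm[, d]
  res
}
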