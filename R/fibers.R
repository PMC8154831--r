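#' Discrete fiber direction set
#'
#' Builds the discrete set of reference fiber directions used by the fiber
#' terms of the strain energy: \code{N/2} azimuthally uniform directions at
#' elevation \code{+theta} from the tissue plane (the e1-e2 plane; e3 is the
#' out-of-plane axis) and their mirror images at \code{-theta}. The set is
#' closed under azimuthal rotation by \code{2*pi/(N/2)} and under elevation
#' sign flip, so the in-plane response is isotropic (transverse isotropy
#' about e3). \code{N = 16} is the package default; doubling it changes the
#' uniaxial response by well under 1 percent (see the methods vignette).
#'
#' @param theta_degrees out-of-plane fiber elevation in degrees, in [0, 90].
#' @param N even number of directions, at least 4.
#' @return object of class \code{FiberSet}: list with \code{N},
#'   \code{theta_degrees} and \code{directions} (an \code{N x 3} matrix of
#'   unit rows).
#' @export
make_fiber_set <- function(theta_degrees, N = 16L) {
  if (N %% 2 != 0 || N < 4) stop("make_fiber_set: N must be even and >= 4")
  if (theta_degrees < 0 || theta_degrees > 90)
    stop("make_fiber_set: theta must be in [0, 90] degrees")
  th <- theta_degrees * pi / 180
  m <- N %/% 2
  phi <- 2 * pi * (seq_len(m) - 1) / m
  up <- cbind(cos(th) * cos(phi), cos(th) * sin(phi),
              rep(sin(th), m))
  dn <- cbind(up[, 1], up[, 2], -up[, 3])
  structure(list(N = as.integer(N), theta_degrees = theta_degrees,
                 directions = rbind(up, dn)),
            class = "FiberSet")
}

#' @export
print.FiberSet <- function(x, ...) {
  cat("<FiberSet> N =", x$N, " elevation =", x$theta_degrees, "deg\n")
  invisible(x)
}

#' Fiber stretches under a deformation gradient
#'
#' Fiber stretch of each reference direction \code{a}: \code{|F a|}. Fibers
#' are referred to the swollen reference configuration, so they carry no
#' osmotic pre-stretch (see the methods vignette for the rationale).
#'
#' @param F 3x3 deformation gradient (from the swollen reference).
#' @param directions N x 3 matrix of unit reference directions, or a
#'   \code{\link{make_fiber_set}} object.
#' @return numeric vector of N stretches.
#' @export
fiber_stretch <- function(F, directions) {
  if (inherits(directions, "FiberSet")) directions <- directions$directions
  La <- directions %*% t(F)            # row i = (F a_i)^T
  sqrt(rowSums(La * La))
}
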