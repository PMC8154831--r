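# Structured mixed-interpolation meshes: 27-node hexahedra (3-D) and 9-node
# quadrilaterals (axisymmetric), displacement quadratic, fluid chemical
# potential linear on the corner nodes.

# node positions of a quadratic grid along one axis given cell breaks
quad_axis_nodes <- function(breaks) {
  n <- length(breaks) - 1L
  out <- numeric(2L * n + 1L)
  out[seq(1L, 2L * n + 1L, by = 2L)] <- breaks
  out[seq(2L, 2L * n, by = 2L)] <- (breaks[-1] + breaks[-(n + 1L)]) / 2
  out
}

new_poromesh <- function(nodes, elems, connM, mu_node_ids, layer,
                         layer_names, sets, dim, meta = list(),
                         edge_sets = list()) {
  structure(list(nodes = nodes, elems = elems, connM = connM,
                 mu_node_ids = mu_node_ids, layer = as.integer(layer),
                 layer_names = layer_names, sets = sets, dim = dim,
                 meta = meta, edge_sets = edge_sets),
            class = "PoroMesh")
}

#' @export
print.PoroMesh <- function(x, ...) {
  cat("<PoroMesh>", if (x$dim == 3) "3-D hexahedral" else
      "axisymmetric quadrilateral", "\n")
  cat("  nodes:", nrow(x$nodes), "  elements:", nrow(x$elems),
      "  mu-nodes:", length(x$mu_node_ids), "\n")
  cat("  layers:", paste(x$layer_names, collapse = ", "), "\n")
  invisible(x)
}

#' Structured hexahedral mesh for the uniaxial tension domain
#'
#' Rectangular cuboid of \code{Lx x Ly x Lz} mm (default 1 x 2.5 x 2, the
#' quarter-symmetric uniaxial domain), meshed with 27-node hexahedra. The
#' stack is laid out along z with the first layer at the top; through-
#' thickness element counts follow \code{nz_layers} (one entry per layer,
#' top to bottom; default 1 for Epi, 1 for PD and 5 for a single remaining
#' layer, which together with \code{nx = 6, ny = 6} gives the default
#' resolution of 252 elements).
#'
#' @param stack a \code{\link{layer_stack}}; thicknesses must sum to
#'   \code{Lz}.
#' @param nx,ny in-plane element counts (x = loading direction).
#' @param nz_layers integer vector of through-thickness element counts per
#'   layer (top to bottom).
#' @param Lx,Ly domain dimensions in mm.
#' @return a \code{PoroMesh} with node sets \code{xmin, xmax, ymin, ymax,
#'   zmin, zmax} and \code{origin} (the node at (0, 0, 0)).
#' @export
build_uniaxial_mesh <- function(stack, nx = 6, ny = 6, nz_layers = NULL,
                                Lx = 1, Ly = 2.5) {
  stopifnot(inherits(stack, "LayerStack"))
  nlay <- length(stack$layers)
  th <- vapply(stack$layers, `[[`, 0, "thickness")
  Lz <- sum(th)
  if (is.null(nz_layers)) {
    nz_layers <- rep(1L, nlay)
    nz_layers[nlay] <- 5L        # refine the thick bottom layer
    if (nlay == 1L) nz_layers <- 7L
  }
  if (length(nz_layers) != nlay)
    stop("build_uniaxial_mesh: nz_layers must have one entry per layer")
  # z breaks bottom -> top; layers are given top -> bottom
  zb <- 0
  ztag <- integer(0)
  for (l in rev(seq_len(nlay))) {
    z0 <- zb[length(zb)]
    zb <- c(zb, z0 + th[l] / nz_layers[l] * seq_len(nz_layers[l]))
    ztag <- c(ztag, rep(l, nz_layers[l]))
  }
  xb <- seq(0, Lx, length.out = nx + 1)
  yb <- seq(0, Ly, length.out = ny + 1)
  xs <- quad_axis_nodes(xb); ys <- quad_axis_nodes(yb)
  zs <- quad_axis_nodes(zb)
  nxn <- length(xs); nyn <- length(ys); nzn <- length(zs)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  gid <- function(i, j, k) 1L + i + nxn * (j + nyn * k)  # 0-based i,j,k
  nz <- length(zb) - 1L
  nel <- nx * ny * nz
  elems <- matrix(0L, nel, 27)
  connM <- matrix(0L, nel, 8)
  layer <- integer(nel)
  # mu nodes: even grid indices
  is_corner <- outer(outer((seq_len(nxn) - 1L) %% 2L == 0L,
                           (seq_len(nyn) - 1L) %% 2L == 0L, "&"),
                     (seq_len(nzn) - 1L) %% 2L == 0L, "&")
  mu_node_ids <- which(as.vector(is_corner))
  mu_of <- integer(nrow(nodes)); mu_of[mu_node_ids] <- seq_along(mu_node_ids)
  e <- 0L
  for (cz in 0:(nz - 1L)) for (cy in 0:(ny - 1L)) for (cx in 0:(nx - 1L)) {
    e <- e + 1L
    loc <- integer(27)
    for (c in 0:2) for (b in 0:2) for (a in 0:2)
      loc[1L + a + 3L * b + 9L * c] <- gid(2L * cx + a, 2L * cy + b,
                                           2L * cz + c)
    elems[e, ] <- loc
    cc <- integer(8)
    for (c in c(0L, 2L)) for (b in c(0L, 2L)) for (a in c(0L, 2L))
      cc[1L + a %/% 2L + 2L * (b %/% 2L) + 4L * (c %/% 2L)] <-
        mu_of[gid(2L * cx + a, 2L * cy + b, 2L * cz + c)]
    connM[e, ] <- cc
    layer[e] <- ztag[cz + 1L]
  }
  tolg <- 1e-9
  sets <- list(
    xmin = which(abs(nodes[, 1]) < tolg),
    xmax = which(abs(nodes[, 1] - Lx) < tolg),
    ymin = which(abs(nodes[, 2]) < tolg),
    ymax = which(abs(nodes[, 2] - Ly) < tolg),
    zmin = which(abs(nodes[, 3]) < tolg),
    zmax = which(abs(nodes[, 3] - Lz) < tolg),
    origin = which(abs(nodes[, 1]) < tolg & abs(nodes[, 2]) < tolg &
                   abs(nodes[, 3]) < tolg))
  new_poromesh(nodes, elems, connM, mu_node_ids, layer,
               names(stack$layers), sets, dim = 3,
               meta = list(Lx = Lx, Ly = Ly, Lz = Lz, th = th,
                           nz_layers = nz_layers))
}

# graded radial breaks refined at the probe edge r = a
radial_breaks <- function(a, R, h_edge, grow = 1.35) {
  # inward from a to 0
  hin <- h_edge; r <- a; inner <- a
  while (r > 1e-12) {
    r <- max(0, r - hin)
    inner <- c(r, inner)
    hin <- min(hin * grow, a / 4)
  }
  if (inner[2] - inner[1] < 0.4 * h_edge && length(inner) > 2)
    inner <- inner[-2]
  inner[1] <- 0
  # outward from a to R
  hout <- h_edge; r <- a; outer <- a
  while (r < R - 1e-12) {
    r <- min(R, r + hout)
    outer <- c(outer, r)
    hout <- min(hout * grow, (R - a) / 3)
  }
  if (outer[length(outer)] - outer[length(outer) - 1] < 0.4 * h_edge &&
      length(outer) > 2)
    outer <- outer[-(length(outer) - 1)]
  outer[length(outer)] <- R
  unique(c(inner, outer[-1]))
}

#' Axisymmetric mesh for the suction domain
#'
#' Meshes the (r, z) half-section with 9-node quadrilaterals, graded
#' radially so that the band around the probe edge \code{r = opening/2} is
#' refined (mesh size \code{h_edge / refine} there, growing geometrically
#' away from it). The stack is laid out along z with the first layer on
#' top; the top surface is at \code{z = sum(thicknesses)}.
#'
#' @param stack a \code{\link{layer_stack}} (top to bottom).
#' @param opening_diameter probe opening diameter (mm).
#' @param radius outer domain radius (mm); default 3.2x the opening
#'   diameter, bounded below by opening + 3 mm.
#' @param nz_layers element counts per layer (top to bottom); default one
#'   per 0.6 mm with a minimum of 1 (3 for layers thicker than 1 mm).
#' @param h_edge base radial mesh size at the probe edge (mm).
#' @param refine refinement factor: divides \code{h_edge} and multiplies
#'   all through-thickness counts.
#' @return a \code{PoroMesh} with node sets \code{axis, outer, bottom, top,
#'   top_opening} (top nodes with \code{r < opening/2}), \code{top_probe}
#'   (top nodes under the probe face) and \code{apex}; edge set
#'   \code{opening} holds the quadratic top edges inside the opening for
#'   the pressure load.
#' @export
build_suction_mesh <- function(stack, opening_diameter, radius = NULL,
                               nz_layers = NULL, h_edge = 0.35,
                               refine = 1) {
  stopifnot(inherits(stack, "LayerStack"))
  a <- opening_diameter / 2
  h_edge <- min(h_edge, opening_diameter / 6)   # resolve the dome
  if (is.null(radius)) radius <- max(3.2 * opening_diameter,
                                     opening_diameter + 3)
  if (a >= radius)
    stop("build_suction_mesh: opening radius must be below domain radius")
  nlay <- length(stack$layers)
  th <- vapply(stack$layers, `[[`, 0, "thickness")
  H <- sum(th)
  if (is.null(nz_layers))
    nz_layers <- pmax(1L, ifelse(th > 1, 3L, 1L))
  nz_layers <- pmax(1L, as.integer(round(nz_layers * refine)))
  rb <- radial_breaks(a, radius, h_edge / refine)
  zb <- 0; ztag <- integer(0)
  for (l in rev(seq_len(nlay))) {
    z0 <- zb[length(zb)]
    zb <- c(zb, z0 + th[l] / nz_layers[l] * seq_len(nz_layers[l]))
    ztag <- c(ztag, rep(l, nz_layers[l]))
  }
  rs <- quad_axis_nodes(rb); zs <- quad_axis_nodes(zb)
  nrn <- length(rs); nzn <- length(zs)
  nodes <- as.matrix(expand.grid(r = rs, z = zs))
  dimnames(nodes) <- NULL
  gid <- function(i, k) 1L + i + nrn * k
  nr <- length(rb) - 1L; nz <- length(zb) - 1L
  nel <- nr * nz
  elems <- matrix(0L, nel, 9)
  connM <- matrix(0L, nel, 4)
  layer <- integer(nel)
  is_corner <- outer((seq_len(nrn) - 1L) %% 2L == 0L,
                     (seq_len(nzn) - 1L) %% 2L == 0L, "&")
  mu_node_ids <- which(as.vector(is_corner))
  mu_of <- integer(nrow(nodes)); mu_of[mu_node_ids] <- seq_along(mu_node_ids)
  e <- 0L
  for (cz in 0:(nz - 1L)) for (cr in 0:(nr - 1L)) {
    e <- e + 1L
    loc <- integer(9)
    for (b in 0:2) for (a2 in 0:2)
      loc[1L + a2 + 3L * b] <- gid(2L * cr + a2, 2L * cz + b)
    elems[e, ] <- loc
    cc <- integer(4)
    for (b in c(0L, 2L)) for (a2 in c(0L, 2L))
      cc[1L + a2 %/% 2L + 2L * (b %/% 2L)] <-
        mu_of[gid(2L * cr + a2, 2L * cz + b)]
    connM[e, ] <- cc
    layer[e] <- ztag[cz + 1L]
  }
  tolg <- 1e-9
  top <- which(abs(nodes[, 2] - H) < tolg)
  sets <- list(
    axis = which(abs(nodes[, 1]) < tolg),
    outer = which(abs(nodes[, 1] - radius) < tolg),
    bottom = which(abs(nodes[, 2]) < tolg),
    top = top,
    top_opening = top[nodes[top, 1] < a - 1e-9],
    top_probe = top[nodes[top, 1] >= a - 1e-9],
    apex = which(abs(nodes[, 1]) < tolg & abs(nodes[, 2] - H) < tolg))
  # quadratic top edges fully inside the opening
  ktop <- nzn - 1L
  nedge_r <- (nrn - 1L) %/% 2L
  edges <- list()
  for (ce in 0:(nedge_r - 1L)) {
    ids <- c(gid(2L * ce, ktop), gid(2L * ce + 1L, ktop),
             gid(2L * ce + 2L, ktop))
    if (max(nodes[ids, 1]) <= a + 1e-9)
      edges[[length(edges) + 1L]] <- ids
  }
  edge_sets <- list(opening = do.call(rbind, edges))
  new_poromesh(nodes, elems, connM, mu_node_ids, layer,
               names(stack$layers), sets, dim = 2,
               meta = list(radius = radius, H = H, th = th,
                           opening = opening_diameter, a = a,
                           nz_layers = nz_layers),
               edge_sets = edge_sets)
}
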