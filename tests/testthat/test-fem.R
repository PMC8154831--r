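# Finite-element verification on small meshes: exact rest equilibrium,
# patch-test agreement with the material-point driver, conservation and
# equilibrium checks, and the post-processors on fabricated histories.

test_that("the swollen multilayer mesh is in exact equilibrium at rest", {
  st <- skin_stack(2)
  mesh <- build_uniaxial_mesh(st, nx = 2, ny = 2, nz_layers = c(1, 1, 2))
  bcs <- list(
    u = list(bc_dirichlet(mesh$sets$xmin, 1, 0),
             bc_dirichlet(mesh$sets$xmax, 1, 0),
             bc_dirichlet(mesh$sets$ymin, 2, 0),
             bc_dirichlet(mesh$sets$origin, 3, 0)),
    mu = intersect(mesh$mu_node_ids, union(mesh$sets$ymax,
                                           mesh$sets$zmin)))
  h <- solve_transient(mesh, st, bcs, times = c(10, 1000))
  expect_equal(max(abs(h$U[[2]])), 0)
  expect_lt(max(abs(h$Ru[[2]])), 1e-12)
  expect_equal(h$newton, c(1L, 1L))     # converged without any update
})

test_that("homogeneous FE deformation matches the point driver (patch)", {
  p <- tab1$RD
  st <- mono_stack(p, 1)
  mesh <- build_uniaxial_mesh(st, nx = 2, ny = 2, nz_layers = 2,
                              Lx = 1, Ly = 1)
  rate <- 1e-3
  # drive all three displacement components homogeneously from the point
  # driver solution so the FE state is spatially uniform, then compare
  # reaction tension; drained boundaries everywhere
  bcs <- list(
    u = list(bc_dirichlet(mesh$sets$xmin, 1, 0),
             bc_dirichlet(mesh$sets$xmax, 1, function(t) rate * t),
             bc_dirichlet(mesh$sets$ymin, 2, 0),
             bc_dirichlet(mesh$sets$zmin, 3, 0)),
    mu = mesh$mu_node_ids)               # mu = 0 everywhere: drained
  times <- seq(2.5, 100, by = 2.5)
  h <- solve_transient(mesh, st, bcs, times = times)
  Tfem <- reaction_force(h, mesh$sets$xmax, 1) / mesh$meta$Ly
  cv <- run_point(p, rate = rate, lambda_max = 1.105, dt = 2.5,
                  thickness = 1)
  Tpt <- stats::approx(cv$lambda1, cv$T, xout = 1 + rate * times)$y
  expect_lt(max(abs(Tfem - Tpt) / pmax(abs(Tpt), 1e-4)), 0.01)
})

test_that("fluid mass is conserved with impermeable boundaries", {
  st <- skin_stack(2)
  mesh <- build_uniaxial_mesh(st, nx = 2, ny = 2, nz_layers = c(1, 1, 2))
  rate <- 2e-3
  bcs <- list(
    u = list(bc_dirichlet(mesh$sets$xmin, 1, 0),
             bc_dirichlet(mesh$sets$xmax, 1, function(t) rate * t),
             bc_dirichlet(mesh$sets$ymin, 2, 0),
             bc_dirichlet(mesh$sets$origin, 3, 0)),
    mu = integer(0))                     # no drainage anywhere
  h <- solve_transient(mesh, st, bcs, times = seq(5, 25, by = 5))
  V <- fluid_volume(h)
  V0 <- sum(h$dVgp)
  expect_true(all(abs(V - V0) / V0 < 1e-8))
})

test_that("reactions balance the applied load (global equilibrium)", {
  st <- skin_stack(2)
  mesh <- build_uniaxial_mesh(st, nx = 2, ny = 2, nz_layers = c(1, 1, 2))
  rate <- 1e-3
  bcs <- list(
    u = list(bc_dirichlet(mesh$sets$xmin, 1, 0),
             bc_dirichlet(mesh$sets$xmax, 1, function(t) rate * t),
             bc_dirichlet(mesh$sets$ymin, 2, 0),
             bc_dirichlet(mesh$sets$origin, 3, 0)),
    mu = intersect(mesh$mu_node_ids, union(mesh$sets$ymax,
                                           mesh$sets$zmin)))
  h <- solve_transient(mesh, st, bcs, times = c(20, 40, 60))
  Rplus <- reaction_force(h, mesh$sets$xmax, 1)
  Rminus <- reaction_force(h, mesh$sets$xmin, 1)
  expect_lt(max(abs(Rplus + Rminus) / abs(Rplus)), 1e-6)
  # per-layer tensions sum to the total applied tension
  Tsum <- Reduce(`+`, lapply(names(st$layers), function(nm)
    layer_tension(h, nm)$T))
  expect_equal(Tsum, Rplus / mesh$meta$Ly, tolerance = 1e-6)
  # at lambda = 1 (t -> 0) every layer tension starts from zero
  lt <- layer_tension(h, "RD")
  expect_equal(lt$lambda, 1 + rate * h$times, tolerance = 1e-12)
})

test_that("apparent stretches and deflection read rigid motion correctly", {
  st <- skin_stack(2)
  mesh <- build_uniaxial_mesh(st, nx = 2, ny = 2, nz_layers = c(1, 1, 2))
  nn <- nrow(mesh$nodes)
  # rigid translation
  Ut <- matrix(rep(c(0.3, -0.2, 0.5), each = nn), nn, 3)
  h <- fake_history(mesh, list(Ut), st)
  attr(h, "lambda") <- 1
  app <- apparent_stretches(h)
  expect_equal(app$lambda2a, 1, tolerance = 1e-12)
  expect_equal(app$lambda3a, 1, tolerance = 1e-12)
  expect_equal(deflection_metric(h)$w, 0, tolerance = 1e-12)
  # prescribed homogeneous diagonal stretch
  Uh <- cbind(0.2 * mesh$nodes[, 1], -0.1 * mesh$nodes[, 2],
              -0.2 * mesh$nodes[, 3])
  h2 <- fake_history(mesh, list(Uh), st)
  attr(h2, "lambda") <- 1.2
  app2 <- apparent_stretches(h2)
  expect_equal(app2$lambda2a, 0.9, tolerance = 1e-12)
  expect_equal(app2$lambda3a, 0.8, tolerance = 1e-12)
})

test_that("fluid particles follow the prescribed kinematics", {
  st <- skin_stack(2)
  mesh <- build_uniaxial_mesh(st, nx = 2, ny = 2, nz_layers = c(1, 1, 2))
  ngp <- 27L
  nq <- nrow(mesh$elems) * ngp
  h <- fake_history(mesh, list(matrix(0, nrow(mesh$nodes), 3)), st,
                    times = 2)
  h$Xgp0 <- matrix(0.5, nq, 3)
  h$Ugp <- list(matrix(0, nq, 3))
  h$Gmu <- list(matrix(0, nq, 3))
  h$Kgp <- list(rep(1, nq))
  seeds <- rbind(c(0.5, 1, 1), c(0.2, 2, 0.5))
  # zero flux, zero solid velocity: stationary
  tr <- trace_fluid_particles(h, seeds)
  expect_equal(tr$x1[tr$t == 2], seeds[, 1])
  expect_equal(tr$x3[tr$t == 2], seeds[, 3])
  # uniform flux q = -k grad(mu), phi_f from J = 1: dx = q / phi_f * dt
  h$Gmu <- list(matrix(rep(c(-0.1, 0, 0.05), each = nq), nq, 3))
  tr2 <- trace_fluid_particles(h, seeds)
  phi_f <- 1 - 0.3
  expect_equal(tr2$x1[tr2$t == 2] - seeds[, 1],
               rep(0.1 / phi_f * 2, 2), tolerance = 1e-12)
  expect_equal(tr2$x3[tr2$t == 2] - seeds[, 3],
               rep(-0.05 / phi_f * 2, 2), tolerance = 1e-12)
})
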