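test_that("strain energy vanishes in the zero-energy state and splits", {
  p <- tab1$RD
  se <- strain_energy(diag(3), p, rd_fibers, J0 = 1)
  expect_equal(se$Psi_s, 0, tolerance = 1e-15)
  expect_equal(se$g_m, 0, tolerance = 1e-15)
  # equibiaxial in-plane compression: all fiber stretches < 1, fiber terms
  # vanish exactly (tension-only fibers)
  F <- diag(c(0.9, 0.9, 1.0))
  se <- strain_energy(F, p, rd_fibers, J0 = 1)
  expect_identical(se$g_fe, 0)
  expect_identical(se$g_fd, 0)
})

test_that("strain energy matches an independent term-by-term evaluation", {
  p <- tab1$RD
  J0 <- 1
  F <- diag(c(1.1, 1, 1))
  # independent scalar evaluation of the energy terms
  gm <- p$m1 * (sum(diag(F %*% t(F))) - 3) +
    p$m1 / p$m2 * (det(F)^(-2 * p$m2) - 1)
  lam <- apply(rd_fibers$directions, 1, function(a) sqrt(sum((F %*% a)^2)))
  gfe <- p$m_fe / p$m_4e * mean(pmax(lam - 1, 0)^(2 * p$m_4e))
  gfd <- p$m_fd / p$m_4d * mean(pmax(lam - 1, 0)^(2 * p$m_4d))
  psi <- p$phi_s_ref * p$mu0 / (2 * p$q) * (exp(p$q * (gm + gfe + gfd)) - 1)
  got <- strain_energy(F, p, rd_fibers, J0 = J0,
                       lambda_r = rep(1, rd_fibers$N))
  expect_equal(got$g_m, gm, tolerance = 1e-13)
  expect_equal(got$g_fe, gfe, tolerance = 1e-13)
  expect_equal(got$g_fd, gfd, tolerance = 1e-13)
  expect_equal(got$Psi_s, psi, tolerance = 1e-13)
})

test_that("analytic solid stress equals the finite-difference gradient", {
  set.seed(7)
  p <- tab1$RD
  for (rep in 1:20) {
    F <- random_F(0.08)
    J0 <- runif(1, 1, 2.5)
    lr <- runif(rd_fibers$N, 1, 1.08)
    P_fd <- matrix(0, 3, 3)
    h <- 1e-6
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P_fd[i, j] <- (strain_energy(Fp, p, rd_fibers, J0, lr)$Psi_s -
                     strain_energy(Fm, p, rd_fibers, J0, lr)$Psi_s) /
        (2 * h)
    }
    sig_fd <- P_fd %*% t(F) / det(F)
    sig <- solid_stress(F, p, rd_fibers, J0, lr)
    expect_lt(max(abs(sig - sig_fd)) / max(abs(sig)), 1e-5)
    expect_equal(sig, t(sig), tolerance = 1e-12)
  }
})

test_that("strain energy is objective under rotations", {
  set.seed(11)
  p <- tab1$PD
  fib <- make_fiber_set(p$theta, 16L)
  for (rep in 1:10) {
    F <- random_F(0.1)
    A <- matrix(rnorm(9), 3, 3)
    Q <- qr.Q(qr(A))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    e1 <- strain_energy(F, p, fib, J0 = 1.4)$Psi_s
    e2 <- strain_energy(Q %*% F, p, fib, J0 = 1.4)$Psi_s
    expect_equal(e1, e2, tolerance = 1e-10)
  }
})

test_that("a fiber-free material responds in-plane isotropically", {
  F1 <- diag(c(1.2, 0.95, 0.9))
  F2 <- diag(c(0.95, 1.2, 0.9))
  fib <- make_fiber_set(0, 8L)
  s1 <- solid_stress(F1, iso_params, fib, J0 = 1.2)
  s2 <- solid_stress(F2, iso_params, fib, J0 = 1.2)
  expect_equal(s1[1, 1], s2[2, 2], tolerance = 1e-12)
  expect_equal(s1[2, 2], s2[1, 1], tolerance = 1e-12)
})

test_that("osmotic pressure follows the closed form and monotonicity", {
  p <- tab1$RD
  expect_equal(osmotic_pressure(1, p), p$beta0)   # Delta_pi(1) = beta0
  expect_equal(osmotic_pressure(1.7, p), p$beta0 / 4)  # (0.7/1.4)^2
  p0 <- p; p0$beta0 <- 0
  expect_equal(osmotic_pressure(c(0.8, 1, 3), p0), c(0, 0, 0))
  J <- seq(0.35, 4, by = 0.05)
  expect_true(all(diff(osmotic_pressure(J, p)) < 0))
  expect_error(osmotic_pressure(0.3, p), "phi_s_ref")
})

test_that("permeability follows the closed form", {
  p <- tab1$RD
  expect_equal(permeability(1, p), p$k0)
  expect_equal(permeability(1.7, p), 4 * p$k0)   # (1.4/0.7)^2
  expect_lt(permeability(0.3 + 1e-9, p), 1e-15)
  expect_error(permeability(0.2, p), "phi_s_ref")
})

test_that("Darcy flux is antiparallel to the potential gradient", {
  expect_equal(darcy_flux(c(0, 0, 0), 5), c(0, 0, 0))
  expect_equal(sqrt(sum(darcy_flux(c(1, 0, 0), 0.7)^2)), 0.7)
  g <- c(0.3, -1.2, 2)
  expect_equal(darcy_flux(g, 2.5), -2.5 * g)
})

test_that("compiled and reference constitutive paths agree", {
  set.seed(3)
  p <- tab1$RD
  for (rep in 1:5) {
    F <- random_F(0.08)
    lr <- runif(16, 1, 1.06)
    expect_equal(
      solid_stress(F, p, rd_fibers, 1.5, lr),
      skinphase:::cpp_solid_stress(F, unclass(p), rd_fibers$directions,
                                   1.5, lr),
      tolerance = 1e-12)
    expect_equal(
      strain_energy(F, p, rd_fibers, 1.5, lr)$Psi_s,
      skinphase:::cpp_strain_energy(F, unclass(p), rd_fibers$directions,
                                    1.5, lr),
      tolerance = 1e-12)
    lrR <- evolve_dissipative_fibers(F, rep(1, 16), p, rd_fibers, 1.5, 50)
    lrC <- skinphase:::cpp_evolve_lr(F, rep(1, 16), unclass(p),
                                     rd_fibers$directions, 1.5, 50)
    expect_equal(lrR, as.numeric(lrC), tolerance = 1e-9)
  }
})

test_that("dissipative fibers relax towards the applied stretch", {
  p <- tab1$PD   # fastest healthy rate factor
  fib <- make_fiber_set(p$theta, 16L)
  F <- diag(c(1.15, 0.95, 0.95))
  lf <- fiber_stretch(F, fib)
  # k_fd = 0: no evolution at all
  p0 <- p; p0$k_fd <- 0
  expect_identical(evolve_dissipative_fibers(F, rep(1, 16), p0, fib, 1, 10),
                   rep(1, 16))
  # one small step changes lambda_r by O(dt)
  d1 <- max(abs(evolve_dissipative_fibers(F, rep(1, 16), p, fib, 1,
                                          1e-3) - 1))
  d2 <- max(abs(evolve_dissipative_fibers(F, rep(1, 16), p, fib, 1,
                                          2e-3) - 1))
  expect_lt(d1, 1e-4)
  expect_gt(d2 / d1, 1.8)
  expect_lt(d2 / d1, 2.2)
  # under a hold, lambda_r grows monotonically towards lambda_f, so the
  # branch stretch decays to 1 and the dissipative energy vanishes
  lr <- rep(1, 16)
  g0 <- strain_energy(F, p, fib, 1, lr)$g_fd
  gprev <- g0
  for (s in 1:40) {
    lr2 <- evolve_dissipative_fibers(F, lr, p, fib, 1, 50)
    expect_true(all(lr2 >= lr - 1e-12))
    # relaxed stretch approaches lambda_f from below; compressed fibers
    # (lambda_f < 1) keep lambda_r = 1
    expect_true(all(lr2 <= pmax(lf, 1) + 1e-12))
    lr <- lr2
    g <- strain_energy(F, p, fib, 1, lr)$g_fd
    expect_lte(g, gprev + 1e-15)
    gprev <- g
  }
  # the dissipative contribution has relaxed away (algebraic tail)
  expect_lt(gprev, 2e-3 * g0)
})

test_that("backward-Euler fiber update matches an ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- tab1$PD
  fib <- make_fiber_set(p$theta, 16L)
  F <- diag(c(1.12, 0.96, 0.97))
  # independent integration of d(lambda_r)/dt = k_fd f_fd lambda_r at
  # fixed F with a high-order adaptive scheme
  rhs <- function(t, y, parms) {
    lf <- fiber_stretch(F, fib)
    g <- strain_energy(F, p, fib, 1, y)  # g terms with lambda_r = y
    gg <- g$g_m + g$g_fe + g$g_fd
    f <- p$phi_s_ref * p$mu0 / 2 * exp(p$q * gg) *
      2 * p$m_fd / fib$N * pmax(lf / y - 1, 0)^(2 * p$m_4d - 1)
    list(p$k_fd * f * y)
  }
  t_end <- 200
  ode <- deSolve::ode(y = rep(1, 16), times = c(0, t_end), func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  oracle <- as.numeric(ode[2, -1])
  # backward Euler with small steps converges to the same state
  lr <- rep(1, 16)
  nstep <- 400
  for (s in 1:nstep)
    lr <- evolve_dissipative_fibers(F, lr, p, fib, 1, t_end / nstep)
  expect_equal(lr, oracle, tolerance = 2e-4)
})
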