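test_that("tangent stiffness reproduces analytic derivatives", {
  lam <- seq(1, 1.3, by = 0.002)
  lin <- data.frame(lambda1 = lam, T = 3.5 * (lam - 1))
  for (l in c(1.005, 1.1, 1.25))
    expect_equal(tangent_stiffness(lin, l, thickness = 2), 3.5 / 2,
                 tolerance = 1e-10)
  quad <- data.frame(lambda1 = lam, T = (lam - 1)^2)
  expect_equal(tangent_stiffness(quad, 1.1, thickness = 1), 0.2,
               tolerance = 1e-3)
  expect_error(tangent_stiffness(lin, 1.5, thickness = 1), "range")
})

test_that("drained uniaxial response is J-shaped and laterally contracting", {
  cv <- run_point(tab1$RD, rate = 1e-3, lambda_max = 1.2, dt = 1)
  expect_true(all(diff(cv$T) > -1e-12))            # monotone nondecreasing
  # J-shape: the tangent stiffness grows across the stretch anchors
  E <- vapply(c(1.005, 1.10, 1.19), function(l)
    tangent_stiffness(cv, l, thickness = 1.7), 0)
  expect_true(all(diff(E) > 0))
  expect_lt(tail(cv$lambda2, 1), 1)
  expect_lt(tail(cv$lambda3, 1), 1)
  expect_lt(tail(cv$J, 1), 1)                      # volume loss
  expect_equal(cv$T[1], 0, tolerance = 1e-8)
  # transverse isotropy is broken by the fibers: in-plane and out-of-plane
  # lateral stretches differ
  expect_gt(abs(tail(cv$lambda2, 1) - tail(cv$lambda3, 1)), 1e-3)
})

test_that("undrained response conserves volume and is stiffer", {
  p <- tab1$RD
  und <- run_point(p, rate = 0.05, lambda_max = 1.12, drainage = "undrained")
  expect_true(all(abs(und$J - 1) < 1e-6))          # mixture incompressible
  dr <- run_point(p, rate = 0.05, lambda_max = 1.12, drainage = "drained")
  iT <- function(cv, l) stats::approx(cv$lambda1, cv$T, xout = l)$y
  for (l in c(1.04, 1.08, 1.11))
    expect_gt(iT(und, l), iT(dr, l))
})

test_that("drained curves without fiber dissipation are rate independent", {
  p <- tab1$Epi; p$k_fd <- 0      # elastic solid + equilibrated fluid
  c1 <- run_point(p, rate = 1e-4, lambda_max = 1.1, dt = 25)
  c2 <- run_point(p, rate = 5e-5, lambda_max = 1.1, dt = 50)
  T1 <- tail(c1$T, 1); T2 <- tail(c2$T, 1)
  expect_lt(abs(T1 - T2) / abs(T2), 0.01)
})

test_that("time-step refinement converges", {
  p <- tab1$PD
  c1 <- run_point(p, rate = 1e-3, lambda_max = 1.15, dt = 2.5)
  c2 <- run_point(p, rate = 1e-3, lambda_max = 1.15, dt = 1.25)
  expect_lt(abs(tail(c1$T, 1) - tail(c2$T, 1)) / abs(tail(c2$T, 1)),
            0.005)
})

test_that("relaxation holds the stretch and decays the tension", {
  p <- tab1$RD
  cv <- run_relaxation(p, rate = 0.05, peak_tension = 0.15, hold = 200)
  ramp <- cv[cv$T < 0.15 & cv$t < cv$t[which(cv$T >= 0.15)[1]], ]
  hold <- cv[cv$t > cv$t[which(cv$T >= 0.15)[1]], ]
  expect_gt(nrow(hold), 5)
  expect_true(all(diff(hold$lambda1) == 0))
  expect_true(all(diff(hold$T) < 0))               # strictly decreasing
  # zero hold ends at the peak
  cv0 <- run_relaxation(p, rate = 0.05, peak_tension = 0.15, hold = 0)
  expect_gte(tail(cv0$T, 1), 0.15)
  expect_equal(nrow(cv0), which(cv0$T >= 0.15)[1])
})

test_that("without dissipative mechanisms a drained hold does not decay", {
  p <- tab1$RD; p$k_fd <- 0
  cv <- run_relaxation(p, rate = 1e-4, peak_tension = 0.05, hold = 500)
  hold <- cv[cv$t > cv$t[which(cv$T >= 0.05)[1]], ]
  expect_lt(max(abs(hold$T - hold$T[1])), 1e-6)
})
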