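# Protocol runners on deliberately coarse meshes (the full-resolution runs
# are exercised by the acceptance suite).

test_that("FE relaxation ramps to the peak tension and then decays", {
  st <- skin_stack(2)
  res <- run_uniaxial_relaxation(stack = st, rate = 0.05,
                                 peak_tension = 0.06, hold = 120,
                                 dl_step = 0.01, nx = 2, ny = 2,
                                 nz_layers = c(1, 1, 2))
  d <- res$decay
  k_peak <- which(d$t == res$summary$t_peak)
  expect_gte(d$T[k_peak], 0.06)
  hold <- d[d$t > res$summary$t_peak, ]
  expect_true(all(diff(hold$lambda) == 0))
  expect_true(all(diff(hold$T) < 0))
  expect_gt(res$summary$decay_fraction, 0.1)   # pronounced relaxation
})

test_that("zero suction pressure produces zero apex displacement", {
  res <- run_suction(opening = 2, protocol = "linear", p_max = 0,
                     t_ramp = 2, t_hold = 2, t_recover = 2, dt = 2,
                     h_edge = 0.5, radius = 6)
  expect_true(all(abs(res$apex$apex) < 1e-10))
  expect_true(all(abs(res$thickness$skin - 1) < 1e-10))
})

test_that("suction apex displacement grows with pressure during loading", {
  res <- run_suction(opening = 2, protocol = "linear", p_max = 0.015,
                     t_ramp = 10, t_hold = 5, t_recover = 5, dt = 2.5,
                     h_edge = 0.35, radius = 6)
  load_phase <- res$apex$apex[res$apex$t <= 10]
  expect_true(all(diff(load_phase) > 0))
  expect_gt(max(res$apex$apex), 0.05)
  # thickness ratios stay physical throughout
  expect_true(all(is.finite(as.matrix(res$thickness[, -1]))))
  expect_true(all(as.matrix(res$thickness[, -1]) > 0.3))
})

test_that("fixture curves are exact, reproducible and correctly noisy", {
  p <- tab1$Epi
  fx0 <- generate_fixture_curves(p, noise_sd = 0, n = 30,
                                 lambda_max = 1.15)
  cv <- run_point(p, rate = 1e-3, lambda_max = 1.15)
  expect_equal(fx0$T,
               stats::approx(cv$lambda1, cv$T, xout = fx0$lambda)$y,
               tolerance = 1e-12)
  f1 <- generate_fixture_curves(p, noise_sd = 1e-3, seed = 7, n = 40,
                                lambda_max = 1.15)
  f2 <- generate_fixture_curves(p, noise_sd = 1e-3, seed = 7, n = 40,
                                lambda_max = 1.15)
  expect_identical(f1, f2)
  expect_error(generate_fixture_curves(p, noise_sd = -1), "noise_sd")
  # sample SD of the injected noise matches within 3 standard errors
  sd0 <- 5e-3
  fbig <- generate_fixture_curves(p, noise_sd = sd0, seed = 3, n = 1e4,
                                  lambda_max = 1.15)
  resid <- fbig$T - stats::approx(cv$lambda1, cv$T, xout = fbig$lambda)$y
  se <- sd0 / sqrt(2 * (1e4 - 1))
  expect_lt(abs(stats::sd(resid) - sd0), 3 * se)
})

test_that("parameter fitting recovers generating values on clean data", {
  p <- tab1$RD
  target <- generate_fixture_curves(p, noise_sd = 0, n = 40,
                                    lambda_max = 1.2)
  start <- p
  start$mu0 <- p$mu0 * 1.6
  start$m_fe <- p$m_fe * 0.6
  ft <- fit_parameters(target, start, free = c("mu0", "m_fe"))
  expect_lt(abs(ft$estimate[["mu0"]] - p$mu0) / p$mu0, 0.05)
  expect_lt(abs(ft$estimate[["m_fe"]] - p$m_fe) / p$m_fe, 0.05)
  # single-parameter fit on clean data is essentially exact
  start2 <- p; start2$mu0 <- p$mu0 * 1.3
  ft2 <- fit_parameters(target, start2, free = "mu0")
  expect_lt(ft2$residual_norm, 1e-8)
  expect_error(fit_parameters(data.frame(lambda = numeric(0),
                                         T = numeric(0)), p), "empty")
})

test_that("protocol results export to CSV", {
  p <- tab1$Epi
  res <- structure(list(protocol = "x", config = list(),
                        tensions = list(Epi = data.frame(t = 1, lambda = 1,
                                                         T = 0)),
                        moduli = matrix(1, 1, 1,
                                        dimnames = list("Epi", "l")),
                        summary = list(a = 1)),
                   class = "ProtocolResult")
  d <- file.path(tempdir(), "resout")
  export_result_csv(res, d)
  expect_true(file.exists(file.path(d, "tension_Epi.csv")))
  expect_true(file.exists(file.path(d, "summary.csv")))
})
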