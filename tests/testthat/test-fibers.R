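test_that("fiber sets are unit, symmetric and transversely isotropic", {
  fs <- make_fiber_set(30, 16L)
  a <- fs$directions
  expect_equal(nrow(a), 16L)
  expect_true(all(abs(sqrt(rowSums(a^2)) - 1) < 1e-12))
  # closure under azimuthal rotation by 2*pi/(N/2)
  phi <- 2 * pi / 8
  R <- rbind(c(cos(phi), -sin(phi), 0), c(sin(phi), cos(phi), 0),
             c(0, 0, 1))
  rotated <- a %*% t(R)
  match_dist <- apply(rotated, 1, function(v)
    min(sqrt(colSums((t(a) - v)^2))))
  expect_true(all(match_dist < 1e-12))
  # closure under elevation flip
  flipped <- a %*% diag(c(1, 1, -1))
  match_dist <- apply(flipped, 1, function(v)
    min(sqrt(colSums((t(a) - v)^2))))
  expect_true(all(match_dist < 1e-12))
  # structure tensor transversely isotropic about e3 (direct summation)
  M <- matrix(0, 3, 3)
  for (i in 1:16) M <- M + tcrossprod(a[i, ]) / 16
  expect_lt(abs(M[1, 1] - M[2, 2]), 1e-12)
  expect_lt(max(abs(M[upper.tri(M)])), 1e-12)
  expect_equal(M[1, 1], cos(pi / 6)^2 / 2, tolerance = 1e-12)
  expect_equal(M[3, 3], sin(pi / 6)^2, tolerance = 1e-12)
})

test_that("degenerate elevations and invalid N are handled", {
  flat <- make_fiber_set(0, 8L)
  expect_true(all(abs(flat$directions[, 3]) < 1e-15))
  vert <- make_fiber_set(90, 8L)
  expect_true(all(abs(abs(vert$directions[, 3]) - 1) < 1e-15))
  expect_error(make_fiber_set(30, 7L), "even")
  expect_error(make_fiber_set(30, 2L), "even")
})

test_that("fiber stretch equals the mapped-vector norm", {
  fs <- make_fiber_set(20, 8L)
  expect_equal(fiber_stretch(diag(3), fs), rep(1, 8))
  expect_equal(fiber_stretch(diag(c(1.3, 1, 1)), rbind(c(1, 0, 0))), 1.3)
  set.seed(42)
  F <- random_F()
  brute <- apply(fs$directions, 1, function(v) sqrt(sum((F %*% v)^2)))
  expect_equal(fiber_stretch(F, fs), brute, tolerance = 1e-14)
})
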