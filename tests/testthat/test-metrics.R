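# Cushioning and stress observables.

test_that("min_distance recovers the radius of a finely discretized circle", {
  th <- 2 * pi * (0:719) / 720
  circ <- cbind(0.05 * cos(th), 0.05 * sin(th))
  d <- min_distance(c(0, 0), circ)
  expect_equal(d, 0.05, tolerance = 1e-4)  # chord error only
  expect_equal(min_distance(circ[13, , drop = FALSE], circ), 0)
})

test_that("min_distance equals the exhaustive oracle on random instances", {
  set.seed(31)
  poly <- matrix(runif(60, -1, 1), ncol = 2)  # 30-node closed polyline
  pts <- matrix(runif(100, -1.5, 1.5), ncol = 2)
  expect_equal(min_distance(pts, poly, closed = TRUE),
               oracle_min_dist(pts, poly, closed = TRUE), tolerance = 1e-12)
  expect_equal(min_distance(pts, poly, closed = FALSE),
               oracle_min_dist(pts, poly, closed = FALSE), tolerance = 1e-12)
  expect_error(min_distance(pts, poly[1, , drop = FALSE]), "empty surface")
})

test_that("point-to-triangle distance handles the face/edge/vertex regions", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  F <- matrix(1:3, 1)
  s <- list(V = V, F = F)
  expect_equal(min_distance(matrix(c(0.2, 0.2, 0.7), 1), s), 0.7)   # face
  expect_equal(min_distance(matrix(c(-1, -1, 0), 1), s), sqrt(2))   # vertex
  expect_equal(min_distance(matrix(c(0.5, -2, 0), 1), s), 2)        # edge
  # rotation invariance
  set.seed(32)
  ang <- runif(1, 0, 2 * pi)
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  p <- matrix(c(0.3, 0.2, -0.4), 1)
  expect_equal(min_distance(p %*% t(R), list(V = V %*% t(R), F = F)),
               min_distance(p, s), tolerance = 1e-12)
})

test_that("normalized series start at exactly one and scale linearly", {
  x <- c(0.004, 0.005, 0.008, 0.002)
  n <- normalized_series(x)
  expect_identical(n[1], 1)
  expect_equal(n[3], 2)
  expect_equal(normalized_series(rep(0.37, 5)), rep(1, 5))
  expect_error(normalized_series(c(0, 1)), "zero baseline")
  df <- tibble::tibble(time = rep(0:2, 2),
                       landmark = rep(c("a", "b"), each = 3),
                       raw_m = c(2, 4, 1, 5, 5, 10))
  out <- normalized_series(df)
  expect_equal(out$normalized, c(1, 2, 0.5, 1, 1, 2))
})

test_that("von Mises reproduces the worked peak-loading example", {
  vm <- von_mises(115, 38, 9)
  expect_equal(vm, sqrt(0.5 * ((115 - 38)^2 + (38 - 9)^2 + (9 - 115)^2)))
  expect_equal(vm, 94.88, tolerance = 1e-4)
  expect_equal(von_mises(115, 38, 9, truncate = TRUE), 94)
})

test_that("von Mises is zero for hydrostatic states and sigma for uniaxial", {
  expect_equal(von_mises(7, 7, 7), 0)
  expect_equal(von_mises(42, 0, 0), 42)
})

test_that("von Mises is invariant under permutation and hydrostatic shifts", {
  set.seed(33)
  for (k in 1:25) {
    s <- rnorm(3, 0, 50)
    off <- rnorm(1, 0, 100)
    v <- von_mises(s[1], s[2], s[3])
    p <- sample(3)
    expect_equal(von_mises(s[p[1]], s[p[2]], s[p[3]]), v, tolerance = 1e-12)
    expect_equal(von_mises(s[1] + off, s[2] + off, s[3] + off), v,
                 tolerance = 1e-9)
  }
})

test_that("triaxiality reproduces the worked example and degenerate cases", {
  tt <- triaxiality(115, 38, 9)
  expect_equal(tt$mean_stress, 54)
  expect_equal(round(tt$triaxiality, 2), 0.57)
  shear <- triaxiality(10, 0, -10)
  expect_equal(shear$mean_stress, 0)
  expect_equal(shear$triaxiality, 0)
  hydro <- triaxiality(5, 5, 5)
  expect_true(is.na(hydro$triaxiality))
})

test_that("first deviatoric principal stress: worked value, hydrostatic zero, rotation invariance", {
  expect_equal(first_deviatoric_principal_stress(diag(c(115, 38, 9))), 61)
  expect_equal(first_deviatoric_principal_stress(diag(c(3, 3, 3))), 0)
  set.seed(34)
  A <- matrix(rnorm(9), 3)
  S <- A + t(A)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(first_deviatoric_principal_stress(Q %*% S %*% t(Q)),
               first_deviatoric_principal_stress(S), tolerance = 1e-9)
  expect_error(first_deviatoric_principal_stress(matrix(1:9 / 10, 3)),
               "symmetric")
})

test_that("attenuation percentages follow the definition", {
  expect_equal(attenuation_percent(10, 100), 90)
  expect_equal(attenuation_percent(5, 5), 0)
  expect_warning(a <- attenuation_percent(12, 10), "amplification")
  expect_equal(a, -20)
  expect_error(attenuation_percent(1, 0), "positive")
})
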