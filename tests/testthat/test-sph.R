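# Weakly compressible SPH operators: kernel, interpolation, continuity,
# equation of state, momentum, Shepard reinitialization, neighbor search.

test_that("cubic spline kernel has compact support and the closed-form centre", {
  ks <- kernel_spec(0.01)
  expect_equal(kernel_value(ks$support_radius, ks, 2), 0)
  expect_equal(kernel_value(0.05, ks, 2), 0)
  expect_equal(kernel_value(0, ks, 1), 2 / (3 * 0.01))
  expect_equal(kernel_value(0, ks, 2), 10 / (7 * pi * 0.01^2))
  expect_equal(kernel_value(0, ks, 3), 1 / (pi * 0.01^3))
  r <- seq(0, 0.025, by = 1e-4)
  w <- kernel_value(r, ks, 2)
  expect_true(all(w >= 0))
  expect_equal(which.max(w), 1L)
  expect_error(kernel_value(-0.001, ks), "nonnegative")
})

test_that("kernel integrates to one in 1-D, 2-D and 3-D (quadrature oracle)", {
  ks <- kernel_spec(0.013)
  i1 <- stats::integrate(function(r) cubic_w(abs(r), ks$h, 1),
                         -ks$support_radius, ks$support_radius)$value
  i2 <- stats::integrate(function(r) 2 * pi * r * cubic_w(r, ks$h, 2),
                         0, ks$support_radius)$value
  i3 <- stats::integrate(function(r) 4 * pi * r^2 * cubic_w(r, ks$h, 3),
                         0, ks$support_radius)$value
  # the same quadrature applied to the implementation
  j2 <- stats::integrate(function(r) 2 * pi * r * kernel_value(r, ks, 2),
                         0, ks$support_radius)$value
  for (v in c(i1, i2, i3, j2)) expect_lt(abs(v - 1), 1e-6)
})

test_that("kernel gradient points along the separation and matches dW/dr", {
  ks <- kernel_spec(0.01)
  dx <- matrix(c(0.006, 0.008), 1)   # r = 0.01
  g <- kernel_gradient(dx, ks)
  expect_equal(as.numeric(g), as.numeric(dx / 0.01 * cubic_dw(0.01, ks$h, 2)),
               tolerance = 1e-12)
})

test_that("Shepard-normalized interpolation reproduces constants on any cloud", {
  set.seed(42)
  ps <- lattice_particles(10, 10, 0.01, jitter = 0.002)
  q <- cbind(runif(20, 0.02, 0.07), runif(20, 0.02, 0.07))
  v <- sph_interpolate(rep(3.7, nrow(ps$pos)), q, ps, shepard = TRUE)
  expect_equal(as.numeric(v), rep(3.7, 20), tolerance = 1e-12)
})

test_that("interpolation far from all particles returns 0 with an empty flag", {
  ps <- lattice_particles(4, 4, 0.01)
  v <- sph_interpolate(seq_len(nrow(ps$pos)), c(10, 10), ps)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "empty"))
})

test_that("interpolation of a linear field matches the direct-summation oracle", {
  ps <- lattice_particles(12, 12, 0.01)
  a <- 2.5 * ps$pos[, 1] - 1.2 * ps$pos[, 2]
  q <- matrix(c(0.055, 0.055), 1)
  raw <- sph_interpolate(a, q, ps, shepard = FALSE)
  # brute-force Eq-1 sum
  w <- cubic_w(sqrt(colSums((t(ps$pos) - as.numeric(q))^2)), ps$kernel$h, 2)
  oracle <- sum(ps$mass * a / ps$rho * w)
  expect_equal(as.numeric(raw), oracle, tolerance = 1e-12)
})

test_that("continuity rate vanishes for uniform motion and isolated particles", {
  ps <- lattice_particles(6, 6, 0.01)
  ps$vel <- matrix(rep(c(0.3, -0.2), each = nrow(ps$pos)), ncol = 2)
  expect_equal(continuity_rate(ps), rep(0, nrow(ps$pos)), tolerance = 1e-14)
  lone <- particle_set(matrix(c(0, 0), 1), mass = 1,
                       material = fluid_material(1000, 10),
                       kernel = kernel_spec(0.013))
  expect_equal(continuity_rate(lone), 0)
})

test_that("two approaching particles compress: positive density rate on both", {
  m <- fluid_material(1000, 10)
  h <- 0.013
  ps <- particle_set(rbind(c(0, 0), c(0.01, 0)),
                     vel = rbind(c(0.1, 0), c(-0.1, 0)),
                     mass = 0.1, material = m, kernel = kernel_spec(h))
  got <- continuity_rate(ps)
  # hand evaluation of the two-term sum with the cubic kernel:
  # m_j (v_i - v_j) . (x_i - x_j)/r dW/dr, direction cosine -1, dW/dr < 0
  expected <- 0.1 * 0.2 * (-1) * cubic_dw(0.01, h, 2)
  expect_equal(got, rep(expected, 2), tolerance = 1e-12)
  expect_true(all(got > 0))
})

test_that("equation of state is the printed linear law", {
  m <- fluid_material(1000, 10)
  expect_equal(eos_pressure(1000, m), 0)
  expect_equal(eos_pressure(1001, m), 100)
  expect_equal(eos_pressure(1002, m) , 2 * eos_pressure(1001, m))
  expect_lt(eos_pressure(999, m), 0)  # tension permitted
  expect_error(eos_pressure(-1, m))
})

test_that("momentum rate reduces to gravity without pressure or viscosity", {
  ps <- lattice_particles(5, 5, 0.01)
  acc <- momentum_rate(ps, sph_params(alpha = 0, beta = 0,
                                      gravity = c(0, -9.81)))
  expect_equal(acc[, 1], rep(0, 25), tolerance = 1e-12)
  expect_equal(acc[, 2], rep(-9.81, 25), tolerance = 1e-12)
})

test_that("pairwise momentum forces are antisymmetric (internal momentum conserved)", {
  set.seed(7)
  ps <- lattice_particles(8, 8, 0.01, jitter = 0.002)
  ps$vel <- matrix(rnorm(128, 0, 0.1), ncol = 2)
  ps$rho <- ps$rho * runif(64, 0.99, 1.01)
  ps$p <- eos_pressure(ps$rho, ps$material)
  acc <- momentum_rate(ps, sph_params(alpha = 1, beta = 2, gravity = c(0, 0)))
  ptot <- colSums(ps$mass * acc)
  expect_lt(max(abs(ptot)), 1e-12 * max(abs(ps$mass * acc)))
})

test_that("momentum rate matches the brute-force pairwise oracle", {
  set.seed(11)
  pos <- rbind(c(0, 0), c(0.009, 0.002), c(0.004, 0.008))
  vel <- matrix(rnorm(6, 0, 0.2), 3)
  m <- fluid_material(1000, 12)
  ps <- particle_set(pos, vel = vel, mass = c(0.1, 0.12, 0.09),
                     material = m, kernel = kernel_spec(0.012),
                     rho = c(1005, 998, 1001))
  ps$p <- eos_pressure(ps$rho, m)
  pr <- sph_params(alpha = 1, beta = 2, gravity = c(0, -9.81), epsilon = 0.01)
  got <- momentum_rate(ps, pr)
  want <- oracle_sph_rates(pos, vel, ps$mass, ps$rho, ps$p, 0.012,
                           1, 2, 0.01, 12, c(0, -9.81))
  expect_equal(got, want$acc, tolerance = 1e-12)
  expect_equal(continuity_rate(ps), want$drho, tolerance = 1e-12)
})

test_that("Shepard reinitialization is exact on uniform density", {
  ps <- lattice_particles(9, 9, 0.01)
  expect_equal(shepard_density(ps), ps$rho, tolerance = 1e-12)
  # and pulls perturbed densities back towards the field implied by geometry
  set.seed(3)
  ps$rho <- ps$rho * runif(81, 0.98, 1.02)
  re <- shepard_density(ps)
  expect_lt(sd(re), sd(ps$rho))
})

test_that("cell-list neighbor search finds exactly the brute-force pairs", {
  set.seed(5)
  pos <- matrix(runif(120, 0, 0.08), ncol = 2)
  supp <- 0.015
  got <- neighbor_pairs(pos, supp)
  got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  want <- which(as.matrix(dist(pos)) < supp, arr.ind = TRUE)
  want <- want[want[, 1] < want[, 2], , drop = FALSE]
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(want))
})

test_that("isolated fluid conserves momentum and mass over 1000 steps", {
  set.seed(9)
  ps <- lattice_particles(8, 8, 0.01)
  ps$vel <- matrix(rnorm(128, 0, 0.05), ncol = 2)
  p0 <- colSums(ps$mass * ps$vel)
  m0 <- ps$mass
  out <- step_fluid(ps, sph_params(alpha = 1, beta = 2, gravity = c(0, 0)),
                    dt = 2e-5, n_steps = 1000)
  p1 <- colSums(out$mass * out$vel)
  expect_equal(p1, p0, tolerance = 1e-10)
  expect_identical(out$mass, m0)  # dynamics never mutate mass
})

test_that("artificial viscosity dissipates kinetic energy in a relaxation test", {
  set.seed(13)
  ps <- lattice_particles(8, 8, 0.01)
  ps$vel[30, ] <- c(0.5, 0.2)  # still fluid with one perturbed particle
  ke0 <- sum(0.5 * ps$mass * rowSums(ps$vel^2))
  out <- step_fluid(ps, sph_params(alpha = 1, beta = 2, gravity = c(0, 0)),
                    dt = 2e-5, n_steps = 2000)
  ke1 <- sum(0.5 * out$mass * rowSums(out$vel^2))
  expect_lt(ke1, 0.5 * ke0)
})
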