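# Viscoelastic solids: relaxation modulus, Maxwell internal-variable update,
# element assembly, explicit stepping.

one_triangle <- function(material, X = rbind(c(0, 0), c(1, 0), c(0.5, 0.9))) {
  solid_mesh(X, matrix(1:3, 1), material)
}

test_that("relaxation modulus has the closed-form limits and is monotone", {
  m <- viscoelastic_material(G_inf = 1000, G_modes = c(500, 250),
                             tau_modes = c(0.1, 1), density = 1000,
                             bulk_modulus = 1e5)
  expect_equal(relaxation_modulus(0, m), 1750)
  expect_equal(relaxation_modulus(1e6, m), 1000)
  single <- viscoelastic_material(1000, 500, 0.2, 1000, 1e5)
  expect_equal(relaxation_modulus(0.2, single), 1000 + 500 / exp(1))
  t <- seq(0, 5, by = 0.01)
  expect_true(all(diff(relaxation_modulus(t, m)) <= 0))
  expect_error(relaxation_modulus(-0.1, m), "t >= 0")
})

test_that("zero strain history gives zero stress; held strain relaxes to equilibrium", {
  m <- viscoelastic_material(1000, 800, 0.05, 1000, 1e5)
  st <- update_viscoelastic_stress(diag(0, 3), dt = 1e-3, material = m)
  expect_equal(st$sigma, matrix(0, 3, 3))
  # step deviatoric strain, then hold for t >> tau
  eps <- diag(c(0.01, -0.01, 0))
  st <- update_viscoelastic_stress(eps, dt = 1e-3, material = m)
  for (i in 1:2000) {
    st <- update_viscoelastic_stress(diag(0, 3), dt = 1e-3, st, m)
  }
  expect_equal(st$sigma, st$sigma_eq, tolerance = 1e-6)
  expect_equal(st$sigma[1, 1], 2 * 1000 * 0.01, tolerance = 1e-6)
})

test_that("step-strain response matches the hereditary integral within 1%", {
  m <- viscoelastic_material(G_inf = 2000, G_modes = 3000, tau_modes = 0.1,
                             density = 1000, bulk_modulus = 1e5)
  e0 <- 0.005
  eps <- diag(c(e0, -e0, 0))  # traceless: purely deviatoric
  run_hist <- function(dt, t_end) {
    st <- update_viscoelastic_stress(eps, dt = dt, material = m)
    times <- dt
    sig <- st$sigma[1, 1]
    while (times[length(times)] < t_end) {
      st <- update_viscoelastic_stress(diag(0, 3), dt = dt, st, m)
      times <- c(times, times[length(times)] + dt)
      sig <- c(sig, st$sigma[1, 1])
    }
    list(t = times, sig = sig)
  }
  dt <- 0.1 / 100  # tau / 100
  got <- run_hist(dt, 0.3)
  want <- 2 * relaxation_modulus(got$t, m) * e0  # sigma(t) = 2 G(t) eps0
  expect_lt(max(abs(got$sig - want) / abs(want)), 0.01)
  # convergence towards the hereditary integral as dt decreases
  coarse <- run_hist(0.1 / 25, 0.3)
  err_c <- max(abs(coarse$sig - 2 * relaxation_modulus(coarse$t, m) * e0))
  err_f <- max(abs(got$sig - want))
  expect_lt(err_f, err_c)
})

test_that("internal forces vanish for zero displacement and rigid-body motion", {
  m <- viscoelastic_material(1e4, 5e3, 0.1, 1000, 1e5)
  mesh <- one_triangle(m)
  n <- nrow(mesh$X)
  expect_equal(internal_force(mesh, matrix(0, n, 2))$force, matrix(0, n, 2))
  # rigid translation
  u_t <- matrix(rep(c(0.01, -0.02), each = n), n, 2)
  expect_equal(internal_force(mesh, u_t)$force, matrix(0, n, 2),
               tolerance = 1e-12)
  # linearized rigid rotation (skew-symmetric displacement field)
  w <- 0.01
  u_r <- cbind(-w * mesh$X[, 2], w * mesh$X[, 1])
  f <- internal_force(mesh, u_r)$force
  expect_lt(max(abs(f)), 1e-9 * m$bulk_modulus * w)
})

test_that("assembled patch of elements also passes the rigid-motion test", {
  m <- viscoelastic_material(1e4, 5e3, 0.1, 1000, 1e5)
  X <- as.matrix(expand.grid(x = seq(0, 0.03, 0.01), y = seq(0, 0.03, 0.01)))
  colnames(X) <- NULL
  tri <- NULL
  for (r in 1:3) for (cc in 1:3) {
    i <- (r - 1) * 4 + cc
    tri <- rbind(tri, c(i, i + 1, i + 5), c(i, i + 5, i + 4))
  }
  mesh <- solid_mesh(X, tri, m)
  w <- 0.02
  u <- cbind(-w * X[, 2], w * X[, 1]) + 0.005
  f <- internal_force(mesh, u)$force
  expect_lt(max(abs(f)), 1e-9)
})

test_that("uniaxial stretch of one element matches the hand-assembled stiffness", {
  m <- viscoelastic_material(G_inf = 1e4, density = 1000, bulk_modulus = 1e5)
  X <- rbind(c(0, 0), c(1, 0), c(0, 1))
  mesh <- one_triangle(m, X)
  delta <- 1e-4
  u <- rbind(c(0, 0), c(delta, 0), c(0, 0))  # exx = delta
  got <- internal_force(mesh, u)
  # hand assembly: constant-strain triangle, area 1/2
  K <- m$bulk_modulus; G <- m$G_inf
  sxx <- K * delta + 2 * G * (delta - delta / 3)
  syy <- K * delta + 2 * G * (-delta / 3)
  szz <- syy
  expect_equal(got$sigma[1, ], c(sxx, syy, szz, 0), tolerance = 1e-12)
  A <- 0.5
  dNdx <- c(-1, 1, 0); dNdy <- c(-1, 0, 1)
  f_hand <- -A * cbind(dNdx * sxx, dNdy * syy)
  expect_equal(got$force, f_hand, tolerance = 1e-12)
})

test_that("degenerate elements are rejected by name", {
  m <- viscoelastic_material(1e4, density = 1000, bulk_modulus = 1e5)
  X <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_error(solid_mesh(X, matrix(1:3, 1), m), "degenerate element")
})

test_that("a one-DOF oscillator built from one element has the closed-form period", {
  m <- viscoelastic_material(G_inf = 2e4, density = 1200, bulk_modulus = 2e5,
                             rayleigh_mass = 0)
  X <- rbind(c(0, 0), c(0.1, 0), c(0.05, 0.08))
  fixed <- rbind(c(TRUE, TRUE), c(TRUE, TRUE), c(TRUE, FALSE))  # apex: y free
  mesh <- solid_mesh(X, matrix(1:3, 1), m, fixed = fixed)
  # effective stiffness of the free DOF measured from the static response
  probe <- 1e-6
  u <- matrix(0, 3, 2); u[3, 2] <- probe
  k_eff <- -internal_force(mesh, u)$force[3, 2] / probe
  m_eff <- mesh$mass[3]
  period <- 2 * pi * sqrt(m_eff / k_eff)
  dt <- period / 200
  st <- new_state <- NULL
  st <- solid_step(mesh, NULL, dt)  # initialise
  st$u[3, 2] <- 1e-4
  st$v[] <- 0
  ys <- numeric(700)
  for (i in seq_along(ys)) {
    st <- solid_step(mesh, st, dt)
    ys[i] <- st$u[3, 2]
  }
  # period from successive downward zero crossings
  cross <- which(ys[-1] < 0 & ys[-length(ys)] >= 0)
  measured <- diff(cross[1:3]) * dt
  expect_equal(mean(measured), period, tolerance = 0.01)
})

test_that("zero net force gives uniform motion", {
  m <- viscoelastic_material(1e4, density = 1000, bulk_modulus = 1e5)
  mesh <- one_triangle(m)
  st <- solid_step(mesh, NULL, 1e-4)
  st$v <- matrix(rep(c(0.2, -0.1), each = 3), 3, 2)
  st$u[] <- 0
  v0 <- st$v
  for (i in 1:100) st <- solid_step(mesh, st, 1e-4)
  # rigid translation: no internal force, no damping
  expect_equal(st$v, v0, tolerance = 1e-12)
  expect_equal(st$u, v0 * 100 * 1e-4, tolerance = 1e-10)
})

test_that("damped free vibration never gains mechanical energy", {
  m <- viscoelastic_material(G_inf = 2e4, density = 1200, bulk_modulus = 2e5,
                             rayleigh_mass = 20)
  X <- rbind(c(0, 0), c(0.1, 0), c(0.05, 0.08))
  fixed <- rbind(c(TRUE, TRUE), c(TRUE, TRUE), c(FALSE, FALSE))
  mesh <- solid_mesh(X, matrix(1:3, 1), m, fixed = fixed)
  st <- solid_step(mesh, NULL, 1e-5)
  st$u[3, ] <- c(2e-4, -1e-4)
  st$v[] <- 0
  energy <- function(st) {
    fi <- internal_force(mesh, st$u)
    0.5 * sum(st$v^2 * mesh$mass) + 0.5 * sum(-fi$force * st$u)
  }
  e_prev <- energy(st)
  worst <- 0
  for (i in 1:400) {
    st <- solid_step(mesh, st, 1e-5)
    e <- energy(st)
    worst <- max(worst, e - e_prev)
    e_prev <- e
  }
  expect_lte(worst, 1e-12)
})

test_that("prescribed nodes follow their trajectories exactly", {
  m <- viscoelastic_material(1e4, density = 1000, bulk_modulus = 1e5)
  mesh <- one_triangle(m)
  st <- solid_step(mesh, NULL, 1e-4,
                   prescribed = list(nodes = 1L,
                                     u = matrix(c(0.003, -0.001), 1),
                                     v = matrix(c(0.1, 0.2), 1)))
  expect_identical(st$u[1, ], c(0.003, -0.001))
  expect_identical(st$v[1, ], c(0.1, 0.2))
})
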