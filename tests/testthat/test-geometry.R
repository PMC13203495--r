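# Parametric nested anatomy: configuration invariants, particle seeding,
# landmark baselines, determinism.

test_that("infeasible configurations are rejected naming the violated gap", {
  expect_error(
    nested_model_config(brain_semi_axes = c(0.040, 0.034)),
    "csf gap")
  expect_error(
    nested_model_config(fetal_body_semi_axes = c(0.12, 0.095)),
    "amniotic gap")
  expect_error(nested_model_config(particle_spacing_csf = 0.01),
               "csf particle spacing")
  expect_error(nested_model_config(uterine_wall_thickness = -0.01),
               "positive")
  expect_error(nested_model_config(spatial_dimension = 3), "spatial_dimension")
})

test_that("default model has ten positive baselines matching the analytic gaps", {
  cfg <- nested_model_config()
  model <- build_nested_model(cfg)
  lm <- model$landmarks
  expect_equal(nrow(lm), 10L)
  expect_equal(sum(lm$level == "outer"), 4L)
  expect_equal(sum(lm$level == "inner"), 6L)
  expect_true(all(lm$baseline_m > 0))
  # axis-aligned landmarks sit at concentric-ellipse poles where the minimum
  # distance equals the semi-axis difference (up to chord error of the
  # discretized surfaces)
  tol <- 3e-4
  expect_equal(lm$baseline_m[lm$name == "dFL_U"],
               cfg$uterus_semi_axes[1] - cfg$fetal_body_semi_axes[1],
               tolerance = tol / cfg$amniotic_gap)
  expect_equal(lm$baseline_m[lm$name == "dP_U"],
               cfg$uterus_semi_axes[2] - cfg$fetal_body_semi_axes[2],
               tolerance = tol / cfg$amniotic_gap)
  skull_inner <- cfg$skull_semi_axes - cfg$skull_thickness
  expect_equal(lm$baseline_m[lm$name == "dLH_S"],
               skull_inner[2] - cfg$brain_semi_axes[2],
               tolerance = tol / cfg$csf_gap)
})

test_that("the initial state is stress-free and quiescent", {
  model <- build_nested_model(nested_model_config())
  for (nm in c("amniotic_fluid", "csf")) {
    f <- model[[nm]]
    expect_true(all(f$p == 0))
    expect_true(all(f$vel == 0))
    expect_true(all(f$rho == f$material$rho0))
  }
})

test_that("model construction is bit-identical across calls", {
  cfg <- nested_model_config()
  a <- build_nested_model(cfg)
  b <- build_nested_model(cfg)
  expect_identical(a$amniotic_fluid$pos, b$amniotic_fluid$pos)
  expect_identical(a$brain$X, b$brain$X)
  expect_identical(a$landmarks, b$landmarks)
})

test_that("fetal-body and skull interface nodes coincide (rigid junction)", {
  model <- build_nested_model(nested_model_config())
  ties <- model$ties
  expect_equal(model$fetal_body$X[ties$node_a, ],
               model$skull$X[ties$node_b, ], tolerance = 1e-14)
})

test_that("seeded particles respect the clipping contract on a circular annulus", {
  m <- fluid_material(1000, 10)
  ps <- seed_fluid_particles(c(0.10, 0.10), c(0.11, 0.11), 0.0025, m)
  r <- sqrt(rowSums(ps$pos^2))
  expect_true(all(r > 0.10 & r < 0.11))
  expect_equal(sum(ps$mass), 1000 * 0.0025^2 * nrow(ps$pos))
  expect_true(all(ps$p == 0))
})

test_that("halving the spacing multiplies the count by about 2^dimension", {
  m <- fluid_material(1000, 10)
  # lattice-counting oracle: the clipped annulus area over spacing^2
  n1 <- nrow(seed_fluid_particles(c(0.06, 0.05), c(0.10, 0.09), 0.004, m)$pos)
  n2 <- nrow(seed_fluid_particles(c(0.06, 0.05), c(0.10, 0.09), 0.002, m)$pos)
  expect_equal(n2 / n1, 4, tolerance = 0.12)
  n3 <- nrow(seed_fluid_particles(c(0.02, 0.02, 0.02), c(0.04, 0.04, 0.04),
                                  0.004, m, dim = 3)$pos)
  n4 <- nrow(seed_fluid_particles(c(0.02, 0.02, 0.02), c(0.04, 0.04, 0.04),
                                  0.002, m, dim = 3)$pos)
  expect_equal(n4 / n3, 8, tolerance = 0.2)
})

test_that("3-D fills have per-particle mass rho0 * spacing^3", {
  m <- fluid_material(1000, 10)
  ps <- seed_fluid_particles(NULL, c(0.03, 0.03, 0.03), 0.003, m, dim = 3)
  expect_equal(unique(ps$mass), 1000 * 0.003^3)
  expect_true(all(rowSums(sweep(ps$pos, 2, c(0.03, 0.03, 0.03) - 0.0015,
                                "/")^2) <= 1))
})

test_that("degenerate seeding requests fail loudly", {
  m <- fluid_material(1000, 10)
  expect_error(seed_fluid_particles(c(0.10, 0.10), c(0.101, 0.101), 0.0025, m),
               "spacing")
  expect_error(seed_fluid_particles(NULL, c(1e-4, 1e-4), 0.0025, m), "empty")
})

test_that("solid meshes have positive element areas and consistent lumped mass", {
  model <- build_nested_model(nested_model_config())
  for (nm in c("uterus", "fetal_body", "skull", "brain")) {
    mesh <- model[[nm]]
    expect_true(all(mesh$area > 0))
    expect_equal(sum(mesh$mass),
                 mesh$material$density * sum(mesh$area), tolerance = 1e-12)
  }
  # brain disk area should approximate the ellipse area
  brain <- model$brain
  cfg <- nested_model_config()
  expect_equal(sum(brain$area),
               pi * prod(cfg$brain_semi_axes), tolerance = 0.02)
})
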