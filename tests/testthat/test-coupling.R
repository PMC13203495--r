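# Penalty contact and fluid-structure force accumulation.

square_loop <- function(side = 0.1, n_per_edge = 5) {
  # CCW closed square polyline centred at the origin
  s <- seq(-side / 2, side / 2, length.out = n_per_edge + 1)
  bottom <- cbind(s[-length(s)], -side / 2)
  right <- cbind(side / 2, s[-length(s)])
  top <- cbind(rev(s)[-1], side / 2)
  left <- cbind(-side / 2, rev(s)[-1])
  rbind(bottom, right, top, left)
}

test_that("non-penetrating points feel no force", {
  surf <- square_loop()
  spec <- contact_spec(kc = 1000)
  res <- contact_force(matrix(c(0, 0), 1), surf, spec, orient = -1L)
  expect_equal(res$delta, 0)
  expect_equal(res$force, matrix(0, 1, 2))
  expect_equal(res$nodal, matrix(0, nrow(surf), 2))
})

test_that("a 1 mm penetration at kc = 1000 gives a 1 N outward normal force", {
  surf <- square_loop()
  spec <- contact_spec(kc = 1000)
  # solid fills the square (orient +1); the point sits 1 mm inside the
  # bottom face, so it is pushed back out along the outward normal (0, -1)
  p <- matrix(c(0.012, -0.049), 1)
  res <- contact_force(p, surf, spec, orient = 1L)
  expect_equal(res$delta, 0.001, tolerance = 1e-12)
  expect_equal(sqrt(sum(res$force^2)), 1, tolerance = 1e-12)
  expect_equal(res$force[1, ] / sqrt(sum(res$force^2)), c(0, -1),
               tolerance = 1e-12)
})

test_that("reaction concentrates on a node when the contact point is that node", {
  surf <- square_loop(n_per_edge = 2)   # mid-edge nodes exist
  spec <- contact_spec(kc = 500)
  # closest point is exactly the mid-bottom node (0, -0.05)
  res <- contact_force(matrix(c(0, -0.045), 1), surf, spec, orient = 1L)
  nz <- which(rowSums(abs(res$nodal)) > 0)
  expect_equal(length(nz), 1L)
  expect_equal(surf[nz, ], c(0, -0.05))
  expect_equal(res$nodal[nz, ], -res$force[1, ], tolerance = 1e-15)
})

test_that("reaction splits equally at an edge midpoint", {
  surf <- square_loop(n_per_edge = 2)
  spec <- contact_spec(kc = 500)
  res <- contact_force(matrix(c(-0.025, -0.045), 1), surf, spec, orient = 1L)
  nz <- which(rowSums(abs(res$nodal)) > 0)
  expect_equal(length(nz), 2L)
  expect_equal(res$nodal[nz[1], ], res$nodal[nz[2], ], tolerance = 1e-12)
  expect_equal(colSums(res$nodal), -res$force[1, ], tolerance = 1e-15)
})

test_that("global action-reaction balance holds exactly for random clouds", {
  set.seed(21)
  surf <- square_loop(n_per_edge = 7)
  spec <- contact_spec(kc = 2e4)
  for (rep in 1:5) {
    pts <- matrix(runif(60, -0.08, 0.08), ncol = 2)
    res <- contact_force(pts, surf, spec, orient = -1L)
    total <- colSums(res$force) + colSums(res$nodal)
    expect_lt(max(abs(total)), 1e-12)
  }
})

test_that("accumulate_fsi_forces balances particles against all surfaces", {
  set.seed(22)
  m <- fluid_material(1000, 10)
  pos <- matrix(runif(80, -0.07, 0.07), ncol = 2)
  ps <- particle_set(pos, mass = 0.01, material = m,
                     kernel = kernel_spec(0.005))
  surfaces <- list(list(pos = square_loop(0.1, 4), orient = -1L),
                   list(pos = square_loop(0.05, 3), orient = 1L))
  out <- accumulate_fsi_forces(ps, surfaces, contact_spec(kc = 1e4))
  total <- colSums(out$acc * ps$mass) +
    colSums(out$nodal[[1]]) + colSums(out$nodal[[2]])
  expect_lt(max(abs(total)), 1e-12)
  expect_true(all(out$delta >= 0))
})

test_that("penetration beyond the cap aborts with diagnostics", {
  surf <- square_loop()
  spec <- contact_spec(kc = 1000, cap = 0.005)
  expect_error(
    contact_force(matrix(c(0, -0.02), 1), surf, spec, orient = 1L),
    "exceeds the cap")
})
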