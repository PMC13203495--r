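# Shared heavy runs for the acceptance tests, computed once per session.

.run_cache <- new.env(parent = emptyenv())

acceptance_comparison <- function() {
  if (is.null(.run_cache$cmp)) {
    .run_cache$cmp <- run_comparison(simulation_config(seed = 1L))
  }
  .run_cache$cmp
}

# Still water column in a fixed rectangular basin under gravity: the classic
# hydrostatic benchmark for the particle-wall coupling.
hydrostatic_column <- function(width = 0.1, depth = 0.1, spacing = 0.005,
                               t_end = 1.5, g = 9.81, shepard_every = 30L) {
  m <- fluid_material(1000, sound_speed = 10 * sqrt(2 * g * depth))
  xs <- seq(spacing / 2, width - spacing / 2, by = spacing)
  ys <- seq(spacing / 2, depth - spacing / 2, by = spacing)
  pos <- as.matrix(expand.grid(xs, ys))
  colnames(pos) <- NULL
  ps <- particle_set(pos, mass = m$rho0 * spacing^2, material = m,
                     kernel = kernel_spec(1.3 * spacing))
  # rigid basin: inner rectangle (contact surface) inside a fixed frame
  rect_ring <- function(x0, y0, x1, y1, nx, ny) {
    b <- cbind(seq(x0, x1, length.out = nx + 1)[-(nx + 1)], y0)
    r <- cbind(x1, seq(y0, y1, length.out = ny + 1)[-(ny + 1)])
    t <- cbind(rev(seq(x0, x1, length.out = nx + 1))[-(nx + 1)], y1)
    l <- cbind(x0, rev(seq(y0, y1, length.out = ny + 1))[-(ny + 1)])
    rbind(b, r, t, l)
  }
  lid <- 2.5 * depth
  inner <- rect_ring(0, 0, width, lid, 8, 12)
  outer <- rect_ring(-0.02, -0.02, width + 0.02, lid + 0.02, 8, 12)
  n <- nrow(inner)
  X <- rbind(inner, outer)
  tri <- NULL
  for (k in seq_len(n)) {
    k2 <- k %% n + 1
    tri <- rbind(tri, c(k, k2, n + k2), c(k, n + k2, n + k))
  }
  mat <- viscoelastic_material(1e4, density = 1000, bulk_modulus = 1e5)
  basin <- solid_mesh(X, tri, mat, "basin",
                      fixed = matrix(TRUE, nrow(X), 2),
                      rings = list(inner = seq_len(n)))
  sp <- sph_params(alpha = 1, beta = 2, gravity = c(0, -g))
  fl <- list(pos = ps$pos, vel = ps$vel, mass = ps$mass, rho = ps$rho,
             rho0 = m$rho0, c0 = m$c0, h = ps$kernel$h, alpha = sp$alpha,
             beta = sp$beta, eps = sp$epsilon, g = c(0, -g))
  so <- list(list(X = basin$X, tri = basin$tri, mass = basin$mass,
                  K = mat$bulk_modulus, Ginf = mat$G_inf, Gk = mat$G_modes,
                  tauk = mat$tau_modes, rho = mat$density, ra = 0,
                  fixed = basin$fixed, prescribed = integer(),
                  rigid = FALSE))
  surf <- list(list(solid = 1L, nodes = basin$rings$inner, orient = -1L))
  kc <- m$rho0 * m$c0^2
  ct <- list(list(type = 0L, fluid = 1L, surface = 1L, kc = kc,
                  cap = 6 * spacing, standoff = spacing / 2,
                  tension_range = 0, reach = 4 * spacing))
  dt <- 0.25 * ps$kernel$h / (m$c0 * (1 + 1.2 * sp$alpha))
  nst <- as.integer(ceiling(t_end / dt))
  theta <- rep(0, nst + 2)
  res <- nestedfsi:::cpp_fsi_engine(list(fl), so, surf, ct, list(), list(),
                                    theta, dt, nst, nst, 0L,
                                    as.integer(shepard_every), -1L, FALSE)
  fin <- res$fluids[[1]]
  list(pos = fin$pos, p = fin$p, rho = fin$rho, vel = fin$vel,
       material = m, spacing = spacing, width = width, g = g)
}
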