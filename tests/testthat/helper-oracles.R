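# Independent R-level oracles used against the compiled implementation.
# These are deliberately written as direct double loops over the printed
# formulas, sharing no code with the package internals.

cubic_w <- function(r, h, d) {
  sigma <- switch(d, 2 / (3 * h), 10 / (7 * pi * h^2), 1 / (pi * h^3))
  q <- r / h
  f <- ifelse(q < 1, 1 - 1.5 * q^2 + 0.75 * q^3,
              ifelse(q < 2, 0.25 * (2 - q)^3, 0))
  sigma * f
}

cubic_dw <- function(r, h, d) {
  sigma <- switch(d, 2 / (3 * h), 10 / (7 * pi * h^2), 1 / (pi * h^3))
  q <- r / h
  fp <- ifelse(q < 1, -3 * q + 2.25 * q^2,
               ifelse(q < 2, -0.75 * (2 - q)^2, 0))
  sigma * fp / h
}

# brute-force continuity and momentum rates, straight off the printed sums
oracle_sph_rates <- function(pos, vel, mass, rho, p, h, alpha, beta, eps, c0,
                             g = c(0, 0)) {
  n <- nrow(pos)
  d <- ncol(pos)
  drho <- numeric(n)
  acc <- matrix(rep(g, each = n), n, d)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- pos[i, ] - pos[j, ]
      r <- sqrt(sum(dx^2))
      if (r >= 2 * h || r == 0) next
      gradw <- dx / r * cubic_dw(r, h, d)
      dv <- vel[i, ] - vel[j, ]
      drho[i] <- drho[i] + mass[j] * sum(dv * gradw)
      vdotx <- sum(dv * dx)
      Pi <- 0
      if (vdotx < 0) {
        mu <- h * vdotx / (r^2 + eps * h^2)
        Pi <- (-alpha * c0 * mu + beta * mu^2) / (0.5 * (rho[i] + rho[j]))
      }
      acc[i, ] <- acc[i, ] -
        mass[j] * (p[i] / rho[i]^2 + p[j] / rho[j]^2 + Pi) * gradw
    }
  }
  list(drho = drho, acc = acc)
}

# brute-force point-to-segment minimum distance
oracle_min_dist <- function(pts, poly, closed = TRUE) {
  ns <- nrow(poly)
  segs <- if (closed) cbind(seq_len(ns), c(2:ns, 1)) else
    cbind(seq_len(ns - 1), 2:ns)
  apply(pts, 1, function(p) {
    min(apply(segs, 1, function(s) {
      a <- poly[s[1], ]; b <- poly[s[2], ]
      ab <- b - a
      t <- if (sum(ab^2) == 0) 0 else
        max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
      sqrt(sum((p - (a + t * ab))^2))
    }))
  })
}

# regular lattice particle block for operator tests
lattice_particles <- function(nx = 8, ny = 8, spacing = 0.01,
                              material = fluid_material(1000, 10),
                              jitter = 0) {
  g <- as.matrix(expand.grid(x = (seq_len(nx) - 1) * spacing,
                             y = (seq_len(ny) - 1) * spacing))
  colnames(g) <- NULL
  if (jitter > 0) g <- g + matrix(runif(length(g), -jitter, jitter), nrow(g))
  particle_set(g, mass = material$rho0 * spacing^2, material = material,
               kernel = kernel_spec(1.3 * spacing))
}

# simple R-side symplectic-Euler SPH loop for conservation properties
step_fluid <- function(ps, params, dt, n_steps) {
  for (k in seq_len(n_steps)) {
    ps$p <- eos_pressure(ps$rho, ps$material)
    drho <- continuity_rate(ps)
    acc <- momentum_rate(ps, params)
    ps$vel <- ps$vel + acc * dt
    ps$rho <- ps$rho + drho * dt
    ps$pos <- ps$pos + ps$vel * dt
  }
  ps
}
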