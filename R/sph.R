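# Weakly compressible SPH operators. All operators are dimension-agnostic
# (2-D or 3-D positions); the coupled engine uses the same pairwise physics
# through a 2-D cell list.

#' Cubic spline kernel value
#'
#' Compactly supported cubic B-spline, support radius `2 h`, normalized to
#' unit integral in `dim` dimensions.
#'
#' @param separation Nonnegative distances (m).
#' @param spec A [kernel_spec()].
#' @param dim Spatial dimension (1, 2 or 3).
#' @return Kernel values (1/m^dim).
#' @export
kernel_value <- function(separation, spec, dim = 2) {
  stopifnot(dim %in% 1:3)
  cpp_kernel_value(as.numeric(separation), spec$h, as.integer(dim))
}

#' Cubic spline kernel gradient
#'
#' Gradient of `W(|r|)` with respect to the first particle's position, for
#' separation vectors `r_i - r_j` given as rows.
#'
#' @param dx Matrix of separation vectors (n x dim).
#' @param spec A [kernel_spec()].
#' @return Matrix of gradients (n x dim).
#' @export
kernel_gradient <- function(dx, spec) {
  if (!is.matrix(dx)) dx <- matrix(dx, nrow = 1)
  cpp_kernel_grad(dx, spec$h)
}

#' SPH field interpolation
#'
#' Kernel-weighted sum `A(r) = sum_j m_j A_j / rho_j W(r - r_j, h)`,
#' optionally Shepard-normalized (divide by `sum_j m_j / rho_j W`), which
#' reproduces constants exactly on any particle distribution. Queries with no
#' particle inside the support return 0 and are flagged.
#'
#' @param values Field values at the particles.
#' @param query Query positions (matrix, or vector for a single point).
#' @param particles A [particle_set()].
#' @param shepard Normalize by the local partition of unity (default `TRUE`).
#' @return Numeric vector of interpolated values with attribute `empty`
#'   (logical; `TRUE` where no particle was in support).
#' @export
sph_interpolate <- function(values, query, particles, shepard = TRUE) {
  if (!is.matrix(query)) query <- matrix(query, nrow = 1)
  res <- cpp_interpolate(query, particles$pos, particles$mass, particles$rho,
                         as.numeric(values), particles$kernel$h, shepard)
  structure(res$value, empty = res$empty)
}

#' Continuity equation rate
#'
#' `D rho_i / D t = sum_j m_j (v_i - v_j) . grad_i W_ij` for every particle.
#'
#' @param particles A [particle_set()].
#' @return Density rates (kg/m^dim/s).
#' @export
continuity_rate <- function(particles) {
  d <- ncol(particles$pos)
  res <- cpp_sph_rates(particles$pos, particles$vel, particles$mass,
                       particles$rho, particles$p, particles$kernel$h,
                       0, 0, 0.01, particles$material$c0, rep(0, d))
  res$drho
}

#' Weakly compressible equation of state
#'
#' `p = c0^2 (rho - rho0)`; pressure may be negative (tension).
#'
#' @param rho Densities (kg/m^dim), > 0.
#' @param material A [fluid_material()].
#' @return Pressures (Pa).
#' @export
eos_pressure <- function(rho, material) {
  stopifnot(all(rho > 0))
  material$c0^2 * (rho - material$rho0)
}

#' Momentum equation rate
#'
#' Symmetric pressure-gradient form plus the Monaghan artificial-viscosity
#' term (active only for approaching pairs) and gravity:
#' `Dv_i/Dt = -sum_j m_j (p_i/rho_i^2 + p_j/rho_j^2 + Pi_ij) grad_i W_ij + g`.
#' Pairwise internal forces are antisymmetric, so internal momentum is
#' conserved exactly.
#'
#' @param particles A [particle_set()] with current pressures.
#' @param params An [sph_params()].
#' @return Accelerations (n x dim, m/s^2).
#' @export
momentum_rate <- function(particles, params = sph_params()) {
  d <- ncol(particles$pos)
  g <- params$gravity
  if (length(g) != d) g <- c(g, rep(0, d))[seq_len(d)]
  res <- cpp_sph_rates(particles$pos, particles$vel, particles$mass,
                       particles$rho, particles$p, particles$kernel$h,
                       params$alpha, params$beta, params$epsilon,
                       particles$material$c0, g)
  res$acc
}

#' Shepard density reinitialization
#'
#' `rho_i = sum_j m_j W_ij / sum_j (m_j / rho_j) W_ij` (self term included);
#' applied periodically to control density drift when integrating the
#' continuity equation over long weakly compressible runs.
#'
#' @param particles A [particle_set()].
#' @return Reinitialized densities.
#' @export
shepard_density <- function(particles) {
  cpp_shepard_density(particles$pos, particles$mass, particles$rho,
                      particles$kernel$h)
}

#' Cell-list neighbor search
#'
#' Uniform cell list with cell size equal to the support radius; returns all
#' unordered particle pairs closer than `support` (2-D).
#'
#' @param pos Particle positions (n x 2).
#' @param support Interaction radius (m).
#' @return Integer matrix of pairs (i < j, 1-based).
#' @export
neighbor_pairs <- function(pos, support) {
  cpp_neighbor_pairs(pos, support)
}
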