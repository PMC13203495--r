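# Penalty contact between SPH particles (or solid boundary nodes) and solid
# surface polylines: F = kc * delta * n on the point, the exact opposite
# distributed to the penetrated segment's nodes by its linear interpolation
# weights, so global fluid-solid force balance holds by construction.

surface_matrix <- function(surface) {
  if (is.matrix(surface)) return(surface)
  abort("surface must be a matrix of polyline node positions (closed loop)")
}

#' Penalty contact forces of points against a surface
#'
#' Finds, for every point, the closest segment of the (closed, CCW-ordered)
#' surface polyline; if the point lies past the surface on the solid side,
#' the penetration depth `delta` and the penalty force `kc delta n` along the
#' outward surface normal are returned, with the opposite force distributed
#' to the segment's nodes (weights summing to one).
#'
#' @param points Point positions (n x 2).
#' @param surface Surface polyline node positions (m x 2, closed CCW loop).
#' @param spec A [contact_spec()].
#' @param orient +1 if the non-solid side is the polygon-outward side (e.g.
#'   fluid surrounding a body), -1 if the non-solid side is the polygon
#'   interior (e.g. fluid inside a cavity).
#' @return List with `force` (n x 2 on the points), `delta` (penetrations,
#'   m), `nodal` (m x 2 reactions on the surface nodes), `segment` and `t`
#'   (closest segment index and parameter).
#' @export
contact_force <- function(points, surface, spec, orient = 1L) {
  if (!is.matrix(points)) points <- matrix(points, nrow = 1)
  surface <- surface_matrix(surface)
  res <- cpp_contact_forces(points, surface, TRUE, as.integer(orient),
                            spec$kc)
  if (any(res$delta > spec$cap)) {
    abort(sprintf("contact penetration %.4g m exceeds the cap %.4g m",
                  max(res$delta), spec$cap))
  }
  res
}

#' Accumulate fluid-structure interaction forces over contact interfaces
#'
#' Applies [contact_force()] for each (particle set, surface) pair and
#' returns per-surface nodal force accumulators plus per-particle boundary
#' accelerations. Global balance (sum of nodal forces + sum of particle
#' forces = 0) holds exactly.
#'
#' @param particles A [particle_set()].
#' @param surfaces List of surfaces; each a list with `pos` (polyline node
#'   matrix) and `orient`.
#' @param spec A [contact_spec()] (recycled) or list of specs.
#' @return List with `acc` (particle accelerations, n x 2), `nodal` (list of
#'   per-surface nodal forces), `delta` (n, deepest penetration per particle).
#' @export
accumulate_fsi_forces <- function(particles, surfaces, spec) {
  n <- nrow(particles$pos)
  acc <- matrix(0, n, 2)
  delta <- numeric(n)
  specs <- if (inherits(spec, "contact_spec")) {
    rep(list(spec), length(surfaces))
  } else spec
  nodal <- vector("list", length(surfaces))
  for (k in seq_along(surfaces)) {
    res <- contact_force(particles$pos, surfaces[[k]]$pos, specs[[k]],
                         surfaces[[k]]$orient)
    acc <- acc + res$force / particles$mass
    delta <- pmax(delta, res$delta)
    nodal[[k]] <- res$nodal
  }
  list(acc = acc, nodal = nodal, delta = delta)
}
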