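# Explicit transient dynamics of the deformable solids: linear-triangle
# small-strain kinematics, lumped mass, mass-proportional Rayleigh damping,
# generalized Maxwell viscoelasticity on the deviatoric response.

#' Shear relaxation modulus of a generalized Maxwell material
#'
#' `G(t) = G_inf + sum_k G_k exp(-t / tau_k)`; monotone non-increasing,
#' `G(0) = G_inf + sum G_k`, `G(Inf) = G_inf`.
#'
#' @param t Times (s), >= 0.
#' @param material A [viscoelastic_material()].
#' @return Modulus values (Pa).
#' @export
relaxation_modulus <- function(t, material) {
  if (any(t < 0)) abort("relaxation_modulus requires t >= 0")
  vapply(t, function(ti) {
    material$G_inf + sum(material$G_modes * exp(-ti / material$tau_modes))
  }, numeric(1))
}

new_stress_state <- function(material) {
  nm <- length(material$G_modes)
  structure(list(eps = c(0, 0, 0, 0),
                 sk = matrix(0, max(nm, 1), 4),
                 sigma = matrix(0, 3, 3)),
            class = "stress_state")
}

as_strain4 <- function(eps) {
  if (is.matrix(eps)) {
    stopifnot(nrow(eps) == 3, ncol(eps) == 3)
    if (max(abs(eps - t(eps))) > 1e-12 * max(1, max(abs(eps)))) {
      abort("strain tensor must be symmetric")
    }
    c(eps[1, 1], eps[2, 2], eps[3, 3], eps[1, 2])
  } else {
    stopifnot(length(eps) == 4)
    as.numeric(eps)
  }
}

tensor3 <- function(v4) {
  matrix(c(v4[1], v4[4], 0,
           v4[4], v4[2], 0,
           0, 0, v4[3]), 3, 3)
}

#' Viscoelastic stress update (internal-variable recurrence)
#'
#' Advances one material point by a strain increment over `dt`: the
#' equilibrium stress follows the total strain elastically (bulk modulus on
#' the volumetric part, `2 G_inf` on the deviatoric part) and each Maxwell
#' mode follows the exponential recurrence
#' `s_k <- exp(-dt/tau_k) s_k + 2 G_k exp(-dt/(2 tau_k)) d(dev eps)`,
#' consistent with the relaxation modulus to first order in `dt / tau_k`.
#' Total stress is the sum of the equilibrium part and the mode stresses.
#'
#' Strains are small-strain tensors, given either as 3 x 3 symmetric matrices
#' or as `(xx, yy, zz, xy)` vectors (only one in-plane shear component is
#' carried, matching the plane-strain element formulation).
#'
#' @param strain_increment Strain increment over the step.
#' @param dt Time step (s), > 0.
#' @param state A `stress_state` from a previous call, or `NULL` to start
#'   from the virgin (zero-strain, zero-stress) state.
#' @param material A [viscoelastic_material()].
#' @return Updated `stress_state`: fields `sigma` (3 x 3 total stress, Pa),
#'   `sigma_eq` (equilibrium part), `sk` (mode stresses), `eps` (total
#'   strain), `principal` (sorted descending).
#' @export
update_viscoelastic_stress <- function(strain_increment, dt, state = NULL,
                                       material) {
  stopifnot(dt > 0)
  state <- state %||% new_stress_state(material)
  deps <- as_strain4(strain_increment)
  eps_new <- state$eps + deps
  res <- cpp_maxwell_update(eps_new, state$eps, state$sk, dt,
                            material$bulk_modulus, material$G_inf,
                            material$G_modes, material$tau_modes)
  tr <- sum(eps_new[1:3])
  dev <- eps_new - c(tr / 3, tr / 3, tr / 3, 0)
  sig_eq <- c(rep(material$bulk_modulus * tr, 3), 0) +
    2 * material$G_inf * dev
  sigma <- tensor3(res$sigma)
  structure(list(eps = eps_new,
                 sk = res$sk,
                 sigma = sigma,
                 sigma_eq = tensor3(sig_eq),
                 principal = sort(eigen(sigma, symmetric = TRUE,
                                        only.values = TRUE)$values,
                                  decreasing = TRUE)),
            class = "stress_state")
}

new_solid_state <- function(mesh) {
  nm <- length(mesh$material$G_modes)
  list(u = matrix(0, nrow(mesh$X), 2),
       v = matrix(0, nrow(mesh$X), 2),
       eprev = matrix(0, nrow(mesh$tri), 4),
       sk = matrix(0, nrow(mesh$tri), 4 * max(nm, 1)),
       sigma = matrix(0, nrow(mesh$tri), 4),
       step = 0L)
}

#' Assembled internal nodal forces of a solid mesh
#'
#' Element stresses from the current displacement field (plane strain, unit
#' thickness) assembled to nodal forces. With `dt = 0` the Maxwell modes are
#' held at their stored values (a static evaluation: for a virgin state this
#' is the long-term elastic response); with `dt > 0` the modes are advanced
#' by the internal-variable recurrence, as done every step of the explicit
#' solver.
#'
#' @param mesh A [solid_mesh()].
#' @param u Nodal displacements (n x 2, m).
#' @param state Optional solid state carrying `eprev` (previous deviatoric
#'   strains) and `sk` (mode stresses); default virgin state.
#' @param dt Time step for the viscoelastic advance (s); 0 for a static
#'   evaluation.
#' @return List with `force` (n x 2 nodal forces, N per unit depth), `sigma`
#'   (element stresses, columns xx, yy, zz, xy), `strain`, and the updated
#'   `eprev`, `sk`.
#' @export
internal_force <- function(mesh, u, state = NULL, dt = 0) {
  state <- state %||% new_solid_state(mesh)
  m <- mesh$material
  cpp_internal_force(mesh$X, mesh$tri, u, m$bulk_modulus, m$G_inf,
                     m$G_modes, m$tau_modes, dt, state$eprev, state$sk,
                     dt > 0)
}

#' One explicit time step of a solid mesh
#'
#' Central-difference (semi-implicit Euler) update with lumped mass and
#' mass-proportional damping:
#' `a = (f_int + f_ext + f_fsi) / m - c_a v`, `v <- v + a dt`,
#' `u <- u + v dt`. Fixed degrees of freedom (from `mesh$fixed`) do not move;
#' prescribed nodes follow their target trajectories exactly.
#'
#' @param mesh A [solid_mesh()].
#' @param state Solid state as returned by a previous call (or `NULL` for
#'   the quiescent start).
#' @param dt Time step (s); must be below the element CFL limit (see
#'   [stable_timestep()]).
#' @param fext,ffsi External / fluid-structure nodal forces (n x 2, N per
#'   unit depth); default zero.
#' @param prescribed Optional list with `nodes` (indices), `u` and `v`
#'   (length(nodes) x 2 targets) imposed after the update.
#' @return Updated state (fields `u`, `v`, `a`, `eprev`, `sk`, `sigma`,
#'   `step`).
#' @export
solid_step <- function(mesh, state = NULL, dt, fext = NULL, ffsi = NULL,
                       prescribed = NULL) {
  stopifnot(dt > 0)
  state <- state %||% new_solid_state(mesh)
  fi <- internal_force(mesh, state$u, state, dt = dt)
  f <- fi$force
  if (!is.null(fext)) f <- f + fext
  if (!is.null(ffsi)) f <- f + ffsi
  a <- f / mesh$mass - mesh$material$rayleigh_mass * state$v
  a[mesh$fixed] <- 0
  v <- state$v + a * dt
  v[mesh$fixed] <- 0
  u <- state$u + v * dt
  if (!is.null(prescribed)) {
    u[prescribed$nodes, ] <- prescribed$u
    v[prescribed$nodes, ] <- prescribed$v
  }
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    abort(sprintf("numerical instability (NaN) in solid step %d",
                  state$step + 1L))
  }
  list(u = u, v = v, a = a, eprev = fi$eprev, sk = fi$sk, sigma = fi$sigma,
       strain = fi$strain, step = state$step + 1L)
}
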