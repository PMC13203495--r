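# Simulation driver: time-step control, scenario assembly (nested versus
# no-fluid counterfactual), the coupled run, and the comparison report.

#' Simulation configuration
#'
#' Aggregates the geometry, materials, SPH parameters, seizure kinematics and
#' run controls. The default scaled scenario is 2-D, about 2500 fluid
#' particles, 6 s simulated (three convulsion cycles at 0.5 Hz) -- a
#' desk-scale surrogate for the original full-resolution 60 s run.
#'
#' @param geometry A [nested_model_config()].
#' @param materials Material set as from [default_materials()].
#' @param sph An [sph_params()] (gravity defaults to zero: the fluids start
#'   at rest with uniform zero pressure, the stress-free baseline state).
#' @param sph_csf Optional [sph_params()] for the cerebrospinal fluid domain;
#'   by default the CSF uses a stronger artificial viscosity (alpha = 2) than
#'   the amniotic domain, representing the dissipative squeeze-film character
#'   of the thin brain-skull fluid layer that damps brain oscillation and
#'   transmits skull motion.
#' @param seizure A [seizure_params()]; its seed defaults to `seed`.
#' @param total_time Simulated duration (s).
#' @param output_dt Metrics sampling cadence (s).
#' @param cfl CFL safety factor in (0, 1].
#' @param scenario `"nested"` (both fluid layers present) or `"no_fluids"`
#'   (fluids removed; uterine wall drives the fetal body, and the skull the
#'   brain, through direct penalty contact -- the unprotected counterfactual).
#' @param contact_kc Optional named list overriding the per-interface contact
#'   stiffnesses. `amniotic` (default 3e4 N/m per m, softer than the
#'   `rho0 c0^2` sizing so the driven wall does not re-radiate impact noise
#'   into the fluid) and `csf` (default 3e5, stiffer than the sizing so the
#'   brain's film-tracking resonance sits above the 2-8 Hz jitter band) are
#'   the fluid-wall stiffnesses; `direct` (default 2e6) is the solid-solid
#'   stiffness of the unprotected scenario, sized for near-rigid transmission
#'   (sub-0.1 mm penetrations), since a soft penalty would itself act as a
#'   cushion and understate the unprotected loading.
#' @param wetted_walls Fluid-wall interfaces sustain tapered tension within
#'   half a particle spacing beyond the wall standoff (a no-separation,
#'   wetted-film condition; the thin fluid layers support moderate suction
#'   before cavitation). `FALSE` gives push-only contact.
#' @param rigid_skull Treat the skull as a rigid body (default `TRUE`). At
#'   desk scale a thin bone-like finite element ring cannot be integrated
#'   explicitly (its wave speed forces a prohibitive time step) and any
#'   integrable modulus leaves it orders of magnitude too flexible; the
#'   cranial vault's stiffness is far above every fluid-pressure scale in the
#'   model, so a rigid 3-degree-of-freedom body driven by the total force and
#'   torque from the tied fetal-body interface and the cerebrospinal-fluid
#'   contact is the faithful scaled treatment. Set to `FALSE` to integrate
#'   the skull's viscoelastic mesh explicitly.
#' @param shepard_every Steps between Shepard density reinitializations.
#' @param snapshot_dt Snapshot cadence (s) for field output; `NULL` disables
#'   intermediate snapshots.
#' @param seed Integer seed controlling the seizure realization.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = nested_model_config(),
                              materials = default_materials(),
                              sph = sph_params(alpha = 1, beta = 2,
                                               gravity = c(0, 0)),
                              sph_csf = sph_params(alpha = 2, beta = 2,
                                                   gravity = c(0, 0)),
                              seizure = NULL,
                              total_time = 6,
                              output_dt = 0.01,
                              cfl = 0.25,
                              scenario = c("nested", "no_fluids"),
                              contact_kc = NULL,
                              wetted_walls = TRUE,
                              rigid_skull = TRUE,
                              shepard_every = 30,
                              snapshot_dt = NULL,
                              seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(total_time > 0, output_dt > 0, cfl > 0, cfl <= 1)
  seizure <- seizure %||% seizure_params(seed = seed)
  kc <- list(amniotic = 3e4, csf = 3e5, direct = 2e6)
  if (!is.null(contact_kc)) kc[names(contact_kc)] <- contact_kc
  sph_csf <- sph_csf %||% sph
  structure(list(geometry = geometry, materials = materials, sph = sph,
                 sph_csf = sph_csf, seizure = seizure, total_time = total_time,
                 output_dt = output_dt, cfl = cfl, scenario = scenario,
                 contact_kc = kc, wetted_walls = wetted_walls,
                 rigid_skull = rigid_skull,
                 shepard_every = shepard_every,
                 snapshot_dt = snapshot_dt, seed = as.integer(seed)),
            class = "simulation_config")
}

solid_char_length <- function(mesh) {
  X <- mesh$X; tri <- mesh$tri
  e1 <- sqrt(rowSums((X[tri[, 2], ] - X[tri[, 1], ])^2))
  e2 <- sqrt(rowSums((X[tri[, 3], ] - X[tri[, 2], ])^2))
  e3 <- sqrt(rowSums((X[tri[, 1], ] - X[tri[, 3], ])^2))
  min(2 * mesh$area / pmax(e1, pmax(e2, e3)))
}

solid_wave_speed <- function(material) {
  G0 <- material$G_inf + sum(material$G_modes)
  sqrt((material$bulk_modulus + 4 * G0 / 3) / material$density)
}

#' Stable explicit time step for a nested model
#'
#' `dt = cfl x min(fluid acoustic limits, solid element limits, contact
#' stiffness limits)`: for each fluid `h / (c0 (1 + 1.2 alpha))`; for each
#' solid the minimum element altitude over the dilatational wave speed
#' `sqrt((K + 4 G0 / 3) / rho)` with `G0` the instantaneous shear modulus;
#' for each contact interface `sqrt(m_min / kc)`.
#'
#' @param model A [build_nested_model()] result.
#' @param config A [simulation_config()].
#' @return Time step (s), with the individual limits in `attr(, "limits")`.
#' @export
stable_timestep <- function(model, config) {
  lim <- c()
  has_fluids <- config$scenario != "no_fluids"
  if (has_fluids) {
    for (nm in c("amniotic_fluid", "csf")) {
      f <- model[[nm]]
      a <- if (nm == "csf") config$sph_csf$alpha else config$sph$alpha
      lim[nm] <- f$kernel$h / (f$material$c0 * (1 + 1.2 * a))
    }
  }
  for (nm in c("uterus", "fetal_body", "skull", "brain")) {
    if (nm == "skull" && isTRUE(config$rigid_skull)) next
    s <- model[[nm]]
    lim[nm] <- solid_char_length(s) / solid_wave_speed(s$material)
  }
  if (has_fluids) {
    lim["contact_amniotic"] <- sqrt(min(model$amniotic_fluid$mass) /
                                    config$contact_kc$amniotic)
    lim["contact_csf"] <- sqrt(min(model$csf$mass) / config$contact_kc$csf)
  } else {
    # direct solid-solid contact: lightest boundary node against kc
    m_min <- min(model$fetal_body$mass[model$fetal_body$rings$outer],
                 model$brain$mass[model$brain$rings$outer])
    lim["contact_direct"] <- sqrt(m_min / config$contact_kc$direct)
  }
  if (any(!is.finite(lim)) || any(lim <= 0)) {
    abort(sprintf("non-positive stability limit for: %s",
                  paste(names(lim)[!is.finite(lim) | lim <= 0],
                        collapse = ", ")))
  }
  structure(config$cfl * min(lim), limits = lim)
}

fluid_arg <- function(ps, sph) {
  g <- sph$gravity
  list(pos = ps$pos, vel = ps$vel, mass = ps$mass, rho = ps$rho,
       rho0 = ps$material$rho0, c0 = ps$material$c0, h = ps$kernel$h,
       alpha = sph$alpha, beta = sph$beta, eps = sph$epsilon,
       g = as.numeric(g[1:2]))
}

solid_arg <- function(mesh, prescribed = integer(), rigid = FALSE) {
  m <- mesh$material
  list(X = mesh$X, tri = mesh$tri, mass = mesh$mass, K = m$bulk_modulus,
       Ginf = m$G_inf, Gk = m$G_modes, tauk = m$tau_modes, rho = m$density,
       ra = m$rayleigh_mass, fixed = mesh$fixed,
       prescribed = as.integer(prescribed), rigid = rigid)
}

#' Run the coupled nested FSI simulation
#'
#' Builds the model, synthesizes (or accepts) the seizure roll trace,
#' prescribes it as rigid rotation of the outer uterine boundary, and
#' advances the coupled system: SPH continuity/EOS/momentum for both fluid
#' domains, penalty contact coupling, explicit viscoelastic solid updates.
#' The uterine rotation is applied relative to the trace's initial angle, so
#' the run starts from the stress-free quiescent state. Deterministic for a
#' fixed configuration and seed.
#'
#' At every output step the ten landmark separations, the brain element
#' stress field and per-solid centroid displacements are sampled.
#'
#' @param config A [simulation_config()].
#' @param trace Optional `kin_trace` to use instead of synthesizing one
#'   (must cover `total_time`).
#' @param outdir Optional directory; when given, metrics CSVs, a JSON summary
#'   and VTK-legacy snapshots are written there.
#' @param debug Assert global fluid-solid force balance each step.
#' @return An object of class `fsi_run` with tibbles `metrics` (time,
#'   landmark, level, raw and normalized separation), `stress` (brain stress
#'   scalars over time), `displacement` (relative centroid displacements) and
#'   `diagnostics`.
#' @export
run_simulation <- function(config, trace = NULL, outdir = NULL,
                           debug = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  model <- build_nested_model(config$geometry, config$materials)
  trace <- trace %||% generate_seizure_roll(config$seizure)
  if (max(trace$time_s) < config$total_time) {
    abort(sprintf("trace covers %.3g s but the simulation needs %.3g s",
                  max(trace$time_s), config$total_time))
  }
  dt <- stable_timestep(model, config)
  nsteps <- as.integer(ceiling(config$total_time / dt))
  sample_every <- max(1L, as.integer(round(config$output_dt / dt)))
  snap_every <- if (is.null(config$snapshot_dt)) 0L else
    max(1L, as.integer(round(config$snapshot_dt / dt)))
  tgrid <- (0:(nsteps + 1)) * dt
  theta <- stats::approx(trace$time_s, trace$roll_rad, xout = tgrid,
                         rule = 2)$y
  theta <- theta - theta[1]

  solids <- list(
    solid_arg(model$uterus, prescribed = model$uterus$rings$outer),
    solid_arg(model$fetal_body),
    solid_arg(model$skull, rigid = isTRUE(config$rigid_skull)),
    solid_arg(model$brain))
  surf_names <- names(model$surfaces)
  surfaces <- unname(model$surfaces)
  surf_id <- function(nm) match(nm, surf_names)
  kc <- config$contact_kc
  sp_am <- config$geometry$particle_spacing_amniotic
  sp_cs <- config$geometry$particle_spacing_csf
  wet <- if (isTRUE(config$wetted_walls)) 1 else 0

  if (config$scenario == "nested") {
    fluids <- list(fluid_arg(model$amniotic_fluid, config$sph),
                   fluid_arg(model$csf, config$sph_csf))
    contacts <- list(
      list(type = 0L, fluid = 1L, surface = surf_id("uterus_inner"),
           kc = kc$amniotic, cap = 6 * sp_am, standoff = sp_am / 2,
           tension_range = wet * sp_am / 2, reach = 4 * sp_am),
      list(type = 0L, fluid = 1L, surface = surf_id("fetal_outer"),
           kc = kc$amniotic, cap = 6 * sp_am, standoff = sp_am / 2,
           tension_range = wet * sp_am / 2, reach = 4 * sp_am),
      list(type = 0L, fluid = 2L, surface = surf_id("skull_inner"),
           kc = kc$csf, cap = 6 * sp_cs, standoff = sp_cs / 2,
           tension_range = wet * sp_cs / 2, reach = 4 * sp_cs),
      list(type = 0L, fluid = 2L, surface = surf_id("brain_outer"),
           kc = kc$csf, cap = 6 * sp_cs, standoff = sp_cs / 2,
           tension_range = wet * sp_cs / 2, reach = 4 * sp_cs))
  } else {
    fluids <- list()
    # Without its fluid layer each gap is empty space: the outer structure
    # would rest directly on the inner one. The penalty interface therefore
    # engages at the baseline separation (less a hair, so the rest state is
    # force-free), transmitting motion by direct contact across the void.
    d0_fetal <- min(cpp_min_dist_polyline(
      model$fetal_body$X[model$fetal_body$rings$outer, ],
      model$uterus$X[model$uterus$rings$inner, ], TRUE))
    d0_brain <- min(cpp_min_dist_polyline(
      model$brain$X[model$brain$rings$outer, ],
      model$skull$X[model$skull$rings$inner, ], TRUE))
    contacts <- list(
      list(type = 1L, solid = 2L, nodes = model$fetal_body$rings$outer,
           surface = surf_id("uterus_inner"), kc = kc$direct,
           cap = 2 * config$geometry$amniotic_gap,
           standoff = max(0, d0_fetal - 1e-4),
           tension_range = 0, reach = d0_fetal + 0.01),
      list(type = 1L, solid = 4L, nodes = model$brain$rings$outer,
           surface = surf_id("skull_inner"), kc = kc$direct,
           cap = 2 * config$geometry$csf_gap,
           standoff = max(0, d0_brain - 1e-4),
           tension_range = 0, reach = d0_brain + 0.01))
  }
  # the tie master carries the combined state; a rigid skull must be master
  tie_tab <- model$ties
  if (isTRUE(config$rigid_skull)) {
    tie_tab <- tibble::tibble(solid_a = tie_tab$solid_b,
                              node_a = tie_tab$node_b,
                              solid_b = tie_tab$solid_a,
                              node_b = tie_tab$node_a)
  }
  ties <- lapply(seq_len(nrow(tie_tab)), function(i) as.list(tie_tab[i, ]))
  landmarks <- lapply(seq_len(nrow(model$landmarks)), function(i) {
    list(solid = model$landmarks$solid[i], node = model$landmarks$node[i],
         surface = surf_id(model$landmarks$surface[i]))
  })

  t0 <- Sys.time()
  res <- cpp_fsi_engine(fluids, solids, surfaces, contacts, ties, landmarks,
                        theta, dt, nsteps, sample_every, snap_every,
                        as.integer(config$shepard_every),
                        3L,  # brain (0-based index into the solid list)
                        debug)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  lmn <- model$landmarks$name
  dist <- res$dist
  colnames(dist) <- lmn
  metrics <- tibble::as_tibble(as.data.frame(dist)) |>
    dplyr::mutate(time = res$t) |>
    tidyr::pivot_longer(-"time", names_to = "landmark",
                        values_to = "raw_m") |>
    dplyr::left_join(model$landmarks[, c("name", "level")],
                     by = c(landmark = "name")) |>
    dplyr::arrange(.data$landmark, .data$time) |>
    normalized_series() |>
    dplyr::select("time", "landmark", "level", "raw_m", "normalized")

  principal <- t(apply(res$sig_at_max, 1, function(s4) {
    sort(eigen(tensor3(s4), symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  }))
  vm_max <- apply(res$vm, 1, max)
  tri_tab <- triaxiality(principal[, 1], principal[, 2], principal[, 3])
  stress <- tibble::tibble(
    time = res$t,
    vm_max = vm_max,
    vm_mean = rowMeans(res$vm),
    s1 = principal[, 1], s2 = principal[, 2], s3 = principal[, 3],
    mean_stress = tri_tab$mean_stress,
    triaxiality = tri_tab$triaxiality,
    max_principal_strain = res$strain_max)

  displacement <- tibble::tibble(
    time = res$t,
    brain_skull_m = sqrt((res$cent_ux[, 4] - res$cent_ux[, 3])^2 +
                         (res$cent_uy[, 4] - res$cent_uy[, 3])^2),
    fetus_uterus_m = sqrt((res$cent_ux[, 2] - res$cent_ux[, 1])^2 +
                          (res$cent_uy[, 2] - res$cent_uy[, 1])^2))

  diagnostics <- tibble::tibble(
    time = res$t, theta = res$theta, max_penetration_m = res$pen_max)
  if (length(fluids) == 2) {
    diagnostics$ke_amniotic <- res$ke[, 1]
    diagnostics$ke_csf <- res$ke[, 2]
  }

  run <- structure(list(metrics = metrics, stress = stress,
                        displacement = displacement,
                        diagnostics = diagnostics,
                        landmarks = model$landmarks,
                        scenario = config$scenario, dt = dt,
                        n_steps = nsteps, elapsed_s = elapsed,
                        config = config, final = res[c("fluids", "solids")],
                        snapshots = res$snapshots, model = model),
                   class = "fsi_run")
  if (!is.null(outdir)) write_run_outputs(run, outdir)
  run
}

#' @export
print.fsi_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<fsi_run '%s'> %d steps of %.3g us (%.2f s simulated, %.0f s wall)\n",
              x$scenario, x$n_steps, 1e6 * x$dt, x$n_steps * x$dt,
              x$elapsed_s))
  cat(sprintf("  peak brain von Mises: %.4g Pa\n", g$peak_vm_pa))
  cat(sprintf("  max |1 - d/d0|: inner %.3g, outer %.3g\n",
              g$inner_max_dev, g$outer_max_dev))
  cat(sprintf("  peak brain-skull relative displacement: %.3g mm\n",
              1000 * g$peak_brain_skull_mm))
  invisible(x)
}

#' Run the protected versus unprotected comparison
#'
#' Runs the nested scenario and the no-fluid counterfactual (fluid layers
#' removed, loads transmitted by direct penalty contact) with the same
#' geometry, materials and seizure realization, and reports the attenuation
#' of peak brain von Mises stress and peak brain-skull relative displacement
#' provided by the fluid layers.
#'
#' @param config A [simulation_config()] (its `scenario` field is ignored).
#' @param trace Optional shared `kin_trace`.
#' @param outdir Optional output directory (per-scenario subdirectories).
#' @return An object of class `fsi_comparison`: the two `fsi_run`s plus a
#'   `summary` tibble.
#' @export
run_comparison <- function(config, trace = NULL, outdir = NULL) {
  trace <- trace %||% generate_seizure_roll(config$seizure)
  cfg_n <- config; cfg_n$scenario <- "nested"
  cfg_u <- config; cfg_u$scenario <- "no_fluids"
  nested <- run_simulation(cfg_n, trace = trace,
                           outdir = if (is.null(outdir)) NULL else
                             file.path(outdir, "nested"))
  unprot <- run_simulation(cfg_u, trace = trace,
                           outdir = if (is.null(outdir)) NULL else
                             file.path(outdir, "no_fluids"))
  pk <- function(run) c(vm = max(run$stress$vm_max),
                        disp = max(run$displacement$brain_skull_m))
  pn <- pk(nested); pu <- pk(unprot)
  # negative attenuation (amplification) is expected for the displacement
  # row: direct contact locks the brain to the skull, while the fluid layer
  # lets it move a little; it is flagged in the table rather than warned
  att <- suppressWarnings(attenuation_percent(pn, pu))
  summary <- tibble::tibble(
    quantity = c("peak_brain_von_mises_pa", "peak_brain_skull_displacement_m"),
    nested = pn, no_fluids = pu,
    attenuation_percent = att,
    flag = ifelse(att < 0, "amplification", ""))
  out <- structure(list(nested = nested, no_fluids = unprot,
                        summary = summary),
                   class = "fsi_comparison")
  if (!is.null(outdir)) {
    jsonlite::write_json(summary, file.path(outdir, "comparison.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.fsi_comparison <- function(x, ...) {
  cat("<fsi_comparison>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

write_run_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(run$metrics),
                   file.path(outdir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$stress),
                   file.path(outdir, "stress.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$displacement),
                   file.path(outdir, "displacement.csv"), row.names = FALSE)
  g <- glance(run)
  jsonlite::write_json(as.list(g), file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_model_vtk(run$model, outdir)
  snaps <- run$snapshots
  model <- run$model
  fl_names <- c("amniotic_fluid", "csf")
  so_names <- c("uterus", "fetal_body", "skull", "brain")
  for (si in seq_along(snaps)) {
    sn <- snaps[[si]]
    tag <- sprintf("t%07.3f", sn$time)
    for (q in seq_along(sn$fluids)) {
      f <- sn$fluids[[q]]
      write_vtk_points(file.path(outdir,
                                 sprintf("%s_%s.vtk", fl_names[q], tag)),
                       f$pos,
                       point_data = list(velocity = f$vel, density = f$rho,
                                         pressure = f$p))
    }
    for (q in seq_along(sn$solids)) {
      m <- model[[so_names[q]]]
      write_vtk_mesh(file.path(outdir,
                               sprintf("%s_%s.vtk", so_names[q], tag)),
                     m$X + sn$solids[[q]], m$tri,
                     point_data = list(displacement = sn$solids[[q]]))
    }
  }
  invisible(outdir)
}
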