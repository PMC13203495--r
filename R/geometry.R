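# Parametric nested anatomy: concentric ellipses meshed with linear
# triangles, fluid gaps filled with lattice-seeded SPH particles, and a
# landmark registry for the cushioning distances.

ellipse_perimeter <- function(a, b) {
  # Ramanujan approximation, ample for sizing discretizations
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

ellipse_ring <- function(a, b, n, offset = 0) {
  th <- offset + 2 * pi * (seq_len(n) - 1) / n
  cbind(a * cos(th), b * sin(th))
}

# Triangulate the band between two concentric closed rings given by node
# indices and angular parameters (both CCW). Returns a matrix of triangles.
band_triangulate <- function(idx_a, ang_a, idx_b, ang_b) {
  na <- length(idx_a); nb <- length(idx_b)
  # unwrap: angles ascending from each ring's start
  ang_a <- ang_a - ang_a[1]; ang_a <- ang_a %% (2 * pi)
  ang_b <- ang_b - ang_b[1]; ang_b <- ang_b %% (2 * pi)
  ia <- 1; ib <- 1
  tris <- matrix(0L, na + nb, 3)
  k <- 0
  next_ang <- function(ang, i, n) if (i < n) ang[i + 1] else 2 * pi
  while (ia <= na || ib <= nb) {
    adv_a <- if (ia > na) FALSE
      else if (ib > nb) TRUE
      else next_ang(ang_a, ia, na) <= next_ang(ang_b, ib, nb)
    k <- k + 1
    if (adv_a) {
      i2 <- if (ia < na) ia + 1 else 1
      tris[k, ] <- c(idx_a[ia], idx_b[(ib - 1) %% nb + 1], idx_a[i2])
      ia <- ia + 1
    } else {
      j2 <- if (ib < nb) ib + 1 else 1
      tris[k, ] <- c(idx_a[(ia - 1) %% na + 1], idx_b[(ib - 1) %% nb + 1],
                     idx_b[j2])
      ib <- ib + 1
    }
  }
  tris[seq_len(k), , drop = FALSE]
}

# Structured mesh of the annulus between two concentric ellipses.
annulus_mesh <- function(inner, outer, n_theta, n_r) {
  rings <- lapply(0:n_r, function(r) {
    f <- r / n_r
    ellipse_ring(inner[1] + f * (outer[1] - inner[1]),
                 inner[2] + f * (outer[2] - inner[2]), n_theta)
  })
  X <- do.call(rbind, rings)
  tri <- NULL
  for (r in seq_len(n_r)) {
    base0 <- (r - 1) * n_theta
    base1 <- r * n_theta
    k <- seq_len(n_theta)
    k2 <- c(seq_len(n_theta)[-1], 1)
    tri <- rbind(tri,
                 cbind(base0 + k, base0 + k2, base1 + k2),
                 cbind(base0 + k, base1 + k2, base1 + k))
  }
  list(X = X, tri = tri,
       inner_ring = seq_len(n_theta),
       outer_ring = n_r * n_theta + seq_len(n_theta))
}

# Mesh of a solid ellipse: concentric rings with per-ring node counts
# proportional to perimeter, bands triangulated between rings, central fan.
disk_mesh <- function(semi_axes, edge) {
  a <- semi_axes[1]; b <- semi_axes[2]
  n_r <- max(2, round(min(a, b) / edge))
  fracs <- rev(seq_len(n_r)) / n_r   # 1, ..., 1/n_r (outer to inner)
  X <- NULL; idx <- list(); ang <- list()
  for (j in seq_along(fracs)) {
    f <- fracs[j]
    n_j <- max(10, round(ellipse_perimeter(f * a, f * b) / edge))
    ring <- ellipse_ring(f * a, f * b, n_j)
    idx[[j]] <- nrow(X %||% matrix(0, 0, 2)) + seq_len(n_j)
    ang[[j]] <- 2 * pi * (seq_len(n_j) - 1) / n_j
    X <- rbind(X, ring)
  }
  centre <- nrow(X) + 1L
  X <- rbind(X, c(0, 0))
  tri <- NULL
  for (j in seq_len(n_r - 1)) {
    tri <- rbind(tri, band_triangulate(idx[[j]], ang[[j]],
                                       idx[[j + 1]], ang[[j + 1]]))
  }
  inner <- idx[[n_r]]
  n_in <- length(inner)
  fan <- cbind(inner, rep(centre, n_in), c(inner[-1], inner[1]))
  tri <- rbind(tri, fan)
  list(X = X, tri = tri, outer_ring = idx[[1]])
}

#' Deformable solid mesh
#'
#' Linear-triangle mesh with lumped nodal masses and a viscoelastic material.
#' Elements are reoriented counter-clockwise; degenerate elements are an
#' error. `rings` holds named index vectors of boundary node loops (ordered
#' counter-clockwise) used as contact/measurement surfaces.
#'
#' @param X Node coordinate matrix (n x 2, metres).
#' @param tri Element connectivity (m x 3, 1-based node indices).
#' @param material A [viscoelastic_material()].
#' @param name Component name.
#' @param fixed Logical n x 2 matrix of fixed degrees of freedom (default
#'   none).
#' @param rings Named list of boundary node-index loops.
#' @return An object of class `solid_mesh` with lumped `mass` per node.
#' @export
solid_mesh <- function(X, tri, material, name = "solid", fixed = NULL,
                       rings = list()) {
  stopifnot(is.matrix(X), ncol(X) == 2, is.matrix(tri), ncol(tri) == 3)
  tri <- matrix(as.integer(tri), ncol = 3)
  a2 <- (X[tri[, 2], 1] - X[tri[, 1], 1]) * (X[tri[, 3], 2] - X[tri[, 1], 2]) -
        (X[tri[, 3], 1] - X[tri[, 1], 1]) * (X[tri[, 2], 2] - X[tri[, 1], 2])
  flip <- a2 < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  area <- abs(a2) / 2
  if (any(area <= 1e-14)) {
    abort(sprintf("degenerate element(s): %s",
                  paste(which(area <= 1e-14), collapse = ", ")))
  }
  mass <- numeric(nrow(X))
  share <- material$density * area / 3
  for (k in 1:3) {
    acc <- tapply(share, tri[, k], sum)
    mass[as.integer(names(acc))] <- mass[as.integer(names(acc))] + acc
  }
  if (is.null(fixed)) fixed <- matrix(FALSE, nrow(X), 2)
  structure(list(name = name, X = X, tri = tri, material = material,
                 mass = mass, area = area, fixed = fixed, rings = rings),
            class = "solid_mesh")
}

#' @export
print.solid_mesh <- function(x, ...) {
  cat(sprintf("<solid_mesh '%s'> %d nodes, %d elements, mass %.3g kg/m\n",
              x$name, nrow(x$X), nrow(x$tri), sum(x$mass)))
  invisible(x)
}

#' SPH particle set
#'
#' @param pos,vel Particle positions / velocities (n x d matrices, d = 2
#'   or 3).
#' @param mass Particle masses (kg in 3-D, kg per metre of depth in 2-D).
#' @param material A [fluid_material()].
#' @param kernel A [kernel_spec()].
#' @param rho,p Densities (kg/m^d) and pressures (Pa); default reference
#'   density and zero.
#' @return An object of class `particle_set`.
#' @export
particle_set <- function(pos, vel = NULL, mass, material, kernel,
                         rho = NULL, p = NULL) {
  stopifnot(is.matrix(pos), ncol(pos) %in% c(2, 3))
  n <- nrow(pos)
  vel <- vel %||% matrix(0, n, ncol(pos))
  rho <- rho %||% rep(material$rho0, n)
  p <- p %||% rep(0, n)
  if (length(mass) == 1) mass <- rep(mass, n)
  stopifnot(nrow(vel) == n, length(mass) == n, length(rho) == n,
            length(p) == n, all(mass > 0), all(rho > 0))
  structure(list(pos = pos, vel = vel, mass = mass, rho = rho, p = p,
                 material = material, kernel = kernel),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles, h = %.3g m, rho0 = %g kg/m^%d\n",
              nrow(x$pos), x$kernel$h, x$material$rho0, ncol(x$pos)))
  invisible(x)
}

#' @method as_tibble particle_set
#' @export
as_tibble.particle_set <- function(x, ...) {
  d <- ncol(x$pos)
  out <- tibble::tibble(x = x$pos[, 1], y = x$pos[, 2],
                        vx = x$vel[, 1], vy = x$vel[, 2],
                        mass = x$mass, rho = x$rho, p = x$p)
  if (d == 3) {
    out$z <- x$pos[, 3]
    out$vz <- x$vel[, 3]
  }
  out
}

#' Seed SPH particles in the gap between two concentric ellipses
#'
#' Particles are placed on a regular lattice with the given spacing, clipped
#' to the annular region between the two surfaces with a half-spacing wall
#' offset on both sides (the usual SPH wall gap, so no particle starts in
#' penalty contact). Per-particle mass is `rho0 * spacing^d`; densities start
#' at the reference density and pressures at zero (stress-free, quiescent).
#'
#' @param inner Semi-axes (m) of the inner bounding surface, or `NULL` to
#'   fill the full ellipse.
#' @param outer Semi-axes (m) of the outer bounding surface.
#' @param spacing Lattice spacing (m); must be smaller than the minimum gap.
#' @param material A [fluid_material()].
#' @param dim Spatial dimension, 2 (default) or 3 (axis-aligned ellipsoids).
#' @param h Smoothing length; default `1.3 * spacing`.
#' @param margin Wall offset (m); default half a spacing.
#' @return A [particle_set()].
#' @export
seed_fluid_particles <- function(inner, outer, spacing, material,
                                 dim = 2, h = 1.3 * spacing,
                                 margin = spacing / 2) {
  stopifnot(length(outer) == dim, spacing > 0)
  if (!is.null(inner)) {
    stopifnot(length(inner) == dim)
    gaps <- outer - inner
    if (any(gaps <= spacing)) {
      abort(sprintf("particle spacing %.4g m is not smaller than the minimum gap %.4g m",
                    spacing, min(gaps)))
    }
  }
  ax <- lapply(seq_len(dim), function(k) {
    n <- floor(outer[k] / spacing)
    (seq(-n, n) + 0.5) * spacing
  })
  grid <- as.matrix(expand.grid(ax))
  colnames(grid) <- NULL
  out_ab <- outer - margin
  keep <- rowSums(sweep(grid, 2, out_ab, "/")^2) <= 1
  if (!is.null(inner)) {
    in_ab <- inner + margin
    keep <- keep & rowSums(sweep(grid, 2, in_ab, "/")^2) >= 1
  }
  pos <- grid[keep, , drop = FALSE]
  if (nrow(pos) == 0) abort("empty fluid region: no lattice point fits between the surfaces")
  particle_set(pos, mass = material$rho0 * spacing^dim,
               material = material, kernel = kernel_spec(h))
}

#' Configuration of the parametric nested anatomy
#'
#' Concentric ellipses stand in for the patient-specific anatomy: uterine
#' cavity / wall, amniotic gap, fetal body, skull, cerebrospinal fluid gap,
#' brain. All dimensions are user-set; the defaults are plausible
#' mid-gestation placeholders (no published dimensions exist for the original
#' geometry) chosen to preserve the nested-layer topology the analysis
#' measures. `uterus_semi_axes` are the semi-axes of the *cavity* (the inner
#' wall surface); the outer wall surface lies `uterine_wall_thickness`
#' further out. Gaps are exact at the axis poles: the fetal body semi-axes
#' plus `amniotic_gap` equal the cavity semi-axes, and the brain semi-axes
#' plus `csf_gap` equal the inner skull semi-axes, for the defaults.
#'
#' @param spatial_dimension 2 (the supported simulation dimension; the
#'   particle and distance operators also work in 3-D, but solid meshing and
#'   the coupled engine are 2-D).
#' @param uterus_semi_axes Cavity (inner wall) semi-axes (m).
#' @param uterine_wall_thickness Wall thickness (m).
#' @param amniotic_gap Fetal-body-to-cavity gap at the poles (m).
#' @param fetal_body_semi_axes Fetal body semi-axes (m).
#' @param skull_semi_axes Outer skull semi-axes (m).
#' @param skull_thickness Skull thickness (m).
#' @param csf_gap Brain-to-inner-skull gap at the poles (m).
#' @param brain_semi_axes Brain semi-axes (m).
#' @param particle_spacing_amniotic,particle_spacing_csf Lattice spacings of
#'   the two fluid fills (m); the CSF spacing must resolve the CSF gap.
#' @param mesh_edge_length Target element edge (m).
#' @param random_seed Integer seed recorded with the model (construction is
#'   deterministic; the seed is echoed for provenance).
#' @return Validated list of class `nested_model_config`.
#' @export
nested_model_config <- function(spatial_dimension = 2,
                                uterus_semi_axes = c(0.115, 0.090),
                                uterine_wall_thickness = 0.010,
                                amniotic_gap = 0.020,
                                fetal_body_semi_axes = c(0.095, 0.070),
                                skull_semi_axes = c(0.042, 0.038),
                                skull_thickness = 0.005,
                                csf_gap = 0.006,
                                brain_semi_axes = c(0.031, 0.027),
                                particle_spacing_amniotic = 0.0025,
                                particle_spacing_csf = 0.0012,
                                mesh_edge_length = 0.006,
                                random_seed = 1L) {
  if (!spatial_dimension %in% 2) {
    abort("only spatial_dimension = 2 is supported by the coupled model builder")
  }
  lens <- c(uterus_semi_axes, uterine_wall_thickness, amniotic_gap,
            fetal_body_semi_axes, skull_semi_axes, skull_thickness, csf_gap,
            brain_semi_axes, particle_spacing_amniotic, particle_spacing_csf,
            mesh_edge_length)
  if (any(lens <= 0)) abort("all lengths must be positive")
  skull_inner <- skull_semi_axes - skull_thickness
  if (any(skull_inner <= 0)) abort("skull thickness exceeds the skull semi-axes")
  if (any(brain_semi_axes >= skull_inner)) {
    abort(sprintf(
      "csf gap violated: brain semi-axes (%s m) must be strictly inside the inner skull (%s m)",
      paste(brain_semi_axes, collapse = ", "),
      paste(skull_inner, collapse = ", ")))
  }
  if (any(fetal_body_semi_axes >= uterus_semi_axes)) {
    abort(sprintf(
      "amniotic gap violated: fetal body semi-axes (%s m) must be strictly inside the uterine cavity (%s m)",
      paste(fetal_body_semi_axes, collapse = ", "),
      paste(uterus_semi_axes, collapse = ", ")))
  }
  if (any(skull_semi_axes >= fetal_body_semi_axes)) {
    abort("skull must lie strictly inside the fetal body")
  }
  if (particle_spacing_csf >= csf_gap) {
    abort("csf particle spacing must be smaller than the csf gap")
  }
  if (particle_spacing_amniotic >= amniotic_gap) {
    abort("amniotic particle spacing must be smaller than the amniotic gap")
  }
  structure(list(spatial_dimension = spatial_dimension,
                 uterus_semi_axes = uterus_semi_axes,
                 uterine_wall_thickness = uterine_wall_thickness,
                 amniotic_gap = amniotic_gap,
                 fetal_body_semi_axes = fetal_body_semi_axes,
                 skull_semi_axes = skull_semi_axes,
                 skull_thickness = skull_thickness,
                 csf_gap = csf_gap,
                 brain_semi_axes = brain_semi_axes,
                 particle_spacing_amniotic = particle_spacing_amniotic,
                 particle_spacing_csf = particle_spacing_csf,
                 mesh_edge_length = mesh_edge_length,
                 random_seed = as.integer(random_seed)),
            class = "nested_model_config")
}

ring_node_at_angle <- function(X, ring, angle) {
  ang <- atan2(X[ring, 2], X[ring, 1])
  d <- abs(((ang - angle + pi) %% (2 * pi)) - pi)
  ring[which.min(d)]
}

#' Build the nested anatomical model
#'
#' Constructs the four solid meshes (uterine wall, fetal body, skull, brain),
#' the two fluid particle fills (amniotic fluid, cerebrospinal fluid), the
#' rigid junction between the fetal body and the skull (coincident interface
#' nodes), the contact surfaces and the landmark registry with baseline
#' distances. The initial state is stress-free and quiescent. Construction is
#' deterministic: the same configuration yields a bit-identical model.
#'
#' Landmarks follow the cushioning-distance convention: four outer pairs
#' between fetal-body surface points and the uterine wall (frontal lobe,
#' occipital lobe, placenta, lower back: `dFL_U`, `dOL_U`, `dP_U`, `dLB_U`)
#' and six inner pairs between brain surface points and the skull (left/right
#' frontal, occipital, hemisphere: `dLFL_S`, `dRFL_S`, `dLOL_S`, `dROL_S`,
#' `dLH_S`, `dRH_S`).
#'
#' @param config A [nested_model_config()].
#' @param materials Material set as from [default_materials()].
#' @return An object of class `nested_model`.
#' @export
build_nested_model <- function(config, materials = default_materials()) {
  stopifnot(inherits(config, "nested_model_config"))
  edge <- config$mesh_edge_length
  head_edge <- min(edge, 3.5 * config$particle_spacing_csf)
  skull_inner <- config$skull_semi_axes - config$skull_thickness

  # uterine wall annulus
  nt_u <- max(24, round(ellipse_perimeter(config$uterus_semi_axes[1],
                                          config$uterus_semi_axes[2]) / edge))
  nr_u <- max(1, round(config$uterine_wall_thickness / edge))
  um <- annulus_mesh(config$uterus_semi_axes,
                     config$uterus_semi_axes + config$uterine_wall_thickness,
                     nt_u, nr_u)
  uterus <- solid_mesh(um$X, um$tri, materials$uterus, "uterus",
                       rings = list(inner = um$inner_ring,
                                    outer = um$outer_ring))

  # fetal body + skull share the interface discretization (tied nodes)
  nt_head <- max(24, round(ellipse_perimeter(config$skull_semi_axes[1],
                                             config$skull_semi_axes[2]) /
                           head_edge))
  nr_f <- max(2, round((config$fetal_body_semi_axes[1] -
                        config$skull_semi_axes[1]) / edge))
  fm <- annulus_mesh(config$skull_semi_axes, config$fetal_body_semi_axes,
                     nt_head, nr_f)
  fetal <- solid_mesh(fm$X, fm$tri, materials$fetal_body, "fetal_body",
                      rings = list(inner = fm$inner_ring,
                                   outer = fm$outer_ring))
  nr_s <- max(1, round(config$skull_thickness / head_edge))
  sm <- annulus_mesh(skull_inner, config$skull_semi_axes, nt_head, nr_s)
  skull <- solid_mesh(sm$X, sm$tri, materials$skull, "skull",
                      rings = list(inner = sm$inner_ring,
                                   outer = sm$outer_ring))

  bm <- disk_mesh(config$brain_semi_axes, head_edge)
  brain <- solid_mesh(bm$X, bm$tri, materials$brain, "brain",
                      rings = list(outer = bm$outer_ring))

  amniotic <- seed_fluid_particles(config$fetal_body_semi_axes,
                                   config$uterus_semi_axes,
                                   config$particle_spacing_amniotic,
                                   materials$amniotic)
  csf <- seed_fluid_particles(config$brain_semi_axes, skull_inner,
                              config$particle_spacing_csf, materials$csf)

  # solid order: 1 uterus, 2 fetal body, 3 skull, 4 brain
  surfaces <- list(
    uterus_inner = list(solid = 1L, nodes = uterus$rings$inner, orient = -1L),
    fetal_outer = list(solid = 2L, nodes = fetal$rings$outer, orient = 1L),
    skull_inner = list(solid = 3L, nodes = skull$rings$inner, orient = -1L),
    brain_outer = list(solid = 4L, nodes = brain$rings$outer, orient = 1L)
  )

  ties <- tibble::tibble(solid_a = 2L, node_a = fetal$rings$inner,
                         solid_b = 3L, node_b = skull$rings$outer)
  stopifnot(max(abs(fetal$X[ties$node_a, ] - skull$X[ties$node_b, ])) < 1e-12)

  deg <- pi / 180
  lm_def <- tibble::tibble(
    name = c("dFL_U", "dOL_U", "dP_U", "dLB_U",
             "dLFL_S", "dRFL_S", "dLOL_S", "dROL_S", "dLH_S", "dRH_S"),
    level = c(rep("outer", 4), rep("inner", 6)),
    angle = c(0, pi, pi / 2, -pi / 2,
              20 * deg, -20 * deg, 160 * deg, -160 * deg, 90 * deg, -90 * deg),
    solid = c(rep(2L, 4), rep(4L, 6)),
    surface = c(rep("uterus_inner", 4), rep("skull_inner", 6))
  )
  solids <- list(uterus, fetal, skull, brain)
  lm_def$node <- vapply(seq_len(nrow(lm_def)), function(i) {
    s <- solids[[lm_def$solid[i]]]
    as.integer(ring_node_at_angle(s$X, s$rings$outer, lm_def$angle[i]))
  }, integer(1))
  lm_def$baseline_m <- vapply(seq_len(nrow(lm_def)), function(i) {
    s <- solids[[lm_def$solid[i]]]
    sf <- surfaces[[lm_def$surface[i]]]
    ss <- solids[[sf$solid]]
    min_distance(s$X[lm_def$node[i], , drop = FALSE],
                 ss$X[sf$nodes, , drop = FALSE])
  }, numeric(1))
  if (any(lm_def$baseline_m <= 0)) abort("landmark baseline distance is not positive")

  structure(list(config = config,
                 uterus = uterus, fetal_body = fetal, skull = skull,
                 brain = brain, amniotic_fluid = amniotic, csf = csf,
                 surfaces = surfaces, ties = ties,
                 landmarks = lm_def[, c("name", "level", "solid", "node",
                                        "surface", "baseline_m")]),
            class = "nested_model")
}

#' @export
print.nested_model <- function(x, ...) {
  cat("<nested_model>\n")
  for (nm in c("uterus", "fetal_body", "skull", "brain")) print(x[[nm]])
  cat(sprintf("  amniotic fluid: %d particles; csf: %d particles\n",
              nrow(x$amniotic_fluid$pos), nrow(x$csf$pos)))
  cat(sprintf("  %d landmarks, baselines %.1f-%.1f mm\n",
              nrow(x$landmarks), 1000 * min(x$landmarks$baseline_m),
              1000 * max(x$landmarks$baseline_m)))
  invisible(x)
}
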