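#' Fluid material for a weakly compressible SPH domain
#'
#' The equation of state is linear, `p = c0^2 (rho - rho0)`. The numerical
#' sound speed `c0` is not the physical one: it is chosen by the
#' weak-compressibility rule (at least ten times the largest expected material
#' speed) so that density variations stay near 1% while the explicit time step
#' remains practical. Physical shear viscosity is recorded for reference but
#' is represented through the Monaghan artificial-viscosity term of the
#' momentum equation (see [sph_params()]), which is the only dissipative term
#' in the discretized momentum balance.
#'
#' @param reference_density Reference density rho0 (kg/m^3). Water-like fluids
#'   (amniotic fluid, cerebrospinal fluid) use 1000.
#' @param sound_speed Numerical sound speed c0 (m/s), > 0.
#' @param dynamic_viscosity Dynamic viscosity mu (Pa s), >= 0; water-like
#'   fluids use about 0.001.
#' @return An object of class `fluid_material`.
#' @export
fluid_material <- function(reference_density = 1000,
                           sound_speed = 10,
                           dynamic_viscosity = 0.001) {
  stopifnot(reference_density > 0, sound_speed > 0, dynamic_viscosity >= 0)
  structure(list(rho0 = reference_density, c0 = sound_speed,
                 mu = dynamic_viscosity),
            class = "fluid_material")
}

#' Cubic spline kernel specification
#'
#' The smoothing kernel family is the cubic B-spline with compact support
#' radius `2 h`. `h` defaults to 1.3 times the particle spacing when particle
#' sets are seeded.
#'
#' @param h Smoothing length (m), > 0.
#' @return An object of class `kernel_spec` with fields `family`, `h` and
#'   `support_radius` (= 2 h).
#' @export
kernel_spec <- function(h) {
  stopifnot(is.numeric(h), length(h) == 1, h > 0)
  structure(list(family = "cubic_spline", h = h, support_radius = 2 * h),
            class = "kernel_spec")
}

#' Numerical parameters of the SPH momentum equation
#'
#' @param alpha,beta Monaghan artificial-viscosity coefficients (dimensionless,
#'   >= 0); the term acts only on approaching particle pairs.
#' @param gravity Gravity vector (m/s^2), length 2 (or 3 for the
#'   dimension-agnostic operators).
#' @param epsilon Denominator regularization of the artificial-viscosity
#'   term (dimensionless).
#' @return An object of class `sph_params`.
#' @export
sph_params <- function(alpha = 1, beta = 2, gravity = c(0, 0),
                       epsilon = 0.01) {
  stopifnot(alpha >= 0, beta >= 0, epsilon > 0, length(gravity) %in% c(2, 3))
  structure(list(alpha = alpha, beta = beta, gravity = gravity,
                 epsilon = epsilon),
            class = "sph_params")
}

#' Generalized Maxwell (Prony series) viscoelastic solid material
#'
#' Shear response follows the relaxation modulus
#' `G(t) = G_inf + sum_k G_k exp(-t / tau_k)`; the volumetric response is
#' linear elastic with modulus `bulk_modulus`, i.e. viscoelasticity acts on
#' the deviatoric part only, the standard reading of a shear relaxation
#' modulus. Damping `C` of the solid equation of motion is mass-proportional
#' Rayleigh damping with coefficient `rayleigh_mass` (1/s).
#'
#' No quantitative fetal-tissue moduli are available; the defaults used by
#' [default_materials()] are documented placeholders (see that help page for
#' the reasoning behind the chosen stiffness scale).
#'
#' @param G_inf Long-term shear modulus (Pa), > 0.
#' @param G_modes Shear moduli of the Maxwell modes (Pa), >= 0.
#' @param tau_modes Relaxation times of the modes (s), > 0; same length as
#'   `G_modes`.
#' @param density Mass density (kg/m^3), > 0.
#' @param bulk_modulus Elastic bulk modulus (Pa), > 0.
#' @param rayleigh_mass Mass-proportional damping coefficient (1/s), >= 0.
#' @return An object of class `viscoelastic_material`.
#' @export
viscoelastic_material <- function(G_inf, G_modes = numeric(),
                                  tau_modes = numeric(), density,
                                  bulk_modulus, rayleigh_mass = 0) {
  stopifnot(G_inf > 0, all(G_modes >= 0), all(tau_modes > 0),
            length(G_modes) == length(tau_modes),
            density > 0, bulk_modulus > 0, rayleigh_mass >= 0)
  structure(list(G_inf = G_inf, G_modes = as.numeric(G_modes),
                 tau_modes = as.numeric(tau_modes), density = density,
                 bulk_modulus = bulk_modulus, rayleigh_mass = rayleigh_mass),
            class = "viscoelastic_material")
}

#' Default material set for the nested model
#'
#' Fluids use the printed water-like values (density 1000 kg/m^3, viscosity
#' 0.001 Pa s); numerical sound speeds follow the weak-compressibility rule
#' for the expected wall speeds (amniotic fluid sees the driven uterine wall,
#' the cerebrospinal fluid only the strongly attenuated skull motion). The
#' solid moduli are placeholders (no fetal measurements exist); they are
#' chosen soft enough for desk-scale explicit integration and keep the
#' qualitative ordering skull >> brain ~ uterus ~ fetal body. The brain and
#' skull moduli sit at the effective stiffness scale the reported stress
#' magnitudes imply (tens of kPa stresses at small strain), far softer than
#' adult bone yet stiff enough that the cranial vault keeps its shape under
#' the fluid-pressure loads of the scaled scenario; they are desk-scale
#' surrogates, not physiological measurements.
#'
#' @return Named list with components `uterus`, `fetal_body`, `skull`,
#'   `brain` ([viscoelastic_material()]) and `amniotic`, `csf`
#'   ([fluid_material()]).
#' @export
default_materials <- function() {
  list(
    uterus = viscoelastic_material(G_inf = 10e3, G_modes = 15e3,
                                   tau_modes = 0.1, density = 1050,
                                   bulk_modulus = 150e3, rayleigh_mass = 5),
    fetal_body = viscoelastic_material(G_inf = 8e3, G_modes = 8e3,
                                       tau_modes = 0.1, density = 1000,
                                       bulk_modulus = 100e3,
                                       rayleigh_mass = 5),
    skull = viscoelastic_material(G_inf = 400e3, G_modes = 200e3,
                                  tau_modes = 0.05, density = 1500,
                                  bulk_modulus = 800e3, rayleigh_mass = 5),
    brain = viscoelastic_material(G_inf = 30e3, G_modes = 30e3,
                                  tau_modes = 0.05, density = 1040,
                                  bulk_modulus = 200e3, rayleigh_mass = 5),
    amniotic = fluid_material(1000, sound_speed = 10,
                              dynamic_viscosity = 0.001),
    csf = fluid_material(1000, sound_speed = 10, dynamic_viscosity = 0.001)
  )
}

#' Penalty contact specification
#'
#' The interface force on a penetrating point is `F = kc * delta * n` along
#' the outward surface normal, with the exact opposite distributed to the
#' nodes of the penetrated element (frictionless, purely normal). The default
#' stiffness sizing `kc = rho0 c0^2` (per unit depth in 2-D) keeps the
#' steady penetration under hydrostatic-scale pressures below about a tenth
#' of a particle spacing: a particle column of width `s` under pressure `p`
#' penetrates by `p s / kc`, and dynamic pressures are at most of order
#' `rho0 c0 v` with `v <= c0 / 10`.
#'
#' @param kc Contact stiffness (N/m per metre of penetration, per unit depth),
#'   > 0.
#' @param cap Penetration depth (m) beyond which the run aborts with
#'   diagnostics (indicates a misconfigured `kc` or time step).
#' @return An object of class `contact_spec`.
#' @export
contact_spec <- function(kc, cap = Inf) {
  stopifnot(kc > 0, cap > 0)
  structure(list(kc = kc, cap = cap), class = "contact_spec")
}

#' @rdname contact_spec
#' @param material A [fluid_material()] whose `rho0 c0^2` sizes the stiffness.
#' @export
default_contact_stiffness <- function(material) {
  material$rho0 * material$c0^2
}
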