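#' Ion species description
#'
#' @param charge_number signed integer multiple of the elementary charge
#'   (e.g. 3 for an effective charge of \eqn{3e}). Must be nonzero.
#' @param effective_mass ion effective mass in kg. For convenience,
#'   `effective_mass_me` may be given instead (mass in electron masses).
#' @param effective_mass_me ion effective mass in units of the electron mass.
#' @param label optional text label.
#' @return An object of class `ion_species`.
#' @examples
#' ion_species(charge_number = 3, effective_mass_me = 1e4)
#' @export
ion_species <- function(charge_number, effective_mass = NULL,
                        effective_mass_me = NULL, label = "") {
  if (is.null(effective_mass)) {
    if (is.null(effective_mass_me))
      stop("supply effective_mass (kg) or effective_mass_me")
    effective_mass <- effective_mass_me * physical_constants()$electron_mass_me
  }
  if (!is.numeric(charge_number) || length(charge_number) != 1 ||
      charge_number == 0 || charge_number != round(charge_number))
    stop("charge_number must be a nonzero integer")
  if (!is.numeric(effective_mass) || effective_mass <= 0)
    stop("effective_mass must be > 0")
  structure(list(charge_number = as.integer(charge_number),
                 effective_mass = effective_mass,
                 label = label),
            class = "ion_species")
}

#' Electrolyte description
#'
#' The equilibrium ion concentration can be given directly (`concentration`,
#' ions per cubic metre) or via the molarity \eqn{\eta}, in which case
#' \eqn{n = \eta N_0} with \eqn{N_0} the one-molar concentration.
#'
#' @param molarity molarity \eqn{\eta} in mol/L (optional if `concentration`
#'   is given).
#' @param concentration equilibrium ion concentration \eqn{n} in 1/m^3.
#' @param reference_N0 one-molar ion concentration \eqn{N_0} in 1/m^3 per
#'   molar; defaults to the Avogadro-based value.
#' @param inner_permittivity relative permittivity \eqn{\epsilon} of the
#'   electrolyte interior (dimensionless, >= 1 not required: the model treats
#'   it as a pure Coulomb renormalization).
#' @param temperature temperature in K.
#' @param mean_free_path bulk ion mean free path \eqn{\lambda_b} in m.
#' @return An object of class `electrolyte`.
#' @examples
#' electrolyte(molarity = 1e-2, temperature = 300, mean_free_path = 1e-7)
#' @export
electrolyte <- function(molarity = NULL, concentration = NULL,
                        reference_N0 = physical_constants()$one_molar_N0,
                        inner_permittivity = 1, temperature = 300,
                        mean_free_path) {
  if (is.null(concentration)) {
    if (is.null(molarity)) stop("supply molarity or concentration")
    concentration <- molarity * reference_N0
  } else if (!is.null(molarity)) {
    if (abs(concentration - molarity * reference_N0) >
        1e-9 * abs(concentration))
      stop("concentration and molarity * N0 disagree")
  }
  stopifnot(concentration > 0, temperature > 0, mean_free_path > 0,
            inner_permittivity > 0)
  structure(list(molarity = molarity,
                 reference_N0 = reference_N0,
                 concentration = concentration,
                 inner_permittivity = inner_permittivity,
                 temperature = temperature,
                 mean_free_path = mean_free_path),
            class = "electrolyte")
}

#' Bounded spherical electrolyte system
#'
#' Complete physical description of a spherical electrolyte compartment of
#' radius `radius` filled with `electrolyte` whose mobile carriers are `ion`,
#' embedded in a medium of relative permittivity `outer_permittivity`
#' (\eqn{\epsilon_1}) behind an insulating membrane characterized by the
#' boundary-scattering constant `boundary_C`.
#'
#' `plasma_frequency_override`, when set, pins the bulk plasmon frequency
#' \eqn{\omega_p} to an externally supplied value instead of the value implied
#' by the concentration; the bundled presets use it so that every downstream
#' quantity is computed from the canonical printed \eqn{\omega_p}.
#'
#' @param radius sphere radius a in m.
#' @param electrolyte an [electrolyte()] object.
#' @param ion an [ion_species()] object.
#' @param outer_permittivity relative permittivity \eqn{\epsilon_1 \ge 1} of
#'   the surroundings.
#' @param boundary_C dimensionless boundary-scattering constant C > 0.
#' @param dof_factor kinetic degrees-of-freedom factor f in {3, 5, 6}:
#'   3 for point-like ions, 5 for linear and 6 for 3D ionic molecules
#'   (rotational degrees of freedom add f kT/2 of mean kinetic energy).
#' @param plasma_frequency_override optional bulk plasmon angular frequency
#'   \eqn{\omega_p} in rad/s.
#' @return An object of class `sphere_system`.
#' @examples
#' sphere_system(radius = 1e-6,
#'               electrolyte = electrolyte(molarity = 1e-2, mean_free_path = 1e-7),
#'               ion = ion_species(3, effective_mass_me = 1e4),
#'               outer_permittivity = 2, boundary_C = 2)
#' @export
sphere_system <- function(radius, electrolyte, ion, outer_permittivity = 1,
                          boundary_C = 1, dof_factor = 3,
                          plasma_frequency_override = NULL) {
  stopifnot(inherits(electrolyte, "electrolyte"), inherits(ion, "ion_species"),
            radius > 0, outer_permittivity >= 1, boundary_C > 0,
            dof_factor %in% c(3, 5, 6))
  if (!is.null(plasma_frequency_override))
    stopifnot(plasma_frequency_override > 0)
  structure(list(radius = radius,
                 electrolyte = electrolyte,
                 ion = ion,
                 outer_permittivity = outer_permittivity,
                 boundary_C = boundary_C,
                 dof_factor = dof_factor,
                 plasma_frequency_override = plasma_frequency_override),
            class = "sphere_system")
}

#' @export
print.sphere_system <- function(x, ...) {
  el <- x$electrolyte
  cat("Spherical electrolyte system\n")
  cat(sprintf("  radius a            : %.4g m\n", x$radius))
  cat(sprintf("  ion                 : Z = %+d, m = %.4g kg (%.3g m_e)%s\n",
              x$ion$charge_number, x$ion$effective_mass,
              x$ion$effective_mass / physical_constants()$electron_mass_me,
              if (nzchar(x$ion$label)) paste0(" [", x$ion$label, "]") else ""))
  cat(sprintf("  concentration n     : %.4g 1/m^3%s\n", el$concentration,
              if (!is.null(el$molarity))
                sprintf(" (%.3g M)", el$molarity) else ""))
  cat(sprintf("  T, eps, eps1, C, f  : %g K, %g, %g, %g, %d\n",
              el$temperature, el$inner_permittivity, x$outer_permittivity,
              x$boundary_C, x$dof_factor))
  cat(sprintf("  lambda_b            : %.4g m\n", el$mean_free_path))
  cat(sprintf("  omega_p             : %.4g rad/s%s\n", plasma_frequency(x),
              if (!is.null(x$plasma_frequency_override)) " (override)" else ""))
  invisible(x)
}

#' Bulk ionic plasmon frequency
#'
#' \eqn{\omega_p = \sqrt{n (Z e)^2 / (\epsilon_0 \epsilon m)}} in SI — the
#' transcription of the Gaussian-unit form \eqn{\omega_p^2 = 4\pi n q'^2/m}
#' with the screened charge \eqn{q'^2 = q^2/\epsilon}. If the system carries a
#' `plasma_frequency_override`, that value is returned unchanged.
#'
#' @param system a [sphere_system()].
#' @return angular frequency in rad/s.
#' @examples
#' sys <- preset_system("sample1")
#' plasma_frequency(sys)   # the preset's pinned value
#' @export
plasma_frequency <- function(system) {
  stopifnot(inherits(system, "sphere_system"))
  if (!is.null(system$plasma_frequency_override))
    return(system$plasma_frequency_override)
  cst <- physical_constants()
  n <- system$electrolyte$concentration
  if (is.null(n) || !is.finite(n) || n <= 0)
    stop("ion concentration unset and no plasma frequency override supplied")
  q <- system$ion$charge_number * cst$elementary_charge_e
  sqrt(n * q^2 /
       (cst$vacuum_permittivity * system$electrolyte$inner_permittivity *
        system$ion$effective_mass))
}

#' Mean thermal ion velocity
#'
#' \eqn{v = \sqrt{3 k T / m}}, the Maxwell-Boltzmann root-mean-square speed
#' entering the scattering attenuation rate.
#'
#' @param T temperature in K, or a [sphere_system()] (in which case `m` is
#'   taken from the system).
#' @param m ion mass in kg.
#' @return speed in m/s.
#' @examples
#' thermal_velocity(300, 1e4 * physical_constants()$electron_mass_me)  # ~1168
#' @export
thermal_velocity <- function(T, m) {
  if (inherits(T, "sphere_system")) {
    m <- T$ion$effective_mass
    T <- T$electrolyte$temperature
  }
  stopifnot(T > 0, m > 0)
  sqrt(3 * physical_constants()$boltzmann_k * T / m)
}

#' Mie (dipole surface plasmon) frequency
#'
#' \eqn{\omega_1 = \omega_p / \sqrt{3 \epsilon_1}}: the l = 1 surface-mode
#' self-frequency of a dielectric-embedded sphere, the ionic analogue of the
#' Mie resonance of metallic nanospheres.
#'
#' @param omega_p bulk plasmon frequency in rad/s, or a [sphere_system()]
#'   (then `eps1` is taken from the system).
#' @param eps1 relative permittivity of the surroundings.
#' @return angular frequency in rad/s.
#' @examples
#' mie_frequency(9.3e13, 2)   # ~3.8e13
#' @export
mie_frequency <- function(omega_p, eps1) {
  if (inherits(omega_p, "sphere_system")) {
    eps1 <- omega_p$outer_permittivity
    omega_p <- plasma_frequency(omega_p)
  }
  stopifnot(omega_p > 0, eps1 >= 1)
  omega_p / sqrt(3 * eps1)
}
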