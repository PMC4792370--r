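#' Ion scattering attenuation rate
#'
#' \eqn{1/\tau_0 = v/(2\lambda_b) + C v/(2a)}: Ohmic-type dissipation from
#' ion-ion/solvent scattering in the bulk (mean free path \eqn{\lambda_b})
#' plus scattering on the membrane, which grows as 1/a and therefore
#' dominates for small compartments.
#'
#' @param v mean thermal ion velocity, m/s.
#' @param lambda_b bulk mean free path, m.
#' @param C dimensionless boundary-scattering constant (order unity).
#' @param a sphere radius, m (vectorized).
#' @return attenuation rate in 1/s.
#' @examples
#' scattering_rate(1168, 1e-7, 2, 1e-6)
#' @export
scattering_rate <- function(v, lambda_b, C, a) {
  stopifnot(v > 0, lambda_b > 0, C > 0, all(a > 0))
  v / (2 * lambda_b) + C * v / (2 * a)
}

#' Perturbative Lorentz-friction attenuation rate
#'
#' First-order radiation-reaction damping of the dipole surface plasmon,
#' \eqn{(\omega_1 / (3\sqrt{\epsilon_1}))\,(\omega_p a / (c\sqrt{3}))^3}.
#' It grows as \eqn{a^3} — the dipole scales with the system volume — so
#' radiative losses overtake scattering beyond the cross-over radius.
#'
#' @param omega_p bulk plasmon frequency, rad/s.
#' @param omega_1 dipole surface plasmon (Mie) frequency, rad/s.
#' @param a sphere radius, m (vectorized).
#' @param eps1 relative permittivity of the surroundings.
#' @return attenuation rate in 1/s.
#' @examples
#' lorentz_rate_perturbative(9.3e13, 3.8e13, 1e-6, 2)
#' @export
lorentz_rate_perturbative <- function(omega_p, omega_1, a, eps1) {
  stopifnot(omega_p > 0, omega_1 > 0, all(a > 0), eps1 >= 1)
  c0 <- physical_constants()$light_speed_c
  omega_1 / (3 * sqrt(eps1)) * (omega_p * a / (c0 * sqrt(3)))^3
}

#' Dimensionless damping parameters u and g
#'
#' \eqn{u = 1/(\tau_0 \omega_1)} (scattering rate in units of the Mie
#' frequency) and \eqn{g = (2/(3\sqrt{\epsilon_1}))(a\omega_p/(c\sqrt 3))^3}
#' (radiation coupling of the cubic characteristic equation). The
#' perturbative dimensionless total attenuation is u + g/2.
#'
#' @param system a [sphere_system()].
#' @param a sphere radius, m; defaults to the system radius (vectorized).
#' @return list with numeric components `u` and `g`.
#' @examples
#' damping_parameters(preset_system("sample1"), a = 8e-6)
#' @export
damping_parameters <- function(system, a = system$radius) {
  stopifnot(inherits(system, "sphere_system"), all(a > 0))
  wp <- plasma_frequency(system)
  w1 <- mie_frequency(wp, system$outer_permittivity)
  v <- thermal_velocity(system)
  c0 <- physical_constants()$light_speed_c
  list(u = scattering_rate(v, system$electrolyte$mean_free_path,
                           system$boundary_C, a) / w1,
       g = 2 / (3 * sqrt(system$outer_permittivity)) *
           (a * wp / (c0 * sqrt(3)))^3)
}

#' Total perturbative attenuation of the dipole surface plasmon
#'
#' Assembles the scattering rate, the perturbative Lorentz-friction rate,
#' their sum \eqn{1/\tau}, the dimensionless parameters u and g, and the
#' red-shifted resonance \eqn{\omega_1' = \omega_1\sqrt{1 - 1/(\omega_1
#' \tau)^2}}. When the dimensionless attenuation \eqn{1/(\omega_1\tau)}
#' reaches 1 the perturbative oscillator is over-damped: `overdamped` is set
#' and `redshifted_omega` is reported as 0.
#'
#' @param system a [sphere_system()].
#' @param a sphere radius, m; defaults to the system radius.
#' @param damping_model one of `"scattering+lorentz_perturbative"` (default),
#'   `"scattering"`, `"none"` — which channels enter the total rate.
#' @return An object of class `damping_breakdown`: list with
#'   `scattering_rate`, `lorentz_rate`, `total_rate` (1/s), `u`, `g`,
#'   `dimensionless_total` (\eqn{1/(\omega_1\tau)}), `omega1`,
#'   `redshifted_omega` (rad/s), `overdamped` (logical).
#' @examples
#' total_attenuation(preset_system("sample1"), a = 1e-6)
#' @export
total_attenuation <- function(system, a = system$radius,
                              damping_model = c("scattering+lorentz_perturbative",
                                                "scattering", "none")) {
  damping_model <- match.arg(damping_model)
  stopifnot(inherits(system, "sphere_system"), a > 0)
  wp <- plasma_frequency(system)
  w1 <- mie_frequency(wp, system$outer_permittivity)
  v <- thermal_velocity(system)
  sc <- scattering_rate(v, system$electrolyte$mean_free_path,
                        system$boundary_C, a)
  lr <- lorentz_rate_perturbative(wp, w1, a, system$outer_permittivity)
  if (damping_model == "none") { sc <- 0; lr <- 0 }
  if (damping_model == "scattering") lr <- 0
  total <- sc + lr
  dl <- total / w1
  over <- dl >= 1
  structure(list(scattering_rate = sc,
                 lorentz_rate = lr,
                 total_rate = total,
                 u = sc / w1,
                 g = damping_parameters(system, a)$g,
                 dimensionless_total = dl,
                 omega1 = w1,
                 redshifted_omega = if (over) 0 else w1 * sqrt(1 - dl^2),
                 overdamped = over,
                 radius = a,
                 damping_model = damping_model),
            class = "damping_breakdown")
}

#' @export
print.damping_breakdown <- function(x, ...) {
  cat(sprintf("Dipole plasmon attenuation at a = %.4g m (%s)\n",
              x$radius, x$damping_model))
  cat(sprintf("  scattering 1/tau0 : %.6g 1/s   (u = %.4g)\n",
              x$scattering_rate, x$u))
  cat(sprintf("  Lorentz (pert.)   : %.6g 1/s   (g = %.4g)\n",
              x$lorentz_rate, x$g))
  cat(sprintf("  total 1/tau       : %.6g 1/s   [1/(omega1 tau) = %.4g]\n",
              x$total_rate, x$dimensionless_total))
  if (x$overdamped) cat("  over-damped: redshifted omega reported as 0\n")
  else cat(sprintf("  omega1' (red-shifted): %.6g rad/s\n",
                   x$redshifted_omega))
  invisible(x)
}

#' Radius of minimal total damping
#'
#' The scattering term falls as 1/a while the radiative term grows as a^3,
#' so the total perturbative rate has a unique interior minimum at
#' \deqn{a^* = \left(\frac{9 C v \epsilon_1 c^3}{2\omega_p^4}\right)^{1/4}.}
#' Both the closed form and a numerical minimizer of the total rate are
#' computed and must agree to `check_tol` (relative).
#'
#' @param system a [sphere_system()].
#' @param check_tol relative agreement demanded between the closed form and
#'   the numerical minimizer.
#' @return radius a* in m (closed form), with attribute `"numerical"`
#'   carrying the minimizer result.
#' @examples
#' optimal_radius(preset_system("sample1"))   # ~2.9e-7 m
#' @export
optimal_radius <- function(system, check_tol = 1e-6) {
  stopifnot(inherits(system, "sphere_system"))
  cst <- physical_constants()
  wp <- plasma_frequency(system)
  v <- thermal_velocity(system)
  a_closed <- (9 * system$boundary_C * v * system$outer_permittivity *
               cst$light_speed_c^3 / (2 * wp^4))^(1 / 4)
  total <- function(a) total_attenuation(system, a)$total_rate
  opt <- stats::optimize(total, c(a_closed / 100, a_closed * 100),
                         tol = a_closed * 1e-12)
  if (abs(opt$minimum - a_closed) > check_tol * a_closed)
    stop(sprintf("closed-form a* (%.6g) and numerical minimizer (%.6g) disagree",
                 a_closed, opt$minimum))
  structure(a_closed, numerical = opt$minimum)
}

#' Radius where the perturbative treatment terminates
#'
#' The smallest radius at which the dimensionless perturbative attenuation
#' \eqn{1/(\omega_1\tau) = u + g/2} reaches unity; beyond it the perturbative
#' oscillator is over-damped and its red-shifted frequency is driven to zero
#' (an artifact cured by the exact treatment). The perturbative description
#' is trustworthy up to about \eqn{\tilde a \simeq a_{limit}/2}, which is
#' returned alongside.
#'
#' @param system a [sphere_system()].
#' @param bracket search interval for the root, m.
#' @return list with `a_limit` and `a_tilde` (= a_limit/2), both in m.
#' @examples
#' perturbative_limit_radius(preset_system("sample1"))  # ~9e-6 m
#' @export
perturbative_limit_radius <- function(system, bracket = c(1e-9, 1e-2)) {
  stopifnot(inherits(system, "sphere_system"), length(bracket) == 2,
            bracket[1] > 0, bracket[2] > bracket[1])
  f <- function(a) {
    p <- damping_parameters(system, a)
    p$u + p$g / 2 - 1
  }
  if (f(bracket[1]) >= 0 || f(bracket[2]) <= 0)
    stop("dimensionless attenuation does not cross 1 inside the bracket")
  root <- stats::uniroot(f, bracket, tol = .Machine$double.eps * bracket[2])$root
  list(a_limit = root, a_tilde = root / 2)
}
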