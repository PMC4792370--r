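#' External driving field
#'
#' The forcing field of the dipole equation of motion. Because the resonant
#' wavelength vastly exceeds the compartment size, the field is spatially
#' uniform over the sphere (dipole approximation) and couples only to the
#' l = 1 surface channel.
#'
#' @param amplitude field amplitude: scalar (applied along z) or length-3
#'   vector `c(Ex, Ey, Ez)`.
#' @param waveform `"none"`, `"constant"`, `"harmonic"` (\eqn{E_0
#'   \cos(\omega t + \phi)}), or `"custom"`.
#' @param omega drive angular frequency, rad/s (harmonic only).
#' @param phase drive phase, rad (harmonic only).
#' @param fun for `"custom"`: function of time returning the scalar envelope
#'   multiplying `amplitude`.
#' @return An object of class `drive_field`; calling it as
#'   `drive$eval(t)` returns the 3-vector field at time t.
#' @examples
#' drive_field(1e-3, "harmonic", omega = 3.8e13)
#' @export
drive_field <- function(amplitude = 0,
                        waveform = c("none", "constant", "harmonic", "custom"),
                        omega = NULL, phase = 0, fun = NULL) {
  waveform <- match.arg(waveform)
  if (length(amplitude) == 1) amplitude <- c(0, 0, amplitude)
  stopifnot(length(amplitude) == 3, all(is.finite(amplitude)))
  if (waveform == "harmonic") stopifnot(is.numeric(omega), omega > 0)
  if (waveform == "custom") stopifnot(is.function(fun))
  env <- switch(waveform,
    none     = function(t) 0,
    constant = function(t) 1,
    harmonic = function(t) cos(omega * t + phase),
    custom   = fun)
  structure(list(amplitude = amplitude, waveform = waveform, omega = omega,
                 phase = phase,
                 eval = function(t) amplitude * env(t)),
            class = "drive_field")
}

.effective_rate <- function(system, damping_model) {
  switch(damping_model,
    none = 0,
    scattering = total_attenuation(system,
                                   damping_model = "scattering")$total_rate,
    lorentz_perturbative = total_attenuation(system)$total_rate)
}

#' Time-domain evolution of the plasmon dipole
#'
#' Integrates the dipole equation of motion
#' \deqn{\ddot{\mathbf D} + \frac{2}{\tau}\dot{\mathbf D} + \omega_1^2
#'   \mathbf D = \epsilon_1 a^3 \omega_1^2 \mathbf E(t)}
#' with the attenuation rate \eqn{1/\tau} selected by `damping_model`:
#' `"none"`, `"scattering"` (\eqn{1/\tau_0} only), `"lorentz_perturbative"`
#' (scattering + first-order radiation reaction), or `"lorentz_exact"`.
#'
#' The exact model never integrates the stiff third-order radiation-reaction
#' equation directly: for free decay (zero drive) the trajectory is
#' synthesized from the decaying \eqn{\Omega_2/\Omega_3} pair of the
#' characteristic cubic, fitted to the initial conditions, with the runaway
#' root discarded by prescription.
#'
#' Default initial conditions are \eqn{\mathbf D = \dot{\mathbf D} = 0}.
#'
#' @param system a [sphere_system()].
#' @param drive a [drive_field()] (default: no drive).
#' @param damping_model character; see above.
#' @param initial_D,initial_dDdt length-3 initial dipole and its time
#'   derivative (scalars are applied along z).
#' @param times strictly increasing sample times, s.
#' @param rel_tol,abs_tol solver tolerances (numerical models).
#' @return An object of class `dipole_trajectory`: list with `times`, and
#'   n-by-3 matrices `D`, `dDdt`, `d2Ddt2`, plus metadata.
#' @examples
#' sys <- preset_system("sample1")
#' tt <- seq(0, 40 * 2 * pi / mie_frequency(sys), length.out = 2000)
#' tr <- evolve_dipole(sys, damping_model = "lorentz_perturbative",
#'                     initial_D = 1e-30, times = tt)
#' @export
evolve_dipole <- function(system, drive = drive_field(),
                          damping_model = c("lorentz_perturbative", "none",
                                            "scattering", "lorentz_exact"),
                          initial_D = c(0, 0, 0), initial_dDdt = c(0, 0, 0),
                          times, rel_tol = 1e-10, abs_tol = 0) {
  damping_model <- match.arg(damping_model)
  stopifnot(inherits(system, "sphere_system"), inherits(drive, "drive_field"),
            length(times) > 1, all(diff(times) > 0))
  if (length(initial_D) == 1) initial_D <- c(0, 0, initial_D)
  if (length(initial_dDdt) == 1) initial_dDdt <- c(0, 0, initial_dDdt)
  stopifnot(length(initial_D) == 3, length(initial_dDdt) == 3)
  w1 <- mie_frequency(system)
  a <- system$radius
  eps1 <- system$outer_permittivity
  pref <- eps1 * a^3 * w1^2         # right-hand prefactor = a^3 omega_p^2 / 3

  overdamped <- FALSE
  if (damping_model == "lorentz_exact") {
    if (drive$waveform != "none" && any(drive$amplitude != 0))
      stop("the exact radiation-damped path supports free decay only")
    sol <- exact_mode_solution(system)
    if (sol$overdamped)
      stop("exact solution over-damped: no oscillatory pair to synthesize")
    O2 <- sol$Omega2
    # D(t) = Re{ (alpha + i beta) exp(i Omega2 w1 t) } per component
    alpha <- initial_D
    beta <- -(initial_dDdt / w1 + alpha * Im(O2)) / Re(O2)
    ph <- outer(times, rep(1, 3)) * w1
    Dc <- exp(1i * O2 * ph) *
      matrix(alpha + 1i * beta, nrow = length(times), ncol = 3, byrow = TRUE)
    D <- Re(Dc)
    dDdt <- Re(Dc * 1i * O2 * w1)
    d2D <- Re(Dc * (1i * O2 * w1)^2)
  } else {
    rate2 <- 2 * .effective_rate(system, damping_model)
    dl <- rate2 / (2 * w1)
    if (dl >= 1) {
      warning("over-damped perturbative regime: monotone decay returned")
      overdamped <- TRUE
    }
    deriv <- function(t, y, parms) {
      D <- y[1:3]; V <- y[4:6]
      E <- drive$eval(t)
      list(c(V, pref * E - rate2 * V - w1^2 * D))
    }
    # absolute tolerance from the natural dipole scale of the problem, so
    # trajectories starting from the zero state remain well conditioned
    scale <- max(abs(initial_D), abs(initial_dDdt) / w1,
                 pref * max(abs(drive$amplitude)) / w1^2)
    if (scale == 0) scale <- 1
    out <- deSolve::lsoda(c(initial_D, initial_dDdt), times, deriv,
                          parms = NULL, rtol = rel_tol,
                          atol = if (abs_tol > 0) abs_tol
                                 else rel_tol * scale)
    D <- unname(out[, 2:4, drop = FALSE])
    dDdt <- unname(out[, 5:7, drop = FALSE])
    Emat <- t(vapply(times, drive$eval, numeric(3)))
    d2D <- pref * Emat - rate2 * dDdt - w1^2 * D
  }
  structure(list(times = times, D = D, dDdt = dDdt, d2Ddt2 = d2D,
                 damping_model = damping_model, omega1 = w1,
                 overdamped = overdamped,
                 rel_tol = rel_tol, system = system),
            class = "dipole_trajectory")
}

#' @export
print.dipole_trajectory <- function(x, ...) {
  cat(sprintf("Dipole trajectory: %d samples over [%.4g, %.4g] s (%s damping)\n",
              length(x$times), min(x$times), max(x$times), x$damping_model))
  cat(sprintf("  |D| range: [%.4g, %.4g]\n",
              min(sqrt(rowSums(x$D^2))), max(sqrt(rowSums(x$D^2)))))
  invisible(x)
}

#' Steady-state response of the driven dipole
#'
#' Closed-form stationary amplitude and phase of the damped driven oscillator
#' under a harmonic drive of amplitude \eqn{E_0}:
#' \deqn{|D| = \frac{\epsilon_1 a^3 \omega_1^2 E_0}
#'   {\sqrt{(\omega_1^2-\omega^2)^2 + 4\omega^2/\tau^2}}, \qquad
#'   \varphi = \mathrm{atan2}(2\omega/\tau,\ \omega_1^2-\omega^2).}
#'
#' @param system a [sphere_system()].
#' @param omega_grid drive frequencies, rad/s.
#' @param E0 drive amplitude (field units).
#' @param damping_model `"lorentz_perturbative"`, `"scattering"`, or
#'   `"none"`.
#' @return data.frame with columns `omega_rad_s`, `amplitude`, `phase_rad`.
#' @examples
#' sys <- preset_system("sample1")
#' steady_state_response(sys, mie_frequency(sys) * c(0.5, 1, 2))
#' @export
steady_state_response <- function(system, omega_grid, E0 = 1,
                                  damping_model = c("lorentz_perturbative",
                                                    "scattering", "none")) {
  damping_model <- match.arg(damping_model)
  stopifnot(inherits(system, "sphere_system"), all(omega_grid >= 0))
  w1 <- mie_frequency(system)
  rate <- .effective_rate(system, damping_model)
  if (rate / w1 >= 1)
    stop("over-damped regime: the oscillatory steady state does not apply")
  pref <- system$outer_permittivity * system$radius^3 * w1^2 * E0
  amp <- pref / sqrt((w1^2 - omega_grid^2)^2 + 4 * omega_grid^2 * rate^2)
  data.frame(omega_rad_s = omega_grid,
             amplitude = amp,
             phase_rad = atan2(2 * omega_grid * rate, w1^2 - omega_grid^2))
}

#' Lorentz friction field along a trajectory
#'
#' \eqn{\mathbf E_L = (2/(3c^3))\, \partial^3 \mathbf D/\partial t^3}: the
#' effective radiation-reaction field of the oscillating dipole. The third
#' derivative is obtained by cubic-spline differentiation of the stored
#' second derivative, which is smooth for all supported damping models.
#' For a pure harmonic \eqn{D = D_0\cos\omega t} the amplitude is
#' \eqn{(2/(3c^3))\,\omega^3 D_0}.
#'
#' @param trajectory a [dipole_trajectory()] (or a list with `times` and `D`
#'   matrices); must resolve the oscillation with at least 4 samples per
#'   period of the mode frequency.
#' @return n-by-3 matrix of E_L samples.
#' @examples
#' sys <- preset_system("sample1")
#' tt <- seq(0, 10 * 2 * pi / mie_frequency(sys), length.out = 800)
#' tr <- evolve_dipole(sys, damping_model = "scattering", initial_D = 1, times = tt)
#' EL <- lorentz_field(tr)
#' @export
lorentz_field <- function(trajectory) {
  stopifnot(inherits(trajectory, "dipole_trajectory"))
  times <- trajectory$times
  dt <- max(diff(times))
  period <- 2 * pi / trajectory$omega1
  if (dt > period / 4)
    stop("trajectory undersampled: need >= 4 points per oscillation period")
  c0 <- physical_constants()$light_speed_c
  d3 <- vapply(1:3, function(k) {
    f <- stats::splinefun(times, trajectory$d2Ddt2[, k], method = "natural")
    f(times, deriv = 1)
  }, numeric(length(times)))
  2 / (3 * c0^3) * d3
}
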