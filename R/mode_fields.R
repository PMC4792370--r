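# Associated Legendre P_l^m(x) for m >= 0, WITHOUT the Condon-Shortley phase,
# by the standard stable upward recurrence in l.
.assoc_legendre <- function(l, m, x) {
  stopifnot(m >= 0, m <= l)
  # P_m^m = (2m-1)!! (1-x^2)^{m/2}
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, 1 - x^2))
    fact <- 1
    for (k in seq_len(m)) {
      pmm <- pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in (m + 2):l) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pmmp1
}

#' Real spherical harmonics
#'
#' Real-valued orthonormal spherical harmonics over the unit sphere:
#' \deqn{Y_{l0} = N_{l0} P_l(\cos\theta), \quad
#'       Y_{lm} = \sqrt{2} N_{lm} P_l^m(\cos\theta)\cos(m\phi)\ (m>0), \quad
#'       Y_{l,-m} = \sqrt{2} N_{lm} P_l^m(\cos\theta)\sin(m\phi),}
#' with \eqn{N_{lm} = \sqrt{(2l+1)(l-m)!/(4\pi (l+m)!)}}. The Condon-Shortley
#' phase is absorbed, so \eqn{Y_{1,0} \propto +\cos\theta} and
#' \eqn{Y_{1,\pm 1} \propto +\sin\theta \{\cos\phi, \sin\phi\}}.
#'
#' @param l degree, integer >= 0.
#' @param m order, integer with |m| <= l.
#' @param theta polar angle in radians (0 at the +z pole).
#' @param phi azimuthal angle in radians.
#' @return numeric vector (recycled over `theta`/`phi`).
#' @examples
#' real_spherical_harmonic(0, 0, 0, 0)        # 1/sqrt(4*pi)
#' real_spherical_harmonic(1, 0, 0, 0)        # sqrt(3/(4*pi))
#' @export
real_spherical_harmonic <- function(l, m, theta, phi) {
  stopifnot(l >= 0, l == round(l), abs(m) <= l, m == round(m))
  n <- max(length(theta), length(phi))
  theta <- rep_len(theta, n)
  phi <- rep_len(phi, n)
  am <- abs(m)
  # log-normalization avoids factorial overflow at large l
  norm <- sqrt((2 * l + 1) / (4 * pi) *
               exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  p <- .assoc_legendre(l, am, cos(theta))
  if (m == 0) norm * p
  else if (m > 0) sqrt(2) * norm * p * cos(am * phi)
  else sqrt(2) * norm * p * sin(am * phi)
}

#' Volume-mode charge-density fluctuation field
#'
#' Density fluctuation of a single volume plasmon mode,
#' \deqn{\delta\rho_1 = n\,A\, j_l(x_{li} r/a)\, Y_{lm}(\theta,\phi)\,
#'       \sin(\omega_{li} t)} for r < a and identically zero for r >= a:
#' the radial profile vanishes at the membrane by construction
#' (\eqn{x_{li}} is a node of \eqn{j_l}) and the fluctuation of each mode
#' lives entirely inside the sphere.
#'
#' @param system a [sphere_system()].
#' @param mode a volume [mode_index()].
#' @param amplitude dimensionless mode amplitude A (arbitrary in the
#'   homogeneous problem; default 1).
#' @param r radius, m (vectorized).
#' @param theta,phi angles, radians.
#' @param t time, s.
#' @return charge-density fluctuation (ions/m^3 times the amplitude
#'   convention), same length as `r`.
#' @examples
#' sys <- preset_system("sample1")
#' volume_mode_density(sys, mode_index("volume", 1, 0, 1),
#'                     r = sys$radius / 2, theta = 0, phi = 0,
#'                     t = 1e-14)
#' @export
volume_mode_density <- function(system, mode, amplitude = 1, r, theta, phi, t) {
  stopifnot(inherits(system, "sphere_system"), inherits(mode, "mode_index"),
            all(r >= 0))
  if (mode$kind != "volume") stop("volume_mode_density needs a volume mode")
  pm <- plasmon_mode(system, mode)
  a <- system$radius
  val <- numeric(length(r))
  inside <- r < a
  if (any(inside)) {
    val[inside] <- system$electrolyte$concentration * amplitude *
      spherical_bessel_j(mode$l, pm$x_li * r[inside] / a) *
      real_spherical_harmonic(mode$l, mode$m, theta, phi) *
      sin(pm$omega * t)
  }
  val
}

#' Surface amplitude induced by one volume mode
#'
#' The surface-charge oscillation driven by a volume plasmon, per unit volume
#' amplitude \eqn{A_{lmi}}:
#' \deqn{n\,\frac{(l+1)\,\omega_p^2}{l\,\omega_p^2 - (2l+1)\,\omega_{li}^2}
#'       \int_0^a \frac{r^{l+2}}{a^{l+2}} j_l(x_{li} r/a)\, dr.}
#' Because \eqn{\omega_{li} \ge \omega_p > \omega_p\sqrt{l/(2l+1)}}, the
#' denominator is negative for every physical volume mode, so the induced
#' surface response is in antiphase with the driving volume oscillation. At
#' T = 0 (\eqn{\omega_{li} = \omega_p}) the coefficient is exactly -1.
#'
#' @param l,i volume-mode indices.
#' @param omega_p bulk plasmon frequency, rad/s.
#' @param omega_li the volume-mode frequency, rad/s.
#' @param a sphere radius, m.
#' @param n ion concentration, 1/m^3.
#' @param rel_tol resonance guard: an error is raised if the denominator is
#'   within `rel_tol` of zero (relative to \eqn{\omega_p^2}).
#' @return induced surface amplitude (same units as `n` times length) per
#'   unit \eqn{A_{lmi}}.
#' @examples
#' induced_surface_amplitude(1, 1, 1e6, 1.2e6, 1e-6, 1e20)
#' @export
induced_surface_amplitude <- function(l, i, omega_p, omega_li, a, n,
                                      rel_tol = 1e-9) {
  stopifnot(l >= 1, i >= 1, omega_p > 0, omega_li > 0, a > 0, n > 0)
  denom <- l * omega_p^2 - (2 * l + 1) * omega_li^2
  if (abs(denom) < rel_tol * omega_p^2)
    stop("singular volume-surface coupling: omega_li at the surface resonance")
  coef <- (l + 1) * omega_p^2 / denom
  x <- bessel_node(l, i)
  # substitute s = r/a: integral = a * int_0^1 s^{l+2} j_l(x s) ds
  radial <- a * stats::integrate(function(s)
    s^(l + 2) * spherical_bessel_j(l, x * s),
    0, 1, rel.tol = 1e-12, abs.tol = 0)$value
  n * coef * radial
}

#' Surface charge-density fluctuation
#'
#' Total surface density on r = a: the surface self-oscillations
#' \eqn{\sum (B_{lm}/a^2) Y_{lm} \sin(\omega_{0l} t)} plus the contribution
#' induced by the excited volume modes (computed through
#' [induced_surface_amplitude()], oscillating at the volume-mode
#' frequencies).
#'
#' @param system a [sphere_system()].
#' @param amplitudes list with optional components `surface` (data.frame with
#'   columns l, m, B) and `volume` (data.frame with columns l, m, i, A).
#' @param theta,phi evaluation angles, radians.
#' @param t time, s.
#' @return surface charge density at the given angle(s) and time.
#' @examples
#' sys <- preset_system("sample1")
#' amp <- list(surface = data.frame(l = 1, m = 0, B = 1))
#' surface_density(sys, amp, theta = pi / 3, phi = 0, t = 1e-14)
#' @export
surface_density <- function(system, amplitudes, theta, phi, t) {
  stopifnot(inherits(system, "sphere_system"))
  a <- system$radius
  wp <- plasma_frequency(system)
  val <- 0
  surf <- amplitudes$surface
  if (!is.null(surf) && nrow(surf) > 0) {
    for (k in seq_len(nrow(surf))) {
      w <- surface_mode_frequency(wp, surf$l[k], system$outer_permittivity)
      val <- val + surf$B[k] / a^2 *
        real_spherical_harmonic(surf$l[k], surf$m[k], theta, phi) *
        sin(w * t)
    }
  }
  vol <- amplitudes$volume
  if (!is.null(vol) && nrow(vol) > 0) {
    for (k in seq_len(nrow(vol))) {
      wli <- volume_mode_frequency(wp, a, system$electrolyte$temperature,
                                   system$ion$effective_mass,
                                   vol$l[k], vol$i[k], system$dof_factor)
      val <- val + vol$A[k] *
        induced_surface_amplitude(vol$l[k], vol$i[k], wp, wli, a,
                                  system$electrolyte$concentration) *
        real_spherical_harmonic(vol$l[k], vol$m[k], theta, phi) *
        sin(wli * t)
    }
  }
  val
}

#' Dipole moment of the l = 1 surface mode
#'
#' Converts the dipole-channel surface amplitudes \eqn{Q_{1m}} into the
#' Cartesian dipole vector:
#' \deqn{D_x = \sqrt{2\pi/3}\, q' Q_{1,1} a^3,\quad
#'       D_y = \sqrt{2\pi/3}\, q' Q_{1,-1} a^3,\quad
#'       D_z = \sqrt{4\pi/3}\, q' Q_{1,0} a^3.}
#' The dipole scales as the system volume (\eqn{a^3}): every ion participates
#' in the uniform translational surface oscillation.
#'
#' @param Q named numeric vector with elements `"m-1"`, `"m0"`, `"m1"` (any
#'   subset; missing entries are zero).
#' @param a sphere radius, m.
#' @param q_eff effective (screened) ion charge \eqn{q' = q/\sqrt{\epsilon}}
#'   in C.
#' @return numeric length-3 dipole vector `c(Dx, Dy, Dz)`.
#' @examples
#' dipole_from_mode(c(m0 = 1), a = 1, q_eff = 1)  # Dz = sqrt(4*pi/3)
#' @export
dipole_from_mode <- function(Q, a, q_eff) {
  stopifnot(a > 0)
  get0q <- function(nm) if (nm %in% names(Q)) unname(Q[[nm]]) else 0
  c(sqrt(2 * pi / 3) * q_eff * get0q("m1")  * a^3,
    sqrt(2 * pi / 3) * q_eff * get0q("m-1") * a^3,
    sqrt(4 * pi / 3) * q_eff * get0q("m0")  * a^3)
}
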