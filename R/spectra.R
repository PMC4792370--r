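#' Spherical Bessel function of the first kind
#'
#' \eqn{j_l(x) = \sqrt{\pi/(2x)}\, J_{l+1/2}(x)}, evaluated through the
#' half-integer-order Bessel function. \eqn{j_0(0) = 1}, \eqn{j_l(0) = 0} for
#' l >= 1.
#'
#' @param l order, integer >= 0.
#' @param x argument, numeric vector >= 0.
#' @return numeric vector of \eqn{j_l(x)}.
#' @examples
#' spherical_bessel_j(0, pi)   # ~0: pi is the first node of j_0
#' @export
spherical_bessel_j <- function(l, x) {
  stopifnot(l >= 0, l == round(l), all(x >= 0))
  out <- numeric(length(x))
  z <- x == 0
  out[z] <- if (l == 0) 1 else 0
  if (any(!z))
    out[!z] <- sqrt(pi / (2 * x[!z])) * besselJ(x[!z], l + 0.5)
  out
}

# Default enumeration caps for the infinite mode sums.
.L_MAX <- 60L
.I_MAX <- 100L

# cache of node tables, one numeric vector per order l
.node_cache <- new.env(parent = emptyenv())

.bessel_nodes_upto <- function(l, imax) {
  key <- as.character(l)
  have <- if (exists(key, envir = .node_cache)) get(key, envir = .node_cache)
          else numeric(0)
  if (length(have) >= imax) return(have[seq_len(imax)])
  if (l == 0) {
    nodes <- pi * seq_len(imax)               # j_0 = sin(x)/x
  } else {
    # zeros of consecutive orders interlace: x_{l-1,i} < x_{l,i} < x_{l-1,i+1};
    # bracket each node of order l by the neighbouring nodes of order l-1 and
    # refine by bisection (uniroot) to machine precision.
    lower <- .bessel_nodes_upto(l - 1, imax + 1)
    nodes <- vapply(seq_len(imax), function(i) {
      stats::uniroot(function(x) spherical_bessel_j(l, x),
                     lower = lower[i], upper = lower[i + 1],
                     tol = .Machine$double.eps)$root
    }, numeric(1))
  }
  assign(key, nodes, envir = .node_cache)
  nodes
}

#' Nodes of the spherical Bessel function
#'
#' The i-th strictly positive zero \eqn{x_{li}} of \eqn{j_l}. These set the
#' allowed radial wavenumbers \eqn{k_{li} = x_{li}/a} of the volume plasmon
#' modes, since the density fluctuation must vanish at the membrane (r = a).
#'
#' Brackets come from the interlacing of zeros of consecutive orders and are
#' refined by bisection, which is robust for every (l, i) rather than relying
#' on asymptotic expansions.
#'
#' @param l order, integer >= 0.
#' @param i node index, integer >= 1 (capped at 100; `l` capped at 60).
#' @return the node \eqn{x_{li}}, accurate to machine precision.
#' @examples
#' bessel_node(0, 1)   # pi
#' bessel_node(1, 1)   # 4.493409...
#' @export
bessel_node <- function(l, i) {
  stopifnot(l >= 0, l == round(l), i >= 1, i == round(i))
  if (l > .L_MAX) stop("l exceeds the enumeration cap (", .L_MAX, ")")
  if (i > .I_MAX) stop("i exceeds the enumeration cap (", .I_MAX, ")")
  .bessel_nodes_upto(as.integer(l), as.integer(i))[i]
}

#' Surface plasmon self-frequency
#'
#' \eqn{\omega_{0l} = \omega_p \sqrt{l / ((2l+1)\,\epsilon_1)}}. Surface modes
#' start at l = 1 (no monopole: total charge is conserved); l = 1 with
#' \eqn{\epsilon_1 = 1} is the classical Mie value \eqn{\omega_p/\sqrt{3}}.
#'
#' @param omega_p bulk plasmon frequency, rad/s.
#' @param l multipole order, integer >= 1.
#' @param eps1 relative permittivity of the surroundings (>= 1); the
#'   dielectric renormalization applies to surface modes only.
#' @return angular frequency in rad/s (vectorized over `l`).
#' @examples
#' surface_mode_frequency(9.3e13, 1, 2)  # the Sample-1 Mie frequency
#' @export
surface_mode_frequency <- function(omega_p, l, eps1 = 1) {
  stopifnot(omega_p > 0, eps1 >= 1, all(l == round(l)))
  if (any(l < 1)) stop("no monopole surface mode: l must be >= 1")
  omega_p * sqrt(l / ((2 * l + 1) * eps1))
}

#' Volume plasmon self-frequency
#'
#' \eqn{\omega_{li} = \omega_p \sqrt{1 + (f/3)\, k T x_{li}^2 /
#' (\omega_p^2 a^2 m)}}. The thermal pressure of the ion gas stiffens the
#' compressional modes, so \eqn{\omega_{li} \ge \omega_p} always, with
#' equality at T = 0 or in the bulk limit \eqn{a \to \infty}. `f = 3` is the
#' point-like-ion case printed in the closed-form formula; f = 5 (linear
#' molecules) and f = 6 (3D molecules) scale the thermal term by 5/3 and 2.
#'
#' @param omega_p bulk plasmon frequency, rad/s.
#' @param a sphere radius, m.
#' @param T temperature, K (T = 0 allowed: the thermal term vanishes).
#' @param m_ion ion mass, kg.
#' @param l,i mode indices (l >= 1, i >= 1).
#' @param f degrees-of-freedom factor, one of 3, 5, 6.
#' @return angular frequency in rad/s.
#' @examples
#' volume_mode_frequency(1e6, 50e-6, 300, 1e4 * physical_constants()$electron_mass_me, 1, 1)
#' @export
volume_mode_frequency <- function(omega_p, a, T, m_ion, l, i, f = 3) {
  stopifnot(omega_p > 0, a > 0, T >= 0, m_ion > 0, l >= 1, i >= 1,
            f %in% c(3, 5, 6))
  x <- bessel_node(l, i)
  thermal <- (f / 3) * physical_constants()$boltzmann_k * T * x^2 /
    (omega_p^2 * a^2 * m_ion)
  omega_p * sqrt(1 + thermal)
}

#' Mode index constructor
#'
#' @param kind `"surface"` or `"volume"`.
#' @param l multipole order, integer >= 1.
#' @param m azimuthal index, integer in \[-l, l\].
#' @param i radial index (volume modes only), integer >= 1.
#' @return An object of class `mode_index`.
#' @examples
#' mode_index("volume", l = 1, m = 0, i = 1)
#' @export
mode_index <- function(kind = c("surface", "volume"), l, m = 0, i = NULL) {
  kind <- match.arg(kind)
  stopifnot(l >= 1, l == round(l), abs(m) <= l, m == round(m))
  if (kind == "volume") {
    if (is.null(i)) stop("volume modes need a radial index i")
    stopifnot(i >= 1, i == round(i))
  } else if (!is.null(i)) {
    stop("surface modes carry no radial index")
  }
  structure(list(kind = kind, l = as.integer(l), m = as.integer(m),
                 i = if (is.null(i)) NA_integer_ else as.integer(i)),
            class = "mode_index")
}

#' One plasmon eigenmode of a system
#'
#' Resolves a [mode_index()] against a [sphere_system()]: surface modes get
#' \eqn{\omega_{0l}} (with the dielectric renormalization), volume modes get
#' \eqn{\omega_{li}}, the node \eqn{x_{li}} and the wavenumber
#' \eqn{k_{li} = x_{li}/a}.
#'
#' @param system a [sphere_system()].
#' @param index a [mode_index()].
#' @return An object of class `plasmon_mode` with fields `index`, `omega`,
#'   and for volume modes `x_li`, `k_li`.
#' @examples
#' plasmon_mode(preset_system("sample1"), mode_index("surface", 1))
#' @export
plasmon_mode <- function(system, index) {
  stopifnot(inherits(system, "sphere_system"), inherits(index, "mode_index"))
  wp <- plasma_frequency(system)
  if (index$kind == "surface") {
    out <- list(index = index,
                omega = surface_mode_frequency(wp, index$l,
                                               system$outer_permittivity),
                x_li = NA_real_, k_li = NA_real_)
  } else {
    x <- bessel_node(index$l, index$i)
    out <- list(index = index,
                omega = volume_mode_frequency(
                  wp, system$radius, system$electrolyte$temperature,
                  system$ion$effective_mass, index$l, index$i,
                  system$dof_factor),
                x_li = x, k_li = x / system$radius)
  }
  structure(out, class = "plasmon_mode")
}

#' @export
print.plasmon_mode <- function(x, ...) {
  ix <- x$index
  cat(sprintf("%s plasmon mode l=%d m=%d%s: omega = %.6g rad/s",
              ix$kind, ix$l, ix$m,
              if (ix$kind == "volume") sprintf(" i=%d", ix$i) else "",
              x$omega))
  if (ix$kind == "volume")
    cat(sprintf("  (x_li = %.6f, k_li = %.6g 1/m)", x$x_li, x$k_li))
  cat("\n")
  invisible(x)
}

#' Self-frequency table over a temperature grid
#'
#' Tabulates mode self-frequencies across temperatures: volume-mode
#' frequencies rise monotonically with T (thermal stiffening of the
#' compressional modes) while surface modes are temperature-independent
#' constants, as in the canonical \eqn{\omega_{li}}(T) plots for li = 11, 12,
#' 21.
#'
#' @param system a [sphere_system()].
#' @param modes list of [mode_index()] objects.
#' @param T_grid nonempty numeric vector of temperatures in K.
#' @return data.frame with columns kind, l, m, i, T_K, omega_rad_s, x_li.
#' @examples
#' sys <- preset_system("sample1")
#' temperature_scan(sys, list(mode_index("volume", 1, 0, 1)), c(200, 300))
#' @export
temperature_scan <- function(system, modes, T_grid) {
  stopifnot(inherits(system, "sphere_system"), length(modes) > 0,
            length(T_grid) > 0, all(T_grid >= 0))
  wp <- plasma_frequency(system)
  rows <- lapply(modes, function(ix) {
    stopifnot(inherits(ix, "mode_index"))
    omega <- if (ix$kind == "surface") {
      rep(surface_mode_frequency(wp, ix$l, system$outer_permittivity),
          length(T_grid))
    } else {
      vapply(T_grid, function(T)
        volume_mode_frequency(wp, system$radius, T,
                              system$ion$effective_mass, ix$l, ix$i,
                              system$dof_factor), numeric(1))
    }
    data.frame(kind = ix$kind, l = ix$l, m = ix$m, i = ix$i,
               T_K = T_grid, omega_rad_s = omega,
               x_li = if (ix$kind == "volume") bessel_node(ix$l, ix$i)
                      else NA_real_)
  })
  do.call(rbind, rows)
}
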