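# Gauss-Legendre x uniform-phi product quadrature over the unit sphere
sphere_quadrature <- function(f, n_theta = 40, n_phi = 80) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  w_phi <- 2 * pi / n_phi
  total <- 0
  for (k in seq_len(n_theta)) {
    theta <- acos(gl$x[k])
    total <- total + gl$w[k] * w_phi * sum(f(theta, phi))
  }
  total
}

test_that("real spherical harmonics: closed-form values and orthonormality", {
  expect_equal(real_spherical_harmonic(0, 0, 0.7, 1.3), 1 / sqrt(4 * pi))
  expect_equal(real_spherical_harmonic(1, 0, 0, 0), sqrt(3 / (4 * pi)))
  # sign convention: Y_10 ~ +cos(theta), Y_1,+-1 ~ +sin(theta){cos,sin}(phi)
  th <- 0.9; ph <- 0.4
  expect_equal(real_spherical_harmonic(1, 0, th, ph),
               sqrt(3 / (4 * pi)) * cos(th), tolerance = 1e-14)
  expect_equal(real_spherical_harmonic(1, 1, th, ph),
               sqrt(3 / (4 * pi)) * sin(th) * cos(ph), tolerance = 1e-14)
  expect_equal(real_spherical_harmonic(1, -1, th, ph),
               sqrt(3 / (4 * pi)) * sin(th) * sin(ph), tolerance = 1e-14)
  # orthonormality under product-Gauss quadrature, all pairs up to l = 4
  idx <- do.call(rbind, lapply(0:4, function(l)
    data.frame(l = l, m = seq(-l, l))))
  for (p in seq_len(nrow(idx))) {
    for (q in p:nrow(idx)) {
      ip <- sphere_quadrature(function(th, ph)
        real_spherical_harmonic(idx$l[p], idx$m[p], th, ph) *
        real_spherical_harmonic(idx$l[q], idx$m[q], th, ph))
      expect_equal(ip, as.numeric(p == q), tolerance = 1e-8)
    }
  }
})

test_that("volume-mode density vanishes at the membrane and beyond, and at t = 0", {
  sys <- sample1()
  a <- sys$radius
  for (li in list(c(1, 1), c(2, 1), c(1, 3))) {
    mode <- mode_index("volume", li[1], 0, li[2])
    v_at_a <- volume_mode_density(sys, mode, r = c(a, 1.5 * a, 10 * a),
                                  theta = 0.4, phi = 0.2, t = 1e-14)
    expect_identical(v_at_a, c(0, 0, 0))
    # just inside: field nonzero but the r = a boundary value is below
    # machine precision relative to the interior maximum
    r_in <- seq(0, a * (1 - 1e-12), length.out = 200)
    v_in <- volume_mode_density(sys, mode, r = r_in, theta = 0.4, phi = 0.2,
                                t = 1e-14)
    expect_lt(abs(v_in[length(v_in)]), 1e-10 * max(abs(v_in)))
  }
  expect_identical(
    volume_mode_density(sys, mode_index("volume", 1, 0, 1),
                        r = a / 2, theta = 0.4, phi = 0.2, t = 0), 0)
  expect_error(volume_mode_density(sys, mode_index("surface", 1, 0),
                                   r = a / 2, theta = 0, phi = 0, t = 0),
               "volume mode")
})

test_that("volume-mode density value agrees with closed-form j_1 at r = a/2", {
  sys <- sample1()
  a <- sys$radius
  mode <- mode_index("volume", 1, 1, 1)
  pm <- plasmon_mode(sys, mode)
  t <- 3e-15; th <- 1.1; ph <- 0.6
  expected <- sys$electrolyte$concentration *
    j1_closed(pm$x_li / 2) *
    real_spherical_harmonic(1, 1, th, ph) * sin(pm$omega * t)
  expect_equal(volume_mode_density(sys, mode, r = a / 2, theta = th,
                                   phi = ph, t = t),
               expected, tolerance = 1e-12)
})

test_that("induced surface amplitude: T = 0 coefficient, quadrature, sign", {
  # at omega_li = omega_p the coupling coefficient is exactly -1 for every l
  for (l in 1:4) {
    amp <- induced_surface_amplitude(l, 1, 1e6, 1e6, 1e-6, 1)
    radial <- 1e-6 * integrate(function(s)
      s^(l + 2) * spherical_bessel_j(l, bessel_node(l, 1) * s), 0, 1,
      rel.tol = 1e-12)$value
    expect_equal(amp, -radial, tolerance = 1e-10)
  }
  # adaptive quadrature vs a high-resolution trapezoid oracle
  x11 <- bessel_node(1, 1)
  s <- seq(0, 1, length.out = 20001)
  y <- s^3 * j1_closed(x11 * s)
  trap <- sum((y[-1] + y[-length(y)]) / 2) * (s[2] - s[1])
  quad <- integrate(function(s) s^3 * spherical_bessel_j(1, x11 * s), 0, 1,
                    rel.tol = 1e-12)$value
  expect_equal(quad, trap, tolerance = 1e-8)
  # physical volume modes (omega_li >= omega_p) always couple with a
  # negative coefficient
  for (ratio in c(1, 1.05, 1.3, 2)) {
    for (l in 1:3) {
      amp <- induced_surface_amplitude(l, 1, 1e6, ratio * 1e6, 1e-6, 1)
      radial <- integrate(function(s)
        s^(l + 2) * spherical_bessel_j(l, bessel_node(l, 1) * s), 0, 1)$value
      expect_lt(amp * sign(radial), 0)
    }
  }
  expect_error(induced_surface_amplitude(1, 1, 1e6, 1e6 * sqrt(1 / 3), 1e-6, 1),
               "singular")
})

test_that("surface density: zeros, pure Y_lm dependence, zero net charge", {
  sys <- sample1()
  expect_identical(surface_density(sys, list(), 0.3, 0.4, 1e-14), 0)
  amp <- list(surface = data.frame(l = 2, m = 1, B = 1.7))
  th <- c(0.3, 1.2, 2.2); ph <- c(0.1, 2.5, 4.0)
  w <- surface_mode_frequency(plasma_frequency(sys), 2,
                              sys$outer_permittivity)
  t <- 2e-14
  vals <- surface_density(sys, amp, th, ph, t)
  expect_equal(vals,
               1.7 / sys$radius^2 *
                 real_spherical_harmonic(2, 1, th, ph) * sin(w * t),
               tolerance = 1e-12)
  # net fluctuation charge integrates to zero for every l >= 1 term
  for (lm in list(c(1, 0), c(1, 1), c(2, -1), c(3, 2))) {
    ampk <- list(surface = data.frame(l = lm[1], m = lm[2], B = 1))
    net <- sphere_quadrature(function(th, ph)
      surface_density(sys, ampk, th, ph, t)) * sys$radius^2
    expect_lt(abs(net), 1e-10)
  }
  # volume-induced term present and oscillating at the volume frequency
  ampv <- list(volume = data.frame(l = 1, m = 0, i = 1, A = 1e-24))
  expect_true(is.finite(surface_density(sys, ampv, 0.3, 0.1, 1e-14)))
})

test_that("dipole from the l = 1 mode: closed forms and volume scaling", {
  expect_identical(dipole_from_mode(c(m0 = 0, m1 = 0, `m-1` = 0), 1, 1),
                   c(0, 0, 0))
  expect_equal(dipole_from_mode(c(m0 = 1), 1, 1)[3], sqrt(4 * pi / 3))
  expect_equal(dipole_from_mode(c(m1 = 2), 1, 3)[1],
               3 * 2 * sqrt(2 * pi / 3))
  Q <- c(m0 = 0.3, m1 = -1.1, `m-1` = 0.7)
  expect_equal(dipole_from_mode(Q, 2e-6, 1.5),
               8 * dipole_from_mode(Q, 1e-6, 1.5), tolerance = 1e-12)
})
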