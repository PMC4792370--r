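# a Sample-1-like system at a = 3 um: strong radiative damping, so decay
# and settling are fast enough to resolve cheaply
fast_system <- function() {
  s <- sample1()
  sphere_system(radius = 3e-6, electrolyte = s$electrolyte, ion = s$ion,
                outer_permittivity = s$outer_permittivity,
                boundary_C = s$boundary_C,
                plasma_frequency_override = s$plasma_frequency_override)
}

test_that("zero drive and zero initial conditions stay identically zero", {
  sys <- fast_system()
  tt <- seq(0, 5 * 2 * pi / mie_frequency(sys), length.out = 200)
  for (model in c("none", "scattering", "lorentz_perturbative")) {
    tr <- evolve_dipole(sys, damping_model = model, times = tt)
    expect_equal(max(abs(tr$D)), 0)
  }
  tr <- evolve_dipole(sys, damping_model = "lorentz_exact", times = tt)
  expect_equal(max(abs(tr$D)), 0)
})

test_that("perturbative free decay: envelope rate within 1%, frequency within 0.1%", {
  sys <- fast_system()
  att <- total_attenuation(sys)
  w1p <- att$redshifted_omega
  tt <- seq(0, 6 / att$total_rate, length.out = 6000)
  tr <- evolve_dipole(sys, damping_model = "lorentz_perturbative",
                      initial_D = 1, times = tt)
  z <- tr$D[, 3]
  # successive maxima of the damped cosine decay exactly at the total rate
  pk <- which(diff(sign(diff(z))) == -2) + 1
  pk <- pk[z[pk] > 1e-4 * max(z)]
  fit <- lm(log(z[pk]) ~ tt[pk])
  expect_equal(-unname(coef(fit)[2]), att$total_rate, tolerance = 0.01)
  # oscillation frequency from zero-crossing spacing equals omega_1'
  cross <- which(z[-1] * z[-length(z)] < 0)
  t0 <- tt[cross] - z[cross] * (tt[cross + 1] - tt[cross]) /
    (z[cross + 1] - z[cross])
  expect_equal(pi / mean(diff(t0)), w1p, tolerance = 1e-3)
})

test_that("over-damped perturbative evolution warns and decays monotonically", {
  s <- sample1()
  big <- sphere_system(radius = 2e-5, electrolyte = s$electrolyte,
                       ion = s$ion, outer_permittivity = 2, boundary_C = 2,
                       plasma_frequency_override = 9.3e13)
  tt <- seq(0, 3 * 2 * pi / mie_frequency(big), length.out = 400)
  expect_warning(
    tr <- evolve_dipole(big, damping_model = "lorentz_perturbative",
                        initial_D = 1, times = tt),
    "over-damped")
  expect_true(all(diff(abs(tr$D[, 3])) <= 1e-12))
})

test_that("steady-state response: statics, peak position, time-domain consistency", {
  sys <- fast_system()
  w1 <- mie_frequency(sys)
  # omega = 0: static polarisability eps1 * a^3 * E0
  st <- steady_state_response(sys, 0, E0 = 2)
  expect_equal(st$amplitude, 2 * sys$outer_permittivity * sys$radius^3,
               tolerance = 1e-12)
  # resonance peak below omega_1, approaching it for weak damping
  grid <- seq(0.2 * w1, 1.5 * w1, length.out = 4001)
  resp <- steady_state_response(sys, grid)
  expect_lte(grid[which.max(resp$amplitude)], w1)
  weak <- bare_system(omega_p = 9.3e13, eps1 = 2, C = 2, a = 3e-7)
  respw <- steady_state_response(weak, grid, damping_model = "scattering")
  expect_equal(grid[which.max(respw$amplitude)], w1, tolerance = 1e-3)
  # long-run harmonic drive converges to the closed-form amplitude
  wd <- 0.9 * w1
  rate <- total_attenuation(sys)$total_rate
  tt <- seq(0, 30 / rate, length.out = 8000)
  tr <- evolve_dipole(sys, drive_field(1, "harmonic", omega = wd),
                      damping_model = "lorentz_perturbative", times = tt)
  tail_idx <- tt > 25 / rate
  amp_num <- max(abs(tr$D[tail_idx, 3]))
  amp_cf <- steady_state_response(sys, wd)$amplitude
  expect_equal(amp_num, amp_cf, tolerance = 0.01)
})

test_that("synthesized exact free decay reproduces Im(Omega2)*omega1 to 1e-6", {
  sys <- fast_system()
  sol <- exact_mode_solution(sys)
  w1 <- mie_frequency(sys)
  tt <- seq(0, 4 / sol$rate_exact, length.out = 3000)
  tr <- evolve_dipole(sys, damping_model = "lorentz_exact", initial_D = 1,
                      times = tt)
  # Prony recurrence fit: arithmetic fully independent of the root solver
  est <- prony_damped_cosine(tr$D[, 3], tt[2] - tt[1])
  expect_equal(est$rate, sol$rate_exact, tolerance = 1e-6)
  expect_equal(est$omega, sol$omega_exact, tolerance = 1e-6)
  # trajectory honours the initial conditions
  expect_equal(tr$D[1, 3], 1, tolerance = 1e-12)
  expect_equal(tr$dDdt[1, 3], 0, tolerance = 1e-6 * w1)
})

test_that("lorentz field: closed-form harmonic amplitude and omega^3 law", {
  sys <- fast_system()
  w1 <- mie_frequency(sys)
  c0 <- physical_constants()$light_speed_c
  # undamped free oscillation is a pure harmonic D0 cos(omega_1 t)
  tt <- seq(0, 12 * 2 * pi / w1, length.out = 4000)
  tr <- evolve_dipole(sys, damping_model = "none", initial_D = 1, times = tt)
  EL <- lorentz_field(tr)
  # drop spline edges, compare the interior amplitude to (2/(3c^3)) w^3 D0
  interior <- seq(200, length(tt) - 200)
  expect_equal(max(abs(EL[interior, 3])), 2 / (3 * c0^3) * w1^3,
               tolerance = 5e-3)
  expect_equal(max(abs(EL[, 1])), 0)
  # doubling the frequency multiplies |E_L| by 8: synthetic harmonic check
  mk <- function(w) {
    tr2 <- tr
    tr2$times <- tt
    tr2$D <- cbind(0, 0, cos(w * tt))
    tr2$d2Ddt2 <- cbind(0, 0, -w^2 * cos(w * tt))
    tr2$omega1 <- w
    max(abs(lorentz_field(tr2)[interior, 3]))
  }
  expect_equal(mk(2 * w1 / 10) / mk(w1 / 10), 8, tolerance = 5e-3)
  # undersampled trajectories are rejected
  coarse <- evolve_dipole(sys, damping_model = "none", initial_D = 1,
                          times = seq(0, 10 * 2 * pi / w1, length.out = 30))
  expect_error(lorentz_field(coarse), "undersampled")
})

test_that("grid halving shrinks the solver error", {
  sys <- fast_system()
  w1 <- mie_frequency(sys)
  att <- total_attenuation(sys)
  tt_c <- seq(0, 3 / att$total_rate, length.out = 500)
  tt_f <- seq(0, 3 / att$total_rate, length.out = 999)  # same endpoints
  analytic <- function(t) {
    r <- att$total_rate; wp <- att$redshifted_omega
    exp(-r * t) * (cos(wp * t) + r / wp * sin(wp * t))
  }
  err <- function(tt) {
    tr <- evolve_dipole(sys, damping_model = "lorentz_perturbative",
                        initial_D = 1, times = tt, rel_tol = 1e-11)
    max(abs(tr$D[, 3] - analytic(tt)))
  }
  # output-grid refinement must not inflate the solution error, and the
  # trajectory matches the closed-form damped cosine tightly
  expect_lt(err(tt_f), 1e-6)
  expect_lt(err(tt_c), 1e-6)
})
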