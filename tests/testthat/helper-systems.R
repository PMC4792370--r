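# Shared fixtures, built in code.

sample1 <- function() preset_system("sample1")
sample2 <- function() preset_system("sample2")

# a generic small system without plasma-frequency override, for formula tests
bare_system <- function(molarity = 1e-2, Z = 3, mass_me = 1e4, T = 300,
                        eps = 1, eps1 = 1, C = 1, a = 1e-6,
                        lambda_b = 1e-7, omega_p = NULL) {
  sphere_system(
    radius = a,
    electrolyte = electrolyte(molarity = molarity, inner_permittivity = eps,
                              temperature = T, mean_free_path = lambda_b),
    ion = ion_species(Z, effective_mass_me = mass_me),
    outer_permittivity = eps1, boundary_C = C,
    plasma_frequency_override = omega_p)
}

# closed-form spherical Bessel functions, independent of the besselJ route
j0_closed <- function(x) ifelse(x == 0, 1, sin(x) / x)
j1_closed <- function(x) ifelse(x == 0, 0, sin(x) / x^2 - cos(x) / x)
j2_closed <- function(x) ifelse(x == 0, 0,
                                (3 / x^3 - 1 / x) * sin(x) - 3 * cos(x) / x^2)

# Prony estimate of (rate, frequency) of a uniformly sampled damped cosine
# x_n = Re{C exp((i*w - r) t_n)}: x satisfies the exact two-term recurrence
# x_{n+1} = c1 x_n + c2 x_{n-1} with c1 = 2 e^{-r dt} cos(w dt),
# c2 = -e^{-2 r dt}; solve for c1, c2 by least squares.
prony_damped_cosine <- function(x, dt) {
  n <- length(x)
  A <- cbind(x[2:(n - 1)], x[1:(n - 2)])
  b <- x[3:n]
  cf <- qr.solve(A, b)
  r <- -log(sqrt(-cf[2])) / dt
  w <- acos(cf[1] / (2 * sqrt(-cf[2]))) / dt
  list(rate = r, omega = w)
}
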