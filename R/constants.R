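#' Physical constants (CODATA 2018 snapshot)
#'
#' All internal computation is carried out in SI units. The constants are
#' frozen to the CODATA-2018 recommended values so that every derived number
#' is bit-reproducible across platforms and sessions.
#'
#' @return A named list with components
#'   \describe{
#'     \item{boltzmann_k}{Boltzmann constant, J/K (exact since the 2019 SI).}
#'     \item{light_speed_c}{speed of light in vacuum, m/s (exact).}
#'     \item{elementary_charge_e}{elementary charge, C (exact).}
#'     \item{electron_mass_me}{electron mass, kg.}
#'     \item{vacuum_permittivity}{electric constant \eqn{\epsilon_0}, F/m.}
#'     \item{avogadro_NA}{Avogadro constant, 1/mol (exact).}
#'     \item{one_molar_N0}{ions per cubic metre of a one-molar solution,
#'       \eqn{N_0 = N_A \times 10^3} m\eqn{^{-3}}/M.}
#'   }
#' @examples
#' physical_constants()$boltzmann_k
#' @export
physical_constants <- function() {
  list(
    boltzmann_k          = 1.380649e-23,
    light_speed_c        = 299792458,
    elementary_charge_e  = 1.602176634e-19,
    electron_mass_me     = 9.1093837015e-31,
    vacuum_permittivity  = 8.8541878128e-12,
    avogadro_NA          = 6.02214076e23,
    one_molar_N0         = 6.02214076e26
  )
}
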