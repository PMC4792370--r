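# Allowed configuration keys, by block. Every physical field carries its
# unit in the key name; conversion to SI happens here, at the boundary.
.CFG_KEYS <- list(
  top = c("name", "preset", "system", "operation", "damping_model",
          "radius_grid", "temperature_grid", "omega_grid", "time_grid",
          "lmax", "imax", "drive", "out", "verbosity"),
  system = c("ion", "electrolyte", "radius_m", "outer_permittivity",
             "boundary_C", "dof_factor", "plasma_frequency_override_per_s"),
  ion = c("charge_number_e", "effective_mass_me", "effective_mass_kg",
          "label"),
  electrolyte = c("molarity_mol_per_L", "concentration_per_m3",
                  "inner_permittivity", "temperature_K", "mean_free_path_m"),
  drive = c("waveform", "amplitude", "omega_per_s", "phase_rad")
)

.check_keys <- function(block, what) {
  bad <- setdiff(names(block), .CFG_KEYS[[what]])
  if (length(bad))
    stop(sprintf("unknown %s key(s): %s", what, paste(bad, collapse = ", ")))
}

.system_from_block <- function(blk) {
  .check_keys(blk, "system")
  .check_keys(blk$ion, "ion")
  .check_keys(blk$electrolyte, "electrolyte")
  ion <- ion_species(charge_number = blk$ion$charge_number_e,
                     effective_mass = blk$ion$effective_mass_kg,
                     effective_mass_me = blk$ion$effective_mass_me,
                     label = blk$ion$label %||% "")
  el <- electrolyte(molarity = blk$electrolyte$molarity_mol_per_L,
                    concentration = blk$electrolyte$concentration_per_m3,
                    inner_permittivity = blk$electrolyte$inner_permittivity %||% 1,
                    temperature = blk$electrolyte$temperature_K,
                    mean_free_path = blk$electrolyte$mean_free_path_m)
  sphere_system(radius = blk$radius_m,
                electrolyte = el, ion = ion,
                outer_permittivity = blk$outer_permittivity %||% 1,
                boundary_C = blk$boundary_C %||% 1,
                dof_factor = blk$dof_factor %||% 3,
                plasma_frequency_override =
                  blk$plasma_frequency_override_per_s)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.preset_path <- function(name) {
  p <- system.file("extdata", paste0(name, ".yaml"), package = "ionplasm")
  if (!nzchar(p)) stop("unknown preset: ", name)
  p
}

#' Build a sphere system from a bundled preset
#'
#' Two canonical parameter sets are bundled: `"sample1"` (a 0.01-molar
#' electrolyte, \eqn{\omega_p = 9.3\times 10^{13}} rad/s) and `"sample2"`
#' (0.001-molar, \eqn{\omega_p = 2.93\times 10^{12}} rad/s), both with
#' effective ion charge 3e, effective mass \eqn{10^4 m_e}, T = 300 K,
#' \eqn{\epsilon_1 = 2}, C = 2. The presets pin \eqn{\omega_p} to the
#' canonical value through the override field.
#'
#' @param name `"sample1"` or `"sample2"`, or a path to a preset YAML file.
#' @return a [sphere_system()].
#' @examples
#' preset_system("sample1")
#' @export
preset_system <- function(name) {
  path <- if (file.exists(name)) name else .preset_path(name)
  raw <- yaml::read_yaml(path)
  .check_keys(raw, "top")
  .system_from_block(raw$system)
}

#' Parse a grid specification string
#'
#' Grids are written `"lo:hi:N"` (linear) or `"lo:hi:Nlog"` (log-spaced);
#' endpoints are reproduced exactly. A numeric vector passes through
#' unchanged.
#'
#' @param spec grid string or numeric vector.
#' @return strictly monotone numeric vector.
#' @examples
#' parse_grid("1e-8:1e-4:5log")
#' @export
parse_grid <- function(spec) {
  if (is.numeric(spec)) {
    if (length(spec) == 0 || any(diff(spec) <= 0))
      stop("numeric grid must be nonempty and strictly increasing")
    return(spec)
  }
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("grid spec must be lo:hi:N or lo:hi:Nlog")
  lo <- as.numeric(parts[1]); hi <- as.numeric(parts[2])
  logspaced <- grepl("log$", parts[3])
  n <- as.integer(sub("(log|lin)$", "", parts[3]))
  if (is.na(lo) || is.na(hi) || is.na(n) || n < 1 || hi <= lo)
    stop("invalid grid spec: ", spec)
  if (n == 1) return(lo)
  g <- if (logspaced) exp(seq(log(lo), log(hi), length.out = n))
       else seq(lo, hi, length.out = n)
  g[1] <- lo; g[n] <- hi
  g
}

#' Load a run configuration
#'
#' A run configuration names the physical system (inline `system:` block or
#' `preset:`), the operation to perform (`spectrum`, `damping`, `exact`,
#' `response`, `temperature`, `dynamics`), the relevant grids, and the
#' damping model. Unknown keys are rejected with an itemized error.
#'
#' @param path path to a YAML config file, or a bundled preset name (then
#'   the operation defaults to `"damping"`).
#' @return An object of class `run_config`.
#' @examples
#' cfg <- load_config(system.file("extdata", "sample1.yaml", package = "ionplasm"))
#' @export
load_config <- function(path) {
  file <- if (file.exists(path)) path else .preset_path(path)
  raw <- yaml::read_yaml(file)
  .check_keys(raw, "top")
  if (!is.null(raw$preset) && !is.null(raw$system))
    stop("give either preset or an inline system block, not both")
  system <- if (!is.null(raw$preset)) preset_system(raw$preset)
            else if (!is.null(raw$system)) .system_from_block(raw$system)
            else stop("config must name a preset or define a system block")
  op <- raw$operation %||% "damping"
  ops <- c("spectrum", "damping", "exact", "response", "temperature",
           "dynamics")
  if (!op %in% ops)
    stop("operation must be one of: ", paste(ops, collapse = ", "))
  structure(list(system = system,
                 operation = op,
                 damping_model = raw$damping_model %||% "lorentz_perturbative",
                 radius_grid = raw$radius_grid,
                 temperature_grid = raw$temperature_grid,
                 omega_grid = raw$omega_grid,
                 time_grid = raw$time_grid,
                 lmax = raw$lmax %||% 5L,
                 imax = raw$imax %||% 3L,
                 drive = raw$drive,
                 out = raw$out,
                 raw = raw, source = file),
            class = "run_config")
}

#' Save a run configuration
#'
#' Writes back the raw configuration list; `load_config(save_config(cfg))`
#' reproduces the configuration (round-trip identity).
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config$raw, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run a parameter sweep
#'
#' Dispatches the configured operation over its grid and returns a tidy
#' table. Per-row failures of downstream operations are collected in an
#' `error` column instead of aborting the sweep; row order is deterministic
#' and identical configurations produce identical tables.
#'
#' @param config a `run_config` from [load_config()].
#' @return data.frame with attributes `schema_version`, `config_hash`,
#'   `operation`.
#' @examples
#' cfg <- load_config(system.file("extdata", "sample1.yaml", package = "ionplasm"))
#' head(run_sweep(cfg))
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sys <- config$system
  grid_or <- function(spec, default) parse_grid(spec %||% default)
  tab <- switch(config$operation,
    spectrum = {
      wp <- plasma_frequency(sys)
      rows <- list()
      for (l in seq_len(config$lmax)) {
        rows[[length(rows) + 1]] <- data.frame(
          kind = "surface", l = l, i = NA_integer_, x_li = NA_real_,
          omega_rad_s = surface_mode_frequency(wp, l, sys$outer_permittivity))
        for (i in seq_len(config$imax)) {
          rows[[length(rows) + 1]] <- data.frame(
            kind = "volume", l = l, i = i, x_li = bessel_node(l, i),
            omega_rad_s = volume_mode_frequency(
              wp, sys$radius, sys$electrolyte$temperature,
              sys$ion$effective_mass, l, i, sys$dof_factor))
        }
      }
      do.call(rbind, rows)
    },
    damping = {
      a_grid <- grid_or(config$radius_grid, "1e-8:1e-4:200log")
      rows <- lapply(a_grid, function(a) {
        tryCatch({
          d <- total_attenuation(sys, a)
          data.frame(a_m = a, scattering_rate_s = d$scattering_rate,
                     lorentz_rate_s = d$lorentz_rate,
                     total_rate_s = d$total_rate, u = d$u, g = d$g,
                     omega1_prime_rad_s = d$redshifted_omega,
                     overdamped = d$overdamped, error = NA_character_)
        }, error = function(e)
          data.frame(a_m = a, scattering_rate_s = NA, lorentz_rate_s = NA,
                     total_rate_s = NA, u = NA, g = NA,
                     omega1_prime_rad_s = NA, overdamped = NA,
                     error = conditionMessage(e)))
      })
      do.call(rbind, rows)
    },
    exact = {
      a_grid <- grid_or(config$radius_grid, "1e-7:1e-4:300log")
      exact_vs_perturbative(sys, a_grid)
    },
    response = {
      w1 <- mie_frequency(sys)
      w_grid <- grid_or(config$omega_grid,
                        sprintf("%g:%g:200", w1 / 4, 2 * w1))
      steady_state_response(sys, w_grid,
                            damping_model =
                              if (config$damping_model == "lorentz_exact")
                                "lorentz_perturbative"
                              else config$damping_model)
    },
    temperature = {
      T_grid <- grid_or(config$temperature_grid, "250:370:25")
      modes <- list(mode_index("volume", 1, 0, 1),
                    mode_index("volume", 1, 0, 2),
                    mode_index("volume", 2, 0, 1),
                    mode_index("surface", 1, 0))
      temperature_scan(sys, modes, T_grid)
    },
    dynamics = {
      w1 <- mie_frequency(sys)
      tt <- grid_or(config$time_grid,
                    sprintf("0:%g:2000", 40 * 2 * pi / w1))
      drv <- if (is.null(config$drive)) drive_field() else {
        .check_keys(config$drive, "drive")
        drive_field(amplitude = config$drive$amplitude %||% 0,
                    waveform = config$drive$waveform %||% "none",
                    omega = config$drive$omega_per_s,
                    phase = config$drive$phase_rad %||% 0)
      }
      tr <- evolve_dipole(sys, drv, damping_model = config$damping_model,
                          initial_D = if (drv$waveform == "none") 1 else 0,
                          times = tt)
      data.frame(t_s = tr$times, Dx = tr$D[, 1], Dy = tr$D[, 2],
                 Dz = tr$D[, 3])
    })
  attr(tab, "schema_version") <- "1"
  attr(tab, "config_hash") <- .config_hash(config)
  attr(tab, "operation") <- config$operation
  tab
}

#' Write a result table as CSV with a metadata header
#'
#' Plain RFC-4180 CSV preceded by `#`-commented metadata lines (schema
#' version, operation, configuration hash, constants snapshot).
#'
#' @param table result from [run_sweep()] (or any data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# ionplasm result table, schema %s",
            attr(table, "schema_version") %||% "1"),
    sprintf("# operation: %s", attr(table, "operation") %||% "unknown"),
    sprintf("# config_hash: %s", attr(table, "config_hash") %||% "none"),
    "# constants: CODATA-2018"), con)
  utils::write.table(table, con, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}
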