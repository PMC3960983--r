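#' Thermodynamic state
#'
#' Bundles the temperature and Boltzmann constant used throughout the
#' package. All energies are in kcal/mol, so the default Boltzmann constant
#' is 0.0019872041 kcal/(mol K); at the default 300 K, \eqn{k_B T \approx}
#' 0.596 kcal/mol.
#'
#' @param temperature Temperature in kelvin (> 0).
#' @param boltzmann_constant Boltzmann constant in kcal/(mol K).
#' @return An object of class `"thermo_state"` with elements `temperature`
#'   and `boltzmann_constant`.
#' @examples
#' st <- thermo_state(300)
#' kBT(st)
#' @export
thermo_state <- function(temperature = 300,
                         boltzmann_constant = 0.0019872041) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop_amd("parameter", "temperature must be a single positive number")
  }
  if (!is.numeric(boltzmann_constant) || length(boltzmann_constant) != 1L ||
      !is.finite(boltzmann_constant) || boltzmann_constant <= 0) {
    stop_amd("parameter", "boltzmann_constant must be a single positive number")
  }
  structure(list(temperature = temperature,
                 boltzmann_constant = boltzmann_constant),
            class = "thermo_state")
}

#' @rdname thermo_state
#' @param state A `thermo_state`.
#' @export
kBT <- function(state) {
  stopifnot(inherits(state, "thermo_state"))
  state$boltzmann_constant * state$temperature
}

#' aMD boost specification
#'
#' Reference energy `E` and acceleration factor `alpha` of a single aMD
#' boost term. The boost is applied only when the instantaneous potential
#' falls below `E`; smaller `alpha` flattens the landscape more. `alpha`
#' must be strictly positive (at `alpha = 0` the boost expression is
#' singular at `V = E`).
#'
#' @param E Reference energy, kcal/mol.
#' @param alpha Acceleration factor, kcal/mol (> 0).
#' @return An object of class `"boost_spec"`.
#' @examples
#' boost_spec(E = 100, alpha = 10)
#' @export
boost_spec <- function(E, alpha) {
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E)) {
    stop_amd("parameter", "E must be a single finite number")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop_amd("parameter", "alpha must be a single positive number")
  }
  structure(list(E = E, alpha = alpha), class = "boost_spec")
}

#' Dual-boost aMD parameters
#'
#' Holds the dihedral-boost and total-boost specifications plus the
#' acceleration parameter lambda of the dual-boost recipe.
#'
#' @param dihedral,total [boost_spec()] objects.
#' @param lambda_accel Dimensionless acceleration parameter, in (0, 1].
#' @return An object of class `"boost_parameters"`.
#' @seealso [compute_amd_parameters()] for deriving these from short
#'   conventional-MD energy averages.
#' @export
boost_parameters <- function(dihedral, total, lambda_accel = 0.3) {
  stopifnot(inherits(dihedral, "boost_spec"), inherits(total, "boost_spec"))
  if (!is.numeric(lambda_accel) || length(lambda_accel) != 1L ||
      !is.finite(lambda_accel) || lambda_accel <= 0 || lambda_accel > 1) {
    stop_amd("parameter", "lambda_accel must be in (0, 1]")
  }
  structure(list(dihedral = dihedral, total = total,
                 lambda_accel = lambda_accel),
            class = "boost_parameters")
}

#' @export
print.boost_spec <- function(x, ...) {
  cat(sprintf("aMD boost spec: E = %g kcal/mol, alpha = %g kcal/mol\n",
              x$E, x$alpha))
  invisible(x)
}

#' @export
print.boost_parameters <- function(x, ...) {
  cat("Dual-boost aMD parameters (lambda =", x$lambda_accel, ")\n")
  cat(sprintf("  dihedral: E = %g, alpha = %g kcal/mol\n",
              x$dihedral$E, x$dihedral$alpha))
  cat(sprintf("  total:    E = %g, alpha = %g kcal/mol\n",
              x$total$E, x$total$alpha))
  invisible(x)
}

check_v <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v))) {
    stop_amd("input", "potential energy values must be finite numbers")
  }
}

#' aMD boost potential
#'
#' The energy added to the system when the instantaneous potential `v`
#' falls below the reference energy: \deqn{\Delta V(v) = (E - v)^2 /
#' (\alpha + E - v) \quad (v < E), \qquad \Delta V(v) = 0 \quad (v \ge E).}
#' The boost is non-negative, vanishes (together with its first derivative)
#' at `v = E`, and never raises the modified energy above `E`.
#'
#' @param v Potential energy (kcal/mol); vectorized.
#' @param spec A [boost_spec()].
#' @return Boost energy, kcal/mol (same length as `v`).
#' @examples
#' sp <- boost_spec(E = 100, alpha = 10)
#' boost_potential(90, sp)   # (10)^2 / (10 + 10) = 5
#' boost_potential(120, sp)  # 0, no boost above E
#' @export
boost_potential <- function(v, spec) {
  stopifnot(inherits(spec, "boost_spec"))
  check_v(v)
  gap <- spec$E - v
  ifelse(gap > 0, gap^2 / (spec$alpha + gap), 0)
}

#' Boosted energy record
#'
#' Applies the boost of [boost_potential()] and returns the full record of
#' original energy, boost, and modified energy `v + dv`.
#'
#' @inheritParams boost_potential
#' @return A list of class `"boost_record"` with `v_original`, `v_boosted`
#'   and `delta_v` (vectorized over `v`).
#' @export
boosted_energy <- function(v, spec) {
  dv <- boost_potential(v, spec)
  structure(list(v_original = v, v_boosted = v + dv, delta_v = dv),
            class = "boost_record")
}

#' Derivative of the boosted energy with respect to the original energy
#'
#' `dV*/dV = alpha^2 / (alpha + E - V)^2` for `V < E` and 1 otherwise.
#' This is the factor by which forces are scaled on the boosted surface;
#' it lies in (0, 1], increases monotonically with `v` below `E`, and
#' tends to 1 as `alpha` grows (the conventional-MD limit).
#'
#' @inheritParams boost_potential
#' @return Dimensionless scale factor in (0, 1].
#' @export
force_scale_factor <- function(v, spec) {
  stopifnot(inherits(spec, "boost_spec"))
  check_v(v)
  gap <- spec$E - v
  ifelse(gap > 0, (spec$alpha / (spec$alpha + gap))^2, 1)
}

#' Dual-boost modified energy
#'
#' Applies the dihedral boost to the dihedral term first, then the total
#' boost to the already-dihedral-boosted total energy (the composition
#' order of the dual-boost literature):
#' `v* = v_total + dV_dihed(v_dihed) + dV_total(v_total + dV_dihed(v_dihed))`.
#'
#' @param v_total Total potential energy, kcal/mol.
#' @param v_dihed Dihedral-term potential energy, kcal/mol.
#' @param params A [boost_parameters()].
#' @return A list with `v_star` (modified total energy) and `delta_v`
#'   (total applied boost, the sum of both terms; >= 0).
#' @examples
#' p <- boost_parameters(boost_spec(1000, 60), boost_spec(-100, 25))
#' dual_boost_energy(v_total = 50, v_dihed = 900, params = p)
#' @export
dual_boost_energy <- function(v_total, v_dihed, params) {
  stopifnot(inherits(params, "boost_parameters"))
  check_v(v_total); check_v(v_dihed)
  dv_d <- boost_potential(v_dihed, params$dihedral)
  v_mid <- v_total + dv_d
  dv_t <- boost_potential(v_mid, params$total)
  list(v_star = v_mid + dv_t, delta_v = dv_d + dv_t)
}

#' Dual-boost parameter recipe for membrane-protein-scale systems
#'
#' Derives the dual-boost reference energies and acceleration factors from
#' average dihedral and total potential energies of short conventional-MD
#' runs: \deqn{E_{dihed} = (1+\lambda) V_{dihed,avg}, \quad
#' \alpha_{dihed} = \lambda V_{dihed,avg} / 5,} \deqn{E_{total} =
#' V_{total,avg} + 0.2 N_{atoms}, \quad \alpha_{total} = 0.2 N_{atoms}.}
#' Proper acceleration for membrane proteins is achieved around
#' `lambda_accel = 0.3`. The dihedral divisor 5 is a fixed constant of the
#' recipe; it can be overridden via `dihed_divisor` for methodological
#' experiments.
#'
#' @param avgs A list/`energy_averages` with `v_dihed_avg` (> 0, kcal/mol),
#'   `v_total_avg` (kcal/mol) and `n_atoms` (>= 1).
#' @param lambda_accel Acceleration parameter in (0, 1].
#' @param dihed_divisor Advanced option; divisor of the dihedral alpha
#'   (default 5).
#' @return A [boost_parameters()] object.
#' @examples
#' compute_amd_parameters(energy_averages(1000, -150000, 50000), 0.3)
#' @export
compute_amd_parameters <- function(avgs, lambda_accel = 0.3,
                                   dihed_divisor = 5) {
  avgs <- as_energy_averages(avgs)
  if (lambda_accel <= 0) {
    stop_amd("parameter", "lambda_accel must be positive")
  }
  if (avgs$v_dihed_avg <= 0) {
    stop_amd("parameter",
             "v_dihed_avg must be positive (alpha_dihed would not be)")
  }
  boost_parameters(
    dihedral = boost_spec(E = (1 + lambda_accel) * avgs$v_dihed_avg,
                          alpha = lambda_accel * avgs$v_dihed_avg /
                            dihed_divisor),
    total = boost_spec(E = avgs$v_total_avg + 0.2 * avgs$n_atoms,
                       alpha = 0.2 * avgs$n_atoms),
    lambda_accel = min(lambda_accel, 1)
  )
}

#' Energy averages from short conventional MD
#'
#' @param v_dihed_avg Average dihedral potential energy, kcal/mol.
#' @param v_total_avg Average total potential energy, kcal/mol.
#' @param n_atoms Number of atoms in the system (>= 1).
#' @return An object of class `"energy_averages"`.
#' @export
energy_averages <- function(v_dihed_avg, v_total_avg, n_atoms) {
  if (!is.finite(v_dihed_avg) || !is.finite(v_total_avg)) {
    stop_amd("parameter", "energy averages must be finite")
  }
  n_atoms <- as.integer(n_atoms)
  if (is.na(n_atoms) || n_atoms < 1L) {
    stop_amd("parameter", "n_atoms must be at least 1")
  }
  structure(list(v_dihed_avg = v_dihed_avg, v_total_avg = v_total_avg,
                 n_atoms = n_atoms),
            class = "energy_averages")
}

as_energy_averages <- function(x) {
  if (inherits(x, "energy_averages")) return(x)
  if (is.list(x) && all(c("v_dihed_avg", "v_total_avg", "n_atoms") %in%
                        names(x))) {
    return(energy_averages(x$v_dihed_avg, x$v_total_avg, x$n_atoms))
  }
  stop_amd("parameter",
           "avgs must provide v_dihed_avg, v_total_avg and n_atoms")
}

#' Serialize dual-boost parameters to JSON
#'
#' The layout is `{"dihedral": {"E": ..., "alpha": ...}, "total": {...},
#' "lambda": ...}` with energies in kcal/mol.
#'
#' @param params A [boost_parameters()].
#' @param path File path; when `NULL` the JSON string is returned.
#' @return `path` invisibly (or the JSON string).
#' @export
write_boost_parameters <- function(params, path = NULL) {
  stopifnot(inherits(params, "boost_parameters"))
  x <- list(dihedral = list(E = params$dihedral$E,
                            alpha = params$dihedral$alpha),
            total = list(E = params$total$E, alpha = params$total$alpha),
            lambda = params$lambda_accel)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_boost_parameters
#' @param source A file path or JSON string produced by
#'   [write_boost_parameters()].
#' @export
read_boost_parameters <- function(source) {
  x <- jsonlite::fromJSON(source)
  boost_parameters(boost_spec(x$dihedral$E, x$dihedral$alpha),
                   boost_spec(x$total$E, x$total$alpha),
                   lambda_accel = x$lambda)
}

# classed conditions so callers (and the CLI) can map errors to exit codes
stop_amd <- function(type = c("parameter", "input", "format", "selection",
                              "geometry", "integration", "numerical",
                              "comparison", "config", "reweight"),
                     msg, call. = FALSE) {
  type <- match.arg(type)
  cond <- structure(
    class = c(paste0("amd_", type, "_error"), "amd_error", "error",
              "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}
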