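#' Langevin simulation configuration
#'
#' @param n_steps Number of integration steps (>= 1).
#' @param timestep Integration timestep, reduced time units (default 0.01).
#' @param friction Langevin friction, 1/time (default 1).
#' @param temperature Temperature in kelvin (drives `k_B T` in kcal/mol).
#' @param save_stride Save every `save_stride`-th step (>= 1).
#' @param rng_seed Integer seed recorded in the trajectory metadata.
#' @param boost Optional boost: a [boost_spec()] applied to the total toy
#'   potential energy, or [boost_parameters()] of which the total-boost
#'   term is used (toy potentials declare no dihedral term, so the
#'   dual-boost recipe reduces to the total boost here).
#' @param x0 Initial configuration (default: the potential's minimum).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_steps, timestep = 0.01, friction = 1,
                       temperature = 300, save_stride = 1L, rng_seed = 1L,
                       boost = NULL, x0 = NULL) {
  if (timestep <= 0 || friction <= 0 || n_steps < 1 || save_stride < 1) {
    stop_amd("parameter",
             "timestep and friction must be > 0; n_steps, save_stride >= 1")
  }
  if (!is.null(boost) && !inherits(boost, c("boost_spec",
                                            "boost_parameters"))) {
    stop_amd("parameter", "boost must be a boost_spec or boost_parameters")
  }
  structure(list(n_steps = as.integer(n_steps), timestep = timestep,
                 friction = friction, temperature = temperature,
                 save_stride = as.integer(save_stride),
                 rng_seed = as.integer(rng_seed), boost = boost, x0 = x0),
            class = "sim_config")
}

total_boost_spec <- function(boost) {
  if (is.null(boost)) return(NULL)
  if (inherits(boost, "boost_parameters")) boost$total else boost
}

#' Langevin dynamics on a toy potential, with optional aMD boost
#'
#' Integrates underdamped Langevin dynamics with the BAOAB splitting
#' (unit mass). With a boost, the dynamics run on the modified surface:
#' forces are the unbiased forces scaled by the analytic factor
#' [force_scale_factor()] evaluated at the instantaneous total potential
#' energy, and the per-frame boost energy is stored with each saved frame
#' for later reweighting. Identical seed and configuration give
#' bit-identical trajectories.
#'
#' Potentials built by the package constructors run in compiled code;
#' user-supplied closures use an equivalent pure-R loop drawing the same
#' random stream.
#'
#' @param potential A [toy_potential()].
#' @param config A [sim_config()].
#' @return An object of class `"amd_trajectory"`: `times`, `coords`
#'   (frames x dim matrix), `v_original`, `delta_v`, and the generating
#'   `config`/`potential` metadata.
#' @examples
#' dw <- make_double_well(4, 1)
#' tr <- langevin_simulate(dw, sim_config(2000, rng_seed = 7))
#' print(tr)
#' @export
langevin_simulate <- function(potential, config) {
  stopifnot(inherits(potential, "toy_potential"),
            inherits(config, "sim_config"))
  x0 <- if (is.null(config$x0)) potential$minimum else config$x0
  x0 <- as.numeric(x0)
  if (length(x0) != potential$dim) {
    stop_amd("parameter", "x0 must have the potential's dimension")
  }
  kT <- 0.0019872041 * config$temperature
  bs <- total_boost_spec(config$boost)
  set.seed(config$rng_seed)
  if (!is.null(potential$kernel)) {
    res <- cpp_langevin(potential$kernel$id,
                        as.numeric(potential$kernel$par), x0,
                        config$timestep, config$friction, kT,
                        config$n_steps, config$save_stride,
                        !is.null(bs),
                        if (is.null(bs)) 0 else bs$E,
                        if (is.null(bs)) 1 else bs$alpha)
  } else {
    res <- r_langevin(potential, x0, config, kT, bs)
  }
  if (res$err_step > 0) {
    stop_amd("integration",
             sprintf("coordinates diverged at step %d", res$err_step))
  }
  structure(list(times = as.numeric(res$times),
                 coords = as.matrix(res$coords),
                 v_original = as.numeric(res$v),
                 delta_v = as.numeric(res$dv),
                 dim = potential$dim,
                 potential = potential$name,
                 config = config),
            class = "amd_trajectory")
}

# pure-R BAOAB drawing the identical RNG stream as the compiled path
r_langevin <- function(potential, x0, config, kT, bs) {
  dt <- config$timestep
  c1 <- exp(-config$friction * dt)
  c2 <- sqrt(kT * (1 - c1^2))
  dim <- potential$dim
  n_save <- config$n_steps %/% config$save_stride
  times <- numeric(n_save); vout <- numeric(n_save)
  dvout <- numeric(n_save)
  coords <- matrix(0, n_save, dim)
  x <- x0; vel <- rep(0, dim)
  scale_at <- function(vp) if (is.null(bs)) 1 else force_scale_factor(vp, bs)
  vp <- potential$energy(x)
  f <- -scale_at(vp) * potential$gradient(x)
  isave <- 0L
  for (step in seq_len(config$n_steps)) {
    vel <- vel + 0.5 * dt * f
    x <- x + 0.5 * dt * vel
    vel <- c1 * vel + c2 * stats::rnorm(dim)
    x <- x + 0.5 * dt * vel
    vp <- potential$energy(x)
    if (!is.finite(vp) || abs(x[1]) > 1e8) {
      return(list(err_step = step))
    }
    f <- -scale_at(vp) * potential$gradient(x)
    vel <- vel + 0.5 * dt * f
    if (step %% config$save_stride == 0L) {
      isave <- isave + 1L
      times[isave] <- step * dt
      coords[isave, ] <- x
      vout[isave] <- vp
      dvout[isave] <- if (is.null(bs)) 0 else boost_potential(vp, bs)
    }
  }
  list(times = times, coords = coords, v = vout, dv = dvout, err_step = 0L)
}

#' @export
print.amd_trajectory <- function(x, ...) {
  cat(sprintf("Langevin trajectory on '%s': %d frames (%dD), t in [%g, %g]\n",
              x$potential, length(x$times), x$dim,
              x$times[1], x$times[length(x$times)]))
  boosted <- any(x$delta_v > 0)
  cat(sprintf("  boost: %s; seed %d; dt %g; T %g K\n",
              if (boosted) sprintf("active (mean dV = %.3g kcal/mol)",
                                   mean(x$delta_v)) else "none",
              x$config$rng_seed, x$config$timestep, x$config$temperature))
  invisible(x)
}

#' @export
as.data.frame.amd_trajectory <- function(x, ...) {
  cn <- if (x$dim == 1L) "x" else c("x", "y")
  out <- data.frame(time = x$times)
  for (d in seq_len(x$dim)) out[[cn[d]]] <- x$coords[, d]
  out$v_original <- x$v_original
  out$delta_v <- x$delta_v
  out
}

#' Extract a coordinate of a toy trajectory as a reaction-coordinate series
#'
#' @param trajectory An `amd_trajectory`.
#' @param coord Coordinate index (default 1).
#' @return An [rc_series()] carrying the per-frame boost energies.
#' @export
trajectory_rc <- function(trajectory, coord = 1L) {
  stopifnot(inherits(trajectory, "amd_trajectory"))
  dt <- diff(trajectory$times[1:2])
  rc_series(trajectory$coords[, coord], unit = "coordinate",
            delta_v = trajectory$delta_v,
            stride = if (length(trajectory$times) > 1L) dt else 1)
}

#' Write / read a toy trajectory as lossless TSV
#'
#' Columns: `time`, the coordinates (`x`, and `y` for 2D), `v_original`
#' and `delta_v`;
#' commented header lines carry the generating parameters. 17 significant
#' digits make the round-trip bit-exact.
#'
#' @param trajectory An `amd_trajectory`.
#' @param path Output file.
#' @param extra_header Optional named character vector of extra header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path, extra_header = NULL) {
  stopifnot(inherits(trajectory, "amd_trajectory"))
  cfg <- trajectory$config
  hdr <- c(potential = trajectory$potential,
           dim = as.character(trajectory$dim),
           timestep = format_g17(cfg$timestep),
           friction = format_g17(cfg$friction),
           temperature = format_g17(cfg$temperature),
           save_stride = as.character(cfg$save_stride),
           rng_seed = as.character(cfg$rng_seed), extra_header)
  cn <- if (trajectory$dim == 1L) "x" else c("x", "y")
  cols <- c(list(time = format_g17(trajectory$times)),
            stats::setNames(lapply(seq_len(trajectory$dim), function(d)
              format_g17(trajectory$coords[, d])), cn),
            list(v_original = format_g17(trajectory$v_original),
                 delta_v = format_g17(trajectory$delta_v)))
  writeLines(c(paste0("# ", names(hdr), "=", hdr),
               paste(names(cols), collapse = "\t"),
               do.call(paste, c(cols, sep = "\t"))), path)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  lines <- readLines(path)
  hl <- sub("^# *", "", grep("^#", lines, value = TRUE))
  keys <- sub("=.*$", "", hl); vals <- sub("^[^=]*=", "", hl)
  names(vals) <- keys
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  dim <- as.integer(vals[["dim"]])
  cn <- if (dim == 1L) "x" else c("x", "y")
  cfg <- sim_config(n_steps = nrow(tab) *
                      as.integer(vals[["save_stride"]]),
                    timestep = as.numeric(vals[["timestep"]]),
                    friction = as.numeric(vals[["friction"]]),
                    temperature = as.numeric(vals[["temperature"]]),
                    save_stride = as.integer(vals[["save_stride"]]),
                    rng_seed = as.integer(vals[["rng_seed"]]))
  structure(list(times = tab$time,
                 coords = as.matrix(tab[, cn, drop = FALSE]),
                 v_original = tab$v_original, delta_v = tab$delta_v,
                 dim = dim, potential = vals[["potential"]], config = cfg),
            class = "amd_trajectory")
}

#' Count barrier crossings of a 1D trajectory
#'
#' Counts sign changes of `x - threshold`, the standard transition count
#' for a double-well coordinate.
#'
#' @param trajectory An `amd_trajectory` (1D).
#' @param threshold Dividing surface (default 0).
#' @return Integer number of crossings.
#' @export
count_transitions <- function(trajectory, threshold = 0) {
  s <- sign(trajectory$coords[, 1] - threshold)
  s <- s[s != 0]
  sum(diff(s) != 0)
}
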