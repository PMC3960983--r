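# internal constructor shared by pmf_1d / pmf_2d / analytic_pmf
new_pmf <- function(edges, free_energy, counts, prob, bin_size, state,
                    weighted, periodic, meta = list()) {
  structure(list(edges = edges, free_energy = free_energy, counts = counts,
                 prob = prob, bin_size = bin_size, state = state,
                 weighted = weighted, periodic = periodic, meta = meta),
            class = "amd_pmf")
}

bin_centers <- function(edges) (utils::head(edges, -1) +
                                  utils::tail(edges, -1)) / 2

#' @export
print.amd_pmf <- function(x, ...) {
  dim2 <- is.list(x$edges)
  nb <- if (dim2) paste(dim(x$free_energy), collapse = " x ")
        else length(x$free_energy)
  cat(sprintf("%s PMF profile: %s bins%s, T = %g K%s\n",
              if (dim2) "2D" else "1D", nb,
              if (all(is.na(x$bin_size))) ""
              else paste0(" (bin size ", paste(x$bin_size, collapse = ", "),
                          ")"),
              x$state$temperature,
              if (x$weighted) ", reweighted" else ""))
  fr <- range(x$free_energy, na.rm = TRUE)
  cat(sprintf("  free energy range [0, %.3g] kcal/mol; %d empty bin(s)\n",
              fr[2], sum(is.na(x$free_energy))))
  invisible(x)
}

#' @export
summary.amd_pmf <- function(object, ...) {
  out <- list(profile = object,
              minima = if (!is.list(object$edges))
                tryCatch(pmf_minima(object), error = function(e) numeric(0))
              else NULL)
  class(out) <- "summary.amd_pmf"
  out
}

#' @export
print.summary.amd_pmf <- function(x, ...) {
  print(x$profile)
  if (!is.null(x$minima) && length(x$minima)) {
    cat("  local minima at:",
        paste(sprintf("%.4g", x$minima), collapse = ", "), "\n")
  }
  invisible(x)
}

# bin geometry ---------------------------------------------------------

# Bins are anchored at 0 for aperiodic coordinates and at -period/2 for
# periodic ones, so profiles with different bin sizes share an origin.
pmf_edges <- function(values, bin_size, periodic, period = 360) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    stop_amd("parameter", "bin_size must be a single positive number")
  }
  if (periodic) {
    nb <- period / bin_size
    if (abs(nb - round(nb)) > 1e-9) {
      stop_amd("parameter", sprintf(
        "bin_size %g does not divide the period %g of a periodic coordinate",
        bin_size, period))
    }
    return(seq(-period / 2, period / 2, length.out = round(nb) + 1L))
  }
  lo <- floor(min(values) / bin_size)
  hi <- ceiling(max(values) / bin_size)
  if (hi <= lo) hi <- lo + 1L
  seq(lo, hi) * bin_size
}

# bin index under the shared-anchor convention; intervals are [e_i, e_{i+1})
# for aperiodic axes and (e_i, e_{i+1}] for periodic ones (so the wrapped
# representative +period/2 lands in the last bin)
pmf_bin_index <- function(values, edges, periodic) {
  nb <- length(edges) - 1L
  bs <- edges[2L] - edges[1L]
  if (periodic) {
    idx <- ceiling((values - edges[1L]) / bs - 1e-12)
  } else {
    idx <- floor((values - edges[1L]) / bs + 1e-12) + 1L
  }
  pmin(pmax(as.integer(idx), 1L), nb)
}

# weights --------------------------------------------------------------

#' Exponential (Boltzmann-factor) reweighting weights
#'
#' Per-frame weights proportional to \eqn{e^{\Delta V / k_B T}}, the
#' Boltzmann factor of the boost potential applied to each frame, computed
#' with max-shifted exponentials so arbitrarily large boosts do not
#' overflow. Weights are normalized to sum to one.
#'
#' @param delta_v Per-frame boost energies (kcal/mol, >= 0), or an
#'   [rc_series()] carrying them.
#' @param state A [thermo_state()].
#' @return A numeric vector of class `"amd_weights"` summing to 1.
#' @examples
#' st <- thermo_state(300)
#' exponential_weights(c(0, kBT(st) * log(2)), st)  # 1/3, 2/3
#' @export
exponential_weights <- function(delta_v, state = thermo_state()) {
  if (inherits(delta_v, "amd_rc")) {
    if (is.null(delta_v$delta_v)) {
      stop_amd("reweight", "series carries no per-frame boost energies")
    }
    delta_v <- delta_v$delta_v
  }
  delta_v <- as.numeric(delta_v)
  if (any(!is.finite(delta_v))) {
    stop_amd("input", "delta_v must be finite")
  }
  if (any(delta_v < 0)) {
    stop_amd("input", "delta_v must be non-negative (boosts never are)")
  }
  w <- exp((delta_v - max(delta_v)) / kBT(state))
  structure(w / sum(w), class = "amd_weights")
}

check_weights <- function(weights, n) {
  if (is.null(weights)) return(NULL)
  w <- as.numeric(weights)
  if (length(w) != n) stop_amd("input", "weights length must match frames")
  if (any(!is.finite(w)) || any(w < 0)) {
    stop_amd("input", "weights must be finite and non-negative")
  }
  w / sum(w)
}

# estimators -----------------------------------------------------------

#' 1D potential of mean force from a reaction-coordinate series
#'
#' Histogram free-energy estimate \eqn{F_i = -k_B T \log P_i} with
#' \eqn{P_i} the (optionally weighted) fraction of frames in bin i. The
#' minimum over defined bins is shifted to zero; empty bins have
#' undefined (`NA`) free energy. Bins are anchored at 0 (distances) or at
#' `-period/2` (periodic dihedrals, which must use bin sizes dividing the
#' period) so that different bin sizes share an origin.
#'
#' @param series An [rc_series()] or numeric vector.
#' @param bin_size Bin width in the coordinate's unit (> 0).
#' @param state A [thermo_state()].
#' @param weights Optional per-frame weights (e.g.
#'   [exponential_weights()]); unweighted profiles use raw fractions.
#' @return An object of class `"amd_pmf"`.
#' @examples
#' x <- synth_ionic_lock_series(20000, rng_seed = 1)
#' p <- pmf_1d(x, bin_size = 0.2)
#' print(p)
#' @export
pmf_1d <- function(series, bin_size, state = thermo_state(),
                   weights = NULL) {
  if (!inherits(series, "amd_rc")) series <- rc_series(series)
  vals <- series$values
  edges <- pmf_edges(vals, bin_size, series$periodic, series$period)
  idx <- pmf_bin_index(vals, edges, series$periodic)
  nb <- length(edges) - 1L
  counts <- tabulate(idx, nbins = nb)
  w <- check_weights(weights, length(vals))
  if (is.null(w)) {
    prob <- counts / length(vals)
  } else {
    prob <- numeric(nb)
    agg <- rowsum(w, idx)
    prob[as.integer(rownames(agg))] <- agg[, 1L]
  }
  f <- ifelse(prob > 0, -kBT(state) * log(prob), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  new_pmf(edges = edges, free_energy = f, counts = counts, prob = prob,
          bin_size = bin_size, state = state, weighted = !is.null(w),
          periodic = series$periodic,
          meta = list(unit = series$unit, n_frames = length(vals)))
}

#' 2D potential of mean force
#'
#' Two-dimensional analogue of [pmf_1d()] on a pair of synchronized
#' reaction-coordinate series (e.g. the chi1/chi2 toggle-switch
#' dihedrals). Periodic axes are binned over `(-period/2, period/2]`.
#'
#' @param series_x,series_y [rc_series()] of equal length.
#' @param bin_size Bin width; a scalar (both axes) or length-2 vector.
#' @param state A [thermo_state()].
#' @param weights Optional per-frame weights.
#' @return An `"amd_pmf"` with matrix `free_energy` (x bins as rows).
#' @export
pmf_2d <- function(series_x, series_y, bin_size, state = thermo_state(),
                   weights = NULL) {
  if (!inherits(series_x, "amd_rc")) series_x <- rc_series(series_x)
  if (!inherits(series_y, "amd_rc")) series_y <- rc_series(series_y)
  if (length(series_x$values) != length(series_y$values)) {
    stop_amd("input", "series_x and series_y must have equal length")
  }
  bs <- rep_len(as.numeric(bin_size), 2L)
  ex <- pmf_edges(series_x$values, bs[1L], series_x$periodic,
                  series_x$period)
  ey <- pmf_edges(series_y$values, bs[2L], series_y$periodic,
                  series_y$period)
  ix <- pmf_bin_index(series_x$values, ex, series_x$periodic)
  iy <- pmf_bin_index(series_y$values, ey, series_y$periodic)
  nx <- length(ex) - 1L; ny <- length(ey) - 1L
  flat <- ix + nx * (iy - 1L)
  counts <- matrix(tabulate(flat, nbins = nx * ny), nx, ny)
  w <- check_weights(weights, length(series_x$values))
  if (is.null(w)) {
    prob <- counts / sum(counts)
  } else {
    acc <- numeric(nx * ny)
    agg <- rowsum(w, flat)
    acc[as.integer(rownames(agg))] <- agg[, 1L]
    prob <- matrix(acc, nx, ny)
  }
  f <- ifelse(prob > 0, -kBT(state) * log(prob), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  new_pmf(edges = list(ex, ey), free_energy = f, counts = counts,
          prob = prob, bin_size = bs, state = state,
          weighted = !is.null(w),
          periodic = c(series_x$periodic, series_y$periodic),
          meta = list(units = c(series_x$unit, series_y$unit),
                      n_frames = length(series_x$values)))
}

#' Evaluate a 1D profile at arbitrary coordinates
#'
#' @param profile An `"amd_pmf"` (1D).
#' @param x Coordinates.
#' @param method `"bin"` for the piecewise-constant bin value, `"curve"`
#'   for linear interpolation through defined bin centers (the way
#'   profiles of different bin sizes are overlaid as curves).
#' @return Free energies (`NA` outside the defined support).
#' @export
pmf_evaluate <- function(profile, x, method = c("bin", "curve")) {
  stopifnot(inherits(profile, "amd_pmf"), !is.list(profile$edges))
  method <- match.arg(method)
  if (method == "bin") {
    idx <- findInterval(x, profile$edges, rightmost.closed = TRUE)
    out <- rep(NA_real_, length(x))
    ok <- idx >= 1L & idx <= length(profile$free_energy)
    out[ok] <- profile$free_energy[idx[ok]]
    return(out)
  }
  ok <- !is.na(profile$free_energy)
  if (sum(ok) < 2L) stop_amd("comparison", "profile has < 2 defined bins")
  ctr <- bin_centers(profile$edges)
  stats::approx(ctr[ok], profile$free_energy[ok], xout = x, rule = 1)$y
}

# bin counts of `profile` at coordinates x (piecewise-constant; NA outside)
pmf_counts_at <- function(profile, x) {
  idx <- findInterval(x, profile$edges, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(x))
  ok <- idx >= 1L & idx <= length(profile$counts)
  out[ok] <- profile$counts[idx[ok]]
  out
}

#' Multi-bin-size precision sweep
#'
#' Recomputes the PMF at several bin sizes (all sharing the anchored
#' origin) and reports the maximum pairwise free-energy deviation, the
#' convergence diagnostic of the five-bin-size protocol: poorly sampled
#' coordinates show large variation across bin sizes, converged ones show
#' negligible differences.
#'
#' Profiles are compared as curves (linear interpolation through their
#' defined bin centers) at the finest profile's bin centers, restricted
#' to centers that every profile resolves with at least `min_count`
#' samples; each curve is re-zeroed on that common support before the
#' deviation is taken. When no bin meets `min_count` (heavily
#' undersampled series) all commonly defined bins are used and the report
#' is flagged `low_sampling`.
#'
#' @param series An [rc_series()] or numeric vector.
#' @param sizes At least two positive bin sizes.
#' @param state A [thermo_state()].
#' @param weights Optional per-frame weights.
#' @param min_count Well-sampled threshold per compared bin (default 200).
#' @return An object of class `"amd_pmf_sweep"`: `sizes`, `profiles`,
#'   `deviation` (max pairwise, kcal/mol), `support` (compared centers),
#'   `low_sampling` flag.
#' @examples
#' x <- synth_ionic_lock_series(50000, rng_seed = 2)
#' sw <- bin_size_sweep(x, sizes = seq(0.1, 0.5, by = 0.1))
#' summary(sw)
#' @export
bin_size_sweep <- function(series, sizes, state = thermo_state(),
                           weights = NULL, min_count = 200) {
  sizes <- as.numeric(sizes)
  if (length(sizes) < 2L || any(sizes <= 0)) {
    stop_amd("parameter", "need at least two positive bin sizes")
  }
  sizes <- sort(sizes)
  profiles <- lapply(sizes, function(b)
    pmf_1d(series, b, state = state, weights = weights))
  fine <- profiles[[1L]]
  ctr <- bin_centers(fine$edges)
  curves <- vapply(profiles, pmf_evaluate, numeric(length(ctr)), x = ctr,
                   method = "curve")
  cnts <- vapply(profiles, pmf_counts_at, numeric(length(ctr)), x = ctr)
  defined <- rowSums(is.na(curves)) == 0L & rowSums(is.na(cnts)) == 0L
  well <- defined & apply(cnts, 1L, min) >= min_count
  low_sampling <- !any(well)
  use <- if (low_sampling) defined else well
  if (!any(use)) stop_amd("comparison", "profiles share no defined bins")
  sub <- curves[use, , drop = FALSE]
  sub <- sweep(sub, 2L, apply(sub, 2L, min))
  dev_per_center <- apply(sub, 1L, function(r) diff(range(r)))
  structure(list(sizes = sizes, profiles = profiles,
                 deviation = max(dev_per_center),
                 support = ctr[use], dev_per_center = dev_per_center,
                 min_count = min_count, low_sampling = low_sampling),
            class = "amd_pmf_sweep")
}

#' @export
print.amd_pmf_sweep <- function(x, ...) {
  cat(sprintf(
    "Bin-size sweep over {%s}: max pairwise deviation %.4g kcal/mol\n",
    paste(x$sizes, collapse = ", "), x$deviation))
  if (x$low_sampling) {
    cat("  NOTE: no bin reached the well-sampled threshold (",
        x$min_count, " counts); all commonly defined bins compared\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.amd_pmf_sweep <- function(object, ...) {
  print(object)
  cat(sprintf("  compared support: %d centers in [%.4g, %.4g]\n",
              length(object$support), min(object$support),
              max(object$support)))
  invisible(object)
}

#' Cumulant-expansion reweighting of a PMF profile
#'
#' Corrects an unweighted profile computed from boosted frames using the
#' per-bin cumulant expansion of the log Boltzmann factor:
#' \deqn{F_i^{rw} = F_i - [\langle \Delta V \rangle_i +
#' (\beta/2)\,\mathrm{Var}(\Delta V)_i]} (the second term only at
#' `order = 2`), then re-shifts the minimum to zero. The expansion is
#' accurate when per-bin boost energies are near-Gaussian with modest
#' spread; for broad noisy boost distributions it deviates from exact
#' exponential reweighting, which is the known failure mode of energetic
#' reweighting for large systems. Orders above 2 amplify noise and are
#' not supported.
#'
#' @param profile An unweighted 1D `"amd_pmf"` from the boosted frames.
#' @param delta_v The per-frame boost energies grouped by bin: either an
#'   [rc_series()] carrying `delta_v` (grouped using the profile's bin
#'   geometry) or a list with one numeric vector per bin.
#' @param order 1 (mean only) or 2 (mean + variance).
#' @param state Defaults to the profile's thermodynamic state.
#' @return A reweighted `"amd_pmf"`; bins whose correction could not be
#'   estimated (fewer than `order` boost samples) are `NA` and listed in
#'   `meta$skipped_bins`.
#' @export
cumulant_reweight <- function(profile, delta_v, order = 2,
                              state = profile$state) {
  stopifnot(inherits(profile, "amd_pmf"), !is.list(profile$edges))
  if (!order %in% c(1, 2)) {
    stop_amd("parameter",
             "only cumulant orders 1 and 2 are supported (higher orders amplify noise)")
  }
  nb <- length(profile$free_energy)
  if (inherits(delta_v, "amd_rc")) {
    if (is.null(delta_v$delta_v)) {
      stop_amd("reweight", "series carries no per-frame boost energies")
    }
    idx <- pmf_bin_index(delta_v$values, profile$edges,
                         isTRUE(profile$periodic))
    groups <- split(delta_v$delta_v, factor(idx, levels = seq_len(nb)))
  } else if (is.list(delta_v)) {
    if (length(delta_v) != nb) {
      stop_amd("input", "per-bin delta_v list must match the bin count")
    }
    groups <- delta_v
  } else {
    stop_amd("input", "delta_v must be an rc_series or per-bin list")
  }
  beta <- 1 / kBT(state)
  f <- profile$free_energy
  skipped <- integer(0)
  for (i in seq_len(nb)) {
    if (is.na(f[i])) next
    g <- groups[[i]]
    if (length(g) < order) { f[i] <- NA_real_; skipped <- c(skipped, i); next }
    corr <- mean(g)
    if (order == 2) corr <- corr + beta / 2 * stats::var(g)
    f[i] <- f[i] - corr
  }
  f <- f - min(f, na.rm = TRUE)
  out <- profile
  out$free_energy <- f
  out$weighted <- TRUE
  out$meta$reweighting <- paste0("cumulant order ", order)
  out$meta$skipped_bins <- skipped
  out
}

#' Maximum absolute deviation between two PMF profiles
#'
#' Profiles are compared on their common defined support after aligning
#' both zeros to the shared-support minimum. Profiles with identical bin
#' geometry are compared bin by bin; 1D profiles with different bin sizes
#' are compared as curves at the finer profile's bin centers.
#'
#' @param a,b `"amd_pmf"` profiles (both 1D or both 2D with identical
#'   grids).
#' @return Max absolute deviation in kcal/mol, with attribute
#'   `"per_bin"` (deviation per compared bin) and `"support"`.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "amd_pmf"), inherits(b, "amd_pmf"))
  if (is.list(a$edges) != is.list(b$edges)) {
    stop_amd("comparison", "cannot compare 1D with 2D profiles")
  }
  if (is.list(a$edges)) {
    if (!isTRUE(all.equal(a$edges, b$edges))) {
      stop_amd("comparison", "2D profiles must share the same grid")
    }
    ok <- !is.na(a$free_energy) & !is.na(b$free_energy)
    if (!any(ok)) stop_amd("comparison", "profiles share no defined bins")
    fa <- a$free_energy[ok] - min(a$free_energy[ok])
    fb <- b$free_energy[ok] - min(b$free_energy[ok])
    d <- abs(fa - fb)
    return(structure(max(d), per_bin = d, support = which(ok)))
  }
  same_geom <- length(a$edges) == length(b$edges) &&
    isTRUE(all.equal(a$edges, b$edges))
  if (same_geom) {
    ok <- !is.na(a$free_energy) & !is.na(b$free_energy)
    if (!any(ok)) stop_amd("comparison", "profiles share no defined bins")
    fa <- a$free_energy[ok] - min(a$free_energy[ok])
    fb <- b$free_energy[ok] - min(b$free_energy[ok])
    d <- abs(fa - fb)
    return(structure(max(d), per_bin = d,
                     support = bin_centers(a$edges)[ok]))
  }
  fine <- if (diff(a$edges[1:2]) <= diff(b$edges[1:2])) a else b
  ctr <- bin_centers(fine$edges)
  va <- pmf_evaluate(a, ctr, method = "curve")
  vb <- pmf_evaluate(b, ctr, method = "curve")
  ok <- !is.na(va) & !is.na(vb)
  if (!any(ok)) stop_amd("comparison", "profiles share no defined support")
  fa <- va[ok] - min(va[ok]); fb <- vb[ok] - min(vb[ok])
  d <- abs(fa - fb)
  structure(max(d), per_bin = d, support = ctr[ok])
}

#' Locate the free-energy minima of a profile
#'
#' For 1D profiles: local minima of the profile curve over well-sampled
#' bins, filtered by topographic prominence (the rise to the lowest
#' saddle separating a minimum from any deeper one) and refined by a
#' quadratic fit across the well bottom. For 2D profiles: the `n` lowest
#' defined cells separated by at least `exclusion` in each coordinate
#' (periodic-aware), returned with their free energies.
#'
#' @param profile An `"amd_pmf"`.
#' @param prominence Minimum topographic prominence, kcal/mol (1D).
#' @param min_count Only bins with at least this many samples are
#'   considered (ignored for analytic profiles without counts).
#' @param refine Quadratic refinement of each 1D well bottom.
#' @param n Number of minima to return (2D).
#' @param exclusion Minimum separation between reported 2D minima, in
#'   coordinate units.
#' @return 1D: numeric vector of minima locations with attribute
#'   `"free_energy"`. 2D: a data frame with columns `x`, `y`,
#'   `free_energy`.
#' @export
pmf_minima <- function(profile, prominence = 0.15, min_count = 100,
                       refine = TRUE, n = 3, exclusion = 30) {
  stopifnot(inherits(profile, "amd_pmf"))
  if (is.list(profile$edges)) {
    return(pmf_minima_2d(profile, n = n, exclusion = exclusion,
                         min_count = min_count))
  }
  ok <- !is.na(profile$free_energy)
  if (!all(is.na(profile$counts))) {
    ok <- ok & profile$counts >= min_count
  }
  x <- bin_centers(profile$edges)[ok]
  f <- profile$free_energy[ok]
  nbin <- length(f)
  if (nbin < 3L) stop_amd("comparison", "too few defined bins")
  is_min <- vapply(seq_len(nbin), function(i) {
    f[i] <= f[max(1L, i - 1L)] && f[i] <= f[min(nbin, i + 1L)]
  }, logical(1))
  cand <- which(is_min)
  prom <- vapply(cand, function(i) {
    deeper <- which(f < f[i])
    lp <- Inf; rp <- Inf
    dl <- deeper[deeper < i]; dr <- deeper[deeper > i]
    if (length(dl)) lp <- max(f[max(dl):i]) - f[i]
    if (length(dr)) rp <- max(f[i:min(dr)]) - f[i]
    min(lp, rp)
  }, numeric(1))
  keep <- prom >= prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(structure(numeric(0), free_energy = numeric(0)))
  bs <- profile$edges[2L] - profile$edges[1L]
  locs <- mapply(function(i, pri) {
    if (!refine) return(x[i])
    cap <- min(0.5, 0.9 * pri)
    lo <- i
    while (lo > 1L && f[lo - 1L] <= f[i] + cap && f[lo - 1L] >= f[i] - 0.05)
      lo <- lo - 1L
    hi <- i
    while (hi < nbin && f[hi + 1L] <= f[i] + cap &&
           f[hi + 1L] >= f[i] - 0.05)
      hi <- hi + 1L
    win <- lo:hi
    if (length(win) >= 4L) {
      cf <- stats::coef(stats::lm(f[win] ~ x[win] + I(x[win]^2)))
      m <- -cf[[2L]] / (2 * cf[[3L]])
      if (is.finite(m) && abs(m - x[i]) <= 2 * bs) return(m)
    }
    x[i]
  }, cand, prom)
  structure(as.numeric(locs), free_energy = f[cand])
}

pmf_minima_2d <- function(profile, n = 3, exclusion = 30,
                          min_count = 100) {
  f <- profile$free_energy
  ok <- !is.na(f)
  if (!all(is.na(profile$counts))) ok <- ok & profile$counts >= min_count
  cx <- bin_centers(profile$edges[[1L]])
  cy <- bin_centers(profile$edges[[2L]])
  # keep only local minima over the 8-neighbourhood (periodic wrap;
  # undefined neighbours count as +Inf) so basin shoulders never outrank
  # a genuinely separate, shallower basin
  nx <- nrow(f); ny <- ncol(f)
  nb_idx <- function(i, n, per) {
    out <- c(i - 1L, i, i + 1L)
    if (per) ((out - 1L) %% n) + 1L else out[out >= 1L & out <= n]
  }
  per <- profile$periodic
  local_min <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      if (!ok[i, j]) next
      nbrs <- as.matrix(expand.grid(nb_idx(i, nx, per[1L]),
                                    nb_idx(j, ny, per[2L])))
      vals <- f[nbrs]
      vals[is.na(vals)] <- Inf
      local_min[i, j] <- all(f[i, j] <= vals)
    }
  }
  ok <- ok & local_min
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      free_energy = numeric(0)))
  }
  ord <- order(f[ok])
  idx <- idx[ord, , drop = FALSE]
  per <- profile$periodic
  span <- c(diff(range(profile$edges[[1L]])),
            diff(range(profile$edges[[2L]])))
  sep <- function(a, b, d) {
    dd <- abs(a - b)
    if (per[d]) dd <- min(dd, span[d] - dd)
    dd
  }
  picked <- matrix(numeric(0), 0, 2)
  fe <- numeric(0)
  for (r in seq_len(nrow(idx))) {
    p <- c(cx[idx[r, 1L]], cy[idx[r, 2L]])
    if (nrow(picked) == 0L ||
        all(apply(picked, 1L, function(q)
          max(sep(p[1L], q[1L], 1L), sep(p[2L], q[2L], 2L)) >= exclusion))) {
      picked <- rbind(picked, p)
      fe <- c(fe, f[idx[r, 1L], idx[r, 2L]])
    }
    if (nrow(picked) == n) break
  }
  data.frame(x = picked[, 1L], y = picked[, 2L], free_energy = fe,
             row.names = NULL)
}

# serialization --------------------------------------------------------

#' Write a PMF profile to TSV / JSON / dense-matrix text
#'
#' `write_pmf_tsv` writes 1D profiles as `bin_center`,
#' `free_energy_kcal_mol`, `count`. `write_pmf_json` writes 1D or 2D
#' profiles with full metadata (bin size, temperature, weighted flag,
#' zero convention). `write_pmf_matrix` writes a 2D profile as a dense
#' matrix with axis headers. `read_pmf_json` restores a profile written
#' by `write_pmf_json`.
#'
#' @param profile An `"amd_pmf"`.
#' @param path Output file.
#' @param extra_header Optional named character vector of `# key=value`
#'   lines (TSV only).
#' @return `path`, invisibly.
#' @export
write_pmf_tsv <- function(profile, path, extra_header = NULL) {
  stopifnot(inherits(profile, "amd_pmf"), !is.list(profile$edges))
  hdr <- c(bin_size = format_g17(profile$bin_size),
           temperature = format_g17(profile$state$temperature),
           weighted = tolower(as.character(profile$weighted)),
           zero = "min-over-defined-bins", extra_header)
  ctr <- bin_centers(profile$edges)
  writeLines(c(paste0("# ", names(hdr), "=", hdr),
               "bin_center\tfree_energy_kcal_mol\tcount",
               paste(format_g17(ctr),
                     ifelse(is.na(profile$free_energy), "NA",
                            format_g17(profile$free_energy)),
                     ifelse(is.na(profile$counts), "NA",
                            as.character(profile$counts)),
                     sep = "\t")), path)
  invisible(path)
}

#' @rdname write_pmf_tsv
#' @export
write_pmf_json <- function(profile, path) {
  stopifnot(inherits(profile, "amd_pmf"))
  x <- list(dimension = if (is.list(profile$edges)) 2L else 1L,
            edges = profile$edges,
            free_energy = as.numeric(profile$free_energy),
            counts = as.numeric(profile$counts),
            dims = if (is.list(profile$edges)) dim(profile$free_energy)
                   else NULL,
            bin_size = profile$bin_size,
            temperature = profile$state$temperature,
            boltzmann_constant = profile$state$boltzmann_constant,
            weighted = profile$weighted,
            periodic = profile$periodic,
            zero_convention = "minimum over defined bins shifted to 0",
            meta = profile$meta)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_pmf_tsv
#' @export
read_pmf_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  st <- thermo_state(x$temperature, x$boltzmann_constant)
  null_na <- function(v) {
    vapply(as.list(v), function(e)
      if (is.null(e) || length(e) == 0L) NA_real_ else as.numeric(e),
      numeric(1))
  }
  if (x$dimension == 2L) {
    # jsonlite may simplify two equal-length edge vectors into a matrix
    ed <- if (is.matrix(x$edges)) list(x$edges[1L, ], x$edges[2L, ])
          else lapply(x$edges, as.numeric)
    x$edges <- ed
    nx <- x$dims[1L]; ny <- x$dims[2L]
    fe <- matrix(null_na(x$free_energy), nx, ny)
    ct <- matrix(null_na(x$counts), nx, ny)
    return(new_pmf(edges = list(as.numeric(x$edges[[1L]]),
                                as.numeric(x$edges[[2L]])),
                   free_energy = fe, counts = ct, prob = NULL,
                   bin_size = x$bin_size, state = st,
                   weighted = x$weighted, periodic = x$periodic,
                   meta = x$meta))
  }
  new_pmf(edges = as.numeric(x$edges), free_energy = null_na(x$free_energy),
          counts = x$counts, prob = NULL, bin_size = x$bin_size,
          state = st, weighted = x$weighted, periodic = x$periodic,
          meta = x$meta)
}

#' @rdname write_pmf_tsv
#' @export
write_pmf_matrix <- function(profile, path) {
  stopifnot(inherits(profile, "amd_pmf"), is.list(profile$edges))
  cx <- bin_centers(profile$edges[[1L]])
  cy <- bin_centers(profile$edges[[2L]])
  lines <- c(paste0("# rows: x bin centers; columns: y bin centers"),
             paste0("# y\t", paste(format_g17(cy), collapse = "\t")))
  body <- vapply(seq_along(cx), function(i)
    paste(format_g17(cx[i]),
          paste(ifelse(is.na(profile$free_energy[i, ]), "NA",
                       format_g17(profile$free_energy[i, ])),
                collapse = "\t"), sep = "\t"), character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Plot method for PMF profiles
#'
#' 1D profiles are drawn as curves through defined bin centers; 2D
#' profiles as filled images with contours.
#'
#' @param x An `"amd_pmf"`.
#' @param ... Passed to the underlying base-graphics call.
#' @export
plot.amd_pmf <- function(x, ...) {
  if (is.list(x$edges)) {
    cx <- bin_centers(x$edges[[1L]]); cy <- bin_centers(x$edges[[2L]])
    graphics::image(cx, cy, x$free_energy,
                    col = grDevices::hcl.colors(40, "viridis"),
                    xlab = "coordinate 1", ylab = "coordinate 2", ...)
    graphics::contour(cx, cy, x$free_energy, add = TRUE,
                      col = "grey30")
  } else {
    ok <- !is.na(x$free_energy)
    graphics::plot(bin_centers(x$edges)[ok], x$free_energy[ok],
                   type = "l", xlab = "reaction coordinate",
                   ylab = "PMF (kcal/mol)", ...)
  }
  invisible(x)
}

#' @export
plot.amd_pmf_sweep <- function(x, ...) {
  fine <- x$profiles[[1L]]
  ok <- !is.na(fine$free_energy)
  graphics::plot(bin_centers(fine$edges)[ok], fine$free_energy[ok],
                 type = "l", xlab = "reaction coordinate",
                 ylab = "PMF (kcal/mol)", ...)
  for (i in seq_along(x$profiles)[-1L]) {
    p <- x$profiles[[i]]
    ok <- !is.na(p$free_energy)
    graphics::lines(bin_centers(p$edges)[ok], p$free_energy[ok], col = i)
  }
  graphics::legend("topright", legend = x$sizes, col = seq_along(x$sizes),
                   lty = 1, title = "bin size", bty = "n")
  invisible(x)
}
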