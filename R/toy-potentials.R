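#' Analytic toy potential
#'
#' A named energy/gradient pair on a 1D or 2D configuration space, used
#' both to drive the Langevin simulator and as a Boltzmann-integration
#' oracle for PMF estimates. Potentials built by the package constructors
#' also carry a compiled-kernel tag so the C++ integrator can evaluate
#' them without calling back into R; user-supplied closures fall back to
#' the (slower) pure-R integration path.
#'
#' @param name Identifier.
#' @param energy Function `x ->` energy in kcal/mol (`x` a numeric vector
#'   of length `dim`).
#' @param gradient Function `x ->` gradient (length `dim`).
#' @param dim Configuration dimension (1 or 2).
#' @param parameters Named list of scalars.
#' @param kernel Optional list `(id, par)` naming a compiled kernel.
#' @param minimum A configuration at (or near) the global minimum, used as
#'   default initial condition.
#' @return An object of class `"toy_potential"`.
#' @export
toy_potential <- function(name, energy, gradient, dim = 1L,
                          parameters = list(), kernel = NULL,
                          minimum = rep(0, dim)) {
  stopifnot(is.function(energy), is.function(gradient), dim %in% c(1L, 2L))
  structure(list(name = name, energy = energy, gradient = gradient,
                 dim = as.integer(dim), parameters = parameters,
                 kernel = kernel, minimum = minimum),
            class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  cat(sprintf("Toy potential '%s' (%dD)\n", x$name, x$dim))
  if (length(x$parameters)) {
    cat("  parameters:",
        paste(names(x$parameters), unlist(x$parameters), sep = " = ",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Symmetric double-well potential
#'
#' `V(x) = h ((x/w)^2 - 1)^2`: minima at `x = +/- w` with `V = 0` and a
#' barrier of height `h` at `x = 0`. The standard two-state test surface
#' for enhanced-sampling methods.
#'
#' @param barrier_height Barrier height `h`, kcal/mol (> 0).
#' @param well_separation Half-distance `w` between the minima (> 0).
#' @return A [toy_potential()].
#' @examples
#' dw <- make_double_well(4, 1)
#' dw$energy(0)   # barrier height
#' dw$energy(1)   # 0 at the minimum
#' @export
make_double_well <- function(barrier_height = 4, well_separation = 1) {
  h <- barrier_height; w <- well_separation
  if (!is.finite(h) || h <= 0 || !is.finite(w) || w <= 0) {
    stop_amd("parameter", "barrier_height and well_separation must be > 0")
  }
  toy_potential(
    name = "double_well",
    energy = function(x) h * ((x / w)^2 - 1)^2,
    gradient = function(x) 4 * h * x * ((x / w)^2 - 1) / w^2,
    dim = 1L,
    parameters = list(barrier_height = h, well_separation = w),
    kernel = list(id = 1L, par = c(h, w)),
    minimum = -w
  )
}

#' Multi-well 2D potential from inverted Gaussians
#'
#' A sum of inverted Gaussian wells plus a weak confining quartic,
#' emulating the inactive/intermediate/active basins of a 2D free-energy
#' surface. The global minimum is at the deepest center; well energies at
#' the centers follow the requested depth ordering.
#'
#' @param centers A matrix (k x 2) or list of 2D points.
#' @param depths Well depths in kcal/mol (> 0), length k; larger = deeper.
#' @param widths Gaussian widths (sd, coordinate units), length k or 1.
#' @param confine Coefficient of the confining quartic
#'   `confine * (|x - x_c|/L)^4` centered on the well centroid with scale
#'   `L` the largest center spread (default 1 kcal/mol).
#' @return A [toy_potential()].
#' @export
make_three_well_2d <- function(centers, depths, widths, confine = 1) {
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- as.matrix(centers)
  if (ncol(centers) != 2L || nrow(centers) < 1L) {
    stop_amd("parameter", "centers must be 2D points")
  }
  k <- nrow(centers)
  depths <- rep_len(as.numeric(depths), k)
  if (length(widths) != 1L && length(widths) != k) {
    stop_amd("parameter", "widths must have length 1 or match centers")
  }
  widths <- rep_len(as.numeric(widths), k)
  if (any(depths <= 0) || any(widths <= 0)) {
    stop_amd("parameter", "depths and widths must be positive")
  }
  cen <- colMeans(centers)
  L <- max(1, max(sqrt(rowSums(sweep(centers, 2, cen)^2))))
  energy <- function(x) {
    d2 <- (x[1] - centers[, 1])^2 + (x[2] - centers[, 2])^2
    r2 <- sum((x - cen)^2)
    -sum(depths * exp(-d2 / (2 * widths^2))) + confine * (r2 / L^2)^2
  }
  gradient <- function(x) {
    dx <- x[1] - centers[, 1]; dy <- x[2] - centers[, 2]
    g <- depths * exp(-(dx^2 + dy^2) / (2 * widths^2)) / widths^2
    r2 <- sum((x - cen)^2)
    conf <- confine * 4 * r2 / L^4
    c(sum(g * dx) + conf * (x[1] - cen[1]),
      sum(g * dy) + conf * (x[2] - cen[2]))
  }
  toy_potential(
    name = "gaussian_wells_2d", energy = energy, gradient = gradient,
    dim = 2L,
    parameters = list(k = k, confine = confine),
    kernel = list(id = 2L,
                  par = c(k, confine, cen, L, t(cbind(centers, depths,
                                                      widths)))),
    minimum = centers[which.max(depths), ]
  )
}

#' Analytic Boltzmann PMF of a toy potential
#'
#' Integrates the Boltzmann weight of the potential over each bin,
#' \eqn{F_i = -k_B T \log \int_{bin} e^{-V/k_B T} dx}, by composite
#' Simpson quadrature, and shifts the minimum to zero. This is the exact
#' reference profile that a converged unbiased simulation should
#' reproduce.
#'
#' @param potential A 1D [toy_potential()] (or 2D with a list of two edge
#'   vectors for `grid`).
#' @param state A [thermo_state()].
#' @param grid Bin edges (strictly increasing numeric vector), or for 2D a
#'   list of two such vectors.
#' @param points_per_bin Quadrature points per bin (odd; default 33).
#' @return An `"amd_pmf"` profile (counts are `NA`; metadata records the
#'   quadrature tolerance estimate).
#' @export
analytic_pmf <- function(potential, state = thermo_state(), grid,
                         points_per_bin = 33L) {
  stopifnot(inherits(potential, "toy_potential"))
  if (potential$dim == 2L) {
    return(analytic_pmf_2d(potential, state, grid, points_per_bin))
  }
  edges <- as.numeric(grid)
  if (length(edges) < 2L || any(diff(edges) <= 0)) {
    stop_amd("parameter", "grid must be strictly increasing bin edges")
  }
  m <- as.integer(points_per_bin)
  if (m %% 2L == 0L) m <- m + 1L
  beta <- 1 / kBT(state)
  nb <- length(edges) - 1L
  Z <- numeric(nb)
  for (i in seq_len(nb)) {
    xs <- seq(edges[i], edges[i + 1L], length.out = m)
    fx <- exp(-beta * vapply(xs, potential$energy, numeric(1)))
    h <- (edges[i + 1L] - edges[i]) / (m - 1L)
    wts <- c(1, rep(c(4, 2), length.out = m - 2L), 1)
    Z[i] <- h / 3 * sum(wts * fx)
  }
  if (all(Z <= 0) || !any(is.finite(Z) & Z > 0)) {
    stop_amd("numerical", "grid excludes all Boltzmann density")
  }
  f <- ifelse(Z > 0, -log(Z) / beta, NA_real_)
  f <- f - min(f, na.rm = TRUE)
  new_pmf(edges = edges, free_energy = f, counts = rep(NA_real_, nb),
          prob = Z / sum(Z), bin_size = NA_real_, state = state,
          weighted = FALSE, periodic = FALSE,
          meta = list(source = "analytic", points_per_bin = m,
                      quadrature = "composite Simpson"))
}

analytic_pmf_2d <- function(potential, state, grid, points_per_bin = 17L) {
  if (!is.list(grid) || length(grid) != 2L) {
    stop_amd("parameter", "2D analytic PMF needs a list of two edge vectors")
  }
  ex <- as.numeric(grid[[1L]]); ey <- as.numeric(grid[[2L]])
  m <- as.integer(points_per_bin); if (m %% 2L == 0L) m <- m + 1L
  beta <- 1 / kBT(state)
  nx <- length(ex) - 1L; ny <- length(ey) - 1L
  wts <- c(1, rep(c(4, 2), length.out = m - 2L), 1)
  Z <- matrix(0, nx, ny)
  for (i in seq_len(nx)) {
    xs <- seq(ex[i], ex[i + 1L], length.out = m)
    hx <- (ex[i + 1L] - ex[i]) / (m - 1L)
    for (j in seq_len(ny)) {
      ys <- seq(ey[j], ey[j + 1L], length.out = m)
      hy <- (ey[j + 1L] - ey[j]) / (m - 1L)
      vals <- outer(seq_len(m), seq_len(m), Vectorize(function(a, b)
        exp(-beta * potential$energy(c(xs[a], ys[b])))))
      Z[i, j] <- (hx / 3) * (hy / 3) * as.numeric(t(wts) %*% vals %*% wts)
    }
  }
  if (!any(is.finite(Z) & Z > 0)) {
    stop_amd("numerical", "grid excludes all Boltzmann density")
  }
  f <- ifelse(Z > 0, -log(Z) / beta, NA_real_)
  f <- f - min(f, na.rm = TRUE)
  new_pmf(edges = list(ex, ey), free_energy = f,
          counts = matrix(NA_real_, nx, ny), prob = Z / sum(Z),
          bin_size = NA_real_, state = state, weighted = FALSE,
          periodic = c(FALSE, FALSE),
          meta = list(source = "analytic", points_per_bin = m))
}
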