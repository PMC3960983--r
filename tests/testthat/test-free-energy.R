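st300 <- thermo_state(300)

test_that("exponential weights are normalized, shifted and overflow-safe", {
  w0 <- exponential_weights(c(0, 0, 0, 0), st300)
  expect_equal(as.numeric(w0), rep(0.25, 4))
  w2 <- exponential_weights(c(0, kBT(st300) * log(2)), st300)
  expect_equal(as.numeric(w2), c(1 / 3, 2 / 3))
  # a 500 kcal/mol boost dwarfs everything without overflowing
  w <- exponential_weights(c(0, 0, 0, 500), st300)
  expect_true(all(is.finite(w)))
  expect_equal(sum(w), 1)
  expect_gt(w[4], 1 - 1e-12)
  expect_error(exponential_weights(c(0, -1), st300),
               class = "amd_input_error")
})

test_that("pmf_1d reproduces closed-form counts and stays normalized", {
  # two bins with 100 and 10 frames: gap is exactly kT log 10
  vals <- c(rep(0.25, 100), rep(0.75, 10))
  p <- pmf_1d(vals, 0.5, st300)
  defined <- !is.na(p$free_energy)
  expect_equal(sum(p$prob), 1)
  expect_identical(min(p$free_energy[defined]), 0)
  expect_equal(max(p$free_energy, na.rm = TRUE),
               kBT(st300) * log(10))

  # uniform series over commensurate bins is flat
  set.seed(23)
  u <- pmf_1d(runif(2e5, 0, 2), 0.5, st300)
  expect_lt(max(u$free_energy, na.rm = TRUE), 0.02)

  # all frames in one bin: valid single-bin profile
  one <- pmf_1d(rep(0.2, 50), 0.5, st300)
  expect_equal(sum(!is.na(one$free_energy)), 1L)
  expect_error(pmf_1d(vals, -0.1), class = "amd_parameter_error")
})

test_that("pmf_1d matches the naive two-pass oracle bit for bit", {
  x <- synth_ionic_lock_series(10000, rng_seed = 31)
  for (bs in c(0.1, 0.3, 0.5)) {
    p <- pmf_1d(x, bs, st300)
    expect_identical(p$free_energy,
                     naive_pmf_oracle(x$values, bs, 300))
  }
})

test_that("profiles are invariant to weight scaling", {
  x <- synth_ionic_lock_series(5000, rng_seed = 32)
  w <- runif(5000, 0.1, 1)
  p1 <- pmf_1d(x, 0.3, st300, weights = w)
  p2 <- pmf_1d(x, 0.3, st300, weights = w * 7.3)
  expect_equal(p1$free_energy, p2$free_energy)
  expect_true(p1$weighted)
})

test_that("periodic binning wraps, conserves counts and rejects bad sizes", {
  set.seed(33)
  ang <- rc_series(runif(5000, -180, 180), unit = "degrees",
                   periodic = TRUE)
  p <- pmf_1d(ang, 10, st300)
  expect_identical(sum(p$counts), 5000L)
  expect_equal(range(p$edges), c(-180, 180))
  # rotating the periodic origin conserves every frame
  rot <- rc_series(ang$values + 37, unit = "degrees", periodic = TRUE)
  expect_identical(sum(pmf_1d(rot, 10, st300)$counts), 5000L)
  expect_error(pmf_1d(ang, 7, st300), class = "amd_parameter_error")
})

test_that("pmf_2d recovers cluster structure and depth ladders", {
  set.seed(34)
  # independent uniform axes are flat
  u1 <- rc_series(runif(2e5, -180, 180), "degrees", periodic = TRUE)
  u2 <- rc_series(runif(2e5, -180, 180), "degrees", periodic = TRUE)
  pu <- pmf_2d(u1, u2, 30, st300)
  expect_lt(max(pu$free_energy, na.rm = TRUE), 0.15)
  expect_equal(sum(pu$prob), 1)

  # one cluster at the inactive toggle-switch rotamer
  g1 <- rc_series(rnorm(5e4, -75, 10), "degrees", periodic = TRUE)
  g2 <- rc_series(rnorm(5e4, 40, 10), "degrees", periodic = TRUE)
  pg <- pmf_2d(g1, g2, 6, st300)
  amin <- which(pg$free_energy == 0, arr.ind = TRUE)
  cx <- (pg$edges[[1]][-1] + pg$edges[[1]][-length(pg$edges[[1]])]) / 2
  cy <- (pg$edges[[2]][-1] + pg$edges[[2]][-length(pg$edges[[2]])]) / 2
  expect_lt(abs(cx[amin[1]] + 75), 6)
  expect_lt(abs(cy[amin[2]] - 40), 6)

  # three clusters with the 0/2/3 kcal/mol depth ladder
  tog <- synth_toggle_series(250000, rng_seed = 35)
  p3 <- pmf_2d(tog$chi1, tog$chi2, 6, st300)
  m <- pmf_minima(p3, n = 3, min_count = 20)
  expect_equal(nrow(m), 3L)
  ord <- order(m$free_energy)
  expect_equal(m$free_energy[ord], c(0, 2, 3), tolerance = 0.2)
  expect_lt(max(abs(m$x[ord] - c(-75, -165, -160))), 6)
  expect_lt(max(abs(m$y[ord] - c(40, 40, -100))), 6)

  expect_error(pmf_2d(g1, rc_series(1:10), 6), class = "amd_input_error")
})

test_that("bin-size sweeps separate converged from undersampled series", {
  big <- synth_ionic_lock_series(1e5, rng_seed = 36)
  sw <- bin_size_sweep(big, seq(0.1, 0.5, by = 0.1), st300)
  expect_false(sw$low_sampling)
  small <- synth_ionic_lock_series(50, rng_seed = 36)
  sw_small <- bin_size_sweep(small, seq(0.1, 0.5, by = 0.1), st300)
  expect_true(sw_small$low_sampling)
  expect_gt(sw_small$deviation, sw$deviation)
  expect_error(bin_size_sweep(big, 0.1), class = "amd_parameter_error")
  # shared anchoring: every profile's edges are multiples of its bin size
  for (i in seq_along(sw$sizes)) {
    e <- sw$profiles[[i]]$edges
    expect_equal(e / sw$sizes[i], round(e / sw$sizes[i]), tolerance = 1e-9)
  }
})

test_that("constant per-bin boost leaves the cumulant-reweighted shape unchanged", {
  x <- synth_ionic_lock_series(20000, rng_seed = 37)
  xs <- rc_series(x$values, delta_v = rep(2.5, length(x$values)))
  p <- pmf_1d(xs, 0.3, st300)
  rw <- cumulant_reweight(p, xs, order = 2)
  ok <- !is.na(rw$free_energy)
  expect_equal(rw$free_energy[ok], p$free_energy[ok], tolerance = 1e-12)
})

test_that("order-2 cumulant matches exponential reweighting for Gaussian boosts", {
  x <- synth_ionic_lock_series(2e5, rng_seed = 38)
  set.seed(38)
  # smooth bin-dependent mean, Gaussian spread sigma = 0.3 < kT
  dv <- pmax(0, 2 + sin(x$values / 2) +
               rnorm(length(x$values), 0, 0.3))
  xs <- rc_series(x$values, delta_v = dv)
  pu <- pmf_1d(xs, 0.2, st300)
  pe <- pmf_1d(xs, 0.2, st300,
               weights = exponential_weights(xs, st300))
  pc <- cumulant_reweight(pu, xs, order = 2)
  ok <- pu$counts >= 200 & !is.na(pc$free_energy) &
    !is.na(pe$free_energy)
  fa <- pe$free_energy[ok] - min(pe$free_energy[ok])
  fb <- pc$free_energy[ok] - min(pc$free_energy[ok])
  gauss_dev <- max(abs(fa - fb))
  expect_lt(gauss_dev, 0.1)

  # heavy-tailed boosts break the expansion (the documented failure mode)
  set.seed(39)
  dvh <- pmax(0, 2 + sin(x$values / 2) +
                (rlnorm(length(x$values), 0, 1.2) - exp(0.72)))
  xh <- rc_series(x$values, delta_v = dvh)
  puh <- pmf_1d(xh, 0.2, st300)
  peh <- pmf_1d(xh, 0.2, st300,
                weights = exponential_weights(xh, st300))
  pch <- cumulant_reweight(puh, xh, order = 2)
  okh <- puh$counts >= 200 & !is.na(pch$free_energy) &
    !is.na(peh$free_energy)
  fah <- peh$free_energy[okh] - min(peh$free_energy[okh])
  fbh <- pch$free_energy[okh] - min(pch$free_energy[okh])
  expect_gt(max(abs(fah - fbh)), gauss_dev)

  expect_error(cumulant_reweight(pu, xs, order = 3),
               class = "amd_parameter_error")
})

test_that("profile comparison is shift-invariant on shared support", {
  x <- synth_ionic_lock_series(20000, rng_seed = 40)
  p <- pmf_1d(x, 0.2, st300)
  expect_equal(as.numeric(compare_profiles(p, p)), 0)
  q <- p
  q$free_energy <- q$free_energy + 0.7
  expect_equal(as.numeric(compare_profiles(p, q)), 0)
  # cross-bin-size comparison uses curve interpolation
  p2 <- pmf_1d(x, 0.4, st300)
  expect_lt(as.numeric(compare_profiles(p, p2)), 1.5)
  far <- pmf_1d(rc_series(x$values + 1000), 0.2, st300)
  expect_error(compare_profiles(p, far), class = "amd_comparison_error")
})

test_that("profiles serialize to TSV, JSON and matrix text", {
  x <- synth_ionic_lock_series(5000, rng_seed = 41)
  p <- pmf_1d(x, 0.3, st300)
  tsv <- tempfile(fileext = ".tsv")
  write_pmf_tsv(p, tsv)
  tab <- utils::read.table(tsv, header = TRUE, sep = "\t",
                           comment.char = "#")
  expect_equal(nrow(tab), length(p$free_energy))

  js <- tempfile(fileext = ".json")
  write_pmf_json(p, js)
  back <- read_pmf_json(js)
  expect_equal(back$free_energy, p$free_energy)
  expect_equal(back$counts, p$counts)
  expect_equal(back$edges, p$edges)

  tog <- synth_toggle_series(5000, rng_seed = 42)
  p2 <- pmf_2d(tog$chi1, tog$chi2, 30, st300)
  js2 <- tempfile(fileext = ".json")
  write_pmf_json(p2, js2)
  back2 <- read_pmf_json(js2)
  expect_equal(back2$free_energy, p2$free_energy)
  mtx <- tempfile(fileext = ".txt")
  write_pmf_matrix(p2, mtx)
  expect_true(file.exists(mtx))
  expect_gt(length(readLines(mtx)), nrow(p2$free_energy))
})
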