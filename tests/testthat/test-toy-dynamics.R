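test_that("double-well construction matches its closed form", {
  dw <- make_double_well(4, 1)
  expect_equal(dw$energy(1), 0)
  expect_equal(dw$energy(-1), 0)
  expect_equal(dw$energy(0), 4)
  expect_equal(dw$gradient(1), 0)
  expect_equal(dw$gradient(-1), 0)
  expect_error(make_double_well(-1, 1), class = "amd_parameter_error")

  # gradient consistent with finite differences (toy-potential invariant)
  set.seed(3)
  for (x in runif(20, -2, 2)) {
    fd <- (dw$energy(x + 1e-6) - dw$energy(x - 1e-6)) / 2e-6
    expect_equal(dw$gradient(x), fd, tolerance = 1e-5)
  }
})

test_that("2D multi-well surface places and orders its wells", {
  one <- make_three_well_2d(rbind(c(1, 2)), depths = 3, widths = 1)
  grid <- expand.grid(x = seq(-2, 4, by = 0.25), y = seq(-1, 5, by = 0.25))
  vals <- apply(grid, 1, function(r) one$energy(as.numeric(r)))
  expect_equal(as.numeric(grid[which.min(vals), ]), c(1, 2))

  two <- make_three_well_2d(rbind(c(-1, 0), c(1, 0)), depths = c(2, 2),
                            widths = 0.8)
  expect_equal(two$energy(c(-1, 0)), two$energy(c(1, 0)))

  three <- make_three_well_2d(rbind(c(0, 0), c(3, 0), c(0, 3)),
                              depths = c(5, 3, 2), widths = 0.7)
  e <- c(three$energy(c(0, 0)), three$energy(c(3, 0)),
         three$energy(c(0, 3)))
  expect_true(all(diff(e) > 0))  # deeper wells have lower energy

  # gradient matches finite differences
  set.seed(4)
  for (i in 1:20) {
    p <- runif(2, -1, 4)
    g <- three$gradient(p)
    for (d in 1:2) {
      h <- c(0, 0); h[d] <- 1e-6
      fd <- (three$energy(p + h) - three$energy(p - h)) / 2e-6
      expect_equal(g[d], fd, tolerance = 1e-5)
    }
  }
  expect_error(make_three_well_2d(rbind(c(0, 0)), depths = c(1, 2),
                                  widths = c(1, 1, 1)),
               class = "amd_parameter_error")
})

test_that("analytic Boltzmann PMF matches a dense quadrature oracle", {
  dw <- make_double_well(4, 1)
  st <- thermo_state(300)
  edges <- seq(-1.75, 1.75, by = 0.1)  # bins centred on the minima
  p <- analytic_pmf(dw, st, edges)
  expect_equal(p$free_energy, quad_pmf_oracle(dw$energy, edges),
               tolerance = 1e-6)
  # symmetry: both wells at zero
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  iL <- which.min(abs(ctr + 1)); iR <- which.min(abs(ctr - 1))
  expect_equal(p$free_energy[iL], p$free_energy[iR], tolerance = 1e-9)
  expect_lt(abs(p$free_energy[iL]), 1e-6)
  # barrier height equals the oracle's (entropy-corrected) barrier
  ib <- which.min(abs(ctr))
  expect_equal(p$free_energy[ib], quad_pmf_oracle(dw$energy, edges)[ib],
               tolerance = 0.1)
  expect_error(analytic_pmf(dw, st, seq(50, 60, 1)),
               class = "amd_numerical_error")
})

test_that("harmonic-well analytic PMF is quadratic across a wide grid", {
  hw <- toy_potential("harmonic", function(x) 2 * x^2,
                      function(x) 4 * x, dim = 1L)
  st <- thermo_state(300)
  edges <- seq(-2, 2, by = 0.05)
  p <- analytic_pmf(hw, st, edges)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  # quadratic up to the tiny bin-averaging correction
  expect_equal(p$free_energy, 2 * ctr^2 - min(2 * ctr^2),
               tolerance = 0.01)
})

test_that("zero-temperature dynamics stay at a minimum", {
  dw <- make_double_well(4, 1)
  tr <- langevin_simulate(dw, sim_config(500, temperature = 0,
                                         rng_seed = 1, x0 = -1))
  expect_true(all(abs(tr$coords[, 1] + 1) < 1e-8))
  expect_true(all(tr$delta_v == 0))
})

test_that("identical seeds give byte-identical trajectories", {
  dw <- make_double_well(4, 1)
  cfg <- sim_config(3000, rng_seed = 99, boost = boost_spec(5, 5))
  t1 <- langevin_simulate(dw, cfg)
  t2 <- langevin_simulate(dw, cfg)
  expect_identical(t1$coords, t2$coords)
  f1 <- tempfile(); f2 <- tempfile()
  write_trajectory_tsv(t1, f1)
  write_trajectory_tsv(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("compiled and pure-R integrators draw the same path", {
  dw <- make_double_well(4, 1)
  dw_r <- dw; dw_r$kernel <- NULL  # force the R fallback
  for (boost in list(NULL, boost_spec(5, 5))) {
    cfg <- sim_config(2000, rng_seed = 5, boost = boost)
    t_cpp <- langevin_simulate(dw, cfg)
    t_r <- langevin_simulate(dw_r, cfg)
    expect_equal(t_cpp$coords, t_r$coords, tolerance = 1e-12)
    expect_equal(t_cpp$delta_v, t_r$delta_v, tolerance = 1e-12)
  }
})

test_that("a boost below the global minimum never triggers", {
  dw <- make_double_well(4, 1)
  t_plain <- langevin_simulate(dw, sim_config(4000, rng_seed = 21))
  t_boost <- langevin_simulate(dw, sim_config(4000, rng_seed = 21,
                                              boost = boost_spec(-1, 10)))
  expect_identical(t_plain$coords, t_boost$coords)
  expect_true(all(t_boost$delta_v == 0))
})

test_that("boosting above the barrier accelerates well-to-well transitions", {
  dw <- make_double_well(4, 1)
  t_plain <- langevin_simulate(dw, sim_config(2e5, rng_seed = 13))
  t_boost <- langevin_simulate(dw, sim_config(2e5, rng_seed = 13,
                                              boost = boost_spec(5, 2)))
  expect_gt(count_transitions(t_boost), 4 * max(1, count_transitions(t_plain)))
})

test_that("trajectory TSV round-trips losslessly", {
  dw <- make_double_well(4, 1)
  tr <- langevin_simulate(dw, sim_config(500, rng_seed = 3,
                                         boost = boost_spec(5, 5)))
  path <- tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, path)
  back <- read_trajectory_tsv(path)
  expect_identical(back$coords[, 1], tr$coords[, 1])
  expect_identical(back$v_original, tr$v_original)
  expect_identical(back$delta_v, tr$delta_v)
  expect_identical(back$times, tr$times)
})

test_that("synthetic mixtures draw from the requested wells", {
  s1 <- synth_rc_series(5, 1, 0.3, n_frames = 40000, rng_seed = 8)
  expect_lt(abs(mean(s1$values) - 5), 3 * 0.3 / sqrt(40000))
  expect_identical(sum(attr(s1, "component_counts")), 40000L)

  # two wells: free-energy gap equals kT log(w1/w2) for equal widths
  s2 <- synth_rc_series(c(0, 5), c(0.7, 0.3), c(0.5, 0.5),
                        n_frames = 3e5, rng_seed = 9)
  st <- thermo_state(300)
  p <- pmf_1d(s2, 0.25, st)
  ctr <- (p$edges[-1] + p$edges[-length(p$edges)]) / 2
  f0 <- p$free_energy[which.min(abs(ctr - 0.125))]
  f5 <- p$free_energy[which.min(abs(ctr - 5.125))]
  expect_equal(f5 - f0, kBT(st) * log(0.7 / 0.3), tolerance = 0.05)

  expect_error(synth_rc_series(0, 1, -0.1, 10),
               class = "amd_parameter_error")
  expect_error(synth_rc_series(c(0, 1), c(0.6, 0.6), c(1, 1), 10),
               class = "amd_parameter_error")
})

test_that("ionic-lock generator reproduces its design depths", {
  x <- synth_ionic_lock_series(2e5, rng_seed = 10)
  st <- thermo_state(300)
  p <- pmf_1d(x, 0.3, st)
  m <- pmf_minima(p)
  expect_length(m, 3L)
  expect_equal(as.numeric(m), c(4.6, 6.4, 14.2), tolerance = 0.3)
  depths <- attr(m, "free_energy")
  expect_equal(depths[1], 0)
  expect_equal(depths[3], 1.5, tolerance = 0.15)
})

test_that("rc series TSV round-trips bit-exactly", {
  x <- synth_rc_series(c(4.6, 6.4), c(0.5, 0.5), c(0.4, 0.4), 500,
                       rng_seed = 12)
  x$delta_v <- abs(sin(x$values))
  path <- tempfile(fileext = ".tsv")
  write_rc_tsv(x, path)
  y <- read_rc_tsv(path)
  expect_identical(y$values, x$values)
  expect_identical(y$delta_v, x$delta_v)
  expect_identical(y$unit, x$unit)
  expect_identical(y$periodic, x$periodic)
})
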