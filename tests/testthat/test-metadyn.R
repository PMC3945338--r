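# Hill bookkeeping, the Langevin walker, FES reconstruction and analysis.

test_that("bias potential is a periodic minimum-image Gaussian sum", {
  empty <- hill_history(data.frame(time = numeric(0), cv1 = numeric(0),
                                   cv2 = numeric(0), sigma1 = numeric(0),
                                   sigma2 = numeric(0), height = numeric(0)))
  expect_equal(bias_potential(empty, c(0, 0)), 0)

  one <- hill_history(data.frame(time = 1, cv1 = -40, cv2 = -40,
                                 sigma1 = 15, sigma2 = 15, height = 0.3))
  expect_equal(bias_potential(one, c(-40, -40)), 0.3)
  # wraparound: 179 vs -179 is a 2-degree separation, not 358
  seam <- hill_history(data.frame(time = 1, cv1 = -179, cv2 = 0,
                                  sigma1 = 10, sigma2 = 10, height = 1))
  expect_equal(bias_potential(seam, c(179, 0)), exp(-4 / 200), tolerance = 1e-12)
  # full-period translation changes nothing
  set.seed(6)
  hh <- hill_history(data.frame(time = 1:20, cv1 = runif(20, -180, 180),
                                cv2 = runif(20, -180, 180), sigma1 = 12,
                                sigma2 = 12, height = 0.05))
  p <- c(-33, 71)
  expect_equal(bias_potential(hh, p + 360), bias_potential(hh, p),
               tolerance = 1e-12)
})

test_that("hill history validates its invariants", {
  bad_time <- data.frame(time = c(2, 1), cv1 = 0, cv2 = 0, sigma1 = 1,
                         sigma2 = 1, height = 0.1)
  expect_error(hill_history(bad_time), "increasing")
  bad_sigma <- data.frame(time = 1, cv1 = 0, cv2 = 0, sigma1 = 0,
                          sigma2 = 1, height = 0.1)
  expect_error(hill_history(bad_sigma), "widths")
  # centers are wrapped on construction
  h <- hill_history(data.frame(time = 1, cv1 = 270, cv2 = -190, sigma1 = 1,
                               sigma2 = 1, height = 0))
  expect_equal(h$hills$cv1, -90)
  expect_equal(h$hills$cv2, 170)
})

test_that("the walker is bit-reproducible per seed and seed-sensitive", {
  pot <- toy_potential("doublewell")
  args <- list(pot, hill = list(height = 0.1, sigma = 15),
               deposition_interval = 100, n_steps = 20000)
  h1 <- do.call(run_metadynamics, c(args, list(langevin = langevin_params(seed = 5))))
  h2 <- do.call(run_metadynamics, c(args, list(langevin = langevin_params(seed = 5))))
  h3 <- do.call(run_metadynamics, c(args, list(langevin = langevin_params(seed = 6))))
  expect_identical(h1$hills, h2$hills)
  expect_false(isTRUE(all.equal(h1$hills$cv1, h3$hills$cv1)))
  # and the FES reconstructed from them is identical too
  expect_identical(reconstruct_fes(h1)$f, reconstruct_fes(h2)$f)
})

test_that("an unbiased walker samples the Boltzmann density of a harmonic well", {
  pot <- toy_potential("harmonic", list(center = c(-30, -30), k = 0.005))
  hh <- run_metadynamics(pot, hill = list(height = 0, sigma = 15),
                         deposition_interval = 100, n_steps = 200000,
                         langevin = langevin_params(seed = 2), cv_bounds = NULL,
                         sample_interval = 100)
  s <- attr(hh, "samples")
  # stationary sd is sqrt(kT/k) (up to a ~1% Euler discretization correction)
  expect_equal(colMeans(s), c(-30, -30), tolerance = 2)
  expect_equal(apply(s, 2, sd), rep(sqrt(0.596 / 0.005), 2), tolerance = 0.08,
               ignore_attr = TRUE)
})

test_that("unbiased basin occupancy of the double well matches theory", {
  pot <- toy_potential("doublewell")
  hh <- run_metadynamics(pot, hill = list(height = 0, sigma = 15),
                         deposition_interval = 100, n_steps = 400000,
                         langevin = langevin_params(dt = 1, seed = 3),
                         sample_interval = 100)
  s <- attr(hh, "samples")
  frac <- mean(s[, 1] > pot$saddle_point[1])
  f <- function(x) exp(-pot$U(x, pot$params$y_center) / 0.596)
  z1 <- integrate(Vectorize(f), -75, pot$saddle_point[1])$value
  z2 <- integrate(Vectorize(f), pot$saddle_point[1], 10)$value
  theory <- z2 / (z1 + z2)
  # basin transits are rare, so the band is wide (factor ~2)
  expect_gt(frac, theory / 2.5)
  expect_lt(frac, theory * 2.5)
})

test_that("long metadynamics on a flat torus spreads hills uniformly", {
  pot <- toy_potential("harmonic", list(center = c(0, 0), k = 0))
  hh <- run_metadynamics(pot, hill = list(height = 0.1, sigma = 15),
                         deposition_interval = 100, n_steps = 300000,
                         langevin = langevin_params(seed = 4), cv_bounds = NULL)
  expect_gt(stats::ks.test(hh$hills$cv1, "punif", -180, 180)$p.value, 0.01)
  expect_gt(stats::ks.test(hh$hills$cv2, "punif", -180, 180)$p.value, 0.01)
})

test_that("a divergent step raises a stability error", {
  pot <- toy_potential("doublewell")
  expect_error(run_metadynamics(pot, hill = list(height = 0, sigma = 15),
                                deposition_interval = 100, n_steps = 5000,
                                langevin = langevin_params(dt = 5000, seed = 1)),
               "dt|friction")
})

test_that("FES reconstruction has its closed-form limits", {
  empty <- hill_history(data.frame(time = numeric(0), cv1 = numeric(0),
                                   cv2 = numeric(0), sigma1 = numeric(0),
                                   sigma2 = numeric(0), height = numeric(0)))
  g <- seq(-178, 180, by = 2)
  f0 <- reconstruct_fes(empty, g, g)
  expect_true(all(f0$f == 0))
  # single hill on the periodic torus: F(center) = 0, far field = height
  one <- hill_history(data.frame(time = 1, cv1 = 0, cv2 = 0, sigma1 = 10,
                                 sigma2 = 10, height = 0.7))
  f1 <- reconstruct_fes(one, g, g)
  ic <- c(which(g == 0), which(g == 0))
  expect_equal(f1$f[ic[1], ic[2]], 0, tolerance = 1e-12)
  expect_equal(f1$f[which(g == 180), which(g == 180)], 0.7, tolerance = 1e-6)
})

test_that("metadynamics recovers the planted free-energy difference", {
  pot <- toy_potential("doublewell")
  dfs <- sapply(1:2, function(sd) {
    hh <- run_metadynamics(pot, hill = list(height = 0.1, sigma = 15),
                           deposition_interval = 100, n_steps = 400000,
                           langevin = langevin_params(seed = sd))
    fes_delta_estimate(hh, pot$minima[1, ], pot$minima[2, ])
  })
  expect_true(all(abs(dfs - pot$delta_f) <= 0.3))
})

test_that("FES recovery error shrinks with deposition time", {
  pot <- toy_potential("doublewell")
  g <- seq(-75, 10, by = 1)
  truth <- potential_surface(pot, g, g)
  mean_rms <- sapply(c(50000, 200000, 800000), function(nst) {
    mean(sapply(1:3, function(sd) {
      hh <- run_metadynamics(pot, hill = list(height = 0.1, sigma = 15),
                             deposition_interval = 100, n_steps = nst,
                             langevin = langevin_params(seed = sd))
      sqrt(mean((reconstruct_fes(hh, g, g)$f - truth$f)^2))
    }))
  })
  expect_true(all(diff(mean_rms) < 0))
})

test_that("basin minima and barriers match the analytic saddle", {
  pot <- toy_potential("doublewell")
  g <- seq(-75, 10, by = 1)
  sur <- potential_surface(pot, g, g)
  mb <- fes_minima_and_barrier(sur, pot$minima)
  # within one grid cell's F range around the saddle
  sc <- helixkink:::nearest_cell(sur, pot$saddle_point)
  nb <- helixkink:::cell_neighbors(sc[1], sc[2], length(g), length(g), FALSE)
  cell_range <- max(abs(sur$f[cbind(nb[, 1], nb[, 2])] - sur$f[sc[1], sc[2]]))
  expect_lt(abs(mb$barrier - pot$barrier_from_deep), max(cell_range, 0.05))
  expect_equal(mb$minima$f[2] - mb$minima$f[1], pot$delta_f, tolerance = 0.02)
  # offset invariance: adding a constant before min-shifting changes nothing
  sur2 <- free_energy_surface(g, g, sur$f + 3.14)
  mb2 <- fes_minima_and_barrier(sur2, pot$minima)
  expect_equal(mb2$barrier, mb$barrier, tolerance = 1e-10)
  # degenerate: both seeds in one basin
  single <- toy_potential("harmonic", list(center = c(-30, -30), k = 0.01))
  ssur <- potential_surface(single, g, g)
  expect_warning(res <- fes_minima_and_barrier(ssur, rbind(c(-35, -30), c(-25, -30))),
                 "same basin")
  expect_equal(res$barrier, 0)
})

test_that("surface differencing is shift-invariant and matches manual math", {
  g3 <- c(-10, 0, 10)
  a <- free_energy_surface(g3, g3, matrix(c(0, 1, 2, 1, 3, 1, 2, 1, 0), 3, 3))
  expect_true(all(fes_difference(a, a) == 0))
  b <- free_energy_surface(g3, g3, a$f + 1)
  expect_true(all(abs(fes_difference(a, b)) < 1e-12))
  c_ <- free_energy_surface(g3, g3, matrix(c(0, 2, 1, 0, 1, 2, 0, 1, 1), 3, 3))
  expect_equal(fes_difference(a, c_), a$f - c_$f)
  other <- free_energy_surface(c(-9, 0, 9), g3, a$f)
  expect_error(fes_difference(a, other), "different grids")
})

test_that("deposited bias integrates to the hill bookkeeping total", {
  set.seed(10)
  hh <- hill_history(data.frame(time = 1:30, cv1 = runif(30, -180, 180),
                                cv2 = runif(30, -180, 180), sigma1 = 15,
                                sigma2 = 15, height = runif(30, 0, 0.2)))
  g <- seq(-179.5, 179.5, by = 1)
  V <- matrix(0, length(g), length(g))
  for (k in 1:30) {
    e1 <- exp(-ang_diff_deg(g, hh$hills$cv1[k])^2 / (2 * 225))
    e2 <- exp(-ang_diff_deg(g, hh$hills$cv2[k])^2 / (2 * 225))
    V <- V + hh$hills$height[k] * outer(e1, e2)
  }
  total <- sum(V) * 1 * 1  # quadrature over the torus
  expect_equal(total, sum(hh$hills$height) * 2 * pi * 225, tolerance = 1e-6)
})

test_that("HILLS files round-trip", {
  pot <- toy_potential("doublewell")
  hh <- run_metadynamics(pot, hill = list(height = 0.1, sigma = 15),
                         deposition_interval = 200, n_steps = 10000,
                         langevin = langevin_params(seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hills(hh, path)
  back <- read_hills(path, deposition_interval = 200, cv_bounds = c(-75, 10))
  expect_equal(back$hills$cv1, hh$hills$cv1, tolerance = 1e-6)
  expect_equal(back$hills$height, hh$hills$height, tolerance = 1e-6)
  expect_equal(nrow(back$hills), nrow(hh$hills))
})
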