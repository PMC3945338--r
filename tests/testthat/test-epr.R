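# Pseudo spin labels, DEER distance distributions, Boltzmann weighting and
# membrane depth profiles.

# one isolated glycine-like residue (N, CA, C only) at the origin
isolated_site <- function() {
  conformation(data.frame(
    atom = c("N", "CA", "C"), element = c("N", "C", "C"),
    resno = 700, resname = "GLY",
    x = c(-1.458, 0, 0.55), y = c(0, 0, 1.42), z = c(0, 0, 0)))
}

test_that("pseudo-label clouds sit at the requested radius on the CB cone axis", {
  site <- isolated_site()
  L <- place_pseudo_label(site, 700, n_samples = 2000, seed = 3)
  CA <- c(0, 0, 0)
  d <- sqrt(rowSums(sweep(L$positions, 2, CA)^2))
  expect_equal(mean(d), 7, tolerance = 0.5)
  expect_equal(sum(L$weights), 1, tolerance = 1e-9)
  # mean position lies along the cone axis within the cone half-angle
  axis <- helixkink:::cb_direction(site, 700)
  mdir <- colMeans(L$positions) - CA
  mdir <- mdir / sqrt(sum(mdir^2))
  expect_lt(acos(min(1, sum(mdir * axis))) * 180 / pi, 15)
})

test_that("a fully enclosed site raises a placement error", {
  site <- isolated_site()
  # dense dummy-atom ball blanketing the whole sampling shell
  g <- expand.grid(x = seq(-12, 12, by = 2), y = seq(-12, 12, by = 2),
                   z = seq(-12, 12, by = 2))
  r <- sqrt(rowSums(g^2))
  g <- g[r > 3 & r < 12, ]
  shell <- data.frame(atom = "DUM", element = "C",
                      resno = 701, resname = "DUM",
                      x = g$x, y = g$y, z = g$z)
  enclosed <- site
  enclosed$atoms <- rbind(enclosed$atoms, shell)
  expect_error(place_pseudo_label(enclosed, 700, n_samples = 200, seed = 1),
               "clash")
})

test_that("burial weighting pulls the label ensemble toward the membrane center", {
  h <- fx_ideal()
  frame <- fx_frame()
  for (seed in 1:3) {
    plain <- place_pseudo_label(h, 700, seed = seed)
    weighted <- place_pseudo_label(h, 700, seed = seed, frame = frame)
    d_plain <- mean(burial_depth(plain$positions[, 3], frame))
    d_weighted <- sum(weighted$weights * burial_depth(weighted$positions[, 3], frame))
    expect_gte(d_weighted, d_plain)
  }
})

test_that("two point labels 20 A apart give a delta distribution", {
  la <- structure(list(site = 1, positions = matrix(c(0, 0, 0), 1, 3), weights = 1),
                  class = "LabelEnsemble")
  lb <- structure(list(site = 2, positions = matrix(c(20, 0, 0), 1, 3), weights = 1),
                  class = "LabelEnsemble")
  dd <- distance_distribution(la, lb)
  expect_equal(dd$mean, 20, tolerance = 1e-12)
  expect_equal(dd$sd, 0, tolerance = 1e-12)
})

test_that("distribution moments match a large Monte-Carlo pair sample", {
  set.seed(44)
  A <- matrix(rnorm(3 * 400, sd = 2), ncol = 3)
  B <- sweep(matrix(rnorm(3 * 400, sd = 2), ncol = 3), 2, c(30, 0, 0), "+")
  la <- structure(list(site = 1, positions = A, weights = rep(1 / 400, 400)),
                  class = "LabelEnsemble")
  lb <- structure(list(site = 2, positions = B, weights = rep(1 / 400, 400)),
                  class = "LabelEnsemble")
  dd <- distance_distribution(la, lb)
  # independent MC oracle: 1e6 fresh pairs from the same generating law
  n <- 1e6
  d_mc <- sqrt(rowSums((matrix(rnorm(3 * n, sd = 2), ncol = 3) -
                          sweep(matrix(rnorm(3 * n, sd = 2), ncol = 3), 2,
                                c(30, 0, 0), "+"))^2))
  expect_equal(dd$mean, mean(d_mc), tolerance = 0.01 * mean(d_mc))
  expect_equal(dd$sd, sd(d_mc), tolerance = 0.06 * sd(d_mc))
})

test_that("distributions are symmetric, normalized, and moment-consistent", {
  set.seed(9)
  A <- matrix(rnorm(30, sd = 1.5), 10, 3)
  B <- sweep(matrix(rnorm(30, sd = 1.5), 10, 3), 2, c(25, 5, 0), "+")
  wa <- runif(10); wa <- wa / sum(wa)
  wb <- runif(10); wb <- wb / sum(wb)
  la <- structure(list(site = 1, positions = A, weights = wa), class = "LabelEnsemble")
  lb <- structure(list(site = 2, positions = B, weights = wb), class = "LabelEnsemble")
  d1 <- distance_distribution(la, lb)
  d2 <- distance_distribution(lb, la)
  expect_equal(d1$density, d2$density, tolerance = 1e-12)
  expect_equal(d1$mean, d2$mean, tolerance = 1e-12)
  # unit area by trapezoid
  step <- d1$grid[2] - d1$grid[1]
  area <- sum((d1$density[-1] + d1$density[-length(d1$density)]) / 2) * step
  expect_equal(area, 1, tolerance = 1e-6)
  # reported moments equal the raw weighted pair moments (pre-smoothing)
  D <- sqrt(pmax(0, outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)))
  W <- outer(wa, wb)
  expect_equal(d1$mean, sum(W * D), tolerance = 1e-6)
  # too-narrow grid is a range error
  expect_error(distance_distribution(la, lb, grid_min = 0, grid_max = 10), "grid")
})

test_that("Boltzmann weights follow the closed forms and shift invariance", {
  kT <- 0.0019872 * 300
  expect_equal(boltzmann_weights(c(1, 1, 1)), rep(1 / 3, 3))
  w <- boltzmann_weights(c(0, kT * log(2)))
  expect_equal(w, c(2 / 3, 1 / 3), tolerance = 1e-9)
  f3 <- c(0, 1, 2)
  w3 <- boltzmann_weights(f3)
  ref <- exp(-f3 / kT) / sum(exp(-f3 / kT))
  expect_equal(w3, ref, tolerance = 1e-12)
  expect_equal(boltzmann_weights(f3 + 11.7), w3, tolerance = 1e-12)
  # via a surface and bin assignments
  fes <- free_energy_surface(seq(-75, 10, 5), seq(-75, 10, 5),
                             matrix(0, 18, 18))
  expect_equal(boltzmann_weights(fes, rbind(c(1, 1), c(5, 9), c(18, 2))),
               rep(1 / 3, 3))
  expect_error(boltzmann_weights(fes, matrix(numeric(0), 0, 2)), "empty")
})

test_that("depth profile has its closed forms and is translation-equivariant", {
  frame <- fx_frame()  # planes at +/-19, center 0
  mk <- function(site, z) structure(list(site = site,
                                         positions = matrix(c(0, 0, z), 1, 3),
                                         weights = 1), class = "LabelEnsemble")
  prof <- depth_profile(list(mk(700, 19), mk(711, 0), mk(723, -19)), frame)
  expect_equal(prof$depth_ang, c(0, 19, 0))
  expect_equal(prof$phi[1], 0)
  expect_equal(prof$phi[2], 5 * tanh(19 / 10), tolerance = 1e-12)
  # translating upper-leaflet labels 3 A toward the center (-z) deepens
  # every site by exactly 3
  sites <- list(mk(700, 16), mk(705, 12), mk(710, 8))
  p0 <- depth_profile(sites, frame)
  shifted <- lapply(sites, function(L) {
    L$positions[, 3] <- L$positions[, 3] - 3; L
  })
  p3 <- depth_profile(shifted, frame)
  expect_equal(p3$depth_ang, p0$depth_ang + 3, tolerance = 1e-12)
})

test_that("profile correlation matches an explicit covariance formula", {
  a <- data.frame(residue_index = 1:5, phi = c(1, 3, 2, 5, 4))
  b2 <- data.frame(residue_index = 1:5, phi = 2 * c(1, 3, 2, 5, 4) + 1)
  expect_equal(profile_correlation(a, b2), 1, tolerance = 1e-12)
  bneg <- data.frame(residue_index = 1:5, phi = -c(1, 3, 2, 5, 4))
  expect_equal(profile_correlation(a, bneg), -1, tolerance = 1e-12)
  x <- c(1, 3, 2, 5, 4); y <- c(2, 1, 4, 3, 6)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(profile_correlation(x, y), manual, tolerance = 1e-12)
  expect_error(profile_correlation(x[1:2], y[1:2]), "at least 3")
  expect_error(profile_correlation(rep(1, 5), y), "zero variance")
})

test_that("DEER tables round-trip through TSV", {
  la <- structure(list(site = 1, positions = matrix(c(0, 0, 0), 1, 3), weights = 1),
                  class = "LabelEnsemble")
  lb <- structure(list(site = 2, positions = matrix(c(30, 0, 0), 1, 3), weights = 1),
                  class = "LabelEnsemble")
  dd <- distance_distribution(la, lb)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_deer_table(dd, path)
  back <- read_deer_table(path)
  expect_equal(back$distance_ang, dd$grid)
  expect_equal(back$density, dd$density, tolerance = 1e-12)
})
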