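## Desk-scale metadynamics over the two hinge dihedral collective variables:
## hill bookkeeping, the Langevin walker (compiled core), free-energy-surface
## reconstruction and analysis.

#' Langevin walker parameters
#'
#' Overdamped dynamics: s <- s - (gradU + gradV) * dt/friction +
#' sqrt(2 kT dt/friction) * xi. Only the mobility dt/friction and kT enter;
#' "time" is nominal walker time, not physical time.
#'
#' @param kT thermal energy, kcal/mol (0.596 ~ 300 K).
#' @param friction friction coefficient (1/steps).
#' @param dt step size.
#' @param seed RNG seed.
#' @return object of class `LangevinParams`.
#' @export
langevin_params <- function(kT = 0.596, friction = 1, dt = 3, seed = 1) {
  if (kT <= 0 || friction <= 0 || dt <= 0) stop("kT, friction, dt must be positive")
  structure(list(kT = kT, friction = friction, dt = dt, seed = as.integer(seed)),
            class = "LangevinParams")
}

#' Construct a hill history
#'
#' @param hills data frame with columns `time`, `cv1`, `cv2`, `sigma1`,
#'   `sigma2`, `height` (time strictly increasing, centers wrapped).
#' @param deposition_interval steps between depositions.
#' @param cv_bounds NULL (periodic torus) or c(lo, hi) applied to both CVs
#'   (reflecting window).
#' @return object of class `HillHistory`.
#' @export
hill_history <- function(hills, deposition_interval = NA_integer_,
                         cv_bounds = NULL) {
  req <- c("time", "cv1", "cv2", "sigma1", "sigma2", "height")
  miss <- setdiff(req, names(hills))
  if (length(miss)) stop("hills is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(hills) > 1 && any(diff(hills$time) <= 0)) {
    stop("hill times must be strictly increasing")
  }
  if (any(hills$sigma1 <= 0 | hills$sigma2 <= 0)) stop("hill widths must be > 0")
  if (any(hills$height < 0)) stop("hill heights must be >= 0")
  hills$cv1 <- wrap_deg(hills$cv1); hills$cv2 <- wrap_deg(hills$cv2)
  structure(list(hills = hills, deposition_interval = deposition_interval,
                 cv_bounds = cv_bounds),
            class = "HillHistory")
}

#' @export
print.HillHistory <- function(x, ...) {
  cat(sprintf("<HillHistory: %d hills, interval %s>\n", nrow(x$hills),
              x$deposition_interval))
  invisible(x)
}

#' Metadynamics bias potential at points
#'
#' V(s) = sum over hills of h * exp(-(d1^2 + d2^2)/(2 sigma^2)) with d_i the
#' minimum-image angular difference to the hill center.
#'
#' @param history a `HillHistory`.
#' @param point length-2 vector (cv1, cv2) or an n x 2 matrix of points.
#' @param n_hills evaluate using only the first `n_hills` hills (default all).
#' @return bias in kcal/mol (scalar or vector).
#' @export
bias_potential <- function(history, point, n_hills = NULL) {
  P <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  h <- history$hills
  if (!is.null(n_hills)) h <- h[seq_len(min(n_hills, nrow(h))), , drop = FALSE]
  v <- numeric(nrow(P))
  if (nrow(h) == 0) return(if (is.matrix(point)) v else v[1])
  for (k in seq_len(nrow(h))) {
    d1 <- ang_diff_deg(P[, 1], h$cv1[k])
    d2 <- ang_diff_deg(P[, 2], h$cv2[k])
    v <- v + h$height[k] * exp(-(d1^2 / (2 * h$sigma1[k]^2) +
                                 d2^2 / (2 * h$sigma2[k]^2)))
  }
  if (is.matrix(point)) v else v[1]
}

#' Run metadynamics with the Langevin walker
#'
#' A hill of the given height and width is dropped at the walker position
#' every `deposition_interval` steps; the accumulated bias acts on the
#' walker through a gradient grid. With `cv_bounds` the walker reflects at
#' the window edges (the sampling window used throughout is [-75, 10]
#' degrees per CV); without bounds the space is the periodic torus.
#' Bit-reproducible for a fixed seed.
#'
#' @param potential a `ToyPotential`.
#' @param hill list with `height` (kcal/mol) and `sigma` (deg).
#' @param deposition_interval steps between hills.
#' @param n_steps total walker steps.
#' @param langevin a [langevin_params()].
#' @param cv_bounds NULL or c(lo, hi) for both CVs.
#' @param start length-2 start point (default: the deepest known minimum,
#'   else the window/torus center).
#' @param grid_spacing bias-grid spacing in degrees.
#' @param sample_interval record the walker position every this many steps
#'   (0 = never).
#' @return a `HillHistory`; walker samples (if any) in attribute `samples`.
#' @export
run_metadynamics <- function(potential, hill = list(height = 0.1, sigma = 15),
                             deposition_interval = 100, n_steps = 100000,
                             langevin = langevin_params(),
                             cv_bounds = c(-75, 10), start = NULL,
                             grid_spacing = 1, sample_interval = 0) {
  if (n_steps <= 0 || deposition_interval <= 0) stop("steps and interval must be positive")
  if (hill$height < 0 || hill$sigma <= 0) stop("invalid hill parameters")
  if (is.null(start)) {
    start <- if (!is.null(potential$minima)) {
      potential$minima[1, ]
    } else if (!is.null(cv_bounds)) {
      rep(mean(cv_bounds), 2)
    } else c(0, 0)
  }
  mobility <- langevin$dt / langevin$friction
  bounds <- if (is.null(cv_bounds)) numeric(0) else
    c(cv_bounds[1], cv_bounds[2], cv_bounds[1], cv_bounds[2])
  if (is.na(potential$cpp_type)) {
    res <- metadyn_walk_r(potential, start, n_steps, deposition_interval,
                          hill$height, hill$sigma, langevin$kT, mobility,
                          cv_bounds, grid_spacing, sample_interval,
                          langevin$seed)
  } else {
    set.seed(langevin$seed)
    res <- .metadyn_walk_cpp(potential$cpp_type, potential$cpp_params,
                             start[1], start[2], as.integer(n_steps),
                             as.integer(deposition_interval),
                             hill$height, hill$sigma, langevin$kT, mobility,
                             bounds, grid_spacing, as.integer(sample_interval))
  }
  hh <- res$hills
  hills <- data.frame(time = hh[, 1], cv1 = hh[, 2], cv2 = hh[, 3],
                      sigma1 = rep(hill$sigma, nrow(hh)),
                      sigma2 = rep(hill$sigma, nrow(hh)),
                      height = rep(hill$height, nrow(hh)))
  out <- hill_history(hills, deposition_interval, cv_bounds)
  attr(out, "samples") <- res$samples
  out
}

## pure-R fallback walker for custom potentials (small runs only): same
## algorithm as the compiled core, with the bias force summed over hills
metadyn_walk_r <- function(potential, start, n_steps, dep, h, sigma, kT,
                           mobility, cv_bounds, grid_spacing, sample_interval,
                           seed) {
  set.seed(seed)
  bounded <- !is.null(cv_bounds)
  x <- start[1]; y <- start[2]
  noise_sd <- sqrt(2 * kT * mobility)
  hx <- hy <- ht <- numeric(0)
  ix <- iy <- numeric(0)  # hill centers + mirror images, for the bias force
  sx <- sy <- numeric(0)
  s2 <- sigma^2
  for (step in seq_len(n_steps)) {
    g <- potential$grad(x, y)
    bx <- by <- 0
    if (length(ix)) {
      d1 <- ang_diff_deg(x, ix); d2 <- ang_diff_deg(y, iy)
      e <- h * exp(-(d1^2 + d2^2) / (2 * s2))
      bx <- -sum(e * d1 / s2)   # dV/dx
      by <- -sum(e * d2 / s2)
    }
    dxs <- -mobility * (g[1] + bx) + noise_sd * stats::rnorm(1)
    dys <- -mobility * (g[2] + by) + noise_sd * stats::rnorm(1)
    if (abs(dxs) > 90 || abs(dys) > 90) stop("divergent step: reduce dt or friction")
    x <- x + dxs; y <- y + dys
    if (bounded) {
      while (x < cv_bounds[1] || x > cv_bounds[2]) {
        x <- if (x < cv_bounds[1]) 2 * cv_bounds[1] - x else 2 * cv_bounds[2] - x
      }
      while (y < cv_bounds[1] || y > cv_bounds[2]) {
        y <- if (y < cv_bounds[1]) 2 * cv_bounds[1] - y else 2 * cv_bounds[2] - y
      }
    } else {
      x <- wrap_deg(x); y <- wrap_deg(y)
    }
    if (h > 0 && step %% dep == 0) {
      hx <- c(hx, x); hy <- c(hy, y); ht <- c(ht, step)
      imgs <- hill_image_centers(x, y, cv_bounds)
      ix <- c(ix, imgs[, 1]); iy <- c(iy, imgs[, 2])
    }
    if (sample_interval > 0 && step %% sample_interval == 0) {
      sx <- c(sx, x); sy <- c(sy, y)
    }
  }
  list(hills = cbind(ht, hx, hy), samples = cbind(sx, sy))
}

#' Free-energy difference between two points, averaged over late hills
#'
#' The running estimate F(b) - F(a) = V(a, t) - V(b, t) is evaluated at
#' every deposition time in the final `tail_fraction` of the history and
#' averaged, damping the oscillation of the non-well-tempered estimator.
#'
#' @param history a `HillHistory`.
#' @param point_a,point_b length-2 CV points (a = reference, typically the
#'   deep minimum).
#' @return mean of the running F(b) - F(a) over the tail.
#' @export
fes_delta_estimate <- function(history, point_a, point_b, tail_fraction = 0.2) {
  h <- history$hills
  n <- nrow(h)
  if (n == 0) stop("empty hill history")
  one <- function(p) {
    # include mirror images for reflecting windows (see reconstruct_fes)
    v <- 0
    if (is.null(history$cv_bounds)) {
      imgs1 <- matrix(h$cv1, ncol = 1); imgs2 <- matrix(h$cv2, ncol = 1)
    } else {
      lo <- history$cv_bounds[1]; hi <- history$cv_bounds[2]
      imgs1 <- cbind(h$cv1, 2 * lo - h$cv1, 2 * hi - h$cv1)
      imgs2 <- cbind(h$cv2, 2 * lo - h$cv2, 2 * hi - h$cv2)
    }
    for (a in seq_len(ncol(imgs1))) for (b in seq_len(ncol(imgs2))) {
      d1 <- ang_diff_deg(p[1], imgs1[, a]); d2 <- ang_diff_deg(p[2], imgs2[, b])
      v <- v + h$height * exp(-(d1^2 / (2 * h$sigma1^2) + d2^2 / (2 * h$sigma2^2)))
    }
    cumsum(v)
  }
  va <- one(point_a); vb <- one(point_b)
  tail_idx <- seq(max(1, ceiling((1 - tail_fraction) * n)), n)
  mean(va[tail_idx] - vb[tail_idx])
}

#' Write a hill history as a PLUMED-style HILLS text file
#'
#' Columns: time, center1, center2, sigma1, sigma2, height.
#'
#' @param history a `HillHistory`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_hills <- function(history, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time cv1 cv2 sigma_cv1 sigma_cv2 height", con)
  h <- history$hills
  writeLines(sprintf("%12.1f %12.6f %12.6f %10.4f %10.4f %12.6f",
                     h$time, h$cv1, h$cv2, h$sigma1, h$sigma2, h$height), con)
  invisible(path)
}

#' Read a PLUMED-style HILLS text file
#'
#' @param path file path.
#' @param deposition_interval,cv_bounds metadata not stored in the file.
#' @return a `HillHistory`.
#' @export
read_hills <- function(path, deposition_interval = NA_integer_, cv_bounds = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) < 6) stop("HILLS file needs 6 columns: time cv1 cv2 sigma1 sigma2 height")
  hill_history(data.frame(time = m[, 1], cv1 = m[, 2], cv2 = m[, 3],
                          sigma1 = m[, 4], sigma2 = m[, 5], height = m[, 6]),
               deposition_interval, cv_bounds)
}
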