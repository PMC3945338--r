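## Simplified pseudo spin labels, DEER-style inter-label distance
## distributions (including Boltzmann-weighted ensembles), and membrane
## depth-parameter profiles.
##
## The label model is a documented accessible-volume proxy: nitroxide N-O
## midpoint positions are sampled in a cone about the CA->CB direction at a
## Gaussian radial distance, clash-filtered against the protein, and (when a
## membrane frame is given) reweighted by a burial preference
## exp(depth / lambda_bury) that encodes the tendency of the hydrophobic tag
## to bury itself below the phosphate plane.

## ideal CB direction reconstructed from backbone N, C, CA (tetrahedral)
cb_direction <- function(conf, resno) {
  CA <- get_atom(conf, resno, "CA")
  N <- get_atom(conf, resno, "N")
  C <- get_atom(conf, resno, "C")
  CB <- get_atom(conf, resno, "CB")
  if (!is.null(CB)) return(unit(CB - CA))
  if (is.null(CA) || is.null(N) || is.null(C)) {
    stop("residue ", resno, " lacks CB and the backbone atoms needed to rebuild it")
  }
  b1 <- unit(N - CA); b2 <- unit(C - CA)
  bis <- unit(b1 + b2)          # in-plane bisector
  perp <- unit(vcross(b2, b1))  # out-of-plane normal
  # tetrahedral: CB sits opposite the bisector, tipped out of the N-CA-C plane
  unit(-bis * sin(deg2rad(54.75)) + perp * cos(deg2rad(54.75)))
}

#' Signed membrane burial depth of z positions
#'
#' Distance from the nearer phosphate plane, positive toward the membrane
#' center, negative toward water.
#'
#' @param z numeric vector of coordinates along the membrane normal.
#' @param frame a `MembraneFrame`.
#' @return numeric vector of signed depths in Angstrom.
#' @export
burial_depth <- function(z, frame) {
  pmin(frame$z_phosphate_upper - z, z - frame$z_phosphate_lower)
}

#' Place a pseudo spin label at a site
#'
#' Samples candidate N-O midpoint positions in a cone about the CA->CB
#' direction, at radial distances ~ Normal(radius_mean, radius_sd); rejects
#' candidates within `clash_cutoff` of any protein heavy atom. With a
#' membrane frame, candidate weights are multiplied by
#' exp(burial_depth / lambda_bury) and renormalized (deeper positions are
#' preferred, mimicking the hydrophobic tag's membrane burial).
#'
#' @param conf a `Conformation`.
#' @param site residue index of the labeled site.
#' @param n_samples candidate count before clash filtering.
#' @param radius_mean,radius_sd radial distance law, Angstrom.
#' @param cone_half_angle_deg cone half-angle about the CA->CB axis.
#' @param clash_cutoff rejection distance to protein heavy atoms, Angstrom.
#' @param lambda_bury burial weight decay length, Angstrom.
#' @param frame optional `MembraneFrame` enabling burial weighting.
#' @param seed RNG seed.
#' @return a `LabelEnsemble`: list with `site`, `positions` (n x 3),
#'   `weights` (sum 1).
#' @export
place_pseudo_label <- function(conf, site, n_samples = 500, radius_mean = 7,
                               radius_sd = 1, cone_half_angle_deg = 40,
                               clash_cutoff = 2.5, lambda_bury = 5,
                               frame = NULL, seed = 1) {
  CA <- get_atom(conf, site, "CA")
  if (is.null(CA)) stop("site ", site, " has no CA atom")
  axis <- cb_direction(conf, site)
  # orthonormal frame around the cone axis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit(vcross(axis, ref)); e2 <- vcross(axis, e1)
  set.seed(seed)
  n <- n_samples
  # uniform over the spherical cap of the cone
  cmin <- cos(deg2rad(cone_half_angle_deg))
  u <- stats::runif(n, cmin, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  sint <- sqrt(pmax(0, 1 - u^2))
  dirs <- cbind(u) %*% rbind(axis) + cbind(sint * cos(phi)) %*% rbind(e1) +
    cbind(sint * sin(phi)) %*% rbind(e2)
  r <- stats::rnorm(n, radius_mean, radius_sd)
  pos <- sweep(dirs * r, 2, CA, "+")
  # clash filter against all protein heavy atoms
  heavy <- as.matrix(conf$atoms[conf$atoms$element != "H", c("x", "y", "z")])
  cut2 <- clash_cutoff^2
  ok <- rep(TRUE, n)
  for (j in seq_len(nrow(heavy))) {
    d2 <- (pos[, 1] - heavy[j, 1])^2 + (pos[, 2] - heavy[j, 2])^2 +
      (pos[, 3] - heavy[j, 3])^2
    ok <- ok & (d2 >= cut2)
    if (!any(ok)) break
  }
  if (!any(ok)) stop("label placement failed at site ", site,
                     ": all candidates clash with the protein")
  pos <- pos[ok, , drop = FALSE]
  w <- rep(1, nrow(pos))
  if (!is.null(frame)) {
    depth <- burial_depth(pos %*% frame$normal, frame)
    w <- exp(depth / lambda_bury)
  }
  w <- w / sum(w)
  structure(list(site = site, positions = pos, weights = as.numeric(w)),
            class = "LabelEnsemble")
}

#' DEER-style distance distribution between two label ensembles
#'
#' Weighted histogram of all cross pairs (weight = w_a * w_b) on a uniform
#' distance grid, Gaussian-kernel smoothed and renormalized to unit area
#' (trapezoid). The reported mean and sd are the weighted moments of the
#' raw pair distances, computed before smoothing.
#'
#' @param a,b `LabelEnsemble` objects.
#' @param grid_min,grid_max,grid_step distance grid in Angstrom (default
#'   0-80 at 0.25, covering the DEER-sensitive 18-60 Angstrom range).
#' @param bandwidth Gaussian kernel sd in Angstrom.
#' @return a `DistanceDistribution`: list with `grid`, `density`, `mean`,
#'   `sd`.
#' @export
distance_distribution <- function(a, b, grid_min = 0, grid_max = 80,
                                  grid_step = 0.25, bandwidth = 1.0) {
  pa <- a$positions; pb <- b$positions
  # all cross-pair distances
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  dist <- sqrt(pmax(0, d2))
  w <- outer(a$weights, b$weights)
  w <- w / sum(w)
  if (max(dist) > grid_max || min(dist) < grid_min) {
    stop(sprintf("distance grid [%g, %g] does not cover pair distances [%g, %g]",
                 grid_min, grid_max, min(dist), max(dist)))
  }
  mu <- sum(w * dist)
  sdv <- sqrt(max(0, sum(w * (dist - mu)^2)))
  grid <- seq(grid_min, grid_max, by = grid_step)
  # kernel-smoothed density on the grid
  dens <- numeric(length(grid))
  dv <- as.numeric(dist); wv <- as.numeric(w)
  for (i in seq_along(grid)) {
    dens[i] <- sum(wv * stats::dnorm(grid[i], dv, bandwidth))
  }
  area <- sum((dens[-1] + dens[-length(dens)]) / 2) * grid_step
  if (area > 0) dens <- dens / area
  structure(list(grid = grid, density = dens, mean = mu, sd = sdv),
            class = "DistanceDistribution")
}

#' @export
print.DistanceDistribution <- function(x, ...) {
  cat(sprintf("<DistanceDistribution: mean %.2f A, sd %.2f A>\n", x$mean, x$sd))
  invisible(x)
}

#' Boltzmann weights of conformers from a free-energy surface
#'
#' w_i proportional to exp(-F(bin_i)/kT) with kT = 0.0019872 kcal/mol/K x T.
#' Weights are invariant to any constant shift of the surface.
#'
#' @param fes a `FreeEnergySurface` (see [reconstruct_fes()]), or a numeric
#'   vector of free energies per conformer.
#' @param assignments for a surface: 2-column matrix of (grid1, grid2) bin
#'   indices per conformer; ignored when `fes` is already a vector.
#' @param temperature_K temperature in Kelvin.
#' @return numeric weights summing to 1.
#' @export
boltzmann_weights <- function(fes, assignments = NULL, temperature_K = 300) {
  f <- if (is.numeric(fes)) {
    fes
  } else {
    if (is.null(assignments) || NROW(assignments) == 0) {
      stop("empty conformer assignment")
    }
    assignments <- matrix(as.integer(assignments), ncol = 2)
    fes$f[assignments]
  }
  if (length(f) == 0) stop("empty conformer assignment")
  if (!all(is.finite(f))) stop("assigned bins have non-finite free energy")
  kT <- 0.0019872 * temperature_K
  w <- exp(-(f - min(f)) / kT)
  w / sum(w)
}

#' Membrane depth-parameter profile of labeled sites
#'
#' For each label ensemble, the depth is the signed distance of the
#' weighted-mean label position from the nearer phosphate plane (positive
#' toward the membrane center); the dimensionless depth parameter uses the
#' monotone saturating calibration phi = phi_max * tanh(depth/lambda), a
#' proxy for the power-saturation collision-rate calibration.
#'
#' @param labels list of `LabelEnsemble` (one per labeled residue).
#' @param frame a `MembraneFrame`.
#' @param phi_max,lambda_ang calibration parameters (default 5 and 10 A).
#' @return a `DepthProfile`: data frame with columns `residue_index`,
#'   `depth_ang`, `phi`.
#' @export
depth_profile <- function(labels, frame, phi_max = 5, lambda_ang = 10) {
  rows <- lapply(labels, function(L) {
    mpos <- colSums(L$positions * L$weights)
    z <- sum(mpos * frame$normal)
    depth <- burial_depth(z, frame)
    data.frame(residue_index = L$site, depth_ang = depth,
               phi = phi_max * tanh(depth / lambda_ang))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("DepthProfile", class(out))
  out
}

#' Pearson correlation between two per-residue profiles
#'
#' Computed over the shared residue set; requires at least 3 shared residues
#' and nonzero variance in both tracks.
#'
#' @param a,b data frames with columns `residue_index` and a value column
#'   (the first non-index numeric column is used), or plain numeric vectors
#'   of equal length.
#' @return Pearson r.
#' @export
profile_correlation <- function(a, b) {
  if (is.data.frame(a) && is.data.frame(b)) {
    va <- setdiff(names(a), "residue_index")[1]
    vb <- setdiff(names(b), "residue_index")[1]
    shared <- intersect(a$residue_index, b$residue_index)
    x <- a[[va]][match(shared, a$residue_index)]
    y <- b[[vb]][match(shared, b$residue_index)]
  } else {
    x <- as.numeric(a); y <- as.numeric(b)
  }
  if (length(x) < 3) stop("need at least 3 shared residues")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in a profile")
  }
  stats::cor(x, y)
}

#' Read a DEER distance distribution table
#'
#' Tab-separated text `distance_ang<TAB>density`.
#'
#' @param path file path.
#' @return data frame with columns `distance_ang`, `density`.
#' @export
read_deer_table <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t")
  names(tb)[1:2] <- c("distance_ang", "density")
  tb[, c("distance_ang", "density")]
}

#' Write a distance distribution as a TSV table
#' @param dist a `DistanceDistribution`.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_deer_table <- function(dist, path) {
  utils::write.table(data.frame(distance_ang = dist$grid, density = dist$density),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
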