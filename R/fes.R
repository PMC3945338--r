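## Free-energy surfaces over the 2D angular CV space: reconstruction from a
## hill history (F = -V, min-shifted), basin minima and barrier extraction
## by a monotone flood, and surface differencing.

#' Construct a FreeEnergySurface
#'
#' @param grid1,grid2 uniform degree grids.
#' @param f matrix of free energies, `length(grid1)` x `length(grid2)`,
#'   kcal/mol; min-shifted to zero on construction.
#' @return object of class `FreeEnergySurface`.
#' @export
free_energy_surface <- function(grid1, grid2, f) {
  f <- as.matrix(f)
  if (nrow(f) != length(grid1) || ncol(f) != length(grid2)) {
    stop("f must be length(grid1) x length(grid2)")
  }
  if (!all(is.finite(f))) stop("non-finite free energies")
  f <- f - min(f)
  span1 <- diff(range(grid1)) + (grid1[2] - grid1[1])
  span2 <- diff(range(grid2)) + (grid2[2] - grid2[1])
  structure(list(grid1 = grid1, grid2 = grid2, f = f,
                 periodic = isTRUE(all.equal(span1, 360)) &&
                   isTRUE(all.equal(span2, 360))),
            class = "FreeEnergySurface")
}

#' @export
print.FreeEnergySurface <- function(x, ...) {
  cat(sprintf("<FreeEnergySurface: %d x %d grid, max %.2f kcal/mol%s>\n",
              length(x$grid1), length(x$grid2), max(x$f),
              if (x$periodic) ", periodic" else ""))
  invisible(x)
}

#' Reconstruct the free-energy surface from a hill history
#'
#' F = -V_bias on the grid, shifted so min(F) = 0 (the standard
#' non-well-tempered estimator). Optionally uses only the first
#' `hill_fraction` of the hills.
#'
#' @param history a `HillHistory`.
#' @param grid1,grid2 degree grids (default: the sampling window of the
#'   history at 1 degree, or the full torus at 2 degrees).
#' @param hill_fraction fraction of hills (from the start) to accumulate.
#' @return a `FreeEnergySurface`.
#' @export
reconstruct_fes <- function(history, grid1 = NULL, grid2 = NULL,
                            hill_fraction = 1) {
  if (is.null(grid1)) {
    grid1 <- if (!is.null(history$cv_bounds)) {
      seq(history$cv_bounds[1], history$cv_bounds[2], by = 1)
    } else seq(-179, 180, by = 2)
  }
  if (is.null(grid2)) grid2 <- grid1
  h <- history$hills
  n <- floor(hill_fraction * nrow(h))
  V <- matrix(0, length(grid1), length(grid2))
  if (n >= 1) {
    for (k in seq_len(n)) {
      centers <- hill_image_centers(h$cv1[k], h$cv2[k], history$cv_bounds)
      for (r in seq_len(nrow(centers))) {
        e1 <- exp(-ang_diff_deg(grid1, centers[r, 1])^2 / (2 * h$sigma1[k]^2))
        e2 <- exp(-ang_diff_deg(grid2, centers[r, 2])^2 / (2 * h$sigma2[k]^2))
        V <- V + h$height[k] * outer(e1, e2)
      }
    }
  }
  free_energy_surface(grid1, grid2, -V)
}

## mirror-image centers of a hill for a reflecting window (the walker is
## reflected at the window edges, so the bias must be too); for periodic
## sampling the hill is its own single image
hill_image_centers <- function(cv1, cv2, cv_bounds) {
  if (is.null(cv_bounds)) return(cbind(cv1, cv2))
  lo <- cv_bounds[1]; hi <- cv_bounds[2]
  xs <- c(cv1, 2 * lo - cv1, 2 * hi - cv1)
  ys <- c(cv2, 2 * lo - cv2, 2 * hi - cv2)
  as.matrix(expand.grid(xs, ys))
}

## nearest grid cell of a CV point
nearest_cell <- function(fes, point) {
  c(which.min(abs(ang_diff_deg(fes$grid1, point[1]))),
    which.min(abs(ang_diff_deg(fes$grid2, point[2]))))
}

## 8-connected neighbors with wrap/clamp
cell_neighbors <- function(i, j, n1, n2, periodic) {
  di <- rep(-1:1, times = 3); dj <- rep(-1:1, each = 3)
  keep <- !(di == 0 & dj == 0)
  ii <- i + di[keep]; jj <- j + dj[keep]
  if (periodic) {
    ii <- ((ii - 1) %% n1) + 1; jj <- ((jj - 1) %% n2) + 1
  } else {
    ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2
    ii <- ii[ok]; jj <- jj[ok]
  }
  cbind(ii, jj)
}

## steepest-descent walk on the grid to the local minimum nearest a seed
descend_to_minimum <- function(fes, seed_cell) {
  n1 <- length(fes$grid1); n2 <- length(fes$grid2)
  cur <- seed_cell
  repeat {
    nb <- cell_neighbors(cur[1], cur[2], n1, n2, fes$periodic)
    vals <- fes$f[cbind(nb[, 1], nb[, 2])]
    if (min(vals) >= fes$f[cur[1], cur[2]]) return(cur)
    cur <- nb[which.min(vals), ]
  }
}

#' Basin minima and the barrier between them
#'
#' Finds the local grid minimum nearest each basin seed (steepest descent),
#' then the barrier as (minimum over grid paths between the two minima of
#' the maximum F along the path) minus F(start minimum), by a monotone
#' flood on the 8-connected grid (cells activated in increasing F until the
#' basins connect).
#'
#' @param fes a `FreeEnergySurface`.
#' @param basin_seeds 2 x 2 matrix (rows = CV points seeding the basins).
#' @return list with `minima` (data frame cv1, cv2, f) and `barrier`
#'   (kcal/mol, from the first minimum). If both seeds descend to the same
#'   cell, a degenerate-basin warning is raised and barrier is 0.
#' @export
fes_minima_and_barrier <- function(fes, basin_seeds) {
  basin_seeds <- rbind(basin_seeds)
  if (nrow(basin_seeds) != 2) stop("need exactly two basin seeds")
  n1 <- length(fes$grid1); n2 <- length(fes$grid2)
  cellA <- descend_to_minimum(fes, nearest_cell(fes, basin_seeds[1, ]))
  cellB <- descend_to_minimum(fes, nearest_cell(fes, basin_seeds[2, ]))
  minima <- data.frame(cv1 = fes$grid1[c(cellA[1], cellB[1])],
                       cv2 = fes$grid2[c(cellA[2], cellB[2])],
                       f = c(fes$f[cellA[1], cellA[2]], fes$f[cellB[1], cellB[2]]))
  if (all(cellA == cellB)) {
    warning("both seeds descend to the same basin; barrier is 0")
    return(list(minima = minima, barrier = 0))
  }
  # monotone flood: activate cells in increasing F, union-find components
  idx <- function(i, j) (j - 1L) * n1 + i
  parent <- seq_len(n1 * n2)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  active <- rep(FALSE, n1 * n2)
  ord <- order(as.numeric(fes$f))
  ia <- idx(cellA[1], cellA[2]); ib <- idx(cellB[1], cellB[2])
  barrier_level <- NA_real_
  for (cell in ord) {
    j <- ((cell - 1L) %/% n1) + 1L; i <- ((cell - 1L) %% n1) + 1L
    active[cell] <- TRUE
    nb <- cell_neighbors(i, j, n1, n2, fes$periodic)
    for (r in seq_len(nrow(nb))) {
      ncell <- idx(nb[r, 1], nb[r, 2])
      if (active[ncell]) {
        ra <- find(cell); rb <- find(ncell)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (find(ia) == find(ib)) {
      barrier_level <- fes$f[i, j]
      break
    }
  }
  list(minima = minima, barrier = barrier_level - minima$f[1])
}

#' Difference of two free-energy surfaces
#'
#' Element-wise a - b after each surface is min-shifted (so any constant
#' offset is immaterial).
#'
#' @param a,b `FreeEnergySurface` objects on identical grids.
#' @return matrix of delta-F values on the shared grid.
#' @export
fes_difference <- function(a, b) {
  if (!isTRUE(all.equal(a$grid1, b$grid1)) || !isTRUE(all.equal(a$grid2, b$grid2))) {
    stop("surfaces are on different grids")
  }
  (a$f - min(a$f)) - (b$f - min(b$f))
}

#' Bin assignment of CV points on a surface grid
#'
#' @param fes a `FreeEnergySurface`.
#' @param points n x 2 matrix of (cv1, cv2) points.
#' @return n x 2 integer matrix of grid indices (for [boltzmann_weights()]).
#' @export
assign_bins <- function(fes, points) {
  points <- rbind(points)
  t(apply(points, 1, function(p) nearest_cell(fes, p)))
}

#' Write a free-energy surface as a TSV grid
#'
#' Long format: cv1, cv2, f.
#'
#' @param fes a `FreeEnergySurface`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fes_table <- function(fes, path) {
  df <- expand.grid(cv1 = fes$grid1, cv2 = fes$grid2)
  df$f <- as.numeric(fes$f)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a free-energy surface written by [write_fes_table()]
#'
#' @param path file path.
#' @return a `FreeEnergySurface`.
#' @export
read_fes_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  grid1 <- sort(unique(df$cv1)); grid2 <- sort(unique(df$cv2))
  f <- matrix(NA_real_, length(grid1), length(grid2))
  f[cbind(match(df$cv1, grid1), match(df$cv2, grid2))] <- df$f
  free_energy_surface(grid1, grid2, f)
}
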