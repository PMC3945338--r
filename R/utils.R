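## Small numeric helpers shared across modules.

#' Wrap angles in degrees to the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector wrapped to (-180, 180].
#' @export
wrap_deg <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor maps +180 to -180; convention here keeps +180
  w[w == -180] <- 180
  w
}

#' Minimum-image angular difference in degrees
#'
#' Signed difference `a - b` on the circle, in (-180, 180].
#'
#' @param a,b angles in degrees.
#' @return signed minimum-image difference in degrees.
#' @export
ang_diff_deg <- function(a, b) wrap_deg(a - b)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

`%dot%` <- function(a, b) sum(a * b)

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Circular mean of angles in degrees
#'
#' Mean direction via the resultant of unit vectors, wrapped to (-180, 180].
#' Used for ensemble averages of backbone dihedrals, where arithmetic means
#' are meaningless near the +/-180 seam.
#'
#' @param angles numeric vector of angles in degrees (non-empty).
#' @return scalar mean direction in degrees.
#' @export
circular_mean_deg <- function(angles) {
  if (length(angles) == 0) stop("empty angle set")
  s <- mean(sin(deg2rad(angles)))
  c_ <- mean(cos(deg2rad(angles)))
  if (sqrt(s^2 + c_^2) < 1e-9) {
    stop("circular mean undefined: angles are uniformly opposed (resultant ~ 0)")
  }
  wrap_deg(rad2deg(atan2(s, c_)))
}

#' Circular standard deviation of angles in degrees
#'
#' sqrt(-2 log R) on the resultant length R, reported in degrees.
#'
#' @param angles numeric vector of angles in degrees.
#' @return circular sd in degrees.
#' @export
circular_sd_deg <- function(angles) {
  s <- mean(sin(deg2rad(angles)))
  c_ <- mean(cos(deg2rad(angles)))
  R <- min(1, sqrt(s^2 + c_^2))
  if (R < 1e-12) return(Inf)
  rad2deg(sqrt(-2 * log(R)))
}

## population (divide-by-n) standard deviation; the ensemble spread
## convention used for RMSD populations.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

## md5 of a string (via a temp file; base R has no in-memory digest)
md5_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}
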