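## Analytic toy potentials over the 2D angular collective-variable space,
## with closed-form/refined reference minima, free-energy difference and
## saddle height. These are the planted-truth oracles for the metadynamics
## engine.

#' Construct an analytic toy potential
#'
#' Supported names:
#' \describe{
#'   \item{harmonic}{single well: U = k/2 (|dx|^2 + |dy|^2), min-image
#'     differences to `center`; parameters `center` (deg), `k`
#'     (kcal/mol/deg^2). Barrier is undefined (flagged NA).}
#'   \item{doublewell}{two Gaussian wells on the cv1 axis at `x1`, `x2`
#'     (depths `barrier` and `barrier - delta_f`), width `sigma_well`, plus
#'     a harmonic confinement k_y/2 dy^2 about `y_center`. Well separation
#'     is several sigma, so the reference minima depths are exact to ~1e-5;
#'     the reported minima, delta_f and saddle are refined numerically to
#'     1e-10 from the analytic form.}
#'   \item{custom}{user-supplied `U(x, y)` and `grad(x, y)`; reference
#'     values refined from supplied starting guesses `minima_guess`.}
#' }
#'
#' @param name one of "harmonic", "doublewell", "custom".
#' @param params named list overriding the defaults above.
#' @return object of class `ToyPotential`: list with `U` (vectorized),
#'   `grad`, `minima` (2 x 2 matrix of refined minimum positions, deepest
#'   first), `f_minima`, `delta_f`, `saddle_point`, `saddle_f`,
#'   `barrier_from_deep`, plus `cpp_type`/`cpp_params` for the compiled
#'   walker where available.
#' @export
toy_potential <- function(name = c("doublewell", "harmonic", "custom"),
                          params = list()) {
  name <- match.arg(name)
  if (name == "harmonic") {
    p <- utils::modifyList(list(center = c(-35, -43.5), k = 0.005), params)
    U <- function(x, y) {
      dx <- ang_diff_deg(x, p$center[1]); dy <- ang_diff_deg(y, p$center[2])
      0.5 * p$k * (dx^2 + dy^2)
    }
    grad <- function(x, y) {
      c(p$k * ang_diff_deg(x, p$center[1]), p$k * ang_diff_deg(y, p$center[2]))
    }
    return(structure(list(name = name, params = p, U = U, grad = grad,
                          minima = rbind(p$center, p$center),
                          f_minima = c(0, 0), delta_f = 0,
                          saddle_point = NULL, saddle_f = NA_real_,
                          barrier_from_deep = NA_real_,
                          cpp_type = 1L,
                          cpp_params = c(p$center[1], p$center[2], p$k)),
                     class = "ToyPotential"))
  }
  if (name == "doublewell") {
    p <- utils::modifyList(list(x1 = -50, x2 = -15, y_center = -32.5,
                                sigma_well = 8, barrier = 5, delta_f = 2,
                                k_y = 0.004), params)
    fx <- function(x) {
      u1 <- ang_diff_deg(x, p$x1); u2 <- ang_diff_deg(x, p$x2)
      p$barrier - p$barrier * exp(-u1^2 / (2 * p$sigma_well^2)) -
        (p$barrier - p$delta_f) * exp(-u2^2 / (2 * p$sigma_well^2))
    }
    U <- function(x, y) fx(x) + 0.5 * p$k_y * ang_diff_deg(y, p$y_center)^2
    grad <- function(x, y) {
      u1 <- ang_diff_deg(x, p$x1); u2 <- ang_diff_deg(x, p$x2)
      s2 <- p$sigma_well^2
      gx <- p$barrier * exp(-u1^2 / (2 * s2)) * u1 / s2 +
        (p$barrier - p$delta_f) * exp(-u2^2 / (2 * s2)) * u2 / s2
      c(gx, p$k_y * ang_diff_deg(y, p$y_center))
    }
    # refine minima and saddle of the 1D profile
    m1 <- stats::optimize(fx, c(p$x1 - 5, p$x1 + 5), tol = 1e-10)
    m2 <- stats::optimize(fx, c(p$x2 - 5, p$x2 + 5), tol = 1e-10)
    deep <- if (m1$objective <= m2$objective) m1 else m2
    shal <- if (m1$objective <= m2$objective) m2 else m1
    sad <- stats::optimize(fx, sort(c(m1$minimum, m2$minimum)),
                           maximum = TRUE, tol = 1e-10)
    return(structure(list(name = name, params = p, U = U, grad = grad,
                          minima = rbind(c(deep$minimum, p$y_center),
                                         c(shal$minimum, p$y_center)),
                          f_minima = c(deep$objective, shal$objective),
                          delta_f = shal$objective - deep$objective,
                          saddle_point = c(sad$maximum, p$y_center),
                          saddle_f = sad$objective,
                          barrier_from_deep = sad$objective - deep$objective,
                          cpp_type = 2L,
                          cpp_params = c(p$x1, p$x2, p$y_center, p$sigma_well,
                                         p$barrier, p$delta_f, p$k_y)),
                     class = "ToyPotential"))
  }
  # custom
  if (is.null(params$U) || is.null(params$grad)) {
    stop("custom potential needs params$U and params$grad")
  }
  p <- params
  minima <- NULL; f_min <- NULL
  if (!is.null(p$minima_guess)) {
    refine <- function(g) {
      o <- stats::optim(g, function(v) p$U(v[1], v[2]), method = "Nelder-Mead",
                        control = list(reltol = 1e-12))
      list(par = o$par, val = o$value)
    }
    ref <- lapply(asplit(rbind(p$minima_guess), 1), refine)
    ord <- order(vapply(ref, `[[`, numeric(1), "val"))
    minima <- do.call(rbind, lapply(ref[ord], `[[`, "par"))
    f_min <- vapply(ref[ord], `[[`, numeric(1), "val")
  }
  structure(list(name = "custom", params = p, U = p$U, grad = p$grad,
                 minima = minima, f_minima = f_min,
                 delta_f = if (length(f_min) >= 2) f_min[2] - f_min[1] else NA_real_,
                 saddle_point = NULL, saddle_f = NA_real_,
                 barrier_from_deep = NA_real_,
                 cpp_type = NA_integer_, cpp_params = numeric(0)),
            class = "ToyPotential")
}

#' @export
print.ToyPotential <- function(x, ...) {
  cat(sprintf("<ToyPotential '%s': delta_f %.3g, barrier %.3g kcal/mol>\n",
              x$name, x$delta_f, x$barrier_from_deep))
  invisible(x)
}

#' Evaluate a toy potential on a grid
#'
#' @param pot a `ToyPotential`.
#' @param grid1,grid2 degree grids.
#' @return a `FreeEnergySurface` of the exact potential (min-shifted), for
#'   use as the analytic oracle of the surface analysis.
#' @export
potential_surface <- function(pot, grid1, grid2) {
  f <- outer(grid1, grid2, function(a, b) pot$U(a, b))
  free_energy_surface(grid1, grid2, f)
}
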