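## Helix axis fitting, kink/bend angles, membrane tilt, and the two
## nitrogen-linked hinge dihedral collective variables.
##
## The axis is the first principal component of smoothed local helix centers
## (each center = mean of 4 consecutive CA positions), which cancels the
## helical wobble of raw CA traces. Bend is reported in both printed
## conventions: deviation from straight (0 = straight) and the inter-segment
## axis angle (180 = straight).

#' Fit a helix axis over a residue range
#'
#' @param conf a `Conformation` with CA atoms for the range.
#' @param residue_range integer vector (or length-2 range) of author residue
#'   numbers; at least 5 consecutive residues with CA are required.
#' @return object of class `HelixAxis`: list with `centroid`, `direction`
#'   (unit vector oriented N-terminus to C-terminus) and `residue_range`.
#' @export
fit_helix_axis <- function(conf, residue_range) {
  if (length(residue_range) == 2) residue_range <- seq(residue_range[1], residue_range[2])
  ca <- conf$atoms[conf$atoms$atom == "CA" & conf$atoms$resno %in% residue_range, ]
  ca <- ca[order(ca$resno), ]
  if (nrow(ca) < 5) stop("helix axis fit needs at least 5 residues with CA (got ", nrow(ca), ")")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(xyz)
  # local helix centers: running mean of 4 consecutive CA
  centers <- (xyz[1:(n - 3), , drop = FALSE] + xyz[2:(n - 2), , drop = FALSE] +
              xyz[3:(n - 1), , drop = FALSE] + xyz[4:n, , drop = FALSE]) / 4
  centroid <- colMeans(centers)
  sv <- svd(sweep(centers, 2, centroid))
  dir <- sv$v[, 1]
  # orient N -> C
  if (sum(dir * (xyz[n, ] - xyz[1, ])) < 0) dir <- -dir
  structure(list(centroid = centroid, direction = unit(dir),
                 residue_range = range(ca$resno)),
            class = "HelixAxis")
}

#' Bend (kink) angle between two helix segments
#'
#' Fits an axis to the segments flanking a hinge and returns the angle
#' between their N->C direction vectors in both conventions.
#'
#' @param conf a `Conformation`.
#' @param segment_N,segment_C residue ranges for the N- and C-terminal
#'   segments (length-2 ranges or integer vectors); must not overlap.
#' @param hinge optional residue pair recorded in the result.
#' @return object of class `KinkGeometry`: list with `bend_deg` (0 =
#'   straight), `axis_angle_deg` (= 180 - bend_deg), `hinge`.
#' @export
bend_angle <- function(conf, segment_N, segment_C, hinge = NULL) {
  rN <- if (length(segment_N) == 2) seq(segment_N[1], segment_N[2]) else segment_N
  rC <- if (length(segment_C) == 2) seq(segment_C[1], segment_C[2]) else segment_C
  if (length(intersect(rN, rC))) stop("helix segments overlap")
  aN <- fit_helix_axis(conf, rN)
  aC <- fit_helix_axis(conf, rC)
  cosang <- max(-1, min(1, sum(aN$direction * aC$direction)))
  bend <- rad2deg(acos(cosang))
  structure(list(bend_deg = bend, axis_angle_deg = 180 - bend, hinge = hinge),
            class = "KinkGeometry")
}

#' Tilt of a helix axis with respect to the membrane normal
#'
#' arccos(|direction . normal|), in [0, 90] degrees; 0 = transmembrane
#' (parallel to the normal), 90 = lying in the membrane plane.
#'
#' @param axis a `HelixAxis`.
#' @param frame a `MembraneFrame`.
#' @return tilt angle in degrees.
#' @export
tilt_angle <- function(axis, frame) {
  rad2deg(acos(min(1, abs(sum(axis$direction * frame$normal)))))
}

#' Four-point torsion angle (IUPAC sign convention)
#'
#' @param p1,p2,p3,p4 3-vectors.
#' @return torsion in degrees, wrapped to (-180, 180].
#' @export
torsion_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  x <- sum(n1 * n2); y <- sum(vcross(n1, n2) * unit(b2))
  wrap_deg(rad2deg(atan2(y, x)))
}

#' The two hinge dihedral collective variables
#'
#' cv1 is the dihedral N(h1)-CA(h1)-C(h1)-N(h1+1) and cv2 the dihedral
#' N(h2)-CA(h2)-C(h2)-N(h2+1), i.e. the backbone psi torsions linking the
#' nitrogen atoms across the hinge glycines (defaults: residues 708 and
#' 709, so the torsions connect N708-N709 and N709-N710).
#'
#' @param conf a `Conformation`.
#' @param sites integer pair of hinge residues (default `c(708, 709)`).
#' @return object of class `KinkDihedrals`: list with `cv1_deg`, `cv2_deg`
#'   in (-180, 180].
#' @export
cv_dihedrals <- function(conf, sites = c(708, 709)) {
  one <- function(r) {
    need <- list(N = get_atom(conf, r, "N"), CA = get_atom(conf, r, "CA"),
                 C = get_atom(conf, r, "C"), N2 = get_atom(conf, r + 1, "N"))
    miss <- names(need)[vapply(need, is.null, logical(1))]
    if (length(miss)) {
      stop(sprintf("missing atom for dihedral at residue %d: %s",
                   r, paste(sub("N2", paste0("N of ", r + 1), miss), collapse = ", ")))
    }
    torsion_deg(need$N, need$CA, need$C, need$N2)
  }
  structure(list(cv1_deg = one(sites[1]), cv2_deg = one(sites[2])),
            class = "KinkDihedrals")
}

#' Geometry table for every member of an ensemble
#'
#' Convenience wrapper computing, per member: bend (both conventions),
#' tilt (if a frame is given) and the two hinge dihedrals.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param segment_N,segment_C segment ranges as in [bend_angle()].
#' @param sites hinge residues as in [cv_dihedrals()].
#' @param frame optional `MembraneFrame` for tilt (fitted over both segments).
#' @return data frame with one row per member.
#' @export
ensemble_geometry <- function(ensemble, segment_N = c(700, 708),
                              segment_C = c(710, 723), sites = c(708, 709),
                              frame = NULL) {
  rows <- lapply(seq_along(ensemble$members), function(i) {
    cf <- ensemble$members[[i]]
    kg <- bend_angle(cf, segment_N, segment_C, hinge = sites)
    cv <- cv_dihedrals(cf, sites)
    tilt <- if (!is.null(frame)) {
      ax <- fit_helix_axis(cf, seq(segment_N[1], segment_C[2]))
      tilt_angle(ax, frame)
    } else NA_real_
    data.frame(model = i, bend_deg = kg$bend_deg, axis_angle_deg = kg$axis_angle_deg,
               tilt_deg = tilt, cv1_deg = cv$cv1_deg, cv2_deg = cv$cv2_deg)
  })
  do.call(rbind, rows)
}
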