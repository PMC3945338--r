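## Rigid-body least-squares superposition (Kabsch) and ensemble RMSD
## statistics. The rotation is constrained proper (det = +1).

kabsch <- function(P, Q) {
  # P, Q: n x 3 paired coordinates; returns R, t minimizing |R P + t - Q|
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  list(R = R, t = t)
}

#' Superpose one conformation onto another
#'
#' Least-squares rigid superposition of `mobile` onto `reference` over the
#' atoms named by `selection` (default backbone N, CA, C of the shared
#' residue range). Returns the proper rotation, translation and minimum RMSD.
#'
#' @param mobile,reference `Conformation` objects sharing the selected atoms.
#' @param selection selection string `"start-end:ATOM1,ATOM2"` or a parsed
#'   selection from [parse_selection()]; NULL selects N,CA,C of all shared
#'   residues.
#' @return list with `rotation` (3x3, det +1), `translation` (3-vector),
#'   `rmsd` (Angstrom) over the selection.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  sel <- resolve_selection(mobile, reference, selection)
  P <- sel$P; Q <- sel$Q
  if (nrow(P) < 3) stop("selection resolves to fewer than 3 atom pairs")
  # collinearity check: rank of centered coordinates
  s <- svd(sweep(P, 2, colMeans(P)))$d
  if (s[2] < 1e-8 * max(s[1], 1)) stop("selection is collinear; superposition is degenerate")
  k <- kabsch(P, Q)
  Pf <- sweep(P %*% t(k$R), 2, k$t, "+")
  rmsd <- sqrt(mean(rowSums((Pf - Q)^2)))
  list(rotation = k$R, translation = k$t, rmsd = rmsd)
}

## resolve matched coordinate sets for superposition
resolve_selection <- function(mobile, reference, selection) {
  if (is.character(selection)) selection <- parse_selection(selection)
  if (is.null(selection)) {
    shared <- intersect(unique(mobile$atoms$resno), unique(reference$atoms$resno))
    selection <- list(resno = shared, atoms = c("N", "CA", "C"))
  }
  atoms <- if (is.null(selection$atoms)) {
    setdiff(intersect(unique(mobile$atoms$atom), unique(reference$atoms$atom)), character(0))
  } else selection$atoms
  am <- mobile$atoms; ar <- reference$atoms
  km <- am$resno %in% selection$resno & am$atom %in% atoms
  kr <- ar$resno %in% selection$resno & ar$atom %in% atoms
  keym <- paste(am$resno[km], am$atom[km])
  keyr <- paste(ar$resno[kr], ar$atom[kr])
  shared <- intersect(keym, keyr)
  P <- as.matrix(am[km, c("x", "y", "z")])[match(shared, keym), , drop = FALSE]
  Q <- as.matrix(ar[kr, c("x", "y", "z")])[match(shared, keyr), , drop = FALSE]
  list(P = P, Q = Q)
}

#' RMSD of the superposed selection without returning the transform
#' @inheritParams superpose
#' @return scalar RMSD in Angstrom.
#' @export
superposed_rmsd <- function(mobile, reference, selection = NULL) {
  superpose(mobile, reference, selection)$rmsd
}

#' Population RMSD of an ensemble against a reference
#'
#' Superposes every member on `reference` over `selection` and returns the
#' mean and population (divide-by-n) standard deviation of the per-member
#' RMSD values; sd is 0 for a single member.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param reference a `Conformation`.
#' @param selection as in [superpose()].
#' @return list with `mean`, `sd` (Angstrom) and `rmsd` (per-member vector).
#' @export
ensemble_rmsd_population <- function(ensemble, reference, selection = NULL) {
  r <- vapply(ensemble$members, function(m) superpose(m, reference, selection)$rmsd,
              numeric(1))
  list(mean = mean(r), sd = pop_sd(r), rmsd = r)
}
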