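## Residual dipolar couplings: N-H bond vectors, SVD alignment-tensor fit,
## back-calculation and Q-factor. Couplings are handled in reduced units:
## the dipolar prefactor is folded into the tensor, so the fitted axial
## magnitude is reported in the units of the input couplings.

#' Construct an AlignmentTensor from a symmetric traceless 3x3 matrix
#'
#' Carries the Saupe matrix, its eigen decomposition, the axial magnitude
#' and the rhombicity. Eigenvalues are ordered |Sxx'| <= |Syy'| <= |Szz'|;
#' da = Szz'/2 and rhombicity = (Syy' - Sxx')/Szz', both in the reduced
#' units of the couplings the tensor was fit to.
#'
#' @param S symmetric traceless 3x3 matrix.
#' @return object of class `AlignmentTensor`.
#' @export
alignment_tensor <- function(S) {
  S <- (S + t(S)) / 2
  if (abs(sum(diag(S))) > 1e-9 * max(1, max(abs(S)))) {
    S <- S - diag(3) * sum(diag(S)) / 3
  }
  e <- eigen(S, symmetric = TRUE)
  ord <- order(abs(e$values))  # |Sxx'| <= |Syy'| <= |Szz'|
  vals <- e$values[ord]
  da <- vals[3] / 2
  rhomb <- if (abs(vals[3]) < 1e-14) 0 else (vals[2] - vals[1]) / vals[3]
  structure(list(saupe = S, eigenvalues = vals, da = da, rhombicity = rhomb),
            class = "AlignmentTensor")
}

#' @export
print.AlignmentTensor <- function(x, ...) {
  cat(sprintf("<AlignmentTensor: da %.4g, rhombicity %.3f>\n", x$da, x$rhombicity))
  invisible(x)
}

## 5-vector parameterization s = (Syy, Szz, Sxy, Sxz, Syz), Sxx = -Syy-Szz
saupe_from_s5 <- function(s) {
  matrix(c(-s[1] - s[2], s[3], s[4],
           s[3], s[1], s[5],
           s[4], s[5], s[2]), 3, 3)
}

s5_from_saupe <- function(S) c(S[2, 2], S[3, 3], S[1, 2], S[1, 3], S[2, 3])

## design row for a unit vector v: d = M s  with s as above
design_matrix <- function(V) {
  cbind(V[, 2]^2 - V[, 1]^2,
        V[, 3]^2 - V[, 1]^2,
        2 * V[, 1] * V[, 2],
        2 * V[, 1] * V[, 3],
        2 * V[, 2] * V[, 3])
}

#' Backbone N-H unit vectors of a conformation
#'
#' Uses the explicit amide H where present; otherwise the H is rebuilt in
#' the peptide plane opposite the bisector of N->C(prev) and N->CA at an
#' N-H length of 1.02 Angstrom. The first residue (no preceding carbonyl)
#' and prolines are skipped.
#'
#' @param conf a `Conformation`.
#' @param strict error (instead of silently skipping) on residues that have
#'   neither an H nor the atoms needed to rebuild one.
#' @return list with `resno` and `vectors` (n x 3 unit vectors).
#' @export
nh_vectors <- function(conf, strict = FALSE) {
  resnos <- sort(unique(conf$atoms$resno))
  out_r <- integer(0); out_v <- list(); skipped <- integer(0)
  for (i in seq_along(resnos)) {
    r <- resnos[i]
    row <- conf$atoms[conf$atoms$resno == r, ][1, ]
    if (row$resname == "PRO" || i == 1) next
    N <- get_atom(conf, r, "N")
    if (is.null(N)) { skipped <- c(skipped, r); next }
    H <- get_atom(conf, r, "H")
    if (is.null(H)) {
      CA <- get_atom(conf, r, "CA")
      Cp <- get_atom(conf, resnos[i - 1], "C")
      if (is.null(CA) || is.null(Cp)) { skipped <- c(skipped, r); next }
      hdir <- -unit(unit(Cp - N) + unit(CA - N))
      H <- N + 1.02 * hdir
    }
    out_r <- c(out_r, r)
    out_v[[length(out_v) + 1]] <- unit(H - N)
  }
  if (strict && length(skipped)) {
    stop("cannot define N-H vector for residues: ", paste(skipped, collapse = ", "))
  }
  list(resno = out_r, vectors = do.call(rbind, out_v))
}

#' Fit the alignment tensor to couplings by SVD
#'
#' Least-squares solution of M s = d, where row i of M is
#' [vy^2-vx^2, vz^2-vx^2, 2 vx vy, 2 vx vz, 2 vy vz] for unit vector v_i,
#' solved via singular value decomposition of M; the Saupe matrix is rebuilt
#' from s with zero trace.
#'
#' @param vectors n x 3 matrix of unit N-H vectors.
#' @param rdcs numeric couplings (length n), or a data frame with column
#'   `d_exp`.
#' @return an `AlignmentTensor`.
#' @export
svd_fit_tensor <- function(vectors, rdcs) {
  d <- if (is.data.frame(rdcs)) rdcs$d_exp else rdcs
  V <- as.matrix(vectors)
  if (nrow(V) != length(d)) stop("vectors and couplings differ in length")
  if (nrow(V) < 5) stop("tensor fit needs at least 5 (vector, coupling) pairs; got ", nrow(V))
  M <- design_matrix(V)
  sv <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (rank < 5) stop("rank-deficient design matrix (rank ", rank, " < 5): vectors span too few directions")
  s <- sv$v %*% (crossprod(sv$u, d) / sv$d)
  alignment_tensor(saupe_from_s5(as.numeric(s)))
}

#' Back-calculate couplings from a tensor and bond vectors
#'
#' d_i = v_i' S v_i in reduced units.
#'
#' @param tensor an `AlignmentTensor` (or plain 3x3 matrix).
#' @param vectors n x 3 matrix of unit vectors.
#' @return numeric vector of couplings.
#' @export
backcalc_rdc <- function(tensor, vectors) {
  S <- if (inherits(tensor, "AlignmentTensor")) tensor$saupe else tensor
  V <- as.matrix(vectors)
  rowSums((V %*% S) * V)
}

#' RDC Q-factor
#'
#' sqrt(sum((d_calc - d_exp)^2)) / sqrt(sum(d_exp^2)); 0 is a perfect fit.
#'
#' @param d_calc,d_exp equal-length coupling vectors.
#' @return dimensionless Q.
#' @export
q_factor <- function(d_calc, d_exp) {
  if (length(d_calc) != length(d_exp) || length(d_exp) < 1) {
    stop("coupling vectors must have equal length >= 1")
  }
  denom <- sqrt(sum(d_exp^2))
  if (denom == 0) stop("Q-factor undefined: experimental couplings are all zero")
  sqrt(sum((d_calc - d_exp)^2)) / denom
}

#' Fit a tensor to an ensemble and score it
#'
#' The ensemble is treated as exchanging on the alignment timescale: design
#' matrix rows are averaged over the members before a single SVD fit (one
#' alignment medium, one tensor). Returns the fit together with the
#' back-calculated couplings and Q-factor.
#'
#' @param ensemble a `StructureEnsemble` (or list of `Conformation`).
#' @param rdcs data frame with columns `residue`, `d_exp`.
#' @return list with `tensor`, `d_calc`, `d_exp`, `residues`, `q_factor`.
#' @export
fit_ensemble_rdc <- function(ensemble, rdcs) {
  members <- if (inherits(ensemble, "StructureEnsemble")) ensemble$members else ensemble
  Ms <- ensemble_design_matrices(members, rdcs)
  Mbar <- Reduce(`+`, Ms) / length(Ms)
  sv <- svd(Mbar)
  if (sum(sv$d > max(dim(Mbar)) * .Machine$double.eps * sv$d[1]) < 5) {
    stop("rank-deficient averaged design matrix")
  }
  s <- as.numeric(sv$v %*% (crossprod(sv$u, attr(Ms, "d_exp")) / sv$d))
  tensor <- alignment_tensor(saupe_from_s5(s))
  d_calc <- as.numeric(Mbar %*% s)
  d_exp <- attr(Ms, "d_exp")
  list(tensor = tensor, d_calc = d_calc, d_exp = d_exp,
       residues = attr(Ms, "residues"), q_factor = q_factor(d_calc, d_exp))
}

## per-member design matrices restricted to the residues of the RDC table
ensemble_design_matrices <- function(members, rdcs) {
  vsets <- lapply(members, nh_vectors)
  shared <- Reduce(intersect, lapply(vsets, function(v) v$resno))
  shared <- intersect(shared, rdcs$residue)
  if (length(shared) < 5) stop("fewer than 5 residues shared between ensemble and RDC table")
  d_exp <- rdcs$d_exp[match(shared, rdcs$residue)]
  Ms <- lapply(vsets, function(v) {
    design_matrix(v$vectors[match(shared, v$resno), , drop = FALSE])
  })
  attr(Ms, "d_exp") <- d_exp
  attr(Ms, "residues") <- shared
  Ms
}

#' Read an RDC table
#'
#' Tab-separated text with header `residue<TAB>rdc` (extra columns ignored).
#'
#' @param path file path.
#' @return data frame with columns `residue`, `d_exp`.
#' @export
read_rdc_table <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t")
  names(tb)[1:2] <- c("residue", "d_exp")
  if (anyDuplicated(tb$residue)) stop("duplicate residues in RDC table")
  if (!all(is.finite(tb$d_exp))) stop("non-finite couplings in RDC table")
  tb[, c("residue", "d_exp")]
}

#' Write an RDC table
#' @param rdcs data frame with columns `residue`, `d_exp`.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_rdc_table <- function(rdcs, path) {
  out <- data.frame(residue = rdcs$residue, rdc = rdcs$d_exp)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
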