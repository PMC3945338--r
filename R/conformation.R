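## Core containers: a Conformation is one set of coordinates on a fixed
## topology; a StructureEnsemble is an ordered list of Conformations sharing
## that topology (NMR models or trajectory-like frames).

#' Construct a Conformation
#'
#' A conformation is a data frame of atoms (one row per atom) with columns
#' `atom` (PDB atom name), `element`, `resno` (author residue numbering),
#' `resname` (3-letter code) and Cartesian coordinates `x`, `y`, `z` in
#' Angstrom, plus a free-text `label` (model number or frame time).
#'
#' @param atoms data frame with columns atom, element, resno, resname, x, y, z.
#' @param label free-text identifier.
#' @return object of class `Conformation`.
#' @export
conformation <- function(atoms, label = "") {
  req <- c("atom", "element", "resno", "resname", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms[, req], stringsAsFactors = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in conformation")
  }
  if (is.unsorted(atoms$resno)) {
    stop("residue_index must be non-decreasing along the chain")
  }
  dup <- duplicated(atoms[, c("resno", "atom")])
  if (any(dup)) {
    stop("duplicate atom name within a residue: ",
         paste(unique(paste0(atoms$resno[dup], ":", atoms$atom[dup])), collapse = ", "))
  }
  structure(list(atoms = atoms, label = label), class = "Conformation")
}

#' @export
print.Conformation <- function(x, ...) {
  rr <- range(x$atoms$resno)
  cat(sprintf("<Conformation '%s': %d atoms, residues %d-%d>\n",
              x$label, nrow(x$atoms), rr[1], rr[2]))
  invisible(x)
}

## compact topology key: identical across members of a valid ensemble
topology_key <- function(conf) {
  a <- conf$atoms
  paste(a$resno, a$resname, a$atom, sep = ":", collapse = "|")
}

#' Construct a StructureEnsemble
#'
#' @param members non-empty list of `Conformation` objects sharing one topology.
#' @return object of class `StructureEnsemble` with fields `members` and
#'   `topology_hash`.
#' @export
structure_ensemble <- function(members) {
  if (length(members) == 0) stop("ensemble must have at least one member")
  keys <- vapply(members, topology_key, character(1))
  bad <- which(keys != keys[1])
  if (length(bad)) {
    stop(sprintf("inconsistent topology across models: member %d differs from member 1",
                 bad[1]))
  }
  structure(list(members = members, topology_hash = md5_string(keys[1])),
            class = "StructureEnsemble")
}

#' @export
print.StructureEnsemble <- function(x, ...) {
  cat(sprintf("<StructureEnsemble: %d members, %d atoms each, topology %s>\n",
              length(x$members), nrow(x$members[[1]]$atoms), x$topology_hash))
  invisible(x)
}

#' Number of members in an ensemble
#' @param ensemble a `StructureEnsemble`.
#' @return integer count.
#' @export
n_members <- function(ensemble) length(ensemble$members)

#' Construct a membrane frame
#'
#' The membrane is an implicit slab: a unit normal (convention +z), two
#' phosphate planes and the bilayer center, all along the normal coordinate.
#'
#' @param z_phosphate_upper,z_phosphate_lower phosphate plane positions, Angstrom.
#' @param z_center bilayer center (defaults to the midpoint).
#' @param normal unit 3-vector, defaults to +z.
#' @return object of class `MembraneFrame`.
#' @export
membrane_frame <- function(z_phosphate_upper = 19, z_phosphate_lower = -19,
                           z_center = (z_phosphate_upper + z_phosphate_lower) / 2,
                           normal = c(0, 0, 1)) {
  normal <- unit(normal)
  if (!(z_phosphate_lower < z_center && z_center < z_phosphate_upper)) {
    stop("need z_phosphate_lower < z_center < z_phosphate_upper")
  }
  structure(list(normal = normal,
                 z_phosphate_upper = z_phosphate_upper,
                 z_phosphate_lower = z_phosphate_lower,
                 z_center = z_center),
            class = "MembraneFrame")
}

## coordinate matrix (n x 3) for selected atoms of a conformation
coords_of <- function(conf, resno = NULL, atom_names = NULL) {
  a <- conf$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(atom_names)) keep <- keep & a$atom %in% atom_names
  as.matrix(a[keep, c("x", "y", "z")])
}

## fetch one named atom of one residue as a 3-vector (or NULL)
get_atom <- function(conf, resno, name) {
  a <- conf$atoms
  i <- which(a$resno == resno & a$atom == name)
  if (length(i) == 0) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}

#' Parse an atom selection string
#'
#' Selections are written `"start-end:ATOM1,ATOM2"`, e.g. `"700-723:N,CA,C"`.
#' The atom part is optional; `"700-723"` selects all atoms of the range.
#'
#' @param selection selection string.
#' @return list with `resno` (integer vector) and `atoms` (character or NULL).
#' @export
parse_selection <- function(selection) {
  parts <- strsplit(selection, ":", fixed = TRUE)[[1]]
  rng <- as.integer(strsplit(parts[1], "-", fixed = TRUE)[[1]])
  if (length(rng) != 2 || any(is.na(rng))) stop("bad residue range in selection: ", selection)
  atoms <- if (length(parts) > 1) strsplit(parts[2], ",", fixed = TRUE)[[1]] else NULL
  list(resno = seq(rng[1], rng[2]), atoms = atoms)
}

## apply a rigid transform y = R x + t to a conformation
transform_conf <- function(conf, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  conf$atoms$x <- xyz[, 1]; conf$atoms$y <- xyz[, 2]; conf$atoms$z <- xyz[, 3]
  conf
}
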