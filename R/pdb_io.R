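## Multi-model PDB I/O, delegated to bio3d behind the package's containers.
## Both MODEL-delimited NMR entries and concatenated frame dumps are accepted;
## HETATM records other than water (HOH) are dropped, waters are kept aside
## for the hydration stage.

#' Read a multi-model PDB file as a StructureEnsemble
#'
#' One `Conformation` per MODEL record (a single coordinate block yields a
#' one-member ensemble). Author residue numbering is preserved verbatim.
#' Alternate locations other than blank/'A' are dropped (bio3d default).
#' Waters (resname HOH) are excluded from the ensemble topology; use
#' [read_pdb_waters()] to recover them.
#'
#' @param path PDB file path.
#' @return a `StructureEnsemble`.
#' @export
read_pdb_ensemble <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("unreadable PDB file '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$resid != "HOH"
  if (!any(keep)) stop("no non-water ATOM records in ", path)
  idx <- which(keep)
  nmod <- nrow(pdb$xyz)
  members <- vector("list", nmod)
  for (m in seq_len(nmod)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    atoms <- data.frame(atom = at$elety[idx],
                        element = ifelse(is.na(at$elesy[idx]) | at$elesy[idx] == "",
                                         substr(trimws(at$elety[idx]), 1, 1),
                                         at$elesy[idx]),
                        resno = at$resno[idx],
                        resname = at$resid[idx],
                        x = xyz[idx, 1], y = xyz[idx, 2], z = xyz[idx, 3],
                        stringsAsFactors = FALSE)
    members[[m]] <- conformation(atoms, label = as.character(m))
  }
  tryCatch(structure_ensemble(members),
           error = function(e) stop("topology error in '", path, "': ",
                                    conditionMessage(e)))
}

#' Read per-model water oxygen coordinates from a PDB file
#'
#' Returns a `WaterSet`: a list with `frames`, one n x 3 matrix of water
#' oxygen coordinates per MODEL. Water hydrogens are ignored.
#'
#' @param path PDB file path.
#' @return object of class `WaterSet`.
#' @export
read_pdb_waters <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  idx <- which(at$resid == "HOH" & trimws(at$elety) %in% c("O", "OW", "OH2"))
  nmod <- nrow(pdb$xyz)
  frames <- vector("list", nmod)
  for (m in seq_len(nmod)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    frames[[m]] <- xyz[idx, , drop = FALSE]
  }
  water_set(frames)
}

#' Construct a WaterSet
#' @param frames list of n x 3 matrices (water oxygen coordinates per frame).
#' @return object of class `WaterSet`.
#' @export
water_set <- function(frames) {
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (length(f) && ncol(f) != 3) stop("water frames must be n x 3 matrices")
    f
  })
  structure(list(frames = frames), class = "WaterSet")
}

#' Write a StructureEnsemble as a multi-model PDB file
#'
#' Standard PDB with one MODEL/ENDMDL block per member and coordinates at
#' three decimals.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  if (!inherits(ensemble, "StructureEnsemble")) stop("not a StructureEnsemble")
  a1 <- ensemble$members[[1]]$atoms
  xyz <- t(vapply(ensemble$members, function(cf) {
    as.numeric(t(as.matrix(cf$atoms[, c("x", "y", "z")])))
  }, numeric(3 * nrow(a1))))
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = a1$resno, resid = a1$resname,
                     eleno = seq_len(nrow(a1)), elety = a1$atom,
                     chain = rep("A", nrow(a1)))
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("could not write PDB file: ", path)
  invisible(path)
}
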