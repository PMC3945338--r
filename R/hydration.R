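## Per-residue water-contact profiles over an ensemble/trajectory,
## normalized to a relative hydration track. The metric is a first-shell
## contact count: distinct water oxygens within `cutoff` of any heavy atom
## of the residue (one water may count toward several residues).

#' Water contacts of one frame
#'
#' @param conf a `Conformation`.
#' @param waters n x 3 matrix of water oxygen coordinates.
#' @param cutoff contact cutoff in Angstrom (water O to residue heavy atom).
#' @return named integer vector of counts, one per residue (names = resno).
#' @export
water_contacts_frame <- function(conf, waters, cutoff = 3.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  a <- conf$atoms[conf$atoms$element != "H", ]
  resnos <- sort(unique(conf$atoms$resno))
  counts <- stats::setNames(integer(length(resnos)), resnos)
  waters <- as.matrix(waters)
  if (length(waters) == 0 || nrow(waters) == 0) return(counts)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  cut2 <- cutoff^2
  for (k in seq_along(resnos)) {
    sub <- xyz[a$resno == resnos[k], , drop = FALSE]
    # any water within cutoff of any heavy atom of this residue
    hit <- rep(FALSE, nrow(waters))
    for (j in seq_len(nrow(sub))) {
      d2 <- (waters[, 1] - sub[j, 1])^2 + (waters[, 2] - sub[j, 2])^2 +
        (waters[, 3] - sub[j, 3])^2
      hit <- hit | (d2 <= cut2)
    }
    counts[k] <- sum(hit)
  }
  counts
}

#' Hydration profile over an ensemble
#'
#' Mean over frames of per-frame water contacts, with a relative track
#' normalized by the profile maximum (all-zero profiles stay all-zero).
#'
#' @param ensemble a `StructureEnsemble`.
#' @param waters a `WaterSet` with one frame per ensemble member.
#' @param cutoff contact cutoff in Angstrom.
#' @return object of class `HydrationProfile`: data frame with columns
#'   `residue_index`, `mean_contacts`, `relative`.
#' @export
hydration_profile <- function(ensemble, waters, cutoff = 3.5) {
  nf <- length(waters$frames)
  if (nf != n_members(ensemble)) {
    stop(sprintf("frame count mismatch: %d water frames vs %d members",
                 nf, n_members(ensemble)))
  }
  per <- vapply(seq_len(nf), function(k) {
    water_contacts_frame(ensemble$members[[k]], waters$frames[[k]], cutoff)
  }, numeric(length(unique(ensemble$members[[1]]$atoms$resno))))
  mean_contacts <- if (nf == 1) as.numeric(per) else rowMeans(per)
  resnos <- sort(unique(ensemble$members[[1]]$atoms$resno))
  rel <- if (max(mean_contacts) > 0) mean_contacts / max(mean_contacts) else mean_contacts
  out <- data.frame(residue_index = resnos, mean_contacts = mean_contacts,
                    relative = rel)
  class(out) <- c("HydrationProfile", class(out))
  out
}
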