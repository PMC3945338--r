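#!/usr/bin/env Rscript
# Build the synthetic study ensembles: a straight-like helix ensemble (hinge
# dihedrals at the straight NMR-ensemble averages) and a bent-like ensemble
# (hinge dihedrals at the kinked-ensemble averages), each with 5-degree
# Gaussian dihedral noise, plus a 40-degree hinge-kinked reference helix.
# Writes multi-model PDBs under results/analysis/.

suppressMessages(library(helixkink))
outdir <- "results/analysis"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

spec <- helix_spec()   # APP 686-728, author numbering
hinge <- c(708, 709) - spec$start_resno + 1

make_like <- function(psi_hinge, seed) {
  psi <- rep(spec$psi_deg, length(spec$sequence))
  psi[hinge] <- psi_hinge
  sample_ensemble(build_custom_helix(spec, psi = psi), 20,
                  dihedral_noise_deg = 5, seed = seed)
}

straight_like <- make_like(c(-41, -46), seed = 101)
bent_like <- make_like(c(-1, 13), seed = 102)
kinked40 <- build_kinked_helix(spec, kink_spec(target_bend_deg = 40))

write_pdb_ensemble(straight_like, file.path(outdir, "straight_like_synthetic.pdb"))
write_pdb_ensemble(bent_like, file.path(outdir, "bent_like_synthetic.pdb"))
write_pdb_ensemble(structure_ensemble(list(kinked40)),
                   file.path(outdir, "kinked40_synthetic.pdb"))

rp <- ensemble_rmsd_population(straight_like, straight_like$members[[1]],
                               "700-723:N,CA,C")
cat(sprintf("straight-like ensemble: %d models, population RMSD %.1f +/- %.1f A\n",
            n_members(straight_like), rp$mean, rp$sd))
rp2 <- ensemble_rmsd_population(bent_like, bent_like$members[[1]],
                                "700-723:N,CA,C")
cat(sprintf("bent-like ensemble:     %d models, population RMSD %.1f +/- %.1f A\n",
            n_members(bent_like), rp2$mean, rp2$sd))
cat("wrote", file.path(outdir, c("straight_like_synthetic.pdb",
                                 "bent_like_synthetic.pdb",
                                 "kinked40_synthetic.pdb")), sep = "\n  ")
cat("\n")
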