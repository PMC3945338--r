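#!/usr/bin/env Rscript
# Per-residue hydration of the straight-like and bent-like ensembles in an
# implicit membrane slab: scattered waters outside the phosphate planes,
# first-shell contact counts (3.5 A to any heavy atom), relative track
# normalized by the profile maximum.

suppressMessages(library(helixkink))
outdir <- "results/analysis"
frame <- membrane_frame()   # phosphate planes at +/-19 A

for (name in c("straight_like_synthetic", "bent_like_synthetic")) {
  ens <- read_pdb_ensemble(file.path(outdir, paste0(name, ".pdb")))
  waters <- make_membrane_and_waters(ens$members[[1]], frame, density = 0.02,
                                     n_frames = n_members(ens), seed = 103)
  prof <- hydration_profile(ens, waters, cutoff = 3.5)
  utils::write.table(as.data.frame(prof),
                     file.path(outdir, paste0(name, "_hydration.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  interfacial <- prof$mean_contacts[prof$residue_index %in% c(698:701, 722:725)]
  core <- prof$mean_contacts[prof$residue_index %in% 706:714]
  cat(sprintf("%s: interfacial %.2f waters/frame, TM core %.2f waters/frame\n",
              name, mean(interfacial), mean(core)))
}
cat("Waters concentrate at the membrane interface; the TM core of the\n")
cat("implicit slab model stays dry (no kink-driven water wires: the slab\n")
cat("has no defects, unlike the micelle systems this emulates).\n")
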