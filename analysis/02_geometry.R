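#!/usr/bin/env Rscript
# Hinge geometry of the synthetic ensembles: per-model bend (both printed
# conventions), membrane tilt and the two hinge dihedral collective
# variables, plus ensemble circular means. Reads the PDBs written by
# 01_build_ensembles.R and writes TSV tables.

suppressMessages(library(helixkink))
outdir <- "results/analysis"

for (name in c("straight_like_synthetic", "bent_like_synthetic")) {
  ens <- read_pdb_ensemble(file.path(outdir, paste0(name, ".pdb")))
  tab <- ensemble_geometry(ens, segment_N = c(700, 708), segment_C = c(710, 723),
                           sites = c(708, 709), frame = membrane_frame())
  utils::write.table(tab, file.path(outdir, paste0(name, "_geometry.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s (%d models):\n", name, nrow(tab)))
  cat(sprintf("  hinge CV circular means: [%.1f; %.1f] deg\n",
              circular_mean_deg(tab$cv1_deg), circular_mean_deg(tab$cv2_deg)))
  cat(sprintf("  mean bend %.1f deg (0 = straight) | mean axis angle %.1f deg (180 = straight)\n",
              mean(tab$bend_deg), mean(tab$axis_angle_deg)))
  cat(sprintf("  mean membrane tilt %.1f deg\n", mean(tab$tilt_deg)))
}
cat("A straight-like ensemble with 5-degree dihedral noise shows a nonzero\n")
cat("apparent mean bend: the bend statistic is positively biased for\n")
cat("near-straight helices, so a 'minor bend' can emerge from noise alone.\n")
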