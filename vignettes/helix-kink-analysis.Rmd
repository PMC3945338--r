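---
title: "Characterizing a kinked transmembrane helix: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a kinked transmembrane helix: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

The transmembrane (TM) segment of the amyloid precursor protein (residues
~700–723 in the author numbering used throughout this package) is an
α-helix with a glycine-rich hinge at Gly708–Gly709. Deposited NMR ensembles
disagree about its shape — one is essentially straight, the other strongly
kinked — and the discrepancy traces back to the micelle environments the
structures were solved in. Resolving it requires a set of quantitative
tools: hinge geometry on multi-model ensembles, per-residue hydration,
back-calculated residual dipolar couplings (RDCs) with sparse ensemble
selection, spin-label distance and depth observables, and free-energy
surfaces over the hinge dihedrals. `helixkink` implements that tool chain
with a synthetic-data module rich enough to test every stage against
planted truth.

```{r}
library(helixkink)
```

# Containers and geometry

A `Conformation` is a data frame of atoms with author residue numbering; a
`StructureEnsemble` is an ordered list of conformations sharing one
topology (enforced by a topology digest at construction). PDB I/O is
delegated to bio3d behind `read_pdb_ensemble()` / `write_pdb_ensemble()`;
alternate locations other than blank/'A' are dropped, waters (HOH) are kept
aside for the hydration stage, and everything round-trips at the 3-decimal
PDB precision.

Superposition is a proper-rotation Kabsch fit (base `svd`); RMSD population
statistics use the divide-by-*n* convention, which is what "population
RMSD" means here and in the ensemble literature.

**Helix axis.** The axis is the first principal component of smoothed
local helix centers (each center is the mean of 4 consecutive Cα). The
4-residue window cancels the helical wobble that contaminates raw-Cα PCA;
with fewer than 5 residues the fit refuses to run.

**Bend and tilt.** The bend at the hinge is the angle between the N→C axis
directions of the flanking segments, defaulting to 700–708 and 710–723 —
the TM span minus the second hinge glycine. Two conventions are printed in
the literature, so `KinkGeometry` carries both: `bend_deg` (0 = straight)
and `axis_angle_deg` = 180 − bend. Tilt is arccos|d·n| against the membrane
normal, in [0°, 90°].

**Hinge collective variables.** The two CVs are the backbone ψ torsions of
residues 708 and 709 — the dihedrals that connect the nitrogen atoms
N708→N709 and N709→N710. Torsions follow the IUPAC sign convention
(α-helical ψ ≈ −47°), and ensemble averages use circular means; an
arithmetic mean would be wrong near the ±180° seam.

One measurement caveat worth knowing: the bend statistic is non-negative,
so a noisy but straight ensemble has a positively biased mean bend. With
5° dihedral noise the straight synthetic ensemble shows an apparent mean
bend in the mid-teens of degrees — a "minor bend" can be a noise floor,
not a structural feature.

# Hydration

Hydration is a first-shell contact count: distinct water oxygens within a
cutoff (default 3.5 Å) of any heavy atom of a residue, averaged over
frames, with a `relative` track normalized by the profile maximum. One
water may count toward several residues. The cutoff is a parameter because
the underlying metric (contact count vs occupancy vs radial density) is a
modeling choice; contact counting is implemented and labeled as such.

# RDC back-calculation and ensemble selection

A residual dipolar coupling reports the orientation of the N–H bond unit
vector v through d = vᵀS v, with S the symmetric traceless Saupe
(alignment) tensor. Couplings are handled in reduced units — the dipolar
prefactor is folded into S — so the fitted axial magnitude is in the units
of the input couplings.

Amide hydrogens absent from the input are rebuilt in the peptide plane
opposite the bisector of N→C(prev) and N→Cα at 1.02 Å; the first residue
and prolines are skipped.

**SVD fit.** With rows m = [vy²−vx², vz²−vx², 2vxvy, 2vxvz, 2vyvz], the
least-squares problem M s = d is solved by singular value decomposition
and S rebuilt traceless from s = (Syy, Szz, Sxy, Sxz, Syz). Rank below 5
is an error, not a silent pseudo-inverse. A conditioning fact the tests
document: N–H vectors of a straight helix cluster in a narrow cone, the
design matrix has condition number ~30, and at 10% coupling noise the
tensor error can reach ~30% even though the *couplings* are recovered to a
few percent. The fit is exact at zero noise, and recovers the tensor to a
few percent from isotropically scattered vectors; for helical data the
reliable quantities are the fitted couplings and the Q-factor
Q = rms(d_calc − d_exp)/rms(d_exp).

**Genetic algorithm.** Ensemble selection uses a fixed-size subset
chromosome (binary mask with repair), tournament selection of size 3,
uniform crossover (rate 0.8), swap mutation, elitism 1, population 100,
generations 150–200. Fitness is the Q of a *single* tensor fit to the
subset-averaged design matrix: one alignment medium implies one tensor,
so rows of M are averaged over the subset before solving — the standard
sparse ensemble-selection formulation. Runs are bit-reproducible per seed,
and a random-subset baseline (`random_subset_baseline()`) with a 10× eval
budget is kept as the sanity bar the GA must beat.

**Jarvis-Patrick.** Conformers are clustered on pairwise superposed
backbone RMSD. Two items join iff each is in the other's k-nearest list
(k = 6) and they share at least k_min = 3 neighbors; clusters are
connected components, unjoined items are noise (−1). Neighbor lists
include *all* items tied at the k-th distance: that makes the partition
independent of input order and lets a set of identical conformers collapse
into one cluster, which a strict index-tie-break rule would not do.

# Spin labels, DEER distances and membrane depth

Real nitroxide (MTSL) rotamer libraries are out of scope; the package uses
a documented accessible-volume pseudo-label: N–O midpoint positions
sampled in a 40° cone about the Cα→Cβ direction at Gaussian radial
distance 7 ± 1 Å, clash-rejected within 2.5 Å of protein heavy atoms.
When a membrane frame is supplied, candidate weights get a burial factor
exp(depth/λ) with λ = 5 Å — the hydrophobic tag prefers the membrane
interior, which is the key qualitative effect: burial shortens apparent
inter-label distances on the straight helix and blurs the straight/bent
distinction.

Distance distributions are weighted histograms of all cross pairs on a
0–80 Å grid (0.25 Å spacing, covering the DEER-sensitive 18–60 Å window),
Gaussian-smoothed with 1 Å bandwidth and renormalized to unit area. The
reported mean and sd are the weighted moments of the raw pair distances,
computed before smoothing, so the kernel cannot shift them.

Boltzmann weights over a free-energy surface use
w ∝ exp(−F/kT), kT = 0.0019872 kcal mol⁻¹ K⁻¹ × T; any constant shift of F
cancels.

The EPR depth parameter is represented by a monotone saturating proxy
Φ(depth) = Φmax·tanh(depth/λ), Φmax = 5, λ = 10 Å, on the signed distance
from the nearer phosphate plane (positive toward the membrane center).
The true power-saturation calibration is instrument-specific; only
monotonicity and saturation are relied on, and both parameters are
exposed.

# Metadynamics and free-energy surfaces

The walker is overdamped Langevin in the 2D angular CV space:

s ← s − (∇U + ∇V)·dt/γ + sqrt(2·kT·dt/γ)·ξ

with defaults kT = 0.596 kcal/mol (300 K), dt/γ = 3 deg²·mol/kcal per
step. Time is nominal walker time; mapping to the all-atom deposition
stride ("every 300 fs") is not meaningful for a toy walker and is not
attempted. Repulsive Gaussians of height 0.1 kcal/mol and width σ = 15°
are deposited every 100 steps at the walker position; the free energy is
the standard non-well-tempered estimator F = −V, min-shifted to zero.

Two numerical choices matter:

* **Hill units.** The all-atom reference setting "width 0.3, weight 0.01"
  is unit-ambiguous; 0.3° would be implausibly narrow for a dihedral CV,
  so 0.3 is read as radians (≈17°) and 0.01 as kcal/mol. Both are plain
  parameters; the desk-scale defaults (0.1 kcal/mol, 15°) are chosen so a
  few-kcal/mol well fills within ~10⁵ steps with hill-height-sized ripple.
* **Reflecting windows need mirror hills.** The sampling window is
  [−75°, 10°] per CV with a reflecting walker (the full torus, minimum-
  image periodic, is used when no window is set). A hill deposited near a
  reflecting wall leaks part of its mass outside; without correction the
  boundary stays under-biased, the walker piles up against the walls and
  the reconstructed surface grows a spurious rim. Deposition therefore
  adds the mirror images of each hill about both walls (in the compiled
  engine, in `reconstruct_fes()` and in `fes_delta_estimate()`); with the
  images in place the surface reconstruction error decreases
  monotonically with deposition time, which is one of the test suite's
  properties.

The bias acting on the walker is accumulated on a gradient grid (1°
spacing, truncated at 4.5σ), so the cost per step is O(1) in the number of
hills; the engine core is compiled (Rcpp) and uses R's RNG, making runs
bit-reproducible under `set.seed`. ΔF between basins is estimated as the
running V difference at the two minima averaged over the final 20% of
hills, which damps the estimator's oscillation.

**Basin and barrier analysis.** `fes_minima_and_barrier()` descends from
each seed to its local grid minimum, then finds the barrier by a monotone
flood: cells are activated in increasing F (8-connected, union-find) until
the two basins join; the activation level is the minimax path height. On
the exactly sampled double well the extracted barrier matches the
analytic saddle to within one grid cell. Surface differences are computed
after min-shifting each surface, so constant offsets never matter.

**Toy potentials.** The double well places two Gaussian wells (σ = 8°) on
the cv1 axis at −50° and −15° with depths 5 and 3 kcal/mol plus a harmonic
confinement in cv2, giving a planted ΔF = 2 kcal/mol and a saddle of
~4.3 kcal/mol (the Gaussian tails overlap slightly, so the `ToyPotential`
object refines its reference minima, ΔF and saddle numerically to 1e-10
from the analytic form rather than quoting the nominal depths). These
refined values are the oracle all engine tests compare against.

# The synthetic-data module

Helices are built by sequential internal-coordinate (NeRF) construction
with standard backbone geometry (N–Cα 1.458, Cα–C 1.525, C–N 1.329 Å;
angles 111.2°, 116.2°, 121.7°; ideal torsions ϕ = −57°, ψ = −47°,
ω = 180°), on the 686–728 sequence so every hinge site resolves naturally.
Kinks are induced by adjusting the hinge residue's ψ (and ϕ, for swivel)
with bisection until the measured bend matches the target within 0.5°;
chemistry stays ideal. Targets at or below the straight helix's intrinsic
wobble (~0.7°) return the straight helix. Ensembles add independent
Gaussian noise to all ϕ/ψ and are superposed back onto the base frame.
Membrane waters are uniform outside the phosphate slab (planes at ±19 Å,
a typical phosphate-to-center half-thickness for a POPC-like bilayer)
with Poisson counts at density 0.02 Å⁻³ — about 2/3 of bulk water, a
deliberate thinning that keeps contact counting fast while preserving the
interfacial-vs-core contrast. Planted RDC sets always return their
ground-truth tensor and weights alongside the couplings.

What the generator does *not* emulate: side chains beyond an implicit Cβ
direction, lipid molecules and membrane defects, kink-driven water wires
into the core, real rotamer statistics of the nitroxide tag, and any
force-field energetics. Passing tests therefore demonstrate that the
estimators recover planted geometric and statistical truth, not that the
biology of a real bilayer is reproduced.

# Problem sizes and reproducibility

The shipped analyses and checks use: 20-model synthetic NMR-like
ensembles (5° dihedral noise); a 100-conformer straight/bent pool with a
10-member GA selection (population 100, 150 generations, 5 seeds);
metadynamics runs of 4×10⁵ steps (4000 hills) per seed, 3 seeds, on an
86×86 1° grid. These sizes give planted-truth recovery well inside the
tolerances asserted by the tests (ΔF within ±0.3 kcal/mol, mixture
fraction within ±0.1) while a full test run stays in the minutes range.
Every stochastic stage takes an explicit seed; pipeline runs
(`run_pipeline()`) derive per-stage seeds from one global seed by a fixed
splitting rule and record everything in a JSON manifest.

# Known limitations

* The pseudo-label is a geometric proxy; absolute distances carry its
  7 ± 1 Å radial law, so only comparisons between conformations are
  meaningful, not absolute agreement with measured DEER distributions.
* The depth-parameter calibration is a monotone stand-in; correlations
  against other profiles are meaningful, absolute Φ values are not.
* F = −V (non-well-tempered) oscillates with hill-height amplitude;
  the late-time averaging reduces but does not eliminate this, which is
  why ΔF tolerances are a few tenths of kcal/mol.
* Deposited NMR ensembles are not redistributable with the package; the
  ensemble-geometry checks run on them only when the PDB files are placed
  under `inst/extdata/` (2LLM.pdb, 2LP1.pdb), and on labelled synthetic
  stand-ins otherwise.
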