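Package: helixkink
Title: Conformational Analysis of Kinked Transmembrane Helix Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for characterizing the conformational ensemble of a
    transmembrane alpha-helix with a flexible glycine hinge, modelled on the
    amyloid precursor protein transmembrane segment (residues 686-728, author
    numbering). Provides multi-model PDB ensemble handling with rigid-body
    superposition, helix axis / kink / tilt geometry and the two hinge dihedral
    collective variables, per-residue hydration profiles, residual dipolar
    coupling back-calculation with SVD alignment-tensor fitting, genetic-algorithm
    sparse ensemble selection and Jarvis-Patrick clustering, pseudo spin-label
    placement with DEER-style distance distributions and membrane depth-parameter
    profiles (including Boltzmann-weighted ensembles), and a desk-scale
    metadynamics engine with free-energy-surface reconstruction, basin/barrier
    analysis and surface differencing over the two dihedral collective variables.
    Includes synthetic generators (ideal and hinge-kinked helices, dihedral-noise
    ensembles, membrane frames and waters, planted-tensor RDC sets, analytic toy
    potentials) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
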