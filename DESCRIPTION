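Package: ConsensusDock
Title: Consensus Protein-Protein Docking by Multi-Engine Pose Clustering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for consensus (meta) protein-protein docking analysis:
    pooling of docked complex poses from multiple docking engines with
    provenance manifests, all-pairs heavy-atom RMSD matrices with Kabsch
    superposition, agglomerative conformer clustering with Kelley-penalty
    model selection, centroid-based consensus pose selection and per-engine
    cluster component analysis. Also provides interface characterization
    (residue contacts at a distance cutoff, hot-spot anchored native-contact
    retention over trajectories, geometric hydrogen bonds and salt bridges,
    RMSD time series, per-residue RMSF) and assembly of composite
    multi-protein models by iterative domain superposition grafting, with
    clash reporting. Includes a deterministic synthetic-data generator for
    rigid-body perturbed pose pools with planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralBioinformatics, Clustering, Proteomics
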