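---
title: "Consensus docking by pose clustering: methods and design"
author: "ConsensusDock"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Consensus docking by pose clustering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConsensusDock)
```

# The problem

No single protein–protein docking engine is reliably accurate: sampling
algorithms, scoring functions and flexibility treatment differ, and the
best engine varies case by case. A consensus (meta) strategy sidesteps
engine-specific scoring: the top-ranked poses from several engines are
pooled (each further refined under two relaxation protocols, giving ten
refined models per docked pose), the pool is clustered by structural
similarity, and the pose nearest the centroid of the most populated
cluster is taken as the prediction. The rationale is that independent
engines agreeing on a binding mode is stronger evidence than any one
engine's score. `ConsensusDock` implements this pipeline together with
the interface analyses used to scrutinize the resulting complexes
(contacts, hot-spot anchored native-contact retention over trajectories,
hydrogen bonds, salt bridges, RMSD series, RMSF) and a
superposition-grafting assembler for composite multi-protein models.

# The consensus pipeline

## Pose pools and provenance

A pose pool is described by a manifest (`path`, `engine`, `rank`,
`protocol`). A pose refined from the engine's rank-*m* model under
protocol *n* is labelled `ENGINE_m_n`, with *n* in 1–5 for the
distance-restrained and 6–10 for the distance+position-restrained
relaxation protocol. Five engines each contributing five poses with ten
refined models gives the canonical 250-member pool; engines may return
fewer poses (a single-pose engine contributes 10, giving 210).

## RMSD matrix

`buildRMSDMatrix()` computes all-pairs dissimilarities over the common
atom roster of the pool (atoms missing from any pose are dropped
everywhere, with a message). The default selection is **all heavy
atoms** and each pair is **superposed (Kabsch) before measuring**. The
no-fit alternative is exposed (`superpose = FALSE`) because refined
poses only approximately share a receptor frame; superposition is the
conservative choice and a configuration flag rather than a hard-coded
convention. Mirror solutions are rejected (the rotation determinant is
forced to +1), and the pairwise residual is computed from explicitly
transformed coordinates rather than the singular-value trace identity,
which cancels catastrophically near zero.

Chain-swap ambiguity in homodimers is handled by *declared* permutable
chain groups: every allowed chain permutation is evaluated and the
minimum-RMSD one kept. Groups are never auto-detected, because
sequence-identical chains in different conformational states must not be
silently permuted.

## Clustering and the Kelley penalty

The matrix is clustered agglomeratively (`stats::hclust`; average
linkage by default, complete and single exposed — published cluster
counts can depend on the linkage convention, which the original
conformer-clustering software does not document). The number of
clusters *N* is chosen by the Kelley–Gardner–Sutcliffe penalty: at each
tree level *k*, every multi-member cluster's spread is the mean pairwise
RMSD of its members and the level's spread averages these; spreads are
rescaled linearly so they span 1 to *P*−1 across the retained levels
(levels whose clusters are all singletons carry no spread and are
excluded), and the penalty is the rescaled spread plus *k*. The optimum
minimizes the penalty; ties resolve to the smaller *k*. An all-zero
matrix (identical poses) degenerates to *N* = 1 with a warning.

## Cluster statistics and the consensus pose

A cluster's centroid is the member minimizing the mean RMSD to its
co-members (ties: lexicographically first label). Reported per cluster:
population, centroid label, the mean and standard deviation of
member-to-centroid RMSD computed over the *non-centroid* members
(the centroid's trivial zero would otherwise dilute the spread;
singletons report 0), and the RMSD from each centroid to the main
cluster's centroid. The most populated cluster is the main cluster
(population ties: smaller mean member–centroid RMSD, then smaller
cluster id), and its centroid member is the consensus pose *Q*.
Per-engine component analysis reports each engine's member count and
percentage of a cluster; percentages round half-up to integers to match
the reporting convention of consensus-docking studies, with raw
fractions retained in the machine output.

Predicted complexes are validated against crystal references with
`compareToReference()`: a C-alpha Kabsch superposition honouring
permutable groups.

# Interface analyses

* **Contacts** (`detectContacts`): a residue pair across the declared
  partner partition is a contact when *any* heavy-atom pair lies within
  the cutoff (default 5 Å); the minimum distance is recorded. Hydrogens
  are excluded for robustness to protonation differences between
  refinement protocols. The implementation uses a cell-list neighbour
  search; tests verify it against a brute-force all-pairs oracle.
* **Native contacts** (`nativeContacts`): contacts in which at least one
  residue is a hot spot — a residue whose alanine-substitution change in
  binding affinity exceeds a threshold (default > 10 kcal/mol). The
  affinity values are *consumed* from a user-supplied table (typically
  published alanine-scanning results); the package never computes
  binding energies. `contactRetention()` recomputes the native pairs in
  every trajectory frame; the fraction at the native-defining frame is
  exactly 1.
* **Hydrogen bonds** (`detectHBonds`): donor/acceptor N/O heavy atoms
  from residue templates; counted at donor–acceptor distance ≤ 3.5 Å
  with a D–H···A angle ≥ 120° when hydrogens are present, and by
  distance alone (flagged) otherwise. Pairs closer than 2.5 Å and the
  peptide-bonded backbone N(i)···O(i−1) pair are excluded as covalent
  context. These thresholds are common literature defaults and are
  config-exposed; published absolute counts obtained with other
  software's criteria are not expected to reproduce exactly.
* **Salt bridges** (`detectSaltBridges`): Asp/Glu carboxylate oxygen to
  Lys/Arg/His side-chain nitrogen within 4.0 Å, one bridge per residue
  pair.
* **RMSD series and RMSF**: each frame is superposed onto the reference
  frame (C-alpha by default) before the RMSD; RMSF superposes frames
  onto an iteratively refined mean structure (two passes) and reports,
  per residue, the root-mean-square deviation of its selected-atom
  centroid from its time-average position. The mean-structure reference
  is a deliberate choice where the literature convention is often left
  unstated; note that the fit reabsorbs a small share of any localized
  motion, so a single oscillating residue's RMSF is recovered to within
  a few percent, not exactly.

# Composite assembly by grafting

`graft()` places a larger construct into a complex by superposing the
C-alpha atoms of a shared domain onto its counterpart in the scaffold
(C-alpha only, because side-chain states differ between contexts), then
appends the requested chains under deterministic next-free-letter
identifiers. Fit RMSD is logged per step; a configurable threshold
(default 2 Å) warns without failing. `buildUnit()` chains grafts so each
step can target chains added by earlier steps — the pattern used to
build, e.g., a six-molecule signalling-complex unit from three pairwise
complexes — and attaches a clash report (inter-unit heavy atoms closer
than 2 Å). No steric relaxation is attempted: clashes are reported, not
resolved.

# The synthetic generator

The generator makes every pipeline property testable without downloads.

* `makeToyComplex()` builds two parallel ideal-geometry poly-alanine
  chains (internal-coordinate construction; helix φ = −57°, ψ = −47°,
  rise ≈ 1.5 Å/residue). The default inter-axis separation of 8.5 Å
  keeps every interface contact at least ~0.4 Å inside the 5 Å cutoff,
  so small coordinate jitter cannot toggle contacts — a condition the
  stable-trajectory retention guarantee relies on. `charged = TRUE`
  plants a Lys/Glu pair 3 Å across the interface for salt-bridge and
  H-bond fixtures.
* `generatePool()` emulates a multi-engine pool: each planted cluster
  center is a distinct binding mode (a 90° ligand rotation about a
  center-specific axis plus a translation along near-uniform directions
  on a sphere, scaled so the smallest ligand displacement between
  centers equals `interSeparation`); members add Gaussian jitter scaled
  to `intraSpread`; engine/rank/protocol labels follow the recipe.
  Centers are placed on a spherical code rather than along a line
  because a whole-complex rigid fit absorbs ligand-only translations
  (the fitted separation saturates with displacement), and strongly
  non-uniform center distances make coarser partitions attractive to
  any spread-based model selection. Defaults: 10 members per cluster
  (mirroring the ten refined models per docked pose), `intraSpread`
  1 Å, `interSeparation` 20 Å; recipes must satisfy
  `interSeparation > 2 * intraSpread`. Output is byte-deterministic per
  seed, with a ground-truth sidecar (`label,true_cluster`).
* `generateTrajectory()` produces multi-model PDB trajectories: `stable`
  jitters about the base; `dissociating` adds a monotone ligand
  translation so native contacts break and the final frame is fully
  separated.

What the generator does **not** emulate: refinement-induced backbone
flexibility, side-chain repacking, engine-specific pose biases and
cluster-size imbalance of real docking pools. Passing the planted-
recovery tests therefore shows the clustering/model-selection machinery
is correct under rigid-body pose variability, not that the meta-approach
succeeds on any particular real system.

# Numerical choices and degenerate inputs

* Altloc resolution: highest occupancy, ties to the alphabetically first
  identifier. Residue identity is (chain, resseq, insertion code).
* Superposition requires ≥ 3 non-collinear paired atoms; collinear sets
  and sub-3-atom pairings raise degenerate-superposition errors.
* Merge-distance ties in the agglomerative tree are resolved by
  `stats::hclust`'s deterministic ordering; identical manifests and
  configuration yield byte-identical reports.
* Half-up integer rounding is used for report percentages (R's
  `round()` rounds half to even, which does not match the field's
  reporting style).
* Centroid and final-pose ties resolve lexicographically / to the
  smaller cluster id, so every selection is reproducible.

# Validation against deposited data

The published cluster counts (e.g. an optimum of 14 clusters with an
83-member main cluster for a death-domain homodimer pool, consensus
pose `ZDOCK_3_6`, C-alpha RMSD ~1.1 Å to the crystal dimer) were
obtained from refined pose pools deposited in an external archive and
from crystal structures in the PDB. Those inputs are not bundled here;
a user holding them can reproduce every reported quantity with:

```r
pool <- loadManifest("deposited/manifest.csv")
res  <- consensusPipeline(pool)           # matrix, tree, Kelley N, stats, Q
componentAnalysis(res$stats, pool)        # per-engine membership
compareToReference(res$finalRecord@structure, readPDB("3ezq.pdb"),
                   chainMapping(permutableGroups = list(c("A", "B"))))
```

Reproduction of the exact published numbers additionally depends on the
(undocumented) linkage convention of the original clustering software;
the linkage is therefore a configuration knob, not a constant.

# Problem sizes used in the shipped checks

The test-suite and acceptance script run on synthetic pools of 30–250
poses built from 5–10-residue-per-chain toys, 20 recovery seeds spanning
3–14 planted clusters, and 6–20-frame trajectories. These sizes were
chosen as the smallest at which every contract (pool arithmetic,
planted recovery, oracle equivalence, retention behaviour) is exercised
with comfortable statistical margin.

# Known limitations

* PDB fixed-column input/output only (via bio3d); no mmCIF writing, no
  ligand or nucleic-acid chemistry.
* Chain correspondence is identity- or mapping-based; no
  sequence-alignment-driven pairing, no TM-score/lDDT metrics.
* H-bond/salt-bridge counts are geometric and threshold-sensitive;
  absolute counts are comparable only within one criterion set.
* The assembler executes explicit recipes; it does not search for the
  mutual arrangement of repeating units in higher-order assemblies.
* Binding-affinity changes (alanine scanning) and free energies are
  inputs, never outputs.
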