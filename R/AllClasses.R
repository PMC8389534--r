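#' @import methods
NULL

setOldClass("hclust")

## ---------------------------------------------------------------------------
## Structure: one macromolecular model as an ordered atom table
## ---------------------------------------------------------------------------

#' Structure: an ordered atom table for one macromolecular model
#'
#' The central coordinate container. Atoms are stored as an ordered
#' `data.frame` with one row per atom and columns `serial`, `name`,
#' `element`, `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`, `occ`.
#' Residue identity is the triple `(chain, resseq, icode)`; hydrogens are
#' kept on read but excluded from all default heavy-atom selections.
#'
#' @slot atoms data.frame of atoms in file order.
#' @seealso [readPDB()], [atoms()], [coords()], [chains()], [residues()]
#' @export
setClass("Structure", representation(atoms = "data.frame"))

.ATOM_COLS <- c("serial", "name", "element", "resname", "chain",
                "resseq", "icode", "x", "y", "z", "occ")

setValidity("Structure", function(object) {
  at <- object@atoms
  if (!all(.ATOM_COLS %in% names(at)))
    return(paste("atoms must have columns:", paste(.ATOM_COLS, collapse = ", ")))
  if (nrow(at) == 0L) return("Structure has no atoms")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) return("non-finite coordinates")
  if (any(!nzchar(at$element))) return("empty element symbols")
  key <- paste(at$chain, at$resseq, at$icode, at$name, sep = "|")
  if (anyDuplicated(key))
    return("duplicate (chain, resseq, icode, name) atom after altloc resolution")
  TRUE
})

#' Create a Structure from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`, `occ`. Missing
#'   `serial`/`icode`/`occ`/`element` are filled with defaults (`element`
#'   from the first letter of the atom name).
#' @return A [Structure-class] object.
#' @export
Structure <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$element)) atoms$element <- .guessElement(atoms$name)
  atoms$resseq <- as.integer(atoms$resseq)
  atoms$serial <- as.integer(atoms$serial)
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms[, .ATOM_COLS])
}

## Element from PDB atom-name conventions: two-character elements only for
## common cases; a leading digit (e.g. "1HB1") marks a hydrogen.
.guessElement <- function(name) {
  nm <- toupper(trimws(name))
  el <- substr(gsub("^[0-9]", "", nm), 1, 1)
  two <- nm %in% c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE")
  el[two] <- nm[two]
  el
}

## ---------------------------------------------------------------------------
## Trajectory: ordered frames sharing one atom roster
## ---------------------------------------------------------------------------

#' Trajectory: an ordered series of Structure frames
#'
#' All frames must share an identical atom roster (same atom count, names,
#' and ordering), as in a multi-model PDB written from a molecular-dynamics
#' run.
#'
#' @slot frames list of [Structure-class] objects.
#' @slot frameTimes numeric vector of frame times (ns), possibly empty.
#' @export
setClass("Trajectory",
         representation(frames = "list", frameTimes = "numeric"))

setValidity("Trajectory", function(object) {
  fr <- object@frames
  if (length(fr) < 1L) return("empty trajectory")
  if (!all(vapply(fr, is, logical(1), "Structure")))
    return("frames must all be Structure objects")
  key0 <- .rosterKey(fr[[1L]])
  for (i in seq_along(fr)[-1L]) {
    if (!identical(.rosterKey(fr[[i]]), key0))
      return(sprintf("frame %d atom roster differs from frame 1", i))
  }
  if (length(object@frameTimes) &&
      length(object@frameTimes) != length(fr))
    return("frameTimes length must match frame count")
  TRUE
})

.rosterKey <- function(s) {
  at <- s@atoms
  paste(at$chain, at$resseq, at$icode, at$name, sep = "|")
}

#' @rdname Trajectory-class
#' @param frames list of [Structure-class] frames with identical rosters.
#' @param frameTimes optional numeric frame times in ns.
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(frames, frameTimes = numeric()) {
  new("Trajectory", frames = frames, frameTimes = as.numeric(frameTimes))
}

## ---------------------------------------------------------------------------
## PoseRecord / PosePool: docked poses with engine provenance
## ---------------------------------------------------------------------------

#' PoseRecord: one docked pose with engine provenance
#'
#' The label is a pure function of the provenance triple: `ENGINE_m_n`
#' for engine name, rank `m` (the engine's ranked model, m >= 1) and
#' refinement protocol index `n` in 1..10 (1-5 distance-restrained, 6-10
#' distance+position-restrained relaxation).
#'
#' @slot structure the pose coordinates.
#' @slot engine docking-engine name (free string; the five common engines
#'   HADDOCK, ClusPro, HDOCK, GRAMM-X, ZDOCK are recognized in reports).
#' @slot rank integer model rank within the engine, >= 1.
#' @slot protocol integer refinement protocol index in 1..10.
#' @export
setClass("PoseRecord",
         representation(structure = "Structure", engine = "character",
                        rank = "integer", protocol = "integer"))

setValidity("PoseRecord", function(object) {
  if (length(object@engine) != 1L || !nzchar(object@engine))
    return("engine must be a non-empty string")
  if (object@rank < 1L) return("rank must be >= 1")
  if (object@protocol < 1L || object@protocol > 10L)
    return("protocol must be in 1..10")
  TRUE
})

#' @rdname PoseRecord-class
#' @param structure a [Structure-class].
#' @param engine,rank,protocol provenance fields.
#' @return A [PoseRecord-class].
#' @export
PoseRecord <- function(structure, engine, rank, protocol) {
  new("PoseRecord", structure = structure, engine = as.character(engine),
      rank = as.integer(rank), protocol = as.integer(protocol))
}

#' Pose label from provenance
#'
#' @param engine engine name; @param rank model rank; @param protocol
#'   refinement protocol index.
#' @return `"ENGINE_m_n"` label string.
#' @export
poseLabel <- function(engine, rank, protocol) {
  sprintf("%s_%d_%d", engine, as.integer(rank), as.integer(protocol))
}

#' PosePool: an ordered pool of PoseRecord objects
#'
#' @slot records list of [PoseRecord-class]; labels must be unique.
#' @export
setClass("PosePool", representation(records = "list"))

setValidity("PosePool", function(object) {
  rs <- object@records
  if (!all(vapply(rs, is, logical(1), "PoseRecord")))
    return("records must all be PoseRecord objects")
  lab <- vapply(rs, function(r) poseLabel(r@engine, r@rank, r@protocol), "")
  if (anyDuplicated(lab)) return("duplicate (engine, rank, protocol)")
  TRUE
})

#' @rdname PosePool-class
#' @param records list of [PoseRecord-class] objects.
#' @return A [PosePool-class].
#' @export
PosePool <- function(records) new("PosePool", records = records)

## ---------------------------------------------------------------------------
## Geometry helpers
## ---------------------------------------------------------------------------

#' AtomSelection: which atoms enter a superposition or RMSD
#'
#' @slot mode `"heavy"` (all non-hydrogen atoms; the default used for
#'   conformer clustering), `"ca"` (C-alpha only, used for comparisons to
#'   crystal references), `"all"`, or `"custom"` (explicit atom names).
#' @slot chains optional chain restriction (character, empty = all).
#' @slot residueFilter optional data.frame with columns `chain`, `from`,
#'   `to` restricting to residue-number ranges.
#' @slot atomNames atom names for `mode = "custom"`.
#' @export
setClass("AtomSelection",
         representation(mode = "character", chains = "character",
                        residueFilter = "data.frame", atomNames = "character"))

#' @rdname AtomSelection-class
#' @param mode,chains,residueFilter,atomNames see slots.
#' @return An [AtomSelection-class].
#' @export
atomSelection <- function(mode = c("heavy", "ca", "all", "custom"),
                          chains = character(),
                          residueFilter = NULL,
                          atomNames = character()) {
  mode <- match.arg(mode)
  if (is.null(residueFilter))
    residueFilter <- data.frame(chain = character(), from = integer(),
                                to = integer())
  if (mode == "custom" && !length(atomNames))
    stop("custom selection requires atomNames")
  new("AtomSelection", mode = mode, chains = as.character(chains),
      residueFilter = residueFilter, atomNames = atomNames)
}

#' ChainMapping: chain correspondence between two structures
#'
#' Homodimer (or higher) chain-swap ambiguity is handled by declaring
#' `permutableGroups`: sets of chains that are chemically identical and may
#' be permuted during superposition; the minimum-RMSD permutation is
#' returned. Groups are never auto-detected.
#'
#' @slot pairs data.frame with columns `from` (chain in the mobile/first
#'   structure) and `to` (chain in the reference/second structure); a
#'   bijection. Empty = identity mapping over shared chains.
#' @slot permutableGroups list of character vectors of reference chains.
#' @export
setClass("ChainMapping",
         representation(pairs = "data.frame", permutableGroups = "list"))

setValidity("ChainMapping", function(object) {
  p <- object@pairs
  if (nrow(p)) {
    if (anyDuplicated(p$from) || anyDuplicated(p$to))
      return("chain mapping must be a bijection")
  }
  TRUE
})

#' @rdname ChainMapping-class
#' @param pairs named character vector (`c(A = "B")` maps mobile chain A to
#'   reference chain B) or data.frame with columns `from`, `to`; NULL for
#'   identity.
#' @param permutableGroups list of character vectors of chains declared
#'   chemically identical.
#' @return A [ChainMapping-class].
#' @export
chainMapping <- function(pairs = NULL, permutableGroups = list()) {
  if (is.null(pairs)) {
    pairs <- data.frame(from = character(), to = character())
  } else if (!is.data.frame(pairs)) {
    pairs <- data.frame(from = names(pairs), to = unname(pairs))
  }
  new("ChainMapping", pairs = pairs, permutableGroups = permutableGroups)
}

#' SuperpositionResult: optimal rigid transform and its RMSD
#'
#' @slot rotation 3x3 proper rotation matrix (det = +1).
#' @slot translation length-3 translation vector (Angstrom); the transform
#'   maps mobile coordinates as `x %*% rotation + translation`.
#' @slot rmsd RMSD over the paired roster (Angstrom).
#' @slot nAtoms number of paired atoms used.
#' @export
setClass("SuperpositionResult",
         representation(rotation = "matrix", translation = "numeric",
                        rmsd = "numeric", nAtoms = "integer"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det = +1)")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Consensus clustering containers
## ---------------------------------------------------------------------------

#' RMSDMatrix: symmetric all-pairs dissimilarity over a pose pool
#'
#' @slot values symmetric non-negative matrix (Angstrom) with zero diagonal;
#'   dimnames carry the pose labels.
#' @export
setClass("RMSDMatrix", representation(values = "matrix"))

setValidity("RMSDMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("matrix must carry identical row/col labels")
  if (any(!is.finite(v))) return("non-finite RMSD values")
  if (any(v < 0)) return("negative RMSD values")
  if (max(abs(v - t(v))) > 1e-9) return("matrix not symmetric to 1e-9")
  if (any(diag(v) != 0)) return("diagonal must be exactly zero")
  TRUE
})

#' @rdname RMSDMatrix-class
#' @param values labelled symmetric matrix.
#' @return An [RMSDMatrix-class].
#' @export
RMSDMatrix <- function(values) new("RMSDMatrix", values = values)

#' ClusteringResult: agglomerative merge tree over a pose pool
#'
#' Wraps the merge tree so that `assignmentsAt(x, k)` yields the nested
#' partition into k clusters for any k in 1..P.
#'
#' @slot tree an `hclust` merge tree.
#' @slot labels pose labels in matrix order.
#' @slot linkage linkage criterion used.
#' @export
setClass("ClusteringResult",
         representation(tree = "hclust", labels = "character",
                        linkage = "character"))

#' KelleyProfile: per-level Kelley penalty and the optimal level
#'
#' @slot profile data.frame with one row per retained tree level:
#'   `k`, `meanSpread` (mean over multi-member clusters of their mean
#'   pairwise member RMSD), `normSpread` (normalized to span 1..P-1 across
#'   retained levels) and `penalty` (= normSpread + k).
#' @slot optimalK the penalty-minimizing number of clusters (tie: smaller k).
#' @slot nPoses pool size P.
#' @export
setClass("KelleyProfile",
         representation(profile = "data.frame", optimalK = "integer",
                        nPoses = "integer"))

#' ClusterStats: per-cluster population, centroid and spread summaries
#'
#' @slot stats data.frame with one row per cluster: `cluster`, `population`,
#'   `centroid` (label of the member minimizing mean RMSD to co-members),
#'   `avgRMSD` and `sdRMSD` of member-to-centroid distances (excluding the
#'   centroid itself), and `rmsdToMain` (this centroid to the main cluster's
#'   centroid).
#' @slot mainCluster index of the most populated cluster (ties: smaller
#'   avgRMSD, then smaller cluster id).
#' @slot assignments named integer vector: cluster id per pose label.
#' @export
setClass("ClusterStats",
         representation(stats = "data.frame", mainCluster = "integer",
                        assignments = "integer"))

setValidity("ClusterStats", function(object) {
  if (sum(object@stats$population) != length(object@assignments))
    return("cluster populations must sum to pool size")
  TRUE
})

#' ComponentReport: per-engine composition of one cluster
#'
#' @slot table data.frame with columns `engine`, `count`, `percent`
#'   (half-up integer rounding) and `fraction` (raw).
#' @slot cluster cluster id analysed.
#' @slot nearestToCentroid label of the cluster's centroid member.
#' @export
setClass("ComponentReport",
         representation(table = "data.frame", cluster = "integer",
                        nearestToCentroid = "character"))

## ---------------------------------------------------------------------------
## Interface containers
## ---------------------------------------------------------------------------

#' PartnerPartition: the two sides of a protein-protein interface
#'
#' @slot sideA,sideB disjoint non-empty chain sets.
#' @export
setClass("PartnerPartition",
         representation(sideA = "character", sideB = "character"))

setValidity("PartnerPartition", function(object) {
  if (!length(object@sideA) || !length(object@sideB))
    return("both sides must be non-empty")
  if (length(intersect(object@sideA, object@sideB)))
    return("sides must be disjoint")
  TRUE
})

#' @rdname PartnerPartition-class
#' @param sideA,sideB chain identifiers for the two binding partners.
#' @return A [PartnerPartition-class].
#' @export
partnerPartition <- function(sideA, sideB)
  new("PartnerPartition", sideA = as.character(sideA),
      sideB = as.character(sideB))

#' ContactSet: interface residue-pair contacts
#'
#' A residue pair is a contact when any heavy-atom pair across the
#' partition lies within the cutoff; the minimum heavy-atom distance is
#' recorded per pair.
#'
#' @slot contacts data.frame with columns `chainA`, `resseqA`, `resnameA`,
#'   `chainB`, `resseqB`, `resnameB`, `dist`.
#' @slot cutoff distance cutoff (Angstrom).
#' @slot partition the [PartnerPartition-class] used.
#' @export
setClass("ContactSet",
         representation(contacts = "data.frame", cutoff = "numeric",
                        partition = "PartnerPartition"))

setValidity("ContactSet", function(object) {
  ct <- object@contacts
  if (nrow(ct) && any(ct$dist > object@cutoff + 1e-12))
    return("stored distances must not exceed the cutoff")
  TRUE
})

#' RetentionSeries: per-frame native-contact survival
#'
#' @slot fraction numeric in [0, 1], one value per frame.
#' @slot surviving list (per frame) of row indices into the native set.
#' @slot native the native [ContactSet-class].
#' @export
setClass("RetentionSeries",
         representation(fraction = "numeric", surviving = "list",
                        native = "ContactSet"))

## ---------------------------------------------------------------------------
## Assembly containers
## ---------------------------------------------------------------------------

#' GraftSpec: one superposition-grafting step
#'
#' An incoming structure is rigidly placed by superposing the C-alpha atoms
#' of its shared domain onto the counterpart domain of the scaffold, after
#' which the requested chains of the incoming structure are appended to the
#' composite under fresh chain identifiers.
#'
#' @slot incoming the structure to place.
#' @slot scaffoldSelection [AtomSelection-class] picking the shared domain
#'   in the scaffold (chain + residue range; C-alpha pairing enforced).
#' @slot incomingSelection [AtomSelection-class] picking the shared domain
#'   in the incoming structure.
#' @slot keepChains chains of the incoming structure to add to the composite.
#' @slot warnRMSD fit-RMSD threshold (Angstrom) above which a warning is
#'   raised (never a failure).
#' @export
setClass("GraftSpec",
         representation(incoming = "Structure",
                        scaffoldSelection = "AtomSelection",
                        incomingSelection = "AtomSelection",
                        keepChains = "character",
                        warnRMSD = "numeric"))

#' @rdname GraftSpec-class
#' @param incoming,scaffoldSelection,incomingSelection,keepChains,warnRMSD
#'   see slots.
#' @return A [GraftSpec-class].
#' @export
graftSpec <- function(incoming, scaffoldSelection, incomingSelection,
                      keepChains, warnRMSD = 2.0) {
  new("GraftSpec", incoming = incoming,
      scaffoldSelection = scaffoldSelection,
      incomingSelection = incomingSelection,
      keepChains = as.character(keepChains), warnRMSD = warnRMSD)
}

#' CompositeComplex: a multi-protein model built by iterative grafting
#'
#' @slot structure the merged coordinates (unique chain ids).
#' @slot provenance data.frame with one row per graft: `step`, `fitRMSD`,
#'   `nFitAtoms`, `sourceChains`, `newChains`.
#' @slot transforms list of the rigid transforms applied (rotation,
#'   translation) per graft.
#' @slot clashes data.frame of inter-unit heavy-atom clashes.
#' @export
setClass("CompositeComplex",
         representation(structure = "Structure", provenance = "data.frame",
                        transforms = "list", clashes = "data.frame"))

setValidity("CompositeComplex", function(object) {
  if (nrow(object@provenance) != length(object@transforms))
    return("one transform must be logged per graft step")
  TRUE
})
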