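#' Atom table of a Structure
#' @param x a [Structure-class].
#' @return data.frame of atoms.
#' @export
atoms <- function(x) {
  stopifnot(is(x, "Structure"))
  x@atoms
}

#' Coordinate matrix of a Structure
#' @param x a [Structure-class].
#' @return numeric matrix (nAtoms x 3), Angstrom.
#' @export
coords <- function(x) {
  stopifnot(is(x, "Structure"))
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace the coordinates of a Structure
#' @param x a [Structure-class].
#' @param value numeric matrix (nAtoms x 3).
#' @return the updated Structure.
#' @export
`coords<-` <- function(x, value) {
  stopifnot(is(x, "Structure"), nrow(value) == nrow(x@atoms))
  x@atoms$x <- value[, 1]
  x@atoms$y <- value[, 2]
  x@atoms$z <- value[, 3]
  validObject(x)
  x
}

#' Chain identifiers of a Structure (order of first appearance)
#' @param x a [Structure-class].
#' @return character vector.
#' @export
chains <- function(x) unique(atoms(x)$chain)

#' Residue table of a Structure
#'
#' Unique ordered projection of the atom table onto residue identity.
#' @param x a [Structure-class].
#' @return data.frame with columns `chain`, `resseq`, `icode`, `resname`.
#' @export
residues <- function(x) {
  at <- atoms(x)
  key <- paste(at$chain, at$resseq, at$icode, sep = "|")
  idx <- !duplicated(key)
  out <- at[idx, c("chain", "resseq", "icode", "resname")]
  rownames(out) <- NULL
  out
}

#' Number of atoms
#' @param x a [Structure-class].
#' @return integer.
#' @export
nAtoms <- function(x) nrow(atoms(x))

#' Heavy-atom indicator
#' @param x a [Structure-class].
#' @return logical vector, TRUE where the element is not hydrogen.
#' @export
isHeavy <- function(x) toupper(atoms(x)$element) != "H"

#' Number of frames in a Trajectory
#' @param x a [Trajectory-class].
#' @return integer.
#' @export
nFrames <- function(x) {
  stopifnot(is(x, "Trajectory"))
  length(x@frames)
}

#' Extract one frame of a Trajectory
#' @param x a [Trajectory-class].
#' @param i frame index.
#' @return a [Structure-class].
#' @export
frame <- function(x, i) {
  stopifnot(is(x, "Trajectory"))
  if (i < 1L || i > length(x@frames)) stop("frame index out of range")
  x@frames[[i]]
}

#' Pose records of a PosePool
#' @param x a [PosePool-class].
#' @return list of [PoseRecord-class].
#' @export
poseRecords <- function(x) {
  stopifnot(is(x, "PosePool"))
  x@records
}

#' Labels of a pose pool
#' @param x a [PosePool-class].
#' @return character vector of `"ENGINE_m_n"` labels in pool order.
#' @export
poseLabels <- function(x) {
  vapply(poseRecords(x), function(r) poseLabel(r@engine, r@rank, r@protocol), "")
}

#' Engines of a pose pool
#' @param x a [PosePool-class].
#' @return character vector, one engine name per pose.
#' @export
poseEngines <- function(x) vapply(poseRecords(x), function(r) r@engine, "")

#' Number of poses in a pool
#' @param x a [PosePool-class].
#' @return integer.
#' @export
nPoses <- function(x) length(poseRecords(x))

#' RMSD matrix values
#' @param x an [RMSDMatrix-class].
#' @return labelled symmetric numeric matrix.
#' @export
rmsdValues <- function(x) {
  stopifnot(is(x, "RMSDMatrix"))
  x@values
}

#' Partition of poses at a given tree level
#' @param x a [ClusteringResult-class].
#' @param k number of clusters, 1..P.
#' @return named integer vector of cluster ids per pose label.
#' @export
assignmentsAt <- function(x, k) {
  stopifnot(is(x, "ClusteringResult"))
  P <- length(x@labels)
  if (k < 1L || k > P) stop("k must be in 1..", P)
  cl <- stats::cutree(x@tree, k = k)
  names(cl) <- x@labels
  cl
}

#' Optimal number of clusters from a Kelley profile
#' @param x a [KelleyProfile-class].
#' @return integer N.
#' @export
optimalK <- function(x) {
  stopifnot(is(x, "KelleyProfile"))
  x@optimalK
}

#' Kelley per-level penalty table
#' @param x a [KelleyProfile-class].
#' @return data.frame (`k`, `meanSpread`, `normSpread`, `penalty`).
#' @export
kelleyTable <- function(x) {
  stopifnot(is(x, "KelleyProfile"))
  x@profile
}

#' Per-cluster statistics table
#' @param x a [ClusterStats-class].
#' @return data.frame, one row per cluster.
#' @export
statsTable <- function(x) {
  stopifnot(is(x, "ClusterStats"))
  x@stats
}

#' Index of the most populated cluster
#' @param x a [ClusterStats-class].
#' @return integer cluster id.
#' @export
mainCluster <- function(x) {
  stopifnot(is(x, "ClusterStats"))
  x@mainCluster
}

#' Contact table of a ContactSet
#' @param x a [ContactSet-class].
#' @return data.frame of residue pairs with minimum heavy-atom distances.
#' @export
contactPairs <- function(x) {
  stopifnot(is(x, "ContactSet"))
  x@contacts
}

#' Number of contacts
#' @param x a [ContactSet-class].
#' @return integer.
#' @export
nContacts <- function(x) nrow(contactPairs(x))

#' Retention fractions per frame
#' @param x a [RetentionSeries-class].
#' @return numeric vector in [0, 1].
#' @export
retentionFraction <- function(x) {
  stopifnot(is(x, "RetentionSeries"))
  x@fraction
}

#' Merged structure of a composite complex
#' @param x a [CompositeComplex-class].
#' @return a [Structure-class].
#' @export
compositeStructure <- function(x) {
  stopifnot(is(x, "CompositeComplex"))
  x@structure
}

#' Graft provenance log
#' @param x a [CompositeComplex-class].
#' @return data.frame, one row per graft step.
#' @export
graftLog <- function(x) {
  stopifnot(is(x, "CompositeComplex"))
  x@provenance
}

## show methods ---------------------------------------------------------------

setMethod("show", "Structure", function(object) {
  at <- object@atoms
  cat(sprintf("Structure: %d atoms, %d residues, chains: %s\n",
              nrow(at), nrow(residues(object)),
              paste(unique(at$chain), collapse = ",")))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d atoms\n",
              length(object@frames), nrow(object@frames[[1L]]@atoms)))
})

setMethod("show", "PoseRecord", function(object) {
  cat(sprintf("PoseRecord %s: ", poseLabel(object@engine, object@rank,
                                           object@protocol)))
  show(object@structure)
})

setMethod("show", "PosePool", function(object) {
  eng <- table(vapply(object@records, function(r) r@engine, ""))
  cat(sprintf("PosePool: %d poses from %d engine(s) [%s]\n",
              length(object@records), length(eng),
              paste(sprintf("%s:%d", names(eng), as.integer(eng)),
                    collapse = ", ")))
})

setMethod("show", "RMSDMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat(sprintf("RMSDMatrix: %d x %d, range %.3f-%.3f A\n", nrow(v), ncol(v),
              if (length(off)) min(off) else 0,
              if (length(off)) max(off) else 0))
})

setMethod("show", "ClusteringResult", function(object) {
  cat(sprintf("ClusteringResult: %d poses, %s linkage\n",
              length(object@labels), object@linkage))
})

setMethod("show", "KelleyProfile", function(object) {
  cat(sprintf("KelleyProfile: optimal N = %d over %d poses (%d levels)\n",
              object@optimalK, object@nPoses, nrow(object@profile)))
})

setMethod("show", "ClusterStats", function(object) {
  s <- object@stats
  cat(sprintf("ClusterStats: %d clusters over %d poses; main cluster %d (%d members, centroid %s)\n",
              nrow(s), length(object@assignments), object@mainCluster,
              s$population[s$cluster == object@mainCluster],
              s$centroid[s$cluster == object@mainCluster]))
})

setMethod("show", "ComponentReport", function(object) {
  cat(sprintf("ComponentReport for cluster %d (nearest to centroid: %s)\n",
              object@cluster, object@nearestToCentroid))
  print(object@table, row.names = FALSE)
})

setMethod("show", "ContactSet", function(object) {
  cat(sprintf("ContactSet: %d residue-pair contacts at %.1f A cutoff\n",
              nrow(object@contacts), object@cutoff))
})

setMethod("show", "RetentionSeries", function(object) {
  f <- object@fraction
  cat(sprintf("RetentionSeries: %d frames, fraction %.2f -> %.2f (native: %d contacts)\n",
              length(f), f[1L], f[length(f)], nrow(object@native@contacts)))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A over %d atoms\n",
              object@rmsd, object@nAtoms))
})

setMethod("show", "CompositeComplex", function(object) {
  cat(sprintf("CompositeComplex: %d chains, %d atoms; %d graft(s), %d clash(es)\n",
              length(unique(object@structure@atoms$chain)),
              nrow(object@structure@atoms), nrow(object@provenance),
              nrow(object@clashes)))
})
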