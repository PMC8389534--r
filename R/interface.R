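## Interface characterization and trajectory analysis.

## Residue key helper (chain|resseq|icode).
.resKey <- function(chain, resseq, icode = "") paste(chain, resseq, icode,
                                                     sep = "|")

## Cell-list neighbour search: all (i, j, dist) pairs between coordinate
## sets A and B within cutoff. Voxels of edge = cutoff; each A voxel is
## tested against the 27 surrounding B voxels.
.pairsWithin <- function(A, B, cutoff) {
  cellA <- floor(A / cutoff)
  cellB <- floor(B / cutoff)
  keyB <- paste(cellB[, 1], cellB[, 2], cellB[, 3])
  bByCell <- split(seq_len(nrow(B)), keyB)
  keyA <- paste(cellA[, 1], cellA[, 2], cellA[, 3])
  aByCell <- split(seq_len(nrow(A)), keyA)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", length(aByCell))
  k <- 0L
  for (cell in names(aByCell)) {
    ai <- aByCell[[cell]]
    base <- as.integer(strsplit(cell, " ", fixed = TRUE)[[1L]])
    neigh <- paste(base[1L] + offs[, 1], base[2L] + offs[, 2],
                   base[3L] + offs[, 3])
    bi <- unlist(bByCell[neigh], use.names = FALSE)
    if (!length(bi)) next
    d2 <- outer(rowSums(A[ai, , drop = FALSE]^2),
                rowSums(B[bi, , drop = FALSE]^2), "+") -
      2 * A[ai, , drop = FALSE] %*% t(B[bi, , drop = FALSE])
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (!nrow(hit)) next
    k <- k + 1L
    out[[k]] <- data.frame(i = ai[hit[, 1L]], j = bi[hit[, 2L]],
                           dist = sqrt(pmax(0, d2[hit])))
  }
  if (!k) return(data.frame(i = integer(), j = integer(), dist = numeric()))
  do.call(rbind, out[seq_len(k)])
}

#' Detect interface residue contacts
#'
#' A residue pair across the partition is a contact when any heavy-atom
#' pair between the two residues lies within the cutoff (default 5
#' Angstrom); the minimum heavy-atom distance is recorded.
#'
#' @param structure a [Structure-class].
#' @param partition a [PartnerPartition-class].
#' @param cutoff distance cutoff in Angstrom.
#' @return A [ContactSet-class].
#' @export
detectContacts <- function(structure, partition, cutoff = 5.0) {
  at <- structure@atoms
  heavy <- isHeavy(structure)
  ia <- which(heavy & at$chain %in% partition@sideA)
  ib <- which(heavy & at$chain %in% partition@sideB)
  if (!length(ia) || !length(ib))
    stop("partition side has no atoms in the structure", call. = FALSE)
  hits <- .pairsWithin(coords(structure)[ia, , drop = FALSE],
                       coords(structure)[ib, , drop = FALSE], cutoff)
  if (!nrow(hits)) {
    ct <- data.frame(chainA = character(), resseqA = integer(),
                     resnameA = character(), chainB = character(),
                     resseqB = integer(), resnameB = character(),
                     dist = numeric())
    return(new("ContactSet", contacts = ct, cutoff = cutoff,
               partition = partition))
  }
  aIdx <- ia[hits$i]; bIdx <- ib[hits$j]
  pairKey <- paste(.resKey(at$chain[aIdx], at$resseq[aIdx], at$icode[aIdx]),
                   .resKey(at$chain[bIdx], at$resseq[bIdx], at$icode[bIdx]),
                   sep = "::")
  minD <- tapply(hits$dist, pairKey, min)
  rep1 <- !duplicated(pairKey)
  ct <- data.frame(chainA = at$chain[aIdx][rep1],
                   resseqA = at$resseq[aIdx][rep1],
                   resnameA = at$resname[aIdx][rep1],
                   chainB = at$chain[bIdx][rep1],
                   resseqB = at$resseq[bIdx][rep1],
                   resnameB = at$resname[bIdx][rep1],
                   dist = as.numeric(minD[pairKey[rep1]]),
                   stringsAsFactors = FALSE)
  ct <- ct[order(ct$chainA, ct$resseqA, ct$chainB, ct$resseqB), ]
  rownames(ct) <- NULL
  new("ContactSet", contacts = ct, cutoff = cutoff, partition = partition)
}

#' Native contacts anchored on hot-spot residues
#'
#' Contacts (as in [detectContacts()]) restricted to pairs in which at
#' least one member is a hot-spot residue: a residue whose alanine-scan
#' change in binding affinity exceeds the threshold (default > 10
#' kcal/mol). Hot spots on either side anchor contacts with all residues
#' of the other side.
#'
#' @param structure a [Structure-class].
#' @param partition a [PartnerPartition-class].
#' @param hotspots data.frame with columns `chain`, `resseq`, `resname`,
#'   `delta_aff` (see [loadHotspots()]).
#' @param threshold hot-spot inclusion threshold, kcal/mol (strict >).
#' @param cutoff contact distance cutoff, Angstrom.
#' @return A [ContactSet-class] (possibly empty, with a warning when no
#'   residue passes the threshold).
#' @export
nativeContacts <- function(structure, partition, hotspots, threshold = 10.0,
                           cutoff = 5.0) {
  res <- residues(structure)
  have <- .resKey(res$chain, res$resseq)
  want <- .resKey(hotspots$chain, hotspots$resseq)
  if (any(!want %in% have))
    stop("hotspot residue(s) absent from structure: ",
         paste(utils::head(want[!want %in% have], 3L), collapse = ", "),
         call. = FALSE)
  hot <- want[hotspots$delta_aff > threshold]
  ct <- detectContacts(structure, partition, cutoff)
  if (!length(hot)) {
    warning("no hotspot residue above threshold ", threshold, " kcal/mol")
    ct@contacts <- ct@contacts[0L, ]
    return(ct)
  }
  keep <- .resKey(ct@contacts$chainA, ct@contacts$resseqA) %in% hot |
    .resKey(ct@contacts$chainB, ct@contacts$resseqB) %in% hot
  ct@contacts <- ct@contacts[keep, ]
  rownames(ct@contacts) <- NULL
  ct
}

#' Native-contact retention over a trajectory
#'
#' Recomputes the native residue pairs in every frame and reports, per
#' frame, the fraction still within the cutoff and which pairs survive.
#'
#' @param trajectory a [Trajectory-class].
#' @param native the native [ContactSet-class] (e.g. from the docking
#'   pose / frame 1).
#' @param partition a [PartnerPartition-class].
#' @param cutoff distance cutoff, Angstrom; defaults to the native set's.
#' @return A [RetentionSeries-class].
#' @export
contactRetention <- function(trajectory, native, partition,
                             cutoff = native@cutoff) {
  nat <- native@contacts
  if (!nrow(nat)) stop("native contact set is empty", call. = FALSE)
  natKey <- paste(nat$chainA, nat$resseqA, nat$chainB, nat$resseqB)
  frames <- trajectory@frames
  fr <- numeric(length(frames))
  sv <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    ct <- detectContacts(frames[[t]], partition, cutoff)@contacts
    key <- paste(ct$chainA, ct$resseqA, ct$chainB, ct$resseqB)
    alive <- which(natKey %in% key)
    fr[t] <- length(alive) / nrow(nat)
    sv[[t]] <- alive
  }
  new("RetentionSeries", fraction = fr, surviving = sv, native = native)
}

## Donor/acceptor atom templates (N/O only; protonation-robust).
.HB_DONORS <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), TRP = "NE1", SER = "OG", THR = "OG1", TYR = "OH")
.HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))

.templateIdx <- function(at, templates, heavy) {
  hit <- heavy & at$name %in% templates$backbone &
    !(at$resname == "PRO" & at$name == "N")
  for (rn in setdiff(names(templates), "backbone"))
    hit <- hit | (heavy & at$resname == rn & at$name %in% templates[[rn]])
  which(hit)
}

.scopeFilter <- function(at, iD, iA, scope, partition) {
  if (scope == "within-chain") return(at$chain[iD] == at$chain[iA])
  if (scope == "cross-partition") {
    if (is.null(partition)) stop("cross-partition scope requires a partition",
                                 call. = FALSE)
    (at$chain[iD] %in% partition@sideA & at$chain[iA] %in% partition@sideB) |
      (at$chain[iD] %in% partition@sideB & at$chain[iA] %in% partition@sideA)
  } else rep(TRUE, length(iD))
}

#' Geometric hydrogen-bond detection
#'
#' Donor and acceptor heavy atoms are identified from residue templates
#' (backbone N/O plus side-chain N/O donors and acceptors). A donor-
#' acceptor pair in different residues is counted when the heavy-atom
#' distance is at most `distCutoff` (default 3.5 Angstrom) and, when
#' hydrogens are present on the donor, some D-H...A angle is at least
#' `angleCutoff` (default 120 degrees). Structures without hydrogens fall
#' back to the distance-only criterion, flagged via the `"criterion"`
#' attribute. Pairs closer than 2.5 Angstrom and the peptide-bonded
#' backbone N(i)...O(i-1) pair are excluded as covalent context.
#'
#' @param structure a [Structure-class].
#' @param scope `"all"`, `"within-chain"` or `"cross-partition"`.
#' @param partition required for `"cross-partition"` scope.
#' @param distCutoff donor-acceptor heavy-atom cutoff, Angstrom.
#' @param angleCutoff minimum D-H...A angle, degrees.
#' @return data.frame of bonds (donor and acceptor identity, distance,
#'   angle where computed); `nrow()` is the count. Attribute `"criterion"`
#'   is `"distance+angle"` or `"distance"`.
#' @export
detectHBonds <- function(structure,
                         scope = c("all", "within-chain", "cross-partition"),
                         partition = NULL, distCutoff = 3.5,
                         angleCutoff = 120) {
  scope <- match.arg(scope)
  at <- structure@atoms
  heavy <- isHeavy(structure)
  xyz <- coords(structure)
  iD <- .templateIdx(at, .HB_DONORS, heavy)
  iA <- .templateIdx(at, .HB_ACCEPTORS, heavy)
  empty <- data.frame(chainD = character(), resseqD = integer(),
                      resnameD = character(), atomD = character(),
                      chainA = character(), resseqA = integer(),
                      resnameA = character(), atomA = character(),
                      dist = numeric(), angle = numeric())
  hasH <- any(!heavy)
  criterion <- if (hasH) "distance+angle" else "distance"
  if (!length(iD) || !length(iA)) {
    attr(empty, "criterion") <- criterion
    return(empty)
  }
  hits <- .pairsWithin(xyz[iD, , drop = FALSE], xyz[iA, , drop = FALSE],
                       distCutoff)
  if (nrow(hits)) {
    d <- iD[hits$i]; a <- iA[hits$j]
    keep <- .resKey(at$chain[d], at$resseq[d], at$icode[d]) !=
      .resKey(at$chain[a], at$resseq[a], at$icode[a])
    ## covalent-context exclusions: the peptide-bonded backbone
    ## N(i)...O(i-1) pair sits ~2.2 A apart and is not an H-bond; likewise
    ## any D-A pair closer than 2.5 A is in bonded contact
    keep <- keep & hits$dist >= 2.5
    keep <- keep & !(at$name[d] == "N" & at$name[a] == "O" &
                       at$chain[d] == at$chain[a] &
                       at$resseq[d] == at$resseq[a] + 1L)
    keep <- keep & .scopeFilter(at, d, a, scope, partition)
    hits <- hits[keep, , drop = FALSE]
    d <- d[keep]; a <- a[keep]
  } else d <- a <- integer()
  angle <- rep(NA_real_, length(d))
  if (hasH && length(d)) {
    hIdx <- which(!heavy)
    keep <- logical(length(d))
    for (k in seq_along(d)) {
      ## hydrogens covalently bonded to this donor (within 1.25 A)
      dH <- sqrt(rowSums(sweep(xyz[hIdx, , drop = FALSE], 2,
                               xyz[d[k], ])^2))
      bonded <- hIdx[dH <= 1.25]
      if (!length(bonded)) { keep[k] <- TRUE; next }  # bare donor: distance only
      ## D-H...A angle = angle at H between H->D and H->A
      ang <- vapply(bonded, function(h) {
        u <- xyz[d[k], ] - xyz[h, ]
        w <- xyz[a[k], ] - xyz[h, ]
        acos(min(1, max(-1, sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) *
          180 / pi
      }, 0)
      angle[k] <- max(ang)
      keep[k] <- angle[k] >= angleCutoff
    }
    d <- d[keep]; a <- a[keep]
    hits <- hits[keep, , drop = FALSE]; angle <- angle[keep]
  }
  if (!length(d)) {
    attr(empty, "criterion") <- criterion
    return(empty)
  }
  out <- data.frame(chainD = at$chain[d], resseqD = at$resseq[d],
                    resnameD = at$resname[d], atomD = at$name[d],
                    chainA = at$chain[a], resseqA = at$resseq[a],
                    resnameA = at$resname[a], atomA = at$name[a],
                    dist = hits$dist, angle = angle,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chainD, out$resseqD, out$chainA, out$resseqA,
                   out$atomD, out$atomA), ]
  rownames(out) <- NULL
  attr(out, "criterion") <- criterion
  out
}

.SB_ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.SB_BASIC <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2"))

#' Geometric salt-bridge detection
#'
#' An Asp/Glu side-chain carboxylate oxygen within `cutoff` (default 4.0
#' Angstrom) of a Lys/Arg/His side-chain nitrogen counts as a salt bridge;
#' one bridge is reported per residue pair with the minimum atom distance.
#'
#' @inheritParams detectHBonds
#' @param cutoff O...N distance cutoff, Angstrom.
#' @return data.frame of bridges (acidic and basic residue identity,
#'   minimum distance); `nrow()` is the count.
#' @export
detectSaltBridges <- function(structure,
                              scope = c("all", "within-chain",
                                        "cross-partition"),
                              partition = NULL, cutoff = 4.0) {
  scope <- match.arg(scope)
  at <- structure@atoms
  heavy <- isHeavy(structure)
  xyz <- coords(structure)
  iAc <- .templateIdx(at, c(list(backbone = character()), .SB_ACIDIC), heavy)
  iBa <- .templateIdx(at, c(list(backbone = character()), .SB_BASIC), heavy)
  empty <- data.frame(chainAcid = character(), resseqAcid = integer(),
                      resnameAcid = character(), chainBase = character(),
                      resseqBase = integer(), resnameBase = character(),
                      dist = numeric())
  if (!length(iAc) || !length(iBa)) return(empty)
  hits <- .pairsWithin(xyz[iAc, , drop = FALSE], xyz[iBa, , drop = FALSE],
                       cutoff)
  if (!nrow(hits)) return(empty)
  ac <- iAc[hits$i]; ba <- iBa[hits$j]
  keep <- .scopeFilter(at, ac, ba, scope, partition)
  hits <- hits[keep, , drop = FALSE]; ac <- ac[keep]; ba <- ba[keep]
  if (!length(ac)) return(empty)
  pairKey <- paste(.resKey(at$chain[ac], at$resseq[ac], at$icode[ac]),
                   .resKey(at$chain[ba], at$resseq[ba], at$icode[ba]),
                   sep = "::")
  minD <- tapply(hits$dist, pairKey, min)
  rep1 <- !duplicated(pairKey)
  out <- data.frame(chainAcid = at$chain[ac][rep1],
                    resseqAcid = at$resseq[ac][rep1],
                    resnameAcid = at$resname[ac][rep1],
                    chainBase = at$chain[ba][rep1],
                    resseqBase = at$resseq[ba][rep1],
                    resnameBase = at$resname[ba][rep1],
                    dist = as.numeric(minD[pairKey[rep1]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chainAcid, out$resseqAcid, out$chainBase,
                   out$resseqBase), ]
  rownames(out) <- NULL
  out
}

#' Per-frame RMSD time series
#'
#' Each frame is superposed (Kabsch) onto the chosen reference frame over
#' the selection (C-alpha by default) before the RMSD is measured.
#'
#' @param trajectory a [Trajectory-class].
#' @param referenceFrame index of the reference frame (default 1).
#' @param selection an [AtomSelection-class].
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsdTimeseries <- function(trajectory, referenceFrame = 1L,
                           selection = atomSelection("ca")) {
  frames <- trajectory@frames
  if (referenceFrame < 1L || referenceFrame > length(frames))
    stop("reference frame index out of range", call. = FALSE)
  ref <- frames[[referenceFrame]]
  vapply(frames, function(f) rmsd(f, ref, selection, superpose = TRUE), 0)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto their mean structure (the mean is refined
#' over `passes` superposition rounds, starting from the first frame);
#' the RMSF of a residue is the root-mean-square deviation of its
#' selected-atom centroid from its time-average position.
#'
#' @param trajectory a [Trajectory-class] with at least 2 frames.
#' @param selection an [AtomSelection-class] (default C-alpha).
#' @param passes mean-structure refinement rounds.
#' @return data.frame with columns `chain`, `resseq`, `resname`, `rmsf`.
#' @export
calcRMSF <- function(trajectory, selection = atomSelection("ca"),
                     passes = 2L) {
  frames <- trajectory@frames
  if (length(frames) < 2L) stop("RMSF requires at least 2 frames",
                                call. = FALSE)
  idx <- .selectIdx(frames[[1L]], selection)
  if (!length(idx)) stop("empty selection for RMSF", call. = FALSE)
  X <- lapply(frames, function(f) coords(f)[idx, , drop = FALSE])
  ref <- X[[1L]]
  for (p in seq_len(passes)) {
    X <- lapply(X, function(m) {
      fit <- .kabsch(m, ref)
      sweep(m %*% fit$rotation, 2, fit$translation, "+")
    })
    ref <- Reduce(`+`, X) / length(X)
  }
  at <- frames[[1L]]@atoms[idx, ]
  rkey <- .resKey(at$chain, at$resseq, at$icode)
  groups <- split(seq_along(rkey), factor(rkey, levels = unique(rkey)))
  ## per-frame residue centroids
  cent <- lapply(X, function(m)
    t(vapply(groups, function(g) colMeans(m[g, , drop = FALSE]),
             numeric(3L))))
  avg <- Reduce(`+`, cent) / length(cent)
  dev2 <- Reduce(`+`, lapply(cent, function(m) rowSums((m - avg)^2))) /
    length(cent)
  first <- vapply(groups, `[`, 0L, 1L)
  data.frame(chain = at$chain[first], resseq = at$resseq[first],
             resname = at$resname[first], rmsf = sqrt(dev2),
             row.names = NULL, stringsAsFactors = FALSE)
}
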