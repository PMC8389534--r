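## Superposition, RMSD and chain-correspondence machinery.

## Atom indices selected by an AtomSelection (integer, in structure order).
.selectIdx <- function(structure, selection) {
  at <- structure@atoms
  keep <- switch(selection@mode,
                 heavy = isHeavy(structure),
                 ca = at$name == "CA" & isHeavy(structure),
                 all = rep(TRUE, nrow(at)),
                 custom = at$name %in% selection@atomNames)
  if (length(selection@chains))
    keep <- keep & at$chain %in% selection@chains
  rf <- selection@residueFilter
  if (nrow(rf)) {
    inRange <- rep(FALSE, nrow(at))
    for (i in seq_len(nrow(rf)))
      inRange <- inRange | (at$chain == rf$chain[i] &
                              at$resseq >= rf$from[i] &
                              at$resseq <= rf$to[i])
    keep <- keep & inRange
  }
  which(keep)
}

## Effective mobile->reference chain map as a named character vector.
.effectiveMap <- function(mobile, reference, mapping) {
  p <- mapping@pairs
  if (nrow(p)) return(stats::setNames(p$to, p$from))
  shared <- intersect(chains(mobile), chains(reference))
  stats::setNames(shared, shared)
}

## All chain maps allowed by the permutable groups (list of named vectors).
.candidateMaps <- function(baseMap, permutableGroups) {
  maps <- list(baseMap)
  for (grp in permutableGroups) {
    grp <- intersect(grp, unname(baseMap))
    if (length(grp) < 2L) next
    perms <- .permutations(grp)
    expanded <- list()
    for (m in maps) {
      affected <- names(m)[m %in% grp]
      ord <- match(m[affected], grp)
      for (p in perms) {
        m2 <- m
        m2[affected] <- p[ord]
        expanded[[length(expanded) + 1L]] <- m2
      }
    }
    maps <- expanded
  }
  unique(maps)
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

## Pair atoms of mobile and reference under one chain map + selection.
## Returns list(ia, ib) of equal-length index vectors (reference order).
.pairAtoms <- function(mobile, reference, selection, chainMap) {
  ia <- .selectIdx(mobile, selection)
  ib <- .selectIdx(reference, selection)
  atA <- mobile@atoms[ia, ]
  atB <- reference@atoms[ib, ]
  mappedChain <- chainMap[atA$chain]
  keepA <- !is.na(mappedChain)
  keyA <- paste(mappedChain[keepA], atA$resseq[keepA], atA$icode[keepA],
                atA$name[keepA], sep = "|")
  keyB <- paste(atB$chain, atB$resseq, atB$icode, atB$name, sep = "|")
  common <- intersect(keyB, keyA)
  if (!length(common)) return(NULL)
  list(ia = ia[keepA][match(common, keyA)], ib = ib[match(common, keyB)])
}

#' Common atom roster across structures
#'
#' Returns, for each structure, the indices of atoms present (by
#' chain/resseq/icode/name) in every structure under the selection; atoms
#' missing from any structure are dropped everywhere (with a message when
#' any are dropped).
#'
#' @param structures list of at least two [Structure-class] objects.
#' @param selection an [AtomSelection-class].
#' @return list of integer index vectors, one per structure, all the same
#'   length and in a common key order.
#' @export
commonAtomRoster <- function(structures, selection = atomSelection("heavy")) {
  stopifnot(length(structures) >= 2L)
  idx <- lapply(structures, .selectIdx, selection = selection)
  keys <- mapply(function(s, i) {
    at <- s@atoms[i, ]
    paste(at$chain, at$resseq, at$icode, at$name, sep = "|")
  }, structures, idx, SIMPLIFY = FALSE)
  common <- Reduce(intersect, keys)
  if (!length(common))
    stop("empty common atom roster across structures", call. = FALSE)
  dropped <- sum(lengths(keys)) - length(common) * length(keys)
  if (dropped > 0L)
    message(sprintf("common roster: %d atoms retained; %d atom entries dropped",
                    length(common), dropped))
  mapply(function(k, i) i[match(common, k)], keys, idx, SIMPLIFY = FALSE)
}

## Core Kabsch solver on paired n x 3 coordinate matrices.
## Returns rotation R (x %*% R), translation t, and rmsd.
.kabsch <- function(P, Q) {
  n <- nrow(P)
  if (n < 3L) stop("degenerate superposition: fewer than 3 paired atoms",
                   call. = FALSE)
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP); Qc <- sweep(Q, 2, cQ)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2L] <= max(sv$d[1L], 1) * 1e-10)
    stop("degenerate superposition: collinear atom set", call. = FALSE)
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  ## explicit residual (the closed-form trace expression cancels
  ## catastrophically near zero)
  msd <- mean(rowSums((Pc %*% R - Qc)^2))
  list(rotation = R, translation = as.numeric(cQ - cP %*% R),
       rmsd = sqrt(msd))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares optimal proper rotation + translation of `mobile` onto
#' `reference` over the paired atom roster. When the mapping declares
#' `permutableGroups` (chemically identical chains), every allowed chain
#' permutation is evaluated and the minimum-RMSD one returned. Mirror
#' solutions are rejected (det = +1 enforced).
#'
#' @param mobile,reference [Structure-class] objects.
#' @param selection an [AtomSelection-class]; default all heavy atoms.
#' @param mapping a [ChainMapping-class]; default identity over shared
#'   chains.
#' @return A [SuperpositionResult-class]. Apply with [transformStructure()].
#' @export
kabschSuperpose <- function(mobile, reference,
                            selection = atomSelection("heavy"),
                            mapping = chainMapping()) {
  baseMap <- .effectiveMap(mobile, reference, mapping)
  if (!length(baseMap))
    stop("no mappable chains between structures", call. = FALSE)
  best <- NULL
  for (cm in .candidateMaps(baseMap, mapping@permutableGroups)) {
    pr <- .pairAtoms(mobile, reference, selection, cm)
    if (is.null(pr)) next
    fit <- .kabsch(coords(mobile)[pr$ia, , drop = FALSE],
                   coords(reference)[pr$ib, , drop = FALSE])
    if (is.null(best) || fit$rmsd < best$rmsd)
      best <- c(fit, list(n = length(pr$ia)))
  }
  if (is.null(best))
    stop("empty paired atom roster under the chain mapping", call. = FALSE)
  new("SuperpositionResult", rotation = best$rotation,
      translation = best$translation, rmsd = best$rmsd,
      nAtoms = as.integer(best$n))
}

#' Root-mean-square deviation between two structures
#'
#' With `superpose = TRUE` (default) the optimal rigid transform is removed
#' first; with `FALSE` the in-place RMSD over the paired roster is
#' returned. Permutable chain groups are honoured in both modes.
#'
#' @inheritParams kabschSuperpose
#' @param a,b [Structure-class] objects.
#' @param superpose remove the optimal rigid transform first?
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, selection = atomSelection("heavy"),
                 mapping = chainMapping(), superpose = TRUE) {
  if (superpose)
    return(kabschSuperpose(a, b, selection, mapping)@rmsd)
  baseMap <- .effectiveMap(a, b, mapping)
  if (!length(baseMap)) stop("no mappable chains between structures",
                             call. = FALSE)
  best <- Inf
  for (cm in .candidateMaps(baseMap, mapping@permutableGroups)) {
    pr <- .pairAtoms(a, b, selection, cm)
    if (is.null(pr)) next
    d2 <- rowSums((coords(a)[pr$ia, , drop = FALSE] -
                     coords(b)[pr$ib, , drop = FALSE])^2)
    best <- min(best, sqrt(mean(d2)))
  }
  if (!is.finite(best))
    stop("empty paired atom roster under the chain mapping", call. = FALSE)
  best
}

#' Apply a rigid transform to a Structure
#'
#' @param structure a [Structure-class].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector (Angstrom).
#' @return the transformed [Structure-class]
#'   (coordinates `x %*% rotation + translation`).
#' @export
transformStructure <- function(structure, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  xyz <- coords(structure) %*% rotation
  xyz <- sweep(xyz, 2, translation, "+")
  coords(structure) <- xyz
  structure
}

#' Superpose a mobile structure onto a reference
#'
#' Convenience wrapper: computes [kabschSuperpose()] and returns the
#' transformed mobile structure with the fit attached as attribute `"fit"`.
#'
#' @inheritParams kabschSuperpose
#' @return the transformed mobile [Structure-class].
#' @export
superpose <- function(mobile, reference, selection = atomSelection("heavy"),
                      mapping = chainMapping()) {
  fit <- kabschSuperpose(mobile, reference, selection, mapping)
  out <- transformStructure(mobile, fit@rotation, fit@translation)
  attr(out, "fit") <- fit
  out
}
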