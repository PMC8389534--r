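## Composite-model assembly by iterative domain-superposition grafting.

.CHAIN_POOL <- c(LETTERS, letters, as.character(0:9))

.nextFreeChains <- function(used, n) {
  free <- setdiff(.CHAIN_POOL, used)
  if (length(free) < n) stop("chain identifier pool exhausted", call. = FALSE)
  free[seq_len(n)]
}

## C-alpha pairing between two domain selections. Pairs by
## (resseq, icode, name) key when the chains differ; falls back to
## positional pairing when keys do not intersect but counts match.
.graftPairing <- function(scaffold, incoming, scafSel, incSel) {
  caOnly <- function(sel) {
    s <- sel
    s@mode <- "custom"
    s@atomNames <- "CA"
    s
  }
  is <- .selectIdx(scaffold, caOnly(scafSel))
  ii <- .selectIdx(incoming, caOnly(incSel))
  if (!length(is) || !length(ii))
    stop("graft error: empty shared-domain C-alpha selection", call. = FALSE)
  atS <- scaffold@atoms[is, ]
  atI <- incoming@atoms[ii, ]
  keyS <- paste(atS$resseq, atS$icode)
  keyI <- paste(atI$resseq, atI$icode)
  common <- intersect(keyS, keyI)
  if (length(common) >= 3L)
    return(list(is = is[match(common, keyS)], ii = ii[match(common, keyI)]))
  if (length(is) == length(ii)) return(list(is = is, ii = ii))
  stop("graft error: shared selections not alignable (",
       length(is), " vs ", length(ii), " C-alpha atoms, no residue overlap)",
       call. = FALSE)
}

#' Graft an incoming structure onto a scaffold
#'
#' Superposes the C-alpha atoms of the incoming structure's shared domain
#' onto the counterpart domain of the scaffold, applies the resulting
#' rigid transform to the whole incoming structure, and appends the
#' requested chains under fresh chain identifiers (deterministic
#' next-free-letter policy). The fit RMSD is recorded; above `warnRMSD` a
#' warning is raised but the graft proceeds. No steric relaxation is
#' performed; use [clashCheck()] to inspect the result.
#'
#' @param scaffold a [Structure-class] or [CompositeComplex-class].
#' @param spec a [GraftSpec-class].
#' @return A [CompositeComplex-class].
#' @export
graft <- function(scaffold, spec) {
  if (is(scaffold, "CompositeComplex")) {
    comp <- scaffold
    base <- comp@structure
  } else {
    stopifnot(is(scaffold, "Structure"))
    base <- scaffold
    comp <- new("CompositeComplex", structure = base,
                provenance = data.frame(step = integer(),
                                        fitRMSD = numeric(),
                                        nFitAtoms = integer(),
                                        sourceChains = character(),
                                        newChains = character(),
                                        stringsAsFactors = FALSE),
                transforms = list(), clashes = data.frame())
  }
  pr <- .graftPairing(base, spec@incoming, spec@scaffoldSelection,
                      spec@incomingSelection)
  fit <- .kabsch(coords(spec@incoming)[pr$ii, , drop = FALSE],
                 coords(base)[pr$is, , drop = FALSE])
  if (fit$rmsd > spec@warnRMSD)
    warning(sprintf("graft fit RMSD %.2f A exceeds %.2f A", fit$rmsd,
                    spec@warnRMSD))
  placed <- transformStructure(spec@incoming, fit$rotation, fit$translation)
  keep <- spec@keepChains
  missing <- setdiff(keep, chains(placed))
  if (length(missing))
    stop("graft error: keepChains not in incoming structure: ",
         paste(missing, collapse = ","), call. = FALSE)
  add <- placed@atoms[placed@atoms$chain %in% keep, , drop = FALSE]
  newIds <- .nextFreeChains(unique(base@atoms$chain), length(keep))
  add$chain <- newIds[match(add$chain, keep)]
  merged <- rbind(base@atoms, add)
  merged$serial <- seq_len(nrow(merged))
  step <- nrow(comp@provenance) + 1L
  comp@structure <- Structure(merged)
  comp@provenance <- rbind(comp@provenance, data.frame(
    step = step, fitRMSD = fit$rmsd, nFitAtoms = length(pr$is),
    sourceChains = paste(keep, collapse = ","),
    newChains = paste(newIds, collapse = ","),
    stringsAsFactors = FALSE))
  comp@transforms <- c(comp@transforms,
                       list(list(rotation = fit$rotation,
                                 translation = fit$translation)))
  validObject(comp)
  comp
}

## chain -> unit id (0 = original scaffold, i = chains added by graft i)
.unitOfChain <- function(composite) {
  allChains <- unique(composite@structure@atoms$chain)
  unit <- stats::setNames(rep(0L, length(allChains)), allChains)
  pv <- composite@provenance
  for (i in seq_len(nrow(pv))) {
    for (ch in strsplit(pv$newChains[i], ",", fixed = TRUE)[[1L]])
      unit[ch] <- i
  }
  unit
}

#' Inter-unit steric clash report
#'
#' Lists heavy-atom pairs closer than the cutoff (default 2.0 Angstrom)
#' between different units of a composite (the original scaffold and each
#' grafted addition are separate units); intra-unit pairs are excluded.
#'
#' @param composite a [CompositeComplex-class].
#' @param cutoff clash distance, Angstrom.
#' @return data.frame of clashing atom pairs with distances.
#' @export
clashCheck <- function(composite, cutoff = 2.0) {
  stopifnot(is(composite, "CompositeComplex"))
  s <- composite@structure
  at <- s@atoms
  heavy <- which(isHeavy(s))
  unit <- .unitOfChain(composite)[at$chain[heavy]]
  xyz <- coords(s)[heavy, , drop = FALSE]
  hits <- .pairsWithin(xyz, xyz, cutoff)
  hits <- hits[hits$i < hits$j & unit[hits$i] != unit[hits$j], ,
               drop = FALSE]
  i <- heavy[hits$i]; j <- heavy[hits$j]
  out <- data.frame(chain1 = at$chain[i], resseq1 = at$resseq[i],
                    atom1 = at$name[i], chain2 = at$chain[j],
                    resseq2 = at$resseq[j], atom2 = at$name[j],
                    dist = hits$dist, stringsAsFactors = FALSE)
  out[order(out$dist), , drop = FALSE]
}

#' Build a composite unit from an ordered graft recipe
#'
#' Applies each [GraftSpec-class] in sequence (each step superposes its
#' shared domain onto the evolving composite), then attaches a final
#' clash report. An empty recipe returns the scaffold unchanged as a
#' composite.
#'
#' @param scaffold the starting [Structure-class].
#' @param recipe list of [GraftSpec-class] objects, applied in order.
#' @param clashCutoff cutoff for the final clash report, Angstrom.
#' @return A [CompositeComplex-class] with full provenance.
#' @export
buildUnit <- function(scaffold, recipe = list(), clashCutoff = 2.0) {
  comp <- new("CompositeComplex", structure = scaffold,
              provenance = data.frame(step = integer(), fitRMSD = numeric(),
                                      nFitAtoms = integer(),
                                      sourceChains = character(),
                                      newChains = character(),
                                      stringsAsFactors = FALSE),
              transforms = list(), clashes = data.frame())
  for (i in seq_along(recipe)) {
    comp <- tryCatch(graft(comp, recipe[[i]]), error = function(e)
      stop(sprintf("graft step %d failed: %s", i, conditionMessage(e)),
           call. = FALSE))
  }
  comp@clashes <- clashCheck(comp, clashCutoff)
  comp
}
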