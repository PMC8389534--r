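## Structure I/O: fixed-column PDB via bio3d, pose manifests, hotspot tables.

.AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
          "MSE","SEC","PYL")

## Split raw PDB lines into MODEL blocks; a file without MODEL records is a
## single block. Returns list of character vectors of ATOM/HETATM/TER lines.
.modelBlocks <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
}

## Parse one model block with bio3d and convert to Structure.
.parseBlock <- function(lines, keepHet = FALSE) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(c(lines, "END"), tf)
  pdb <- bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  ## protein records only: ATOM plus HETATM with standard residue names
  ## (modified residues such as MSE); waters and ligands excluded
  keep <- at$type == "ATOM" | (keepHet & at$resid %in% .AA3) |
    (at$type == "HETATM" & at$resid %in% .AA3)
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("no protein atoms in PDB input", call. = FALSE)
  ## altloc: keep highest occupancy; tie -> lexicographically first altloc id
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety, sep = "|")
  if (anyDuplicated(key)) {
    ord <- order(key, -occ, alt)
    at <- at[ord, , drop = FALSE][!duplicated(sort(key)), , drop = FALSE]
    at <- at[order(match(paste(at$chain, at$resno,
                               ifelse(is.na(at$insert), "", at$insert),
                               at$elety, sep = "|"), unique(key))), ,
             drop = FALSE]
  }
  el <- at$elesy
  el[is.na(el) | !nzchar(trimws(el))] <- NA
  el <- ifelse(is.na(el), .guessElement(at$elety), trimws(el))
  Structure(data.frame(
    serial = at$eleno, name = at$elety, element = el, resname = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resseq = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE))
}

#' Read a PDB file
#'
#' Parses fixed-column PDB records. Waters and non-protein HETATM records
#' are excluded; alternate locations are resolved to the highest-occupancy
#' conformer (ties to the alphabetically first altloc id). `MODEL` blocks
#' yield a [Trajectory-class] under `modelPolicy = "all"`; under `"first"`
#' only the first model is read.
#'
#' @param path PDB file path.
#' @param modelPolicy `"first"` (default) or `"all"`.
#' @return A [Structure-class], or a [Trajectory-class] when
#'   `modelPolicy = "all"` and the file holds MODEL blocks.
#' @export
readPDB <- function(path, modelPolicy = c("first", "all")) {
  modelPolicy <- match.arg(modelPolicy)
  if (!file.exists(path)) stop("cannot read PDB file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM|HETATM)", lines)))
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  blocks <- .modelBlocks(lines)
  if (modelPolicy == "first" || length(blocks) == 1L) {
    s <- .parseBlock(blocks[[1L]])
    if (modelPolicy == "all" && length(blocks) == 1L)
      return(Trajectory(list(s)))
    return(s)
  }
  frames <- lapply(blocks, .parseBlock)
  key0 <- .rosterKey(frames[[1L]])
  for (i in seq_along(frames)[-1L]) {
    if (!identical(.rosterKey(frames[[i]]), key0))
      stop(sprintf("atom roster of MODEL %d differs from MODEL 1 in %s",
                   i, path), call. = FALSE)
  }
  Trajectory(frames)
}

#' Write a Structure, Trajectory or CompositeComplex as PDB
#'
#' Round-trip safe at PDB precision: re-reading reproduces atom count,
#' names, residue numbering and coordinates to 3 decimals. Chains are
#' TER-separated; trajectories are written as MODEL/ENDMDL blocks. Atom
#' serials are renumbered sequentially; beyond 99999 atoms they wrap with a
#' message (fixed-column serial overflow policy).
#'
#' @param x a [Structure-class], [Trajectory-class] or
#'   [CompositeComplex-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
  if (is(x, "CompositeComplex")) x <- x@structure
  if (is(x, "Trajectory")) {
    s <- x@frames[[1L]]
    xyz <- do.call(rbind, lapply(x@frames, function(f) as.vector(t(coords(f)))))
  } else {
    stopifnot(is(x, "Structure"))
    s <- x
    xyz <- matrix(as.vector(t(coords(s))), nrow = 1L)
  }
  at <- s@atoms
  n <- nrow(at)
  serial <- seq_len(n)
  if (n > 99999L) {
    message("more than 99999 atoms: serials wrap modulo 99999")
    serial <- (serial - 1L) %% 99999L + 1L
  }
  bio3d::write.pdb(file = path, xyz = bio3d::as.xyz(xyz),
                   type = rep("ATOM", n), eleno = serial, elety = at$name,
                   resid = at$resname, chain = at$chain, resno = at$resseq,
                   insert = ifelse(nzchar(at$icode), at$icode, NA),
                   o = at$occ, b = rep(0, n), elesy = at$element,
                   chainter = TRUE)
  invisible(path)
}

## Delimited table reader tolerant of comma or tab separation.
.readDelim <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, strip.white = TRUE)
}

#' Load a pose manifest
#'
#' A manifest is delimited text (comma or tab) with header columns `path`,
#' `engine`, `rank`, `protocol`; one docked, refined pose per row. Relative
#' paths are resolved against the manifest's directory. Records are
#' returned in file order.
#'
#' @param path manifest file path.
#' @return A [PosePool-class].
#' @export
loadManifest <- function(path) {
  m <- .readDelim(path)
  need <- c("path", "engine", "rank", "protocol")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(m)) stop("empty manifest: ", path, call. = FALSE)
  key <- paste(m$engine, m$rank, m$protocol, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (engine, rank, protocol) in manifest: ",
         key[duplicated(key)][1L], call. = FALSE)
  base <- dirname(normalizePath(path))
  files <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path,
                  file.path(base, m$path))
  missing <- !file.exists(files)
  if (any(missing))
    stop("manifest references missing file(s): ",
         paste(utils::head(m$path[missing], 3L), collapse = ", "),
         call. = FALSE)
  recs <- lapply(seq_len(nrow(m)), function(i)
    PoseRecord(readPDB(files[i]), m$engine[i], m$rank[i], m$protocol[i]))
  PosePool(recs)
}

#' Load a hot-spot residue table
#'
#' Delimited text with header `chain`, `resseq`, `resname`, `delta_aff`
#' giving, per interface residue, the change in binding affinity upon
#' alanine substitution (kcal/mol). These values are consumed as input
#' (e.g. from published alanine-scanning tables); the package never
#' computes them.
#'
#' @param path file path.
#' @return data.frame with the four columns above.
#' @export
loadHotspots <- function(path) {
  h <- .readDelim(path)
  need <- c("chain", "resseq", "resname", "delta_aff")
  if (!all(need %in% names(h)))
    stop("hotspot table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(h$delta_aff)))
    stop("non-finite delta_aff values", call. = FALSE)
  h[, need]
}
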