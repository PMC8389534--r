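# Fixtures and independent oracles used across test files.

# Minimal structure from explicit atom rows.
atomRow <- function(name, element, resname, chain, resseq, x, y, z) {
  data.frame(name = name, element = element, resname = resname,
             chain = chain, resseq = resseq, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# Two single-residue chains whose closest heavy atoms sit `gap` apart.
gapComplex <- function(gap) {
  Structure(rbind(
    atomRow("CA", "C", "GLY", "A", 1, 0, 0, 0),
    atomRow("CA", "C", "GLY", "B", 1, gap, 0, 0)))
}

randomRotation <- function() {
  repeat {
    q <- rnorm(4)
    if (sum(q^2) > 1e-8) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Independent no-fit RMSD oracle: explicit loop over atom pairs matched by
# (chain, resseq, icode, name).
bruteNoFitRMSD <- function(a, b) {
  atA <- atoms(a)[isHeavy(a), ]
  atB <- atoms(b)[isHeavy(b), ]
  keyA <- paste(atA$chain, atA$resseq, atA$icode, atA$name)
  keyB <- paste(atB$chain, atB$resseq, atB$icode, atB$name)
  common <- intersect(keyA, keyB)
  ss <- 0
  for (k in common) {
    pa <- unlist(atA[match(k, keyA), c("x", "y", "z")])
    pb <- unlist(atB[match(k, keyB), c("x", "y", "z")])
    ss <- ss + sum((pa - pb)^2)
  }
  sqrt(ss / length(common))
}

# O(n^2) contact oracle: full residue-pair double loop, no spatial index.
bruteContacts <- function(structure, sideA, sideB, cutoff) {
  at <- atoms(structure)[isHeavy(structure), ]
  a <- at[at$chain %in% sideA, ]
  b <- at[at$chain %in% sideB, ]
  resA <- unique(paste(a$chain, a$resseq))
  resB <- unique(paste(b$chain, b$resseq))
  out <- character()
  for (ra in resA) for (rb in resB) {
    pa <- as.matrix(a[paste(a$chain, a$resseq) == ra, c("x", "y", "z")])
    pb <- as.matrix(b[paste(b$chain, b$resseq) == rb, c("x", "y", "z")])
    dmin <- Inf
    for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb)))
      dmin <- min(dmin, sqrt(sum((pa[i, ] - pb[j, ])^2)))
    if (dmin <= cutoff) out <- c(out, paste(ra, rb, sep = "::"))
  }
  sort(out)
}

contactKeys <- function(cs) {
  ct <- contactPairs(cs)
  sort(paste(paste(ct$chainA, ct$resseqA), paste(ct$chainB, ct$resseqB),
             sep = "::"))
}

# Adjusted-for-nothing Rand index of two labelings (1.0 = identical
# partitions up to relabeling).
randIndex <- function(x, y) {
  x <- unname(x); y <- unname(y)
  n <- length(x)
  same <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- same + ((x[i] == x[j]) == (y[i] == y[j]))
  }
  same / (n * (n - 1) / 2)
}

# Write a PDB text fixture, returning its path.
writePDBText <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

pdbAtomLine <- function(serial, name, resname, chain, resseq, x, y, z,
                        occ = 1, alt = " ", element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt,
          resname, chain, resseq, x, y, z, occ, 0, element)
}
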