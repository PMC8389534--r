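## Deterministic fixture generator: toy two-chain complexes with ideal
## backbone geometry, rigid-body perturbed pose pools with planted cluster
## structure and engine labels, and synthetic trajectories.

## Place atom D bonded to c with given bond length, angle b-c-D (deg) and
## dihedral a-b-c-D (deg); the NeRF internal-coordinate construction.
.placeAtom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  cbind(bc, m, n) %*% d2 + c
}

## Ideal poly-alanine backbone (N, CA, C, O, CB) for given phi/psi.
.buildChain <- function(n, phi, psi, chain) {
  rows <- vector("list", n * 5L)
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- .placeAtom(c(0, 1, 0), N, CA, 1.525, 111.2, 60)
  k <- 0L
  addRow <- function(name, el, xyz, res) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(serial = k, name = name, element = el,
                             resname = "ALA", chain = chain, resseq = res,
                             icode = "", x = xyz[1], y = xyz[2], z = xyz[3],
                             occ = 1, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    O <- .placeAtom(N, CA, C, 1.231, 120.8, psi + 180)
    CB <- .placeAtom(C, N, CA, 1.521, 110.5, 122.6)
    addRow("N", "N", N, i)
    addRow("CA", "C", CA, i)
    addRow("C", "C", C, i)
    addRow("O", "O", O, i)
    addRow("CB", "C", CB, i)
    if (i < n) {
      N1 <- .placeAtom(N, CA, C, 1.329, 116.2, psi)
      CA1 <- .placeAtom(CA, C, N1, 1.458, 121.7, 180)
      C1 <- .placeAtom(C, N1, CA1, 1.525, 111.2, phi)
      N <- N1; CA <- CA1; C <- C1
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

.principalAxis <- function(xyz) {
  sv <- svd(sweep(xyz, 2, colMeans(xyz)))
  sv$v[, 1L]
}

#' Generate a toy two-chain complex with ideal backbone geometry
#'
#' Builds two parallel poly-alanine chains (A and B) with ideal bond
#' lengths/angles and helix (phi = -57, psi = -47; rise about 1.5
#' Angstrom per residue) or strand (phi = -139, psi = 135) dihedrals,
#' separated by `separation` Angstrom between their axes (default 8.5, so
#' that an interface of heavy-atom contacts comfortably inside a
#' 5-Angstrom cutoff exists). With `charged = TRUE` the middle residue of chain
#' A becomes a lysine (adds NZ) and of chain B a glutamate (adds
#' OE1/OE2), placed 3 Angstrom apart across the interface for
#' salt-bridge/H-bond fixtures. Deterministic for a given argument set.
#'
#' @param nResiduesPerChain residues per chain (>= 4).
#' @param geometry `"helix"` or `"strand"`.
#' @param separation inter-axis distance, Angstrom.
#' @param charged add the Lys/Glu interface pair?
#' @param seed accepted for interface symmetry with the other generators;
#'   the construction itself is deterministic.
#' @return A [Structure-class] with chains A and B.
#' @export
makeToyComplex <- function(nResiduesPerChain = 20L,
                           geometry = c("helix", "strand"),
                           separation = 8.5, charged = FALSE, seed = 1L) {
  geometry <- match.arg(geometry)
  n <- as.integer(nResiduesPerChain)
  if (n < 4L) stop("nResiduesPerChain must be >= 4", call. = FALSE)
  ang <- if (geometry == "helix") c(-57, -47) else c(-139, 135)
  chA <- .buildChain(n, ang[1L], ang[2L], "A")
  ## chain B: translated copy, perpendicular to the chain axis
  axis <- .principalAxis(as.matrix(chA[chA$name == "CA", c("x", "y", "z")]))
  perp <- c(-axis[2L], axis[1L], 0)
  if (sqrt(sum(perp^2)) < 1e-6) perp <- c(1, 0, 0)
  perp <- perp / sqrt(sum(perp^2))
  chB <- chA
  chB$chain <- "B"
  chB[, c("x", "y", "z")] <- sweep(as.matrix(chA[, c("x", "y", "z")]), 2,
                                   separation * perp, "+")
  at <- rbind(chA, chB)
  if (charged) {
    mid <- (n + 1L) %/% 2L
    at$resname[at$chain == "A" & at$resseq == mid] <- "LYS"
    at$resname[at$chain == "B" & at$resseq == mid] <- "GLU"
    caA <- unlist(at[at$chain == "A" & at$resseq == mid & at$name == "CA",
                     c("x", "y", "z")])
    caB <- unlist(at[at$chain == "B" & at$resseq == mid & at$name == "CA",
                     c("x", "y", "z")])
    dir <- (caB - caA) / sqrt(sum((caB - caA)^2))
    midPt <- (caA + caB) / 2
    nz <- midPt - 1.5 * dir
    oe1 <- midPt + 1.5 * dir
    oe2 <- oe1 + c(0, 0, 1.0)
    extra <- data.frame(
      serial = 0L, name = c("NZ", "OE1", "OE2"),
      element = c("N", "O", "O"), resname = c("LYS", "GLU", "GLU"),
      chain = c("A", "B", "B"), resseq = mid, icode = "",
      x = c(nz[1], oe1[1], oe2[1]), y = c(nz[2], oe1[2], oe2[2]),
      z = c(nz[3], oe1[3], oe2[3]), occ = 1, stringsAsFactors = FALSE)
    at <- rbind(at, extra)
    at <- at[order(match(at$chain, c("A", "B")), at$resseq), ]
  }
  at$serial <- seq_len(nrow(at))
  Structure(at)
}

## Rodrigues rotation matrix for axis u (unit) and angle deg.
.axisRotation <- function(u, deg) {
  th <- deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.randomUnit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Rigid-body perturbation of a docking pose
#'
#' The ligand chain (by default the last chain) is rigidly rotated about
#' its centroid (random axis) and translated, then per-atom Gaussian
#' jitter of the stated standard deviation is added to its atoms; the
#' receptor chain(s) stay fixed — mirroring how docking poses of one
#' complex differ.
#'
#' @param base a [Structure-class].
#' @param rotationDeg rotation magnitude, degrees.
#' @param translation either a length-3 vector (Angstrom) or a scalar
#'   magnitude applied along a random direction.
#' @param jitter per-coordinate Gaussian sigma, Angstrom.
#' @param seed optional integer; when given, `set.seed` is called first.
#'   `NULL` draws from the ambient RNG stream.
#' @param ligandChain chain to move; default the last chain.
#' @return the perturbed [Structure-class].
#' @export
perturbPose <- function(base, rotationDeg = 0, translation = 0, jitter = 0,
                        seed = NULL, ligandChain = NULL) {
  if (rotationDeg < 0 || jitter < 0)
    stop("perturbation magnitudes must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ligandChain)) ligandChain <- utils::tail(chains(base), 1L)
  at <- base@atoms
  lig <- which(at$chain %in% ligandChain)
  xyz <- coords(base)
  L <- xyz[lig, , drop = FALSE]
  if (rotationDeg != 0) {
    ctr <- colMeans(L)
    R <- .axisRotation(.randomUnit(), rotationDeg)
    L <- sweep(sweep(L, 2, ctr) %*% R, 2, ctr, "+")
  }
  tvec <- if (length(translation) == 3L) as.numeric(translation)
          else if (translation != 0) .randomUnit() * translation
          else c(0, 0, 0)
  L <- sweep(L, 2, tvec, "+")
  if (jitter > 0)
    L <- L + matrix(stats::rnorm(length(L), 0, jitter), ncol = 3L)
  xyz[lig, ] <- L
  coords(base) <- xyz
  base
}

#' PoolRecipe: parameters of a planted-cluster synthetic pose pool
#'
#' @slot base toy complex the decoys derive from.
#' @slot nClusters planted cluster count.
#' @slot membersPerCluster members per cluster (recycled to nClusters).
#' @slot intraSpread within-cluster ligand RMSD scale, Angstrom.
#' @slot interSeparation minimum between-center ligand displacement,
#'   Angstrom; must exceed twice `intraSpread` for a separable recipe.
#' @slot engines engine vocabulary for label assignment.
#' @slot engineAssignment optional list (one element per cluster) of named
#'   engine proportions; `list()` means round-robin.
#' @slot seed integer seed; the full output is deterministic per seed.
#' @export
setClass("PoolRecipe",
         representation(base = "Structure", nClusters = "integer",
                        membersPerCluster = "integer",
                        intraSpread = "numeric",
                        interSeparation = "numeric", engines = "character",
                        engineAssignment = "list", seed = "integer"))

setValidity("PoolRecipe", function(object) {
  if (object@nClusters < 1L) return("nClusters must be >= 1")
  if (any(object@membersPerCluster < 1L))
    return("member counts must be positive")
  if (object@interSeparation <= 2 * object@intraSpread)
    return("interSeparation must exceed 2 * intraSpread (separable recipe)")
  if (length(object@engineAssignment) &&
      length(object@engineAssignment) != object@nClusters)
    return("engineAssignment must have one element per cluster")
  TRUE
})

#' @rdname PoolRecipe-class
#' @param base,nClusters,membersPerCluster,intraSpread,interSeparation,engines,engineAssignment,seed
#'   see slots.
#' @return A [PoolRecipe-class].
#' @export
poolRecipe <- function(base = makeToyComplex(), nClusters = 3L,
                       membersPerCluster = 10L, intraSpread = 1.0,
                       interSeparation = 20.0,
                       engines = c("ZDOCK", "ClusPro", "HDOCK", "HADDOCK",
                                   "GRAMM-X"),
                       engineAssignment = list(), seed = 1L) {
  new("PoolRecipe", base = base, nClusters = as.integer(nClusters),
      membersPerCluster = rep(as.integer(membersPerCluster),
                              length.out = nClusters),
      intraSpread = intraSpread, interSeparation = interSeparation,
      engines = engines, engineAssignment = engineAssignment,
      seed = as.integer(seed))
}

## near-uniform directions on the unit sphere (golden spiral), so that
## planted cluster centers are mutually well separated rather than
## collinear
.clusterDirections <- function(n) {
  if (n == 1L) return(matrix(c(1, 0, 0), 1L))
  i <- seq_len(n)
  z <- 1 - 2 * (i - 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(cos(phi) * s, sin(phi) * s, z)
}

.minPairDist <- function(m) {
  best <- Inf
  for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):nrow(m))
    best <- min(best, sqrt(sum((m[i, ] - m[j, ])^2)))
  best
}

## largest-remainder apportionment of m members to named proportions
.apportion <- function(props, m) {
  if (any(props < 0) || sum(props) <= 0)
    stop("infeasible engine proportions", call. = FALSE)
  raw <- props / sum(props) * m
  counts <- floor(raw)
  left <- m - sum(counts)
  if (left > 0) {
    up <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[up] <- counts[up] + 1
  }
  counts
}

#' Generate a planted-cluster pose pool
#'
#' Emulates a multi-engine refined docking pool: cluster centers are
#' distinct rigid ligand placements separated by at least
#' `interSeparation` (translation construction plus per-center rotation),
#' members are jittered copies within `intraSpread`, and each pose gets
#' engine/rank/protocol provenance per the recipe. Pose PDB files, a
#' manifest, and a ground-truth sidecar (`label,true_cluster`) are
#' written; output is byte-deterministic per seed.
#'
#' @param recipe a [PoolRecipe-class].
#' @param dir output directory (created if needed).
#' @return list with `pool` (the in-memory [PosePool-class]), `truth`
#'   (data.frame `label`, `true_cluster`), `manifest` and `truthFile`
#'   (paths), `dir`.
#' @export
generatePool <- function(recipe, dir = tempfile("posepool")) {
  validObject(recipe)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(recipe@seed)
  nc <- recipe@nClusters
  dirs <- .clusterDirections(nc)
  ## near-uniform directions on a sphere keep every planted binding mode
  ## equally distinct (collinear placements make coarser partitions look
  ## attractive to any spread-based model selection); the radius is set
  ## so the smallest ligand-displacement between centers is
  ## interSeparation
  r <- if (nc > 1L) recipe@interSeparation / .minPairDist(dirs) else
    recipe@interSeparation
  ## each center is a distinct binding mode: a 90-degree ligand rotation
  ## about a center-specific random axis plus the spherical-code
  ## translation
  centers <- lapply(seq_len(nc), function(c) {
    set.seed(recipe@seed + c)
    perturbPose(recipe@base, rotationDeg = if (nc > 1L) 90 else 0,
                translation = r * dirs[c, ])
  })
  set.seed(recipe@seed)
  engines <- recipe@engines
  engCounter <- stats::setNames(integer(length(engines)), engines)
  recs <- list()
  truth <- list()
  rr <- 0L  # round-robin pointer
  for (c in seq_len(nc)) {
    m <- recipe@membersPerCluster[c]
    if (length(recipe@engineAssignment)) {
      props <- recipe@engineAssignment[[c]]
      counts <- .apportion(unlist(props), m)
      engSeq <- rep(names(props), counts)
    } else {
      engSeq <- engines[(rr + seq_len(m) - 1L) %% length(engines) + 1L]
      rr <- rr + m
    }
    for (k in seq_len(m)) {
      s <- perturbPose(centers[[c]], jitter = recipe@intraSpread / sqrt(3))
      eng <- engSeq[k]
      engCounter[eng] <- engCounter[eng] + 1L
      rank <- (engCounter[eng] - 1L) %/% 10L + 1L
      protocol <- (engCounter[eng] - 1L) %% 10L + 1L
      recs[[length(recs) + 1L]] <- PoseRecord(s, eng, rank, protocol)
      truth[[length(truth) + 1L]] <-
        data.frame(label = poseLabel(eng, rank, protocol), true_cluster = c,
                   stringsAsFactors = FALSE)
    }
  }
  pool <- PosePool(recs)
  truth <- do.call(rbind, truth)
  labels <- poseLabels(pool)
  files <- file.path(dir, paste0(labels, ".pdb"))
  for (i in seq_along(recs)) writePDB(recs[[i]]@structure, files[i])
  manifest <- file.path(dir, "manifest.csv")
  m <- data.frame(path = basename(files),
                  engine = vapply(recs, function(r) r@engine, ""),
                  rank = vapply(recs, function(r) r@rank, 0L),
                  protocol = vapply(recs, function(r) r@protocol, 0L))
  utils::write.csv(m, manifest, row.names = FALSE, quote = FALSE)
  truthFile <- file.path(dir, "truth.csv")
  utils::write.csv(truth, truthFile, row.names = FALSE, quote = FALSE)
  list(pool = pool, truth = truth, manifest = manifest,
       truthFile = truthFile, dir = dir)
}

#' Generate a synthetic trajectory
#'
#' `"stable"` mode jitters all atoms about the base complex; the first
#' frame is the base itself, so contacts defined on frame 1 are retained
#' throughout (jitter far below the contact cutoff). `"dissociating"`
#' mode additionally translates the ligand chain monotonically away from
#' the receptor by `step` Angstrom per frame, so native contacts break
#' and the final frame is fully separated for default parameters.
#'
#' @param base a [Structure-class] (e.g. from [makeToyComplex()]).
#' @param mode `"stable"` or `"dissociating"`.
#' @param nFrames number of frames (>= 2).
#' @param jitter per-coordinate Gaussian sigma, Angstrom.
#' @param step per-frame ligand displacement in dissociating mode.
#' @param seed integer seed.
#' @param ligandChain chain that moves; default the last chain.
#' @param path optional output path; when given the trajectory is also
#'   written as a multi-model PDB.
#' @return A [Trajectory-class].
#' @export
generateTrajectory <- function(base, mode = c("stable", "dissociating"),
                               nFrames = 10L, jitter = 0.1, step = 5.0,
                               seed = 1L, ligandChain = NULL, path = NULL) {
  mode <- match.arg(mode)
  nFrames <- as.integer(nFrames)
  if (nFrames < 2L) stop("nFrames must be >= 2", call. = FALSE)
  set.seed(seed)
  if (is.null(ligandChain)) ligandChain <- utils::tail(chains(base), 1L)
  at <- base@atoms
  lig <- at$chain %in% ligandChain
  dirOut <- colMeans(coords(base)[lig, , drop = FALSE]) -
    colMeans(coords(base)[!lig, , drop = FALSE])
  dirOut <- dirOut / sqrt(sum(dirOut^2))
  frames <- vector("list", nFrames)
  frames[[1L]] <- base
  for (t in 2L:nFrames) {
    s <- base
    xyz <- coords(s)
    if (mode == "dissociating")
      xyz[lig, ] <- sweep(xyz[lig, , drop = FALSE], 2,
                          (t - 1) * step * dirOut, "+")
    if (jitter > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter), ncol = 3L)
    coords(s) <- xyz
    frames[[t]] <- s
  }
  traj <- Trajectory(frames)
  if (!is.null(path)) writePDB(traj, path)
  traj
}
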