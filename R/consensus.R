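## Consensus-docking core: all-pairs RMSD, agglomerative clustering,
## Kelley-penalty model selection, cluster statistics, final pose choice,
## per-engine component analysis.

#' All-pairs RMSD matrix over a pose pool
#'
#' Computes the symmetric dissimilarity matrix used for conformer
#' clustering. The default replicates the clustering input convention for
#' refined docking pools: all heavy atoms, with optimal superposition
#' removed before each pairwise measurement. All poses are first reduced
#' to their common atom roster.
#'
#' @param pool a [PosePool-class].
#' @param selection an [AtomSelection-class] (default heavy atoms).
#' @param mapping a [ChainMapping-class]; permutable groups force the
#'   slower per-pair permutation search.
#' @param superpose remove the optimal rigid transform before measuring?
#' @return An [RMSDMatrix-class] labelled with the pose labels.
#' @export
buildRMSDMatrix <- function(pool, selection = atomSelection("heavy"),
                            mapping = chainMapping(), superpose = TRUE) {
  recs <- poseRecords(pool)
  if (length(recs) < 2L) stop("pose pool must contain at least 2 poses",
                              call. = FALSE)
  labels <- poseLabels(pool)
  structs <- lapply(recs, function(r) r@structure)
  P <- length(structs)
  v <- matrix(0, P, P, dimnames = list(labels, labels))
  if (length(mapping@permutableGroups) || nrow(mapping@pairs)) {
    for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
      v[i, j] <- v[j, i] <- rmsd(structs[[i]], structs[[j]], selection,
                                 mapping, superpose = superpose)
    }
    return(RMSDMatrix(v))
  }
  roster <- tryCatch(commonAtomRoster(structs, selection),
                     error = function(e) stop("roster error over pool [",
                                              labels[1L], "...]: ",
                                              conditionMessage(e),
                                              call. = FALSE))
  X <- lapply(seq_len(P), function(i)
    coords(structs[[i]])[roster[[i]], , drop = FALSE])
  n <- nrow(X[[1L]])
  if (superpose) {
    Xc <- lapply(X, function(m) sweep(m, 2, colMeans(m)))
    for (i in seq_len(P - 1L)) {
      Ci <- Xc[[i]]
      for (j in (i + 1L):P) {
        sv <- svd(crossprod(Ci, Xc[[j]]))
        d <- sign(det(sv$u) * det(sv$v))
        R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
        v[i, j] <- v[j, i] <- sqrt(mean(rowSums((Ci %*% R - Xc[[j]])^2)))
      }
    }
  } else {
    for (i in seq_len(P - 1L)) for (j in (i + 1L):P)
      v[i, j] <- v[j, i] <- sqrt(mean(rowSums((X[[i]] - X[[j]])^2)))
  }
  RMSDMatrix(v)
}

#' Agglomerative clustering of a pose pool
#'
#' Builds the hierarchical merge tree over the RMSD matrix. The tree is
#' deterministic for a given matrix and label order; nested partitions at
#' any level are available via [assignmentsAt()].
#'
#' @param matrix an [RMSDMatrix-class].
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return A [ClusteringResult-class].
#' @export
clusterPoses <- function(matrix, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  v <- rmsdValues(matrix)
  if (any(!is.finite(v))) stop("RMSD matrix contains non-finite values",
                               call. = FALSE)
  tree <- stats::hclust(stats::as.dist(v), method = linkage)
  new("ClusteringResult", tree = tree, labels = rownames(v),
      linkage = linkage)
}

#' Kelley penalty profile and optimal cluster count
#'
#' For each tree level with k clusters, the spread of every multi-member
#' cluster is the mean pairwise RMSD of its members and the level's mean
#' spread averages these. Mean spreads are rescaled linearly so that they
#' span 1 to P-1 across the retained levels (levels whose clusters are all
#' singletons are excluded), and the penalty at level k is the rescaled
#' spread plus k. The optimal number of clusters N minimizes the penalty;
#' ties resolve to the smaller k.
#'
#' @param matrix an [RMSDMatrix-class].
#' @param clustering the matching [ClusteringResult-class].
#' @return A [KelleyProfile-class].
#' @export
kelleyPenalty <- function(matrix, clustering) {
  v <- rmsdValues(matrix)
  P <- nrow(v)
  if (P < 3L) stop("Kelley profile requires at least 3 poses", call. = FALSE)
  ks <- seq_len(P)
  meanSpread <- rep(NA_real_, P)
  for (k in ks) {
    cl <- stats::cutree(clustering@tree, k = k)
    spreads <- vapply(split(seq_len(P), cl), function(members) {
      if (length(members) < 2L) return(NA_real_)
      sub <- v[members, members, drop = FALSE]
      mean(sub[upper.tri(sub)])
    }, 0)
    spreads <- spreads[!is.na(spreads)]
    if (length(spreads)) meanSpread[k] <- mean(spreads)
  }
  retained <- which(!is.na(meanSpread))
  if (!length(retained)) stop("no multi-member cluster at any level",
                              call. = FALSE)
  ms <- meanSpread[retained]
  rng <- range(ms)
  if (rng[2L] - rng[1L] > 0) {
    norm <- (ms - rng[1L]) / (rng[2L] - rng[1L]) * (P - 2L) + 1
  } else {
    if (max(v) == 0)
      warning("all-pairs RMSD matrix is zero: degenerate Kelley profile")
    norm <- rep(1, length(ms))
  }
  penalty <- norm + retained
  prof <- data.frame(k = retained, meanSpread = ms, normSpread = norm,
                     penalty = penalty)
  new("KelleyProfile", profile = prof,
      optimalK = as.integer(retained[which.min(penalty)]),
      nPoses = as.integer(P))
}

.roundHalfUp <- function(x) floor(x + 0.5)

#' Per-cluster population, centroid and spread statistics
#'
#' The centroid of a cluster is the member minimizing the mean RMSD to its
#' co-members (ties: lexicographically first label). `avgRMSD`/`sdRMSD`
#' summarise member-to-centroid distances over the non-centroid members
#' (singletons report 0). `rmsdToMain` is the distance from each cluster's
#' centroid to the centroid of the most populated cluster (population
#' ties: smaller `avgRMSD`, then smaller cluster id).
#'
#' @param matrix an [RMSDMatrix-class].
#' @param assignments named integer vector (pose label -> cluster id), as
#'   from [assignmentsAt()].
#' @return A [ClusterStats-class].
#' @export
clusterStats <- function(matrix, assignments) {
  v <- rmsdValues(matrix)
  labels <- rownames(v)
  if (!setequal(names(assignments), labels) ||
      length(assignments) != length(labels))
    stop("assignments must cover exactly the matrix labels", call. = FALSE)
  assignments <- assignments[labels]
  ids <- sort(unique(assignments))
  rows <- lapply(ids, function(cid) {
    members <- labels[assignments == cid]
    if (length(members) == 1L)
      return(data.frame(cluster = cid, population = 1L,
                        centroid = members, avgRMSD = 0, sdRMSD = 0,
                        stringsAsFactors = FALSE))
    sub <- v[members, members, drop = FALSE]
    meanTo <- rowSums(sub) / (length(members) - 1L)
    ord <- order(meanTo, members)
    centroid <- members[ord[1L]]
    dists <- sub[centroid, setdiff(members, centroid)]
    data.frame(cluster = cid, population = length(members),
               centroid = centroid, avgRMSD = mean(dists),
               sdRMSD = if (length(dists) > 1L) stats::sd(dists) else 0,
               stringsAsFactors = FALSE)
  })
  st <- do.call(rbind, rows)
  ord <- order(-st$population, st$avgRMSD, st$cluster)
  main <- st$cluster[ord[1L]]
  mainCentroid <- st$centroid[st$cluster == main]
  st$rmsdToMain <- v[st$centroid, mainCentroid]
  new("ClusterStats", stats = st, mainCluster = as.integer(main),
      assignments = assignments)
}

#' Final consensus pose Q
#'
#' The model nearest to the centroid of the most populated cluster, i.e.
#' that cluster's centroid member.
#'
#' @param stats a [ClusterStats-class].
#' @return pose label (character).
#' @export
selectFinalPose <- function(stats) {
  st <- statsTable(stats)
  st$centroid[st$cluster == mainCluster(stats)]
}

#' Per-engine component analysis of a cluster
#'
#' Reports how many members each docking engine contributes to a cluster
#' and the percentage of the cluster (integer, half-up rounding, matching
#' the reporting convention of consensus-docking studies; raw fractions
#' are retained), plus the label of the member nearest to the cluster
#' centroid.
#'
#' @param stats a [ClusterStats-class].
#' @param pool the [PosePool-class] the clustering was computed over.
#' @param cluster cluster id; defaults to the most populated cluster.
#' @return A [ComponentReport-class].
#' @export
componentAnalysis <- function(stats, pool, cluster = mainCluster(stats)) {
  assignments <- stats@assignments
  if (!cluster %in% assignments) stop("no such cluster: ", cluster,
                                      call. = FALSE)
  members <- names(assignments)[assignments == cluster]
  eng <- stats::setNames(poseEngines(pool), poseLabels(pool))[members]
  counts <- sort(table(eng), decreasing = TRUE)
  tab <- data.frame(engine = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab$fraction <- tab$count / sum(tab$count)
  tab$percent <- .roundHalfUp(100 * tab$fraction)
  st <- statsTable(stats)
  new("ComponentReport", table = tab[, c("engine", "count", "percent",
                                         "fraction")],
      cluster = as.integer(cluster),
      nearestToCentroid = st$centroid[st$cluster == cluster])
}

#' Compare a pose to a crystal reference (C-alpha RMSD)
#'
#' Superposes the pose onto the reference over C-alpha atoms (Kabsch,
#' permutable chain groups honoured) and returns the RMSD, the figure
#' reported when validating predicted complexes against crystal
#' structures.
#'
#' @param pose,reference [Structure-class] objects.
#' @param mapping a [ChainMapping-class].
#' @return C-alpha RMSD in Angstrom.
#' @export
compareToReference <- function(pose, reference, mapping = chainMapping()) {
  kabschSuperpose(pose, reference, atomSelection("ca"), mapping)@rmsd
}

#' Run the full consensus-selection pipeline on a pose pool
#'
#' Convenience wrapper chaining [buildRMSDMatrix()], [clusterPoses()],
#' [kelleyPenalty()], [clusterStats()] at the optimal level and
#' [selectFinalPose()].
#'
#' @inheritParams buildRMSDMatrix
#' @param linkage linkage criterion for [clusterPoses()].
#' @return list with elements `matrix`, `clustering`, `kelley`, `stats`,
#'   `finalPose` (label) and `finalRecord` (the selected
#'   [PoseRecord-class]).
#' @export
consensusPipeline <- function(pool, selection = atomSelection("heavy"),
                              mapping = chainMapping(),
                              linkage = "average", superpose = TRUE) {
  m <- buildRMSDMatrix(pool, selection, mapping, superpose = superpose)
  cl <- clusterPoses(m, linkage)
  kp <- kelleyPenalty(m, cl)
  st <- clusterStats(m, assignmentsAt(cl, optimalK(kp)))
  q <- selectFinalPose(st)
  list(matrix = m, clustering = cl, kelley = kp, stats = st,
       finalPose = q,
       finalRecord = poseRecords(pool)[[match(q, poseLabels(pool))]])
}
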