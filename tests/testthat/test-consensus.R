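makePool <- function(structures, engines = NULL) {
  n <- length(structures)
  if (is.null(engines)) engines <- rep("ZDOCK", n)
  PosePool(lapply(seq_len(n), function(i)
    PoseRecord(structures[[i]], engines[i], (i - 1) %/% 10 + 1,
               (i - 1) %% 10 + 1)))
}

test_that("RMSD matrices are symmetric, zero-diagonal and oracle-exact", {
  s <- makeToyComplex(6)
  ## identical poses: zero matrix
  m0 <- buildRMSDMatrix(makePool(list(s, s, s)))
  expect_lt(max(rmsdValues(m0)), 1e-9)
  ## pose and its translate: zero off-diagonal after superposition
  mt <- buildRMSDMatrix(makePool(list(s, transformStructure(s, diag(3),
                                                            c(5, 5, 5)))))
  expect_lt(max(rmsdValues(mt)), 1e-9)
  ## 10-pose pool vs independent pairwise double loop
  set.seed(17)
  poses <- c(list(s), lapply(1:9, function(i)
    perturbPose(s, rotationDeg = runif(1, 0, 30),
                translation = runif(1, 0, 4), jitter = 0.2)))
  pool <- makePool(poses)
  m <- rmsdValues(buildRMSDMatrix(pool))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(m[i, j], rmsd(poses[[i]], poses[[j]]), tolerance = 1e-9)
    expect_equal(m[i, j], m[j, i], tolerance = 1e-12)
  }
  expect_true(all(diag(m) == 0))
})

test_that("clustering recovers planted groups and is order-invariant", {
  g <- generatePool(poolRecipe(base = makeToyComplex(6), nClusters = 3,
                               membersPerCluster = 4, intraSpread = 0.5,
                               interSeparation = 10, seed = 13))
  m <- buildRMSDMatrix(g$pool)
  cl <- clusterPoses(m)
  a3 <- assignmentsAt(cl, 3)
  truth <- setNames(g$truth$true_cluster, g$truth$label)
  expect_equal(randIndex(a3[names(truth)], truth), 1.0)
  ## nestedness endpoints
  expect_equal(length(unique(assignmentsAt(cl, 1))), 1L)
  expect_equal(length(unique(assignmentsAt(cl, nPoses(g$pool)))),
               nPoses(g$pool))
  ## permuting the pool leaves partitions invariant up to relabeling
  set.seed(3)
  perm <- sample(nPoses(g$pool))
  poolP <- PosePool(poseRecords(g$pool)[perm])
  a3p <- assignmentsAt(clusterPoses(buildRMSDMatrix(poolP)), 3)
  expect_equal(randIndex(a3[names(a3p)], a3p), 1.0)
})

test_that("two poses make a single merge", {
  s <- makeToyComplex(5)
  m <- buildRMSDMatrix(makePool(list(s, perturbPose(s, translation = 3,
                                                    seed = 2))))
  cl <- clusterPoses(m)
  expect_equal(nrow(cl@tree$merge), 1L)
})

test_that("Kelley penalty selects planted cluster counts with normalized spread", {
  ## two tight well-separated groups force N = 2
  g2 <- generatePool(poolRecipe(base = makeToyComplex(6), nClusters = 2,
                                membersPerCluster = 5, intraSpread = 0.3,
                                interSeparation = 15, seed = 19))
  m2 <- buildRMSDMatrix(g2$pool)
  k2 <- kelleyPenalty(m2, clusterPoses(m2))
  expect_equal(optimalK(k2), 2L)
  ## seeded 3-cluster pool
  g3 <- generatePool(poolRecipe(base = makeToyComplex(6), nClusters = 3,
                                membersPerCluster = 5, seed = 23))
  m3 <- buildRMSDMatrix(g3$pool)
  k3 <- kelleyPenalty(m3, clusterPoses(m3))
  expect_equal(optimalK(k3), 3L)
  ## normalized spread spans [1, P-1] across retained levels
  prof <- kelleyTable(k3)
  P <- nPoses(g3$pool)
  expect_equal(min(prof$normSpread), 1)
  expect_equal(max(prof$normSpread), P - 1)
  expect_true(all(prof$penalty == prof$normSpread + prof$k))
})

test_that("a zero RMSD matrix degenerates to a single cluster with warning", {
  lab <- paste0("Z_1_", 1:4)
  m <- RMSDMatrix(matrix(0, 4, 4, dimnames = list(lab, lab)))
  cl <- clusterPoses(m)
  expect_warning(k <- kelleyPenalty(m, cl), "degenerate")
  expect_equal(optimalK(k), 1L)
})

test_that("Kelley optimum equals exhaustive penalty evaluation on small pools", {
  set.seed(29)
  s <- makeToyComplex(5)
  poses <- c(list(s), lapply(1:7, function(i)
    perturbPose(s, translation = sample(c(1, 8, 16), 1), jitter = 0.3)))
  pool <- makePool(poses)
  m <- buildRMSDMatrix(pool)
  cl <- clusterPoses(m)
  k <- kelleyPenalty(m, cl)
  ## independent evaluation: loop over every tree level, recompute spreads
  v <- rmsdValues(m)
  P <- nrow(v)
  ms <- rep(NA_real_, P)
  for (kk in 1:P) {
    cut <- stats::cutree(cl@tree, kk)
    sp <- c()
    for (cid in unique(cut)) {
      mem <- which(cut == cid)
      if (length(mem) < 2) next
      sub <- v[mem, mem]
      sp <- c(sp, mean(sub[upper.tri(sub)]))
    }
    if (length(sp)) ms[kk] <- mean(sp)
  }
  keep <- which(!is.na(ms))
  norm <- (ms[keep] - min(ms[keep])) / diff(range(ms[keep])) * (P - 2) + 1
  pen <- norm + keep
  expect_equal(optimalK(k), keep[which.min(pen)])
})

test_that("cluster statistics find brute-force centroids and spread summaries", {
  ## 3-member toy: d(A,B)=1, d(A,C)=1, d(B,C)=2 -> centroid A
  v <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3, 3,
              dimnames = list(c("E_1_1", "E_1_2", "E_1_3"),
                              c("E_1_1", "E_1_2", "E_1_3")))
  st <- clusterStats(RMSDMatrix(v),
                     setNames(c(1L, 1L, 1L), rownames(v)))
  tab <- statsTable(st)
  expect_equal(tab$centroid, "E_1_1")
  expect_equal(tab$population, 3L)
  expect_equal(tab$avgRMSD, 1)
  expect_equal(tab$rmsdToMain, 0)
  ## singleton cluster: itself, zero spread
  st2 <- clusterStats(RMSDMatrix(v),
                      setNames(c(1L, 1L, 2L), rownames(v)))
  tab2 <- statsTable(st2)
  expect_equal(tab2$population, c(2L, 1L))
  expect_equal(tab2$centroid[2], "E_1_3")
  expect_equal(tab2$avgRMSD[2], 0)
  expect_equal(tab2$sdRMSD[2], 0)
  ## synthetic pool: centroid equals exhaustive search in every cluster
  g <- generatePool(poolRecipe(base = makeToyComplex(6), nClusters = 3,
                               membersPerCluster = 4, seed = 37))
  m <- buildRMSDMatrix(g$pool)
  a <- assignmentsAt(clusterPoses(m), 3)
  st3 <- clusterStats(m, a)
  vv <- rmsdValues(m)
  for (cid in unique(a)) {
    mem <- names(a)[a == cid]
    best <- mem[which.min(vapply(mem, function(l)
      mean(vv[l, setdiff(mem, l)]), 0))]
    expect_equal(statsTable(st3)$centroid[statsTable(st3)$cluster == cid],
                 best)
  }
  ## populations sum to pool size
  expect_equal(sum(statsTable(st3)$population), nPoses(g$pool))
})

test_that("the final pose Q is the centroid of the most populated cluster", {
  ## single cluster of one pose
  v1 <- matrix(0, 1, 1, dimnames = list("Z_1_1", "Z_1_1"))
  st1 <- clusterStats(RMSDMatrix(v1), setNames(1L, "Z_1_1"))
  expect_equal(selectFinalPose(st1), "Z_1_1")
  ## planted pool where one engine dominates the main cluster:
  ## Q carries that engine
  g <- generatePool(poolRecipe(
    base = makeToyComplex(6), nClusters = 2, membersPerCluster = c(8, 4),
    engineAssignment = list(c(ZDOCK = 1), c(HDOCK = 1)), seed = 41))
  res <- consensusPipeline(g$pool)
  expect_equal(optimalK(res$kelley), 2L)
  expect_match(res$finalPose, "^ZDOCK")
  ## Q equals a manual brute-force centroid of the biggest cluster
  a <- res$stats@assignments
  main <- as.integer(names(which.max(table(a))))
  mem <- names(a)[a == main]
  vv <- rmsdValues(res$matrix)
  manual <- mem[which.min(vapply(mem, function(l)
    mean(vv[l, setdiff(mem, l)]), 0))]
  expect_equal(res$finalPose, manual)
})

test_that("component analysis reports counts, half-up percentages and the centroid", {
  ## single-engine cluster reports 100%
  s <- makeToyComplex(5)
  g <- generatePool(poolRecipe(base = s, nClusters = 1,
                               membersPerCluster = 5,
                               engineAssignment = list(c(HADDOCK = 1)),
                               seed = 43))
  m <- buildRMSDMatrix(g$pool)
  st <- clusterStats(m, assignmentsAt(clusterPoses(m), 1))
  rep1 <- componentAnalysis(st, g$pool)
  expect_equal(rep1@table$percent, 100)
  ## counts always sum to the cluster population
  g2 <- generatePool(poolRecipe(base = s, nClusters = 2,
                                membersPerCluster = c(7, 5), seed = 47))
  m2 <- buildRMSDMatrix(g2$pool)
  st2 <- clusterStats(m2, assignmentsAt(clusterPoses(m2), 2))
  rep2 <- componentAnalysis(st2, g2$pool)
  expect_equal(sum(rep2@table$count),
               statsTable(st2)$population[statsTable(st2)$cluster ==
                                            mainCluster(st2)])
  expect_equal(rep2@nearestToCentroid, selectFinalPose(st2))
})

test_that("comparing a structure against itself gives zero C-alpha RMSD", {
  s <- makeToyComplex(8)
  expect_equal(compareToReference(s, s), 0)
  moved <- transformStructure(s, randomRotation(), c(4, 4, 4))
  expect_lt(compareToReference(moved, s), 1e-6)
})
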