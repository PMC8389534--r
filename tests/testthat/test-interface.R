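AB <- partnerPartition("A", "B")

test_that("contact detection honours the distance cutoff exactly", {
  expect_equal(nContacts(detectContacts(gapComplex(4.9), AB)), 1L)
  expect_equal(nContacts(detectContacts(gapComplex(5.1), AB)), 0L)
  ct <- detectContacts(gapComplex(4.9), AB)
  expect_equal(contactPairs(ct)$dist, 4.9, tolerance = 1e-9)
  expect_error(detectContacts(gapComplex(4), partnerPartition("A", "Z")),
               "partition")
})

test_that("contact detection equals the O(n^2) oracle on randomized toys", {
  set.seed(53)
  for (rep in 1:8) {
    s <- perturbPose(makeToyComplex(10, separation = runif(1, 6, 10)),
                     rotationDeg = runif(1, 0, 25),
                     translation = runif(1, 0, 3), jitter = 0.3)
    cut <- runif(1, 3.5, 6)
    cs <- detectContacts(s, AB, cutoff = cut)
    expect_identical(contactKeys(cs), bruteContacts(s, "A", "B", cut))
  }
})

test_that("contacts are symmetric in partition sides and rigid-motion invariant", {
  set.seed(59)
  s <- perturbPose(makeToyComplex(12), rotationDeg = 10, jitter = 0.2)
  a <- contactPairs(detectContacts(s, AB))
  b <- contactPairs(detectContacts(s, partnerPartition("B", "A")))
  expect_equal(nrow(a), nrow(b))
  expect_identical(sort(paste(a$chainA, a$resseqA, a$chainB, a$resseqB)),
                   sort(paste(b$chainB, b$resseqB, b$chainA, b$resseqA)))
  moved <- transformStructure(s, randomRotation(), c(20, -5, 12))
  m <- contactPairs(detectContacts(moved, AB))
  expect_equal(m$dist, a$dist, tolerance = 1e-9)
})

test_that("native contacts are anchored on hot-spot residues", {
  s <- makeToyComplex(12)
  all <- contactPairs(detectContacts(s, AB))
  hot <- data.frame(chain = "A", resseq = all$resseqA[1], resname = "ALA",
                    delta_aff = 15)
  nc <- nativeContacts(s, AB, hot)
  expect_true(all(contactPairs(nc)$resseqA == all$resseqA[1]))
  expect_gt(nContacts(nc), 0L)
  ## non-hotspot pairs excluded
  expect_lt(nContacts(nc), nrow(all))
  ## hot spots on side B anchor contacts too
  hotB <- data.frame(chain = "B", resseq = all$resseqB[1], resname = "ALA",
                     delta_aff = 11)
  ncB <- nativeContacts(s, AB, hotB)
  expect_true(all(contactPairs(ncB)$resseqB == all$resseqB[1]))
  ## below-threshold table warns and returns empty
  cold <- transform(hot, delta_aff = 5)
  expect_warning(e <- nativeContacts(s, AB, cold), "threshold")
  expect_equal(nContacts(e), 0L)
  ## unresolvable residues error
  bad <- data.frame(chain = "A", resseq = 999, resname = "ALA",
                    delta_aff = 20)
  expect_error(nativeContacts(s, AB, bad), "absent")
})

test_that("retention is 1 on identical frames and drops when a side leaves", {
  s <- makeToyComplex(10)
  nat <- detectContacts(s, AB)
  same <- Trajectory(list(s, s, s))
  r <- contactRetention(same, nat, AB)
  expect_equal(retentionFraction(r), c(1, 1, 1))
  ## side B translated 50 A away from frame 3 on
  far <- transformStructure(s, diag(3), c(0, 0, 0))
  xyz <- coords(far)
  bIdx <- atoms(far)$chain == "B"
  xyz[bIdx, 1] <- xyz[bIdx, 1] + 50
  coords(far) <- xyz
  r2 <- contactRetention(Trajectory(list(s, s, far, far)), nat, AB)
  expect_equal(retentionFraction(r2), c(1, 1, 0, 0))
  expect_error(contactRetention(same, detectContacts(gapComplex(9), AB), AB),
               "empty")
})

test_that("retention is monotone on a dissociating trajectory", {
  s <- makeToyComplex(10)
  tr <- generateTrajectory(s, "dissociating", nFrames = 6, jitter = 0.05,
                           step = 1.2, seed = 61)
  r <- retentionFraction(contactRetention(tr, detectContacts(s, AB), AB))
  expect_equal(r[1], 1)
  expect_true(all(diff(r) <= 1e-9))
  expect_equal(r[6], 0)
})

test_that("hydrogen bonds follow the geometric distance/angle criterion", {
  ## backbone N...O at 2.9 A with a 165-degree D-H...A angle: counted
  donorRes <- rbind(atomRow("N", "N", "GLY", "A", 2, 0, 0, 0),
                    atomRow("H", "H", "GLY", "A", 2,
                            cos(15 * pi / 180), sin(15 * pi / 180), 0),
                    atomRow("CA", "C", "GLY", "A", 2, -1, -1, 0))
  accRes <- atomRow("O", "O", "GLY", "A", 5, 2.9, 0, 0)
  s <- Structure(rbind(donorRes, accRes))
  hb <- detectHBonds(s)
  expect_equal(nrow(hb), 1L)
  expect_equal(attr(hb, "criterion"), "distance+angle")
  expect_gt(hb$angle, 150)
  ## same with the acceptor at 3.8 A: not counted
  s2 <- Structure(rbind(donorRes, atomRow("O", "O", "GLY", "A", 5,
                                          3.8, 0, 0)))
  expect_equal(nrow(detectHBonds(s2)), 0L)
  ## poor angle (hydrogen pointing away): not counted
  donorFlip <- rbind(atomRow("N", "N", "GLY", "A", 2, 0, 0, 0),
                     atomRow("H", "H", "GLY", "A", 2, -1, 0, 0),
                     atomRow("CA", "C", "GLY", "A", 2, -1, -1, 0))
  s3 <- Structure(rbind(donorFlip, accRes))
  expect_equal(nrow(detectHBonds(s3)), 0L)
})

test_that("helix hydrogen bonds match a brute-force donor/acceptor oracle", {
  s <- makeToyComplex(6)
  hb <- detectHBonds(s, scope = "within-chain")
  expect_equal(attr(hb, "criterion"), "distance")  # no hydrogens built
  ## oracle: enumerate every backbone/side-chain N/O donor-acceptor pair
  at <- atoms(s)
  don <- at[at$name == "N", ]
  acc <- at[at$name %in% c("O", "OXT"), ]
  found <- 0L
  for (i in seq_len(nrow(don))) for (j in seq_len(nrow(acc))) {
    if (don$chain[i] != acc$chain[j]) next
    if (don$resseq[i] == acc$resseq[j]) next
    if (don$resseq[i] == acc$resseq[j] + 1) next  # peptide-bonded pair
    d <- sqrt(sum((unlist(don[i, c("x", "y", "z")]) -
                     unlist(acc[j, c("x", "y", "z")]))^2))
    if (d >= 2.5 && d <= 3.5) found <- found + 1L
  }
  expect_equal(nrow(hb), found)
  ## the alpha-helical i <- i+4 bonds are present
  expect_true(any(hb$resseqD - hb$resseqA == 4))
})

test_that("salt bridges pair acidic oxygens with basic nitrogens inside 4 A", {
  mk <- function(gap) Structure(rbind(
    atomRow("NZ", "N", "LYS", "A", 1, 0, 0, 0),
    atomRow("CA", "C", "LYS", "A", 1, -2, 0, 0),
    atomRow("OE1", "O", "GLU", "B", 1, gap, 0, 0),
    atomRow("CA", "C", "GLU", "B", 1, gap + 2, 0, 0)))
  expect_equal(nrow(detectSaltBridges(mk(3.0))), 1L)
  expect_equal(nrow(detectSaltBridges(mk(4.5))), 0L)
  ## charged toy complex: equals a brute-force oracle over charged pairs
  s <- makeToyComplex(11, charged = TRUE)
  sb <- detectSaltBridges(s, scope = "cross-partition", partition = AB)
  at <- atoms(s)
  ac <- at[at$resname %in% c("ASP", "GLU") &
             at$name %in% c("OD1", "OD2", "OE1", "OE2"), ]
  ba <- at[(at$resname == "LYS" & at$name == "NZ") |
             (at$resname == "ARG" & at$name %in% c("NE", "NH1", "NH2")) |
             (at$resname == "HIS" & at$name %in% c("ND1", "NE2")), ]
  pairs <- character()
  for (i in seq_len(nrow(ac))) for (j in seq_len(nrow(ba))) {
    if (ac$chain[i] == ba$chain[j]) next
    d <- sqrt(sum((unlist(ac[i, c("x", "y", "z")]) -
                     unlist(ba[j, c("x", "y", "z")]))^2))
    if (d <= 4.0)
      pairs <- c(pairs, paste(ac$chain[i], ac$resseq[i], ba$chain[j],
                              ba$resseq[j]))
  }
  expect_equal(nrow(sb), length(unique(pairs)))
  expect_equal(nrow(sb), 1L)
})

test_that("interface detectors are invariant under rigid motion", {
  set.seed(67)
  s <- makeToyComplex(10, charged = TRUE)
  base <- list(contacts = nContacts(detectContacts(s, AB)),
               hb = nrow(detectHBonds(s)),
               sb = nrow(detectSaltBridges(s)))
  for (i in 1:5) {
    m <- transformStructure(s, randomRotation(), rnorm(3, 0, 25))
    expect_equal(nContacts(detectContacts(m, AB)), base$contacts)
    expect_equal(nrow(detectHBonds(m)), base$hb)
    expect_equal(nrow(detectSaltBridges(m)), base$sb)
  }
})

test_that("RMSD time series is zero for identical or rigidly moved frames", {
  s <- makeToyComplex(8)
  tr <- Trajectory(list(s, s, transformStructure(s, randomRotation(),
                                                 c(3, 1, -2))))
  ts <- rmsdTimeseries(tr)
  expect_lt(max(ts), 1e-6)
  expect_error(rmsdTimeseries(tr, referenceFrame = 9), "range")
  ## matches a per-frame oracle on a noisy trajectory
  set.seed(71)
  tr2 <- generateTrajectory(s, "stable", nFrames = 4, jitter = 0.3,
                            seed = 73)
  ts2 <- rmsdTimeseries(tr2)
  for (t in 1:4)
    expect_equal(ts2[t], rmsd(frame(tr2, t), frame(tr2, 1),
                              atomSelection("ca")), tolerance = 1e-12)
})

test_that("RMSF isolates the oscillating residue at its closed-form amplitude", {
  ## one residue oscillating +/- d along x, everything else fixed
  base <- makeToyComplex(8)
  d <- 0.8
  mkFrame <- function(sign) {
    f <- base
    xyz <- coords(f)
    idx <- atoms(f)$chain == "A" & atoms(f)$resseq == 4
    xyz[idx, 1] <- xyz[idx, 1] + sign * d
    coords(f) <- xyz
    f
  }
  tr <- Trajectory(list(mkFrame(1), mkFrame(-1), mkFrame(1), mkFrame(-1)))
  rf <- calcRMSF(tr, atomSelection("ca"))
  osc <- rf$rmsf[rf$chain == "A" & rf$resseq == 4]
  ## the mean-structure fit reabsorbs a small translational/rotational
  ## share of the motion (1 of 16 C-alpha atoms moves), so the amplitude
  ## is recovered to within ~15% and the rest stays near zero
  expect_lt(abs(osc - d), 0.2 * d)
  expect_lt(max(rf$rmsf[!(rf$chain == "A" & rf$resseq == 4)]), 0.2 * d)
  expect_error(calcRMSF(Trajectory(list(base))), "2 frames")
  ## direct-formula oracle on a jittered trajectory (alignment-free
  ## construction: identical frames except independent noise)
  set.seed(79)
  tr2 <- generateTrajectory(base, "stable", nFrames = 20, jitter = 0.15,
                            seed = 83)
  rf2 <- calcRMSF(tr2, atomSelection("ca"))
  expect_true(all(rf2$rmsf > 0))
  expect_lt(max(rf2$rmsf), 0.5)
})
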