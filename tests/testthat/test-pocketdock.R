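test_that("pose clustering recovers planted partitions", {
  ctr <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0))
  ps <- generatePoseFixture(poseSimConfig(ctr, c(4, 4, 2), spreadSd = 0.5,
                                          seed = 5))
  cl <- clusterPoses(ps, cutoff = 5)
  expect_equal(nTypes(cl), 3)
  # members match the planted labels exactly (type ids follow best rank)
  expect_equal(unname(typeAssignments(cl)), trueClusters(ps))
  expect_equal(as.vector(table(typeAssignments(cl))), c(4L, 4L, 2L))

  # single pose and coincident poses each give one cluster
  one <- dockingPoseSet(list(matrix(1:6, 2, 3)))
  expect_equal(nTypes(clusterPoses(one)), 1)
  same <- dockingPoseSet(rep(list(matrix(1:6, 2, 3)), 5))
  expect_equal(nTypes(clusterPoses(same)), 1)
})

test_that("clustering is a partition and merges monotonically in cutoff", {
  ctr <- rbind(c(0, 0, 0), c(12, 0, 0), c(24, 0, 0))
  ps <- generatePoseFixture(poseSimConfig(ctr, c(3, 3, 3), spreadSd = 1,
                                          seed = 8))
  prev <- NULL
  for (cut in c(2, 5, 13, 30)) {
    cl <- clusterPoses(ps, cutoff = cut)
    asg <- typeAssignments(cl)
    # partition: every pose has exactly one type, ids contiguous
    expect_equal(sort(names(asg)), sort(as.character(poseRanks(ps))))
    expect_equal(sort(unique(asg)), seq_len(nTypes(cl)))
    if (!is.null(prev)) {
      # growing the cutoff can only merge clusters, never split: poses
      # together at the smaller cutoff remain together
      for (k in unique(prev)) {
        members <- names(prev)[prev == k]
        expect_length(unique(asg[members]), 1)
      }
      expect_lte(nTypes(cl), length(unique(prev)))
    }
    prev <- asg
  }
  # type 1 contains pose #1 by construction
  expect_equal(unname(typeAssignments(clusterPoses(ps, 5))[["1"]]), 1L)
})

test_that("contact detection matches the brute-force all-pairs oracle", {
  # boundary-inclusive toy: residues at 3.0 / 4.0 / 4.1 Angstrom
  rec <- toyReceptor(c(3, 4, 4.1))
  cs <- ligandContacts(matrix(0, 1, 3), rec, cutoff = 4)
  expect_equal(contactResidues(cs)$resno, c(1L, 2L))
  expect_equal(contactResidues(cs)$minDist, c(3, 4))

  # far-away ligand: empty set
  far <- ligandContacts(matrix(c(100, 0, 0), 1), rec, cutoff = 4)
  expect_equal(nrow(contactResidues(far)), 0L)

  # random clouds against the quadratic scan oracle
  for (seed in 1:3) {
    recR <- randomReceptor(12, atomsPerRes = 3, seed = seed)
    set.seed(seed + 100)
    lig <- matrix(runif(15, -10, 10), ncol = 3)
    for (cutoff in c(2, 4, 6)) {
      cs <- ligandContacts(lig, recR, cutoff = cutoff)
      expect_equal(contactResidues(cs)$resno,
                   bruteForceContacts(lig, recR, cutoff))
    }
  }
  expect_error(ligandContacts(matrix(0, 0, 3), rec), "no atoms")
})

test_that("critical residues follow the response-loss threshold", {
  tab <- exampleMutagenesisTable()
  crit <- criticalResidues(tab)           # default < 1% of WT
  expect_equal(unname(crit),
               c(99L, 103L, 161L, 165L, 189L, 193L, 354L, 358L))
  expect_length(crit, 8)
  expect_equal(names(crit)[1], "D99")

  # raising the threshold is monotone: the 1-50% class joins
  crit50 <- criticalResidues(tab, threshold = 0.5)
  expect_true(all(crit %in% crit50))
  expect_true(all(c(157L, 355L) %in% crit50))

  # intact responses yield an empty set
  ok <- data.frame(residue_number = 1:3, residue_name = c("A", "C", "D"),
                   relative_response = c(1, 0.9, 1.2))
  expect_length(criticalResidues(ok), 0)
})

test_that("binding-type ranking scores coverage of critical residues", {
  # two types; contacts split the critical set 3 to 1
  asg <- setNames(c(1L, 1L, 2L, 2L), as.character(1:4))
  clustering <- new("PoseClustering", assignments = asg,
                    centroids = matrix(0, 2, 3), cutoff = 5)
  mkCS <- function(resnos) new("ContactSet",
    residues = data.frame(chain = rep("A", length(resnos)), resno = resnos,
                          resid = rep("ALA", length(resnos)),
                          minDist = rep(3, length(resnos))), cutoff = 4)
  contactSets <- list(`1` = mkCS(c(10L, 20L)), `2` = mkCS(30L),
                      `3` = mkCS(40L), `4` = mkCS(integer(0)))
  rk <- rankBindingTypes(clustering, contactSets,
                         critical = c(10L, 20L, 30L, 40L))
  expect_equal(rk$typeId, c(1L, 2L))
  expect_equal(rk$coverage, c(0.75, 0.25))
  expect_equal(rk$memberRanks[[1]], c(1L, 2L))

  # ranking is invariant under pose reordering within clusters
  rk2 <- rankBindingTypes(clustering, contactSets[c("2", "1", "4", "3")],
                          critical = c(10L, 20L, 30L, 40L))
  expect_equal(rk2$coverage, rk$coverage)

  expect_error(rankBindingTypes(clustering, contactSets, integer(0)),
               "empty")
})

test_that("full-coverage type reproduces the binding-site conclusion", {
  # plant three pose clusters near distinct receptor patches; only the
  # first patch carries the eight response-critical pocket residues
  tab <- exampleMutagenesisTable()
  crit <- criticalResidues(tab)
  patch <- function(resnos, center) data.frame(
    chain = "A", resno = resnos, resid = "ALA", elety = "CA",
    x = center[1] + seq_along(resnos), y = center[2], z = center[3])
  receptor <- rbind(patch(crit, c(0, 0, 0)),
                    patch(501:506, c(40, 0, 0)),
                    patch(601:604, c(0, 40, 0)))
  ctr <- rbind(c(4, 2, 0), c(43, 2, 0), c(2, 42, 0))
  ps <- generatePoseFixture(poseSimConfig(ctr, c(4, 4, 2), spreadSd = 0.3,
                                          nLigandAtoms = 8, seed = 2))
  cl <- clusterPoses(ps, cutoff = 5)
  contactSets <- lapply(poseRanks(ps), function(r)
    ligandContacts(ps, receptor, cutoff = 6, pose = r))
  rk <- rankBindingTypes(cl, contactSets, crit)
  expect_equal(rk$typeId[1], 1L)
  expect_equal(rk$coverage[1], 1)
  expect_equal(rk$coverage[-1], c(0, 0))
})
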