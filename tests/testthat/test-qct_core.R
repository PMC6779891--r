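test_that("reads carrying a QCT identifier are extracted as QCT observations", {
  assay <- toyAssay()
  reads <- rep(toyQCTRead(assay, "QCT1", "ACGTACGTAC"), 100)
  part <- partitionReads(reads, assay)
  expect_equal(sum(qctObservations(part)$count), 100L)
  expect_equal(goiDepth(part), 0L)
  expect_equal(unmatchedReads(part), 0L)
  expect_equal(qctObservations(part)$emi, "ACGTACGTAC")
  expect_equal(qctObservations(part)$pool, "QCT1")
})

test_that("a single mismatch inside the QCT identifier disqualifies a read", {
  assay <- toyAssay()
  r <- toyQCTRead(assay, "QCT1", "ACGTACGTAC")
  substr(r, 61, 61) <- ifelse(substr(r, 61, 61) == "A", "C", "A")  # in ID
  part <- partitionReads(r, assay, maxMismatch = 0L)
  expect_equal(sum(qctObservations(part)$count), 0L)
  ## with the default GOI budget of 3 the read is also not a QCT read
  part3 <- partitionReads(r, assay)
  expect_equal(sum(qctObservations(part3)$count), 0L)
})

test_that("error-free simulated reads are classified exactly as generated", {
  assay <- toyAssay()
  cfg <- simConfig(nQCTMoleculesMean = 100, nGOIMolecules = 200,
                   depthPerMolecule = 10, amplificationBiasSD = 0,
                   seqErrorRate = 0)
  sim <- simulateReaction(assay, cfg, seed = 11)
  part <- partitionReads(sim$reads, assay)
  expect_equal(sum(qctObservations(part)$count), sum(sim$origin == "qct"))
  expect_equal(goiDepth(part), sum(sim$origin == "goi"))
  expect_equal(unmatchedReads(part), 0L)
  ## every true molecule's EMI observed with its exact depth
  obs <- qctObservations(part)
  tr <- sim$truth$qct
  m <- merge(obs, tr, by.x = c("pool", "emi"), by.y = c("pool", "emi"))
  expect_equal(nrow(m), nrow(tr))
  expect_equal(m$count, m$depth)
})

test_that("reads shorter than the configured offsets are counted unmatched", {
  assay <- toyAssay()
  short <- substr(TOY_REF, 1, 50)
  expect_warning(part <- partitionReads(short, assay), "shorter")
  expect_equal(unmatchedReads(part), 1L)
  ## empty stream -> all-zero partition
  p0 <- partitionReads(character(0), assay)
  expect_equal(p0@totalReads, 0L)
  expect_equal(goiDepth(p0), 0L)
})

test_that("the partition is exhaustive under mixed input", {
  assay <- toyAssay()
  reads <- c(rep(toyQCTRead(assay, "QCT2", "GGGGGCCCCC"), 7),
             rep(TOY_REF, 5),
             strrep("A", 150))         # matches nothing
  part <- partitionReads(reads, assay)
  expect_equal(sum(qctObservations(part)$count) + goiDepth(part) +
                 unmatchedReads(part), length(reads))
  expect_equal(goiDepth(part), 5L)
  expect_equal(unmatchedReads(part), 1L)
})

test_that("GOI reads report the base observed at the variant locus", {
  assay <- toyAssay()
  alt <- TOY_REF
  substr(alt, 31, 31) <- assay@variantLoci$alt[1]
  part <- partitionReads(c(rep(TOY_REF, 6), rep(alt, 4)), assay)
  ad <- goiAlleleDepth(part)
  expect_equal(ad$reads[ad$base == assay@variantLoci$ref[1]], 6L)
  expect_equal(ad$reads[ad$base == assay@variantLoci$alt[1]], 4L)
})

test_that("singleton and near-duplicate EMIs cluster as specified", {
  cl1 <- clusterEMIs(data.frame(emi = "AAAAAAAAAA", count = 50L))
  expect_equal(length(cl1), 1L)
  expect_equal(clusterDepth(cl1), 50L)

  cl2 <- clusterEMIs(data.frame(emi = c("AAAAAAAAAA", "AAAAAAAAAT"),
                                count = c(50L, 2L)))
  expect_equal(length(cl2), 1L)
  expect_equal(clusterDepth(cl2), 52L)
  expect_equal(consensusEMI(cl2), "AAAAAAAAAA")

  ## tie on count -> lexicographically smallest member is the consensus
  cl3 <- clusterEMIs(data.frame(emi = c("CAAAAAAAAA", "AAAAAAAAAA"),
                                count = c(5L, 5L)))
  expect_equal(consensusEMI(cl3), "AAAAAAAAAA")

  expect_error(clusterEMIs(data.frame(emi = c("AAAA", "AAAAA"),
                                      count = c(1L, 1L))), "length")
})

test_that("clustering equals an all-pairs union-find brute force", {
  skip_if_not_installed("igraph")
  bruteForce <- function(emi) {
    n <- length(emi)
    A <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d <- sum(strsplit(emi[i], "")[[1]] != strsplit(emi[j], "")[[1]])
      A[i, j] <- d <= 2
    }
    igraph::components(
      igraph::graph_from_adjacency_matrix(A, mode = "undirected"))$membership
  }
  set.seed(101)
  for (rep in 1:5) {
    ## mix random EMIs with deliberate 1-2 mismatch satellites
    base <- randomEMIs(20)
    sat <- vapply(sample(base, 10, replace = TRUE), function(e) {
      p <- sample(10, sample(1:2, 1))
      for (q in p) substr(e, q, q) <- sample(c("A", "C", "G", "T"), 1)
      e
    }, character(1), USE.NAMES = FALSE)
    emi <- unique(c(base, sat))
    cnt <- sample(1:40, length(emi), replace = TRUE)
    cl <- clusterEMIs(data.frame(emi = emi, count = cnt))
    memb <- bruteForce(emi)
    ## same partition of EMIs into groups
    got <- lapply(clusterMembers(cl), function(m) sort(names(m)))
    want <- lapply(split(emi, memb), sort)
    expect_setequal(vapply(got, paste, character(1), collapse = "|"),
                    vapply(want, paste, character(1), collapse = "|"))
  }
})

test_that("clustering is invariant under permutation of the input", {
  set.seed(7)
  emi <- unique(randomEMIs(30))
  cnt <- sample(1:50, length(emi), replace = TRUE)
  d <- data.frame(emi = emi, count = cnt)
  cl1 <- clusterEMIs(d)
  for (k in 1:3) {
    p <- sample(nrow(d))
    cl2 <- clusterEMIs(d[p, ])
    expect_identical(consensusEMI(cl1), consensusEMI(cl2))
    expect_identical(clusterDepth(cl1), clusterDepth(cl2))
  }
})

test_that("the depth threshold is sqrt of the mean depth over all clusters", {
  emis <- c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG", "TTTTTTTTTT")
  cl <- thresholdClusters(clusterEMIs(
    data.frame(emi = emis, count = c(100L, 100L, 100L, 1L))))
  expect_equal(depthThreshold(cl), sqrt(75.25))
  expect_equal(sum(depthClass(cl) == "high"), 3L)
  expect_equal(sum(depthClass(cl) == "low"), 1L)

  cl1 <- thresholdClusters(clusterEMIs(
    data.frame(emi = "AAAAAAAAAA", count = 9L)))
  expect_equal(depthThreshold(cl1), 3)
  expect_equal(depthClass(cl1), "high")

  ## boundary depth exactly t is classed low (strict comparison)
  clb <- thresholdClusters(clusterEMIs(
    data.frame(emi = c("AAAAAAAAAA", "CCCCCCCCCC"),
               count = c(15L, 3L))))   # mean 9, t = 3; depth 3 == t -> low
  expect_equal(depthClass(clb), c("high", "low"))

  ## empty set: undefined threshold, zero molecules
  cl0 <- thresholdClusters(clusterEMIs(
    data.frame(emi = character(0), count = integer(0))))
  expect_true(is.na(depthThreshold(cl0)))
  summ0 <- suppressWarnings(summarizeQCT(cl0, "empty"))
  expect_equal(nMolecules(summ0), 0L)
})

test_that("summaries report molecule count, mean depth and fingerprint", {
  cl <- thresholdClusters(clusterEMIs(
    data.frame(pool = c("QCT1", "QCT1", "QCT1"),
               emi = c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG"),
               count = c(20L, 40L, 1L))))
  summ <- summarizeQCT(cl, "s1")
  expect_equal(nMolecules(summ), 2L)
  expect_equal(meanDepthPerMolecule(summ), 30)
  expect_equal(fingerprint(summ),
               c("QCT1:AAAAAAAAAA", "QCT1:CCCCCCCCCC"))
  expect_equal(lowDepthClusters(summ)$emi, "GGGGGGGGGG")
  expect_true(qcPass(summ))

  ## zero high clusters -> QC failure flag
  clLow <- new("EMIClusterSet", consensus = "AAAAAAAAAA", pool = "QCT1",
               depth = 4L, members = list(c(AAAAAAAAAA = 4L)),
               depthClass = "low", threshold = 5)
  expect_warning(sf <- summarizeQCT(clLow, "bad"), "QC failure|zero")
  expect_false(qcPass(sf))
})

test_that("genomic equivalents are GOI depth over mean QCT depth", {
  summ <- toySummary("s", paste0("QCT1:", randomEMIs(10)))
  summ@meanDepth <- 20
  expect_equal(countGE(40000, summ)$genomicEquivalents, 2000)
  expect_equal(countGE(0, summ)$genomicEquivalents, 0)
  bad <- suppressWarnings(toySummary("b", character(0)))
  expect_error(countGE(100, bad), "zero QCT molecules")
})

test_that("molecule counts survive 2-fold read subsampling at >=10x depth", {
  assay <- toyAssay(pools = c(QCT1 = "TCGCC"))
  cfg <- simConfig(nQCTMoleculesMean = 80, nGOIMolecules = 0,
                   depthPerMolecule = 30, amplificationBiasSD = 0.2,
                   seqErrorRate = 0.001)
  sim <- simulateReaction(assay, cfg, seed = 21)
  both <- subsampleAndRecount(sim$reads, assay, fraction = 0.5, seed = 22)
  expect_equal(both[["full"]], both[["sub"]])

  ## fraction 1 is a no-op
  same <- subsampleAndRecount(sim$reads, assay, fraction = 1)
  expect_equal(same[["full"]], same[["sub"]])

  ## at 4x/molecule counts may drop, but never increase
  cfgLow <- simConfig(nQCTMoleculesMean = 80, nGOIMolecules = 0,
                      depthPerMolecule = 4, amplificationBiasSD = 0.2,
                      seqErrorRate = 0.001)
  simLow <- simulateReaction(assay, cfgLow, seed = 23)
  bothLow <- subsampleAndRecount(simLow$reads, assay, fraction = 0.5,
                                 seed = 24)
  expect_gte(bothLow[["full"]], bothLow[["sub"]])
})

test_that("GE estimates recover a known spike within sampling error", {
  assay <- toyAssay(pools = c(QCT1 = "TCGCC"))
  set.seed(31)
  ge <- replicate(6, {
    sim <- simulateReaction(assay, simConfig(
      nQCTMoleculesMean = 100, nGOIMolecules = 1850,
      depthPerMolecule = 12, seqErrorRate = 0.001), seed = NULL)
    d <- decodeSample(sim$reads, assay)
    d$count$genomicEquivalents
  })
  se <- sd(ge) / sqrt(length(ge))
  expect_lt(abs(mean(ge) - 1850), 3 * max(se, 1850 / sqrt(100) / sqrt(6)))
})
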