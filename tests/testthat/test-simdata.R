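test_that("pool templates reject geometry conflicts and draw uniform EMIs", {
  assay <- toyAssay()
  pool <- makeQCTPool("QCT1", "TCGCC", assay)
  expect_equal(substr(pool$template, 61, 65), "TCGCC")
  ## an identifier long enough to reach the EMI span is rejected
  expect_error(makeQCTPool("bad", strrep("A", 15), assay), "overlaps")
})

test_that("simulated draws are byte-identical for a fixed seed", {
  assay <- toyAssay()
  cfg <- simConfig(nQCTMoleculesMean = 30, nGOIMolecules = 40,
                   depthPerMolecule = 10)
  s1 <- simulateReaction(assay, cfg, seed = 5)
  s2 <- simulateReaction(assay, cfg, seed = 5)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateReaction(assay, cfg, seed = 6)
  expect_false(identical(s1$reads, s3$reads))
})

test_that("zero bias and zero error give exactly the nominal depth", {
  assay <- toyAssay()
  cfg <- simConfig(nQCTMoleculesMean = 25, nGOIMolecules = 10,
                   depthPerMolecule = 30, amplificationBiasSD = 0,
                   seqErrorRate = 0)
  sim <- simulateReaction(assay, cfg, seed = 8)
  expect_true(all(sim$truth$qct$depth == 30L))
  expect_equal(sim$truth$goiDepth, 10L * 30L)
})

test_that("spiked molecule numbers are Poisson across replicates", {
  assay <- toyAssay(pools = c(QCT1 = "TCGCC"))
  cfg <- simConfig(nQCTMoleculesMean = 100, nGOIMolecules = 0,
                   depthPerMolecule = 5)
  set.seed(14)
  n <- replicate(24, nrow(simulateReaction(assay, cfg, seed = NULL)$truth$qct))
  ## sample variance of Poisson(100) over 24 draws: chi-square bounds
  ratio <- var(n) / 100
  expect_gt(ratio, qchisq(0.005, 23) / 23)
  expect_lt(ratio, qchisq(0.995, 23) / 23)
})

test_that("per-base errors hit the EMI at the closed-form rate", {
  assay <- toyAssay(pools = c(QCT1 = "TCGCC"))
  cfg <- simConfig(nQCTMoleculesMean = 150, nGOIMolecules = 0,
                   depthPerMolecule = 30, amplificationBiasSD = 0,
                   seqErrorRate = 0.01)
  sim <- simulateReaction(assay, cfg, seed = 17)
  part <- partitionReads(sim$reads, assay, maxMismatch = 10L)
  obs <- qctObservations(part)
  trueEMIs <- sim$truth$qct$emi
  errReads <- sum(obs$count[!obs$emi %in% trueEMIs])
  ## an erroneous EMI requires >=1 error among its 10 bases, but reads whose
  ## error fell in the identifier leave the QCT set entirely
  qctReads <- sum(obs$count)
  frac <- errReads / qctReads
  expected <- 1 - 0.99^10
  expect_lt(abs(frac - expected), 0.015)
})

test_that("EMI collision probability follows the birthday closed form", {
  ## two molecules share a 10-base EMI with probability 4^-10;
  ## among n molecules the expected number of colliding pairs is C(n,2)/4^10
  assay <- toyAssay(pools = c(QCT1 = "TCGCC"))
  pool <- makeQCTPool("QCT1", "TCGCC", assay)
  set.seed(20)
  dup <- replicate(200, {
    emis <- QCTcount:::drawQCTMolecules(pool, 100)$emi
    100 - length(unique(emis))
  })
  expected <- choose(100, 2) / 4^10          # ~ 0.0047 per reaction
  expect_lt(mean(dup), expected + 3 * sqrt(expected / 200))
})

test_that("cfDNA allele counts follow the maternal/fetal mixture", {
  expect_equal(attr(simulateCfDNACounts("0/1", "1/1", 0.10, 100, 1), "p"),
               0.55)
  expect_equal(attr(simulateCfDNACounts("0/1", "0/1", 0.37, 100, 1), "p"),
               0.50)
  expect_equal(attr(simulateCfDNACounts("0/0", "0/1", 0.10, 100, 1), "p"),
               0.05)
  cnt <- simulateCfDNACounts("0/1", "1/1", 0.10, 2000, seed = 3)
  expect_equal(sum(cnt), 2000)
  expect_lt(abs(cnt[["alt"]] / 2000 - 0.55), 4 * sqrt(0.55 * 0.45 / 2000))
})

test_that("plate simulation with no contamination reports zero everywhere", {
  assay <- toyAssay(pools = c(QCT1 = "TCGCC"))
  cfgs <- list(A = simConfig(40, 0, depthPerMolecule = 15),
               B = simConfig(40, 0, depthPerMolecule = 15))
  plate <- simulatePlate(cfgs, assay, seed = 30)
  summs <- lapply(names(plate$samples), function(id)
    decodeSample(plate$samples[[id]]$reads, assay, sampleId = id)$summary)
  rep <- detectContamination(summs)
  expect_true(all(rep$contamination_fraction == 0))
  expect_true(all(plate$truth$contamInjected == 0))
})

test_that("contamination matrix row sums above one are rejected", {
  assay <- toyAssay(pools = c(QCT1 = "TCGCC"))
  cfgs <- list(A = simConfig(10, 0), B = simConfig(10, 0))
  m <- matrix(c(0, 0.9, 0.9, 0), 2, 2, byrow = TRUE) + diag(2) * 0.5
  expect_error(simulatePlate(cfgs, assay, contaminationMatrix = m,
                             seed = 1), "row sums")
})

test_that("simulated FASTQ round-trips through the decoder", {
  assay <- toyAssay()
  cfg <- simConfig(nQCTMoleculesMean = 20, nGOIMolecules = 15,
                   depthPerMolecule = 8, seqErrorRate = 0)
  sim <- simulateReaction(assay, cfg, seed = 44)
  fq <- tempfile(fileext = ".fastq")
  writeSimFastq(sim$reads, fq)
  back <- readFastqSeqs(fq)
  expect_equal(unname(back), sim$reads)
  part <- partitionReads(back, assay)
  expect_equal(sum(qctObservations(part)$count), sum(sim$origin == "qct"))
  expect_equal(goiDepth(part), sum(sim$origin == "goi"))
  unlink(fq)
})
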