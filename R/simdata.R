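#' Simulation configuration for one PCR reaction
#'
#' Defaults reflect the standard assay regime: ~100 spiked QCT molecules per
#' reaction (the 1x spike-in level), ~2000 amplifiable gene-of-interest
#' molecules (typical cfDNA input), 30 reads per molecule, lognormal
#' per-molecule amplification bias with sdlog 0.5 (so molecules within
#' +/- 2 sd span roughly an 8-fold read-depth range), and a 0.1% per-base
#' sequencing error rate (reads carry constant Q30-equivalent qualities,
#' which the decoder does not use).
#'
#' @param nQCTMoleculesMean Poisson mean of spiked QCT molecules per pool.
#' @param nGOIMolecules number of amplifiable gene-of-interest molecules.
#' @param goiAlleleCounts optional named integer vector of GOI molecule
#'   counts per allele (names \code{"ref"}/\code{"alt"}); overrides
#'   \code{nGOIMolecules}.
#' @param depthPerMolecule mean sequencing depth per molecule (reads).
#' @param amplificationBiasSD log-scale sd of the per-molecule depth
#'   (lognormal amplification bias); 0 disables bias.
#' @param seqErrorRate per-base substitution error probability.
#' @param meanFragmentLen mean fragment length in bp of the (sheared or
#'   cell-free) input DNA; when set, GOI molecules are thinned with the
#'   geometric amplifiable fraction \code{(1 - 1/L)^ampliconSpan} before
#'   amplification. NULL disables thinning.
#' @param seed default seed used when the simulation functions are not given
#'   one explicitly.
#'
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(nQCTMoleculesMean = 100,
                      nGOIMolecules = 2000L,
                      goiAlleleCounts = NULL,
                      depthPerMolecule = 30,
                      amplificationBiasSD = 0.5,
                      seqErrorRate = 0.001,
                      meanFragmentLen = NULL,
                      seed = NULL) {
  stopifnot(nQCTMoleculesMean >= 0, nGOIMolecules >= 0,
            depthPerMolecule > 0, amplificationBiasSD >= 0,
            seqErrorRate >= 0, seqErrorRate <= 1)
  if (!is.null(meanFragmentLen) && meanFragmentLen <= 1)
    stop("meanFragmentLen must be > 1", call. = FALSE)
  structure(list(nQCTMoleculesMean = nQCTMoleculesMean,
                 nGOIMolecules = as.integer(nGOIMolecules),
                 goiAlleleCounts = goiAlleleCounts,
                 depthPerMolecule = depthPerMolecule,
                 amplificationBiasSD = amplificationBiasSD,
                 seqErrorRate = seqErrorRate,
                 meanFragmentLen = meanFragmentLen,
                 seed = seed),
            class = "SimConfig")
}

#' Define a QCT pool template
#'
#' A pool template is the amplicon-length QCT sequence with the pool's
#' identifier substituted at the identifier offset and the EMI positions
#' left to be randomized per molecule. Sampling a molecule from the pool
#' draws i.i.d. uniform bases at the EMI positions, mirroring stochastic
#' base incorporation during oligo synthesis.
#'
#' @param poolId pool name (e.g. \code{"QCT1"}).
#' @param qctIdSeq the pool's identifier sequence.
#' @param assay a [QCTAssay] providing the amplicon geometry.
#'
#' @return a list of class \code{QCTPool} with the template sequence.
#' @export
makeQCTPool <- function(poolId, qctIdSeq, assay) {
  stopifnot(is(assay, "QCTAssay"))
  qctIdSeq <- toupper(qctIdSeq)
  if (!isDNA(qctIdSeq)) stop("qctIdSeq must be an A/C/G/T string",
                             call. = FALSE)
  idLen <- nchar(qctIdSeq)
  idSpan <- assay@qctIdOffset + seq_len(idLen) - 1L
  if (any(assay@emiOffsets %in% idSpan))
    stop("QCT identifier span overlaps the EMI positions", call. = FALSE)
  if (max(idSpan) >= assay@ampliconLength)
    stop("QCT identifier does not fit in the amplicon", call. = FALSE)
  template <- assay@referenceSeq
  substr(template, assay@qctIdOffset + 1L,
         assay@qctIdOffset + idLen) <- qctIdSeq
  structure(list(poolId = as.character(poolId), qctIdSeq = qctIdSeq,
                 template = template, emiOffsets = assay@emiOffsets),
            class = "QCTPool")
}

## Draw n molecules from a pool: returns list(emis, sequences).
drawQCTMolecules <- function(pool, n) {
  if (n == 0L)
    return(list(emi = character(0), seq = character(0)))
  k <- length(pool$emiOffsets)
  bases <- matrix(sample(DNA_BASES, n * k, replace = TRUE), nrow = n)
  emis <- apply(bases, 1L, paste, collapse = "")
  seqs <- rep(pool$template, n)
  for (j in seq_len(k)) {
    o <- pool$emiOffsets[j]
    substr(seqs, o + 1L, o + 1L) <- bases[, j]
  }
  list(emi = emis, seq = seqs)
}

## Apply i.i.d. per-base substitution errors to a character vector of reads.
applySeqErrors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads[1L])
  nerr <- rbinom(length(reads), L, rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(L, nerr[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }
  reads
}

#' Simulate the reads of one PCR reaction
#'
#' Draws the number of spiked QCT molecules per pool from a Poisson
#' distribution, assigns every molecule (QCT and gene-of-interest) a read
#' depth from a lognormal amplification-bias model (median =
#' \code{depthPerMolecule}, sdlog = \code{amplificationBiasSD}, rounded to
#' an integer), and applies i.i.d. per-base substitution errors. Ground
#' truth for every molecule is recorded.
#'
#' @param assay a [QCTAssay].
#' @param config a [simConfig()] object.
#' @param pools optional list of [makeQCTPool()] templates; defaults to one
#'   pool per identifier configured in the assay.
#' @param seed integer seed (falls back to \code{config$seed}).
#'
#' @return list with elements \code{reads} (character vector, shuffled),
#'   \code{origin} (\code{"qct"}/\code{"goi"} per read), and \code{truth}
#'   (list: \code{qct} data.frame(pool, emi, depth), \code{nGOI},
#'   \code{goiAlleleCounts}, \code{nGOIAmplifiable}).
#' @examples
#' ref <- strrep("ACGTT", 12)
#' assay <- QCTAssay("toy", ref, c(P1 = "TCGCC"), 10, emiOffsets = 30:39)
#' sim <- simulateReaction(assay, simConfig(nQCTMoleculesMean = 20,
#'                         nGOIMolecules = 50), seed = 1)
#' nrow(sim$truth$qct)
#' @export
simulateReaction <- function(assay, config = simConfig(), pools = NULL,
                             seed = NULL) {
  stopifnot(is(assay, "QCTAssay"), inherits(config, "SimConfig"))
  if (is.null(pools))
    pools <- lapply(names(assay@qctIds), function(p)
      makeQCTPool(p, assay@qctIds[[p]], assay))
  if (is.null(seed)) seed <- config$seed
  withSeed(seed, {
    ## --- QCT molecules -------------------------------------------------
    qctList <- lapply(pools, function(pool) {
      n <- rpois(1L, config$nQCTMoleculesMean)
      mol <- drawQCTMolecules(pool, n)
      data.frame(pool = rep(pool$poolId, n), emi = mol$emi, seq = mol$seq,
                 stringsAsFactors = FALSE)
    })
    qct <- do.call(rbind, qctList)

    ## --- GOI molecules -------------------------------------------------
    alleles <- config$goiAlleleCounts
    if (is.null(alleles)) alleles <- c(ref = config$nGOIMolecules)
    nGOI <- sum(alleles)
    nAmp <- nGOI
    if (!is.null(config$meanFragmentLen)) {
      pAmp <- (1 - 1 / config$meanFragmentLen)^assay@ampliconLength
      alleles <- vapply(alleles, function(n) rbinom(1L, n, pAmp), integer(1))
      nAmp <- sum(alleles)
    }
    goiSeq <- character(0)
    goiAllele <- character(0)
    for (a in names(alleles)) {
      s <- assay@referenceSeq
      if (a == "alt" && nrow(assay@variantLoci)) {
        for (r in seq_len(nrow(assay@variantLoci))) {
          o <- assay@variantLoci$offset[r]
          substr(s, o + 1L, o + 1L) <- assay@variantLoci$alt[r]
        }
      }
      goiSeq <- c(goiSeq, rep(s, alleles[[a]]))
      goiAllele <- c(goiAllele, rep(a, alleles[[a]]))
    }

    ## --- amplification and sequencing ----------------------------------
    molSeq <- c(qct$seq, goiSeq)
    molOrigin <- c(rep("qct", nrow(qct)), rep("goi", length(goiSeq)))
    depth <- as.integer(round(rlnorm(length(molSeq),
                                     log(config$depthPerMolecule),
                                     config$amplificationBiasSD)))
    reads <- rep(molSeq, depth)
    origin <- rep(molOrigin, depth)
    reads <- applySeqErrors(reads, config$seqErrorRate)
    if (length(reads)) {
      o <- sample.int(length(reads))
      reads <- reads[o]
      origin <- origin[o]
    }
    qctTruth <- if (nrow(qct)) {
      data.frame(pool = qct$pool, emi = qct$emi,
                 depth = depth[seq_len(nrow(qct))],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(pool = character(0), emi = character(0), depth = integer(0))
    }
    list(reads = reads, origin = origin,
         truth = list(qct = qctTruth, nGOI = nGOI, nGOIAmplifiable = nAmp,
                      goiAlleleCounts = alleles,
                      goiDepth = sum(depth[molOrigin == "goi"])))
  })
}

#' Simulate a multi-sample plate with contamination and index misassignment
#'
#' Generates one reaction per sample, then re-routes reads to emulate batch
#' effects: (i) liquid-handling cross-contamination duplicates a small
#' fraction of a source sample's QCT reads into a destination, as
#' contaminating EMIs at 1-2x depth each; (ii) index misassignment swaps
#' one index of a read at the given rate. With a combinatorial (Truseq-
#' style) layout the swapped pair usually matches another sample, so the
#' read lands there; with dual-unique indexes any single swap produces an
#' invalid pair and the read is discarded, which is why dual-unique
#' indexing suppresses observed contamination.
#'
#' @param sampleConfigs named list of [simConfig()] objects, one per sample.
#' @param assay a [QCTAssay].
#' @param contaminationMatrix optional square matrix (source x destination)
#'   of contaminating read fractions, expressed relative to the source's
#'   QCT reads; row sums must be <= 1.
#' @param indexMisassignmentRate per-read probability of an index swap.
#' @param layout \code{"dual_unique"} or \code{"combinatorial"}.
#' @param seed integer seed.
#'
#' @return list with \code{samples} (named list: \code{reads},
#'   \code{origin}) and \code{truth} (per-sample reaction truths plus
#'   \code{contamInjected} and \code{misassigned} source x destination read
#'   count matrices, and the index pair table).
#' @export
simulatePlate <- function(sampleConfigs, assay, contaminationMatrix = NULL,
                          indexMisassignmentRate = 0,
                          layout = c("dual_unique", "combinatorial"),
                          seed = NULL) {
  layout <- match.arg(layout)
  ids <- names(sampleConfigs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sampleConfigs must be a named list with unique sample ids",
         call. = FALSE)
  n <- length(ids)
  if (!is.null(contaminationMatrix)) {
    stopifnot(is.matrix(contaminationMatrix),
              nrow(contaminationMatrix) == n, ncol(contaminationMatrix) == n)
    if (any(rowSums(contaminationMatrix) > 1))
      stop("contaminationMatrix row sums must be <= 1", call. = FALSE)
  }

  ## index layout
  if (layout == "dual_unique") {
    pairs <- data.frame(sample = ids, i5 = seq_len(n), i7 = seq_len(n))
  } else {
    k <- ceiling(sqrt(n))
    pairs <- data.frame(sample = ids,
                        i5 = ((seq_len(n) - 1L) %/% k) + 1L,
                        i7 = ((seq_len(n) - 1L) %% k) + 1L)
  }

  pools <- lapply(names(assay@qctIds), function(p)
    makeQCTPool(p, assay@qctIds[[p]], assay))
  names(pools) <- names(assay@qctIds)

  reactions <- lapply(seq_len(n), function(i)
    simulateReaction(assay, sampleConfigs[[i]], pools = pools,
                     seed = childSeed(seed, i)))
  names(reactions) <- ids

  contamInjected <- matrix(0L, n, n, dimnames = list(ids, ids))
  misassigned <- matrix(0L, n, n, dimnames = list(ids, ids))
  samples <- lapply(reactions, function(r)
    list(reads = r$reads, origin = r$origin))

  withSeed(childSeed(seed, 10000L), {
    ## --- cross-contamination ------------------------------------------
    if (!is.null(contaminationMatrix)) {
      for (src in seq_len(n)) for (dst in seq_len(n)) {
        f <- contaminationMatrix[src, dst]
        if (src == dst || f <= 0) next
        srcTruth <- reactions[[src]]$truth$qct
        srcQCTReads <- sum(reactions[[src]]$origin == "qct")
        target <- round(f * srcQCTReads)
        if (target < 1L || nrow(srcTruth) == 0L) next
        addReads <- character(0)
        got <- 0L
        mols <- srcTruth[sample.int(nrow(srcTruth)), , drop = FALSE]
        ri <- 1L
        while (got < target) {
          m <- mols[((ri - 1L) %% nrow(mols)) + 1L, ]
          ## contaminants appear at 1-2x, overwhelmingly as singletons:
          ## two independent read-level misassignments of one molecule to
          ## the same destination are orders of magnitude rarer than one
          d <- 1L + rbinom(1L, 1L, 0.02)
          mol <- pools[[m$pool]]
          s <- mol$template
          emiB <- strsplit(m$emi, "")[[1L]]
          for (j in seq_along(mol$emiOffsets)) {
            o <- mol$emiOffsets[j]
            substr(s, o + 1L, o + 1L) <- emiB[j]
          }
          addReads <- c(addReads, rep(s, d))
          got <- got + d
          ri <- ri + 1L
        }
        samples[[dst]]$reads <- c(samples[[dst]]$reads, addReads)
        samples[[dst]]$origin <- c(samples[[dst]]$origin,
                                   rep("qct", length(addReads)))
        contamInjected[src, dst] <- contamInjected[src, dst] +
          length(addReads)
      }
    }

    ## --- index misassignment -------------------------------------------
    if (indexMisassignmentRate > 0) {
      moved <- vector("list", n)
      for (s in seq_len(n)) {
        rd <- samples[[s]]$reads
        org <- samples[[s]]$origin
        if (!length(rd)) next
        hop <- runif(length(rd)) < indexMisassignmentRate
        if (!any(hop)) next
        idx <- which(hop)
        keep <- rep(TRUE, length(rd))
        for (i in idx) {
          swapI5 <- runif(1) < 0.5
          newPair <- c(pairs$i5[s], pairs$i7[s])
          if (swapI5) {
            cand <- setdiff(unique(pairs$i5), pairs$i5[s])
            if (!length(cand)) next
            newPair[1L] <- sample(cand, 1L)
          } else {
            cand <- setdiff(unique(pairs$i7), pairs$i7[s])
            if (!length(cand)) next
            newPair[2L] <- sample(cand, 1L)
          }
          dst <- which(pairs$i5 == newPair[1L] & pairs$i7 == newPair[2L])
          keep[i] <- FALSE                 # leaves the source either way
          if (length(dst) == 1L) {
            moved[[dst]] <- c(moved[[dst]], setNames(rd[i], org[i]))
            if (org[i] == "qct")
              misassigned[s, dst] <- misassigned[s, dst] + 1L
          }                                # invalid pair -> read discarded
        }
        samples[[s]]$reads <- rd[keep]
        samples[[s]]$origin <- org[keep]
      }
      for (s in seq_len(n)) {
        if (length(moved[[s]])) {
          samples[[s]]$reads <- c(samples[[s]]$reads, unname(moved[[s]]))
          samples[[s]]$origin <- c(samples[[s]]$origin, names(moved[[s]]))
        }
      }
    }
  })

  list(samples = samples,
       truth = list(reactions = lapply(reactions, `[[`, "truth"),
                    contamInjected = contamInjected,
                    misassigned = misassigned,
                    indexPairs = pairs))
}

#' Simulate cfDNA allele molecule counts at a given fetal fraction
#'
#' The variant-allele probability of one cfDNA molecule is the mixture
#' \code{p = (1 - ff) * dose_m/2 + ff * dose_f/2}, where dose is the number
#' of variant alleles in the maternal/fetal genotype; the observed variant
#' molecule count is Binomial(N, p).
#'
#' @param maternalGenotype,fetalGenotype genotype strings (\code{"0/0"},
#'   \code{"0/1"}, \code{"1/1"}).
#' @param fetalFraction fetal fraction in [0, 1].
#' @param nMolecules number of cfDNA molecules assayed (N).
#' @param seed integer seed.
#'
#' @return named integer vector \code{c(ref = ..., alt = ...)}, with the
#'   mixture probability as attribute \code{"p"}.
#' @examples
#' simulateCfDNACounts("0/1", "1/1", 0.10, 2000, seed = 1)  # p = 0.55
#' @export
simulateCfDNACounts <- function(maternalGenotype, fetalGenotype,
                                fetalFraction, nMolecules, seed = NULL) {
  stopifnot(fetalFraction >= 0, fetalFraction <= 1, nMolecules >= 1)
  p <- expectedVAF(fetalFraction, maternalGenotype, fetalGenotype)
  alt <- withSeed(seed, rbinom(1L, nMolecules, p))
  structure(c(ref = nMolecules - alt, alt = alt), p = p)
}

#' Write simulated reads as FASTQ
#'
#' Emits plain (or gzipped) FASTQ with constant Q30-equivalent quality
#' strings via [Biostrings::writeXStringSet].
#'
#' @param reads character vector of read sequences.
#' @param path output file path (".gz" suffix triggers compression).
#' @param idPrefix read name prefix.
#' @return the path, invisibly.
#' @export
writeSimFastq <- function(reads, path, idPrefix = "read") {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0(idPrefix, seq_along(x))
  qual <- Biostrings::BStringSet(rep(strrep("?", unique(nchar(reads))[1]),
                                     length(x)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read amplicon FASTQ into a character vector of sequences
#'
#' @param path FASTQ file (plain or gzip).
#' @return character vector of read sequences.
#' @export
readFastqSeqs <- function(path) {
  if (!file.exists(path))
    stop("FASTQ file not found: ", path, call. = FALSE)
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}
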