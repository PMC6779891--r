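#' Classify amplicon reads into QCT, gene-of-interest and unmatched
#'
#' A read is a QCT observation iff it carries one of the configured QCT
#' identifier sequences at the identifier offset (exact match by default;
#' the 5-base identifiers of distinct pools differ by >= 5 mismatches, so
#' exact matching is safe). Otherwise it is a gene-of-interest (GOI) read if
#' it matches the reference amplicon outside the variant loci within
#' \code{maxMismatch} mismatches; otherwise it is unmatched. The EMI of a
#' QCT read is the concatenation of its bases at the EMI offsets.
#'
#' Reads too short to cover the identifier span and the EMI offsets (for the
#' QCT test) or the full amplicon (for the GOI test) are counted as
#' unmatched, with a warning.
#'
#' @param reads a [Biostrings::DNAStringSet], or a character vector of read
#'   sequences, demultiplexed for one sample.
#' @param assay a [QCTAssay].
#' @param maxMismatch mismatch budget for GOI identification (variant loci
#'   excluded from the count); default 3.
#' @param idMaxMismatch mismatch budget for the QCT identifier; default 0
#'   (exact).
#'
#' @return a [ReadPartition-class] object.
#' @examples
#' ref <- strrep("A", 60)
#' assay <- QCTAssay("toy", ref, c(P1 = "TCGCC"), 10, emiOffsets = 30:39)
#' qct <- paste0(strrep("A", 10), "TCGCC", strrep("A", 15), "GGGGGGGGGG",
#'               strrep("A", 20))
#' partitionReads(c(qct, ref), assay)
#' @export
partitionReads <- function(reads, assay, maxMismatch = 3L,
                           idMaxMismatch = 0L) {
  stopifnot(is(assay, "QCTAssay"))
  reads <- toupper(as.character(reads))
  n <- length(reads)
  emptyObs <- data.frame(pool = character(0), emi = character(0),
                         count = integer(0), stringsAsFactors = FALSE)
  alleleDepth <- data.frame(locus = integer(0), base = character(0),
                            reads = integer(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    return(new("ReadPartition", qctObservations = emptyObs,
               goiAlleleDepth = alleleDepth, goiDepth = 0L, unmatched = 0L,
               totalReads = 0L))
  }

  idLen <- nchar(assay@qctIds[1L])
  idEnd <- assay@qctIdOffset + idLen            # 1-based end of ID span
  qctCoverNeeded <- max(idEnd, assay@emiOffsets + 1L)
  len <- nchar(reads)

  ## --- QCT identification ---------------------------------------------
  poolOf <- rep(NA_character_, n)
  canQCT <- len >= qctCoverNeeded
  if (any(canQCT)) {
    obsId <- substr(reads[canQCT], assay@qctIdOffset + 1L, idEnd)
    if (idMaxMismatch == 0L) {
      hit <- match(obsId, assay@qctIds)
      poolOf[canQCT] <- names(assay@qctIds)[hit]
    } else {
      best <- rep(NA_integer_, length(obsId))
      bestD <- rep(idLen + 1L, length(obsId))
      for (p in seq_along(assay@qctIds)) {
        d <- integer(length(obsId))
        for (j in seq_len(idLen)) {
          d <- d + (substr(obsId, j, j) !=
                      substr(assay@qctIds[p], j, j))
        }
        better <- d < bestD
        best[better] <- p
        bestD[better] <- d[better]
      }
      ok <- bestD <= idMaxMismatch
      poolOf[canQCT][ok] <- names(assay@qctIds)[best[ok]]
    }
  }
  isQCT <- !is.na(poolOf)

  ## --- EMI extraction --------------------------------------------------
  if (any(isQCT)) {
    qr <- reads[isQCT]
    emiCols <- vapply(assay@emiOffsets,
                      function(o) substr(qr, o + 1L, o + 1L),
                      character(sum(isQCT)))
    emis <- if (sum(isQCT) == 1L) paste(emiCols, collapse = "") else
      do.call(paste0, as.data.frame(emiCols, stringsAsFactors = FALSE))
    obs <- aggregate(
      list(count = rep(1L, sum(isQCT))),
      by = list(pool = poolOf[isQCT], emi = emis), FUN = sum)
    obs <- obs[order(obs$pool, obs$emi), c("pool", "emi", "count")]
    rownames(obs) <- NULL
  } else {
    obs <- emptyObs
  }

  ## --- GOI identification ----------------------------------------------
  L <- assay@ampliconLength
  cand <- which(!isQCT & len >= L)
  tooShort <- sum(!isQCT & len < L)
  isGOI <- logical(n)
  if (length(cand)) {
    cr <- substr(reads[cand], 1L, L)
    refBase <- strsplit(assay@referenceSeq, "")[[1L]]
    varOffsets <- assay@variantLoci$offset
    mism <- integer(length(cand))
    for (j in seq_len(L)) {
      if ((j - 1L) %in% varOffsets) next
      mism <- mism + (substr(cr, j, j) != refBase[j])
    }
    pass <- mism <= maxMismatch
    isGOI[cand[pass]] <- TRUE
    if (any(pass) && length(varOffsets)) {
      rows <- lapply(varOffsets, function(o) {
        b <- substr(cr[pass], o + 1L, o + 1L)
        tb <- table(b)
        data.frame(locus = o, base = names(tb),
                   reads = as.integer(tb), stringsAsFactors = FALSE)
      })
      alleleDepth <- do.call(rbind, rows)
      rownames(alleleDepth) <- NULL
    }
  }

  unmatched <- n - sum(isQCT) - sum(isGOI)
  if (tooShort > 0L)
    warning(tooShort, " read(s) shorter than the configured amplicon were ",
            "counted as unmatched")
  new("ReadPartition", qctObservations = obs, goiAlleleDepth = alleleDepth,
      goiDepth = sum(isGOI), unmatched = as.integer(unmatched),
      totalReads = n)
}

#' Cluster EMI observations into putative QCT molecules
#'
#' Groups observed EMI sequences by single linkage under Hamming distance:
#' two EMIs belong to the same cluster iff they are connected by a chain of
#' pairs differing by \code{maxDist} (default 2) or fewer mismatches. This
#' collapses PCR/sequencing-error derivatives onto their parent molecule.
#' When a \code{pool} column is present, clustering is performed within each
#' pool. The consensus of a cluster is its highest-count member EMI, ties
#' broken by lexicographic order; the result is deterministic and invariant
#' under permutation of the input.
#'
#' @param observations data.frame with columns \code{emi} and \code{count}
#'   (and optionally \code{pool}), e.g. \code{qctObservations(partition)}.
#' @param maxDist maximum Hamming distance for linkage (default 2).
#'
#' @return an [EMIClusterSet-class] (not yet thresholded).
#' @examples
#' obs <- data.frame(emi = c("AAAAAAAAAA", "AAAAAAAAAT"), count = c(50L, 2L))
#' cl <- clusterEMIs(obs)
#' consensusEMI(cl); clusterDepth(cl)
#' @export
clusterEMIs <- function(observations, maxDist = 2L) {
  stopifnot(is.data.frame(observations),
            all(c("emi", "count") %in% names(observations)))
  if (!"pool" %in% names(observations))
    observations$pool <- rep("QCT", nrow(observations))
  if (nrow(observations) == 0L) {
    return(new("EMIClusterSet", consensus = character(0), pool = character(0),
               depth = integer(0), members = list(),
               depthClass = character(0), threshold = numeric(0)))
  }
  if (length(unique(nchar(observations$emi))) > 1L)
    stop("EMI sequences must all have the same length", call. = FALSE)
  ## collapse duplicate (pool, emi) rows
  observations <- aggregate(count ~ pool + emi, data = observations, FUN = sum)

  out <- lapply(split(observations, observations$pool), function(d) {
    emi <- d$emi
    cnt <- as.integer(d$count)
    n <- length(emi)
    comp <- if (n == 1L) 1L else {
      D <- hammingMatrix(emi)
      idx <- which(D <= maxDist & upper.tri(D), arr.ind = TRUE)
      unionFind(n, idx)
    }
    lapply(split(seq_len(n), comp), function(ix) {
      mem <- setNames(cnt[ix], emi[ix])
      ## consensus: highest count, tie -> lexicographically smallest
      mem <- mem[order(-mem, names(mem))]
      list(pool = d$pool[1L], consensus = names(mem)[1L],
           depth = sum(mem), members = mem)
    })
  })
  flat <- unlist(out, recursive = FALSE, use.names = FALSE)
  cons <- vapply(flat, `[[`, character(1), "consensus")
  pool <- vapply(flat, `[[`, character(1), "pool")
  dep <- vapply(flat, function(x) as.integer(x$depth), integer(1))
  mem <- lapply(flat, `[[`, "members")
  ## deterministic order: pool, then depth desc, then consensus
  o <- order(pool, -dep, cons)
  new("EMIClusterSet", consensus = cons[o], pool = pool[o], depth = dep[o],
      members = mem[o], depthClass = rep(NA_character_, length(o)),
      threshold = numeric(0))
}

#' Threshold EMI clusters into high- and low-depth classes
#'
#' The per-reaction read-depth threshold is the square root of the mean
#' cluster read depth, computed once over all clusters (no iteration). A
#' cluster is high-depth iff its depth strictly exceeds the threshold;
#' boundary depths are classed low. High-depth clusters correspond to
#' genuinely spiked QCT molecules; low-depth clusters arise from residual
#' errors, contamination or index misassignment.
#'
#' @param clusters an [EMIClusterSet-class] from [clusterEMIs()].
#'
#' @return the cluster set with \code{depthClass} and \code{threshold} set.
#' @examples
#' obs <- data.frame(emi = c("AAAAAAAAAA", "CCCCCCCCCC"), count = c(100L, 1L))
#' thresholdClusters(clusterEMIs(obs))
#' @export
thresholdClusters <- function(clusters) {
  stopifnot(is(clusters, "EMIClusterSet"))
  n <- length(clusters)
  if (n == 0L) {
    clusters@threshold <- NA_real_
    return(clusters)
  }
  t <- sqrt(mean(clusters@depth))
  clusters@depthClass <- ifelse(clusters@depth > t, "high", "low")
  clusters@threshold <- t
  clusters
}

#' Summarize a thresholded cluster set into per-reaction molecule counts
#'
#' The number of QCT molecules in the reaction is the number of high-depth
#' clusters; the mean read depth per molecule (the denominator of the
#' genomic-equivalents estimate) is the mean depth of the high-depth
#' clusters, overall and per pool. The fingerprint is the set of
#' \code{"pool:EMI"} keys of the high-depth clusters. A reaction with zero
#' high-depth clusters is flagged as a QC failure.
#'
#' @param clusters a thresholded [EMIClusterSet-class].
#' @param sampleId sample identifier recorded in the summary.
#'
#' @return a [QCTSummary-class] object.
#' @export
summarizeQCT <- function(clusters, sampleId = "sample") {
  stopifnot(is(clusters, "EMIClusterSet"))
  if (length(clusters) > 0L &&
      (!length(clusters@threshold) || anyNA(clusters@depthClass)))
    stop("clusters must be thresholded first (see thresholdClusters())",
         call. = FALSE)
  hi <- which(clusters@depthClass == "high")
  lo <- which(clusters@depthClass == "low")
  nMol <- length(hi)
  if (nMol == 0L)
    warning("sample '", sampleId, "' decoded zero QCT molecules; flagged ",
            "as QC failure")
  perPool <- if (nMol) {
    vapply(split(clusters@depth[hi], clusters@pool[hi]), mean, numeric(1))
  } else numeric(0)
  new("QCTSummary",
      sampleId = as.character(sampleId),
      nMolecules = nMol,
      meanDepth = if (nMol) mean(clusters@depth[hi]) else NA_real_,
      perPoolMeanDepth = perPool,
      depthThreshold = if (length(clusters@threshold))
        clusters@threshold else NA_real_,
      fingerprint = sort(paste(clusters@pool[hi], clusters@consensus[hi],
                               sep = ":")),
      lowClusters = data.frame(pool = clusters@pool[lo],
                               emi = clusters@consensus[lo],
                               depth = clusters@depth[lo],
                               stringsAsFactors = FALSE),
      totalQCTReads = sum(clusters@depth),
      qcPass = nMol > 0L)
}

#' Genomic equivalents from GOI depth and QCT mean depth
#'
#' The absolute number of amplifiable input molecules of the gene of
#' interest (haploid genomic equivalents) is estimated as
#' \code{GE = D_GOI / <D_QCT>}: gene read depth divided by the mean read
#' depth per QCT molecule, which cancels the common amplification factor.
#'
#' @param goiDepth total gene-of-interest read depth (D_GOI).
#' @param summary a [QCTSummary-class] with at least one decoded molecule.
#'
#' @return a list of class \code{MolecularCount} with elements
#'   \code{goiDepth}, \code{genomicEquivalents} and \code{nQCT}.
#' @examples
#' \dontrun{countGE(40000, summary)  # <D_QCT> = 20 -> GE = 2000}
#' @export
countGE <- function(goiDepth, summary) {
  stopifnot(is(summary, "QCTSummary"))
  if (nMolecules(summary) == 0L)
    stop("cannot compute genomic equivalents: sample '", sampleId(summary),
         "' decoded zero QCT molecules", call. = FALSE)
  ge <- goiDepth / meanDepthPerMolecule(summary)
  structure(list(goiDepth = as.integer(goiDepth),
                 genomicEquivalents = ge,
                 nQCT = nMolecules(summary)),
            class = "MolecularCount")
}

#' @export
print.MolecularCount <- function(x, ...) {
  cat("MolecularCount: GE =", format(x$genomicEquivalents, digits = 6),
      "(D_GOI =", x$goiDepth, ", n QCT =", x$nQCT, ")\n")
  invisible(x)
}

#' Decode one sample end to end
#'
#' Convenience wrapper: partition reads, cluster EMIs per pool, threshold,
#' summarize, and estimate genomic equivalents.
#'
#' @inheritParams partitionReads
#' @param sampleId sample identifier.
#' @return list with elements \code{partition}, \code{clusters},
#'   \code{summary} and (when molecules were decoded) \code{count}.
#' @export
decodeSample <- function(reads, assay, sampleId = "sample", maxMismatch = 3L,
                         idMaxMismatch = 0L) {
  part <- partitionReads(reads, assay, maxMismatch = maxMismatch,
                         idMaxMismatch = idMaxMismatch)
  cl <- thresholdClusters(clusterEMIs(qctObservations(part)))
  summ <- withCallingHandlers(
    summarizeQCT(cl, sampleId = sampleId),
    warning = function(w) invokeRestart("muffleWarning"))
  res <- list(partition = part, clusters = cl, summary = summ)
  if (nMolecules(summ) > 0L)
    res$count <- countGE(goiDepth(part), summ)
  res
}

#' Recount molecules after random read subsampling
#'
#' Retains each read independently with probability \code{fraction}, runs
#' the full decode pipeline on both the full and the subsampled read set,
#' and reports both molecule counts. Counts are expected to agree as long
#' as the subsampled depth stays at or above ~10 reads per molecule.
#'
#' @inheritParams partitionReads
#' @param fraction retention probability in (0, 1].
#' @param seed integer seed for the subsampling draw.
#' @return named numeric vector \code{c(full = ..., sub = ...)}.
#' @export
subsampleAndRecount <- function(reads, assay, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  reads <- as.character(reads)
  keep <- if (fraction == 1) rep(TRUE, length(reads)) else
    withSeed(seed, runif(length(reads)) < fraction)
  full <- decodeSample(reads, assay)$summary
  sub <- decodeSample(reads[keep], assay)$summary
  c(full = nMolecules(full), sub = nMolecules(sub))
}

#' @importFrom stats aggregate
NULL
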