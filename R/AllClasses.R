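#' @import methods
NULL

#' Amplicon/QCT assay geometry
#'
#' An \code{QCTAssay} describes one amplicon assay: the reference amplicon
#' sequence, the fixed-offset QCT identifier(s) that distinguish synthetic
#' counting-template (QCT) reads from gene-of-interest (GOI) reads, the
#' offsets of the randomized embedded molecular index (EMI) bases, and the
#' variant loci interrogated by the assay.
#'
#' All offsets are 0-based; spans are half-open. Several QCT pools may be
#' configured for one amplicon (e.g. pools with identifiers \code{"TCGCC"}
#' and \code{"CTAGT"}); they share the identifier offset and the EMI
#' geometry.
#'
#' @slot ampliconName single character name.
#' @slot referenceSeq reference amplicon sequence (A/C/G/T character string).
#' @slot qctIds named character vector, pool id -> QCT identifier sequence;
#'   all identifiers the same length.
#' @slot qctIdOffset 0-based offset of the identifier within the amplicon.
#' @slot emiOffsets integer vector of 0-based offsets of the randomized EMI
#'   bases (10 in the standard design).
#' @slot variantLoci data.frame with columns \code{offset}, \code{ref},
#'   \code{alt} (0-based offset, single reference and alternate base).
#' @slot ampliconLength amplicon length in bp.
#'
#' @seealso [QCTAssay()] for the constructor, [partitionReads()].
#' @exportClass QCTAssay
setClass("QCTAssay", representation(
  ampliconName = "character",
  referenceSeq = "character",
  qctIds = "character",
  qctIdOffset = "integer",
  emiOffsets = "integer",
  variantLoci = "data.frame",
  ampliconLength = "integer"
))

setValidity("QCTAssay", function(object) {
  msg <- character(0)
  if (length(object@ampliconName) != 1L)
    msg <- c(msg, "ampliconName must be a single string")
  if (length(object@referenceSeq) != 1L || !isDNA(object@referenceSeq))
    msg <- c(msg, "referenceSeq must be a single A/C/G/T string")
  if (length(object@qctIds) < 1L || !isDNA(object@qctIds))
    msg <- c(msg, "qctIds must be one or more A/C/G/T strings")
  if (is.null(names(object@qctIds)) || anyDuplicated(names(object@qctIds)))
    msg <- c(msg, "qctIds must have unique pool names")
  if (length(unique(nchar(object@qctIds))) > 1L)
    msg <- c(msg, "all QCT identifiers must have the same length")
  if (anyDuplicated(object@qctIds))
    msg <- c(msg, "QCT identifier sequences must be distinct across pools")
  L <- object@ampliconLength
  if (nchar(object@referenceSeq) != L)
    msg <- c(msg, "referenceSeq length must equal ampliconLength")
  idLen <- nchar(object@qctIds[1L])
  idSpan <- object@qctIdOffset + seq_len(idLen) - 1L
  if (any(object@emiOffsets %in% idSpan))
    msg <- c(msg, "emiOffsets must be disjoint from the QCT identifier span")
  offs <- c(object@emiOffsets, idSpan, object@variantLoci$offset)
  if (any(offs < 0L) || any(offs >= L))
    msg <- c(msg, "all offsets must lie within [0, ampliconLength)")
  if (anyDuplicated(object@emiOffsets))
    msg <- c(msg, "emiOffsets must be unique")
  if (nrow(object@variantLoci)) {
    if (!all(c("offset", "ref", "alt") %in% names(object@variantLoci)))
      msg <- c(msg, "variantLoci needs columns offset, ref, alt")
    else if (!isDNA(object@variantLoci$ref) || !isDNA(object@variantLoci$alt))
      msg <- c(msg, "variantLoci ref/alt must be A/C/G/T bases")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a QCTAssay
#'
#' @param ampliconName name of the amplicon (e.g. \code{"HBB_exon1"}).
#' @param referenceSeq reference amplicon sequence; a character string or a
#'   [Biostrings::DNAString].
#' @param qctIds named character vector of QCT pool identifier sequences.
#' @param qctIdOffset 0-based offset of the identifier within the amplicon.
#' @param emiOffsets 0-based offsets of the randomized EMI bases.
#' @param variantLoci data.frame with columns \code{offset}, \code{ref},
#'   \code{alt}; may be empty.
#'
#' @return a validated \code{QCTAssay} object.
#' @examples
#' ref <- paste(rep("ACGT", 25), collapse = "")
#' assay <- QCTAssay("toy", ref, c(QCT1 = "TCGCC"), qctIdOffset = 20,
#'                   emiOffsets = 40:49)
#' assay
#' @export
QCTAssay <- function(ampliconName, referenceSeq, qctIds, qctIdOffset,
                     emiOffsets,
                     variantLoci = data.frame(offset = integer(0),
                                              ref = character(0),
                                              alt = character(0))) {
  referenceSeq <- toupper(as.character(referenceSeq))
  new("QCTAssay",
      ampliconName = as.character(ampliconName),
      referenceSeq = referenceSeq,
      qctIds = toupper(qctIds),
      qctIdOffset = as.integer(qctIdOffset),
      emiOffsets = as.integer(sort(emiOffsets)),
      variantLoci = variantLoci,
      ampliconLength = nchar(referenceSeq))
}

#' Partition of one sample's reads
#'
#' Result of [partitionReads()]: every read is classified as a QCT
#' observation (it carries a configured QCT identifier at the identifier
#' offset), a gene-of-interest (GOI) read (it matches the reference amplicon
#' outside the variant loci within the mismatch budget), or unmatched. The
#' partition is exhaustive.
#'
#' @slot qctObservations data.frame with columns \code{pool}, \code{emi},
#'   \code{count}: distinct observed EMI sequences per pool and their read
#'   counts.
#' @slot goiAlleleDepth data.frame with columns \code{locus} (0-based
#'   offset), \code{base}, \code{reads}: per-variant-locus read depth by
#'   observed base.
#' @slot goiDepth total GOI read count (D_GOI).
#' @slot unmatched number of unclassifiable reads.
#' @slot totalReads total reads seen.
#' @exportClass ReadPartition
setClass("ReadPartition", representation(
  qctObservations = "data.frame",
  goiAlleleDepth = "data.frame",
  goiDepth = "integer",
  unmatched = "integer",
  totalReads = "integer"
))

setValidity("ReadPartition", function(object) {
  msg <- character(0)
  qctReads <- sum(object@qctObservations$count)
  if (any(object@qctObservations$count < 0L) || object@goiDepth < 0L ||
      object@unmatched < 0L)
    msg <- c(msg, "all counts must be non-negative")
  if (qctReads + object@goiDepth + object@unmatched != object@totalReads)
    msg <- c(msg, "partition must be exhaustive (qct + goi + unmatched = total)")
  if (length(msg)) msg else TRUE
})

#' Single-linkage EMI sequence clusters
#'
#' One element per putative QCT molecule: EMI observations grouped by
#' single-linkage under Hamming distance (<= 2 mismatches by default), with
#' the consensus EMI (highest-count member, ties broken lexicographically),
#' total read depth, and -- after [thresholdClusters()] -- a high/low depth
#' class and the reaction-wide depth threshold.
#'
#' @slot consensus consensus EMI per cluster.
#' @slot pool QCT pool of each cluster.
#' @slot depth total read depth per cluster.
#' @slot members list of named integer vectors (member EMI -> read count).
#' @slot depthClass \code{"high"}/\code{"low"} per cluster (NA before
#'   thresholding).
#' @slot threshold the depth threshold t = sqrt(mean cluster depth)
#'   (length 0 before thresholding).
#' @exportClass EMIClusterSet
setClass("EMIClusterSet", representation(
  consensus = "character",
  pool = "character",
  depth = "integer",
  members = "list",
  depthClass = "character",
  threshold = "numeric"
))

setValidity("EMIClusterSet", function(object) {
  msg <- character(0)
  n <- length(object@consensus)
  if (length(object@pool) != n || length(object@depth) != n ||
      length(object@members) != n || length(object@depthClass) != n)
    msg <- c(msg, "all per-cluster slots must have equal length")
  if (n && !all(object@depth == vapply(object@members, sum, numeric(1))))
    msg <- c(msg, "cluster depth must equal the sum of member counts")
  ok <- object@depthClass %in% c("high", "low") | is.na(object@depthClass)
  if (!all(ok)) msg <- c(msg, "depthClass must be 'high', 'low' or NA")
  if (length(msg)) msg else TRUE
})

#' Per-reaction QCT decoding summary
#'
#' Decoded molecular-counting results for one PCR reaction: the number of
#' spiked QCT molecules (high-depth EMI clusters), the mean read depth per
#' molecule (the denominator of the genomic-equivalents estimate), per-pool
#' mean depths, the depth threshold, and the EMI fingerprint used for
#' contamination tracing and mixup detection.
#'
#' @slot sampleId sample identifier.
#' @slot nMolecules number of high-depth EMI clusters.
#' @slot meanDepth mean read depth per molecule over high-depth clusters.
#' @slot perPoolMeanDepth named numeric, pool -> mean high-cluster depth.
#' @slot depthThreshold sqrt(mean depth over all clusters).
#' @slot fingerprint sorted character vector of \code{"pool:EMI"} keys of the
#'   high-depth clusters.
#' @slot lowClusters data.frame(pool, emi, depth) of the low-depth clusters.
#' @slot totalQCTReads total QCT reads in the reaction (all clusters).
#' @slot qcPass FALSE when the reaction decoded zero molecules.
#' @exportClass QCTSummary
setClass("QCTSummary", representation(
  sampleId = "character",
  nMolecules = "integer",
  meanDepth = "numeric",
  perPoolMeanDepth = "numeric",
  depthThreshold = "numeric",
  fingerprint = "character",
  lowClusters = "data.frame",
  totalQCTReads = "integer",
  qcPass = "logical"
))

setValidity("QCTSummary", function(object) {
  msg <- character(0)
  if (object@nMolecules != length(object@fingerprint))
    msg <- c(msg, "nMolecules must equal the fingerprint size")
  if (object@nMolecules > 0L &&
      (!is.finite(object@meanDepth) || object@meanDepth <= 0))
    msg <- c(msg, "meanDepth must be positive when molecules were decoded")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QCTAssay", function(object) {
  cat("QCTAssay '", object@ampliconName, "': ", object@ampliconLength,
      " bp amplicon\n", sep = "")
  cat("  QCT pools: ",
      paste(names(object@qctIds), object@qctIds, sep = "=", collapse = ", "),
      " at offset ", object@qctIdOffset, "\n", sep = "")
  cat("  EMI bases: ", length(object@emiOffsets), " at offsets ",
      paste(range(object@emiOffsets), collapse = "-"), "\n", sep = "")
  cat("  variant loci: ", nrow(object@variantLoci), "\n", sep = "")
})

setMethod("show", "ReadPartition", function(object) {
  cat("ReadPartition: ", object@totalReads, " reads = ",
      sum(object@qctObservations$count), " QCT + ", object@goiDepth,
      " GOI + ", object@unmatched, " unmatched\n", sep = "")
  cat("  distinct EMIs observed: ", nrow(object@qctObservations), "\n",
      sep = "")
})

setMethod("show", "EMIClusterSet", function(object) {
  n <- length(object@consensus)
  cat("EMIClusterSet with ", n, " cluster(s)\n", sep = "")
  if (length(object@threshold)) {
    cat("  depth threshold: ", format(object@threshold, digits = 4),
        "; high: ", sum(object@depthClass == "high"),
        ", low: ", sum(object@depthClass == "low"), "\n", sep = "")
  } else {
    cat("  not yet thresholded\n")
  }
})

setMethod("show", "QCTSummary", function(object) {
  cat("QCTSummary for '", object@sampleId, "'", if (!object@qcPass)
    " [QC FAIL]", "\n", sep = "")
  cat("  molecules: ", object@nMolecules, "; <D_QCT>: ",
      format(object@meanDepth, digits = 4), " reads/molecule; threshold: ",
      format(object@depthThreshold, digits = 4), "\n", sep = "")
  if (length(object@perPoolMeanDepth))
    cat("  per-pool <D_QCT>: ",
        paste(names(object@perPoolMeanDepth),
              format(object@perPoolMeanDepth, digits = 4),
              sep = "=", collapse = ", "), "\n", sep = "")
})

setMethod("length", "EMIClusterSet", function(x) length(x@consensus))
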