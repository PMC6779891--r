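#' Quantify cross-sample contamination from QCT fingerprints
#'
#' An EMI cluster in sample A is classified as a contaminant iff (i) it is
#' low-depth in A and (ii) its consensus EMI appears in the fingerprint
#' (high-depth set) of some other sample B, in the same QCT pool. The
#' contaminating reads are attributed to B; when several samples' fingerprints
#' contain the EMI, the credit is split equally. The contamination fraction
#' of a sample is the ratio of attributed contaminating QCT reads over its
#' total QCT reads.
#'
#' @param summaries list of [QCTSummary-class] objects (>= 2 samples).
#'
#' @return data.frame with one row per sample: \code{sample},
#'   \code{contamination_fraction}, \code{contaminating_reads},
#'   \code{total_qct_reads}, \code{top_source}, \code{top_source_reads},
#'   \code{unattributed_low_depth_reads}. The full source x destination
#'   attributed-read matrix is attached as attribute \code{"perSource"}.
#' @export
detectContamination <- function(summaries) {
  stopifnot(is.list(summaries),
            all(vapply(summaries, is, logical(1), "QCTSummary")))
  ids <- vapply(summaries, sampleId, character(1))
  names(summaries) <- ids
  n <- length(ids)
  perSource <- matrix(0, n, n, dimnames = list(source = ids,
                                               destination = ids))
  report <- data.frame(sample = ids,
                       contamination_fraction = 0,
                       contaminating_reads = 0,
                       total_qct_reads = vapply(summaries, totalQCTReads,
                                                integer(1)),
                       top_source = NA_character_,
                       top_source_reads = 0,
                       unattributed_low_depth_reads = 0L,
                       stringsAsFactors = FALSE, row.names = NULL)
  if (n < 2L) {
    warning("contamination detection needs at least 2 samples; ",
            "returning an empty report")
    attr(report, "perSource") <- perSource
    return(report)
  }
  fps <- lapply(summaries, fingerprint)
  for (i in seq_len(n)) {
    low <- lowDepthClusters(summaries[[i]])
    if (!nrow(low)) next
    keys <- paste(low$pool, low$emi, sep = ":")
    attributed <- 0
    unattr <- 0L
    for (k in seq_along(keys)) {
      owners <- setdiff(ids[vapply(fps, function(f) keys[k] %in% f,
                                   logical(1))], ids[i])
      if (length(owners)) {
        share <- low$depth[k] / length(owners)
        perSource[owners, ids[i]] <- perSource[owners, ids[i]] + share
        attributed <- attributed + low$depth[k]
      } else {
        unattr <- unattr + low$depth[k]
      }
    }
    report$contaminating_reads[i] <- attributed
    report$unattributed_low_depth_reads[i] <- unattr
    tot <- report$total_qct_reads[i]
    report$contamination_fraction[i] <- if (tot > 0) attributed / tot else 0
    if (attributed > 0) {
      src <- perSource[, ids[i]]
      report$top_source[i] <- names(which.max(src))
      report$top_source_reads[i] <- max(src)
    }
  }
  attr(report, "perSource") <- perSource
  report
}

#' Pairwise fingerprint collision matrix
#'
#' \code{counts[i, j]} is the number of high-depth EMI clusters shared by
#' samples i and j (exact consensus EMI intersection, within pool); the
#' diagonal holds each sample's fingerprint size. Independent reactions
#' share essentially no EMIs (expected collisions ~ size^2 / 4^10), so any
#' substantial off-diagonal count indicates that one PCR was indexed to
#' multiple barcodes.
#'
#' @param summaries list of [QCTSummary-class] objects.
#' @return symmetric integer matrix with sample ids as dimnames.
#' @export
collisionMatrix <- function(summaries) {
  stopifnot(is.list(summaries),
            all(vapply(summaries, is, logical(1), "QCTSummary")))
  ids <- vapply(summaries, sampleId, character(1))
  fps <- lapply(summaries, fingerprint)
  n <- length(ids)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    m[i, i] <- length(fps[[i]])
    if (i < n) for (j in seq((i + 1L), n)) {
      c_ij <- length(intersect(fps[[i]], fps[[j]]))
      m[i, j] <- m[j, i] <- c_ij
    }
  }
  m
}

#' Flag sample pairs with suspiciously many fingerprint collisions
#'
#' @param matrix a [collisionMatrix()] result.
#' @param minCollisions minimum number of shared high-depth clusters for a
#'   pair to be flagged (default 10; duplicated reactions share ~150
#'   clusters while independent ones share ~0, so any value in between
#'   separates them).
#' @return data.frame with columns \code{sample1}, \code{sample2},
#'   \code{collisions} (zero rows when nothing is flagged).
#' @export
flagMixups <- function(matrix, minCollisions = 10L) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            minCollisions >= 1L)
  ids <- rownames(matrix)
  out <- data.frame(sample1 = character(0), sample2 = character(0),
                    collisions = integer(0), stringsAsFactors = FALSE)
  n <- nrow(matrix)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (matrix[i, j] >= minCollisions) {
      out <- rbind(out, data.frame(sample1 = ids[i], sample2 = ids[j],
                                   collisions = as.integer(matrix[i, j]),
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
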