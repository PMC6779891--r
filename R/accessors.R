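#' Accessors for QCTcount classes
#'
#' Small accessor generics so that downstream code never touches slots
#' directly.
#'
#' @param x an object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("consensusEMI", function(x) standardGeneric("consensusEMI"))
#' @rdname accessors
#' @export
setMethod("consensusEMI", "EMIClusterSet", function(x) x@consensus)

#' @rdname accessors
#' @export
setGeneric("clusterDepth", function(x) standardGeneric("clusterDepth"))
#' @rdname accessors
#' @export
setMethod("clusterDepth", "EMIClusterSet", function(x) x@depth)

#' @rdname accessors
#' @export
setGeneric("depthClass", function(x) standardGeneric("depthClass"))
#' @rdname accessors
#' @export
setMethod("depthClass", "EMIClusterSet", function(x) x@depthClass)

#' @rdname accessors
#' @export
setGeneric("clusterPool", function(x) standardGeneric("clusterPool"))
#' @rdname accessors
#' @export
setMethod("clusterPool", "EMIClusterSet", function(x) x@pool)

#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname accessors
#' @export
setMethod("clusterMembers", "EMIClusterSet", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("depthThreshold", function(x) standardGeneric("depthThreshold"))
#' @rdname accessors
#' @export
setMethod("depthThreshold", "EMIClusterSet", function(x) {
  if (length(x@threshold)) x@threshold else NA_real_
})
#' @rdname accessors
#' @export
setMethod("depthThreshold", "QCTSummary", function(x) x@depthThreshold)

#' @rdname accessors
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))
#' @rdname accessors
#' @export
setMethod("nMolecules", "QCTSummary", function(x) x@nMolecules)

#' @rdname accessors
#' @export
setGeneric("meanDepthPerMolecule",
           function(x) standardGeneric("meanDepthPerMolecule"))
#' @rdname accessors
#' @export
setMethod("meanDepthPerMolecule", "QCTSummary", function(x) x@meanDepth)

#' @rdname accessors
#' @export
setGeneric("perPoolMeanDepth", function(x) standardGeneric("perPoolMeanDepth"))
#' @rdname accessors
#' @export
setMethod("perPoolMeanDepth", "QCTSummary", function(x) x@perPoolMeanDepth)

#' @rdname accessors
#' @export
setGeneric("fingerprint", function(x) standardGeneric("fingerprint"))
#' @rdname accessors
#' @export
setMethod("fingerprint", "QCTSummary", function(x) x@fingerprint)

#' @rdname accessors
#' @export
setGeneric("lowDepthClusters", function(x) standardGeneric("lowDepthClusters"))
#' @rdname accessors
#' @export
setMethod("lowDepthClusters", "QCTSummary", function(x) x@lowClusters)

#' @rdname accessors
#' @export
setGeneric("totalQCTReads", function(x) standardGeneric("totalQCTReads"))
#' @rdname accessors
#' @export
setMethod("totalQCTReads", "QCTSummary", function(x) x@totalQCTReads)

#' @rdname accessors
#' @export
setGeneric("qcPass", function(x) standardGeneric("qcPass"))
#' @rdname accessors
#' @export
setMethod("qcPass", "QCTSummary", function(x) x@qcPass)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "QCTSummary", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("qctObservations", function(x) standardGeneric("qctObservations"))
#' @rdname accessors
#' @export
setMethod("qctObservations", "ReadPartition", function(x) x@qctObservations)

#' @rdname accessors
#' @export
setGeneric("goiDepth", function(x) standardGeneric("goiDepth"))
#' @rdname accessors
#' @export
setMethod("goiDepth", "ReadPartition", function(x) x@goiDepth)

#' @rdname accessors
#' @export
setGeneric("goiAlleleDepth", function(x) standardGeneric("goiAlleleDepth"))
#' @rdname accessors
#' @export
setMethod("goiAlleleDepth", "ReadPartition", function(x) x@goiAlleleDepth)

#' @rdname accessors
#' @export
setGeneric("unmatchedReads", function(x) standardGeneric("unmatchedReads"))
#' @rdname accessors
#' @export
setMethod("unmatchedReads", "ReadPartition", function(x) x@unmatched)
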