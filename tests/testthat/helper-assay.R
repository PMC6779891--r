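## Shared toy assay: 150 bp amplicon, QCT identifier at offset 60,
## 10 EMI bases at offsets 70-74 and 80-84, one variant locus at offset 30.
TOY_REF <- paste0(
  "GTCGGTCGTTCCGGACGAAAGGGGTAGGAACACATTTATAAAGCATTATGTAATAGGCAC",
  "CGGGTGCCCTAGGTATGGCTCTGACCCAAGACAGATATTCACGTACAGGTAGCCAGGGCG",
  "TTAATCGGCGCGCCATGTCTGGCTTAAGCA")

toyAssay <- function(pools = c(QCT1 = "TCGCC", QCT2 = "CTAGT"),
                     withVariant = TRUE) {
  refBase <- substr(TOY_REF, 31, 31)
  vl <- if (withVariant) {
    data.frame(offset = 30L, ref = refBase,
               alt = setdiff(c("A", "C", "G", "T"), refBase)[1],
               stringsAsFactors = FALSE)
  } else {
    data.frame(offset = integer(0), ref = character(0), alt = character(0))
  }
  QCTAssay("toy_amplicon", TOY_REF, pools, qctIdOffset = 60L,
           emiOffsets = c(70:74, 80:84), variantLoci = vl)
}

## Build a QCT read carrying a given pool identifier and EMI (10 bases).
toyQCTRead <- function(assay, pool = "QCT1", emi = "AAAAAAAAAA") {
  tmpl <- makeQCTPool(pool, assay@qctIds[[pool]], assay)$template
  b <- strsplit(emi, "")[[1]]
  for (j in seq_along(assay@emiOffsets)) {
    o <- assay@emiOffsets[j]
    substr(tmpl, o + 1, o + 1) <- b[j]
  }
  tmpl
}

## Minimal QCTSummary for integrity tests (fingerprint keys "pool:EMI").
toySummary <- function(id, fingerprint, lowClusters = NULL,
                       totalReads = NULL) {
  if (is.null(lowClusters))
    lowClusters <- data.frame(pool = character(0), emi = character(0),
                              depth = integer(0), stringsAsFactors = FALSE)
  nHigh <- length(fingerprint)
  highReads <- 30L * nHigh
  if (is.null(totalReads))
    totalReads <- highReads + sum(lowClusters$depth)
  new("QCTSummary", sampleId = id, nMolecules = nHigh,
      meanDepth = if (nHigh) 30 else NA_real_,
      perPoolMeanDepth = if (nHigh) c(QCT1 = 30) else numeric(0),
      depthThreshold = 5, fingerprint = sort(fingerprint),
      lowClusters = lowClusters, totalQCTReads = as.integer(totalReads),
      qcPass = nHigh > 0L)
}

## Random EMI strings.
randomEMIs <- function(n, len = 10L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
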