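#' Build a QCTAssay from a YAML or JSON config file
#'
#' The config documents the amplicon geometry with fields
#' \code{amplicon_name}, \code{reference_seq}, \code{qct_ids} (named map
#' pool -> identifier), \code{qct_id_offset}, \code{emi_offsets} (0-based)
#' and optionally \code{variant_loci} (list of \code{offset}/\code{ref}/
#' \code{alt} entries).
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a [QCTAssay].
#' @export
readAssayConfig <- function(path) {
  if (!file.exists(path))
    stop("assay config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vl <- cfg$variant_loci
  vl <- if (is.null(vl) || length(vl) == 0L) {
    data.frame(offset = integer(0), ref = character(0), alt = character(0))
  } else if (is.data.frame(vl)) vl else {
    do.call(rbind, lapply(vl, as.data.frame))
  }
  QCTAssay(ampliconName = cfg$amplicon_name,
           referenceSeq = cfg$reference_seq,
           qctIds = unlist(cfg$qct_ids),
           qctIdOffset = cfg$qct_id_offset,
           emiOffsets = unlist(cfg$emi_offsets),
           variantLoci = vl)
}

## VAF at the assay's first variant locus from a partition's per-base depths.
partitionVAF <- function(partition, assay, shearFactor = 1) {
  ad <- goiAlleleDepth(partition)
  if (!nrow(assay@variantLoci) || !nrow(ad)) return(NULL)
  o <- assay@variantLoci$offset[1L]
  d <- ad[ad$locus == o, ]
  refD <- sum(d$reads[d$base == assay@variantLoci$ref[1L]])
  altD <- sum(d$reads[d$base == assay@variantLoci$alt[1L]])
  if (refD + altD == 0) return(NULL)
  alleleFraction(refD, altD, shearFactor)
}

#' Run the decode -> integrity -> quantify -> call pipeline
#'
#' For every row of the sample sheet the FASTQ is read and decoded
#' (partition, EMI clustering, depth thresholding, molecule count, genomic
#' equivalents). Fingerprints of all samples are then crossed for
#' contamination and mixup detection. If the sample sheet carries
#' \code{maternal_genotype} and \code{fetal_fraction} columns, the NIPT
#' caller is applied to the per-sample VAF at the assay's variant locus.
#' All outputs are plain TSV/JSON; re-running with identical inputs
#' produces byte-identical files.
#'
#' @param sampleSheet data.frame (or TSV path) with columns
#'   \code{sample_id} and \code{fastq}, optionally
#'   \code{maternal_genotype}, \code{fetal_fraction},
#'   \code{shear_factor}.
#' @param assay a [QCTAssay] or the path to a config readable by
#'   [readAssayConfig()].
#' @param outDir output directory (created if needed); NULL skips writing.
#' @param permissive keep going (with a warning) when a sample fails QC;
#'   otherwise QC failures raise an error.
#' @param minGE minimum genomic equivalents for NIPT calling (default 200).
#' @param maxMismatch GOI mismatch budget, as in [partitionReads()].
#' @return (invisibly) a list with \code{summaries}, \code{qctTable},
#'   \code{contamination}, \code{collisions}, \code{mixups} and, when
#'   calling was possible, \code{calls}.
#' @export
runPipeline <- function(sampleSheet, assay, outDir = NULL,
                        permissive = FALSE, minGE = 200, maxMismatch = 3L) {
  if (is.character(sampleSheet)) {
    if (!file.exists(sampleSheet))
      stop("sample sheet not found: ", sampleSheet, call. = FALSE)
    sampleSheet <- read.delim(sampleSheet, stringsAsFactors = FALSE)
  }
  if (is.character(assay)) assay <- readAssayConfig(assay)
  stopifnot(is(assay, "QCTAssay"))
  if (nrow(sampleSheet) == 0L)
    stop("sample sheet is empty: nothing to run", call. = FALSE)
  if (!all(c("sample_id", "fastq") %in% names(sampleSheet)))
    stop("sample sheet needs columns 'sample_id' and 'fastq'", call. = FALSE)
  if (anyDuplicated(sampleSheet$sample_id))
    stop("sample ids must be unique", call. = FALSE)
  missing <- !file.exists(sampleSheet$fastq)
  if (any(missing))
    stop("FASTQ file(s) not found: ",
         paste(sampleSheet$fastq[missing], collapse = ", "), call. = FALSE)

  decoded <- lapply(seq_len(nrow(sampleSheet)), function(i) {
    reads <- readFastqSeqs(sampleSheet$fastq[i])
    decodeSample(reads, assay, sampleId = sampleSheet$sample_id[i],
                 maxMismatch = maxMismatch)
  })
  names(decoded) <- sampleSheet$sample_id
  summaries <- lapply(decoded, `[[`, "summary")

  qctTable <- data.frame(
    sample_id = sampleSheet$sample_id,
    n_qct = vapply(summaries, nMolecules, integer(1)),
    mean_depth_per_molecule = vapply(summaries, meanDepthPerMolecule,
                                     numeric(1)),
    depth_threshold = vapply(summaries, depthThreshold, numeric(1)),
    goi_depth = vapply(decoded, function(d) goiDepth(d$partition),
                       integer(1)),
    genomic_equivalents = vapply(decoded, function(d)
      if (is.null(d$count)) NA_real_ else d$count$genomicEquivalents,
      numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  failed <- !vapply(summaries, qcPass, logical(1)) |
    (is.na(qctTable$genomic_equivalents) |
       qctTable$genomic_equivalents < minGE)
  if (any(failed)) {
    msg <- paste0("QC failure (zero molecules or < ", minGE, " GE): ",
                  paste(sampleSheet$sample_id[failed], collapse = ", "))
    if (permissive) warning(msg) else stop(msg, call. = FALSE)
  }

  contamination <- if (length(summaries) >= 2L)
    detectContamination(summaries) else NULL
  collisions <- collisionMatrix(summaries)
  mixups <- flagMixups(collisions)

  calls <- NULL
  if (all(c("maternal_genotype", "fetal_fraction") %in% names(sampleSheet))) {
    vafRows <- lapply(seq_along(decoded), function(i) {
      sf <- if ("shear_factor" %in% names(sampleSheet))
        sampleSheet$shear_factor[i] else 1
      v <- partitionVAF(decoded[[i]]$partition, assay, sf)
      if (is.null(v)) NA_real_ else v$vaf
    })
    tbl <- data.frame(sample_id = sampleSheet$sample_id,
                      maternal_genotype = sampleSheet$maternal_genotype,
                      vaf = unlist(vafRows),
                      n_molecules = round(qctTable$genomic_equivalents),
                      fetal_fraction = sampleSheet$fetal_fraction,
                      stringsAsFactors = FALSE)
    ok <- !is.na(tbl$vaf) & !is.na(tbl$n_molecules) & tbl$n_molecules >= 1
    if (any(ok)) calls <- callNIPTTable(tbl[ok, ], minMolecules = minGE)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTSV <- function(d, f)
      write.table(d, file.path(outDir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    writeTSV(qctTable, "qct_summary.tsv")
    fps <- lapply(summaries, fingerprint)
    jsonlite::write_json(fps, file.path(outDir, "fingerprints.json"),
                         auto_unbox = FALSE, pretty = TRUE)
    if (!is.null(contamination)) writeTSV(contamination, "contamination.tsv")
    writeTSV(as.data.frame(collisions), "collisions.tsv")
    if (nrow(mixups)) writeTSV(mixups, "mixups.tsv")
    if (!is.null(calls)) writeTSV(calls, "nipt_calls.tsv")
  }

  invisible(list(summaries = summaries, qctTable = qctTable,
                 contamination = contamination, collisions = collisions,
                 mixups = mixups, calls = calls))
}
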