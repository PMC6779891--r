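#' Bundled clinical validation measurements
#'
#' Published cfDNA measurements for 27 pregnancies with newborn follow-up
#' genotyping: 14 samples analysed on the paternal-inheritance track
#' (homozygous mother; maternal genotype inferred from the VAF side) and 13
#' on the recessive-inheritance track (heterozygous carrier mother). Each
#' row carries the measured fetal fraction, variant allele fraction,
#' molecule count N, the originally reported likelihood ratio
#' (\code{lr_printed}; error-vs-paternal orientation for the paternal
#' track, affected-vs-het for the recessive track), the reported NIPT
#' result and the follow-up neonate genotype.
#'
#' These measurements are the canonical worked example for the caller:
#' \code{callNIPTTable(niptValidationMeasurements())} reproduces all 27
#' reported calls.
#'
#' @return data.frame with 27 rows.
#' @examples
#' tbl <- niptValidationMeasurements()
#' calls <- callNIPTTable(tbl)
#' sum(niptConcordance(calls, tbl$neonate_genotype))   # 27
#' @export
niptValidationMeasurements <- function() {
  path <- system.file("extdata", "nipt_validation_measurements.tsv",
                      package = "QCTcount", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    track = "character", sample_id = "character",
    fetal_fraction = "numeric", vaf = "numeric", n_molecules = "integer",
    lr_printed = "numeric", nipt_printed = "character",
    neonate_genotype = "character", maternal_genotype = "character"))
}
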