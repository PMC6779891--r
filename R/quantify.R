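#' Variant allele fraction from read depths
#'
#' \code{vaf = shearFactor * alt / (ref + alt)}, clamped to [0, 1]. The
#' optional shear factor corrects for the over-representation of shorter
#' alleles among amplifiable fragments of sheared DNA (see
#' [shearingCorrection()]).
#'
#' @param refDepth,altDepth reference/alternate read depths (vectors allowed).
#' @param shearFactor multiplicative correction factor (default 1).
#' @return data.frame with columns \code{ref_depth}, \code{alt_depth},
#'   \code{vaf}, \code{shear_factor_applied}.
#' @examples
#' alleleFraction(500, 500)                 # vaf 0.5
#' alleleFraction(1000, 1042, 0.980)        # vaf 0.5001
#' @export
alleleFraction <- function(refDepth, altDepth, shearFactor = 1) {
  stopifnot(all(refDepth >= 0), all(altDepth >= 0))
  total <- refDepth + altDepth
  if (any(total == 0))
    stop("allele fraction undefined at zero total depth", call. = FALSE)
  data.frame(ref_depth = refDepth, alt_depth = altDepth,
             vaf = clamp01(shearFactor * altDepth / total),
             shear_factor_applied = shearFactor)
}

#' Shearing correction factor for alleles of unequal span
#'
#' Random fragmentation with mean fragment length L is modelled as a
#' geometric process: a fragment covers a span of b bases with probability
#' \code{(1 - 1/L)^b}. An allele whose amplicon span is shorter (e.g. a
#' 3 bp deletion) is therefore over-represented among amplifiable
#' fragments; the correction factor
#' \code{(1 - 1/L)^spanLong / (1 - 1/L)^spanShort} rescales its measured
#' fraction. Only the span difference matters (translation invariance).
#'
#' @param meanFragmentLen mean fragment length L in bp (> 1).
#' @param spanLong,spanShort amplicon spans (bp) of the longer and shorter
#'   allele.
#' @return the correction factor (a scalar <= 1 when spanLong >= spanShort).
#' @examples
#' shearingCorrection(150, 100, 97)   # 0.980
#' @export
shearingCorrection <- function(meanFragmentLen, spanLong, spanShort) {
  if (meanFragmentLen <= 1) stop("meanFragmentLen must be > 1", call. = FALSE)
  stopifnot(spanLong >= 1, spanShort >= 1)
  (1 - 1 / meanFragmentLen)^spanLong / (1 - 1 / meanFragmentLen)^spanShort
}

#' Fraction of fragments amplifiable by an amplicon of a given span
#'
#' \code{(1 - 1/L)^span}: the geometric-model probability that a random
#' fragment of mean length L spans both primer binding sites.
#'
#' @inheritParams shearingCorrection
#' @param span amplicon span in bp.
#' @export
amplifiableFraction <- function(meanFragmentLen, span) {
  if (meanFragmentLen <= 1) stop("meanFragmentLen must be > 1", call. = FALSE)
  (1 - 1 / meanFragmentLen)^span
}

#' Poisson counting coefficient of variation
#'
#' Sampling N molecules carries irreducible counting noise with
#' CV = 100/sqrt(N) percent, reported to one decimal. This is the physical
#' precision limit of any molecule-counting assay.
#'
#' @param nMolecules number of molecules (>= 1; vector allowed).
#' @return CV in percent, one decimal.
#' @examples
#' poissonCV(c(2200, 2000, 3500))  # 2.1 2.2 1.7
#' @export
poissonCV <- function(nMolecules) {
  if (any(nMolecules < 1)) stop("nMolecules must be >= 1", call. = FALSE)
  round(100 / sqrt(nMolecules), 1)
}

#' Capture efficiency of genomic equivalents per nanogram
#'
#' @param ge measured genomic equivalents.
#' @param massNg input DNA mass in ng (> 0).
#' @param haploidMassPg haploid genome mass in pg (default 3.6, giving a
#'   theoretical maximum of 1000/3.6 = 277.8 GE/ng).
#' @return list with \code{ge_per_ng}, \code{theoretical_max_ge_per_ng} and
#'   \code{fraction_of_theoretical}.
#' @examples
#' captureEfficiency(1920, 30)   # 64 GE/ng, ~23% of theoretical
#' @export
captureEfficiency <- function(ge, massNg, haploidMassPg = 3.6) {
  stopifnot(massNg > 0, haploidMassPg > 0, ge >= 0)
  gePerNg <- ge / massNg
  theo <- 1000 / haploidMassPg
  list(ge_per_ng = gePerNg,
       theoretical_max_ge_per_ng = theo,
       fraction_of_theoretical = gePerNg / theo)
}

#' Classify panel SNVs as paternally inherited
#'
#' A locus where the mother is homozygous shows a minor allele fraction of
#' ~ff/2 in cfDNA when the fetus inherited a different paternal allele, and
#' ~0 otherwise. A locus is classified paternally inherited iff its MAF
#' lies in the band [0.005, 0.20] (inclusive).
#'
#' @param maf named numeric vector of per-locus minor allele fractions,
#'   each in [0, 0.5].
#' @param lower,upper band bounds (defaults 0.005 and 0.20).
#' @return the classified subset of \code{maf} (named).
#' @export
classifyPaternalSNVs <- function(maf, lower = 0.005, upper = 0.20) {
  stopifnot(all(maf >= 0), all(maf <= 0.5))
  maf[maf >= lower & maf <= upper]
}

#' Fetal fraction from paternally inherited SNV MAFs
#'
#' The fetal fraction is estimated as twice the median MAF of paternally
#' inherited panel SNVs: \code{ff = 2 * epsilon_hat * adjustment}, where
#' epsilon_hat is the median MAF of \code{nLoci} selected loci. When more
#' than \code{nLoci} loci are classified, the \code{nLoci} with MAF closest
#' to the median of all classified MAFs are selected (robust to outliers).
#' Fewer than \code{nLoci} classified loci mark the estimate unreliable
#' (still computed over the available loci, but flagged).
#'
#' @param classifiedMAF named numeric vector of MAFs of classified loci
#'   (from [classifyPaternalSNVs()]).
#' @param nLoci number of loci used for the median (default 9).
#' @param adjustment multiplicative calibration applied to the fetal
#'   fraction (default 1; the HBB exon 1 assay uses 0.74).
#' @return list of class \code{FetalFractionEstimate}: \code{per_snv_maf},
#'   \code{selected_loci}, \code{epsilon_hat}, \code{fetal_fraction},
#'   \code{adjustment}, \code{reliable}.
#' @examples
#' maf <- setNames(rep(0.05, 9), paste0("L", 1:9))
#' fetalFraction(maf)$fetal_fraction   # 0.10
#' @export
fetalFraction <- function(classifiedMAF, nLoci = 9L, adjustment = 1.0) {
  reliable <- length(classifiedMAF) >= nLoci
  if (!reliable)
    warning("only ", length(classifiedMAF), " classified loci (need ",
            nLoci, "); fetal fraction flagged unreliable")
  if (length(classifiedMAF) == 0L) {
    est <- list(per_snv_maf = classifiedMAF, selected_loci = character(0),
                epsilon_hat = NA_real_, fetal_fraction = NA_real_,
                adjustment = adjustment, reliable = FALSE)
    return(structure(est, class = "FetalFractionEstimate"))
  }
  if (is.null(names(classifiedMAF)))
    names(classifiedMAF) <- paste0("locus", seq_along(classifiedMAF))
  ctr <- median(classifiedMAF)
  sel <- names(sort(abs(classifiedMAF - ctr)))[
    seq_len(min(nLoci, length(classifiedMAF)))]
  eps <- median(classifiedMAF[sel])
  structure(list(per_snv_maf = classifiedMAF, selected_loci = sort(sel),
                 epsilon_hat = eps,
                 fetal_fraction = 2 * eps * adjustment,
                 adjustment = adjustment, reliable = reliable),
            class = "FetalFractionEstimate")
}

#' @export
print.FetalFractionEstimate <- function(x, ...) {
  cat("FetalFractionEstimate: ff =",
      format(x$fetal_fraction, digits = 4),
      "(epsilon_hat =", format(x$epsilon_hat, digits = 4),
      ", adjustment =", x$adjustment, ")",
      if (!x$reliable) "[UNRELIABLE]", "\n")
  invisible(x)
}
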