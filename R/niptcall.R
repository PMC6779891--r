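#' Expected cfDNA variant allele fraction
#'
#' cfDNA is a mixture of maternal and fetal DNA; each molecule carries the
#' variant allele with probability
#' \code{p = (1 - ff) * dose_m/2 + ff * dose_f/2}, where dose is the number
#' of variant alleles in the respective genotype. E.g. a heterozygous
#' mother carrying a homozygous-variant fetus at 10\% fetal fraction gives
#' p = 0.55.
#'
#' @param ff fetal fraction in [0, 1].
#' @param maternalGenotype,fetalGenotype genotype strings (\code{"0/0"},
#'   \code{"0/1"}, \code{"1/1"}); vectors are recycled.
#' @return expected variant allele fraction.
#' @examples
#' expectedVAF(0.10, "0/1", "1/1")  # 0.55
#' expectedVAF(0.20, "0/1", "1/1")  # 0.60
#' @export
expectedVAF <- function(ff, maternalGenotype, fetalGenotype) {
  stopifnot(all(ff >= 0), all(ff <= 1))
  (1 - ff) * genotypeDose(maternalGenotype) / 2 +
    ff * genotypeDose(fetalGenotype) / 2
}

## Effective epsilon: half the (calibration-adjusted) fetal fraction --
## the expected non-maternal allele fraction contributed by the fetus.
niptEpsilon <- function(fetalFraction, adjustment) {
  adjustment * fetalFraction / 2
}

#' Likelihood ratio for paternal inheritance vs sequencing error
#'
#' For a homozygous mother, a fetal allele inherited from the father
#' appears at non-maternal allele fraction ~epsilon = adjusted ff/2. The
#' binomial likelihood of the observed non-maternal allele fraction x_eff
#' under paternal inheritance (success probability epsilon) is compared to
#' the sequencing-error model (success probability s_err):
#' \deqn{\log LR = N x_{eff} \log(\epsilon/s) +
#'       N (1 - x_{eff}) \log((1-\epsilon)/(1-s))}
#' The binomial coefficients cancel in the ratio, so non-integer
#' \code{N*x} needs no rounding. All computation is in log space; both
#' orientations are returned (published tables print the reciprocal,
#' error vs paternal).
#'
#' @param vaf measured variant allele fraction in [0, 1].
#' @param nMolecules number of molecules assayed (N).
#' @param fetalFraction fetal fraction (pre-adjustment).
#' @param maternalGenotype \code{"0/0"} or \code{"1/1"} (a heterozygous
#'   mother has no paternal-inheritance test).
#' @param adjustment calibration factor applied to the fetal fraction
#'   (default 0.74, the HBB exon 1 assay calibration).
#' @param sErr sequencing error rate (default 0.005).
#' @return data.frame with columns \code{x_eff}, \code{log10_lr_paternal},
#'   \code{lr_paternal}, \code{lr_error_vs_paternal}.
#' @examples
#' # Table-style worked example: ff 0.174, VAF 0.961, N 436, mother 1/1
#' lrPaternal(0.961, 436, 0.174, "1/1")
#' @export
lrPaternal <- function(vaf, nMolecules, fetalFraction, maternalGenotype,
                       adjustment = 0.74, sErr = 0.005) {
  stopifnot(all(vaf >= 0), all(vaf <= 1), all(nMolecules >= 1),
            sErr > 0, sErr < 0.5)
  n <- max(length(vaf), length(nMolecules), length(fetalFraction),
           length(maternalGenotype))
  vaf <- rep_len(vaf, n); nMolecules <- rep_len(nMolecules, n)
  fetalFraction <- rep_len(fetalFraction, n)
  maternalGenotype <- rep_len(maternalGenotype, n)
  if (any(maternalGenotype %in% c("0/1", "1/0")))
    stop("paternal-inheritance LR is undefined for a heterozygous mother",
         call. = FALSE)
  eps <- niptEpsilon(fetalFraction, adjustment)
  if (any(eps <= 0) || any(eps >= 1))
    stop("adjusted fetal fraction gives epsilon outside (0, 1)",
         call. = FALSE)
  xEff <- ifelse(maternalGenotype == "0/0", vaf, 1 - vaf)
  logLR <- nMolecules * xEff * log(eps / sErr) +
    nMolecules * (1 - xEff) * log((1 - eps) / (1 - sErr))
  data.frame(x_eff = xEff,
             log10_lr_paternal = logLR / log(10),
             lr_paternal = exp(logLR),
             lr_error_vs_paternal = exp(-logLR))
}

#' Likelihood ratio for an affected vs a heterozygous fetus
#'
#' For a heterozygous (carrier) mother, a homozygous-variant (affected)
#' fetus shifts the expected variant allele fraction from 1/2 to
#' 1/2 + epsilon (epsilon = adjusted ff/2), while a heterozygous fetus
#' leaves it at 1/2. The binomial likelihood ratio p_aff/p_het reduces to
#' \deqn{\log LR = N x \log(1 + 2\epsilon) + N (1 - x) \log(1 - 2\epsilon)}
#' (binomial coefficients and the 1/2^N factor cancel).
#'
#' @inheritParams lrPaternal
#' @return data.frame with columns \code{log10_lr_recessive},
#'   \code{lr_recessive}.
#' @examples
#' # ff 0.219, VAF 0.603, N 1611 -> LR ~ 1.8e14 (affected)
#' lrRecessive(0.603, 1611, 0.219)
#' @export
lrRecessive <- function(vaf, nMolecules, fetalFraction, adjustment = 0.74) {
  stopifnot(all(vaf >= 0), all(vaf <= 1), all(nMolecules >= 1))
  eps <- niptEpsilon(fetalFraction, adjustment)
  if (any(2 * eps >= 1) || any(eps <= 0))
    stop("adjusted fetal fraction must give 0 < 2*epsilon < 1",
         call. = FALSE)
  logLR <- nMolecules * vaf * log(1 + 2 * eps) +
    nMolecules * (1 - vaf) * log(1 - 2 * eps)
  data.frame(log10_lr_recessive = logLR / log(10),
             lr_recessive = exp(logLR))
}

#' Call the fetal genotype from one cfDNA measurement
#'
#' For a heterozygous mother the recessive track is used: the fetus is
#' called \code{"affected"} (homozygous variant) when the affected-vs-het
#' likelihood ratio strictly exceeds \code{lrHigh}, \code{"normal"} when it
#' is strictly below \code{lrLow}, and \code{"no-call"} otherwise. For a
#' homozygous mother the paternal track is used: \code{"het"} (the fetus
#' inherited a distinct paternal allele) when the paternal-vs-error LR
#' strictly exceeds \code{lrHigh}, \code{"hom-matching-mother"} when it is
#' strictly below \code{lrLow}, else \code{"no-call"}. The no-call band is
#' open on both sides: an LR of exactly 8 or 1/8 is a no-call. Samples with
#' fewer than \code{minMolecules} molecules are no-calls on QC grounds.
#'
#' @inheritParams lrPaternal
#' @param maternalGenotype genotype string(s); determines the track.
#' @param lrHigh,lrLow call thresholds (defaults 8 and 1/8).
#' @param minMolecules minimum molecule count for a call (default 200).
#' @return data.frame with columns \code{maternal_genotype}, \code{track},
#'   \code{log10_lr}, \code{call}, \code{fetal_genotype} (NA where the call
#'   implies a genotype set rather than a single genotype), \code{qc_pass}.
#' @examples
#' niptCall("0/1", 0.603, 1611, 0.219)    # affected
#' niptCall("1/1", 0.961, 436, 0.174)     # het (paternal allele detected)
#' @export
niptCall <- function(maternalGenotype, vaf, nMolecules, fetalFraction,
                     adjustment = 0.74, sErr = 0.005,
                     lrHigh = 8, lrLow = 1 / 8, minMolecules = 200L) {
  stopifnot(lrHigh > 1, lrLow < 1, lrLow > 0)
  n <- max(length(vaf), length(nMolecules), length(fetalFraction),
           length(maternalGenotype))
  maternalGenotype <- rep_len(maternalGenotype, n)
  vaf <- rep_len(vaf, n); nMolecules <- rep_len(nMolecules, n)
  fetalFraction <- rep_len(fetalFraction, n)

  track <- ifelse(maternalGenotype %in% c("0/1", "1/0"),
                  "recessive", "paternal")
  log10LR <- numeric(n)
  call <- character(n)
  fetalGT <- rep(NA_character_, n)
  log10Hi <- log10(lrHigh); log10Lo <- log10(lrLow)

  rec <- track == "recessive"
  if (any(rec)) {
    lr <- lrRecessive(vaf[rec], nMolecules[rec], fetalFraction[rec],
                      adjustment)
    log10LR[rec] <- lr$log10_lr_recessive
    call[rec] <- ifelse(lr$log10_lr_recessive > log10Hi, "affected",
                        ifelse(lr$log10_lr_recessive < log10Lo, "normal",
                               "no-call"))
    fetalGT[rec] <- ifelse(call[rec] == "affected", "1/1", NA_character_)
  }
  pat <- !rec
  if (any(pat)) {
    lr <- lrPaternal(vaf[pat], nMolecules[pat], fetalFraction[pat],
                     maternalGenotype[pat], adjustment, sErr)
    log10LR[pat] <- lr$log10_lr_paternal
    call[pat] <- ifelse(lr$log10_lr_paternal > log10Hi, "het",
                        ifelse(lr$log10_lr_paternal < log10Lo,
                               "hom-matching-mother", "no-call"))
    fetalGT[pat] <- ifelse(call[pat] == "het", "0/1",
                           ifelse(call[pat] == "hom-matching-mother",
                                  maternalGenotype[pat], NA_character_))
  }
  qc <- nMolecules >= minMolecules
  call[!qc] <- "no-call"
  fetalGT[!qc] <- NA_character_
  data.frame(maternal_genotype = maternalGenotype, track = track,
             vaf = vaf, n_molecules = nMolecules,
             fetal_fraction = fetalFraction,
             log10_lr = log10LR, call = call, fetal_genotype = fetalGT,
             qc_pass = qc, stringsAsFactors = FALSE)
}

#' Call a table of NIPT measurements
#'
#' Applies [niptCall()] row-wise to a data.frame shaped like the clinical
#' validation tables: columns \code{sample_id}, \code{maternal_genotype},
#' \code{vaf}, \code{n_molecules}, \code{fetal_fraction}. When the
#' \code{maternal_genotype} column is absent, homozygous maternal genotypes
#' are inferred from the VAF (\code{"0/0"} below 0.5, \code{"1/1"} at or
#' above) -- valid for paternal-track tables only.
#'
#' @param tbl input data.frame.
#' @inheritParams niptCall
#' @return the input with the [niptCall()] result columns appended.
#' @export
callNIPTTable <- function(tbl, adjustment = 0.74, sErr = 0.005,
                          lrHigh = 8, lrLow = 1 / 8, minMolecules = 200L) {
  need <- c("vaf", "n_molecules", "fetal_fraction")
  if (!all(need %in% names(tbl)))
    stop("input table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"maternal_genotype" %in% names(tbl))
    tbl$maternal_genotype <- ifelse(tbl$vaf < 0.5, "0/0", "1/1")
  res <- niptCall(tbl$maternal_genotype, tbl$vaf, tbl$n_molecules,
                  tbl$fetal_fraction, adjustment = adjustment, sErr = sErr,
                  lrHigh = lrHigh, lrLow = lrLow,
                  minMolecules = minMolecules)
  cbind(tbl[setdiff(names(tbl), names(res))], res)
}

#' Concordance of NIPT calls with follow-up genotypes
#'
#' A paternal-track call is concordant when the inferred fetal genotype
#' equals the follow-up genotype. A recessive-track call is concordant when
#' \code{"affected"} matches a homozygous-variant follow-up and
#' \code{"normal"} matches a heterozygous or homozygous-reference
#' follow-up. No-calls are never concordant.
#'
#' @param calls a [callNIPTTable()]/[niptCall()] result.
#' @param neonateGenotype follow-up genotype strings, parallel to
#'   \code{calls}.
#' @return logical vector of per-row concordance.
#' @export
niptConcordance <- function(calls, neonateGenotype) {
  stopifnot(nrow(calls) == length(neonateGenotype))
  ifelse(calls$call == "no-call", FALSE,
         ifelse(calls$track == "paternal",
                calls$fetal_genotype == neonateGenotype,
                (calls$call == "affected") == (neonateGenotype == "1/1")))
}

#' Monte Carlo sensitivity/specificity of recessive-inheritance NIPT
#'
#' Simulates pregnancies of carrier (heterozygous) mothers: the father is a
#' carrier with probability \code{carrierRate}; the fetal genotype is a
#' Mendelian draw; the measured variant allele fraction is
#' Binomial(N, expected VAF)/N; and the recessive-track caller is applied.
#' Sensitivity and specificity are computed among called samples ("affected"
#' = positive; truth = homozygous-variant fetus); the no-call rate is
#' reported separately.
#'
#' @param nSims number of simulated pregnancies.
#' @param fetalFraction fetal fraction: a scalar or a function(n) returning
#'   draws.
#' @param nMolecules molecule count: a scalar or a function(n).
#' @param carrierRate paternal carrier probability (default 1/12).
#' @param adjustment calibration factor for the simulated assay (default 1:
#'   the simulated fetal fraction is the true one).
#' @param lrHigh,lrLow,minMolecules call thresholds as in [niptCall()].
#' @param seed integer seed.
#' @return list: \code{sensitivity}, \code{specificity}, \code{no_call_rate},
#'   \code{n_affected}, \code{n_called}.
#' @export
monteCarloPerformance <- function(nSims, fetalFraction, nMolecules,
                                  carrierRate = 1 / 12, adjustment = 1,
                                  lrHigh = 8, lrLow = 1 / 8,
                                  minMolecules = 0L, seed = NULL) {
  stopifnot(nSims >= 1)
  drawOr <- function(x, n) if (is.function(x)) x(n) else rep_len(x, n)
  withSeed(seed, {
    ff <- drawOr(fetalFraction, nSims)
    N <- round(drawOr(nMolecules, nSims))
    fatherCarrier <- runif(nSims) < carrierRate
    ## mother 0/1; fetus: one maternal allele (Bernoulli 1/2) + one paternal
    maternalAllele <- rbinom(nSims, 1L, 0.5)
    paternalAllele <- ifelse(fatherCarrier, rbinom(nSims, 1L, 0.5), 0L)
    dose <- maternalAllele + paternalAllele
    fetusGT <- c("0/0", "0/1", "1/1")[dose + 1L]
    p <- expectedVAF(ff, "0/1", fetusGT)
    x <- rbinom(nSims, N, p) / N
    calls <- niptCall(rep("0/1", nSims), x, N, ff, adjustment = adjustment,
                      lrHigh = lrHigh, lrLow = lrLow,
                      minMolecules = minMolecules)
    affected <- fetusGT == "1/1"
    called <- calls$call != "no-call"
    sens <- if (any(affected & called))
      mean(calls$call[affected & called] == "affected") else NA_real_
    spec <- if (any(!affected & called))
      mean(calls$call[!affected & called] == "normal") else NA_real_
    list(sensitivity = sens, specificity = spec,
         no_call_rate = mean(!called),
         n_affected = sum(affected), n_called = sum(called))
  })
}
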