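---
title: "QCT molecular counting and single-gene NIPT: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QCT molecular counting and single-gene NIPT: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(QCTcount)
```

## The counting model

Amplicon sequencing destroys absolute abundance information: per-molecule
PCR efficiency varies severalfold, so read depth alone cannot say how many
input molecules a reaction contained. Quantitative Counting Templates
(QCTs) restore that information. A QCT is a synthetic copy of the target
amplicon that (i) shares the primer binding sites and length of the gene
of interest (GOI), so it co-amplifies at the same rate, (ii) carries a
short fixed pool identifier that distinguishes QCT reads from genomic
reads, and (iii) contains an embedded molecular index (EMI) of 10 bases
randomized at synthesis. Because a pool holds up to $4^{10}$ distinct
EMIs and only ~100–1000 molecules are spiked per reaction, each spiked
molecule is (almost) uniquely labeled.

Decoding proceeds in four steps:

1. **Partition** (`partitionReads`): a read is a QCT observation iff it
   carries a configured pool identifier at the identifier offset (exact
   match by default — identifiers of different pools differ by at least 5
   bases, so a mismatch budget buys nothing and risks misassignment).
   Remaining reads are GOI reads if they match the reference amplicon
   outside the variant loci within a mismatch budget (default 3),
   otherwise unmatched. The partition is exhaustive by construction.
2. **EMI clustering** (`clusterEMIs`): observed EMIs are grouped by
   single linkage under Hamming distance ≤ 2, per pool, collapsing
   PCR/sequencing-error derivatives onto their parent molecule. The
   consensus is the highest-count member, ties broken lexicographically,
   making the result deterministic and permutation-invariant.
3. **Depth thresholding** (`thresholdClusters`): the per-reaction
   threshold is $t = \sqrt{\overline{d}}$ with $\overline{d}$ the mean
   cluster depth over *all* clusters, computed once with no iteration.
   Clusters with depth strictly above $t$ are genuine molecules; the rest
   are residual errors, contamination, or index misassignment. The
   boundary case (depth exactly $t$) is classed low; with the strongly
   bimodal depth distributions this assay produces, the choice is
   immaterial but must be fixed.
4. **Counting** (`summarizeQCT`, `countGE`): the molecule count is the
   number of high-depth clusters; $\langle D_{QCT}\rangle$ is their mean
   depth; and the GOI molecular count in genomic equivalents is
   $GE = D_{GOI} / \langle D_{QCT}\rangle$.

One point the thresholding rule leaves open is which clusters enter
$\langle D_{QCT}\rangle$. This package uses high-depth clusters only: low
clusters are by definition not amplified molecules, and including their
1–2 read depths would bias $GE$ upward. The threshold mean, by contrast,
deliberately uses all clusters, since it must sit between the two modes.

## Integrity: fingerprints, contamination, mixups

The set of high-depth consensus EMIs of a reaction is a fingerprint of
essentially unbounded diversity. A low-depth cluster in sample A whose
consensus appears in the fingerprint of sample B (same pool, exact string
match — fingerprints are post-clustering consensus sequences, so a
mismatch radius is not needed) is a contaminating trace of B's material.
The contamination fraction is contaminated QCT reads over total QCT
reads. When several fingerprints contain the same EMI the credit is split
equally — the data cannot distinguish the true source, and equal splitting
keeps the per-source matrix additive. Pairwise fingerprint intersections
(`collisionMatrix`) expose mixups: duplicated indexing of one PCR shares
on the order of the full fingerprint (~100+ clusters), while independent
reactions share essentially none (expected $\approx n_1 n_2/4^{10}$), so
any flagging threshold between those extremes works; the default is 10.

## The NIPT likelihood-ratio model

cfDNA from a pregnancy is a mixture: a molecule carries the variant with
probability $p = (1-f\!f)\,d_m/2 + f\!f\,d_f/2$, where $d_m, d_f$ are
maternal/fetal variant doses. Measurement is modeled as Binomial($N$,
$p$) over the $N$ molecules actually assayed — which is why the molecule
count, not the read depth, sets the precision (Poisson CV $=
100/\sqrt{N}$%). With $\varepsilon$ = half the (calibrated) fetal
fraction:

- paternal track (homozygous mother): paternal-inheritance likelihood
  with success probability $\varepsilon$ vs sequencing-error likelihood
  with $s = 0.005$; the binomial coefficients cancel, so the log-LR is
  linear in the measured non-maternal fraction and non-integer $N x$
  needs no rounding.
- recessive track (carrier mother): affected ($p = 1/2 + \varepsilon$)
  vs heterozygous ($p = 1/2$) fetus; the ratio reduces to
  $N x \ln(1+2\varepsilon) + N(1-x)\ln(1-2\varepsilon)$.

All computation stays in log space; magnitudes up to $10^{\pm 90}$ arise
in real samples and $N$ up to $10^7$ is safe. Calls require the LR to
*strictly* exceed 8 (or fall strictly below 1/8); the band between is an
open no-call interval. Samples with fewer than 200 molecules are no-calls
on QC grounds (configurable), reflecting the practice of excluding
low-yield cfDNA samples.

Three further conventions are inferred rather than dictated:

- The 0.74 fetal-fraction calibration is applied inside $\varepsilon$ on
  *both* tracks. It is an assay-level calibration between the SNV-panel
  fetal fraction and the target amplicon, and applying it in the caller
  reproduces the bundled validation rows far better than omitting it.
  The panel-level fetal fraction itself is reported unadjusted.
- The recessive track has no explicit homozygous-reference model; a
  measured fraction below 1/2 simply drives the affected-vs-het LR to
  tiny values and a "normal" call, which is the clinically relevant
  dichotomy.
- Monte Carlo sensitivity/specificity (`monteCarloPerformance`) are
  computed among called samples, with the no-call rate reported
  separately, so that call-rate and accuracy trade off transparently.

The fetal fraction itself is estimated as twice the median minor allele
fraction of paternally inherited panel SNVs, classified by the inclusive
band $0.005 \le \mathrm{MAF} \le 0.20$. When more than 9 loci qualify,
the 9 with MAF closest to the median of all classified MAFs are used —
a selection that is robust to outlier loci and reduces to "all of them"
in the typical case; an explicit locus list can be supplied instead.
Fewer than 9 classified loci flag the estimate unreliable.

## What the simulator emulates — and what it does not

`simConfig()` defaults are the package's reference conditions:

| parameter | default | units | rationale |
|---|---|---|---|
| `nQCTMoleculesMean` | 100 | molecules | the 1x spike-in level; draws are Poisson |
| `nGOIMolecules` | 2000 | molecules | typical cfDNA input per reaction |
| `depthPerMolecule` | 30 | reads | the regime where cluster depths sit well above the threshold |
| `amplificationBiasSD` | 0.5 | log-units | lognormal per-molecule depth; ±2 sd spans ~7–8 fold, the spread seen between the best- and worst-amplified molecules |
| `seqErrorRate` | 0.001 | per base | Q30-class substitution errors, i.i.d.; qualities are constant and unused |
| `meanFragmentLen` | off | bp | optional geometric thinning $(1-1/L)^{\mathrm{span}}$ of amplifiable molecules, for sheared/cfDNA capture studies |

Plate-level effects: liquid-handling contamination duplicates a fraction
of a source's QCT reads into a destination as low-depth EMIs; index
misassignment swaps one index per affected read. Contaminant depths are
drawn as $1 + \mathrm{Bernoulli}(0.02)$ — "1–2x", but singleton-
dominated, because two independent read-level hops of the same molecule
into the same destination are orders of magnitude rarer than one. This
matters: with, say, equal weight on depths 1 and 2, a well containing
*only* contaminant reads would have mean cluster depth ≈ 1.5 and
threshold ≈ 1.2, so every depth-2 cluster would masquerade as a genuine
molecule and the measured contamination fraction would saturate near
50% instead of approaching 100%. Under a combinatorial (Truseq-style)
layout a swapped index usually lands on another valid sample; under
dual-unique indexing any single swap produces an invalid pair and the
read is discarded — which is exactly why dual-unique indexing suppresses
observed contamination.

The generator does not model chimeric reads, PCR jackpotting beyond the
lognormal, position- or motif-dependent error profiles, quality-score
information, or instrument-specific artifacts. Passing tests therefore
demonstrate correctness of the decoding and calling logic under a clean
generative model, not robustness to every failure mode of real
sequencing runs.

## Numerical and degenerate-input choices

- Offsets are 0-based, spans half-open, throughout.
- Empty read streams partition to all-zero; an empty cluster set has an
  undefined threshold and decodes to zero molecules with a QC-fail flag;
  zero decoded molecules make $GE$ an error rather than an infinity.
- Reads too short to cover the configured offsets are counted unmatched
  and warned about.
- VAFs are clamped to $[0,1]$ after shearing correction.
- All stochastic functions accept explicit seeds; plate simulation
  derives per-sample child seeds (kept within 32-bit range), and outputs
  are byte-identical for identical inputs and seeds. Replicate studies
  should draw from a single seeded stream rather than consecutive
  integer seeds, whose first draws are correlated.

## Known limitations

- **EMI birthday collisions.** Two spiked molecules whose EMIs fall
  within Hamming distance 2 are inherently indistinguishable and merge
  into one cluster. For 10-base EMIs the per-pair probability is
  $\approx 4.2\times10^{-4}$, i.e. ~2 merges at 100 molecules but ~10%
  at 400 molecules and growing quadratically. The package's property
  tests therefore score recovery against the number of *distinguishable*
  spiked molecules; assays counting many hundreds of molecules per pool
  should use more EMI bases or a smaller linkage radius.
- The shearing correction and capture model assume geometric
  fragmentation with a single mean fragment length.
- The caller treats molecules as exchangeable draws; read-depth noise is
  assumed negligible (valid at the ≥ 10 reads/molecule the decoder
  needs anyway) and maternal genotype is assumed known.
- Contamination reporting is diagnostic only: contaminated reads are not
  removed from downstream counts.

## Test problem sizes

The test and acceptance suites run reactions of 100–400 QCT molecules at
4–30 reads/molecule, plates of 4–18 samples, SNV panels of 86 loci at
2000 molecules/locus, LR oracles at $N \le 60$, and $10^4$ Monte Carlo
pregnancies — sizes at which every property being asserted has adequate
statistical power while the full suite completes in well under a minute
per file.
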