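---
title: "Detecting and quantifying aquatic eDNA with TaqMan qPCR: models, limits and decision rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying aquatic eDNA with TaqMan qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednaqpcr)
```

## The problem

Freshwater crayfish — and aquatic species generally — shed DNA into the
water around them. A litre of filtered lake water, extracted and assayed
with a species-specific TaqMan qPCR, can therefore reveal whether a species
is present without ever catching it. Making that inference defensible
requires more than a fluorescence trace: a calibration from cycle
thresholds to copy numbers, explicit limits of detection (LOD) and
quantification (LOQ), a guard against PCR inhibition by co-extracted humic
substances, replicate-based decision rules that control false positives,
and evidence that the primers and probe will not amplify co-occurring
relatives. This package implements that whole chain of analysis and a
synthetic plate generator with which every link can be tested end to end.

## The calibration model

Detected wells follow the standard log-linear qPCR response

$$Ct = b_0 + b_1 \log_{10}(\text{copies/reaction}),$$

fitted by ordinary least squares over the detected replicates of a
dilution-standard series (`fit_standard_curve()`). Non-detect replicates
are excluded, not imputed at the cycle budget: imputation would drag the
curve toward the censoring limit precisely where single-molecule noise is
largest. The amplification efficiency follows from the slope as
$E = (10^{-1/b_1} - 1) \cdot 100\%$, with $b_1 = -1/\log_{10} 2 \approx
-3.32$ corresponding to perfect per-cycle doubling. Inversion
(`copies_from_ct()`) is only defined for detected wells; callers must
branch on detection first, which the decision rules below do.

Two kinds of standards are supported. Purified double-stranded amplicon
standards are quantified fluorometrically and converted to copies via the
molecular weight of the 65-bp duplex (`oligo_molecular_weight()`,
`copies_per_ul_from_mass()`; per-nucleotide monophosphate masses with the
terminal phosphate subtracted, strand plus reverse complement for the
duplex). Genomic-DNA standards have no independently known copy number;
there the series is anchored statistically, as follows.

## Poisson occupancy and MPN anchoring

At limiting dilution, template molecules partition into reactions
approximately as a Poisson process, so a standard with a mean of
$\lambda$ copies/reaction is detected with probability
$p = 1 - e^{-\lambda}$ (`detection_probability()`). Observing $k$ positives
of $n$ replicates at one dilution inverts to the most-probable-number
estimate $\hat\lambda = -\ln\frac{n-k}{n}$ (`mpn_estimate()`); a 7:3
positive:negative ratio corresponds to $\hat\lambda \approx 1.2$, i.e.
roughly one copy per reaction. The estimate is propagated up the series by
the dilution fold (`propagate_standard_copies()`), which is how a four-fold
genomic series acquires copy numbers such as $2.4 \cdot 4^7 = 39321.6$ at
its top standard. We use the single-dilution closed form rather than
multi-dilution maximum likelihood because the anchoring protocol reads
exactly one standard — the one nearest 70% detection; a saturated standard
(no negatives) is escalated by running further replicates, never by
pretending a negative. Clopper–Pearson intervals on the positive fraction,
transformed through $-\ln(1-p)$, are available but optional output.

## Two LOD/LOQ schemes

*Replicate rule* (`lod_loq_danish()`): LOD is the lowest standard with at
least one positive of (by default) three replicates; LOQ the lowest with
all replicates positive. The two can coincide when one dilution satisfies
both, so they are kept as separate outputs.

*Statistical/repeatability rule* (`lod_statistical()`, `loq_norwegian()`):
LOD is the smallest $\lambda$ with false-negative probability
$e^{-\lambda} < \alpha$, i.e. $\ln(1/\alpha) \approx 3$ copies at
$\alpha = 0.05$ — a candidate working LOD of 5 copies/reaction passes with
a false-negative rate of 0.67%. LOQ is the lowest standard whose replicate
Ct standard deviation stays below 0.5 cycles with all replicates detected.

In both schemes a replicate counts as positive only if its Ct lies below
the reliability cutoff (default 41 cycles; `censor_cutoff()` retains the
raw value in an audit column). The boundary is censored inclusively —
a Ct of exactly 41 is not detected; 40.7 is.

## Inhibition and the three-branch quantification rule

Running each extract both undiluted and ten-fold diluted turns the dilution
itself into an internal inhibition control: without inhibition the diluted
replicates trail by $\log_2 10 = 3.32$ cycles. The observed
$\Delta Ct$ (`delta_ct()`, mean diluted minus mean undiluted over detected
replicates) is classified against the window $3.32 \pm 0.5$
(`classify_inhibition()`), boundaries inclusive — the exception branches
are defined by strict inequalities, which forces the window to keep its
edges. Quantification (`quantify_norwegian()`) then uses: all four
replicates (diluted scaled by 10) when the window holds; the diluted pair
alone under inhibition; the undiluted pair alone when the dilution
overshoots. Detection requires at least two positive replicates of four —
a single positive is reported as 0 — and quantification additionally
requires at least two of the branch-relevant replicates at or above the
LOQ in their own reaction; otherwise the verdict is "<LOQ". When one
dilution level is entirely negative the $\Delta Ct$ is not assessable and
quantification is never attempted; the sample is flagged `not_assessed`.

The four-undiluted-replicate variant (`detect_danish()`) applies the same
two-of-four detection gate against the LOD, and when quantifying lets
non-detect replicates enter the mean as zero copies — the convention under
which a 3/4-positive sample above LOQ is averaged over all four wells.

Copy numbers per reaction convert to copies per litre of filtered water by

$$C_L = C_r \cdot \frac{V_e / V_r}{V_w},$$

with $V_e$ the elution volume, $V_r$ the template volume per reaction and
$V_w$ the filtered volume (`copies_per_liter()`). At $V_e = 200$ µL,
$V_r = 2$ µL and $V_w = 5$ L, per-reaction limits of 5 and 10 copies map
to 100 and 200 copies/L. The elution volume of the 5 µL-template workflow
is not fixed by the protocol and is therefore an explicit context
parameter; the worked analyses use 100 µL.

Site summaries (`summarize_site()`) average copies/L across a site's
filters with not-detected filters as zero; below-LOQ filters are counted
and flagged but never imputed (no LOQ/2 conventions), since any imputation
would manufacture precision the replicate design cannot support. A
log10-binned level grade (grade 1 starting at a configurable base, capped
at 5) supports coarse mapping.

## Specificity screening

`specificity_table()` scans each assay's forward primer and probe along the
sense strand and its reverse primer along the antisense strand of every
record (`best_window_mismatches()`), reporting the minimum Hamming mismatch
count over all placements, leftmost on ties. Records are degapped before
scanning, so pre-aligned FASTA input is acceptable; coordinates refer to
the degapped sequence. IUPAC codes in an oligo match any base in their set;
codes in a record match iff the base sets intersect — the conservative
choice, since an ambiguous record position *might* be complementary.
Best-window scanning was chosen over fixed alignment columns because it
never overstates a mismatch count: a count of $m$ means no placement
anywhere does better, which is the claim a specificity screen must defend.
No thermodynamic modelling ($T_m$, $\Delta G$) is attempted; the metric is
the mismatch count alone.

`synthetic_nontarget_records()` builds a labelled-synthetic stand-in for a
non-target CO1 collection: records derived from the consensus of the four
assay design amplicons, mutated at a fixed number of columns per oligo
region to bases carried by no assay, guaranteeing a known minimum mismatch
separation. It emulates the *separation structure* of real congener
sequences, not their phylogeny; passing the screen on it shows the scanner
and the flagging logic work, not that the published assays are specific
against every real relative — that claim needs real sequence collections.

## The synthetic plate generator

`simulate_reactions()` draws realized copies $k \sim
\text{Poisson}(\lambda)$ per well, emits a non-detect at $k = 0$, and
otherwise generates $Ct = b_0 + b_1\log_{10}k + \varepsilon$,
$\varepsilon \sim N(0, \sigma)$, censored at the 50-cycle budget, plus an
additive inhibition shift in undiluted wells. Generating Ct from the
*realized* rather than expected copy number is what reproduces the
stochastic sub-LOQ scatter real trace samples show; it also means
noiseless series are exactly log-linear only in the high-copy limit.
Defaults: slope $-3.32$, intercept 40, $\sigma = 0.3$ cycles — chosen once
so that replicate repeatability approaches the 0.5-cycle SD boundary near
a 10-copy LOQ, matching how the repeatability rule behaves on real series —
and inhibition modelled as a constant Ct shift on undiluted wells only,
fully removed by ten-fold dilution: the minimal model consistent with the
$\Delta Ct$ remedy. The generator does not model eDNA transport or
degradation, sequence-level amplification bias, or between-plate effects;
site truth is stated directly in copies/L. Tests passing on this generator
therefore validate the statistical machinery, not field sampling designs.

`simulate_survey()` lays out whole plates — Danish-style (4 undiluted
wells/filter) or Norwegian-style (2 + 2) — with no-template and extraction
blank controls that stay negative unless a contamination rate is
configured, plus the ground-truth table for recovery tests.

## Numerical and design choices

- Non-detects are `NA` throughout and never coerce to a numeric Ct; file
  round trips preserve them via a configurable token (default `"ND"`).
- Plate files are plain CSV with a documented five-column header; the
  package does not parse proprietary instrument exports.
- $R^2$ is computed from residuals directly so that noiseless synthetic
  standards do not trigger spurious perfect-fit warnings.
- Efficiency is reported in percent at 0.1% display precision.
- The verdict renderer prints "0", "<LOQ" or "mean (SD)" — the reporting
  convention of eDNA survey tables.
- Validation problem sizes: curve-recovery and inhibition properties use
  40 fixed seeds; end-to-end recovery uses 100 seeds of a four-site survey
  with per-run calibration, and MPN recovery uses 1000 reactions per seed.
  At these sizes the statistical guards (median recovery within ±25%,
  ≥90–95% of seeds in tolerance) are comfortably separated from the
  failure modes they police.

## Known limitations

Single-plate calibration only (no mixed-effect multi-plate curves, no
weighted or robust regression); the MPN machinery assumes ideal Poisson
partitioning (no pipetting overdispersion); the specificity screen counts
mismatches without position weighting, though a 3'-terminal mismatch
suppresses amplification far more than a central one; and site summaries
deliberately refuse to combine quantified and below-LOQ filters into one
number. The per-litre limits scale with the filtered volume, so they are
survey-design quantities, not assay constants.
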