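---
title: "Methods: a tiered methylation screen for chromosome 15 imprinting disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a tiered methylation screen for chromosome 15 imprinting disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscreen)
```

## The measurement model

The screen rests on one biological fact: the *SNRPN* promoter at 15q11.2 is
methylated on the maternal allele and unmethylated on the paternal allele.
Writing `k_mat` for methylated maternal copies and `c` for total copies over
the imprinted region, the expected methylation fraction of a genotype is
`m = k_mat / c`:

| genotype | `k_mat / c` | m |
|---|---|---|
| control | 1/2 | 0.50 |
| PWS (deletion, UPD or imprinting defect) | 1/1 | 1.00 |
| AS (deletion or nondeletion epimutation) | 0/2 or 0/1 | 0.00 |
| AS by *UBE3A* point mutation | 1/2 | 0.50 |
| maternal interstitial duplication | 2/3 | 0.667 |
| idic15 (supernumerary) | 3/4 | 0.75 |
| tricentric 15 | 5/7 | 0.714 |

Mosaic cases blend with the euploid baseline:
`m = f * m_class + (1 - f) * 0.5` for abnormal-cell fraction `f`
(`true_methylation()`). Two entries are modelling assumptions rather than
empirically anchored values: the tricentric methylation (5/7 from the
parent-of-origin arithmetic) and its 7-copy profile. The *UBE3A* class exists
so the screen's known blind spot is representable; its default prevalence is
zero and its methylation (0.50) is indistinguishable from controls by design.

## What the cohort generator emulates — and what it does not

`draw_measured_ratios()` maps a genotype's `m` to a measured first-tier ratio
in three steps:

1. **Bisulfite conversion failure.** A fraction `eps = 0.02` of unmethylated
   cytosines escapes conversion and reads as methylated:
   `centre = m + eps * (1 - m)`. This single mechanism centres controls at
   0.51 rather than 0.50 — the observed population mean — while leaving fully
   methylated samples at 1.
2. **Population scatter.** Normal noise with SD `control_sd` for controls and
   `affected_sd` for disease classes.
3. **Archival tail broadening.** Blood spots stored for years at room
   temperature develop heavier distribution tails. With probability
   `w = min(0.02 * storage_years, 0.2)` the noise draw is replaced by an
   unscaled Student-t with `df = max(3, 8 - storage_years)`. Both the weight
   and the degrees of freedom move with storage time, so tail mass (empirical
   kurtosis) is nondecreasing in storage years — a property the test suite
   asserts on 12 000 simulated controls.

Two named profiles fix these parameters (`noise_profile()`):

* **`archival`** — `control_sd = 0.0776` so that, with the t-tail mixture at
  five storage years, the total control SD is 0.085 and the ±3 SD span is
  0.255. The ±3-empirical-SD exceedance is then a few tenths of a percent of
  the cohort, which is what makes a first-tier referral list of order
  0.5% emerge from controls alone. This profile reproduces the population
  *distribution*.
* **`calibrated`** — `control_sd = 0.05`, `affected_sd = 0.01`, no tails.
  This is the separation-guaranteed setting used for end-to-end tier-flow
  reproduction, and its values come from an explicit margin analysis rather
  than from fitting: the binding constraint is the idic15 class. Its expected
  measured ratio is `0.75 + 0.02 * 0.25 = 0.755` plus quantifier error
  (bounded by 0.02), and it must exceed the sd-rule upper threshold
  `0.51 + 3 * control_sd` by at least three affected-class SDs while staying
  three SDs below the fixed 0.88 band. With `control_sd = 0.05` the upper
  threshold sits near 0.66, leaving ≥ 0.07 of clearance on one side and
  ≥ 0.10 on the other. Under the archival SD of 0.085 the same expectation
  (0.755–0.775) sits essentially *at* mean + 3 SD = 0.765, so whether an
  idic15 newborn is flagged is a coin flip — the two profiles make that
  trade-off explicit instead of hiding it in a seed.

The generator emulates class mixes, parent-of-origin methylation, copy-number
architecture, conversion bias, storage tails and plate effects. It does **not**
emulate: sex or cell-composition effects, DNA-quality-driven assay dropout,
GC bias in sequencing (bins are uniform; a real-data pipeline would normalise
counts upstream), inter-locus crosstalk, or *UBE3A* point mutations appearing
at realistic prevalence. Passing tests therefore demonstrate that the callers
are correct *given this forward model*, not that the assays perform to these
numbers on real blood spots — the validation-cohort sensitivities and
specificities of the source assays were measured on real archived samples and
are deliberately not asserted anywhere in this package.

## Tier 1: melt-curve quantification

`simulate_melt()` renders `F(T) = m * S(T; Tm_meth) + (1-m) * S(T; Tm_unmeth)`
with `S` a falling logistic. Defaults: grid 65–95 °C at 0.1 °C (301 points),
`Tm_unmeth = 78`, `Tm_meth = 82` (bisulfite-converted unmethylated template is
AT-richer and melts ~4 °C earlier), width 0.6 °C. The quantifier
(`raw_area_fraction()`) computes −dF/dT, smooths it with a Savitzky-Golay
local polynomial (window 11, order 3), and splits the area at the valley
between the two transition peaks; the high-Tm share estimates `m`.

Numerical choices:

* A *peak* must be an interior local maximum of the smoothed derivative inside
  a ±2 °C window around its nominal Tm; a monotone shoulder does not count.
  Curves with a single transition return exactly 0 or 1 with a `single_peak`
  qc flag rather than an error.
* If the two peak positions degenerate (less than two grid steps apart), the
  split falls back to the midpoint of the nominal Tm values.
* Raw fractions are mildly nonlinear in `m` (peak-overlap crosstalk of a few
  percent); `fit_calibration()` removes this with a spiked-standard series
  (isotonic regression, linear interpolation, at least three mix levels
  including 0 and 1; inversions larger than 0.05 reject the calibration).
  The test suite holds the calibrated quantifier to |error| ≤ 0.02 across a
  21-level grid, noise-free, and demonstrates recovery of a 30%
  channel-efficiency amplification bias to within 0.02.
* `quantify_plate()` estimates a per-plate shift from control wells (observed
  minus expected calibrated ratio), preferring mid-range standards because
  controls at 0 or 1 truncate; plates without a PWS control and spiked
  standards are rejected, and shifts beyond 0.05 qc-flag the plate's calls.

Thresholds (`compute_thresholds()`): the sd-rule normal range is mean ± k·SD
of the supplied population (plain sample SD by default — the tails are part of
the distribution being summarised; a median/MAD option exists behind
`robust =`), clipped to [0, 1], with *strictly outside* flagging, so a ratio
exactly at a bound is negative. The conservative mode uses fixed inclusive
bands (≤ 0.12, ≥ 0.88). Populations under 100 samples are refused for the sd
rule and directed to fixed thresholds. Referral percentages round half away
from zero to two decimals.

## Tier 2: droplet PCR and CNV qPCR

**Droplet methylation.** Template partitions into ~20 000 droplets; each
channel's concentration is `lambda = -ln(neg/total)` copies per droplet
(`poisson_lambda()`), with `neg = 0` a saturation error propagated as a qc
failure, never a confirmed call. The methylation ratio
`lambda_m / (lambda_m + lambda_u)` is symmetric under channel swap and
consistent (bias < 0.005 at 100 000 droplets in the test suite). The
competitive-priming nested chemistry itself is abstracted to an unbiased
two-channel measurement: downstream logic depends only on the ratio and its
reference range. Confirmation uses the min/max of ≥ 20 storage-matched
control wells, expanded by a guard band (pipeline default 0.05): the min/max
of n exchangeable controls excludes a fresh null sample with probability
≈ 2/(n+1) (~9.5% at n = 20), so a raw min/max range would generate false
confirmations among the tier-1 false positives; the guard band encodes the
fact that true positives sit ≥ 0.25 from the null ratio while null samples
scatter within ~0.01. A mean ± k·SD range is available behind a flag. Absolute
copies/µL assumes a 0.85 nL droplet volume (documented assumption; only
ratios matter downstream).

**CNV qPCR.** Quantities are read off target and reference standard curves
(`Ct = intercept + slope * log10(q)`; 100% efficiency = slope −3.3219, qc
floor r² ≥ 0.98, efficiency within 0.8–1.1) and the ratio is
`2 * bias * q_SNRPN / q_HBB`. The per-assay `bias = 0.91` is the midpoint of
the empirical 2-copy range (1.62–2.02) over 2 — the empirical ranges are not
centred on integer copy numbers, so the scale is empirical. Deletions deviate
further (1-copy range centred at 1.115, not 0.91), which the simulator encodes
as a per-copy distortion table; the uniform-bias arithmetic alone would place
a deletion at 0.91, below the 1-copy floor. Classification is inclusive at
range endpoints, indeterminate in gaps, with values below all ranges or above
the 5-copy range flagged for third-tier reflex. The 4-, 5- and 7-copy ranges
are synthetic (no empirical minima/maxima available): `centre * 10^(±3σ)` with
σ = 0.015 on the log10 scale — the dispersion at which ±3σ reproduces the
relative widths of the two empirical ranges.

The Ct noise model decomposes the total per-well SD (default 0.15) into a
shared per-sample component (input mass, lysate quality, run effects —
identical for target and reference wells from one lysate, hence cancelled by
the beta-globin normalisation, which is the point of normalising) and an
independent well component (default 0.035 Ct, the value consistent with the
empirical range widths). Under that decomposition simulated copy numbers
reclassify to themselves with ≥ 99% accuracy at total Ct SD 0.15, which the
suite asserts at 500 replicates per class. Had the full 0.15 been independent
per well, the implied ratio spread (~16%) would contradict the width of the empirical
±11% ranges — the decomposition is forced by the data, not tuned to the test.
Replicate averaging is available (`replicates =`) but the default models the
single-punch reality.

## Tier 3: low-coverage WGS

Bins are 50 kb over chr15:20.0–35.0 Mb; counts are Poisson with mean
`coverage * c / 2` and the log2 ratio is taken against the median count of
reference bins outside the BP1–BP5 neighbourhood (±1 Mb) — the within-region
median would be wrong for an idic15, where diploid bins are the minority. A
0.5 pseudo-count keeps zero-count bins finite. Segmentation median-smooths
(window 5), classifies bins to the nearest band `log2(c/2)` within ±0.25,
absorbs unclassifiable bins and runs shorter than 4 bins into whichever
flanking run has the closer band, then re-assigns each segment's copy number
from its mean raw log2 ratio (averaging n bins shrinks noise by √n) and
re-merges. Segmentation is idempotent, and internal 0-based half-open
coordinates convert to 1-based inclusive HGVS `g.` strings by an exact
bijection (property-tested on random segments).

Subtype assignment snaps segment boundaries to BP1–BP5 within 500 kb
(defaults BP1 = 22.30, BP2 = 23.10, BP3 = 28.30, BP4 = 30.30, BP5 = 32.25 Mb
on NC_000015.9; approximate, overridable). The copy number over the imprinted
centre is the *length-weighted mode* across 23.6–27.8 Mb rather than a point
lookup, so a short spurious segment cannot flip the call. CN = 1 spanning
BP1–BP3 is a type I deletion, BP2–BP3 type II (AS vs PWS resolved by the
tier-1 methylation band); CN = 4 is idic15, with breakpoints reported at the
distal copy-number transitions where the supernumerary's arms end; CN = 3 is
an interstitial duplication; CN ≥ 5 tricentric; anything unsnappable is
unclassified with raw coordinates retained. At 50 reads per bin the suite
observes perfect subtype recovery over 100 simulations per class; accuracy
degrades at a few reads per bin, which the package reports rather than
guarantees.

## Orchestration, reflex rule and statistics

`run_screen()` derives an independent sub-seed per stage, so editing one stage
never silently changes another, and a fixed config reproduces its report
exactly. Plates carry a shared normal plate effect (SD 0.01 archival / 0.005
calibrated) on the template scale, exercised and removed by the control
correction. The tier-3 reflex rule is configurable because no single
rule is canonical: the default (`"extremes"`) sends the lowest and highest
CNV-ratio outliers among the flags, the pattern confirmatory sequencing
typically follows when material is scarce; `"all_outliers"` reflexes every
non-2-copy call.

Statistics follow screening conventions: PPV = confirmed/flagged; prevalence =
confirmed/screened with Clopper-Pearson exact intervals (beta-quantile
inversion, equal to brute-force binomial tail inversion to 1e-9 in the suite)
and "1 in N" rendering with half-away-from-zero rounding (two confirmed in
16 579 gives 1 in 8290); percents render to one decimal, two decimals below
1%. Tier-flow conservation (`screened = negative + flagged`;
`flagged = confirmed + unconfirmed + qc-failed`) is asserted on every run.

## Problem sizes and limitations

The shipped tests run the full pipeline at cohort sizes 16 579 (once, the
end-to-end reproduction) and 800–3000 elsewhere, with 100–500 replicates for
Monte-Carlo properties — sizes chosen to pin each property without redundant
repetition. Known limitations: the melt quantifier's valley split degrades
when the two transitions are closer than ~2 sigmoid widths (not the regime
modelled here); ddPCR confirmation assumes storage-matched controls — a
mismatch would shift the reference range; CNV classes 4 and 5 are separated by
only 1.25× and depend on the well-to-well noise staying near 0.035 Ct; and an
AS case caused by a *UBE3A* point mutation is invisible to every tier by
construction.
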