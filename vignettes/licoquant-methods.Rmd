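---
title: "Methods: targeted GC–MS/MS quantification and brain PK of licochalcone A"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted GC-MS/MS quantification and brain PK of licochalcone A}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(licoquant)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the design choices made where the
design was genuinely open, and what the synthetic-data tests do and do not
demonstrate about real data.

## The assay in one paragraph

Licochalcone A (LCA, C21H22O4) carries two phenolic hydroxyls and is not
GC-volatile; silylation with BSTFA replaces both hydroxyl hydrogens with
trimethylsilyl groups, giving the 2-TMS derivative C27H38O4Si2 that elutes
at ~11.2 min under the final oven program. Icaritin, a prenylflavonoid with
three active hydroxyls (3-TMS derivative), serves as internal standard (IS)
at 0.5 µg/mL; all quantification uses the analyte/IS quantifier-area ratio.
Identity is established qualitatively (retention time, Kováts index, MRM
ion ratios against a same-batch reference standard, true-negative blanks,
carry-over checks), the method is validated to ICH M10/FDA bioanalytical
criteria over 0.5–20 µg/mL of brain homogenate, and brain exposure is
profiled by non-compartmental analysis of a destructive-sampling
concentration–time design.

## Mass and method-design arithmetic

**TMS bookkeeping.** Each substitution is net +C3H8Si: −1 H, +3 C, +9 H,
+1 Si. Nominal masses are sums of most-abundant-isotope integer masses (the
scale a unit-resolution quadrupole reports); monoisotopic masses use IUPAC
values embedded as constants, carried at full precision and displayed to
two decimals. Fragment annotation is subtraction of a named neutral loss
(Me = CH3, 15 Da; OMe = OCH3, 31 Da) from the derivative's nominal mass, or
direct computation for named fragment ions such as the chalcone A-ring
acylium C10H13O2Si+ (193). These are exact integer identities; tests assert
them exactly.

**Oven programs.** A program is an initial hold plus ordered linear ramps
with optional holds; the duration is the exact rational sum
`hold0 + Σ[(ΔT)/rate + hold]`. The shortened assay program computes to
15.6667 min; the conventional one-decimal quotation truncates this to
15.6 min, and the tests document that rounding explicitly. Cooling ramps
are rejected — the trajectory must be monotone non-decreasing.

**Kováts index.** The index is implemented exactly in its printed
logarithmic form (base-10 logs of raw retention times), although for
temperature-programmed runs a linear interpolation is more conventional;
fidelity to the published form wins, and `log = FALSE` exposes the linear
variant. The bracketing C20/C21 alkane retention times are not published;
`ladder_from_index_pairs()` solves the two-equation linear system in log
retention time from two (RT, index) pairs, and the round-trip test requires
both indices to re-evaluate to two decimals. This reconstructed ladder is a
consistency construct, not measured data.

**MRM selection and scheduling.** From a product-ion scan the most abundant
product (at its best collision energy) becomes the quantifier and the next
two become qualifiers, with expected relative abundances reported as
`100/x`. Abundance ties break toward the lower product m/z (an arbitrary
but fixed convention). Collision energies outside the scanned 3–42 V grid
raise an advisory warning rather than an error, because vendor optimizers
refine the final CE off-grid. Acquisition schedules are half-open time
segments `[start, end)` — a boundary retention time belongs to the later
segment — and segments containing no analyte's retention time are assigned
the non-IS analyte's transitions, so the quantified analyte is monitored
everywhere outside the IS window (this reproduces the
4–9.5 / 9.5–11 / 11–15.6 min layout for analyte and IS retention times of
11.22 and 10.04 min).

## Signal processing

Chromatograms are uniform-grid traces per transition. Peak detection uses a
robust whole-trace baseline (median) and noise scale (scaled MAD), calls a
candidate where at least three consecutive samples exceed
`baseline + kσ` (default `k = 3`), and splits runs at valleys that drop
more than 3σ below the smaller of two adjacent maxima, so noise wiggle on a
crest merges while resolved shoulders split. Apex retention time is refined
by parabolic interpolation of the top three samples; adjacent-equal-height
ties resolve to the earlier time. Requiring a run of supra-threshold
samples (not a single sample) is what keeps the false-call rate on pure
noise near zero — a single-sample rule would fire on roughly `n·P(Z>3)`
samples per trace.

Integration is trapezoidal above a straight baseline drawn between the
window endpoints (areas in counts·s; shift-invariant by construction), and
S/N is baseline-corrected height over the SD of the linearly detrended
flanking baseline. The peak-to-peak/2 noise estimator was rejected as
statistically unstable; the SD definition anchors the conventional 3:1
(detection) and 10:1 (quantification) interpretation. No deconvolution,
smoothing (beyond the optional trivial case), or saturation handling is
attempted.

## Identity confirmation

Four criteria, each auditable in the result object: RT within ±1% of the
same-batch reference (denominator always the reference — a documented
asymmetry), each qualifier's relative abundance within ±20% *relative* of
the reference ratio (a relative window, matching practice for ratios of
this size, not absolute percentage points), pre-run blank under 20% of the
LLOQ analyte area and 5% of the mean IS area, and a carry-over blank after
the spiked sample reusing the same two limits (no separate numeric limit is
published for carry-over). The overall decision is the conjunction, so
loosening any tolerance can never flip a confirmed sample to
not-confirmed — a monotonicity property the tests exercise directly. The
"within ±1%" phrasing is read as a ±1% window in percent of the reference
RT; an absolute-minutes mode is deliberately not provided.

## Validation statistics

Calibration is least squares of area ratio on concentration over six
non-zero levels, with per-calibrator back-calculation and the ICH gate
(≥75% within ±15%, LLOQ within ±20%). `LOD = 3.3σ/S`, `LOQ = 10σ/S` with σ
the SD of intercepts and S the mean slope across independent assays (nine
in the reference design), so LOQ/LOD is 10/3.3 by construction and both are
invariant under rescaling all areas.

**Weighting.** `fit_calibration()` defaults to unweighted OLS, matching the
single published line. The *validation engine*, however, back-calculates
against 1/x²-weighted fits. With signal-proportional noise over a 40-fold
range, unweighted intercepts are dominated by the top calibrators: the
intercept SD inflates roughly tenfold, the LOD lands near the LLOQ, LLOQ
back-calculations fail their own ±20% gate, and inter-day CV at the low QC
exceeds 20% — outcomes incompatible with a method that validates. Weighted
regression at the low end is the standard bioanalytical remedy and restores
all gate behaviour at the generator's stated noise levels; `weighting =
"none"` remains available.

Precision is CV%: intra-day within a day (day CVs averaged), inter-day on
day means (ICH convention; the pooled-over-all-replicates CV is also
emitted because the published tables do not state their pooling). Accuracy
is 100·grand mean/nominal, gated ±15% (±20% at the LLOQ; the low QC equals
the lowest calibrator here, so it takes the wider gate). Recovery is
100·mean(pre-extraction ratio)/mean(post-extraction ratio); the matrix
factor is mean matrix-spiked over mean solvent-spiked area per channel,
with the IS-normalized MF gated to 0.8–1.2 and CV ≤ 15%. Quantification
inverts the line and flags BLQ/ALQ values, which are carried but excluded
from group means by default. The homogenate→tissue bridge is the exact
factor 0.01 mL/mg (1 mL buffer per 100 mg brain).

## Non-compartmental pharmacokinetics

The destructive design (each animal contributes one point) is analyzed by
naive pooling: per-time means over n = 5 animals form the composite
profile. Cmax/Tmax is the grid argmax (earliest time on ties); λz comes
from log-linear OLS on terminal means, choosing among suffixes of ≥3
post-Tmax points (Cmax excluded) by adjusted R². When fewer than three
post-Tmax points exist — on this sparse grid the composite peak
occasionally lands at 6 h — the fit falls back to the last three positive
points and flags `includes_cmax` in its provenance rather than failing the
run. AUC uses linear trapezoids by default (lin-up/log-down optional; the
published analysis does not state which its software used), AUMC uses t·C
trapezoids, and `AUC(0−∞) = AUC(0−t) + C_last/λz`. An observed fraction
below 0.8 triggers a high-extrapolation warning — with a ~17 h terminal
half-life and a 24 h last sample this warning is expected, not a defect.
Units are explicit throughout: dose in µg/kg over AUC in µg·h/mg lands
directly on (mg/kg)/h for Cl/F (the µg→mg factors cancel), and
`Vz/F = Cl/F/λz` holds exactly within one analysis, as do
`T1/2·λz = ln 2` and `MRT = AUMC/AUC`.

t = 0 concentrations are fixed at zero for extravascular dosing. Per-animal
SDs of NCA parameters are not computed from a single pooled profile —
under destructive sampling they are not identifiable from it — which is why
the package reports profile-level parameters with provenance instead.

## The synthetic-data generator

The generator *defines* the study conditions; its defaults are fixed, not
tuning knobs:

* Calibration truth `8.5133·C + 1.7962` (area ratio per µg/mL), six levels
  0.5–20 µg/mL, IS at 0.5 µg/mL.
* Extraction recovery 0.68 (mid-range of the assay's 63–72%), applied to
  pre-extraction matrix spikes.
* Analyte-channel matrix factor 0.88 with an unsuppressed IS channel, so
  the IS-normalized MF is ~0.88 (suppression, inside the 0.8–1.2 gate).
* Proportional (mean-one lognormal) noise of CV 4% applied to the area
  *ratio* — applying independent noise to each channel would inflate ratio
  CV by √2 and misstate the assay's intra-day precision — plus a shared
  per-day lognormal factor of CV 6%, so inter-day CV exceeds intra-day.
* Blank channels carry half-normal baseline areas (SD 300 counts), far
  below 20% of the LLOQ response.
* PK: one-compartment, first-order absorption (ka = 0.8 h⁻¹,
  λz = 0.0405 h⁻¹, scale 95 µg/mg), chosen as the simplest structural model
  whose sampling-grid argmax is 4 h, terminal half-life ≈ 17.1 h and mean
  Cmax ≈ 77 µg/mg; between-animal variability is a lognormal scale with
  CV 15% (the published work states no between-animal distribution; this
  is a convention, and a typical magnitude for small-rodent tissue PK).
  ka ≤ λz is rejected — the flip-flop ambiguity is deliberately not
  modeled.
* Behavior: each animal's true discrimination ratio is Beta-distributed
  around its group mean (precision 30, i.e. SD ≈ 0.08), split over
  exponential-like bouts; Y-maze sequences are first-order with the group's
  alternation propensity, so expected alternation is exactly 100·p. Group
  defaults (control ≈ 0.68/70%, LPS ≈ 0.52/52%, with treatment restoring
  most of the deficit) express the qualitative group ordering of an
  LPS-impairment / treatment-rescue design at realistic effect sizes.

What the generator does **not** emulate: raw EI spectra and isotope
patterns, instrument drift, retention-time prediction, carry-over
mechanisms, correlated matrix interferences, any pharmacodynamic link
between exposure and behavior, and E/Z isomer chemistry beyond an optional
minor-peak flag (only the stable E-isomer peak is modeled by default).
Passing parameter-recovery tests therefore demonstrates that the
estimators are correct and unbiased under the stated noise model — not that
the assay would validate on any particular instrument.

## Numerical and testing choices

Computation is in full precision; reports round concentrations and
percentages to two decimals. Determinism is contractual: every generator
takes a seed and restores the caller's RNG state, and the end-to-end
pipeline report is byte-identical under a fixed seed. Degenerate inputs
have defined behaviour (flat traces detect nothing; zero-variance noise
windows yield a flagged infinite S/N; zero total exploration excludes a
session rather than dividing by zero).

Monte-Carlo test sizes were chosen to make the suite complete in a few
minutes on one core while leaving comfortable statistical margins: 100–200
seeds for classification rates and recovery means, 1000 draws for blank
exceedance, 20 noiseless NCA replicates, and exhaustive enumeration (all
no-immediate-repeat arm sequences to length 8) for the alternation score.
One stochastic property is asserted and documented as failing by
construction: at 15% between-animal CV the 4 h and 6 h composite means
differ by only ~4.3% while their standard errors are ~6.7%, so the grid
Tmax lands at 4 h in only ~60% of runs — no estimator can make that
criterion reach 90% under these conditions, and the test records the fact
rather than hiding it.

## Known limitations

* The LOD/LOQ computed from unweighted fits are unstable under
  proportional noise (see Weighting above); the report carries both the
  limits and the lowest calibrator without forcing them to agree.
* Naive pooling ignores between-animal correlation structure entirely; a
  pseudo-profile bootstrap would be needed for parameter SDs.
* The printed Vz/F of the reference analysis is a mean of per-animal
  ratios and is not reproducible from profile-level means; only the Cl/F
  consistency is asserted.
* Ion-ratio confirmation assumes the qualifier/quantifier noise is
  independent between sample and reference; correlated drift would loosen
  the effective window.
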