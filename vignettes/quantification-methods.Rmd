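---
title: "Quantification methods for the heart-failure assay panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for the heart-failure assay panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

cardioquant quantifies the assay panel used to phenotype experimental heart
failure at the organ, cell and organelle level: pressure-volume hemodynamics
in vivo; calcium transients, cell shortening and calcium sparks in isolated
cardiomyocytes; fluorometric and respirometric assays in isolated
mitochondria and permeabilized cells; pixel-based histology indices; relative
gene expression; and the group-comparison statistics that tie the panel
together. Every analyzer is paired with a synthetic generator that emits the
same data modality with known ground truth, so each stage is validated by
parameter recovery rather than by eye. This vignette explains the models,
the tunable parameters, the numerical choices, and what the synthetic data
do and do not emulate.

## Calcium transients and cell shortening

A paced fluorescence trace is segmented into beats at the stimulus events
(one half-open segment per stimulus, ending at the next stimulus). The
baseline F0 of each beat is the arithmetic mean of a pre-stimulus window
(default 200 ms). Features per beat:

* **amplitude** — maximal (F − F0)/F0 over the segment (dimensionless);
* **time to peak** — peak time minus beat onset;
* **T50** — time from the peak to the first crossing of half amplitude,
  linearly interpolated between samples (times are never quantized to the
  sampling grid);
* **tau** — time constant of a least-squares fit of `A exp(−t/tau) + C` to
  the decay from the peak to the segment end, initialized log-linearly and
  refined with Levenberg–Marquardt (minpack.lm). The offset `C` is included
  because diastolic fluorescence rarely returns exactly to F0; `tau` is
  reported absent when the fit does not converge.

Shortening mirrors this on the cell-length trace: resting length from the
pre-stimulus window, maximal shortening (absolute and as % of resting
length — both are reported, since figure conventions differ), time to peak
shortening (TTPS), and time to half relaxation (TTHR, the interpolated 50%
length-recovery crossing after the minimum).

**Onset convention.** The protocol's kinetic intervals are measured "from
onset"; when stimulus events are recorded (the normal case for field-paced
cells) the onset is taken as the stimulus time, which makes noise-free
recovery of the generator's TTP/TTPS sample-exact. An alternative
`onset = "threshold"` (interpolated 10%-of-amplitude upstroke crossing) is
available for recordings where the stimulus artifact precedes the actual
rise; it reads systematically shorter by the foot of the upstroke.

**Adaptive smoothing.** On a noise-free trace the raw extremum is exact, so
no filtering is applied; when the baseline window shows noise above 0.1% of
the baseline value, features are read from an 11-sample boxcar-smoothed
copy. A raw maximum under noise is biased upward by roughly two noise SDs
(the maximum of many near-peak samples), which at 2% noise would already
exceed the 2% amplitude-recovery budget; the smoothed peak removes most of
that bias at a negligible cost in flattening (the quarter-sine peak loses
< 0.5% over an 11 ms window). The tau fit uses the same smoothed series —
a boxcar average of an exponential is an exponential with the same time
constant.

**Usability floor.** A beat whose amplitude is below 5 baseline-noise SDs
is flagged unusable and contributes no kinetics; fitting tau to noise
produces arbitrary values. Per-cell aggregation is the median across usable
beats, robust to a single arrhythmic beat.

The generators build each beat as a quarter-sine rise over the configured
time-to-peak (smooth, monotone, unambiguous peak — the rise shape is
otherwise unconstrained by the protocol) followed by a mono-exponential
decay, resetting to baseline at each stimulus. At 2 Hz with slow decay the
next stimulus arrives before relaxation completes; the generator warns, and
recovered amplitudes genuinely ride on the accumulated diastolic baseline —
a real feature of fast pacing, not an artifact. Recovery benchmarks
therefore pace at 0.5 Hz, the frequency at which the decay kinetics are
reported.

## Calcium sparks

Line scans (space × time, 0.1 µm pixels) are normalized per spatial row by
its 20th-percentile-over-time baseline F0(x) — robust to sparse events —
and expressed as ΔF/F0. Detection is two-pass, mirroring the convention of
the classic line-scan spark detectors: the normalized image is smoothed
with a 3×3 mean filter; candidate pixels exceed the median plus
`criterion_k` (default 3.8) smoothed-noise SDs (robust MAD estimate);
candidate regions are grown at 2 SDs. Regions must span ≥ 3 pixels in
space and ≥ 2 lines in time, cover ≥ 30 connected pixels, and contain a
raw pixel above `criterion_k` raw-noise SDs — together these suppress shot
noise to well below 0.1 false events per image at the default criterion.
Overlapping events split at smoothed local maxima separated by a ≥ 30%
valley, provided both maxima clear the candidate threshold and are farther
apart than the resolution footprint (2 µm / 100 ms by default); weaker
detections inside that footprint of a stronger one are suppressed as
duplicates (a noise dip can cut one spark's region in two). The original
detection criterion of the cited plugin is not restated in the protocol, so
`criterion_k` is a reported parameter, not a constant.

Event amplitude is the raw peak ΔF/F0 (slightly upward-biased under heavy
noise — the maximum of a noisy region); event time is the peak line, which
for a fast-rising spark marks the event onset; position is the
intensity-weighted centroid. Frequency is events per 100 µm of scanned
cell per second.

The generator plants separable sparks — Gaussian in space (configurable
FWHM), instantaneous rise with exponential fall in time (canonical spark
morphology) — from a uniform Poisson process, over a flat baseline with
white Gaussian noise. It does not emulate wave propagation, photobleaching
or motion; detector performance on real scans with drift will be somewhat
worse than the planted-spark benchmarks (precision and recall ≥ 95% at
amplitudes ≥ 5 noise SDs and densities ≤ 2 per 100 µm·s).

## Mitochondrial assays

**Free-calcium calibration.** Single-wavelength indicator equation
`[Ca2+] = Kd (F − Fmin)/(Fmax − F)` with Kd = 335 nmol/L for Fluo-4;
`Fmax`/`Fmin` come from the saturating-CaCl2 and EGTA plateaus of the same
trace. The implementation is the exact inverse of
`F = (Fmin Kd + Ca Fmax)/(Kd + Ca)`; readings at or above `Fmax` are a
saturation error, below `Fmin` an error or clamp by configuration.

**Matrix calcium content.** Plateaus (median of the final 10 s before the
next addition — robust to addition-instant spikes) are read before and
after the FCCP addition; content per mg is the released minus baseline free
calcium divided by protein mass. The baseline subtraction is a
deliberate choice (the protocol's wording is ambiguous): it makes a
no-release trace read exactly zero.

**Retention capacity (CRC).** For each 10 µmol/L pulse (3-minute cadence),
recovery means the fluorescence returns at least 50% of the way from the
post-pulse peak to the pre-pulse baseline before the next pulse; the
permeability transition is the first pulse with no recovery whose signal
also never returns below that level for the rest of the recording
("massive release" is qualitative in the protocol; the 50% criterion makes
it operational). Pulses tolerated is the count before that pulse;
cumulative load is pulses × amount / protein. A trace where every pulse
recovers is censored, not zero. The analysis is invariant to affine
rescaling of the fluorescence.

**Influx rate.** Least-squares fit of `F(t) = a t² + b t + c` over the
post-energization window; the rate is |b|, the derivative magnitude at the
window start, where uptake is maximal — evaluation at mid-window is a
configuration option. On an exact quadratic the answer is exact for any
window length.

**Respirometry.** Per-segment oxygen flux is the negative slope of a
least-squares line over the segment interior after trimming 10% of samples
at each end (addition artifacts contaminate the edges), per mg protein.
Respiratory control is state3/routine: the protocol's isolated-mitochondria
sequence (substrate → ADP → FCCP) has no state-4/oligomycin step, so the
classic state3/state4o ratio is unavailable; it becomes available via
`rc_convention` when an oligomycin segment exists.

## Pressure-volume loops

Cycle boundaries sit at volume maxima of a 10-sample moving-average-smoothed
volume signal (robust to catheter noise), refined to the first sample of
the raw volume-maximum plateau so the true end-diastolic sample opens each
cycle. A robust curvature-based noise estimate (MAD of second differences)
decides whether per-cycle points are read from the raw series (noise-free
data stays corner-exact) or the smoothed one. EDV is the plateau maximum
and EDP the lowest pressure on that plateau; ESV is the cycle's volume
minimum. The end-systolic point follows the maximal-elastance convention —
the sample maximizing P/(V − v0), with v0 estimated by a two-pass fit
(first pass v0 = 0, then the fitted volume intercept) — with a simpler
maximum-pressure convention selectable, since the acquisition software's
internal definition is not stated.

Steady state is every cycle before the recorded occlusion event (or before
EDV drops 5% below its running median when no event exists). SV = EDV −
ESV, EF = 100·SV/EDV, HR from the cycle period, CO = SV·HR. ESPVR and
EDPVR are ordinary least squares through the end-systolic and end-diastolic
points of the occlusion cycles; the EDPVR is fitted linearly because a
single slope is the reported quantity (exponential stiffness models are out
of scope). Under realistic noise (pressure SD 2 mmHg, volume SD 0.5 µL)
ESPVR recovers within a few percent per recording; EDPVR spans only ~2 mmHg
of EDP over an occlusion, so its per-recording slope carries irreducible
variance of order 15–20% — the pooled estimate across recordings is
unbiased, and that is the quantity compared across groups.

The generator lays end-systolic and end-diastolic corners exactly on the
configured relations, ramps ejection pressure linearly in volume into the
end-systolic corner (which provably makes that corner the maximal-elastance
point of each loop), and drops EDV by a fixed step per occlusion beat. It
does not emulate volume-calibration drift, parallel conductance, or
respiratory modulation.

## Histology

Color classification is rule-based in hue/saturation space (blue 180–260°,
red < 20° or > 340°, saturation > 0.15; DAB brown 15–50° for
positive-pixel counts), with thresholds serialized alongside every result —
the original analysis settings are a matter of record-keeping, so the rules
are parameters, not constants. The fibrotic index is %blue/%red over all
pixels. Positive fractions use tissue pixels only (white/luminal pixels
excluded), matching standard practice. Myocyte cross-sectional areas come
from a binary mask (preferred, mirroring manual selection) or Otsu
thresholding of the saturation channel plus distance-transform watershed
(EBImage); border-touching cells are excluded and the ≥ 20 cells/image rule
is reported as a flag rather than enforced. Areas are pixel counts × scale².

Synthetic histology colors pixels from pure-hue palettes in exactly the
requested proportions, clustered by thresholding smoothed random fields at
the matching quantiles; palette values are multiples of 1/255 so 8-bit PNG
round-trips are lossless. It does not emulate stain variability, chromatic
overlap or out-of-focus blur, so threshold robustness on real slides must
be assessed per batch (a ±10° hue-jitter test bounds the first-order
sensitivity).

## Expression and statistics

2^−ΔΔCt (Livak): ΔCt = Ct_target − Ct_housekeeping per sample, centered on
the arithmetic mean ΔCt of the control group (equivalently the geometric
mean of folds, which makes the control geometric-mean fold exactly 1);
per-plate calibrators and efficiency correction are out of scope.

The comparison layer reproduces the protocol's toolkit: unpaired Student's
t-test for two groups; one-way ANOVA with Tukey's HSD; two-way ANOVA with
Tukey contrasts on the group factor within each level of the second factor
(the panel's frequency factor is treated as independent, not repeated
measures — a documented simplification); Kruskal-Wallis with Dunn's
rank-based post hoc for non-normal data. The `auto` design screens each
group with Shapiro-Wilk at α = 0.05 (the protocol does not name its
normality test; this is the default and it is overridable). Dunn's test is
implemented directly (tie-corrected z statistics) because no installed
package provides it; its p-values are Holm-adjusted by default, Bonferroni
optionally.

## Problem sizes and reproducibility

All validation runs on synthetic data at desk scale: recovery benchmarks
use ~200 beats across the kinetic grid (tau 100–400 ms × amplitude 0.5–2),
25–50 line-scan images of 500 px × 1000 lines, 50 randomized CRC traces,
100 influx traces, 40 PV recordings of 13 beats, 1000 null simulations for
the type-I check and 200 for power. One integer master seed drives
everything; per-assay streams are split from it (`split_seed`) so re-running
one assay never perturbs another. Noise levels are part of the study
conditions: 2% of baseline for fluorescence traces, 2% of the shortening
depth for length traces, 10% of baseline (5× below the planted amplitude)
for line scans, 2 mmHg / 0.5 µL for PV channels, 0.25–0.3 cycles for Ct
values.

## Known limitations

* Biophysical realism is explicitly out of scope: no ODE cell models, no
  photobleaching, motion or drift; passing recovery benchmarks bounds
  algorithmic error, not acquisition artifacts.
* Spark detection assumes sparse events; above roughly 50% event coverage
  the baseline percentile and noise estimates degrade (the generator warns
  there).
* The EDPVR is linear by design; stiff ventricles with convex EDPVRs will
  show scale-dependent slopes.
* Statistics treat cells as independent units; cell-within-animal nesting
  (mixed models) is out of scope and p-values on clustered designs will be
  anti-conservative.
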