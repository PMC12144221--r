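---
title: "Consistency testing of lesion-detection AI with a simulated CT phantom study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistency testing of lesion-detection AI with a simulated CT phantom study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomqc)
```

## The problem

Diagnostic AI tools for CT angiography return their findings as colour
heatmap overlays (a positive triage decision) or as a negative summary
report. Whether such a tool keeps behaving consistently when the radiation
dose or the reconstruction algorithm changes is a quality-assurance
question, not a diagnostic one: the same anatomy, scanned repeatedly under
a controlled dose x reconstruction grid, should yield stable labels.
An anthropomorphic head phantom with three intracranial aneurysms — middle
cerebral artery (MCA, 4 mm), anterior communicating artery (ACoA, 4 mm)
near the skull base, and a small basilar artery (BA, 2 mm) aneurysm —
makes that experiment repeatable: 21 CTDIvol levels (0.47–20.09 mGy), two
reconstructions (iterative reconstruction, IR, and filtered back
projection, FBP), three repetitions per cell, 126 scans in total.

`phantomqc` implements the complete analysis chain for such an experiment
and, because vendor heatmaps are proprietary, a synthetic-study generator
with the same statistical structure, so every stage is testable end to end
without scanner data.

## Label quantification

Heatmap overlays are 8-bit RGB stacks. A voxel is a positive label pixel
iff its **blue channel is at most 100** (the threshold is the *maximum*
admissible blue value, hence inclusive; hot label colours have high red
and low blue, backgrounds are bright in all channels). Positive pixels are
grouped into connected components, volumetric 26-connectivity by default
so a label spanning adjacent slices stays one component; in-plane 8- or
4-connectivity are available.

Per component:

* **size** — pixel count x pixel size. The phrase is dimensionally
  ambiguous, so the default is the physically meaningful area convention
  (count x pixel-size², reported in mm²) and the literal-linear product
  (count x pixel size) is always computed alongside it; both are carried
  in every output table.
* **intensity** — RGB converted to grayscale, inverted, normalised,
  averaged: `mean((255 - gray) / 255)`, in [0, 1]. Grayscale defaults to
  the ITU-R BT.601 luma (0.299 R + 0.587 G + 0.114 B), computed in
  floating point with no intermediate rounding; an equal-weights mean is
  selectable.

```{r quant}
design <- make_default_design()
design
s <- render_heatmap(design, dose_mGy = 10, reconstruction = "IR",
                    detected_lesions = default_lesions(design), seed = 1)
quantify_series(s)[, c("component_id", "n_pixels", "size", "intensity")]
```

## Matching and triage

The human label review of a real study is replaced by geometric matching:
greedy nearest-distance one-to-one assignment between component centroids
and lesion centroids in millimetre coordinates (anisotropic spacing:
pixel size in-plane, slice thickness through-plane), accepting pairs
within a tolerance of 10 mm by default. The tolerance is a declared
parameter chosen to accept slightly offset low-dose labels while rejecting
distant blobs; it is not a recovered quantity. For well-separated lesions
(the phantom's geometry; separations are several times the tolerance)
greedy assignment coincides with the exhaustive minimum-total-distance
assignment, and the test suite asserts that parity. Ties are broken by
lexicographic lesion id so results are order-independent.

A scan with at least one component (matched or not) is triage-positive;
zero components is the negative summary report. Since the phantom always
contains lesions, negatives are false-negative triage decisions. Leftover
components are flagged candidate false positives and surfaced as warnings,
but no false-positive modelling is attempted.

## Consistency metrics

Counts of matched labels per lesion x dose x reconstruction cell, rates as
percentages (full precision plus the one-decimal rounding used in
reports), and reproducibility as the coefficient of variation (CV =
SD/mean, sample SD by default as repeats are n = 3). **Only fully
reproducible cells qualify for the CV**: a dose contributes for a lesion
and reconstruction only if all repetitions produced a matched label.
Because the pooling behind published single CVs is generally unstated, two
defensible schemes are both computed: the default takes the CV across
repetitions within each qualifying dose and averages across doses
(isolating repeat-to-repeat reproducibility from dose-driven size trends);
the pooled mode computes one CV over all contributing values. When no cell
qualifies the result is flagged not-computable rather than zero.

## Reader arm

Five readers rate visibility (yes/no; the 1 = yes / 2 = no response
encoding is normalised at ingest) and image quality (3 = good, 2 =
intermediate, 1 = poor) for each lesion on each scan. A quality rating of
1 is recoded to 0 when the lesion was also rated invisible. Aggregation is
a two-stage mean — within reader across the three repetitions of a cell,
then across readers — with the standard error of the mean across readers
as the error bar. On a balanced design the two-stage mean equals the flat
mean; the test suite asserts this.

## Statistics

Label sizes, intensities and quality ratings are compared with the
two-sided Mann–Whitney U test and Bonferroni correction (adjusted
p = min(1, m x p)), significance at adjusted p < 0.05. The unit of
analysis is the per-cell mean across repetitions — up to 21 values per
lesion and reconstruction — because measures are averaged across repeated
acquisitions before comparison. Exact permutation p-values are used for
small tie-free samples (n ≤ 20 combined); otherwise the normal
approximation with continuity correction and tie-corrected variance. When
exact mode is requested but ties exist, the test falls back to the
approximation and records a note. A condition under which a lesion never
receives a label has no measurement to compare; in the pipeline such
pairs are omitted and the family size counts the comparisons actually
performed.

## The synthetic study generator

The generator emulates the statistical structure the analysis assumes,
not CT physics. Per scan and lesion, a Bernoulli draw from a logistic
model in log-dose decides whether a label is produced:

\[
  \operatorname{logit} p = a + b \log d - r \max(0, d - k),
\]

with the optional high-dose degradation term (rate *r* above knee *k*)
reproducing reconstruction-specific instability at high dose. Detected
lesions are rendered as filled in-plane discs in a hot colour (red 255,
blue 60) on a neutral grey background (230 in all channels), so the
blue-100 rule separates label from background exactly. Disc radius is the
lesion radius scaled by a dose-dependent factor saturating at 1; the
label's green channel is solved so the rendered inverted-grayscale
intensity hits a dose-dependent target; centroids receive an isotropic
in-plane offset (2 mm SD per axis by default, echoing slightly offset
low-dose labels); small per-scan jitter (5% relative on radius, 0.02 on
intensity) keeps repeated acquisitions similar but not identical so CVs
are non-degenerate.

Default logistic parameters were calibrated analytically — by solving for
the intercept that makes the expected label count under the default
design match the marginal totals of the motivating experiment (60/57 MCA,
52/42 ACoA, 3/0 BA for IR/FBP; ACoA-FBP with degradation above 13 mGy) —
and then frozen. The same defaults imply about nine expected
triage-negative scans (the lowest dose with both reconstructions, plus
1 mGy with FBP), i.e. a ~7% false-negative triage fraction.

The reader model mirrors this: per-reader visibility is logistic in
log-dose with per-lesion intercepts chosen so expected positive-response
counts sit near 629/621/601 of 630 for MCA/ACoA/BA with full visibility
above ~2 mGy, and quality is an ordinal cut of a logistic latent score
rising with log-dose, shifted down when the lesion was invisible. Quality
is deliberately independent of reconstruction, reflecting the absence of
a reconstruction effect in visual grading.

All randomness flows from one top-level seed through named substreams
(one per scan, one per reader x scan), so enlarging a design never
perturbs existing scans. A short warm-up of each substream is discarded
because Mersenne–Twister states seeded from related integers are poorly
mixed in their first outputs. Everything is bit-reproducible given the
seed.

What the generator does **not** emulate: CT noise texture, reconstruction
kernels, anatomy, vendor colormaps (the disc rendering is an assumption,
recorded here, not an inference about any vendor's output), reader
idiosyncrasy, or false-positive labels. Passing tests therefore
demonstrate the correctness of the *analysis* under the assumed
statistical structure — they say nothing about any particular AI
product's behaviour on real scans.

## Numerical and design choices

* Geometry defaults: 512 x 512 matrix, 0.41 mm pixels, 0.75 mm slices.
  Stack depth defaults to 6 slices — overlays are standalone, so the stack
  only needs to hold the three lesion centroids on distinct slices.
* Lesion centroid placement is the package's own choice; in-plane
  separations (tens of mm) are several times the matching tolerance so
  cross-assignment is geometrically impossible.
* Degenerate inputs: empty masks yield empty component lists; cells with
  no matched label yield absent (NA) summaries, never zeros; CV without
  qualifying cells is flagged not-computable; a blob falling entirely
  outside the stack is a generation error; partially out-of-bounds blobs
  are clipped, with at least the centre pixel guaranteed.
* Component ordering is deterministic (min slice, then row, then column);
  matching ties break by lesion id.
* Rates are rounded to one decimal and CVs to two decimals in formatted
  output; CSV and JSON artefacts keep full precision alongside.
* Connected components are resolved as graph components over the positive
  voxel adjacency; the test suite checks the partition against an
  independent flood-fill implementation.

## Problem sizes used in the test suite

Unit tests run on compact geometries (96 x 96 x 4 stacks, 3 doses) where
every property can also be recomputed by brute force. The end-to-end
checks run the full default 126-scan study at the default 512 x 512 x 6
geometry, the Bernoulli calibration at 2 000 simulated scans, and the
dose-response recovery at 50 repetitions per cell — sizes at which Monte
Carlo tolerances (3 standard errors; 20% relative error on the recovered
slope) are meaningful.

## Limitations

The pipeline analyses overlays only; it never sees the underlying CT
data. DICOM RGB secondary-capture input is not implemented — the PNG
stack dialect is the reference format. Published CV values from any real
experiment depend on the proprietary AI's label measurements and are not
reproduction targets for the synthetic defaults; the synthetic study
reproduces marginal detection structure, not per-dose label curves.
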