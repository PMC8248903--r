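---
title: "Digitizing paper ECG records: methods and design choices"
author: "PaperECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digitizing paper ECG records: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PaperECG)
```

# The problem and the model

A paper ECG record is a raster image: a background calibration grid, several
rows of trace ink, a leading rectangular DC pulse per row that defines the
voltage scale, printed lead labels that may cross the trace, and a
demographic text block. Digitization means recovering, for each row, the
calibrated function *voltage(time)* that the pen drew, and the text around
it. Two families of information are involved:

* **Vendor conventions**, captured once per machine in a `TemplateSpec`:
  region rectangles, expected row count, lead-label ROIs, demographic field
  ROIs, paper speed (mm/s), gain (mm/mV), grid pitch (mm), DC pulse
  amplitude and duration. When a template omits calibration constants the
  conventional printing values are filled in (25 mm/s, 10 mm/mV, 5 mm grid,
  1 mV × 0.2 s pulse) and flagged in `calibration$assumed`.
* **Per-scan nuisances** estimated from the image itself: skew angle, ink
  threshold, ROI misfeed offset, pulse height and baseline.

The processing order is preprocessing → lead-character removal →
segmentation → extraction. Character removal runs on the binary mask
*before* component analysis, so glyph ink can neither merge with the trace
during row assembly nor distort the column scan.

## Preprocessing

Grayscale conversion uses the ITU-R BT.601 luminance weights. Skew is
estimated by a Hough-transform vote: dark pixels (grid + ink) are projected
onto `ρ = row·cos φ + col·sin φ` for candidate orientations; the φ whose
accumulator has the greatest energy (sum of squared bin counts) is the
grid-line direction. The search covers ±15° — a page skewed further is
treated as misfed — with a 0.5° coarse sweep refined at 0.05°. Deskewing
rotates about the image centre with bilinear interpolation **keeping the
canvas size**, background-filling exposed corners: template rectangles are
defined on the original canvas and enlarging it on deskew would invalidate
every template coordinate. Records carry margins wide enough that no
content is lost below |15°|.

Grid removal is a histogram decision: the 256-bin intensity histogram is
smoothed (Gaussian, σ = 3 bins), modes closer than 40 gray levels are
merged (pure-black salt pixels belong to the ink mode), and the threshold
is the midpoint of the minimal plateau between the darkest (ink) mode and
the next one (grid or paper). A unimodal histogram is a hard "no trace
found" error; if the valley is degenerate the Otsu threshold is used and
recorded in the mask's provenance. A manual threshold simply bypasses the
estimate. The mask convention is ink-dark: `TRUE ⇔ intensity < threshold`.

The binary clean-up is a 3×3 majority (median) filter — reduced windows at
the borders — followed by 1-D horizontal morphological closing of the
stated kernel length (default 5 px), united with its input so bridging is
extensive and idempotent. Filtering precedes bridging so that salt noise is
not welded into the trace.

## Segmentation

Connected components are labelled on the pixel-adjacency graph (default
8-connectivity — trace strokes run diagonally), with labels renumbered in
scan order for determinism. Components smaller than
`minComponentArea = 100` px are discarded (strictly smaller: an exactly
100-px component is kept), which also disposes of most non-overlapping
label fragments.

For fusing fragments into rows the package keeps two distance notions
deliberately separate:

* `hausdorffFull` / `hausdorffTruncated` — the classical symmetric
  sup–min Hausdorff distance, the truncated form restricted to each
  component's `endpointPixels` leftmost + rightmost pixels (column order,
  matching the left-to-right time axis; a row-extremal variant sits behind
  the `axis` flag). These are exact, oracle-tested measures; truncation
  equals the full form whenever the subset saturates the component.
* the **fusion metric** of `assembleRows` — the *closest approach* (minimum
  Euclidean distance) between the same endpoint subsets. The sup–min form
  is the wrong predicate for merging: between two adjacent fragments of one
  row it is on the order of the fragment length, so no threshold could both
  bridge within-row gaps and respect inter-row spacing. A merge threshold
  is meaningful exactly when it sits above the largest within-row gap and
  below the inter-row clearance, and those quantities bound the closest
  approach. `metric = "full"` computes the closest approach over all
  pixels instead of the truncated subsets.

Fusion is single-linkage (transitive closure of `distance < threshold`,
strict, ties do not merge), which makes the group count monotone
non-increasing in the threshold and the result independent of component
order. Groups are sorted top-to-bottom by mean row; groups narrower than
`minWidth` (default: half the widest group's column span) are set aside as
*rejects* — stray specks and non-overlapping lead characters — and
reported, never silently dropped, as are surplus groups beyond the
template's expected row count.

Defaults: `endpointPixels = 75`, the midpoint of the 50–100 range that the
tradeoff analysis of the underlying method explores; the merge distance
defaults to **twice the grid pitch in pixels** so the setting transfers
across DPI (an absolute pixel override is accepted).

## Correlation-template OCR

The matcher is zero-mean normalized cross-correlation (ZNCC) of exemplar
bitmaps slid over the region, computed with FFTs and window sum tables.
Exemplars are trimmed to their ink bounding box; solid-block glyphs ('-',
'.') keep a 2-px background border because an all-ink template has zero
variance and could never match. Candidate peaks at or above `minScore`
(default 0.6 — a design choice; the matcher never guesses below it) are
resolved greedily: scores are quantized to 10⁻⁶ so FFT rounding noise
cannot reorder exact ties, ties prefer the **larger** glyph (a small glyph
can be an exact sub-pattern of a larger one — a colon is literally a column
slice of 'D' in a dot-matrix font), then the leftmost. Accepted boxes
suppress overlapping candidates; survivors are read left-to-right, with
spaces re-inserted at gaps wider than 0.6 of the median glyph width.

Lead-label removal exploits the template's knowledge: a lead ROI declares
*which* label it holds. Matching inside it is restricted to that label's
characters, at a relaxed acceptance of `0.75 × minScore` (the label's
presence is near-certain there, and a trace crossing a glyph depresses its
correlation). When the library carries its font scale, the **whole label
bitmap** is matched first — the full word's correlation is far more robust
to a trace crossing one glyph than any single character's — and its entire
ink footprint erased; otherwise matching falls back to per-character. The
erased pixels are exactly the matched exemplar footprint (not the bounding
box), so trace ink next to a glyph survives; the erased column span is
reported so extraction re-interpolates the gap. Scan misfeeds are handled
by `alignRois`: a single global (Δrow, Δcol) offset from the FFT
cross-correlation peak against a standard reference scan, applied to every
ROI, with out-of-canvas ROIs clamped under a warning.

Demographics are read with an independently chosen threshold (text printed
over residual grid needs its own level — the known failure mode), optional
3×3 opening (`skeletonizeForOcr`, erosion-then-dilation) to strip burrs,
and the full library; fields with nothing above threshold are reported as
empty strings, never omitted and never guessed. The default library is
rendered from the package's 5×7 dot-matrix font at scale 3 — the same
bitmaps the synthetic renderer prints, which gives synthetic-record
recognition a self-consistent ceiling; user libraries are built from
labelled sample bitmaps (`buildGlyphLibrary`) and round-trip through a
directory of PNG exemplars plus a JSON index. The interactive re-annotation
loop of GUI-based training is replaced by that labelled-sample file format.

## Extraction and calibration

The column scan takes, per column of a row group, the mean of the ink
pixels' row indices; empty columns are gaps. Interior gaps are filled
linearly, leading/trailing gaps by nearest value, and filled columns stay
flagged in the output. The DC pulse is found as the first sustained run of
columns deviating from the reference level by more than 4 px whose plateau
reaches at least 40 % of the trace's maximum deviation; the run must start
within the leading quarter of the trace and its central 70 % must be flat
(SD ≤ 2 px). The *detection reference* is the median row (robust both to
the plateau and to baseline wander — the mode is not: a long flat plateau
can outvote a drifting baseline), while the reported *baseline* is the
modal trace row outside the pulse, which serves as the isoelectric
reference. A missing pulse is a hard, named failure: without it the record
cannot be calibrated, and the package refuses to guess a scale.

Calibration is then affine: `voltage = (baseline − row)·A_DC/h_pulse`,
`time = Δcol/(px_per_mm · paper_speed)`; pulse columns are excluded from
the signal. The mean-of-rows rule low-passes near-vertical strokes: on the
default 3-px ink stroke the worst column (the R peak) deviates by a few
hundredths of a millivolt while the typical column stays within one pixel's
voltage quantum — the tests measure this rather than hide it. The native
column grid is always preserved; `resampleSignal` offers a conventional
uniform rate (default 500 Hz) on top, since consumers differ in sampling
expectations.

## Validation statistics

`computeQtc` is Bazett's `QT/√RR` (ms from ms and s). The four abnormality
flags use strict inequalities — QTc > 450 ms, PR > 200 ms, RR > 1 s,
QRS > 120 ms — so boundary values are negative. `pearsonR` validates and
defers to the standard product-moment estimator; zero-variance input is an
error, never a silent zero. `cohenKappa` is the unweighted two-rater kappa
from the 2×2 table (binary flags make weighting moot), computed per flag
rather than pooled; degenerate marginals with perfect agreement are defined
as 1. `agreementReport` pairs two interval tables on `record_id` and emits
per-interval correlations and per-flag kappas.

# The synthetic-data generator

`generateWaveform` models one beat as a sum of five Gaussian bumps (P, Q,
R, S, T; amplitude mV, centre offset s, width s) — any smooth parametric
family would do; Gaussians give closed-form extrema for oracle tests — plus
a slow sinusoidal baseline wander whose phase is the only per-row
randomness. Defaults are a plausible sinus rhythm at 75 bpm with a 1 mV R
wave and 0.05 mV wander. `renderRecord` composes paper (gray 240), grid
(150), and ink (20), draws per column the vertical span of the continuous
curve over that column's time interval (so adjacent columns always
connect), precedes each trace with the DC pulse, prints labels and
demographics from the same glyph font the OCR trains on, then degrades in
the fixed order **rotate → fade → salt-and-pepper** — fixed so that skew
estimation is exercised on degraded grids. Ink thickness is not something
the source material standardizes, so stroke width is a parameter (default
3 px at 300 DPI, about 0.25 mm). All randomness flows through explicit
seeds; identical inputs render bit-identical images.

The manifest records per-row continuous truth on the column grid, the true
skew, every glyph's box and ink pixel, the calibration actually used, and
the ideal (pre-degradation) trace mask, and round-trips losslessly through
JSON.

What the generator does **not** emulate: printer/scanner physics (optical
blur, JPEG artefacts, paper texture), fonts other than its own dot matrix,
perspective distortion, colour grids, and traces that genuinely overlap
across rows. Passing tests therefore demonstrate correctness of the
algorithms under controlled degradation, not performance on arbitrary
archival scans — real-scan OCR accuracy in particular sits below the
synthetic ceiling.

# Numerical and convention choices

* Coordinates are 1-based `(row, col)` with row increasing downward and
  closed rectangle intervals — the R-native convention.
* Labelling, merging, thresholding, correlation and the FFTs are all
  deterministic; repeated runs are bit-identical, and every output embeds
  the run-configuration hash and template name.
* Degenerate inputs fail loudly with stage-named errors (`[preprocess] no
  trace found`, `[extract] missing DC pulse`); a batch isolates per-record
  failures and reports exit status 2 for partial failure.
* Test and acceptance problem sizes: records of 3 rows × 3 beats at
  300 DPI (about 810 × 940 px), the size at which one record digitizes in a
  few seconds; unit tests use 1–2 rows of 1–2 beats.

# Known limitations

* Rows whose high-amplitude excursions genuinely overlap are not separated;
  single-linkage fusion will join them if they touch the merge window.
* The DC pulse is load-bearing: records printed without one need the
  template's gain, and `detectDcPulse` refuses traces with no plateau.
* The mean-of-rows rule attenuates very steep QRS flanks (measured above).
* Correlation OCR is font-specific by design; general text recognition is
  out of scope, and an external OCR engine can be plugged in for
  demographics only.
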