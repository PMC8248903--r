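# PaperECG

Legacy and low-resource clinical workflows still produce electrocardiograms
(ECGs) on paper. Retrospective research at scale — risk stratification,
algorithm development, EMR linkage — needs those records as digital signals,
not as scans. **PaperECG** converts scanned paper ECG record images
(PNG/JPEG, typically 300 DPI) into calibrated voltage–time series, in a
vendor-agnostic way: everything machine-specific lives in a small *template*
file describing the page layout and calibration conventions.

The pipeline runs in four stages:

* **Preprocessing** — grayscale conversion, optional downscaling, skew
  estimation by a Hough-transform vote over the background grid-line family
  (search ±15°, 0.05° resolution), rotation back to axis alignment,
  partition into demographic and waveform regions, automatic grid removal by
  histogram-valley thresholding (ink mode vs. grid/paper modes, Otsu
  fallback), 3×3 median filtering, and horizontal morphological closing to
  bridge threshold-induced gaps.
* **Character removal (OCR)** — correlation-template OCR over a trainable
  glyph library. Printed lead labels (e.g. "aVL") that overlap the trace are
  located by zero-mean normalized cross-correlation and their ink footprint
  erased, so label glyphs neither distort the trace nor contaminate
  segmentation; the same engine extracts patient demographic text. ROIs can
  be realigned against a standard reference scan by a global FFT
  cross-correlation offset.
* **Segmentation** — connected-component labelling (4- or 8-connectivity),
  discarding of specks below ~100 px, and fusion of trace fragments into row
  waveforms. Distances between components are computed over truncated
  *endpoint pixel subsets* (the `n` leftmost + `n` rightmost pixels, default
  75 per side) rather than all `N` pixels, turning an `O(N²)` Hausdorff-type
  computation into a cheap one; fusion is the transitive closure of
  "closest approach below the merge threshold" (default: twice the grid
  pitch).
* **Extraction** — per-column mean of ink row indices (the printed trace has
  thickness), linear interpolation across gaps, detection of the leading
  rectangular DC calibration pulse, and conversion
  `voltage = (baseline − row) · A_DC / h_pulse` (mV),
  `time = Δcol / (px/mm · paper speed)` (s).

A **synthetic record renderer** (`generateWaveform`, `renderRecord`,
`degradeImage`) draws records with a known continuous ground truth — grid,
DC pulse, Gaussian-bump PQRST beats, overlapping labels, demographic text,
skew, fading, salt-and-pepper noise — and emits a JSON manifest of
everything it did, so every stage is testable without patient data. A
**clinical module** provides the validation statistics: Bazett QTc
(`QT/√RR`), the four abnormality flags (QTc > 450 ms, PR > 200 ms,
RR > 1 s, QRS > 120 ms; strict inequalities), Pearson correlation and
Cohen's kappa over reader interval tables.

## Worked example

```r
library(PaperECG)

# render a 3-row synthetic record with overlapping lead labels
p      <- waveformParams()                      # PQRST Gaussian-bump beats
labels <- data.frame(text = c("II", "aVL", "V5"), row = 1:3,
                     colOffset = c(120, 260, 430), overlap = TRUE)
cfg    <- renderConfig(labels = labels, seed = 42)
tpl    <- makeSyntheticTemplate(p, cfg, nRows = 3)
rec    <- renderRecord(generateWaveform(p, 3, seed = 42), cfg, tpl)

# digitize it and compare against the renderer's ground truth
res <- digitizeRecord(rec$image, tpl, runConfig())
res$report$rowsFound
#> [1] 3
sapply(res$signals, signalLead)
#> [1] "II"  "aVL" "V5"
compareToManifest(res$signals, rec$manifest)
#>   row         r lag   n
#> 1   1 0.9963061  11 709
#> 2   2 0.9960821  11 709
#> 3   3 0.9963684  11 709
```

Each `DigitizedSignal` holds uniform `(time s, voltage mV)` pairs plus full
provenance (threshold, skew, pulse height, config hash); `r ≥ 0.995` means
the digitized curve is essentially the rendered truth, including across the
erased label footprints. Interval agreement between two readers:

```r
stats <- agreementReport(paperReads, digitalReads)  # CSV-shaped data.frames
print(stats)   # Pearson r per interval (PR, QRS, QT, RR, QTc), kappa per flag
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/ecgdigitize.R synth    --out demo/ --rows 3 --seed 1
Rscript inst/cli/ecgdigitize.R digitize --template demo/template.yaml \
                                        --input demo/ --out results/
Rscript inst/cli/ecgdigitize.R validate --paper a.csv --digital b.csv
```

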