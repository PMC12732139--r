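---
title: "Reading truncation positions off the FastQC quality plot"
author: "pixeltrim"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pixeltrim)
```

## The procedure and its assumptions

Illumina amplicon reads degrade toward the 3′ end, and ASV pipelines are
sensitive to how much of that degraded tail is kept. `pixeltrim` infers a
truncation position from the FastQC per-base sequence quality plot alone —
the artifact practitioners already inspect — rather than from raw FASTQ
data, and needs no biological priors such as amplicon size.

The pipeline assumes the input raster is a FastQC-style per-base quality
plot: quality bands in the background (red below Q20, orange Q20–Q28, green
above), one yellow interquartile-range (IQR) box per position bin, numeric
tick labels on both axes. Three stages follow.

**Colour mapping.** The image is partitioned into non-overlapping square
patches (default 10 px, the scale of the plot's colour blocks). Each patch's
dominant colour is its per-channel median — deliberately robust to the thin
median/mean lines and whiskers overdrawn on the boxes. Dominants within an
RGB radius of 10 merge into centroids (first value kept, so the map is
deterministic), and every centroid receives a broad label by nearest
Euclidean match in plain RGB space against fixed pure-hue anchors. Neither a
perceptual colour space nor a data-driven clustering rule is required: the
decision the algorithm ultimately makes — yellow versus not yellow — is far
from the anchors' decision boundaries on FastQC-like palettes, and the fixed
rule is reproducible and cheap.

**Axis calibration.** The data area is the bounding box of the
band-coloured pixels (dark strokes excluded, since thin black strokes never
dominate a patch and would otherwise inherit a band label). Y-axis tick rows
are read from the tick marks hugging the left frame; each tick's label is
recognized and the threshold row is the row of the tick equal to the quality
threshold, or the linear interpolation between the two flanking ticks (the
axis is linear, so interpolation is exact to rounding). X-axis ticks are
detected under the bottom frame and read through 80 × 20 px windows centred
on each tick; a window reaching past the image edge is narrowed to fit. The
affine map from pixel column to base position is then a least-squares fit
through the recognized (column, position) pairs — exact when the renderer's
axis is linear, and averaging out single-tick recognition jitter otherwise.

**Transition scan.** Scanning right-to-left in patch-size steps along the
band of rows centred on the threshold row, a patch that classifies *yellow*
means the IQR box straddles the threshold — quality at that position is
marginal. The scan continues while patches are yellow and stops at the first
non-yellow patch: the boundary where boxes clear the threshold. Because the
patch step quantizes the stop to 10 px, the stop is refined at pixel
resolution: each plot column is classed *above* (its yellow span lies
entirely at or above the threshold row, i.e. q25 ≥ threshold), *straddling*,
or *below*, and the transition column is the rightmost *above* column. The
same per-column analysis is the fallback when the very first patch is
already non-yellow — which happens whenever the terminal bins have dropped
entirely below the threshold, so that the patch row shows background rather
than box — and distinguishes `never_below` (no box ever touches the
threshold row; keep the whole read) from `always_below` (no box ever clears
it; nothing survives).

### Which statistic defines "falls below the threshold"

The plot geometry forces a choice the raster itself does not label: a box
straddles the Q20 row exactly when its lower quartile is below 20 and its
upper quartile above. Stopping where boxes *clear* the row therefore means
the truncation criterion is **q25 ≥ threshold** — the read is kept through
the last bin whose 25th-percentile quality is at or above Q20. The numeric
oracle `oracle_trim()` uses the same statistic so the two routes are
comparable; users preferring a median criterion can see the effect by
adjusting the threshold. Binned bars resolve to the bin **end**: the
conservative-right choice, consistent with the right-to-left stop semantics
and within the ±1-bin comparison band either way.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `quality_threshold` | 20 | Phred | Q20 ≈ 1% error rate, the standard cutoff separating reliable from unreliable calls; tunable because aggressive trimming trades detected taxa for reliability |
| `patch_size` | 10 | px | matches the colour-block scale of FastQC plots; smaller patches lose the robustness of the median, larger ones blur the transition |
| `ocr_patch_width`, `ocr_patch_height` | 80, 20 | px | wide enough to contain any tick label with margin, short enough to exclude neighbouring plot elements |

The scan is monotone in the threshold by construction: lowering the
threshold moves its row down, which can only grow the set of *above*
columns, so the kept length never decreases.

## The synthetic generator

`simulate_profile()` emulates the canonical MiSeq amplicon shape: a plateau
(default Q38) followed by linear decay (default 0.5 Phred/base from 70% of
the read), Gaussian per-position noise, quartiles at median ∓ 4 and whiskers
at median ∓ 8 Phred, all clamped to [2, 41], then aggregated into
FastQC-style bins (per-base through position 9, width 5 after) and rounded
to one decimal — FastQC's printed precision, so the rendered raster and the
numeric table describe identical values and the two routes never split on
sub-0.1 differences. The defaults are the study conditions every
verification grid uses; the grid spans read lengths {150, 250, 300}, decay
onsets at 40–95% of the read, rates 0.2–1.0 Phred/base and noise sd {0, 1, 2}.

`render_plot()` draws the profile with the band/box/whisker/median/mean
anatomy described above and returns a *sidecar* of exact pixel anchors (plot
box, tick rows and columns, the Q20 row) plus the ground-truth truncation
implied by the binned profile. Tick labels use a bundled 5 × 7 bitmap font,
shared with the recognition engine's template atlas, which is what makes
digit recognition deterministic without an external OCR binary; the engine
is pluggable for users who want to run tesseract or similar on real
reports.

What the fixtures deliberately do **not** model: position-correlated,
heavy-tailed noise of real flow cells, anti-aliased fonts and version-
dependent image sizes of real FastQC output, chemistry artifacts, primers,
or taxonomic composition. Passing the verification grid therefore
demonstrates the algorithm's correctness on FastQC-like geometry, not
pixel-level robustness to every FastQC build; real-report parsing is
best-effort and falls back cleanly to calibration errors when labels cannot
be read.

### A note on the noiseless closed form

For plateau 38, decay start 200, rate 0.5 and IQR half-width 4, the
per-position lower quartile 34 − 0.5 (p − 200) first drops below 20 at
p = 229. After binning (statistic = mean over member positions) the bin
226–230 carries q25 = 20.0 ≥ 20, so the binned — and reported — truncation
is 230. The sidecar's ground-truth crossing is defined on the binned
profile, i.e. as the value `oracle_trim()` yields, keeping generator,
oracle and vision pipeline consistent with one another (and within one bin
of the unbinned closed form).

## Numerical choices and degenerate inputs

* Exposed pixel coordinates are 1-based `(row, col)` with the origin at the
  top-left, matching R matrix indexing; base positions are 1-based
  inclusive, and a truncation of *k* means "keep the first *k* bases"
  (0 = nothing survives).
* Colour ties break to the first centroid in map order; glyph matches
  require an exact bounding-box size and at most 15% pixel mismatch.
* `pixel_to_position()` rounds to the nearest base and clamps to the axis
  extent; predictions clamp to `[0, read_length]`.
* A report whose plot lacks readable ticks raises `axis calibration
  failed` rather than guessing; a blank or bandless image fails the same
  way. Reads shorter than the truncation are kept unchanged by default
  (`discard_short = FALSE`); DADA2's `truncLen` discards them, and the flag
  provides parity.
* Verification uses 50-fixture grids and 2,000-read FASTQ samples — large
  enough that recovery percentages are meaningful, small enough to run
  comfortably on a laptop.

## Known limitations

The predictor reads one report at a time; paired mates are predicted
independently, not forced to a common length. Only fixed-position
truncation is provided (no expected-error filtering or merging). The
recognition engine is calibrated on the bundled font; arbitrary fonts
require plugging in an external OCR engine. Primer and adapter sequences
must be removed before the FastQC report is generated, or the 3′ quality
distribution — and hence the prediction — is distorted.
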