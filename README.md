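# pixeltrim

Predicts where to truncate the 3′ ends of 16S rRNA amplicon reads — with no
amplicon-size estimate, primer information, or other biological priors — by
reading the FastQC per-base sequence quality plot the way a human does: as an
image.

## The problem and the approach

ASV pipelines such as DADA2 need a `truncLen` that removes the low-quality 3′
tail of each read while keeping enough sequence for paired-end merging. Tools
that derive this from raw FASTQ files (e.g. FIGARO) require parameters like
the expected amplicon size, and mis-specifying them changes downstream
taxonomic profiles drastically. The quality information practitioners
actually look at, however, is already summarised in the FastQC report's
per-base sequence quality plot: per position bin, a yellow box spans the
interquartile range (IQR) of Phred scores, whiskers mark the 10th/90th
percentiles, a red segment the median, a blue line the mean, over background
bands (red below Q20, orange Q20–Q28, green above).

`pixeltrim` analyses that plot raster directly:

1. **Colour mapping** — the image is cut into 10 × 10 px patches; each
   patch's dominant RGB value (per-channel median) is clustered and mapped to
   a broad colour label (yellow, green, orange, red, blue, black, white,
   gray) by nearest match against fixed RGB anchors.
2. **Axis calibration** — numeric tick labels are read by template matching
   against a bundled digit-glyph atlas (an external OCR engine can be
   plugged in); the y calibration fixes the pixel row of the quality
   threshold *Q* (default 20, ≈ 1% error rate since the error probability is
   10^(−Q/10)), and 80 × 20 px windows over the bottom label strip fix the
   affine pixel ↔ base-position map.
3. **Transition scan** — starting from the right edge, patches centred on
   the threshold row are examined right-to-left: while a patch classifies as
   broad yellow (the IQR box straddles the threshold) the scan continues;
   the stop is refined to the rightmost pixel column whose yellow span lies
   entirely at or above the Q20 row, and mapped back to a base position —
   the recommended truncation position (the last base kept).

A numeric oracle (`oracle_trim()`) computes the same decision from the
`fastqc_data.txt` table — the rightmost bin whose lower quartile is at or
above the threshold — so the two independent routes can be checked against
each other. A synthetic generator renders FastQC-style reports with
pixel-exact ground truth, making the whole pipeline verifiable offline.

## Worked example

```r
library(pixeltrim)

# a synthetic MiSeq-like run: plateau Q38, decay from base 175 at 0.5 Phred/base
prof <- simulate_profile(profile_spec(read_length = 250, noise_sd = 0))
r <- render_plot(prof)
report_path <- tempfile(fileext = ".html")
wrap_html(r$image, 250, "demo_sample", path = report_path)

rec <- predict_trim(parse_fastqc_html(report_path))
rec
#> Trim recommendation (image route) for demo_sample:
#>   keep first 204 bases (Q20 threshold, status 'found')

oracle_trim(prof)
#> Trim recommendation (table route):
#>   keep first 204 bases (Q20 threshold, status 'found')
```

Both routes keep 204 bases: the lower quartile of the rendered profile stays
at or above Q20 through the bin ending at base 204 and falls below it
afterwards, so bases 205–250 are flagged for removal. Applying it:

```r
fq <- tempfile(fileext = ".fastq")
simulate_fastq(prof, 1000, seed = 1, fq)
trim_fastq(fq, rec$truncation_position, discard_short = FALSE,
           tempfile(fileext = ".fastq"))
#>      read   written discarded
#>      1000      1000         0
```

The same operations are scriptable from a shell via `exec/pixeltrim`:

```sh
pixeltrim predict --report-r1 fastqc_report.html --out trim.json
pixeltrim trim --fastq reads.fastq.gz --report fastqc_report.html --out trimmed.fastq.gz
pixeltrim simulate --out-dir fixtures/ --read-length 250 --seed 7
```

Exit codes: 0 = usable truncation, 2 = degenerate (quality everywhere below
threshold), 1 = operational error.

## Scope notes

Primer/adapter sequences must be removed before generating the FastQC
report, as non-biological bases distort the 3′ quality distribution. The
package performs fixed-position truncation only — no sliding-window or
expected-error filtering, no paired-end merging; each read's report is
treated independently.
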