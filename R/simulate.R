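# Synthetic fixture generators: parametric quality profiles with known ground
# truth, FastQC-style plot renderings with a pixel-level sidecar, wrapped HTML
# reports, numeric data tables and FASTQ reads.

#' Specification of a synthetic quality profile
#'
#' Parametrises the canonical Illumina amplicon quality shape: a high plateau
#' followed by linear degradation toward the 3' end, with optional Gaussian
#' position noise. Defaults emulate a typical MiSeq 2x250 run: plateau Q38,
#' decay starting at 70% of the read, half a Phred unit lost per base.
#'
#' @param read_length Read length in cycles.
#' @param plateau_q Plateau median quality (Phred).
#' @param decay_start 1-based position where degradation begins (default 70%
#'   of `read_length`).
#' @param decay_rate Phred units lost per base after `decay_start`.
#' @param noise_sd Standard deviation of per-position Gaussian noise (Phred).
#' @param iqr_half_width Half-width of the interquartile range: `q25`/`q75`
#'   sit at `median -/+ iqr_half_width`, whiskers at twice that.
#' @param bin_width Bin width for positions 10 onward (positions 1-9 are
#'   per-base, as in FastQC).
#' @param seed Integer seed making the profile reproducible.
#' @return Object of class `profile_spec`.
#' @export
profile_spec <- function(read_length = 250, plateau_q = 38,
                         decay_start = NULL, decay_rate = 0.5,
                         noise_sd = 1, iqr_half_width = 4,
                         bin_width = 5, seed = 1L) {
  if (is.null(decay_start)) decay_start <- ceiling(0.7 * read_length)
  spec <- structure(list(read_length = as.integer(read_length),
                         plateau_q = plateau_q,
                         decay_start = as.integer(decay_start),
                         decay_rate = decay_rate,
                         noise_sd = noise_sd,
                         iqr_half_width = iqr_half_width,
                         bin_width = as.integer(bin_width),
                         seed = as.integer(seed)),
                    class = "profile_spec")
  validate_profile_spec(spec)
  spec
}

validate_profile_spec <- function(spec) {
  if (!is.finite(spec$read_length) || spec$read_length < 1) {
    stop("invalid profile spec: read_length must be >= 1")
  }
  if (spec$decay_start < 1) {
    stop("invalid profile spec: decay_start must be >= 1")
  }
  if (spec$plateau_q < 2 || spec$plateau_q > 41) {
    stop("invalid profile spec: plateau_q must lie in [2, 41]")
  }
  if (spec$noise_sd < 0) stop("invalid profile spec: noise_sd must be >= 0")
  if (spec$iqr_half_width < 0) stop("invalid profile spec: iqr_half_width must be >= 0")
  if (spec$bin_width < 1) stop("invalid profile spec: bin_width must be >= 1")
  invisible(spec)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a per-base quality profile
#'
#' Generates the per-position median as `plateau_q` before `decay_start` and
#' `plateau_q - decay_rate * (p - decay_start)` after it, adds seeded Gaussian
#' noise, clamps to Phred `[2, 41]`, derives `q25`/`q75` at `median -/+
#' iqr_half_width` and `q10`/`q90` at twice that offset (mean = median), then
#' aggregates into FastQC-style bins (bin statistic = mean over member
#' positions) and rounds to one decimal, FastQC's printed precision.
#'
#' @param spec A [profile_spec()].
#' @return A [quality_profile()].
#' @export
#' @examples
#' prof <- simulate_profile(profile_spec(read_length = 250, noise_sd = 0))
#' prof
simulate_profile <- function(spec) {
  stopifnot(inherits(spec, "profile_spec"))
  validate_profile_spec(spec)
  p <- seq_len(spec$read_length)
  med <- spec$plateau_q - spec$decay_rate * pmax(0, p - spec$decay_start)
  if (spec$noise_sd > 0) {
    med <- med + with_local_seed(spec$seed, stats::rnorm(length(p), 0, spec$noise_sd))
  }
  med <- clamp(med, 2, 41)
  per_pos <- data.frame(
    median = med,
    mean = med,
    q25 = clamp(med - spec$iqr_half_width, 2, 41),
    q75 = clamp(med + spec$iqr_half_width, 2, 41),
    q10 = clamp(med - 2 * spec$iqr_half_width, 2, 41),
    q90 = clamp(med + 2 * spec$iqr_half_width, 2, 41)
  )
  layout <- fastqc_bin_layout(spec$read_length, spec$bin_width)
  agg <- function(v) {
    vapply(seq_len(nrow(layout)),
           function(i) round(mean(v[layout$start[i]:layout$end[i]]), 1), 0)
  }
  bins <- data.frame(start = layout$start, end = layout$end,
                     mean = agg(per_pos$mean), median = agg(per_pos$median),
                     q25 = agg(per_pos$q25), q75 = agg(per_pos$q75),
                     q10 = agg(per_pos$q10), q90 = agg(per_pos$q90))
  quality_profile(bins, spec$read_length)
}

# Default rendering style; all sizes in pixels.
default_render_style <- function() {
  list(px_per_base = 3, px_per_q = 10, q_max = 41,
       margin_left = 50, margin_top = 15, margin_right = 25,
       tick_len = 4, label_scale = 2, y_tick_every = 2,
       x_tick_interval = NULL, palette = render_palette())
}

#' Render a quality profile as a FastQC-style plot
#'
#' Draws the per-base sequence quality plot the way FastQC does: background
#' bands (red below Q20, orange Q20-Q28, green above), one yellow
#' interquartile-range box per bin with 10th/90th-percentile whiskers, a red
#' median segment per bin, a blue mean poly-line, y-axis ticks every 2 Phred
#' units and x-axis ticks at regular base positions. Tick labels use the
#' bundled bitmap font shared with [digit_atlas()].
#'
#' Alongside the raster it returns a sidecar of exact pixel anchors (plot box,
#' tick rows/columns, Q20 row) and the ground-truth truncation implied by the
#' binned profile, for verifying the vision pipeline.
#'
#' @param profile A [quality_profile()].
#' @param style Named list overriding entries of the default style
#'   (`px_per_base`, `px_per_q`, `q_max`, margins, `tick_len`, `label_scale`,
#'   `y_tick_every`, `x_tick_interval`, `palette`).
#' @return List with elements `image` (RGB array) and `sidecar` (list with
#'   `plot_box`, `y_tick_rows`, `x_tick_cols`, `threshold_row_q20`,
#'   `ground_truth_crossing`, `ground_truth_status`, `palette`,
#'   `px_per_base`, `read_length`).
#' @export
render_plot <- function(profile, style = list()) {
  stopifnot(inherits(profile, "quality_profile"))
  st <- utils::modifyList(default_render_style(), style)
  pal <- st$palette
  ppb <- st$px_per_base
  ppq <- st$px_per_q
  rl <- profile$read_length
  b <- profile$bins

  plot_w <- rl * ppb
  plot_left <- st$margin_left + 1L
  plot_right <- plot_left + plot_w - 1L
  plot_top <- st$margin_top + 1L
  plot_bottom <- plot_top + st$q_max * ppq
  margin_bottom <- st$tick_len + 2L + glyph_height(st$label_scale) + 10L
  width <- st$margin_left + plot_w + st$margin_right
  height <- plot_bottom + margin_bottom

  row_of <- function(q) plot_bottom - round(q * ppq)
  col_span <- function(p) c(plot_left + (p - 1L) * ppb, plot_left + p * ppb - 1L)
  col_center <- function(p) plot_left + (p - 1L) * ppb + floor(ppb / 2)

  cv <- canvas_new(height, width, pal$background)

  # quality bands: red [0, 20), orange [20, 28), green [28, q_max]
  canvas_rect(cv, row_of(min(20, st$q_max)) + 1L, plot_bottom,
              plot_left, plot_right, pal$band_red)
  if (st$q_max > 20) {
    canvas_rect(cv, row_of(min(28, st$q_max)) + 1L, row_of(20),
                plot_left, plot_right, pal$band_orange)
  }
  if (st$q_max > 28) {
    canvas_rect(cv, plot_top, row_of(28), plot_left, plot_right, pal$band_green)
  }

  # whiskers, boxes, median segments
  for (i in seq_len(nrow(b))) {
    cs <- col_span(b$start[i]); ce <- col_span(b$end[i])
    cc <- floor((cs[1] + ce[2]) / 2)
    canvas_rect(cv, row_of(b$q90[i]), row_of(b$q75[i]), cc, cc, pal$ink)
    canvas_rect(cv, row_of(b$q25[i]), row_of(b$q10[i]), cc, cc, pal$ink)
    canvas_rect(cv, row_of(b$q90[i]), row_of(b$q90[i]), cc - 2L, cc + 2L, pal$ink)
    canvas_rect(cv, row_of(b$q10[i]), row_of(b$q10[i]), cc - 2L, cc + 2L, pal$ink)
    canvas_rect(cv, row_of(b$q75[i]), row_of(b$q25[i]), cs[1], ce[2], pal$box_yellow)
    med_row <- row_of(b$median[i])
    canvas_rect(cv, max(med_row - 1L, row_of(b$q75[i])),
                min(med_row + 1L, row_of(b$q25[i])), cs[1], ce[2], pal$median_red)
  }

  # blue mean poly-line across bin centers, two pixels thick
  centers <- vapply(seq_len(nrow(b)),
                    function(i) floor((col_span(b$start[i])[1] + col_span(b$end[i])[2]) / 2), 0)
  mean_rows <- row_of(b$mean)
  if (nrow(b) == 1) {
    canvas_rect(cv, mean_rows[1], mean_rows[1] + 1L,
                col_span(b$start[1])[1], col_span(b$end[1])[2], pal$mean_blue)
  } else {
    line_cols <- centers[1]:centers[length(centers)]
    line_rows <- round(stats::approx(centers, mean_rows, xout = line_cols)$y)
    idx <- cbind(c(line_rows, line_rows + 1L), rep(line_cols, 2L))
    canvas_pixels(cv, idx, pal$mean_blue)
  }

  # frame around the data area
  canvas_rect(cv, plot_top - 1L, plot_top - 1L, plot_left - 1L, plot_right + 1L, pal$ink)
  canvas_rect(cv, plot_bottom + 1L, plot_bottom + 1L, plot_left - 1L, plot_right + 1L, pal$ink)
  canvas_rect(cv, plot_top - 1L, plot_bottom + 1L, plot_left - 1L, plot_left - 1L, pal$ink)
  canvas_rect(cv, plot_top - 1L, plot_bottom + 1L, plot_right + 1L, plot_right + 1L, pal$ink)

  # y-axis ticks and labels
  y_scores <- seq(0, st$q_max - st$q_max %% st$y_tick_every, by = st$y_tick_every)
  y_rows <- row_of(y_scores)
  for (i in seq_along(y_scores)) {
    canvas_rect(cv, y_rows[i], y_rows[i],
                plot_left - 1L - st$tick_len, plot_left - 2L, pal$ink)
    lab <- as.character(y_scores[i])
    w <- text_width(lab, st$label_scale)
    canvas_text(cv, y_rows[i] - floor(glyph_height(st$label_scale) / 2),
                plot_left - st$tick_len - 4L - w, lab, st$label_scale, pal$ink)
  }

  # x-axis ticks and labels
  interval <- st$x_tick_interval
  if (is.null(interval)) {
    cand <- c(5, 10, 20, 25, 50, 100, 200)
    interval <- cand[which(cand * ppb >= 48)[1]]
    if (is.na(interval)) interval <- 200
  }
  x_pos <- unique(c(1L, seq(interval, rl, by = interval)))
  x_cols <- vapply(x_pos, col_center, 0)
  lab_top <- plot_bottom + 1L + st$tick_len + 3L
  for (i in seq_along(x_pos)) {
    canvas_rect(cv, plot_bottom + 2L, plot_bottom + 1L + st$tick_len,
                x_cols[i], x_cols[i], pal$ink)
    lab <- as.character(x_pos[i])
    w <- text_width(lab, st$label_scale)
    canvas_text(cv, lab_top, x_cols[i] - floor(w / 2), lab, st$label_scale, pal$ink)
  }
  img <- canvas_image(cv)

  gt <- oracle_trim(profile, threshold = 20)
  sidecar <- list(
    plot_box = c(left = as.integer(plot_left), top = as.integer(plot_top),
                 right = as.integer(plot_right), bottom = as.integer(plot_bottom)),
    y_tick_rows = data.frame(score = y_scores, row = as.integer(y_rows)),
    x_tick_cols = data.frame(position = as.integer(x_pos), col = as.integer(x_cols)),
    threshold_row_q20 = as.integer(row_of(20)),
    ground_truth_crossing = if (gt$status == "found") gt$truncation_position else NA_integer_,
    ground_truth_status = gt$status,
    ground_truth_truncation = gt$truncation_position,
    palette = pal,
    px_per_base = ppb,
    read_length = rl
  )
  list(image = img, sidecar = sidecar)
}

#' Wrap a plot raster in a FastQC-style HTML report
#'
#' Emits a minimal report shell with the layout [parse_fastqc_html()] expects
#' from FastQC: a Basic Statistics table carrying Filename and Sequence
#' length, a "Per base sequence quality" heading, and the plot embedded as a
#' base64 PNG data URI.
#'
#' @param image RGB array to embed.
#' @param read_length Integer sequence length written to Basic Statistics.
#' @param sample_name Report filename entry.
#' @param path Optional output file; when given the document is written there.
#' @param length_text Optional literal Sequence length text (e.g. `"35-251"`)
#'   overriding `read_length`, to emulate variable-length runs.
#' @return The HTML document as a single character string (invisibly when
#'   `path` is given).
#' @export
wrap_html <- function(image, read_length, sample_name, path = NULL,
                      length_text = NULL) {
  stopifnot(length(dim(image)) == 3, read_length >= 1, nzchar(sample_name))
  b64 <- jsonlite::base64_enc(write_plot_image(image, raw()))
  b64 <- gsub("[\r\n]", "", b64)
  len <- if (is.null(length_text)) as.character(as.integer(read_length)) else length_text
  html <- paste0(
    "<html><head><title>", xml_escape(sample_name), " FastQC Report</title></head>\n",
    "<body>\n",
    "<h2>Basic Statistics</h2>\n",
    "<table>\n",
    "<tr><th>Measure</th><th>Value</th></tr>\n",
    "<tr><td>Filename</td><td>", xml_escape(sample_name), "</td></tr>\n",
    "<tr><td>Sequence length</td><td>", len, "</td></tr>\n",
    "</table>\n",
    "<h2>Per base sequence quality</h2>\n",
    "<p><img class=\"indented\" src=\"data:image/png;base64,", b64,
    "\" alt=\"Per base quality graph\"/></p>\n",
    "</body></html>\n")
  if (!is.null(path)) {
    writeLines(html, path, sep = "")
    return(invisible(html))
  }
  html
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a quality profile as a FastQC data table
#'
#' Writes the `>>Per base sequence quality` block in the `fastqc_data.txt`
#' column layout (Base, Mean, Median, Lower Quartile, Upper Quartile, 10th
#' Percentile, 90th Percentile) at one-decimal precision. Binned rows carry
#' `"start-end"` base labels, single-position rows a bare position.
#'
#' @param profile A [quality_profile()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_data_table <- function(profile, path) {
  stopifnot(inherits(profile, "quality_profile"))
  validate_quality_profile(profile)
  b <- profile$bins
  base_lab <- ifelse(b$start == b$end, as.character(b$start),
                     paste0(b$start, "-", b$end))
  fmt <- function(v) sprintf("%.1f", v)
  lines <- c(
    "##FastQC\t0.12.0",
    ">>Per base sequence quality\tpass",
    "#Base\tMean\tMedian\tLower Quartile\tUpper Quartile\t10th Percentile\t90th Percentile",
    paste(base_lab, fmt(b$mean), fmt(b$median), fmt(b$q25), fmt(b$q75),
          fmt(b$q10), fmt(b$q90), sep = "\t"),
    ">>END_MODULE")
  writeLines(lines, path)
  invisible(path)
}

#' Simulate FASTQ reads consistent with a quality profile
#'
#' Writes `n_reads` records of the profile's read length. Per-position
#' qualities are drawn from a Gaussian matching the containing bin's median
#' and interquartile range (sd = IQR / 1.349), rounded, clamped to Phred
#' `[2, 41]` and encoded as Phred+33; bases are uniform over A/C/G/T.
#' Deterministic under `seed`. A `.gz` suffix on `path` gzip-compresses the
#' output.
#'
#' @param profile A [quality_profile()].
#' @param n_reads Number of records to write (0 gives a valid empty file).
#' @param seed Integer seed.
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
simulate_fastq <- function(profile, n_reads, seed, path) {
  stopifnot(inherits(profile, "quality_profile"), n_reads >= 0)
  rl <- profile$read_length
  b <- profile$bins
  pos_median <- rep(b$median, b$end - b$start + 1)
  pos_sd <- rep((b$q75 - b$q25) / 1.349, b$end - b$start + 1)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (n_reads == 0) return(invisible(path))
  recs <- with_local_seed(seed, {
    q <- matrix(stats::rnorm(n_reads * rl, mean = pos_median, sd = pos_sd),
                nrow = rl, ncol = n_reads)
    q <- clamp(round(q), 2, 41)
    bases <- matrix(sample(c("A", "C", "G", "T"), n_reads * rl, replace = TRUE),
                    nrow = rl, ncol = n_reads)
    list(q = q, bases = bases)
  })
  lines <- character(4L * n_reads)
  for (i in seq_len(n_reads)) {
    k <- 4L * (i - 1L)
    lines[k + 1L] <- sprintf("@sim_read_%d", i)
    lines[k + 2L] <- paste(recs$bases[, i], collapse = "")
    lines[k + 3L] <- "+"
    lines[k + 4L] <- intToUtf8(recs$q[, i] + 33L)
  }
  writeLines(lines, con)
  invisible(path)
}
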