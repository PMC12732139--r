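# The vision pipeline: patch-based colour labelling, digit recognition for
# axis calibration, and the right-to-left transition scan that turns the
# per-base quality plot raster into a pixel-level trim location.

#' Vision algorithm parameters
#'
#' Houses every constant of the pixel pipeline: the patch edge used for
#' colour analysis (10 px, matching the colour blocks of the quality plot),
#' the Phred quality threshold (default 20, approximately a 1% base-call
#' error rate), and the width/height of the windows the recognition engine
#' extracts from the axis label strip (80 x 20 px).
#'
#' @param patch_size Edge length in pixels of the square analysis patches.
#' @param quality_threshold Phred threshold in `[1, 41]`.
#' @param ocr_patch_width,ocr_patch_height Recognition window size in pixels.
#' @return Object of class `vision_params`.
#' @export
vision_params <- function(patch_size = 10, quality_threshold = 20,
                          ocr_patch_width = 80, ocr_patch_height = 20) {
  if (patch_size < 2) stop("vision_params: patch_size must be >= 2")
  if (quality_threshold < 1 || quality_threshold > 41) {
    stop("vision_params: quality_threshold must lie in [1, 41]")
  }
  if (ocr_patch_width < 1 || ocr_patch_height < 1) {
    stop("vision_params: OCR patch dimensions must be positive")
  }
  structure(list(patch_size = as.integer(patch_size),
                 quality_threshold = quality_threshold,
                 ocr_patch_width = as.integer(ocr_patch_width),
                 ocr_patch_height = as.integer(ocr_patch_height)),
            class = "vision_params")
}

broad_labels <- function() names(reference_palette())

# Nearest reference anchor for an n x 3 RGB matrix -> character labels.
nearest_anchor_label <- function(m, max_dist = Inf) {
  pal <- reference_palette()
  best <- rep(Inf, nrow(m)); lab <- rep("other", nrow(m))
  for (nm in names(pal)) {
    a <- pal[[nm]]
    d <- (m[, 1] - a[1])^2 + (m[, 2] - a[2])^2 + (m[, 3] - a[3])^2
    hit <- d < best
    best[hit] <- d[hit]; lab[hit] <- nm
  }
  lab[best > max_dist^2] <- "other"
  lab
}

# Per-channel median of a tile (h x w x 3): robust to thin overdrawn lines.
patch_dominant <- function(patch) {
  c(stats::median(patch[, , 1]), stats::median(patch[, , 2]), stats::median(patch[, , 3]))
}

#' Build a colour map from an image
#'
#' Partitions the image into non-overlapping `patch_size` x `patch_size`
#' tiles (ragged edge tiles allowed), takes each tile's dominant RGB value
#' (per-channel median), merges dominants lying within a small RGB radius
#' into representative centroids, and assigns each centroid a broad
#' human-readable label by nearest match against a fixed reference palette
#' (pure yellow/green/orange/red/blue/black/white/gray anchors). The result
#' maps fine-grained colours such as light or dark yellow onto the broad
#' labels the transition scan reasons about.
#'
#' @param image RGB array.
#' @param params A [vision_params()].
#' @param merge_radius RGB Euclidean radius within which dominant values are
#'   merged into one centroid (first-seen value kept).
#' @return Object of class `color_map`: a `data.frame` of centroids with
#'   columns `r`, `g`, `b`, `label`.
#' @export
build_color_map <- function(image, params = vision_params(), merge_radius = 10) {
  d <- dim(image)
  ps <- params$patch_size
  if (d[1] < ps || d[2] < ps) {
    stop("image too small: need at least ", ps, " x ", ps, " pixels")
  }
  row_starts <- seq(1L, d[1], by = ps)
  col_starts <- seq(1L, d[2], by = ps)
  doms <- matrix(0, nrow = length(row_starts) * length(col_starts), ncol = 3)
  i <- 0L
  for (r0 in row_starts) {
    r1 <- min(r0 + ps - 1L, d[1])
    for (c0 in col_starts) {
      c1 <- min(c0 + ps - 1L, d[2])
      i <- i + 1L
      doms[i, ] <- patch_dominant(image[r0:r1, c0:c1, , drop = FALSE])
    }
  }
  doms <- round(doms)
  doms <- doms[!duplicated(doms[, 1] * 65536 + doms[, 2] * 256 + doms[, 3]), , drop = FALSE]
  # sequential merge in raster order: deterministic, first value kept
  cents <- doms[1, , drop = FALSE]
  if (nrow(doms) > 1) {
    for (j in 2:nrow(doms)) {
      d2 <- (cents[, 1] - doms[j, 1])^2 + (cents[, 2] - doms[j, 2])^2 +
        (cents[, 3] - doms[j, 3])^2
      if (min(d2) > merge_radius^2) cents <- rbind(cents, doms[j, ])
    }
  }
  cm <- data.frame(r = cents[, 1], g = cents[, 2], b = cents[, 3],
                   label = nearest_anchor_label(cents))
  class(cm) <- c("color_map", "data.frame")
  cm
}

#' @export
print.color_map <- function(x, ...) {
  cat("Colour map: ", nrow(x), " centroids; labels: ",
      paste(sort(unique(x$label)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Nearest-centroid labels for an n x 3 RGB matrix (ties -> first centroid).
classify_rgb <- function(m, color_map) {
  best <- rep(Inf, nrow(m)); idx <- rep(1L, nrow(m))
  for (j in seq_len(nrow(color_map))) {
    d <- (m[, 1] - color_map$r[j])^2 + (m[, 2] - color_map$g[j])^2 +
      (m[, 3] - color_map$b[j])^2
    hit <- d < best
    best[hit] <- d[hit]; idx[hit] <- j
  }
  color_map$label[idx]
}

#' Classify a patch to a broad colour label
#'
#' Labels the patch by the nearest colour-map centroid (Euclidean distance in
#' RGB) to its dominant value, the per-channel median. Ties break to the
#' first centroid in map order. Total on non-empty patches: every patch
#' receives exactly one label.
#'
#' @param patch RGB array tile.
#' @param color_map A [build_color_map()] result.
#' @return Single character label.
#' @export
classify_patch <- function(patch, color_map) {
  stopifnot(length(patch) > 0)
  classify_rgb(matrix(patch_dominant(patch), 1, 3), color_map)
}

# Label matrix for a rectangular image region.
classify_region <- function(image, color_map, rows, cols) {
  sub <- image[rows, cols, , drop = FALSE]
  m <- cbind(as.vector(sub[, , 1]), as.vector(sub[, , 2]), as.vector(sub[, , 3]))
  matrix(classify_rgb(m, color_map), nrow = length(rows), ncol = length(cols))
}

# Dark-pixel (text/tick ink) mask for a region.
ink_mask <- function(image, rows, cols, cutoff = 100) {
  sub <- image[rows, cols, , drop = FALSE]
  (sub[, , 1] < cutoff) & (sub[, , 2] < cutoff) & (sub[, , 3] < cutoff)
}

#' Recognize an integer in an image region
#'
#' The default engine is template matching against the bundled digit-glyph
#' atlas (the same bitmap font the fixture renderer draws with): ink pixels
#' are segmented into glyph runs, runs are grouped into labels by horizontal
#' gaps, each glyph is matched against the atlas, and the valid label group
#' nearest the horizontal centre of the region is parsed. A range label
#' `"A-B"` yields `B`. Partially clipped glyphs never match a template, so
#' neighbouring labels cut off at the region edge are ignored. An external
#' OCR engine can be plugged in behind the same contract via `engine`.
#'
#' @param image RGB array.
#' @param region Integer vector `c(left, top, right, bottom)`, 1-based
#'   inclusive pixel bounds, inside the image.
#' @param atlas Glyph templates from [digit_atlas()].
#' @param engine Optional function `(image, region) -> integer or NA`
#'   replacing the template engine.
#' @return Integer, or `NA_integer_` when no digits are found.
#' @export
recognize_number <- function(image, region, atlas = digit_atlas(), engine = NULL) {
  d <- dim(image)
  region <- as.integer(region)
  if (region[1] < 1 || region[2] < 1 || region[3] > d[2] || region[4] > d[1] ||
      region[1] > region[3] || region[2] > region[4]) {
    stop("recognize_number: region outside image bounds")
  }
  if (!is.null(engine)) return(engine(image, region))
  rows <- region[2]:region[4]; cols <- region[1]:region[3]
  ink <- ink_mask(image, rows, cols)
  col_ink <- colSums(ink) > 0
  if (!any(col_ink)) return(NA_integer_)

  runs <- rle(col_ink)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  glyph_runs <- data.frame(start = starts[runs$values], end = ends[runs$values])

  # group glyph runs into labels: gaps wider than 10 px separate labels
  gap_thresh <- 10L
  group <- cumsum(c(1L, diff(glyph_runs$start) - 0))
  group <- integer(nrow(glyph_runs)); g <- 1L; group[1] <- 1L
  if (nrow(glyph_runs) > 1) {
    for (i in 2:nrow(glyph_runs)) {
      if (glyph_runs$start[i] - glyph_runs$end[i - 1] - 1L > gap_thresh) g <- g + 1L
      group[i] <- g
    }
  }

  match_glyph <- function(bm) {
    best_char <- NA_character_; best_score <- Inf
    for (tpl in atlas) {
      if (is.null(tpl$bitmap)) next
      if (!all(dim(tpl$bitmap) == dim(bm))) next
      ham <- sum(tpl$bitmap != bm) / length(bm)
      if (ham < best_score) { best_score <- ham; best_char <- tpl$char }
    }
    if (is.finite(best_score) && best_score <= 0.15) best_char else NA_character_
  }

  region_center <- (ncol(ink) + 1) / 2
  groups <- split(seq_len(nrow(glyph_runs)), group)
  candidates <- list()
  for (idx in groups) {
    chars <- character(0); ok <- TRUE
    for (i in idx) {
      gcols <- glyph_runs$start[i]:glyph_runs$end[i]
      sub <- ink[, gcols, drop = FALSE]
      rrows <- which(rowSums(sub) > 0)
      bm <- (sub[min(rrows):max(rrows), , drop = FALSE]) * 1L
      ch <- match_glyph(bm)
      if (is.na(ch)) { ok <- FALSE; break }
      chars <- c(chars, ch)
    }
    if (!ok) next
    center <- (glyph_runs$start[idx[1]] + glyph_runs$end[idx[length(idx)]]) / 2
    candidates[[length(candidates) + 1L]] <-
      list(text = paste(chars, collapse = ""), dist = abs(center - region_center))
  }
  if (length(candidates) == 0) return(NA_integer_)
  best <- candidates[[which.min(vapply(candidates, `[[`, 0, "dist"))]]
  parse_label_value(best$text)
}

# "A-B" -> B; bare integer -> itself; anything else -> NA.
parse_label_value <- function(text) {
  if (grepl("-", text, fixed = TRUE)) {
    parts <- strsplit(text, "-", fixed = TRUE)[[1]]
    text <- parts[length(parts)]
  }
  if (!grepl("^[0-9]+$", text)) return(NA_integer_)
  as.integer(text)
}

#' Locate the quality-threshold row on the y axis
#'
#' Finds the plot data area (the bounding box of the green/orange/red
#' quality-band pixels), detects the y-axis tick marks hugging its left
#' edge, reads each tick's numeric label with [recognize_number()], and
#' resolves the pixel row of the quality threshold: the row of the tick
#' equal to the threshold, or linear interpolation between the two flanking
#' ticks when no tick matches.
#'
#' @param image RGB array of a per-base quality plot.
#' @param params A [vision_params()].
#' @param color_map Optional precomputed [build_color_map()] result.
#' @return A y-calibrated `plot_geometry` (plot box, y ticks, threshold
#'   row); pass to [calibrate_x_axis()] to complete calibration.
#' @export
locate_threshold_row <- function(image, params = vision_params(), color_map = NULL) {
  d <- dim(image)
  if (is.null(color_map)) color_map <- build_color_map(image, params)
  labels <- classify_region(image, color_map, seq_len(d[1]), seq_len(d[2]))
  # dark strokes (text, frame, whiskers) are excluded: with no black area in
  # the image the colour map may lack a black centroid, and ink would then
  # fall to the nearest band colour and inflate the bounding box
  band <- labels %in% c("green", "orange", "red") &
    !ink_mask(image, seq_len(d[1]), seq_len(d[2]))
  band_m <- matrix(band, nrow = d[1])
  band_rows <- which(rowSums(band_m) > 0)
  band_cols <- which(colSums(band_m) > 0)
  if (length(band_rows) == 0) {
    stop("axis calibration failed: no quality-band area found in image")
  }
  box <- c(left = min(band_cols), top = min(band_rows),
           right = max(band_cols), bottom = max(band_rows))

  if (box["left"] < 8) stop("axis calibration failed: no room for y-axis labels")
  # y tick marks: ink just left of the frame
  tick_col <- box[["left"]] - 2L
  tick_rows <- which(ink_mask(image, box[["top"]]:box[["bottom"]], tick_col))
  tick_rows <- box[["top"]] - 1L + tick_rows
  tick_rows <- cluster_centers(tick_rows)

  # label clusters in the strip left of the tick marks
  strip_right <- box[["left"]] - 6L
  strip <- ink_mask(image, seq_len(d[1]), 1:strip_right)
  ink_rows <- which(rowSums(strip) > 0)
  ticks <- data.frame(score = integer(0), row = integer(0))
  if (length(ink_rows) > 0) {
    cl <- split(ink_rows, cumsum(c(1L, diff(ink_rows) > 2)))
    for (rows in cl) {
      top <- max(1L, min(rows) - 1L); bot <- min(d[1], max(rows) + 1L)
      val <- recognize_number(image, c(1L, top, strip_right, bot))
      if (is.na(val)) next
      center <- (min(rows) + max(rows)) / 2
      row <- if (length(tick_rows) > 0 && min(abs(tick_rows - center)) <= 3) {
        tick_rows[which.min(abs(tick_rows - center))]
      } else round(center)
      ticks <- rbind(ticks, data.frame(score = val, row = row))
    }
  }
  if (nrow(ticks) < 2) {
    stop("axis calibration failed: fewer than two y-axis ticks recognized")
  }
  ticks <- ticks[order(ticks$score), ]
  if (any(diff(ticks$row) >= 0)) {
    stop("axis calibration failed: y-axis rows not decreasing with score")
  }

  thr <- params$quality_threshold
  exact <- which(ticks$score == thr)
  threshold_row <- if (length(exact) > 0) {
    ticks$row[exact[1]]
  } else {
    # interpolate between the two flanking ticks (extrapolate at the ends)
    lo <- max(which(ticks$score < thr), 1L)
    hi <- min(lo + 1L, nrow(ticks))
    if (hi == lo) { lo <- hi - 1L }
    round(ticks$row[lo] + (thr - ticks$score[lo]) *
            (ticks$row[hi] - ticks$row[lo]) / (ticks$score[hi] - ticks$score[lo]))
  }
  structure(list(plot_box = box, y_ticks = ticks, x_ticks = NULL,
                 threshold_row = threshold_row,
                 quality_threshold = thr,
                 px_per_base = NA_real_, x_affine = NULL, x_extent = NA_integer_),
            class = "plot_geometry")
}

cluster_centers <- function(v) {
  if (length(v) == 0) return(integer(0))
  cl <- split(v, cumsum(c(1L, diff(v) > 1)))
  vapply(cl, function(x) as.integer(round(mean(x))), 0L)
}

#' @export
print.plot_geometry <- function(x, ...) {
  cat("Plot geometry: data area [", x$plot_box[["left"]], ",", x$plot_box[["top"]],
      "] - [", x$plot_box[["right"]], ",", x$plot_box[["bottom"]], "]\n", sep = "")
  cat("  threshold Q", x$quality_threshold, " at row ", x$threshold_row, "; ",
      nrow(x$y_ticks), " y ticks", sep = "")
  if (!is.null(x$x_ticks)) {
    cat("; ", nrow(x$x_ticks), " x ticks, ", signif(x$px_per_base, 4),
        " px/base", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Calibrate the x axis of a quality plot
#'
#' Detects the tick marks under the plot box, slides recognition windows of
#' `ocr_patch_width` x `ocr_patch_height` pixels along the bottom label
#' strip (windows extending past the image edge are narrowed to fit), reads
#' each tick label with [recognize_number()] (a range label `"A-B"` yields
#' `B`), and fits the affine pixel-to-base-position map by least squares.
#'
#' @param image RGB array.
#' @param params A [vision_params()].
#' @param geometry Y-calibrated geometry from [locate_threshold_row()].
#' @return Fully calibrated `plot_geometry` with `x_ticks`, `x_affine`
#'   (intercept, slope of position ~ column), `px_per_base`, `x_extent`.
#' @export
calibrate_x_axis <- function(image, params, geometry) {
  d <- dim(image)
  box <- geometry$plot_box
  if (box[["bottom"]] + 7L > d[1]) {
    stop("axis calibration failed: no x-axis label strip below the plot")
  }
  tick_band <- (box[["bottom"]] + 2L):min(box[["bottom"]] + 4L, d[1])
  ink <- ink_mask(image, tick_band, seq_len(d[2]))
  tick_cols <- which(colSums(ink) == length(tick_band))
  tick_cols <- cluster_centers(tick_cols)
  tick_cols <- tick_cols[tick_cols >= box[["left"]] - 2 & tick_cols <= box[["right"]] + 2]

  # the strip starts below the tick marks and below the bottom y-axis label,
  # whose glyphs dangle up to 6 px under the plot box
  strip_top <- box[["bottom"]] + 7L
  strip_bottom <- min(strip_top + params$ocr_patch_height - 1L, d[1])
  half <- floor(params$ocr_patch_width / 2)
  vals <- integer(0); cols <- integer(0)
  for (tc in tick_cols) {
    left <- max(1L, tc - half)
    right <- min(d[2], tc + (params$ocr_patch_width - half) - 1L)
    val <- recognize_number(image, c(left, strip_top, right, strip_bottom))
    if (!is.na(val)) { vals <- c(vals, val); cols <- c(cols, tc) }
  }
  if (length(vals) < 2) {
    stop("axis calibration failed: fewer than two x-axis ticks recognized")
  }
  ord <- order(cols)
  vals <- vals[ord]; cols <- cols[ord]
  if (any(diff(vals) <= 0)) {
    stop("axis calibration failed: x-axis tick values not increasing with column")
  }
  fit <- stats::lm.fit(cbind(1, cols), vals)
  a <- fit$coefficients[1]; s <- fit$coefficients[2]
  geometry$x_ticks <- data.frame(position = vals, col = cols)
  geometry$x_affine <- c(intercept = unname(a), slope = unname(s))
  geometry$px_per_base <- 1 / unname(s)
  geometry$x_extent <- as.integer(round(a + s * box[["right"]]))
  geometry
}

#' Map a pixel column to a base position
#'
#' Applies the calibrated affine x map and rounds to the nearest integer
#' base in `[1, read extent]`.
#'
#' @param column Pixel column inside the plot box.
#' @param geometry Fully calibrated geometry from [calibrate_x_axis()].
#' @return Integer base position (1-based).
#' @export
pixel_to_position <- function(column, geometry) {
  if (is.null(geometry$x_affine)) stop("geometry is not x-calibrated")
  box <- geometry$plot_box
  if (column < box[["left"]] || column > box[["right"]]) {
    stop("column ", column, " outside plot box [", box[["left"]], ", ",
         box[["right"]], "]")
  }
  p <- round(geometry$x_affine[["intercept"]] + geometry$x_affine[["slope"]] * column)
  as.integer(clamp(p, 1, geometry$x_extent))
}

#' Scan for the quality transition column
#'
#' Starting at the right edge of the plot box, steps leftward in
#' `patch_size` increments examining the square patch vertically centred on
#' the threshold row. While a patch classifies as broad yellow (the
#' interquartile box straddles the threshold) the search continues; the
#' first non-yellow patch stops it. The stop is then refined at pixel
#' resolution by per-column yellow spans: each plot column is classified as
#' above / straddling / below the threshold row according to the vertical
#' extent of its yellow pixels, and the transition column is the rightmost
#' column whose yellow span lies entirely at or above the threshold row.
#' The same column analysis serves as the fallback when the very first
#' (rightmost) patch is already non-yellow, distinguishing `never_below`
#' (all boxes clear the threshold) from `always_below` (no box ever does).
#'
#' @param image RGB array.
#' @param geometry Fully calibrated geometry.
#' @param color_map A [build_color_map()] result.
#' @param params A [vision_params()].
#' @return Object of class `transition_result`: `transition_column`
#'   (or `NA`), `scanned_patches`, `stop_label`, `status` (one of
#'   `"found"`, `"never_below"`, `"always_below"`).
#' @export
scan_transition <- function(image, geometry, color_map, params = vision_params()) {
  box <- geometry$plot_box
  thr_row <- geometry$threshold_row
  ps <- params$patch_size
  rows <- clamp((thr_row - floor(ps / 2)):(thr_row + ceiling(ps / 2) - 1L),
                box[["top"]], box[["bottom"]])

  # the paper's right-to-left patch loop (coarse localization + diagnostics)
  scanned <- 0L
  stop_label <- "yellow"
  col_hi <- box[["right"]]
  while (col_hi - ps + 1L >= box[["left"]]) {
    patch <- image[rows, (col_hi - ps + 1L):col_hi, , drop = FALSE]
    lab <- classify_patch(patch, color_map)
    scanned <- scanned + 1L
    if (lab != "yellow") { stop_label <- lab; break }
    col_hi <- col_hi - ps
  }

  # pixel-resolution refinement / fallback: per-column yellow spans
  labels <- classify_region(image, color_map, box[["top"]]:box[["bottom"]],
                            box[["left"]]:box[["right"]])
  yellow <- labels == "yellow"
  thr_local <- thr_row - box[["top"]] + 1L
  n_col <- ncol(yellow)
  col_class <- character(n_col)
  for (j in seq_len(n_col)) {
    yr <- which(yellow[, j])
    col_class[j] <- if (length(yr) == 0) "none"
    else if (max(yr) <= thr_local) "above"
    else if (min(yr) > thr_local) "below"
    else "straddle"
  }
  above <- which(col_class == "above")

  if (length(above) == 0) {
    return(structure(list(transition_column = NA_integer_, scanned_patches = scanned,
                          stop_label = stop_label, status = "always_below"),
                     class = "transition_result"))
  }
  transition_column <- box[["left"]] - 1L + max(above)
  pos <- pixel_to_position(transition_column, geometry)
  status <- if (pos >= geometry$x_extent) "never_below" else "found"
  structure(list(transition_column = as.integer(transition_column),
                 scanned_patches = scanned, stop_label = stop_label,
                 status = status),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  cat("Transition scan: status ", x$status, sep = "")
  if (!is.na(x$transition_column)) cat(" at column ", x$transition_column, sep = "")
  cat(" (", x$scanned_patches, " patches scanned, stop label '",
      x$stop_label, "')\n", sep = "")
  invisible(x)
}

#' Serialize geometry or a transition result to JSON
#'
#' Schema: `plot_box` (left/top/right/bottom), `y_ticks`, `x_ticks`,
#' `threshold_row`, `quality_threshold`, `px_per_base`, and, for transition
#' results, `transition_column` and `status`.
#'
#' @param x A `plot_geometry` or `transition_result`.
#' @return JSON string.
#' @export
vision_json <- function(x) {
  if (inherits(x, "plot_geometry")) {
    obj <- list(plot_box = as.list(x$plot_box), y_ticks = x$y_ticks,
                x_ticks = x$x_ticks, threshold_row = x$threshold_row,
                quality_threshold = x$quality_threshold,
                px_per_base = x$px_per_base)
  } else if (inherits(x, "transition_result")) {
    obj <- unclass(x)
  } else {
    stop("vision_json: unsupported object")
  }
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"))
}
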