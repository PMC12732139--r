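# Quality-profile container: per-position (or per-bin) Phred quality
# distribution summaries, the numeric ground truth behind the FastQC plot.

#' Construct a quality profile
#'
#' A `quality_profile` holds the per-base sequence quality table: one row per
#' position bin with the distribution summaries FastQC reports (mean, median,
#' quartiles, 10th/90th percentiles). It is the input of the plot renderer and
#' of the table-based oracle [oracle_trim()].
#'
#' @param bins `data.frame` with columns `start`, `end` (1-based inclusive
#'   base positions), `mean`, `median`, `q25`, `q75`, `q10`, `q90` (Phred
#'   scores).
#' @param read_length Integer; must equal the last bin's `end`.
#' @return Object of class `quality_profile`.
#' @export
quality_profile <- function(bins, read_length = NULL) {
  stopifnot(is.data.frame(bins))
  needed <- c("start", "end", "mean", "median", "q25", "q75", "q10", "q90")
  missing_cols <- setdiff(needed, names(bins))
  if (length(missing_cols) > 0) {
    stop("quality profile bins missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bins <- bins[needed]
  if (nrow(bins) == 0) stop("quality profile must contain at least one bin")
  if (is.null(read_length)) read_length <- bins$end[nrow(bins)]
  prof <- structure(list(bins = bins, read_length = as.integer(read_length)),
                    class = "quality_profile")
  validate_quality_profile(prof)
  prof
}

validate_quality_profile <- function(prof) {
  b <- prof$bins
  if (any(b$start > b$end)) stop("quality profile: bin start exceeds bin end")
  if (nrow(b) > 1) {
    if (any(diff(b$start) <= 0)) stop("quality profile: bins not sorted by start")
    if (any(b$start[-1] != b$end[-nrow(b)] + 1)) {
      stop("quality profile: bins not contiguous")
    }
  }
  if (b$end[nrow(b)] != prof$read_length) {
    stop("quality profile: last bin end (", b$end[nrow(b)],
         ") does not equal read_length (", prof$read_length, ")")
  }
  bad <- which(!(b$q10 <= b$q25 & b$q25 <= b$median &
                   b$median <= b$q75 & b$q75 <= b$q90))
  if (length(bad) > 0) {
    stop("quality profile: percentile ordering violated in bin ", bad[1],
         " (positions ", b$start[bad[1]], "-", b$end[bad[1]], ")")
  }
  vals <- unlist(b[c("mean", "median", "q25", "q75", "q10", "q90")])
  if (any(vals < 0 | vals > 45)) {
    stop("quality profile: quality values outside [0, 45]")
  }
  invisible(prof)
}

#' @export
print.quality_profile <- function(x, ...) {
  b <- x$bins
  cat("Per-base quality profile: ", nrow(b), " bins, read length ",
      x$read_length, "\n", sep = "")
  cat("  median range [", min(b$median), ", ", max(b$median), "]",
      ", q25 range [", min(b$q25), ", ", max(b$q25), "]\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.quality_profile <- function(x, ...) x$bins

#' Render and display a quality profile
#'
#' Renders the profile with [render_plot()] and displays the raster on the
#' active graphics device.
#'
#' @param x A `quality_profile`.
#' @param ... Passed to [render_plot()] as style options.
#' @return Invisibly, the rendered image array.
#' @export
plot.quality_profile <- function(x, ...) {
  r <- render_plot(x, ...)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = NA)
  graphics::rasterImage(grDevices::as.raster(r$image / 255), 0, 0, 1, 1)
  invisible(r$image)
}

# FastQC-style binning: one bin per base for positions 1..9, fixed-width bins
# (default 5) afterwards, final bin truncated at read_length.
fastqc_bin_layout <- function(read_length, bin_width = 5) {
  read_length <- as.integer(read_length)
  stopifnot(read_length >= 1, bin_width >= 1)
  singles <- seq_len(min(9L, read_length))
  starts <- singles
  ends <- singles
  if (read_length > 9L) {
    s <- seq(10L, read_length, by = bin_width)
    starts <- c(starts, s)
    ends <- c(ends, pmin(s + bin_width - 1L, read_length))
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}
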