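# End-to-end truncation prediction, the independent numeric oracle, and
# FASTQ truncation.

#' Construct a trim recommendation
#'
#' @param truncation_position Number of bases kept (equivalently the 1-based
#'   position of the last kept base; 0 means nothing survives).
#' @param quality_threshold Phred threshold used.
#' @param status One of `"found"`, `"never_below"`, `"always_below"`.
#' @param source `"image"` (vision pipeline) or `"table"` (numeric oracle).
#' @param read_label Read label, e.g. `"read1"`.
#' @param sample Sample name.
#' @param read_length Read length the position is expressed on (may be `NA`).
#' @param diagnostics Named list (transition column, patches scanned, ...).
#' @return Object of class `trim_recommendation`.
#' @export
trim_recommendation <- function(truncation_position, quality_threshold, status,
                                source, read_label = "read1", sample = NA_character_,
                                read_length = NA_integer_, diagnostics = list()) {
  status <- match.arg(status, c("found", "never_below", "always_below"))
  truncation_position <- as.integer(truncation_position)
  read_length <- as.integer(read_length)
  if (truncation_position < 0) stop("truncation_position must be >= 0")
  if (!is.na(read_length)) {
    if (truncation_position > read_length) {
      stop("truncation_position exceeds read_length")
    }
    if (status == "never_below" && truncation_position != read_length) {
      stop("status 'never_below' requires truncation_position == read_length")
    }
  }
  if (status == "always_below" && truncation_position != 0L) {
    stop("status 'always_below' requires truncation_position == 0")
  }
  structure(list(sample = sample, read_label = read_label,
                 truncation_position = truncation_position,
                 quality_threshold = quality_threshold,
                 status = status, source = source,
                 read_length = read_length, diagnostics = diagnostics),
            class = "trim_recommendation")
}

#' @export
print.trim_recommendation <- function(x, ...) {
  cat("Trim recommendation (", x$source, " route)", sep = "")
  if (!is.na(x$sample)) cat(" for ", x$sample, sep = "")
  cat(":\n  keep first ", x$truncation_position, " bases (Q",
      x$quality_threshold, " threshold, status '", x$status, "')\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trim_recommendation <- function(x, ...) {
  data.frame(sample = x$sample, read_label = x$read_label,
             truncation = x$truncation_position,
             threshold = x$quality_threshold, status = x$status,
             source = x$source, stringsAsFactors = FALSE)
}

#' Trim recommendation as JSON
#'
#' Schema: `sample`, `read_label`, `truncation_position`, `threshold`,
#' `status`, `source`, `diagnostics`.
#'
#' @param x A `trim_recommendation`.
#' @return JSON string.
#' @export
recommendation_json <- function(x) {
  obj <- list(sample = x$sample, read_label = x$read_label,
              truncation_position = x$truncation_position,
              threshold = x$quality_threshold, status = x$status,
              source = x$source, diagnostics = x$diagnostics)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"))
}

#' Predict the truncation position from a QC report image
#'
#' Runs the full vision pipeline on the report's per-base quality plot:
#' colour-map construction, y-axis threshold location, x-axis calibration,
#' right-to-left transition scan, and pixel-to-position mapping. The result
#' is clamped to `[0, read_length]`.
#'
#' @param report A [qc_report()].
#' @param params A [vision_params()].
#' @param read_label Label recorded in the recommendation.
#' @return A [trim_recommendation()] with `source = "image"`.
#' @export
#' @examples
#' prof <- simulate_profile(profile_spec(read_length = 150, noise_sd = 0))
#' r <- render_plot(prof)
#' rep <- qc_report("example", 150, r$image)
#' predict_trim(rep)
predict_trim <- function(report, params = vision_params(), read_label = "read1") {
  stopifnot(inherits(report, "qc_report"))
  res <- tryCatch({
    img <- report$plot_image
    cm <- build_color_map(img, params)
    geom <- locate_threshold_row(img, params, color_map = cm)
    geom <- calibrate_x_axis(img, params, geom)
    tr <- scan_transition(img, geom, cm, params)
    list(geom = geom, tr = tr)
  }, error = function(e) {
    stop("sample '", report$sample_name, "': ", conditionMessage(e), call. = FALSE)
  })
  geom <- res$geom; tr <- res$tr
  rl <- if (is.na(report$read_length)) geom$x_extent else report$read_length
  trunc <- switch(tr$status,
                  found = pixel_to_position(tr$transition_column, geom),
                  never_below = rl,
                  always_below = 0L)
  trunc <- as.integer(clamp(trunc, 0, rl))
  status <- tr$status
  if (status == "found" && trunc >= rl) status <- "never_below"
  if (status == "never_below") trunc <- rl
  trim_recommendation(trunc, params$quality_threshold, status, "image",
                      read_label = read_label, sample = report$sample_name,
                      read_length = rl,
                      diagnostics = list(transition_column = tr$transition_column,
                                         scanned_patches = tr$scanned_patches,
                                         stop_label = tr$stop_label,
                                         x_extent = geom$x_extent))
}

#' Truncation position from the numeric quality table
#'
#' The independent table-based oracle for the image pipeline: scanning bins
#' from last to first, the truncation position is the end of the first
#' (rightmost) bin whose lower quartile is at or above the threshold — the
#' same lower-quartile geometry the yellow-box scan reads off the raster.
#' If no bin qualifies the status is `always_below` (position 0); if the
#' last bin qualifies it is `never_below` (position = read length).
#'
#' @param profile A [quality_profile()].
#' @param threshold Phred threshold (default 20).
#' @param read_label,sample Labels recorded in the recommendation.
#' @return A [trim_recommendation()] with `source = "table"`.
#' @export
oracle_trim <- function(profile, threshold = 20, read_label = "read1",
                        sample = NA_character_) {
  stopifnot(inherits(profile, "quality_profile"))
  b <- profile$bins
  ok <- which(b$q25 >= threshold)
  if (length(ok) == 0) {
    return(trim_recommendation(0L, threshold, "always_below", "table",
                               read_label = read_label, sample = sample,
                               read_length = profile$read_length,
                               diagnostics = list(bins_scanned = nrow(b))))
  }
  last_ok <- max(ok)
  if (last_ok == nrow(b)) {
    return(trim_recommendation(profile$read_length, threshold, "never_below",
                               "table", read_label = read_label, sample = sample,
                               read_length = profile$read_length,
                               diagnostics = list(bins_scanned = 1L)))
  }
  trim_recommendation(b$end[last_ok], threshold, "found", "table",
                      read_label = read_label, sample = sample,
                      read_length = profile$read_length,
                      diagnostics = list(bins_scanned = nrow(b) - last_ok + 1L))
}

#' Phred score to error probability
#'
#' `10^(-q/10)`: Q20 corresponds to a 1% base-call error rate.
#'
#' @param q Phred score(s), `>= 0`.
#' @return Error probabilities.
#' @export
phred_error_rate <- function(q) {
  if (any(q < 0)) stop("phred_error_rate: q must be >= 0")
  10^(-q / 10)
}

#' Truncate reads in a FASTQ file
#'
#' Cuts every read to its first `truncation_position` bases (sequence and
#' quality strings identically). Reads already shorter than the truncation
#' position are kept unchanged when `discard_short = FALSE` and dropped when
#' `TRUE` (DADA2's `truncLen` discards such reads; the flag provides
#' parity). Input and output may be gzip-compressed (`.gz` suffix).
#'
#' @param fastq_in Input FASTQ path (plain or gzip).
#' @param truncation_position Number of bases to keep (>= 0).
#' @param discard_short Drop reads shorter than `truncation_position`?
#' @param fastq_out Output FASTQ path (`.gz` suffix gzips).
#' @return Named integer vector `c(read, written, discarded)` (also logged).
#' @export
trim_fastq <- function(fastq_in, truncation_position, discard_short = FALSE,
                       fastq_out) {
  stopifnot(truncation_position >= 0)
  if (!file.exists(fastq_in)) stop("cannot read FASTQ: ", fastq_in)
  t <- as.integer(truncation_position)
  con_in <- gzfile(fastq_in, "rb")
  con_out <- if (grepl("\\.gz$", fastq_out)) gzfile(fastq_out, "wb") else file(fastq_out, "wb")
  on.exit({ close(con_in); close(con_out) })

  n_read <- 0L; n_written <- 0L; n_discarded <- 0L
  carry <- character(0)
  repeat {
    chunk <- readLines(con_in, n = 40000L, warn = FALSE)
    lines <- c(carry, chunk)
    if (length(lines) == 0) break
    n_rec <- length(lines) %/% 4L
    if (length(chunk) == 0 && length(lines) %% 4L != 0L) {
      stop("format error: truncated FASTQ record at end of ", fastq_in)
    }
    carry <- if (n_rec * 4L < length(lines)) lines[(n_rec * 4L + 1L):length(lines)] else character(0)
    if (n_rec == 0) { if (length(chunk) == 0) break else next }
    idx <- seq_len(n_rec)
    ids <- lines[4L * idx - 3L]
    seqs <- lines[4L * idx - 2L]
    pluses <- lines[4L * idx - 1L]
    quals <- lines[4L * idx]
    bad_id <- which(!startsWith(ids, "@"))
    if (length(bad_id) > 0) {
      stop("format error in record ", n_read + bad_id[1],
           ": header does not start with '@' (", ids[bad_id[1]], ")")
    }
    bad_plus <- which(!startsWith(pluses, "+"))
    if (length(bad_plus) > 0) {
      stop("format error in record '", ids[bad_plus[1]],
           "': separator line does not start with '+'")
    }
    len_s <- nchar(seqs); len_q <- nchar(quals)
    bad <- which(len_s != len_q)
    if (length(bad) > 0) {
      stop("format error in record '", ids[bad[1]],
           "': sequence length (", len_s[bad[1]],
           ") differs from quality length (", len_q[bad[1]], ")")
    }
    n_read <- n_read + n_rec
    short <- len_s < t
    if (discard_short) {
      keep <- !short
      n_discarded <- n_discarded + sum(short)
    } else {
      keep <- rep(TRUE, n_rec)
    }
    if (any(keep)) {
      out_seq <- ifelse(short[keep], seqs[keep], substr(seqs[keep], 1L, t))
      out_qual <- ifelse(short[keep], quals[keep], substr(quals[keep], 1L, t))
      writeLines(as.vector(rbind(ids[keep], out_seq, pluses[keep], out_qual)), con_out)
      n_written <- n_written + sum(keep)
    }
    if (length(chunk) == 0) break
  }
  counts <- c(read = n_read, written = n_written, discarded = n_discarded)
  log_line("trim: ", fastq_in, " -> ", fastq_out, " at ", t, " bases: ",
           n_read, " read, ", n_written, " written, ", n_discarded, " discarded")
  counts
}
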