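# Reading FastQC artifacts: the HTML report (plot raster + read length) and
# the numeric fastqc_data.txt per-base quality table.

#' Construct a QC report object
#'
#' Container for the pieces of a FastQC report the predictor consumes: the
#' per-base sequence quality plot raster and the read (cycle) length.
#'
#' @param sample_name Non-empty sample label.
#' @param read_length Integer number of cycles (maximum sequence length), or
#'   `NA` when unknown (e.g. a bare plot image); predictions are then clamped
#'   to the extent recovered from axis calibration.
#' @param plot_image RGB array (see [load_plot_image()]).
#' @param source_path Path the report was read from.
#' @param has_data_table Whether a companion `fastqc_data.txt` is known.
#' @return Object of class `qc_report`.
#' @export
qc_report <- function(sample_name, read_length, plot_image,
                      source_path = NA_character_, has_data_table = FALSE) {
  if (!nzchar(sample_name)) stop("qc_report: sample_name must be non-empty")
  if (!is.na(read_length) && read_length < 1) {
    stop("qc_report: read_length must be >= 1")
  }
  d <- dim(plot_image)
  if (length(d) != 3 || d[1] < 1 || d[2] < 1) {
    stop("qc_report: plot_image must be a height x width x 3 array")
  }
  structure(list(sample_name = sample_name,
                 read_length = as.integer(read_length),
                 plot_image = plot_image,
                 source_path = source_path,
                 has_data_table = isTRUE(has_data_table)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  d <- dim(x$plot_image)
  cat("FastQC report: ", x$sample_name, "\n", sep = "")
  cat("  read length: ", x$read_length, " cycles; plot raster ",
      d[2], " x ", d[1], " px\n", sep = "")
  invisible(x)
}

#' Parse a FastQC HTML report
#'
#' Extracts the per-base sequence quality plot raster and the read length
#' from a FastQC-style HTML report. The plot is located via the "Per base
#' sequence quality" module heading (falling back to the first image whose
#' alt text mentions per-base quality); both base64-embedded payloads and
#' sibling-file references (`Images/per_base_quality.png`) are supported.
#' The read length comes from the Basic Statistics "Sequence length" entry;
#' a range entry `"A-B"` yields `B`, the maximum cycle count, since
#' truncation positions are expressed on the longest read.
#'
#' @param html_path Path to the HTML report.
#' @return A [qc_report()].
#' @export
parse_fastqc_html <- function(html_path) {
  if (!file.exists(html_path)) stop("cannot read report: ", html_path)
  doc <- xml2::read_html(html_path)

  img_node <- locate_quality_img(doc)
  if (is.null(img_node)) {
    stop("module not found: no 'Per base sequence quality' section in ", html_path)
  }
  src <- xml2::xml_attr(img_node, "src")
  image <- decode_img_src(src, html_path)

  len_text <- extract_sequence_length(doc)
  if (is.na(len_text)) {
    stop("metadata missing: no parseable 'Sequence length' entry in ", html_path)
  }
  read_length <- parse_length_entry(len_text)
  if (is.na(read_length)) {
    stop("metadata missing: unparseable 'Sequence length' value '", len_text, "'")
  }

  sample_name <- extract_sample_name(doc, html_path)
  qc_report(sample_name, read_length, image, source_path = html_path)
}

# Find the <img> for the per-base quality module: heading text first, alt
# text as fallback (FastQC dialect drift across versions).
locate_quality_img <- function(doc) {
  heads <- xml2::xml_find_all(
    doc, "//h2[contains(translate(., 'PBSQ', 'pbsq'), 'per base sequence quality')]")
  if (length(heads) > 0) {
    img <- xml2::xml_find_first(heads[[1]], "following::img[1]")
    if (!inherits(img, "xml_missing")) return(img)
  }
  imgs <- xml2::xml_find_all(doc, "//img")
  for (img in imgs) {
    alt <- tolower(xml2::xml_attr(img, "alt"))
    if (!is.na(alt) && grepl("per base", alt) && grepl("quality", alt)) return(img)
  }
  NULL
}

decode_img_src <- function(src, html_path) {
  if (is.na(src)) stop("corrupt image: quality plot <img> has no src")
  if (grepl("^data:image/", src)) {
    payload <- sub("^data:image/[a-zA-Z]+;base64,", "", src)
    bytes <- tryCatch(jsonlite::base64_dec(payload),
                      error = function(e) stop("corrupt image: undecodable base64 payload"))
    raw_img <- tryCatch(png::readPNG(bytes),
                        error = function(e) stop("corrupt image: payload is not a valid PNG"))
    return(decode_png_array(raw_img))
  }
  # sibling-file reference relative to the report
  img_path <- file.path(dirname(html_path), src)
  if (!file.exists(img_path)) stop("corrupt image: referenced file missing: ", src)
  load_plot_image(img_path)
}

extract_sequence_length <- function(doc) {
  cells <- xml2::xml_find_all(doc, "//td|//th")
  texts <- trimws(xml2::xml_text(cells))
  hit <- which(texts == "Sequence length")
  if (length(hit) == 0) return(NA_character_)
  sib <- xml2::xml_find_first(cells[[hit[1]]], "following-sibling::td[1]")
  if (inherits(sib, "xml_missing")) return(NA_character_)
  trimws(xml2::xml_text(sib))
}

# "A-B" ranges yield B (maximum cycle count).
parse_length_entry <- function(text) {
  m <- regmatches(text, regexec("^([0-9]+)(-([0-9]+))?$", text))[[1]]
  if (length(m) == 0) return(NA_integer_)
  if (nzchar(m[4])) as.integer(m[4]) else as.integer(m[2])
}

extract_sample_name <- function(doc, html_path) {
  cells <- xml2::xml_find_all(doc, "//td|//th")
  texts <- trimws(xml2::xml_text(cells))
  hit <- which(texts == "Filename")
  if (length(hit) > 0) {
    sib <- xml2::xml_find_first(cells[[hit[1]]], "following-sibling::td[1]")
    if (!inherits(sib, "xml_missing")) {
      nm <- trimws(xml2::xml_text(sib))
      if (nzchar(nm)) return(nm)
    }
  }
  title <- xml2::xml_text(xml2::xml_find_first(doc, "//title"))
  if (!is.na(title) && nzchar(title)) {
    return(trimws(sub("\\s*FastQC Report\\s*$", "", title)))
  }
  basename(html_path)
}

#' Parse a FastQC data table
#'
#' Reads the `>>Per base sequence quality` block of a `fastqc_data.txt` file
#' into a [quality_profile()]. Base labels `"A-B"` become bins spanning
#' `A..B`; single numbers become one-position bins. This is the numeric
#' (oracle) input route; the vision pipeline never sees it.
#'
#' @param data_path Path to a `fastqc_data.txt`-style file.
#' @return A [quality_profile()].
#' @export
parse_fastqc_data <- function(data_path) {
  if (!file.exists(data_path)) stop("cannot read data table: ", data_path)
  lines <- readLines(data_path, warn = FALSE)
  start <- grep("^>>Per base sequence quality", lines)
  if (length(start) == 0) {
    stop("parse error: no '>>Per base sequence quality' block in ", data_path)
  }
  start <- start[1]
  endm <- grep("^>>END_MODULE", lines)
  endm <- endm[endm > start]
  end <- if (length(endm) > 0) endm[1] else length(lines) + 1L
  body <- lines[(start + 1L):(end - 1L)]
  body_idx <- (start + 1L):(end - 1L)
  keep <- !grepl("^#", body) & nzchar(trimws(body))
  body <- body[keep]
  body_idx <- body_idx[keep]
  if (length(body) == 0) stop("parse error: empty per-base quality block")

  parse_row <- function(line, lineno) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 7) {
      stop("parse error at line ", lineno, ": expected 7 tab-separated fields")
    }
    m <- regmatches(f[1], regexec("^([0-9]+)(-([0-9]+))?$", trimws(f[1])))[[1]]
    if (length(m) == 0) stop("parse error at line ", lineno, ": bad base label '", f[1], "'")
    start <- as.integer(m[2])
    end <- if (nzchar(m[4])) as.integer(m[4]) else start
    vals <- suppressWarnings(as.numeric(f[2:7]))
    if (any(is.na(vals))) stop("parse error at line ", lineno, ": non-numeric value")
    c(start = start, end = end, mean = vals[1], median = vals[2],
      q25 = vals[3], q75 = vals[4], q10 = vals[5], q90 = vals[6])
  }
  rows <- mapply(parse_row, body, body_idx, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  bins <- as.data.frame(do.call(rbind, rows))
  bins$start <- as.integer(bins$start)
  bins$end <- as.integer(bins$end)
  for (i in seq_len(nrow(bins))) {
    if (!(bins$q10[i] <= bins$q25[i] && bins$q25[i] <= bins$median[i] &&
            bins$median[i] <= bins$q75[i] && bins$q75[i] <= bins$q90[i])) {
      stop("parse error at line ", body_idx[i],
           ": percentile ordering violated (q10 <= q25 <= median <= q75 <= q90)")
    }
  }
  quality_profile(bins)
}
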