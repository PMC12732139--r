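# Bundled 5x7 bitmap glyphs for the characters the renderer ever draws
# ("0"-"9" and "-"). The same atlas drives both the fixture renderer and the
# default template-matching recognition engine, so tick-label recognition is
# deterministic and needs no external OCR binary.

.glyph_rows <- list(
  "0" = c("01110", "10001", "10011", "10101", "11001", "10001", "01110"),
  "1" = c("00100", "01100", "00100", "00100", "00100", "00100", "01110"),
  "2" = c("01110", "10001", "00001", "00010", "00100", "01000", "11111"),
  "3" = c("11111", "00010", "00100", "00010", "00001", "10001", "01110"),
  "4" = c("00010", "00110", "01010", "10010", "11111", "00010", "00010"),
  "5" = c("11111", "10000", "11110", "00001", "00001", "10001", "01110"),
  "6" = c("00110", "01000", "10000", "11110", "10001", "10001", "01110"),
  "7" = c("11111", "00001", "00010", "00100", "01000", "01000", "01000"),
  "8" = c("01110", "10001", "10001", "01110", "10001", "10001", "01110"),
  "9" = c("01110", "10001", "10001", "01111", "00001", "00010", "01100"),
  "-" = c("00000", "00000", "00000", "11111", "00000", "00000", "00000")
)

glyph_bitmap <- function(ch, scale = 1) {
  rows <- .glyph_rows[[ch]]
  if (is.null(rows)) stop("no glyph for character '", ch, "'")
  m <- do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
  if (scale > 1) m <- m %x% matrix(1L, scale, scale)
  m
}

# Glyph metrics at a given scale.
glyph_width <- function(scale) 5L * scale
glyph_height <- function(scale) 7L * scale
glyph_spacing <- function(scale) 1L * scale

text_width <- function(text, scale = 1) {
  n <- nchar(text)
  n * glyph_width(scale) + (n - 1) * glyph_spacing(scale)
}

# Blit `text` onto `image` with its top-left corner at (row, col).
draw_text <- function(image, row, col, text, scale = 1, rgb = c(0, 0, 0)) {
  chars <- strsplit(text, "")[[1]]
  x <- col
  for (ch in chars) {
    bm <- glyph_bitmap(ch, scale)
    idx <- which(bm == 1L, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      rr <- row + idx[, 1] - 1L
      cc <- x + idx[, 2] - 1L
      ok <- rr >= 1 & rr <= dim(image)[1] & cc >= 1 & cc <= dim(image)[2]
      for (k in 1:3) image[cbind(rr[ok], cc[ok], k)] <- rgb[k]
    }
    x <- x + glyph_width(scale) + glyph_spacing(scale)
  }
  image
}

#' Digit-glyph atlas for template matching
#'
#' Returns the templates the default recognition engine compares tick-label
#' glyphs against: one binary bitmap per character ("0"-"9", "-") per scale,
#' cropped to the glyph's ink bounding box. The atlas uses the same bundled
#' bitmap font as [render_plot()], so recognition on rendered fixtures is
#' exact by construction.
#'
#' @param scales Integer vector of pixel scales to include (default `1:3`).
#' @return A list of entries with elements `char`, `scale`, `bitmap`.
#' @export
digit_atlas <- function(scales = 1:3) {
  out <- list()
  for (s in scales) {
    for (ch in names(.glyph_rows)) {
      bm <- crop_to_ink(glyph_bitmap(ch, s))
      out[[length(out) + 1L]] <- list(char = ch, scale = s, bitmap = bm)
    }
  }
  out
}

# Crop a binary matrix to its ink (value 1) bounding box; NULL if blank.
crop_to_ink <- function(m) {
  rows <- which(rowSums(m) > 0)
  cols <- which(colSums(m) > 0)
  if (length(rows) == 0) return(NULL)
  m[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
}
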