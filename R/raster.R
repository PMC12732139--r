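# Raster primitives.
#
# Images are numeric arrays of dim c(height, width, 3) holding integer RGB
# values in [0, 255]; pixel (row, col) is 1-based with the origin at the
# top-left corner, so rows increase downwards.

# Clamp helper shared across modules; x first so its attributes survive.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Mutable canvas: one matrix per channel inside an environment. Drawing goes
# through evalq() so the subassignments happen on the bindings themselves and
# mutate in place; the `cv$R[...] <- v` sugar would copy the full channel on
# every call.
canvas_new <- function(height, width, fill) {
  cv <- new.env(parent = baseenv())
  cv$R <- matrix(fill[1], height, width)
  cv$G <- matrix(fill[2], height, width)
  cv$B <- matrix(fill[3], height, width)
  cv$h <- height; cv$w <- width
  cv
}

canvas_rect <- function(cv, row1, row2, col1, col2, rgb) {
  row1 <- max(1L, as.integer(row1)); row2 <- min(cv$h, as.integer(row2))
  col1 <- max(1L, as.integer(col1)); col2 <- min(cv$w, as.integer(col2))
  if (row1 > row2 || col1 > col2) return(invisible(cv))
  cv$i <- row1:row2; cv$j <- col1:col2; cv$v <- rgb
  evalq({ R[i, j] <- v[1]; G[i, j] <- v[2]; B[i, j] <- v[3] }, cv)
  invisible(cv)
}

# Set individual pixels given an index matrix cbind(row, col).
canvas_pixels <- function(cv, idx, rgb) {
  ok <- idx[, 1] >= 1 & idx[, 1] <= cv$h & idx[, 2] >= 1 & idx[, 2] <= cv$w
  idx <- idx[ok, , drop = FALSE]
  if (nrow(idx) == 0) return(invisible(cv))
  cv$px <- idx; cv$v <- rgb
  evalq({ R[px] <- v[1]; G[px] <- v[2]; B[px] <- v[3] }, cv)
  invisible(cv)
}

canvas_text <- function(cv, row, col, text, scale = 1, rgb = c(0, 0, 0)) {
  x <- col
  for (ch in strsplit(text, "")[[1]]) {
    bm <- glyph_bitmap(ch, scale)
    idx <- which(bm == 1L, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      canvas_pixels(cv, cbind(row + idx[, 1] - 1L, x + idx[, 2] - 1L), rgb)
    }
    x <- x + glyph_width(scale) + glyph_spacing(scale)
  }
  invisible(cv)
}

canvas_image <- function(cv) {
  img <- array(0, dim = c(cv$h, cv$w, 3))
  img[, , 1] <- cv$R; img[, , 2] <- cv$G; img[, , 3] <- cv$B
  img
}

#' Load a plot image from a PNG or JPEG file
#'
#' Reads a raster image into the package's internal representation: a numeric
#' array of dim `c(height, width, 3)` with RGB values in `[0, 255]`. An alpha
#' channel, if present, is composited on a white background; grayscale images
#' are expanded to three identical channels.
#'
#' @param image_path Path to a readable PNG (or JPEG decoded by [png::readPNG]
#'   compatible readers is not supported; PNG is the format FastQC embeds).
#' @return Numeric array `c(height, width, 3)`, values in `[0, 255]`.
#' @export
#' @examples
#' img <- render_plot(simulate_profile(profile_spec(read_length = 60)))$image
#' f <- tempfile(fileext = ".png")
#' write_plot_image(img, f)
#' identical(load_plot_image(f), img)
load_plot_image <- function(image_path) {
  if (!file.exists(image_path)) {
    stop("cannot read image: file does not exist: ", image_path)
  }
  raw_img <- tryCatch(png::readPNG(image_path),
                      error = function(e) stop("cannot read image '", image_path,
                                               "': ", conditionMessage(e)))
  decode_png_array(raw_img)
}

# Convert png::readPNG output ([0,1] doubles, 2 or 3 dims, 1-4 channels) to the
# internal 0..255 RGB array.
decode_png_array <- function(raw_img) {
  if (length(dim(raw_img)) == 2) {
    raw_img <- array(rep(raw_img, 3), dim = c(dim(raw_img), 3))
  }
  nch <- dim(raw_img)[3]
  rgb <- raw_img[, , 1:min(3, nch), drop = FALSE]
  if (nch == 2) rgb <- array(rep(rgb[, , 1], 3), dim = c(dim(raw_img)[1:2], 3))
  if (nch == 4) {
    alpha <- raw_img[, , 4]
    for (k in 1:3) rgb[, , k] <- rgb[, , k] * alpha + 1 * (1 - alpha)
  }
  round(rgb * 255)
}

#' Write an RGB raster to a PNG file
#'
#' @param image Numeric array `c(height, width, 3)`, values in `[0, 255]`.
#' @param path Output file path, or `raw()` to return the encoded bytes.
#' @return Invisibly, `path` (or the raw vector when `path` is `raw()`).
#' @export
write_plot_image <- function(image, path) {
  out <- png::writePNG(image / 255, target = path)
  if (is.raw(out)) return(out)
  invisible(path)
}
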