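test_that("the threshold row is located within one pixel of ground truth", {
  r <- std_render()
  geom <- locate_threshold_row(r$image, vision_params(), std_color_map())
  expect_lte(abs(geom$threshold_row - r$sidecar$threshold_row_q20), 1)
  expect_identical(unname(geom$plot_box), unname(r$sidecar$plot_box))
  # recognized y ticks match the sidecar exactly
  m <- merge(r$sidecar$y_tick_rows, geom$y_ticks, by = "score",
             suffixes = c("_true", "_seen"))
  expect_identical(nrow(m), nrow(r$sidecar$y_tick_rows))
  expect_true(all(abs(m$row_true - m$row_seen) <= 1))
})

test_that("an off-tick threshold interpolates between the flanking ticks", {
  r <- std_render()
  geom <- locate_threshold_row(r$image, vision_params(quality_threshold = 21),
                               std_color_map())
  rows <- r$sidecar$y_tick_rows
  mid <- (rows$row[rows$score == 20] + rows$row[rows$score == 22]) / 2
  expect_lte(abs(geom$threshold_row - mid), 1)
})

test_that("a blank image fails axis calibration", {
  img <- array(255, dim = c(100, 100, 3))
  expect_error(locate_threshold_row(img, vision_params()),
               "axis calibration failed")
})

test_that("x calibration recovers every tick column and value", {
  r <- std_render()
  params <- vision_params()
  geom <- calibrate_x_axis(r$image, params,
                           locate_threshold_row(r$image, params, std_color_map()))
  m <- merge(r$sidecar$x_tick_cols, geom$x_ticks, by = "position",
             suffixes = c("_true", "_seen"))
  expect_identical(nrow(m), nrow(r$sidecar$x_tick_cols))
  expect_true(all(abs(m$col_true - m$col_seen) <= 2))
  expect_identical(geom$x_extent, 250L)
})

test_that("erasing the x labels fails calibration", {
  r <- std_render()
  img <- r$image
  strip <- (r$sidecar$plot_box[["bottom"]] + 2):dim(img)[1]
  img[strip, , ] <- 255
  params <- vision_params()
  geom <- locate_threshold_row(img, params, build_color_map(img, params))
  expect_error(calibrate_x_axis(img, params, geom), "axis calibration failed")
})

test_that("pixel_to_position inverts the renderer's position map at every tick", {
  for (rl in c(150, 250)) {
    prof <- simulate_profile(profile_spec(read_length = rl, noise_sd = 0))
    r <- render_plot(prof)
    params <- vision_params()
    cm <- build_color_map(r$image, params)
    geom <- calibrate_x_axis(r$image, params,
                             locate_threshold_row(r$image, params, cm))
    for (i in seq_len(nrow(r$sidecar$x_tick_cols))) {
      expect_lte(abs(pixel_to_position(r$sidecar$x_tick_cols$col[i], geom) -
                       r$sidecar$x_tick_cols$position[i]), 1)
    }
  }
})

test_that("pixel_to_position interpolates affinely and rejects out-of-box columns", {
  r <- std_render()
  params <- vision_params()
  geom <- calibrate_x_axis(r$image, params,
                           locate_threshold_row(r$image, params, std_color_map()))
  tk <- geom$x_ticks
  c1 <- tk$col[tk$position == 40]; c2 <- tk$col[tk$position == 80]
  expect_lte(abs(pixel_to_position(round((c1 + c2) / 2), geom) - 60), 1)
  expect_error(pixel_to_position(geom$plot_box[["left"]] - 5, geom),
               "outside plot box")
})

test_that("the clipped rightmost OCR window reads the same value as an unclipped render", {
  # at 300 cycles the last tick label window extends past the image edge
  prof <- simulate_profile(profile_spec(read_length = 300, noise_sd = 0))
  clipped <- render_plot(prof)
  wide <- render_plot(prof, style = list(margin_right = 120))
  params <- vision_params()
  read_last_tick <- function(r) {
    sc <- r$sidecar
    col <- sc$x_tick_cols$col[nrow(sc$x_tick_cols)]
    half <- floor(params$ocr_patch_width / 2)
    left <- max(1, col - half)
    right <- min(dim(r$image)[2], col + params$ocr_patch_width - half - 1)
    recognize_number(r$image, c(left, sc$plot_box[["bottom"]] + 7,
                                right, sc$plot_box[["bottom"]] + 26))
  }
  col <- clipped$sidecar$x_tick_cols$col[nrow(clipped$sidecar$x_tick_cols)]
  expect_lt(dim(clipped$image)[2], col + 40)  # the window really is clipped
  expect_identical(read_last_tick(clipped), read_last_tick(wide))
  expect_identical(read_last_tick(clipped), 300L)
})
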