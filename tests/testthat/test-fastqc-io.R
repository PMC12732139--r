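test_that("HTML round trip recovers the raster bit-exactly and the read length", {
  r <- std_render()
  f <- withr::local_tempfile(fileext = ".html")
  wrap_html(r$image, 250, "sample one", path = f)
  rep <- parse_fastqc_html(f)
  expect_s3_class(rep, "qc_report")
  expect_identical(rep$read_length, 250L)
  expect_identical(rep$plot_image, r$image)
  expect_identical(rep$sample_name, "sample one")
})

test_that("a Sequence length range 'A-B' yields B, the maximum cycle count", {
  r <- std_render()
  f <- withr::local_tempfile(fileext = ".html")
  wrap_html(r$image, 251, "s", path = f, length_text = "35-251")
  expect_identical(parse_fastqc_html(f)$read_length, 251L)
})

test_that("missing report pieces raise the documented errors", {
  f <- withr::local_tempfile(fileext = ".html")
  writeLines(paste0("<html><body><h2>Basic Statistics</h2><table>",
                    "<tr><td>Sequence length</td><td>250</td></tr>",
                    "</table></body></html>"), f)
  expect_error(parse_fastqc_html(f), "module not found")

  # image present, metadata absent
  r <- render_plot(simulate_profile(profile_spec(read_length = 60, noise_sd = 0)))
  g <- withr::local_tempfile(fileext = ".html")
  html <- wrap_html(r$image, 60, "s")
  html <- gsub("<tr><td>Sequence length</td><td>60</td></tr>", "", html, fixed = TRUE)
  writeLines(html, g, sep = "")
  expect_error(parse_fastqc_html(g), "metadata missing")

  # corrupt base64 payload
  h <- withr::local_tempfile(fileext = ".html")
  html2 <- wrap_html(r$image, 60, "s")
  html2 <- sub("base64,[A-Za-z0-9+/=]+", "base64,!!!notbase64", html2)
  writeLines(html2, h, sep = "")
  expect_error(parse_fastqc_html(h), "corrupt image")
})

test_that("sibling-file image references resolve relative to the report", {
  r <- std_render()
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "Images"))
  write_plot_image(r$image, file.path(dir, "Images", "per_base_quality.png"))
  f <- file.path(dir, "report.html")
  writeLines(paste0("<html><body><h2>Basic Statistics</h2><table>",
                    "<tr><td>Filename</td><td>sib</td></tr>",
                    "<tr><td>Sequence length</td><td>250</td></tr></table>",
                    "<h2>Per base sequence quality</h2>",
                    "<img src=\"Images/per_base_quality.png\" alt=\"Per base quality graph\"/>",
                    "</body></html>"), f)
  rep <- parse_fastqc_html(f)
  expect_identical(rep$plot_image, r$image)
  expect_identical(rep$sample_name, "sib")
})

test_that("data table round trip preserves every bin at FastQC print precision", {
  prof <- simulate_profile(profile_spec(read_length = 250, noise_sd = 1, seed = 9))
  f <- withr::local_tempfile()
  write_data_table(prof, f)
  back <- parse_fastqc_data(f)
  expect_equal(back$bins, prof$bins, tolerance = 1e-12)
  expect_identical(back$read_length, 250L)
  # binned rows carry range labels
  expect_true(any(grepl("^10-14\t", readLines(f))))
})

test_that("data table parsing enforces format and percentile ordering", {
  f <- withr::local_tempfile()
  writeLines(c(">>Per base sequence quality\tpass",
               "#Base\tMean\tMedian\tLower Quartile\tUpper Quartile\t10th Percentile\t90th Percentile",
               "1\t38.0\t38.0\t34.0\t42.0\t30.0\t45.0",
               "2\t38.0\t38.0\t39.0\t42.0\t30.0\t45.0",  # q25 > median
               ">>END_MODULE"), f)
  expect_error(parse_fastqc_data(f), "percentile ordering")

  g <- withr::local_tempfile()
  writeLines(c(">>Per base sequence quality\tpass",
               "#Base\tMean\tMedian\tLower Quartile\tUpper Quartile\t10th Percentile\t90th Percentile",
               "100-104\t30.0\t30.0\t26.0\t34.0\t22.0\t38.0"), g)
  prof <- parse_fastqc_data(g)
  expect_identical(prof$bins$start, 100L)
  expect_identical(prof$bins$end, 104L)

  h <- withr::local_tempfile()
  writeLines("no block here", h)
  expect_error(parse_fastqc_data(h), "Per base sequence quality")
})

test_that("plot images round trip through PNG files, compositing alpha on white", {
  img <- std_render()$image
  f <- withr::local_tempfile(fileext = ".png")
  write_plot_image(img, f)
  expect_identical(load_plot_image(f), img)

  # opaque RGBA loads to the same RGB; half-transparent blends toward white
  rgba <- array(0, dim = c(4, 4, 4))
  rgba[, , 1] <- 0.2; rgba[, , 2] <- 0.4; rgba[, , 3] <- 0.6; rgba[, , 4] <- 1
  g <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgba, g)
  expect_equal(load_plot_image(g)[1, 1, ], round(c(0.2, 0.4, 0.6) * 255))
  rgba[, , 4] <- 0
  png::writePNG(rgba, g)
  expect_equal(load_plot_image(g)[1, 1, ], c(255, 255, 255))

  # truncated file
  bytes <- readBin(f, "raw", file.info(f)$size)
  h <- withr::local_tempfile(fileext = ".png")
  writeBin(bytes[1:20], h)
  expect_error(load_plot_image(h), "cannot read image")
})
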