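test_that("predict_trim recovers the simulated crossing and records its threshold", {
  r <- std_render()
  rep <- qc_report("fixture", 250, r$image)
  rec <- predict_trim(rep)
  expect_s3_class(rec, "trim_recommendation")
  expect_identical(rec$source, "image")
  expect_identical(rec$quality_threshold, 20)
  expect_lte(abs(rec$truncation_position - r$sidecar$ground_truth_truncation), 5)

  hi <- render_plot(flat_profile(35))
  rec_hi <- predict_trim(qc_report("hi", 250, hi$image))
  expect_identical(rec_hi$status, "never_below")
  expect_identical(rec_hi$truncation_position, 250L)
})

test_that("calibration errors carry the sample name", {
  img <- array(255, dim = c(60, 60, 3))
  expect_error(predict_trim(qc_report("bad_sample", 100, img)), "bad_sample")
})

test_that("the table oracle picks the rightmost bin at or above threshold", {
  prof <- per_position_profile(c(rep(30, 200), rep(15, 50)))
  rec <- oracle_trim(prof, 20)
  expect_identical(rec$truncation_position, 200L)
  expect_identical(rec$status, "found")
  expect_identical(rec$source, "table")

  expect_identical(oracle_trim(per_position_profile(rep(35, 250)), 20)$status,
                   "never_below")
  expect_identical(oracle_trim(per_position_profile(rep(35, 250)), 20)$truncation_position,
                   250L)
  lo <- oracle_trim(per_position_profile(rep(10, 250)), 20)
  expect_identical(lo$status, "always_below")
  expect_identical(lo$truncation_position, 0L)
})

test_that("the oracle equals an independent exhaustive right-to-left scan", {
  set.seed(99)
  for (i in 1:20) {
    spec <- profile_spec(read_length = sample(c(80, 150, 250), 1),
                         decay_start = sample(40:200, 1),
                         decay_rate = stats::runif(1, 0.1, 1.2),
                         noise_sd = sample(0:2, 1), seed = i)
    prof <- simulate_profile(spec)
    for (th in c(15, 20, 25)) {
      ref <- exhaustive_trim_ref(prof, th)
      rec <- oracle_trim(prof, th)
      expect_identical(rec$truncation_position, as.integer(ref$position))
      expect_identical(rec$status, ref$status)
    }
  }
})

test_that("phred_error_rate is the closed-form Phred transform", {
  expect_identical(phred_error_rate(20), 0.01)
  expect_identical(phred_error_rate(0), 1)
  expect_equal(phred_error_rate(30), 0.001)
  expect_error(phred_error_rate(-1), ">= 0")
})

test_that("trim_fastq cuts records and conserves counts", {
  prof <- std_profile()
  fq <- withr::local_tempfile(fileext = ".fastq")
  simulate_fastq(prof, 100, 7, fq)
  out <- withr::local_tempfile(fileext = ".fastq")
  ct <- trim_fastq(fq, 200, FALSE, out)
  expect_identical(unname(ct), c(100L, 100L, 0L))
  lines <- readLines(out)
  expect_identical(length(lines), 400L)
  expect_true(all(nchar(lines[seq(2, 400, 4)]) == 200))
  expect_true(all(nchar(lines[seq(4, 400, 4)]) == 200))
  # conservation and re-parse through an independent FASTQ reader
  reparsed <- Biostrings::readDNAStringSet(out, format = "fastq")
  expect_identical(length(reparsed), 100L)
  expect_true(all(Biostrings::width(reparsed) == 200))
})

test_that("short reads are kept or discarded according to discard_short", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", strrep("A", 150), "+", strrep("I", 150),
               "@r2", strrep("C", 250), "+", strrep("I", 250)), fq)
  keep <- withr::local_tempfile(fileext = ".fastq")
  ct1 <- trim_fastq(fq, 200, FALSE, keep)
  expect_identical(unname(ct1), c(2L, 2L, 0L))
  expect_identical(nchar(readLines(keep)[c(2, 6)]), c(150L, 200L))

  drop <- withr::local_tempfile(fileext = ".fastq")
  ct2 <- trim_fastq(fq, 200, TRUE, drop)
  expect_identical(unname(ct2), c(2L, 1L, 1L))
  expect_identical(nchar(readLines(drop)[2]), 200L)
})

test_that("empty input yields an empty valid output and zero counts", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  file.create(fq)
  out <- withr::local_tempfile(fileext = ".fastq")
  ct <- trim_fastq(fq, 100, FALSE, out)
  expect_identical(unname(ct), c(0L, 0L, 0L))
  expect_true(file.exists(out))
  expect_identical(length(readLines(out)), 0L)
})

test_that("malformed records are reported by name", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@ok", "ACGT", "+", "IIII",
               "@broken", "ACGTACGT", "+", "III"), fq)
  expect_error(trim_fastq(fq, 2, FALSE, withr::local_tempfile()), "@broken")
})

test_that("recommendation invariants reject inconsistent states", {
  expect_error(trim_recommendation(10, 20, "never_below", "table", read_length = 50),
               "never_below")
  expect_error(trim_recommendation(3, 20, "always_below", "table", read_length = 50),
               "always_below")
  expect_error(trim_recommendation(60, 20, "found", "table", read_length = 50),
               "exceeds")
  rec <- trim_recommendation(40, 20, "found", "image", read_length = 50)
  j <- jsonlite::fromJSON(recommendation_json(rec))
  expect_identical(j$truncation_position, 40L)
  expect_identical(j$source, "image")
})
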