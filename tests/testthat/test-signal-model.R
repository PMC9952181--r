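test_that("CSV + sidecar round trip preserves channels bit-exactly", {
  rec <- small_dataset()[[1]]
  csv <- withr::local_tempfile(fileext = ".csv")
  side <- withr::local_tempfile(fileext = ".json")
  write_recording_csv(rec, csv, side)
  back <- read_recording_csv(csv, side)
  for (ch in sensor_channels(with_temp = TRUE)) {
    expect_identical(back$data[[ch]], rec$data[[ch]])
  }
  expect_equal(back$motions$class, rec$motions$class)
  expect_equal(back$motions$start, rec$motions$start)
  expect_equal(back$motions$end, rec$motions$end)
  expect_identical(back$participant_id, rec$participant_id)
  expect_equal(back$sample_rate, rec$sample_rate)
})

test_that("temperature channel is carried through but never analyzed", {
  rec <- small_dataset()[[1]]
  expect_true("temp" %in% names(rec$data))
  motions <- split_motions(rec)
  expect_equal(colnames(motions[[1]]$data), sensor_channels())
})

test_that("malformed input is rejected with informative errors", {
  rec <- small_dataset()[[1]]
  csv <- withr::local_tempfile(fileext = ".csv")
  side <- withr::local_tempfile(fileext = ".json")
  write_recording_csv(rec, csv, side)

  # drop a required channel
  d <- readr::read_csv(csv, show_col_types = FALSE)
  readr::write_csv(d[, setdiff(names(d), "ypr_z")], csv)
  expect_error(read_recording_csv(csv, side), class = "vbdtw_format_error")
  expect_error(read_recording_csv(csv, side), "ypr_z")

  # header-only CSV
  readr::write_csv(d[0, ], csv)
  expect_error(read_recording_csv(csv, side),
               class = "vbdtw_validation_error")

  # boundary beyond stream
  bad <- rec
  bad$motions$end[nrow(bad$motions)] <- nrow(rec$data) + 10
  expect_error(validate_sensor_recording(bad),
               class = "vbdtw_validation_error")
})

test_that("split_motions crops blocks, drops calibration, sorts by time", {
  rec <- small_dataset()[[1]]
  motions <- split_motions(rec)
  expect_length(motions, 14)
  expect_true(all(vapply(motions, function(m) nrow(m$data), integer(1)) ==
                    2000))
  expect_equal(vapply(motions, function(m) m$motion_class, integer(1)),
               1:14)

  # shuffled sidecar rows still give temporal order
  shuf <- rec
  shuf$motions <- shuf$motions[sample(nrow(shuf$motions)), ]
  motions2 <- split_motions(shuf)
  expect_equal(vapply(motions2, function(m) m$motion_class, integer(1)),
               1:14)

  # sample conservation: blocks concatenated equal the post-calibration
  # stream
  stream <- as.matrix(rec$data[, sensor_channels()])
  calib <- rec$motions$start[1]
  rebuilt <- do.call(rbind, lapply(motions, function(m) m$data))
  expect_equal(unname(rebuilt), unname(stream[(calib + 1):nrow(stream), ]))
})

test_that("min-max normalization follows the per-channel rescaling rule", {
  X <- cbind(a = c(0, 5, 10), b = c(2, 2, 2), c = c(-1, 0, 3))
  expect_warning(out <- normalize_minmax(X), "constant")
  expect_equal(out[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(out[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  expect_true(all(out >= 0 & out <= 1))
  # non-constant channels hit both endpoints
  expect_equal(range(out[, "c"]), c(0, 1))
  # idempotent on already-normalized channels
  expect_equal(suppressWarnings(normalize_minmax(out)), out)
})

test_that("normalization of a motion sequence is per channel, in [0,1]", {
  seq <- split_motions(small_dataset()[[1]])[[6]]
  nrm <- normalize_minmax(seq)
  expect_true(all(nrm$data >= 0 & nrm$data <= 1))
  expect_equal(unname(apply(nrm$data, 2, min)), rep(0, 6))
  expect_equal(unname(apply(nrm$data, 2, max)), rep(1, 6))
  expect_s3_class(nrm, "motion_sequence")
})

test_that("burst truth slices require a minimum overlap fraction", {
  # burst covering samples [100, 600): slices 3..12 fully, slice 2 not at
  # all; with slice length 50 and 20% overlap, slices 3..12
  expect_equal(burst_truth_slices(100, 600, 2000, 50), 3:12)
  # full-length burst marks every slice
  expect_equal(burst_truth_slices(0, 2000, 2000, 50), 1:40)
  # a 5-sample graze (10% of a slice) is not enough
  expect_equal(burst_truth_slices(145, 600, 2000, 50), 4:12)
})
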