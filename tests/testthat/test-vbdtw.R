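make_motion <- function(values, class = 5L) {
  motion_sequence(matrix(values, ncol = 1, dimnames = list(NULL, "acc_x")),
                  motion_class = class)
}

test_that("slice_motion produces contiguous non-overlapping slices", {
  seq <- split_motions(small_dataset()[[1]])[[4]]
  slices <- slice_motion(seq, 50)
  expect_length(slices, 40)
  expect_equal(vapply(slices, function(s) s$origin_index, integer(1)),
               seq(0L, 1950L, by = 50L))

  seq2 <- make_motion(rnorm(300))
  slices2 <- slice_motion(seq2, 60)
  expect_length(slices2, 5)
  expect_equal(vapply(slices2, function(s) s$origin_index, integer(1)),
               seq(0L, 240L, by = 60L))
  expect_length(slice_motion(make_motion(rnorm(50)), 50), 1)

  expect_error(slice_motion(make_motion(rnorm(70)), 50),
               class = "vbdtw_validation_error")
})

test_that("voting follows the hand-traced extraction rules", {
  d <- c(1, 1, 1, 9, 9, 9, 1)
  v <- vbdtw:::vote_d_values(d)
  expect_equal(v$threshold, 31 / 7)
  expect_equal(v$flagged, c(4L, 5L, 6L))
  expect_equal(v$valid_slices, 4:7)
  # independent scripted trace agrees on random profiles
  set.seed(3)
  for (case in 1:50) {
    d <- round(runif(sample(7:39, 1), 0, 10), 2)
    expect_equal(vbdtw:::vote_d_values(d)$valid_slices, trace_vote(d),
                 ignore_attr = TRUE)
  }
})

test_that("all-equal D values flag nothing", {
  v <- vbdtw:::vote_d_values(rep(2.5, 39))
  expect_length(v$valid_slices, 0)
})

test_that("profiles have N-1 D values and Sv within bounds", {
  seq <- split_motions(small_dataset()[[1]])[[6]]
  nrm <- suppressWarnings(normalize_minmax(seq))
  prof <- vbdtw_extract(nrm, mode = "dependent")
  expect_length(prof$d_values, 39)
  expect_equal(prof$threshold, mean(prof$d_values))
  expect_true(all(prof$valid_slices >= 1 & prof$valid_slices <= 40))
  expect_equal(prof$valid_slices,
               sort(unique(c(prof$flagged, prof$flagged + 1L))))

  profs <- vbdtw_extract(nrm, mode = "independent")
  expect_named(profs, sensor_channels())
  expect_true(all(vapply(profs, function(p) length(p$d_values),
                         integer(1)) == 39))
})

test_that("flag decisions are invariant to joint positive scaling of D", {
  set.seed(9)
  d <- runif(39, 0, 5)
  v1 <- vbdtw:::vote_d_values(d)
  v2 <- vbdtw:::vote_d_values(d * 37.5)
  expect_equal(v1$flagged, v2$flagged)
  expect_equal(v1$valid_slices, v2$valid_slices)
})

test_that("merge_channel_profiles unions valid slices", {
  p1 <- dtw_profile(NULL, NULL, integer(0), c(3L, 4L), 40)
  p2 <- dtw_profile(NULL, NULL, integer(0), c(4L, 5L), 40)
  expect_equal(merge_channel_profiles(list(p1, p2))$valid_slices, 3:5)
  p0 <- dtw_profile(NULL, NULL, integer(0), integer(0), 40)
  expect_length(merge_channel_profiles(list(p0, p0))$valid_slices, 0)
  p3 <- dtw_profile(NULL, NULL, integer(0), 1L, 20)
  expect_error(merge_channel_profiles(list(p1, p3)),
               class = "vbdtw_validation_error")
  # merged set is a superset of every channel's set
  seq <- split_motions(small_dataset()[[2]])[[8]]
  profs <- vbdtw_extract(suppressWarnings(normalize_minmax(seq)))
  mg <- merge_channel_profiles(profs)
  for (p in profs) {
    expect_true(all(p$valid_slices %in% mg$valid_slices))
  }
})

test_that("uniform resampling downsamples by index, upsamples linearly", {
  X <- matrix(1:10, ncol = 1)
  expect_identical(resample_uniform(X, 10), X)
  down <- resample_uniform(X, 5)
  expect_equal(nrow(down), 5)
  expect_equal(down[c(1, 5), 1], c(1, 10))  # endpoints kept
  # linear interpolation at rational grid points: n = 3 -> 5 inserts the
  # midpoints
  up <- resample_uniform(matrix(c(0, 1, 4), ncol = 1), 5)
  expect_equal(up[, 1], c(0, 0.5, 1, 2.5, 4))
})

test_that("extract_valid_segment concatenates Sv slices then resamples", {
  # 200-sample motion, 4 slices of 50; burst values on slices 2-3
  vals <- c(rep(0, 50), rep(1, 50), rep(2, 50), rep(0, 50))
  seq <- make_motion(vals)
  prof <- dtw_profile(NULL, NULL, integer(0), c(2L, 3L), 4)
  seg <- extract_valid_segment(seq, prof, target_len = 100, slice_len = 50)
  expect_equal(nrow(seg$data), 100)
  expect_equal(unname(seg$data[, 1]), c(rep(1, 50), rep(2, 50)))
  expect_equal(seg$source_slices, c(2L, 3L))

  # shorter than target: linear upsampling
  prof1 <- dtw_profile(NULL, NULL, integer(0), 3L, 4)
  seg1 <- extract_valid_segment(seq, prof1, target_len = 285,
                                slice_len = 50)
  expect_equal(nrow(seg1$data), 285)
  expect_true(all(seg1$data == 2))

  # identity when already at target length
  prof2 <- dtw_profile(NULL, NULL, integer(0), 1:4, 4)
  seg2 <- extract_valid_segment(seq, prof2, target_len = 200,
                                slice_len = 50)
  expect_equal(unname(seg2$data[, 1]), vals)
})

test_that("sitting still and empty-Sv motions fall back to the whole block", {
  vals <- rnorm(200)
  still <- make_motion(vals, class = 1L)
  prof <- dtw_profile(NULL, NULL, integer(0), integer(0), 4)
  seg <- extract_valid_segment(still, prof, target_len = 120,
                               slice_len = 50)
  expect_equal(nrow(seg$data), 120)

  dyn <- make_motion(vals, class = 9L)
  expect_warning(seg2 <- extract_valid_segment(dyn, prof, target_len = 120,
                                               slice_len = 50),
                 "falling back")
  expect_equal(nrow(seg2$data), 120)
  expect_length(seg2$source_slices, 0)
})

test_that("planted bursts are recovered with high Jaccard", {
  recs <- small_dataset()
  seqs <- split_motions(recs[[1]])
  seq <- seqs[[8]]
  nrm <- suppressWarnings(normalize_minmax(seq))
  prof <- vbdtw_extract(nrm, mode = "dependent")
  expect_gte(jaccard(prof$valid_slices, seq$truth_valid_slices), 0.85)
})
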