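test_that("generated recordings follow the study design", {
  recs <- small_dataset()  # 2 participants x 2 trials
  expect_length(recs, 4)
  for (rec in recs) {
    expect_equal(nrow(rec$motions), 14)
    expect_equal(rec$motions$class, 1:14)
    expect_equal(nrow(rec$data), 2000 + 14 * 2000)  # calibration + blocks
    expect_equal(unique(rec$motions$end - rec$motions$start), 2000L)
    expect_true(all(diff(rec$motions$start) == 2000))
  }
  expect_equal(vapply(recs, function(r) r$participant_id, character(1)),
               c("P01", "P01", "P02", "P02"))
})

test_that("generation is deterministic per seed and varies across seeds", {
  cfg <- sim_config(n_participants = 1, n_trials = 1, seed = 5)
  r1 <- generate_dataset(cfg)[[1]]
  r2 <- generate_dataset(cfg)[[1]]
  expect_identical(r1$data, r2$data)
  r3 <- generate_dataset(sim_config(n_participants = 1, n_trials = 1,
                                    seed = 6))[[1]]
  expect_false(identical(r3$data, r1$data))
})

test_that("ground-truth slices always overlap the planted burst", {
  for (rec in small_dataset()) {
    m <- rec$motions
    for (i in which(m$class != 1)) {
      truth <- burst_truth_slices(m$burst_start[i], m$burst_end[i])
      expect_gt(length(truth), 0)
      starts <- (truth - 1) * 50
      # every truth slice intersects the burst; none lies wholly in
      # baseline
      expect_true(all(pmin(starts + 50, m$burst_end[i]) -
                        pmax(starts, m$burst_start[i]) > 0))
    }
    # sitting still has no burst
    expect_true(is.na(m$burst_start[m$class == 1]))
  }
})

test_that("a full-motion burst marks all slices as valid", {
  bf <- default_burst_fractions()
  bf["9"] <- 1.0
  cfg <- sim_config(n_participants = 1, n_trials = 1,
                    burst_fraction = bf, seed = 3)
  rec <- generate_dataset(cfg)[[1]]
  i <- which(rec$motions$class == 9)
  truth <- burst_truth_slices(rec$motions$burst_start[i],
                              rec$motions$burst_end[i])
  expect_equal(truth, 1:40)
})

test_that("invalid burst fractions are rejected", {
  bf <- default_burst_fractions()
  bf["5"] <- 0
  expect_error(sim_config(burst_fraction = bf),
               class = "vbdtw_validation_error")
  bf2 <- default_burst_fractions()
  bf2["1"] <- 0.4
  expect_error(sim_config(burst_fraction = bf2),
               class = "vbdtw_validation_error")
})

test_that("participant variation preserves class identity", {
  cfg <- sim_config()
  tmpl <- motion_template(8, cfg)
  # zero scales leave the template unchanged
  t0 <- participant_variation(tmpl, 1,
                              scales = list(amp = 0, freq = 0, onset = 0),
                              seed = 42)
  expect_equal(t0$amp, tmpl$amp)
  expect_equal(t0$freq, tmpl$freq)
  expect_equal(t0$phase, rep(0, 6))

  # two participants get different draws, deterministically
  ta <- participant_variation(tmpl, 1, seed = 42)
  tb <- participant_variation(tmpl, 2, seed = 42)
  expect_false(identical(ta$amp, tb$amp))
  expect_identical(ta, participant_variation(tmpl, 1, seed = 42))

  # margin: across classes and participants, between-class template
  # distance exceeds within-class jitter
  feat <- function(tm) c(tm$freq, tm$amp, tm$harm2, tm$harm3)
  classes <- 4:14
  per_class <- lapply(classes, function(k) {
    lapply(1:5, function(p) {
      feat(participant_variation(motion_template(k, cfg), p, seed = 42))
    })
  })
  within <- max(unlist(lapply(per_class, function(vs) {
    max(vapply(vs, function(v) sqrt(sum((v - vs[[1]])^2)), numeric(1)))
  })))
  between <- min(unlist(lapply(seq_along(classes), function(i) {
    vapply(seq_along(classes)[-i], function(j) {
      sqrt(sum((per_class[[i]][[1]] - per_class[[j]][[1]])^2))
    }, numeric(1))
  })))
  expect_gt(between, within)
})

test_that("truth slice counts are stable across participants", {
  cfg <- sim_config(n_participants = 2, n_trials = 1, seed = 19)
  recs <- generate_dataset(cfg)
  for (k in c(6, 9, 12)) {
    counts <- vapply(recs, function(rec) {
      i <- which(rec$motions$class == k)
      length(burst_truth_slices(rec$motions$burst_start[i],
                                rec$motions$burst_end[i]))
    }, integer(1))
    expect_lte(diff(range(counts)), 2)
  }
})

test_that("a nearest-centroid classifier finds signal in whole motions", {
  recs <- small_dataset()
  X <- list()
  y <- c()
  for (rec in recs) {
    for (seq in split_motions(rec)) {
      nrm <- suppressWarnings(normalize_minmax(seq))
      X[[length(X) + 1]] <- colMeans(abs(diff(nrm$data)))
      y <- c(y, seq$motion_class)
    }
  }
  X <- do.call(rbind, X)
  train <- seq_along(y) <= 28  # first two recordings
  cent <- sapply(sort(unique(y[train])), function(k) {
    colMeans(X[train & y == k, , drop = FALSE])
  })
  pred <- apply(X[!train, , drop = FALSE], 1, function(r) {
    which.min(colSums((cent - r)^2))
  })
  expect_gt(mean(pred == y[!train]), 3 / 14)
})
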