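test_that("Jaccard index matches set arithmetic", {
  expect_equal(jaccard(1:7, 1:7), 1)
  expect_equal(jaccard(1:3, 8:9), 0)
  expect_equal(jaccard(1:10, 6:15), 5 / 15)
  expect_warning(j <- jaccard(integer(0), integer(0)), "empty")
  expect_equal(j, 1)
})

test_that("Jaccard identities hold on random sets", {
  set.seed(13)
  for (case in 1:40) {
    a <- sample(40, sample(1:20, 1))
    b <- sample(40, sample(1:20, 1))
    j <- jaccard(a, b)
    expect_gte(j, 0)
    expect_lte(j, 1)
    expect_equal(j, jaccard(b, a))
  }
  # monotone when the intersection grows at fixed union
  u <- 1:20
  a <- 1:10
  js <- vapply(10:20, function(k) jaccard(a, c(a[seq_len(k - 10)], 11:20)),
               numeric(1))
  expect_true(all(diff(js) >= 0))
})

test_that("accuracy equals the mean of per-segment correctness", {
  set.seed(4)
  truth <- sample(1:14, 17, replace = TRUE)
  pred <- truth
  flip <- sample(17, 5)
  pred[flip] <- ((pred[flip] + 3) %% 14) + 1
  hand_count <- sum(truth == pred)
  expect_equal(segment_accuracy(truth, pred), hand_count / 17)
  expect_equal(segment_accuracy(truth, truth), 1)
  expect_error(segment_accuracy(integer(0), integer(0)),
               class = "vbdtw_validation_error")
})

test_that("jaccard_report averages over the six motion channels", {
  profs <- lapply(sensor_channels(), function(ch) {
    dtw_profile(NULL, NULL, integer(0),
                if (ch == "acc_z") 1:10 else 1:9, 40, channel = ch)
  })
  names(profs) <- sensor_channels()
  rep <- jaccard_report(profs, 1:10, motion_class = 6L)
  expect_equal(nrow(rep), 6)
  expect_equal(rep$jaccard[rep$channel == "acc_z"], 1)
  expect_equal(rep$jaccard[rep$channel == "acc_x"], 0.9)
  expect_equal(rep$mean_jaccard, rep(mean(c(rep(0.9, 5), 1)), 6))
})

test_that("ablation tables have the paired-arm shape", {
  recs <- small_dataset()
  cfn <- function(f, nc, s) {
    classifier_config(f, input_channels = nc, input_len = s,
                      n_classes = 14, lr = 2e-3, batch_size = 128,
                      epochs = 2)
  }
  aug <- ablation_augmentation(recs, families = "dnn", seed = 1,
                               s = 48, target_len = 60, config_fn = cfn)
  expect_named(aug, c("family", "with_augmentation",
                      "without_augmentation", "improvement"))
  expect_equal(aug$improvement,
               aug$with_augmentation - aug$without_augmentation)
  ext <- ablation_extraction(recs, families = "dnn", seed = 1,
                             s = 48, target_len = 60, config_fn = cfn)
  expect_named(ext, c("family", "with_vbdtw", "without_vbdtw",
                      "improvement"))
  expect_equal(ext$improvement, ext$with_vbdtw - ext$without_vbdtw)
})
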