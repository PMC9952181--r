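# small separable two-class window sets: class 1 = low-frequency sine,
# class 2 = high-frequency sine, across 6 channels
toy_sets <- function(n_per_class = 8, len = 40, s = 32) {
  sets <- list()
  for (k in 1:2) {
    for (i in seq_len(n_per_class)) {
      t <- seq(0, 1, length.out = len)
      f <- if (k == 1) 2 else 7
      X <- sapply(1:6, function(c) {
        sin(2 * pi * f * t + i / 3 + c) + rnorm(len, 0, 0.05)
      })
      colnames(X) <- sensor_channels()
      seg <- valid_segment(X, k, participant_id = sprintf("P%02d", i),
                           trial_id = "T1")
      sets[[length(sets) + 1]] <- window_slice(seg, s = s)
    }
  }
  sets
}

test_that("config validation catches bad settings", {
  expect_error(classifier_config("cnn1d", input_channels = 4),
               class = "vbdtw_validation_error")
  expect_error(classifier_config("cnn1d", n_classes = 1),
               class = "vbdtw_validation_error")
  expect_error(classifier_config("transformer"))
})

test_that("every family separates a linearly separable two-class set", {
  sets <- withr::with_seed(0, toy_sets())
  for (family in c("dnn", "cnn1d", "lstm", "bilstm")) {
    cfg <- classifier_config(family, input_channels = 6, input_len = 32,
                             n_classes = 2, class_levels = 1:2,
                             epochs = 30, lr = 5e-3, units = 16,
                             filters = c(8, 12))
    m <- train_classifier(cfg, sets, seed = 0)
    final <- tail(m$training_log$window_accuracy, 1)
    expect_gte(final, 0.99)
  }
})

test_that("training is deterministic for a fixed seed", {
  sets <- withr::with_seed(0, toy_sets(n_per_class = 4))
  cfg <- classifier_config("cnn1d", input_channels = 6, input_len = 32,
                           n_classes = 2, class_levels = 1:2, epochs = 4,
                           filters = c(6, 8))
  m1 <- train_classifier(cfg, sets, seed = 11)
  m2 <- train_classifier(cfg, sets, seed = 11)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$layers, m2$layers)
  m3 <- train_classifier(cfg, sets, seed = 12)
  expect_false(identical(m3$training_log$loss, m1$training_log$loss))
})

test_that("degenerate label sets are rejected", {
  sets <- withr::with_seed(0, toy_sets(n_per_class = 3))
  one_class <- sets[1:3]
  cfg2 <- classifier_config("dnn", input_channels = 6, input_len = 32,
                            n_classes = 2, class_levels = 1:2, epochs = 2)
  expect_error(train_classifier(cfg2, one_class, seed = 0),
               class = "vbdtw_validation_error")
  cfg3 <- classifier_config("dnn", input_channels = 6, input_len = 32,
                            n_classes = 3, class_levels = 1:3, epochs = 2)
  expect_error(train_classifier(cfg3, sets, seed = 0), "absent")
  expect_error(train_classifier(cfg2, list(), seed = 0),
               class = "vbdtw_validation_error")
})

test_that("evaluation majority-votes windows into segment accuracy", {
  sets <- withr::with_seed(0, toy_sets(n_per_class = 6))
  cfg <- classifier_config("cnn1d", input_channels = 6, input_len = 32,
                           n_classes = 2, class_levels = 1:2, epochs = 20,
                           lr = 5e-3, filters = c(8, 12))
  m <- train_classifier(cfg, sets, seed = 0)
  acc <- evaluate_classifier(m, sets)
  expect_gte(acc, 0.99)
  pr <- predict_segments(m, sets)
  expect_equal(nrow(pr), length(sets))
  expect_equal(acc, mean(pr$truth == pr$predicted))
  expect_error(predict_segments(m, list()),
               class = "vbdtw_validation_error")
})

test_that("a constant-output model scores at chance on a balanced set", {
  segs <- study_segments()
  sets <- lapply(segs[1:224], window_slice, s = 256)
  cfg <- classifier_config("dnn", input_channels = 6, input_len = 256,
                           n_classes = 14, epochs = 1, hidden = c(4))
  m <- train_classifier(cfg, sets[1:28], seed = 0)
  # force constant logits favoring class 1
  last <- length(m$layers)
  m$layers[[last]]$W[] <- 0
  m$layers[[last]]$b <- c(5, rep(0, 13))
  acc <- evaluate_classifier(m, sets)
  expect_equal(acc, mean(vapply(sets, function(a) a$label, integer(1)) ==
                           1L))
  expect_lt(abs(acc - 1 / 14), 0.05)
})

test_that("segment splits are stratified and leakage-free", {
  segs <- study_segments()
  sp <- split_segments(segs, prop = 0.8, seed = 3)
  expect_equal(length(sp$train) + length(sp$test), length(segs))
  lab_test <- table(vapply(sp$test, function(s) s$motion_class,
                           integer(1)))
  expect_equal(length(lab_test), 14)  # every class represented
  ids <- function(x) {
    vapply(x, function(s) paste(s$participant_id, s$trial_id,
                                s$motion_class), character(1))
  }
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
})

test_that("tidy and glance expose the training record", {
  sets <- withr::with_seed(0, toy_sets(n_per_class = 3))
  cfg <- classifier_config("dnn", input_channels = 6, input_len = 32,
                           n_classes = 2, class_levels = 1:2, epochs = 3)
  m <- train_classifier(cfg, sets, seed = 0)
  td <- tidy(m)
  expect_named(td, c("epoch", "loss", "window_accuracy"))
  expect_equal(nrow(td), 3)
  gl <- glance(m)
  expect_equal(gl$family, "dnn")
  expect_equal(gl$epochs, 3)
})

test_that("compare_families covers the family-by-channel grid", {
  segs <- small_dataset()
  segs60 <- lapply(segment_recordings(segs, target_len = 60),
                   identity)
  sp <- split_segments(segs60, seed = 1)
  cfn <- function(f, nc, s) {
    classifier_config(f, input_channels = nc, input_len = s,
                      n_classes = 14, epochs = 2, units = 8,
                      filters = c(6, 8), batch_size = 128)
  }
  res <- compare_families(sp, families = c("dnn", "cnn1d"),
                          channel_sets = c("acc", "ypr", "acc_ypr"),
                          seed = 1, s = 48, config_fn = cfn)
  expect_equal(nrow(res), 6)
  expect_named(res, c("family", "channels", "accuracy"))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  # deterministic given the same inputs
  res2 <- compare_families(sp, families = c("dnn", "cnn1d"),
                           channel_sets = c("acc", "ypr", "acc_ypr"),
                           seed = 1, s = 48, config_fn = cfn)
  expect_identical(res, res2)
})

test_that("recurrent and dense families beat chance on the study data", {
  segs96 <- cached("study96", {
    lapply(study_segments(), function(s) {
      s$data <- resample_uniform(s$data, 96)
      s
    })
  })
  sp <- split_segments(segs96, seed = 1)
  tr <- lapply(sp$train, window_slice, s = 64)
  te <- lapply(sp$test, window_slice, s = 64)
  for (family in c("dnn", "lstm", "bilstm")) {
    epochs <- if (family == "dnn") 10 else 8
    cfg <- fast_config(family, 6, 64, epochs = epochs)
    m <- train_classifier(cfg, tr, seed = 1)
    acc <- evaluate_classifier(m, te)
    expect_gt(acc, 2 / 14)
  }
})
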