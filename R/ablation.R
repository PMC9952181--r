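#' Ablation: effect of VB-DTW valid-segment extraction
#'
#' Paired accuracy comparison per model family: the "with" arm classifies
#' VB-DTW-extracted segments; the "without" arm resamples each whole
#' motion block to the canonical length directly. Splits and seeds are
#' identical across arms.
#'
#' @param recordings list of [sensor_recording()].
#' @param families model families to test (default `"cnn1d"`).
#' @param channel_set channel set (default `"acc_ypr"`, the strongest).
#' @param seed split/training seed.
#' @param s window length (default 256).
#' @param target_len canonical segment length (default 285).
#' @param prop training proportion (default 0.8).
#' @param config_fn optional `function(family, n_channels, input_len)`
#'   returning a [classifier_config()].
#' @param segments_with,segments_without optionally, precomputed segment
#'   lists for the two arms (extraction is deterministic, so repeated
#'   ablation runs over seeds can share them); computed from `recordings`
#'   when NULL.
#' @return tibble with columns `family`, `with_vbdtw`, `without_vbdtw`,
#'   `improvement`.
#' @export
ablation_extraction <- function(recordings, families = "cnn1d",
                                channel_set = "acc_ypr", seed = 0,
                                s = 256, target_len = 285, prop = 0.8,
                                config_fn = NULL, segments_with = NULL,
                                segments_without = NULL) {
  segs_with <- segments_with %||%
    segment_recordings(recordings, use_vbdtw = TRUE,
                       target_len = target_len)
  segs_without <- segments_without %||%
    segment_recordings(recordings, use_vbdtw = FALSE,
                       target_len = target_len)
  acc <- purrr::map_dfr(families, function(fam) {
    a_with <- arm_accuracy(segs_with, fam, channel_set, seed, s, prop,
                           config_fn)
    a_without <- arm_accuracy(segs_without, fam, channel_set, seed, s, prop,
                              config_fn)
    tibble::tibble(family = fam, with_vbdtw = a_with,
                   without_vbdtw = a_without,
                   improvement = a_with - a_without)
  })
  acc
}

#' Ablation: effect of window-slicing augmentation
#'
#' The "with" arm trains on the stride-1 windows (30 per segment at the
#' defaults); the "without" arm trains on a single full-length instance
#' per segment. Same segments, splits and seeds across arms.
#'
#' @inheritParams ablation_extraction
#' @param segments optionally, precomputed VB-DTW segments; computed from
#'   `recordings` when NULL.
#' @return tibble with columns `family`, `with_augmentation`,
#'   `without_augmentation`, `improvement`.
#' @export
ablation_augmentation <- function(recordings, families = "cnn1d",
                                  channel_set = "acc_ypr", seed = 0,
                                  s = 256, target_len = 285, prop = 0.8,
                                  config_fn = NULL, segments = NULL) {
  segs <- segments %||%
    segment_recordings(recordings, use_vbdtw = TRUE,
                       target_len = target_len)
  purrr::map_dfr(families, function(fam) {
    a_with <- arm_accuracy(segs, fam, channel_set, seed, s, prop, config_fn)
    a_without <- arm_accuracy(segs, fam, channel_set, seed, target_len,
                              prop, config_fn)
    tibble::tibble(family = fam, with_augmentation = a_with,
                   without_augmentation = a_without,
                   improvement = a_with - a_without)
  })
}

# one train/evaluate arm at window length s (s = target_len means a
# single full-length instance per segment, i.e. no augmentation)
arm_accuracy <- function(segments, family, channel_set, seed, s, prop,
                         config_fn = NULL) {
  split <- split_segments(segments, prop = prop, seed = seed)
  ch <- channel_set_names(channel_set)
  class_levels <- sort(unique(vapply(segments, function(x) x$motion_class,
                                     integer(1))))
  cfg <- if (is.null(config_fn)) {
    classifier_config(family, input_channels = length(ch), input_len = s,
                      n_classes = length(class_levels),
                      class_levels = class_levels)
  } else {
    config_fn(family, length(ch), s)
  }
  train_aug <- lapply(split$train, window_slice, s = s)
  test_aug <- lapply(split$test, window_slice, s = s)
  model <- train_classifier(cfg, train_aug, seed = seed, channels = ch)
  evaluate_classifier(model, test_aug)
}
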