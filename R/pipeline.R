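# Stage commands: each reads the previous stage's on-disk artifacts and
# writes its own, so any stage can be rerun from persisted state. Every
# stage drops a <stage>_info.json with the seed/config it ran under; no
# timestamps, so a rerun with the same seed is byte-identical.

write_stage_info <- function(dir, stage, info) {
  info$stage <- stage
  info$package_version <- as.character(utils::packageVersion("vbdtw"))
  jsonlite::write_json(info, file.path(dir, paste0(stage, "_info.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    abort(paste0("missing upstream artifact ", path,
                 "; run ", producer, " first"),
          class = "vbdtw_pipeline_error")
  }
  path
}

#' Stage 1: simulate a synthetic dataset to disk
#'
#' Writes one CSV + JSON sidecar pair per recording.
#'
#' @param out_dir output directory (created if needed).
#' @param cfg a [sim_config()].
#' @return invisibly, the recording basenames written.
#' @export
cmd_simulate <- function(out_dir, cfg = sim_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  recs <- generate_dataset(cfg)
  names <- vapply(recs, function(rec) {
    base <- paste0("rec_", rec$participant_id, "_", rec$trial_id)
    write_recording_csv(rec, file.path(out_dir, paste0(base, ".csv")),
                        file.path(out_dir, paste0(base, ".json")))
    base
  }, character(1))
  write_stage_info(out_dir, "simulate",
                   list(config = unclass(cfg), n_recordings = length(recs)))
  invisible(names)
}

read_recording_dir <- function(in_dir, producer = "cmd_simulate") {
  sidecars <- sort(list.files(in_dir, pattern = "^rec_.*\\.json$",
                              full.names = TRUE))
  if (length(sidecars) == 0) {
    abort(paste0("no recordings found in ", in_dir, "; run ", producer,
                 " first"),
          class = "vbdtw_pipeline_error")
  }
  lapply(sidecars, function(sc) {
    read_recording_csv(sub("\\.json$", ".csv", sc), sc)
  })
}

segments_to_json <- function(segments, path) {
  recs <- lapply(segments, function(s) {
    list(class = s$motion_class, participant = s$participant_id,
         trial = s$trial_id, source_slices = s$source_slices,
         data = apply(s$data, 2, identity, simplify = FALSE))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
}

segments_from_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    X <- do.call(cbind, lapply(r$data, unlist))
    valid_segment(X, r$class, unlist(r$source_slices) %||% integer(0),
                  r$participant, r$trial)
  })
}

#' Stage 2: VB-DTW segment extraction over a recording directory
#'
#' @param in_dir directory of [cmd_simulate()] artifacts.
#' @param out_dir output directory; writes `segments.json`.
#' @param slice_len,vote_radius,vote_count,mode,target_len extractor
#'   settings.
#' @param use_vbdtw set FALSE for the no-extraction ablation arm.
#' @return invisibly, the number of segments written.
#' @export
cmd_segment <- function(in_dir, out_dir, slice_len = 50, vote_radius = 2,
                        vote_count = 3, mode = "dependent",
                        target_len = 285, use_vbdtw = TRUE) {
  recs <- read_recording_dir(in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  segs <- segment_recordings(recs, use_vbdtw = use_vbdtw,
                             slice_len = slice_len,
                             vote_radius = vote_radius,
                             vote_count = vote_count, mode = mode,
                             target_len = target_len)
  segments_to_json(segs, file.path(out_dir, "segments.json"))
  write_stage_info(out_dir, "segment",
                   list(slice_len = slice_len, vote_radius = vote_radius,
                        vote_count = vote_count, mode = mode,
                        target_len = target_len, use_vbdtw = use_vbdtw,
                        n_segments = length(segs)))
  invisible(length(segs))
}

#' Stage 3: window-slicing augmentation manifest
#'
#' Windows are a deterministic function of (segment, window length,
#' stride), so the stage persists a manifest rather than materialized
#' copies; training reconstructs the windows from it.
#'
#' @param in_dir directory holding `segments.json`.
#' @param out_dir output directory; writes `windows_manifest.json`.
#' @param s window length (default 256).
#' @return invisibly, the total window count.
#' @export
cmd_augment <- function(in_dir, out_dir, s = 256) {
  seg_path <- require_artifact(file.path(in_dir, "segments.json"),
                               "cmd_segment")
  segs <- segments_from_json(seg_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- vapply(segs, function(x) nrow(x$data), integer(1))
  manifest <- list(segments_path = normalizePath(seg_path),
                   s = s, stride = 1,
                   n_windows = as.integer(n - s + 1))
  jsonlite::write_json(manifest, file.path(out_dir, "windows_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_stage_info(out_dir, "augment",
                   list(s = s, stride = 1,
                        total_windows = sum(manifest$n_windows)))
  invisible(sum(manifest$n_windows))
}

read_manifest_segments <- function(in_dir) {
  man_path <- require_artifact(file.path(in_dir, "windows_manifest.json"),
                               "cmd_augment")
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  list(segments = segments_from_json(man$segments_path), s = man$s)
}

#' Stage 4: train one classifier from persisted artifacts
#'
#' @param in_dir directory holding `windows_manifest.json`.
#' @param out_dir output directory; writes the model (`model.rds`) and
#'   its training log (`train_log.csv`).
#' @param family model family.
#' @param channel_set `"acc"`, `"ypr"`, or `"acc_ypr"`.
#' @param seed split/training seed.
#' @param prop training proportion.
#' @param epochs maximum epochs.
#' @return invisibly, the trained model.
#' @export
cmd_train <- function(in_dir, out_dir, family = "cnn1d",
                      channel_set = "acc_ypr", seed = 0, prop = 0.8,
                      epochs = 50) {
  ms <- read_manifest_segments(in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  split <- split_segments(ms$segments, prop = prop, seed = seed)
  ch <- channel_set_names(channel_set)
  class_levels <- sort(unique(vapply(ms$segments,
                                     function(x) x$motion_class,
                                     integer(1))))
  cfg <- classifier_config(family, input_channels = length(ch),
                           input_len = ms$s,
                           n_classes = length(class_levels),
                           class_levels = class_levels, epochs = epochs)
  train_aug <- lapply(split$train, window_slice, s = ms$s)
  model <- train_classifier(cfg, train_aug, seed = seed, channels = ch)
  saveRDS(model, file.path(out_dir, "model.rds"))
  readr::write_csv(model$training_log, file.path(out_dir, "train_log.csv"))
  write_stage_info(out_dir, "train",
                   list(family = family, channel_set = channel_set,
                        seed = seed, prop = prop,
                        n_train_segments = length(split$train),
                        n_test_segments = length(split$test)))
  invisible(model)
}

#' Stage 5: family-by-channel-set evaluation report
#'
#' Trains and evaluates every (family, channel set) cell on one shared
#' split and writes the accuracy table as CSV — the main-results report
#' of the pipeline.
#'
#' @param in_dir directory holding `windows_manifest.json`.
#' @param out_dir output directory; writes `accuracy_table.csv`.
#' @param families,channel_sets grid to evaluate.
#' @param seed split/training seed.
#' @param prop training proportion.
#' @return the results tibble, invisibly.
#' @export
cmd_evaluate <- function(in_dir, out_dir,
                         families = c("dnn", "lstm", "bilstm", "cnn1d"),
                         channel_sets = c("acc", "ypr", "acc_ypr"),
                         seed = 0, prop = 0.8) {
  ms <- read_manifest_segments(in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  split <- split_segments(ms$segments, prop = prop, seed = seed)
  res <- compare_families(split, families = families,
                          channel_sets = channel_sets, seed = seed,
                          s = ms$s)
  readr::write_csv(res, file.path(out_dir, "accuracy_table.csv"))
  write_stage_info(out_dir, "evaluate",
                   list(families = families, channel_sets = channel_sets,
                        seed = seed, prop = prop))
  invisible(res)
}

#' Stage 6: ablation reports
#'
#' Writes paired accuracy tables for the two ablations (segment
#' extraction on/off; augmentation on/off) from the raw recording
#' directory.
#'
#' @param in_dir directory of [cmd_simulate()] artifacts.
#' @param out_dir output directory; writes `ablation_extraction.csv` and
#'   `ablation_augmentation.csv`.
#' @param families model families (default `"cnn1d"`).
#' @param seed split/training seed.
#' @param s window length.
#' @param target_len canonical segment length.
#' @return invisibly, a list of the two tibbles.
#' @export
cmd_ablate <- function(in_dir, out_dir, families = "cnn1d", seed = 0,
                       s = 256, target_len = 285) {
  recs <- read_recording_dir(in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- ablation_extraction(recs, families = families, seed = seed,
                             s = s, target_len = target_len)
  aug <- ablation_augmentation(recs, families = families, seed = seed,
                               s = s, target_len = target_len)
  readr::write_csv(ext, file.path(out_dir, "ablation_extraction.csv"))
  readr::write_csv(aug, file.path(out_dir, "ablation_augmentation.csv"))
  write_stage_info(out_dir, "ablate",
                   list(families = families, seed = seed, s = s,
                        target_len = target_len))
  invisible(list(extraction = ext, augmentation = aug))
}
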