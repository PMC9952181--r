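#' Canonical sensor channel names
#'
#' The wearable unit streams three accelerometer axes and three gyroscope
#' (yaw/pitch/roll) axes, in this fixed order, plus an optional temperature
#' channel that is carried through I/O but never analyzed.
#'
#' @param with_temp logical; append the optional `temp` channel.
#' @return character vector of channel names.
#' @export
sensor_channels <- function(with_temp = FALSE) {
  ch <- c("acc_x", "acc_y", "acc_z", "ypr_x", "ypr_y", "ypr_z")
  if (with_temp) ch <- c(ch, "temp")
  ch
}

#' Construct a sensor recording
#'
#' A `sensor_recording` holds one participant-trial stream: a samples-by-
#' channels tibble in canonical channel order, the sampling rate, and a
#' motion index giving the class and sample boundaries of each labeled
#' motion block. Sample indices are 0-based and intervals half-open
#' `[start, end)`.
#'
#' @param data data frame with the canonical channel columns
#'   (see [sensor_channels()]); extra columns are preserved but ignored by
#'   analysis.
#' @param motions data frame with columns `class` (integer 1..14), `start`,
#'   `end` (0-based half-open sample interval). May carry extra columns
#'   (e.g. ground-truth burst boundaries from the simulator).
#' @param participant_id,trial_id identifiers.
#' @param sample_rate samples per second (default 100).
#' @return an object of class `sensor_recording`.
#' @export
sensor_recording <- function(data, motions, participant_id, trial_id,
                             sample_rate = 100) {
  data <- tibble::as_tibble(data)
  motions <- tibble::as_tibble(motions)
  rec <- structure(
    list(
      participant_id = as.character(participant_id),
      trial_id = as.character(trial_id),
      sample_rate = as.numeric(sample_rate),
      data = data,
      motions = motions
    ),
    class = "sensor_recording"
  )
  validate_sensor_recording(rec)
  rec
}

validate_sensor_recording <- function(rec) {
  required <- sensor_channels()
  missing <- setdiff(required, names(rec$data))
  if (length(missing) > 0) {
    abort(paste0("missing required channel column(s): ",
                 paste(missing, collapse = ", ")),
          class = "vbdtw_format_error")
  }
  n <- nrow(rec$data)
  if (n == 0) {
    abort("zero-length sensor stream", class = "vbdtw_validation_error")
  }
  m <- rec$motions
  if (nrow(m) > 0) {
    if (!all(c("class", "start", "end") %in% names(m))) {
      abort("motion index must have columns class, start, end",
            class = "vbdtw_format_error")
    }
    if (any(m$start < 0) || any(m$end > n)) {
      abort("motion boundary outside stream length",
            class = "vbdtw_validation_error")
    }
    if (any(m$end <= m$start)) {
      abort("motion interval empty or reversed",
            class = "vbdtw_validation_error")
    }
    o <- order(m$start)
    so <- m[o, ]
    if (any(so$start[-1] < so$end[-nrow(so)])) {
      abort("motion intervals overlap", class = "vbdtw_validation_error")
    }
  }
  invisible(rec)
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat("<sensor_recording> participant", x$participant_id,
      "trial", x$trial_id, "\n")
  cat("  ", nrow(x$data), "samples @", x$sample_rate, "Hz,",
      nrow(x$motions), "labeled motions\n")
  invisible(x)
}

#' @export
tidy.sensor_recording <- function(x, ...) {
  d <- x$data[, intersect(c(sensor_channels(TRUE)), names(x$data))]
  d$sample <- seq_len(nrow(d)) - 1L
  tidyr::pivot_longer(d, -"sample", names_to = "channel",
                      values_to = "value")
}

#' Read a sensor recording from CSV plus a JSON label sidecar
#'
#' The CSV holds one sample per row with a header naming the canonical
#' channels; a leading sample-index column is tolerated and dropped. The
#' sidecar is JSON with fields `participant_id`, `trial_id`, `sample_rate`,
#' and `motions`, a list of `{class, start, end}` records (0-based,
#' half-open).
#'
#' @param path CSV file path.
#' @param sidecar_path JSON sidecar path.
#' @return a [sensor_recording()].
#' @export
read_recording_csv <- function(path, sidecar_path) {
  # parse numbers via strtod (correctly rounded), so values written at
  # full precision round-trip bit-exactly
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  for (nm in names(d)) {
    y <- suppressWarnings(as.double(d[[nm]]))
    if (!anyNA(y) || all(is.na(d[[nm]]))) d[[nm]] <- y
  }
  if (ncol(d) > 0 && names(d)[1] %in% c("sample", "index", "i", "...1")) {
    d <- d[, -1, drop = FALSE]
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  motions <- side$motions
  if (is.null(motions) || length(motions) == 0) {
    motions <- tibble::tibble(class = integer(), start = integer(),
                              end = integer())
  } else {
    motions <- tibble::as_tibble(motions)
  }
  sensor_recording(
    data = d,
    motions = motions,
    participant_id = side$participant_id,
    trial_id = side$trial_id,
    sample_rate = side$sample_rate %||% 100
  )
}

#' Write a sensor recording to CSV plus a JSON label sidecar
#'
#' Values are serialized at full precision so that
#' `read_recording_csv(write_recording_csv(rec))` reproduces the channel
#' arrays bit-exactly.
#'
#' @param rec a [sensor_recording()].
#' @param path CSV destination.
#' @param sidecar_path JSON sidecar destination.
#' @return `rec`, invisibly.
#' @export
write_recording_csv <- function(rec, path, sidecar_path) {
  validate_sensor_recording(rec)
  # 17 significant digits round-trip IEEE doubles exactly
  out <- rec$data
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- sprintf("%.17g", out[[nm]])
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  side <- list(
    participant_id = rec$participant_id,
    trial_id = rec$trial_id,
    sample_rate = rec$sample_rate,
    motions = rec$motions
  )
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(rec)
}

#' Construct a motion sequence
#'
#' One motion's fixed-length multi-channel block (2000 samples at the
#' default 100 Hz x 20 s design), stored samples-in-rows with named channel
#' columns.
#'
#' @param data numeric matrix, samples x channels, with channel colnames.
#' @param motion_class integer class label (1..14 in the standard design;
#'   class 1 is sitting still).
#' @param participant_id,trial_id identifiers.
#' @param truth_valid_slices optional integer vector of ground-truth valid
#'   slice indices (1-based), when known.
#' @return object of class `motion_sequence`.
#' @export
motion_sequence <- function(data, motion_class, participant_id = NA_character_,
                            trial_id = NA_character_,
                            truth_valid_slices = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1) {
    abort("motion data must be a non-empty numeric matrix",
          class = "vbdtw_validation_error")
  }
  structure(
    list(
      motion_class = as.integer(motion_class),
      data = data,
      participant_id = as.character(participant_id),
      trial_id = as.character(trial_id),
      truth_valid_slices = if (is.null(truth_valid_slices)) NULL
                           else sort(unique(as.integer(truth_valid_slices)))
    ),
    class = "motion_sequence"
  )
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat("<motion_sequence> class", x$motion_class, "-", nrow(x$data),
      "samples x", ncol(x$data), "channels\n")
  invisible(x)
}

#' @export
tidy.motion_sequence <- function(x, ...) {
  d <- tibble::as_tibble(x$data)
  d$sample <- seq_len(nrow(d)) - 1L
  out <- tidyr::pivot_longer(d, -"sample", names_to = "channel",
                             values_to = "value")
  out$motion_class <- x$motion_class
  out
}

#' Split a recording into its labeled motion sequences
#'
#' Crops each labeled motion block out of the stream and discards
#' everything else (in particular the leading system-calibration window).
#' Output is always in temporal order regardless of the sidecar's row
#' order. When the motion index carries ground-truth burst boundaries
#' (columns `burst_start`, `burst_end`, sample offsets relative to the
#' motion block) the corresponding slice-index truth is attached.
#'
#' @param rec a [sensor_recording()].
#' @param slice_len slice length used to derive ground-truth slice indices
#'   from burst boundaries, when present (default 50).
#' @return list of [motion_sequence()] objects.
#' @export
split_motions <- function(rec, slice_len = 50) {
  validate_sensor_recording(rec)
  m <- rec$motions
  if (nrow(m) == 0) {
    abort("recording has no labeled motions", class = "vbdtw_validation_error")
  }
  m <- m[order(m$start), ]
  ch <- sensor_channels()
  X <- as.matrix(rec$data[, ch])
  lapply(seq_len(nrow(m)), function(i) {
    block <- X[(m$start[i] + 1):m$end[i], , drop = FALSE]
    truth <- NULL
    if (all(c("burst_start", "burst_end") %in% names(m)) &&
        !is.na(m$burst_start[i]) && m$burst_end[i] > m$burst_start[i]) {
      truth <- burst_truth_slices(m$burst_start[i], m$burst_end[i],
                                  n_samples = nrow(block),
                                  slice_len = slice_len)
    }
    motion_sequence(block, m$class[i], rec$participant_id, rec$trial_id,
                    truth_valid_slices = truth)
  })
}

#' Ground-truth valid slices for a planted burst
#'
#' A slice counts as valid when at least `min_overlap` of its samples fall
#' inside the burst interval; this emulates how a human labeler marks
#' slice-level validity (a slice brushed by a couple of burst samples is
#' not a valid motion slice).
#'
#' @param burst_start,burst_end 0-based half-open sample interval of the
#'   burst within the motion block.
#' @param n_samples motion block length.
#' @param slice_len slice length.
#' @param min_overlap minimum fraction of a slice inside the burst
#'   (default 0.2).
#' @return integer vector of 1-based slice indices.
#' @export
burst_truth_slices <- function(burst_start, burst_end, n_samples = 2000,
                               slice_len = 50, min_overlap = 0.2) {
  n_slices <- n_samples %/% slice_len
  starts <- (seq_len(n_slices) - 1L) * slice_len
  ends <- starts + slice_len
  ov <- pmin(ends, burst_end) - pmax(starts, burst_start)
  which(ov >= min_overlap * slice_len)
}

#' Min-max normalize a motion sequence to [0, 1]
#'
#' Each channel is rescaled independently by its own extrema,
#' `(X - Xmin) / (Xmax - Xmin)`, over this motion sequence. A constant
#' channel (zero range) maps to all zeros with a warning.
#'
#' @param seq a [motion_sequence()] or a plain numeric matrix
#'   (samples x channels).
#' @return same type as the input, values in `[0, 1]`.
#' @export
normalize_minmax <- function(seq) {
  UseMethod("normalize_minmax")
}

#' @export
normalize_minmax.motion_sequence <- function(seq) {
  seq$data <- normalize_minmax(seq$data)
  seq
}

#' @export
normalize_minmax.default <- function(seq) {
  X <- as.matrix(seq)
  if (!all(is.finite(X))) {
    abort("non-finite values in motion data", class = "vbdtw_validation_error")
  }
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  rng <- hi - lo
  flat <- rng == 0
  if (any(flat)) {
    warn(paste0("constant channel(s) mapped to zeros: ",
                paste(colnames(X)[flat] %||% which(flat), collapse = ", ")))
    rng[flat] <- 1
  }
  out <- sweep(sweep(X, 2, lo, "-"), 2, rng, "/")
  out[, flat] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
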