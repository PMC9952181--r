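#' Cut a motion sequence into contiguous equal-length slices
#'
#' The 2000-sample motion block at the default slice length of 50 yields
#' N = 40 slices; adjacent-slice DTW then produces N - 1 = 39 warped-path
#' values.
#'
#' @param seq a [motion_sequence()].
#' @param slice_len slice length in samples (default 50); the motion length
#'   must be divisible by it.
#' @return list of [sensor_slice()] objects in temporal order.
#' @export
slice_motion <- function(seq, slice_len = 50) {
  X <- seq$data
  n <- nrow(X)
  if (slice_len < 1 || n %% slice_len != 0) {
    abort(paste0("motion length ", n, " not divisible by slice length ",
                 slice_len, "; crop first"),
          class = "vbdtw_validation_error")
  }
  n_slices <- n %/% slice_len
  lapply(seq_len(n_slices), function(i) {
    start <- (i - 1L) * slice_len
    sensor_slice(X[(start + 1):(start + slice_len), , drop = FALSE],
                 origin_index = start)
  })
}

#' Construct a DTW profile
#'
#' Holds the N - 1 adjacent-slice warped-path values, the mean threshold,
#' the flagged D-indices, and the resulting valid slice set Sv.
#'
#' @param d_values numeric vector of adjacent-slice DTW costs (may be NULL
#'   for merged profiles).
#' @param threshold mean of `d_values` (NULL for merged profiles).
#' @param flagged integer vector of flagged D-indices (1-based).
#' @param valid_slices integer vector Sv of valid slice indices (1-based).
#' @param n_slices total slice count N.
#' @param channel optional channel name the profile belongs to.
#' @return object of class `dtw_profile`.
#' @export
dtw_profile <- function(d_values, threshold, flagged, valid_slices, n_slices,
                        channel = NA_character_) {
  structure(
    list(d_values = d_values, threshold = threshold,
         flagged = as.integer(flagged),
         valid_slices = as.integer(valid_slices),
         n_slices = as.integer(n_slices), channel = channel),
    class = "dtw_profile"
  )
}

#' @export
print.dtw_profile <- function(x, ...) {
  cat("<dtw_profile>", length(x$d_values), "D values, threshold",
      if (is.null(x$threshold)) "NA" else signif(x$threshold, 4),
      "- Sv:", if (length(x$valid_slices)) paste(x$valid_slices, collapse = " ")
               else "(empty)", "\n")
  invisible(x)
}

#' @export
tidy.dtw_profile <- function(x, ...) {
  if (is.null(x$d_values)) {
    return(tibble::tibble(index = integer(), d = numeric(),
                          flagged = logical()))
  }
  tibble::tibble(
    index = seq_along(x$d_values),
    d = as.numeric(x$d_values),
    flagged = seq_along(x$d_values) %in% x$flagged
  )
}

# Voting stage of the segment extractor, on a precomputed D vector.
# Interior D-indices use a (2r+1)-member window (the index itself plus r
# neighbors each side, truncated at the array ends) and are flagged when at
# least vote_count members exceed the mean threshold; the 2r edge indices
# at each end are compared against the threshold directly.
vote_d_values <- function(d_values, vote_radius = 2, vote_count = 3) {
  n_d <- length(d_values)
  threshold <- mean(d_values)
  interior <- if (n_d >= 2 * vote_radius + 1) {
    seq.int(vote_radius + 1, n_d - vote_radius)
  } else integer(0)
  flagged <- integer(0)
  for (j in seq_len(n_d)) {
    if (j %in% interior) {
      win <- d_values[max(1, j - vote_radius):min(n_d, j + vote_radius)]
      if (sum(win > threshold) >= vote_count) flagged <- c(flagged, j)
    } else {
      if (d_values[j] > threshold) flagged <- c(flagged, j)
    }
  }
  list(threshold = threshold, flagged = flagged,
       valid_slices = sort(unique(c(flagged, flagged + 1L))))
}

#' Voting-based DTW valid-segment extraction
#'
#' The valid-segment extractor: the motion block is cut into N contiguous
#' slices, the DTW warped-path value of every adjacent pair gives
#' D_1..D_{N-1}, their arithmetic mean is the threshold, and a voting
#' window over each interior D-index (the index plus `vote_radius`
#' neighbors on each side, 5 values by default) flags the index when at
#' least `vote_count` members exceed the threshold. Edge D-indices (the
#' first and last `vote_radius` of them) are compared against the
#' threshold directly. The valid slice set is the union of `{j, j+1}` over
#' flagged indices `j`.
#'
#' In `independent` mode the extraction runs per channel and a profile is
#' returned for each; in `dependent` mode the channels are aligned jointly
#' and a single profile is returned.
#'
#' @param seq a [motion_sequence()] (normalize first; see
#'   [normalize_minmax()]).
#' @param slice_len slice length (default 50).
#' @param vote_radius neighbors on each side in the voting window
#'   (default 2).
#' @param vote_count votes required to flag an interior index (default 3).
#' @param mode `"independent"` (per channel, the default) or
#'   `"dependent"`.
#' @return a [dtw_profile()] in dependent mode; a named list of them (class
#'   `dtw_profile_list`, one per channel) in independent mode.
#' @export
vbdtw_extract <- function(seq, slice_len = 50, vote_radius = 2,
                          vote_count = 3,
                          mode = c("independent", "dependent")) {
  mode <- match.arg(mode)
  slices <- slice_motion(seq, slice_len)
  n <- length(slices)
  if (n < 2) {
    abort("need at least 2 slices", class = "vbdtw_validation_error")
  }
  if (mode == "dependent") {
    d <- vapply(seq_len(n - 1), function(i) {
      dtw_distance(slices[[i]], slices[[i + 1]], mode = "dependent")
    }, numeric(1))
    v <- vote_d_values(d, vote_radius, vote_count)
    return(dtw_profile(d, v$threshold, v$flagged, v$valid_slices, n))
  }
  dmat <- vapply(seq_len(n - 1), function(i) {
    dtw_distance(slices[[i]], slices[[i + 1]], mode = "independent")
  }, numeric(ncol(seq$data)))
  dmat <- matrix(dmat, nrow = ncol(seq$data))
  channels <- colnames(seq$data)
  out <- lapply(seq_len(nrow(dmat)), function(c) {
    d <- dmat[c, ]
    v <- vote_d_values(d, vote_radius, vote_count)
    dtw_profile(d, v$threshold, v$flagged, v$valid_slices, n,
                channel = channels[c] %||% as.character(c))
  })
  names(out) <- channels
  structure(out, class = "dtw_profile_list")
}

#' Merge per-channel DTW profiles into one
#'
#' The merged valid slice set is the union over channels; D values and
#' threshold are channel-specific quantities and are carried as absent.
#'
#' @param per_channel list of [dtw_profile()] objects sharing the same N.
#' @return a [dtw_profile()] with `d_values = NULL`.
#' @export
merge_channel_profiles <- function(per_channel) {
  ns <- vapply(per_channel, function(p) p$n_slices, integer(1))
  if (length(unique(ns)) != 1) {
    abort("profiles disagree on slice count N",
          class = "vbdtw_validation_error")
  }
  sv <- sort(unique(unlist(lapply(per_channel, function(p) p$valid_slices))))
  dtw_profile(NULL, NULL, integer(0), sv, ns[1], channel = "merged")
}

#' Uniformly resample a matrix along time to a target length
#'
#' Downsampling takes samples at uniformly spaced (rounded) indices;
#' upsampling interpolates linearly. Equal length is the identity.
#'
#' @param X numeric matrix, samples x channels.
#' @param target_len desired length.
#' @return matrix `target_len` x channels.
#' @export
resample_uniform <- function(X, target_len = 285) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == target_len) return(X)
  if (n > target_len) {
    idx <- round(seq(1, n, length.out = target_len))
    return(X[idx, , drop = FALSE])
  }
  xout <- seq(1, n, length.out = target_len)
  out <- apply(X, 2, function(col) approx(seq_len(n), col, xout)$y)
  matrix(out, nrow = target_len, dimnames = list(NULL, colnames(X)))
}

#' Construct a valid segment
#'
#' @param data numeric matrix, canonical length (285 by default) x
#'   channels.
#' @param motion_class integer class label.
#' @param source_slices slice indices the segment was assembled from.
#' @param participant_id,trial_id identifiers.
#' @return object of class `valid_segment`.
#' @export
valid_segment <- function(data, motion_class, source_slices = integer(0),
                          participant_id = NA_character_,
                          trial_id = NA_character_) {
  structure(
    list(data = as.matrix(data), motion_class = as.integer(motion_class),
         source_slices = as.integer(source_slices),
         participant_id = as.character(participant_id),
         trial_id = as.character(trial_id)),
    class = "valid_segment"
  )
}

#' @export
print.valid_segment <- function(x, ...) {
  cat("<valid_segment> class", x$motion_class, "-", nrow(x$data), "x",
      ncol(x$data), "from", length(x$source_slices), "slices\n")
  invisible(x)
}

#' Extract and canonicalize the valid segment of a motion
#'
#' Concatenates the samples of the valid slices in temporal order, then
#' resamples to exactly `target_len`. Sitting still (class 1) is valid
#' throughout, so the whole sequence is resampled directly. For any other
#' motion with an empty valid slice set the whole sequence is used as a
#' fallback, with a warning, so no labeled motion is ever dropped.
#'
#' @param seq the [motion_sequence()] the profile was computed from.
#' @param profile a [dtw_profile()], or the per-channel list returned by
#'   [vbdtw_extract()] in independent mode (merged by union internally).
#' @param target_len canonical segment length (default 285).
#' @param slice_len slice length the profile was computed at (default 50).
#' @param sitting_still_class class treated as valid throughout
#'   (default 1).
#' @return a [valid_segment()].
#' @export
extract_valid_segment <- function(seq, profile, target_len = 285,
                                  slice_len = 50, sitting_still_class = 1L) {
  if (inherits(profile, "dtw_profile_list")) {
    profile <- merge_channel_profiles(profile)
  }
  sv <- profile$valid_slices
  X <- seq$data
  if (seq$motion_class == sitting_still_class) {
    data <- resample_uniform(X, target_len)
    sv_used <- seq_len(nrow(X) %/% slice_len)
  } else if (length(sv) == 0) {
    warn(paste0("empty valid slice set for motion class ", seq$motion_class,
                "; falling back to whole-sequence resampling"))
    data <- resample_uniform(X, target_len)
    sv_used <- integer(0)
  } else {
    rows <- unlist(lapply(sv, function(i) {
      ((i - 1L) * slice_len + 1L):(i * slice_len)
    }))
    data <- resample_uniform(X[rows, , drop = FALSE], target_len)
    sv_used <- sv
  }
  valid_segment(data, seq$motion_class, sv_used,
                seq$participant_id, seq$trial_id)
}

#' Run VB-DTW end-to-end on one motion sequence
#'
#' Convenience wrapper: min-max normalization, per-channel (or joint)
#' extraction, channel-union merge, and canonical-length resampling.
#'
#' @inheritParams vbdtw_extract
#' @inheritParams extract_valid_segment
#' @param normalize min-max normalize first (default TRUE).
#' @return list with elements `profiles` (per-channel or single profile),
#'   `merged` ([dtw_profile()]), and `segment` ([valid_segment()]).
#' @export
vbdtw_segment_motion <- function(seq, slice_len = 50, vote_radius = 2,
                                 vote_count = 3,
                                 mode = c("independent", "dependent"),
                                 target_len = 285, normalize = TRUE,
                                 sitting_still_class = 1L) {
  mode <- match.arg(mode)
  if (normalize) seq <- suppressWarnings(normalize_minmax(seq))
  if (seq$motion_class == sitting_still_class) {
    segment <- extract_valid_segment(seq, dtw_profile(NULL, NULL, integer(0),
                                                      integer(0),
                                                      nrow(seq$data) %/% slice_len),
                                     target_len, slice_len,
                                     sitting_still_class)
    return(list(profiles = NULL, merged = NULL, segment = segment))
  }
  profiles <- vbdtw_extract(seq, slice_len, vote_radius, vote_count, mode)
  merged <- if (inherits(profiles, "dtw_profile_list")) {
    merge_channel_profiles(profiles)
  } else profiles
  segment <- suppressWarnings(
    extract_valid_segment(seq, merged, target_len, slice_len,
                          sitting_still_class)
  )
  list(profiles = profiles, merged = merged, segment = segment)
}
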