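#' Jaccard index of two index sets
#'
#' `|A intersect B| / |A union B|`, the standard overlap score between an
#' extracted valid-slice index set and a benchmark set. Two empty sets are
#' scored 1 (vacuous perfect agreement) with a warning.
#'
#' @param a,b finite index vectors (duplicates ignored).
#' @return numeric in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    warn("both index sets empty; Jaccard defined as 1")
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Per-channel Jaccard report for one motion
#'
#' Scores each channel's extracted valid-slice set against the benchmark
#' and averages over the six motion channels.
#'
#' @param profiles per-channel profile list from [vbdtw_extract()]
#'   (independent mode).
#' @param benchmark integer vector of benchmark (ground-truth) slice
#'   indices.
#' @param motion_class class label carried into the report.
#' @return tibble with one row per channel plus the per-motion mean in the
#'   `mean_jaccard` column (repeated), columns `motion_class`, `channel`,
#'   `jaccard`, `mean_jaccard`.
#' @export
jaccard_report <- function(profiles, benchmark, motion_class = NA_integer_) {
  js <- vapply(profiles, function(p) {
    suppressWarnings(jaccard(p$valid_slices, benchmark))
  }, numeric(1))
  tibble::tibble(
    motion_class = as.integer(motion_class),
    channel = names(js),
    jaccard = as.numeric(js),
    mean_jaccard = mean(js)
  )
}

#' Segmentation study over a set of recordings
#'
#' Runs per-channel VB-DTW extraction on every non-sitting-still motion of
#' every recording, scores each channel against the ground-truth slice
#' indices, and averages: first over the six channels within a motion,
#' then over recordings within a class.
#'
#' @param recordings list of [sensor_recording()] objects whose motion
#'   index carries ground-truth burst boundaries (see the simulator).
#' @param slice_len,vote_radius,vote_count extractor settings.
#' @return tibble with columns `motion_class`, `mean_jaccard`, `n_motions`.
#' @export
segmentation_study <- function(recordings, slice_len = 50, vote_radius = 2,
                               vote_count = 3) {
  rows <- purrr::map_dfr(recordings, function(rec) {
    motions <- split_motions(rec, slice_len = slice_len)
    purrr::map_dfr(motions, function(seq) {
      if (seq$motion_class == 1L || is.null(seq$truth_valid_slices)) {
        return(NULL)
      }
      nrm <- suppressWarnings(normalize_minmax(seq))
      profs <- vbdtw_extract(nrm, slice_len, vote_radius, vote_count,
                             mode = "independent")
      rep <- jaccard_report(profs, seq$truth_valid_slices, seq$motion_class)
      tibble::tibble(motion_class = seq$motion_class,
                     motion_jaccard = rep$mean_jaccard[1])
    })
  })
  dplyr::summarise(dplyr::group_by(rows, .data$motion_class),
                   mean_jaccard = mean(.data$motion_jaccard),
                   n_motions = dplyr::n(), .groups = "drop")
}

#' Segment-level classification accuracy
#'
#' The proportion `a / m` of segments whose majority-voted label matches
#' the truth; equals the mean of per-segment 0/1 correctness.
#'
#' @param truth,predicted equal-length class vectors.
#' @return numeric in `[0, 1]`.
#' @export
segment_accuracy <- function(truth, predicted) {
  if (length(truth) == 0 || length(truth) != length(predicted)) {
    abort("truth/prediction length mismatch or empty",
          class = "vbdtw_validation_error")
  }
  mean(truth == predicted)
}
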