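#' Construct a slice of a motion sequence
#'
#' @param data numeric matrix, samples x channels (default slice length 50).
#' @param origin_index 0-based sample position of the slice in its parent
#'   motion sequence.
#' @return object of class `sensor_slice`.
#' @export
sensor_slice <- function(data, origin_index = 0L) {
  data <- as.matrix(data)
  if (nrow(data) < 1) {
    abort("empty slice", class = "vbdtw_validation_error")
  }
  structure(list(data = data, origin_index = as.integer(origin_index)),
            class = "sensor_slice")
}

slice_data <- function(x) {
  if (inherits(x, "sensor_slice")) x$data else as.matrix(x)
}

#' Dynamic time warping distance between two slices
#'
#' Classic boundary-anchored DTW with the unweighted step set
#' (match, insert, delete) and no warping-window constraint; the returned
#' value is the raw cumulative cost of the minimum warped path (no path
#' normalization, since downstream thresholds compare equal-length slices
#' against their own mean).
#'
#' Two channel treatments are offered: `independent` computes one DTW per
#' channel with absolute-difference local cost and returns a named vector;
#' `dependent` aligns all channels jointly with Euclidean local cost and
#' returns a scalar.
#'
#' @param a,b [sensor_slice()] objects or numeric matrices/vectors with the
#'   same channel count.
#' @param mode `"independent"` (per channel) or `"dependent"`
#'   (multivariate).
#' @return non-negative numeric; per-channel vector in independent mode.
#' @export
dtw_distance <- function(a, b, mode = c("independent", "dependent")) {
  mode <- match.arg(mode)
  A <- slice_data(a)
  B <- slice_data(b)
  if (is.null(dim(A))) A <- matrix(A, ncol = 1)
  if (is.null(dim(B))) B <- matrix(B, ncol = 1)
  if (nrow(A) < 1 || nrow(B) < 1) {
    abort("empty slice", class = "vbdtw_validation_error")
  }
  if (ncol(A) != ncol(B)) {
    abort("channel count mismatch", class = "vbdtw_validation_error")
  }
  if (mode == "dependent") {
    return(.dtw_cost_cpp(A, B, TRUE))
  }
  out <- vapply(seq_len(ncol(A)), function(c) {
    .dtw_cost_cpp(A[, c, drop = FALSE], B[, c, drop = FALSE], FALSE)
  }, numeric(1))
  names(out) <- colnames(A)
  out
}
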