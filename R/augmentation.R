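#' Window-slicing augmentation of a valid segment
#'
#' Cuts a length-n segment into `n - s + 1` stride-1 sliding windows of
#' length `s`, each inheriting the parent's label. At the default segment
#' length 285 and window length 256 (about 90% of the parent) this yields
#' 30 windows per segment.
#'
#' @param seg a [valid_segment()] or numeric matrix (samples x channels).
#' @param s window length (default 256); must not exceed the parent
#'   length.
#' @param stride window stride (default, and the standard setting, 1).
#' @return object of class `augmented_set` with fields `windows` (3-D
#'   array: window x sample x channel), `starts` (0-based window offsets),
#'   `label`, `parent_id`, `s`.
#' @export
window_slice <- function(seg, s = 256, stride = 1) {
  if (inherits(seg, "valid_segment")) {
    X <- seg$data
    label <- seg$motion_class
    parent_id <- paste(seg$participant_id, seg$trial_id, seg$motion_class,
                       sep = "/")
  } else {
    X <- as.matrix(seg)
    label <- NA_integer_
    parent_id <- NA_character_
  }
  n <- nrow(X)
  if (s > n || s < 1) {
    abort(paste0("window length ", s, " invalid for parent length ", n),
          class = "vbdtw_validation_error")
  }
  starts <- seq.int(0L, n - s, by = stride)
  W <- array(NA_real_, dim = c(length(starts), s, ncol(X)),
             dimnames = list(NULL, NULL, colnames(X)))
  for (k in seq_along(starts)) {
    W[k, , ] <- X[(starts[k] + 1):(starts[k] + s), ]
  }
  structure(
    list(windows = W, starts = starts, label = label,
         parent_id = parent_id, s = as.integer(s)),
    class = "augmented_set"
  )
}

#' @export
print.augmented_set <- function(x, ...) {
  cat("<augmented_set>", dim(x$windows)[1], "windows of length", x$s,
      "- label", x$label, "\n")
  invisible(x)
}

#' Majority vote over per-window predictions
#'
#' Returns the modal predicted class over a segment's windows. Ties are
#' broken by the higher summed score, then by the lower class index.
#' The result is invariant to the order of the predictions.
#'
#' @param window_predictions data frame with columns `class` and `score`
#'   (e.g. the predicted class and its probability per window).
#' @return the winning class (integer).
#' @export
majority_vote <- function(window_predictions) {
  wp <- as.data.frame(window_predictions)
  if (nrow(wp) == 0) {
    abort("no window predictions to vote over",
          class = "vbdtw_validation_error")
  }
  if (is.null(wp$score)) wp$score <- 1
  agg <- stats::aggregate(score ~ class, data = wp,
                          FUN = function(z) c(n = length(z), s = sum(z)))
  counts <- agg$score[, "n"]
  scores <- agg$score[, "s"]
  cls <- agg$class
  ord <- order(-counts, -scores, cls)
  as.integer(cls[ord[1]])
}
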