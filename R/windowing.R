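#' Segment a recording into fixed-length sliding windows
#'
#' Windows of `window_ms` milliseconds are taken at offsets 0, S, 2S, ...
#' samples, where `S` is the stride in samples; the trailing partial window
#' is dropped, giving `floor((n_samples - W) / S) + 1` windows. Each window
#' receives one class label and one repetition index by majority vote over
#' its samples (see [assign_label()]). Windows are allowed to straddle
#' movement/rest transitions; set `strict = TRUE` to drop windows whose
#' sample labels are not unanimous.
#'
#' @param recording An [emg_recording()].
#' @param window_ms Window length in milliseconds.
#' @param stride_ms Stride in milliseconds (must not exceed `window_ms`).
#' @param channel_index Integer vector of source channel columns to keep
#'   (default all).
#' @param strict Drop windows with non-unanimous sample labels.
#' @return An object of class `emg_windows` with fields `windows`
#'   (`n_windows x window_len x n_channels` array), `labels`, `repetitions`,
#'   `starts` (0-based sample offsets), `window_ms`, `stride_ms`, `fs`,
#'   `channel_index`.
#' @export
segment <- function(recording, window_ms, stride_ms,
                    channel_index = NULL, strict = FALSE) {
  stopifnot(inherits(recording, "emg_recording"))
  fs <- recording$fs
  wl <- as.integer(round(fs * window_ms / 1000))
  ss <- as.integer(round(fs * stride_ms / 1000))
  if (ss < 1L) emg_input_error("stride must be at least one sample")
  if (wl < ss) emg_input_error("window must be at least as long as the stride")
  nch_all <- ncol(recording$emg)
  channel_index <- if (is.null(channel_index)) seq_len(nch_all)
                   else as.integer(channel_index)
  if (any(channel_index < 1L) || any(channel_index > nch_all))
    emg_input_error("channel_index out of range")

  n <- nrow(recording$emg)
  if (n < wl) {
    warning("recording shorter than one window; returning empty window set")
    starts <- integer(0)
  } else {
    starts <- seq.int(0L, n - wl, by = ss)
  }
  nw <- length(starts)
  nch <- length(channel_index)

  windows <- array(0, dim = c(nw, wl, nch))
  labels <- integer(nw)
  repetitions <- integer(nw)
  emg <- recording$emg[, channel_index, drop = FALSE]
  for (i in seq_len(nw)) {
    idx <- starts[i] + seq_len(wl)
    windows[i, , ] <- emg[idx, ]
    labels[i] <- assign_label(recording$stimulus[idx])
    repetitions[i] <- assign_label(recording$repetition[idx])
  }

  keep <- rep(TRUE, nw)
  if (strict && nw > 0L) {
    for (i in seq_len(nw)) {
      idx <- starts[i] + seq_len(wl)
      keep[i] <- length(unique(recording$stimulus[idx])) == 1L
    }
  }

  structure(
    list(windows = windows[keep, , , drop = FALSE],
         labels = labels[keep], repetitions = repetitions[keep],
         starts = starts[keep],
         window_ms = window_ms, stride_ms = stride_ms, fs = fs,
         channel_index = channel_index),
    class = "emg_windows")
}

#' @export
print.emg_windows <- function(x, ...) {
  cat(sprintf("sEMG window set: %d windows x %d samples x %d channels (%g/%g ms @ %g Hz)\n",
              dim(x$windows)[1], dim(x$windows)[2], dim(x$windows)[3],
              x$window_ms, x$stride_ms, x$fs))
  if (length(x$labels))
    cat("  classes:", paste(sort(unique(x$labels)), collapse = " "), "\n")
  invisible(x)
}

#' Majority label for a window of per-sample labels
#'
#' Returns the modal label. Ties are broken in favour of 0 (rest) when 0 is
#' among the tied labels — conservative towards predicting no movement —
#' and otherwise towards the smallest class index.
#'
#' @param sample_labels Non-empty integer vector.
#' @return A single integer label.
#' @export
assign_label <- function(sample_labels) {
  if (length(sample_labels) == 0L) emg_input_error("empty label sequence")
  tab <- table(sample_labels)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (0L %in% top) 0L else min(top)
}

#' Split a window set by repetition index
#'
#' Movement windows are routed by their repetition index. Rest windows
#' (repetition 0) are routed by the repetition of the nearest preceding
#' movement window, so the rest following repetition r travels with
#' repetition r; rest before any movement defaults to the training split.
#' Windows whose routing repetition is in neither set are dropped.
#'
#' @param ws An `emg_windows` object.
#' @param train_reps,test_reps Disjoint integer sets of repetition indices.
#' @return A list with elements `train` and `test`, both `emg_windows`.
#' @export
split_by_repetition <- function(ws, train_reps = c(1, 3, 4, 6),
                                test_reps = c(2, 5)) {
  stopifnot(inherits(ws, "emg_windows"))
  train_reps <- as.integer(train_reps); test_reps <- as.integer(test_reps)
  if (length(intersect(train_reps, test_reps)))
    emg_config_error("train and test repetition sets overlap")

  routing <- ws$repetitions
  last <- NA_integer_
  for (i in seq_along(routing)) {
    if (routing[i] > 0L) last <- routing[i]
    else routing[i] <- if (is.na(last)) -1L else last  # -1: leading rest
  }
  in_train <- routing %in% train_reps |
    (routing == -1L & length(train_reps) > 0L)
  in_test <- routing %in% test_reps
  list(train = subset_windows(ws, which(in_train)),
       test = subset_windows(ws, which(in_test)))
}

subset_windows <- function(ws, idx) {
  structure(
    list(windows = ws$windows[idx, , , drop = FALSE],
         labels = ws$labels[idx], repetitions = ws$repetitions[idx],
         starts = ws$starts[idx],
         window_ms = ws$window_ms, stride_ms = ws$stride_ms, fs = ws$fs,
         channel_index = ws$channel_index),
    class = "emg_windows")
}

#' Keep only windows from a subset of movement classes
#'
#' @param ws An `emg_windows` object.
#' @param keep Non-empty set of movement class labels to retain.
#' @param include_rest Also retain rest (label 0) windows (default TRUE).
#' @return An `emg_windows` with windows in their original order.
#' @export
filter_movements <- function(ws, keep, include_rest = TRUE) {
  stopifnot(inherits(ws, "emg_windows"))
  if (length(keep) == 0L) emg_input_error("'keep' must be non-empty")
  keep <- as.integer(keep)
  if (include_rest) keep <- union(keep, 0L)
  subset_windows(ws, which(ws$labels %in% keep))
}

#' The six SHAP prehensile-pattern movement classes
#'
#' Ninapro movement classes representing the six Southampton Hand Assessment
#' Procedure patterns: power sphere (27, spherical), writing tripod (26,
#' tripod), prismatic pinch (31, tip), large diameter (18, power), lateral
#' (34) and extension type (36) grasps.
#'
#' @return Integer vector of class labels.
#' @export
shap_classes <- function() c(27L, 26L, 31L, 18L, 34L, 36L)
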