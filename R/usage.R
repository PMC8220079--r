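#' Simulate continuous use over an uncut recording
#'
#' Slides the model across the full signal — rest, movements and the
#' transitions between them — predicting one class per window, exactly as a
#' prosthesis controller would at run time. Labels are used only to annotate
#' the per-window majority truth, never for prediction. An optional
#' majority-vote smoother over the last `smooth_k` predictions can be
#' enabled (off by default).
#'
#' @param model An [emg_dnn()] model.
#' @param recording An [emg_recording()] covering the period to simulate.
#' @param window_ms,stride_ms Windowing parameters; the model's feature
#'   dimension must equal `6 * n_channels` of the recording.
#' @param threshold Noise threshold for feature extraction.
#' @param channel_index Channels to use (default all).
#' @param smooth_k Majority vote over the last `smooth_k` raw predictions
#'   (1 = no smoothing).
#' @return An object of class `emg_usage_trace`: `window_start_s`
#'   (strictly increasing by `stride_ms / 1000`), `predicted`, `truth`,
#'   `movement_spans` (data.frame of class, start, end window indices),
#'   `window_ms`, `stride_ms`.
#' @export
simulate_usage <- function(model, recording, window_ms = 200, stride_ms = 100,
                           threshold = 0.01, channel_index = NULL,
                           smooth_k = 1L) {
  stopifnot(inherits(model, "emg_dnn"), inherits(recording, "emg_recording"))
  ws <- segment(recording, window_ms, stride_ms, channel_index)
  if (dim(ws$windows)[3] * 6L != model$spec$n_features)
    emg_input_error(sprintf(
      "model expects %d features but recording yields %d channels x 6",
      model$spec$n_features, dim(ws$windows)[3]))
  feats <- extract_features(ws, threshold)
  predicted <- predict(model, feats)
  if (smooth_k > 1L && length(predicted)) {
    raw <- predicted
    for (i in seq_along(raw)) {
      lo <- max(1L, i - smooth_k + 1L)
      predicted[i] <- assign_label(raw[lo:i])
    }
  }
  truth <- ws$labels

  spans <- locate_spans(truth)
  structure(
    list(window_start_s = ws$starts / ws$fs,
         predicted = predicted, truth = truth,
         movement_spans = spans,
         window_ms = window_ms, stride_ms = stride_ms),
    class = "emg_usage_trace")
}

# Runs of constant non-rest truth, as (class, start, end) window indices.
locate_spans <- function(truth) {
  if (!length(truth))
    return(data.frame(class = integer(0), start = integer(0), end = integer(0)))
  r <- rle(truth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  data.frame(class = r$values[keep], start = starts[keep], end = ends[keep])
}

#' @export
print.emg_usage_trace <- function(x, ...) {
  cat(sprintf("Usage trace: %d windows (%g/%g ms), %d movement spans\n",
              length(x$predicted), x$window_ms, x$stride_ms,
              nrow(x$movement_spans)))
  cat(sprintf("  window-level agreement %.1f %%\n",
              100 * mean(x$predicted == x$truth)))
  invisible(x)
}

#' Prediction-continuity statistics of a usage trace
#'
#' Within each span of constant non-rest truth, the first and last
#' `margin_windows` windows are treated as transitional (errors there are
#' expected while the hand moves between rest and the posture); wrong
#' predictions strictly inside the remaining interior are the ones that
#' would interrupt the user's movement. The default margin of 2 windows
#' allows one window of boundary context plus one for the lag of the
#' majority truth label.
#'
#' @param trace An `emg_usage_trace` from [simulate_usage()].
#' @param margin_windows Windows excluded at each span end (>= 0).
#' @return An object of class `emg_continuity`: `mid_movement_errors`,
#'   `interior_windows`, `transition_errors`, `transition_windows`,
#'   `longest_correct_run` (windows), `per_span` (data.frame).
#' @export
continuity_stats <- function(trace, margin_windows = 2L) {
  stopifnot(inherits(trace, "emg_usage_trace"))
  if (margin_windows < 0L) emg_input_error("margin_windows must be >= 0")
  spans <- trace$movement_spans
  mid_err <- 0L; interior_n <- 0L; trans_err <- 0L; trans_n <- 0L
  longest <- 0L
  per_span <- vector("list", nrow(spans))
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]; cls <- spans$class[i]
    ilo <- s + margin_windows; ihi <- e - margin_windows
    margin_idx <- setdiff(seq(s, e), if (ilo <= ihi) seq(ilo, ihi) else integer(0))
    trans_n <- trans_n + length(margin_idx)
    trans_err <- trans_err + sum(trace$predicted[margin_idx] != cls)
    run <- 0L; span_err <- 0L; span_longest <- 0L; span_int <- 0L
    if (ilo <= ihi) {
      for (k in ilo:ihi) {
        span_int <- span_int + 1L
        if (trace$predicted[k] == cls) {
          run <- run + 1L
          span_longest <- max(span_longest, run)
        } else {
          span_err <- span_err + 1L
          run <- 0L
        }
      }
    }
    mid_err <- mid_err + span_err
    interior_n <- interior_n + span_int
    longest <- max(longest, span_longest)
    per_span[[i]] <- data.frame(class = cls, start = s, end = e,
                                interior = span_int, mid_errors = span_err,
                                longest_run = span_longest)
  }
  structure(
    list(mid_movement_errors = mid_err, interior_windows = interior_n,
         transition_errors = trans_err, transition_windows = trans_n,
         longest_correct_run = longest,
         per_span = do.call(rbind, per_span) %||%
           data.frame(class = integer(0), start = integer(0), end = integer(0),
                      interior = integer(0), mid_errors = integer(0),
                      longest_run = integer(0))),
    class = "emg_continuity")
}

#' @export
print.emg_continuity <- function(x, ...) {
  cat(sprintf("Continuity: %d/%d mid-movement errors (%.1f %%), longest correct run %d windows\n",
              x$mid_movement_errors, x$interior_windows,
              if (x$interior_windows > 0)
                100 * x$mid_movement_errors / x$interior_windows else 0,
              x$longest_correct_run))
  cat(sprintf("  %d/%d errors in transition margins\n",
              x$transition_errors, x$transition_windows))
  invisible(x)
}

#' Export a usage trace as CSV
#'
#' Columns: `time_s`, `truth`, `predicted`.
#'
#' @param trace An `emg_usage_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_usage_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$window_start_s,
                              truth = trace$truth,
                              predicted = trace$predicted),
                   path, row.names = FALSE)
  invisible(path)
}
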