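#' Construct an sEMG recording object
#'
#' A recording bundles a multichannel sEMG sample matrix with per-sample
#' movement labels (`stimulus`, 0 = rest), per-sample repetition indices
#' (`repetition`, 0 during rest) and the sampling rate, mirroring the layout
#' of Ninapro database files.
#'
#' @param emg Numeric matrix, `n_samples x n_channels`, raw amplitude units.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param stimulus Integer vector of per-sample movement labels, length
#'   `n_samples`; 0 denotes rest.
#' @param repetition Integer vector of per-sample repetition indices, length
#'   `n_samples`; 0 denotes rest between repetitions.
#' @param subject_id,exercise_id Free-form identifiers.
#' @param source_tag Free text describing provenance, e.g. `"DB5"`, `"DB7"`
#'   or `"synthetic"`.
#' @param label_source Which label dialect the values came from
#'   (`"stimulus"` or `"restimulus"`); recorded for provenance.
#'
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(emg, fs, stimulus, repetition,
                          subject_id = "S1", exercise_id = "E1",
                          source_tag = "unknown", label_source = "stimulus") {
  emg <- as.matrix(emg)
  storage.mode(emg) <- "double"
  stimulus <- as.integer(stimulus)
  repetition <- as.integer(repetition)

  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    emg_format_error("sampling rate 'fs' must be a single positive number")
  if (ncol(emg) < 1L)
    emg_format_error("recording must have at least one channel")
  if (length(stimulus) != nrow(emg) || length(repetition) != nrow(emg))
    emg_alignment_error(sprintf(
      "label vectors (stimulus %d, repetition %d) must match emg rows (%d)",
      length(stimulus), length(repetition), nrow(emg)))
  if (anyNA(stimulus) || anyNA(repetition) ||
      any(stimulus < 0L) || any(repetition < 0L))
    emg_data_error("stimulus and repetition must be non-negative integers")
  if (any(!is.finite(emg)))
    emg_data_error("emg matrix contains non-finite values")

  structure(
    list(emg = emg, fs = as.numeric(fs), stimulus = stimulus,
         repetition = repetition, subject_id = as.character(subject_id),
         exercise_id = as.character(exercise_id),
         source_tag = as.character(source_tag),
         label_source = as.character(label_source)),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cl <- sort(unique(x$stimulus[x$stimulus > 0L]))
  cat(sprintf("sEMG recording [%s / %s, %s]\n",
              x$subject_id, x$exercise_id, x$source_tag))
  cat(sprintf("  %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$emg), ncol(x$emg), x$fs, nrow(x$emg) / x$fs))
  cat(sprintf("  %d movement classes, repetitions %s, rest fraction %.2f\n",
              length(cl),
              paste(range(x$repetition[x$repetition > 0L]), collapse = "-"),
              mean(x$stimulus == 0L)))
  invisible(x)
}

#' @export
summary.emg_recording <- function(object, ...) {
  tab <- table(movement = object$stimulus)
  out <- list(
    n_samples = nrow(object$emg), n_channels = ncol(object$emg),
    fs = object$fs, duration_s = nrow(object$emg) / object$fs,
    classes = sort(unique(object$stimulus)),
    samples_per_class = tab,
    rest_fraction = mean(object$stimulus == 0L))
  class(out) <- "summary.emg_recording"
  out
}

#' @export
print.summary.emg_recording <- function(x, ...) {
  cat(sprintf("%d samples, %d channels, %g Hz, %.1f s, rest fraction %.3f\n",
              x$n_samples, x$n_channels, x$fs, x$duration_s, x$rest_fraction))
  print(x$samples_per_class)
  invisible(x)
}
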