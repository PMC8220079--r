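#' Zero crossings with a noise threshold
#'
#' Counts adjacent sample pairs that cross zero with an amplitude change of
#' at least `T`: pair (k, k+1) counts when `x_k < 0 < x_{k+1}` or
#' `x_k > 0 > x_{k+1}` (strict inequalities, so exact zeros never cross) and
#' `|x_k - x_{k+1}| >= T`. The threshold excludes crossings caused by
#' low-amplitude noise.
#'
#' @param x Numeric vector (single-channel window), length >= 2.
#' @param T Non-negative noise threshold, in the signal's amplitude units.
#' @return Integer count in `[0, length(x) - 1]`.
#' @export
zero_crossings <- function(x, T = 0) {
  if (length(x) < 2L) emg_input_error("zero_crossings needs at least 2 samples")
  if (T < 0) emg_input_error("threshold must be non-negative")
  a <- x[-length(x)]; b <- x[-1L]
  sum(((a < 0 & b > 0) | (a > 0 & b < 0)) & abs(a - b) >= T)
}

#' Slope sign changes with a noise threshold
#'
#' Counts interior samples that are strict local extrema
#' (`x_k > x_{k-1} and x_k > x_{k+1}`, or both reversed) where the amplitude
#' change to at least one neighbour is `>= T`.
#'
#' @param x Numeric vector (single-channel window), length >= 3.
#' @param T Non-negative noise threshold.
#' @return Integer count in `[0, length(x) - 2]`.
#' @export
slope_sign_changes <- function(x, T = 0) {
  if (length(x) < 3L) emg_input_error("slope_sign_changes needs at least 3 samples")
  if (T < 0) emg_input_error("threshold must be non-negative")
  n <- length(x)
  prev <- x[1:(n - 2L)]; mid <- x[2:(n - 1L)]; nxt <- x[3:n]
  extremum <- (mid > prev & mid > nxt) | (mid < prev & mid < nxt)
  sum(extremum & (abs(mid - nxt) >= T | abs(mid - prev) >= T))
}

#' Amplitude-based time-domain features of one window
#'
#' Computes the four amplitude features of the Hudgins time-domain set:
#' root mean square `rms = sqrt(mean(x^2))`, mean absolute value
#' `mav = mean(|x|)`, waveform length `wl = sum(|x_{k+1} - x_k|)`, and mean
#' absolute value slope `mavs`, the difference between the MAVs of adjacent
#' equal sub-segments of the window (default two halves, giving one value).
#'
#' @param x Numeric vector, length >= 2.
#' @param n_segments Number of equal sub-segments for the MAV slope
#'   (default 2; the returned `mavs` is the mean of adjacent-segment MAV
#'   differences, so dimensionality stays fixed for any segment count).
#' @return Named numeric vector `c(rms, mav, mavs, wl)`.
#' @export
amplitude_features <- function(x, n_segments = 2L) {
  if (length(x) < 2L) emg_input_error("amplitude_features needs at least 2 samples")
  if (n_segments < 2L || n_segments > length(x))
    emg_input_error("n_segments must be in [2, length(x)]")
  rms <- sqrt(mean(x^2))
  mav <- mean(abs(x))
  wl <- sum(abs(diff(x)))
  seg <- split(x, cut(seq_along(x), n_segments, labels = FALSE))
  mavseg <- vapply(seg, function(s) mean(abs(s)), numeric(1))
  mavs <- mean(diff(mavseg))
  c(rms = rms, mav = mav, mavs = mavs, wl = wl)
}

#' Extract the six time-domain features from every window
#'
#' For each channel, in order: RMS, MAV, MAV slope, zero crossings, slope
#' sign changes, waveform length; columns are named `<feature>_ch<j>`.
#' Row order matches the window set.
#'
#' @param ws An `emg_windows` object (see [segment()]).
#' @param T Noise threshold applied to zero crossings and slope sign
#'   changes (see [default_threshold()] for per-dataset defaults).
#' @param n_segments Sub-segment count for the MAV slope.
#' @return An object of class `emg_features`: list with `values`
#'   (`n_windows x (6 * n_channels)` matrix with column names), `labels`,
#'   `repetitions`, `threshold_used`.
#' @export
extract_features <- function(ws, T = 0.01, n_segments = 2L) {
  stopifnot(inherits(ws, "emg_windows"))
  nw <- dim(ws$windows)[1]
  wl <- dim(ws$windows)[2]
  nch <- dim(ws$windows)[3]
  if (wl < 3L) emg_input_error("windows must have at least 3 samples for the full feature set")
  feat_names <- c("rms", "mav", "mavs", "zc", "ssc", "wl")
  cols <- as.vector(vapply(seq_len(nch),
                           function(ch) paste0(feat_names, "_ch", ch),
                           character(6)))
  values <- matrix(0, nw, 6L * nch, dimnames = list(NULL, cols))
  for (ch in seq_len(nch)) {
    block <- ws$windows[, , ch, drop = FALSE]
    dim(block) <- c(nw, wl)
    off <- (ch - 1L) * 6L
    for (i in seq_len(nw)) {
      x <- block[i, ]
      af <- amplitude_features(x, n_segments)
      values[i, off + 1L] <- af[["rms"]]
      values[i, off + 2L] <- af[["mav"]]
      values[i, off + 3L] <- af[["mavs"]]
      values[i, off + 4L] <- zero_crossings(x, T)
      values[i, off + 5L] <- slope_sign_changes(x, T)
      values[i, off + 6L] <- af[["wl"]]
    }
  }
  feature_table(values, ws$labels, ws$repetitions, threshold_used = T)
}

#' Construct a feature table
#'
#' @param values Numeric matrix `n_windows x n_features` with unique column
#'   names.
#' @param labels,repetitions Per-row integer vectors.
#' @param threshold_used Noise threshold recorded for provenance.
#' @return An object of class `emg_features`.
#' @export
feature_table <- function(values, labels, repetitions, threshold_used = NA_real_) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    emg_format_error("feature columns must have unique names")
  if (nrow(values) != length(labels) || nrow(values) != length(repetitions))
    emg_alignment_error("labels/repetitions must match feature rows")
  if (nrow(values) > 0 && any(!is.finite(values)))
    emg_data_error("feature values must be finite")
  structure(list(values = values, labels = as.integer(labels),
                 repetitions = as.integer(repetitions),
                 threshold_used = threshold_used),
            class = "emg_features")
}

#' @export
print.emg_features <- function(x, ...) {
  cat(sprintf("sEMG feature table: %d windows x %d features (threshold %g)\n",
              nrow(x$values), ncol(x$values), x$threshold_used))
  if (length(x$labels))
    cat("  classes:", paste(sort(unique(x$labels)), collapse = " "), "\n")
  invisible(x)
}

#' Default noise threshold per dataset tag
#'
#' `0.01` (amplitude units as stored) for DB5-style Myo data; `1e-8` for the
#' DB7 intact group and `1e-6` for the DB7 amputee group, the grid-search
#' optima for those groups. Always overridable wherever a threshold is
#' accepted.
#'
#' @param source_tag One of `"DB5"`, `"DB7"`, `"DB7-amputee"`.
#' @return Threshold value.
#' @export
default_threshold <- function(source_tag) {
  switch(source_tag,
         "DB5" = 0.01,
         "DB7" = 1e-8,
         "DB7-amputee" = 1e-6,
         emg_config_error(sprintf("no default threshold for source tag '%s'", source_tag)))
}

#' Fit column standardization parameters on a training table
#'
#' Means and standard deviations (population estimator, dividing by n) of
#' every feature column, computed from the training split only. Columns with
#' zero variance are flagged; they are centred but not scaled.
#'
#' @param train An `emg_features` table with at least 2 rows.
#' @return An object of class `emg_standardizer` with `mean`, `sd`,
#'   `zero_var` (logical per column).
#' @export
fit_standardizer <- function(train) {
  stopifnot(inherits(train, "emg_features"))
  if (nrow(train$values) < 2L)
    emg_input_error("standardizer needs at least 2 rows to fit")
  mu <- colMeans(train$values)
  n <- nrow(train$values)
  sdev <- sqrt(colMeans(sweep(train$values, 2, mu)^2))
  zero_var <- sdev <= 0
  sdev[zero_var] <- 1
  structure(list(mean = mu, sd = sdev, zero_var = zero_var),
            class = "emg_standardizer")
}

#' Apply (or invert) a fitted standardizer
#'
#' @param params An `emg_standardizer` from [fit_standardizer()].
#' @param table An `emg_features` table with matching columns.
#' @param inverse Undo the transformation instead.
#' @return A transformed `emg_features` table.
#' @export
apply_standardizer <- function(params, table, inverse = FALSE) {
  stopifnot(inherits(params, "emg_standardizer"), inherits(table, "emg_features"))
  if (!identical(colnames(table$values), names(params$mean)))
    emg_input_error("feature columns do not match the fitted standardizer")
  v <- if (inverse) sweep(sweep(table$values, 2, params$sd, `*`), 2, params$mean, `+`)
       else sweep(sweep(table$values, 2, params$mean), 2, params$sd, `/`)
  out <- table
  out$values <- v
  out
}
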