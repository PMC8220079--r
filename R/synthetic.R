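#' Configuration for the synthetic sEMG generator
#'
#' The generator emulates the Ninapro acquisition protocol: each movement
#' class is performed as `n_repetitions` blocks of `movement_s` seconds of
#' activity, each followed by `rest_s` seconds of rest (defaults 5 s and 3 s,
#' six repetitions). The signal model is amplitude-modulated zero-mean
#' Gaussian noise: during rest every channel has standard deviation
#' `baseline_noise_sd`; during a movement of class `c` channel `j` has
#' standard deviation `baseline_noise_sd * (1 + activation[c, j] * (1 + e))`,
#' where `e` is a per-repetition Gaussian jitter with standard deviation
#' `envelope_jitter_sd`. Distinct activation rows give each class a distinct
#' per-channel amplitude signature, which is exactly the statistical
#' structure that amplitude-based time-domain features pick up.
#'
#' @param n_channels Number of sEMG channels.
#' @param fs Sampling rate in Hz.
#' @param movement_classes Positive integer class labels (0 is reserved for
#'   rest).
#' @param n_repetitions Repetitions per movement (default 6).
#' @param movement_s Seconds of activity per repetition (default 5).
#' @param rest_s Seconds of rest after each repetition (default 3).
#' @param inter_class_rest_s Extra seconds of rest inserted before each
#'   movement class block, mimicking the rest padding between exercises that
#'   brings the rest class towards about half of all samples (default 0).
#' @param activation Non-negative matrix `n_classes x n_channels` of
#'   amplitude multipliers; default gives each class a distinct signature.
#' @param baseline_noise_sd Rest-state noise standard deviation (amplitude
#'   units).
#' @param envelope_jitter_sd Relative jitter of the activation per
#'   repetition (and per subject in [generate_dataset()]).
#' @param seed Integer seed; the generator is deterministic given the seed.
#'
#' @return An object of class `emg_synth_config`.
#' @seealso [generate_recording()], [generate_dataset()]
#' @export
synthetic_config <- function(n_channels = 8, fs = 200,
                             movement_classes = 1:10,
                             n_repetitions = 6,
                             movement_s = 5, rest_s = 3,
                             inter_class_rest_s = 0,
                             activation = NULL,
                             baseline_noise_sd = 0.01,
                             envelope_jitter_sd = 0.1,
                             seed = 1L) {
  movement_classes <- as.integer(movement_classes)
  if (any(movement_classes <= 0L))
    emg_config_error("movement class label 0 is reserved for rest; labels must be positive")
  if (anyDuplicated(movement_classes))
    emg_config_error("movement_classes must be distinct")
  if (movement_s <= 0 || rest_s < 0 || inter_class_rest_s < 0)
    emg_config_error("movement_s must be > 0 and rest durations >= 0")
  if (n_repetitions < 1)
    emg_config_error("n_repetitions must be >= 1")

  if (is.null(activation))
    activation <- default_activation(length(movement_classes), n_channels)
  activation <- as.matrix(activation)
  if (nrow(activation) != length(movement_classes) ||
      ncol(activation) != n_channels)
    emg_config_error("activation must be n_classes x n_channels")
  if (any(activation < 0))
    emg_config_error("activation entries must be non-negative")

  structure(
    list(n_channels = as.integer(n_channels), fs = fs,
         movement_classes = movement_classes,
         n_repetitions = as.integer(n_repetitions),
         movement_s = movement_s, rest_s = rest_s,
         inter_class_rest_s = inter_class_rest_s,
         activation = activation,
         baseline_noise_sd = baseline_noise_sd,
         envelope_jitter_sd = envelope_jitter_sd,
         seed = as.integer(seed)),
    class = "emg_synth_config")
}

# Distinct, well-separated per-channel amplitude signatures: class i activates
# a sliding pair of channels strongly plus a class-specific overall gain.
default_activation <- function(n_classes, n_channels) {
  act <- matrix(0.5, n_classes, n_channels)
  for (i in seq_len(n_classes)) {
    ch <- ((i - 1L) %% n_channels) + 1L
    ch2 <- (i %% n_channels) + 1L
    act[i, ch] <- 3 + 0.5 * i
    act[i, ch2] <- 1.5 + 0.25 * i
  }
  act
}

#' Generate one synthetic sEMG recording
#'
#' Lays out, for each movement class in turn, `n_repetitions` blocks of
#' `round(movement_s * fs)` activity samples (labelled with the class and the
#' repetition index 1..n_repetitions) each followed by `round(rest_s * fs)`
#' rest samples (labelled 0/0). See [synthetic_config()] for the signal
#' model.
#'
#' @param config An [synthetic_config()] object.
#' @param subject_id Identifier stored on the recording.
#' @return An [emg_recording()].
#' @export
generate_recording <- function(config, subject_id = "synthetic-1") {
  stopifnot(inherits(config, "emg_synth_config"))
  gen_recording_impl(config, config$activation, config$seed, subject_id)
}

gen_recording_impl <- function(config, activation, seed, subject_id) {
  fs <- config$fs
  n_move <- round(config$movement_s * fs)
  n_rest <- round(config$rest_s * fs)
  n_pad <- round(config$inter_class_rest_s * fs)
  nch <- config$n_channels
  classes <- config$movement_classes

  set.seed(seed)

  per_block <- n_move + n_rest
  total <- length(classes) * (config$n_repetitions * per_block + n_pad)
  emg <- matrix(0, total, nch)
  stimulus <- integer(total)
  repetition <- integer(total)

  pos <- 0L
  for (ci in seq_along(classes)) {
    if (n_pad > 0L) {
      idx <- pos + seq_len(n_pad)
      emg[idx, ] <- matrix(stats::rnorm(n_pad * nch, sd = config$baseline_noise_sd),
                           n_pad, nch)
      pos <- pos + n_pad
    }
    for (rep_i in seq_len(config$n_repetitions)) {
      jit <- stats::rnorm(1, sd = config$envelope_jitter_sd)
      sds <- config$baseline_noise_sd * (1 + activation[ci, ] * (1 + jit))
      sds <- pmax(sds, 1e-12)
      idx <- pos + seq_len(n_move)
      emg[idx, ] <- matrix(stats::rnorm(n_move * nch), n_move, nch) %*% diag(sds, nch)
      stimulus[idx] <- classes[ci]
      repetition[idx] <- rep_i
      pos <- pos + n_move
      if (n_rest > 0L) {
        idx <- pos + seq_len(n_rest)
        emg[idx, ] <- matrix(stats::rnorm(n_rest * nch, sd = config$baseline_noise_sd),
                             n_rest, nch)
        pos <- pos + n_rest
      }
    }
  }

  emg_recording(emg, fs, stimulus, repetition,
                subject_id = subject_id, exercise_id = "synthetic",
                source_tag = "synthetic")
}

#' Generate a multi-subject synthetic dataset
#'
#' Each subject gets an independent recording with a seed derived
#' reproducibly from the master seed and an activation matrix perturbed by
#' multiplicative jitter (`envelope_jitter_sd`), mimicking between-subject
#' amplitude variability. Label structure is identical across subjects.
#'
#' @param config An [synthetic_config()] object (its `seed` is the master
#'   seed).
#' @param n_subjects Number of subjects (>= 1).
#' @return A list of [emg_recording()] objects.
#' @export
generate_dataset <- function(config, n_subjects) {
  stopifnot(inherits(config, "emg_synth_config"))
  if (n_subjects < 1) emg_config_error("n_subjects must be >= 1")
  set.seed(config$seed)
  # keep derived seeds within 32-bit integer range
  seeds <- sample.int(2147483646L, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    set.seed(seeds[i])
    mult <- 1 + matrix(stats::rnorm(length(config$activation),
                                    sd = config$envelope_jitter_sd),
                       nrow(config$activation))
    act <- pmax(config$activation * mult, 0)
    gen_recording_impl(config, act, seeds[i], sprintf("synthetic-%d", i))
  })
}
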