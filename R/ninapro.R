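#' Read a Ninapro-style MAT recording
#'
#' Loads a MAT-file containing at minimum an `emg` matrix, a per-sample
#' movement label vector and a per-sample repetition vector, and returns an
#' [emg_recording()]. The refined annotations (`restimulus` /
#' `rerepetition`) are preferred when present, falling back to
#' `stimulus` / `repetition`; which dialect was used is recorded in the
#' result's `label_source`. Classic (v5) MAT files are parsed natively;
#' HDF5-backed v7.3 files are read through the system `python` interpreter
#' with `h5py` (see Details).
#'
#' @details Sampling rate is not stored in all Ninapro files. It is taken
#' from, in order of precedence: `field_map$fs` (a literal number), a
#' variable named in `field_map` as `fs`, a `frequency`/`fs` variable in the
#' file, or the `fs` argument. The standard rates are 200 Hz for DB5 and
#' 2000 Hz for DB7.
#'
#' @param path MAT-file path.
#' @param field_map Optional named list overriding field names, e.g.
#'   `list(emg = "EMG", stimulus = "glove_labels")`; `fs` may be a number.
#' @param fs Sampling rate in Hz when absent from the file.
#' @param source_tag Provenance tag stored on the recording (e.g. `"DB5"`).
#' @return An [emg_recording()].
#' @export
read_ninapro_mat <- function(path, field_map = list(), fs = NULL,
                             source_tag = "ninapro") {
  if (!file.exists(path)) emg_format_error(sprintf("file not found: %s", path))
  vars <- if (is_mat73(path)) read_mat73(path) else read_mat5(path)

  pick <- function(role, candidates) {
    override <- field_map[[role]]
    if (!is.null(override) && is.character(override)) candidates <- override
    for (nm in candidates) if (!is.null(vars[[nm]])) return(nm)
    NULL
  }

  emg_name <- pick("emg", "emg")
  if (is.null(emg_name))
    emg_format_error("required field 'emg' not found in MAT-file")
  stim_name <- pick("stimulus", c("restimulus", "stimulus"))
  if (is.null(stim_name))
    emg_format_error("required field 'stimulus' (or 'restimulus') not found in MAT-file")
  rep_name <- pick("repetition", c("rerepetition", "repetition"))
  if (is.null(rep_name))
    emg_format_error("required field 'repetition' (or 'rerepetition') not found in MAT-file")

  emg <- as.matrix(vars[[emg_name]])
  stimulus <- as.vector(vars[[stim_name]])
  repetition <- as.vector(vars[[rep_name]])
  if (length(stimulus) != nrow(emg) || length(repetition) != nrow(emg))
    emg_alignment_error(sprintf(
      "emg has %d samples but %s has %d and %s has %d",
      nrow(emg), stim_name, length(stimulus), rep_name, length(repetition)))
  if (any(!is.finite(emg)))
    emg_data_error("emg matrix contains non-finite values")

  fs_val <- field_map$fs
  if (is.character(fs_val)) fs_val <- vars[[fs_val]]
  fs_val <- fs_val %||% vars[["fs"]] %||% vars[["frequency"]] %||% fs
  if (is.null(fs_val))
    emg_format_error("sampling rate not present in file; supply fs= or field_map$fs")

  emg_recording(emg, as.numeric(fs_val)[1], stimulus, repetition,
                subject_id = as.character(vars[["subject"]] %||% "S?")[1],
                exercise_id = as.character(vars[["exercise"]] %||% "E?")[1],
                source_tag = source_tag,
                label_source = if (stim_name == "restimulus") "restimulus" else "stimulus")
}

is_mat73 <- function(path) {
  sig <- readBin(path, "raw", 520)
  hdf5 <- as.raw(c(0x89, 0x48, 0x44, 0x46, 0x0d, 0x0a, 0x1a, 0x0a))
  (length(sig) >= 8 && identical(sig[1:8], hdf5)) ||
    (length(sig) >= 520 && identical(sig[513:520], hdf5))
}

# Read a v7.3 (HDF5) MAT-file by delegating to `python` + h5py: datasets are
# dumped as little-endian float64 binaries plus a JSON manifest, then read
# back with readBin. Requires a python with h5py on the PATH.
read_mat73 <- function(path) {
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python))
    emg_format_error("reading v7.3 MAT-files requires a 'python' with h5py on the PATH")
  script <- system.file("python", "dump_mat73.py", package = "emgmotion")
  if (!nzchar(script))
    emg_format_error("bundled dump_mat73.py not found")
  outdir <- tempfile("mat73_")
  dir.create(outdir)
  on.exit(unlink(outdir, recursive = TRUE))
  status <- system2(python, c(script, shQuote(path), shQuote(outdir)),
                    stdout = TRUE, stderr = TRUE)
  manifest_path <- file.path(outdir, "manifest.json")
  if (!file.exists(manifest_path))
    emg_format_error(paste("failed to read v7.3 MAT-file:",
                           paste(status, collapse = "\n")))
  manifest <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  out <- list()
  for (entry in manifest) {
    dims <- unlist(entry$dims)
    vals <- readBin(file.path(outdir, entry$file), "double",
                    n = prod(dims), size = 8, endian = "little")
    value <- array(vals, dim = dims)
    if (length(dims) == 2L && any(dims == 1L)) value <- as.vector(value)
    out[[entry$name]] <- value
  }
  out
}

#' Write a recording as a classic MAT v5 file
#'
#' The file is readable by [read_ninapro_mat()] with default field names:
#' variables `emg` (double), `stimulus` and `repetition` (int32,
#' bitwise-exact round trip), `fs`, `subject`, `exercise`.
#'
#' @param recording An [emg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_mat <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  if (nrow(recording$emg) == 0L)
    emg_format_error("refusing to write a recording with 0 samples")
  vars <- list(
    emg = recording$emg,
    stimulus = matrix(recording$stimulus, ncol = 1),
    repetition = matrix(recording$repetition, ncol = 1),
    fs = recording$fs,
    subject = suppressWarnings(as.numeric(gsub("\\D", "", recording$subject_id))),
    exercise = suppressWarnings(as.numeric(gsub("\\D", "", recording$exercise_id))))
  vars$subject <- if (is.na(vars$subject)) 0 else vars$subject
  vars$exercise <- if (is.na(vars$exercise)) 0 else vars$exercise
  write_mat5(vars, path, integer_vars = c("stimulus", "repetition"))
  invisible(path)
}

#' Write / read a feature table as CSV
#'
#' Columns are the feature names followed by `label` and `repetition`;
#' numeric values round-trip within 1e-12 relative error.
#'
#' @param table An `emg_features` table.
#' @param path CSV path.
#' @return `write_feature_table`: `path`, invisibly. `read_feature_table`:
#'   an `emg_features` table.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "emg_features"))
  if (anyDuplicated(colnames(table$values)))
    emg_format_error("duplicate feature column names")
  df <- as.data.frame(table$values)
  df$label <- table$labels
  df$repetition <- table$repetitions
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("label", "repetition") %in% names(df)))
    emg_format_error("feature CSV must contain 'label' and 'repetition' columns")
  feat_cols <- setdiff(names(df), c("label", "repetition"))
  values <- as.matrix(df[, feat_cols, drop = FALSE])
  storage.mode(values) <- "double"
  feature_table(values, df$label, df$repetition)
}
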