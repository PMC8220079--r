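# Structured error conditions used across the package. Each error carries a
# machine-readable class ("emg_<kind>_error") so callers and the CLI can route
# failures without parsing messages.

emg_error <- function(kind, message, ...) {
  stop(errorCondition(
    message,
    ...,
    class = c(paste0("emg_", kind, "_error"), "emg_error")
  ))
}

emg_format_error    <- function(message, ...) emg_error("format", message, ...)
emg_alignment_error <- function(message, ...) emg_error("alignment", message, ...)
emg_data_error      <- function(message, ...) emg_error("data", message, ...)
emg_input_error     <- function(message, ...) emg_error("input", message, ...)
emg_config_error    <- function(message, ...) emg_error("config", message, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
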