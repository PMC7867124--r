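# Channel names of a 6-axis wrist recording, in dialect order.
CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

CLASS_LEVELS <- c("healthy", "tremor", "bradykinesia")

TASKS <- c("rest", "postural", "kinetic", "finger_tap", "fist_open_close",
           "pronation_supination")

abort_invalid <- function(msg, ...) {
  abort(msg, class = "pdmotor_invalid_argument", ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = "pdmotor_format_error", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
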