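# Classed conditions so callers (and tests) can distinguish failure modes.
# All inherit from "xe_error".

xe_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "xe_error"), call = call))
}

xe_format_error    <- function(msg) xe_error(msg, "xe_format_error")
xe_integrity_error <- function(msg) xe_error(msg, "xe_integrity_error")
xe_config_error    <- function(msg) xe_error(msg, "xe_config_error")
xe_value_error     <- function(msg) xe_error(msg, "xe_value_error")
xe_insufficient_data_error <- function(msg) {
  xe_error(msg, c("xe_insufficient_data_error", "xe_value_error"))
}

# %||% is not in base until 4.4
`%||%` <- function(a, b) if (is.null(a)) b else a
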