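# Classed conditions so callers can distinguish failure modes programmatically.

tm_error <- function(message, class) {
  stop(errorCondition(message, class = c(class, "turnmetry_error")))
}

tm_schema_error <- function(msg) tm_error(msg, "tm_schema_error")
tm_format_error <- function(msg) tm_error(msg, "tm_format_error")
tm_validation_error <- function(msg) tm_error(msg, "tm_validation_error")
tm_argument_error <- function(msg) tm_error(msg, "tm_argument_error")
tm_degenerate_error <- function(msg) tm_error(msg, "tm_degenerate_error")
tm_insufficient_frames <- function(msg) tm_error(msg, "tm_insufficient_frames")
tm_io_error <- function(msg) tm_error(msg, "tm_io_error")
tm_join_error <- function(msg) tm_error(msg, "tm_join_error")
tm_index_error <- function(msg) tm_error(msg, "tm_index_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
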