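# Condition helpers: every user-facing failure is one of four classes so
# callers (and the CLI) can distinguish bad configuration from bad data from
# filesystem trouble from plain invalid arguments.

stop_config <- function(msg, ...) {
  abort(msg, class = c("illumfield_config_error", "illumfield_error"), ...)
}

stop_data <- function(msg, ...) {
  abort(msg, class = c("illumfield_data_error", "illumfield_error"), ...)
}

stop_io <- function(msg, ...) {
  abort(msg, class = c("illumfield_io_error", "illumfield_error"), ...)
}

stop_value <- function(msg, ...) {
  abort(msg, class = c("illumfield_value_error", "illumfield_error"), ...)
}
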