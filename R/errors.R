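# Structured conditions so callers (and the command-line wrapper) can map
# failures to exit codes: config -> 2, data format -> 3, numerical -> 4.

abort_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fccs_config_error", "fccs_error")))
}

abort_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fccs_format_error", "fccs_error")))
}

abort_numeric <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fccs_numeric_error", "fccs_error")))
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
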