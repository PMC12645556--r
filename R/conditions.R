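# Classed conditions so callers (and tests) can distinguish bad input data from
# bad usage without matching on message text.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("spinemorph_validation_error", "spinemorph_error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("spinemorph_format_error", "spinemorph_error")))
}

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("spinemorph_usage_error", "spinemorph_error")))
}
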