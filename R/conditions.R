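# Classed error conditions so callers and tests can distinguish failure
# modes (parse vs validation vs degenerate input etc.) without matching
# on message text.

stop_cond <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "pssmDBP_error")))
}

stop_parse      <- function(...) stop_cond("pssmDBP_parse_error", ...)
stop_validation <- function(...) stop_cond("pssmDBP_validation_error", ...)
stop_degenerate <- function(...) stop_cond("pssmDBP_degenerate_error", ...)
stop_schema     <- function(...) stop_cond("pssmDBP_schema_error", ...)
stop_empty      <- function(...) stop_cond("pssmDBP_empty_error", ...)
stop_io         <- function(...) stop_cond("pssmDBP_io_error", ...)
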