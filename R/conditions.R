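# Classed conditions so callers (and the CLI) can map failures to exit codes.

rv_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "rv_error"), call = call))
}

rv_format_error     <- function(msg) rv_stop(msg, "rv_format_error")
rv_parse_error      <- function(msg) rv_stop(msg, "rv_parse_error")
rv_empty_error      <- function(msg) rv_stop(msg, "rv_empty_error")
rv_degenerate_error <- function(msg) rv_stop(msg, "rv_degenerate_error")
rv_domain_error     <- function(msg) rv_stop(msg, "rv_domain_error")
rv_alignment_error  <- function(msg) rv_stop(msg, "rv_alignment_error")
rv_io_error         <- function(msg) rv_stop(msg, "rv_io_error")
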