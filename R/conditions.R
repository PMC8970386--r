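# Classed conditions so callers can distinguish montage problems from
# format problems etc. without matching message strings.

dlb_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "dlb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

dlb_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "dlb_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
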