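# Classed conditions so callers (and the optimizer) can react to specific
# failure modes without string-matching messages.

abort_wbc <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "wbc_error"), call = call))
}

warn_wbc <- function(message, class) {
  warning(warningCondition(message, class = c(class, "wbc_warning")))
}

#' @keywords internal
is_wbc_error <- function(e, class) inherits(e, class)
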