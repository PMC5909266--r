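# Classed conditions so callers and tests can distinguish failure modes.

rm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "respmotion_error"), call = call))
}

err_invalid <- function(msg) rm_stop(msg, "rm_invalid_input")
err_degenerate_fit <- function(msg) rm_stop(msg, "rm_degenerate_fit")
err_degenerate_branch <- function(msg) rm_stop(msg, "rm_degenerate_branch")
err_insufficient_cycles <- function(msg) rm_stop(msg, "rm_insufficient_cycles")
err_undefined_correlation <- function(msg) rm_stop(msg, "rm_undefined_correlation")
err_parse <- function(msg) rm_stop(msg, "rm_parse_error")
err_usage <- function(msg) rm_stop(msg, "rm_usage_error")

warn_illconditioned <- function(msg) {
  warning(warningCondition(msg, class = "rm_illconditioned_warning"))
}
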