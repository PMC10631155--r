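# Classed conditions so callers and tests can distinguish failure modes.
abort_jshape <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "jshape_error"), call = call))
}

warn_jshape <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "jshape_warning")))
}
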