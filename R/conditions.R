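# Classed conditions so callers can distinguish bad values (domain), bad
# structure (input), missing configuration, and tail-fit failure.

abort_glnbolus <- function(message, class) {
  stop(structure(
    class = c(class, "glnbolus_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_domain <- function(message) abort_glnbolus(message, "glnbolus_domain_error")
abort_input <- function(message) abort_glnbolus(message, "glnbolus_input_error")
abort_config <- function(message) abort_glnbolus(message, "glnbolus_config_error")
abort_no_valid_tail <- function(message) abort_glnbolus(message, "glnbolus_no_valid_tail")

# Re-raise a classed error with a pipeline stage label prepended.
with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    glnbolus_error = function(e) {
      e$message <- sprintf("[%s] %s", stage, conditionMessage(e))
      stop(e)
    }
  )
}
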