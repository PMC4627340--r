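# Classed conditions so callers (and the CLI) can distinguish bad user input
# (exit 2) from numerical/convergence failures (exit 3).

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("prognet_input_error", "prognet_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("prognet_format_error",
                                             "prognet_input_error", "prognet_error")))
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("prognet_param_error",
                                             "prognet_input_error", "prognet_error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("prognet_numeric_error", "prognet_error")))
}
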