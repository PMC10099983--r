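# condition helpers: validation errors (bad inputs/config, exit code 2 in the
# CLI) vs numerical errors (sampler/initialization failures, exit code 3)

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("nestipm_validation_error",
                                             "error", "condition")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("nestipm_numeric_error",
                                             "error", "condition")))
}
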