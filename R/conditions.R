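# Classed conditions so callers (and the CLI) can map failures to exit codes:
# config/parameter errors, data/geometry errors, I/O errors.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("vxp_config_error", "vxp_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("vxp_data_error", "vxp_error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("vxp_io_error", "vxp_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
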