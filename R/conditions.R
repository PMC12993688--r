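#' @keywords internal
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("microgwas_config_error", "error")))
}

#' @keywords internal
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("microgwas_data_error", "error")))
}

#' @keywords internal
stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("microgwas_numeric_error", "error")))
}
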