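#' @keywords internal
#' Classed errors so callers can test failure modes precisely.
ps_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message,
                      class = c(paste0("pairedslip_", class), "pairedslip_error"),
                      call = call))
}

ps_warn <- function(message, class) {
  warning(warningCondition(message,
                           class = c(paste0("pairedslip_", class), "pairedslip_warning")))
}
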