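#' Package logging
#'
#' Messages go to stderr. The level is controlled by
#' `options(dlamreg.verbose = )`: 0 silences everything, 1 (default) emits
#' progress messages, 2 adds debug detail.
#'
#' @param ... Message parts, passed to [message()].
#' @param level Minimum verbosity at which the message is emitted.
#' @return Invisibly, `NULL`.
#' @export
dlam_log <- function(..., level = 1) {
  if (getOption("dlamreg.verbose", 1) >= level) message(...)
  invisible(NULL)
}
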