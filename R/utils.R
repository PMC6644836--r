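#' @keywords internal
"_PACKAGE"

# Structured conditions so callers (and the CLI) can map failures to exit
# codes without string matching.
fp_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(class, "fuzzypath_error"), ...))
}

validation_error <- function(msg, ...) fp_stop(msg, "fuzzypath_validation_error", ...)
integrity_error  <- function(msg, ...) fp_stop(msg, "fuzzypath_integrity_error", ...)
usage_error      <- function(msg, ...) fp_stop(msg, "fuzzypath_usage_error", ...)
runtime_error    <- function(msg, ...) fp_stop(msg, "fuzzypath_runtime_error", ...)

`%||%` <- function(x, y) if (is.null(x)) y else x

# scalar string check used throughout the readers/validators
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

as_chr <- function(x) {
  if (is.null(x)) character(0) else as.character(unlist(x, use.names = FALSE))
}
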