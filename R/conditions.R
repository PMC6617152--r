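# Structured error conditions. Every error raised by the package carries the
# class "blockpls_error" plus one of the specific classes below, so callers
# (and the CLI exit-code mapping) can dispatch without parsing messages.
#
#   blockpls_schema_error      -- wrong shape / names / column structure
#   blockpls_alignment_error   -- row IDs do not match across files (schema subclass)
#   blockpls_missing_data_error-- empty cells / NA values (no imputation in v1)
#   blockpls_parameter_error   -- invalid tuning parameter (e.g. lambda < 0)
#   blockpls_degenerate_error  -- degenerate input (e.g. zero within-group variance)
#   blockpls_no_signal_error   -- all cross-covariances identically zero
#   blockpls_spec_error        -- invalid synthetic-data specification

stop_blockpls <- function(class, message, ...) {
  stop(structure(
    class = c(class, "blockpls_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

stop_schema     <- function(message, ...) stop_blockpls("blockpls_schema_error", message, ...)
stop_alignment  <- function(message, ...) {
  stop(structure(
    class = c("blockpls_alignment_error", "blockpls_schema_error",
              "blockpls_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
stop_missing    <- function(message, ...) stop_blockpls("blockpls_missing_data_error", message, ...)
stop_parameter  <- function(message, ...) stop_blockpls("blockpls_parameter_error", message, ...)
stop_degenerate <- function(message, ...) stop_blockpls("blockpls_degenerate_error", message, ...)
stop_no_signal  <- function(message, ...) stop_blockpls("blockpls_no_signal_error", message, ...)
stop_spec       <- function(message, ...) stop_blockpls("blockpls_spec_error", message, ...)
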