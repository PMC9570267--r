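#' @keywords internal
"_PACKAGE"

## Classed conditions so callers/tests can distinguish failure modes.
stop_deskqsar <- function(class, msg, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "deskqsar_error", "error", "condition"),
    list(message = msg, call = call)
  )
  stop(cond)
}

stop_schema     <- function(msg) stop_deskqsar("deskqsar_schema_error", msg)
stop_parse      <- function(msg) stop_deskqsar("deskqsar_parse_error", msg)
stop_validation <- function(msg) stop_deskqsar("deskqsar_validation_error", msg)
stop_lookup     <- function(msg) stop_deskqsar("deskqsar_lookup_error", msg)
stop_domain     <- function(msg) stop_deskqsar("deskqsar_domain_error", msg)
stop_dimension  <- function(msg) stop_deskqsar("deskqsar_dimension_error", msg)
stop_io         <- function(msg) stop_deskqsar("deskqsar_io_error", msg)
stop_config     <- function(msg) stop_deskqsar("deskqsar_config_error", msg)

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}
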