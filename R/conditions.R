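# Typed error conditions so callers (and the CLI) can map failures to
# distinct exit statuses instead of matching on message text.

cypsom_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cypsom_error"), call = call))
}

stop_input         <- function(msg) cypsom_stop(msg, "cypsom_input_error")
stop_config        <- function(msg) cypsom_stop(msg, "cypsom_config_error")
stop_geometry      <- function(msg) cypsom_stop(msg, "cypsom_geometry_error")
stop_orientation   <- function(msg) cypsom_stop(msg, "cypsom_orientation_error")
stop_selection     <- function(msg) cypsom_stop(msg, "cypsom_selection_error")
stop_io            <- function(msg) cypsom_stop(msg, "cypsom_io_error")
stop_identifiability <- function(msg) cypsom_stop(msg, "cypsom_identifiability_error")
stop_comparability <- function(msg) cypsom_stop(msg, "cypsom_comparability_error")
stop_convergence   <- function(msg) cypsom_stop(msg, "cypsom_convergence_error")
stop_lookup        <- function(msg) cypsom_stop(msg, "cypsom_lookup_error")

# diagnostics for recoverable internal failures (multi-start optimisation);
# silenced unless the option is set
wf_debug <- function(...) {
  if (isTRUE(getOption("cypsom.debug", FALSE))) message("[cypsom debug] ", ...)
}
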