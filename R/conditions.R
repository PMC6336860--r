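# Classed error conditions so callers (and the CLI) can map failures to
# distinct exit codes instead of string-matching messages.

vb_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "vb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_invalid_input <- function(msg, ...) vb_stop(msg, "vb_invalid_input", ...)
stop_domain <- function(msg, ...) vb_stop(msg, "vb_domain_error", ...)
stop_degenerate <- function(msg, ...) vb_stop(msg, "vb_degenerate_configuration", ...)
stop_segmentation <- function(msg, ...) vb_stop(msg, "vb_segmentation_failure", ...)
stop_fit_failure <- function(msg, ...) vb_stop(msg, "vb_fit_failure", ...)
stop_empty_series <- function(msg, ...) vb_stop(msg, "vb_empty_series", ...)
stop_insufficient_data <- function(msg, ...) vb_stop(msg, "vb_insufficient_data", ...)
stop_infeasible <- function(msg, ...) vb_stop(msg, "vb_infeasible_trajectory", ...)
stop_render <- function(msg, ...) vb_stop(msg, "vb_render_error", ...)
stop_config <- function(msg, ...) vb_stop(msg, "vb_config_error", ...)
stop_io <- function(msg, ...) vb_stop(msg, "vb_io_error", ...)
stop_validation <- function(msg, ...) vb_stop(msg, "vb_validation_error", ...)

check_finite_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid_input(sprintf("`%s` must be a single finite positive number", name))
  invisible(x)
}
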