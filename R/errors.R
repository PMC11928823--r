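# Condition helpers: every user-facing failure carries a class so callers and
# tests can distinguish format/data/contract problems without string matching.

stop_format <- function(msg, ...) abort(msg, class = "tissuemech_format_error", ...)
stop_data <- function(msg, ...) abort(msg, class = "tissuemech_data_error", ...)
stop_contract <- function(msg, ...) abort(msg, class = "tissuemech_contract_error", ...)
stop_geometry <- function(msg, ...) abort(msg, class = "tissuemech_geometry_error", ...)
stop_calibration <- function(msg, ...) abort(msg, class = "tissuemech_calibration_error", ...)
stop_config <- function(msg, ...) abort(msg, class = "tissuemech_config_error", ...)
stop_io <- function(msg, ...) abort(msg, class = "tissuemech_io_error", ...)

# R^2 computed directly (summary.lm warns on numerically perfect fits, which
# are routine on noiseless synthetic data)
r_squared <- function(fit, y) {
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  max(0, min(1, 1 - rss / tss))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_contract(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) stop_contract(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) stop_contract(sprintf("`%s` must be >= 0", name))
  invisible(x)
}
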