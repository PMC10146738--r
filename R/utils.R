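# Condition helpers: every error carries class "relkin_error" plus a
# machine-matchable subclass so callers (and the batch pipeline) can
# distinguish bad inputs from numerical failures.

stop_relkin <- function(msg, subclass, ...) {
  abort(msg, class = c(subclass, "relkin_error"), ...)
}

stop_domain <- function(msg, ...) stop_relkin(msg, "relkin_domain_error", ...)
stop_arity <- function(msg, ...) stop_relkin(msg, "relkin_arity_error", ...)
stop_ordering <- function(msg, ...) stop_relkin(msg, "relkin_ordering_error", ...)
stop_validation <- function(msg, ...) stop_relkin(msg, "relkin_validation_error", ...)
stop_insufficient <- function(msg, ...) stop_relkin(msg, "relkin_insufficient_data_error", ...)
stop_lookup <- function(msg, ...) stop_relkin(msg, "relkin_lookup_error", ...)
stop_undefined_stat <- function(msg, ...) stop_relkin(msg, "relkin_undefined_statistic_error", ...)
stop_config <- function(msg, ...) stop_relkin(msg, "relkin_config_error", ...)
stop_selection <- function(msg, ...) stop_relkin(msg, "relkin_selection_error", ...)

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_domain(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

# Accept a curve as any data frame with time and cumulative-release columns.
curve_columns <- function(data, time_col = "time_min", q_col = "Q_percent") {
  if (!is.data.frame(data)) {
    stop_validation("A release curve must be a data frame.")
  }
  missing_cols <- setdiff(c(time_col, q_col), names(data))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf(
      "Release curve is missing column(s): %s.",
      paste0("`", missing_cols, "`", collapse = ", ")
    ))
  }
  list(time = data[[time_col]], q = data[[q_col]])
}

check_times <- function(time) {
  if (length(time) == 0L) {
    stop_ordering("Release series is empty.")
  }
  if (anyNA(time) || any(time < 0)) {
    stop_ordering("Times must be non-negative and non-missing.")
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop_ordering("Times must be strictly increasing.")
  }
  invisible(time)
}
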