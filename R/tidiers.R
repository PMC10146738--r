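# broom-style accessors for fitted objects.

#' Tidy a fitted release model
#'
#' @param x A `release_fit`.
#' @param ... Unused.
#' @return Tibble with columns `model`, `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.release_fit <- function(x, ...) {
  tibble(model = x$model, term = names(x$params), estimate = unname(x$params))
}

#' One-row goodness-of-fit summary of a release fit
#'
#' @param x A `release_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `n_used`, `dof`, `rss`, `reduced_chi_sq`,
#'   `adj_r_square`, `pearson_r`, `converged`.
#' @exportS3Method generics::glance
glance.release_fit <- function(x, ...) {
  tibble(
    model = x$model, n_used = x$n_used, dof = x$dof, rss = x$rss,
    reduced_chi_sq = x$reduced_chi_sq, adj_r_square = x$adj_r_square,
    pearson_r = x$pearson_r, converged = x$converged
  )
}

#' Fitted points of a release fit
#'
#' @param x A `release_fit`.
#' @param ... Unused.
#' @return The fitted points with `.fitted` and `.resid` columns.
#' @exportS3Method generics::augment
augment.release_fit <- function(x, ...) {
  dplyr::transmute(
    x$data,
    time_min = .data$time_min,
    Q_percent = .data$observed,
    .fitted = .data$predicted,
    .resid = .data$observed - .data$predicted
  )
}

#' @rdname tidy.release_fit
#' @exportS3Method generics::tidy
tidy.release_fit_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), tidy)
}

#' @rdname glance.release_fit
#' @exportS3Method generics::glance
glance.release_fit_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), glance)
}

#' Tidy a model comparison
#'
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @return The per-model metrics with a logical `selected` column.
#' @exportS3Method generics::tidy
tidy.model_comparison <- function(x, ...) {
  dplyr::mutate(x$metrics, selected = .data$model == x$selected)
}

#' @rdname tidy.model_comparison
#' @exportS3Method generics::glance
glance.model_comparison <- function(x, ...) {
  tibble(
    selected = x$selected,
    rationale = paste(x$rationale, collapse = ","),
    adj_r2_tolerance = x$adj_r2_tolerance
  )
}

#' Tidy a release report
#'
#' @param x A `release_report`.
#' @param ... Unused.
#' @return The per-drug, per-model results table.
#' @exportS3Method generics::tidy
tidy.release_report <- function(x, ...) x$results

#' @rdname tidy.release_report
#' @exportS3Method generics::glance
glance.release_report <- function(x, ...) x$selection
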