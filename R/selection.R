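# Model selection formalizes the usual two-step reasoning: shortlist the
# models whose adjusted R^2 is within a relative tolerance of the best,
# then prefer the smallest residual sum of squares, then the smallest
# reduced chi-squared. RSS precedes reduced chi-squared deliberately: the
# two can disagree when the candidate models use different numbers of
# points (the Korsmeyer-Peppas 60 % window) and the smaller absolute
# misfit is the accepted winner in that situation.

#' Rank fitted models and select a winner
#'
#' @param fits A `release_fit_set`, a list of `release_fit` objects, or a
#'   data frame with columns `model`, `adj_r_square`, `rss` and optionally
#'   `reduced_chi_sq` and `converged` (so selections can also be replayed
#'   from published metric tables).
#' @param adj_r2_tolerance Relative adjusted-R-squared tolerance defining
#'   the shortlist: a model is a candidate when
#'   `(max_adj_r2 - adj_r2) / |max_adj_r2| <= adj_r2_tolerance`.
#'   Default 0.05.
#' @return An object of class `model_comparison`: a list with `metrics`
#'   (one row per model), `selected`, and `rationale` (ordered criterion
#'   codes among `"adj_r2"`, `"rss"`, `"reduced_chi_sq"`, `"tie"`).
#' @export
#' @examples
#' metrics <- tibble::tibble(
#'   model = c("first_order", "korsmeyer_peppas"),
#'   adj_r_square = c(0.99108, 0.99062),
#'   rss = c(137.58277, 93.76934),
#'   reduced_chi_sq = c(4.43815, 3.34891)
#' )
#' rank_models(metrics)$selected
rank_models <- function(fits, adj_r2_tolerance = 0.05) {
  metrics <- as_fit_metrics(fits)
  if (nrow(metrics) < 2L) {
    stop_selection("rank_models needs at least 2 fitted models.")
  }
  if (adj_r2_tolerance <= 0) stop_config("`adj_r2_tolerance` must be positive.")
  usable <- metrics[metrics$converged & is.finite(metrics$adj_r_square) &
                      is.finite(metrics$rss), , drop = FALSE]
  if (nrow(usable) == 0L) {
    stop_selection("No converged fit with valid metrics to rank.")
  }
  # deterministic registry order for tie-breaking and output
  ord <- order(match(usable$model, kinetic_model_names()))
  usable <- usable[ord, , drop = FALSE]

  rationale <- "adj_r2"
  best_r2 <- max(usable$adj_r_square)
  shortlist <- usable[(best_r2 - usable$adj_r_square) / abs(best_r2) <=
                        adj_r2_tolerance, , drop = FALSE]
  if (nrow(shortlist) > 1L) {
    rationale <- c(rationale, "rss")
    shortlist <- shortlist[shortlist$rss == min(shortlist$rss), , drop = FALSE]
  }
  if (nrow(shortlist) > 1L && any(is.finite(shortlist$reduced_chi_sq))) {
    rationale <- c(rationale, "reduced_chi_sq")
    shortlist <- shortlist[shortlist$reduced_chi_sq == min(shortlist$reduced_chi_sq),
                           , drop = FALSE]
  }
  if (nrow(shortlist) > 1L) rationale <- c(rationale, "tie")
  structure(
    list(
      metrics = as_tibble(metrics),
      selected = shortlist$model[1L],
      rationale = rationale,
      adj_r2_tolerance = adj_r2_tolerance
    ),
    class = "model_comparison"
  )
}

as_fit_metrics <- function(fits) {
  if (is.data.frame(fits)) {
    needed <- c("model", "adj_r_square", "rss")
    if (!all(needed %in% names(fits))) {
      stop_validation(sprintf(
        "Metrics table needs columns %s.", paste0("`", needed, "`", collapse = ", ")
      ))
    }
    out <- as_tibble(fits)
    if (!"reduced_chi_sq" %in% names(out)) out$reduced_chi_sq <- NA_real_
    if (!"converged" %in% names(out)) out$converged <- TRUE
    return(out)
  }
  if (inherits(fits, "release_fit")) fits <- list(fits)
  if (!all(vapply(fits, inherits, logical(1), "release_fit"))) {
    stop_validation("`fits` must be release_fit objects or a metrics data frame.")
  }
  purrr::map_dfr(fits, function(f) {
    tibble(
      model = f$model, adj_r_square = f$adj_r_square, rss = f$rss,
      reduced_chi_sq = f$reduced_chi_sq, converged = f$converged
    )
  })
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "<model_comparison> selected: %s (criteria: %s)\n",
    x$selected, paste(x$rationale, collapse = " -> ")
  ))
  print(x$metrics)
  invisible(x)
}

#' Classify the release transport mechanism from the power-law exponent
#'
#' For a cylindrical matrix the Korsmeyer-Peppas exponent `n` diagnoses
#' the transport mechanism: `n < 0.45` Fickian diffusion,
#' `0.45 <= n < 0.89` non-Fickian (anomalous) transport, `n = 0.89`
#' (within `case2_tolerance`) Case II transport, and `n > 0.89` super
#' Case II transport. The lower boundary 0.45 is assigned to the
#' non-Fickian class so the partition is exhaustive.
#'
#' @param n Release exponent(s); finite numeric.
#' @param geometry Matrix geometry; only `"cylinder"` is supported.
#' @param n_low,n_high Class boundaries (defaults 0.45 and 0.89).
#' @param case2_tolerance Absolute tolerance around `n_high` treated as
#'   Case II (default 1e-6).
#' @return Character vector with values among `"fickian"`,
#'   `"non_fickian"`, `"case_II"`, `"super_case_II"`.
#' @export
#' @examples
#' classify_mechanism(c(0.3732, 0.5381, 0.89, 0.95))
classify_mechanism <- function(n, geometry = "cylinder",
                               n_low = 0.45, n_high = 0.89,
                               case2_tolerance = 1e-6) {
  if (!identical(geometry, "cylinder")) {
    stop_config(sprintf(
      "Unsupported geometry %s: only \"cylinder\" thresholds are shipped.",
      deparse1(geometry)
    ))
  }
  if (!is.numeric(n) || any(!is.finite(n))) {
    stop_domain("`n` must be finite numeric.")
  }
  dplyr::case_when(
    abs(n - n_high) <= case2_tolerance ~ "case_II",
    n < n_low ~ "fickian",
    n < n_high ~ "non_fickian",
    TRUE ~ "super_case_II"
  )
}

#' Flag burst release from the power-law rate constant
#'
#' A large Korsmeyer-Peppas rate constant indicates a disproportionately
#' fast initial release (drug localized at the fiber surface). The default
#' threshold 6 sits in the empirical gap between the slow-release
#' (K < 0.87) and burst-release (K > 6.09) clusters and is a documented
#' heuristic, not a physical constant.
#'
#' @param K Rate constant(s), `>= 0` (percent per minute^n).
#' @param threshold Positive threshold; `K >= threshold` flags burst.
#' @return Logical vector.
#' @export
#' @examples
#' flag_burst(c(0.3556, 8.2661))
flag_burst <- function(K, threshold = 6) {
  if (!is.numeric(K) || any(!is.finite(K)) || any(K < 0)) {
    stop_domain("`K` must be finite and non-negative.")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_config("`threshold` must be a single positive number.")
  }
  K >= threshold
}

#' Mechanism call from a fitted Korsmeyer-Peppas model
#'
#' Bundles [classify_mechanism()] and [flag_burst()] applied to the fitted
#' `(K, n)` of a Korsmeyer-Peppas `release_fit`.
#'
#' @param fit A `release_fit` with `model == "korsmeyer_peppas"`.
#' @inheritParams classify_mechanism
#' @param burst_threshold Passed to [flag_burst()].
#' @return One-row tibble with `K`, `n`, `geometry`, `transport_class`,
#'   `burst_flag` and the thresholds used.
#' @export
mechanism_call <- function(fit, geometry = "cylinder", n_low = 0.45,
                           n_high = 0.89, case2_tolerance = 1e-6,
                           burst_threshold = 6) {
  if (!inherits(fit, "release_fit") || fit$model != "korsmeyer_peppas") {
    stop_validation("`fit` must be a korsmeyer_peppas release_fit.")
  }
  n <- fit$params[["n"]]
  K <- fit$params[["K"]]
  tibble(
    K = K, n = n, geometry = geometry,
    transport_class = classify_mechanism(
      n, geometry = geometry, n_low = n_low, n_high = n_high,
      case2_tolerance = case2_tolerance
    ),
    burst_flag = flag_burst(K, threshold = burst_threshold),
    n_low = n_low, n_high = n_high, burst_threshold = burst_threshold
  )
}
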