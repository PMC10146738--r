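# The four classical dissolution models. The first-order model is kept in
# its saturating-exponential parameterization Qt = K1*exp(a*t) + b1 (a < 0,
# K1 < 0 for release toward a plateau b1), so reference fitted equations can
# be loaded verbatim as parameter vectors.

.model_registry <- tibble::tibble(
  model = c("zero_order", "first_order", "higuchi", "korsmeyer_peppas"),
  parameters = list(
    c("K0", "b0"),
    c("K1", "a", "b1"),
    c("KH", "bH"),
    c("K", "n")
  ),
  n_params = c(2L, 3L, 2L, 2L),
  domain_rule = c("all_points", "all_points", "all_points", "below_60_percent")
)

#' Names of the supported release-kinetics models
#'
#' The registry order (zero-order, first-order, Higuchi, Korsmeyer-Peppas)
#' is also the deterministic tie-break order used by [rank_models()].
#'
#' @return A character vector of model names.
#' @export
#' @examples
#' kinetic_model_names()
kinetic_model_names <- function() .model_registry$model

#' Registry of the four release-kinetics models
#'
#' Each model is a parametric form for the cumulative release percentage
#' \eqn{Q_t} as a function of time in minutes:
#' \describe{
#'   \item{zero_order}{\eqn{Q_t = K_0 t + b_0}}
#'   \item{first_order}{\eqn{Q_t = K_1 e^{a t} + b_1}}
#'   \item{higuchi}{\eqn{Q_t = K_H \sqrt{t} + b_H}}
#'   \item{korsmeyer_peppas}{\eqn{Q_t = K t^n}, valid for the first 60\% of
#'     fractional release (`domain_rule = "below_60_percent"`)}
#' }
#'
#' @return A tibble with columns `model`, `parameters` (list column of
#'   parameter names in canonical order), `n_params` and `domain_rule`.
#' @export
#' @examples
#' kinetic_models()
kinetic_models <- function() .model_registry

match_model <- function(model) {
  if (!is.character(model) || length(model) != 1L ||
      !model %in% .model_registry$model) {
    stop_lookup(sprintf(
      "Unknown model %s; available: %s.",
      deparse1(model), paste(.model_registry$model, collapse = ", ")
    ))
  }
  model
}

model_parameters <- function(model) {
  .model_registry$parameters[[match(match_model(model), .model_registry$model)]]
}

# Coerce a params vector (named in any order, or positional) to canonical
# order, enforcing arity.
canonical_params <- function(model, params) {
  wanted <- model_parameters(model)
  if (!is.numeric(params)) {
    stop_arity(sprintf("Parameters for %s must be numeric.", model))
  }
  if (length(params) != length(wanted)) {
    stop_arity(sprintf(
      "%s takes %d parameter(s) (%s), got %d.",
      model, length(wanted), paste(wanted, collapse = ", "), length(params)
    ))
  }
  if (!is.null(names(params)) && all(nzchar(names(params)))) {
    if (!setequal(names(params), wanted)) {
      stop_arity(sprintf(
        "Parameter names for %s must be {%s}, got {%s}.",
        model, paste(wanted, collapse = ", "), paste(names(params), collapse = ", ")
      ))
    }
    params <- params[wanted]
  } else {
    names(params) <- wanted
  }
  params
}

#' Evaluate a release-kinetics model
#'
#' Computes the predicted cumulative release percentage \eqn{Q_t} at the
#' given times for one of the four registered models.
#'
#' For the Korsmeyer-Peppas power law, \eqn{0^n} is defined as 0 for
#' \eqn{n > 0} so the curve passes through the origin; evaluation at
#' `t = 0` with `n <= 0` is a domain error.
#'
#' @param model Model name, one of [kinetic_model_names()].
#' @param params Numeric parameter vector, either positional in canonical
#'   order or named (`K0, b0`; `K1, a, b1`; `KH, bH`; `K, n`).
#' @param t Numeric vector of times in minutes, all `>= 0`.
#' @return Numeric vector of predicted cumulative release percentages.
#' @export
#' @examples
#' evaluate_model("zero_order", c(K0 = 0.00363, b0 = 7.7436), t = c(0, 1000))
#' evaluate_model("korsmeyer_peppas", c(K = 0.3556, n = 0.5381), t = 100)
evaluate_model <- function(model, params, t) {
  model <- match_model(model)
  params <- canonical_params(model, params)
  if (!is.numeric(t) || anyNA(t)) {
    stop_domain("`t` must be numeric and non-missing.")
  }
  if (any(t < 0)) {
    stop_domain("Times must be non-negative.")
  }
  switch(model,
    zero_order = params[["K0"]] * t + params[["b0"]],
    first_order = params[["K1"]] * exp(params[["a"]] * t) + params[["b1"]],
    higuchi = params[["KH"]] * sqrt(t) + params[["bH"]],
    korsmeyer_peppas = {
      n <- params[["n"]]
      if (any(t == 0) && n <= 0) {
        stop_domain("korsmeyer_peppas at t = 0 requires n > 0.")
      }
      out <- params[["K"]] * t^n
      # R evaluates 0^n correctly for n > 0 (gives 0); nothing to patch.
      out
    }
  )
}
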