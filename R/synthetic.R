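# Synthetic release curves: model mean plus additive homoscedastic
# Gaussian noise on the percent scale (optionally multiplicative for
# sensitivity studies). The generator stands in for unavailable raw
# release data; its defaults mimic a typical dissolution assay (34
# samples, denser early sampling) while keeping Korsmeyer-Peppas curves
# inside their 60 % validity window.

#' Default sampling grid for a model
#'
#' 34 time points starting at 5 min. The grid is logarithmically spaced
#' (denser early sampling, as in release assays) up to an upper limit
#' chosen from the model itself: for the Korsmeyer-Peppas power law the
#' grid stops at 95 % of the time the curve crosses `kp_cutoff` percent,
#' and for the unbounded linear forms where it would cross 100 %; grids
#' that would end within 200 min are linearly spaced (fast, burst-type
#' release), longer ones logarithmically. Models with a negative intercept
#' start just after their zero crossing so the noiseless curve stays in
#' the valid release window.
#'
#' @param model Model name.
#' @param params Parameter vector for the model.
#' @param n_points Number of samples (default 34).
#' @param t_min,t_max Grid limits in minutes before capping.
#' @param kp_cutoff Validity cutoff used to cap Korsmeyer-Peppas grids.
#' @return Strictly increasing numeric vector of times in minutes.
#' @export
#' @examples
#' release_time_grid("korsmeyer_peppas", c(K = 8.2661, n = 0.3732))
release_time_grid <- function(model, params, n_points = 34L, t_min = 5,
                              t_max = 5000, kp_cutoff = 60) {
  model <- match_model(model)
  params <- canonical_params(model, params)
  cap <- switch(model,
    korsmeyer_peppas = {
      K <- params[["K"]]; n <- params[["n"]]
      if (K > 0 && n > 0) 0.95 * (kp_cutoff / K)^(1 / n) else t_max
    },
    zero_order = {
      K0 <- params[["K0"]]
      if (K0 > 0) (100 - params[["b0"]]) / K0 else t_max
    },
    higuchi = {
      KH <- params[["KH"]]
      if (KH > 0) ((100 - params[["bH"]]) / KH)^2 else t_max
    },
    first_order = t_max # bounded above by b1
  )
  floor_t <- switch(model,
    higuchi = if (params[["bH"]] < 0 && params[["KH"]] > 0) {
      (-params[["bH"]] / params[["KH"]])^2
    } else 0,
    zero_order = if (params[["b0"]] < 0 && params[["K0"]] > 0) {
      -params[["b0"]] / params[["K0"]]
    } else 0,
    0
  )
  t_min <- max(t_min, 1.05 * floor_t)
  t_max <- max(min(t_max, cap), t_min * 2)
  if (t_max <= 200) {
    seq(t_min, t_max, length.out = n_points)
  } else {
    exp(seq(log(t_min), log(t_max), length.out = n_points))
  }
}

#' Simulate a release curve
#'
#' Evaluates a release model on a time grid and adds independent Gaussian
#' observation noise: `Q_i = f(t_i; params) + eps_i` with
#' `eps_i ~ N(0, noise_sd^2)` (or `f * (1 + eps_i)` in multiplicative
#' mode). Identical `seed` and arguments give bit-identical curves. Values
#' are not clipped by default; `clip_at_zero = TRUE` floors them at 0.
#'
#' @param model Model name, one of [kinetic_model_names()].
#' @param params Parameter vector (named or canonical order).
#' @param times Strictly increasing times in minutes (for
#'   `korsmeyer_peppas` all `> 0` unless `n > 0`). Defaults to
#'   [release_time_grid()].
#' @param noise_sd Additive noise standard deviation in percent (`>= 0`).
#' @param seed Optional integer seed; when supplied the generator is
#'   deterministic and the seed is recorded as an attribute.
#' @param drug_id Optional label attached as column `drug`.
#' @param noise `"additive"` (default) or `"multiplicative"`.
#' @param clip_at_zero Floor noisy values at 0 (default `FALSE`).
#' @return Tibble with columns (`drug`,) `time_min`, `Q_percent`;
#'   attributes `model`, `params`, `seed`.
#' @export
#' @examples
#' simulate_release("zero_order", c(K0 = 0.00363, b0 = 7.7436),
#'                  times = seq(100, 1000, by = 100))
simulate_release <- function(model, params, times = NULL, noise_sd = 0,
                             seed = NULL, drug_id = NULL,
                             noise = c("additive", "multiplicative"),
                             clip_at_zero = FALSE) {
  model <- match_model(model)
  params <- canonical_params(model, params)
  noise <- match.arg(noise)
  if (is.null(times)) times <- release_time_grid(model, params)
  check_times(times)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop_domain("`noise_sd` must be a single non-negative number.")
  }
  mean_q <- evaluate_model(model, params, times)
  bad <- mean_q < 0 | mean_q > 110
  if (any(bad)) {
    warn(sprintf(
      "Noiseless curve leaves the valid release window [0, 110] at t = %s.",
      paste(signif(times[bad], 6), collapse = ", ")
    ))
  }
  draw <- function() rnorm(length(times), 0, noise_sd)
  eps <- if (noise_sd == 0) {
    rep(0, length(times))
  } else if (is.null(seed)) {
    draw()
  } else {
    withr::with_seed(as.integer(seed), draw())
  }
  q <- if (noise == "additive") mean_q + eps else mean_q * (1 + eps)
  if (clip_at_zero) q <- pmax(q, 0)
  out <- tibble(time_min = as.numeric(times), Q_percent = q)
  if (!is.null(drug_id)) out <- dplyr::mutate(out, drug = drug_id, .before = 1L)
  attr(out, "model") <- model
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}

#' Simulate a curve from a reference fitted equation
#'
#' Convenience wrapper: looks up the fitted parameters for
#' `(drug, model)` in [release_fixtures()] and simulates on the default
#' grid for that equation.
#'
#' @inheritParams simulate_release
#' @param drug Drug label (see [reference_drugs()]).
#' @param ... Passed to [simulate_release()].
#' @return Tibble as for [simulate_release()], with a `drug` column.
#' @export
#' @examples
#' simulate_fixture("PHBA", "korsmeyer_peppas")
simulate_fixture <- function(drug, model, times = NULL, ...) {
  params <- fixture_params(drug, model)
  if (is.null(times)) times <- release_time_grid(model, params)
  simulate_release(model, params, times = times, drug_id = drug, ...)
}
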