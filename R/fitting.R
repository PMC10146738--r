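# Least-squares fitting of the four models on the untransformed Qt scale,
# with the Origin-style metric set (adjusted R^2, RSS, reduced chi-squared
# with unit weights, Pearson's r between observed and predicted). The two
# linear forms are solved in closed form; the two nonlinear forms use
# Levenberg-Marquardt from deterministic starting values with a few
# seeded jittered restarts as a fallback.

#' Adjusted R-squared of a fit
#'
#' \eqn{1 - \frac{RSS/(N-p)}{TSS/(N-1)}} with
#' \eqn{TSS = \sum (y_i - \bar y)^2}.
#'
#' @param observed,predicted Numeric vectors of equal length
#'   `N >= n_params + 2`.
#' @param n_params Number of fitted parameters `p`.
#' @return Adjusted R-squared (dimensionless, `<= 1`).
#' @export
adj_r_square <- function(observed, predicted, n_params) {
  n <- length(observed)
  if (length(predicted) != n) stop_domain("`observed` and `predicted` lengths differ.")
  if (n < n_params + 2L) {
    stop_insufficient("adj_r_square needs at least n_params + 2 points.")
  }
  tss <- sum((observed - mean(observed))^2)
  if (tss <= 0) {
    stop_undefined_stat("adj_r_square is undefined for constant observations (zero TSS).")
  }
  rss <- sum((observed - predicted)^2)
  1 - (rss / (n - n_params)) / (tss / (n - 1))
}

#' Pearson correlation between observed and predicted values
#'
#' A single goodness-of-fit definition valid for all four models: the
#' sample correlation between the observations and the model predictions.
#'
#' @param observed,predicted Numeric vectors of equal length `>= 3`,
#'   neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3L) {
    stop_domain("pearson_r needs two equal-length vectors of at least 3 points.")
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop_undefined_stat("pearson_r is undefined for a constant vector.")
  }
  cor(observed, predicted)
}

#' Reduced chi-squared with unit weights
#'
#' Residual sum of squares divided by the residual degrees of freedom,
#' \eqn{RSS / (N - p)}.
#'
#' @param rss Residual sum of squares (percent squared, `>= 0`).
#' @param n_used Number of fitted points `N`.
#' @param n_params Number of fitted parameters `p` (`< n_used`).
#' @return Reduced chi-squared in percent squared.
#' @export
#' @examples
#' reduced_chi_sq(137.58277, n_used = 34, n_params = 3)
reduced_chi_sq <- function(rss, n_used, n_params) {
  if (n_used <= n_params) stop_domain("Degrees of freedom must be positive.")
  if (rss < 0) stop_domain("`rss` must be non-negative.")
  rss / (n_used - n_params)
}

#' Restrict a curve to the Korsmeyer-Peppas validity window
#'
#' The power law is valid for the first 60 % of fractional release. The
#' rule is a prefix rule: points are kept strictly below the cutoff up to
#' the first crossing; everything at or after the crossing is excluded,
#' even if later values dip back below the cutoff.
#'
#' @param data Data frame with columns `time_min`, `Q_percent`.
#' @param cutoff Cumulative-release cutoff in percent (default 60).
#' @return The retained prefix as a tibble (possibly with zero rows).
#' @export
#' @examples
#' curve <- tibble::tibble(time_min = 1:5, Q_percent = c(10, 30, 55, 70, 80))
#' restrict_kp_domain(curve)
restrict_kp_domain <- function(data, cutoff = 60) {
  cols <- curve_columns(data)
  if (nrow(data) == 0L) stop_validation("Release curve is empty.")
  below <- cols$q < cutoff
  n_keep <- if (all(below)) length(below) else which(!below)[1L] - 1L
  as_tibble(data[seq_len(n_keep), , drop = FALSE])
}

# ---- starting values ---------------------------------------------------

start_korsmeyer_peppas <- function(t, q) {
  ok <- t > 0 & q > 0
  if (sum(ok) < 2L) {
    stop_insufficient("Not enough positive (t, Qt) pairs to start the power-law fit.")
  }
  fit <- lm(log(q[ok]) ~ log(t[ok]))
  c(K = unname(exp(coef(fit)[1L])), n = unname(coef(fit)[2L]))
}

start_first_order <- function(t, q) {
  b1 <- 1.05 * max(q)
  r <- b1 - q
  fit <- lm(log(r) ~ t)
  c(K1 = -unname(exp(coef(fit)[1L])), a = unname(coef(fit)[2L]), b1 = b1)
}

fit_nls <- function(formula, data, start, max_restarts, seed) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1024, ftol = 1e-10, ptol = 1e-12)
  attempt <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = as.list(st), control = ctrl),
      error = function(e) NULL
    )
  }
  fit <- attempt(start)
  restart <- 0L
  while (is.null(fit) && restart < max_restarts) {
    restart <- restart + 1L
    jitter <- withr::with_seed(seed + restart, rnorm(length(start), 0, 0.2))
    fit <- attempt(start * exp(jitter))
  }
  fit
}

# ---- fitting -----------------------------------------------------------

#' Fit one release-kinetics model to a curve
#'
#' Minimizes the squared error between observed and predicted cumulative
#' release on the untransformed percent scale. `zero_order` and `higuchi`
#' are solved by ordinary least squares on `t` and `sqrt(t)`; `first_order`
#' and `korsmeyer_peppas` by Levenberg-Marquardt from deterministic
#' starting values (log-linear regressions), with up to `max_restarts`
#' seeded jittered restarts on failure. For `korsmeyer_peppas` the curve is
#' first restricted with [restrict_kp_domain()].
#'
#' @param data Data frame with columns `time_min`, `Q_percent`.
#' @param model Model name, one of [kinetic_model_names()].
#' @param kp_cutoff Korsmeyer-Peppas validity cutoff in percent
#'   (default 60).
#' @param fit_scale `"untransformed"` (default) or `"linearized"`; the
#'   linearized mode fits the Korsmeyer-Peppas model by log-log ordinary
#'   least squares (a sensitivity check, not the primary estimator).
#' @param max_restarts Maximum jittered restarts for the iterative fits.
#' @param seed Integer seed driving the restart jitter (deterministic).
#' @return An object of class `release_fit`: fitted parameters, the four
#'   goodness-of-fit metrics, the fitted points and a convergence flag.
#'   Supports [tidy()], [glance()], [augment()] and [autoplot()].
#' @export
#' @examples
#' curve <- simulate_release("korsmeyer_peppas", c(K = 0.3556, n = 0.5381),
#'                           times = seq(100, 3000, by = 100))
#' fit <- fit_release_model(curve, "korsmeyer_peppas")
#' glance(fit)
fit_release_model <- function(data, model,
                              kp_cutoff = 60,
                              fit_scale = c("untransformed", "linearized"),
                              max_restarts = 3L,
                              seed = 1L) {
  model <- match_model(model)
  fit_scale <- match.arg(fit_scale)
  cols <- curve_columns(data)
  check_times(cols$time)
  if (model == "korsmeyer_peppas") {
    kept <- restrict_kp_domain(data, cutoff = kp_cutoff)
    if (nrow(kept) < 3L) {
      stop_insufficient(sprintf(
        "Only %d point(s) below the %g %% cutoff; at least 3 are required for the Korsmeyer-Peppas fit.",
        nrow(kept), kp_cutoff
      ))
    }
    cols <- curve_columns(kept)
  }
  t <- as.numeric(cols$time)
  q <- as.numeric(cols$q)
  p <- .model_registry$n_params[match(model, .model_registry$model)]
  if (length(t) < p + 1L) {
    stop_insufficient(sprintf(
      "%s needs at least %d points, got %d.", model, p + 1L, length(t)
    ))
  }

  converged <- TRUE
  params <- switch(model,
    zero_order = {
      fit <- lm(q ~ t)
      c(K0 = unname(coef(fit)[2L]), b0 = unname(coef(fit)[1L]))
    },
    higuchi = {
      st <- sqrt(t)
      fit <- lm(q ~ st)
      c(KH = unname(coef(fit)[2L]), bH = unname(coef(fit)[1L]))
    },
    korsmeyer_peppas = {
      start <- start_korsmeyer_peppas(t, q)
      if (fit_scale == "linearized") {
        start
      } else {
        df <- data.frame(t = t, q = q)
        fit <- fit_nls(q ~ K * t^n, df, start, max_restarts, seed)
        if (is.null(fit)) {
          converged <- FALSE
          start
        } else {
          coef(fit)[c("K", "n")]
        }
      }
    },
    first_order = {
      start <- start_first_order(t, q)
      df <- data.frame(t = t, q = q)
      fit <- fit_nls(q ~ K1 * exp(a * t) + b1, df, start, max_restarts, seed)
      if (is.null(fit)) {
        converged <- FALSE
        start
      } else {
        coef(fit)[c("K1", "a", "b1")]
      }
    }
  )
  params <- canonical_params(model, params)
  predicted <- evaluate_model(model, params, t)
  rss <- sum((q - predicted)^2)
  metrics <- list(
    adj_r_square = tryCatch(adj_r_square(q, predicted, p), error = function(e) NA_real_),
    pearson_r = tryCatch(pearson_r(q, predicted), error = function(e) NA_real_),
    reduced_chi_sq = reduced_chi_sq(rss, length(t), p)
  )
  structure(
    list(
      model = model,
      params = params,
      n_used = length(t),
      dof = length(t) - p,
      rss = rss,
      reduced_chi_sq = metrics$reduced_chi_sq,
      adj_r_square = metrics$adj_r_square,
      pearson_r = metrics$pearson_r,
      converged = converged,
      data = tibble(time_min = t, observed = q, predicted = predicted),
      equation = format_equation(model, params)
    ),
    class = "release_fit"
  )
}

#' Fit all (or a subset of) the release-kinetics models to one curve
#'
#' @inheritParams fit_release_model
#' @param models Character vector of model names (default: all four).
#' @param ... Passed on to [fit_release_model()].
#' @return An object of class `release_fit_set`: a named list of
#'   `release_fit` objects. Supports [tidy()], [glance()] and
#'   [autoplot()]; feed it to [rank_models()] to select a winner.
#' @export
fit_release_models <- function(data, models = kinetic_model_names(), ...) {
  models <- vapply(models, match_model, character(1))
  # lapply, not purrr::map: per-model errors must propagate unwrapped so the
  # batch pipeline can classify them
  fits <- lapply(models, function(m) fit_release_model(data, m, ...))
  names(fits) <- models
  structure(fits, class = "release_fit_set")
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf("<release_fit> %s: %s\n", x$model, x$equation))
  cat(sprintf(
    "  n = %d, dof = %d, adj R2 = %.5f, RSS = %.5f, red. chi2 = %.5f, r = %.5f, converged: %s\n",
    x$n_used, x$dof, x$adj_r_square, x$rss, x$reduced_chi_sq, x$pearson_r, x$converged
  ))
  invisible(x)
}

#' @export
print.release_fit_set <- function(x, ...) {
  cat(sprintf("<release_fit_set> %d model(s)\n", length(x)))
  for (f in x) print(f)
  invisible(x)
}
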