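test_that("the 60 % window is a prefix rule", {
  curve <- tibble::tibble(time_min = 1:5, Q_percent = c(10, 30, 55, 70, 80))
  expect_equal(nrow(restrict_kp_domain(curve)), 3L)
  # never reaching the cutoff keeps everything
  low <- tibble::tibble(time_min = 1:3, Q_percent = c(10, 20, 30))
  expect_equal(nrow(restrict_kp_domain(low)), 3L)
  # later sub-cutoff points after the first crossing are not re-admitted
  dip <- tibble::tibble(time_min = 1:4, Q_percent = c(10, 65, 50, 55))
  expect_equal(nrow(restrict_kp_domain(dip)), 1L)
  # the boundary value itself is excluded
  edge <- tibble::tibble(time_min = 1:3, Q_percent = c(10, 60, 70))
  expect_equal(nrow(restrict_kp_domain(edge)), 1L)
  expect_error(restrict_kp_domain(curve[0, ]), class = "relkin_validation_error")
})

test_that("adjusted R-squared matches its definition on a hand-computed case", {
  obs <- c(1, 2, 3, 5)
  pred <- c(1.1, 1.9, 3.2, 4.8)
  # hand arithmetic: RSS = 0.10, TSS = 8.75, N = 4, p = 2
  # 1 - (0.10 / 2) / (8.75 / 3)
  expect_equal(adj_r_square(obs, pred, 2), 0.982857142857143)
  expect_equal(adj_r_square(obs, obs, 1), 1)
  # predicting the mean with one parameter gives exactly 0
  expect_equal(adj_r_square(obs, rep(mean(obs), 4), 1), 0)
  expect_error(adj_r_square(rep(2, 5), rep(2, 5), 1), class = "relkin_undefined_statistic_error")
})

test_that("pearson_r is the observed-vs-predicted correlation", {
  expect_equal(pearson_r(c(1, 2, 4), c(1, 2, 4)), 1)
  expect_equal(pearson_r(c(1, 2, 4), -c(1, 2, 4)), -1)
  expect_equal(pearson_r(c(1, 2, 4), c(2, 3, 5)), 1) # affine relation
  expect_error(pearson_r(c(1, 2, 4), c(3, 3, 3)), class = "relkin_undefined_statistic_error")
})

test_that("reduced chi-squared is RSS over residual degrees of freedom", {
  expect_equal(reduced_chi_sq(137.58277, 34, 3), 4.43815, tolerance = 1e-5)
  expect_equal(reduced_chi_sq(93.76934, 30, 2), 3.34891, tolerance = 1e-5)
  expect_equal(reduced_chi_sq(0, 10, 2), 0)
  expect_error(reduced_chi_sq(1, 3, 3), class = "relkin_domain_error")
})

test_that("noiseless data round-trips through every model fit", {
  cases <- list(
    list(model = "zero_order", params = c(K0 = 0.00363, b0 = 7.7436), tol = 1e-6),
    list(model = "higuchi", params = c(KH = 0.5086, bH = -0.1951), tol = 1e-6),
    list(model = "korsmeyer_peppas", params = c(K = 0.2575, n = 0.6062), tol = 1e-4),
    list(model = "first_order", params = c(K1 = -59.78837, a = -0.00017754, b1 = 61.99435), tol = 1e-4)
  )
  grid <- seq(100, 3000, by = 100)
  for (case in cases) {
    curve <- simulate_release(case$model, case$params, times = grid)
    fit <- fit_release_model(curve, case$model)
    expect_true(fit$converged)
    for (term in names(case$params)) {
      expect_rel_error(fit$params[[term]], case$params[[term]], case$tol)
    }
    expect_lt(fit$rss, 1e-8)
    expect_equal(fit$adj_r_square, 1, tolerance = 1e-8)
  }
})

test_that("round trips hold across random parameter draws", {
  draws <- withr::with_seed(42, {
    list(
      zero_order = replicate(5, c(K0 = runif(1, 0.001, 0.02), b0 = runif(1, 0, 20)), simplify = FALSE),
      higuchi = replicate(5, c(KH = runif(1, 0.2, 1), bH = runif(1, -5, 5)), simplify = FALSE),
      korsmeyer_peppas = replicate(5, c(K = runif(1, 0.2, 5), n = runif(1, 0.2, 0.9)), simplify = FALSE),
      first_order = replicate(5, {
        b1 <- runif(1, 40, 95)
        c(K1 = -runif(1, 0.6, 0.95) * b1, a = -runif(1, 1e-4, 5e-3), b1 = b1)
      }, simplify = FALSE)
    )
  })
  for (model in names(draws)) {
    for (params in draws[[model]]) {
      grid <- release_time_grid(model, params, n_points = 20)
      curve <- simulate_release(model, params, times = grid)
      fit <- fit_release_model(curve, model)
      tol <- if (model %in% c("zero_order", "higuchi")) 1e-6 else 1e-4
      for (term in names(params)) {
        expect_rel_error(fit$params[[term]], params[[term]], tol)
      }
    }
  }
})

test_that("reduced chi-squared times dof recovers RSS exactly", {
  curve <- simulate_release("korsmeyer_peppas", c(K = 0.5, n = 0.5),
                            times = seq(10, 500, by = 10), noise_sd = 2, seed = 7)
  for (model in kinetic_model_names()) {
    fit <- fit_release_model(curve, model)
    expect_equal(fit$reduced_chi_sq * fit$dof, fit$rss, tolerance = 1e-14)
    expect_equal(fit$dof, fit$n_used - kinetic_models()$n_params[kinetic_models()$model == model])
  }
})

test_that("closed-form linear fits agree with the iterative optimizer started from them", {
  curve <- simulate_release("higuchi", c(KH = 0.6, bH = 2),
                            times = seq(5, 2000, length.out = 25), noise_sd = 1.5, seed = 11)
  for (model in c("zero_order", "higuchi")) {
    fit <- fit_release_model(curve, model)
    x <- if (model == "zero_order") curve$time_min else sqrt(curve$time_min)
    df <- data.frame(x = x, q = curve$Q_percent)
    it <- minpack.lm::nlsLM(q ~ slope * x + intercept, data = df,
                            start = list(slope = fit$params[[1]], intercept = fit$params[[2]]))
    expect_rel_error(coef(it)[["slope"]], fit$params[[1]], 1e-9)
    expect_rel_error(coef(it)[["intercept"]], fit$params[[2]], 1e-9)
  }
})

test_that("adjusted R-squared is invariant when the time axis is rescaled and refit", {
  curve <- simulate_release("korsmeyer_peppas", c(K = 0.4, n = 0.55),
                            times = seq(10, 800, by = 20), noise_sd = 1, seed = 3)
  for (model in kinetic_model_names()) {
    fit <- fit_release_model(curve, model)
    rescaled <- dplyr::mutate(curve, time_min = time_min * 3.7)
    refit <- fit_release_model(rescaled, model)
    expect_equal(refit$adj_r_square, fit$adj_r_square, tolerance = 1e-6)
  }
})

test_that("degenerate and undersized inputs are rejected or handled", {
  flat <- tibble::tibble(time_min = c(1, 2, 3, 4), Q_percent = rep(12, 4))
  fit <- fit_release_model(flat, "zero_order")
  expect_equal(fit$params[["K0"]], 0, tolerance = 1e-12)
  expect_equal(fit$params[["b0"]], 12)
  expect_true(is.na(fit$adj_r_square)) # zero TSS: statistic undefined

  tiny <- tibble::tibble(time_min = 1:2, Q_percent = c(1, 2))
  expect_error(fit_release_model(tiny, "first_order"), class = "relkin_insufficient_data_error")
  # fewer than 3 points below the cutoff
  high <- tibble::tibble(time_min = 1:5, Q_percent = c(10, 55, 70, 80, 90))
  expect_error(fit_release_model(high, "korsmeyer_peppas"),
               class = "relkin_insufficient_data_error")
})

test_that("the linearized power-law mode matches log-log least squares", {
  curve <- simulate_release("korsmeyer_peppas", c(K = 0.9, n = 0.45),
                            times = seq(20, 600, by = 20), noise_sd = 1, seed = 5)
  fit <- fit_release_model(curve, "korsmeyer_peppas", fit_scale = "linearized")
  ols <- lm(log(Q_percent) ~ log(time_min), data = curve)
  expect_equal(fit$params[["K"]], exp(unname(coef(ols)[1])))
  expect_equal(fit$params[["n"]], unname(coef(ols)[2]))
})
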