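test_that("loading capacity follows (kA + b) V / G", {
  expect_equal(
    loading_capacity(0, slope_k = 0.05, intercept_b = 0, volume_l = 0.25, fabric_mass_g = 1),
    0
  )
  expect_equal(
    loading_capacity(0.5, slope_k = 0.04, intercept_b = 0.002, volume_l = 0.25, fabric_mass_g = 2),
    0.00275
  )
  expect_equal(
    loading_capacity(1, slope_k = 1, intercept_b = 0, volume_l = 1, fabric_mass_g = 1),
    1
  )
  expect_error(
    loading_capacity(1, slope_k = 1, intercept_b = 0, volume_l = 1, fabric_mass_g = 0),
    class = "relkin_domain_error"
  )
  expect_warning(
    loading_capacity(0.01, slope_k = 0.1, intercept_b = -0.5, volume_l = 1, fabric_mass_g = 1),
    "below the calibration range"
  )
})

test_that("loading capacity is linear in the calibrated concentration", {
  base <- loading_capacity(0.3, slope_k = 0.04, intercept_b = 0, volume_l = 0.25, fabric_mass_g = 2)
  doubled <- loading_capacity(0.6, slope_k = 0.04, intercept_b = 0, volume_l = 0.25, fabric_mass_g = 2)
  expect_equal(doubled, 2 * base)
})

test_that("cumulative release normalizes released mass against the loading", {
  expect_equal(
    cumulative_release(0.5, slope_k = 0.04, intercept_b = 0.002, volume_l = 0.15,
                       fabric_mass_g = 1, loading = 0.0066),
    50
  )
  # released mass exactly LA * G1 gives 100 %
  expect_equal(
    cumulative_release(1, slope_k = 0.01, intercept_b = 0, volume_l = 0.2,
                       fabric_mass_g = 1, loading = 0.002),
    100
  )
  # zero concentration gives zero release
  expect_equal(
    cumulative_release(0, slope_k = 0.04, intercept_b = 0, volume_l = 0.15,
                       fabric_mass_g = 1, loading = 0.01),
    0
  )
  expect_error(
    cumulative_release(0.5, slope_k = 0.04, intercept_b = 0, volume_l = 0.15,
                       fabric_mass_g = 1, loading = 0),
    class = "relkin_domain_error"
  )
})

test_that("absolute released mass is independent of the normalizer", {
  # Qt * LA = (k At + b) V1 / G1 * 100 regardless of LA
  for (la in c(0.001, 0.0066, 0.5)) {
    q <- cumulative_release(0.5, slope_k = 0.04, intercept_b = 0.002, volume_l = 0.15,
                            fabric_mass_g = 2, loading = la)
    expect_equal(q * la, (0.04 * 0.5 + 0.002) * 0.15 / 2 * 100)
  }
})

test_that("quantify_release builds, validates, and preserves length", {
  readings <- tibble::tibble(
    time_min = c(10, 20, 40, 80, 160),
    absorbance = rep(0.2, 5)
  )
  curve <- quantify_release(readings, slope_k = 0.05, intercept_b = 0,
                            volume_l = 0.15, fabric_mass_g = 1, loading = 0.01)
  expect_equal(nrow(curve), 5L)
  expect_equal(unique(curve$Q_percent), 15) # constant absorbance, constant release
  expect_named(curve, c("time_min", "Q_percent"))

  # a point above 110 % fails validation
  hot <- tibble::tibble(time_min = c(1, 2, 3, 4), absorbance = c(0.1, 0.2, 0.3, 2.4))
  expect_error(
    quantify_release(hot, slope_k = 0.05, intercept_b = 0, volume_l = 0.15,
                     fabric_mass_g = 1, loading = 0.01),
    class = "relkin_validation_error"
  )
  # (100, 110] passes with a warning
  warm <- tibble::tibble(time_min = c(1, 2, 3, 4), absorbance = c(0.1, 0.2, 0.3, 1.4))
  expect_warning(
    quantify_release(warm, slope_k = 0.05, intercept_b = 0, volume_l = 0.15,
                     fabric_mass_g = 1, loading = 0.01),
    "exceeds 100"
  )

  expect_error(
    quantify_release(readings[0, ], slope_k = 0.05, intercept_b = 0,
                     volume_l = 0.15, fabric_mass_g = 1, loading = 0.01),
    class = "relkin_insufficient_data_error"
  )
  disordered <- tibble::tibble(time_min = c(10, 10, 20, 30), absorbance = rep(0.1, 4))
  expect_error(
    quantify_release(disordered, slope_k = 0.05, intercept_b = 0,
                     volume_l = 0.15, fabric_mass_g = 1, loading = 0.01),
    class = "relkin_ordering_error"
  )
})
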