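test_that("selection shortlists on adjusted R-squared and then minimizes RSS", {
  # published metric set where the power law wins on smaller RSS and chi2
  phba <- release_fixtures(drug = "PHBA")
  cmp <- rank_models(phba)
  expect_s3_class(cmp, "model_comparison")
  expect_equal(cmp$selected, "korsmeyer_peppas")
  expect_equal(cmp$rationale[1], "adj_r2")
  expect_true("rss" %in% cmp$rationale)

  # metric set where the winner's reduced chi2 exceeds the runner-up's:
  # the RSS criterion dominates
  mba2 <- release_fixtures(drug = "2-MBA")
  kp <- mba2[mba2$model == "korsmeyer_peppas", ]
  fo <- mba2[mba2$model == "first_order", ]
  expect_gt(kp$reduced_chi_sq, fo$reduced_chi_sq)
  expect_lt(kp$rss, fo$rss)
  expect_equal(rank_models(mba2)$selected, "korsmeyer_peppas")
})

test_that("ties break deterministically by registry order and are flagged", {
  twin <- tibble::tibble(
    model = c("higuchi", "zero_order"),
    adj_r_square = c(0.95, 0.95),
    rss = c(10, 10),
    reduced_chi_sq = c(1, 1)
  )
  cmp <- rank_models(twin)
  expect_equal(cmp$selected, "zero_order") # registry order, not input order
  expect_true("tie" %in% cmp$rationale)
})

test_that("ranking is permutation-invariant and returns a member of its input", {
  metrics <- release_fixtures(drug = "EPAB")
  perms <- list(1:4, 4:1, c(2, 4, 1, 3))
  selected <- vapply(
    perms,
    function(p) rank_models(metrics[p, ])$selected,
    character(1)
  )
  expect_equal(unique(selected), "korsmeyer_peppas")
  expect_true(all(selected %in% metrics$model))
})

test_that("ranking rejects degenerate inputs", {
  expect_error(rank_models(release_fixtures(drug = "PHBA")[1, ]),
               class = "relkin_selection_error")
  dead <- tibble::tibble(
    model = c("zero_order", "higuchi"), adj_r_square = c(0.9, 0.8),
    rss = c(1, 2), converged = FALSE
  )
  expect_error(rank_models(dead), class = "relkin_selection_error")
})

test_that("the exponent classifies transport with cylinder thresholds", {
  expect_equal(classify_mechanism(0.5381), "non_fickian")
  expect_equal(classify_mechanism(0.3732), "fickian")
  expect_equal(classify_mechanism(0.89), "case_II")
  expect_equal(classify_mechanism(0.95), "super_case_II")
  # closed lower boundary keeps the partition exhaustive
  expect_equal(classify_mechanism(0.45), "non_fickian")
  expect_error(classify_mechanism(0.5, geometry = "slab"), class = "relkin_config_error")
  expect_error(classify_mechanism(NaN), class = "relkin_domain_error")
})

test_that("classification is monotone in n", {
  grid <- seq(0.05, 1.3, by = 0.005)
  classes <- classify_mechanism(grid)
  rank <- match(classes, c("fickian", "non_fickian", "case_II", "super_case_II"))
  expect_true(all(diff(rank) >= 0))
})

test_that("burst flagging is an inclusive threshold on K", {
  expect_true(flag_burst(8.2661))
  expect_false(flag_burst(0.3556))
  expect_true(flag_burst(6)) # boundary inclusive
  expect_error(flag_burst(-1), class = "relkin_domain_error")
  expect_error(flag_burst(1, threshold = 0), class = "relkin_config_error")
})

test_that("mechanism_call bundles classification and burst from a power-law fit", {
  curve <- noiseless_fixture_curve("BPAB", "korsmeyer_peppas")
  fit <- fit_release_model(curve, "korsmeyer_peppas")
  call <- mechanism_call(fit)
  expect_equal(call$transport_class, "fickian")
  expect_true(call$burst_flag)
  expect_equal(call$n, 0.3732, tolerance = 1e-4)
  other <- fit_release_model(curve, "zero_order")
  expect_error(mechanism_call(other), class = "relkin_validation_error")
})
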