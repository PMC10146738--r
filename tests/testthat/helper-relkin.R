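# Shared helpers: relative-error expectation and a noiseless fixture curve.

expect_rel_error <- function(actual, expected, tol) {
  expect_true(
    abs(actual - expected) <= tol * abs(expected),
    label = sprintf(
      "relative error of %.10g vs %.10g is %.3g (tol %.1g)",
      actual, expected, abs(actual - expected) / abs(expected), tol
    )
  )
}

# Noiseless curve from a reference fitted equation on its default grid.
noiseless_fixture_curve <- function(drug, model) {
  simulate_fixture(drug, model, noise_sd = 0)
}
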