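# Compare a prf object against expected (base, low, high) at a tolerance.
expect_prf_equal <- function(prf, base, low, high, tol = 1e-12) {
  expect_s3_class(prf, "prf")
  expect_equal(prf$base, base, tolerance = tol)
  expect_equal(prf$low, low, tolerance = tol)
  expect_equal(prf$high, high, tolerance = tol)
}

# A tiny inventory used across tests: 2 FULL, 1 PARTIAL, 1 NONE.
mixed_profile <- function(basis = "PERCENT") {
  use_profile("TEST", c("a", "b", "c", "d"), c(40, 30, 20, 10), basis,
              c("FULL", "FULL", "PARTIAL", "NONE"))
}
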