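test_that("bud_params constructs a valid default set", {
  p <- bud_params()
  expect_s3_class(p, "bud_params")
  expect_no_error(validate_bud_params(p))
  expect_equal(p$v0, 0.05)
  expect_equal(p$mu, 0.4)
})

test_that("invalid parameters are rejected with field-level messages", {
  expect_error(bud_params(mu = 0), "mu")
  expect_error(bud_params(v0 = -0.1), "v0")
  expect_error(bud_params(n = 0.5), "n")
  expect_error(bud_params(K = 0), "K")
  expect_error(bud_params(eta = -1), "eta")
  expect_error(bud_params(S = Inf), "S")
})

test_that("update replaces single fields and revalidates", {
  p <- bud_params()
  q <- update(p, v0 = 0.2)
  expect_equal(q$v0, 0.2)
  expect_equal(q$mu, p$mu)
  expect_error(update(p, mu = -1), "mu")
})

test_that("parameter YAML round trip is exact", {
  p <- bud_params(v0 = 0.123456789012345, eta = 0)
  f <- withr::local_tempfile(fileext = ".yml")
  write_bud_params(p, f)
  q <- read_bud_params(f)
  expect_equal(unclass(q), unclass(p), tolerance = 0)
})

test_that("default slice spans the calibrated ranges", {
  sl <- default_slice()
  expect_length(sl$v0, 159)
  expect_length(sl$mu, 159)
  expect_equal(range(sl$v0), c(0.005, 0.35))
  expect_equal(range(sl$mu), c(0.25, 2.0))
  expect_false(is.unsorted(sl$v0, strictly = TRUE))
})
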