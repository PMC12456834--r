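test_that("efflux rates at the dormant origin reduce to v0", {
  p <- bud_params()
  r <- efflux_rates(0, 0, p)
  expect_equal(r$dE, p$v0)
  expect_equal(r$dF, p$v0)
})

test_that("efflux rates are symmetric under bud swap", {
  p <- bud_params()
  a <- efflux_rates(0.7, 0.2, p)
  b <- efflux_rates(0.2, 0.7, p)
  expect_equal(a$dE, b$dF)
  expect_equal(a$dF, b$dE)
})

test_that("efflux rates are vectorized", {
  p <- bud_params()
  E <- c(0, 0.3, 1.2); F <- c(0.1, 0.3, 0.4)
  r <- efflux_rates(E, F, p)
  expect_length(r$dE, 3)
  one <- efflux_rates(E[2], F[2], p)
  expect_equal(r$dE[2], one$dE)
})

test_that("analytic efflux Jacobian matches finite differences", {
  p <- bud_params()
  for (st in list(c(0.2, 0.1), c(1.5, 0.4), c(2.3, 2.3))) {
    J <- efflux_jacobian(st[1], st[2], p)
    h <- 1e-7
    num <- matrix(NA_real_, 2, 2)
    base <- efflux_rates(st[1], st[2], p)
    dE1 <- efflux_rates(st[1] + h, st[2], p)
    dF1 <- efflux_rates(st[1], st[2] + h, p)
    num[1, 1] <- (dE1$dE - base$dE) / h
    num[1, 2] <- (dF1$dE - base$dE) / h
    num[2, 1] <- (dE1$dF - base$dF) / h
    num[2, 2] <- (dF1$dF - base$dF) / h
    expect_equal(J, num, tolerance = 1e-5)
  }
})

test_that("growth rate is a saturating Hill of efflux with half point Q", {
  p <- bud_params()
  g <- growth_rates(c(0, p$Q, 1e6), c(0, 0, 0), p)
  expect_equal(g$dN[1], 0)
  expect_equal(g$dN[2], 0.5)
  expect_lt(abs(g$dN[3] - 1), 1e-6)
  expect_false(is.unsorted(g$dN))
})

test_that("mutual inhibition: the competitor's efflux lowers dE", {
  p <- bud_params()
  lone <- efflux_rates(1, 0, p)$dE
  crowded <- efflux_rates(1, 2, p)$dE
  expect_lt(crowded, lone)
})
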