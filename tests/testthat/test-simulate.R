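test_that("deterministic simulation preserves bud symmetry exactly", {
  p0 <- update(bud_params(), eta = 0)
  tr <- simulate_explant(p0, t_end = 60, dt = 0.01)
  expect_equal(max(abs(tr$E - tr$F)), 0)
  expect_equal(max(abs(tr$N - tr$M)), 0)
})

test_that("same seed reproduces a stochastic trajectory bit for bit", {
  p <- bud_params()
  a <- simulate_explant(p, t_end = 40, dt = 0.1, seed = 99)
  b <- simulate_explant(p, t_end = 40, dt = 0.1, seed = 99)
  expect_identical(a$E, b$E)
  expect_identical(a$M, b$M)
  c <- simulate_explant(p, t_end = 40, dt = 0.1, seed = 100)
  expect_false(identical(a$E, c$E))
})

test_that("trajectories are recorded at unit steps including t = 0", {
  tr <- simulate_explant(bud_params(), t_end = 25, dt = 0.1, seed = 1)
  expect_equal(tr$t, 0:25)
  expect_equal(unname(unlist(tr[1, c("E", "F", "N", "M")])),
               c(0.01, 0.01, 0.1, 0.1))
})

test_that("state stays nonnegative and lengths are nondecreasing", {
  p <- update(bud_params(), eta = 0.1)  # strong noise exercises the clamp
  tr <- simulate_explant(p, t_end = 120, dt = 0.1, seed = 7)
  expect_true(all(tr$E >= 0 & tr$F >= 0))
  expect_true(all(diff(tr$N) >= 0))
  expect_true(all(diff(tr$M) >= 0))
  expect_gte(attr(tr, "clamps"), 0)
})

test_that("ensemble members use base_seed + i and are reproducible", {
  p <- bud_params()
  ens <- simulate_ensemble(p, n_sims = 3, t_end = 20, dt = 0.1, base_seed = 10)
  expect_equal(sort(unique(ens$sim)), 1:3)
  solo <- simulate_explant(p, t_end = 20, dt = 0.1, seed = 12)
  m2 <- ens[ens$sim == 2, c("t", "E", "F", "N", "M")]
  expect_equal(m2$E, solo$E)
})

test_that("zero-noise integrator tracks the independent reference", {
  p0 <- update(bud_params(), eta = 0)
  tr <- simulate_explant(p0, t_end = 60, dt = 5e-4)
  ref <- reference_trajectory(p0, times = 0:60)
  keep <- match(ref$t, tr$t)
  rel <- abs(tr$E[keep] - ref$E) / pmax(abs(ref$E), 1e-8)
  expect_lt(max(rel), 5e-3)
})

test_that("reference integrator refuses stochastic parameters", {
  expect_error(reference_trajectory(bud_params()), "eta")
})

test_that("switch time decreases when basal efflux rises", {
  p <- bud_params()
  expect_gt(switch_time(update(p, v0 = 0.02)),
            switch_time(update(p, v0 = 0.08)))
})

test_that("trajectory files round trip with metadata", {
  p <- bud_params()
  tr <- simulate_explant(p, t_end = 15, dt = 0.1, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(back$N, tr$N)
  expect_equal(attr(back, "seed"), 3)
  expect_equal(unclass(attr(back, "params")), unclass(p), tolerance = 0)
  expect_equal(attr(back, "clamps"), attr(tr, "clamps"))
})

test_that("invalid initial states are rejected", {
  expect_error(simulate_explant(bud_params(), init = c(E = -1, F = 0, N = 0, M = 0)),
               "init")
  expect_error(simulate_explant(bud_params(), init = c(E = 0.01, F = NA, N = 0.1, M = 0.1)),
               "init")
})
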