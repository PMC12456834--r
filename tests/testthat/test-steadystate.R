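test_that("symmetric steady states solve the fixed-point equation", {
  p <- bud_params()
  x <- symmetric_steady_states(p)
  expect_gt(length(x), 0)
  res <- abs(efflux_rates(x, x, p)$dE)
  expect_lt(max(res), 1e-9)
})

test_that("steady-state sets are swap-closed with small residuals", {
  p <- bud_params()
  ss <- find_steady_states(p)
  res <- efflux_rates(ss$E, ss$F, p)
  expect_lt(max(abs(res$dE), abs(res$dF)), 1e-9)
  # every asymmetric point has its mirror in the set
  for (i in which(abs(ss$E - ss$F) > 1e-5)) {
    d <- pmax(abs(ss$E - ss$F[i]), abs(ss$F - ss$E[i]))
    expect_lt(min(d), 1e-5)
  }
})

test_that("stability labels match the Jacobian eigenvalues", {
  p <- bud_params()
  ss <- find_steady_states(p)
  for (i in seq_len(nrow(ss))) {
    lab <- classify_stability(ss$E[i], ss$F[i], p)
    expect_equal(lab == "stable", ss$stable[i])
  }
  expect_true(all((ss$eig_max < 0) == ss$stable))
})

test_that("the reference parameter set is class 2 (both-or-one)", {
  ss <- find_steady_states(bud_params())
  cls <- classify_behavior(ss)
  expect_s3_class(cls, "behavior_class")
  expect_equal(cls$class_id, 2L)
  # one stable symmetric active state + one stable asymmetric pair
  st <- ss[ss$stable, ]
  expect_equal(nrow(st), 3)
  expect_equal(sum(abs(st$E - st$F) < 1e-5), 1)
})

test_that("behavior table enumerates the six classes once each", {
  tb <- behavior_table()
  expect_equal(tb$class_id, 1:6)
  expect_equal(anyDuplicated(tb$description), 0)
  expect_equal(anyDuplicated(tb$color_role), 0)
})

test_that("configurations outside the taxonomy raise budcanal_unclassifiable", {
  p <- bud_params()
  ss <- find_steady_states(p)
  # hand-build an impossible stable set: three symmetric stable points
  fake <- tibble::tibble(E = c(0.1, 0.5, 1.2), F = c(0.1, 0.5, 1.2),
                         stable = TRUE, eig_max = -1)
  fake <- structure(fake, class = class(ss),
                    params = p, tolerance = 1e-10, dedup_radius = 1e-6)
  expect_error(classify_behavior(fake), class = "budcanal_unclassifiable")
})

test_that("nullcline intersections land on the fixed points", {
  p <- bud_params()
  ss <- find_steady_states(p)
  nc <- nullclines(p, resolution = 301)
  expect_setequal(unique(nc$curve), c("dE", "dF"))
  # each fixed point lies within grid resolution of both curve families
  hi <- (p$v0 + p$v) / p$mu * 1.05
  h <- hi / 300
  for (i in seq_len(nrow(ss))) {
    for (cv in c("dE", "dF")) {
      seg <- nc[nc$curve == cv, ]
      d <- sqrt((seg$E - ss$E[i])^2 + (seg$F - ss$F[i])^2)
      expect_lt(min(d), 3 * h)
    }
  }
})

test_that("tidy and glance summarize a steady-state set", {
  ss <- find_steady_states(bud_params())
  td <- tidy(ss)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("E", "F", "stable", "eig_max"))
  gl <- glance(ss)
  expect_equal(gl$n_points, nrow(ss))
  expect_equal(gl$n_stable, sum(ss$stable))
})
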