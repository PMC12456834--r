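test_that("centered differences are exact on a quadratic", {
  t <- 0:10
  y <- 2 + 3 * t + 0.5 * t^2   # derivative 3 + t
  rs <- growth_rate_series(y, t, window = 1)
  inner <- 2:10
  expect_equal(rs$rate[inner], 3 + t[inner], tolerance = 1e-12)
})

test_that("activity uses a strict threshold", {
  expect_false(is_active(c(0, 2.5, 2.5), threshold = 2.5))
  expect_true(is_active(c(0, 2.5000001), threshold = 2.5))
})

test_that("lag time errors for an inactive bud", {
  expect_error(lag_time(c(0, 0.1), c(0, 1), threshold = 2.5), "inactive")
  expect_equal(lag_time(c(0, 1, 3, 4), c(0, 1, 2, 3), threshold = 2.5), 2)
})

test_that("RGI is bounded and errors on all-zero lengths", {
  expect_equal(relative_growth_index(5, 5), 0.5)
  expect_equal(relative_growth_index(0, 7), 1)
  expect_equal(relative_growth_index(c(2, 8), c(6, 8)), c(0.75, 0.5))
  expect_error(relative_growth_index(0, 0), "RGI")
})

test_that("growth outcome follows the ratio rule in simulated mode", {
  expect_equal(growth_outcome(9, 2, mode = "simulated"), "one")    # 9 > 3*2
  expect_equal(growth_outcome(6, 2.5, mode = "simulated"), "both") # 6 <= 7.5
  expect_equal(growth_outcome(0.5, 0.2, mode = "simulated"), "none")
  # experimental mode counts active flags
  expect_equal(growth_outcome(active_top = TRUE, active_bottom = FALSE,
                              mode = "experimental"), "one")
  expect_equal(growth_outcome(active_top = FALSE, active_bottom = FALSE,
                              mode = "experimental"), "none")
})

test_that("excluded explants are dropped before any computation", {
  tr <- tidyr::expand_grid(explant_id = c("a", "b"), bud = c("top", "bottom"),
                           t = 0:5) |>
    dplyr::mutate(label = "x",
                  length = 1 + 4 * t * (bud == "top"),
                  excluded = explant_id == "b")
  m <- trace_metrics(tr, mode = "experimental")
  expect_equal(nrow(m$explants), 1)
  expect_equal(m$explants$explant_id, "a")
  expect_equal(m$explants$outcome, "one")
  expect_equal(nrow(m$buds), 2)
})

test_that("per-bud metrics report lag, max rate and final length", {
  # top bud: flat 3 days then slope 4; bottom bud: flat
  t <- 0:10
  top <- c(rep(1, 4), 1 + 4 * (1:7))
  bottom <- rep(1, 11)
  tr <- dplyr::bind_rows(
    tibble::tibble(explant_id = "e1", label = "x", t = t, bud = "top",
                   length = top),
    tibble::tibble(explant_id = "e1", label = "x", t = t, bud = "bottom",
                   length = bottom))
  m <- trace_metrics(tr, mode = "experimental", window = 1)
  b <- m$buds[order(m$buds$bud), ]
  expect_equal(b$active, c(FALSE, TRUE))
  expect_true(is.na(b$lag[1]))
  expect_equal(b$lag[2], 4)          # first centered rate > 2.5 is at t = 4
  expect_equal(b$max_rate[2], 4)
  expect_equal(b$final_length[2], 29)
  expect_equal(m$explants$rgi, 29 / 30)
})

test_that("outcome_summary returns consistent fractions", {
  ex <- tibble::tibble(outcome = c("both", "one", "one", "none"))
  s <- outcome_summary(ex)
  expect_equal(s$p_both + s$p_one + s$p_none, 1)
  expect_equal(s$p_one, 0.5)
  expect_equal(s$pct_active, 75)
  expect_equal(s$n, 4)
})

test_that("mitchison series pairs buds and tags outcomes", {
  t <- 0:6
  tr <- dplyr::bind_rows(
    tibble::tibble(explant_id = "e1", label = "x", t = t, bud = "top",
                   length = 1 + 4 * t),
    tibble::tibble(explant_id = "e1", label = "x", t = t, bud = "bottom",
                   length = rep(1, 7)))
  ms <- mitchison_series(tr, mode = "experimental")
  expect_named(ms, c("explant_id", "label", "t", "top", "bottom", "outcome"))
  expect_equal(nrow(ms), 7)
  expect_equal(unique(ms$outcome), "one")
  expect_equal(ms$top, 1 + 4 * t)
})
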