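# hand-built behavior map over an ni x nj grid from an n_stable matrix
fake_behavior_map <- function(ns, class_id = NULL) {
  ni <- nrow(ns); nj <- ncol(ns)
  v0 <- seq(0.01, 0.1, length.out = ni)
  mu <- seq(0.3, 1, length.out = nj)
  cells <- tidyr::expand_grid(i = seq_len(ni), j = seq_len(nj)) |>
    dplyr::mutate(v0 = v0[i], mu = mu[j],
                  class_id = if (is.null(class_id)) 1L else class_id[cbind(i, j)],
                  n_stable = ns[cbind(i, j)],
                  failed = FALSE, repaired = FALSE, boundary = FALSE)
  budcanal:::new_grid_map(cells, v0, mu, "behavior", list())
}

test_that("a small behavior map carries valid classes on every cell", {
  sl <- default_slice(4, 4)
  map <- behavior_map(sl$v0, sl$mu, bud_params())
  expect_s3_class(map, "grid_map")
  expect_equal(nrow(map$cells), 16)
  expect_true(all(map$cells$class_id[!map$cells$failed] %in% 1:6))
  expect_true(all(map$cells$n_stable[!map$cells$failed] >= 1))
  gl <- glance(map)
  expect_equal(c(gl$n_v0, gl$n_mu), c(4, 4))
  expect_equal(nrow(tidy(map)), 16)
})

test_that("boundary pixels flank a step in the stable-state count", {
  ns <- matrix(1L, 5, 5)
  ns[, 3:5] <- 3L
  map <- mark_boundaries(fake_behavior_map(ns))
  b <- matrix(map$cells$boundary[order(map$cells$j, map$cells$i)], 5, 5)
  expect_true(all(b[, 2:3]))
  expect_false(any(b[, c(1, 4, 5)]))
  # a uniform map has no boundary
  u <- mark_boundaries(fake_behavior_map(matrix(2L, 4, 4)))
  expect_false(any(u$cells$boundary))
})

test_that("repair copies identical neighbors and averages numeric payloads", {
  # outcome map, center cell failed, all neighbors identical
  mk <- function(p_both_center_nb) {
    cells <- tidyr::expand_grid(i = 1:3, j = 1:3) |>
      dplyr::mutate(v0 = i / 100, mu = j / 10,
                    p_both = p_both_center_nb[(i + j) %% 2 + 1],
                    p_one = 1 - p_both, p_none = 0,
                    class_id = 2L, n_stable = 3L,
                    failed = i == 2 & j == 2,
                    repaired = FALSE, boundary = FALSE)
    budcanal:::new_grid_map(cells, (1:3) / 100, (1:3) / 10, "outcome", list())
  }
  same <- repair_pixels(mk(c(0.4, 0.4)))
  c22 <- same$cells[same$cells$i == 2 & same$cells$j == 2, ]
  expect_false(c22$failed); expect_true(c22$repaired)
  expect_equal(c22$p_both, 0.4)
  mixed <- repair_pixels(mk(c(0.2, 0.6)))
  m22 <- mixed$cells[mixed$cells$i == 2 & mixed$cells$j == 2, ]
  expect_true(m22$repaired)
  expect_equal(m22$p_both, 0.4)  # mean of 4 x 0.2 and 4 x 0.6
})

test_that("behavior-class repairs never average disagreeing neighbors", {
  ns <- matrix(3L, 3, 3)
  cls <- matrix(c(1L, 2L)[(1:9 %% 2) + 1], 3, 3)
  map <- fake_behavior_map(ns, class_id = cls)
  map$cells$failed[map$cells$i == 2 & map$cells$j == 2] <- TRUE
  expect_warning(rep <- repair_pixels(map), "cannot be averaged")
  c22 <- rep$cells[rep$cells$i == 2 & rep$cells$j == 2, ]
  expect_true(c22$failed); expect_false(c22$repaired)
})

test_that("outcome maps are deterministic in the base seed", {
  v0 <- 0.05; mu <- c(0.4, 0.45)   # two class-2 (stochastic) cells
  a <- outcome_fraction_map(v0, mu, bud_params(), n_sims = 40, base_seed = 4)
  b <- outcome_fraction_map(v0, mu, bud_params(), n_sims = 40, base_seed = 4)
  expect_identical(a$cells, b$cells)
  expect_true(all(abs(a$cells$p_both + a$cells$p_one + a$cells$p_none - 1)
                  < 1e-12))
  d <- outcome_fraction_map(v0, mu, bud_params(), n_sims = 40, base_seed = 999)
  expect_false(identical(a$cells$p_both, d$cells$p_both))
})

test_that("metric heatmaps use activated buds only, NA when none", {
  p6 <- update(bud_params(), S = 0.5)   # class 6 at low v0 / high mu
  hm <- metric_heatmaps(c(0.01, 0.3), c(0.4, 1.8), p6, n_sims = 5, t_end = 60)
  lag <- hm$lag$cells
  dormant <- lag$v0 == 0.01 & lag$mu == 1.8  # nothing ever activates here
  active <- lag$v0 == 0.3 & lag$mu == 0.4
  expect_true(is.na(lag$mean_lag[dormant]))
  expect_false(is.na(lag$mean_lag[active]))
  rate <- hm$max_rate$cells
  expect_gt(rate$mean_max_rate[active], 0.02)
  expect_true(is.na(rate$mean_max_rate[dormant]))
})

test_that("sensitivity scan perturbs each parameter both ways", {
  sl <- default_slice(3, 3)
  scan <- sensitivity_scan(behavior_map, sl$v0, sl$mu, bud_params(),
                           fraction = 0.1, parameters = c("S", "D"))
  expect_equal(nrow(scan), 4)
  expect_setequal(scan$direction, c("down", "up"))
  expect_equal(scan$factor, rep(c(0.9, 1.1), 2))
  m <- scan$map[[1]]
  expect_s3_class(m, "grid_map")
  expect_equal(attr(m$provenance$base_params, "class"), "bud_params")
  expect_equal(m$provenance$base_params$S, 0.9)
})
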