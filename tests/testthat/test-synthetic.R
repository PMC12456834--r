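test_that("a cohort is a deterministic function of its seed", {
  a <- explant_archetype(days = 10)
  c1 <- generate_explants(a, n = 5, seed = 11)
  c2 <- generate_explants(a, n = 5, seed = 11)
  expect_identical(c1$traces, c2$traces)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_explants(a, n = 5, seed = 12)
  expect_false(identical(c1$traces, c3$traces))
  expect_error(generate_explants(a, n = 5), "seed")
})

test_that("archetype validation rejects inconsistent settings", {
  expect_error(explant_archetype(p_both = 0.5, p_one = 0.6, p_none = 0.1),
               "sum to 1")
  expect_error(explant_archetype(days = 2))
  expect_error(explant_archetype(plateau = 0))
})

test_that("an all-none archetype yields no active explants", {
  a <- explant_archetype(p_both = 0, p_one = 0, p_none = 1, noise_sd = 0.1)
  co <- generate_explants(a, n = 20, seed = 3)
  expect_true(all(!co$truth$active))
  m <- trace_metrics(co$traces, mode = "experimental")
  expect_true(all(m$explants$outcome == "none"))
  expect_equal(outcome_summary(m)$pct_active, 0)
})

test_that("realized outcome fractions track the archetype probabilities", {
  a <- explant_archetype(p_both = 0.3, p_one = 0.6, p_none = 0.1)
  co <- generate_explants(a, n = 400, seed = 21)
  drawn <- dplyr::distinct(co$truth, explant_id, outcome)
  p_hat <- mean(drawn$outcome == "one")
  se <- sqrt(0.6 * 0.4 / 400)
  expect_lt(abs(p_hat - 0.6), 3 * se)
})

test_that("the extractor recovers ground truth from a noise-free cohort", {
  a <- explant_archetype(noise_sd = 0, p_both = 0.3, p_one = 0.6,
                         p_none = 0.1)
  co <- generate_explants(a, n = 60, seed = 7)
  m <- trace_metrics(co$traces, mode = "experimental", window = 1)
  j <- dplyr::inner_join(m$buds, co$truth, by = c("explant_id", "bud"),
                         suffix = c("_est", "_true"))
  # activity agreement (rare slow-rate buds may fall below the threshold)
  expect_gte(mean(j$active_est == j$active_true), 0.95)
  both <- j[j$active_est & j$active_true, ]
  lag_err <- abs(both$lag_est - both$lag_true)
  expect_equal(median(lag_err), 0)
  expect_lte(stats::quantile(lag_err, 0.9), 1)
  rate_rel <- abs(both$max_rate_est - both$max_rate_true) / both$max_rate_true
  expect_lte(median(rate_rel), 0.10)
  expect_lte(max(rate_rel), 0.25)
})

test_that("model-sourced traces are reproducible and well-formed", {
  pl <- tibble::tibble(label = c("a", "b"), v0 = c(0.05, 0.09),
                       mu = c(0.65, 0.45))
  tr <- generate_from_model(pl, bud_params(), n = 3, t_end = 30, seed = 5)
  expect_setequal(unique(tr$label), c("a", "b"))
  # 2 labels x 3 explants x 2 buds x 31 time points
  expect_equal(nrow(tr), 2 * 3 * 2 * 31)
  tr2 <- generate_from_model(pl, bud_params(), n = 3, t_end = 30, seed = 5)
  expect_identical(tr, tr2)
  # label b's first explant reproduces the solo simulation at its seed
  solo <- simulate_explant(update(bud_params(), v0 = 0.09, mu = 0.45),
                           t_end = 30, dt = 0.1, seed = 5 + 3 + 1)
  got <- tr[tr$explant_id == "b-0001" & tr$bud == "top", ]
  expect_equal(got$length, solo$N)
})
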