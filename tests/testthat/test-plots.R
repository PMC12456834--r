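test_that("autoplot methods build without evaluation errors", {
  sl <- default_slice(3, 3)
  map <- behavior_map(sl$v0, sl$mu, bud_params())
  g1 <- ggplot2::autoplot(map)
  expect_s3_class(g1, "ggplot")
  expect_no_error(ggplot2::ggplot_build(g1))

  om <- outcome_fraction_map(c(0.03, 0.05), c(0.4, 0.5), bud_params(),
                             n_sims = 5, t_end = 60)
  g2 <- ggplot2::autoplot(om)
  expect_no_error(ggplot2::ggplot_build(g2))

  tr <- simulate_explant(bud_params(), t_end = 20, dt = 0.1, seed = 1)
  g3 <- ggplot2::autoplot(tr)
  expect_s3_class(g3, "ggplot")
  expect_no_error(ggplot2::ggplot_build(g3))
})

test_that("mitchison plot accepts trace tables", {
  pl <- tibble::tibble(label = "a", v0 = 0.09, mu = 0.45)
  trs <- generate_from_model(pl, bud_params(), n = 3, t_end = 40, seed = 2)
  g <- plot_mitchison(mitchison_series(trs, mode = "simulated"))
  expect_s3_class(g, "ggplot")
  expect_no_error(ggplot2::ggplot_build(g))
})
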