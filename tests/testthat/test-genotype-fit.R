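# hand-built outcome map whose fractions identify each cell uniquely:
# p_both = i/20, p_one = j/20
toy_map <- function(ni = 6, nj = 6, failed_at = NULL) {
  v0 <- seq(0.01, 0.06, length.out = ni)
  mu <- seq(0.3, 0.8, length.out = nj)
  cells <- tidyr::expand_grid(i = seq_len(ni), j = seq_len(nj)) |>
    dplyr::mutate(v0 = v0[i], mu = mu[j],
                  p_both = i / 20, p_one = j / 20,
                  p_none = 1 - p_both - p_one,
                  failed = FALSE, repaired = FALSE, boundary = FALSE,
                  n_stable = 3L, class_id = 2L)
  if (!is.null(failed_at)) {
    hit <- cells$i == failed_at[1] & cells$j == failed_at[2]
    cells$failed[hit] <- TRUE
  }
  budcanal:::new_grid_map(cells, v0, mu, "outcome", list())
}

obs_at <- function(label, i, j, n = 100) {
  genotype_observation(label, p_both = i / 20, p_one = j / 20,
                       p_none = 1 - i / 20 - j / 20, n = n)
}

test_that("observations and constraints validate their invariants", {
  expect_error(genotype_observation("x", 0.5, 0.6, 0.1, 100), "sum to 1")
  expect_error(constraint_set(
    mu_groups = list(a = c("x", "y"), b = "x"),
    v0_groups = list(a = c("x", "y"))), "at most one")
  expect_error(constraint_set(
    mu_groups = list(a = "x"), v0_groups = list(a = "x"),
    mu_order = c("a", "b")), "exactly once")
  expect_error(constraint_set(
    mu_groups = list(a = c("x", "y")), v0_groups = list(a = "x")),
    "both a mu group and a v0 group")
})

test_that("match_region returns cells within the TV tolerance", {
  map <- toy_map()
  obs <- obs_at("x", 3, 4)
  hits <- match_region(obs, map, tolerance = 0.049)
  # TV distance between adjacent cells is 0.05 per step on each axis
  expect_equal(nrow(hits), 1)
  expect_equal(c(hits$i, hits$j), c(3, 4))
  # at TV 0.05: the cell, its 4 axis neighbors, and the 2 anti-diagonal
  # neighbors (where the p_both and p_one shifts cancel inside p_none)
  wider <- match_region(obs, map, tolerance = 0.0501)
  expect_equal(nrow(wider), 7)
  expect_true(all(wider$tv_dist <= 0.0501))
})

test_that("placement recovers exact observations on a toy map", {
  map <- toy_map()
  cons <- constraint_set(
    mu_groups = list(g1 = "A", g2 = "B"),
    v0_groups = list(r1 = "A", r2 = "B"),
    mu_order = c("g1", "g2"), v0_order = c("r1", "r2"))
  obs <- dplyr::bind_rows(obs_at("A", 2, 2), obs_at("B", 4, 5))
  pl <- place_genotypes(obs, cons, map)
  expect_s3_class(pl, "genotype_placement")
  expect_equal(pl$i[pl$label == "A"], 2)
  expect_equal(pl$j[pl$label == "A"], 2)
  expect_equal(pl$i[pl$label == "B"], 4)
  expect_equal(pl$j[pl$label == "B"], 5)
  expect_equal(pl$score, c(0, 0))
  expect_equal(attr(pl, "total_score"), 0)
})

test_that("equality groups force shared bars and orderings bind", {
  map <- toy_map()
  cons <- constraint_set(
    mu_groups = list(g1 = c("C", "D")),
    v0_groups = list(r1 = "C", r2 = "D"),
    v0_order = c("r1", "r2"))
  # C prefers column 2, D prefers column 4 -> shared bar compromises; the
  # summed TV is flat on columns 2..4, so the tie breaks to the smallest
  obs <- dplyr::bind_rows(obs_at("C", 2, 2), obs_at("D", 4, 4))
  pl <- place_genotypes(obs, cons, map)
  expect_equal(length(unique(pl$j)), 1)
  expect_equal(pl$j[1], 2)
  expect_lt(pl$i[pl$label == "C"], pl$i[pl$label == "D"])
  # reversed preferences cannot break the strict v0 ordering
  obs2 <- dplyr::bind_rows(obs_at("C", 5, 3), obs_at("D", 2, 3))
  pl2 <- place_genotypes(obs2, cons, map)
  expect_lt(pl2$i[pl2$label == "C"], pl2$i[pl2$label == "D"])
})

test_that("prediction-only labels are placed with NA score", {
  map <- toy_map()
  cons <- constraint_set(
    mu_groups = list(g1 = "A", g2 = c("B", "P")),
    v0_groups = list(r1 = c("A", "P"), r2 = "B"),
    mu_order = c("g1", "g2"), v0_order = c("r1", "r2"))
  obs <- dplyr::bind_rows(obs_at("A", 2, 2), obs_at("B", 4, 5))
  pl <- place_genotypes(obs, cons, map)
  p_row <- pl[pl$label == "P", ]
  expect_true(is.na(p_row$score))
  expect_equal(p_row$i, pl$i[pl$label == "A"])  # shares A's v0 bar
  expect_equal(p_row$j, pl$j[pl$label == "B"])  # shares B's mu bar
})

test_that("infeasible constraints error instead of degrading", {
  map <- toy_map(ni = 2, nj = 2)
  cons <- constraint_set(
    mu_groups = list(g1 = "A", g2 = "B", g3 = "C"),
    v0_groups = list(r1 = c("A", "B", "C")))
  obs <- dplyr::bind_rows(obs_at("A", 1, 1), obs_at("B", 1, 2),
                          obs_at("C", 2, 2))
  expect_error(place_genotypes(obs, cons, map), "infeasible")
  expect_error(place_genotypes(obs_at("Z", 1, 1), genotype_constraints(),
                               toy_map()), "unconstrained")
})

test_that("failed cells are avoided when an alternative exists", {
  map <- toy_map(failed_at = c(3, 3))
  cons <- constraint_set(mu_groups = list(g1 = "A"),
                         v0_groups = list(r1 = "A"))
  pl <- place_genotypes(obs_at("A", 3, 3), cons, map)
  # the exact-match cell is failed; a neighbor (TV 0.05) wins over penalty 2
  expect_false(pl$i == 3 && pl$j == 3)
  expect_equal(pl$score, 0.05)
})

test_that("the shipped presets satisfy the shipped constraints", {
  pre <- genotype_presets()
  cons <- genotype_constraints()
  for (g in names(cons$mu_groups)) {
    expect_length(unique(pre$mu[pre$label %in% cons$mu_groups[[g]]]), 1)
  }
  for (g in names(cons$v0_groups)) {
    expect_length(unique(pre$v0[pre$label %in% cons$v0_groups[[g]]]), 1)
  }
  mu_vals <- vapply(cons$mu_order, function(g)
    pre$mu[pre$label %in% cons$mu_groups[[g]]][1], numeric(1))
  expect_false(is.unsorted(mu_vals, strictly = TRUE))
  v0_vals <- vapply(cons$v0_order, function(g)
    pre$v0[pre$label %in% cons$v0_groups[[g]]][1], numeric(1))
  expect_false(is.unsorted(v0_vals, strictly = TRUE))
})

test_that("sip1_slice reduces S and inherits background v0", {
  pl <- genotype_presets()
  sl <- sip1_slice(bud_params(), pl, d14_mu = 0.45,
                   backgrounds = c(sip1 = "Col-0", `sip1 brc1` = "brc1brc2"))
  expect_equal(sl$params$S, 0.8)
  expect_equal(sl$placement$v0,
               c(pl$v0[pl$label == "Col-0"], pl$v0[pl$label == "brc1brc2"]))
  expect_true(all(sl$placement$mu == 0.45))
  expect_error(sip1_slice(bud_params(), pl, 0.45, c(x = "nope")), "nope")
})
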