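#' Observed outcome frequencies for a genotype or treatment
#'
#' @param label genotype/treatment name.
#' @param p_both,p_one,p_none observed outcome fractions (must sum to 1).
#' @param n number of explants behind the fractions.
#' @return One-row tibble of class `genotype_observation` fields; bind rows
#'   to build a cohort.
#' @export
genotype_observation <- function(label, p_both, p_one, p_none, n) {
  stopifnot(n >= 1, p_both >= 0, p_one >= 0, p_none >= 0)
  if (abs(p_both + p_one + p_none - 1) > 1e-9) {
    stop("outcome fractions must sum to 1", call. = FALSE)
  }
  tibble::tibble(label = label, p_both = p_both, p_one = p_one,
                 p_none = p_none, n = n)
}

#' Cross-genotype parameter constraints
#'
#' Encodes the biological placement rules: labels sharing a PIN1-removal
#' level share one `mu` value (a vertical bar on the map), labels sharing a
#' BRC1-expression level share one `v0` value (a horizontal bar), and known
#' orderings fix the relative position of the bars.
#'
#' @param mu_groups named list: group name -> character vector of labels
#'   sharing one `mu` value. Groups must be disjoint.
#' @param v0_groups same for `v0`.
#' @param mu_order,v0_order character vectors of group names in strictly
#'   *increasing* parameter order. Every group on an axis with an ordering
#'   must appear in it (the orderings used here are total).
#' @return A `constraint_set` list.
#' @export
constraint_set <- function(mu_groups, v0_groups,
                           mu_order = names(mu_groups),
                           v0_order = names(v0_groups)) {
  check_groups <- function(groups, ord, axis) {
    labs <- unlist(groups)
    if (anyDuplicated(labs)) {
      stop("labels must belong to at most one ", axis, " group", call. = FALSE)
    }
    if (!setequal(ord, names(groups))) {
      stop(axis, " ordering must mention each group exactly once", call. = FALSE)
    }
  }
  check_groups(mu_groups, mu_order, "mu")
  check_groups(v0_groups, v0_order, "v0")
  if (!setequal(unlist(mu_groups), unlist(v0_groups))) {
    stop("every label needs both a mu group and a v0 group", call. = FALSE)
  }
  structure(list(mu_groups = mu_groups, v0_groups = v0_groups,
                 mu_order = mu_order, v0_order = v0_order),
            class = "constraint_set")
}

#' Cells of an outcome map matching an observation
#'
#' Total-variation distance on the 3-outcome simplex between the observed and
#' the modelled fractions; cells within `tolerance` match. The default
#' tolerance is twice the pooled binomial standard error of the observation.
#'
#' @param obs one row of [genotype_observation()] output.
#' @param map an outcome `grid_map`.
#' @param tolerance maximal total-variation distance; `NULL` uses
#'   `2 * sqrt(0.5 / n)` (a pooled binomial standard error at the observed
#'   sample size).
#' @return Tibble of matching cells (`i, j, v0, mu, tv_dist`); may be empty.
#' @export
match_region <- function(obs, map, tolerance = NULL) {
  stopifnot(inherits(map, "grid_map"), map$kind == "outcome")
  if (is.null(tolerance)) tolerance <- 2 * sqrt(0.5 / obs$n)
  map$cells |>
    dplyr::filter(!.data$failed) |>
    dplyr::mutate(tv_dist = 0.5 * (abs(.data$p_both - obs$p_both) +
                                     abs(.data$p_one - obs$p_one) +
                                     abs(.data$p_none - obs$p_none))) |>
    dplyr::filter(.data$tv_dist <= tolerance) |>
    dplyr::select("i", "j", "v0", "mu", "tv_dist")
}

# per-cell total-variation distance field of one observation over the map;
# failed cells get a penalty above the maximal TV distance of 1 so they are
# avoided but never make the search infeasible
tv_field <- function(obs_row, map) {
  ni <- length(map$v0_values); nj <- length(map$mu_values)
  cells <- map$cells
  tv <- 0.5 * (abs(cells$p_both - obs_row$p_both) +
                 abs(cells$p_one - obs_row$p_one) +
                 abs(cells$p_none - obs_row$p_none))
  tv[cells$failed | is.na(tv)] <- 2
  D <- matrix(0, ni, nj)
  D[cbind(cells$i, cells$j)] <- tv
  D
}

#' Constrained placement of genotypes on the parameter plane
#'
#' Positions one shared `mu` column per mu-group (a vertical bar) and one
#' shared `v0` row per v0-group (a horizontal bar), placing each label at the
#' intersection of its two bars. The bar positions minimize the summed
#' total-variation distance between each label's observed outcome fractions
#' and the map cell it lands on, subject to the strict orderings; the search
#' is exact (exhaustive over ordered column combinations, with an exact
#' dynamic program over the ordered rows for each column choice). Ties break
#' toward the lexicographically smallest grid positions.
#'
#' @param observations tibble of [genotype_observation()] rows, one per
#'   observed label. Constrained labels without an observation row are placed
#'   by their constraints alone (prediction-only; they contribute zero to the
#'   objective).
#' @param constraints a [constraint_set()].
#' @param map the outcome `grid_map` to place on.
#' @return A `genotype_placement`: tibble (`label, i, j, v0, mu, score`) with
#'   the constraint set and total score in attributes. `score` is the
#'   label's total-variation distance at its placed cell (`NA` for
#'   prediction-only labels).
#' @export
place_genotypes <- function(observations, constraints, map) {
  stopifnot(inherits(constraints, "constraint_set"), inherits(map, "grid_map"),
            map$kind == "outcome")
  ni <- length(map$v0_values); nj <- length(map$mu_values)
  labels <- unlist(constraints$mu_groups, use.names = FALSE)
  miss <- setdiff(observations$label, labels)
  if (length(miss)) stop("observations given for unconstrained label(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  fields <- lapply(stats::setNames(labels, labels), function(l) {
    k <- match(l, observations$label)
    if (is.na(k)) matrix(0, ni, nj) else tv_field(observations[k, ], map)
  })
  mu_of <- label_group(constraints$mu_groups)
  v0_of <- label_group(constraints$v0_groups)
  mu_ord <- constraints$mu_order
  v0_ord <- constraints$v0_order
  G_mu <- length(mu_ord); G_v0 <- length(v0_ord)
  if (nj < G_mu || ni < G_v0) {
    stop("infeasible constraints: grid too small for ", G_mu, " ordered mu ",
         "column(s) and ", G_v0, " ordered v0 row(s)", call. = FALSE)
  }

  col_combos <- utils::combn(nj, G_mu)  # strictly increasing columns
  best <- NULL
  for (cc in seq_len(ncol(col_combos))) {
    cols <- stats::setNames(col_combos[, cc], mu_ord)
    # per v0-group cost as a function of the row
    cost <- vapply(v0_ord, function(g) {
      labs <- constraints$v0_groups[[g]]
      rowSums(vapply(labs, function(l) fields[[l]][, cols[[mu_of[[l]]]]],
                     numeric(ni)))
    }, numeric(ni))  # ni x G_v0
    sol <- ordered_row_dp(cost)
    if (is.null(best) || sol$total < best$total - 1e-12) {
      best <- list(total = sol$total, rows = stats::setNames(sol$rows, v0_ord),
                   cols = cols)
    }
  }
  if (is.null(best) || !is.finite(best$total)) {
    stop("infeasible constraints: no bar assignment satisfies the orderings",
         call. = FALSE)
  }
  out <- tibble::tibble(
    label = labels,
    i = vapply(labels, function(l) best$rows[[v0_of[[l]]]], integer(1),
               USE.NAMES = FALSE),
    j = vapply(labels, function(l) best$cols[[mu_of[[l]]]], integer(1),
               USE.NAMES = FALSE))
  out$v0 <- map$v0_values[out$i]
  out$mu <- map$mu_values[out$j]
  out$score <- vapply(seq_len(nrow(out)), function(k) {
    if (out$label[k] %in% observations$label) {
      fields[[out$label[k]]][out$i[k], out$j[k]]
    } else NA_real_
  }, numeric(1))
  check_placement(out, constraints)
  structure(out, class = c("genotype_placement", class(out)),
            constraints = constraints, total_score = best$total)
}

label_group <- function(groups) {
  out <- list()
  for (g in names(groups)) for (l in groups[[g]]) out[[l]] <- g
  out
}

# exact DP: choose strictly increasing rows r_1 < ... < r_G minimizing
# sum_g cost[r_g, g]; returns chosen rows (lexicographically smallest among
# minima) and the total
ordered_row_dp <- function(cost) {
  ni <- nrow(cost); G <- ncol(cost)
  best_val <- matrix(Inf, ni, G)
  best_prev <- matrix(NA_integer_, ni, G)
  best_val[, 1] <- cost[, 1]
  for (g in seq_len(G)[-1]) {
    run_min <- Inf; run_arg <- NA_integer_
    for (r in seq_len(ni)) {
      if (r > 1) {
        v <- best_val[r - 1, g - 1]
        if (v < run_min - 1e-15) { run_min <- v; run_arg <- r - 1L }
      }
      best_val[r, g] <- run_min + cost[r, g]
      best_prev[r, g] <- run_arg
    }
  }
  r <- which.min(best_val[, G])
  total <- best_val[r, G]
  rows <- integer(G); rows[G] <- r
  for (g in rev(seq_len(G))[-1]) {
    rows[g] <- best_prev[rows[g + 1], g + 1]
    # recover lexicographically smallest argmin: which.min picks the first
  }
  list(rows = rows, total = total)
}

check_placement <- function(placement, constraints) {
  v0_of <- label_group(constraints$v0_groups)
  mu_of <- label_group(constraints$mu_groups)
  for (axis in c("v0", "mu")) {
    groups <- if (axis == "v0") constraints$v0_groups else constraints$mu_groups
    ord <- if (axis == "v0") constraints$v0_order else constraints$mu_order
    vals <- vapply(ord, function(g) {
      v <- unique(placement[[axis]][placement$label %in% groups[[g]]])
      if (length(v) != 1) stop("equality group `", g, "` violated on ", axis,
                               call. = FALSE)
      v
    }, numeric(1))
    if (is.unsorted(vals, strictly = TRUE)) {
      stop("ordering violated on ", axis, " across groups ",
           paste(ord, collapse = " < "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.genotype_placement <- function(x, ...) {
  cat(sprintf("<genotype_placement> %d label(s), total score %.4g\n",
              nrow(x), attr(x, "total_score")))
  NextMethod()
}

#' @export
tidy.genotype_placement <- function(x, ...) tibble::as_tibble(x)

#' Ensemble predictions at placed parameter values
#'
#' For each placed label, runs a stochastic ensemble at its `(v0, mu)` and
#' extracts outcome fractions, lag / max-growth-rate / RGI distributions and
#' the Mitchison series through the simulated-mode trace pipeline.
#'
#' @param placement a `genotype_placement` (or any tibble with `label, v0,
#'   mu`).
#' @param base_params parameters supplying everything but `v0, mu`.
#' @param n_sims ensemble size per label.
#' @param t_end,dt simulation horizon and step.
#' @param base_seed seed root; label `k` (in row order) uses
#'   `base_seed + (k - 1) * n_sims` as its ensemble base.
#' @param ... passed to [trace_metrics()] (e.g. `window`,
#'   `activation_length`).
#' @return A `genotype_predictions` list: `summary` (per-label outcome
#'   fractions, mean lag, mean max rate, mean RGI), `buds` and `explants`
#'   metric tibbles, and `mitchison` series, all carrying a `label` column.
#' @export
predict_metrics <- function(placement, base_params, n_sims = 100,
                            t_end = 120, dt = 0.1, base_seed = 1, ...) {
  stopifnot(all(c("label", "v0", "mu") %in% names(placement)))
  per <- purrr::imap(stats::setNames(seq_len(nrow(placement)),
                                     placement$label),
                     function(k, lab) {
    p <- update(base_params, v0 = placement$v0[k], mu = placement$mu[k])
    traces <- model_traces(p, n = n_sims, t_end = t_end, dt = dt,
                           base_seed = base_seed + (k - 1) * n_sims,
                           label = lab)
    m <- trace_metrics(traces, mode = "simulated", ...)
    list(metrics = m,
         mit = mitchison_series(traces, mode = "simulated", ...))
  })
  buds <- purrr::map_dfr(per, ~.x$metrics$buds)
  explants <- purrr::map_dfr(per, ~.x$metrics$explants)
  mit <- purrr::map_dfr(per, ~.x$mit)
  summary <- explants |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(p_both = mean(.data$outcome == "both"),
                     p_one = mean(.data$outcome == "one"),
                     p_none = mean(.data$outcome == "none"),
                     mean_rgi = mean(.data$rgi, na.rm = TRUE),
                     n = dplyr::n(), .groups = "drop")
  lagsum <- buds |>
    dplyr::filter(.data$active) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(mean_lag = mean(.data$lag),
                     mean_max_rate = mean(.data$max_rate), .groups = "drop")
  summary <- dplyr::left_join(summary, lagsum, by = "label")
  # keep the placement's row order
  summary <- summary[match(placement$label, summary$label), ]
  structure(list(summary = summary, buds = buds, explants = explants,
                 mitchison = mit),
            class = "genotype_predictions")
}

#' @export
print.genotype_predictions <- function(x, ...) {
  cat("<genotype_predictions>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.genotype_predictions <- function(x, ...) x$summary

#' Reduced-efficiency slice for strigolactone-insensitive PIN1 lines
#'
#' Builds the parameter slice used to predict SIP1 (strigolactone-insensitive
#' PIN1) phenotypes: the feedback efficiency `S` is reduced by a fixed
#' fraction (default 20%) to account for the lower bulk auxin transport of
#' these lines, every SIP1 label inherits the `v0` of its genetic background
#' (no effect on BRC1 expression), and all SIP1 labels take the low `mu` of
#' the strigolactone-receptor mutant (no strigolactone-mediated PIN1
#' removal).
#'
#' @param base_params baseline parameter set; its `S` is scaled by
#'   `1 - s_reduction`.
#' @param placement a `genotype_placement` giving each background's `v0`.
#' @param d14_mu the `mu` value of the receptor mutant, assigned to every
#'   SIP1 label.
#' @param backgrounds named character vector: SIP1 label -> background label
#'   in `placement` whose `v0` it inherits.
#' @param s_reduction fraction by which `S` is reduced, in \[0, 1).
#' @return A list with `params` (the reduced-S parameter set) and `placement`
#'   (tibble `label, v0, mu` for the SIP1 labels).
#' @export
sip1_slice <- function(base_params, placement, d14_mu, backgrounds,
                       s_reduction = 0.20) {
  stopifnot(s_reduction >= 0, s_reduction < 1)
  new_params <- update(base_params, S = (1 - s_reduction) * base_params$S)
  v0 <- vapply(backgrounds, function(bg) {
    k <- match(bg, placement$label)
    if (is.na(k)) stop("background `", bg, "` not in placement", call. = FALSE)
    placement$v0[k]
  }, numeric(1))
  list(params = new_params,
       placement = tibble::tibble(label = names(backgrounds),
                                  v0 = unname(v0), mu = d14_mu))
}

#' Default genotype placement on the calibrated slice
#'
#' Ships the package's reference positions for the seven strigolactone
#' genotypes/treatments on the calibrated `(v0, mu)` slice, satisfying the
#' biological constraint topology: the BRC1-null group (and the receptor
#' mutant) at high `v0`; wild type below; GR24 treatment lower still;
#' the constitutive-signaling mutant lowest; `mu` increasing from the
#' receptor mutant through wild type, GR24 and constitutive signaling.
#'
#' @return A tibble (`label, v0, mu`) usable wherever a placement is
#'   accepted.
#' @export
genotype_presets <- function() {
  v0_rows <- c(brc1 = 0.09, col = 0.05, gr24 = 0.03, smxl = 0.025)
  mu_cols <- c(d14 = 0.45, col = 0.65, gr24 = 0.85, smxl = 0.88)
  tibble::tibble(
    label = c("d14", "brc1brc2", "Col-0", "Col-0+GR24", "brc1brc2+GR24",
              "smxl678", "brc1brc2smxl678"),
    v0 = unname(v0_rows[c("brc1", "brc1", "col", "gr24", "brc1", "smxl", "brc1")]),
    mu = unname(mu_cols[c("d14", "col", "col", "gr24", "gr24", "smxl", "smxl")]))
}

#' Default constraint set for the seven reference genotypes
#'
#' @return A [constraint_set()] mirroring the biological placement rules used
#'   by [genotype_presets()].
#' @export
genotype_constraints <- function() {
  constraint_set(
    mu_groups = list(d14 = "d14",
                     col = c("brc1brc2", "Col-0"),
                     gr24 = c("Col-0+GR24", "brc1brc2+GR24"),
                     smxl = c("smxl678", "brc1brc2smxl678")),
    v0_groups = list(smxl = "smxl678",
                     gr24 = "Col-0+GR24",
                     col = "Col-0",
                     brc1 = c("d14", "brc1brc2", "brc1brc2+GR24",
                              "brc1brc2smxl678")),
    mu_order = c("d14", "col", "gr24", "smxl"),
    v0_order = c("smxl", "gr24", "col", "brc1"))
}
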