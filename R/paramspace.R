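new_grid_map <- function(cells, v0_values, mu_values, kind, provenance) {
  stopifnot(nrow(cells) == length(v0_values) * length(mu_values))
  structure(list(cells = tibble::as_tibble(cells),
                 v0_values = v0_values, mu_values = mu_values,
                 kind = kind, provenance = provenance),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("<grid_map> kind = %s, %d x %d (v0 x mu), %d failed, %d boundary\n",
              x$kind, length(x$v0_values), length(x$mu_values),
              sum(x$cells$failed), sum(x$cells$boundary)))
  invisible(x)
}

#' @export
tidy.grid_map <- function(x, ...) x$cells

#' @export
glance.grid_map <- function(x, ...) {
  tibble::tibble(kind = x$kind,
                 n_v0 = length(x$v0_values), n_mu = length(x$mu_values),
                 n_failed = sum(x$cells$failed),
                 n_boundary = sum(x$cells$boundary))
}

#' @export
as.data.frame.grid_map <- function(x, ...) as.data.frame(x$cells)

grid_cells_skeleton <- function(v0_values, mu_values) {
  tidyr::expand_grid(i = seq_along(v0_values), j = seq_along(mu_values)) |>
    dplyr::mutate(v0 = v0_values[.data$i], mu = mu_values[.data$j])
}

check_axes <- function(v0_values, mu_values) {
  stopifnot(all(v0_values > 0), all(mu_values > 0),
            !is.unsorted(v0_values, strictly = TRUE),
            !is.unsorted(mu_values, strictly = TRUE))
}

#' Deterministic behavior map over the (v0, mu) plane
#'
#' Classifies every grid cell with all other parameters held at
#' `base_params`, records the number of stable steady states, and marks
#' region boundaries. Cells where the steady-state search fails or the
#' stable-point configuration falls outside the six-class table are entered
#' into the failure mask (see [repair_pixels()]).
#'
#' @param v0_values,mu_values sorted positive axis values.
#' @param base_params a [bud_params()] object supplying all non-swept
#'   parameters.
#' @param ... passed to [find_steady_states()] and [classify_behavior()]
#'   (e.g. `n_starts`, thresholds).
#' @return A `grid_map` of kind `"behavior"` whose cells carry `class_id` and
#'   `n_stable`.
#' @export
behavior_map <- function(v0_values, mu_values, base_params, ...) {
  check_axes(v0_values, mu_values)
  validate_bud_params(base_params)
  dots <- rlang::list2(...)
  ss_args <- dots[names(dots) %in% names(formals(find_steady_states))]
  cl_args <- dots[names(dots) %in% names(formals(classify_behavior))[-1]]
  cells <- grid_cells_skeleton(v0_values, mu_values)
  res <- purrr::map2(cells$v0, cells$mu, function(v0, mu) {
    p <- update(base_params, v0 = v0, mu = mu)
    tryCatch({
      ss <- do.call(find_steady_states, c(list(p), ss_args))
      b <- do.call(classify_behavior, c(list(ss), cl_args))
      list(class_id = b$class_id, n_stable = b$n_stable, failed = FALSE)
    }, error = function(e) {
      list(class_id = NA_integer_, n_stable = NA_integer_, failed = TRUE)
    })
  })
  cells$class_id <- purrr::map_int(res, "class_id")
  cells$n_stable <- purrr::map_int(res, "n_stable")
  cells$failed <- purrr::map_lgl(res, "failed")
  cells$repaired <- FALSE
  cells$boundary <- FALSE
  map <- new_grid_map(cells, v0_values, mu_values, "behavior",
                      list(base_params = base_params))
  mark_boundaries(map)
}

#' Mark boundary pixels between regions
#'
#' A cell is a boundary pixel iff more than one of its (up to 8) neighbors
#' has a different number of stable steady states.
#'
#' @param map a `grid_map` whose cells carry `n_stable`.
#' @param connectivity 8 (default) or 4 neighborhood.
#' @return The map with its `boundary` mask recomputed.
#' @export
mark_boundaries <- function(map, connectivity = 8) {
  stopifnot(inherits(map, "grid_map"), connectivity %in% c(4, 8))
  ni <- length(map$v0_values); nj <- length(map$mu_values)
  ns <- matrix(map$cells$n_stable[order(map$cells$j, map$cells$i)], ni, nj)
  offs <- if (connectivity == 8) {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  ndiff <- matrix(0L, ni, nj)
  for (k in seq_len(nrow(offs))) {
    di <- offs[k, 1]; dj <- offs[k, 2]
    if (max(1, 1 + di) > min(ni, ni + di) ||
        max(1, 1 + dj) > min(nj, nj + dj)) next
    i0 <- max(1, 1 + di):min(ni, ni + di)
    j0 <- max(1, 1 + dj):min(nj, nj + dj)
    diff <- ns[i0, j0, drop = FALSE] != ns[i0 - di, j0 - dj, drop = FALSE]
    diff[is.na(diff)] <- FALSE
    ndiff[i0 - di, j0 - dj] <- ndiff[i0 - di, j0 - dj] + diff
  }
  bmat <- ndiff > 1
  map$cells$boundary <- bmat[cbind(map$cells$i, map$cells$j)]
  map
}

outcome_cols <- c("p_both", "p_one", "p_none")

#' Stochastic outcome-fraction map
#'
#' In the mono- and bistable regions stochasticity cannot change the outcome,
#' so those cells get degenerate fractions without simulation (class 1:
#' all-both; class 3: all-one; class 6: all-none). In the tristable and
#' quadrastable regions (classes 2, 4, 5) the fractions are estimated from
#' `n_sims` stochastic simulations per cell; a run's outcome uses the
#' final-length dominance rule of [growth_outcome()] (one bud "wins" iff it
#' ends more than three times longer than the other).
#'
#' Reproducibility: run `r` (0-based) of cell `(i, j)` (0-based) uses seed
#' `base_seed + r + n_sims * (j + i * n_mu)`.
#'
#' @inheritParams behavior_map
#' @param n_sims stochastic simulations per multistable cell.
#' @param t_end,dt simulation horizon and internal step.
#' @param base_seed integer seed root.
#' @param behavior optional precomputed behavior `grid_map` on the same axes
#'   (avoids re-running the steady-state classification).
#' @param activation_length,ratio outcome rule settings, see
#'   [growth_outcome()].
#' @return A `grid_map` of kind `"outcome"`: cells carry `p_both`, `p_one`,
#'   `p_none`, `class_id`, `n_stable`.
#' @export
outcome_fraction_map <- function(v0_values, mu_values, base_params,
                                 n_sims = 100, t_end = 120, base_seed = 1,
                                 dt = 0.1, behavior = NULL,
                                 activation_length = 1.1, ratio = 3, ...) {
  stopifnot(n_sims >= 1)
  if (is.null(behavior)) {
    behavior <- behavior_map(v0_values, mu_values, base_params, ...)
  }
  stopifnot(identical(behavior$v0_values, v0_values),
            identical(behavior$mu_values, mu_values))
  cells <- behavior$cells
  n_mu <- length(mu_values)
  frac <- purrr::pmap(cells[c("i", "j", "v0", "mu", "class_id", "failed")],
                      function(i, j, v0, mu, class_id, failed) {
    if (failed) return(list(p_both = NA_real_, p_one = NA_real_,
                            p_none = NA_real_, failed = TRUE))
    if (class_id == 1) return(list(p_both = 1, p_one = 0, p_none = 0, failed = FALSE))
    if (class_id == 3) return(list(p_both = 0, p_one = 1, p_none = 0, failed = FALSE))
    if (class_id == 6) return(list(p_both = 0, p_one = 0, p_none = 1, failed = FALSE))
    p <- update(base_params, v0 = v0, mu = mu)
    outs <- character(0)
    for (r in seq_len(n_sims) - 1L) {
      seed <- base_seed + r + n_sims * ((j - 1L) + (i - 1L) * n_mu)
      tr <- tryCatch(simulate_explant(p, t_end = t_end, dt = dt, seed = seed),
                     error = function(e) NULL)
      if (is.null(tr)) next
      last <- tr[nrow(tr), ]
      outs <- c(outs, growth_outcome(last$N, last$M, mode = "simulated",
                                     activation_length = activation_length,
                                     ratio = ratio))
    }
    if (!length(outs)) return(list(p_both = NA_real_, p_one = NA_real_,
                                   p_none = NA_real_, failed = TRUE))
    list(p_both = mean(outs == "both"), p_one = mean(outs == "one"),
         p_none = mean(outs == "none"), failed = FALSE)
  })
  cells$p_both <- purrr::map_dbl(frac, "p_both")
  cells$p_one <- purrr::map_dbl(frac, "p_one")
  cells$p_none <- purrr::map_dbl(frac, "p_none")
  cells$failed <- purrr::map_lgl(frac, "failed")
  cells$repaired <- FALSE
  map <- new_grid_map(cells, v0_values, mu_values, "outcome",
                      list(base_params = base_params, n_sims = n_sims,
                           t_end = t_end, dt = dt, base_seed = base_seed))
  mark_boundaries(map)
}

#' Repair failed pixels from their neighbors
#'
#' Each failed cell is assigned the common value of its non-failed neighbors
#' when they are all identical; otherwise the mean of the neighboring values
#' (for class payloads, where a mean is meaningless, the cell is left failed
#' with a warning instead). Failed cells whose neighbors all failed too stay
#' failed, with a warning. Repaired cells are flagged in the `repaired`
#' column.
#'
#' @param map a `grid_map`.
#' @param connectivity 8 (default) or 4 neighborhood.
#' @return The repaired map.
#' @export
repair_pixels <- function(map, connectivity = 8) {
  stopifnot(inherits(map, "grid_map"))
  bad <- which(map$cells$failed)
  if (!length(bad)) return(map)
  payload <- switch(map$kind,
                    behavior = c("class_id", "n_stable"),
                    outcome = c(outcome_cols, "class_id", "n_stable"),
                    mean_lag = "mean_lag",
                    mean_max_rate = "mean_max_rate")
  ni <- length(map$v0_values); nj <- length(map$mu_values)
  offs <- if (connectivity == 8) {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  idx <- function(i, j) (j - 1L) * ni + i  # position in (j, i)-sorted cells
  cells <- dplyr::arrange(map$cells, .data$j, .data$i)
  for (b in which(cells$failed)) {
    i <- cells$i[b]; j <- cells$j[b]
    nb_i <- i + offs[, 1]; nb_j <- j + offs[, 2]
    okn <- nb_i >= 1 & nb_i <= ni & nb_j >= 1 & nb_j <= nj
    nb <- idx(nb_i[okn], nb_j[okn])
    nb <- nb[!cells$failed[nb]]
    if (!length(nb)) {
      warning(sprintf("cell (%d, %d): all neighbors failed; left unrepaired",
                      i, j))
      next
    }
    vals <- cells[nb, payload, drop = FALSE]
    identical_all <- all(vapply(vals, function(col) length(unique(col)) == 1,
                                logical(1)))
    if (identical_all) {
      cells[b, payload] <- vals[1, ]
    } else if (map$kind == "behavior") {
      warning(sprintf(
        "cell (%d, %d): neighbors disagree; class payload cannot be averaged",
        i, j))
      next
    } else {
      cells[b, payload] <- as.list(colMeans(as.matrix(vals), na.rm = TRUE))
    }
    cells$failed[b] <- FALSE
    cells$repaired[b] <- TRUE
  }
  map$cells <- dplyr::arrange(cells, .data$i, .data$j)
  map
}

#' Lag and maximum-growth-rate heatmaps
#'
#' For every cell, runs `n_sims` stochastic simulations and extracts per-bud
#' lag and maximum growth rate (simulated-mode threshold) with the trace
#' extractor; cell values are means over *activated buds only*, across all
#' runs. Cells where no bud ever activates carry `NA`, not 0. Seeds follow
#' the same per-cell formula as [outcome_fraction_map()].
#'
#' @inheritParams outcome_fraction_map
#' @param threshold activity threshold on the growth rate (default 0.02).
#' @param window smoothing window for the rate extractor.
#' @return A list with two `grid_map`s: `lag` (kind `"mean_lag"`) and
#'   `max_rate` (kind `"mean_max_rate"`).
#' @export
metric_heatmaps <- function(v0_values, mu_values, base_params,
                            n_sims = 100, t_end = 120, base_seed = 1,
                            dt = 0.1, threshold = 0.02, window = 3) {
  check_axes(v0_values, mu_values)
  stopifnot(n_sims >= 1)
  cells <- grid_cells_skeleton(v0_values, mu_values)
  n_mu <- length(mu_values)
  res <- purrr::pmap(cells, function(i, j, v0, mu) {
    p <- update(base_params, v0 = v0, mu = mu)
    lags <- c(); rates <- c()
    for (r in seq_len(n_sims) - 1L) {
      seed <- base_seed + r + n_sims * ((j - 1L) + (i - 1L) * n_mu)
      tr <- tryCatch(simulate_explant(p, t_end = t_end, dt = dt, seed = seed),
                     error = function(e) NULL)
      if (is.null(tr)) next
      for (col in c("N", "M")) {
        rs <- growth_rate_series(tr[[col]], tr$t, window)
        if (is_active(rs$rate, threshold)) {
          lags <- c(lags, lag_time(rs$rate, rs$t, threshold))
          rates <- c(rates, max_growth_rate(rs$rate))
        }
      }
    }
    list(mean_lag = if (length(lags)) mean(lags) else NA_real_,
         mean_max_rate = if (length(rates)) mean(rates) else NA_real_)
  })
  prov <- list(base_params = base_params, n_sims = n_sims, t_end = t_end,
               dt = dt, base_seed = base_seed, threshold = threshold,
               window = window)
  common <- dplyr::mutate(cells, n_stable = NA_integer_,
                          failed = FALSE, repaired = FALSE, boundary = FALSE)
  lag_cells <- dplyr::mutate(common, mean_lag = purrr::map_dbl(res, "mean_lag"))
  rate_cells <- dplyr::mutate(common,
                              mean_max_rate = purrr::map_dbl(res, "mean_max_rate"))
  list(lag = new_grid_map(lag_cells, v0_values, mu_values, "mean_lag", prov),
       max_rate = new_grid_map(rate_cells, v0_values, mu_values,
                               "mean_max_rate", prov))
}

#' Sensitivity scan of a parameter-plane map
#'
#' Recomputes a map with each non-swept parameter perturbed by a fixed
#' fraction in both directions (`(1 - f)` and `(1 + f)` times its value),
#' one parameter at a time. The swept axes (`v0`, `mu`) are never perturbed.
#' Perturbations that would violate a parameter invariant are skipped with a
#' warning.
#'
#' @param map_fun a map constructor taking `(v0_values, mu_values,
#'   base_params, ...)`, e.g. [behavior_map()] or [outcome_fraction_map()].
#' @param v0_values,mu_values axis values passed through to `map_fun`.
#' @param base_params baseline parameter set.
#' @param fraction perturbation fraction in (0, 1); default 0.05.
#' @param parameters which parameters to perturb.
#' @param ... passed to `map_fun`.
#' @return A tibble with columns `parameter`, `direction` ("down"/"up"),
#'   `factor` and a list-column `map`.
#' @export
sensitivity_scan <- function(map_fun, v0_values, mu_values, base_params,
                             fraction = 0.05,
                             parameters = c("S", "D", "v", "K", "Q", "n", "eta"),
                             ...) {
  stopifnot(fraction >= 0, fraction < 1)
  parameters <- setdiff(parameters, c("v0", "mu"))
  grid <- tidyr::expand_grid(parameter = parameters,
                             direction = c("down", "up"))
  grid$factor <- ifelse(grid$direction == "down", 1 - fraction, 1 + fraction)
  grid$map <- purrr::pmap(grid, function(parameter, direction, factor) {
    p <- tryCatch({
      args <- stats::setNames(list(base_params[[parameter]] * factor), parameter)
      do.call(update, c(list(base_params), args))
    }, error = function(e) {
      warning(sprintf("skipping %s %s: %s", parameter, direction,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(p)) return(NULL)
    map_fun(v0_values, mu_values, p, ...)
  })
  grid
}
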