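#' Archetype of a two-bud explant for synthetic data generation
#'
#' Describes the distribution a synthetic cohort is drawn from: outcome
#' probabilities, lag (switch-day) and maximum-growth-rate distributions for
#' activating buds, plateau height, the residual creep rate of inhibited
#' buds, measurement noise, and the probability that a "both" explant is
#' realized sequentially (the dominant bud plateaus early and the second bud
#' activates afterwards) rather than simultaneously.
#'
#' @param label cohort label carried into the traces.
#' @param p_both,p_one,p_none outcome probabilities (sum to 1).
#' @param lag_mean,lag_sd switch-day distribution (days); realized switch
#'   days are rounded to whole days and clamped into `[1, days - 3]`.
#' @param rate_mean,rate_sd maximum growth rate distribution (mm/day);
#'   realized rates are clamped to at least 0.5 mm/day.
#' @param plateau total length gained by an activating bud (mm).
#' @param residual_rate slow creep rate of inhibited buds (mm/day); keep it
#'   below the activity threshold (2.5 mm/day) or inhibited buds will count
#'   as active.
#' @param noise_sd i.i.d. Gaussian measurement noise per observation (mm).
#' @param days number of days measured after day 0 (>= 3; observations at
#'   days `0:days`).
#' @param stop_switch probability that a "both" explant is staggered: the
#'   first bud rises to half the plateau, then the second activates.
#' @param baseline initial bud length (mm).
#' @return An `explant_archetype` list.
#' @export
explant_archetype <- function(label = "synthetic",
                              p_both = 0.3, p_one = 0.6, p_none = 0.1,
                              lag_mean = 4, lag_sd = 1.5,
                              rate_mean = 6, rate_sd = 1.5,
                              plateau = 25, residual_rate = 0.1,
                              noise_sd = 0.2, days = 14,
                              stop_switch = 0.25, baseline = 1.5) {
  stopifnot(p_both >= 0, p_one >= 0, p_none >= 0,
            lag_sd >= 0, rate_mean > 0, rate_sd >= 0, plateau > 0,
            residual_rate >= 0, noise_sd >= 0,
            days == round(days), days >= 3,
            stop_switch >= 0, stop_switch <= 1, baseline > 0)
  if (abs(p_both + p_one + p_none - 1) > 1e-9) {
    stop("outcome probabilities must sum to 1", call. = FALSE)
  }
  structure(list(label = label, p_both = p_both, p_one = p_one,
                 p_none = p_none, lag_mean = lag_mean, lag_sd = lag_sd,
                 rate_mean = rate_mean, rate_sd = rate_sd, plateau = plateau,
                 residual_rate = residual_rate, noise_sd = noise_sd,
                 days = as.integer(days), stop_switch = stop_switch,
                 baseline = baseline),
            class = "explant_archetype")
}

#' @export
print.explant_archetype <- function(x, ...) {
  cat(sprintf(paste0("<explant_archetype> %s: P(both/one/none) = %g/%g/%g, ",
                     "lag %g +/- %g d, rate %g +/- %g mm/d, plateau %g mm, ",
                     "noise %g mm, %d days\n"),
              x$label, x$p_both, x$p_one, x$p_none, x$lag_mean, x$lag_sd,
              x$rate_mean, x$rate_sd, x$plateau, x$noise_sd, x$days))
  invisible(x)
}

# steepness of a unit logistic started at its switch day: the curve
# L0 + c * (plogis(k (t - s - 1)) - plogis(-k)), c = A / (1 - plogis(-k)),
# is continuous at t = s, monotone, gains A in total, and has maximum slope
# c k / 4 = g exactly one day after the switch. k solves the implicit
# equation k = (4 g / A) (1 - plogis(-k)).
logistic_steepness <- function(g, A) {
  r <- 4 * g / A
  stats::uniroot(function(k) k - r * (1 - stats::plogis(-k)),
                 lower = 1e-9, upper = r, tol = 1e-12)$root
}

active_curve <- function(t, switch_day, g, A, baseline) {
  k <- logistic_steepness(g, A)
  c0 <- A / (1 - stats::plogis(-k))
  ifelse(t <= switch_day, baseline,
         baseline + c0 * (stats::plogis(k * (t - switch_day - 1)) -
                            stats::plogis(-k)))
}

inhibited_curve <- function(t, rate, baseline) baseline + rate * t

#' Generate a synthetic experimental-format cohort with known ground truth
#'
#' Draws `n` explants from an [explant_archetype()]: each explant's outcome
#' is drawn from the archetype probabilities; activating buds stay at the
#' baseline length until their drawn switch day and then rise logistically
#' (maximum slope equal to the drawn rate) to the plateau; inhibited buds
#' creep at the residual rate; i.i.d. Gaussian noise is added and lengths are
#' truncated at 0. The latent (noise-free) curves are monotone.
#'
#' The construction makes the ground truth exactly identifiable from
#' noise-free daily samples: the latent length at the switch day still equals
#' the baseline, the first above-threshold smoothed rate lands on the switch
#' day (for sufficiently fast rates), and the slope one day later equals the
#' drawn maximum rate.
#'
#' @param archetype an [explant_archetype()].
#' @param n number of explants (>= 1).
#' @param seed integer seed (required; the dataset is a deterministic
#'   function of it).
#' @return A `synthetic_cohort` list with `traces` (long-format tibble
#'   `explant_id, label, t, bud, length, excluded`, one row per bud per day)
#'   and `truth` (tibble `explant_id, bud, outcome, active, lag, max_rate`;
#'   `lag` is `NA` for inhibited buds, whose true rate is the residual rate).
#' @export
generate_explants <- function(archetype, n, seed) {
  stopifnot(inherits(archetype, "explant_archetype"), n >= 1)
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  a <- archetype
  set.seed(seed)
  times <- 0:a$days
  draw_lag <- function() {
    s <- round(stats::rnorm(1, a$lag_mean, a$lag_sd))
    as.integer(min(max(s, 1), a$days - 3))
  }
  draw_rate <- function() max(0.5, stats::rnorm(1, a$rate_mean, a$rate_sd))

  rows <- list()
  truths <- list()
  for (e in seq_len(n)) {
    id <- sprintf("%s-%04d", a$label, e)
    outcome <- sample(c("both", "one", "none"), 1,
                      prob = c(a$p_both, a$p_one, a$p_none))
    bud <- list()
    if (outcome == "none") {
      bud$top <- list(active = FALSE)
      bud$bottom <- list(active = FALSE)
    } else if (outcome == "one") {
      winner <- sample(c("top", "bottom"), 1)
      bud[[winner]] <- list(active = TRUE, s = draw_lag(), g = draw_rate(),
                            A = a$plateau)
      bud[[setdiff(c("top", "bottom"), winner)]] <- list(active = FALSE)
    } else {
      staggered <- stats::runif(1) < a$stop_switch
      first <- sample(c("top", "bottom"), 1)
      second <- setdiff(c("top", "bottom"), first)
      s1 <- draw_lag(); g1 <- draw_rate()
      if (staggered) {
        A1 <- a$plateau / 2
        s2 <- min(s1 + max(2L, as.integer(round(A1 / g1))), a$days - 2L)
        bud[[first]] <- list(active = TRUE, s = s1, g = g1, A = A1)
        bud[[second]] <- list(active = TRUE, s = s2, g = draw_rate(),
                              A = a$plateau)
      } else {
        bud[[first]] <- list(active = TRUE, s = s1, g = g1, A = a$plateau)
        bud[[second]] <- list(active = TRUE, s = draw_lag(), g = draw_rate(),
                              A = a$plateau)
      }
    }
    for (b in c("top", "bottom")) {
      spec_b <- bud[[b]]
      latent <- if (spec_b$active) {
        active_curve(times, spec_b$s, spec_b$g, spec_b$A, a$baseline)
      } else {
        inhibited_curve(times, a$residual_rate, a$baseline)
      }
      noisy <- pmax(0, latent + stats::rnorm(length(times), 0, a$noise_sd))
      rows[[length(rows) + 1]] <- tibble::tibble(
        explant_id = id, label = a$label, t = times, bud = b,
        length = noisy, excluded = FALSE)
      truths[[length(truths) + 1]] <- tibble::tibble(
        explant_id = id, bud = b, outcome = outcome,
        active = spec_b$active,
        lag = if (spec_b$active) as.numeric(spec_b$s) else NA_real_,
        max_rate = if (spec_b$active) spec_b$g else a$residual_rate)
    }
  }
  traces <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_rows(truths)
  structure(list(traces = traces, truth = truth,
                 archetype = a, seed = seed, n = n),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d explant(s) of `%s`, seed %d\n",
              x$n, x$archetype$label, x$seed))
  invisible(x)
}

#' @export
tidy.synthetic_cohort <- function(x, ...) x$truth

# ensemble trajectories at one parameter point, re-expressed as long-format
# bud traces at unit time steps (N = top bud, M = bottom bud)
model_traces <- function(params, n, t_end = 120, dt = 0.1, base_seed = 1,
                         label = "model") {
  ens <- simulate_ensemble(params, n_sims = n, t_end = t_end, dt = dt,
                           base_seed = base_seed)
  ens |>
    tibble::as_tibble() |>
    dplyr::transmute(explant_id = sprintf("%s-%04d", label, .data$sim),
                     label = label, t = .data$t,
                     top = .data$N, bottom = .data$M) |>
    tidyr::pivot_longer(c("top", "bottom"), names_to = "bud",
                        values_to = "length") |>
    dplyr::mutate(excluded = FALSE)
}

#' Simulated-source bud traces at placed parameter values
#'
#' Closes the loop between the map/placement machinery and the trace
#' pipeline: runs a stochastic ensemble at each placed `(v0, mu)` and
#' re-expresses the bud-length trajectories as long-format traces that
#' [trace_metrics()] reads in simulated mode.
#'
#' @param placement tibble with `label, v0, mu` (e.g. a `genotype_placement`
#'   or [genotype_presets()]).
#' @param base_params parameters supplying everything but `v0, mu`.
#' @param n explants (= ensemble members) per label.
#' @param t_end,dt simulation horizon and internal step; traces are recorded
#'   at unit time steps.
#' @param seed seed root; label `k` (row order) uses `seed + (k - 1) * n` as
#'   its ensemble base seed.
#' @return Long-format trace tibble (`explant_id, label, t, bud, length,
#'   excluded`).
#' @export
generate_from_model <- function(placement, base_params, n = 100,
                                t_end = 120, dt = 0.1, seed = 1) {
  stopifnot(all(c("label", "v0", "mu") %in% names(placement)), n >= 1)
  purrr::map_dfr(seq_len(nrow(placement)), function(k) {
    p <- update(base_params, v0 = placement$v0[k], mu = placement$mu[k])
    model_traces(p, n = n, t_end = t_end, dt = dt,
                 base_seed = seed + (k - 1) * n, label = placement$label[k])
  })
}
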