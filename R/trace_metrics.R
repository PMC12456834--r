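#' Smoothed growth-rate series of a bud-length trace
#'
#' Lengths are smoothed with a centered moving average of width `window`
#' (odd; shorter one-sided windows at the edges), then differentiated with
#' centered differences: the rate at time `t[i]` is
#' `(s[i+1] - s[i-1]) / (t[i+1] - t[i-1])` (one-sided at the ends). This is
#' the single extractor used for both experimental-format and simulated
#' traces.
#'
#' @param lengths bud lengths.
#' @param times strictly increasing time points (>= 3).
#' @param window moving-average width in samples (odd, default 3; 1 disables
#'   smoothing).
#' @return A tibble with columns `t` and `rate`.
#' @export
growth_rate_series <- function(lengths, times, window = 3) {
  n <- length(lengths)
  if (n < 3) stop("need at least 3 time points", call. = FALSE)
  stopifnot(length(times) == n, all(diff(times) > 0), window >= 1,
            window %% 2 == 1)
  s <- smooth_ma(lengths, window)
  lo <- pmax(seq_len(n) - 1, 1)
  hi <- pmin(seq_len(n) + 1, n)
  rate <- (s[hi] - s[lo]) / (times[hi] - times[lo])
  tibble::tibble(t = times, rate = rate)
}

smooth_ma <- function(x, window) {
  if (window == 1) return(x)
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    mean(x[idx])
  }, numeric(1))
}

#' Bud activity flag
#'
#' A bud is active iff any smoothed growth rate strictly exceeds the
#' threshold (2.5 mm/day for experimental traces, 0.02 length units per time
#' step for simulated ones).
#'
#' @param rates growth-rate series (e.g. from [growth_rate_series()]).
#' @param threshold activity threshold (> 0).
#' @return Logical flag.
#' @export
is_active <- function(rates, threshold) {
  stopifnot(threshold > 0)
  any(rates > threshold)
}

#' Lag time before activation
#'
#' Time elapsed from the start of the trace to the first rate sample that
#' strictly exceeds the threshold.
#'
#' @inheritParams is_active
#' @param times time coordinates aligned to `rates`.
#' @return Lag in the trace's time units. Errors for an inactive bud (use
#'   [is_active()] first).
#' @export
lag_time <- function(rates, times, threshold) {
  stopifnot(threshold > 0, length(rates) == length(times))
  i <- which(rates > threshold)[1]
  if (is.na(i)) stop("lag time undefined for an inactive bud", call. = FALSE)
  times[i] - times[1]
}

#' Maximum growth rate
#'
#' @inheritParams is_active
#' @return Maximum of the smoothed rate series. Errors on an empty series.
#' @export
max_growth_rate <- function(rates) {
  if (!length(rates)) stop("empty rate series", call. = FALSE)
  max(rates)
}

#' Relative growth index (RGI)
#'
#' Length of the longest bud divided by the summed length of both buds;
#' 0.5 means both buds grew equally, 1 means one bud dominated completely.
#' Defined for active explants only.
#'
#' @param top_final,bottom_final final bud lengths (vectors of equal length).
#' @return Numeric vector in \[0.5, 1\].
#' @export
relative_growth_index <- function(top_final, bottom_final) {
  stopifnot(length(top_final) == length(bottom_final))
  tot <- top_final + bottom_final
  if (any(tot <= 0)) stop("RGI undefined when both bud lengths are zero",
                          call. = FALSE)
  pmax(top_final, bottom_final) / tot
}

#' Per-explant growth outcome
#'
#' In simulated mode the outcome follows the final-length ratio rule:
#' "one" iff the longer bud is strictly more than `ratio` (default 3) times
#' the shorter; "both" if both final lengths exceed `activation_length` and
#' the ratio is within bound; "none" otherwise. In experimental mode the
#' outcome counts active flags (2 active buds = "both", 1 = "one", 0 =
#' "none").
#'
#' @param final_top,final_bottom final bud lengths (simulated mode).
#' @param active_top,active_bottom logical activity flags (experimental
#'   mode).
#' @param mode `"simulated"` or `"experimental"`.
#' @param activation_length minimum final length for a bud to count as grown
#'   in simulated mode. The default, used throughout the package for model
#'   traces started at length 0.1, is the initial length plus ten times the
#'   initial length (1.1): the ratio rule alone cannot distinguish "both
#'   grow" from "neither grows".
#' @param ratio dominance ratio (strict inequality).
#' @return `"both"`, `"one"` or `"none"`.
#' @export
growth_outcome <- function(final_top = NULL, final_bottom = NULL,
                           active_top = NULL, active_bottom = NULL,
                           mode = c("simulated", "experimental"),
                           activation_length = 1.1, ratio = 3) {
  mode <- match.arg(mode)
  if (mode == "experimental") {
    n_active <- sum(active_top, active_bottom)
    return(c("none", "one", "both")[n_active + 1])
  }
  long <- max(final_top, final_bottom)
  short <- min(final_top, final_bottom)
  if (long > ratio * short) return("one")
  if (final_top > activation_length && final_bottom > activation_length) {
    return("both")
  }
  "none"
}

#' Per-bud and per-explant metrics of bud-length traces
#'
#' Runs the full extractor over a long-format trace table: smoothed rates,
#' activity, lag, maximum growth rate per bud; growth outcome, final lengths
#' and RGI per explant. Explants flagged `excluded` (wilted samples in the
#' experimental assays) are dropped before any computation.
#'
#' @param traces long-format tibble with columns `explant_id`, `label`, `t`,
#'   `bud` ("top"/"bottom"), `length`, and optionally `excluded` (logical).
#' @param mode `"experimental"` (threshold 2.5 mm/day, outcomes from activity
#'   flags) or `"simulated"` (threshold 0.02, outcomes from the final-length
#'   ratio rule).
#' @param threshold activity threshold; defaults by mode.
#' @param window smoothing window for [growth_rate_series()].
#' @param activation_length,ratio see [growth_outcome()] (simulated mode).
#' @return A `bud_metrics` object: list with tibbles `buds` (`explant_id`,
#'   `label`, `bud`, `active`, `lag`, `max_rate`, `final_length`) and
#'   `explants` (`explant_id`, `label`, `final_top`, `final_bottom`,
#'   `outcome`, `explant_active`, `rgi`). `lag` is `NA` for inactive buds and
#'   `rgi` is `NA` for inactive explants.
#' @export
trace_metrics <- function(traces, mode = c("experimental", "simulated"),
                          threshold = NULL, window = 3,
                          activation_length = 1.1, ratio = 3) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "experimental") 2.5 else 0.02
  traces <- check_traces(traces)

  buds <- traces |>
    dplyr::group_by(.data$explant_id, .data$label, .data$bud) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::summarise(
      metrics = list(bud_metrics_one(.data$length, .data$t, threshold, window)),
      .groups = "drop") |>
    tidyr::unnest_wider("metrics")

  explants <- buds |>
    tidyr::pivot_wider(id_cols = c("explant_id", "label"),
                       names_from = "bud",
                       values_from = c("final_length", "active")) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      outcome = growth_outcome(.data$final_length_top, .data$final_length_bottom,
                               .data$active_top, .data$active_bottom,
                               mode = mode,
                               activation_length = activation_length,
                               ratio = ratio),
      explant_active = .data$active_top || .data$active_bottom,
      rgi = if (.data$explant_active) {
        relative_growth_index(.data$final_length_top, .data$final_length_bottom)
      } else NA_real_) |>
    dplyr::ungroup() |>
    dplyr::rename(final_top = "final_length_top",
                  final_bottom = "final_length_bottom")

  structure(list(buds = buds, explants = explants,
                 mode = mode, threshold = threshold, window = window),
            class = "bud_metrics")
}

bud_metrics_one <- function(lengths, times, threshold, window) {
  rs <- growth_rate_series(lengths, times, window)
  act <- is_active(rs$rate, threshold)
  list(active = act,
       lag = if (act) lag_time(rs$rate, rs$t, threshold) else NA_real_,
       max_rate = max_growth_rate(rs$rate),
       final_length = lengths[length(lengths)])
}

check_traces <- function(traces) {
  need <- c("explant_id", "label", "t", "bud", "length")
  if (!all(need %in% names(traces))) {
    stop("traces must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if ("excluded" %in% names(traces)) {
    traces <- dplyr::filter(traces, !.data$excluded)
  }
  if (any(traces$length < 0)) stop("lengths must be nonnegative", call. = FALSE)
  tibble::as_tibble(traces)
}

#' @export
print.bud_metrics <- function(x, ...) {
  cat(sprintf("<bud_metrics> %d explant(s), mode = %s, threshold = %g\n",
              nrow(x$explants), x$mode, x$threshold))
  print(x$explants)
  invisible(x)
}

#' @export
tidy.bud_metrics <- function(x, ...) x$buds

#' @export
glance.bud_metrics <- function(x, ...) outcome_summary(x)

#' Outcome fractions and percent active explants
#'
#' @param metrics a `bud_metrics` object (or a tibble with an `outcome`
#'   column, one row per explant).
#' @return One-row tibble with `p_both`, `p_one`, `p_none`, `pct_active`
#'   (percentage of explants with at least one active bud) and `n`.
#' @export
outcome_summary <- function(metrics) {
  ex <- if (inherits(metrics, "bud_metrics")) metrics$explants else metrics
  if (!nrow(ex)) stop("no explants", call. = FALSE)
  n <- nrow(ex)
  p_both <- mean(ex$outcome == "both")
  p_one <- mean(ex$outcome == "one")
  p_none <- mean(ex$outcome == "none")
  tibble::tibble(p_both = p_both, p_one = p_one, p_none = p_none,
                 pct_active = 100 * (p_both + p_one), n = n)
}

#' Mitchison series: paired bud lengths over time
#'
#' Re-arranges traces into per-explant (top length, bottom length) pairs over
#' time, tagged by growth outcome for coloring — the data behind a Mitchison
#' plot (top-bud length versus bottom-bud length trajectory per explant).
#'
#' @inheritParams trace_metrics
#' @return A tibble with columns `explant_id`, `label`, `t`, `top`, `bottom`,
#'   `outcome`.
#' @export
mitchison_series <- function(traces, mode = c("experimental", "simulated"),
                             ...) {
  mode <- match.arg(mode)
  traces <- check_traces(traces)
  m <- trace_metrics(traces, mode = mode, ...)
  wide <- traces |>
    tidyr::pivot_wider(id_cols = c("explant_id", "label", "t"),
                       names_from = "bud", values_from = "length") |>
    dplyr::arrange(.data$explant_id, .data$t)
  dplyr::left_join(wide,
                   dplyr::select(m$explants, "explant_id", "outcome"),
                   by = "explant_id")
}
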