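#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

outcome_blend <- function(p_both, p_one, p_none) {
  # yellow = both, blue = one, red = none, blended linearly in RGB
  w <- cbind(p_both, p_one, p_none)
  base <- rbind(both = c(1, 1, 0), one = c(0, 0, 1), none = c(1, 0, 0))
  rgbm <- pmin(pmax(w %*% base, 0), 1)
  miss <- !stats::complete.cases(rgbm)
  out <- rep(NA_character_, nrow(rgbm))
  out[!miss] <- grDevices::rgb(rgbm[!miss, 1], rgbm[!miss, 2], rgbm[!miss, 3])
  out
}

behavior_palette <- function() {
  c(`1` = "#f7e84b", `2` = "#b8d46e", `3` = "#4d7fd1",
    `4` = "#7f5fa8", `5` = "#d98a3d", `6` = "#d64545")
}

#' Plot a grid map
#'
#' Outcome maps blend the three outcome fractions into one color per cell
#' (yellow = both buds grow, blue = one, red = neither); behavior maps use a
#' discrete six-class palette; metric maps use a continuous fill. Boundary
#' pixels are overdrawn in black and failed pixels in grey.
#'
#' @param object a `grid_map`.
#' @param boundaries draw boundary pixels in black.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.grid_map <- function(object, boundaries = TRUE, ...) {
  cells <- object$cells
  if (object$kind == "outcome") {
    cells$fill <- outcome_blend(cells$p_both, cells$p_one, cells$p_none)
  }
  base <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$mu, y = .data$v0)) +
    ggplot2::labs(x = expression(mu), y = expression(v[0]),
                  title = paste("grid map:", object$kind)) +
    ggplot2::theme_minimal()
  p <- if (object$kind == "outcome") {
    base + ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
      ggplot2::scale_fill_identity(na.value = "grey70")
  } else if (object$kind == "behavior") {
    base + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$class_id))) +
      ggplot2::scale_fill_manual(values = behavior_palette(),
                                 na.value = "grey70", name = "class")
  } else {
    value_col <- setdiff(grid_channels(object), c("class_id", "n_stable"))[1]
    base + ggplot2::geom_raster(ggplot2::aes(fill = .data[[value_col]])) +
      ggplot2::scale_fill_viridis_c(na.value = "grey70", name = value_col)
  }
  if (any(object$cells$failed)) {
    p <- p + ggplot2::geom_tile(data = dplyr::filter(cells, .data$failed),
                                fill = "grey40")
  }
  if (boundaries && any(cells$boundary)) {
    p <- p + ggplot2::geom_tile(data = dplyr::filter(cells, .data$boundary),
                                fill = "black")
  }
  p
}

#' Plot a simulated trajectory
#'
#' Efflux commitments (E, F) and bud lengths (N, M) over time in two facets.
#'
#' @param object a `bud_trajectory`.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.bud_trajectory <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("E", "F", "N", "M"),
                        names_to = "variable", values_to = "value") |>
    dplyr::mutate(panel = ifelse(.data$variable %in% c("E", "F"),
                                 "auxin efflux", "bud length"),
                  bud = ifelse(.data$variable %in% c("E", "N"),
                               "top", "bottom"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     color = .data$bud)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "time steps", y = NULL,
                  subtitle = paste0(attr(object, "scheme"), " simulation")) +
    ggplot2::theme_minimal()
}

#' Mitchison plot: top-bud length against bottom-bud length
#'
#' One path per explant through the (bottom, top) length plane, colored by
#' growth outcome; the diagonal marks equal growth.
#'
#' @param series tibble from [mitchison_series()].
#' @return A ggplot.
#' @export
plot_mitchison <- function(series) {
  stopifnot(all(c("top", "bottom", "explant_id", "outcome") %in% names(series)))
  ggplot2::ggplot(series, ggplot2::aes(x = .data$bottom, y = .data$top,
                                       group = .data$explant_id,
                                       color = .data$outcome)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(both = "#c2a829", one = "#4d7fd1",
                                           none = "#d64545")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "bottom bud length", y = "top bud length") +
    ggplot2::theme_minimal()
}
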