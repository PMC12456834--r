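# vectorized drift and Jacobian over point sets (internal, no validation)
v_efflux <- function(E, F, p) {
  w <- p$D * (E + F) + p$K
  wn <- w^p$n
  uE <- hill_pow(p$S * E, p$n)
  uF <- hill_pow(p$S * F, p$n)
  list(fE = p$v0 + p$v * safe_frac(uE, uE + wn) - p$mu * E,
       fF = p$v0 + p$v * safe_frac(uF, uF + wn) - p$mu * F)
}

v_jac <- function(E, F, p) {
  n <- p$n
  w <- p$D * (E + F) + p$K
  wn <- w^n
  dwn <- ifelse(w > 0, n * w^(n - 1) * p$D, 0)
  uE <- hill_pow(p$S * E, n)
  uF <- hill_pow(p$S * F, n)
  duE <- ifelse(E > 0, n * p$S * (p$S * E)^(n - 1), if (n == 1) p$S else 0)
  duF <- ifelse(F > 0, n * p$S * (p$S * F)^(n - 1), if (n == 1) p$S else 0)
  qE <- uE + wn; qF <- uF + wn
  list(J11 = p$v * (duE * wn - uE * dwn) / qE^2 - p$mu,
       J12 = p$v * (-uE * dwn) / qE^2,
       J21 = p$v * (-uF * dwn) / qF^2,
       J22 = p$v * (duF * wn - uF * dwn) / qF^2 - p$mu)
}

#' Steady states on the symmetric line E = F
#'
#' For integer Hill exponent `n` the symmetric fixed-point condition
#' `(v0 - mu x)((S x)^n + (2 D x + K)^n) + v (S x)^n = 0` is a degree `n + 1`
#' polynomial whose real nonnegative roots are enumerated exactly
#' (`polyroot`); for non-integer `n` a dense sign-change scan with `uniroot`
#' refinement is used instead.
#'
#' @param params a [bud_params()] object.
#' @param tol residual tolerance used to polish and accept roots.
#' @return Sorted numeric vector of symmetric fixed-point values.
#' @export
symmetric_steady_states <- function(params, tol = 1e-10) {
  p <- params
  f <- function(x) v_efflux(x, x, p)$fE
  if (abs(p$n - round(p$n)) < 1e-12) {
    n <- as.integer(round(p$n))
    # coefficients (x^0 .. x^n) of (Sx)^n + (2Dx+K)^n
    g <- sapply(0:n, function(k) choose(n, k) * (2 * p$D)^k * p$K^(n - k))
    g[n + 1] <- g[n + 1] + p$S^n
    coefs <- c(p$v0 * g, 0) + c(0, -p$mu * g)
    coefs[n + 1] <- coefs[n + 1] + p$v * p$S^n
    r <- polyroot(coefs)
    x <- Re(r)[abs(Im(r)) < 1e-7 & Re(r) > -1e-9]
    x <- pmax(x, 0)
  } else {
    hi <- (p$v0 + p$v) / p$mu
    grid <- seq(0, hi * 1.05, length.out = 2000)
    fg <- f(grid)
    sc <- which(fg[-1] * fg[-length(fg)] <= 0)
    x <- vapply(sc, function(i) {
      stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-14)$root
    }, numeric(1))
  }
  # polish with 1-D Newton and filter by residual
  for (k in seq_len(8)) {
    if (!length(x)) break
    jac <- v_jac(x, x, p)
    d <- f(x) / (jac$J11 + jac$J12)
    d[!is.finite(d)] <- 0
    x <- pmax(x - d, 0)
  }
  x <- x[abs(f(x)) < tol]
  sort(unique(round(x, 12)))
}

#' Find all fixed points of the efflux subsystem
#'
#' Locates the fixed points of `(dE/dt, dF/dt)` by combining exact
#' enumeration on the symmetric line (see [symmetric_steady_states()]) with
#' vectorized damped-Newton iteration from a dense lattice of starting
#' points plus all pairings of the symmetric roots. Points are deduplicated,
#' closed under the `(E, F) <-> (F, E)` swap, and labelled stable or unstable
#' by linear stability (see [classify_stability()]).
#'
#' @param params a [bud_params()] object.
#' @param n_starts lattice density per axis for the Newton multi-start.
#' @param dedup_radius points closer than this (in efflux units, max norm)
#'   are merged.
#' @param tol residual tolerance: accepted fixed points satisfy
#'   `|dE/dt|, |dF/dt| < tol`.
#' @param eps_margin stability margin: a point is stable iff the largest real
#'   part of the Jacobian eigenvalues is below `-eps_margin`.
#' @param box upper bound of the search box; defaults to the invariant bound
#'   `(v0 + v)/mu`.
#' @return A `steady_state_set`: tibble with columns `E, F, stable, eig_max`
#'   (largest real part of the Jacobian eigenvalues) and attributes `params`,
#'   `tolerance`, `dedup_radius`.
#' @export
find_steady_states <- function(params, n_starts = 12, dedup_radius = 1e-6,
                               tol = 1e-10, eps_margin = 1e-8, box = NULL) {
  validate_bud_params(params)
  p <- params
  if (is.null(box)) box <- (p$v0 + p$v) / p$mu
  sym <- symmetric_steady_states(p, tol = tol)

  ax <- seq(0, box, length.out = n_starts)
  E0 <- c(rep(ax, times = n_starts), rep(sym, each = length(sym)))
  F0 <- c(rep(ax, each = n_starts), rep(sym, times = length(sym)))
  # also pair each symmetric root with the extremes (catches far-out asymmetry)
  if (length(sym)) {
    E0 <- c(E0, sym, rep(box, length(sym)))
    F0 <- c(F0, rep(box, length(sym)), sym)
  }
  pts <- newton_multi(E0, F0, p, box)
  # keep converged fixed points
  res <- v_efflux(pts$E, pts$F, p)
  ok <- is.finite(pts$E) & is.finite(pts$F) &
    abs(res$fE) < tol & abs(res$fF) < tol
  E <- c(pts$E[ok], sym)
  F <- c(pts$F[ok], sym)
  # swap closure
  E2 <- c(E, F); F2 <- c(F, E)
  keep <- dedup_points(E2, F2, dedup_radius)
  E <- E2[keep]; F <- F2[keep]
  if (!length(E)) {
    stop("steady-state search failed to converge from all starts",
         call. = FALSE)
  }
  eig <- vapply(seq_along(E), function(i) {
    max(Re(eigen(efflux_jacobian(E[i], F[i], p), only.values = TRUE)$values))
  }, numeric(1))
  out <- tibble::tibble(E = E, F = F, stable = eig < -eps_margin,
                        eig_max = eig)
  out <- dplyr::arrange(out, E, F)
  structure(out, class = c("steady_state_set", class(out)),
            params = p, tolerance = tol, dedup_radius = dedup_radius)
}

# vectorized damped Newton on the efflux drift from many starts
newton_multi <- function(E, F, p, box, maxit = 80) {
  for (it in seq_len(maxit)) {
    f <- v_efflux(E, F, p)
    J <- v_jac(E, F, p)
    det <- J$J11 * J$J22 - J$J12 * J$J21
    det[det == 0 | !is.finite(det)] <- NA
    dE <- (J$J22 * f$fE - J$J12 * f$fF) / det
    dF <- (J$J11 * f$fF - J$J21 * f$fE) / det
    dE[is.na(dE)] <- 0; dF[is.na(dF)] <- 0
    damp <- rep(1, length(E))
    for (h in 1:40) {
      bad <- (E - damp * dE < 0) | (F - damp * dF < 0) |
        (E - damp * dE > 2 * box) | (F - damp * dF > 2 * box)
      if (!any(bad)) break
      damp[bad] <- damp[bad] / 2
    }
    E <- pmax(E - damp * dE, 0)
    F <- pmax(F - damp * dF, 0)
  }
  list(E = E, F = F)
}

dedup_points <- function(E, F, radius) {
  keep <- logical(length(E))
  for (i in seq_along(E)) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- which(keep[seq_len(i - 1)])
    keep[i] <- !any(pmax(abs(E[prev] - E[i]), abs(F[prev] - F[i])) < radius)
  }
  keep
}

#' Linear stability of a fixed point
#'
#' A fixed point is stable iff the largest real part of the efflux Jacobian's
#' eigenvalues is below `-eps_margin`; marginal cases (within `eps_margin` of
#' zero) and saddles are labelled unstable, preserving the binary labelling
#' of the classification scheme.
#'
#' @param E,F fixed-point coordinates.
#' @param params a [bud_params()] object.
#' @param eps_margin stability margin.
#' @return `"stable"` or `"unstable"`.
#' @export
classify_stability <- function(E, F, params, eps_margin = 1e-8) {
  eig <- max(Re(eigen(efflux_jacobian(E, F, params), only.values = TRUE)$values))
  if (eig < -eps_margin) "stable" else "unstable"
}

#' @export
print.steady_state_set <- function(x, ...) {
  cat(sprintf("<steady_state_set> %d point(s), %d stable (tol = %g)\n",
              nrow(x), sum(x$stable), attr(x, "tolerance")))
  NextMethod()
}

behavior_descriptions <- c(
  "both activate", "both-or-one", "only one",
  "one-or-neither", "all four outcomes", "neither activates")
behavior_colors <- c("yellow", "green", "navy", "light blue", "white", "red")

#' The six-class behavior taxonomy
#'
#' @return A tibble with columns `class_id`, `description`, `color_role`.
#' @export
behavior_table <- function() {
  tibble::tibble(class_id = 1:6,
                 description = behavior_descriptions,
                 color_role = behavior_colors)
}

#' Classify a steady-state set into one of six behaviors
#'
#' The classification uses only the *stable* points. With `sym` the stable
#' symmetric points (E = F) and `asym` the stable asymmetric swap-pairs:
#' \itemize{
#' \item one sym with value >= `active_threshold`, no asym: class 1 (both activate)
#' \item one sym with value >= `distinguish_threshold` plus asym pair(s): class 2 (both-or-one)
#' \item asym pair(s) only: class 3 (only one)
#' \item one sym with value < `distinguish_threshold` plus asym pair(s): class 4 (one-or-neither)
#' \item two sym (one >= `active_threshold`, one below) plus asym pair(s): class 5 (all four outcomes)
#' \item one sym with value < `active_threshold`, no asym: class 6 (neither activates)
#' }
#' A stable configuration outside this table raises an error (condition class
#' `budcanal_unclassifiable`); it is never silently coerced.
#'
#' @param sset a `steady_state_set` from [find_steady_states()].
#' @param active_threshold symmetric steady-state value separating a
#'   both-activate from a neither-activates state (default 0.4).
#' @param distinguish_threshold value separating the active symmetric state
#'   of the both-or-one class from the inactive one of one-or-neither
#'   (default 0.24).
#' @param sym_tol points with `|E - F|` below this count as symmetric.
#' @return A list of class `behavior_class` with elements `class_id`,
#'   `description`, `color_role`, `n_stable`.
#' @export
classify_behavior <- function(sset, active_threshold = 0.4,
                              distinguish_threshold = 0.24, sym_tol = 1e-5) {
  st <- sset[sset$stable, , drop = FALSE]
  sym <- st$E[abs(st$E - st$F) < sym_tol]
  n_asym_pairs <- sum(abs(st$E - st$F) >= sym_tol) / 2
  id <- NA_integer_
  if (length(sym) == 1 && n_asym_pairs == 0) {
    id <- if (sym >= active_threshold) 1L else 6L
  } else if (length(sym) == 1 && n_asym_pairs >= 1) {
    id <- if (sym >= distinguish_threshold) 2L else 4L
  } else if (length(sym) == 0 && n_asym_pairs >= 1) {
    id <- 3L
  } else if (length(sym) == 2 && n_asym_pairs >= 1) {
    v <- sort(sym)
    if (v[1] < active_threshold && v[2] >= active_threshold) id <- 5L
  }
  if (is.na(id)) {
    stop(structure(class = c("budcanal_unclassifiable", "error", "condition"),
                   list(message = sprintf(
                     paste0("stable-point configuration outside the six-class ",
                            "table: %d symmetric value(s) [%s], %g asymmetric pair(s)"),
                     length(sym), paste(signif(sym, 4), collapse = ", "),
                     n_asym_pairs),
                     call = NULL)))
  }
  structure(list(class_id = id,
                 description = behavior_descriptions[id],
                 color_role = behavior_colors[id],
                 n_stable = nrow(st)),
            class = "behavior_class")
}

#' @export
print.behavior_class <- function(x, ...) {
  cat(sprintf("<behavior_class> %d: %s (%s), %d stable state(s)\n",
              x$class_id, x$description, x$color_role, x$n_stable))
  invisible(x)
}

#' Nullclines of the efflux subsystem
#'
#' Traces the zero-level curves of `dE/dt` and `dF/dt` on a regular grid
#' (marching squares via `grDevices::contourLines`). Pairwise intersections
#' of the two families coincide with the fixed points up to grid resolution.
#'
#' @param params a [bud_params()] object.
#' @param E_range,F_range axis ranges (positive).
#' @param resolution grid points per axis (>= 2).
#' @return A tibble with columns `curve` ("dE" or "dF"), `piece` (curve
#'   segment index), `E`, `F`.
#' @export
nullclines <- function(params, E_range = NULL, F_range = NULL, resolution = 201) {
  validate_bud_params(params)
  stopifnot(resolution >= 2)
  hi <- (params$v0 + params$v) / params$mu * 1.05
  if (is.null(E_range)) E_range <- c(0, hi)
  if (is.null(F_range)) F_range <- c(0, hi)
  Es <- seq(E_range[1], E_range[2], length.out = resolution)
  Fs <- seq(F_range[1], F_range[2], length.out = resolution)
  grid <- expand.grid(E = Es, F = Fs)
  r <- v_efflux(grid$E, grid$F, params)
  zE <- matrix(r$fE, resolution, resolution)
  zF <- matrix(r$fF, resolution, resolution)
  one <- function(z, label) {
    cl <- grDevices::contourLines(Es, Fs, z, levels = 0)
    purrr::imap_dfr(cl, function(seg, i) {
      tibble::tibble(curve = label, piece = i, E = seg$x, F = seg$y)
    })
  }
  dplyr::bind_rows(one(zE, "dE"), one(zF, "dF"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.steady_state_set <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.steady_state_set <- function(x, ...) {
  tibble::tibble(n_points = nrow(x), n_stable = sum(x$stable),
                 tolerance = attr(x, "tolerance"))
}
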