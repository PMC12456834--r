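#' Right-hand sides of the efflux equations
#'
#' Evaluates the drift of the two-bud efflux subsystem,
#' \deqn{dE/dt = v_0 + v (S E)^n / ((S E)^n + (D(E+F)+K)^n) - \mu E,}
#' and symmetrically for `F`. The shared sink term `D(E+F)+K` couples the
#' buds: each bud's efflux dampens both its own positive feedback and the
#' partner's, at strength `D`.
#'
#' @param E,F auxin efflux of the top and bottom bud (nonnegative, may be
#'   vectors of equal length).
#' @param params a [bud_params()] object.
#' @return A tibble with columns `dE`, `dF`.
#' @examples
#' efflux_rates(0.2, 0.2, bud_params(v0 = 0.05, v = 1, S = 1, n = 2,
#'                                   K = 0.5, D = 0.5, mu = 0.5))
#' @export
efflux_rates <- function(E, F, params) {
  validate_bud_params(params)
  check_state(E, F)
  w <- params$D * (E + F) + params$K
  uE <- hill_pow(params$S * E, params$n)
  uF <- hill_pow(params$S * F, params$n)
  wn <- w^params$n
  tibble::tibble(
    dE = params$v0 + params$v * safe_frac(uE, uE + wn) - params$mu * E,
    dF = params$v0 + params$v * safe_frac(uF, uF + wn) - params$mu * F
  )
}

#' Growth rates of the two buds
#'
#' Bud elongation is a Hill function of the bud's own efflux:
#' \deqn{dN/dt = E^m / (Q^m + E^m).}
#' Rates lie in \[0, 1) and equal 0.5 exactly at `E = Q`.
#'
#' @inheritParams efflux_rates
#' @return A tibble with columns `dN`, `dM`.
#' @export
growth_rates <- function(E, F, params) {
  validate_bud_params(params)
  check_state(E, F)
  Qm <- params$Q^params$m
  tibble::tibble(
    dN = safe_frac(hill_pow(E, params$m), Qm + hill_pow(E, params$m)),
    dM = safe_frac(hill_pow(F, params$m), Qm + hill_pow(F, params$m))
  )
}

#' Jacobian of the efflux subsystem
#'
#' Analytic 2x2 matrix of partial derivatives of `(dE/dt, dF/dt)` with
#' respect to `(E, F)`, used for the implicit integrator, Newton root
#' polishing and linear stability classification.
#'
#' @param E,F scalar efflux values (>= 0).
#' @param params a [bud_params()] object.
#' @return A 2x2 numeric matrix.
#' @export
efflux_jacobian <- function(E, F, params) {
  validate_bud_params(params)
  check_state(E, F)
  stopifnot(length(E) == 1, length(F) == 1)
  n <- params$n; S <- params$S; D <- params$D; v <- params$v
  w <- D * (E + F) + params$K
  wn <- w^n
  dwn <- if (w > 0) n * w^(n - 1) * D else 0
  uE <- hill_pow(S * E, n); uF <- hill_pow(S * F, n)
  duE <- dhill_pow(S * E, n) * S
  duF <- dhill_pow(S * F, n) * S
  qE <- uE + wn; qF <- uF + wn
  if (qE == 0 || qF == 0) {
    stop("Hill denominator is zero; evaluation undefined here", call. = FALSE)
  }
  J11 <- v * (duE * wn - uE * dwn) / qE^2 - params$mu
  J12 <- v * (-uE * dwn) / qE^2
  J21 <- v * (-uF * dwn) / qF^2
  J22 <- v * (duF * wn - uF * dwn) / qF^2 - params$mu
  matrix(c(J11, J21, J12, J22), 2, 2)
}

# x^n with the 0^n = 0 convention for n >= 1 (avoids NaN from 0^0 paths)
hill_pow <- function(x, n) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos]^n
  out
}

# d/dx x^n, finite at 0 for n >= 1 (equals 1 when n == 1, else 0)
dhill_pow <- function(x, n) {
  if (x > 0) return(n * x^(n - 1))
  if (n == 1) 1 else 0
}

safe_frac <- function(num, den) {
  out <- numeric(length(num))
  nz <- den > 0
  out[nz] <- num[nz] / den[nz]
  out
}

check_state <- function(E, F) {
  if (!is.numeric(E) || !is.numeric(F) || length(E) != length(F)) {
    stop("E and F must be numeric vectors of equal length", call. = FALSE)
  }
  if (any(!is.finite(E)) || any(!is.finite(F)) || any(E < 0) || any(F < 0)) {
    stop("state values must be finite and nonnegative", call. = FALSE)
  }
  invisible(TRUE)
}
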