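#' Simulate the four-variable bud-competition system
#'
#' Integrates `(E, F, N, M)` with a drift-implicit (semi-implicit)
#' Euler-Maruyama scheme: the efflux drift is solved implicitly by damped
#' Newton at every step, noise is added explicitly. With `eta = 0` the same
#' scheme runs deterministically. Stochasticity enters the efflux equations
#' only, as chemical-Langevin increments built from two reaction channels per
#' bud -- production `a = v0 + v * Hill` and decay `b = mu * x` -- scaled
#' linearly by `eta`:
#' \deqn{dE = (a - b)\,dt + \eta(\sqrt{a}\,dW_1 - \sqrt{b}\,dW_2).}
#' Bud lengths integrate the growth Hill of the solved efflux without noise.
#' Any efflux driven below 0 by noise is clamped to 0 before the next step;
#' clamping events are counted in the result's attributes.
#'
#' @param params a [bud_params()] object.
#' @param init named numeric vector with entries `E, F, N, M`. The default is
#'   the standard dormant start (0.01 efflux, 0.1 length).
#' @param t_end simulation horizon in time steps.
#' @param dt internal integration step.
#' @param seed integer seed; required when `eta > 0` (if omitted, one is
#'   drawn and recorded).
#' @param save_every record every `save_every`-th internal step (plus t = 0);
#'   the default records at unit time steps.
#' @return A `bud_trajectory`: a tibble with columns `t, E, F, N, M` and
#'   attributes `params`, `scheme` ("deterministic" or "stochastic"), `seed`,
#'   `dt` and `clamps`.
#' @examples
#' tr <- simulate_explant(bud_params(eta = 0), t_end = 40)
#' @export
simulate_explant <- function(params, init = c(E = 0.01, F = 0.01, N = 0.1, M = 0.1),
                             t_end = 120, dt = 0.05, seed = NULL,
                             save_every = max(1L, round(1 / dt))) {
  validate_bud_params(params)
  stopifnot(dt > 0, t_end >= dt)
  init <- init[c("E", "F", "N", "M")]
  if (anyNA(init) || any(!is.finite(init)) || any(init < 0)) {
    stop("`init` must supply finite nonnegative E, F, N, M", call. = FALSE)
  }
  steps <- round(t_end / dt)
  stochastic <- params$eta > 0
  if (stochastic) {
    if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
    set.seed(seed)
    noise <- matrix(stats::rnorm(steps * 4), steps, 4)
  } else {
    noise <- matrix(0, 0, 4)
  }
  res <- .sde_path(param_vec(params), as.numeric(init), steps * dt, dt,
                   noise, as.integer(save_every))
  if (!res$ok) {
    stop(sprintf("integration failed (non-finite state) at t = %.4g",
                 res$fail_time), call. = FALSE)
  }
  out <- tibble::tibble(t = res$t, E = res$E, F = res$F, N = res$N, M = res$M)
  structure(out,
            class = c("bud_trajectory", class(out)),
            params = params,
            scheme = if (stochastic) "stochastic" else "deterministic",
            seed = if (stochastic) seed else NA_integer_,
            dt = dt,
            clamps = res$clamps)
}

#' @export
print.bud_trajectory <- function(x, ...) {
  cat(sprintf("<bud_trajectory> %s, dt = %g, seed = %s, clamps = %d\n",
              attr(x, "scheme"), attr(x, "dt"),
              format(attr(x, "seed")), attr(x, "clamps")))
  NextMethod()
}

#' Ensemble of stochastic simulations
#'
#' Runs `n_sims` independent trajectories; member `i` uses seed
#' `base_seed + i`, making the whole ensemble a deterministic function of
#' `base_seed`.
#'
#' @inheritParams simulate_explant
#' @param n_sims number of ensemble members (>= 1).
#' @param base_seed integer; member `i` is seeded with `base_seed + i`.
#' @return A `bud_ensemble` tibble with columns `sim, t, E, F, N, M` and
#'   attributes `params`, `dt`, `base_seed`.
#' @export
simulate_ensemble <- function(params, init = c(E = 0.01, F = 0.01, N = 0.1, M = 0.1),
                              n_sims = 100, t_end = 120, dt = 0.05,
                              base_seed = 1,
                              save_every = max(1L, round(1 / dt))) {
  stopifnot(n_sims >= 1)
  runs <- purrr::map(seq_len(n_sims), function(i) {
    tr <- tryCatch(
      simulate_explant(params, init, t_end, dt, seed = base_seed + i,
                       save_every = save_every),
      error = function(e) {
        stop(sprintf("ensemble member %d: %s", i, conditionMessage(e)),
             call. = FALSE)
      })
    dplyr::mutate(tibble::as_tibble(tr), sim = i, .before = 1)
  })
  out <- dplyr::bind_rows(runs)
  structure(out, class = c("bud_ensemble", class(out)),
            params = params, dt = dt, base_seed = base_seed)
}

#' High-accuracy reference integration (deterministic)
#'
#' Independent cross-check for the package's own integrator: solves the
#' deterministic system with `deSolve::ode` (lsoda, tight tolerances).
#' Only valid for `eta = 0`.
#'
#' @inheritParams simulate_explant
#' @param times output time points.
#' @return A tibble with columns `t, E, F, N, M`.
#' @export
reference_trajectory <- function(params, init = c(E = 0.01, F = 0.01, N = 0.1, M = 0.1),
                                 times = 0:120) {
  validate_bud_params(params)
  if (params$eta > 0) stop("reference integrator is deterministic; set eta = 0",
                           call. = FALSE)
  rhs <- function(t, y, parms) {
    er <- efflux_rates(y[1], y[2], params)
    gr <- growth_rates(y[1], y[2], params)
    list(c(er$dE, er$dF, gr$dN, gr$dM))
  }
  sol <- deSolve::ode(as.numeric(init[c("E", "F", "N", "M")]), times, rhs,
                      NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  tibble::tibble(t = sol[, 1], E = sol[, 2], F = sol[, 3],
                 N = sol[, 4], M = sol[, 5])
}

#' Deterministic switch time
#'
#' Time at which the (deterministic) growth rate of the top bud first exceeds
#' the activity threshold, located by linear interpolation between internal
#' integration steps. This is the model's lag phase duration in the absence
#' of noise.
#'
#' @inheritParams simulate_explant
#' @param threshold growth-rate activity threshold (default 0.02, the
#'   simulated-trace convention).
#' @return Switch time in time steps, or `Inf` if growth never crosses the
#'   threshold before `t_end`.
#' @export
switch_time <- function(params, init = c(E = 0.01, F = 0.01, N = 0.1, M = 0.1),
                        t_end = 300, dt = 0.01, threshold = 0.02) {
  p0 <- update(params, eta = 0)
  tr <- simulate_explant(p0, init, t_end, dt, save_every = 1L)
  g <- growth_rates(tr$E, tr$F, p0)$dN
  i <- which(g > threshold)[1]
  if (is.na(i)) return(Inf)
  if (i == 1) return(tr$t[1])
  # linear interpolation of the crossing
  tr$t[i - 1] + (threshold - g[i - 1]) / (g[i] - g[i - 1]) * (tr$t[i] - tr$t[i - 1])
}

#' Export a trajectory with its metadata sidecar
#'
#' Writes the state table as TSV and a JSON sidecar carrying the parameters,
#' scheme, seed, step size and clamp count.
#'
#' @param trajectory a `bud_trajectory`.
#' @param path output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "bud_trajectory"))
  readr::write_tsv(tibble::as_tibble(trajectory), path)
  meta <- list(params = lapply(unclass(attr(trajectory, "params")), as.numeric),
               scheme = attr(trajectory, "scheme"),
               seed = attr(trajectory, "seed"),
               dt = attr(trajectory, "dt"),
               clamps = attr(trajectory, "clamps"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  structure(tibble::as_tibble(tab),
            class = c("bud_trajectory", class(tab)),
            params = do.call(bud_params, as.list(meta$params)),
            scheme = meta$scheme,
            seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
            dt = meta$dt, clamps = meta$clamps)
}

sidecar_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".json")
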