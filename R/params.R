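#' Model parameters for the two-bud canalization model
#'
#' Constructs the full parameter set of the efflux/growth model. Auxin efflux
#' out of each bud follows
#' \deqn{dE/dt = v_0 + v (S E)^n / ((S E)^n + (D(E+F)+K)^n) - \mu E}
#' (and symmetrically for `F`), and bud length grows as
#' \deqn{dN/dt = E^m / (Q^m + E^m).}
#'
#' The defaults are the package's calibrated slice: with the other parameters
#' held at these values, sweeping `v0` and `mu` reproduces the qualitative
#' region structure of the two-bud system (both-activate, tristable,
#' one-only, one-or-neither, quadrastable and neither-activates regions).
#'
#' @param v0 basal efflux rate (efflux units per time step). Non-polar efflux
#'   out of the bud; lowered by BRC1 activity in the biological reading.
#' @param v maximum feedback-driven efflux rate (same units).
#' @param S feedback efficiency, a dimensionless multiplier on the bud's own
#'   efflux inside the Hill term.
#' @param n Hill exponent of the efflux feedback (>= 1).
#' @param K Hill threshold offset (efflux units, > 0).
#' @param D mutual-inhibition / stem-sink coupling strength (dimensionless).
#' @param mu linear efflux decay rate (per time step, > 0); maps to PIN1
#'   removal from the plasma membrane.
#' @param Q growth half-saturation (efflux units, > 0).
#' @param m growth Hill exponent (>= 1).
#' @param eta noise scale (>= 0); 0 gives deterministic dynamics. Scales the
#'   chemical-Langevin noise on the efflux equations linearly.
#' @return An object of class `bud_params` (a validated named list).
#' @examples
#' p <- bud_params()
#' p2 <- update(p, v0 = 0.02, mu = 1)
#' @export
bud_params <- function(v0 = 0.05, v = 1, S = 1, n = 4, K = 0.1, D = 0.3,
                       mu = 0.4, Q = 1, m = 2, eta = 0.02) {
  p <- list(v0 = v0, v = v, S = S, n = n, K = K, D = D, mu = mu,
            Q = Q, m = m, eta = eta)
  validate_bud_params(p)
  structure(p, class = "bud_params")
}

#' Validate a parameter set
#'
#' Checks the model invariants: all fields finite scalars >= 0, `n >= 1`,
#' `m >= 1`, `mu > 0` (needed for bounded efflux), `Q > 0` and `K > 0`
#' (`K = 0` makes the Hill term 0/0 at the origin; the package requires a
#' strictly positive threshold).
#'
#' @param p a `bud_params` object or plain named list with the same fields.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_bud_params <- function(p) {
  fields <- c("v0", "v", "S", "n", "K", "D", "mu", "Q", "m", "eta")
  missing <- setdiff(fields, names(p))
  if (length(missing)) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in fields) {
    x <- p[[f]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
      stop("parameter `", f, "` must be a finite nonnegative scalar",
           call. = FALSE)
    }
  }
  if (p$n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (p$m < 1) stop("`m` must be >= 1", call. = FALSE)
  if (p$mu <= 0) stop("`mu` must be > 0 (bounded efflux)", call. = FALSE)
  if (p$Q <= 0) stop("`Q` must be > 0", call. = FALSE)
  if (p$K <= 0) stop("`K` must be > 0 (Hill term undefined at the origin otherwise)",
                     call. = FALSE)
  invisible(p)
}

#' @export
update.bud_params <- function(object, ...) {
  new <- list(...)
  bad <- setdiff(names(new), names(object))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(bud_params, utils::modifyList(unclass(object), new))
}

#' @export
print.bud_params <- function(x, ...) {
  cat("<bud_params>\n")
  cat(paste0("  ", names(x), " = ", format(unlist(x), digits = 6),
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.data.frame.bud_params <- function(x, ...) {
  as.data.frame(unclass(x))
}

# internal: parameter vector in the order the C++ stepper expects
param_vec <- function(p) {
  unlist(p[c("v0", "v", "S", "n", "K", "D", "mu", "Q", "m", "eta")])
}

#' Read and write parameter files
#'
#' Parameter sets serialize to a flat key-value YAML file, one key per model
#' field (`v0, v, S, n, K, D, mu, Q, m, eta`).
#'
#' @param p a `bud_params` object.
#' @param path file path.
#' @return `write_bud_params()` returns `path` invisibly; `read_bud_params()`
#'   returns a `bud_params` object.
#' @export
write_bud_params <- function(p, path) {
  validate_bud_params(p)
  yaml::write_yaml(lapply(unclass(p), as.numeric), path, precision = 17)
  invisible(path)
}

#' @rdname write_bud_params
#' @export
read_bud_params <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(bud_params, vals)
}

#' Default (v0, mu) slice of the calibrated model
#'
#' Axis values used for the package's parameter-plane maps. The defaults span
#' the full qualitative region structure: the both-activate region at high
#' `v0` / low `mu`, the tristable competition region in the middle, and the
#' one-only / one-or-neither regions at low `v0` / high `mu`.
#'
#' @param n_v0,n_mu number of grid values per axis.
#' @param v0_range,mu_range axis ranges.
#' @return A list with numeric vectors `v0` and `mu`.
#' @export
default_slice <- function(n_v0 = 159, n_mu = 159,
                          v0_range = c(0.005, 0.35),
                          mu_range = c(0.25, 2.0)) {
  list(v0 = seq(v0_range[1], v0_range[2], length.out = n_v0),
       mu = seq(mu_range[1], mu_range[2], length.out = n_mu))
}
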