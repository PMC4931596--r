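# broom-style tidiers for fitted / simulated objects.

#' Tidy an MC trajectory
#'
#' @param x An `mc_trajectory` from [mc_run()].
#' @param ... Unused.
#' @return The per-sweep order-parameter series as a tibble
#'   (`sweep`, `lambda_max`).
#' @export
tidy.mc_trajectory <- function(x, ...) x$order

#' One-row summary of an MC trajectory
#'
#' @inheritParams tidy.mc_trajectory
#' @return Tibble with counts, acceptance rate, step sizes and the
#'   final order parameter.
#' @export
glance.mc_trajectory <- function(x, ...) {
  tibble(n_rods = nrow(x$final), n_sweeps = nrow(x$order),
         n_snapshots = length(x$snapshots),
         acceptance = x$acceptance,
         delta_t = x$delta_t, delta_r = x$delta_r,
         lambda_max_final = tail(x$order$lambda_max, 1),
         eta = packing_fraction(nrow(x$final), x$confinement,
                                x$params$L_over_D),
         seed = x$params$seed)
}

#' Tidy a bipolar fit
#'
#' @param x A `bipolar_fit` from [fit_bipolar()].
#' @param ... Unused.
#' @return One row per fitted parameter (`term`, `estimate`).
#' @export
tidy.bipolar_fit <- function(x, ...) {
  tibble(term = c("a_hat", "axis"), estimate = c(x$a_hat, x$axis))
}

#' One-row summary of a bipolar fit
#'
#' @inheritParams tidy.bipolar_fit
#' @return Tibble with `a_hat`, `axis`, `residual`, `converged`.
#' @export
glance.bipolar_fit <- function(x, ...) {
  tibble(a_hat = x$a_hat, axis = x$axis, residual = x$residual,
         converged = x$converged)
}

#' One-row summary of a continuum relaxation
#'
#' @param x A `continuum_fit` from [relax_q2d()].
#' @param ... Unused.
#' @return Tibble with the final free energy, iteration count,
#'   convergence flag and the bulk S_eq of the parameters.
#' @export
glance.continuum_fit <- function(x, ...) {
  en <- attr(x, "energy")
  tibble(energy = tail(en, 1), iterations = attr(x, "iterations"),
         converged = attr(x, "converged"),
         S_eq = s_eq(attr(x, "params")))
}
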