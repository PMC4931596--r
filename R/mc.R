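# Metropolis Monte Carlo over rod translations and rotations.

#' Simulation parameters
#'
#' @param L_over_D Rod aspect ratio L/D.
#' @param eta Target packing fraction in [0, 1).
#' @param n_sweeps Production sweeps; one sweep is N attempted
#'   single-particle moves on uniformly chosen rods.
#' @param sample_every Sweeps between stored snapshots (0 = none).
#' @param delta_t Max translation step (D); `NULL` auto-tunes during
#'   initialisation toward 30-40 % acceptance, then freezes.
#' @param delta_r Max rotation step (radians); `NULL` auto-tunes likewise.
#' @param seed RNG seed; every stochastic stage draws from one seeded stream.
#' @param mode `"quasi-2d"` (full 3D moves between the plates),
#'   `"strict-2d"` (z and u_z frozen; requires H = D) or `"auto"`
#'   (strict when H = D).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(L_over_D, eta, n_sweeps = 1000, sample_every = 10,
                       delta_t = NULL, delta_r = NULL, seed = 1,
                       mode = c("auto", "quasi-2d", "strict-2d")) {
  mode <- match.arg(mode)
  if (eta < 0 || eta >= 1) abort("eta must lie in [0, 1)")
  if (n_sweeps < 1) abort("n_sweeps must be >= 1")
  if (!is.null(delta_t) && delta_t <= 0) abort("delta_t must be > 0")
  if (!is.null(delta_r) && (delta_r <= 0 || delta_r > pi))
    abort("delta_r must lie in (0, pi]")
  structure(list(L_over_D = L_over_D, eta = eta, n_sweeps = n_sweeps,
                 sample_every = sample_every, delta_t = delta_t,
                 delta_r = delta_r, seed = seed, mode = mode),
            class = "sim_params")
}

resolve_mode <- function(params, conf) {
  if (params$mode == "strict-2d" && abs(conf$H - 1) > 1e-12)
    abort("strict-2d mode requires H = D")
  if (params$mode == "auto")
    if (abs(conf$H - 1) < 1e-12) "strict-2d" else "quasi-2d"
  else params$mode
}

#' Initialise a valid configuration at the target packing fraction
#'
#' Shrink-insert-inflate protocol: N rods are inserted by rejection
#' sampling at a reduced diameter, the diameter is then inflated to D in
#' stages with relaxation sweeps between stages. Infeasible targets (e.g.
#' eta far above the achievable density) raise an initialisation error
#' reporting the packing fraction actually achieved.
#'
#' @param params A [sim_params()].
#' @param conf A [confinement()].
#' @param d0 Starting diameter for insertion (in D).
#' @param dstep Diameter increment per inflation stage.
#' @param max_stage_sweeps Relaxation-sweep budget per stage before the
#'   protocol gives up.
#' @return A valid [rod_config()] with N = [particle_count()] rods.
#' @export
mc_initialize <- function(params, conf, d0 = 0.4, dstep = 0.05,
                          max_stage_sweeps = 4000) {
  L <- params$L_over_D
  if (conf$H >= L) abort("plate spacing must be smaller than the rod length")
  planar <- resolve_mode(params, conf) == "strict-2d"
  N <- particle_count(params$eta, conf, L)
  set.seed(params$seed)
  res <- mc_init_cpp(N, L, 1, conf$R_outer, conf$R_inner, conf$H, planar,
                     d0, dstep, relax_sweeps = 5L,
                     max_stage_sweeps = as.integer(max_stage_sweeps),
                     insert_tries = 20000L,
                     dt0 = if (is.null(params$delta_t)) 0.5 else params$delta_t,
                     dr0 = if (is.null(params$delta_r)) 0.3 else params$delta_r,
                     tune_sweeps = if (is.null(params$delta_t) ||
                                       is.null(params$delta_r)) 50L else 0L)
  if (!isTRUE(res$ok)) {
    achieved <- packing_fraction(res$n_placed, conf, L, res$diameter)
    abort(sprintf(
      "initialisation failed at stage '%s': %d rods at diameter %.3f D (achieved eta = %.3f of target %.3f)",
      res$stage, res$n_placed, res$diameter, achieved, params$eta),
      class = "confinedrods_init_error")
  }
  cfg <- rod_config(tibble(x = res$centers[, 1], y = res$centers[, 2],
                           z = res$centers[, 3], ux = res$us[, 1],
                           uy = res$us[, 2], uz = res$us[, 3]), L, conf)
  attr(cfg, "delta_t") <- res$delta_t
  attr(cfg, "delta_r") <- res$delta_r
  cfg
}

#' Run a Metropolis Monte Carlo trajectory
#'
#' Performs `n_sweeps` sweeps from a fresh initialisation (or a supplied
#' configuration), recording the largest eigenvalue of the global tensor
#' order parameter each sweep and a snapshot every `sample_every` sweeps.
#' Fully reproducible given `params$seed`.
#'
#' @inheritParams mc_initialize
#' @param config Optional starting [rod_config()]; when `NULL` the run
#'   initialises itself with [mc_initialize()].
#' @param audit_every Debug option: exhaustively re-check the validity
#'   invariant every so many sweeps (0 = never).
#' @return An `mc_trajectory`: snapshots, per-sweep order series,
#'   acceptance rate and the final configuration. See [tidy.mc_trajectory()].
#' @export
mc_run <- function(params, conf, config = NULL, audit_every = 0) {
  L <- params$L_over_D
  planar <- resolve_mode(params, conf) == "strict-2d"
  if (is.null(config)) {
    config <- mc_initialize(params, conf)  # seeds the RNG stream
  } else {
    set.seed(params$seed)
  }
  dt <- params$delta_t %||% attr(config, "delta_t") %||% 0.5
  dr <- params$delta_r %||% attr(config, "delta_r") %||% 0.3
  cen <- as.matrix(config[, c("x", "y", "z")])
  us <- as.matrix(config[, c("ux", "uy", "uz")])
  res <- mc_run_cpp(cen, us, L, 1, conf$R_outer, conf$R_inner, conf$H,
                    planar, as.integer(params$n_sweeps), dt, dr,
                    as.integer(params$sample_every),
                    as.integer(audit_every))
  snaps <- lapply(res$snapshots, function(s)
    rod_config(tibble(x = s$centers[, 1], y = s$centers[, 2],
                      z = s$centers[, 3], ux = s$us[, 1], uy = s$us[, 2],
                      uz = s$us[, 3]), L, conf))
  structure(list(
    snapshots = snaps,
    snap_sweeps = as.integer(res$snap_sweeps),
    order = tibble(sweep = seq_len(params$n_sweeps), lambda_max = res$lambda),
    acceptance = res$acceptance,
    final = rod_config(tibble(x = res$centers[, 1], y = res$centers[, 2],
                              z = res$centers[, 3], ux = res$us[, 1],
                              uy = res$us[, 2], uz = res$us[, 3]), L, conf),
    params = params, confinement = conf,
    delta_t = dt, delta_r = dr),
    class = "mc_trajectory")
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<mc_trajectory: %d rods, %d sweeps, %d snapshots, acceptance %.2f, final lambda_max %.3f>\n",
    nrow(x$final), nrow(x$order), length(x$snapshots), x$acceptance,
    tail(x$order$lambda_max, 1)))
  invisible(x)
}

#' Attempt one single-particle move
#'
#' Proposes a joint uniform translation (cube of side 2 delta_t) and
#' rotation (angle up to delta_r about a random axis; in-plane in
#' strict-2D mode) for rod `i`, accepting iff the moved rod overlaps no
#' other rod and stays wall-feasible. The returned configuration is valid
#' whether or not the move was accepted.
#'
#' @param config A valid [rod_config()].
#' @param i Rod index (1-based).
#' @param delta_t,delta_r Step sizes.
#' @param planar Use strict-2D moves.
#' @return List with elements `config` and `accepted`.
#' @export
attempt_move <- function(config, i, delta_t = 0.5, delta_r = 0.3,
                         planar = FALSE) {
  if (i < 1 || i > nrow(config)) abort("rod index out of range")
  conf <- attr(config, "confinement")
  L <- attr(config, "L")
  res <- attempt_move_cpp(as.matrix(config[, c("x", "y", "z")]),
                          as.matrix(config[, c("ux", "uy", "uz")]),
                          L, 1, conf$R_outer, conf$R_inner, conf$H, planar,
                          as.integer(i - 1), delta_t, delta_r)
  out <- rod_config(tibble(x = res$centers[, 1], y = res$centers[, 2],
                           z = res$centers[, 3], ux = res$us[, 1],
                           uy = res$us[, 2], uz = res$us[, 3]), L, conf)
  list(config = out, accepted = isTRUE(res$accepted))
}

#' Global tensor order parameter
#'
#' Q = <(3 u u' - I)/2> over all rods; the largest positive eigenvalue is
#' the scalar measure of ordering used to monitor equilibration.
#'
#' @param config A [rod_config()] with at least one rod.
#' @return List with the symmetric traceless 3x3 `Q` and `lambda_max`.
#' @examples
#' cfg <- rod_config(rod(), L = 15, conf = confinement(40, 0, 6))
#' global_order_parameter(cfg)$lambda_max  # 1
#' @export
global_order_parameter <- function(config) {
  if (nrow(config) == 0) abort("empty configuration")
  U <- as.matrix(config[, c("ux", "uy", "uz")])
  Q <- (3 * crossprod(U) / nrow(U) - diag(3)) / 2
  list(Q = Q, lambda_max = max(eigen(Q, symmetric = TRUE,
                                     only.values = TRUE)$values))
}

#' Window-mean equilibration test
#'
#' Compares the means of the last two windows of the order series:
#' equilibrated iff their relative difference is below `tol`.
#'
#' @param order_series Numeric per-sweep series (e.g. `tidy(traj)$lambda_max`).
#' @param window Window length in sweeps.
#' @param tol Relative tolerance.
#' @return Logical flag.
#' @export
equilibrated <- function(order_series, window, tol = 0.02) {
  n <- length(order_series)
  if (n < 2 * window) abort("series shorter than two windows")
  m2 <- mean(order_series[(n - window + 1):n])
  m1 <- mean(order_series[(n - 2 * window + 1):(n - window)])
  abs(m2 - m1) / abs(m2) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
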