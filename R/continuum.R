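# Minimal single-elastic-constant 2D Landau-de Gennes relaxation with
# strong tangential (Dirichlet) anchoring -- the continuum baseline.

#' Continuum model parameters
#'
#' Free energy F = integral of (a2/2) tr Q^2 + (a4/4) (tr Q^2)^2 +
#' (K/2) |grad Q|^2 over the chamber footprint, with Q the 2D symmetric
#' traceless tensor (two components q1, q2). The bulk minimiser is
#' S_eq = sqrt(-a2 / (2 a4)); the defect core size is ~ sqrt(K/|a2|).
#'
#' @param a2 Quadratic Landau coefficient (< 0 in the nematic phase).
#' @param a4 Quartic coefficient (> 0).
#' @param K Elastic constant (> 0); with the defaults the coherence
#'   length is one rod diameter.
#' @param grid_spacing Grid spacing h in D.
#' @param step Gradient-descent step; `NULL` picks a stable default
#'   from h, K and a2.
#' @param tol Convergence tolerance: free-energy decrease per step.
#' @param max_iter Iteration budget.
#' @param noise Initial noise amplitude relative to S_eq.
#' @param seed Seed for the initial noise.
#' @return An object of class `continuum_params`.
#' @export
continuum_params <- function(a2 = -1, a4 = 1, K = 1, grid_spacing = 0.4,
                             step = NULL, tol = 1e-8, max_iter = 300000,
                             noise = 0.01, seed = 1) {
  if (a4 <= 0) abort("a4 must be > 0")
  if (a2 >= 0) abort("a2 must be < 0 for a nematic bulk")
  if (K <= 0) abort("K must be > 0")
  if (tol <= 0) abort("tol must be > 0")
  if (is.null(step))
    step <- min(grid_spacing^2 / (10 * K), 0.1 / abs(a2))
  structure(list(a2 = a2, a4 = a4, K = K, grid_spacing = grid_spacing,
                 step = step, tol = tol, max_iter = max_iter,
                 noise = noise, seed = seed),
            class = "continuum_params")
}

#' Bulk equilibrium scalar order
#'
#' @param p A [continuum_params()].
#' @return S_eq = sqrt(-a2 / (2 a4)).
#' @export
s_eq <- function(p) sqrt(-p$a2 / (2 * p$a4))

#' Relax the 2D Q-tensor field in a chamber footprint
#'
#' Gradient-descent minimisation of the single-constant free energy from
#' a small-noise initial state, with strong tangential Dirichlet
#' anchoring on every wall: boundary cells are pinned at S_eq with the
#' director along the local wall tangent. The free energy is
#' non-increasing across iterations (available via `glance()` /
#' attribute `energy`). Non-convergence within the iteration budget
#' raises an error carrying the energy trace.
#'
#' @param conf A [confinement()] (its 2D footprint).
#' @param p A [continuum_params()].
#' @return A `director_field` tibble (also class `continuum_fit`) with
#'   q1 = Qxx, q2 = Qxy, S and theta per cell; attributes `energy`
#'   (trace), `iterations`, `converged`, `params`.
#' @export
relax_q2d <- function(conf, p = continuum_params()) {
  h <- p$grid_spacing
  R <- conf$R_outer
  nx <- as.integer(ceiling(2 * R / h))
  x0 <- -nx * h / 2
  xs <- x0 + (seq_len(nx) - 0.5) * h
  cc <- expand.grid(ix = seq_len(nx), iy = seq_len(nx))
  px <- xs[cc$ix]; py <- xs[cc$iy]
  rr <- sqrt(px^2 + py^2)
  defined <- rr <= R & (conf$R_inner == 0 | rr >= conf$R_inner)
  # boundary = defined cells with an undefined 4-neighbour (Dirichlet ring)
  dm <- matrix(defined, nx, nx)
  pad <- function(m, di, dj) {
    out <- matrix(FALSE, nx, nx)
    si <- max(1, 1 + di):min(nx, nx + di)
    out[si, max(1, 1 + dj):min(nx, nx + dj)] <-
      m[si - di, max(1, 1 + dj):min(nx, nx + dj) - dj]
    out
  }
  nb_def <- pad(dm, 1, 0) & pad(dm, -1, 0) & pad(dm, 0, 1) & pad(dm, 0, -1)
  boundary <- defined & !(as.vector(nb_def))
  interior <- defined & !boundary
  Seq <- s_eq(p)
  q1 <- q2 <- numeric(nx * nx)
  set.seed(p$seed)
  q1[interior] <- p$noise * Seq * rnorm(sum(interior))
  q2[interior] <- p$noise * Seq * rnorm(sum(interior))
  phi <- atan2(py, px)
  # tangential anchoring: theta_b = phi + pi/2 on both rims
  q1[boundary] <- Seq * cos(2 * (phi[boundary] + pi / 2))
  q2[boundary] <- Seq * sin(2 * (phi[boundary] + pi / 2))
  res <- relax_q2d_cpp(q1, q2, as.integer(defined), as.integer(interior),
                       nx, nx, h, p$a2, p$a4, p$K, p$step, p$tol,
                       as.integer(p$max_iter), check_every = 200L)
  if (!isTRUE(res$converged))
    abort("continuum relaxation did not converge within max_iter",
          class = "confinedrods_continuum_error",
          energy_trace = res$energy)
  grid <- structure(list(nx = nx, ny = nx, cell_size = h, x0 = x0, y0 = x0,
                         xs = xs, ys = xs, mask = defined, conf = conf),
                    class = "grid2d")
  S <- sqrt(res$q1^2 + res$q2^2)
  theta <- (atan2(res$q2, res$q1) / 2) %% pi
  # noise-free field: the eigenvector direction is meaningful down to the
  # numerical floor, so only truly degenerate cells lose their director
  theta[!defined | S < 1e-9] <- NA_real_
  out <- tibble(ix = cc$ix, iy = cc$iy, x = px, y = py, mask = defined,
                weight = as.numeric(defined),
                Qxx = ifelse(defined, res$q1, NA_real_),
                Qxy = ifelse(defined, res$q2, NA_real_),
                defined = defined, interior = interior,
                S = ifelse(defined, S, NA_real_), theta = theta)
  structure(out, grid = grid, params = p,
            energy = res$energy, iterations = res$iterations,
            converged = res$converged,
            class = c("continuum_fit", "director_field", class(tibble())))
}
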