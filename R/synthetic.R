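# Analytic fixture fields: director fields with planted defects and rod
# configurations consistent with a field, so the analysis path is testable
# without Monte Carlo.

#' Director field with planted half-integer defects
#'
#' theta(r) = background + sum_i q_i * phi_i(r), phi_i the polar angle
#' about defect i (the standard multi-defect nematic ansatz, taken mod
#' pi). The winding about each planted defect equals its charge.
#' Defects landing exactly on a cell centre are jittered by half a cell.
#'
#' @param defects Tibble/data frame with columns `x`, `y`, `charge`
#'   (half-integers).
#' @param grid A [grid2d()].
#' @param background Uniform background angle (radians).
#' @return A `director_field` tibble with S = 1 on the chamber mask.
#' @export
make_defect_field <- function(defects, grid, background = 0) {
  defects <- as_tibble(defects)
  if (nrow(defects) > 0 && any(abs(defects$charge * 2 -
                                   round(defects$charge * 2)) > 1e-9))
    abort("charges must be half-integers")
  cc <- expand.grid(ix = seq_len(grid$nx), iy = seq_len(grid$ny))
  px <- grid$xs[cc$ix]; py <- grid$ys[cc$iy]
  th <- rep(background, length(px))
  cs <- grid$cell_size
  for (i in seq_len(nrow(defects))) {
    dx <- defects$x[i]; dy <- defects$y[i]
    on_node <- any(abs(px - dx) < 1e-9 & abs(py - dy) < 1e-9)
    if (on_node) { dx <- dx + cs / 2; dy <- dy + cs / 2 }
    th <- th + defects$charge[i] * atan2(py - dy, px - dx)
  }
  out <- tibble(ix = cc$ix, iy = cc$iy, x = px, y = py, mask = grid$mask,
                S = 1, theta = th %% pi, defined = grid$mask)
  out$theta[!out$mask] <- NA_real_
  structure(out, grid = grid, defects = defects,
            class = c("director_field", class(tibble())))
}

#' n-fold symmetric annulus fixture field
#'
#' Plants n equally spaced +1/2 defects just inside the outer rim and n
#' virtual -1/2 defects just inside the hole (outside the accessible
#' domain), on top of a central +1 charge that supplies the tangential
#' base alignment. The result is invariant under rotation by 2 pi / n
#' (covariantly, mod pi) and [symmetry_number()] recovers n.
#'
#' @param n Symmetry count (>= 3).
#' @param conf An annulus [confinement()].
#' @param grid A [grid2d()].
#' @param outer_frac Radius of the planted outer defects as a fraction of
#'   the gap, measured inward from the outer wall.
#' @return A `director_field` tibble.
#' @export
make_dn_field <- function(n, conf, grid, outer_frac = 0.15) {
  if (n < 3) abort("make_dn_field needs n >= 3")
  if (conf$R_inner <= 0) abort("make_dn_field needs an annulus")
  if (n > grid$nx) abort("n exceeds the grid's angular resolution")
  gap <- conf$R_outer - conf$R_inner
  r_out <- conf$R_outer - outer_frac * gap
  r_in <- 0.6 * conf$R_inner
  ang <- 2 * pi * (seq_len(n) - 1) / n
  defects <- tibble(
    x = c(0, r_out * cos(ang), r_in * cos(ang)),
    y = c(0, r_out * sin(ang), r_in * sin(ang)),
    charge = c(1, rep(0.5, n), rep(-0.5, n)))
  make_defect_field(defects, grid, background = pi / 2)
}

#' Rod fixture consistent with a director field
#'
#' Places N rods at uniform accessible positions with orientations drawn
#' from the field value at the rod centre plus wrapped-normal noise.
#' Overlaps are allowed by design -- this is an analysis fixture, flagged
#' non-physical; orientational analysis never looks at excluded volume.
#'
#' @param d A `director_field`.
#' @param N Number of rods.
#' @param sigma Orientation noise (radians).
#' @param conf A [confinement()].
#' @param L Rod length in D.
#' @param seed RNG seed.
#' @return A [rod_config()] with `nonphysical = TRUE`.
#' @export
rods_from_field <- function(d, N, sigma = 0, conf, L, seed = 1) {
  set.seed(seed)
  rlo <- conf$R_inner + 0.5
  rhi <- conf$R_outer - 0.5
  rr <- sqrt(runif(N, rlo^2, rhi^2))
  phi <- runif(N, 0, 2 * pi)
  px <- rr * cos(phi); py <- rr * sin(phi)
  th0 <- sample_director(d, px, py, reach = 3L)
  keep <- !is.na(th0)
  th <- th0[keep] + rnorm(sum(keep), 0, sigma)
  rod_config(tibble(x = px[keep], y = py[keep], z = conf$H / 2,
                    ux = cos(th), uy = sin(th), uz = 0),
             L = L, conf = conf, nonphysical = TRUE)
}
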