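# Exact hard-body geometry: spherocylinder overlap, wall feasibility,
# volume and packing-fraction bookkeeping. All lengths in units of D.

#' Chamber geometry
#'
#' A shallow cylindrical chamber: two parallel plates a distance `H` apart,
#' an outer side wall of radius `R_outer` and, optionally, an inner post of
#' radius `R_inner` turning the disk into an annulus. Lengths are in units
#' of the rod diameter `D` (= 1).
#'
#' @param R_outer Outer side-wall radius (in D).
#' @param R_inner Inner post radius (in D); 0 gives a disk.
#' @param H Plate spacing (in D); must be at least 1 (one rod diameter).
#' @return An object of class `confinement`.
#' @examples
#' confinement(R_outer = 40, R_inner = 7.5, H = 6)
#' @export
confinement <- function(R_outer, R_inner = 0, H) {
  stopifnot(is.numeric(R_outer), is.numeric(R_inner), is.numeric(H))
  if (H < 1) abort("plate spacing H must be at least one rod diameter (H >= 1)")
  if (R_inner < 0) abort("R_inner must be >= 0")
  if (!(R_inner + 1 < R_outer - 1))
    abort("no rod-accessible gap: need R_inner + D < R_outer - D")
  structure(list(R_outer = R_outer, R_inner = R_inner, H = H),
            class = "confinement")
}

#' @export
print.confinement <- function(x, ...) {
  kind <- if (x$R_inner > 0) "annulus" else "disk"
  cat(sprintf("<confinement: %s, R_outer = %g D, R_inner = %g D, H = %g D>\n",
              kind, x$R_outer, x$R_inner, x$H))
  invisible(x)
}

#' Lateral confinement ratio
#'
#' kappa = L / (2 R_outer): unity when a rod can just fit across the
#' chamber, small for nearly unconfined systems.
#'
#' @param L Rod length (in D).
#' @param conf A [confinement()].
#' @return A number in (0, 1].
#' @export
confinement_ratio <- function(L, conf) {
  k <- L / (2 * conf$R_outer)
  if (k <= 0 || k > 1) abort("kappa = L/(2 R_outer) must lie in (0, 1]")
  k
}

#' A single rod as a one-row tibble
#'
#' @param x,y,z Centre coordinates (in D).
#' @param ux,uy,uz Orientation; normalised internally, head-tail symmetric.
#' @return A one-row tibble with columns x, y, z, ux, uy, uz.
#' @export
rod <- function(x = 0, y = 0, z = 0, ux = 1, uy = 0, uz = 0) {
  n <- sqrt(ux^2 + uy^2 + uz^2)
  if (n < 1e-12) abort("rod orientation must be a non-zero vector")
  tibble(x = x, y = y, z = z, ux = ux / n, uy = uy / n, uz = uz / n)
}

#' Rod configuration
#'
#' Bundles a tibble of rods (columns x, y, z, ux, uy, uz) with the rod
#' length and the chamber it lives in.
#'
#' @param rods Tibble with one row per rod.
#' @param L Rod (cylinder) length in D.
#' @param conf A [confinement()].
#' @param nonphysical Logical; `TRUE` marks fixture configurations whose
#'   rods were placed without hard-core checks (analysis-only).
#' @return A tibble of class `rod_config`.
#' @export
rod_config <- function(rods, L, conf, nonphysical = FALSE) {
  rods <- as_tibble(rods)
  need <- c("x", "y", "z", "ux", "uy", "uz")
  if (!all(need %in% names(rods)))
    abort(paste("rod tibble needs columns", paste(need, collapse = ", ")))
  if (nrow(rods) > 0) {
    nn <- sqrt(rods$ux^2 + rods$uy^2 + rods$uz^2)
    if (any(abs(nn - 1) > 1e-9)) {
      rods$ux <- rods$ux / nn; rods$uy <- rods$uy / nn; rods$uz <- rods$uz / nn
    }
  }
  structure(rods, L = L, D = 1, confinement = conf,
            nonphysical = isTRUE(nonphysical),
            class = c("rod_config", class(tibble())))
}

#' Minimum distance between two finite segments
#'
#' The closest approach of the two rod axes; the hard-core overlap
#' criterion compares this against the diameter.
#'
#' @param p1,p2 Segment centres (length-3 numeric).
#' @param u1,u2 Unit directions.
#' @param l1,l2 Half-lengths (>= 0).
#' @return Non-negative distance (in D).
#' @examples
#' segment_min_distance(c(0, 0, 0), c(1, 0, 0), 1, c(0, 1, 0), c(1, 0, 0), 1)
#' @export
segment_min_distance <- function(p1, u1, l1, p2, u2, l2) {
  for (u in list(u1, u2))
    if (abs(sqrt(sum(u^2)) - 1) > 1e-8) abort("orientations must be unit vectors")
  if (l1 < 0 || l2 < 0) abort("half-lengths must be >= 0")
  seg_dist_cpp(as.numeric(p1), as.numeric(u1), l1,
               as.numeric(p2), as.numeric(u2), l2)
}

#' Do two rods overlap?
#'
#' Strict criterion: overlap iff the axis distance is below D; tangency
#' (distance exactly D) counts as non-overlapping.
#'
#' @param a,b One-row rod tibbles (see [rod()]).
#' @param L Rod length in D.
#' @param D Rod diameter; both rods must share it.
#' @return Logical flag.
#' @export
rods_overlap <- function(a, b, L, D = 1) {
  segment_min_distance(c(a$x, a$y, a$z), c(a$ux, a$uy, a$uz), L / 2,
                       c(b$x, b$y, b$z), c(b$ux, b$uy, b$uz), L / 2) < D
}

#' Is a rod feasible inside the chamber?
#'
#' Both axis endpoints must clear the plates and the outer wall by D/2
#' (sufficient for the outer wall by convexity), and for an annulus the
#' axis segment must keep distance R_inner + D/2 from the chamber axis.
#'
#' @param a One-row rod tibble.
#' @param conf A [confinement()].
#' @inheritParams rods_overlap
#' @return Logical flag.
#' @export
rod_in_confinement <- function(a, conf, L, D = 1) {
  as.logical(wall_ok_cpp(matrix(c(a$x, a$y, a$z), 1),
                         matrix(c(a$ux, a$uy, a$uz), 1),
                         L, D, conf$R_outer, conf$R_inner, conf$H))
}

#' Spherocylinder volume
#'
#' Cylinder of length L capped by two hemispheres of diameter D:
#' pi D^2 L / 4 + pi D^3 / 6.
#'
#' @param L Cylinder length (>= 0).
#' @param D Diameter (> 0).
#' @return Volume in D^3.
#' @examples
#' spherocylinder_volume(15)  # ~12.305 D^3
#' @export
spherocylinder_volume <- function(L, D = 1) {
  if (any(L < 0)) abort("L must be >= 0")
  if (any(D <= 0)) abort("D must be > 0")
  pi * D^2 * L / 4 + pi * D^3 / 6
}

#' Particle count for a target packing fraction
#'
#' N = round(eta * V_chamber / v_rod) with V_chamber =
#' pi (R_outer^2 - R_inner^2) H. The realised packing fraction of the
#' rounded count is returned by [packing_fraction()].
#'
#' @param eta Target packing fraction in [0, 1).
#' @param conf A [confinement()].
#' @inheritParams spherocylinder_volume
#' @return Integer particle count.
#' @examples
#' particle_count(0.20, confinement(40, 0, 6), L = 15)  # 490
#' @export
particle_count <- function(eta, conf, L, D = 1) {
  if (any(eta < 0 | eta >= 1)) abort("eta must lie in [0, 1)")
  V <- pi * (conf$R_outer^2 - conf$R_inner^2) * conf$H
  as.integer(round(eta * V / spherocylinder_volume(L, D)))
}

#' Realised packing fraction of N rods
#'
#' Inverse of [particle_count()] before rounding.
#'
#' @param N Number of rods.
#' @inheritParams particle_count
#' @return Packing fraction.
#' @export
packing_fraction <- function(N, conf, L, D = 1) {
  V <- pi * (conf$R_outer^2 - conf$R_inner^2) * conf$H
  N * spherocylinder_volume(L, D) / V
}

#' Check the validity invariant of a configuration
#'
#' No two rods overlap and every rod is wall-feasible. Fixture
#' configurations flagged non-physical skip the pair check by design.
#'
#' @param config A [rod_config()].
#' @param force_pairs Check pairs even on non-physical fixtures.
#' @return Logical flag.
#' @export
config_valid <- function(config, force_pairs = FALSE) {
  conf <- attr(config, "confinement")
  L <- attr(config, "L")
  if (nrow(config) == 0) return(TRUE)
  cen <- as.matrix(config[, c("x", "y", "z")])
  us <- as.matrix(config[, c("ux", "uy", "uz")])
  walls <- all(wall_ok_cpp(cen, us, L, 1, conf$R_outer, conf$R_inner, conf$H))
  if (!walls) return(FALSE)
  if (attr(config, "nonphysical") && !force_pairs) return(TRUE)
  if (nrow(config) < 2) return(TRUE)
  min_pair_dist_cpp(cen, us, L, 1, conf$R_outer, conf$R_inner, conf$H,
                    FALSE) >= 1
}
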