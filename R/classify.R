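# Pattern taxonomy: bipolar fits (B_i / B_b / B_o / B_inf) on the disk,
# n-fold symmetry analysis (D_n) on the annulus, inscribed-n-gon rule.

#' Two-defect bipolar director ansatz
#'
#' The nematic field of two +1/2 defects at (+-a, 0):
#' theta(r) = (phi_+ + phi_-)/2 with phi_+- the polar angles about the two
#' defect points. Exact +1/2 winding about each defect; tends to a uniform
#' field as a grows.
#'
#' @param a Defect half-separation (> 0), in D.
#' @param grid A [grid2d()] (or any tibble with `x`, `y`).
#' @param axis Global axis angle (radians): the defect pair sits at
#'   `a * (cos axis, sin axis)` and its mirror.
#' @return A `director_field` tibble with `theta` (and S = 1 placeholder).
#' @export
bipolar_ansatz <- function(a, grid, axis = 0) {
  if (a <= 0) abort("a = 0 degenerates to a single +1 defect; need a > 0")
  if (inherits(grid, "grid2d")) {
    cc <- expand.grid(ix = seq_len(grid$nx), iy = seq_len(grid$ny))
    px <- grid$xs[cc$ix]; py <- grid$ys[cc$iy]
    out <- tibble(ix = cc$ix, iy = cc$iy, x = px, y = py,
                  mask = grid$mask)
  } else {
    out <- as_tibble(grid)
    px <- out$x; py <- out$y
  }
  th <- bipolar_theta(px, py, a, axis)
  out$S <- 1
  out$theta <- th
  out$defined <- TRUE
  structure(out, grid = if (inherits(grid, "grid2d")) grid else attr(grid, "grid"),
            class = c("director_field", class(tibble())))
}

bipolar_theta <- function(px, py, a, axis) {
  # rotate into the frame where the axis is x
  xr <- cos(axis) * px + sin(axis) * py
  yr <- -sin(axis) * px + cos(axis) * py
  th <- (atan2(yr, xr - a) + atan2(yr, xr + a)) / 2 + axis
  th %% pi
}

#' Fit the bipolar ansatz to a measured director field
#'
#' Least squares in the angle-doubled representation: minimises the mean
#' of sin^2(theta_model - theta_obs) over defined cells inside the disk,
#' over the defect half-separation `a` and the global axis angle. Coarse
#' grid search followed by Nelder-Mead refinement.
#'
#' @param d A `director_field` on a disk.
#' @param conf The disk [confinement()] (R_inner must be 0).
#' @param a_max Largest half-separation searched, as a multiple of R_outer.
#' @param fail_threshold Mean residual above which the field is reported
#'   as unclassified by [classify_disk()].
#' @return A `bipolar_fit`: list with `a_hat`, `axis`, `residual`,
#'   `converged`. See [tidy.bipolar_fit()].
#' @export
fit_bipolar <- function(d, conf, a_max = 8, fail_threshold = 0.25) {
  if (conf$R_inner > 0) abort("bipolar fitting applies to disk geometry only")
  ok <- d$defined & !is.na(d$theta) & d$mask
  px <- d$x[ok]; py <- d$y[ok]; th <- d$theta[ok]
  if (length(px) < 20) abort("director defined on too few cells to fit")
  R <- conf$R_outer
  obj <- function(par, sub = TRUE) {
    a <- par[1]; ax <- par[2]
    if (a <= 0) return(1e6)
    i <- if (sub) seq(1, length(px), by = 3L) else seq_along(px)
    mean(sin(bipolar_theta(px[i], py[i], a, ax) - th[i])^2)
  }
  a_grid <- R * c(seq(0.1, 1.5, by = 0.1), seq(1.75, a_max, by = 0.25))
  ax_grid <- seq(0, pi, length.out = 19)[-19]
  coarse <- expand.grid(a = a_grid, ax = ax_grid)
  vals <- vapply(seq_len(nrow(coarse)),
                 function(i) obj(c(coarse$a[i], coarse$ax[i])), numeric(1))
  best <- coarse[which.min(vals), ]
  fit <- optim(c(best$a, best$ax), function(p) obj(p, sub = FALSE),
               method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-8))
  structure(list(a_hat = fit$par[1], axis = fit$par[2] %% pi,
                 residual = fit$value,
                 converged = fit$convergence == 0,
                 fail_threshold = fail_threshold, R_outer = R),
            class = "bipolar_fit")
}

#' @export
print.bipolar_fit <- function(x, ...) {
  cat(sprintf("<bipolar_fit: a_hat = %.2f D (%.2f R_outer), axis = %.1f deg, residual = %.4f>\n",
              x$a_hat, x$a_hat / x$R_outer, x$axis * 180 / pi, x$residual))
  invisible(x)
}

#' Classify a disk pattern
#'
#' Applies the B-family taxonomy: two +1/2 defects well inside the disk
#' give `B_i`; two +1/2 defects within the boundary band give `B_b`; no
#' interior defects with a fitted virtual-defect separation up to
#' `c_inf * R_outer` give `B_o`; larger separations give `B_inf`
#' (virtual defects effectively infinitely far away). Anything else is
#' reported as unclassified with diagnostics.
#'
#' @param defects Output of [detect_defects()].
#' @param fit A [fit_bipolar()] result.
#' @param conf The disk [confinement()].
#' @param L Rod length, setting the default boundary band.
#' @param w_b Boundary band width (default L/2: within half a rod length
#'   of the wall counts as "at the boundary").
#' @param c_inf Virtual-defect cutoff in units of R_outer.
#' @return A one-row tibble: `family`, `n`, `a_hat`, `axis`, `residual`.
#' @export
classify_disk <- function(defects, fit, conf, L, w_b = L / 2, c_inf = 5) {
  R <- conf$R_outer
  lab <- function(family) tibble(
    family = family, n = NA_integer_, a_hat = fit$a_hat, axis = fit$axis,
    residual = fit$residual)
  interior <- defects[!is.na(defects$charge), ]
  if (nrow(interior) == 2 && all(interior$charge == 0.5)) {
    rad <- sqrt(interior$x^2 + interior$y^2)
    return(if (all(rad < R - w_b)) lab("B_i") else lab("B_b"))
  }
  if (nrow(interior) == 0) {
    if (fit$residual > fit$fail_threshold) return(lab("unclassified"))
    return(if (fit$a_hat <= c_inf * R) lab("B_o") else lab("B_inf"))
  }
  lab("unclassified")
}

#' n-fold symmetry of an annulus pattern
#'
#' Samples the scalar order and the tangential misalignment of the
#' director along the mid-annulus circle and reads the dominant angular
#' harmonic of the combined profile. Domain walls depress S and bend the
#' director away from tangential n times per turn, so the D_n state shows
#' up as the n-th harmonic, without relying on point defects (for n >= 4
#' the domain boundaries are extended disclination walls). Axisymmetric,
#' defect-free fields return `Inf`.
#'
#' @param d A `director_field` on an annulus (S column used when present
#'   and non-constant).
#' @param conf The annulus [confinement()].
#' @param rho Dominance ratio: the winning harmonic must carry at least
#'   `rho` times the power of the runner-up.
#' @param n_max Largest harmonic considered.
#' @param n_samples Points along each sampling circle.
#' @param n_rings Concentric rings (centred on the mid-annulus circle)
#'   whose profiles are averaged; the domain walls are radial, so their
#'   signal adds coherently across rings while sampling noise does not.
#' @param flat_floor Profile standard deviation below which the pattern
#'   counts as axisymmetric.
#' @return Integer symmetry count, or `Inf` for the axisymmetric state.
#' @export
symmetry_number <- function(d, conf, rho = 2, n_max = 12, n_samples = 360,
                            n_rings = 3, flat_floor = 0.02) {
  if (conf$R_inner <= 0) abort("symmetry analysis applies to annular geometry")
  gap <- conf$R_outer - conf$R_inner
  r_mid <- (conf$R_inner + conf$R_outer) / 2
  radii <- r_mid + (seq_len(n_rings) - (n_rings + 1) / 2) * gap / (2 * n_rings)
  ang <- seq(0, 2 * pi, length.out = n_samples + 1)[-(n_samples + 1)]
  g <- field_grid(d)
  cs <- g$cell_size
  Sm <- NULL
  if ("S" %in% names(d)) {
    Sm <- matrix(NA_real_, g$nx, g$ny)
    Sm[cbind(d$ix, d$iy)] <- d$S
  }
  ring_profile <- function(r) {
    px <- r * cos(ang); py <- r * sin(ang)
    th <- sample_director(d, px, py, reach = 3L)
    if (mean(is.na(th)) > 0.25) return(NULL)
    # tangential misalignment profile (nematic metric)
    mis <- (1 - cos(2 * (th - (ang + pi / 2)))) / 2
    mis[is.na(mis)] <- mean(mis, na.rm = TRUE)
    prof <- if (sd(mis) > 1e-12) (mis - mean(mis)) / sd(mis) else mis * 0
    if (!is.null(Sm)) {
      ix <- pmin(pmax(round((px - g$x0) / cs + 0.5), 1), g$nx)
      iy <- pmin(pmax(round((py - g$y0) / cs + 0.5), 1), g$ny)
      Sv <- Sm[cbind(ix, iy)]
      if (sum(!is.na(Sv)) > n_samples / 2 && sd(Sv, na.rm = TRUE) > 1e-6) {
        Sz <- -(Sv - mean(Sv, na.rm = TRUE)) / sd(Sv, na.rm = TRUE)
        Sz[is.na(Sz)] <- 0
        prof <- prof + Sz
      }
    }
    list(prof = prof, raw_sd = sd(mis))
  }
  profs <- lapply(radii, ring_profile)
  profs <- profs[!vapply(profs, is.null, logical(1))]
  # fall back toward the best-covered region if all chosen rings have gaps
  if (length(profs) == 0) {
    for (shrink in c(0.45, 0.4, 0.55, 0.6)) {
      pr <- ring_profile(conf$R_inner + shrink * gap)
      if (!is.null(pr)) { profs <- list(pr); break }
    }
    if (length(profs) == 0) abort("no sufficiently defined sampling ring found")
  }
  raw_sd <- mean(vapply(profs, function(p) p$raw_sd, numeric(1)))
  prof <- rowMeans(do.call(cbind, lapply(profs, function(p) p$prof)))
  if (raw_sd < flat_floor || sd(prof) < 1e-9) return(Inf)
  p <- Mod(fft(prof - mean(prof)))^2 / n_samples
  power <- p[2:(n_max + 1)]          # harmonics 1 .. n_max
  n_star <- which.max(power)
  second <- max(power[-n_star])
  if (power[n_star] >= rho * second) n_star else Inf
}

#' Inscribed-n-gon prediction of the symmetry number
#'
#' Threshold hole radii at which n rods of length L can form a regular
#' n-gon around the inner post: r_n = (L/2) cot(pi/n) + offset. The
#' predicted symmetry is the largest n whose threshold fits inside the
#' hole, with n = 2 (the bipolar-like state) below the threefold
#' threshold. The offset convention accounts for where the rod surface,
#' rather than its axis, meets the hole; the default +D/2 matches the
#' observed regime boundaries.
#'
#' @param R_inner Hole radius (vectorised), in D.
#' @param L Rod length in D.
#' @param D Rod diameter.
#' @param offset Threshold offset convention (in D).
#' @return Integer symmetry number(s).
#' @examples
#' predict_n(7.5, L = 15)   # 3
#' predict_n(15, L = 25)    # 4
#' @export
predict_n <- function(R_inner, L, D = 1, offset = D / 2) {
  if (any(R_inner < 0) || L <= 0) abort("need R_inner >= 0 and L > 0")
  vapply(R_inner, function(r) {
    n <- 2L
    repeat {
      r_next <- (L / 2) / tan(pi / (n + 1)) + offset
      if (r_next <= r) n <- n + 1L else break
      if (n > 1000L) break
    }
    n
  }, integer(1))
}

#' Threshold hole radii of the inscribed-n-gon rule
#'
#' @inheritParams predict_n
#' @param n Symmetry counts (vectorised, n >= 3).
#' @return r_n in D.
#' @export
ngon_radius <- function(n, L, D = 1, offset = D / 2) {
  if (any(n < 3)) abort("the n-gon construction needs n >= 3")
  (L / 2) / tan(pi / n) + offset
}
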