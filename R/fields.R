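# Coarse-grained, sub-particle-resolution order-parameter fields and
# winding-number defect detection.

#' Analysis grid over the chamber footprint
#'
#' Regular square grid covering `[-R_outer, R_outer]^2` with per-cell
#' accessibility mask. The default cell size of one rod diameter resolves
#' defect cores (a few D wide) without starving cells of samples.
#'
#' @param conf A [confinement()].
#' @param cell_size Cell edge in D; must not exceed 1 (sub-particle scale).
#' @return An object of class `grid2d`.
#' @export
grid2d <- function(conf, cell_size = 1) {
  if (cell_size > 1 + 1e-12) abort("cell_size must be <= D (sub-particle scale)")
  R <- conf$R_outer
  nx <- as.integer(ceiling(2 * R / cell_size))
  x0 <- -nx * cell_size / 2
  xs <- x0 + (seq_len(nx) - 0.5) * cell_size
  cc <- expand.grid(ix = seq_len(nx), iy = seq_len(nx))
  cx <- xs[cc$ix]; cy <- xs[cc$iy]
  rr <- sqrt(cx^2 + cy^2)
  mask <- rr <= R & (conf$R_inner == 0 | rr >= conf$R_inner)
  structure(list(nx = nx, ny = nx, cell_size = cell_size, x0 = x0, y0 = x0,
                 xs = xs, ys = xs, mask = mask, conf = conf),
            class = "grid2d")
}

as_snapshot_list <- function(x) {
  if (inherits(x, "mc_trajectory")) return(x$snapshots)
  if (inherits(x, "rod_config")) return(list(x))
  if (is.list(x) && length(x) > 0 && inherits(x[[1]], "rod_config")) return(x)
  abort("expected a rod_config, a list of rod_config, or an mc_trajectory")
}

# accumulate per-cell sums of `vals` (matrix, one row per sample point)
bin_accumulate <- function(grid, px, py, vals) {
  cs <- grid$cell_size
  ix <- floor((px - grid$x0) / cs) + 1
  iy <- floor((py - grid$y0) / cs) + 1
  keep <- ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny
  key <- ix[keep] + grid$nx * (iy[keep] - 1)
  acc <- matrix(0, grid$nx * grid$ny, ncol(vals))
  if (length(key) > 0) {
    s <- rowsum(vals[keep, , drop = FALSE], key)
    acc[as.integer(rownames(s)), ] <- s
  }
  acc
}

# axis sample points of every rod in one snapshot
segment_points <- function(snap, seg_len) {
  L <- attr(snap, "L")
  n_seg <- max(1L, as.integer(ceiling(L / seg_len)))
  t_off <- L * ((seq_len(n_seg) - 0.5) / n_seg - 0.5)
  px <- as.vector(outer(snap$x, rep(1, n_seg)) + outer(snap$ux, t_off))
  py <- as.vector(outer(snap$y, rep(1, n_seg)) + outer(snap$uy, t_off))
  nv <- sqrt(snap$ux^2 + snap$uy^2)
  nv[nv < 1e-12] <- NA_real_
  hx <- rep(snap$ux / nv, n_seg)
  hy <- rep(snap$uy / nv, n_seg)
  list(px = px, py = py, hx = hx, hy = hy, n_seg = n_seg,
       uz2 = mean(snap$uz^2))
}

#' Local (sub-particle) tensor order parameter field
#'
#' Each rod axis is discretised into segments of length `seg_len`; each
#' segment deposits the 2D nematic tensor 2 u u' - I of its in-plane unit
#' orientation into the cell containing its midpoint. The field is the
#' weight-normalised accumulation over all segments and snapshots. In
#' quasi-2D mode orientations are projected in-plane first; the mean
#' out-of-plane amplitude is kept as a diagnostic attribute.
#'
#' @param snapshots A [rod_config()], a list of them, or an `mc_trajectory`.
#' @param grid A [grid2d()].
#' @param seg_len Segment length in D (default D/2).
#' @return A `qfield` tibble: one row per cell with `x, y, weight, Qxx,
#'   Qxy, defined, mask`.
#' @export
local_q_field <- function(snapshots, grid, seg_len = 0.5) {
  snaps <- as_snapshot_list(snapshots)
  if (length(snaps) == 0) abort("empty snapshot list")
  ncell <- grid$nx * grid$ny
  acc <- matrix(0, ncell, 3)
  uz2 <- 0
  for (snap in snaps) {
    if (nrow(snap) == 0) next
    sp <- segment_points(snap, seg_len)
    ok <- !is.na(sp$hx)
    vals <- cbind(1, 2 * sp$hx[ok]^2 - 1, 2 * sp$hx[ok] * sp$hy[ok])
    acc <- acc + bin_accumulate(grid, sp$px[ok], sp$py[ok], vals)
    uz2 <- uz2 + sp$uz2
  }
  w <- acc[, 1]
  defined <- w > 0
  Qxx <- ifelse(defined, acc[, 2] / pmax(w, 1), NA_real_)
  Qxy <- ifelse(defined, acc[, 3] / pmax(w, 1), NA_real_)
  cc <- expand.grid(ix = seq_len(grid$nx), iy = seq_len(grid$ny))
  out <- tibble(ix = cc$ix, iy = cc$iy,
                x = grid$xs[cc$ix], y = grid$ys[cc$iy],
                mask = grid$mask, weight = w,
                Qxx = Qxx, Qxy = Qxy, defined = defined)
  structure(out, grid = grid, n_snapshots = length(snaps),
            seg_len = seg_len, mean_uz2 = uz2 / length(snaps),
            class = c("qfield", class(tibble())))
}

#' Scalar order and director from a Q field
#'
#' Per cell, S is the largest eigenvalue of the 2D Q (in [0, 1]) and
#' theta the orientation (mod pi) of the corresponding eigenvector.
#' Cells with S below `s_floor` have an undefined director.
#'
#' @param q A `qfield` from [local_q_field()] (or [relax_q2d()]).
#' @param s_floor Director floor: below this S the local axis is noise.
#' @return A `director_field` tibble with added `S` and `theta` columns.
#' @export
scalar_and_director <- function(q, s_floor = 0.05) {
  S <- sqrt(q$Qxx^2 + q$Qxy^2)
  theta <- atan2(q$Qxy, q$Qxx) / 2
  theta <- theta %% pi
  theta[!q$defined | S < s_floor] <- NA_real_
  out <- q
  out$S <- S
  out$theta <- theta
  class(out) <- unique(c("director_field", class(q)))
  attr(out, "s_floor") <- s_floor
  out
}

field_grid <- function(df) {
  g <- attr(df, "grid")
  if (is.null(g)) abort("field tibble has lost its grid attribute")
  g
}

theta_matrix <- function(df) {
  g <- field_grid(df)
  m <- matrix(NA_real_, g$nx, g$ny)
  m[cbind(df$ix, df$iy)] <- df$theta
  m
}

# wrap an angle difference into [-pi/2, pi/2) (nematic convention)
wrap_nematic <- function(x) ((x + pi / 2) %% pi) - pi / 2

#' Angular-deficit field
#'
#' At each interior grid vertex, traverses the closed loop of the four
#' surrounding cells' directors, accumulating successive differences
#' wrapped to the nematic half-turn. The normalised deficit |winding|/pi
#' is 1 at the core plaquette of an ideal half-integer defect and 0 on
#' smooth plaquettes; it is the field used to localise defect cores.
#'
#' @param d A `director_field` from [scalar_and_director()].
#' @return A `deficit_field` tibble: vertex `x, y`, `deficit` in [0, 1],
#'   signed `winding` (in units of 2 pi) and `defined`.
#' @export
angular_deficit <- function(d) {
  g <- field_grid(d)
  th <- theta_matrix(d)
  nx <- g$nx; ny <- g$ny
  a <- th[-nx, -ny]; b <- th[-1, -ny]; cth <- th[-1, -1]; dd <- th[-nx, -1]
  s <- wrap_nematic(b - a) + wrap_nematic(cth - b) +
       wrap_nematic(dd - cth) + wrap_nematic(a - dd)
  vx <- g$xs[-nx] + g$cell_size / 2
  vy <- g$ys[-ny] + g$cell_size / 2
  cc <- expand.grid(i = seq_len(nx - 1), j = seq_len(ny - 1))
  out <- tibble(x = vx[cc$i], y = vy[cc$j],
                deficit = abs(as.vector(s)) / pi,
                winding = as.vector(s) / (2 * pi),
                defined = !is.na(as.vector(s)))
  out$deficit[!out$defined] <- NA_real_
  out$winding[!out$defined] <- NA_real_
  structure(out, grid = g, class = c("deficit_field", class(tibble())))
}

# director angle at arbitrary points: nearest defined cell within `reach`
# cells (angle-doubled nearest-neighbour lookup)
sample_director <- function(d, px, py, reach = 2L) {
  g <- field_grid(d)
  th <- theta_matrix(d)
  cs <- g$cell_size
  n <- length(px)
  out <- rep(NA_real_, n)
  ix <- pmin(pmax(round((px - g$x0) / cs + 0.5), 1), g$nx)
  iy <- pmin(pmax(round((py - g$y0) / cs + 0.5), 1), g$ny)
  out <- th[cbind(ix, iy)]
  miss <- which(is.na(out))
  if (length(miss) > 0 && reach > 0) {
    offs <- expand.grid(dx = -reach:reach, dy = -reach:reach)
    offs <- offs[order(offs$dx^2 + offs$dy^2), ]
    for (m in miss) {
      for (r in seq_len(nrow(offs))) {
        jx <- ix[m] + offs$dx[r]; jy <- iy[m] + offs$dy[r]
        if (jx >= 1 && jx <= g$nx && jy >= 1 && jy <= g$ny &&
            !is.na(th[jx, jy])) { out[m] <- th[jx, jy]; break }
      }
    }
  }
  out
}

# nematic winding number along an ordered closed loop of angles
loop_winding <- function(theta) {
  d <- wrap_nematic(diff(c(theta, theta[1])))
  sum(d) / (2 * pi)
}

#' Detect orientational singularities
#'
#' Clusters above-threshold deficit vertices (single linkage within
#' `merge_radius` cells), places one defect per cluster at the
#' deficit-weighted centroid, and assigns the half-integer charge from
#' the director winding along a circle of `charge_radius` cells around
#' it. Clusters whose winding rounds to zero are discarded; circles that
#' leave the defined region fall back to the largest defined arc (at
#' least three quarters of a turn) and are otherwise left uncharged (NA).
#'
#' @param d A `director_field`.
#' @param deficit Optional precomputed [angular_deficit()] field.
#' @param threshold Deficit threshold for core vertices.
#' @param merge_radius Cluster merge radius, in cells.
#' @param charge_radius Charge-loop radius, in cells.
#' @return A tibble with one row per defect: `x, y, charge, score,
#'   residual, n_vertices`.
#' @export
detect_defects <- function(d, deficit = NULL, threshold = 0.5,
                           merge_radius = 2, charge_radius = 3) {
  g <- field_grid(d)
  if (is.null(deficit)) deficit <- angular_deficit(d)
  cs <- g$cell_size
  pts <- deficit[deficit$defined & deficit$deficit > threshold, ]
  empty <- tibble(x = numeric(), y = numeric(), charge = numeric(),
                  score = numeric(), residual = numeric(),
                  n_vertices = integer())
  if (nrow(pts) == 0) return(empty)
  if (nrow(pts) == 1) {
    cl <- 1L
  } else {
    hc <- hclust(dist(cbind(pts$x, pts$y)), method = "single")
    cl <- cutree(hc, h = merge_radius * cs)
  }
  res <- lapply(split(seq_len(nrow(pts)), cl), function(idx) {
    w <- pts$deficit[idx]
    cx <- sum(pts$x[idx] * w) / sum(w)
    cy <- sum(pts$y[idx] * w) / sum(w)
    ang <- seq(0, 2 * pi, length.out = 73)[-73]
    qx <- cx + charge_radius * cs * cos(ang)
    qy <- cy + charge_radius * cs * sin(ang)
    th <- sample_director(d, qx, qy, reach = 1L)
    ok <- !is.na(th)
    if (all(ok)) {
      w_n <- loop_winding(th)
    } else {
      runs <- rle(ok)
      # longest defined run, circularly (join wrap-around runs)
      len <- runs$lengths; val <- runs$values
      if (length(len) > 1 && val[1] && val[length(val)]) {
        len[1] <- len[1] + len[length(len)]
        len <- len[-length(len)]; val <- val[-length(val)]
      }
      best <- max(c(0, len[val]))
      if (best < 0.75 * length(ang)) {
        w_n <- NA_real_
      } else {
        # winding on the arc, scaled to the full turn
        arc_ids <- which(ok)
        th_arc <- th[arc_ids]
        dth <- wrap_nematic(diff(th_arc))
        frac <- (length(arc_ids) - 1) / length(ang)
        w_n <- sum(dth) / (2 * pi) / frac
      }
    }
    ch <- if (is.na(w_n)) NA_real_ else round(2 * w_n) / 2
    tibble(x = cx, y = cy, charge = ch,
           score = max(pts$deficit[idx]),
           residual = if (is.na(w_n)) NA_real_ else abs(w_n - ch),
           n_vertices = length(idx))
  })
  out <- dplyr::bind_rows(res)
  out <- out[is.na(out$charge) | out$charge != 0, ]
  structure(out, grid = g, class = class(empty))
}

#' Director winding along a circle
#'
#' The nematic winding number (total director rotation / 2 pi) along a
#' circle of given radius centred on the chamber axis.
#'
#' @param d A `director_field`.
#' @param radius Circle radius in D.
#' @param n_points Samples along the circle.
#' @return Unrounded winding number.
#' @export
boundary_winding <- function(d, radius, n_points = 720) {
  ang <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  th <- sample_director(d, radius * cos(ang), radius * sin(ang), reach = 3L)
  if (any(is.na(th)))
    abort("boundary ring intersects undefined cells; choose another radius")
  loop_winding(th)
}

#' Total topological charge of a pattern
#'
#' The boundary winding of the director along a ring just inside the
#' outer wall, rounded to the nearest half-integer. On a disk with
#' tangential alignment this is +1 (Euler characteristic 1); on an
#' annulus the net interior charge is 0. The sum of the detected defect
#' charges is attached as attribute `defect_sum` for cross-checking;
#' virtual defects outside the domain legitimately break the equality,
#' so it is reported, not enforced.
#'
#' @param defects Output of [detect_defects()] (may be empty).
#' @param d A `director_field`.
#' @param ring_fraction Ring radius as a fraction of R_outer.
#' @return Half-integer charge with attribute `defect_sum`.
#' @export
total_charge <- function(defects, d, ring_fraction = 0.95) {
  g <- field_grid(d)
  w <- boundary_winding(d, ring_fraction * g$conf$R_outer)
  structure(round(2 * w) / 2,
            winding = w,
            defect_sum = sum(defects$charge, na.rm = TRUE))
}

#' Local packing fraction field
#'
#' Ensemble-averaged fraction of each cell's slab volume occupied by
#' rods, estimated by segment-midpoint counting: each axis segment
#' deposits its share of the rod volume into the cell under its midpoint.
#' The average over accessible cells matches the global packing fraction.
#'
#' @inheritParams local_q_field
#' @return A tibble with per-cell `phi`.
#' @export
local_packing_fraction <- function(snapshots, grid, seg_len = 0.5) {
  snaps <- as_snapshot_list(snapshots)
  if (length(snaps) == 0) abort("empty snapshot list")
  ncell <- grid$nx * grid$ny
  acc <- matrix(0, ncell, 1)
  for (snap in snaps) {
    if (nrow(snap) == 0) next
    L <- attr(snap, "L")
    sp <- segment_points(snap, seg_len)
    v_seg <- spherocylinder_volume(L, 1) / sp$n_seg
    acc <- acc + bin_accumulate(grid, sp$px, sp$py,
                                matrix(v_seg, length(sp$px), 1))
  }
  cell_vol <- grid$cell_size^2 * grid$conf$H
  cc <- expand.grid(ix = seq_len(grid$nx), iy = seq_len(grid$ny))
  out <- tibble(ix = cc$ix, iy = cc$iy, x = grid$xs[cc$ix],
                y = grid$ys[cc$iy], mask = grid$mask,
                phi = acc[, 1] / (length(snaps) * cell_vol))
  structure(out, grid = grid, class = c("packing_field", class(tibble())))
}

#' Subsample (block) standard error
#'
#' Splits the snapshots (or a per-snapshot numeric series) into `k`
#' contiguous blocks, evaluates the statistic on each block, and returns
#' the standard deviation over blocks divided by sqrt(k) -- the standard
#' error of the full-sample statistic under block-independent sampling.
#'
#' @param x List of snapshots or numeric vector, length >= k.
#' @param statistic Function applied to each block (sublist / subvector);
#'   may return a vector (e.g. a per-cell field).
#' @param k Number of blocks (>= 2).
#' @return Per-component standard error.
#' @export
subsample_error <- function(x, statistic, k) {
  if (k < 2) abort("need at least k = 2 blocks")
  n <- if (is.list(x)) length(x) else length(x)
  if (n < k) abort("fewer snapshots than blocks")
  bounds <- floor(seq(0, n, length.out = k + 1))
  vals <- lapply(seq_len(k), function(b) {
    idx <- (bounds[b] + 1):bounds[b + 1]
    statistic(if (is.list(x)) x[idx] else x[idx])
  })
  m <- do.call(rbind, vals)
  apply(m, 2, sd) / sqrt(k)
}
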