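test_that("a single static rod paints S = 1 cells along its axis", {
  conf <- disk40()
  g <- grid2d(conf, 1)
  cfg <- rod_config(rod(0, 0, 3), L = 15, conf = conf)
  qf <- local_q_field(list(cfg, cfg, cfg), g)
  d <- scalar_and_director(qf)
  on_axis <- d[d$defined & abs(d$y) < 1 & abs(d$x) < 7, ]
  expect_gt(nrow(on_axis), 10)
  expect_equal(on_axis$Qxx, rep(1, nrow(on_axis)))
  expect_equal(on_axis$S, rep(1, nrow(on_axis)))
  expect_equal(on_axis$theta, rep(0, nrow(on_axis)))
  # cells never visited are undefined
  off <- d[d$x > 20 & d$y > 20, ]
  expect_true(all(!off$defined))
  expect_true(all(is.na(off$S)))
})

test_that("perpendicular rods crossing in one cell cancel to S ~ 0", {
  conf <- disk40()
  g <- grid2d(conf, 1)
  two <- rod_config(dplyr::bind_rows(rod(0, 0, 3, 1, 0, 0),
                                     rod(0, 0, 3, 0, 1, 0)),
                    L = 15, conf = conf)
  d <- scalar_and_director(local_q_field(two, g))
  centre <- d[d$defined & abs(d$x) < 0.5 & abs(d$y) < 0.5, ]
  expect_equal(centre$S, rep(0, nrow(centre)), tolerance = 1e-12)
  expect_true(all(is.na(centre$theta)))
})

test_that("Q field is traceless, S in [0,1], theta in [0,pi)", {
  conf <- annulus(7.5)
  g <- grid2d(conf, 1)
  f <- make_dn_field(3, conf, g)
  cfg <- rods_from_field(f, 800, sigma = 0.2, conf, L = 15, seed = 8)
  d <- scalar_and_director(local_q_field(cfg, g))
  ok <- d$defined
  expect_true(all(d$S[ok] >= 0 & d$S[ok] <= 1 + 1e-12))
  th <- d$theta[ok & !is.na(d$theta)]
  expect_true(all(th >= 0 & th < pi))
})

test_that("angular deficit peaks only at planted singular plaquettes", {
  conf <- disk40()
  g <- grid2d(conf, 0.5)
  # ideal +1/2 defect at the origin: theta = atan2(y, x)/2
  f <- make_defect_field(data.frame(x = 0, y = 0, charge = 0.5), g)
  def <- angular_deficit(f)
  core <- def[def$defined & sqrt(def$x^2 + def$y^2) < 0.4, ]
  expect_true(all(abs(core$deficit - 1) < 1e-9))
  away <- def[def$defined & sqrt(def$x^2 + def$y^2) > 2, ]
  expect_true(all(away$deficit < 0.2))
  # deficit is sign-blind: -1/2 peaks identically
  fneg <- make_defect_field(data.frame(x = 0, y = 0, charge = -0.5), g)
  dneg <- angular_deficit(fneg)
  coreneg <- dneg[dneg$defined & sqrt(dneg$x^2 + dneg$y^2) < 0.4, ]
  expect_true(all(abs(coreneg$deficit - 1) < 1e-9))
  # uniform field: deficit 0 everywhere
  funi <- make_defect_field(data.frame(x = numeric(), y = numeric(),
                                       charge = numeric()), g, background = 1)
  duni <- angular_deficit(funi)
  expect_true(all(duni$deficit[duni$defined] < 1e-9))
})

test_that("defect detection recovers planted defects with exact charges", {
  conf <- disk40()
  g <- grid2d(conf, 1)
  plant <- data.frame(x = c(-15, 15), y = c(0, 0), charge = c(0.5, -0.5))
  f <- make_defect_field(plant, g)
  found <- detect_defects(f)
  expect_identical(nrow(found), 2L)
  found <- found[order(found$x), ]
  expect_equal(found$charge, c(0.5, -0.5))
  expect_true(all(abs(found$x - plant$x) <= 2 & abs(found$y - plant$y) <= 2))
  expect_equal(sum(found$charge), 0)
  # uniform field: nothing detected
  funi <- make_defect_field(data.frame(x = numeric(), y = numeric(),
                                       charge = numeric()), g, background = 0.7)
  expect_identical(nrow(detect_defects(funi)), 0L)
})

test_that("random multi-defect fields are recovered (round trip property)", {
  set.seed(2024)
  conf <- disk40()
  g <- grid2d(conf, 1)
  for (trial in 1:12) {
    n_def <- sample(2:4, 1)
    repeat {
      px <- runif(n_def, -22, 22); py <- runif(n_def, -22, 22)
      if (n_def < 2 || min(dist(cbind(px, py))) > 9) break
    }
    ch <- sample(c(-0.5, 0.5), n_def, replace = TRUE)
    f <- make_defect_field(data.frame(x = px, y = py, charge = ch), g)
    found <- detect_defects(f)
    expect_identical(nrow(found), as.integer(n_def))
    for (i in seq_len(n_def)) {
      j <- which.min((found$x - px[i])^2 + (found$y - py[i])^2)
      expect_lt(sqrt((found$x[j] - px[i])^2 + (found$y[j] - py[i])^2),
                2 * g$cell_size + 1e-9)
      expect_equal(found$charge[j], ch[i])
      expect_lt(found$residual[j], 0.1)
    }
  }
})

test_that("boundary winding is a homotopy invariant of tangential anchoring", {
  conf <- disk40()
  g <- grid2d(conf, 1)
  set.seed(5150)
  for (trial in 1:10) {
    # interior dipoles do not change the boundary charge
    n_pair <- sample(1:3, 1)
    px <- runif(n_pair, -15, 15); py <- runif(n_pair, -15, 15)
    defects <- rbind(
      data.frame(x = 0, y = 0, charge = 1),        # tangential base
      data.frame(x = px, y = py, charge = 0.5),
      data.frame(x = px + 4, y = py, charge = -0.5))
    f <- make_defect_field(defects, g, background = pi / 2)
    tc <- total_charge(detect_defects(f), f)
    expect_equal(as.numeric(tc), 1)
  }
  # uniform field: charge 0
  funi <- make_defect_field(data.frame(x = numeric(), y = numeric(),
                                       charge = numeric()), g, background = 1)
  expect_equal(as.numeric(total_charge(detect_defects(funi), funi)), 0)
})

test_that("annulus rings both wind +1 for tangential fields (chi = 0)", {
  conf <- annulus(15)
  g <- grid2d(conf, 1)
  f <- make_defect_field(data.frame(x = 0, y = 0, charge = 1), g,
                         background = pi / 2)
  expect_equal(boundary_winding(f, 0.95 * 40), 1)
  expect_equal(boundary_winding(f, 15 + 2), 1)
  # net interior charge = outer - inner = 0
})

test_that("fields transform equivariantly under rigid rotation", {
  conf <- disk40()
  g <- grid2d(conf, 1)
  f <- make_defect_field(data.frame(x = -12, y = 3, charge = 0.5), g,
                         background = 0.4)
  cfg <- rods_from_field(f, 1500, sigma = 0, conf, L = 15, seed = 21)
  alpha <- pi / 3
  cfg_rot <- rod_config(rotate_config(cfg, alpha), L = 15, conf = conf,
                        nonphysical = TRUE)
  d0 <- scalar_and_director(local_q_field(cfg, g))
  d1 <- scalar_and_director(local_q_field(cfg_rot, g))
  # compare on a ring of probe points away from the defect core
  ang <- seq(0, 2 * pi, length.out = 41)[-41]
  px <- 25 * cos(ang); py <- 25 * sin(ang)
  th0 <- confinedrods:::sample_director(d0, px, py)
  qx <- cos(alpha) * px - sin(alpha) * py
  qy <- sin(alpha) * px + cos(alpha) * py
  th1 <- confinedrods:::sample_director(d1, qx, qy)
  dd <- atan2(sin(2 * (th1 - th0 - alpha)), cos(2 * (th1 - th0 - alpha))) / 2
  # directors rotate by alpha (up to grid resampling tolerance)
  expect_lt(median(abs(dd), na.rm = TRUE), 6 * pi / 180)
})

test_that("local packing fraction averages to the global packing fraction", {
  conf <- small_conf()
  p <- small_params()
  traj <- mc_run(p, conf)
  g <- grid2d(conf, 1)
  pf <- local_packing_fraction(traj$snapshots, g)
  eta_hat <- mean(pf$phi[pf$mask])
  eta <- packing_fraction(nrow(traj$final), conf, p$L_over_D)
  expect_lt(abs(eta_hat - eta) / eta, 0.05)
  # empty configuration: zero everywhere
  empty <- rod_config(tibble::tibble(x = numeric(), y = numeric(),
                                     z = numeric(), ux = numeric(),
                                     uy = numeric(), uz = numeric()),
                      L = 8, conf = conf)
  pf0 <- local_packing_fraction(empty, g)
  expect_true(all(pf0$phi == 0))
  # a single static rod covers only its footprint
  one <- rod_config(rod(0, 0, 2), L = 8, conf = conf)
  pf1 <- local_packing_fraction(one, g)
  expect_true(all(pf1$phi[abs(pf1$y) > 2] == 0))
  expect_gt(sum(pf1$phi > 0), 0)
})

test_that("subsample error matches the i.i.d. closed form and edge cases", {
  # identical blocks: zero error
  expect_equal(subsample_error(rep(3.5, 40), function(b) mean(b), k = 8), 0)
  # i.i.d. normal: SE ~ sigma / sqrt(n)
  set.seed(99)
  sigma <- 2
  n <- 8000
  reps <- vapply(1:40, function(i) {
    x <- rnorm(n, sd = sigma)
    subsample_error(x, function(b) mean(b), k = 10)
  }, numeric(1))
  expect_equal(mean(reps), sigma / sqrt(n), tolerance = 0.1)
  # k = 2 is allowed, k < 2 is not
  expect_silent(subsample_error(rnorm(10), function(b) mean(b), k = 2))
  expect_error(subsample_error(rnorm(10), function(b) mean(b), k = 1), "k")
})
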