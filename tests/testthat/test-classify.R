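test_that("bipolar ansatz winds +1/2 about each of its defects", {
  conf <- disk40()
  g <- grid2d(conf, 0.5)
  f <- bipolar_ansatz(a = 12, g)
  defs <- detect_defects(f)
  defs <- defs[order(defs$x), ]
  expect_identical(nrow(defs), 2L)
  expect_equal(defs$charge, c(0.5, 0.5))
  expect_lt(abs(defs$x[1] + 12), 1.5)
  expect_lt(abs(defs$x[2] - 12), 1.5)
  # reflection symmetry in both axes (nematic metric)
  th <- function(x, y) confinedrods:::bipolar_theta(x, y, 12, 0)
  xs <- runif(50, -30, 30); ys <- runif(50, -30, 30)
  d1 <- sin(th(xs, ys) - (-th(xs, -ys)))
  d2 <- sin(th(xs, ys) - (-th(-xs, ys)))
  expect_true(all(abs(d1) < 1e-9))
  expect_true(all(abs(d2) < 1e-9))
  # large separation tends to the uniform field
  f_far <- bipolar_ansatz(a = 4000, g)
  spread <- diff(range(f_far$theta[f_far$mask] %% pi))
  expect_true(spread < 0.05 || spread > pi - 0.05)  # wraps mod pi
  expect_error(bipolar_ansatz(0, g), "a > 0")
})

test_that("fit_bipolar recovers planted separations, also under noise", {
  conf <- disk40()
  g <- grid2d(conf, 1)
  set.seed(31)
  for (a_frac in c(0.4, 0.8, 1.0, 2.0)) {
    a <- a_frac * conf$R_outer
    ax <- runif(1, 0, pi)
    f <- bipolar_ansatz(a, g, axis = ax)
    f$theta <- (f$theta + rnorm(nrow(f), 0, 5 * pi / 180)) %% pi
    f$theta[!f$mask] <- NA_real_
    f$defined <- f$mask
    fit <- fit_bipolar(f, conf)
    expect_lt(abs(fit$a_hat - a) / conf$R_outer, 0.05)
    expect_lt(abs(sin(fit$axis - ax)), 0.1)
  }
})

test_that("a uniform director field fits as an effectively infinite separation", {
  conf <- disk40()
  g <- grid2d(conf, 1)
  f <- make_defect_field(data.frame(x = numeric(), y = numeric(),
                                    charge = numeric()), g, background = 0.9)
  fit <- fit_bipolar(f, conf)
  expect_gt(fit$a_hat, 5 * conf$R_outer)
  lab <- classify_disk(detect_defects(f), fit, conf, L = 15)
  expect_identical(lab$family, "B_inf")
})

test_that("disk taxonomy follows the defect-location rules", {
  conf <- disk40()
  fake_fit <- structure(list(a_hat = 30, axis = 0, residual = 0.01,
                             converged = TRUE, fail_threshold = 0.25,
                             R_outer = 40), class = "bipolar_fit")
  two_in <- tibble::tibble(x = c(-24, 24), y = 0, charge = 0.5, score = 1,
                           residual = 0, n_vertices = 1L)
  expect_identical(classify_disk(two_in, fake_fit, conf, L = 15)$family, "B_i")
  two_edge <- tibble::tibble(x = c(-36, 36), y = 0, charge = 0.5, score = 1,
                             residual = 0, n_vertices = 1L)
  expect_identical(classify_disk(two_edge, fake_fit, conf, L = 15)$family, "B_b")
  none <- two_in[0, ]
  expect_identical(classify_disk(none, fake_fit, conf, L = 15)$family, "B_o")
  far_fit <- fake_fit; far_fit$a_hat <- 250
  expect_identical(classify_disk(none, far_fit, conf, L = 15)$family, "B_inf")
  # anything else is unclassified with diagnostics
  odd <- tibble::tibble(x = 0, y = 0, charge = -0.5, score = 1,
                        residual = 0, n_vertices = 1L)
  expect_identical(classify_disk(odd, fake_fit, conf, L = 15)$family,
                   "unclassified")
})

test_that("classification is invariant under global rotation of the fields", {
  conf <- disk40()
  g <- grid2d(conf, 1)
  f <- bipolar_ansatz(26, g, axis = 0.3)
  f$theta[!f$mask] <- NA_real_; f$defined <- f$mask
  lab0 <- classify_disk(detect_defects(f), fit_bipolar(f, conf), conf, L = 15)
  f_rot <- bipolar_ansatz(26, g, axis = 0.3 + pi / 5)
  f_rot$theta[!f_rot$mask] <- NA_real_; f_rot$defined <- f_rot$mask
  lab1 <- classify_disk(detect_defects(f_rot), fit_bipolar(f_rot, conf),
                        conf, L = 15)
  expect_identical(lab0$family, lab1$family)
})

test_that("symmetry_number reads planted n-fold symmetry up to rho = 3", {
  conf <- annulus(15)
  g <- grid2d(conf, 1)
  for (n in c(3L, 4L, 5L, 6L, 8L)) {
    f <- make_dn_field(n, conf, g)
    expect_identical(symmetry_number(f, conf, rho = 3), n)
  }
  # axisymmetric tangential annulus: infinity sentinel
  f_inf <- make_defect_field(data.frame(x = 0, y = 0, charge = 1), g,
                             background = pi / 2)
  expect_identical(symmetry_number(f_inf, conf), Inf)
})

test_that("inscribed n-gon thresholds follow the apothem construction", {
  # offset-free thresholds: apothem of the regular n-gon with side L
  expect_equal(ngon_radius(3, 15, offset = 0), 7.5 / tan(pi / 3),
               tolerance = 1e-12)
  expect_equal(ngon_radius(4, 15, offset = 0), 7.5)
  expect_equal(ngon_radius(5, 15, offset = 0), 7.5 / tan(pi / 5),
               tolerance = 1e-12)
  expect_identical(predict_n(5, 15, offset = 0), 3L)   # 4.33 <= 5 < 7.5
  expect_identical(predict_n(0, 15), 2L)               # bipolar-like
  # printed parameter sets of the n-fold simulations
  expect_identical(predict_n(7.5, 15), 3L)
  expect_identical(predict_n(15, 25), 4L)
})

test_that("predict_n is monotone in hole radius and rod length", {
  r_sweep <- seq(0, 39, length.out = 100)
  n_sweep <- predict_n(r_sweep, L = 15)
  expect_true(all(diff(n_sweep) >= 0))
  for (r in c(5, 10, 20, 30)) {
    n_L <- vapply(c(10, 15, 20, 25), function(L) predict_n(r, L), integer(1))
    expect_true(all(diff(n_L) <= 0))
  }
})
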