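test_that("initialisation reaches the target count with a valid configuration", {
  p <- small_params()
  conf <- small_conf()
  cfg <- mc_initialize(p, conf)
  expect_s3_class(cfg, "rod_config")
  expect_identical(nrow(cfg), as.integer(particle_count(p$eta, conf, p$L_over_D)))
  expect_true(config_valid(cfg))
  # step sizes were tuned and frozen
  expect_gt(attr(cfg, "delta_t"), 0)
})

test_that("an empty target yields an empty valid configuration", {
  p <- sim_params(L_over_D = 8, eta = 0, n_sweeps = 5, seed = 1)
  cfg <- mc_initialize(p, small_conf())
  expect_identical(nrow(cfg), 0L)
  expect_true(config_valid(cfg))
})

test_that("infeasible packing targets raise an initialisation error", {
  p <- sim_params(L_over_D = 25, eta = 0.55, n_sweeps = 5, seed = 3)
  expect_error(
    mc_initialize(p, confinement(30, 0, 6), max_stage_sweeps = 60),
    class = "confinedrods_init_error")
})

test_that("every stored snapshot satisfies the validity invariant", {
  p <- small_params()
  conf <- small_conf()
  traj <- mc_run(p, conf, audit_every = 50)
  expect_true(all(vapply(traj$snapshots, config_valid, logical(1))))
  expect_true(config_valid(traj$final))
  expect_true(all(traj$order$lambda_max >= -0.5 & traj$order$lambda_max <= 1))
})

test_that("identical seeds give bit-identical runs", {
  p <- small_params()
  conf <- small_conf()
  t1 <- mc_run(p, conf)
  t2 <- mc_run(p, conf)
  expect_identical(t1$order$lambda_max, t2$order$lambda_max)
  expect_identical(t1$final$x, t2$final$x)
  expect_identical(t1$final$ux, t2$final$ux)
})

test_that("attempt_move preserves validity and respects walls", {
  conf <- small_conf()
  cfg <- rod_config(rod(0, 0, 2, 1, 0, 0), L = 8, conf = conf)
  set.seed(5)
  # single rod far from walls: small moves always accepted
  res <- attempt_move(cfg, 1, delta_t = 0.05, delta_r = 0.05)
  expect_true(res$accepted)
  expect_true(config_valid(res$config))
  expect_error(attempt_move(cfg, 7), "range")
  # vanishing steps leave the configuration unchanged
  res0 <- attempt_move(cfg, 1, delta_t = 1e-12, delta_r = 1e-12)
  expect_true(res0$accepted)
  expect_equal(res0$config$x, cfg$x, tolerance = 1e-9)
  # a rod pressed against the inner post cannot cross it
  ann <- confinement(20, 6, 4)
  hug <- rod_config(rod(0, 6 + 0.5 + 1e-3, 2, 1, 0, 0), L = 5, conf = ann)
  set.seed(11)
  rejected_any <- FALSE
  for (i in 1:50) {
    r <- attempt_move(hug, 1, delta_t = 1.0, delta_r = 0.3)
    expect_true(config_valid(r$config))
    if (!r$accepted) rejected_any <- TRUE
  }
  expect_true(rejected_any)
})

test_that("global order parameter reproduces closed forms", {
  conf <- small_conf()
  all_x <- rod_config(tibble::tibble(x = rnorm(20, 0, 2), y = rnorm(20, 0, 2),
                                     z = 2, ux = 1, uy = 0, uz = 0),
                      L = 8, conf = conf)
  expect_equal(global_order_parameter(all_x)$lambda_max, 1)
  half <- rod_config(tibble::tibble(x = 0, y = 0, z = 2,
                                    ux = rep(c(1, 0), each = 10),
                                    uy = rep(c(0, 1), each = 10), uz = 0),
                     L = 8, conf = conf)
  gq <- global_order_parameter(half)
  expect_equal(gq$lambda_max, 0.25)
  expect_equal(sum(diag(gq$Q)), 0, tolerance = 1e-12)
  # isotropy: lambda_max -> 0 as N grows (finite-N positive bias shrinks)
  set.seed(12)
  lam_for <- function(n) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    cfg <- rod_config(tibble::tibble(x = 0, y = 0, z = 2, ux = u[, 1],
                                     uy = u[, 2], uz = u[, 3]),
                      L = 8, conf = conf)
    global_order_parameter(cfg)$lambda_max
  }
  expect_lt(lam_for(4000), 0.05)
  expect_error(global_order_parameter(
    rod_config(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                              ux = numeric(), uy = numeric(), uz = numeric()),
               L = 8, conf = conf)), "empty")
})

test_that("acceptance rate decreases with step size on a frozen dense state", {
  p <- small_params()
  conf <- small_conf()
  cfg <- mc_initialize(p, conf)
  cen <- as.matrix(cfg[, c("x", "y", "z")])
  us <- as.matrix(cfg[, c("ux", "uy", "uz")])
  probe <- function(dt, dr) {
    set.seed(314)
    confinedrods:::acceptance_probe_cpp(cen, us, 8, 1, conf$R_outer,
                                        conf$R_inner, conf$H, FALSE,
                                        20000L, dt, dr)
  }
  rates_t <- c(probe(0.05, 0.1), probe(0.4, 0.1), probe(1.5, 0.1))
  expect_true(all(diff(rates_t) < 0))
  rates_r <- c(probe(0.2, 0.05), probe(0.2, 0.5), probe(0.2, 2.0))
  expect_true(all(diff(rates_r) < 0))
})

test_that("a single ideal rod samples its accessible area uniformly", {
  # large steps decorrelate quickly; uniformity is tested on the core
  # region where all orientations are feasible, in equal-area radial bins
  conf <- confinement(16, 0, 3)
  p <- sim_params(L_over_D = 5, eta = 0, n_sweeps = 30000, sample_every = 30,
                  delta_t = 4, delta_r = 3, seed = 101)
  cfg <- rod_config(rod(0, 0, 1.5), L = 5, conf = conf)
  traj <- mc_run(p, conf, config = cfg)
  xy <- t(vapply(traj$snapshots, function(s) c(s$x, s$y), numeric(2)))
  r <- sqrt(rowSums(xy^2))
  r_core <- 16 - 2.5 - 0.5   # all orientations feasible inside this radius
  r_in <- r[r <= r_core]
  expect_gt(length(r_in), 300)
  k <- 4
  edges <- r_core * sqrt(seq(0, 1, length.out = k + 1))
  counts <- table(cut(r_in, edges, include.lowest = TRUE))
  n <- length(r_in)
  expected <- n / k
  # 3 sigma multinomial band
  expect_true(all(abs(counts - expected) < 3 * sqrt(expected * (1 - 1 / k))))
})

test_that("equilibration detector accepts plateaus and rejects trends", {
  expect_true(equilibrated(rep(0.5, 100), window = 30, tol = 0.02))
  expect_false(equilibrated(seq(0.1, 1, length.out = 100), window = 30,
                            tol = 0.02))
  series <- c(seq(0.1, 0.6, length.out = 50), rep(0.6, 80))
  expect_true(equilibrated(series, window = 30, tol = 0.02))
  expect_error(equilibrated(1:10, window = 8), "short")
})
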