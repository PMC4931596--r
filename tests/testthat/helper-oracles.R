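# Independent oracles and small fixtures shared across tests.

# Brute-force segment-segment distance: dense point-pair sampling with
# local grid refinement (>= 10^4 point pairs per stage). Independent of
# the closed-form closest-point algorithm under test.
brute_segment_distance <- function(p1, u1, l1, p2, u2, l2, stages = 5) {
  lo1 <- -l1; hi1 <- l1; lo2 <- -l2; hi2 <- l2
  best_val <- Inf
  for (st in seq_len(stages)) {
    s <- seq(lo1, hi1, length.out = 101)
    t <- seq(lo2, hi2, length.out = 101)
    a <- outer(s, rep(1, 101))
    b <- outer(rep(1, 101), t)
    dd <- matrix(0, 101, 101)
    for (k in 1:3) {
      diff <- (p1[k] + a * u1[k]) - (p2[k] + b * u2[k])
      dd <- dd + diff^2
    }
    best_val <- min(best_val, min(dd))
    i <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    best <- c(s[i[1]], t[i[2]])
    # window of +-2 grid steps: near-parallel pairs have long shallow
    # valleys and a one-step window can exclude the true minimiser
    hs <- (hi1 - lo1) / 100; ht <- (hi2 - lo2) / 100
    lo1 <- max(-l1, best[1] - 2 * hs); hi1 <- min(l1, best[1] + 2 * hs)
    lo2 <- max(-l2, best[2] - 2 * ht); hi2 <- min(l2, best[2] + 2 * ht)
  }
  sqrt(best_val)
}

random_unit3 <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# rotate a configuration rigidly about the chamber axis
rotate_config <- function(config, alpha) {
  ca <- cos(alpha); sa <- sin(alpha)
  out <- config
  out$x <- ca * config$x - sa * config$y
  out$y <- sa * config$x + ca * config$y
  out$ux <- ca * config$ux - sa * config$uy
  out$uy <- sa * config$ux + ca * config$uy
  out
}

disk40 <- function() confinement(40, 0, 6)
annulus <- function(R_inner = 15) confinement(40, R_inner, 6)

# a small, fast-to-equilibrate physical system for engine tests
small_params <- function(...) {
  sim_params(L_over_D = 8, eta = 0.15, n_sweeps = 200, sample_every = 50,
             seed = 99, ...)
}
small_conf <- function() confinement(18, 0, 4)
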