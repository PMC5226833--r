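test_that("absorbing identity dynamics give constant paths", {
  x <- simulate_internal_path(diag(2), pi = c(1, 0), T_frames = 100, seed = 1)
  expect_length(x, 99)
  expect_true(all(x == 1))
  o <- simulate_observable(x, list(diag(3), diag(3)), o1 = 2, seed = 1)
  expect_length(o, 100)
  expect_true(all(o == 2))
})

test_that("internal dwell lengths follow the geometric expectation", {
  A <- matrix(c(0.999, 0.001, 0.001, 0.999), 2, 2, byrow = TRUE)
  dwells <- c()
  occ1 <- 0; tot <- 0
  for (s in 1:100) {
    x <- simulate_internal_path(A, T_frames = 8801, seed = s)
    r <- rle(x)
    if (length(r$lengths) > 2)
      dwells <- c(dwells, r$lengths[-c(1, length(r$lengths))])
    occ1 <- occ1 + sum(x == 1); tot <- tot + length(x)
  }
  # mean completed dwell ~ 1/0.001 = 1000 frames
  expect_gt(length(dwells), 200)
  se <- sd(dwells) / sqrt(length(dwells))
  expect_lt(abs(mean(dwells) - 1000), 4 * se)
  # symmetric chain: half the time in state 1
  expect_lt(abs(occ1 / tot - 0.5), 0.05)
})

test_that("observable transition frequencies match the generating rates", {
  B <- list(two_state_B(0.05, 0.05))
  n_lh <- 0; n_l <- 0
  for (s in 1:100) {
    x <- rep(1L, 2000)
    o <- simulate_observable(x, B, o1 = 1, seed = 200 + s)
    from_l <- o[-length(o)] == 1
    n_lh <- n_lh + sum(from_l & o[-1] == 2)
    n_l <- n_l + sum(from_l)
  }
  p_hat <- n_lh / n_l
  se <- sqrt(0.05 * 0.95 / n_l)
  expect_lt(abs(p_hat - 0.05), 3 * se)
})

test_that("dwell CV within a homogeneous segment is near one", {
  o <- simulate_observable(rep(1L, 50000), list(two_state_B(0.05, 0.05)),
                           o1 = 1, seed = 5)
  expect_lt(abs(dwell_cv(o, 1) - 1), 0.1)
})

test_that("noise model reproduces levels and spread", {
  o <- rep(c(1L, 2L), 500)
  expect_identical(add_noise(o, c(0.1, 0.9), sigma = 1e-12, seed = 1)[1:4],
                   c(0.1, 0.9, 0.1, 0.9), tolerance = 1e-9)
  o_n <- add_noise(o, c(0.1, 0.9), sigma = 0.1, seed = 2)
  expect_lt(abs(mean(o_n[o == 2]) - 0.9), 0.02)
  expect_lt(abs(sd(o_n[o == 1]) - 0.1), 0.02)
})

test_that("simulation is deterministic given the seed and validates inputs", {
  cfg <- canonical_condition(T_frames = 501)
  t1 <- simulate_dcmm_trace(cfg, seed = 9)
  t2 <- simulate_dcmm_trace(cfg, seed = 9)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$o_n, t2$o_n)
  expect_length(t1$x, length(t1$o) - 1L)
  expect_identical(simulate_dcmm_ensemble(cfg, 0, seed = 1), list())

  bad_A <- matrix(c(0.9, 0.2, 0.1, 0.9), 2, 2)
  expect_error(simulate_internal_path(bad_A, T_frames = 10), "sum to 1")
  expect_error(simulate_observable(c(1L, 3L), list(diag(2), diag(2)), o1 = 1),
               "no B matrix")
  expect_error(sim_config(K = 2, N = 2, A = diag(2), B = list(diag(2), diag(2)),
                          T_frames = 100, levels = c(0.9, 0.1)),
               "increasing")
})

test_that("benchmark grid is reproducible condition by condition", {
  g1 <- simulate_benchmark_grid(ratios_LH = c(0.5, 2), ratios_HL = 1,
                                n_traces = 2, T_frames = 301, seed = 5)
  g2 <- simulate_benchmark_grid(ratios_LH = c(0.5, 2), ratios_HL = 1,
                                n_traces = 2, T_frames = 301, seed = 5)
  expect_length(g1, 2)
  expect_identical(g1[[2]]$traces[[1]]$o_n, g2[[2]]$traces[[1]]$o_n)
  expect_equal(g1[[1]]$config$B[[2]][1, 2], 0.5 * 0.05)
  expect_error(simulate_benchmark_grid(ratios_LH = numeric(0)), "empty grid")
})

test_that("decoding accuracy grows with the rate separation across the grid", {
  mean_chi <- function(ratio, seed0) {
    cfg <- benchmark_config(k2 = c(0.05 * ratio, 0.05 * ratio),
                            T_frames = 4401)
    mean(sapply(1:4, function(i) {
      tr <- simulate_dcmm_trace(cfg, seed = seed0 + i)
      fit <- dcmm(tr$o, K = 2, n_restarts = 3, seed = i)
      perm <- match_labels(fit$model$B, cfg$B)
      overlap_chi(tr$x, viterbi_internal(tr$o, fit$model), perm)
    }))
  }
  # identical kinetics in both states are undecodable; 8-fold separation is
  expect_gt(mean_chi(0.125, 7700), mean_chi(1, 7800) + 0.1)
})

test_that("empirical transition matrices converge to the generating ones", {
  cfg <- clustering_benchmark_config(T_frames = 40001, gamma_dt = 1e-3)
  tr <- simulate_dcmm_trace(cfg, seed = 31)
  # pool transitions by true internal state; compare to B within 3 binomial se
  for (mu in 1:cfg$K) {
    ts <- which(tr$x == mu)
    if (length(ts) < 2000) next
    tab <- table(factor(tr$o[ts], levels = 1:4), factor(tr$o[ts + 1], levels = 1:4))
    est <- tab / rowSums(tab)
    for (a in 1:4) {
      n_a <- sum(tab[a, ])
      for (b in 1:4) {
        p <- cfg$B[[mu]][a, b]
        expect_lt(abs(est[a, b] - p), 3 * sqrt(p * (1 - p) / n_a) + 1e-9)
      }
    }
  }
})
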