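test_that("emission table is the indexed observable-transition probability", {
  B1 <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  B2 <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2, byrow = TRUE)
  o <- c(1L, 2L, 2L, 1L)
  e <- emission_matrix(o, list(B1, B2))
  expect_equal(dim(e), c(3, 2))
  expect_equal(e[1, 1], 0.05)   # o: 1 -> 2 under B1
  expect_equal(e[2, 1], 0.95)   # o: 2 -> 2 under B1
  expect_true(all(e[, 2] == 0.5))
  expect_error(emission_matrix(c(1L, 3L), list(B1)), "outside")
})

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(42)
  for (rep in 1:5) {
    K <- sample(2:3, 1)
    T_ <- 5
    pi <- runif(K); pi <- pi / sum(pi)
    A <- matrix(runif(K * K), K); A <- A / rowSums(A)
    emis <- matrix(runif(T_ * K, 0.05, 1), T_, K)
    fb <- forward_backward(emis, A, pi)
    expect_equal(fb$log_normalizer, brute_log_normalizer(pi, A, emis),
                 tolerance = 1e-10)
    # marginalization identities
    expect_equal(rowSums(fb$responsibilities), rep(1, T_), tolerance = 1e-12)
    expect_equal(sum(fb$pair_marginals), T_ - 1, tolerance = 1e-10)
    expect_equal(as.numeric(rowSums(fb$pair_marginals)),
                 as.numeric(colSums(fb$responsibilities[-T_, , drop = FALSE])),
                 tolerance = 1e-10)
  }
})

test_that("forward-backward accepts sub-stochastic parameters", {
  pi <- c(0.4, 0.4)
  A <- matrix(c(0.8, 0.1, 0.1, 0.8), 2, 2)
  emis <- matrix(runif(8, 0.1, 1), 4, 2)
  fb <- forward_backward(emis, A, pi)
  expect_equal(fb$log_normalizer, brute_log_normalizer(pi, A, emis),
               tolerance = 1e-10)
})

test_that("single internal state reduces to a plain Markov chain", {
  B <- list(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE))
  o <- c(1L, 1L, 2L, 1L, 2L, 2L)
  e <- emission_matrix(o, B)
  fb <- forward_backward(e, matrix(1, 1, 1), 1)
  expect_true(all(fb$responsibilities == 1))
  expect_equal(fb$log_normalizer, sum(log(e)), tolerance = 1e-12)
})

test_that("internal Viterbi equals exhaustive argmax", {
  set.seed(7)
  for (rep in 1:3) {
    T_ <- 8
    model <- list(pi = c(0.5, 0.5),
                  A = matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE),
                  B = list(two_state_B(0.3, 0.3), two_state_B(0.05, 0.6)))
    o <- sample(1:2, T_ + 1, replace = TRUE)
    emis <- emission_matrix(o, model$B)
    got <- viterbi_internal(o, model)
    ref <- brute_viterbi(model$pi, model$A, emis)
    # compare path weights (ties may differ in path, never in weight)
    w_got <- log(model$pi[got[1]]) + log(emis[1, got[1]]) +
      sum(log(model$A[cbind(got[-T_], got[-1])])) +
      sum(log(emis[cbind(2:T_, got[-1])]))
    expect_equal(w_got, ref$logw, tolerance = 1e-10)
  }
})

test_that("evidence bound is monotone non-decreasing over iterations", {
  tr <- simulate_dcmm_trace(canonical_condition(T_frames = 3001), seed = 11)
  fit <- dcmm(tr$o, K = 2, n_restarts = 3, seed = 2)
  dF <- diff(fit$F_history)
  expect_true(all(dF > -1e-8 * pmax(abs(fit$F_history[-1]), 1)))
  expect_true(fit$converged)
})

test_that("flat priors and K = 1 recover the empirical transition matrix", {
  o <- simulate_observable(rep(1L, 2000), list(two_state_B(0.07, 0.12)),
                           o1 = 1, seed = 3)
  pr <- dcmm_priors(u_pi = 1e-8, u_a = 1e-8, u_ad = 1e-8, u_b = 1e-8,
                    u_bd = 1e-8)
  fit <- dcmm(o, K = 1, priors = pr, n_restarts = 1, seed = 1)
  tab <- table(factor(o[-length(o)], levels = 1:2), factor(o[-1], levels = 1:2))
  ml <- tab / rowSums(tab)
  expect_equal(unclass(fit$model$B[[1]]), unclass(as.matrix(ml)),
               ignore_attr = TRUE, tolerance = 1e-5)
})

test_that("the bound is invariant under internal-label permutation", {
  tr <- simulate_dcmm_trace(canonical_condition(T_frames = 2001), seed = 21)
  pr <- dcmm_priors()
  U_B <- matrix(pr$u_b, 2, 2); diag(U_B) <- pr$u_bd
  w0 <- vbdcmm:::init_b_counts(tr$o, 2, 2, pr, mode = "activity")
  f1 <- vbdcmm:::vb_run(tr$o, 2, 2, pr, w0, 1000, 1e-8)
  f2 <- vbdcmm:::vb_run(tr$o, 2, 2, pr, w0[c(2, 1)], 1000, 1e-8)
  expect_equal(f1$F, f2$F, tolerance = 1e-6)
})

test_that("posterior-mean B recovers the generating rates on long traces", {
  cfg <- canonical_condition()
  rel_err <- matrix(NA, 10, 4)
  for (s in 1:10) {
    tr <- simulate_dcmm_trace(cfg, seed = 600 + s)
    fit <- dcmm(tr$o, K = 2, n_restarts = 3, seed = s)
    perm <- match_labels(fit$model$B, cfg$B)
    est <- fit$model$B[order(perm)]
    truth <- c(0.05, 0.05, 0.00625, 0.025)
    got <- c(est[[1]][1, 2], est[[1]][2, 1], est[[2]][1, 2], est[[2]][2, 1])
    rel_err[s, ] <- abs(got - truth) / truth
  }
  expect_lt(max(colMeans(rel_err)), 0.30)
})

test_that("dcmm fit object behaves like a standard model fit", {
  tr <- simulate_dcmm_trace(canonical_condition(T_frames = 2001), seed = 31)
  fit <- dcmm(tr$o, K = 2, n_restarts = 2, seed = 5)
  expect_s3_class(fit, "dcmm")
  cf <- coef(fit)
  expect_equal(rowSums(cf$A), rep(1, 2), tolerance = 1e-12)
  expect_equal(sum(cf$pi), 1, tolerance = 1e-12)
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$F)
  expect_equal(attr(ll, "df"), 1 + 2 + 4)
  xh <- predict(fit)
  expect_length(xh, length(tr$o) - 1L)
  resp <- predict(fit, type = "responsibilities")
  expect_equal(rowSums(resp), rep(1, length(tr$o) - 1L), tolerance = 1e-10)
  sims <- simulate(fit, nsim = 2, seed = 1, T_frames = 100)
  expect_length(sims, 2)
  expect_length(sims[[1]]$o, 100)
  expect_output(print(summary(fit)), "internal states observed")
})
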