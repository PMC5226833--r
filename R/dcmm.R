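#' Dirichlet prior pseudocounts for the double-chain model
#'
#' The variational fit places independent Dirichlet priors on the initial
#' internal-state distribution, on each row of the internal transition matrix
#' `A`, and on each row of every observable transition matrix `B`. The only
#' prior a user normally needs to touch is `u_ad`, the self-transition
#' pseudocount of `A`: a large value encodes the physical requirement that
#' internal states persist for many frames (the interconversion time is much
#' longer than the frame duration). The fit is robust over wide ranges of the
#' remaining pseudocounts.
#'
#' @param u_pi pseudocount for the initial distribution (default 1).
#' @param u_a off-diagonal pseudocount for rows of `A` (default 1).
#' @param u_ad diagonal (self-transition) pseudocount for `A` (default 100).
#' @param u_b off-diagonal pseudocount for rows of `B` (default 1).
#' @param u_bd diagonal pseudocount for `B` (default 1).
#' @return Object of class `"dcmm_priors"`.
#' @export
dcmm_priors <- function(u_pi = 1, u_a = 1, u_ad = 100, u_b = 1, u_bd = 1) {
  vals <- c(u_pi = u_pi, u_a = u_a, u_ad = u_ad, u_b = u_b, u_bd = u_bd)
  if (any(vals <= 0)) stop("all prior pseudocounts must be > 0", call. = FALSE)
  structure(as.list(vals), class = "dcmm_priors")
}

#' Per-step internal-state evidence from an observable trace
#'
#' The observable transition `o(t) -> o(t+1)` carries the evidence for the
#' hidden internal state at step `t`: entry `(t, mu)` of the returned table is
#' `B[[mu]][o(t), o(t+1)]`.
#'
#' @param o integer observable sequence (values `1..N`).
#' @param B list of `N x N` observable transition matrices (one per internal
#'   state); sub-stochastic variational parameters are allowed.
#' @return `(length(o) - 1) x K` matrix of emission weights.
#' @export
emission_matrix <- function(o, B) {
  N <- ncol(B[[1]])
  if (any(o < 1 | o > N))
    stop("observable value outside 1..N", call. = FALSE)
  i1 <- o[-length(o)]
  i2 <- o[-1]
  vapply(B, function(Bm) Bm[cbind(i1, i2)], numeric(length(i1)))
}

#' Forward-backward recursions for the hidden internal chain
#'
#' Scaled forward-backward pass over the internal chain given per-step
#' emission weights. Sub-stochastic parameters (the exponentiated expected
#' log-parameters used in the variational E-step) are accepted; the log
#' normalizer is then the log of the total path weight rather than a
#' log-probability.
#'
#' @param emissions `T x K` emission table (e.g. from [emission_matrix()]).
#' @param A_eff `K x K` (sub-)stochastic transition parameters.
#' @param pi_eff length-`K` initial weights.
#' @return List: `responsibilities` (`T x K`, rows sum to 1), `pair_marginals`
#'   (`K x K`, pairwise posteriors summed over the `T - 1` steps), and
#'   `log_normalizer`.
#' @export
forward_backward <- function(emissions, A_eff, pi_eff) {
  emissions <- as.matrix(emissions)
  fb <- fb_scaled(pi_eff, A_eff, emissions)
  list(responsibilities = fb$gamma, pair_marginals = fb$xi,
       log_normalizer = fb$loglik)
}

# B posterior counts: counts[[mu]][a, b] = sum_t gamma[t, mu] 1{o(t)=a, o(t+1)=b}
b_counts_from_gamma <- function(o, gamma, N) {
  K <- ncol(gamma)
  pair <- (o[-length(o)] - 1L) * N + o[-1]  # 1..N^2
  agg <- rowsum(gamma, group = pair)        # one row per observed pair
  pairs_seen <- as.integer(rownames(agg))
  lapply(seq_len(K), function(mu) {
    M <- matrix(0, N, N)
    M[cbind((pairs_seen - 1L) %/% N + 1L, (pairs_seen - 1L) %% N + 1L)] <-
      agg[, mu]
    M
  })
}

prior_mat <- function(K_or_N, off, diag_) {
  M <- matrix(off, K_or_N, K_or_N)
  diag(M) <- diag_
  M
}

kl_rows <- function(W, U) {
  sum(vapply(seq_len(nrow(W)), function(i) kl_dirichlet(W[i, ], U[i, ]),
             numeric(1)))
}

# One variational fit from given initial B pseudocount matrices.
vb_run <- function(o, K, N, priors, w_B_init, max_iter, tol) {
  T1 <- length(o) - 1L
  U_pi <- rep(priors$u_pi, K)
  U_A <- prior_mat(K, priors$u_a, priors$u_ad)
  U_B <- prior_mat(N, priors$u_b, priors$u_bd)
  w_pi <- U_pi
  w_A <- U_A
  w_B <- w_B_init
  F_hist <- numeric(0)
  converged <- FALSE
  gamma <- NULL; xi <- NULL
  for (it in seq_len(max_iter)) {
    pi_t <- dirichlet_geomean(w_pi)
    A_t <- dirichlet_geomean(w_A)
    B_t <- lapply(w_B, dirichlet_geomean)
    emis <- emission_matrix(o, B_t)
    fb <- fb_scaled(pi_t, A_t, emis)
    gamma <- fb$gamma; xi <- fb$xi
    F_now <- fb$loglik - kl_dirichlet(w_pi, U_pi) - kl_rows(w_A, U_A) -
      sum(vapply(w_B, kl_rows, numeric(1), U = U_B))
    F_hist <- c(F_hist, F_now)
    if (it > 1 && abs(F_now - F_hist[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    # VB-M: Dirichlet posterior counts from the chain posteriors
    w_pi <- U_pi + gamma[1, ]
    w_A <- U_A + xi
    w_B <- Map(`+`, list(U_B)[rep(1, K)], b_counts_from_gamma(o, gamma, N))
  }
  list(F = F_hist[length(F_hist)], F_history = F_hist, converged = converged,
       n_iter = length(F_hist), w_pi = w_pi, w_A = w_A, w_B = w_B,
       responsibilities = gamma)
}

count_segment <- function(seg, N) {
  if (length(seg) < 2) return(matrix(0, N, N))
  tab <- table(factor(seg[-length(seg)], levels = 1:N),
               factor(seg[-1], levels = 1:N))
  matrix(as.numeric(tab), N, N)
}

# Initial B pseudocounts for one restart. Two modes:
#  - "activity": deterministic split of the trace into K groups by local
#    observable-transition density (running mean over ~2/min-rate frames),
#    targeting exactly the structure dynamic disorder produces;
#  - "segments": K random contiguous blocks plus Dirichlet-style jitter.
init_b_counts <- function(o, K, N, priors, mode = "segments", jitter = TRUE) {
  T_ <- length(o)
  U_B <- prior_mat(N, priors$u_b, priors$u_bd)
  if (K == 1) {
    return(list(U_B + count_segment(o, N)))
  }
  if (mode == "activity") {
    hop <- c(0, as.numeric(o[-1] != o[-T_]))
    w <- min(201L, max(11L, (T_ %/% 20L) * 2L + 1L))
    act <- as.numeric(stats::filter(hop, rep(1 / w, w), sides = 2))
    act[is.na(act)] <- mean(hop)
    grp <- cut(rank(act, ties.method = "first"),
               breaks = K, labels = FALSE)
    counts <- lapply(seq_len(K), function(mu) {
      ts <- which(grp[-T_] == mu)  # steps assigned to group mu
      if (length(ts) == 0) return(matrix(0, N, N))
      tab <- table(factor(o[ts], levels = 1:N), factor(o[ts + 1L], levels = 1:N))
      matrix(as.numeric(tab), N, N)
    })
    return(lapply(counts, function(cnt) U_B + cnt))
  }
  cuts <- sort(sample.int(T_ - 2L, K - 1L) + 1L)
  bounds <- c(1L, cuts, T_)
  lapply(seq_len(K), function(mu) {
    cnt <- count_segment(o[bounds[mu]:bounds[mu + 1L]], N)
    jit <- if (jitter) matrix(rgamma(N * N, shape = 0.5), N, N) else 0
    U_B + cnt + jit
  })
}

#' Fit a double-chain Markov model by variational Bayes
#'
#' Core inference for time traces with dynamic disorder. The observable
#' sequence `o` is modeled as a Markov chain whose transition matrix switches
#' among `K` hidden matrices `B[[1]], ..., B[[K]]`, governed by a slow hidden
#' internal-state chain with transition matrix `A`. The fit alternates a
#' forward-backward E-step under the exponentiated expected log-parameters of
#' the Dirichlet posteriors with conjugate pseudocount updates, monotonically
#' increasing the evidence lower bound `F` (an approximation to the log
#' marginal likelihood `log P(o | K)`). A `+log K!` label-degeneracy term is
#' added to the converged bound.
#'
#' Restarts are initialized by counting observable transitions within `K`
#' random contiguous segments of the trace (plus jitter); the restart with the
#' highest converged bound is returned. Internal states of the returned model
#' are ordered by decreasing mean off-diagonal rate of `B` (fastest kinetics
#' first).
#'
#' @param o integer observable sequence (values `1..N`), length >= 3.
#' @param K number of internal states (>= 1).
#' @param priors a [dcmm_priors()] object.
#' @param max_iter maximum variational iterations per restart (default 1000).
#' @param tol absolute convergence tolerance on `F` in nats (default 1e-6).
#' @param n_restarts number of restarts (default 10).
#' @param seed optional integer seed governing all restarts.
#' @param N number of observable states; defaults to `max(o)`.
#' @return Object of class `"dcmm"` with elements `model` (posterior-mean
#'   `pi`, `A`, `B`), `posterior_counts`, `F` (bound including the `+log K!`
#'   term), `F_history`, `responsibilities`, `converged`, `n_iter`, `K`, `N`,
#'   `priors`, and the training sequence `o`.
#' @examples
#' cfg <- benchmark_config(T_frames = 2001)
#' tr <- simulate_dcmm_trace(cfg, seed = 1)
#' fit <- dcmm(tr$o, K = 2, n_restarts = 3, seed = 1)
#' fit
#' @export
dcmm <- function(o, K, priors = dcmm_priors(), max_iter = 1000, tol = 1e-6,
                 n_restarts = 10, seed = NULL, N = max(o)) {
  o <- as.integer(o)
  if (length(o) < 3) stop("need at least 3 frames", call. = FALSE)
  stopifnot(K >= 1, N >= 2)
  if (any(o < 1 | o > N)) stop("observable value outside 1..N", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    w_B0 <- init_b_counts(o, K, N, priors,
                          mode = if (r == 1) "activity" else "segments",
                          jitter = r > 2)
    fit <- vb_run(o, K, N, priors, w_B0, max_iter, tol)
    if (is.null(best) || fit$F > best$F) best <- fit
  }
  model <- list(
    pi = best$w_pi / sum(best$w_pi),
    A = best$w_A / rowSums(best$w_A),
    B = lapply(best$w_B, function(W) W / rowSums(W))
  )
  # canonical ordering: fastest observable kinetics first
  activity <- vapply(model$B, function(Bm) mean(offdiag_vector(Bm)), numeric(1))
  ord <- order(activity, decreasing = TRUE)
  model$pi <- model$pi[ord]
  model$A <- model$A[ord, ord, drop = FALSE]
  model$B <- model$B[ord]
  counts <- list(pi = best$w_pi[ord],
                 A = best$w_A[ord, ord, drop = FALSE],
                 B = best$w_B[ord])
  structure(list(model = model, posterior_counts = counts,
                 F = best$F + lfactorial(K), F_history = best$F_history,
                 responsibilities = best$responsibilities[, ord, drop = FALSE],
                 converged = best$converged, n_iter = best$n_iter,
                 K = K, N = N, priors = priors, o = o),
            class = "dcmm")
}

#' Most probable internal-state path
#'
#' Viterbi decoding of the hidden internal-state sequence under the
#' point-estimate (posterior-mean) model. Ties are broken toward the lower
#' state index.
#'
#' @param o integer observable sequence.
#' @param model a list with `pi`, `A`, `B` (e.g. `fit$model` from [dcmm()]).
#' @return Integer internal path of length `length(o) - 1`.
#' @export
viterbi_internal <- function(o, model) {
  emis <- emission_matrix(o, model$B)
  viterbi_path(log(pmax(model$pi, 1e-300)),
               log(pmax(model$A, 1e-300)),
               log(pmax(emis, 1e-300)))
}

#' @export
print.dcmm <- function(x, ...) {
  cat(sprintf("Double-chain Markov model fit: K = %d internal, N = %d observable states\n",
              x$K, x$N))
  cat(sprintf("  evidence lower bound F = %.2f nats (%d iterations%s)\n",
              x$F, x$n_iter, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @export
summary.dcmm <- function(object, ...) {
  x_hat <- viterbi_internal(object$o, object$model)
  structure(list(fit = object, x_hat = x_hat,
                 K_obs = length(unique(x_hat)),
                 exit_prob = 1 - diag(object$model$A)),
            class = "summary.dcmm")
}

#' @export
print.summary.dcmm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  internal states observed in Viterbi path: %d of %d\n",
              x$K_obs, x$fit$K))
  cat("  per-frame exit probability from each internal state:\n")
  print(signif(x$exit_prob, 3))
  cat("  observable transition matrices (per-frame probabilities):\n")
  for (mu in seq_len(x$fit$K)) {
    cat(sprintf("  B[[%d]]:\n", mu))
    print(signif(x$fit$model$B[[mu]], 3))
  }
  invisible(x)
}

#' @export
coef.dcmm <- function(object, ...) object$model

#' @export
logLik.dcmm <- function(object, ...) {
  K <- object$K; N <- object$N
  structure(object$F, df = (K - 1) + K * (K - 1) + K * N * (N - 1),
            nobs = length(object$o), class = "logLik")
}

#' @export
#' @rdname dcmm
#' @param object,newdata,type for the `predict` method: a fitted `"dcmm"`
#'   object, an optional new observable sequence (default: the training
#'   sequence), and whether to return the Viterbi `"internal"` path or the
#'   per-step posterior `"responsibilities"`.
#' @param ... unused.
predict.dcmm <- function(object, newdata = NULL,
                         type = c("internal", "responsibilities"), ...) {
  type <- match.arg(type)
  o <- if (is.null(newdata)) object$o else as.integer(newdata)
  if (type == "internal") return(viterbi_internal(o, object$model))
  pi_t <- dirichlet_geomean(object$posterior_counts$pi)
  A_t <- dirichlet_geomean(object$posterior_counts$A)
  B_t <- lapply(object$posterior_counts$B, dirichlet_geomean)
  forward_backward(emission_matrix(o, B_t), A_t, pi_t)$responsibilities
}

#' @export
simulate.dcmm <- function(object, nsim = 1, seed = NULL, T_frames = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(T_frames)) T_frames <- length(object$o)
  lapply(seq_len(nsim), function(i) {
    x <- sim_chain(object$model$pi, object$model$A, as.integer(T_frames) - 1L)
    o <- sim_slaved_chain(x, object$model$B, sample.int(object$N, 1L))
    list(x = x, o = o)
  })
}

#' @export
plot.dcmm <- function(x, ...) {
  x_hat <- viterbi_internal(x$o, x$model)
  old <- graphics::par(mfrow = c(2, 1), mar = c(3.2, 3.5, 1.5, 0.5),
                       mgp = c(2.1, 0.7, 0))
  on.exit(graphics::par(old))
  t_o <- seq_along(x$o)
  plot(t_o, x$o, type = "s", xlab = "frame", ylab = "observable state",
       yaxt = "n", main = "idealized observable trace", ...)
  graphics::axis(2, at = seq_len(x$N))
  plot(seq_along(x_hat), x_hat, type = "s", col = "firebrick",
       xlab = "frame", ylab = "internal state", yaxt = "n",
       main = "decoded internal-state path")
  graphics::axis(2, at = seq_len(x$K))
  invisible(x)
}
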