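#' FRET efficiency from donor/acceptor intensities
#'
#' Computes `E(t) = I_A / (I_A + I_D)` frame by frame. Frames whose total
#' intensity is zero are returned as `NA` and should be dropped before
#' idealization.
#'
#' @param donor,acceptor non-negative intensity series of equal length.
#' @return Numeric FRET efficiency series (with `NA` at zero-intensity frames).
#' @export
compute_fret <- function(donor, acceptor) {
  if (length(donor) != length(acceptor))
    stop("donor and acceptor series must have equal length", call. = FALSE)
  if (any(donor < 0, na.rm = TRUE) || any(acceptor < 0, na.rm = TRUE))
    stop("intensities must be non-negative", call. = FALSE)
  tot <- donor + acceptor
  e <- acceptor / tot
  e[tot == 0] <- NA_real_
  e
}

gauss_emissions <- function(y, means, sds) {
  T_ <- length(y)
  N <- length(means)
  e <- matrix(0, T_, N)
  for (k in seq_len(N)) e[, k] <- dnorm(y, means[k], sds[k])
  # guard against total underflow at outlier frames
  e[e < 1e-300] <- 1e-300
  e
}

#' Fit a Gaussian-emission hidden Markov model to a noisy trace
#'
#' Baum-Welch (EM) fit of an `N`-state HMM with per-state Gaussian emissions,
#' used to idealize a noisy FRET-like signal into discrete observable states
#' before double-chain decoding. States are relabeled in ascending order of
#' emission mean, so state 1 is always the lowest-signal state.
#'
#' Restarts are initialized by splitting the signal at empirical quantiles and
#' perturbing the split points; the best-likelihood fit is returned. A state
#' whose occupancy collapses below one frame triggers a warning and that
#' restart is discarded.
#'
#' @param o_n numeric signal trace (`NA` frames are dropped and the chain is
#'   treated as contiguous across the gap).
#' @param N number of observable states.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param n_restarts number of random restarts (default 3).
#' @param seed optional integer seed.
#' @return Object of class `"gaussian_hmm"`: `means`, `sds`, `transmat`,
#'   `startprob`, `loglik`, `n_iter`, `converged`.
#' @export
fit_gaussian_hmm <- function(o_n, N = 2, max_iter = 500, tol = 1e-6,
                             n_restarts = 3, seed = NULL) {
  o_n <- o_n[!is.na(o_n)]
  if (length(o_n) < 10 * N)
    stop("trace too short for reliable HMM fitting (need >= 10 frames per state)",
         call. = FALSE)
  stopifnot(N >= 2)
  if (!is.null(seed)) set.seed(seed)
  T_ <- length(o_n)
  sd_floor <- max(1e-4, diff(range(o_n)) * 1e-4)

  run_once <- function(jitter) {
    qs <- quantile(o_n, probs = (seq_len(N) - 0.5) / N, names = FALSE)
    means <- qs + jitter
    sds <- rep(max(sd(o_n) / N, sd_floor), N)
    transmat <- matrix(0.05 / (N - 1), N, N)
    diag(transmat) <- 0.95
    startprob <- rep(1 / N, N)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      e <- gauss_emissions(o_n, means, sds)
      fb <- fb_scaled(startprob, transmat, e)
      g <- fb$gamma
      occ <- colSums(g)
      if (any(occ < 1)) {
        warning("degenerate HMM fit (near-empty state); restarting",
                call. = FALSE)
        return(NULL)
      }
      means <- as.numeric(crossprod(g, o_n)) / occ
      sds <- sqrt(pmax(colSums(g * (outer(o_n, means, "-"))^2) / occ,
                       sd_floor^2))
      transmat <- fb$xi / rowSums(fb$xi)
      startprob <- g[1, ]
      if (is.finite(ll_old) &&
          abs(fb$loglik - ll_old) < tol * (abs(ll_old) + 1e-10)) {
        return(list(means = means, sds = sds, transmat = transmat,
                    startprob = startprob, loglik = fb$loglik,
                    n_iter = it, converged = TRUE))
      }
      ll_old <- fb$loglik
    }
    list(means = means, sds = sds, transmat = transmat,
         startprob = startprob, loglik = ll_old, n_iter = max_iter,
         converged = FALSE)
  }

  spread <- diff(range(o_n))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    jitter <- if (r == 1) rep(0, N) else rnorm(N, 0, 0.05 * spread)
    fit <- run_once(jitter)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best))
    stop("all HMM restarts degenerated; check N against the data", call. = FALSE)
  ord <- order(best$means)
  structure(list(N = N, means = best$means[ord], sds = best$sds[ord],
                 transmat = best$transmat[ord, ord, drop = FALSE],
                 startprob = best$startprob[ord], loglik = best$loglik,
                 n_iter = best$n_iter, converged = best$converged),
            class = "gaussian_hmm")
}

#' @export
print.gaussian_hmm <- function(x, ...) {
  cat(sprintf("Gaussian HMM (%d states), logLik %.2f after %d iterations%s\n",
              x$N, x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  cat("  means:", paste(signif(x$means, 4), collapse = ", "), "\n")
  cat("  sds:  ", paste(signif(x$sds, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Idealize a noisy trace with a fitted Gaussian HMM
#'
#' Viterbi decoding of the most probable observable-state path; states are
#' numbered `1..N` by ascending emission mean.
#'
#' @param o_n numeric signal trace (`NA` frames dropped).
#' @param hmm a fitted [fit_gaussian_hmm()] object.
#' @return Integer sequence of observable states, one per (non-missing) frame.
#' @export
viterbi_discretize <- function(o_n, hmm) {
  stopifnot(inherits(hmm, "gaussian_hmm"))
  o_n <- o_n[!is.na(o_n)]
  e <- gauss_emissions(o_n, hmm$means, hmm$sds)
  viterbi_path(log(pmax(hmm$startprob, 1e-300)),
               log(pmax(hmm$transmat, 1e-300)), log(e))
}

#' One-call idealization of a noisy trace
#'
#' Convenience wrapper: fit the Gaussian HMM and Viterbi-decode in one step.
#'
#' @inheritParams fit_gaussian_hmm
#' @return List with `o` (discrete trace) and `hmm` (the fit).
#' @export
idealize_trace <- function(o_n, N = 2, n_restarts = 3, seed = NULL, ...) {
  hmm <- fit_gaussian_hmm(o_n, N = N, n_restarts = n_restarts, seed = seed, ...)
  list(o = viterbi_discretize(o_n, hmm), hmm = hmm)
}
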