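#' Number of internal states observed in a decoded path
#'
#' For a model fit with `K` internal states, the Viterbi path often visits
#' only `K_obs <= K` of them; the unused labels inflate the conventional
#' `log K!` degeneracy correction and must be discounted when comparing
#' evidence across `K`.
#'
#' @param x decoded internal path (integer vector).
#' @return Count of distinct labels present.
#' @export
count_observed_states <- function(x) {
  if (length(x) == 0) stop("empty path", call. = FALSE)
  length(unique(as.integer(x)))
}

#' Label-degeneracy-corrected evidence
#'
#' When only `K_obs` of `K` internal states are populated, the labeling
#' degeneracy is `choose(K, K_obs) * K_obs!` rather than `K!`; correcting the
#' bound gives `G(K) = F(K) - log((K - K_obs)!)`.
#'
#' @param F evidence lower bound (including its `+log K!` term).
#' @param K number of internal states in the model.
#' @param K_obs number of states observed in the decoded path.
#' @return The corrected evidence `G`.
#' @export
modified_evidence <- function(F, K, K_obs) {
  if (any(K_obs > K)) stop("K_obs cannot exceed K", call. = FALSE)
  F - lfactorial(K - K_obs)
}

#' Scan model sizes and select the number of internal states
#'
#' Fits the double-chain model for `K = 1..K_max`, decodes each fit, computes
#' the corrected evidence `G(K)`, and selects `K* = argmax G(K)` (ties broken
#' toward the smaller model).
#'
#' @param o integer observable sequence.
#' @param K_max largest model size to consider (default 5).
#' @param priors a [dcmm_priors()] object.
#' @param n_restarts restarts per fit (default 10).
#' @param seed optional integer seed.
#' @param ... further arguments passed to [dcmm()].
#' @return Object of class `"dcmm_scan"`: per-K vectors `F`, `K_obs`, `G`,
#'   the selected `K_star`, the fitted models in `fits`, decoded paths in
#'   `paths`, and any per-K errors in `failures`.
#' @examples
#' cfg <- benchmark_config(T_frames = 2001)
#' tr <- simulate_dcmm_trace(cfg, seed = 1)
#' scan <- select_model(tr$o, K_max = 2, n_restarts = 3, seed = 1)
#' scan
#' @export
select_model <- function(o, K_max = 5, priors = dcmm_priors(),
                         n_restarts = 10, seed = NULL, ...) {
  stopifnot(K_max >= 1)
  if (!is.null(seed)) set.seed(seed)
  K_values <- seq_len(K_max)
  fits <- vector("list", K_max)
  paths <- vector("list", K_max)
  failures <- vector("list", K_max)
  F_vals <- rep(NA_real_, K_max)
  K_obs <- rep(NA_integer_, K_max)
  for (K in K_values) {
    res <- tryCatch({
      fit <- dcmm(o, K, priors = priors, n_restarts = n_restarts, ...)
      path <- viterbi_internal(o, fit$model)
      list(fit = fit, path = path)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[K]] <- conditionMessage(res)
      next
    }
    fits[[K]] <- res$fit
    paths[[K]] <- res$path
    F_vals[K] <- res$fit$F
    K_obs[K] <- count_observed_states(res$path)
  }
  G <- modified_evidence(F_vals, K_values, ifelse(is.na(K_obs), K_values, K_obs))
  K_star <- if (all(is.na(G))) NA_integer_ else which.max(G)  # first max: ties -> smaller K
  structure(list(K_values = K_values, F = F_vals, K_obs = K_obs, G = G,
                 K_star = K_star, fits = fits, paths = paths,
                 failures = failures),
            class = "dcmm_scan")
}

#' @export
print.dcmm_scan <- function(x, ...) {
  cat("Internal-state number selection\n")
  tab <- data.frame(K = x$K_values, F = round(x$F, 2), K_obs = x$K_obs,
                    G = round(x$G, 2))
  print(tab, row.names = FALSE)
  cat(sprintf("Selected K* = %s\n", x$K_star))
  invisible(x)
}

#' @export
plot.dcmm_scan <- function(x, ...) {
  plot(x$K_values, x$G, type = "b", pch = 19, xlab = "K (internal states)",
       ylab = "corrected evidence G(K) [nats]", ...)
  graphics::points(x$K_star, x$G[x$K_star], pch = 1, cex = 2, col = "firebrick")
  invisible(x)
}

#' Decompose a decoded trace into homogeneous components
#'
#' Maximal constant-label runs of the decoded internal path become
#' "components", each of which should behave as a homogeneous Markov chain.
#' Per-component observable transition probabilities are estimated from the
#' empirical counts with a +0.5 pseudocount per cell (so no rate is exactly
#' zero and logarithms are finite downstream). Components shorter than
#' `min_dwell` frames are flagged low-confidence, not dropped.
#'
#' @param o integer observable sequence (length `length(x) + 1`).
#' @param x decoded internal path.
#' @param min_dwell minimum component length in frames before the rate
#'   estimate is considered trustworthy (default 10).
#' @param trace_id identifier recorded with each component.
#' @return A `data.frame` of class `"dcmm_components"` with one row per
#'   component: `trace_id`, half-open frame interval `[start, end)` (1-based,
#'   indexing the internal path), `label`, `n_frames`, `n_trans` (observable
#'   transitions within the interval), `low_confidence`, and the off-diagonal
#'   per-frame transition probabilities `k<a>.<b>`. The full `N x N` rate
#'   matrices are kept in `attr(, "rates")`.
#' @export
decompose_trace <- function(o, x, min_dwell = 10, trace_id = 1L) {
  o <- as.integer(o); x <- as.integer(x)
  if (length(x) != length(o) - 1L)
    stop("internal path must be one shorter than the observable trace",
         call. = FALSE)
  N <- max(o)
  runs <- path_runs(x)
  idx <- offdiag_index(N)
  rates <- vector("list", nrow(runs))
  k_cols <- matrix(NA_real_, nrow(runs), nrow(idx),
                   dimnames = list(NULL, paste0("k", idx$a, ".", idx$b)))
  n_trans <- integer(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    ts <- runs$start[i]:(runs$end[i] - 1L)  # steps governed by this component
    cnt <- matrix(0, N, N)
    tab <- table(factor(o[ts], levels = 1:N), factor(o[ts + 1L], levels = 1:N))
    cnt <- matrix(as.numeric(tab), N, N)
    R <- (cnt + 0.5) / (rowSums(cnt) + 0.5 * N)
    rates[[i]] <- R
    k_cols[i, ] <- R[cbind(idx$a, idx$b)]
    n_trans[i] <- sum(cnt) - sum(diag(cnt))
  }
  out <- data.frame(trace_id = trace_id, start = runs$start, end = runs$end,
                    label = runs$label, n_frames = runs$end - runs$start,
                    n_trans = n_trans,
                    low_confidence = (runs$end - runs$start) < min_dwell)
  out <- cbind(out, as.data.frame(k_cols))
  attr(out, "rates") <- rates
  attr(out, "N") <- N
  class(out) <- c("dcmm_components", "data.frame")
  out
}
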