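#' Match estimated internal-state labels to reference labels
#'
#' Internal-state labels are arbitrary; to compare a fitted model against a
#' reference (e.g. the generating truth), labels are matched by exhaustive
#' search over permutations (feasible for `K <= 6`) minimizing the summed
#' elementwise absolute difference between matched observable transition
#' matrices.
#'
#' @param B_est,B_true lists of `N x N` matrices of equal length `K`.
#' @return Integer permutation `perm` mapping estimated labels to reference
#'   labels: estimated state `j` corresponds to reference state `perm[j]`.
#' @export
match_labels <- function(B_est, B_true) {
  K <- length(B_true)
  if (length(B_est) != K)
    stop("label matching requires equal K; match states on path overlap instead",
         call. = FALSE)
  if (K > 6) stop("exhaustive matching supported for K <= 6", call. = FALSE)
  perms <- permutations_of(K)
  cost <- apply(perms, 1, function(p)
    sum(vapply(seq_len(K), function(j) sum(abs(B_est[[j]] - B_true[[p[j]]])),
               numeric(1))))
  as.integer(perms[which.min(cost), ])
}

permutations_of <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }))
}

#' Frame-wise overlap between decoded and reference internal paths
#'
#' The fraction of steps at which the (relabeled) decoded internal state
#' agrees with the reference: `chi = mean(x_true == perm[x_pred])`.
#'
#' @param x_true,x_pred internal paths of equal length.
#' @param permutation label map for `x_pred` (e.g. from [match_labels()]);
#'   default identity.
#' @return Overlap in `[0, 1]`.
#' @export
overlap_chi <- function(x_true, x_pred, permutation = NULL) {
  if (length(x_true) != length(x_pred))
    stop("paths must have equal length", call. = FALSE)
  if (!is.null(permutation)) x_pred <- permutation[x_pred]
  mean(x_true == x_pred)
}

#' Dissimilarity of intra-basin kinetics across internal states
#'
#' Averages, over unordered pairs of internal states and ordered pairs of
#' observable states, the absolute base-2 log ratio of the corresponding
#' intra-basin transition rates. Because only rate ratios enter, per-frame
#' transition probabilities can be used directly (the frame duration cancels).
#'
#' @param B list of `K` observable transition matrices (per-frame
#'   probabilities), `K >= 2`.
#' @return `D_conf` in bits (0 when all states share identical kinetics).
#' @export
d_conf <- function(B) {
  K <- length(B)
  stopifnot(K >= 2)
  N <- ncol(B[[1]])
  rates <- lapply(B, offdiag_vector)
  if (any(unlist(rates) <= 0))
    stop("zero intra-basin rate; estimate rates with pseudocounts first",
         call. = FALSE)
  pairs <- combn(K, 2)
  total <- 0
  for (p in seq_len(ncol(pairs))) {
    total <- total + mean(abs(log2(rates[[pairs[1, p]]] / rates[[pairs[2, p]]])))
  }
  2 / (K * (K - 1)) * total
}

#' Time-scale separation between intra- and inter-basin transitions
#'
#' For each internal state, compares every intra-basin transition probability
#' against the state's total per-frame exit probability to other internal
#' states, as an absolute base-2 log ratio; the per-state means are averaged.
#' Large values mean many conformational transitions occur per interconversion,
#' the regime in which hidden-state decoding is reliable.
#'
#' An internal state with zero exit probability (absorbing) would give an
#' infinite score; it is reported as the capped sentinel 64 bits with a
#' warning.
#'
#' @param B list of `K` observable transition matrices (per-frame
#'   probabilities).
#' @param A `K x K` internal transition matrix (per-frame probabilities).
#' @return `D_int` in bits.
#' @export
d_int <- function(B, A) {
  K <- length(B)
  stopifnot(nrow(A) == K)
  per_state <- numeric(K)
  for (mu in seq_len(K)) {
    exit <- if (K > 1) sum(A[mu, -mu]) else 0
    k <- offdiag_vector(B[[mu]])
    if (any(k <= 0))
      stop("zero intra-basin rate; estimate rates with pseudocounts first",
           call. = FALSE)
    if (exit <= 0) {
      warning(sprintf("internal state %d has no exit path; capping its score at 64 bits", mu),
              call. = FALSE)
      per_state[mu] <- 64
    } else {
      per_state[mu] <- min(mean(abs(log2(k / exit))), 64)
    }
  }
  mean(per_state)
}

#' Combined reliability score
#'
#' `D_tot = D_conf + alpha * D_int` with the empirical weight `alpha = 0.8`;
#' decoded internal states are trustworthy when `D_tot` is large (mean overlap
#' with truth collapses onto a single curve in `D_tot` across benchmark
#' conditions).
#'
#' @inheritParams d_int
#' @param alpha combination weight (default 0.8).
#' @return List of class `"reliability_scores"` with `D_conf`, `D_int`,
#'   `D_tot`, `alpha`.
#' @export
reliability_scores <- function(B, A, alpha = 0.8) {
  dc <- d_conf(B)
  di <- d_int(B, A)
  structure(list(D_conf = dc, D_int = di, D_tot = dc + alpha * di,
                 alpha = alpha),
            class = "reliability_scores")
}

#' @export
print.reliability_scores <- function(x, ...) {
  cat(sprintf("D_conf = %.3f, D_int = %.3f, D_tot = D_conf + %.2g D_int = %.3f bits\n",
              x$D_conf, x$D_int, x$alpha, x$D_tot))
  invisible(x)
}

#' Coefficient of variation of dwell times
#'
#' For a homogeneous Markov process, dwell times in a state are geometrically
#' distributed and their coefficient of variation is close to 1; values well
#' above 1 indicate a mixture of dwell scales, i.e. dynamic disorder. The
#' first and last (truncated) dwells are excluded. With `window = m`, the
#' statistic is computed over sliding blocks of `m` consecutive dwells and a
#' vector is returned.
#'
#' @param labels discrete state sequence.
#' @param state the state whose dwells are measured.
#' @param window optional block size for the windowed variant (e.g. 20).
#' @return The CV `sqrt(mean(tau^2) - mean(tau)^2) / mean(tau)`, or a vector
#'   of per-window CVs; `NA` when fewer than 2 completed dwells exist.
#' @export
dwell_cv <- function(labels, state, window = NULL) {
  runs <- path_runs(labels)
  # completed dwells only: drop the first and last run of the whole sequence
  if (nrow(runs) > 2) runs <- runs[-c(1, nrow(runs)), , drop = FALSE]
  else runs <- runs[0, , drop = FALSE]
  tau <- (runs$end - runs$start)[runs$label == state]
  cv <- function(tt) {
    m <- mean(tt)
    sqrt(max(mean(tt^2) - m^2, 0)) / m
  }
  if (is.null(window)) {
    if (length(tau) < 2) return(NA_real_)
    return(cv(tau))
  }
  if (length(tau) < window) return(NA_real_)
  vapply(seq_len(length(tau) - window + 1L),
         function(i) cv(tau[i:(i + window - 1L)]), numeric(1))
}
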