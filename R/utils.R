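# Internal validators and small numerical helpers shared across modules.

check_stochastic <- function(M, name = deparse(substitute(M)), tol = 1e-12) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  if (any(M < 0))
    stop(sprintf("'%s' has negative entries", name), call. = FALSE)
  rs <- rowSums(M)
  if (any(abs(rs - 1) > max(tol, 1e-8)))
    stop(sprintf("rows of '%s' must sum to 1 (max deviation %.3g)",
                 name, max(abs(rs - 1))), call. = FALSE)
  invisible(M)
}

check_prob_vector <- function(p, name = deparse(substitute(p))) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop(sprintf("'%s' must be a probability vector summing to 1", name),
         call. = FALSE)
  invisible(p)
}

# Dirichlet(w) || Dirichlet(u) KL divergence for one row of pseudocounts.
kl_dirichlet <- function(w, u) {
  sw <- sum(w)
  lgamma(sw) - sum(lgamma(w)) - lgamma(sum(u)) + sum(lgamma(u)) +
    sum((w - u) * (digamma(w) - digamma(sw)))
}

# exp(E[log theta]) under Dirichlet(w): the sub-stochastic geometric-mean
# parameters used in the variational E-step.
dirichlet_geomean <- function(w) {
  if (is.matrix(w)) {
    exp(digamma(w) - digamma(rowSums(w)))
  } else {
    exp(digamma(w) - digamma(sum(w)))
  }
}

# Run-length encoding of an integer path: data.frame(start, end, label) with
# half-open [start, end) intervals, 1-based.
path_runs <- function(x) {
  r <- rle(as.integer(x))
  end <- cumsum(r$lengths) + 1L
  start <- c(1L, head(end, -1L))
  data.frame(start = start, end = end, label = r$values)
}

# Lexicographic (a, b) order, a != b, used for all flattened off-diagonal
# rate vectors (rows a, then columns b within a).
offdiag_index <- function(N) {
  idx <- expand.grid(b = seq_len(N), a = seq_len(N))
  idx <- idx[idx$a != idx$b, c("a", "b")]
  idx <- idx[order(idx$a, idx$b), ]
  rownames(idx) <- NULL
  idx
}

offdiag_vector <- function(M) {
  idx <- offdiag_index(ncol(M))
  v <- M[cbind(idx$a, idx$b)]
  names(v) <- paste0("k", idx$a, ".", idx$b)
  v
}
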