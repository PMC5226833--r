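# Shared fixtures, built in code.

two_state_B <- function(k_lh, k_hl) {
  matrix(c(1 - k_lh, k_lh, k_hl, 1 - k_hl), 2, 2, byrow = TRUE)
}

# The canonical two-internal-state benchmark condition (fast state 0.05/0.05,
# slow state 0.00625/0.025, symmetric interconversion 0.001/frame).
canonical_condition <- function(T_frames = 8801, sigma = 0.1) {
  benchmark_config(T_frames = T_frames, sigma = sigma)
}

# Brute-force log normalizer of the internal chain: sum over all K^T paths.
brute_log_normalizer <- function(pi, A, emis) {
  T_ <- nrow(emis)
  K <- ncol(emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    w <- pi[p[1]] * emis[1, p[1]]
    for (t in seq_len(T_ - 1)) w <- w * A[p[t], p[t + 1]] * emis[t + 1, p[t + 1]]
    total <- total + w
  }
  log(total)
}

# Brute-force most probable path and its log weight.
brute_viterbi <- function(pi, A, emis) {
  T_ <- nrow(emis)
  K <- ncol(emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  best_w <- -Inf
  best_p <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    w <- log(pi[p[1]]) + log(emis[1, p[1]])
    for (t in seq_len(T_ - 1))
      w <- w + log(A[p[t], p[t + 1]]) + log(emis[t + 1, p[t + 1]])
    if (w > best_w + 1e-12) { best_w <- w; best_p <- p }
  }
  list(path = best_p, logw = best_w)
}

# Synthetic mirror-paired arrow set: n arrows per direction around two
# antiparallel centers, optionally with extra mirror pairs.
mirror_arrow_set <- function(centers_bf, centers_af, n = 12, sd = 0.05,
                             seed = 1) {
  set.seed(seed)
  stopifnot(length(centers_bf) == length(centers_af))
  fwd <- t(replicate(n, c(centers_bf, centers_af) +
                       rnorm(2 * length(centers_bf), 0, sd)))
  rev <- t(replicate(n, c(centers_af, centers_bf) +
                       rnorm(2 * length(centers_bf), 0, sd)))
  rbind(fwd, rev)
}
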