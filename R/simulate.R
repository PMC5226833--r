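#' Simulation configuration for two-layer Markov traces
#'
#' Bundles and validates the generative parameters of a double-chain Markov
#' trace: a homogeneous internal-state chain with per-frame transition matrix
#' `A`, an observable chain whose per-frame transition matrix `B[[mu]]` is
#' slaved to the current internal state `mu`, and Gaussian observation noise
#' around per-state signal levels (FRET efficiencies).
#'
#' All transition matrices hold per-frame transition *probabilities*
#' (rate times frame duration), so every row must sum to 1.
#'
#' @param K number of internal states (>= 1).
#' @param N number of observable states (>= 2).
#' @param A `K x K` row-stochastic internal transition matrix.
#' @param B list of `K` row-stochastic `N x N` observable transition matrices.
#' @param T_frames total number of frames in the observable trace (>= 2).
#' @param dt frame duration in seconds (default 0.1 s, i.e. 10 Hz sampling).
#' @param levels strictly increasing signal values, one per observable state,
#'   each in `[-0.2, 1.2]`; defaults to low/high FRET 0.1 and 0.9 for `N = 2`,
#'   otherwise equally spaced in `[0.1, 0.9]`.
#' @param sigma Gaussian noise standard deviation (default 0.1).
#'
#' @return An object of class `"sim_config"`.
#' @seealso [simulate_dcmm_trace()], [simulate_dcmm_ensemble()]
#' @export
sim_config <- function(K, N, A, B, T_frames, dt = 0.1, levels = NULL,
                       sigma = 0.1) {
  stopifnot(K >= 1, N >= 2, T_frames >= 2, dt > 0, sigma >= 0)
  check_stochastic(A, "A")
  if (nrow(A) != K) stop("A must be K x K", call. = FALSE)
  if (length(B) != K) stop("B must hold one matrix per internal state",
                           call. = FALSE)
  for (mu in seq_len(K)) {
    check_stochastic(B[[mu]], sprintf("B[[%d]]", mu))
    if (nrow(B[[mu]]) != N) stop("each B matrix must be N x N", call. = FALSE)
  }
  if (is.null(levels)) {
    levels <- if (N == 2) c(0.1, 0.9) else seq(0.1, 0.9, length.out = N)
  }
  if (length(levels) != N || any(diff(levels) <= 0) ||
      any(levels < -0.2 | levels > 1.2))
    stop("levels must be strictly increasing, one per observable state, in [-0.2, 1.2]",
         call. = FALSE)
  structure(list(K = K, N = N, A = A, B = B, T_frames = as.integer(T_frames),
                 dt = dt, levels = levels, sigma = sigma),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Double-chain simulation config: K = %d internal, N = %d observable states\n",
              x$K, x$N))
  cat(sprintf("  %d frames at dt = %g s; levels %s; noise sd %g\n",
              x$T_frames, x$dt, paste(signif(x$levels, 3), collapse = "/"),
              x$sigma))
  invisible(x)
}

#' Simulate a homogeneous internal-state path
#'
#' Draws an internal-state sequence `x(1), ..., x(T-1)` from a homogeneous
#' Markov chain with per-frame transition matrix `A`. The path has length
#' `T_frames - 1` because each internal state governs one observable
#' transition `o(t) -> o(t+1)`.
#'
#' @param A row-stochastic `K x K` per-frame transition matrix.
#' @param pi initial-state distribution (default uniform).
#' @param T_frames total frame count of the associated observable trace.
#' @param seed optional integer seed.
#' @return Integer vector of length `T_frames - 1` with values in `1..K`.
#' @export
simulate_internal_path <- function(A, pi = NULL, T_frames, seed = NULL) {
  check_stochastic(A, "A")
  K <- nrow(A)
  if (is.null(pi)) pi <- rep(1 / K, K)
  check_prob_vector(pi, "pi")
  stopifnot(T_frames >= 2)
  if (!is.null(seed)) set.seed(seed)
  sim_chain(pi, A, as.integer(T_frames) - 1L)
}

#' Simulate the observable chain slaved to an internal path
#'
#' Generates `o(1), ..., o(T)` where `o(t+1)` is drawn from row `o(t)` of
#' `B[[x(t)]]`: the observable kinetics at each frame are those of the current
#' internal state.
#'
#' @param x internal path of length `T - 1` with values in `1..length(B)`.
#' @param B list of row-stochastic observable transition matrices.
#' @param o1 initial observable state (default drawn uniformly).
#' @param seed optional integer seed.
#' @return Integer vector of length `length(x) + 1` with values in `1..N`.
#' @export
simulate_observable <- function(x, B, o1 = NULL, seed = NULL) {
  if (any(x < 1 | x > length(B)))
    stop("internal path contains a label with no B matrix", call. = FALSE)
  for (mu in seq_along(B)) check_stochastic(B[[mu]], sprintf("B[[%d]]", mu))
  if (!is.null(seed)) set.seed(seed)
  N <- ncol(B[[1]])
  if (is.null(o1)) o1 <- sample.int(N, 1L)
  stopifnot(o1 >= 1, o1 <= N)
  sim_slaved_chain(as.integer(x), B, as.integer(o1))
}

#' Add Gaussian observation noise to a discrete trace
#'
#' Maps each observable state to its signal level and adds i.i.d. Gaussian
#' noise, producing a FRET-like real-valued trace.
#'
#' @param o discrete observable sequence (values `1..N`).
#' @param levels one signal level per observable state.
#' @param sigma noise standard deviation.
#' @param seed optional integer seed.
#' @return Numeric vector of the same length as `o`.
#' @export
add_noise <- function(o, levels, sigma, seed = NULL) {
  if (any(o < 1 | o > length(levels)))
    stop("observable state outside 1..N", call. = FALSE)
  stopifnot(sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  levels[o] + rnorm(length(o), 0, sigma)
}

#' Simulate one complete double-chain trace
#'
#' Runs the full generative process: internal path, slaved observable chain,
#' and noisy signal.
#'
#' @param config a [sim_config()] object.
#' @param seed optional integer seed governing all three layers.
#' @return A list of class `"dcmm_trace"` with elements `x` (internal path,
#'   length `T - 1`), `o` (discrete observables, length `T`), `o_n` (noisy
#'   signal), `time_s`, and the `config`.
#' @export
simulate_dcmm_trace <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  x <- sim_chain(rep(1 / config$K, config$K), config$A,
                 config$T_frames - 1L)
  o1 <- sample.int(config$N, 1L)
  o <- sim_slaved_chain(x, config$B, o1)
  o_n <- config$levels[o] + rnorm(length(o), 0, config$sigma)
  structure(list(x = x, o = o, o_n = o_n,
                 time_s = (seq_along(o) - 1) * config$dt,
                 config = config),
            class = "dcmm_trace")
}

#' @export
print.dcmm_trace <- function(x, ...) {
  cat(sprintf("Simulated double-chain trace: %d frames, K = %d, N = %d\n",
              length(x$o), x$config$K, x$config$N))
  cat(sprintf("  internal states visited: %s\n",
              paste(sort(unique(x$x)), collapse = ", ")))
  invisible(x)
}

#' Simulate an ensemble of traces under one condition
#'
#' Generates `n_traces` independent traces from the same configuration.
#' Per-trace seeds are derived from the root seed by fixed offsets, so any
#' single trace can be regenerated without rerunning the whole ensemble.
#'
#' @param config a [sim_config()] object.
#' @param n_traces number of traces.
#' @param seed root integer seed.
#' @return List of `"dcmm_trace"` objects (empty list if `n_traces = 0`).
#' @export
simulate_dcmm_ensemble <- function(config, n_traces = 100, seed = 1) {
  stopifnot(n_traces >= 0)
  lapply(seq_len(n_traces), function(i)
    simulate_dcmm_trace(config, seed = seed + 1000L * i))
}

#' Benchmark configuration with two-state observables
#'
#' Convenience constructor for the standard two-internal-state, two-observable
#' benchmark: symmetric slow interconversion between internal states with
#' per-frame probability `gamma_dt`, fast kinetics `k1` in state 1 and `k2`
#' in state 2 (per-frame low->high and high->low transition probabilities).
#'
#' Defaults reproduce the canonical validation condition:
#' `k1 = c(0.05, 0.05)`, `k2 = c(0.00625, 0.025)`, `gamma_dt = 0.001`,
#' `T_frames = 8801`.
#'
#' @param k1,k2 length-2 per-frame transition probabilities
#'   `c(L->H, H->L)` for internal states 1 and 2.
#' @param gamma_dt per-frame interconversion probability between internal
#'   states (symmetric).
#' @param T_frames total frames.
#' @param sigma noise standard deviation.
#' @param K number of internal states (1 or 2; `K = 1` drops state 2).
#' @return A [sim_config()] object.
#' @export
benchmark_config <- function(k1 = c(0.05, 0.05), k2 = c(0.00625, 0.025),
                             gamma_dt = 0.001, T_frames = 8801, sigma = 0.1,
                             K = 2) {
  two_state <- function(k) {
    matrix(c(1 - k[1], k[1], k[2], 1 - k[2]), 2, 2, byrow = TRUE)
  }
  if (K == 1) {
    sim_config(K = 1, N = 2, A = matrix(1, 1, 1), B = list(two_state(k1)),
               T_frames = T_frames, sigma = sigma)
  } else {
    A <- matrix(c(1 - gamma_dt, gamma_dt, gamma_dt, 1 - gamma_dt), 2, 2,
                byrow = TRUE)
    sim_config(K = 2, N = 2, A = A, B = list(two_state(k1), two_state(k2)),
               T_frames = T_frames, sigma = sigma)
  }
}

#' Multi-state benchmark for landscape-connectivity clustering
#'
#' Configuration used to validate kinetic-arrow clustering: `K` internal
#' states and `N` observable states, with slow uniform interconversion
#' between all internal-state pairs. Each internal state is distinguished by
#' a binary high/low pattern over the `N (N - 1)` off-diagonal transition
#' cells: every cell is either `rate_high` or `rate_low` (default ratio 4),
#' and distinct states differ in at least half the cells. Keeping every state
#' kinetically active this way gives each decoded component enough observable
#' transitions to pin down its rates, while the per-cell 4-fold contrast
#' cleanly separates the resulting kinetic arrows in log-rate space.
#'
#' For `K = 4` the patterns are: all-high, all-low, alternating cells high,
#' and the complement of the alternation (pairwise differing in 6 or 12 of
#' the 12 cells at `N = 4`); `K < 4` uses the first `K` of these.
#'
#' @param K internal states (2 to 4, default 4).
#' @param N observable states (default 4).
#' @param rate_high,rate_low the two per-frame transition probabilities
#'   (defaults 0.1 and 0.025).
#' @param gamma_dt per-frame interconversion probability between each ordered
#'   internal-state pair (default 4e-4, so components last on average
#'   `1/((K-1) gamma_dt)` ~ 800 frames).
#' @param T_frames frames per trace (default 16001).
#' @param sigma noise standard deviation.
#' @return A [sim_config()] object.
#' @export
clustering_benchmark_config <- function(K = 4, N = 4, rate_high = 0.1,
                                        rate_low = 0.025, gamma_dt = 4e-4,
                                        T_frames = 16001, sigma = 0.1) {
  stopifnot(K >= 2, K <= 4, rate_high * (N - 1) < 1, rate_low > 0,
            rate_low < rate_high)
  n_off <- N * (N - 1)
  alt <- seq_len(n_off) %% 2 == 1
  patterns <- list(rep(TRUE, n_off), rep(FALSE, n_off), alt, !alt)[seq_len(K)]
  idx <- offdiag_index(N)
  B <- lapply(patterns, function(p) {
    M <- matrix(0, N, N)
    M[cbind(idx$a, idx$b)] <- ifelse(p, rate_high, rate_low)
    diag(M) <- 1 - rowSums(M)
    M
  })
  A <- matrix(gamma_dt, K, K)
  diag(A) <- 1 - (K - 1) * gamma_dt
  sim_config(K = K, N = N, A = A, B = B, T_frames = T_frames, sigma = sigma)
}

#' Grid of benchmark conditions over rate ratios
#'
#' Builds the benchmark grid in which internal state 1 keeps
#' `k1 = c(0.05, 0.05)` while state 2's rates are scaled by the given ratios,
#' and simulates an ensemble for each condition.
#'
#' @param ratios_LH,ratios_HL multiplicative factors applied to `k1` to form
#'   state 2's L->H and H->L per-frame probabilities (typical benchmark range
#'   `0.125..8`).
#' @param n_traces traces per condition.
#' @param T_frames frames per trace.
#' @param gamma_dt interconversion probability per frame.
#' @param seed root seed; condition `i` uses `seed + i * 10^6` so the grid is
#'   reproducible condition-by-condition.
#' @return A list with one element per condition: `list(config, traces,
#'   ratio_LH, ratio_HL)`.
#' @export
simulate_benchmark_grid <- function(ratios_LH = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                                    ratios_HL = ratios_LH,
                                    n_traces = 100, T_frames = 8801,
                                    gamma_dt = 0.001, seed = 1) {
  if (length(ratios_LH) == 0 || length(ratios_HL) == 0)
    stop("empty grid", call. = FALSE)
  grid <- expand.grid(ratio_LH = ratios_LH, ratio_HL = ratios_HL)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- benchmark_config(k2 = c(0.05 * grid$ratio_LH[i],
                                   0.05 * grid$ratio_HL[i]),
                            gamma_dt = gamma_dt, T_frames = T_frames)
    out[[i]] <- list(config = cfg,
                     traces = simulate_dcmm_ensemble(cfg, n_traces,
                                                     seed = seed + i * 1000000L),
                     ratio_LH = grid$ratio_LH[i], ratio_HL = grid$ratio_HL[i])
  }
  out
}
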