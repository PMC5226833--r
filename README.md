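# vbdcmm

Variational-Bayes double-chain Markov models for single-molecule time
traces with **dynamic disorder** — trajectories whose apparent kinetics
switch between regimes because a hidden, slowly relaxing "internal state"
modulates the observable transition rates. The canonical example is smFRET
of conformational transitions (e.g. DNA duplex–triplex hopping between a
low-FRET ~0.1 and high-FRET ~0.9 level) in which the hopping rate changes
abruptly partway through a trace while the FRET levels do not.

## Who this is for

Single-molecule biophysicists (and anyone with one-dimensional
regime-switching time series) who want to

1. **idealize** a noisy trace into discrete observable states,
2. **decode** the hidden internal-state path and decide *how many* internal
   states the data support, and
3. **reconstruct** the connectivity of the underlying conformational
   landscape from an ensemble of traces.

## The model

An idealized observable sequence `o(1..T)` with `N` states and a hidden
internal path `x(1..T-1)` with `K` states form a double-chain Markov model:

- internal layer (homogeneous): `P(x(t+1)=ν | x(t)=μ) = A[μ,ν] = γ^(μ→ν) Δt`
- observable layer (slaved): `P(o(t+1)=b | o(t)=a, x(t)=μ) = B^(μ)[a,b] =
  k^(μ)_{a→b} Δt`

`dcmm()` fits the model for a fixed `K` by variational Bayes with Dirichlet
priors, maximizing an evidence lower bound `F ≤ log P(o | K)`;
`select_model()` scans `K` and ranks models by the label-degeneracy-corrected
evidence `G(K) = F(K) − log (K − K_obs)!`, where `K_obs` is the number of
internal states actually visited by the decoded (Viterbi) path. Downstream,
`decompose_trace()` cuts a decoded trace into homogeneous components,
`kinetic_arrows()` turns consecutive components into `2N(N−1)`-dimensional
log-rate vectors, and `select_clusters()` k-means-clusters these arrows and
picks the cluster count `K*` minimizing the antiparallel pairing score
`D(K)` — exploiting detailed balance: every inter-basin transition class has
a mirror-image reverse class.

Reliability without ground truth is scored by `d_conf()` (contrast between
the states' intra-basin rates, in bits), `d_int()` (time-scale separation
between intra- and inter-basin transitions), their combination
`D_tot = D_conf + 0.8 D_int`, and the dwell-time CV diagnostic
`dwell_cv()` (≈1 for a homogeneous Markov chain).

## Worked example

Simulate the canonical benchmark (two internal states sharing two FRET
levels: fast symmetric hopping at `kΔt = 0.05` in state 1, slow asymmetric
hopping `0.00625/0.025` in state 2, interconversion `γΔt = 0.001`), then
idealize, scan `K`, and score the decoded path:

```r
library(vbdcmm)
cfg  <- benchmark_config(T_frames = 4001)
tr   <- simulate_dcmm_trace(cfg, seed = 7)
id   <- idealize_trace(tr$o_n, N = 2, seed = 7)
scan <- select_model(id$o, K_max = 3, n_restarts = 5, seed = 7)
scan
#> Internal-state number selection
#>  K       F K_obs       G
#>  1 -340.73     1 -340.73
#>  2 -328.96     2 -328.96
#>  3 -334.00     2 -334.00
#> Selected K* = 2

perm <- match_labels(scan$fits[[scan$K_star]]$model$B, cfg$B)
overlap_chi(tr$x, scan$paths[[scan$K_star]], perm)
#> [1] 0.9945
```

The scan table reads: the evidence bound `F` rises sharply from one to two
internal states and falls again at three (whose decoded path anyway visits
only `K_obs = 2` labels), so `K* = 2` — the generating truth. The decoded
internal path then agrees with the true hidden path on 99.5% of frames.
`summary(scan$fits[[2]])` prints the recovered per-frame rate matrices
(here ≈0.066/0.049 for the fast state and ≈0.0034/0.029 for the slow one,
close to the generating values above) and each state's per-frame exit
probability.

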