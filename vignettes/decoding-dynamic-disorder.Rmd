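---
title: "Decoding dynamic disorder in single-molecule time traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding dynamic disorder in single-molecule time traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(vbdcmm)
```

## The problem

Long single-molecule FRET trajectories sometimes change their kinetic
character mid-trace: a molecule hopping between a low-FRET and a high-FRET
conformation at one rate abruptly continues hopping between the *same two
levels* at a very different rate. The FRET levels themselves carry no
signature of the change — what switched is a hidden kinetic regime, commonly
called an *internal state*, and the phenomenon is called *dynamic disorder*.
It arises when the conformational landscape has superbasins separated by
barriers much higher than the barriers within each basin, so the
interconversion time $\tau_{\mathrm{int}}$ far exceeds the intra-basin
relaxation time $\tau_{\mathrm{conf}}$.

This package decodes that hidden layer. It models an idealized observable
sequence $o = (o(1), \dots, o(T))$, $o(t) \in \{1..N\}$, together with a
hidden internal path $x = (x(1), \dots, x(T-1))$, $x(t) \in \{1..K\}$, as a
double-chain Markov model (DCMM):

* the internal chain is homogeneous with per-frame transition matrix
  $A_{\mu\nu} = \gamma^{(\mu)\to(\nu)}\Delta t$;
* the observable chain is non-homogeneous and slaved to the internal state:
  $P(o(t{+}1){=}b \mid o(t){=}a, x(t){=}\mu) = B^{(\mu)}_{ab}
  = k^{(\mu)}_{a\to b}\Delta t$.

All matrices hold per-frame transition *probabilities*, so every row sums
to one. The method requires a separation of time scales — the intra-basin
transition probability $k^{(\mu)}_{a\to b}\Delta t$ should be much larger
than the per-frame exit probability $\sum_{\nu \neq \mu}
\gamma^{(\mu)\to(\nu)}\Delta t$ — and distinct internal states must have
discernibly different intra-basin rates.

## Variational inference and model selection

For a candidate number of internal states $K$, `dcmm()` bounds the log
marginal likelihood (evidence)
$\log P(o \mid K) \ge F[q]$, with
$F[q] = \int q(Z) \log \{P(o, Z \mid K)/q(Z)\}\,dZ$ over hidden paths and
parameters $Z = (x, \pi, A, B)$. With independent Dirichlet priors on
$\pi$, the rows of $A$, and the rows of every $B^{(\mu)}$, the variational
update cycle is conjugate:

* **E-step** — a scaled forward–backward pass over the internal chain,
  using the exponentiated expected log-parameters of the current Dirichlet
  posteriors (sub-stochastic "geometric-mean" matrices, the standard
  variational treatment of hidden Markov chains). The evidence for
  $x(t) = \mu$ at step $t$ is the entry $B^{(\mu)}[o(t), o(t{+}1)]$.
* **M-step** — Dirichlet pseudocount updates from the chain posteriors
  (single-frame responsibilities and summed pair marginals).

$F$ is evaluated each iteration as the forward-pass log normalizer minus
the Dirichlet Kullback–Leibler penalties; it is non-decreasing by
construction and the fit stops when $|\Delta F| < 10^{-6}$ nats (or after
1000 iterations, flagged unconverged). A $+\log K!$ label-degeneracy term
is added to the converged bound. Point estimates are posterior means; the
most probable internal path comes from `viterbi_internal()` (ties broken
toward the lower state index).

Because a $K$-state fit often populates only $K_{\mathrm{obs}} \le K$
labels in its decoded path, the true labeling degeneracy is
$\binom{K}{K_{\mathrm{obs}}} K_{\mathrm{obs}}!$ rather than $K!$.
`select_model()` therefore ranks models by the corrected evidence

$$G(K) = F(K) - \log\,(K - K_{\mathrm{obs}})!$$

and returns $K^* = \arg\max_K G(K)$, with ties resolved toward the smaller
model. $G \le F$ always, with equality whenever
$K \le K_{\mathrm{obs}} + 1$.

### Priors

Rows of $A$ get Dirichlet pseudocounts (`u_a = 1` off-diagonal,
`u_ad = 100` diagonal). The large diagonal count is the one prior a user
should care about: it encodes the physical requirement that internal states
persist over many frames. Rows of $B$ and $\pi$ get flat pseudocounts
(`u_b = u_bd = u_pi = 1`); the fit is robust over wide ranges of these.
All are configurable through `dcmm_priors()`.

### Initialization and restarts

The variational objective is multimodal. Each fit runs `n_restarts`
initializations and keeps the highest converged bound. The first restart
is deterministic and informed: the trace is split into $K$ groups by local
observable-transition density (a running mean of the transition indicator),
which directly targets the structure dynamic disorder produces — we found
this reliably reaches the global optimum where random contiguous
segmentation (used for the remaining restarts, plus Dirichlet-style jitter
on the initial counts) can stall in label-duplicated local optima.

## Noise filtering

Raw FRET traces are real-valued and noisy. `fit_gaussian_hmm()` fits an
$N$-state hidden Markov model with per-state Gaussian emissions by
Baum–Welch (quantile-split initialization, relative log-likelihood
tolerance $10^{-6}$, at most 500 iterations, best of `n_restarts`) and
`viterbi_discretize()` produces the idealized sequence $o$, with states
numbered by ascending emission mean. $N$ is a user input; selecting $N$
automatically is outside the scope of this package. Fitting is per-trace.
Missing frames (e.g. zero total intensity in `compute_fret()`) are dropped
and the chain treats the gap as contiguous — the simplest defensible
choice, acceptable when gaps are rare and short. At the default benchmark
conditions (levels 0.1/0.9, noise s.d. 0.1, an 8-sigma separation)
idealization is essentially error-free; accuracy degrades once the level
separation falls below about 6 sigma.

## Accuracy and reliability metrics

With simulated ground truth, decoding accuracy is the frame-wise overlap
$\chi = \frac{1}{T-1}\sum_t \delta_{x(t),\,\hat x(t)}$ after matching
estimated to true labels by exhaustive permutation over the $B$ matrices
(`match_labels()`, $K \le 6$).

For real data, where $\chi$ is unavailable, two ratio-based scores predict
reliability from the fitted rates alone (per-frame probabilities can be
used directly since $\Delta t$ cancels):

* `d_conf()` — mean $|\log_2$ ratio$|$ of intra-basin rates across pairs of
  internal states (how different the kinetic regimes are);
* `d_int()` — mean $|\log_2(k^{(\mu)}_{a\to b} / \sum_{\nu\neq\mu}
  \gamma^{(\mu)\to(\nu)})|$ (how many intra-basin transitions occur per
  interconversion). An absorbing internal state is reported as a capped
  sentinel of 64 bits with a warning rather than infinity.

Their combination $D_{\mathrm{tot}} = D_{\mathrm{conf}} + 0.8\,
D_{\mathrm{int}}$ (empirical weight 0.8, configurable) predicts mean
$\chi$: decoded paths are trustworthy when $D_{\mathrm{tot}}$ is large
(roughly $\gtrsim 6$–7 for $\chi \gtrsim 0.9$ at the benchmark scale).
`dwell_cv()` offers a complementary diagnostic: dwell times of a
homogeneous Markov chain are geometric with coefficient of variation near
1, so per-component CVs well above 1 reveal residual heterogeneity
(a windowed variant over sliding blocks of 20 dwells is available).

## Components, kinetic arrows, and landscape clustering

A decoded trace is decomposed by `decompose_trace()` into maximal
constant-$x$ runs ("components"), each a homogeneous Markov interval.
Component rates are empirical transition counts with a $+0.5$ pseudocount
per cell, so rows stay stochastic and every rate is positive (log-rates
stay finite downstream); components shorter than `min_dwell = 10` frames
are flagged low-confidence rather than dropped, and boundary frames are
counted with their whole segment — the misassignments concentrated at
segment boundaries are small compared with component lengths under the
time-scale-separation assumption.

Individual traces rarely sample every internal state, so connectivity is an
ensemble question. Every adjacent pair of components with different labels
becomes a *kinetic arrow* (`kinetic_arrows()`): the $2N(N-1)$-vector of
log "before" rates followed by log "after" rates (natural log; the paper
base is immaterial since a base change rescales all distances uniformly and
cannot move an argmin). A middle component contributes to both its incoming
and outgoing arrow. At equilibrium, detailed balance makes every transition
class bidirectional: the reverse class is the *mirror* of the forward one
(before/after blocks swapped, `mirror_arrows()`, an involution).

`select_clusters()` k-means-clusters the arrows for each even candidate
count $K$ (`stats::kmeans`, squared-Euclidean, best of `n_init`
initializations; a city-block variant is provided as a robustness check),
then searches all $(K-1)!!$ perfect matchings of the centroids for the
antiparallel pairing minimizing
$D_c(K) = \frac{2}{K}\sum_{(i,j)} \lVert C^c_i - \tilde C^c_j \rVert^2$,
and scores the matched clustering at element level,
$D(K) = \frac{2}{K}\sum_{(i,j)} \langle d_{ij} \rangle$ with
$\langle d_{ij}\rangle$ the mean distance between elements of cluster $i$
and mirrored elements of cluster $j$. The selected $K^*$ minimizes $D(K)$
among solutions whose clusters all hold at least `min_cluster_size = 10`
arrows — without the size rule, a large $K$ with fragmented clusters can
undercut $D$ spuriously. `landscape_graph()` renders the matched pairs as
bidirectional kinetic paths between basins and flags a pair whose before-
and after-blocks coincide as a suspicious self-loop.

The default `n_init = 200` gives stable selections at the ensemble sizes
used here; for publication-grade runs on real data, raising it toward
$2\times 10^4$ matches common practice.

## The synthetic-data generator

`simulate_dcmm_trace()` reproduces the generative process the model
assumes: a homogeneous internal chain (`sim_chain`, Monte Carlo with a
constant transition matrix), an observable chain whose per-frame matrix is
re-selected by the current internal state, and i.i.d. Gaussian noise around
per-state signal levels. Initial states are drawn uniformly ($x(1)$ from
`pi`, default uniform; $o(1)$ uniform over $1..N$) — the generative
description leaves initial conditions open, and with
$T \gg \tau_{\mathrm{int}}$ they are immaterial. One root seed governs an
ensemble, with per-trace streams at fixed offsets so single traces can be
regenerated independently.

Two benchmark constructors pin down the study conditions:

* `benchmark_config()` — the canonical two-internal-state condition:
  $k^{(1)}_{L\to H}\Delta t = k^{(1)}_{H\to L}\Delta t = 0.05$,
  $k^{(2)}_{L\to H}\Delta t = 0.00625$, $k^{(2)}_{H\to L}\Delta t = 0.025$,
  $\gamma\Delta t = 0.001$ both ways, $T = 8801$ frames at 10 Hz, FRET
  levels 0.1/0.9. The noise s.d. defaults to 0.1, a value chosen once as
  visually and statistically representative of smFRET benchmarks (the
  generative description does not state one); it leaves the levels
  separated by 8 sigma and is configurable.
* `clustering_benchmark_config()` — the landscape benchmark with $K = 4$
  internal and $N = 4$ observable states. Internal states differ by a
  binary high/low pattern (0.1 vs 0.025 per frame, a four-fold contrast
  per cell) over the twelve off-diagonal cells, with distinct states
  differing in at least half the cells; interconversion is uniform at
  $4\times 10^{-4}$ per frame per ordered pair and $T = 16001$. These
  values were fixed at design time by two requirements: each component
  (mean length $\approx 830$ frames) must contain enough observable
  transitions that its rate estimates resolve the four-fold contrast, and
  each trace must interconvert often enough ($\sim 15$ switches) that the
  evidence justifies all four states. An earlier scalar-ladder design
  (all rates in a state scaled by a common factor) fails the first
  requirement for the slowest state and is genuinely undecodable at this
  trace length — a useful reminder that "rates differ four-fold" must hold
  per transition with adequate counts, not merely on average.

What the simulator deliberately omits: photophysics (donor/acceptor
blinking, bleaching), photon-arrival statistics, baseline drift, and
non-Gaussian noise. Passing benchmarks therefore demonstrate correctness
of the inference given the model's assumptions, not robustness to every
experimental artifact.

## Benchmark scales and expected results

The package's own acceptance scales, chosen to keep a complete run on one
CPU comfortable while preserving the statistics:

* overlap benchmarks: 100 traces of $T = 8801$ per condition (a 25-trace
  quick mode agrees with the full mean within $\pm 0.05$); expected mean
  $\chi \approx 0.93$–0.94 at the canonical condition, $> 0.9$ whenever
  the two states' rates differ by a factor $\ge 4$;
* model selection: the evidence bound is maximized at $K = 2$ for
  essentially every benchmark trace ($K = 1$ homogeneous controls select
  $K = 1$ by majority);
* dwell-time diagnostic: a homogeneous two-state chain with $> 1000$
  completed dwells gives CV $= 1 \pm 0.1$ (the exact geometric value at
  switch probability 0.05 is $\sqrt{1 - 0.05} \approx 0.975$);
* landscape clustering: 24 traces of the four-state ensemble give roughly
  390 arrows (every directed path represented more than 10 times), and
  $D(K)$ over even $K \in [2, 14]$ is minimized at $K^* = 12$ — the twelve
  directed connection paths among four internal states — with the $K = 14$
  solution excluded by the minimum-cluster-size rule.

```{r quick-example}
cfg <- benchmark_config(T_frames = 4001)
tr <- simulate_dcmm_trace(cfg, seed = 7)
id <- idealize_trace(tr$o_n, N = 2, seed = 7)
scan <- select_model(id$o, K_max = 3, n_restarts = 5, seed = 7)
scan
perm <- match_labels(scan$fits[[scan$K_star]]$model$B, cfg$B)
overlap_chi(tr$x, scan$paths[[scan$K_star]], perm)
```

## Numerical choices and degenerate inputs

* Forward–backward uses per-step scaling (not logs) and is safe for traces
  up to $10^6$ frames; an all-zero emission column raises an error naming
  the frame.
* Gaussian emission densities are floored at $10^{-300}$ to survive
  outlier frames; emission standard deviations are floored at
  $\max(10^{-4}, 10^{-4}\,\mathrm{range})$ so noiseless input cannot
  produce a singular likelihood.
* A Gaussian-HMM restart whose state occupancy collapses below one frame
  is discarded with a warning; if all restarts collapse, the fit errors
  and asks the user to reconsider $N$.
* Odd cluster counts are rejected (antiparallel pairing needs an even
  $K$); an empty k-means cluster under the L1 metric is re-seeded with the
  farthest point.
* Label matching beyond $K = 6$ would need $> 720$ permutations and is
  refused; when decoded and reference $K$ differ, `run_pipeline()` falls
  back to unmatched overlap.

## Known limitations

* Decoding requires both time-scale separation and rate contrast; when
  $D_{\mathrm{tot}}$ is small the evidence legitimately favors fewer
  internal states than the truth, and a state visited once for a short
  interval may be absorbed into its nearest regime.
* Each trace is fit independently; pooling statistical strength across an
  ensemble (joint or empirical-Bayes fitting) is out of scope, as are
  MCMC posterior sampling, covariate-driven switching, automatic selection
  of $N$, and photon-level emission models.
* The evidence reported is the converged variational bound, not the exact
  marginal likelihood; comparisons across $K$ inherit the usual variational
  bias toward simpler models when data are scarce.
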