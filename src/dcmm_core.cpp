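#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a hidden chain with T steps, K states.
// pi (K), A (K x K) may be sub-stochastic (variational geometric-mean
// parameters); emis is T x K with emis(t, k) = evidence for state k at step t.
// Returns per-step posteriors gamma (T x K), summed pairwise posteriors
// xi (K x K, summed over the T-1 transitions), and the log normalizer
// (log of the total path weight).
// [[Rcpp::export]]
List fb_scaled(NumericVector pi, NumericMatrix A, NumericMatrix emis) {
  const int T = emis.nrow(), K = emis.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector c(T);
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = pi[k] * emis(0, k);
    s += alpha(0, k);
  }
  if (s <= 0.0) stop("all-zero emission column at frame 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = a * emis(t, k);
      s += alpha(t, k);
    }
    if (s <= 0.0) stop("all-zero emission column at frame %d", t + 1);
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(k, j) * emis(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / c[t + 1];
    }
  }
  NumericMatrix xi(K, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * A(j, k) * emis(t + 1, k) * beta(t + 1, k) / c[t + 1];
  }
  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}

// Log-space Viterbi; ties broken toward the lower state index.
// Returns 1-based most probable state path of length T.
// [[Rcpp::export]]
IntegerVector viterbi_path(NumericVector logpi, NumericMatrix logA,
                           NumericMatrix logemis) {
  const int T = logemis.nrow(), K = logemis.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logemis(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + logA(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logemis(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = delta(T - 1, 0);
  int arg = 0;
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}

static int draw_state(const NumericMatrix& P, int row, int K) {
  double u = R::unif_rand(), acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += P(row, k);
    if (u <= acc) return k;
  }
  return K - 1;  // guard against rounding
}

// Homogeneous Markov chain of length T (1-based states); uses R's RNG.
// [[Rcpp::export]]
IntegerVector sim_chain(NumericVector pi, NumericMatrix A, int T) {
  const int K = A.ncol();
  IntegerVector x(T);
  RNGScope scope;
  double u = R::unif_rand(), acc = 0.0;
  int cur = K - 1;
  for (int k = 0; k < K; ++k) {
    acc += pi[k];
    if (u <= acc) { cur = k; break; }
  }
  x[0] = cur + 1;
  for (int t = 1; t < T; ++t) {
    cur = draw_state(A, cur, K);
    x[t] = cur + 1;
  }
  return x;
}

// Observable chain slaved to the internal path: o(t+1) ~ row o(t) of B[[x(t)]].
// x is 1-based of length T-1; o1 is the 1-based initial observable.
// [[Rcpp::export]]
IntegerVector sim_slaved_chain(IntegerVector x, List B, int o1) {
  const int T = x.size() + 1;
  IntegerVector o(T);
  RNGScope scope;
  o[0] = o1;
  int cur = o1 - 1;
  for (int t = 0; t < T - 1; ++t) {
    NumericMatrix Bm = B[x[t] - 1];
    cur = draw_state(Bm, cur, Bm.ncol());
    o[t + 1] = cur + 1;
  }
  return o;
}
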