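#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Noise-contrastive training of node embeddings against a precomputed graph
// similarity distribution. One shared embedding matrix; per step: draw a
// source node u uniformly, a positive v from sim_G(u,.) (inverse-CDF on the
// row cumsum), and s uniform negatives; take one gradient step on
// log sigma(w_u.w_v) + sum log(1 - sigma(w_u.w_neg)).
//
// All randomness comes from R's RNG (unif_rand), so results are reproducible
// under set.seed() and can be replayed exactly by an R-level reference loop.

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }
// log sigma(x), numerically stable
static inline double log_sigmoid(double x) {
  return (x >= 0) ? -std::log1p(std::exp(-x)) : x - std::log1p(std::exp(x));
}

static inline int draw_uniform_node(int n) {
  int u = (int)(n * unif_rand());
  return (u >= n) ? n - 1 : u;
}

// first index with cum[idx] >= x (0-based)
static inline int draw_from_cum(const double* cum, int n) {
  double x = unif_rand();
  const double* it = std::lower_bound(cum, cum + n, x);
  int idx = (int)(it - cum);
  return (idx >= n) ? n - 1 : idx;
}

static double pair_loss(const NumericMatrix& W, int u, int v,
                        const std::vector<int>& negs, int s0, int s) {
  int d = W.ncol();
  double dot = 0.0;
  for (int t = 0; t < d; ++t) dot += W(u, t) * W(v, t);
  double loss = -log_sigmoid(dot);
  for (int q = 0; q < s; ++q) {
    int vn = negs[s0 + q];
    double dn = 0.0;
    for (int t = 0; t < d; ++t) dn += W(u, t) * W(vn, t);
    loss -= log_sigmoid(-dn); // log(1 - sigma(x)) = log sigma(-x)
  }
  return loss;
}

// [[Rcpp::export]]
List nce_train_cpp(NumericMatrix W0, NumericMatrix cum_t, int steps, int s,
                   double lr_start, double lr_end, int n_probe,
                   int n_checkpoints) {
  // cum_t: row cumsums of sim_G, transposed so that column u is contiguous
  int n = W0.nrow(), d = W0.ncol();
  NumericMatrix W = clone(W0);

  // fixed Monte-Carlo probe set for the loss trajectory, drawn up front
  std::vector<int> pu(n_probe), pv(n_probe), pneg(n_probe * s);
  for (int p = 0; p < n_probe; ++p) {
    pu[p] = draw_uniform_node(n);
    pv[p] = draw_from_cum(&cum_t(0, pu[p]), n);
    for (int q = 0; q < s; ++q) pneg[p * s + q] = draw_uniform_node(n);
  }
  auto probe_loss = [&]() {
    double tot = 0.0;
    for (int p = 0; p < n_probe; ++p)
      tot += pair_loss(W, pu[p], pv[p], pneg, p * s, s);
    return tot / n_probe;
  };

  if (n_checkpoints < 2) n_checkpoints = 2;
  std::vector<int> ck(n_checkpoints);
  for (int c = 0; c < n_checkpoints; ++c)
    ck[c] = (int)std::lround((double)steps * c / (n_checkpoints - 1));
  NumericVector losses(n_checkpoints);
  IntegerVector ck_steps(n_checkpoints);
  int next_ck = 0;
  if (ck[0] == 0) { losses[0] = probe_loss(); ck_steps[0] = 0; next_ck = 1; }

  std::vector<double> gu(d);
  std::vector<int> negs(s);
  for (int t = 0; t < steps; ++t) {
    double lr = (steps > 1)
      ? lr_start + (lr_end - lr_start) * ((double)t / (steps - 1))
      : lr_start;
    int u = draw_uniform_node(n);
    int v = draw_from_cum(&cum_t(0, u), n);
    for (int q = 0; q < s; ++q) negs[q] = draw_uniform_node(n);

    // gradients at the current point, applied simultaneously
    double dpos = 0.0;
    for (int j = 0; j < d; ++j) dpos += W(u, j) * W(v, j);
    double gpos = 1.0 - sigmoid(dpos);
    for (int j = 0; j < d; ++j) gu[j] = gpos * W(v, j);
    std::vector<double> gneg(s);
    for (int q = 0; q < s; ++q) {
      int vn = negs[q];
      double dn = 0.0;
      for (int j = 0; j < d; ++j) dn += W(u, j) * W(vn, j);
      gneg[q] = -sigmoid(dn);
      for (int j = 0; j < d; ++j) gu[j] += gneg[q] * W(vn, j);
    }
    for (int q = 0; q < s; ++q) {
      int vn = negs[q];
      for (int j = 0; j < d; ++j) W(vn, j) += lr * gneg[q] * W(u, j);
    }
    for (int j = 0; j < d; ++j) W(v, j) += lr * gpos * W(u, j);
    for (int j = 0; j < d; ++j) W(u, j) += lr * gu[j];

    while (next_ck < n_checkpoints && t + 1 == ck[next_ck]) {
      losses[next_ck] = probe_loss();
      ck_steps[next_ck] = t + 1;
      ++next_ck;
    }
  }
  while (next_ck < n_checkpoints) { // steps too small for distinct checkpoints
    losses[next_ck] = probe_loss();
    ck_steps[next_ck] = steps;
    ++next_ck;
  }
  return List::create(_["embedding"] = W, _["checkpoint"] = ck_steps,
                      _["loss"] = losses);
}
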