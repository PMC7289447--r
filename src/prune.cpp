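#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning along a postorder edge list.
//
// Two transition-probability modes:
//   mode = 0: general reversible chain, P(t) = V diag(exp(lambda * rate * t)) Vinv
//             (V, Vinv, lambda from a symmetrized eigendecomposition of Q).
//             Only the action P %*% v is needed, so each edge costs O(N^2).
//   mode = 1: N-state symmetric exchangeable chain normalized to one expected
//             substitution per unit time; closed form
//             P_ij(t) = 1/N + (delta_ij - 1/N) * exp(-N rate t / (N-1)).
//
// edge is the 2-column (parent, child) matrix in postorder (children before
// parents), 1-based as in ape. leaf_state[i] in 1..N, or 0 for missing/gap.
// Per-edge scaling keeps partial likelihoods in range; the log scale factors
// are accumulated into the returned log-likelihood.

// [[Rcpp::export]]
double c_prune_loglik(IntegerMatrix edge, NumericVector edge_len,
                      int n_tip, int n_node,
                      IntegerVector leaf_state, int mode, int N,
                      NumericMatrix V, NumericMatrix Vinv,
                      NumericVector lambda, NumericVector root_pi,
                      double rate, int root) {
  std::vector<double> L(static_cast<size_t>(N) * n_node, 1.0);
  std::vector<bool> touched(n_node, false);
  std::vector<double> v(N), w(N);
  double log_scale = 0.0;

  int n_edge = edge.nrow();
  for (int e = 0; e < n_edge; ++e) {
    int parent = edge(e, 0) - 1;
    int child  = edge(e, 1) - 1;
    double t = edge_len[e] * rate;

    if (child < n_tip && leaf_state[child] == 0) {
      // missing observation: P %*% 1 = 1, contributes nothing
      continue;
    }

    if (mode == 1) {
      double eb = std::exp(-static_cast<double>(N) * t / (N - 1.0));
      if (child < n_tip) {
        int s = leaf_state[child] - 1;
        double off = (1.0 - eb) / N;
        for (int i = 0; i < N; ++i) v[i] = off + (i == s ? eb : 0.0);
      } else {
        double *Lc = &L[static_cast<size_t>(N) * child];
        double sum = 0.0;
        for (int i = 0; i < N; ++i) sum += Lc[i];
        double off = (1.0 - eb) * sum / N;
        for (int i = 0; i < N; ++i) v[i] = off + eb * Lc[i];
      }
    } else {
      // w = exp(lambda t) * (Vinv %*% Lchild); v = V %*% w
      if (child < n_tip) {
        int s = leaf_state[child] - 1;
        for (int i = 0; i < N; ++i) w[i] = std::exp(lambda[i] * t) * Vinv(i, s);
      } else {
        double *Lc = &L[static_cast<size_t>(N) * child];
        for (int i = 0; i < N; ++i) {
          double acc = 0.0;
          for (int j = 0; j < N; ++j) acc += Vinv(i, j) * Lc[j];
          w[i] = std::exp(lambda[i] * t) * acc;
        }
      }
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (int j = 0; j < N; ++j) acc += V(i, j) * w[j];
        v[i] = acc;
      }
    }

    double m = 0.0;
    for (int i = 0; i < N; ++i) {
      if (v[i] < 0.0 && v[i] > -1e-14) v[i] = 0.0;  // clip tiny negatives
      if (v[i] > m) m = v[i];
    }
    if (m <= 0.0) return R_NegInf;
    log_scale += std::log(m);

    double *Lp = &L[static_cast<size_t>(N) * parent];
    for (int i = 0; i < N; ++i) Lp[i] *= v[i] / m;
    touched[parent] = true;
  }

  int r = root - 1;
  double lik = 0.0;
  double *Lr = &L[static_cast<size_t>(N) * r];
  if (!touched[r]) {
    // every tip missing: likelihood 1
    return 0.0;
  }
  for (int i = 0; i < N; ++i) lik += root_pi[i] * Lr[i];
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + log_scale;
}
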