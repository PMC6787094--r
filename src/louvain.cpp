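#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One run of the Louvain greedy algorithm for signed, weighted, undirected
// networks with the asymmetric two-term quality function
//   Q = (1/v+) sum_ij (w+_ij - g e+_ij) d_ij  -  (1/(v+ + v-)) sum_ij (w-_ij - g e-_ij) d_ij
// where e+-_ij = s+-_i s+-_j / v+- (strength-product chance term, summed over
// all node pairs including i == j) and d_ij indicates co-assignment.
// Node sweep order is randomised with R's RNG so repeated runs explore
// different local optima under set.seed().

static void shuffle_order(std::vector<int> &ord) {
  const int n = (int)ord.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
}

// Local node-moving phase on a (possibly aggregated) matrix with self-loops.
// Returns true if any move improved Q.
static bool local_phase(const std::vector<double> &Wp, const std::vector<double> &Wn,
                        int n, double vp, double vn, double gamma,
                        std::vector<int> &comm) {
  std::vector<double> kp(n, 0.0), kn(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      kp[i] += Wp[(size_t)i * n + j];
      kn[i] += Wn[(size_t)i * n + j];
    }
  std::vector<double> Sp(n, 0.0), Sn(n, 0.0);  // community strength sums
  for (int i = 0; i < n; ++i) {
    Sp[comm[i]] += kp[i];
    Sn[comm[i]] += kn[i];
  }
  std::vector<double> conp(n, 0.0), conn_(n, 0.0);  // links of u into each community
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  const double inv_vp = vp > 0 ? 1.0 / vp : 0.0;
  const double inv_tot = (vp + vn) > 0 ? 1.0 / (vp + vn) : 0.0;
  bool improved_any = false, improved = true;
  int guard = 0;
  while (improved && ++guard <= 100) {
    improved = false;
    shuffle_order(ord);
    for (int oi = 0; oi < n; ++oi) {
      const int u = ord[oi];
      const int cu = comm[u];
      std::fill(conp.begin(), conp.end(), 0.0);
      std::fill(conn_.begin(), conn_.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        if (j == u) continue;
        conp[comm[j]] += Wp[(size_t)u * n + j];
        conn_[comm[j]] += Wn[(size_t)u * n + j];
      }
      // gain of moving u from cu to c, relative to staying; one empty
      // community is also considered so nodes can re-isolate (matters for
      // nodes with predominantly negative ties)
      double best_gain = 1e-10;
      int best_c = cu;
      int empty_c = -1;
      for (int c = 0; c < n; ++c) {
        if (c == cu) continue;
        if (Sp[c] == 0.0 && Sn[c] == 0.0 && conp[c] == 0.0 && conn_[c] == 0.0) {
          if (empty_c < 0) empty_c = c;
          continue;  // evaluated once after the loop
        }
        double dqp = 0.0, dqn = 0.0;
        if (vp > 0)
          dqp = (conp[c] - conp[cu] -
                 gamma * kp[u] * (Sp[c] - (Sp[cu] - kp[u])) * inv_vp) * inv_vp;
        if (vn > 0)
          dqn = (conn_[c] - conn_[cu] -
                 gamma * kn[u] * (Sn[c] - (Sn[cu] - kn[u])) / vn) * inv_tot;
        double gain = 2.0 * (dqp - dqn);
        if (gain > best_gain) {
          best_gain = gain;
          best_c = c;
        }
      }
      if (empty_c >= 0 && (Sp[cu] > kp[u] || Sn[cu] > kn[u])) {
        double dqp = 0.0, dqn = 0.0;
        if (vp > 0)
          dqp = (-conp[cu] + gamma * kp[u] * (Sp[cu] - kp[u]) * inv_vp) * inv_vp;
        if (vn > 0)
          dqn = (-conn_[cu] + gamma * kn[u] * (Sn[cu] - kn[u]) / vn) * inv_tot;
        double gain = 2.0 * (dqp - dqn);
        if (gain > best_gain) {
          best_gain = gain;
          best_c = empty_c;
        }
      }
      if (best_c != cu) {
        Sp[cu] -= kp[u]; Sn[cu] -= kn[u];
        Sp[best_c] += kp[u]; Sn[best_c] += kn[u];
        comm[u] = best_c;
        improved = true;
        improved_any = true;
      }
    }
  }
  return improved_any;
}

// [[Rcpp::export(name = ".louvainOnce")]]
IntegerVector louvain_once(NumericMatrix W, double gamma) {
  const int N = W.nrow();
  std::vector<double> Wp((size_t)N * N), Wn((size_t)N * N);
  double vp = 0.0, vn = 0.0;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) {
      double w = (i == j) ? 0.0 : W(i, j);
      double p = w > 0 ? w : 0.0, q = w < 0 ? -w : 0.0;
      Wp[(size_t)i * N + j] = p;
      Wn[(size_t)i * N + j] = q;
      vp += p; vn += q;
    }

  std::vector<int> node2final(N);
  for (int i = 0; i < N; ++i) node2final[i] = i;

  int n = N;
  std::vector<double> Ap = Wp, An = Wn;
  bool keep_going = true;
  while (keep_going && n > 1) {
    std::vector<int> comm(n);
    for (int i = 0; i < n; ++i) comm[i] = i;
    bool improved = local_phase(Ap, An, n, vp, vn, gamma, comm);
    // relabel communities contiguously
    std::vector<int> map(n, -1);
    int nc = 0;
    for (int i = 0; i < n; ++i)
      if (map[comm[i]] < 0) map[comm[i]] = nc++;
    for (int i = 0; i < n; ++i) comm[i] = map[comm[i]];
    // propagate to original nodes
    for (int i = 0; i < N; ++i) node2final[i] = comm[node2final[i]];
    if (!improved || nc == n) {
      keep_going = false;
    } else {
      // aggregate
      std::vector<double> Bp((size_t)nc * nc, 0.0), Bn((size_t)nc * nc, 0.0);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) {
          Bp[(size_t)comm[i] * nc + comm[j]] += Ap[(size_t)i * n + j];
          Bn[(size_t)comm[i] * nc + comm[j]] += An[(size_t)i * n + j];
        }
      Ap.swap(Bp); An.swap(Bn);
      n = nc;
    }
  }

  IntegerVector out(N);
  for (int i = 0; i < N; ++i) out[i] = node2final[i] + 1;
  return out;
}

// Direct evaluation of the signed asymmetric Q for an assignment (1-based).
static double signed_q(NumericMatrix W, const IntegerVector &comm, double gamma) {
  const int N = W.nrow();
  double vp = 0.0, vn = 0.0;
  std::vector<double> sp(N, 0.0), sn(N, 0.0);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) {
      if (i == j) continue;
      double w = W(i, j);
      if (w > 0) { sp[i] += w; vp += w; } else { sn[i] -= w; vn -= w; }
    }
  int nc = 0;
  for (int i = 0; i < N; ++i) nc = std::max(nc, (int)comm[i]);
  std::vector<double> Sp(nc, 0.0), Sn(nc, 0.0);
  double win_p = 0.0, win_n = 0.0;
  for (int i = 0; i < N; ++i) {
    Sp[comm[i] - 1] += sp[i];
    Sn[comm[i] - 1] += sn[i];
    for (int j = 0; j < N; ++j) {
      if (i == j || comm[i] != comm[j]) continue;
      double w = W(i, j);
      if (w > 0) win_p += w; else win_n -= w;
    }
  }
  double ep = 0.0, en = 0.0;
  for (int c = 0; c < nc; ++c) { ep += Sp[c] * Sp[c]; en += Sn[c] * Sn[c]; }
  double Qp = vp > 0 ? (win_p - gamma * ep / vp) / vp : 0.0;
  double Qn = vn > 0 ? (win_n - gamma * en / vn) : 0.0;
  return Qp - ((vp + vn) > 0 ? Qn / (vp + vn) : 0.0);
}

// Best of n_repeats Louvain runs by Q (ties keep the first occurrence).
// [[Rcpp::export(name = ".louvainBest")]]
List louvain_best(NumericMatrix W, double gamma, int n_repeats) {
  IntegerVector best;
  double bestQ = R_NegInf;
  for (int r = 0; r < n_repeats; ++r) {
    IntegerVector a = louvain_once(W, gamma);
    double q = signed_q(W, a, gamma);
    if (q > bestQ + 1e-12) {
      bestQ = q;
      best = a;
    }
  }
  return List::create(_["assignment"] = best, _["q"] = bestQ);
}
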