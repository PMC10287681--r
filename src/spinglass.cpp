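#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Signed-modularity optimisation by simulated annealing with single-node
// moves. Objective (gamma_pos = gamma_neg = 1 by default):
//   Q = sh_pos * Qpos - sh_neg * Qneg
// where Qpos/Qneg are Newman-Girvan weighted modularities of the positive
// and |negative| subgraphs and sh_pos/sh_neg their total-strength shares.
// Uses R's RNG so results are reproducible under set.seed().

struct Graph {
  int n;
  std::vector<std::vector<int> > nbr;
  std::vector<std::vector<double> > w;
  std::vector<double> kpos, kneg; // signed strengths per node
  double A, B;                    // 2*w_pos, 2*w_neg
};

static double total_q(const Graph &g, const std::vector<int> &lab,
                      double gpos, double gneg) {
  int n = g.n;
  std::vector<double> Spos(n, 0.0), Sneg(n, 0.0), Epos(n, 0.0), Eneg(n, 0.0);
  for (int i = 0; i < n; ++i) {
    Spos[lab[i]] += g.kpos[i];
    Sneg[lab[i]] += g.kneg[i];
    for (size_t t = 0; t < g.nbr[i].size(); ++t) {
      int j = g.nbr[i][t];
      if (lab[j] == lab[i]) {
        double ww = g.w[i][t];
        if (ww > 0) Epos[lab[i]] += ww; else Eneg[lab[i]] -= ww;
      }
    }
  }
  double qpos = 0.0, qneg = 0.0;
  for (int c = 0; c < n; ++c) {
    if (g.A > 0) qpos += Epos[c] / g.A - gpos * (Spos[c] / g.A) * (Spos[c] / g.A);
    if (g.B > 0) qneg += Eneg[c] / g.B - gneg * (Sneg[c] / g.B) * (Sneg[c] / g.B);
  }
  double tot = g.A + g.B;
  if (tot <= 0) return 0.0;
  return (g.A / tot) * qpos - (g.B / tot) * qneg;
}

// links of node i into cluster c (positive and |negative| sums)
static inline void links_to(const Graph &g, const std::vector<int> &lab,
                            int i, int c, double &lpos, double &lneg) {
  lpos = 0.0; lneg = 0.0;
  for (size_t t = 0; t < g.nbr[i].size(); ++t) {
    if (lab[g.nbr[i][t]] == c) {
      double ww = g.w[i][t];
      if (ww > 0) lpos += ww; else lneg -= ww;
    }
  }
}

static double delta_q(const Graph &g, const std::vector<int> &lab,
                      const std::vector<double> &Spos,
                      const std::vector<double> &Sneg,
                      int i, int a, int b, double gpos, double gneg) {
  // move i from cluster a to b (a != b)
  double lpa, lna, lpb, lnb;
  links_to(g, lab, i, a, lpa, lna);
  links_to(g, lab, i, b, lpb, lnb);
  double tot = g.A + g.B;
  double d = 0.0;
  if (g.A > 0) {
    double dpos = 2.0 * (lpb - lpa) / g.A
      - gpos * (2.0 * g.kpos[i] * (Spos[b] - Spos[a] + g.kpos[i])) / (g.A * g.A);
    d += (g.A / tot) * dpos;
  }
  if (g.B > 0) {
    double dneg = 2.0 * (lnb - lna) / g.B
      - gneg * (2.0 * g.kneg[i] * (Sneg[b] - Sneg[a] + g.kneg[i])) / (g.B * g.B);
    d -= (g.B / tot) * dneg;
  }
  return d;
}

// [[Rcpp::export(name = ".anneal_signed_modularity")]]
List anneal_signed_modularity(int n, IntegerVector ei, IntegerVector ej,
                              NumericVector ew, double gamma_pos,
                              double gamma_neg, int n_restarts,
                              int sweeps_per_temp, double t0, double t_min,
                              double cooling) {
  Graph g;
  g.n = n;
  g.nbr.assign(n, std::vector<int>());
  g.w.assign(n, std::vector<double>());
  g.kpos.assign(n, 0.0);
  g.kneg.assign(n, 0.0);
  g.A = 0.0; g.B = 0.0;
  for (int e = 0; e < ei.size(); ++e) {
    int i = ei[e] - 1, j = ej[e] - 1;
    double ww = ew[e];
    g.nbr[i].push_back(j); g.w[i].push_back(ww);
    g.nbr[j].push_back(i); g.w[j].push_back(ww);
    if (ww > 0) { g.kpos[i] += ww; g.kpos[j] += ww; g.A += 2.0 * ww; }
    else        { g.kneg[i] -= ww; g.kneg[j] -= ww; g.B -= 2.0 * ww; }
  }

  std::vector<int> best_lab(n);
  double best_q = R_NegInf;

  for (int r = 0; r < n_restarts; ++r) {
    std::vector<int> lab(n);
    // random initial labels from a modest palette, plus all-singletons on
    // the first restart (helps sparse graphs)
    if (r == 0) {
      for (int i = 0; i < n; ++i) lab[i] = i;
    } else {
      int k0 = n < 25 ? n : 25;
      for (int i = 0; i < n; ++i) lab[i] = (int)(unif_rand() * k0);
    }
    std::vector<double> Spos(n, 0.0), Sneg(n, 0.0);
    for (int i = 0; i < n; ++i) { Spos[lab[i]] += g.kpos[i]; Sneg[lab[i]] += g.kneg[i]; }

    for (double T = t0; T > t_min; T *= cooling) {
      int props = sweeps_per_temp * n;
      for (int s = 0; s < props; ++s) {
        int i = (int)(unif_rand() * n);
        if (i >= n) i = n - 1;
        int b;
        if (!g.nbr[i].empty() && unif_rand() < 0.8) {
          int t = (int)(unif_rand() * g.nbr[i].size());
          b = lab[g.nbr[i][t]];
        } else {
          b = (int)(unif_rand() * n);
          if (b >= n) b = n - 1;
        }
        int a = lab[i];
        if (a == b) continue;
        double d = delta_q(g, lab, Spos, Sneg, i, a, b, gamma_pos, gamma_neg);
        if (d > 0 || unif_rand() < std::exp(d / T)) {
          lab[i] = b;
          Spos[a] -= g.kpos[i]; Spos[b] += g.kpos[i];
          Sneg[a] -= g.kneg[i]; Sneg[b] += g.kneg[i];
        }
      }
    }

    // greedy polish: accept only improving single-node moves until a local
    // optimum over the full move set (all target clusters) is reached
    bool improved = true;
    int guard = 0;
    while (improved && guard++ < 200) {
      improved = false;
      for (int i = 0; i < n; ++i) {
        int a = lab[i];
        // candidate targets: clusters of neighbours plus one empty label
        std::vector<int> cand;
        for (size_t t = 0; t < g.nbr[i].size(); ++t) cand.push_back(lab[g.nbr[i][t]]);
        std::vector<char> used(n, 0);
        for (int j = 0; j < n; ++j) used[lab[j]] = 1;
        for (int c = 0; c < n; ++c) if (!used[c]) { cand.push_back(c); break; }
        double bestd = 1e-12; int bestb = a;
        for (size_t t = 0; t < cand.size(); ++t) {
          int b = cand[t];
          if (b == a) continue;
          double d = delta_q(g, lab, Spos, Sneg, i, a, b, gamma_pos, gamma_neg);
          if (d > bestd) { bestd = d; bestb = b; }
        }
        if (bestb != a) {
          lab[i] = bestb;
          Spos[a] -= g.kpos[i]; Spos[bestb] += g.kpos[i];
          Sneg[a] -= g.kneg[i]; Sneg[bestb] += g.kneg[i];
          improved = true;
        }
      }
    }

    double q = total_q(g, lab, gamma_pos, gamma_neg);
    if (q > best_q) { best_q = q; best_lab = lab; }
  }

  // compact labels to 1..k in order of first appearance
  std::vector<int> remap(n, -1);
  int next = 0;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (remap[best_lab[i]] < 0) remap[best_lab[i]] = next++;
    out[i] = remap[best_lab[i]] + 1;
  }
  return List::create(_["membership"] = out, _["Q"] = best_q);
}
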