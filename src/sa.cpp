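#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Simulated-annealing modularity maximization.
//
// State: membership label per node (labels 0..n-1, reusable), per-label
// internal edge count l[s], degree sum ks[s] and member list. Single-node
// reassignments (to an existing or an empty label) plus collective merge /
// random-bisection moves, Metropolis-accepted. Uses R's RNG so runs are
// reproducible under set.seed().

static inline int rand_int(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// [[Rcpp::export(name = ".sa_partition_cpp")]]
List sa_partition_cpp(int n, IntegerMatrix edges, double t0, double cooling,
                      double moves_factor, double t_min) {
  int L = edges.nrow();
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < L; ++i) {
    adj[edges(i, 0)].push_back(edges(i, 1));
    adj[edges(i, 1)].push_back(edges(i, 0));
  }
  std::vector<double> deg(n);
  for (int v = 0; v < n; ++v) deg[v] = (double)adj[v].size();

  std::vector<int> mem(n), l(n, 0);
  std::vector<double> ks(n, 0.0);
  std::vector<std::vector<int>> members(n);
  std::vector<int> active, active_pos(n, -1), freelab;
  for (int v = 0; v < n; ++v) {
    mem[v] = v;
    ks[v] = deg[v];
    members[v].push_back(v);
    active_pos[v] = (int)active.size();
    active.push_back(v);
  }
  double Ld = (double)L, L2 = 4.0 * Ld * Ld;
  double cur_M = 0.0;
  for (int s = 0; s < n; ++s) cur_M += -(ks[s] / (2.0 * Ld)) * (ks[s] / (2.0 * Ld));
  double best_M = cur_M;
  std::vector<int> best_mem = mem;

  auto deactivate = [&](int lab) {
    int pos = active_pos[lab];
    int last = active.back();
    active[pos] = last;
    active_pos[last] = pos;
    active.pop_back();
    active_pos[lab] = -1;
    freelab.push_back(lab);
  };
  auto activate = [&](int lab) {
    active_pos[lab] = (int)active.size();
    active.push_back(lab);
  };
  auto remove_member = [&](int lab, int v) {
    std::vector<int>& m = members[lab];
    for (size_t i = 0; i < m.size(); ++i) {
      if (m[i] == v) { m[i] = m.back(); m.pop_back(); break; }
    }
  };
  auto edges_to = [&](int v, int lab) {
    int c = 0;
    for (int w : adj[v]) if (mem[w] == lab) ++c;
    return c;
  };

  long n_single = (long)std::max(1.0, std::round(moves_factor * (double)n * n));
  std::vector<int> pos(n, -1);  // scratch for split proposals
  double temp = t0;
  while (temp > t_min) {
    for (long it = 0; it < n_single; ++it) {
      int v = rand_int(n);
      int a = mem[v];
      int b;
      if ((unif_rand() < 0.1 && !freelab.empty()) || active.size() == 1) {
        if (freelab.empty()) continue;
        b = freelab.back();
      } else {
        b = active[rand_int((int)active.size())];
      }
      if (b == a) continue;
      int e_va = edges_to(v, a);
      int e_vb = edges_to(v, b);
      double kv = deg[v];
      double dM = (e_vb - e_va) / Ld -
        ((ks[b] + kv) * (ks[b] + kv) + (ks[a] - kv) * (ks[a] - kv) -
         ks[a] * ks[a] - ks[b] * ks[b]) / L2;
      if (dM > 0 || unif_rand() < std::exp(dM / temp)) {
        bool b_was_empty = members[b].empty();
        l[a] -= e_va; l[b] += e_vb;
        ks[a] -= kv; ks[b] += kv;
        remove_member(a, v);
        members[b].push_back(v);
        mem[v] = b;
        cur_M += dM;
        if (b_was_empty) { freelab.pop_back(); activate(b); }
        if (members[a].empty()) deactivate(a);
      }
    }
    // collective moves: merges and random bisections
    for (int it = 0; it < n; ++it) {
      if (unif_rand() < 0.5 && active.size() >= 2) {
        int ia = rand_int((int)active.size());
        int ib = rand_int((int)active.size());
        if (ia == ib) continue;
        int a = active[ia], b = active[ib];
        if (members[a].size() > members[b].size()) std::swap(a, b);
        int e_ab = 0;
        for (int v : members[a]) for (int w : adj[v]) if (mem[w] == b) ++e_ab;
        double dM = e_ab / Ld - (2.0 * ks[a] * ks[b]) / L2;
        if (dM > 0 || unif_rand() < std::exp(dM / temp)) {
          for (int v : members[a]) {
            mem[v] = b;
            members[b].push_back(v);
          }
          l[b] += l[a] + e_ab; ks[b] += ks[a];
          l[a] = 0; ks[a] = 0; members[a].clear();
          cur_M += dM;
          deactivate(a);
        }
      } else {
        int a = active[rand_int((int)active.size())];
        size_t sz = members[a].size();
        if (sz < 2 || freelab.empty()) continue;
        // locally refined bisection: random seed split, then a few sweeps
        // moving each member to the side holding more of its within-module
        // neighbours, so splits follow weak internal ties
        std::vector<int> side(sz);
        for (size_t i = 0; i < sz; ++i) pos[members[a][i]] = (int)i;
        for (size_t i = 0; i < sz; ++i) side[i] = (unif_rand() < 0.5) ? 1 : 0;
        for (int sweep = 0; sweep < 3; ++sweep) {
          for (size_t i = 0; i < sz; ++i) {
            int v = members[a][i];
            int c1 = 0, c0 = 0;
            for (int w : adj[v]) {
              if (pos[w] >= 0 && w != v) {
                if (side[pos[w]]) ++c1; else ++c0;
              }
            }
            if (c1 > c0) side[i] = 1;
            else if (c0 > c1) side[i] = 0;
          }
        }
        std::vector<int> take;
        for (size_t i = 0; i < sz; ++i) if (side[i]) take.push_back(members[a][i]);
        for (size_t i = 0; i < sz; ++i) pos[members[a][i]] = -1;
        if (take.empty() || take.size() == sz) continue;
        int b = freelab.back();
        for (int v : take) mem[v] = b;  // provisional
        int l_a_new = 0, l_b_new = 0;
        double ks_b = 0.0;
        for (int v : members[a]) {
          int lab_v = mem[v];
          for (int w : adj[v]) {
            if (w > v) continue;  // count internal edges once
            if (mem[w] == lab_v && lab_v == a) ++l_a_new;
            if (mem[w] == lab_v && lab_v == b) ++l_b_new;
          }
        }
        for (int v : take) ks_b += deg[v];
        double ks_a = ks[a] - ks_b;
        double dM = (l_a_new + l_b_new - l[a]) / Ld -
          (ks_a * ks_a + ks_b * ks_b - ks[a] * ks[a]) / L2;
        if (dM > 0 || unif_rand() < std::exp(dM / temp)) {
          freelab.pop_back();
          activate(b);
          std::vector<int> keep;
          for (int v : members[a]) if (mem[v] == a) keep.push_back(v);
          members[a] = keep;
          members[b] = take;
          l[a] = l_a_new; l[b] = l_b_new;
          ks[a] = ks_a; ks[b] = ks_b;
          cur_M += dM;
        } else {
          for (int v : take) mem[v] = a;  // revert
        }
      }
    }
    if (cur_M > best_M) { best_M = cur_M; best_mem = mem; }
    temp *= cooling;
  }
  return List::create(Named("membership") = IntegerVector(best_mem.begin(), best_mem.end()),
                      Named("modularity") = best_M);
}
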