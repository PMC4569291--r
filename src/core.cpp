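// Core search, stimulus-design, and policy-evaluation routines.
//
// Conventions shared with the R layer:
//  * A stimulus with K rows is a flat numeric vector of length K(K+1)/2,
//    row-major bottom-up: disk (row k, pos p) lives at k(k+1)/2 + p (0-based).
//  * A path of s steps from a disk is coded as an integer: bit i holds step
//    i+1, with 0 = L (position kept) and 1 = R (position incremented).
//  * All randomness uses R's generator, so set.seed() in R governs results.

#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <functional>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int disk_index(int row, int pos) { return row * (row + 1) / 2 + pos; }

// 128-bit set of path prefixes (prefix length <= 7 -> at most 128 codes).
struct Bits128 {
  uint64_t lo = 0, hi = 0;
  void set(int b) { if (b < 64) lo |= (uint64_t{1} << b); else hi |= (uint64_t{1} << (b - 64)); }
  bool intersects(const Bits128& o) const { return (lo & o.lo) || (hi & o.hi); }
};

struct PlanResult {
  double score = 0.0;
  std::vector<int> codes;   // all maximally scoring step sequences
};

// Tie-preserving dynamic program over d levels above (row, pos).
// Counters (if non-null) accumulate summations and comparisons actually done.
static PlanResult plan_dp(const double* v, int n_rows, int row, int pos, int d,
                          long* n_sum = nullptr, long* n_cmp = nullptr) {
  PlanResult out;
  int d_eff = std::min(d, n_rows - 1 - row);
  if (d_eff <= 0) return out;
  // Frontier indexed by o = number of R steps taken so far.
  std::vector<double> best(1, 0.0), nbest;
  std::vector<std::vector<int>> codes(1, std::vector<int>{0}), ncodes;
  for (int t = 1; t <= d_eff; ++t) {
    nbest.assign(t + 1, 0.0);
    ncodes.assign(t + 1, {});
    for (int o = 0; o <= t; ++o) {
      double val = v[disk_index(row + t, pos + o)];
      bool hasL = o <= t - 1;          // parent o via step L
      bool hasR = o >= 1;              // parent o-1 via step R
      double sL = hasL ? best[o] + val : 0.0;
      double sR = hasR ? best[o - 1] + val : 0.0;
      if (n_sum) *n_sum += (hasL ? 1 : 0) + (hasR ? 1 : 0);
      if (hasL && hasR && n_cmp) ++*n_cmp;
      double b;
      if (hasL && hasR) b = std::max(sL, sR); else b = hasL ? sL : sR;
      nbest[o] = b;
      std::vector<int>& dst = ncodes[o];
      if (hasL && sL == b)
        for (int c : codes[o]) dst.push_back(c);                      // step L: bit stays 0
      if (hasR && sR == b)
        for (int c : codes[o - 1]) dst.push_back(c | (1 << (t - 1))); // step R
    }
    best.swap(nbest);
    codes.swap(ncodes);
  }
  double m = best[0];
  for (int o = 1; o <= d_eff; ++o) m = std::max(m, best[o]);
  if (n_cmp) *n_cmp += d_eff;  // final max over the d_eff+1 terminal disks
  out.score = m;
  for (int o = 0; o <= d_eff; ++o)
    if (best[o] == m) out.codes.insert(out.codes.end(), codes[o].begin(), codes[o].end());
  return out;
}

// Brute-force enumeration of all 2^d paths; same contract as plan_dp.
static PlanResult plan_bf(const double* v, int n_rows, int row, int pos, int d,
                          long* n_sum = nullptr, long* n_cmp = nullptr) {
  PlanResult out;
  int d_eff = std::min(d, n_rows - 1 - row);
  if (d_eff <= 0) return out;
  double best = 0.0;
  for (int code = 0; code < (1 << d_eff); ++code) {
    double s = 0.0;
    int p = pos;
    for (int t = 1; t <= d_eff; ++t) {
      p += (code >> (t - 1)) & 1;
      s += v[disk_index(row + t, p)];
      if (n_sum) ++*n_sum;
    }
    if (n_cmp) ++*n_cmp;
    if (code == 0 || s > best) { best = s; out.codes.assign(1, code); }
    else if (s == best) out.codes.push_back(code);
  }
  out.score = best;
  return out;
}

// Lexicographic order on step sequences: compare bit 0 first, then bit 1, ...
static int lex_min_code(const std::vector<int>& codes, int len) {
  int bestc = codes[0];
  for (size_t i = 1; i < codes.size(); ++i) {
    int a = codes[i], b = bestc;
    for (int t = 0; t < len; ++t) {
      int ba = (a >> t) & 1, bb = (b >> t) & 1;
      if (ba != bb) { if (ba < bb) bestc = a; break; }
    }
  }
  return bestc;
}

// [[Rcpp::export]]
List cpp_plan(NumericVector values, int n_rows, int row, int pos, int d,
              std::string method) {
  PlanResult pr = (method == "bruteforce")
    ? plan_bf(values.begin(), n_rows, row, pos, d)
    : plan_dp(values.begin(), n_rows, row, pos, d);
  int d_eff = std::max(0, std::min(d, n_rows - 1 - row));
  if (pr.codes.empty()) d_eff = 0;
  return List::create(_["score"] = pr.score,
                      _["codes"] = IntegerVector(pr.codes.begin(), pr.codes.end()),
                      _["depth"] = d_eff);
}

// [[Rcpp::export]]
List cpp_count_ops(NumericVector values, int n_rows, int row, int pos, int d,
                   std::string method) {
  long ns = 0, nc = 0;
  if (method == "bruteforce") plan_bf(values.begin(), n_rows, row, pos, d, &ns, &nc);
  else plan_dp(values.begin(), n_rows, row, pos, d, &ns, &nc);
  return List::create(_["summations"] = (double)ns, _["comparisons"] = (double)nc);
}

// [[Rcpp::export]]
double cpp_best_score(NumericVector values, int n_rows, int row, int pos, int d) {
  return plan_dp(values.begin(), n_rows, row, pos, d).score;
}

// Maximum d-deep sums conditional on the first step (L, R).
// [[Rcpp::export]]
NumericVector cpp_conditional_scores(NumericVector values, int n_rows, int row,
                                     int pos, int d) {
  int d_eff = std::min(d, n_rows - 1 - row);
  if (d_eff < 1) stop("no rows above this disk");
  const double* v = values.begin();
  double vl = v[disk_index(row + 1, pos)], vr = v[disk_index(row + 1, pos + 1)];
  double sl = vl + plan_dp(v, n_rows, row + 1, pos, d_eff - 1).score;
  double sr = vr + plan_dp(v, n_rows, row + 1, pos + 1, d_eff - 1).score;
  return NumericVector::create(_["sL"] = sl, _["sR"] = sr);
}

// Optimal-path tie sets for every disk and every depth 1..min(dmax, rows above).
// [[Rcpp::export]]
List cpp_plan_table(NumericVector values, int n_rows, int dmax) {
  int n_disks = n_rows * (n_rows + 1) / 2;
  List out(n_disks);
  const double* v = values.begin();
  for (int row = 0; row < n_rows; ++row) {
    for (int pos = 0; pos <= row; ++pos) {
      int e = std::min(dmax, n_rows - 1 - row);
      List per_d(std::max(e, 0));
      for (int d = 1; d <= e; ++d) {
        PlanResult pr = plan_dp(v, n_rows, row, pos, d);
        per_d[d - 1] = IntegerVector(pr.codes.begin(), pr.codes.end());
      }
      out[disk_index(row, pos)] = per_d;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Redundancy and annealing

struct StrategyGrid {
  std::vector<int> r, d;
  int size() const { return (int)r.size(); }
};

static StrategyGrid full_grid(int dmax) {
  StrategyGrid g;
  for (int d = 1; d <= dmax; ++d)
    for (int r = 1; r <= d; ++r) { g.r.push_back(r); g.d.push_back(d); }
  return g;
}

// Redundancy of one disk. Counting modes:
//   0 (depth_pairs): unordered pairs of distinct depths, restricted to depths
//     not exceeding the rows remaining, whose optimal-path sets overlap (some
//     shorter-depth path is a prefix of some longer-depth path). Same-d
//     strategies predict identical paths, so depths are the informative units.
//   1 (pairs): unordered pairs of (r, d) strategies whose plan prefixes,
//     truncated to the pair's smaller effective recalculation period,
//     coincide for at least one tie combination.
//   2 (strategies): (r, d) strategies participating in >= 1 mode-1 overlap.
static int disk_redundancy_core(const double* v, int n_rows, int row, int pos,
                                const StrategyGrid& g, int dmax, int mode) {
  int e = n_rows - 1 - row;
  if (e <= 0) return 0;
  int emax = std::min(dmax, e);
  // Tie sets per depth
  std::vector<std::vector<int>> S(emax + 1);
  for (int d = 1; d <= emax; ++d) S[d] = plan_dp(v, n_rows, row, pos, d).codes;
  if (mode == 0) {
    std::vector<int> depths;
    for (int d : g.d)
      if (d <= e && std::find(depths.begin(), depths.end(), d) == depths.end())
        depths.push_back(d);
    int cnt = 0;
    for (size_t a = 0; a < depths.size(); ++a)
      for (size_t b = a + 1; b < depths.size(); ++b) {
        int d1 = std::min(depths[a], depths[b]), d2 = std::max(depths[a], depths[b]);
        Bits128 p1, p2;
        int mask = (1 << d1) - 1;
        for (int c : S[d1]) p1.set(c & mask);
        for (int c : S[d2]) p2.set(c & mask);
        if (p1.intersects(p2)) ++cnt;
      }
    return cnt;
  }
  int ns = g.size();
  std::vector<int> re(ns);
  // Truncated prefix bitsets: B[s][m-1] valid for m = 1..re[s]
  std::vector<std::array<Bits128, 7>> B(ns);
  for (int s = 0; s < ns; ++s) {
    int de = std::min(g.d[s], e);
    re[s] = std::min(g.r[s], de);
    for (int m = 1; m <= re[s]; ++m) {
      int mask = (1 << m) - 1;
      for (int c : S[de]) B[s][m - 1].set(c & mask);
    }
  }
  int count = 0;
  std::vector<char> in_overlap(ns, 0);
  for (int a = 0; a < ns; ++a)
    for (int b = a + 1; b < ns; ++b) {
      int m = std::min(re[a], re[b]);
      if (B[a][m - 1].intersects(B[b][m - 1])) {
        ++count;
        in_overlap[a] = in_overlap[b] = 1;
      }
    }
  if (mode == 1) return count;
  int nstrat = 0;
  for (int s = 0; s < ns; ++s) nstrat += in_overlap[s];
  return nstrat;
}

// [[Rcpp::export]]
int cpp_disk_redundancy(NumericVector values, int n_rows, int row, int pos,
                        IntegerVector strat_r, IntegerVector strat_d,
                        int mode) {
  StrategyGrid g;
  int dmax = 1;
  for (int i = 0; i < strat_r.size(); ++i) {
    g.r.push_back(strat_r[i]);
    g.d.push_back(strat_d[i]);
    dmax = std::max(dmax, strat_d[i]);
  }
  return disk_redundancy_core(values.begin(), n_rows, row, pos, g, dmax, mode);
}

// [[Rcpp::export]]
List cpp_stimulus_redundancy(NumericVector values, int n_rows, int dmax,
                             int mode) {
  StrategyGrid g = full_grid(dmax);
  int n_disks = n_rows * (n_rows + 1) / 2;
  IntegerVector per_disk(n_disks);
  long total = 0;
  for (int row = 0; row < n_rows; ++row)
    for (int pos = 0; pos <= row; ++pos) {
      int rd = disk_redundancy_core(values.begin(), n_rows, row, pos, g, dmax, mode);
      per_disk[disk_index(row, pos)] = rd;
      total += rd;
    }
  return List::create(_["per_disk"] = per_disk, _["total"] = (double)total);
}

// Metropolis minimization of stimulus redundancy. One uniformly chosen disk is
// re-valued per iteration (new value uniform over the 9 squared integers, so a
// proposal may leave the value unchanged). Downhill or equal moves are always
// accepted; uphill moves with probability exp(-dR/T). Redundancy is updated
// incrementally over the changed disk's cone of influence (disks within dmax
// rows below it).
// [[Rcpp::export]]
List cpp_anneal(NumericVector values, int n_rows, NumericVector temperatures,
                IntegerVector steps_per_t, int dmax, int mode,
                bool keep_trace) {
  static const double classes[9] = {1, 4, 9, 16, 25, 36, 49, 64, 81};
  StrategyGrid g = full_grid(dmax);
  int n_disks = n_rows * (n_rows + 1) / 2;
  NumericVector v = clone(values);
  std::vector<int> rd(n_disks);
  double total = 0;
  for (int row = 0; row < n_rows; ++row)
    for (int pos = 0; pos <= row; ++pos) {
      int i = disk_index(row, pos);
      rd[i] = disk_redundancy_core(v.begin(), n_rows, row, pos, g, dmax, mode);
      total += rd[i];
    }
  double r_init = total;
  // row/pos lookup per flat index
  std::vector<int> row_of(n_disks), pos_of(n_disks);
  for (int row = 0; row < n_rows; ++row)
    for (int pos = 0; pos <= row; ++pos) {
      row_of[disk_index(row, pos)] = row;
      pos_of[disk_index(row, pos)] = pos;
    }
  long n_iter_total = 0;
  for (int i = 0; i < steps_per_t.size(); ++i) n_iter_total += steps_per_t[i];
  NumericVector tr_T, tr_dR, tr_R;
  IntegerVector tr_acc;
  if (keep_trace) {
    tr_T = NumericVector(n_iter_total);
    tr_dR = NumericVector(n_iter_total);
    tr_R = NumericVector(n_iter_total);
    tr_acc = IntegerVector(n_iter_total);
  }
  long it = 0;
  std::vector<int> aff;
  aff.reserve(64);
  for (int ti = 0; ti < temperatures.size(); ++ti) {
    double T = temperatures[ti];
    for (int s = 0; s < steps_per_t[ti]; ++s, ++it) {
      int j = std::min((int)(unif_rand() * n_disks), n_disks - 1);
      double newval = classes[std::min((int)(unif_rand() * 9), 8)];
      int k = row_of[j], p = pos_of[j];
      // disks whose plans can see disk j: rows k-dmax..k-1, positions p-diff..p
      aff.clear();
      for (int jr = std::max(0, k - dmax); jr < k; ++jr) {
        int diff = k - jr;
        for (int q = std::max(0, p - diff); q <= std::min(jr, p); ++q)
          aff.push_back(disk_index(jr, q));
      }
      double oldval = v[j];
      double d_old = 0, d_new = 0;
      for (int a : aff) d_old += rd[a];
      v[j] = newval;
      std::vector<int> rd_new(aff.size());
      for (size_t ai = 0; ai < aff.size(); ++ai) {
        int a = aff[ai];
        rd_new[ai] = disk_redundancy_core(v.begin(), n_rows, row_of[a], pos_of[a],
                                          g, dmax, mode);
        d_new += rd_new[ai];
      }
      double dR = d_new - d_old;
      bool accept = (dR <= 0) || (unif_rand() < std::exp(-dR / T));
      if (accept) {
        for (size_t ai = 0; ai < aff.size(); ++ai) rd[aff[ai]] = rd_new[ai];
        total += dR;
      } else {
        v[j] = oldval;
      }
      if (keep_trace) {
        tr_T[it] = T; tr_dR[it] = dR; tr_R[it] = total; tr_acc[it] = accept ? 1 : 0;
      }
    }
  }
  List out = List::create(_["values"] = v, _["r_init"] = r_init, _["r_final"] = total,
                          _["per_disk"] = IntegerVector(rd.begin(), rd.end()));
  if (keep_trace)
    out["trace"] = DataFrame::create(_["iteration"] = seq_len(n_iter_total),
                                     _["temperature"] = tr_T, _["delta"] = tr_dR,
                                     _["redundancy"] = tr_R, _["accepted"] = tr_acc);
  return out;
}

// ---------------------------------------------------------------------------
// Policy evaluation

// Probability of stepping L from (row, pos) when planning at depth d
// (d = 0 -> random step; ties among optimal first steps split equally).
static double step_left_prob(const double* v, int n_rows, int row, int pos, int d) {
  if (d == 0) return 0.5;
  PlanResult pr = plan_dp(v, n_rows, row, pos, d);
  bool hasL = false, hasR = false;
  for (int c : pr.codes) { if (c & 1) hasR = true; else hasL = true; }
  if (hasL && hasR) return 0.5;
  return hasL ? 1.0 : 0.0;
}

// Exact expected score of one per-row depth sequence (length n_rows-1) by
// forward propagation of the position distribution.
// [[Rcpp::export]]
double cpp_policy_expected(NumericVector values, int n_rows, IntegerVector depths) {
  if (depths.size() != n_rows - 1) stop("policy must have one depth per step");
  const double* v = values.begin();
  std::vector<double> p(1, 1.0), np;
  double gain = 0.0;
  for (int k = 0; k < n_rows - 1; ++k) {
    int d = depths[k];
    if (d < 0 || d > n_rows - 1 - k) stop("depth out of range at row %d", k);
    np.assign(k + 2, 0.0);
    for (int o = 0; o <= k; ++o) {
      if (p[o] == 0) continue;
      double pl = step_left_prob(v, n_rows, k, o, d);
      double vl = v[disk_index(k + 1, o)], vr = v[disk_index(k + 1, o + 1)];
      gain += p[o] * (pl * vl + (1 - pl) * vr);
      np[o] += p[o] * pl;
      np[o + 1] += p[o] * (1 - pl);
    }
    p.swap(np);
  }
  return gain;
}

// Expected score of every policy with free depths in {0..5} on the first
// n_rows-6 steps and the forced descending tail. Policies are indexed with
// row 0's depth as the most significant base-6 digit. Under the forced tail
// every optimal continuation scores the same, so the expected tail gain from
// a disk equals the DP maximum from that disk.
// [[Rcpp::export]]
NumericVector cpp_eval_policies(NumericVector values, int n_rows) {
  if (n_rows < 7) stop("policy enumeration requires at least 7 rows");
  const double* v = values.begin();
  int n_free = n_rows - 1 - 5;
  // step-left probabilities for free rows
  std::vector<std::vector<std::vector<double>>> pl(n_free);
  for (int k = 0; k < n_free; ++k) {
    pl[k].assign(6, std::vector<double>(k + 1));
    for (int d = 0; d <= 5; ++d)
      for (int o = 0; o <= k; ++o)
        pl[k][d][o] = step_left_prob(v, n_rows, k, o, d);
  }
  // expected tail gain = max path score from row n_free
  std::vector<double> tail(n_free + 1);
  for (int o = 0; o <= n_free; ++o)
    tail[o] = plan_dp(v, n_rows, n_free, o, n_rows - 1 - n_free).score;
  long n_pol = 1;
  for (int k = 0; k < n_free; ++k) n_pol *= 6;
  NumericVector out(n_pol);
  // DFS over the shared prefix tree of free depth choices
  struct Frame { std::vector<double> p; double gain; };
  std::function<void(int, long, const std::vector<double>&, double)> rec =
    [&](int k, long idx, const std::vector<double>& p, double gain) {
      if (k == n_free) {
        double g = gain;
        for (int o = 0; o <= n_free; ++o) g += p[o] * tail[o];
        out[idx] = g;
        return;
      }
      for (int d = 0; d <= 5; ++d) {
        std::vector<double> np(k + 2, 0.0);
        double ng = gain;
        for (int o = 0; o <= k; ++o) {
          if (p[o] == 0) continue;
          double l = pl[k][d][o];
          ng += p[o] * (l * v[disk_index(k + 1, o)] + (1 - l) * v[disk_index(k + 1, o + 1)]);
          np[o] += p[o] * l;
          np[o + 1] += p[o] * (1 - l);
        }
        rec(k + 1, idx * 6 + d, np, ng);
      }
    };
  rec(0, 0, std::vector<double>(1, 1.0), 0.0);
  return out;
}

// ---------------------------------------------------------------------------
// Actor traversal

// Traverse under a fixed (r, d) strategy. tie_random = false picks the
// lexicographically first optimal sequence (L < R); true picks uniformly.
// [[Rcpp::export]]
IntegerVector cpp_traverse_strategy(NumericVector values, int n_rows, int r, int d,
                                    bool tie_random) {
  const double* v = values.begin();
  std::vector<int> steps;
  int row = 0, pos = 0;
  while (row < n_rows - 1) {
    int d_eff = std::min(d, n_rows - 1 - row);
    PlanResult pr = plan_dp(v, n_rows, row, pos, d_eff);
    int code;
    if (pr.codes.size() == 1) code = pr.codes[0];
    else if (tie_random)
      code = pr.codes[std::min((int)(unif_rand() * pr.codes.size()),
                               (int)pr.codes.size() - 1)];
    else code = lex_min_code(pr.codes, d_eff);
    int m = std::min(r, d_eff);
    for (int i = 0; i < m; ++i) {
      int st = (code >> i) & 1;
      steps.push_back(st);
      pos += st;
    }
    row += m;
  }
  return IntegerVector(steps.begin(), steps.end());
}

// Traverse with a per-row depth sequence (r = 1). mode: 0 = optimal step with
// lexicographic tie rule, 1 = optimal step with random tie rule, 2 = sigmoid
// choice P_L = plogis(beta * (sL - sR) + eta) on depth-limited conditional
// scores. Depth 0 always takes a uniformly random step.
// [[Rcpp::export]]
IntegerVector cpp_traverse_depths(NumericVector values, int n_rows,
                                  IntegerVector depths, int mode,
                                  NumericVector beta, NumericVector eta) {
  if (depths.size() != n_rows - 1) stop("need one depth per step");
  const double* v = values.begin();
  IntegerVector steps(n_rows - 1);
  int pos = 0;
  for (int row = 0; row < n_rows - 1; ++row) {
    int d = depths[row];
    int d_eff = std::min(d, n_rows - 1 - row);
    int st;
    if (d == 0) {
      st = unif_rand() < 0.5 ? 0 : 1;
    } else if (mode == 2) {
      double vl = v[disk_index(row + 1, pos)], vr = v[disk_index(row + 1, pos + 1)];
      double sl = vl + plan_dp(v, n_rows, row + 1, pos, d_eff - 1).score;
      double sr = vr + plan_dp(v, n_rows, row + 1, pos + 1, d_eff - 1).score;
      double b = beta[std::min<int>(d - 1, beta.size() - 1)];
      double h = eta[std::min<int>(d - 1, eta.size() - 1)];
      double pL = 1.0 / (1.0 + std::exp(-(b * (sl - sr) + h)));
      st = unif_rand() < pL ? 0 : 1;
    } else {
      PlanResult pr = plan_dp(v, n_rows, row, pos, d_eff);
      int code;
      if (pr.codes.size() == 1) code = pr.codes[0];
      else if (mode == 1)
        code = pr.codes[std::min((int)(unif_rand() * pr.codes.size()),
                                 (int)pr.codes.size() - 1)];
      else code = lex_min_code(pr.codes, d_eff);
      st = code & 1;
    }
    steps[row] = st;
    pos += st;
  }
  return steps;
}
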