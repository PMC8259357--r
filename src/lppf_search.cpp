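// Exact anytime branch-and-bound for the minimum-flip linear perfect
// phylogeny problem.
//
// A completed matrix B' is a linear perfect phylogeny iff its columns can be
// ordered so the one-states are nested.  Building that order from the
// root-adjacent end (largest final one-state first), every row of B' must be
// a prefix of the order: ones on the placed side, zeros after its cut.  The
// search branches on which unplaced column comes next, maintaining per row
//   po  = observed ones among placed columns,
//   pz  = observed zeros among placed columns,
//   closedBest = cheapest 0->1 cost over cuts inside the placed prefix whose
//                1->0 cost (ones left outside the cut) fits the budget z on
//                its own.
// min(pz, closedBest) is an admissible per-row bound: a row whose cut is
// still open pays at least its placed zeros, a row that closed pays its best
// closed cost.  Missing entries contribute to neither cost.
//
// Leaves are scored exactly with a knapsack over the shared z budget across
// the per-row cut options.  For z = 0 a transposition table on the placed
// column set prunes orders revisiting a set at no smaller committed cost
// (sound because, at z = 0, both the committed cost and the achievable
// completions depend on the placed set only).  Identical columns are
// interchangeable and are forced into index order.

#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <chrono>
#include <random>

namespace {

const int INF = INT_MAX / 4;

struct Search {
  int n, m, z;
  std::vector<std::vector<int8_t>> col;  // col[c][i] in {0,1,-1}
  std::vector<int> totalOnes;            // per row, missing excluded
  std::vector<int> colCard;              // per column, number of ones
  std::vector<int> dupPrev;              // identical earlier column or -1
  std::vector<std::vector<int>> supOf;   // strict one-state supersets
  bool useDominance = false;
  double timeLimit;
  std::chrono::steady_clock::time_point t0;
  bool timedOut = false;
  long long nodes = 0;
  std::vector<int> tiebreak;

  int best = INF;
  std::vector<int> bestOrder;

  // mutable search state
  std::vector<int> po, pz, closedBest, closedBest0;
  long long lbSum = 0;   // sum of b_i = min(pz, closedBest): full-budget bound
  long long lbSum0 = 0;  // sum of a_i = min(pz, closedBest0): no-budget bound
  std::vector<int> order;
  std::vector<char> used;
  std::unordered_map<uint64_t, long long> tt;
  bool useTT = false;
  std::vector<std::pair<double, double>> itemBuf;  // (density, weight)

  struct Frame {
    int colId;
    std::vector<std::pair<int, int>> closedUndo;   // (row, old closedBest)
    std::vector<std::pair<int, int>> closed0Undo;  // (row, old closedBest0)
  };
  std::vector<Frame> frames;

  void init(const Rcpp::IntegerMatrix& B, int z_, double tl, int seed) {
    n = B.nrow();
    m = B.ncol();
    z = z_;
    timeLimit = tl;
    col.assign(m, std::vector<int8_t>(n));
    totalOnes.assign(n, 0);
    colCard.assign(m, 0);
    for (int c = 0; c < m; ++c) {
      for (int i = 0; i < n; ++i) {
        int v = B(i, c);
        int8_t w = (v == NA_INTEGER) ? int8_t(-1) : int8_t(v);
        col[c][i] = w;
        if (w == 1) { totalOnes[i]++; colCard[c]++; }
      }
    }
    dupPrev.assign(m, -1);
    for (int c = 1; c < m; ++c)
      for (int c2 = c - 1; c2 >= 0; --c2)
        if (col[c] == col[c2]) { dupPrev[c] = c2; break; }
    // one-state dominance (z = 0, no missing entries): an exchange argument
    // shows some optimal order places a column before every strict subset
    // of its one-state, so a candidate with an unplaced strict superset can
    // be skipped
    bool anyMissing = false;
    for (int i = 0; i < n && !anyMissing; ++i)
      for (int c = 0; c < m; ++c)
        if (col[c][i] < 0) { anyMissing = true; break; }
    useDominance = (z == 0 && !anyMissing);
    supOf.assign(m, std::vector<int>());
    if (useDominance) {
      int words = (n + 63) / 64;
      std::vector<std::vector<uint64_t>> bits(m,
          std::vector<uint64_t>(words, 0));
      for (int c = 0; c < m; ++c)
        for (int i = 0; i < n; ++i)
          if (col[c][i] == 1) bits[c][i >> 6] |= (uint64_t(1) << (i & 63));
      for (int c = 0; c < m; ++c)
        for (int c2 = 0; c2 < m; ++c2) {
          if (c2 == c || colCard[c2] <= colCard[c]) continue;
          bool super = true;
          for (int w = 0; w < words && super; ++w)
            if (bits[c][w] & ~bits[c2][w]) super = false;
          if (super) supOf[c].push_back(c2);
        }
    }
    po.assign(n, 0);
    pz.assign(n, 0);
    closedBest.assign(n, 0);
    closedBest0.assign(n, 0);
    lbSum = 0;
    lbSum0 = 0;
    for (int i = 0; i < n; ++i) {
      closedBest[i] = (totalOnes[i] <= z) ? 0 : INF;
      closedBest0[i] = (totalOnes[i] == 0) ? 0 : INF;
    }
    used.assign(m, 0);
    order.clear();
    frames.clear();
    useTT = (z == 0 && m <= 64);
    std::mt19937 rng(static_cast<uint32_t>(seed));
    tiebreak.resize(m);
    for (int c = 0; c < m; ++c) tiebreak[c] = c;
    std::shuffle(tiebreak.begin(), tiebreak.end(), rng);
    t0 = std::chrono::steady_clock::now();
  }

  double elapsed() const {
    return std::chrono::duration<double>(
        std::chrono::steady_clock::now() - t0).count();
  }

  uint64_t usedMask() const {
    uint64_t mk = 0;
    for (int c = 0; c < m; ++c)
      if (used[c]) mk |= (uint64_t(1) << c);
    return mk;
  }

  void place(int c) {
    Frame fr;
    fr.colId = c;
    const std::vector<int8_t>& cc = col[c];
    for (int i = 0; i < n; ++i) {
      int8_t v = cc[i];
      if (v < 0) continue;
      int oldContrib = std::min(pz[i], closedBest[i]);
      int oldContrib0 = std::min(pz[i], closedBest0[i]);
      if (v == 1) po[i]++; else pz[i]++;
      // the cut closing exactly at the new prefix end
      if (totalOnes[i] - po[i] <= z && pz[i] < closedBest[i]) {
        fr.closedUndo.push_back(std::make_pair(i, closedBest[i]));
        closedBest[i] = pz[i];
      }
      if (totalOnes[i] - po[i] == 0 && pz[i] < closedBest0[i]) {
        fr.closed0Undo.push_back(std::make_pair(i, closedBest0[i]));
        closedBest0[i] = pz[i];
      }
      lbSum += std::min(pz[i], closedBest[i]) - oldContrib;
      lbSum0 += std::min(pz[i], closedBest0[i]) - oldContrib0;
    }
    used[c] = 1;
    order.push_back(c);
    frames.push_back(std::move(fr));
  }

  void unplace() {
    Frame fr = std::move(frames.back());
    frames.pop_back();
    int c = fr.colId;
    for (auto it = fr.closedUndo.rbegin(); it != fr.closedUndo.rend(); ++it)
      closedBest[it->first] = it->second;
    for (auto it = fr.closed0Undo.rbegin(); it != fr.closed0Undo.rend(); ++it)
      closedBest0[it->first] = it->second;
    const std::vector<int8_t>& cc = col[c];
    for (int i = 0; i < n; ++i) {
      int8_t v = cc[i];
      if (v < 0) continue;
      int cur = std::min(pz[i], closedBest[i]);
      int cur0 = std::min(pz[i], closedBest0[i]);
      if (v == 1) po[i]--; else pz[i]--;
      lbSum += std::min(pz[i], closedBest[i]) - cur;
      lbSum0 += std::min(pz[i], closedBest0[i]) - cur0;
    }
    used[c] = 0;
    order.pop_back();
  }

  // budget-aware lower bound for z > 0: start from the no-budget bound
  // sum(a_i) and subtract an upper bound on the savings the shared budget
  // can buy.  Row i can save at most s_i = a_i - b_i, and any option that
  // beats a_i forfeits at least its unplaced ones r_i = totalOnes - po of
  // the budget (every closed cut's 1->0 cost is at least r_i).  A
  // fractional knapsack over (s_i, max(1, r_i)) with capacity z therefore
  // upper-bounds the achievable savings.
  long long budgetBound() {
    if (z == 0 || lbSum0 == lbSum) return lbSum0;
    itemBuf.clear();
    for (int i = 0; i < n; ++i) {
      int a = std::min(pz[i], closedBest0[i]);
      int b = std::min(pz[i], closedBest[i]);
      if (a > b) {
        double w = std::max(1, totalOnes[i] - po[i]);
        itemBuf.push_back(std::make_pair((a - b) / w, w));
      }
    }
    std::sort(itemBuf.begin(), itemBuf.end(),
              std::greater<std::pair<double, double>>());
    double cap = z, save = 0;
    for (size_t k = 0; k < itemBuf.size() && cap > 0; ++k) {
      double take = std::min(cap, itemBuf[k].second);
      save += itemBuf[k].first * take;
      cap -= take;
    }
    long long bound = lbSum0 - (long long)std::ceil(save - 1e-9);
    return std::max(bound, lbSum);
  }

  // exact objective of a complete order: knapsack over the shared z budget
  long long evalOrder(const std::vector<int>& ord) {
    if (z == 0) {
      long long tot = 0;
      for (int i = 0; i < n; ++i) {
        int zeros = 0, cost = 0;
        for (int d = 0; d < m; ++d) {
          int8_t v = col[ord[d]][i];
          if (v == 0) zeros++;
          else if (v == 1) cost = zeros;  // zeros before the last one so far
        }
        tot += cost;
      }
      return tot;
    }
    std::vector<long long> dp(z + 1, 0), ndp(z + 1);
    std::vector<int> c01(m + 1), c10(m + 1);
    for (int i = 0; i < n; ++i) {
      int ones = 0, zeros = 0;
      c01[0] = 0;
      c10[0] = totalOnes[i];
      for (int d = 0; d < m; ++d) {
        int8_t v = col[ord[d]][i];
        if (v == 1) ones++; else if (v == 0) zeros++;
        c01[d + 1] = zeros;
        c10[d + 1] = totalOnes[i] - ones;
      }
      std::fill(ndp.begin(), ndp.end(), (long long)INF);
      for (int t = 0; t <= m; ++t) {
        if (c10[t] > z) continue;
        for (int b = c10[t]; b <= z; ++b) {
          long long candv = dp[b - c10[t]] + c01[t];
          if (candv < ndp[b]) ndp[b] = candv;
        }
      }
      dp.swap(ndp);
    }
    return dp[z];
  }

  void registerLeaf() {
    long long val = evalOrder(order);
    if (val < best) {
      best = (int)val;
      bestOrder = order;
    }
  }

  long long scoreCandidate(int c) {
    place(c);
    long long s = lbSum;
    unplace();
    return s;
  }

  bool blocked(int c) const {
    if (dupPrev[c] >= 0 && !used[dupPrev[c]]) return true;
    if (useDominance)
      for (size_t k = 0; k < supOf[c].size(); ++k)
        if (!used[supOf[c][k]]) return true;
    return false;
  }

  // relocation local search on the incumbent order
  void polishIncumbent(double budget) {
    if (bestOrder.empty() || m < 3) return;
    std::vector<int> cur = bestOrder;
    long long curVal = best;
    double start = elapsed();
    bool improved = true;
    while (improved && elapsed() - start < budget) {
      improved = false;
      for (int from = 0; from < m && !improved; ++from) {
        if (elapsed() - start > budget) break;
        for (int to = 0; to < m && !improved; ++to) {
          if (to == from) continue;
          std::vector<int> trial = cur;
          int c = trial[from];
          trial.erase(trial.begin() + from);
          trial.insert(trial.begin() + to, c);
          long long v = evalOrder(trial);
          if (v < curVal) { cur = trial; curVal = v; improved = true; }
        }
      }
    }
    if (curVal < best) { best = (int)curVal; bestOrder = cur; }
  }

  void greedyFrom(bool randomized, std::mt19937& rng) {
    int depth0 = (int)order.size();
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    while ((int)order.size() < m) {
      int bc = -1;
      double bs = 0;
      for (int c = 0; c < m; ++c) {
        if (used[c] || blocked(c)) continue;
        double s = (double)scoreCandidate(c)
          - 1e-4 * colCard[c] + 1e-7 * tiebreak[c];
        if (randomized) s += unif(rng) * 0.5;
        if (bc < 0 || s < bs) { bc = c; bs = s; }
      }
      place(bc);
    }
    registerLeaf();
    while ((int)order.size() > depth0) unplace();
  }

  void seedIncumbents(int seed) {
    std::mt19937 rng(static_cast<uint32_t>(seed) ^ 0x9e3779b9u);
    std::vector<int> stat(m);
    for (int c = 0; c < m; ++c) stat[c] = c;
    std::stable_sort(stat.begin(), stat.end(), [&](int a, int b) {
      return colCard[a] > colCard[b];
    });
    long long val = evalOrder(stat);  // largest one-state first
    if (val < best) { best = (int)val; bestOrder = stat; }
    greedyFrom(false, rng);
    for (int r = 0; r < 3; ++r) greedyFrom(true, rng);
    polishIncumbent(std::min(0.25 * timeLimit, 3.0));
  }

  void dfs() {
    if (timedOut) return;
    if ((++nodes & 1023) == 0 && elapsed() > timeLimit) {
      timedOut = true;
      return;
    }
    if (lbSum >= best) return;
    if (z > 0 && budgetBound() >= best) return;
    int d = (int)order.size();
    if (d == m) {
      registerLeaf();
      return;
    }
    if (useTT) {
      uint64_t mk = usedMask();
      auto it = tt.find(mk);
      if (it != tt.end() && it->second <= lbSum) return;
      if (it != tt.end()) it->second = lbSum;
      else if (tt.size() < (size_t)(1 << 21)) tt[mk] = lbSum;
    }
    std::vector<std::pair<long long, int>> cand;
    cand.reserve(m - d);
    for (int c = 0; c < m; ++c) {
      if (used[c] || blocked(c)) continue;
      long long s = scoreCandidate(c) * 1000000LL
        - 1000LL * colCard[c] + tiebreak[c];
      cand.push_back(std::make_pair(s, c));
    }
    std::sort(cand.begin(), cand.end());
    for (size_t k = 0; k < cand.size(); ++k) {
      place(cand[k].second);
      dfs();
      unplace();
      if (timedOut) return;
      if (lbSum >= best) return;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".lppf_search_cpp")]]
Rcpp::List lppf_search_cpp(Rcpp::IntegerMatrix B, int z, double time_limit,
                           int seed) {
  Search S;
  S.init(B, z, time_limit, seed);
  S.seedIncumbents(seed);
  S.dfs();
  double rt = S.elapsed();
  Rcpp::IntegerVector ord(S.bestOrder.begin(), S.bestOrder.end());
  return Rcpp::List::create(
      Rcpp::Named("objective") = S.best,
      Rcpp::Named("order") = ord,  // 0-based, root-adjacent column first
      Rcpp::Named("optimal") = !S.timedOut,
      Rcpp::Named("nodes") = (double)S.nodes,
      Rcpp::Named("runtime") = rt);
}
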