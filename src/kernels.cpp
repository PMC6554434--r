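#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Extended Needleman-Wunsch dynamic programme on a precomputed bin-product
// matrix P (L1 x L2).  Matches score the inner product of the two bin
// vectors, a run of g consecutive gaps in either direction costs exp(alpha*g)
// (tracked greedily by per-cell gap counters), and scores are floored at zero
// so alignments may restart anywhere (local alignment).  Gap counters reset
// when the zero floor is taken.
//
// Tie-breaking in the cell maximum: diagonal > vertical > horizontal > zero.
static double dp_fill(const double* P, int L1, int L2, double alpha,
                      std::vector<double>& f, std::vector<int>& v,
                      std::vector<int>& h, std::vector<signed char>* move,
                      std::vector<int>* jump) {
  const int C = L2 + 1; // row stride; cell (i, j) -> i * C + j
  for (int j = 0; j <= L2; ++j) { f[j] = 0.0; v[j] = 0; h[j] = 0; }
  for (int i = 1; i <= L1; ++i) {
    f[i * C] = 0.0; v[i * C] = 0; h[i * C] = 0;
    for (int j = 1; j <= L2; ++j) {
      const int c = i * C + j;
      // vertical gap run (moves along i, skipping bins of the first window)
      double fresh = f[(i - 1) * C + j] - std::exp(alpha);
      int vprev = v[(i - 1) * C + j];
      double ext = f[(i - 1 - vprev) * C + j] - std::exp(alpha * (vprev + 1));
      int vlen; double vcand;
      if (fresh >= ext) { vlen = 1; vcand = fresh; } else { vlen = vprev + 1; vcand = ext; }
      // horizontal gap run (moves along j)
      fresh = f[i * C + (j - 1)] - std::exp(alpha);
      int hprev = h[i * C + (j - 1)];
      ext = f[i * C + (j - 1 - hprev)] - std::exp(alpha * (hprev + 1));
      int hlen; double hcand;
      if (fresh >= ext) { hlen = 1; hcand = fresh; } else { hlen = hprev + 1; hcand = ext; }
      const double dcand = f[(i - 1) * C + (j - 1)] + P[(i - 1) + (size_t)(j - 1) * L1];
      double best = 0.0; signed char mv = 0;
      if (hcand >= best) { best = hcand; mv = 2; }
      if (vcand >= best) { best = vcand; mv = 1; }
      if (dcand >= best) { best = dcand; mv = 3; }
      f[c] = best;
      if (best == 0.0) { // zero floor: restart, gap counters reset
        v[c] = 0; h[c] = 0;
        if (mv != 3) mv = 0;
      } else {
        v[c] = vlen; h[c] = hlen;
      }
      if (move) {
        (*move)[c] = mv;
        (*jump)[c] = (mv == 1) ? vlen : (mv == 2 ? hlen : (mv == 3 ? 1 : 0));
      }
    }
  }
  return f[L1 * C + L2];
}

// [[Rcpp::export]]
double cpp_dp_score(NumericMatrix P, double alpha) {
  const int L1 = P.nrow(), L2 = P.ncol();
  std::vector<double> f((L1 + 1) * (L2 + 1));
  std::vector<int> v(f.size()), h(f.size());
  return dp_fill(REAL(P), L1, L2, alpha, f, v, h, nullptr, nullptr);
}

// [[Rcpp::export]]
List cpp_dp_align(NumericMatrix P, double alpha) {
  const int L1 = P.nrow(), L2 = P.ncol();
  const int C = L2 + 1;
  std::vector<double> f((L1 + 1) * (L2 + 1));
  std::vector<int> v(f.size()), h(f.size());
  std::vector<signed char> move(f.size(), 0);
  std::vector<int> jump(f.size(), 0);
  double score = dp_fill(REAL(P), L1, L2, alpha, f, v, h, &move, &jump);
  // traceback from the top-right cell, collecting diagonal (match) moves
  std::vector<int> mi, mj;
  int i = L1, j = L2;
  while (i > 0 && j > 0) {
    const int c = i * C + j;
    const signed char mv = move[c];
    if (mv == 0) break;
    if (mv == 3) { mi.push_back(i); mj.push_back(j); --i; --j; }
    else if (mv == 1) { i -= jump[c]; }
    else { j -= jump[c]; }
  }
  const int m = (int)mi.size();
  IntegerMatrix pairs(m, 2);
  for (int t = 0; t < m; ++t) { // reverse to increasing order
    pairs(t, 0) = mi[m - 1 - t];
    pairs(t, 1) = mj[m - 1 - t];
  }
  return List::create(_["score"] = score, _["pairs"] = pairs);
}

// Batch edit-similarity scoring over candidate window pairs.
// Windows are given as spike triplets (neuron, bin, count), grouped by
// window via win_ptr (0-based, length M+1) and sorted by neuron within each
// window.  The bin-product matrix of a pair only receives contributions from
// neurons active in both windows, so it is accumulated sparsely.
// [[Rcpp::export]]
NumericVector cpp_score_pairs(IntegerVector win_ptr, IntegerVector neuron,
                              IntegerVector bin, NumericVector count,
                              IntegerMatrix pairs, int L, double alpha) {
  const int n_pairs = pairs.nrow();
  NumericVector out(n_pairs);
  std::vector<double> P((size_t)L * L);
  std::vector<double> f((L + 1) * (L + 1));
  std::vector<int> v(f.size()), h(f.size());
  std::vector<size_t> touched;
  touched.reserve(256);
  for (int p = 0; p < n_pairs; ++p) {
    const int a = pairs(p, 0) - 1, b = pairs(p, 1) - 1;
    int ia = win_ptr[a], ea = win_ptr[a + 1];
    int ib = win_ptr[b], eb = win_ptr[b + 1];
    touched.clear();
    while (ia < ea && ib < eb) {
      const int na = neuron[ia], nb = neuron[ib];
      if (na < nb) { ++ia; }
      else if (na > nb) { ++ib; }
      else {
        int ja = ia, jb = ib;
        while (ja < ea && neuron[ja] == na) ++ja;
        while (jb < eb && neuron[jb] == nb) ++jb;
        for (int x = ia; x < ja; ++x)
          for (int y = ib; y < jb; ++y) {
            const size_t idx = (bin[x] - 1) + (size_t)(bin[y] - 1) * L;
            if (P[idx] == 0.0) touched.push_back(idx);
            P[idx] += count[x] * count[y];
          }
        ia = ja; ib = jb;
      }
    }
    out[p] = dp_fill(P.data(), L, L, alpha, f, v, h, nullptr, nullptr);
    for (size_t t = 0; t < touched.size(); ++t) P[touched[t]] = 0.0;
  }
  return out;
}

// MinHash signatures: for each permutation (row of perms, a permutation of
// 1..N) and each window, the minimum permuted rank over the window's active
// neurons.  Windows with no active neuron get NA.
// [[Rcpp::export]]
IntegerMatrix cpp_minhash(IntegerVector mask_ptr, IntegerVector mask_neuron,
                          IntegerMatrix perms) {
  const int n_hash = perms.nrow();
  const int M = mask_ptr.size() - 1;
  IntegerMatrix S(n_hash, M);
  for (int k = 0; k < M; ++k) {
    const int s = mask_ptr[k], e = mask_ptr[k + 1];
    if (s == e) {
      for (int q = 0; q < n_hash; ++q) S(q, k) = NA_INTEGER;
      continue;
    }
    for (int q = 0; q < n_hash; ++q) {
      int mn = std::numeric_limits<int>::max();
      for (int t = s; t < e; ++t) {
        const int r = perms(q, mask_neuron[t] - 1);
        if (r < mn) mn = r;
      }
      S(q, k) = mn;
    }
  }
  return S;
}

// OPTICS ordering with eps = Inf on a dense precomputed distance matrix.
// Core distance of a point is the min_pts-th smallest distance in its row
// (the point itself, at distance 0, counts as the first).
// [[Rcpp::export]]
List cpp_optics_order(NumericMatrix D, int min_pts) {
  const int n = D.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector core(n);
  std::vector<double> row(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) row[j] = D(i, j);
    row[i] = 0.0;
    std::nth_element(row.begin(), row.begin() + (min_pts - 1), row.end());
    core[i] = row[min_pts - 1];
  }
  std::vector<bool> processed(n, false);
  NumericVector reach(n, INF);
  IntegerVector order(n);
  std::vector<double> seeds(n, INF);
  for (int step = 0; step < n; ++step) {
    // pick the unprocessed point with the smallest reachability (ties ->
    // smallest index); Inf means a fresh start
    int p = -1; double best = INF;
    for (int i = 0; i < n; ++i)
      if (!processed[i] && (p == -1 || seeds[i] < best)) { p = i; best = seeds[i]; }
    processed[p] = true;
    order[step] = p + 1;
    reach[p] = seeds[p];
    for (int q = 0; q < n; ++q) {
      if (processed[q]) continue;
      const double d = std::max(core[p], D(p, q));
      if (d < seeds[q]) seeds[q] = d;
    }
  }
  return List::create(_["order"] = order, _["reachability"] = reach,
                      _["core_dist"] = core);
}
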