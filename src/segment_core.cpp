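// Core numerics for BIC-scored coexpression segmentation.
//
// A segment's data in one tissue is modelled as n iid N(s, sigma^2)
// observations whose shared effect s is drawn from a two-component normal
// mixture and integrated out analytically.  For a segment of genes a..b the
// per-tissue log marginal only needs (n, sum, sum of squares), so prefix sums
// over the gene axis make any contiguous segment scoreable in O(T).
//
// The greedy split/merge/shift descent and the exact dynamic program both sit
// on top of that primitive.  Interval evaluations are memoised in a hash map
// keyed by (first gene, last gene); one map can be shared across all
// replicate descents at fixed model parameters, where the same locally
// optimal intervals recur constantly.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

const double LOG2PI = std::log(2.0 * M_PI);

inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp(b - a));
}

struct Model {
  int G, T;
  // prefix sums, column-major: P1[t * (G + 1) + i] = sum of first i genes
  std::vector<double> P1, P2;
  double inv2s2;           // 1 / (2 sigma^2)
  double logphi, log1mphi; // -Inf when the component has zero weight
  double mu1, mu2;
  // per-n constants of the closed-form marginal, indexed 1..G
  std::vector<double> A1, A2, B1, B2;

  Model(const NumericMatrix& X, double phi, double m1, double s1,
        double m2, double s2, double sigma)
      : G(X.nrow()), T(X.ncol()), mu1(m1), mu2(m2) {
    P1.assign((size_t)(G + 1) * T, 0.0);
    P2.assign((size_t)(G + 1) * T, 0.0);
    for (int t = 0; t < T; ++t) {
      double* p1 = &P1[(size_t)t * (G + 1)];
      double* p2 = &P2[(size_t)t * (G + 1)];
      for (int i = 0; i < G; ++i) {
        double v = X(i, t);
        p1[i + 1] = p1[i] + v;
        p2[i + 1] = p2[i] + v * v;
      }
    }
    double s2sq = sigma * sigma;
    inv2s2 = 1.0 / (2.0 * s2sq);
    logphi = (phi > 0.0) ? std::log(phi) : R_NegInf;
    log1mphi = (phi < 1.0) ? std::log1p(-phi) : R_NegInf;
    A1.assign(G + 1, 0.0); A2.assign(G + 1, 0.0);
    B1.assign(G + 1, 0.0); B2.assign(G + 1, 0.0);
    double t1 = s1 * s1, t2 = s2 * s2, ls = std::log(sigma);
    for (int n = 1; n <= G; ++n) {
      double d1 = s2sq + n * t1, d2 = s2sq + n * t2;
      double base = -0.5 * n * LOG2PI - (n - 1) * ls;
      A1[n] = base - 0.5 * std::log(d1);
      A2[n] = base - 0.5 * std::log(d2);
      B1[n] = n / (2.0 * d1);
      B2[n] = n / (2.0 * d2);
    }
  }

  // total log marginal over tissues for genes a..b (1-based, inclusive)
  double seg_ll(int a, int b) const {
    int n = b - a + 1;
    double ll = 0.0;
    for (int t = 0; t < T; ++t) {
      const double* p1 = &P1[(size_t)t * (G + 1)];
      const double* p2 = &P2[(size_t)t * (G + 1)];
      double sum = p1[b] - p1[a - 1];
      double ss = p2[b] - p2[a - 1];
      double mean = sum / n;
      double S = ss - sum * mean;
      if (S < 0.0) S = 0.0;
      double core = -S * inv2s2;
      double e1 = mean - mu1, e2 = mean - mu2;
      double lp1 = (logphi == R_NegInf) ? R_NegInf
                   : logphi + A1[n] + core - B1[n] * e1 * e1;
      double lp2 = (log1mphi == R_NegInf) ? R_NegInf
                   : log1mphi + A2[n] + core - B2[n] * e2 * e2;
      ll += logsumexp2(lp1, lp2);
    }
    return ll;
  }
};

// Cached summary of one interval a..b: its own log likelihood plus the two
// best two-way cuts (v(p) = ll(a,p) + ll(p+1,b) over p in a..b-1).  The same
// record answers "best split of this segment" and, for a merged neighbour
// pair, "merge likelihood" and "best shift of the shared boundary".
struct Rec {
  double ll;
  double v1; int p1;  // best cut value / cut position (boundary after gene p)
  double v2; int p2;  // runner-up, p2 != p1
};

typedef std::unordered_map<uint64_t, Rec> Cache;

inline uint64_t ckey(int a, int b) {
  return ((uint64_t)a << 32) | (uint64_t)b;
}

const Rec& get_rec(const Model& M, Cache& cache, int a, int b) {
  uint64_t k = ckey(a, b);
  Cache::iterator it = cache.find(k);
  if (it != cache.end()) return it->second;
  Rec r;
  r.ll = M.seg_ll(a, b);
  r.v1 = R_NegInf; r.p1 = -1;
  r.v2 = R_NegInf; r.p2 = -1;
  for (int p = a; p < b; ++p) {
    double v = M.seg_ll(a, p) + M.seg_ll(p + 1, b);
    if (v > r.v1) {
      r.v2 = r.v1; r.p2 = r.p1;
      r.v1 = v; r.p1 = p;
    } else if (v > r.v2) {
      r.v2 = v; r.p2 = p;
    }
  }
  return cache.emplace(k, r).first->second;
}

struct MoveRec {
  int kind;   // 1 split, 2 merge, 3 shift
  int index;  // segment index (split) or boundary index (merge/shift), 1-based
  int pos;    // absolute gene index of the new cut (split/shift), 0 for merge
  double delta;
};

// One greedy descent from `ends` (segment end positions, last == G).
// Modifies `ends` in place; returns applied moves and the score trace.
void descend(const Model& M, Cache& cache, std::vector<int>& ends,
             double ln_n, double eps, int max_iter, double k_dist,
             double& loglik_out, double& score_out,
             std::vector<MoveRec>* moves_out,
             std::vector<double>* trace_out) {
  int G = M.G;
  double total_ll = 0.0;
  {
    int a = 1;
    for (size_t j = 0; j < ends.size(); ++j) {
      total_ll += get_rec(M, cache, a, ends[j]).ll;
      a = ends[j] + 1;
    }
  }
  double score = -2.0 * total_ll + ((double)ends.size() + k_dist) * ln_n;
  if (trace_out) trace_out->push_back(score);

  for (int iter = 0; iter < max_iter; ++iter) {
    if (!std::isfinite(score))
      stop("non-finite segmentation score during greedy descent");
    int nseg = (int)ends.size();
    double best = -eps;
    MoveRec bm; bm.kind = 0;

    // splits, by segment index then position (first strict winner kept)
    int a = 1;
    for (int j = 0; j < nseg; ++j) {
      int b = ends[j];
      if (b > a) {
        const Rec& r = get_rec(M, cache, a, b);
        double d = -2.0 * (r.v1 - r.ll) + ln_n;
        if (d < best) { best = d; bm.kind = 1; bm.index = j + 1; bm.pos = r.p1; bm.delta = d; }
      }
      a = b + 1;
    }
    // merges, by boundary index
    a = 1;
    for (int j = 0; j + 1 < nseg; ++j) {
      int m = ends[j], b = ends[j + 1];
      const Rec& rm = get_rec(M, cache, a, b);
      double llpair = get_rec(M, cache, a, m).ll + get_rec(M, cache, m + 1, b).ll;
      double d = -2.0 * (rm.ll - llpair) - ln_n;
      if (d < best) { best = d; bm.kind = 2; bm.index = j + 1; bm.pos = 0; bm.delta = d; }
      a = m + 1;
    }
    // shifts, by boundary index then position
    a = 1;
    for (int j = 0; j + 1 < nseg; ++j) {
      int m = ends[j], b = ends[j + 1];
      const Rec& rm = get_rec(M, cache, a, b);
      double v; int p;
      if (rm.p1 != m) { v = rm.v1; p = rm.p1; } else { v = rm.v2; p = rm.p2; }
      if (p >= 0) {
        double llpair = get_rec(M, cache, a, m).ll + get_rec(M, cache, m + 1, b).ll;
        double d = -2.0 * (v - llpair);
        if (d < best) { best = d; bm.kind = 3; bm.index = j + 1; bm.pos = p; bm.delta = d; }
      }
      a = m + 1;
    }

    if (bm.kind == 0) break;  // local optimum: no strictly improving move

    if (bm.kind == 1) {
      ends.insert(ends.begin() + (bm.index - 1), bm.pos);
    } else if (bm.kind == 2) {
      ends.erase(ends.begin() + (bm.index - 1));
    } else {
      ends[bm.index - 1] = bm.pos;
    }
    score += bm.delta;
    total_ll += -0.5 * (bm.delta - (bm.kind == 1 ? ln_n : bm.kind == 2 ? -ln_n : 0.0));
    if (moves_out) moves_out->push_back(bm);
    if (trace_out) trace_out->push_back(score);
  }
  loglik_out = total_ll;
  score_out = score;
}

std::vector<int> lengths_to_ends(const IntegerVector& lengths) {
  std::vector<int> ends;
  int acc = 0;
  for (int i = 0; i < lengths.size(); ++i) {
    acc += lengths[i];
    ends.push_back(acc);
  }
  return ends;
}

IntegerVector ends_to_lengths(const std::vector<int>& ends) {
  IntegerVector out(ends.size());
  int prev = 0;
  for (size_t i = 0; i < ends.size(); ++i) {
    out[i] = ends[i] - prev;
    prev = ends[i];
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List greedy_descent_cpp(NumericMatrix X, IntegerVector init_lengths,
                        double phi, double mu1, double sigma1,
                        double mu2, double sigma2, double sigma,
                        double ln_n, double eps, int max_iter,
                        double k_dist_params) {
  Model M(X, phi, mu1, sigma1, mu2, sigma2, sigma);
  Cache cache;
  std::vector<int> ends = lengths_to_ends(init_lengths);
  if (ends.empty() || ends.back() != M.G)
    stop("initial segmentation does not cover the arm");
  std::vector<MoveRec> moves;
  std::vector<double> trace;
  double ll, score;
  descend(M, cache, ends, ln_n, eps, max_iter, k_dist_params,
          ll, score, &moves, &trace);
  int nm = (int)moves.size();
  IntegerVector kind(nm), index(nm), pos(nm);
  NumericVector delta(nm);
  for (int i = 0; i < nm; ++i) {
    kind[i] = moves[i].kind; index[i] = moves[i].index;
    pos[i] = moves[i].pos; delta[i] = moves[i].delta;
  }
  return List::create(
      _["lengths"] = ends_to_lengths(ends),
      _["loglik"] = ll,
      _["score"] = score,
      _["n_iterations"] = nm,
      _["trace"] = NumericVector(trace.begin(), trace.end()),
      _["moves"] = DataFrame::create(_["kind"] = kind, _["index"] = index,
                                     _["pos"] = pos, _["delta"] = delta));
}

// [[Rcpp::export]]
List run_replicates_cpp(NumericMatrix X, List init_lengths,
                        double phi, double mu1, double sigma1,
                        double mu2, double sigma2, double sigma,
                        double ln_n, double eps, int max_iter,
                        double k_dist_params) {
  Model M(X, phi, mu1, sigma1, mu2, sigma2, sigma);
  Cache cache;  // shared: replicate optima revisit the same intervals
  int R = init_lengths.size();
  List lengths_out(R);
  NumericVector loglik(R), score(R);
  IntegerVector iters(R);
  for (int r = 0; r < R; ++r) {
    std::vector<int> ends = lengths_to_ends(init_lengths[r]);
    if (ends.empty() || ends.back() != M.G)
      stop("replicate %d: initial segmentation does not cover the arm", r + 1);
    std::vector<MoveRec> moves;
    double ll, sc;
    descend(M, cache, ends, ln_n, eps, max_iter, k_dist_params,
            ll, sc, &moves, (std::vector<double>*)0);
    lengths_out[r] = ends_to_lengths(ends);
    loglik[r] = ll;
    score[r] = sc;
    iters[r] = (int)moves.size();
  }
  return List::create(_["lengths"] = lengths_out, _["loglik"] = loglik,
                      _["score"] = score, _["n_iterations"] = iters);
}

// Exact minimum-BIC segmentation.  Per-segment cost -2*ll(a,b) + ln_n is
// additive, so a standard O(G^2) partition DP finds the global optimum.
// [[Rcpp::export]]
List dp_optimal_cpp(NumericMatrix X,
                    double phi, double mu1, double sigma1,
                    double mu2, double sigma2, double sigma,
                    double ln_n, double k_dist_params) {
  Model M(X, phi, mu1, sigma1, mu2, sigma2, sigma);
  int G = M.G;
  std::vector<double> best(G + 1, R_PosInf);
  std::vector<double> bestll(G + 1, 0.0);
  std::vector<int> back(G + 1, 0);
  best[0] = 0.0;
  for (int i = 1; i <= G; ++i) {
    for (int j = 0; j < i; ++j) {
      double ll = M.seg_ll(j + 1, i);
      double c = best[j] - 2.0 * ll + ln_n;
      if (c < best[i]) {
        best[i] = c;
        bestll[i] = bestll[j] + ll;
        back[i] = j;
      }
    }
  }
  std::vector<int> ends;
  for (int i = G; i > 0; i = back[i]) ends.push_back(i);
  std::reverse(ends.begin(), ends.end());
  double score = best[G] + k_dist_params * ln_n;
  return List::create(_["lengths"] = ends_to_lengths(ends),
                      _["loglik"] = bestll[G], _["score"] = score);
}

// Batch closed-form segment log marginals: one value per (interval, tissue
// set pooled) — used by the R-level likelihood path for speed on large arms.
// [[Rcpp::export]]
NumericVector seg_ll_batch_cpp(NumericMatrix X, IntegerVector first,
                               IntegerVector last,
                               double phi, double mu1, double sigma1,
                               double mu2, double sigma2, double sigma) {
  Model M(X, phi, mu1, sigma1, mu2, sigma2, sigma);
  int m = first.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    if (first[i] < 1 || last[i] > M.G || first[i] > last[i])
      stop("invalid interval [%d, %d]", first[i], last[i]);
    out[i] = M.seg_ll(first[i], last[i]);
  }
  return out;
}
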