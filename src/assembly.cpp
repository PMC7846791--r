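#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// beta-mean-nearest-taxon distance between two communities given a cophenetic
// distance matrix and (optionally) an index permutation of the tips.
// 0.5 * [ mean_i min_j d(i,j) + mean_j min_i d(i,j) ]; a taxon shared by both
// communities hits d(x,x) = 0 and contributes 0.
static double bmntd_pair(const double *D, int n,
                         const std::vector<int> &A,
                         const std::vector<int> &B,
                         std::vector<double> &min_a) {
  const int na = A.size(), nb = B.size();
  min_a.assign(na, R_PosInf);
  double sum_b = 0.0;
  for (int j = 0; j < nb; ++j) {
    const double *col = D + (size_t)B[j] * n; // D symmetric: column == row
    double mnb = R_PosInf;
    for (int i = 0; i < na; ++i) {
      const double d = col[A[i]];
      if (d < mnb) mnb = d;
      if (d < min_a[i]) min_a[i] = d;
    }
    sum_b += mnb;
  }
  double sum_a = 0.0;
  for (int i = 0; i < na; ++i) sum_a += min_a[i];
  return 0.5 * (sum_a / na + sum_b / nb);
}

static std::vector<std::vector<int>> as_comms(const List &comms) {
  std::vector<std::vector<int>> out(comms.size());
  for (R_xlen_t s = 0; s < comms.size(); ++s) {
    IntegerVector v = comms[s];
    out[s] = std::vector<int>(v.begin(), v.end());
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_bmntd_matrix(NumericMatrix D, List comms) {
  const auto cs = as_comms(comms);
  const int n = cs.size(), nt = D.nrow();
  NumericMatrix out(n, n);
  std::vector<double> scratch;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b)
      out(a, b) = out(b, a) =
        bmntd_pair(REAL(D), nt, cs[a], cs[b], scratch);
  return out;
}

// Null mean and sd of betaMNTD over tip-label permutations. perms holds one
// 0-based permutation of the regional-pool tips per row, shared by all pairs
// within a replicate; communities are mapped through the permutation once per
// replicate.
// [[Rcpp::export]]
List cpp_bmntd_null(NumericMatrix D, List comms, IntegerMatrix perms) {
  const auto cs = as_comms(comms);
  const int n = cs.size(), n_null = perms.nrow(), nt = D.nrow();
  NumericMatrix msum(n, n), msq(n, n);
  std::vector<int> p(perms.ncol());
  std::vector<std::vector<int>> mapped(n);
  std::vector<double> scratch;
  for (int r = 0; r < n_null; ++r) {
    for (int k = 0; k < perms.ncol(); ++k) p[k] = perms(r, k);
    for (int s = 0; s < n; ++s) {
      mapped[s].resize(cs[s].size());
      for (size_t i = 0; i < cs[s].size(); ++i) mapped[s][i] = p[cs[s][i]];
    }
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b) {
        const double v = bmntd_pair(REAL(D), nt, mapped[a], mapped[b], scratch);
        msum(a, b) += v;
        msq(a, b) += v * v;
      }
  }
  NumericMatrix mean(n, n), sd(n, n);
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      const double m = msum(a, b) / n_null;
      double var = (msq(a, b) - n_null * m * m) / (n_null - 1);
      if (var < 0) var = 0;
      mean(a, b) = mean(b, a) = m;
      sd(a, b) = sd(b, a) = std::sqrt(var);
    }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}

// Weighted sampling of k items without replacement (successive draws
// proportional to w), via exponential keys: draw E_i/w_i and keep the k
// smallest. Uses the R RNG so results are reproducible under set.seed().
static void weighted_subsample(const NumericVector &w, int k,
                               std::vector<int> &out,
                               std::vector<std::pair<double, int>> &keys) {
  const int n = w.size();
  keys.clear();
  for (int i = 0; i < n; ++i)
    if (w[i] > 0) keys.emplace_back(exp_rand() / w[i], i);
  std::partial_sort(keys.begin(), keys.begin() + k, keys.end());
  out.clear();
  for (int i = 0; i < k; ++i) out.push_back(keys[i].second);
}

// Raup-Crick matrix: for each sample pair, n_null null pairs preserving each
// sample's richness are drawn from the pool with occupancy weights; RC =
// 2 * [ #(J_null < J_obs) + 0.5 #(J_null = J_obs) ] / n_null - 1, with J the
// Jaccard dissimilarity.
// [[Rcpp::export]]
NumericMatrix cpp_raup_crick(LogicalMatrix pres, NumericVector occupancy,
                             int n_null) {
  const int ns = pres.nrow(), n = pres.ncol();
  int pool = 0;
  for (int i = 0; i < n; ++i) if (occupancy[i] > 0) ++pool;
  std::vector<std::vector<int>> obs(ns);
  for (int s = 0; s < ns; ++s)
    for (int i = 0; i < n; ++i)
      if (pres(s, i)) obs[s].push_back(i);

  NumericMatrix rc(ns, ns);
  std::vector<int> mark(n, 0);
  std::vector<int> ca, cb;
  std::vector<std::pair<double, int>> keys;
  int stamp = 0;
  auto jaccard = [&](const std::vector<int> &A, const std::vector<int> &B) {
    ++stamp;
    for (int i : A) mark[i] = stamp;
    int shared = 0;
    for (int j : B) if (mark[j] == stamp) ++shared;
    const int uni = (int)A.size() + (int)B.size() - shared;
    return 1.0 - (double)shared / uni;
  };

  RNGScope scope;
  for (int a = 0; a < ns; ++a)
    for (int b = a + 1; b < ns; ++b) {
      const int ka = obs[a].size(), kb = obs[b].size();
      if (ka == 0 || kb == 0) stop("empty community in Raup-Crick");
      if (ka > pool || kb > pool) stop("sample richness exceeds pool size");
      const double j_obs = jaccard(obs[a], obs[b]);
      double below = 0.0, ties = 0.0;
      for (int r = 0; r < n_null; ++r) {
        weighted_subsample(occupancy, ka, ca, keys);
        weighted_subsample(occupancy, kb, cb, keys);
        const double j_null = jaccard(ca, cb);
        if (j_null < j_obs - 1e-12) below += 1.0;
        else if (j_null < j_obs + 1e-12) ties += 1.0;
      }
      rc(a, b) = rc(b, a) = 2.0 * ((below + 0.5 * ties) / n_null) - 1.0;
    }
  return rc;
}
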