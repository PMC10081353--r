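#include <Rcpp.h>
using namespace Rcpp;

// Discrete Frechet distance between point sequences P (n x d) and Q (m x d):
// dynamic program over the coupling lattice,
//   ca(i,j) = max(d(P_i, Q_j), min(ca(i-1,j), ca(i-1,j-1), ca(i,j-1))),
// minimizing the maximal pointwise distance over monotone couplings.
// Optionally backtracks one optimal coupling (greedy minimal predecessor).

static double pt_dist(const NumericMatrix& P, int i, const NumericMatrix& Q,
                      int j) {
  double s = 0.0;
  for (int d = 0; d < P.ncol(); ++d) {
    double diff = P(i, d) - Q(j, d);
    s += diff * diff;
  }
  return std::sqrt(s);
}

// [[Rcpp::export]]
List frechet_dp(NumericMatrix P, NumericMatrix Q, bool coupling) {
  const int n = P.nrow(), m = Q.nrow();
  if (n < 1 || m < 1) stop("both curves need at least one point");
  if (P.ncol() != Q.ncol()) stop("dimension mismatch");
  std::vector<double> ca((size_t)n * m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = pt_dist(P, i, Q, j);
      double prev;
      if (i == 0 && j == 0) {
        prev = 0.0;
      } else if (i == 0) {
        prev = ca[(size_t)j - 1];
      } else if (j == 0) {
        prev = ca[(size_t)(i - 1) * m];
      } else {
        prev = std::min({ca[(size_t)(i - 1) * m + j],
                         ca[(size_t)(i - 1) * m + j - 1],
                         ca[(size_t)i * m + j - 1]});
      }
      ca[(size_t)i * m + j] = std::max(d, prev);
    }
  }
  double dist = ca[(size_t)n * m - 1];
  if (!coupling) return List::create(_["distance"] = dist);

  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i == 0) {
      --j;
    } else if (j == 0) {
      --i;
    } else {
      double up = ca[(size_t)(i - 1) * m + j];
      double diag = ca[(size_t)(i - 1) * m + j - 1];
      double left = ca[(size_t)i * m + j - 1];
      if (diag <= up && diag <= left) {
        --i; --j;
      } else if (up <= left) {
        --i;
      } else {
        --j;
      }
    }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  IntegerMatrix path(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    path(k, 0) = pi[k];
    path(k, 1) = pj[k];
  }
  return List::create(_["distance"] = dist, _["coupling"] = path);
}
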