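#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Distance comparisons carry an absolute slack far below the rank-lattice
// spacing (>= 1/(2N)) so that exact rank distances are not lost to
// floating-point rounding of k/N arithmetic.
static const double EPS_SLACK = 1e-12;

// Pairwise-distance counting and recurrence line histograms.
// All routines work on the 1-d series directly so that no N x N matrix is
// ever materialised; counts are returned as doubles because N^2 exceeds
// .Machine$integer.max already at N = 46341.

// Number of ordered pairs (i, j), i = j included, with |x_i - x_j| <= eps.
// `xs` must be sorted increasingly.
// [[Rcpp::export]]
double cpp_count_pairs_le(NumericVector xs, double eps) {
  const int n = xs.size();
  double count = 0.0;
  int lo = 0;
  for (int j = 0; j < n; ++j) {
    while (xs[j] - xs[lo] > eps + EPS_SLACK) ++lo;
    // symmetric window: elements within eps below j, mirrored above
    count += 2.0 * (j - lo) + 1.0;
  }
  return count;
}

// Largest attained pairwise distance <= v (0 if none besides the trivial
// i = j pairs). `xs` sorted increasingly.
// [[Rcpp::export]]
double cpp_largest_distance_le(NumericVector xs, double v) {
  const int n = xs.size();
  double best = 0.0;
  int lo = 0;
  for (int j = 0; j < n; ++j) {
    while (xs[j] - xs[lo] > v + EPS_SLACK) ++lo;
    double d = xs[j] - xs[lo];
    if (d > best) best = d;
  }
  return best;
}

static inline bool recurrent(const NumericVector& x, int i, int j,
                             int m, int tau, double eps) {
  // maximum-norm distance between delay vectors v_i, v_j
  for (int k = 0; k < m; ++k) {
    double d = x[i + k * tau] - x[j + k * tau];
    if (d < 0) d = -d;
    if (d > eps + EPS_SLACK) return false;
  }
  return true;
}

// Full histograms of maximal diagonal and vertical runs of the (implicit)
// recurrence matrix of `x` with threshold eps and (m, tau) delay embedding.
// Diagonal runs: all off-LOI diagonals, both triangles (the matrix is
// symmetric, so the upper-triangle histogram is doubled); diagonals at
// offset <= theiler are skipped. Vertical runs: every column of the full
// matrix, LOI included. Histograms contain *all* maximal run lengths
// (>= 1); minimum-length filtering happens in R.
// [[Rcpp::export]]
List cpp_rqa_histograms(NumericVector x, double eps, int m, int tau,
                        int theiler) {
  const int nv = x.size() - (m - 1) * tau;  // number of delay vectors
  if (nv < 2) stop("embedding leaves fewer than 2 state vectors");

  std::vector<double> dhist(nv + 1, 0.0), vhist(nv + 1, 0.0);
  double n_offdiag = 0.0;  // recurrence points off the LOI (and beyond theiler)

  for (int d = theiler + 1; d < nv; ++d) {
    int run = 0;
    for (int i = 0; i + d < nv; ++i) {
      if (recurrent(x, i, i + d, m, tau, eps)) {
        ++run;
        n_offdiag += 2.0;
      } else if (run > 0) {
        dhist[run] += 2.0;  // both triangles
        run = 0;
      }
    }
    if (run > 0) dhist[run] += 2.0;
  }

  double n_total = n_offdiag + nv;  // LOI contributes nv points
  for (int j = 0; j < nv; ++j) {
    int run = 0;
    for (int i = 0; i < nv; ++i) {
      if (recurrent(x, i, j, m, tau, eps)) {
        ++run;
      } else if (run > 0) {
        vhist[run] += 1.0;
        run = 0;
      }
    }
    if (run > 0) vhist[run] += 1.0;
  }

  return List::create(_["diag_hist"] = NumericVector(dhist.begin() + 1, dhist.end()),
                      _["vert_hist"] = NumericVector(vhist.begin() + 1, vhist.end()),
                      _["n_total"] = n_total,
                      _["n_offdiag"] = n_offdiag,
                      _["n"] = nv);
}
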