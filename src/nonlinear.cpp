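#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman-Moorman convention):
// B = pairs (i<j) of length-M templates within Chebyshev distance r,
// A = the subset whose (M+1)-sample extensions also match. Both template
// sets run over i = 0..N-M-1 so every counted template has an extension;
// self-matches are excluded by construction.
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int M, double r) {
  const int n = x.size();
  const int nt = n - M;  // number of templates with an (M+1)-extension
  if (nt < 2) stop("series too short for template length M");
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < M; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(x[i + M] - x[j + M]) <= r) A += 1.0;
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}

// False-nearest-neighbour fractions for embedding dimensions 1..m_max
// (Kennel criterion): for each delay vector in dimension m, find its
// Euclidean nearest neighbour, then flag it false when the extra
// (m+1)-th coordinate either inflates the distance by more than Rtol or
// pushes the new distance beyond Atol times the attractor size.
// [[Rcpp::export]]
NumericVector fnn_fractions_cpp(NumericVector x, int tau, int m_max,
                                double Rtol, double Atol) {
  const int n = x.size();
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  double sd = 0.0;
  for (int i = 0; i < n; ++i) sd += (x[i] - mean) * (x[i] - mean);
  sd = std::sqrt(sd / (n - 1));
  NumericVector frac(m_max, NA_REAL);
  for (int m = 1; m <= m_max; ++m) {
    const int nv = n - m * tau;  // vectors that still have an (m+1)-th coordinate
    if (nv < 2) break;
    int false_nn = 0, total = 0;
    for (int i = 0; i < nv; ++i) {
      double best = std::numeric_limits<double>::infinity();
      int bj = -1;
      for (int j = 0; j < nv; ++j) {
        if (j == i) continue;
        double d2 = 0.0;
        for (int k = 0; k < m; ++k) {
          double d = x[i + k * tau] - x[j + k * tau];
          d2 += d * d;
          if (d2 >= best) break;
        }
        if (d2 < best) { best = d2; bj = j; }
      }
      if (bj < 0) continue;
      double Rm = std::sqrt(best);
      double extra = std::fabs(x[i + m * tau] - x[bj + m * tau]);
      double Rm1 = std::sqrt(best + extra * extra);
      // ignore distance increments at the floating-point noise floor:
      // exactly periodic signals yield duplicate delay vectors whose
      // distance ratio is pure rounding error
      double eps = 1e-10 * sd;
      bool ratio_false = extra > eps && (Rm <= eps || (extra / Rm) > Rtol);
      bool is_false = ratio_false || (Rm1 / sd) > Atol;
      if (is_false) ++false_nn;
      ++total;
    }
    frac[m - 1] = total > 0 ? (double)false_nn / total : NA_REAL;
  }
  return frac;
}

// Rosenstein divergence curve: embed x with (m, tau); for each point find
// the Euclidean nearest neighbour at temporal distance > theiler; then
// y(k) = mean over pairs of log2 ||X_{i+k} - X_{j+k}||, pairs dropped once
// either trajectory runs off the end or the distance is exactly zero.
// [[Rcpp::export]]
List rosenstein_divergence_cpp(NumericVector x, int m, int tau,
                               int theiler, int max_steps) {
  const int n = x.size();
  const int nv = n - (m - 1) * tau;
  if (nv < theiler + 2) stop("too few delay vectors for the Theiler window");
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  double sd = 0.0;
  for (int i = 0; i < n; ++i) sd += (x[i] - mean) * (x[i] - mean);
  sd = std::sqrt(sd / (n - 1));
  // neighbours separated by less than the floating-point noise floor carry
  // no divergence information (exactly periodic signals duplicate states)
  const double eps2 = 1e-16 * sd * sd;
  std::vector<int> nbr(nv, -1);
  for (int i = 0; i < nv; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bj = -1;
    for (int j = 0; j < nv; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = x[i + k * tau] - x[j + k * tau];
        d2 += d * d;
        if (d2 >= best) break;
      }
      if (d2 < best && d2 > eps2) { best = d2; bj = j; }
    }
    nbr[i] = bj;
  }
  NumericVector curve(max_steps + 1, NA_REAL);
  IntegerVector npairs(max_steps + 1, 0);
  for (int k = 0; k <= max_steps; ++k) {
    double acc = 0.0;
    int cnt = 0;
    for (int i = 0; i < nv; ++i) {
      int j = nbr[i];
      if (j < 0 || i + k >= nv || j + k >= nv) continue;
      double d2 = 0.0;
      for (int q = 0; q < m; ++q) {
        double d = x[i + k + q * tau] - x[j + k + q * tau];
        d2 += d * d;
      }
      if (d2 <= 0.0) continue;
      acc += 0.5 * std::log2(d2);
      ++cnt;
    }
    if (cnt > 0) { curve[k] = acc / cnt; npairs[k] = cnt; }
  }
  return List::create(_["log2_dist"] = curve, _["n_pairs"] = npairs);
}
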