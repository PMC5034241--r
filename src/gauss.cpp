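#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "dimerlink.h"

using namespace Rcpp;

static const double FOUR_PI = 4.0 * M_PI;

double gauss_midpoint_sum(const double* m1, const double* b1, std::size_t n1,
                          const double* m2, const double* b2, std::size_t n2,
                          double* min_dist, std::size_t* argmin_i,
                          std::size_t* argmin_j) {
  // Blocked accumulation: one partial sum per i-row, then a second pass.
  // Keeps round-off growth ~O(sqrt(n)) instead of O(n) for n1*n2 terms.
  std::vector<double> row_sums(n1, 0.0);
  double mind = R_PosInf;
  std::size_t ai = 0, aj = 0;
  for (std::size_t i = 0; i < n1; ++i) {
    const double mx = m1[3 * i], my = m1[3 * i + 1], mz = m1[3 * i + 2];
    const double bx = b1[3 * i], by = b1[3 * i + 1], bz = b1[3 * i + 2];
    double acc = 0.0;
    for (std::size_t j = 0; j < n2; ++j) {
      const double rx = mx - m2[3 * j];
      const double ry = my - m2[3 * j + 1];
      const double rz = mz - m2[3 * j + 2];
      const double cx = by * b2[3 * j + 2] - bz * b2[3 * j + 1];
      const double cy = bz * b2[3 * j]     - bx * b2[3 * j + 2];
      const double cz = bx * b2[3 * j + 1] - by * b2[3 * j];
      const double r2 = rx * rx + ry * ry + rz * rz;
      const double r = std::sqrt(r2);
      if (r < mind) { mind = r; ai = i; aj = j; }
      if (r > 0.0) acc += (rx * cx + ry * cy + rz * cz) / (r2 * r);
    }
    row_sums[i] = acc;
  }
  double total = 0.0;
  for (std::size_t i = 0; i < n1; ++i) total += row_sums[i];
  if (min_dist) *min_dist = mind;
  if (argmin_i) *argmin_i = ai;
  if (argmin_j) *argmin_j = aj;
  return total / FOUR_PI;
}

static void open_segments(const double* x, std::size_t n, std::vector<double>& m,
                          std::vector<double>& b) {
  m.resize(3 * (n - 1));
  b.resize(3 * (n - 1));
  for (std::size_t i = 0; i + 1 < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      b[3 * i + d] = x[3 * (i + 1) + d] - x[3 * i + d];
      m[3 * i + d] = 0.5 * (x[3 * (i + 1) + d] + x[3 * i + d]);
    }
  }
}

double gauss_open_chains(const double* xa, std::size_t na,
                         const double* xb, std::size_t nb) {
  std::vector<double> ma, ba, mb, bb;
  open_segments(xa, na, ma, ba);
  open_segments(xb, nb, mb, bb);
  return gauss_midpoint_sum(ma.data(), ba.data(), na - 1,
                            mb.data(), bb.data(), nb - 1,
                            nullptr, nullptr, nullptr);
}

// [[Rcpp::export]]
List cpp_gauss_pair_sum(NumericMatrix m1, NumericMatrix b1,
                        NumericMatrix m2, NumericMatrix b2) {
  const std::size_t n1 = m1.nrow(), n2 = m2.nrow();
  // Repack into row-major contiguous arrays (R matrices are column-major).
  std::vector<double> M1(3 * n1), B1(3 * n1), M2(3 * n2), B2(3 * n2);
  for (std::size_t i = 0; i < n1; ++i)
    for (int d = 0; d < 3; ++d) {
      M1[3 * i + d] = m1(i, d);
      B1[3 * i + d] = b1(i, d);
    }
  for (std::size_t j = 0; j < n2; ++j)
    for (int d = 0; d < 3; ++d) {
      M2[3 * j + d] = m2(j, d);
      B2[3 * j + d] = b2(j, d);
    }
  double mind;
  std::size_t ai, aj;
  double val = gauss_midpoint_sum(M1.data(), B1.data(), n1,
                                  M2.data(), B2.data(), n2, &mind, &ai, &aj);
  return List::create(_["value"] = val,
                      _["n_pairs"] = (double)(n1 * n2),
                      _["min_dist"] = mind,
                      _["argmin_i"] = (int)(ai + 1),
                      _["argmin_j"] = (int)(aj + 1));
}

// [[Rcpp::export]]
double cpp_gauss_open_chains(NumericMatrix xa, NumericMatrix xb) {
  const std::size_t na = xa.nrow(), nb = xb.nrow();
  std::vector<double> A(3 * na), B(3 * nb);
  for (std::size_t i = 0; i < na; ++i)
    for (int d = 0; d < 3; ++d) A[3 * i + d] = xa(i, d);
  for (std::size_t i = 0; i < nb; ++i)
    for (int d = 0; d < 3; ++d) B[3 * i + d] = xb(i, d);
  return gauss_open_chains(A.data(), na, B.data(), nb);
}
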