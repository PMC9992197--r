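#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with zero initial conditions.
static void df2t(const std::vector<double>& b, const std::vector<double>& a,
                 const double* x, double* y, const int n) {
  const int nf = (int)b.size();           // b and a padded to equal length
  std::vector<double> z(nf, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int j = 1; j < nf; ++j)
      z[j - 1] = b[j] * xi - a[j] * yi + (j < nf - 1 ? z[j] : 0.0);
    y[i] = yi;
  }
}

static void pad_odd(const double* x, int n, int pad, std::vector<double>& out) {
  out.resize(n + 2 * pad);
  for (int i = 0; i < pad; ++i) out[i] = 2.0 * x[0] - x[pad - i];
  std::copy(x, x + n, out.begin() + pad);
  for (int i = 0; i < pad; ++i) out[n + pad + i] = 2.0 * x[n - 1] - x[n - 2 - i];
}

// Zero-phase (forward-backward) IIR filtering of each matrix row, with
// odd-reflection end padding of `pad` samples to absorb edge transients.
// [[Rcpp::export(name = ".cpp_filtfilt_rows")]]
NumericMatrix cpp_filtfilt_rows(NumericVector b, NumericVector a,
                                NumericMatrix X, int pad) {
  const int nr = X.nrow(), nc = X.ncol();
  if (pad >= nc) pad = nc - 1;
  if (pad < 0) pad = 0;
  const int nf = std::max(b.size(), a.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  if (aa[0] == 0.0) stop("a[0] must be non-zero");
  for (int i = 0; i < nf; ++i) { bb[i] /= aa[0]; }
  for (int i = nf - 1; i >= 0; --i) aa[i] /= aa[0];

  NumericMatrix out(nr, nc);
  std::vector<double> row(nc), padded, tmp1, tmp2;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) row[c] = X(r, c);
    pad_odd(row.data(), nc, pad, padded);
    const int m = (int)padded.size();
    tmp1.resize(m); tmp2.resize(m);
    df2t(bb, aa, padded.data(), tmp1.data(), m);
    std::reverse(tmp1.begin(), tmp1.end());
    df2t(bb, aa, tmp1.data(), tmp2.data(), m);
    std::reverse(tmp2.begin(), tmp2.end());
    for (int c = 0; c < nc; ++c) out(r, c) = tmp2[pad + c];
  }
  return out;
}

// Zero-phase filtering of each matrix row through a CASCADE of IIR
// sections (one per row of bmat/amat), padding once: forward cascade,
// reverse, forward cascade, reverse. Sections of length 5 (order 4,
// e.g. second-order Butterworth band-stops) use an unrolled kernel.
// [[Rcpp::export(name = ".cpp_filtfilt_cascade_rows")]]
NumericMatrix cpp_filtfilt_cascade_rows(NumericMatrix bmat, NumericMatrix amat,
                                        NumericMatrix X, int pad) {
  const int nr = X.nrow(), nc = X.ncol(), ns = bmat.nrow();
  if (bmat.ncol() != amat.ncol() || bmat.nrow() != amat.nrow())
    stop("b/a coefficient matrices must match");
  if (pad >= nc) pad = nc - 1;
  if (pad < 0) pad = 0;
  const int nf = bmat.ncol();
  std::vector< std::vector<double> > bs(ns), as(ns);
  for (int s = 0; s < ns; ++s) {
    bs[s].resize(nf); as[s].resize(nf);
    const double a0 = amat(s, 0);
    if (a0 == 0.0) stop("a[0] must be non-zero");
    for (int j = 0; j < nf; ++j) {
      bs[s][j] = bmat(s, j) / a0;
      as[s][j] = amat(s, j) / a0;
    }
  }
  NumericMatrix out(nr, nc);
  std::vector<double> row(nc), padded, tmp;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) row[c] = X(r, c);
    pad_odd(row.data(), nc, pad, padded);
    const int m = (int)padded.size();
    tmp.resize(m);
    for (int dir = 0; dir < 2; ++dir) {
      for (int s = 0; s < ns; ++s) {
        if (nf == 5) {
          const double b0 = bs[s][0], b1 = bs[s][1], b2 = bs[s][2],
                       b3 = bs[s][3], b4 = bs[s][4];
          const double a1 = as[s][1], a2 = as[s][2], a3 = as[s][3],
                       a4 = as[s][4];
          double z1 = 0, z2 = 0, z3 = 0, z4 = 0;
          double* x = padded.data();
          for (int i = 0; i < m; ++i) {
            const double xi = x[i];
            const double yi = b0 * xi + z1;
            z1 = b1 * xi - a1 * yi + z2;
            z2 = b2 * xi - a2 * yi + z3;
            z3 = b3 * xi - a3 * yi + z4;
            z4 = b4 * xi - a4 * yi;
            x[i] = yi;
          }
        } else {
          df2t(bs[s], as[s], padded.data(), tmp.data(), m);
          padded.swap(tmp);
          tmp.resize(m);
        }
      }
      std::reverse(padded.begin(), padded.end());
    }
    for (int c = 0; c < nc; ++c) out(r, c) = padded[pad + c];
  }
  return out;
}

// One-pass IIR filtering of each matrix column (series in columns),
// zero initial conditions.
// [[Rcpp::export(name = ".cpp_filter_cols")]]
NumericMatrix cpp_filter_cols(NumericVector b, NumericVector a,
                              NumericMatrix X) {
  const int nr = X.nrow(), nc = X.ncol();
  const int nf = std::max(b.size(), a.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  if (aa[0] == 0.0) stop("a[0] must be non-zero");
  for (int i = 0; i < nf; ++i) bb[i] /= aa[0];
  for (int i = nf - 1; i >= 0; --i) aa[i] /= aa[0];
  NumericMatrix out(nr, nc);
  std::vector<double> xin(nr), yout(nr);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) xin[r] = X(r, c);
    df2t(bb, aa, xin.data(), yout.data(), nr);
    for (int r = 0; r < nr; ++r) out(r, c) = yout[r];
  }
  return out;
}
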