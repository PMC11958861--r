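#include <Rcpp.h>
using namespace Rcpp;

// Column-major 3D image-to-column lowering for valid convolution.
//
// x is a 4D array [n1, n2, n3, C].  The result is a [k^3 * C, P] matrix whose
// column p holds the receptive field of output position p (positions ordered
// with axis 1 fastest, matching R's column-major array layout) and whose rows
// are ordered k1-fastest, then k2, k3, channel — the same ordering produced by
// flattening a weight array of dim [k, k, k, C_in, C_out] with matrix().
// Loops are position-major so writes stream down each output column.

// [[Rcpp::export(name = ".im2col3d")]]
NumericMatrix im2col3d(NumericVector x, int k, int stride) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("x must be a 4D array [n1, n2, n3, C]");
  const int n1 = d[0], n2 = d[1], n3 = d[2], C = d[3];
  if (n1 < k || n2 < k || n3 < k) stop("input smaller than kernel");
  if (stride < 1) stop("stride must be >= 1");
  const int o1 = (n1 - k) / stride + 1;
  const int o2 = (n2 - k) / stride + 1;
  const int o3 = (n3 - k) / stride + 1;
  const R_xlen_t P = (R_xlen_t)o1 * o2 * o3;
  const R_xlen_t K = (R_xlen_t)k * k * k * C;
  NumericMatrix out((int)K, (int)P);
  const double* xp = REAL(x);
  double* op = REAL(out);
  const R_xlen_t plane = (R_xlen_t)n1 * n2;
  const R_xlen_t vol = plane * n3;
  for (int p3 = 0; p3 < o3; ++p3)
    for (int p2 = 0; p2 < o2; ++p2)
      for (int p1 = 0; p1 < o1; ++p1) {
        double* col = op + K * (p1 + (R_xlen_t)o1 * (p2 + (R_xlen_t)o2 * p3));
        const R_xlen_t base = (R_xlen_t)p1 * stride +
          (R_xlen_t)(p2 * stride) * n1 + (R_xlen_t)(p3 * stride) * plane;
        for (int c = 0; c < C; ++c) {
          const double* xc = xp + base + vol * c;
          for (int k3 = 0; k3 < k; ++k3)
            for (int k2 = 0; k2 < k; ++k2) {
              const double* src = xc + (R_xlen_t)k3 * plane + (R_xlen_t)k2 * n1;
              for (int k1 = 0; k1 < k; ++k1) *col++ = src[k1];
            }
        }
      }
  return out;
}

// Adjoint of im2col3d: scatter-adds columns back onto a zeroed [od1, od2, od3, C]
// array.  Used both as the forward pass of a stride-s transposed convolution and
// as the data-gradient of a stride-s convolution.

// [[Rcpp::export(name = ".col2im3d")]]
NumericVector col2im3d(NumericMatrix cols, IntegerVector odim, int C, int k, int stride) {
  const int n1 = odim[0], n2 = odim[1], n3 = odim[2];
  if (n1 < k || n2 < k || n3 < k) stop("output smaller than kernel");
  const int o1 = (n1 - k) / stride + 1;
  const int o2 = (n2 - k) / stride + 1;
  const int o3 = (n3 - k) / stride + 1;
  const R_xlen_t P = (R_xlen_t)o1 * o2 * o3;
  const R_xlen_t K = (R_xlen_t)k * k * k * C;
  if (cols.nrow() != (int)K || cols.ncol() != (int)P)
    stop("cols has dimensions inconsistent with the output grid");
  NumericVector out((R_xlen_t)n1 * n2 * n3 * C);
  out.attr("dim") = IntegerVector::create(n1, n2, n3, C);
  const double* cp = REAL(cols);
  double* op = REAL(out);
  const R_xlen_t plane = (R_xlen_t)n1 * n2;
  const R_xlen_t vol = plane * n3;
  for (int p3 = 0; p3 < o3; ++p3)
    for (int p2 = 0; p2 < o2; ++p2)
      for (int p1 = 0; p1 < o1; ++p1) {
        const double* col = cp + K * (p1 + (R_xlen_t)o1 * (p2 + (R_xlen_t)o2 * p3));
        const R_xlen_t base = (R_xlen_t)p1 * stride +
          (R_xlen_t)(p2 * stride) * n1 + (R_xlen_t)(p3 * stride) * plane;
        for (int c = 0; c < C; ++c) {
          double* xc = op + base + vol * c;
          for (int k3 = 0; k3 < k; ++k3)
            for (int k2 = 0; k2 < k; ++k2) {
              double* dst = xc + (R_xlen_t)k3 * plane + (R_xlen_t)k2 * n1;
              for (int k1 = 0; k1 < k; ++k1) dst[k1] += *col++;
            }
        }
      }
  return out;
}

// In-place rectifier for large intermediate feature arrays.

// [[Rcpp::export(name = ".relu_inplace")]]
NumericVector relu_inplace(NumericVector x) {
  double* p = REAL(x);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
  return x;
}
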