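// Hot loops of the feature-extraction chain: spectral covariance tensors,
// robust aggregation over segments, per-segment projection onto PCA
// loadings, and zero-phase IIR filtering.  Everything here is plain
// numerics; all algorithmic decisions (filter design, estimator choice,
// component selection) live on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Robust location estimate over a vector of per-segment values.
// method: 0 = median, 1 = trimmed mean (fraction `trim` cut from each
// tail, matching base R's mean(x, trim=)), 2 = plain mean.
static double agg_buf(double* buf, const uword n, const int method,
                      const double trim) {
  if (method == 2) {
    double s = 0;
    for (uword i = 0; i < n; ++i) s += buf[i];
    return s / n;
  }
  if (method == 0) {
    const uword h = n / 2;
    std::nth_element(buf, buf + h, buf + n);
    const double hi = buf[h];
    if (n % 2 == 1) return hi;
    const double lo = *std::max_element(buf, buf + h);
    return (lo + hi) / 2.0;
  }
  std::sort(buf, buf + n);
  uword lo = static_cast<uword>(std::floor(n * trim));
  if (2 * lo >= n) lo = (n - 1) / 2;
  double s = 0;
  for (uword i = lo; i < n - lo; ++i) s += buf[i];
  return s / (n - 2 * lo);
}

static double aggregate_vec(const vec& x, const int method, const double trim) {
  vec tmp = x;
  return agg_buf(tmp.memptr(), tmp.n_elem, method, trim);
}

// Full-spectral-resolution covariance tensor chi[j, p, i] =
// sigma[j, c_p, i] * conj(sigma[j, k_p, i]) for every unordered channel
// pair p (auto pairs first).  sigma is n_freq x n_channels x n_segments;
// pairs is n_pairs x 2, zero-based.
// [[Rcpp::export]]
arma::cx_cube cpp_chi_tensor(const arma::cx_cube& sigma,
                             const arma::umat& pairs) {
  const uword nf = sigma.n_rows, np = pairs.n_rows, ns = sigma.n_slices;
  cx_cube chi(nf, np, ns);
  for (uword i = 0; i < ns; ++i) {
    for (uword p = 0; p < np; ++p) {
      const uword c = pairs(p, 0), k = pairs(p, 1);
      chi.slice(i).col(p) = sigma.slice(i).col(c) % conj(sigma.slice(i).col(k));
      if (c == k) {
        // auto-covariances are |sigma|^2: clamp the imaginary round-off
        chi.slice(i).col(p) = cx_vec(real(chi.slice(i).col(p)),
                                     zeros<vec>(nf));
      }
    }
  }
  return chi;
}

// Robust aggregation of a covariance tensor over segments into the flat
// base-feature vector, ordered (pair, frequency, {re, im}).
// auto_pair[p] marks pairs whose imaginary slots are structural zeros.
// [[Rcpp::export]]
arma::vec cpp_aggregate_chi(const arma::cx_cube& chi,
                            const arma::uvec& auto_pair,
                            const int method, const double trim) {
  const uword nf = chi.n_rows, np = chi.n_cols, ns = chi.n_slices;
  vec out(np * nf * 2);
  vec re(ns), im(ns);
  for (uword p = 0; p < np; ++p) {
    const bool is_auto = auto_pair(p) != 0;
    for (uword j = 0; j < nf; ++j) {
      for (uword i = 0; i < ns; ++i) {
        const cx_double z = chi(j, p, i);
        re(i) = z.real();
        im(i) = z.imag();
      }
      const uword base = p * nf * 2 + j * 2;
      out(base) = aggregate_vec(re, method, trim);
      out(base + 1) = is_auto ? 0.0 : aggregate_vec(im, method, trim);
    }
  }
  return out;
}

// Per-segment projection scores.  loadings is 180 x n_out where column
// q corresponds to (pair p, component a) with q = 2*p + a; center is the
// training-mean base-feature vector (length n_pairs*n_freq*2).  Returns
// an n_segments x n_out matrix of raw projection scores; the robust
// expectation over segments is taken by the caller.
// [[Rcpp::export]]
arma::mat cpp_segment_scores(const arma::cx_cube& chi,
                             const arma::mat& loadings,
                             const arma::vec& center) {
  const uword nf = chi.n_rows, np = chi.n_cols, ns = chi.n_slices;
  const uword block = nf * 2;
  const uword n_out = loadings.n_cols;
  if (loadings.n_rows != block)
    Rcpp::stop("loading length does not match the per-pair block size");
  mat out(ns, n_out);
  vec x(block);
  for (uword i = 0; i < ns; ++i) {
    for (uword p = 0; p < np; ++p) {
      for (uword j = 0; j < nf; ++j) {
        const cx_double z = chi(j, p, i);
        x(2 * j) = z.real() - center(p * block + 2 * j);
        x(2 * j + 1) = z.imag() - center(p * block + 2 * j + 1);
      }
      for (uword a = 0; a < 2; ++a) {
        const uword q = 2 * p + a;
        if (q < n_out) out(i, q) = dot(x, loadings.col(q));
      }
    }
  }
  return out;
}

// Column-wise robust aggregate (shared estimator with cpp_aggregate_chi).
// [[Rcpp::export]]
arma::vec cpp_col_aggregate(const arma::mat& x, const int method,
                            const double trim) {
  vec out(x.n_cols);
  for (uword j = 0; j < x.n_cols; ++j)
    out(j) = aggregate_vec(x.col(j), method, trim);
  return out;
}

// reorganize sigma (n_freq x n_channels x n_segments) into contiguous
// n_segments x n_freq real/imaginary matrices per channel, so
// per-frequency columns are contiguous across segments and the
// covariance products stay in real arithmetic:
// Re(chi) = Rc Rk + Ic Ik, Im(chi) = Ic Rk - Rc Ik.
static void per_channel_ri(const cx_cube& sigma,
                           std::vector<mat>& Rc, std::vector<mat>& Ic) {
  const uword nf = sigma.n_rows, nc = sigma.n_cols, ns = sigma.n_slices;
  Rc.resize(nc);
  Ic.resize(nc);
  for (uword c = 0; c < nc; ++c) {
    Rc[c].set_size(ns, nf);
    Ic[c].set_size(ns, nf);
    for (uword i = 0; i < ns; ++i)
      for (uword j = 0; j < nf; ++j) {
        const cx_double z = sigma(j, c, i);
        Rc[c](i, j) = z.real();
        Ic[c](i, j) = z.imag();
      }
  }
}

// Fast path equivalent of cpp_chi_tensor + cpp_aggregate_chi that never
// materializes the full covariance tensor.
// [[Rcpp::export]]
arma::vec cpp_aggregate_sigma(const arma::cx_cube& sigma,
                              const arma::umat& pairs,
                              const int method, const double trim) {
  const uword nf = sigma.n_rows, np = pairs.n_rows, ns = sigma.n_slices;
  std::vector<mat> Rc, Ic;
  per_channel_ri(sigma, Rc, Ic);
  vec out(np * nf * 2);
  mat R(ns, nf), I(ns, nf);     // mutated in place by agg_buf
  for (uword p = 0; p < np; ++p) {
    const uword c = pairs(p, 0), k = pairs(p, 1);
    const bool is_auto = (c == k);
    R = Rc[c] % Rc[k] + Ic[c] % Ic[k];
    if (!is_auto) I = Ic[c] % Rc[k] - Rc[c] % Ic[k];
    for (uword j = 0; j < nf; ++j) {
      const uword base = p * nf * 2 + j * 2;
      out(base) = agg_buf(R.colptr(j), ns, method, trim);
      out(base + 1) = is_auto ? 0.0 : agg_buf(I.colptr(j), ns, method, trim);
    }
  }
  return out;
}

// Fast path equivalent of cpp_chi_tensor + cpp_segment_scores.  The
// per-pair score block is the matrix product of the segment-major
// real/imaginary covariance parts with the de-interleaved loadings; the
// centring term is a constant per output column.
// [[Rcpp::export]]
arma::mat cpp_segment_scores_sigma(const arma::cx_cube& sigma,
                                   const arma::umat& pairs,
                                   const arma::mat& loadings,
                                   const arma::vec& center) {
  const uword nf = sigma.n_rows, np = pairs.n_rows, ns = sigma.n_slices;
  const uword block = nf * 2;
  const uword n_out = loadings.n_cols;
  if (loadings.n_rows != block)
    Rcpp::stop("loading length does not match the per-pair block size");
  std::vector<mat> Rc, Ic;
  per_channel_ri(sigma, Rc, Ic);
  mat out(ns, n_out);
  mat R(ns, nf), I(ns, nf);
  for (uword p = 0; p < np; ++p) {
    const uword q0 = 2 * p;
    if (q0 >= n_out) break;
    const uword nq = std::min<uword>(2, n_out - q0);
    const uword c = pairs(p, 0), k = pairs(p, 1);
    const bool is_auto = (c == k);
    R = Rc[c] % Rc[k] + Ic[c] % Ic[k];
    mat Lre(nf, nq), Lim(nf, nq);
    for (uword a = 0; a < nq; ++a)
      for (uword j = 0; j < nf; ++j) {
        Lre(j, a) = loadings(2 * j, q0 + a);
        Lim(j, a) = loadings(2 * j + 1, q0 + a);
      }
    mat res = R * Lre;
    if (!is_auto) {
      I = Ic[c] % Rc[k] - Rc[c] % Ic[k];
      res += I * Lim;
    }
    const vec ctr = center.subvec(p * block, (p + 1) * block - 1);
    for (uword a = 0; a < nq; ++a)
      out.col(q0 + a) = res.col(a) - dot(ctr, loadings.col(q0 + a));
  }
  return out;
}

// Direct-form-II-transposed IIR filter with externally supplied initial
// state (state vector length = order).
static vec iir_filter(const vec& b, const vec& a, const vec& x, vec z0) {
  const uword n = x.n_elem, m = z0.n_elem;
  vec y(n);
  const double* xp = x.memptr();
  const double* bp = b.memptr();
  const double* ap = a.memptr();
  double* zp = z0.memptr();
  double* yp = y.memptr();
  for (uword i = 0; i < n; ++i) {
    const double xi = xp[i];
    const double yi = bp[0] * xi + zp[0];
    for (uword k = 0; k < m - 1; ++k)
      zp[k] = bp[k + 1] * xi + zp[k + 1] - ap[k + 1] * yi;
    zp[m - 1] = bp[m] * xi - ap[m] * yi;
    yp[i] = yi;
  }
  return y;
}

// Steady-state initial filter state for a unit step (companion-matrix
// solve), used to suppress start-up transients.
static vec filter_zi(const vec& b, const vec& a) {
  const uword m = a.n_elem - 1;
  // transposed companion matrix of a: state-update matrix of the DF2T
  // realization
  mat A = zeros<mat>(m, m);
  for (uword k = 0; k < m; ++k) A(k, 0) = -a(k + 1);
  for (uword k = 0; k + 1 < m; ++k) A(k, k + 1) = 1.0;
  vec B = b.subvec(1, m) - b(0) * a.subvec(1, m);
  return solve(eye<mat>(m, m) - A, B);
}

// Zero-phase (forward-backward) filtering of each column of x with the
// transfer function b/a, using odd-reflection end padding and
// steady-state state initialization so that slow poles (the 0.1 Hz
// high-pass edge) do not leak start-up transients into the epoch.
// [[Rcpp::export]]
arma::mat cpp_filtfilt(const arma::vec& b_in, const arma::vec& a_in,
                       const arma::mat& x) {
  const uword m = std::max(b_in.n_elem, a_in.n_elem) - 1;
  vec b = zeros<vec>(m + 1), a = zeros<vec>(m + 1);
  b.head(b_in.n_elem) = b_in;
  a.head(a_in.n_elem) = a_in;
  b /= a(0);
  a /= a(0);
  const uword pad = 3 * m;
  const uword n = x.n_rows;
  if (n <= pad + 1) Rcpp::stop("signal too short for the filter order");
  const vec zi = filter_zi(b, a);
  mat out(n, x.n_cols);
  for (uword c = 0; c < x.n_cols; ++c) {
    const vec col = x.col(c);
    vec ext(n + 2 * pad);
    for (uword i = 0; i < pad; ++i)
      ext(i) = 2.0 * col(0) - col(pad - i);
    ext.subvec(pad, pad + n - 1) = col;
    for (uword i = 0; i < pad; ++i)
      ext(pad + n + i) = 2.0 * col(n - 1) - col(n - 2 - i);
    vec y = iir_filter(b, a, ext, zi * ext(0));
    y = reverse(y);
    y = iir_filter(b, a, y, zi * y(0));
    y = reverse(y);
    out.col(c) = y.subvec(pad, pad + n - 1);
  }
  return out;
}
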