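// Robust Gaussian and planar model fitting.
//
// The location/scale estimator is median-anchored: starting from the median,
// absolute residuals are sorted and the inlier set is grown from the minimum
// admissible size upward while the next residual stays within k_grow running
// standard deviations of the accepted set.  The pass is iterated to
// convergence of the centre, which removes the location bias a single pass
// retains under strongly one-sided contamination.  The scale of the accepted
// set underestimates the population scale because the set is a truncated
// Gaussian; the truncation point is estimated self-consistently from the
// acceptance radius and the classical truncated-normal variance factor is
// inverted to undo the bias.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

namespace {

struct GaussFit {
  double mu;
  double sigma;   // truncation-corrected, not floored
  double sd_raw;  // sd of accepted set
  double radius;  // acceptance radius around the final centre
  int n_used;
  bool ok;
};

// sd of a standard normal truncated to [-z, z], as a fraction of 1
double trunc_sd_factor(double z) {
  double q = std::erf(z * M_SQRT1_2);  // = 2 Phi(z) - 1
  if (q <= 1e-12) return z / std::sqrt(3.0);  // small-z limit
  double phi = std::exp(-0.5 * z * z) * 0.39894228040143268;
  double g2 = 1.0 - 2.0 * z * phi / q;
  if (g2 < 1e-12) g2 = 1e-12;
  return std::sqrt(g2);
}

// LSD radix sort on the order-preserving bit pattern of doubles; a large
// constant factor win over comparison sort for the frame-sized inputs of
// the per-frame robust means
void radix_sort_doubles(std::vector<double>& a) {
  const size_t n = a.size();
  std::vector<uint64_t> key(n), tmp(n);
  for (size_t i = 0; i < n; ++i) {
    uint64_t b;
    std::memcpy(&b, &a[i], 8);
    key[i] = (b & 0x8000000000000000ULL) ? ~b : (b | 0x8000000000000000ULL);
  }
  size_t cnt[256];
  for (int pass = 0; pass < 8; ++pass) {
    const int sh = pass * 8;
    std::fill(cnt, cnt + 256, 0);
    for (size_t i = 0; i < n; ++i) ++cnt[(key[i] >> sh) & 0xFF];
    size_t pos = 0;
    for (int b = 0; b < 256; ++b) {
      size_t c = cnt[b];
      cnt[b] = pos;
      pos += c;
    }
    for (size_t i = 0; i < n; ++i) tmp[cnt[(key[i] >> sh) & 0xFF]++] = key[i];
    key.swap(tmp);
  }
  for (size_t i = 0; i < n; ++i) {
    uint64_t b = key[i];
    b = (b & 0x8000000000000000ULL) ? (b & ~0x8000000000000000ULL) : ~b;
    std::memcpy(&a[i], &b, 8);
  }
}

GaussFit gauss_fit(std::vector<double>& x, double min_frac, double k_grow,
                   int max_iter) {
  GaussFit out{NA_REAL, NA_REAL, NA_REAL, NA_REAL, 0, false};
  const int n = static_cast<int>(x.size());
  if (n < 3) return out;

  std::vector<double> xs(x);
  if (n >= 2048) radix_sort_doubles(xs);
  else std::sort(xs.begin(), xs.end());
  double center =
      (n % 2) ? xs[n / 2] : 0.5 * (xs[n / 2 - 1] + xs[n / 2]);

  int m0 = static_cast<int>(std::ceil(min_frac * n));
  if (m0 < 2) m0 = 2;
  if (m0 > n) m0 = n;

  double mu = center, sd_raw = 0.0, radius = 0.0;
  int k = n;
  std::vector<double> v(n);

  for (int iter = 0; iter < max_iter; ++iter) {
    // order values by distance from the centre: two-pointer merge outward
    // from the centre's position in the (already sorted) values
    {
      int j = static_cast<int>(
          std::lower_bound(xs.begin(), xs.end(), center) - xs.begin());
      int i = j - 1, t = 0;
      while (i >= 0 && j < n) {
        if (center - xs[i] <= xs[j] - center) v[t++] = xs[i--];
        else v[t++] = xs[j++];
      }
      while (i >= 0) v[t++] = xs[i--];
      while (j < n) v[t++] = xs[j++];
    }
    // grow the accepted set; accumulate around the centre for conditioning
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < m0; ++i) {
      double w = v[i] - center;
      s1 += w;
      s2 += w * w;
    }
    k = m0;
    while (k < n) {
      double mk = s1 / k;
      double vark = s2 / k - mk * mk;
      if (vark < 0.0) vark = 0.0;
      double r_next = std::fabs(v[k] - center);
      if (r_next <= k_grow * std::sqrt(vark)) {
        double w = v[k] - center;
        s1 += w;
        s2 += w * w;
        ++k;
      } else {
        break;
      }
    }
    double mk = s1 / k;
    mu = center + mk;
    double vark = s2 / k - mk * mk;
    if (vark < 0.0) vark = 0.0;
    sd_raw = std::sqrt(vark * (double)k / (double)(k > 1 ? k - 1 : 1));
    radius = std::fabs(v[k - 1] - center);
    double tol = 1e-11 * (std::fabs(mu) + sd_raw);
    if (std::fabs(mu - center) <= tol) {
      center = mu;
      break;
    }
    center = mu;
  }

  // undo truncation bias: accepted set = inlier mode truncated at radius
  double sigma = sd_raw;
  if (k < n && sd_raw > 0.0) {
    for (int i = 0; i < 100; ++i) {
      double z = radius / sigma;
      double snew = (z > 8.0) ? sd_raw : sd_raw / trunc_sd_factor(z);
      if (std::fabs(snew - sigma) <= 1e-12 * sigma) {
        sigma = snew;
        break;
      }
      sigma = snew;
    }
  }

  out.mu = mu;
  out.sigma = sigma;
  out.sd_raw = sd_raw;
  out.radius = radius;
  out.n_used = k;
  out.ok = true;
  return out;
}

struct PlaneFit {
  double slope_row, slope_col, intercept;  // absolute coordinates
  double sigma;                            // robust residual scale, unfloored
  int n_used;
  int status;  // 0 ok, 1 too few points, 2 collinear/singular
};

// weighted (0/1) least-squares plane through (r, c, v), coords centred
// internally; inliers selected by a robust Gaussian fit to the residuals.
PlaneFit plane_fit(const std::vector<double>& r, const std::vector<double>& c,
                   const std::vector<double>& val, double min_frac,
                   double k_grow, double k_plane, int max_iter,
                   int g_iter) {
  PlaneFit out{NA_REAL, NA_REAL, NA_REAL, NA_REAL, 0, 0};
  const int m = static_cast<int>(val.size());
  if (m < 10) {
    out.status = 1;
    return out;
  }
  double rbar = 0.0, cbar = 0.0, vscale = 1.0;
  for (int i = 0; i < m; ++i) {
    rbar += r[i];
    cbar += c[i];
    double a = std::fabs(val[i]);
    if (a > vscale) vscale = a;
  }
  rbar /= m;
  cbar /= m;
  const double eps_v = 1e-9 * vscale;

  std::vector<char> in(m, 1);
  std::vector<double> resid(m), work(m);
  double br = 0.0, bc = 0.0, b0 = 0.0, med = 0.0;

  // median via partial selection (O(m))
  auto median_of = [](std::vector<double>& w) {
    size_t n = w.size();
    std::nth_element(w.begin(), w.begin() + n / 2, w.end());
    double hi = w[n / 2];
    if (n % 2) return hi;
    std::nth_element(w.begin(), w.begin() + n / 2 - 1, w.begin() + n / 2);
    return 0.5 * (hi + w[n / 2 - 1]);
  };

  for (int iter = 0; iter < max_iter; ++iter) {
    // normal equations over current inliers, centred coordinates
    double S = 0, Sr = 0, Sc = 0, Srr = 0, Scc = 0, Src = 0;
    double Sv = 0, Svr = 0, Svc = 0;
    for (int i = 0; i < m; ++i) {
      if (!in[i]) continue;
      double ri = r[i] - rbar, ci = c[i] - cbar, vi = val[i];
      S += 1;
      Sr += ri;
      Sc += ci;
      Srr += ri * ri;
      Scc += ci * ci;
      Src += ri * ci;
      Sv += vi;
      Svr += vi * ri;
      Svc += vi * ci;
    }
    if (S < 3) {
      out.status = 1;
      return out;
    }
    // solve [Srr Src Sr; Src Scc Sc; Sr Sc S] b = [Svr; Svc; Sv]
    double det = Srr * (Scc * S - Sc * Sc) - Src * (Src * S - Sc * Sr) +
                 Sr * (Src * Sc - Scc * Sr);
    double scale = (Srr + 1.0) * (Scc + 1.0) * S;
    if (std::fabs(det) <= 1e-10 * scale) {
      out.status = 2;
      return out;
    }
    double d1 = Svr * (Scc * S - Sc * Sc) - Src * (Svc * S - Sc * Sv) +
                Sr * (Svc * Sc - Scc * Sv);
    double d2 = Srr * (Svc * S - Sv * Sc) - Svr * (Src * S - Sc * Sr) +
                Sr * (Src * Sv - Svc * Sr);
    double d3 = Srr * (Scc * Sv - Svc * Sc) - Src * (Src * Sv - Svc * Sr) +
                Svr * (Src * Sc - Scc * Sr);
    br = d1 / det;
    bc = d2 / det;
    b0 = d3 / det;

    for (int i = 0; i < m; ++i)
      resid[i] = val[i] - (br * (r[i] - rbar) + bc * (c[i] - cbar) + b0);

    // cheap deterministic trimming: median +/- k_plane * 1.4826 MAD
    work = resid;
    med = median_of(work);
    for (int i = 0; i < m; ++i) work[i] = std::fabs(resid[i] - med);
    double mad = median_of(work);
    double cut = k_plane * 1.4826 * mad + eps_v;
    bool changed = false;
    int n_in = 0;
    for (int i = 0; i < m; ++i) {
      char ni = (std::fabs(resid[i] - med) <= cut) ? 1 : 0;
      if (ni != in[i]) changed = true;
      in[i] = ni;
      n_in += ni;
    }
    if (n_in < 3) {  // degenerate; keep previous fit
      break;
    }
    if (!changed) break;
  }

  // robust scale: corrected sd of the trimmed (inlier) residuals.  The
  // inlier set is a truncated sample, so its sd is deflated; the truncation
  // point is the observed inlier radius, inverted as in gauss_fit.
  int n_used = 0;
  double s1 = 0.0, s2 = 0.0;
  for (int i = 0; i < m; ++i) {
    if (!in[i]) continue;
    ++n_used;
    double w = resid[i] - med;
    s1 += w;
    s2 += w * w;
  }
  double sigma = 0.0, mu_r = 0.0;
  if (n_used >= 2) {
    double mk = s1 / n_used;
    mu_r = med + mk;
    double var = s2 / n_used - mk * mk;
    if (var < 0.0) var = 0.0;
    sigma = std::sqrt(var * (double)n_used / (double)(n_used - 1));
    if (n_used < m && sigma > 0.0) {
      double radius = 0.0;
      for (int i = 0; i < m; ++i)
        if (in[i]) radius = std::max(radius, std::fabs(resid[i] - mu_r));
      double sd_in = sigma;
      for (int it = 0; it < 50; ++it) {
        double z = radius / sigma;
        double snew = (z > 8.0) ? sd_in : sd_in / trunc_sd_factor(z);
        if (std::fabs(snew - sigma) <= 1e-9 * sigma) {
          sigma = snew;
          break;
        }
        sigma = snew;
      }
    }
  }
  out.slope_row = br;
  out.slope_col = bc;
  // absolute coordinates; the robust residual location folds into the level
  out.intercept = (b0 + mu_r) - br * rbar - bc * cbar;
  out.sigma = sigma;
  out.n_used = n_used;
  out.status = 0;
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_fit_gaussian(NumericVector x, double min_frac, double k_grow,
                      int max_iter) {
  std::vector<double> v(x.begin(), x.end());
  GaussFit f = gauss_fit(v, min_frac, k_grow, max_iter);
  if (!f.ok) stop("robust Gaussian fit needs at least 3 finite values");
  return List::create(_["mu"] = f.mu, _["sigma"] = f.sigma,
                      _["sd_raw"] = f.sd_raw, _["radius"] = f.radius,
                      _["n_used"] = f.n_used);
}

// per-column robust location (columns = frames); non-finite entries skipped
// [[Rcpp::export]]
NumericVector cpp_column_robust_mu(NumericMatrix m, double min_frac,
                                   double k_grow, int max_iter) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector out(nc, NA_REAL);
  std::vector<double> buf;
  buf.reserve(nr);
  for (int j = 0; j < nc; ++j) {
    buf.clear();
    const double* col = &m(0, j);
    for (int i = 0; i < nr; ++i) {
      if (std::isfinite(col[i])) buf.push_back(col[i]);
    }
    GaussFit f = gauss_fit(buf, min_frac, k_grow, max_iter);
    if (f.ok) out[j] = f.mu;
  }
  return out;
}

// per-pixel temporal mean / sd / finite count over a HW x T matrix.
// Two passes with extended-precision accumulators so the result does not
// depend on frame order (the features are contractually frame-order
// invariant).
// [[Rcpp::export]]
List cpp_temporal_stats(NumericMatrix m) {
  const int hw = m.nrow(), T = m.ncol();
  NumericVector mean(hw, NA_REAL), sd(hw, NA_REAL);
  IntegerVector count(hw);
  std::vector<long double> s1(hw, 0.0L), s2(hw, 0.0L);
  std::vector<int> cnt(hw, 0);
  for (int t = 0; t < T; ++t) {
    const double* col = &m(0, t);
    for (int i = 0; i < hw; ++i) {
      double v = col[i];
      if (!std::isfinite(v)) continue;
      s1[i] += v;
      ++cnt[i];
    }
  }
  for (int i = 0; i < hw; ++i) {
    count[i] = cnt[i];
    if (cnt[i] >= 1) mean[i] = static_cast<double>(s1[i] / cnt[i]);
  }
  for (int t = 0; t < T; ++t) {
    const double* col = &m(0, t);
    for (int i = 0; i < hw; ++i) {
      double v = col[i];
      if (!std::isfinite(v)) continue;
      long double w = v - mean[i];
      s2[i] += w * w;
    }
  }
  for (int i = 0; i < hw; ++i) {
    if (cnt[i] >= 2)
      sd[i] = static_cast<double>(sqrtl(s2[i] / (cnt[i] - 1.0L)));
  }
  return List::create(_["mean"] = mean, _["sd"] = sd, _["count"] = count);
}

// [[Rcpp::export]]
List cpp_fit_plane(NumericVector row, NumericVector col, NumericVector value,
                   double min_frac, double k_grow, double k_plane,
                   int max_iter) {
  std::vector<double> r(row.begin(), row.end());
  std::vector<double> c(col.begin(), col.end());
  std::vector<double> v(value.begin(), value.end());
  PlaneFit f = plane_fit(r, c, v, min_frac, k_grow, k_plane, max_iter,
                         max_iter);
  return List::create(_["slope_row"] = f.slope_row,
                      _["slope_col"] = f.slope_col,
                      _["intercept"] = f.intercept, _["sigma"] = f.sigma,
                      _["n_used"] = f.n_used, _["status"] = f.status);
}

// Local planar-background SNR for one frame.  Windows are (2*half_width+1)
// squares shifted (not clipped) at the module border so that every window
// keeps its full area; min_pixels guards against pre-masked holes.  With
// stride > 1, one plane is fitted per stride x stride block (window centred
// on the block) and shared by the block's pixels.
// [[Rcpp::export]]
NumericMatrix cpp_local_plane_snr(NumericMatrix frame, LogicalMatrix usable,
                                  int half_width, int min_pixels,
                                  double min_frac, double k_grow,
                                  double k_plane, int max_iter,
                                  double min_scale, int stride) {
  const int H = frame.nrow(), W = frame.ncol();
  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), NA_REAL);
  const int side = 2 * half_width + 1;
  const int wr = std::min(side, H), wc = std::min(side, W);

  std::vector<double> rr, cc, vv;
  rr.reserve(wr * wc);
  cc.reserve(wr * wc);
  vv.reserve(wr * wc);

  auto window_origin = [](int centre, int wlen, int n) {
    int o = centre - wlen / 2;
    if (o < 0) o = 0;
    if (o > n - wlen) o = n - wlen;
    return o;
  };

  for (int bi = 0; bi < H; bi += stride) {
    for (int bj = 0; bj < W; bj += stride) {
      const int bh = std::min(stride, H - bi), bw = std::min(stride, W - bj);
      const int ci = bi + bh / 2, cj = bj + bw / 2;
      const int r0 = window_origin(ci, wr, H), c0 = window_origin(cj, wc, W);
      rr.clear();
      cc.clear();
      vv.clear();
      double vscale = 1.0;
      for (int j = c0; j < c0 + wc; ++j) {  // column-major frame storage
        const double* fcol = &frame(0, j);
        const int* ucol = &usable(0, j);
        for (int i = r0; i < r0 + wr; ++i) {
          double v = fcol[i];
          if (ucol[i] && std::isfinite(v)) {
            rr.push_back(i);
            cc.push_back(j);
            vv.push_back(v);
            double a = std::fabs(v);
            if (a > vscale) vscale = a;
          }
        }
      }
      if (static_cast<int>(vv.size()) < min_pixels) continue;
      PlaneFit f =
          plane_fit(rr, cc, vv, min_frac, k_grow, k_plane, max_iter, 4);
      if (f.status != 0) continue;
      double s = f.sigma;
      if (s < min_scale) s = min_scale;
      double floor_num = 1e-9 * vscale;
      if (s < floor_num) s = floor_num;
      for (int i = bi; i < bi + bh; ++i) {
        for (int j = bj; j < bj + bw; ++j) {
          double v = frame(i, j);
          if (!usable(i, j) || !std::isfinite(v)) continue;
          double mu = f.slope_row * i + f.slope_col * j + f.intercept;
          out(i, j) = (v - mu) / s;
        }
      }
    }
  }
  return out;
}
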