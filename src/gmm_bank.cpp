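#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double LOG_GUARD = 1e-300;

struct EMFit {
  double w1, w2, mu1, mu2, s1, s2;
  int iters;
  bool converged;
  std::vector<double> ll;
};

// Weighted EM for a two-component 1-D Gaussian mixture.
// x: support points, wt: nonnegative weights (counts). Initialisation is a
// deterministic split at the weighted median with equal weights.
static EMFit em_weighted(const std::vector<double> &x,
                         const std::vector<double> &wt,
                         double tol, int max_iter, double sfloor) {
  EMFit r;
  const int n = (int)x.size();
  double wsum = 0.0, mean = 0.0;
  for (int i = 0; i < n; ++i) { wsum += wt[i]; mean += wt[i] * x[i]; }
  mean /= wsum;
  double var = 0.0;
  for (int i = 0; i < n; ++i) var += wt[i] * (x[i] - mean) * (x[i] - mean);
  var /= wsum;

  if (var <= 0.0 || n == 1) {  // identical samples: both components collapse
    r.w1 = r.w2 = 0.5;
    r.mu1 = r.mu2 = mean;
    r.s1 = r.s2 = sfloor;
    r.iters = 0;
    r.converged = true;
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = R::dnorm(x[i], mean, sfloor, 0);
      ll += wt[i] * std::log(d + LOG_GUARD);
    }
    r.ll.push_back(ll);
    return r;
  }

  // weighted-median split initialisation
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double cum = 0.0, med = x[ord[n - 1]];
  for (int k = 0; k < n; ++k) {
    cum += wt[ord[k]];
    if (cum >= 0.5 * wsum) { med = x[ord[k]]; break; }
  }
  double m1 = 0.0, w1s = 0.0, m2 = 0.0, w2s = 0.0;
  for (int i = 0; i < n; ++i) {
    if (x[i] <= med) { m1 += wt[i] * x[i]; w1s += wt[i]; }
    else             { m2 += wt[i] * x[i]; w2s += wt[i]; }
  }
  double mu1 = w1s > 0 ? m1 / w1s : mean;
  double mu2 = w2s > 0 ? m2 / w2s : mean;
  double s1 = std::max(sfloor, std::sqrt(var));
  double s2 = s1;
  double p1 = 0.5, p2 = 0.5;

  std::vector<double> resp(n);
  double ll_prev = -R_PosInf;
  int it = 0;
  bool conv = false;
  const double inv_sqrt2pi = 0.3989422804014326779;
  for (it = 1; it <= max_iter; ++it) {
    // E step + observed-data log-likelihood
    double ll = 0.0;
    const double a1 = p1 * inv_sqrt2pi / s1, b1 = 0.5 / (s1 * s1);
    const double a2 = p2 * inv_sqrt2pi / s2, b2 = 0.5 / (s2 * s2);
    for (int i = 0; i < n; ++i) {
      double e1 = x[i] - mu1, e2 = x[i] - mu2;
      double d1 = a1 * std::exp(-b1 * e1 * e1);
      double d2 = a2 * std::exp(-b2 * e2 * e2);
      double d = d1 + d2;
      resp[i] = d > 0 ? d1 / d : 0.5;
      ll += wt[i] * std::log(d + LOG_GUARD);
    }
    r.ll.push_back(ll);
    // convergence on the per-sample mean log-likelihood (scale-free)
    if (std::fabs(ll - ll_prev) / wsum < tol) { conv = true; break; }
    ll_prev = ll;
    // M step
    double n1 = 0.0, n2 = 0.0, sx1 = 0.0, sx2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double wr = wt[i] * resp[i];
      n1 += wr;
      sx1 += wr * x[i];
      n2 += wt[i] - wr;
      sx2 += (wt[i] - wr) * x[i];
    }
    mu1 = n1 > 0 ? sx1 / n1 : mean;
    mu2 = n2 > 0 ? sx2 / n2 : mean;
    double v1 = 0.0, v2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double wr = wt[i] * resp[i];
      v1 += wr * (x[i] - mu1) * (x[i] - mu1);
      v2 += (wt[i] - wr) * (x[i] - mu2) * (x[i] - mu2);
    }
    s1 = std::max(sfloor, n1 > 0 ? std::sqrt(v1 / n1) : sfloor);
    s2 = std::max(sfloor, n2 > 0 ? std::sqrt(v2 / n2) : sfloor);
    p1 = n1 / wsum;
    p2 = 1.0 - p1;
  }
  r.w1 = p1; r.w2 = p2;
  r.mu1 = mu1; r.mu2 = mu2;
  r.s1 = s1; r.s2 = s2;
  r.iters = std::min(it, max_iter);
  r.converged = conv;
  return r;
}

// [[Rcpp::export]]
List cpp_em_fit(NumericVector x, NumericVector w, double tol, int max_iter,
                double sigma_floor) {
  std::vector<double> xv(x.begin(), x.end()), wv(w.begin(), w.end());
  EMFit r = em_weighted(xv, wv, tol, max_iter, sigma_floor);
  return List::create(
      _["w"] = NumericVector::create(r.w1, r.w2),
      _["mu"] = NumericVector::create(r.mu1, r.mu2),
      _["sigma"] = NumericVector::create(r.s1, r.s2),
      _["loglik"] = wrap(r.ll),
      _["iterations"] = r.iters,
      _["converged"] = r.converged);
}

// Per-voxel GMM bank: pools nonzero FLAIR intensities from a b^3 patch
// (edge-clipped) across subjects, histogrammed at bin_width, and runs the
// weighted EM above. Voxels with < 8 pooled samples fall back to a single
// Gaussian duplicated into both components.
// [[Rcpp::export]]
List cpp_fit_gmm_bank(IntegerVector dims, IntegerVector fit_idx, List f_list,
                      int b, double tol, int max_iter, double sigma_floor,
                      double bin_width, double max_intensity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nsub = f_list.size();
  const int nfit = fit_idx.size();
  const int half = b / 2;
  const int nbins = std::max(64, (int)std::ceil(max_intensity / bin_width));

  std::vector<const double *> fp(nsub);
  for (int s = 0; s < nsub; ++s) fp[s] = REAL(f_list[s]);

  NumericMatrix params(6, nfit);  // w1 w2 mu1 mu2 s1 s2
  IntegerVector iters(nfit);
  LogicalVector converged(nfit);

  std::vector<double> cnt(nbins, 0.0);
  std::vector<int> occ; occ.reserve(nbins);

  for (int v = 0; v < nfit; ++v) {
    R_xlen_t idx = (R_xlen_t)fit_idx[v] - 1;
    int x = (int)(idx % nx), y = (int)((idx / nx) % ny),
        z = (int)(idx / ((R_xlen_t)nx * ny));
    for (int bi : occ) cnt[bi] = 0.0;
    occ.clear();
    double npool = 0.0;
    int zlo = std::max(0, z - half), zhi = std::min(nz - 1, z + half);
    int ylo = std::max(0, y - half), yhi = std::min(ny - 1, y + half);
    int xlo = std::max(0, x - half), xhi = std::min(nx - 1, x + half);
    for (int s = 0; s < nsub; ++s) {
      const double *F = fp[s];
      for (int Z = zlo; Z <= zhi; ++Z)
        for (int Y = ylo; Y <= yhi; ++Y) {
          R_xlen_t base = (R_xlen_t)Z * nx * ny + (R_xlen_t)Y * nx;
          for (int X = xlo; X <= xhi; ++X) {
            double f = F[base + X];
            if (f == 0.0) continue;  // boundary handling: nonzero only
            int bi = (int)(f / bin_width);
            if (bi < 0) bi = 0;
            if (bi >= nbins) bi = nbins - 1;
            if (cnt[bi] == 0.0) occ.push_back(bi);
            cnt[bi] += 1.0;
            npool += 1.0;
          }
        }
    }
    if (npool < 8.0) {
      // single-Gaussian fallback duplicated into both components
      double mean = 0.0, var = 0.0;
      if (npool > 0) {
        for (int bi : occ) mean += cnt[bi] * (bi + 0.5) * bin_width;
        mean /= npool;
        for (int bi : occ) {
          double d = (bi + 0.5) * bin_width - mean;
          var += cnt[bi] * d * d;
        }
        var /= npool;
      }
      double s = std::max(sigma_floor, std::sqrt(var));
      params(0, v) = 0.5; params(1, v) = 0.5;
      params(2, v) = mean; params(3, v) = mean;
      params(4, v) = s; params(5, v) = s;
      iters[v] = 0;
      converged[v] = true;
      continue;
    }
    std::vector<double> xs, ws;
    xs.reserve(occ.size());
    ws.reserve(occ.size());
    std::sort(occ.begin(), occ.end());
    for (int bi : occ) {
      xs.push_back((bi + 0.5) * bin_width);
      ws.push_back(cnt[bi]);
    }
    EMFit r = em_weighted(xs, ws, tol, max_iter, sigma_floor);
    params(0, v) = r.w1; params(1, v) = r.w2;
    params(2, v) = r.mu1; params(3, v) = r.mu2;
    params(4, v) = r.s1; params(5, v) = r.s2;
    iters[v] = r.iters;
    converged[v] = r.converged;
  }
  return List::create(_["params"] = params, _["iterations"] = iters,
                      _["converged"] = converged);
}
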