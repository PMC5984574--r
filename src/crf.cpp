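#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense two-label Potts CRF with two Gaussian pairwise kernels:
//   smoothness: w1 * exp(-|p_i-p_j|^2 / 2 sa^2), truncated per axis at
//     ceil(3 sa / spacing) (a box window, separable);
//   appearance: w2 * exp(-|p_i-p_j|^2 / 2 sb^2 - (I_i-I_j)^2 / 2 sg^2),
//     spatially truncated at 3 sb (spherical).
// Each kernel is normalised by its full-window spatial sum (Zs, Zb), so w1
// and w2 bound the total pairwise influence on a voxel — the convention of
// the dense-CRF filtering implementations. The constants are window-wide,
// keeping the energy symmetric and the mean-field and enumeration paths on
// one model.

struct AppOffset { int dx, dy, dz; double wsb; };

struct CrfModel {
  int rx, ry, rz;                       // smoothness box radii
  std::vector<double> gx, gy, gz;       // per-axis smoothness weights
  double zs;                            // smoothness normaliser (no self)
  std::vector<AppOffset> app;           // normalised appearance offsets
};

static CrfModel build_model(const NumericVector &spacing,
                            double sa, double sb) {
  CrfModel m;
  m.rx = (int)std::ceil(3.0 * sa / spacing[0]);
  m.ry = (int)std::ceil(3.0 * sa / spacing[1]);
  m.rz = (int)std::ceil(3.0 * sa / spacing[2]);
  auto axis = [&](int r, double s) {
    std::vector<double> g(2 * r + 1);
    for (int d = -r; d <= r; ++d)
      g[d + r] = std::exp(-(d * s) * (d * s) / (2.0 * sa * sa));
    return g;
  };
  m.gx = axis(m.rx, spacing[0]);
  m.gy = axis(m.ry, spacing[1]);
  m.gz = axis(m.rz, spacing[2]);
  double sx = 0, sy = 0, sz = 0;
  for (double v : m.gx) sx += v;
  for (double v : m.gy) sy += v;
  for (double v : m.gz) sz += v;
  m.zs = sx * sy * sz - 1.0;            // exclude the self term
  if (m.zs <= 0) m.zs = 1.0;

  int bx = (int)std::ceil(3.0 * sb / spacing[0]);
  int by = (int)std::ceil(3.0 * sb / spacing[1]);
  int bz = (int)std::ceil(3.0 * sb / spacing[2]);
  double zb = 0.0;
  for (int dz = -bz; dz <= bz; ++dz)
    for (int dy = -by; dy <= by; ++dy)
      for (int dx = -bx; dx <= bx; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        double d2 = dx * spacing[0] * dx * spacing[0] +
                    dy * spacing[1] * dy * spacing[1] +
                    dz * spacing[2] * dz * spacing[2];
        if (d2 > 9.0 * sb * sb) continue;
        double w = std::exp(-d2 / (2.0 * sb * sb));
        zb += w;
        m.app.push_back({dx, dy, dz, w});
      }
  if (zb <= 0) zb = 1.0;
  for (auto &o : m.app) o.wsb /= zb;
  return m;
}

// smoothness kernel value between voxels separated by (dx, dy, dz), already
// normalised; zero outside the box window
static double smooth_weight(const CrfModel &m, int dx, int dy, int dz) {
  if (std::abs(dx) > m.rx || std::abs(dy) > m.ry || std::abs(dz) > m.rz)
    return 0.0;
  if (dx == 0 && dy == 0 && dz == 0) return 0.0;
  return m.gx[dx + m.rx] * m.gy[dy + m.ry] * m.gz[dz + m.rz] / m.zs;
}

// separable truncated-Gaussian convolution of q (zero-padded), minus the
// self term, divided by zs: out_i = sum_{j != i} g(i-j) q_j / zs
static void smooth_conv(const CrfModel &m, const int *dims,
                        const std::vector<double> &q,
                        std::vector<double> &tmp1, std::vector<double> &tmp2,
                        std::vector<double> &out) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // x pass
  for (R_xlen_t z = 0; z < nz; ++z)
    for (R_xlen_t y = 0; y < ny; ++y) {
      R_xlen_t base = z * nx * ny + y * nx;
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        int lo = std::max(0, x - m.rx), hi = std::min(nx - 1, x + m.rx);
        for (int X = lo; X <= hi; ++X)
          acc += m.gx[X - x + m.rx] * q[base + X];
        tmp1[base + x] = acc;
      }
    }
  // y pass
  for (R_xlen_t z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = z * nx * ny;
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        int lo = std::max(0, y - m.ry), hi = std::min(ny - 1, y + m.ry);
        for (int Y = lo; Y <= hi; ++Y)
          acc += m.gy[Y - y + m.ry] * tmp1[base + (R_xlen_t)Y * nx + x];
        tmp2[base + (R_xlen_t)y * nx + x] = acc;
      }
    }
  // z pass, subtract self, normalise
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        double acc = 0.0;
        int lo = std::max(0, z - m.rz), hi = std::min(nz - 1, z + m.rz);
        for (int Z = lo; Z <= hi; ++Z)
          acc += m.gz[Z - z + m.rz] * tmp2[(R_xlen_t)Z * nx * ny + (R_xlen_t)y * nx + x];
        out[i] = (acc - q[i]) / m.zs;
      }
  (void)n;
}

// Mean-field inference: parallel updates for `iters` iterations. Smoothness
// messages are computed exactly for every voxel by separable convolution of
// the lesion marginals; appearance messages are accumulated over the
// spherical window with the intensity factor read from a fine lookup table.
// Voxels whose initial lesion belief is below active_eps keep their unary
// marginal (their messages are still received by others via the
// convolution and window sums).
// [[Rcpp::export]]
List cpp_meanfield(IntegerVector dims, NumericVector spacing,
                   NumericVector u0, NumericVector u1,
                   NumericVector intensity,
                   double w1, double w2, double sa, double sb, double sg,
                   int iters, double active_eps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int dd[3] = {nx, ny, nz};
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  CrfModel m = build_model(spacing, sa, sb);

  // intensity-difference lookup: exp(-dI^2 / 2 sg^2), resolution sg/256
  const double step = sg / 256.0;
  const int tmax = 8 * 256;             // cut at 8 sg (weight < 1e-14)
  std::vector<double> itab(tmax + 1);
  for (int k = 0; k <= tmax; ++k)
    itab[k] = std::exp(-(k * step) * (k * step) / (2.0 * sg * sg));

  std::vector<double> q1((size_t)n), q1n((size_t)n), sm((size_t)n),
      t1((size_t)n), t2((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i)
    q1[i] = 1.0 / (1.0 + std::exp(u1[i] - u0[i]));

  std::vector<R_xlen_t> active;
  if (active_eps > 0) {
    std::vector<char> act((size_t)n, 0);
    int arx = m.rx, ary = m.ry, arz = m.rz;
    for (auto &o : m.app) {
      arx = std::max(arx, std::abs(o.dx));
      ary = std::max(ary, std::abs(o.dy));
      arz = std::max(arz, std::abs(o.dz));
    }
    for (R_xlen_t i = 0; i < n; ++i) {
      if (q1[i] <= active_eps) continue;
      int x = (int)(i % nx), y = (int)((i / nx) % ny),
          z = (int)(i / ((R_xlen_t)nx * ny));
      for (int dz = -arz; dz <= arz; ++dz)
        for (int dy = -ary; dy <= ary; ++dy)
          for (int dx = -arx; dx <= arx; ++dx) {
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            act[(R_xlen_t)Z * nx * ny + (R_xlen_t)Y * nx + X] = 1;
          }
    }
    for (R_xlen_t i = 0; i < n; ++i)
      if (act[i]) active.push_back(i);
  } else {
    active.resize((size_t)n);
    for (R_xlen_t i = 0; i < n; ++i) active[i] = i;
  }

  // clipped smoothness mass per voxel (edge-dependent, iteration-invariant):
  // convolve a volume of ones with the same kernel
  std::vector<double> mass((size_t)n);
  {
    std::vector<double> ones((size_t)n, 1.0);
    smooth_conv(m, dd, ones, t1, t2, mass);
  }

  for (int it = 0; it < iters; ++it) {
    smooth_conv(m, dd, q1, t1, t2, sm);   // sm_i = sum_j ks(i,j) q1_j
    std::copy(q1.begin(), q1.end(), q1n.begin());
    for (R_xlen_t i : active) {
      int x = (int)(i % nx), y = (int)((i / nx) % ny),
          z = (int)(i / ((R_xlen_t)nx * ny));
      double s_le = w1 * sm[i];
      double s_k = w1 * mass[i];          // clipped smoothness mass
      const double Ii = intensity[i];
      for (auto &o : m.app) {
        int X = x + o.dx, Y = y + o.dy, Z = z + o.dz;
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        R_xlen_t j = (R_xlen_t)Z * nx * ny + (R_xlen_t)Y * nx + X;
        int k = (int)(std::fabs(Ii - intensity[j]) / step + 0.5);
        if (k > tmax) continue;
        double kij = w2 * o.wsb * itab[k];
        s_le += kij * q1[j];
        s_k += kij;
      }
      double e1 = u1[i] + (s_k - s_le);   // coupling to P(neighbour = 0)
      double e0 = u0[i] + s_le;
      q1n[i] = 1.0 / (1.0 + std::exp(e1 - e0));
    }
    std::swap(q1, q1n);
  }

  NumericVector q(n);
  IntegerVector lab(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    q[i] = q1[i];
    lab[i] = q1[i] > 0.5 ? 1 : 0;
  }
  return List::create(_["q1"] = q, _["labels"] = lab,
                      _["n_active"] = (double)active.size());
}

// full pairwise matrix of the same model (exact exp for the intensity term)
static std::vector<double> dense_K(const CrfModel &m, const int *dims,
                                   const NumericVector &intensity,
                                   double w1, double w2, double sg) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<double> K((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      int X = j % nx, Y = (j / nx) % ny, Z = j / (nx * ny);
      double k = w1 * smooth_weight(m, X - x, Y - y, Z - z);
      // appearance: match the offset list (spherical cut)
      for (auto &o : m.app) {
        if (o.dx == X - x && o.dy == Y - y && o.dz == Z - z) {
          double dI = intensity[i] - intensity[j];
          k += w2 * o.wsb * std::exp(-dI * dI / (2.0 * sg * sg));
          break;
        }
      }
      K[(size_t)i * n + j] = k;
    }
  }
  return K;
}

// Exact MAP by exhaustive enumeration over all 2^N labellings of the same
// dense model, via reflected Gray code with incremental energy updates.
// [[Rcpp::export]]
List cpp_crf_enum(IntegerVector dims, NumericVector spacing,
                  NumericVector u0, NumericVector u1,
                  NumericVector intensity,
                  double w1, double w2, double sa, double sb, double sg) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int dd[3] = {nx, ny, nz};
  const int n = nx * ny * nz;
  if (n > 27) stop("exhaustive CRF enumeration limited to 27 voxels");
  CrfModel m = build_model(spacing, sa, sb);
  std::vector<double> K = dense_K(m, dd, intensity, w1, w2, sg);

  // Gray-code enumeration over the first m voxels, with the last k voxels
  // minimised analytically at every step (exact block elimination):
  //   E(l) = E_enum(l_enum) + min_assign [ sum_w u_w(l_w)
  //          + cross(l_w, l_enum) + intra-block pairwise ].
  // The incremental state is b_v = sum_{j in enum} K_vj (1 - 2 l_j) for
  // enumerated v (flip cost), and a_w = sum_{j in enum} K_wj l_j for
  // eliminated w (cross coupling).
  const int k = std::min(5, n > 1 ? n - 1 : 0);
  const int mm = n - k;
  const int nass = 1 << k;

  std::vector<double> b(mm, 0.0), K2((size_t)mm * mm), du(mm);
  for (int v = 0; v < mm; ++v) {
    for (int j = 0; j < mm; ++j) {
      b[v] += K[(size_t)v * n + j];
      K2[(size_t)v * mm + j] = 2.0 * K[(size_t)v * n + j];
    }
    du[v] = u1[v] - u0[v];
  }
  // eliminated block: cross rows, unary constants, intra-block table
  std::vector<double> Kwe((size_t)k * mm), a(k, 0.0), cw(k), u0w(k);
  for (int wi = 0; wi < k; ++wi) {
    int w = mm + wi;
    double Sp = 0.0;
    for (int j = 0; j < mm; ++j) {
      Kwe[(size_t)wi * mm + j] = K[(size_t)w * n + j];
      Sp += K[(size_t)w * n + j];
    }
    cw[wi] = u1[w] - u0[w] + Sp;
    u0w[wi] = u0[w];
  }
  std::vector<double> intra(nass, 0.0);
  for (int ass = 0; ass < nass; ++ass)
    for (int wi = 0; wi < k; ++wi)
      for (int wj = wi + 1; wj < k; ++wj)
        if (((ass >> wi) & 1) != ((ass >> wj) & 1))
          intra[ass] += K[(size_t)(mm + wi) * n + (mm + wj)];

  double E = 0.0;
  for (int i = 0; i < mm; ++i) E += u0[i];
  double bestE = R_PosInf;
  uint64_t best_code = 0, code = 0;
  std::vector<double> sums(nass);

  auto eval_elim = [&](double Epart, uint64_t enum_code) {
    double baseA = 0.0;
    double d[8];
    for (int wi = 0; wi < k; ++wi) {
      baseA += u0w[wi] + a[wi];
      d[wi] = cw[wi] - 2.0 * a[wi];
    }
    sums[0] = 0.0;
    int best_ass = 0;
    double best_val = baseA + intra[0];
    for (int ass = 1; ass < nass; ++ass) {
      sums[ass] = sums[ass & (ass - 1)] + d[__builtin_ctz(ass)];
      double val = baseA + sums[ass] + intra[ass];
      if (val < best_val) { best_val = val; best_ass = ass; }
    }
    double tot = Epart + best_val;
    if (tot < bestE - 1e-12) {
      bestE = tot;
      best_code = enum_code | ((uint64_t)best_ass << mm);
    }
  };

  eval_elim(E, code);                   // the all-zero enumerated labelling
  double *__restrict bp = b.data();
  const double *__restrict K2p = K2.data();
  const uint64_t total = (uint64_t)1 << mm;
  for (uint64_t step = 1; step < total; ++step) {
    int v = __builtin_ctzll(step);      // reflected Gray code flip position
    uint64_t mask = (uint64_t)1 << v;
    double s = 1.0 - 2.0 * (double)((code & mask) >> v);
    E += s * (du[v] + bp[v]);
    code ^= mask;
    const double *__restrict Kv = K2p + (size_t)v * mm;
    for (int j = 0; j < mm; ++j) bp[j] -= s * Kv[j];
    for (int wi = 0; wi < k; ++wi) a[wi] += s * Kwe[(size_t)wi * mm + v];
    eval_elim(E, code);
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (best_code >> i) & 1;
  return List::create(_["labels"] = out, _["energy"] = bestE);
}

// Energy of a given labelling under the same model (for tests).
// [[Rcpp::export]]
double cpp_crf_energy(IntegerVector dims, NumericVector spacing,
                      NumericVector u0, NumericVector u1,
                      NumericVector intensity, IntegerVector labels,
                      double w1, double w2, double sa, double sb, double sg) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int dd[3] = {nx, ny, nz};
  const int n = nx * ny * nz;
  if (n > 64) stop("dense energy evaluation limited to tiny grids");
  CrfModel m = build_model(spacing, sa, sb);
  std::vector<double> K = dense_K(m, dd, intensity, w1, w2, sg);
  double E = 0.0;
  for (int i = 0; i < n; ++i) E += labels[i] ? u1[i] : u0[i];
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (labels[i] != labels[j]) E += K[(size_t)i * n + j];
  return E;
}
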