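// Simplified voxel Monte Carlo photon dose engine.
//
// Photons: Woodcock (fictitious-interaction) tracking through the voxel
// grid; analog Compton scattering with Klein-Nishina sampling, photoelectric
// absorption, pair production above 1.022 MeV with annihilation photons.
// Electrons: straight-line continuous-slowing-down stepping with Gaussian
// (Highland) small-angle diffusion per step, depositing energy along the
// track.  Energies in MeV, lengths in mm, mass coefficients in cm^2/g.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

// ---- PCG32 RNG ------------------------------------------------------------
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq = 0xda3e39cb94b95bdbULL) {
    state = 0U; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double uniform() {  // (0, 1)
    return (next() + 1.0) * 2.3283064359965952e-10;
  }
  double gauss() {
    double u1 = uniform(), u2 = uniform();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

// ---- physics table lookup --------------------------------------------------
struct Physics {
  std::vector<double> logE;         // uniform grid in log energy
  double logE0, dLog;
  int nE, nMat;
  const double *muTot, *fPE, *fPair, *stopPow, *X0;  // column-major nE x nMat

  void init(const NumericVector &energy, const NumericMatrix &mu,
            const NumericMatrix &pe, const NumericMatrix &pair,
            const NumericMatrix &sp, const NumericVector &x0) {
    nE = energy.size(); nMat = mu.ncol();
    logE.resize(nE);
    for (int i = 0; i < nE; ++i) logE[i] = std::log(energy[i]);
    logE0 = logE[0];
    dLog = (logE[nE - 1] - logE0) / (nE - 1);
    muTot = mu.begin(); fPE = pe.begin(); fPair = pair.begin();
    stopPow = sp.begin(); X0 = x0.begin();
  }
  inline void locate(double E, int &i, double &w) const {
    double t = (std::log(E) - logE0) / dLog;
    if (t <= 0) { i = 0; w = 0; return; }
    if (t >= nE - 1) { i = nE - 2; w = 1; return; }
    i = (int)t; w = t - i;
  }
  inline double interp(const double *tab, int mat, double E) const {
    int i; double w; locate(E, i, w);
    const double *col = tab + (size_t)mat * nE;
    return col[i] * (1 - w) + col[i + 1] * w;
  }
};

struct Grid {
  int nx, ny, nz;
  double sx, sy, sz;      // spacing mm
  double ox, oy, oz;      // corner origin mm
  const double *rho;      // g/cm^3
  const int *mat;         // 0-based material index

  inline bool voxelOf(double x, double y, double z, int &ix, int &iy, int &iz) const {
    ix = (int)std::floor((x - ox) / sx);
    iy = (int)std::floor((y - oy) / sy);
    iz = (int)std::floor((z - oz) / sz);
    return ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz;
  }
  inline size_t idx(int ix, int iy, int iz) const {
    return (size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz);
  }
  // distance along (u,v,w) from (x,y,z) to box entry; <0 if no hit
  double entryDistance(double x, double y, double z,
                       double u, double v, double w) const {
    double t0 = 0.0, t1 = 1e30;
    double lo[3] = {ox, oy, oz};
    double hi[3] = {ox + nx * sx, oy + ny * sy, oz + nz * sz};
    double p[3] = {x, y, z}, d[3] = {u, v, w};
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        if (p[a] < lo[a] || p[a] > hi[a]) return -1.0;
      } else {
        double ta = (lo[a] - p[a]) / d[a], tb = (hi[a] - p[a]) / d[a];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta); t1 = std::min(t1, tb);
        if (t0 > t1) return -1.0;
      }
    }
    return t0;
  }
};

struct Photon { double x, y, z, u, v, w, E; };

// rotate direction (u,v,w) by polar angle (cosTheta) and azimuth phi
inline void rotateDirection(double &u, double &v, double &w,
                            double cosT, double phi) {
  double sinT = std::sqrt(std::max(0.0, 1.0 - cosT * cosT));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double uz = w;
  if (std::fabs(uz) > 0.999999) {
    u = sinT * cphi; v = sinT * sphi; w = (uz > 0 ? cosT : -cosT);
    return;
  }
  double s = std::sqrt(1.0 - uz * uz);
  double nu = u * cosT + sinT * (u * w * cphi - v * sphi) / s;
  double nv = v * cosT + sinT * (v * w * cphi + u * sphi) / s;
  double nw = w * cosT - sinT * s * cphi;
  double norm = 1.0 / std::sqrt(nu * nu + nv * nv + nw * nw);
  u = nu * norm; v = nv * norm; w = nw * norm;
}

// Klein-Nishina sampling of the scattered-photon energy fraction eps.
// Standard two-branch mixture (1/eps and eps terms) with rejection on the
// angular factor; k = E / m_e c^2.
inline double sampleCompton(double k, Pcg32 &rng, double &cosTheta) {
  double epsMin = 1.0 / (1.0 + 2.0 * k);
  double a1 = -std::log(epsMin);
  double a2 = 0.5 * (1.0 - epsMin * epsMin);
  double eps, t, sin2;
  for (;;) {
    if (rng.uniform() * (a1 + a2) < a1)
      eps = epsMin * std::exp(a1 * rng.uniform());
    else
      eps = std::sqrt(epsMin * epsMin + (1.0 - epsMin * epsMin) * rng.uniform());
    t = (1.0 - eps) / (k * eps);
    sin2 = t * (2.0 - t);
    double g = 1.0 - eps * sin2 / (1.0 + eps * eps);
    if (rng.uniform() <= g) break;
  }
  cosTheta = 1.0 - t;
  return eps;
}

struct Engine {
  Physics ph;
  Grid g;
  double *edep;
  double eCutPhoton, eCutElectron, eStep;
  std::vector<double> rhoMaxByMat;   // max density per material in phantom
  bool primaryOnly;                  // score first interaction sites only
  bool killScatter;                  // diagnostic: no scattered-photon dose

  inline double muMax(double E) const {
    double m = 0.0;
    for (int mt = 0; mt < ph.nMat; ++mt) {
      if (rhoMaxByMat[mt] <= 0) continue;
      double mu = ph.interp(ph.muTot, mt, E) * rhoMaxByMat[mt];
      if (mu > m) m = mu;
    }
    return m * 0.1;   // cm^-1 -> mm^-1
  }

  inline void deposit(double x, double y, double z, double E) {
    int ix, iy, iz;
    if (E > 0 && g.voxelOf(x, y, z, ix, iy, iz))
      edep[g.idx(ix, iy, iz)] += E;
  }

  // straight-line CSDA electron (or positron) with Highland angular diffusion
  void transportElectron(double x, double y, double z,
                         double u, double v, double w,
                         double T, Pcg32 &rng) {
    while (T > eCutElectron) {
      int ix, iy, iz;
      if (!g.voxelOf(x, y, z, ix, iy, iz)) return;      // left the phantom
      size_t id = g.idx(ix, iy, iz);
      double rho = g.rho[id];
      if (rho <= 1e-6) {  // vacuum-like: drift one step without loss
        x += u * eStep; y += v * eStep; z += w * eStep;
        continue;
      }
      int mt = g.mat[id];
      double S = ph.interp(ph.stopPow, mt, std::max(T, 0.01)) * rho * 0.1; // MeV/mm
      double ds = eStep;
      double dE = S * ds;
      if (dE >= T - eCutElectron) { dE = T; ds = T / S; }
      deposit(x + u * ds * 0.5, y + v * ds * 0.5, z + w * ds * 0.5, dE);
      x += u * ds; y += v * ds; z += w * ds;
      T -= dE;
      if (T <= eCutElectron) { deposit(x, y, z, T); return; }
      // Highland multiple-scattering angle over this step
      double pc = std::sqrt(T * (T + 1.02199790));
      double pbc = pc * pc / (T + 0.51099895);
      double stepG = rho * ds * 0.1;                     // g/cm^2
      double th0 = 13.6e-3 / pbc * std::sqrt(stepG / ph.X0[mt]);
      double thx = th0 * rng.gauss(), thy = th0 * rng.gauss();
      double th = std::sqrt(thx * thx + thy * thy);
      if (th > 1e-9)
        rotateDirection(u, v, w, std::cos(th), std::atan2(thy, thx));
    }
    deposit(x, y, z, T);
  }

  std::vector<Photon> stack;   // reused across histories

  // track one photon (and its secondaries via an explicit stack)
  void transportPhoton(const Photon &start, Pcg32 &rng) {
    stack.clear();
    stack.push_back(start);
    bool first = true;
    while (!stack.empty()) {
      Photon p = stack.back(); stack.pop_back();
      if (p.E < eCutPhoton) { deposit(p.x, p.y, p.z, p.E); continue; }
      for (;;) {
        double mm = muMax(p.E);
        if (mm <= 0) break;
        double s = -std::log(rng.uniform()) / mm;
        p.x += p.u * s; p.y += p.v * s; p.z += p.w * s;
        int ix, iy, iz;
        if (!g.voxelOf(p.x, p.y, p.z, ix, iy, iz)) break;     // escaped
        size_t id = g.idx(ix, iy, iz);
        double muLoc = ph.interp(ph.muTot, g.mat[id], p.E) * g.rho[id] * 0.1;
        if (rng.uniform() * mm > muLoc) continue;             // fictitious
        // ---- real interaction ----
        if (primaryOnly && first) { deposit(p.x, p.y, p.z, p.E); return; }
        first = false;
        int mt = g.mat[id];
        double u1 = rng.uniform();
        double fpe = ph.interp(ph.fPE, mt, p.E);
        double fpair = ph.interp(ph.fPair, mt, p.E);
        if (u1 < fpe) {
          transportElectron(p.x, p.y, p.z, p.u, p.v, p.w, p.E, rng);
          break;
        } else if (u1 < fpe + fpair && p.E > 1.02199790) {
          double T = 0.5 * (p.E - 1.02199790);
          transportElectron(p.x, p.y, p.z, p.u, p.v, p.w, T, rng);
          transportElectron(p.x, p.y, p.z, p.u, p.v, p.w, T, rng);
          // annihilation at the interaction site: two back-to-back 511 keV
          double ct = 2.0 * rng.uniform() - 1.0;
          double phi = 6.283185307179586 * rng.uniform();
          double st = std::sqrt(1.0 - ct * ct);
          if (!killScatter) {
            Photon a{p.x, p.y, p.z, st * std::cos(phi), st * std::sin(phi), ct, 0.51099895};
            Photon b{p.x, p.y, p.z, -a.u, -a.v, -a.w, 0.51099895};
            stack.push_back(a); stack.push_back(b);
          }
          break;
        } else {
          double k = p.E / 0.51099895;
          double cosT;
          double eps = sampleCompton(k, rng, cosT);
          double Eout = eps * p.E;
          double T = p.E - Eout;
          // electron direction from momentum conservation
          double pe = std::sqrt(T * (T + 1.02199790));
          double u0 = p.u, v0 = p.v, w0 = p.w;
          double phi = 6.283185307179586 * rng.uniform();
          if (pe > 1e-9 && T > eCutElectron) {
            double cosTe = (p.E - Eout * cosT) / pe;
            cosTe = std::min(1.0, std::max(-1.0, cosTe));
            double ue = u0, ve = v0, we = w0;
            rotateDirection(ue, ve, we, cosTe, phi + 3.141592653589793);
            transportElectron(p.x, p.y, p.z, ue, ve, we, T, rng);
          } else {
            deposit(p.x, p.y, p.z, T);
          }
          if (killScatter) break;    // diagnostic primary-dose mode
          rotateDirection(p.u, p.v, p.w, cosT, phi);
          p.E = Eout;
          if (p.E < eCutPhoton) { deposit(p.x, p.y, p.z, p.E); break; }
        }
      }
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".cppTransport")]]
List cppTransport(NumericMatrix particles,
                  NumericVector density, IntegerVector material,
                  IntegerVector dims, NumericVector spacing,
                  NumericVector origin,
                  NumericVector energyGrid, NumericMatrix muTot,
                  NumericMatrix fPE, NumericMatrix fPair,
                  NumericMatrix stopPow, NumericVector X0,
                  double seed,
                  double eCutPhoton = 0.05, double eCutElectron = 0.2,
                  double eStep = 1.0, bool primaryOnly = false,
                  bool killScatter = false) {
  Engine eng;
  eng.ph.init(energyGrid, muTot, fPE, fPair, stopPow, X0);
  eng.g.nx = dims[0]; eng.g.ny = dims[1]; eng.g.nz = dims[2];
  eng.g.sx = spacing[0]; eng.g.sy = spacing[1]; eng.g.sz = spacing[2];
  eng.g.ox = origin[0]; eng.g.oy = origin[1]; eng.g.oz = origin[2];
  eng.g.rho = density.begin();
  std::vector<int> mat0(material.size());
  for (int i = 0; i < material.size(); ++i) mat0[i] = material[i] - 1;
  eng.g.mat = mat0.data();
  eng.eCutPhoton = eCutPhoton; eng.eCutElectron = eCutElectron;
  eng.eStep = eStep; eng.primaryOnly = primaryOnly;
  eng.killScatter = killScatter;

  eng.rhoMaxByMat.assign(eng.ph.nMat, 0.0);
  size_t nvox = density.size();
  for (size_t i = 0; i < nvox; ++i) {
    int mt = mat0[i];
    if (mt >= 0 && mt < eng.ph.nMat && density[i] > eng.rhoMaxByMat[mt])
      eng.rhoMaxByMat[mt] = density[i];
  }

  NumericVector edep(nvox);
  eng.edep = edep.begin();

  Pcg32 rng((uint64_t)seed);
  const double *px = &particles(0, 0);
  int n = particles.nrow();
  const double *c0 = px, *c1 = px + n, *c2 = px + 2 * n, *c3 = px + 3 * n,
               *c4 = px + 4 * n, *c5 = px + 5 * n, *c6 = px + 6 * n;
  double entering = 0.0;
  for (int i = 0; i < n; ++i) {
    Photon p{c0[i], c1[i], c2[i], c3[i], c4[i], c5[i], c6[i]};
    double t = eng.g.entryDistance(p.x, p.y, p.z, p.u, p.v, p.w);
    if (t < 0) continue;                        // misses the phantom
    p.x += p.u * (t + 1e-6); p.y += p.v * (t + 1e-6); p.z += p.w * (t + 1e-6);
    entering += p.E;
    eng.transportPhoton(p, rng);
  }
  double total = 0.0;
  for (size_t i = 0; i < nvox; ++i) total += edep[i];
  return List::create(_["edep"] = edep, _["entering"] = entering,
                      _["deposited"] = total);
}

// [[Rcpp::export(name = ".cppMedianFilter")]]
NumericVector cppMedianFilter(NumericVector arr, IntegerVector dims, int radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz);
  if (radius == 0) { std::copy(arr.begin(), arr.end(), out.begin()); return out; }
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
  for (int iz = 0; iz < nz; ++iz) {
    int z0 = std::max(0, iz - radius), z1 = std::min(nz - 1, iz + radius);
    for (int iy = 0; iy < ny; ++iy) {
      int y0 = std::max(0, iy - radius), y1 = std::min(ny - 1, iy + radius);
      for (int ix = 0; ix < nx; ++ix) {
        int x0 = std::max(0, ix - radius), x1 = std::min(nx - 1, ix + radius);
        buf.clear();
        for (int z = z0; z <= z1; ++z)
          for (int y = y0; y <= y1; ++y) {
            const double *row = &arr[(size_t)nx * ((size_t)y + (size_t)ny * z)];
            for (int x = x0; x <= x1; ++x) buf.push_back(row[x]);
          }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m);
          med = 0.5 * (med + lo);
        }
        out[(size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz)] = med;
      }
    }
  }
  return out;
}

// trilinear interpolation on voxel-center samples; returns NA outside
static inline double trilinear(const double *a, int nx, int ny, int nz,
                               double fx, double fy, double fz) {
  // fx, fy, fz are in voxel-index units (voxel centers at integers)
  if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1)
    return NA_REAL;
  int ix = std::min((int)fx, nx - 2 >= 0 ? nx - 2 : 0);
  int iy = std::min((int)fy, ny - 2 >= 0 ? ny - 2 : 0);
  int iz = std::min((int)fz, nz - 2 >= 0 ? nz - 2 : 0);
  if (nx == 1) ix = 0; if (ny == 1) iy = 0; if (nz == 1) iz = 0;
  double wx = fx - ix, wy = fy - iy, wz = fz - iz;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        int jx = std::min(ix + dx, nx - 1), jy = std::min(iy + dy, ny - 1),
            jz = std::min(iz + dz, nz - 1);
        double w = (dx ? wx : 1 - wx) * (dy ? wy : 1 - wy) * (dz ? wz : 1 - wz);
        acc += w * a[(size_t)jx + (size_t)nx * ((size_t)jy + (size_t)ny * jz)];
      }
  return acc;
}

// [[Rcpp::export(name = ".cppGamma")]]
List cppGamma(NumericVector refDose, NumericVector evalDose,
              IntegerVector dims, NumericVector spacing,
              double doseCrit, double dta, double thresholdAbs,
              double searchStep = 0.2, double searchFactor = 3.0) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  const double *ref = refDose.begin(), *ev = evalDose.begin();

  // precompute search offsets (mm), sorted by distance
  double rad = searchFactor * dta;
  struct Off { double dx, dy, dz, r2; };
  std::vector<Off> offs;
  int kx = (int)(rad / searchStep);
  for (int iz = -kx; iz <= kx; ++iz)
    for (int iy = -kx; iy <= kx; ++iy)
      for (int ix = -kx; ix <= kx; ++ix) {
        double dx = ix * searchStep, dy = iy * searchStep, dz = iz * searchStep;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= rad * rad) offs.push_back({dx, dy, dz, r2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off &a, const Off &b) { return a.r2 < b.r2; });

  NumericVector gamma(nvox, NA_REAL);
  double dta2 = dta * dta;
  size_t nEval = 0, nPass = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        size_t id = (size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz);
        double rd = ref[id];
        if (rd < thresholdAbs) continue;
        double g2min = 1e30;
        for (const Off &o : offs) {
          double rterm = o.r2 / dta2;
          if (rterm >= g2min) break;          // offsets sorted: no improvement
          double fx = ix + o.dx / spacing[0];
          double fy = iy + o.dy / spacing[1];
          double fz = iz + o.dz / spacing[2];
          double de = trilinear(ev, nx, ny, nz, fx, fy, fz);
          if (ISNA(de)) continue;
          double dd = (de - rd) / doseCrit;
          double g2 = rterm + dd * dd;
          if (g2 < g2min) g2min = g2;
        }
        double gm = std::sqrt(g2min);
        gamma[id] = gm;
        ++nEval;
        if (gm < 1.0) ++nPass;
      }
  double pass = nEval ? 100.0 * nPass / nEval : NA_REAL;
  return List::create(_["gamma"] = gamma, _["passRate"] = pass,
                      _["nEvaluated"] = (double)nEval);
}
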