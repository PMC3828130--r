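// Compiled kernel: pair forces (WCA / angular LJ / steric), WLC bonds,
// cell-list neighbour search, BAOAB Langevin propagation, and bound-pair
// detection.  All quantities in reduced units (energy eps0, length sigma_R,
// time tau); temperature enters as kBT.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Counter-free RNG seeded from R's stream so set.seed() governs trajectories.
struct XRng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  void seed_from_R() {
    for (int i = 0; i < 4; i++) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo;
      if (s[i] == 0) s[i] = 0x9E3779B97F4A7C15ULL + (uint64_t)i;
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double runif() { return (double)(next() >> 11) * (1.0 / 9007199254740992.0); }
  inline double rnorm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; have_spare = true;
    return u * f;
  }
};

enum PairKind { PK_NONE = 0, PK_WCA = 1, PK_ANGULAR = 2 };

struct Sim {
  int N, nsp;
  std::vector<double> px, py, pz;     // wrapped positions
  std::vector<double> ux, uy, uz;     // unwrapped (for MSD)
  std::vector<double> vx, vy, vz;
  std::vector<double> fx, fy, fz;
  std::vector<int> sp;
  std::vector<double> sp_sigma, sp_mass, sp_gamma;
  std::vector<int> sp_is2d, sp_frozen;
  // pair tables, index p = a*nsp + b
  std::vector<int> pk;                 // kind
  std::vector<double> peps, psig, prc2, pn, pthc;
  std::vector<double> psr6c, psr12c;   // (sigma/rcut)^6, ^12 for angular shift
  std::vector<int> precsp;             // axis-owning species for angular pairs
  // bonds
  std::vector<int> b_i, b_j;
  std::vector<double> b_L0, b_lp;
  std::vector<int> partner;            // bonded partner (-1 if none)
  double lx, ly, lz, kBT;
  double rmax;                         // largest pair cutoff
  double pot;                          // last computed potential energy
  long n_overstretch = 0;
  double max_bond_x = 0.0;             // max r/L0 seen
  // cell list
  int ncx = -1, ncy = -1, ncz = -1;
  std::vector<int> chead, cnext;
  std::vector<int> occ;                // occupied cell ids
  std::vector<int> nbr;                // half-stencil neighbour table, 13 per cell
  std::vector<int> nbr_cnt;
  bool cells_ok = false, nbr_built = false;

  inline void minimg(double &dx, double &dy) const {
    dx -= lx * std::nearbyint(dx / lx);
    dy -= ly * std::nearbyint(dy / ly);
  }

  void build_cells() {
    ncx = std::max(1, (int)std::floor(lx / rmax));
    ncy = std::max(1, (int)std::floor(ly / rmax));
    ncz = std::max(1, (int)std::floor(lz / rmax));
    cells_ok = (ncx >= 3 && ncy >= 3);
    if (!cells_ok) return;
    size_t ncell = (size_t)ncx * ncy * ncz;
    if (chead.size() != ncell) { chead.assign(ncell, -1); nbr_built = false; }
    else for (int c : occ) chead[c] = -1;
    occ.clear();
    cnext.assign(N, -1);
    for (int i = 0; i < N; i++) {
      int cx = (int)std::floor(px[i] / lx * ncx); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
      int cy = (int)std::floor(py[i] / ly * ncy); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
      int cz = (int)std::floor(pz[i] / lz * ncz); if (cz >= ncz) cz = ncz - 1; if (cz < 0) cz = 0;
      int c = (cz * ncy + cy) * ncx + cx;
      if (chead[c] < 0) occ.push_back(c);
      cnext[i] = chead[c];
      chead[c] = i;
    }
    if (!nbr_built) build_nbr_table();
  }

  // half stencil: same-cell pairs handled separately; 13 displacement
  // vectors cover each cross-cell pair exactly once (z clamped, x/y wrapped)
  void build_nbr_table() {
    size_t ncell = (size_t)ncx * ncy * ncz;
    nbr.assign(ncell * 13, -1);
    nbr_cnt.assign(ncell, 0);
    static const int D[13][3] = {
      {1, 0, 0}, {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
      {-1, -1, 1}, {0, -1, 1}, {1, -1, 1},
      {-1, 0, 1}, {0, 0, 1}, {1, 0, 1},
      {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};
    for (int cz = 0; cz < ncz; cz++)
      for (int cy = 0; cy < ncy; cy++)
        for (int cx = 0; cx < ncx; cx++) {
          int c = (cz * ncy + cy) * ncx + cx;
          int k = 0;
          for (auto &d : D) {
            int zz = cz + d[2];
            if (zz < 0 || zz >= ncz) continue;
            int xx = (cx + d[0] + ncx) % ncx;
            int yy = (cy + d[1] + ncy) % ncy;
            nbr[(size_t)c * 13 + k++] = (zz * ncy + yy) * ncx + xx;
          }
          nbr_cnt[c] = k;
        }
    nbr_built = true;
  }

  // energy and force on particle i from pair (i, j); fdir applies to i.
  // Returns energy; adds force contribution into (gx, gy, gz) acting on i.
  inline double pair_ef(int i, int j, double &gx, double &gy, double &gz) const {
    int a = sp[i], b = sp[j];
    int p = a * nsp + b;
    int kind = pk[p];
    if (kind == PK_NONE) return 0.0;
    if (partner[i] == j) return 0.0;  // bonded pair: linker handles it
    double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
    minimg(dx, dy);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= prc2[p]) return 0.0;
    double sig = psig[p], eps = peps[p];
    if (r2 < 1e-12 * sig * sig)
      stop("particles %d and %d overlap (r < 1e-6 sigma): bad configuration", i + 1, j + 1);
    if (kind == PK_WCA) {
      double s2 = sig * sig / r2;
      double sr6 = s2 * s2 * s2, sr12 = sr6 * sr6;
      double e = 4.0 * eps * (sr12 - sr6) + eps;
      double fr = 24.0 * eps * (2.0 * sr12 - sr6) / r2;
      gx += fr * dx; gy += fr * dy; gz += fr * dz;
      return e;
    }
    // angular LJ: separation taken receptor -> ligand; receptor axis = +z
    double ddx = dx, ddy = dy, ddz = dz;     // i - j
    double sgn = 1.0;                         // force computed for the ligand
    bool i_is_ligand = (sp[i] != precsp[p]);
    if (!i_is_ligand) { ddx = -dx; ddy = -dy; ddz = -dz; sgn = -1.0; }
    double r = std::sqrt(r2);
    double s2 = sig * sig / r2;
    double sr6 = s2 * s2 * s2, sr12 = sr6 * sr6;
    double A  = 4.0 * eps * (sr12 - psr12c[p]);
    double B  = -4.0 * eps * (sr6 - psr6c[p]);
    double dA = -48.0 * eps * sr12 / r;
    double dB = 24.0 * eps * sr6 / r;
    double cth = ddz / r;
    if (cth > 1.0) cth = 1.0; if (cth < -1.0) cth = -1.0;
    double n = pn[p], thc = pthc[p];
    double g = 0.0, dgdc = 0.0;
    if (n == 0.0 && thc >= M_PI / 2.0 - 1e-12) {
      g = 1.0;                                 // isotropic convention
    } else {
      double th = std::acos(cth);
      if (th < thc) {
        double aa = M_PI / (2.0 * thc);
        double c = std::cos(aa * th);
        double c2n1 = std::pow(c, 2.0 * n - 1.0);
        g = c2n1 * c;                          // c^(2n)
        double sth = std::sin(th), sath = std::sin(aa * th);
        double ratio = (sth > 1e-8) ? (sath / sth) : aa;
        dgdc = 2.0 * n * aa * c2n1 * ratio;    // dg/dcos(theta)
      }
    }
    double e = A + g * B;
    double dVdr = dA + g * dB;
    // force on ligand = -dVdr * rhat - B * dgdc * (zhat - cth*rhat)/r
    double rhx = ddx / r, rhy = ddy / r, rhz = ddz / r;
    double c1 = -dVdr, c2 = -B * dgdc / r;
    double Fx = c1 * rhx + c2 * (0.0 - cth * rhx);
    double Fy = c1 * rhy + c2 * (0.0 - cth * rhy);
    double Fz = c1 * rhz + c2 * (1.0 - cth * rhz);
    gx += sgn * Fx; gy += sgn * Fy; gz += sgn * Fz;
    return e;
  }

  // angular pair energy only (for bound detection)
  inline double pair_energy(int i, int j) const {
    double gx = 0, gy = 0, gz = 0;
    return pair_ef(i, j, gx, gy, gz);
  }

  inline double wlc_tension(double r, double L0, double lp) {
    double x = r / L0;
    if (x > max_bond_x) max_bond_x = x;
    if (x >= 1.0) n_overstretch++;
    if (x > 0.99) x = 0.99;
    double om = 1.0 - x;
    return (kBT / lp) * (0.25 / (om * om) - 0.25 + x);
  }

  inline double wlc_energy(double r, double L0, double lp) const {
    double x = std::min(r / L0, 0.99);
    double e = (kBT * L0 / lp) * (0.25 / (1.0 - x) - 0.25 - 0.25 * x + 0.5 * x * x);
    if (r > 0.99 * L0) {
      double xc = 0.99, om = 1.0 - xc;
      double fc = (kBT / lp) * (0.25 / (om * om) - 0.25 + xc);
      e += fc * (r - 0.99 * L0);
    }
    return e;
  }

  void compute_forces(bool use_cell) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    pot = 0.0;
    bool cell = use_cell;
    if (cell) { build_cells(); cell = cells_ok; }
    if (cell) {
      for (int c : occ) {
        for (int i = chead[c]; i >= 0; i = cnext[i]) {
          // same-cell pairs
          for (int j = cnext[i]; j >= 0; j = cnext[j]) {
            double gx = 0, gy = 0, gz = 0;
            double e = pair_ef(i, j, gx, gy, gz);
            if (e != 0.0 || gx != 0.0 || gy != 0.0 || gz != 0.0) {
              pot += e;
              fx[i] += gx; fy[i] += gy; fz[i] += gz;
              fx[j] -= gx; fy[j] -= gy; fz[j] -= gz;
            }
          }
          // cross-cell pairs via the half stencil
          int kmax = nbr_cnt[c];
          const int *nb = &nbr[(size_t)c * 13];
          for (int k = 0; k < kmax; k++) {
            for (int j = chead[nb[k]]; j >= 0; j = cnext[j]) {
              double gx = 0, gy = 0, gz = 0;
              double e = pair_ef(i, j, gx, gy, gz);
              if (e != 0.0 || gx != 0.0 || gy != 0.0 || gz != 0.0) {
                pot += e;
                fx[i] += gx; fy[i] += gy; fz[i] += gz;
                fx[j] -= gx; fy[j] -= gy; fz[j] -= gz;
              }
            }
          }
        }
      }
    } else {
      for (int i = 0; i < N; i++)
        for (int j = i + 1; j < N; j++) {
          double gx = 0, gy = 0, gz = 0;
          double e = pair_ef(i, j, gx, gy, gz);
          if (e != 0.0 || gx != 0.0 || gy != 0.0 || gz != 0.0) {
            pot += e;
            fx[i] += gx; fy[i] += gy; fz[i] += gz;
            fx[j] -= gx; fy[j] -= gy; fz[j] -= gz;
          }
        }
    }
    // WLC bonds (tension pulls the pair together)
    for (size_t b = 0; b < b_i.size(); b++) {
      int i = b_i[b], j = b_j[b];
      double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
      minimg(dx, dy);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double F = wlc_tension(r, b_L0[b], b_lp[b]);
      pot += wlc_energy(r, b_L0[b], b_lp[b]);
      double fr = -F / r;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
  }
};

static Sim make_sim(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                    NumericVector sp_sigma, NumericVector sp_mass, NumericVector sp_gamma,
                    LogicalVector sp_is2d, LogicalVector sp_frozen,
                    IntegerVector pair_kind, NumericVector pair_eps, NumericVector pair_sigma,
                    NumericVector pair_rcut, NumericVector pair_n, NumericVector pair_thetac,
                    IntegerVector pair_recsp,
                    IntegerMatrix bond_idx, NumericVector bond_L0, NumericVector bond_lp,
                    double lx, double ly, double lz, double kBT) {
  Sim S;
  S.N = pos.nrow(); S.nsp = sp_sigma.size();
  S.lx = lx; S.ly = ly; S.lz = lz; S.kBT = kBT;
  S.px.resize(S.N); S.py.resize(S.N); S.pz.resize(S.N);
  S.vx.resize(S.N); S.vy.resize(S.N); S.vz.resize(S.N);
  S.fx.resize(S.N); S.fy.resize(S.N); S.fz.resize(S.N);
  S.sp.resize(S.N);
  for (int i = 0; i < S.N; i++) {
    S.px[i] = pos(i, 0); S.py[i] = pos(i, 1); S.pz[i] = pos(i, 2);
    S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
    S.sp[i] = species[i];
  }
  S.ux = S.px; S.uy = S.py; S.uz = S.pz;
  S.sp_sigma.assign(sp_sigma.begin(), sp_sigma.end());
  S.sp_mass.assign(sp_mass.begin(), sp_mass.end());
  S.sp_gamma.assign(sp_gamma.begin(), sp_gamma.end());
  S.sp_is2d.resize(S.nsp); S.sp_frozen.resize(S.nsp);
  for (int s = 0; s < S.nsp; s++) { S.sp_is2d[s] = sp_is2d[s]; S.sp_frozen[s] = sp_frozen[s]; }
  int np = S.nsp * S.nsp;
  S.pk.assign(pair_kind.begin(), pair_kind.end());
  S.peps.assign(pair_eps.begin(), pair_eps.end());
  S.psig.assign(pair_sigma.begin(), pair_sigma.end());
  S.pn.assign(pair_n.begin(), pair_n.end());
  S.pthc.assign(pair_thetac.begin(), pair_thetac.end());
  S.precsp.assign(pair_recsp.begin(), pair_recsp.end());
  S.prc2.resize(np); S.psr6c.resize(np); S.psr12c.resize(np);
  S.rmax = 0.0;
  for (int p = 0; p < np; p++) {
    double rc = pair_rcut[p];
    S.prc2[p] = rc * rc;
    if (S.pk[p] != PK_NONE && rc > S.rmax) S.rmax = rc;
    double sr = (rc > 0) ? pair_sigma[p] / rc : 0.0;
    double sr3 = sr * sr * sr;
    S.psr6c[p] = sr3 * sr3;
    S.psr12c[p] = S.psr6c[p] * S.psr6c[p];
  }
  if (S.rmax <= 0) S.rmax = 1.0;
  int nb = bond_idx.nrow();
  S.partner.assign(S.N, -1);
  for (int b = 0; b < nb; b++) {
    int i = bond_idx(b, 0), j = bond_idx(b, 1);
    S.b_i.push_back(i); S.b_j.push_back(j);
    S.b_L0.push_back(bond_L0[b]); S.b_lp.push_back(bond_lp[b]);
    S.partner[i] = j; S.partner[j] = i;
  }
  return S;
}

// Greedy lowest-energy one-to-one matching of ligands to receptors across
// all angular pair types; returns counts per type and optionally the pairs.
struct Cand { double e; int l, r, t; };
static void detect_bound(const Sim &S, const std::vector<int> &type_of_pair,
                         int ntypes, double bind_frac,
                         std::vector<int> &counts, std::vector<Cand> *pairs_out) {
  std::vector<Cand> cand;
  for (int i = 0; i < S.N; i++)
    for (int j = i + 1; j < S.N; j++) {
      int p = S.sp[i] * S.nsp + S.sp[j];
      if (S.pk[p] != PK_ANGULAR) continue;
      double dx = S.px[i] - S.px[j], dy = S.py[i] - S.py[j], dz = S.pz[i] - S.pz[j];
      double ddx = dx, ddy = dy; S.minimg(ddx, ddy);
      double r2 = ddx * ddx + ddy * ddy + dz * dz;
      if (r2 >= S.prc2[p]) continue;
      double e = S.pair_energy(i, j);
      if (e < -bind_frac * S.peps[p]) {
        int lig = (S.sp[i] == S.precsp[p]) ? j : i;
        int rec = (lig == i) ? j : i;
        cand.push_back({e, lig, rec, type_of_pair[p]});
      }
    }
  std::sort(cand.begin(), cand.end(), [](const Cand &a, const Cand &b) {
    if (a.e != b.e) return a.e < b.e;
    if (a.l != b.l) return a.l < b.l;
    return a.r < b.r;
  });
  std::vector<char> lig_used(S.N, 0), rec_used(S.N, 0);
  counts.assign(ntypes, 0);
  for (auto &c : cand) {
    if (lig_used[c.l] || rec_used[c.r]) continue;
    lig_used[c.l] = 1; rec_used[c.r] = 1;
    counts[c.t]++;
    if (pairs_out) pairs_out->push_back(c);
  }
}

// Detection via neighbour cells when the system is large
static void detect_bound_cells(Sim &S, const std::vector<int> &type_of_pair,
                               int ntypes, double bind_frac, std::vector<int> &counts) {
  S.build_cells();
  if (!S.cells_ok) { detect_bound(S, type_of_pair, ntypes, bind_frac, counts, nullptr); return; }
  std::vector<Cand> cand;
  for (int i = 0; i < S.N; i++) {
    int cx = (int)std::floor(S.px[i] / S.lx * S.ncx); if (cx >= S.ncx) cx = S.ncx - 1; if (cx < 0) cx = 0;
    int cy = (int)std::floor(S.py[i] / S.ly * S.ncy); if (cy >= S.ncy) cy = S.ncy - 1; if (cy < 0) cy = 0;
    int cz = (int)std::floor(S.pz[i] / S.lz * S.ncz); if (cz >= S.ncz) cz = S.ncz - 1; if (cz < 0) cz = 0;
    int z0 = std::max(0, cz - 1), z1 = std::min(S.ncz - 1, cz + 1);
    for (int zz = z0; zz <= z1; zz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dxc = -1; dxc <= 1; dxc++) {
          int yy = (cy + dy + S.ncy) % S.ncy;
          int xx = (cx + dxc + S.ncx) % S.ncx;
          int cc = (zz * S.ncy + yy) * S.ncx + xx;
          for (int j = S.chead[cc]; j >= 0; j = S.cnext[j]) {
            if (j <= i) continue;
            int p = S.sp[i] * S.nsp + S.sp[j];
            if (S.pk[p] != PK_ANGULAR) continue;
            double e = S.pair_energy(i, j);
            if (e < -bind_frac * S.peps[p]) {
              int lig = (S.sp[i] == S.precsp[p]) ? j : i;
              int rec = (lig == i) ? j : i;
              cand.push_back({e, lig, rec, type_of_pair[p]});
            }
          }
        }
  }
  std::sort(cand.begin(), cand.end(), [](const Cand &a, const Cand &b) {
    if (a.e != b.e) return a.e < b.e;
    if (a.l != b.l) return a.l < b.l;
    return a.r < b.r;
  });
  std::vector<char> lig_used(S.N, 0), rec_used(S.N, 0);
  counts.assign(ntypes, 0);
  for (auto &c : cand)
    if (!lig_used[c.l] && !rec_used[c.r]) {
      lig_used[c.l] = 1; rec_used[c.r] = 1;
      counts[c.t]++;
    }
}

// [[Rcpp::export]]
List cg_forces_cpp(NumericMatrix pos, IntegerVector species,
                   NumericVector sp_sigma, NumericVector sp_mass, NumericVector sp_gamma,
                   LogicalVector sp_is2d, LogicalVector sp_frozen,
                   IntegerVector pair_kind, NumericVector pair_eps, NumericVector pair_sigma,
                   NumericVector pair_rcut, NumericVector pair_n, NumericVector pair_thetac,
                   IntegerVector pair_recsp,
                   IntegerMatrix bond_idx, NumericVector bond_L0, NumericVector bond_lp,
                   double lx, double ly, double lz, double kBT, bool use_cell) {
  NumericMatrix vel(pos.nrow(), 3);
  Sim S = make_sim(pos, vel, species, sp_sigma, sp_mass, sp_gamma, sp_is2d, sp_frozen,
                   pair_kind, pair_eps, pair_sigma, pair_rcut, pair_n, pair_thetac,
                   pair_recsp, bond_idx, bond_L0, bond_lp, lx, ly, lz, kBT);
  S.compute_forces(use_cell);
  NumericMatrix F(S.N, 3);
  for (int i = 0; i < S.N; i++) { F(i, 0) = S.fx[i]; F(i, 1) = S.fy[i]; F(i, 2) = S.fz[i]; }
  return List::create(_["forces"] = F, _["potential"] = S.pot);
}

// [[Rcpp::export]]
List cg_detect_cpp(NumericMatrix pos, IntegerVector species,
                   NumericVector sp_sigma, NumericVector sp_mass, NumericVector sp_gamma,
                   LogicalVector sp_is2d, LogicalVector sp_frozen,
                   IntegerVector pair_kind, NumericVector pair_eps, NumericVector pair_sigma,
                   NumericVector pair_rcut, NumericVector pair_n, NumericVector pair_thetac,
                   IntegerVector pair_recsp,
                   IntegerMatrix bond_idx, NumericVector bond_L0, NumericVector bond_lp,
                   double lx, double ly, double lz, double kBT, double bind_frac) {
  NumericMatrix vel(pos.nrow(), 3);
  Sim S = make_sim(pos, vel, species, sp_sigma, sp_mass, sp_gamma, sp_is2d, sp_frozen,
                   pair_kind, pair_eps, pair_sigma, pair_rcut, pair_n, pair_thetac,
                   pair_recsp, bond_idx, bond_L0, bond_lp, lx, ly, lz, kBT);
  // type index per angular species pair
  std::vector<int> type_of_pair(S.nsp * S.nsp, -1);
  int ntypes = 0;
  IntegerVector t_lig, t_rec;
  for (int a = 0; a < S.nsp; a++)
    for (int b = a; b < S.nsp; b++) {
      int p = a * S.nsp + b;
      if (S.pk[p] == PK_ANGULAR) {
        type_of_pair[p] = ntypes;
        type_of_pair[b * S.nsp + a] = ntypes;
        int rec = S.precsp[p];
        int lig = (rec == a) ? b : a;
        t_lig.push_back(lig); t_rec.push_back(rec);
        ntypes++;
      }
    }
  std::vector<int> counts;
  std::vector<Cand> pairs;
  detect_bound(S, type_of_pair, ntypes, bind_frac, counts, &pairs);
  int m = pairs.size();
  IntegerVector lig(m), rec(m), typ(m);
  NumericVector en(m);
  for (int k = 0; k < m; k++) {
    lig[k] = pairs[k].l + 1; rec[k] = pairs[k].r + 1;
    typ[k] = pairs[k].t + 1; en[k] = pairs[k].e;
  }
  return List::create(_["ligand"] = lig, _["receptor"] = rec, _["type"] = typ,
                      _["energy"] = en, _["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["type_ligand"] = t_lig, _["type_receptor"] = t_rec);
}

// [[Rcpp::export]]
List cg_run_cpp(NumericMatrix pos0, NumericMatrix vel0, IntegerVector species,
                NumericVector sp_sigma, NumericVector sp_mass, NumericVector sp_gamma,
                LogicalVector sp_is2d, LogicalVector sp_frozen,
                IntegerVector pair_kind, NumericVector pair_eps, NumericVector pair_sigma,
                NumericVector pair_rcut, NumericVector pair_n, NumericVector pair_thetac,
                IntegerVector pair_recsp,
                IntegerMatrix bond_idx, NumericVector bond_L0, NumericVector bond_lp,
                double lx, double ly, double lz, double kBT, double dt,
                int n_steps, int sample_every, double bind_frac,
                int frames_every, bool frames_unwrapped, bool record_bonds,
                bool use_cell) {
  Sim S = make_sim(pos0, vel0, species, sp_sigma, sp_mass, sp_gamma, sp_is2d, sp_frozen,
                   pair_kind, pair_eps, pair_sigma, pair_rcut, pair_n, pair_thetac,
                   pair_recsp, bond_idx, bond_L0, bond_lp, lx, ly, lz, kBT);
  XRng rng; rng.seed_from_R();
  int N = S.N;
  // per-species BAOAB coefficients
  std::vector<double> oc1(S.nsp), oc2(S.nsp), hdtm(S.nsp);
  for (int s = 0; s < S.nsp; s++) {
    double g = S.sp_gamma[s];
    double c1 = std::exp(-g * dt);
    oc1[s] = c1;
    oc2[s] = std::sqrt(kBT * (1.0 - c1 * c1) / S.sp_mass[s]);
    hdtm[s] = 0.5 * dt / S.sp_mass[s];
  }
  // angular pair types
  std::vector<int> type_of_pair(S.nsp * S.nsp, -1);
  int ntypes = 0;
  IntegerVector t_lig, t_rec;
  for (int a = 0; a < S.nsp; a++)
    for (int b = a; b < S.nsp; b++) {
      int p = a * S.nsp + b;
      if (S.pk[p] == PK_ANGULAR) {
        type_of_pair[p] = ntypes;
        type_of_pair[b * S.nsp + a] = ntypes;
        int rec = S.precsp[p];
        t_lig.push_back(rec == a ? b : a); t_rec.push_back(rec);
        ntypes++;
      }
    }
  int nsamp = n_steps / sample_every + 1;
  NumericVector time_out(nsamp), pot_out(nsamp), kin_out(nsamp);
  IntegerMatrix counts_out(nsamp, ntypes);
  int nframes = (frames_every > 0) ? (nsamp - 1) / frames_every + 1 : 0;
  NumericVector frames(frames_every > 0 ? (size_t)nframes * N * 3 : 0);
  int nb = S.b_i.size();
  NumericMatrix bond_r(record_bonds ? nsamp : 0, record_bonds ? nb : 0);
  // degrees of freedom for kinetic sampling
  double ndof = 0;
  for (int i = 0; i < N; i++) {
    int s = S.sp[i];
    if (S.sp_frozen[s]) continue;
    ndof += S.sp_is2d[s] ? 2 : 3;
  }

  S.compute_forces(use_cell);
  int isamp = 0, iframe = 0;
  auto record = [&](int step) {
    time_out[isamp] = step * dt;
    pot_out[isamp] = S.pot;
    double ke = 0;
    for (int i = 0; i < N; i++) {
      int s = S.sp[i];
      if (S.sp_frozen[s]) continue;
      double m = S.sp_mass[s];
      ke += 0.5 * m * (S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] + S.vz[i] * S.vz[i]);
    }
    kin_out[isamp] = ke;
    if (ntypes > 0) {
      std::vector<int> counts;
      detect_bound_cells(S, type_of_pair, ntypes, bind_frac, counts);
      for (int t = 0; t < ntypes; t++) counts_out(isamp, t) = counts[t];
    }
    if (record_bonds)
      for (int b = 0; b < nb; b++) {
        double dx = S.px[S.b_i[b]] - S.px[S.b_j[b]];
        double dy = S.py[S.b_i[b]] - S.py[S.b_j[b]];
        double dz = S.pz[S.b_i[b]] - S.pz[S.b_j[b]];
        S.minimg(dx, dy);
        bond_r(isamp, b) = std::sqrt(dx * dx + dy * dy + dz * dz);
      }
    if (frames_every > 0 && isamp % frames_every == 0) {
      for (int i = 0; i < N; i++) {
        size_t off = ((size_t)iframe * N + i) * 3;
        if (frames_unwrapped) {
          frames[off] = S.ux[i]; frames[off + 1] = S.uy[i]; frames[off + 2] = S.uz[i];
        } else {
          frames[off] = S.px[i]; frames[off + 1] = S.py[i]; frames[off + 2] = S.pz[i];
        }
      }
      iframe++;
    }
    // sanity: finite coordinates
    for (int i = 0; i < N; i++)
      if (!std::isfinite(S.px[i]) || !std::isfinite(S.py[i]) || !std::isfinite(S.pz[i]))
        stop("non-finite coordinate for particle %d at t = %g", i + 1, step * dt);
    isamp++;
  };
  record(0);

  for (int step = 1; step <= n_steps; step++) {
    // B
    for (int i = 0; i < N; i++) {
      int s = S.sp[i];
      if (S.sp_frozen[s]) continue;
      S.vx[i] += hdtm[s] * S.fx[i];
      S.vy[i] += hdtm[s] * S.fy[i];
      if (!S.sp_is2d[s]) S.vz[i] += hdtm[s] * S.fz[i];
    }
    // A half + O + A half
    for (int i = 0; i < N; i++) {
      int s = S.sp[i];
      if (S.sp_frozen[s]) continue;
      bool is2d = S.sp_is2d[s];
      double hx = 0.5 * dt * S.vx[i], hy = 0.5 * dt * S.vy[i];
      S.px[i] += hx; S.py[i] += hy; S.ux[i] += hx; S.uy[i] += hy;
      if (!is2d) { double hz = 0.5 * dt * S.vz[i]; S.pz[i] += hz; S.uz[i] += hz; }
      S.vx[i] = oc1[s] * S.vx[i] + oc2[s] * rng.rnorm();
      S.vy[i] = oc1[s] * S.vy[i] + oc2[s] * rng.rnorm();
      if (!is2d) S.vz[i] = oc1[s] * S.vz[i] + oc2[s] * rng.rnorm();
      hx = 0.5 * dt * S.vx[i]; hy = 0.5 * dt * S.vy[i];
      S.px[i] += hx; S.py[i] += hy; S.ux[i] += hx; S.uy[i] += hy;
      if (!is2d) { double hz = 0.5 * dt * S.vz[i]; S.pz[i] += hz; S.uz[i] += hz; }
      // wrap x,y into the primary box (unwrapped copies keep drifting)
      if (S.px[i] < 0) S.px[i] += lx; else if (S.px[i] >= lx) S.px[i] -= lx;
      if (S.py[i] < 0) S.py[i] += ly; else if (S.py[i] >= ly) S.py[i] -= ly;
      // reflective walls in z for bulk species
      if (!is2d) {
        double zmin = 0.5 * S.sp_sigma[s], zmax = lz - 0.5 * S.sp_sigma[s];
        int guard = 0;
        while ((S.pz[i] < zmin || S.pz[i] > zmax) && guard++ < 8) {
          if (S.pz[i] < zmin) {
            double over = zmin - S.pz[i];
            S.pz[i] = zmin + over; S.uz[i] += 2.0 * over; S.vz[i] = -S.vz[i];
          } else {
            double over = S.pz[i] - zmax;
            S.pz[i] = zmax - over; S.uz[i] -= 2.0 * over; S.vz[i] = -S.vz[i];
          }
        }
      } else { S.pz[i] = 0.0; S.vz[i] = 0.0; }
    }
    S.compute_forces(use_cell);
    // B
    for (int i = 0; i < N; i++) {
      int s = S.sp[i];
      if (S.sp_frozen[s]) continue;
      S.vx[i] += hdtm[s] * S.fx[i];
      S.vy[i] += hdtm[s] * S.fy[i];
      if (!S.sp_is2d[s]) S.vz[i] += hdtm[s] * S.fz[i];
    }
    if (step % sample_every == 0) record(step);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(N, 3), vel_out(N, 3);
  for (int i = 0; i < N; i++) {
    pos_out(i, 0) = S.px[i]; pos_out(i, 1) = S.py[i]; pos_out(i, 2) = S.pz[i];
    vel_out(i, 0) = S.vx[i]; vel_out(i, 1) = S.vy[i]; vel_out(i, 2) = S.vz[i];
  }
  List out = List::create(
    _["time"] = time_out, _["counts"] = counts_out,
    _["type_ligand"] = t_lig, _["type_receptor"] = t_rec,
    _["potential"] = pot_out, _["kinetic"] = kin_out, _["ndof"] = ndof,
    _["pos"] = pos_out, _["vel"] = vel_out,
    _["n_overstretch"] = (double)S.n_overstretch, _["max_bond_x"] = S.max_bond_x);
  if (frames_every > 0) {
    frames.attr("dim") = IntegerVector::create(3, N, nframes);
    out["frames"] = frames;
  }
  if (record_bonds) out["bond_r"] = bond_r;
  return out;
}
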