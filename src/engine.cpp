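// CFCMC NPT Monte Carlo engine for rigid multi-site molecules.
//
// Units: kJ/mol, nm, elementary charge, K, bar (converted on entry).
// Electrostatics: Ewald summation (tinfoil boundary), LJ: truncated with
// analytic tail correction. One optional fractional group coupled through
// lambda: soft-core LJ switched on over lambda in [0, 1/2], charges scaled
// linearly over lambda in [1/2, 1].

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <complex>
#include <random>

using namespace Rcpp;

static const double KB = 8.31446261815324e-3;   // kJ/(mol K)
static const double KE = 138.935458;            // kJ nm / (mol e^2)
static const double PBAR = 0.0602214076;        // bar -> kJ/(mol nm^3)
static const double TWO_PI = 6.283185307179586;

// fast erfc (Abramowitz-Stegun 7.1.26 rational form, |err| < 1.5e-7):
// ample for the default Ewald accuracy target and ~4x cheaper than the
// library call in the real-space inner loop
static inline double fast_erfc(double x) {
  double t = 1.0 / (1.0 + 0.3275911 * x);
  double p = t * (0.254829592 +
             t * (-0.284496736 +
             t * (1.421413741 +
             t * (-1.453152027 + t * 1.061405429))));
  return p * std::exp(-x * x);
}

// ---------------------------------------------------------------- rng -----
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  double unif(double a, double b) { return a + (b - a) * unif(); }
  int idx(int n) { return (int)(unif() * n) % n; }
  double gauss() {
    // Box-Muller, deterministic across platforms
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(TWO_PI * u2);
  }
};

// ---------------------------------------------------------- force field ---
struct Species {
  int ns;
  std::vector<double> bx, by, bz;   // body-frame site coordinates
  std::vector<int> type;            // 0-based global LJ type
  std::vector<double> q_pes, q_ecs;
  double mass;                      // g/mol
};

struct FF {
  std::vector<Species> sp;
  int ntype;
  std::vector<double> eps, sig;     // ntype*ntype, row-major
  double rc, rc2;
  bool tail;
  double ew_acc;                    // Ewald accuracy target
  double alpha;                     // derived from rc and ew_acc
  double sc_alpha;                  // soft-core parameter
  bool any_charge;
  double epsp(int a, int b) const { return eps[a * ntype + b]; }
  double sigp(int a, int b) const { return sig[a * ntype + b]; }
};

static FF parse_ff(const List& ffl) {
  FF ff;
  List spl = ffl["species"];
  ff.any_charge = false;
  for (int i = 0; i < spl.size(); ++i) {
    List s = spl[i];
    Species sp;
    NumericMatrix body = s["body"];
    sp.ns = body.nrow();
    for (int j = 0; j < sp.ns; ++j) {
      sp.bx.push_back(body(j, 0));
      sp.by.push_back(body(j, 1));
      sp.bz.push_back(body(j, 2));
    }
    IntegerVector tp = s["type"];
    for (int j = 0; j < sp.ns; ++j) sp.type.push_back(tp[j] - 1);
    NumericVector qp = s["q_pes"], qe = s["q_ecs"];
    for (int j = 0; j < sp.ns; ++j) {
      sp.q_pes.push_back(qp[j]);
      sp.q_ecs.push_back(qe[j]);
      if (qp[j] != 0.0 || qe[j] != 0.0) ff.any_charge = true;
    }
    sp.mass = as<double>(s["mass"]);
    ff.sp.push_back(sp);
  }
  NumericMatrix em = ffl["eps"], sm = ffl["sig"];
  ff.ntype = em.nrow();
  ff.eps.assign(ff.ntype * ff.ntype, 0.0);
  ff.sig.assign(ff.ntype * ff.ntype, 0.0);
  for (int a = 0; a < ff.ntype; ++a)
    for (int b = 0; b < ff.ntype; ++b) {
      ff.eps[a * ff.ntype + b] = em(a, b);
      ff.sig[a * ff.ntype + b] = sm(a, b);
    }
  ff.rc = as<double>(ffl["rc"]);
  ff.rc2 = ff.rc * ff.rc;
  ff.tail = as<bool>(ffl["tail"]);
  ff.ew_acc = as<double>(ffl["ewald_accuracy"]);
  ff.alpha = std::sqrt(-std::log(ff.ew_acc)) / ff.rc;
  ff.sc_alpha = as<double>(ffl["sc_alpha"]);
  return ff;
}

// --------------------------------------------------------------- state ----
struct State {
  double L;
  std::vector<int> spid;                 // 0-based species per molecule
  std::vector<double> cx, cy, cz;        // reference-point positions
  std::vector<double> qw, qx, qy, qz;    // orientations
  std::vector<char> isfrac;
  std::vector<int> frac;                 // molecule indices of the group
  double lambda;
  int surface;                           // 0 PES, 1 ECS for the group
  int nmol() const { return (int)spid.size(); }
};

static State parse_state(const List& sl) {
  State st;
  st.L = as<double>(sl["L"]);
  IntegerVector spid = sl["spid"];
  NumericMatrix com = sl["com"], quat = sl["quat"];
  int n = spid.size();
  for (int i = 0; i < n; ++i) {
    st.spid.push_back(spid[i] - 1);
    st.cx.push_back(com(i, 0));
    st.cy.push_back(com(i, 1));
    st.cz.push_back(com(i, 2));
    st.qw.push_back(quat(i, 0));
    st.qx.push_back(quat(i, 1));
    st.qy.push_back(quat(i, 2));
    st.qz.push_back(quat(i, 3));
  }
  st.isfrac.assign(n, 0);
  IntegerVector fr = sl["frac"];
  for (int i = 0; i < fr.size(); ++i) {
    st.frac.push_back(fr[i] - 1);
    st.isfrac[fr[i] - 1] = 1;
  }
  st.lambda = as<double>(sl["lambda"]);
  std::string surf = as<std::string>(sl["frac_surface"]);
  st.surface = (surf == "ECS") ? 1 : 0;
  return st;
}

static List state_to_list(const State& st) {
  int n = st.nmol();
  IntegerVector spid(n);
  NumericMatrix com(n, 3), quat(n, 4);
  for (int i = 0; i < n; ++i) {
    spid[i] = st.spid[i] + 1;
    com(i, 0) = st.cx[i]; com(i, 1) = st.cy[i]; com(i, 2) = st.cz[i];
    quat(i, 0) = st.qw[i]; quat(i, 1) = st.qx[i];
    quat(i, 2) = st.qy[i]; quat(i, 3) = st.qz[i];
  }
  IntegerVector fr(st.frac.size());
  for (size_t i = 0; i < st.frac.size(); ++i) fr[i] = st.frac[i] + 1;
  return List::create(
    _["L"] = st.L, _["spid"] = spid, _["com"] = com, _["quat"] = quat,
    _["frac"] = fr, _["lambda"] = st.lambda,
    _["frac_surface"] = st.surface == 1 ? "ECS" : "PES");
}

// ------------------------------------------------------------ geometry ----
struct Sites {
  std::vector<double> x, y, z, q;   // q: effective charge (lambda-scaled)
  std::vector<double> q0;           // unscaled surface charge
  std::vector<int> type;
};

static inline double lam_vdw(double lam) {
  return lam >= 0.5 ? 1.0 : 2.0 * lam;
}
static inline double lam_q(double lam) {
  return lam <= 0.5 ? 0.0 : 2.0 * lam - 1.0;
}

// site positions of molecule m (no wrapping; min-image handles periodicity)
static void mol_sites(const FF& ff, const State& st, int m, Sites& out) {
  const Species& sp = ff.sp[st.spid[m]];
  double w = st.qw[m], x = st.qx[m], y = st.qy[m], z = st.qz[m];
  double R[3][3] = {
    {1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y)},
    {2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x)},
    {2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)}};
  out.x.clear(); out.y.clear(); out.z.clear();
  out.q.clear(); out.q0.clear(); out.type.clear();
  double lq = st.isfrac[m] ? lam_q(st.lambda) : 1.0;
  for (int j = 0; j < sp.ns; ++j) {
    double bx = sp.bx[j], by = sp.by[j], bz = sp.bz[j];
    out.x.push_back(st.cx[m] + R[0][0] * bx + R[0][1] * by + R[0][2] * bz);
    out.y.push_back(st.cy[m] + R[1][0] * bx + R[1][1] * by + R[1][2] * bz);
    out.z.push_back(st.cz[m] + R[2][0] * bx + R[2][1] * by + R[2][2] * bz);
    double q0 = (st.isfrac[m] && st.surface == 1) ? sp.q_ecs[j] : sp.q_pes[j];
    out.q0.push_back(q0);
    out.q.push_back(q0 * lq);
    out.type.push_back(sp.type[j]);
  }
}

static inline double min_img(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// ---------------------------------------------------------- pair energy ---
// LJ between two site sets; soft-core with strength lv when coupled=true
static double lj_pair(const FF& ff, const Sites& a, const Sites& b, double L,
                      bool coupled, double lv) {
  if (coupled && lv <= 0.0) return 0.0;
  double e = 0.0;
  for (size_t i = 0; i < a.x.size(); ++i) {
    int ta = a.type[i];
    for (size_t j = 0; j < b.x.size(); ++j) {
      double dx = min_img(a.x[i] - b.x[j], L);
      double dy = min_img(a.y[i] - b.y[j], L);
      double dz = min_img(a.z[i] - b.z[j], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= ff.rc2) continue;
      double epsij = ff.epsp(ta, b.type[j]);
      if (epsij == 0.0) continue;
      double sij = ff.sigp(ta, b.type[j]);
      if (!coupled || lv >= 1.0) {
        if (r2 < 1e-8) return INFINITY;   // hard overlap at full coupling
        double s2 = sij * sij / r2, s6 = s2 * s2 * s2;
        e += 4.0 * epsij * s6 * (s6 - 1.0);
      } else {
        double r6s = r2 * r2 * r2 / (sij * sij * sij * sij * sij * sij);
        double den = ff.sc_alpha * (1.0 - lv) + r6s;
        e += lv * 4.0 * epsij * (1.0 / (den * den) - 1.0 / den);
      }
    }
  }
  return e;
}

// real-space Ewald between two site sets (effective charges)
static double real_pair(const FF& ff, const Sites& a, const Sites& b,
                        double L) {
  double e = 0.0;
  for (size_t i = 0; i < a.x.size(); ++i) {
    if (a.q[i] == 0.0) continue;
    for (size_t j = 0; j < b.x.size(); ++j) {
      if (b.q[j] == 0.0) continue;
      double dx = min_img(a.x[i] - b.x[j], L);
      double dy = min_img(a.y[i] - b.y[j], L);
      double dz = min_img(a.z[i] - b.z[j], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= ff.rc2) continue;
      if (r2 < 1e-8) return INFINITY;
      double r = std::sqrt(r2);
      e += KE * a.q[i] * b.q[j] * fast_erfc(ff.alpha * r) / r;
    }
  }
  return e;
}

// combined LJ + real-space electrostatics between two site sets with a
// single distance evaluation per pair (hot path of the MC moves)
static double pair_energy(const FF& ff, const Sites& a, const Sites& b,
                          double L, bool coupled, double lv,
                          bool any_charge) {
  double e = 0.0;
  size_t na = a.x.size(), nb = b.x.size();
  for (size_t i = 0; i < na; ++i) {
    int ta = a.type[i];
    double qi = a.q[i];
    for (size_t j = 0; j < nb; ++j) {
      double dx = min_img(a.x[i] - b.x[j], L);
      double dy = min_img(a.y[i] - b.y[j], L);
      double dz = min_img(a.z[i] - b.z[j], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= ff.rc2) continue;
      double epsij = ff.epsp(ta, b.type[j]);
      if (epsij != 0.0) {
        if (!coupled || lv >= 1.0) {
          if (r2 < 1e-8) return INFINITY;
          double sij = ff.sigp(ta, b.type[j]);
          double s2 = sij * sij / r2, s6 = s2 * s2 * s2;
          e += 4.0 * epsij * s6 * (s6 - 1.0);
        } else if (lv > 0.0) {
          double sij = ff.sigp(ta, b.type[j]);
          double r6s = r2 * r2 * r2 /
                       (sij * sij * sij * sij * sij * sij);
          double den = ff.sc_alpha * (1.0 - lv) + r6s;
          e += lv * 4.0 * epsij * (1.0 / (den * den) - 1.0 / den);
        }
      }
      if (any_charge && qi != 0.0 && b.q[j] != 0.0) {
        if (r2 < 1e-8) return INFINITY;
        double r = std::sqrt(r2);
        e += KE * qi * b.q[j] * fast_erfc(ff.alpha * r) / r;
      }
    }
  }
  return e;
}

// ------------------------------------------------------------- k-space ----
struct KSpace {
  int nmax;
  std::vector<int> kx, ky, kz;     // integer triples, half space
  std::vector<double> Ak;          // prefactor so E = sum Ak |S|^2
  std::vector<double> Sr, Si;      // current structure factor
  double L;
  void setup(const FF& ff, double Lbox) {
    L = Lbox;
    double kcut = 2.0 * ff.alpha * std::sqrt(-std::log(ff.ew_acc));
    nmax = (int)std::ceil(kcut * L / TWO_PI);
    if (nmax < 1) nmax = 1;
    if (nmax > 63) stop("Ewald k-space too large (box >> cutoff)");
    kx.clear(); ky.clear(); kz.clear(); Ak.clear();
    double V = L * L * L;
    double kc2 = kcut * kcut;
    for (int nx = -nmax; nx <= nmax; ++nx)
      for (int ny = -nmax; ny <= nmax; ++ny)
        for (int nz = 0; nz <= nmax; ++nz) {
          if (nz == 0 && (ny < 0 || (ny == 0 && nx <= 0))) continue;
          double k2 = (TWO_PI / L) * (TWO_PI / L) *
                      (double)(nx * nx + ny * ny + nz * nz);
          if (k2 > kc2) continue;
          kx.push_back(nx); ky.push_back(ny); kz.push_back(nz);
          // factor 2 for the omitted half space
          Ak.push_back(2.0 * TWO_PI * KE / V *
                       std::exp(-k2 / (4.0 * ff.alpha * ff.alpha)) / k2);
        }
  }
  // structure-factor contribution of a site set (appends into dr, di)
  void contrib(const Sites& s, std::vector<double>& dr,
               std::vector<double>& di, double sign) const {
    size_t nk = kx.size();
    int np = nmax + 1;
    std::complex<double> ex[64], ey[64], ez[64];
    for (size_t j = 0; j < s.x.size(); ++j) {
      if (s.q[j] == 0.0) continue;
      std::complex<double> fx(std::cos(TWO_PI * s.x[j] / L),
                              std::sin(TWO_PI * s.x[j] / L));
      std::complex<double> fy(std::cos(TWO_PI * s.y[j] / L),
                              std::sin(TWO_PI * s.y[j] / L));
      std::complex<double> fz(std::cos(TWO_PI * s.z[j] / L),
                              std::sin(TWO_PI * s.z[j] / L));
      ex[0] = ey[0] = ez[0] = 1.0;
      for (int n = 1; n < np; ++n) {
        ex[n] = ex[n - 1] * fx;
        ey[n] = ey[n - 1] * fy;
        ez[n] = ez[n - 1] * fz;
      }
      double q = sign * s.q[j];
      for (size_t k = 0; k < nk; ++k) {
        std::complex<double> cx =
            kx[k] >= 0 ? ex[kx[k]] : std::conj(ex[-kx[k]]);
        std::complex<double> cy =
            ky[k] >= 0 ? ey[ky[k]] : std::conj(ey[-ky[k]]);
        std::complex<double> c = cx * cy * ez[kz[k]];
        dr[k] += q * c.real();
        di[k] += q * c.imag();
      }
    }
  }
  double energy() const {
    double e = 0.0;
    for (size_t k = 0; k < kx.size(); ++k)
      e += Ak[k] * (Sr[k] * Sr[k] + Si[k] * Si[k]);
    return e;
  }
  double energy_with(const std::vector<double>& dr,
                     const std::vector<double>& di) const {
    double e = 0.0;
    for (size_t k = 0; k < kx.size(); ++k) {
      double r = Sr[k] + dr[k], i = Si[k] + di[k];
      e += Ak[k] * (r * r + i * i);
    }
    return e;
  }
};

// ------------------------------------------------------ total energies ----
struct EnergyBook {
  double lj, tail, real, recip, self, excl;
  double total() const { return lj + tail + real + recip + self + excl; }
};

// self + intramolecular exclusion terms (depend on lambda via q)
static void self_excl(const FF& ff, const State& st, double& self_e,
                      double& excl_e) {
  self_e = 0.0; excl_e = 0.0;
  if (!ff.any_charge) return;
  Sites s;
  for (int m = 0; m < st.nmol(); ++m) {
    mol_sites(ff, st, m, s);
    for (size_t i = 0; i < s.q.size(); ++i) {
      self_e -= KE * ff.alpha / std::sqrt(M_PI) * s.q[i] * s.q[i];
      for (size_t j = i + 1; j < s.q.size(); ++j) {
        if (s.q[i] == 0.0 || s.q[j] == 0.0) continue;
        double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j],
               dz = s.z[i] - s.z[j];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        excl_e -= KE * s.q[i] * s.q[j] * std::erf(ff.alpha * r) / r;
      }
    }
  }
}

// self + exclusion terms of the fractional group only (the lambda-dependent
// part; host terms never change during a run)
static void group_self_excl(const FF& ff, const State& st, double& self_e,
                            double& excl_e) {
  self_e = 0.0; excl_e = 0.0;
  if (!ff.any_charge) return;
  Sites s;
  for (int m : st.frac) {
    mol_sites(ff, st, m, s);
    for (size_t i = 0; i < s.q.size(); ++i) {
      self_e -= KE * ff.alpha / std::sqrt(M_PI) * s.q[i] * s.q[i];
      for (size_t j = i + 1; j < s.q.size(); ++j) {
        if (s.q[i] == 0.0 || s.q[j] == 0.0) continue;
        double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j],
               dz = s.z[i] - s.z[j];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        excl_e -= KE * s.q[i] * s.q[j] * std::erf(ff.alpha * r) / r;
      }
    }
  }
}

// LJ tail correction from host (non-fractional) site-type counts
static double tail_energy(const FF& ff, const State& st) {
  if (!ff.tail) return 0.0;
  std::vector<double> ntyp(ff.ntype, 0.0);
  for (int m = 0; m < st.nmol(); ++m) {
    if (st.isfrac[m]) continue;
    const Species& sp = ff.sp[st.spid[m]];
    for (int j = 0; j < sp.ns; ++j) ntyp[sp.type[j]] += 1.0;
  }
  double V = st.L * st.L * st.L, e = 0.0;
  for (int a = 0; a < ff.ntype; ++a)
    for (int b = 0; b < ff.ntype; ++b) {
      if (ntyp[a] == 0.0 || ntyp[b] == 0.0) continue;
      double epsij = ff.epsp(a, b);
      if (epsij == 0.0) continue;
      double sij = ff.sigp(a, b);
      double sr3 = std::pow(sij / ff.rc, 3.0), sr9 = sr3 * sr3 * sr3;
      e += ntyp[a] * ntyp[b] / (2.0 * V) * (16.0 * M_PI / 3.0) * epsij *
           sij * sij * sij * (sr9 / 3.0 - sr3);
    }
  return e;
}

static EnergyBook full_energy(const FF& ff, const State& st, KSpace* ks) {
  EnergyBook eb = {0, 0, 0, 0, 0, 0};
  int n = st.nmol();
  std::vector<Sites> all(n);
  for (int m = 0; m < n; ++m) mol_sites(ff, st, m, all[m]);
  double lv = lam_vdw(st.lambda);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      bool coupled = st.isfrac[i] || st.isfrac[j];
      eb.lj += lj_pair(ff, all[i], all[j], st.L, coupled, lv);
      if (ff.any_charge) eb.real += real_pair(ff, all[i], all[j], st.L);
    }
  eb.tail = tail_energy(ff, st);
  if (ff.any_charge && ks != nullptr) {
    ks->setup(ff, st.L);
    size_t nk = ks->kx.size();
    ks->Sr.assign(nk, 0.0);
    ks->Si.assign(nk, 0.0);
    for (int m = 0; m < n; ++m) ks->contrib(all[m], ks->Sr, ks->Si, 1.0);
    eb.recip = ks->energy();
    self_excl(ff, st, eb.self, eb.excl);
  }
  return eb;
}

// self + exclusion of host (non-fractional) molecules: constant for rigid
// bodies over an entire run
static void host_self_excl(const FF& ff, const State& st, double& self_e,
                           double& excl_e) {
  self_e = 0.0; excl_e = 0.0;
  if (!ff.any_charge) return;
  Sites s;
  for (int m = 0; m < st.nmol(); ++m) {
    if (st.isfrac[m]) continue;
    mol_sites(ff, st, m, s);
    for (size_t i = 0; i < s.q.size(); ++i) {
      self_e -= KE * ff.alpha / std::sqrt(M_PI) * s.q[i] * s.q[i];
      for (size_t j = i + 1; j < s.q.size(); ++j) {
        if (s.q[i] == 0.0 || s.q[j] == 0.0) continue;
        double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j],
               dz = s.z[i] - s.z[j];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        excl_e -= KE * s.q[i] * s.q[j] * std::erf(ff.alpha * r) / r;
      }
    }
  }
}

// fast total energy for the MC loop: merged LJ + real pair loop, cached
// host self/exclusion terms, k-space rebuilt for the current box
static double fast_total(const FF& ff, const State& st, KSpace* ks,
                         double host_self, double host_excl) {
  int n = st.nmol();
  std::vector<Sites> all(n);
  for (int m = 0; m < n; ++m) mol_sites(ff, st, m, all[m]);
  double lv = lam_vdw(st.lambda);
  double e = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      bool coupled = st.isfrac[i] || st.isfrac[j];
      double ep = pair_energy(ff, all[i], all[j], st.L, coupled, lv,
                              ff.any_charge);
      if (std::isinf(ep)) return INFINITY;
      e += ep;
    }
  e += tail_energy(ff, st);
  if (ff.any_charge && ks != nullptr) {
    ks->setup(ff, st.L);
    size_t nk = ks->kx.size();
    ks->Sr.assign(nk, 0.0);
    ks->Si.assign(nk, 0.0);
    for (int m = 0; m < n; ++m) ks->contrib(all[m], ks->Sr, ks->Si, 1.0);
    e += ks->energy();
    double gs = 0, ge = 0;
    group_self_excl(ff, st, gs, ge);
    e += host_self + host_excl + gs + ge;
  }
  return e;
}

// interaction energy (LJ + real-space) of molecule set M with the rest and
// within M across molecules
static double set_interaction(const FF& ff, const State& st,
                              const std::vector<int>& M) {
  std::vector<char> in(st.nmol(), 0);
  for (int m : M) in[m] = 1;
  double lv = lam_vdw(st.lambda);
  double e = 0.0;
  Sites a, b;
  for (size_t ii = 0; ii < M.size(); ++ii) {
    mol_sites(ff, st, M[ii], a);
    for (int j = 0; j < st.nmol(); ++j) {
      if (in[j] && j <= M[ii]) continue;   // count in-set pairs once
      if (j == M[ii]) continue;
      mol_sites(ff, st, j, b);
      bool coupled = st.isfrac[M[ii]] || st.isfrac[j];
      double ep = pair_energy(ff, a, b, st.L, coupled, lv, ff.any_charge);
      if (std::isinf(ep)) return INFINITY;
      e += ep;
    }
  }
  return e;
}

// ------------------------------------------------------- exported ops -----

// [[Rcpp::export]]
List cpp_total_energy(List ffl, List statel, bool with_ewald = true) {
  FF ff = parse_ff(ffl);
  State st = parse_state(statel);
  KSpace ks;
  EnergyBook eb = full_energy(ff, st, (with_ewald && ff.any_charge) ? &ks : nullptr);
  return List::create(
    _["total"] = eb.total(), _["lj"] = eb.lj, _["tail"] = eb.tail,
    _["real"] = eb.real, _["recip"] = eb.recip, _["self"] = eb.self,
    _["excl"] = eb.excl);
}

// energy of coupling the fractional group at the given lambda:
// U_total(lambda) - U_total(0)
// [[Rcpp::export]]
double cpp_group_energy(List ffl, List statel, double lambda) {
  FF ff = parse_ff(ffl);
  State st = parse_state(statel);
  if (lambda < 0.0 || lambda > 1.0) stop("lambda must be in [0, 1]");
  KSpace ks;
  st.lambda = lambda;
  EnergyBook e1 = full_energy(ff, st, ff.any_charge ? &ks : nullptr);
  st.lambda = 0.0;
  EnergyBook e0 = full_energy(ff, st, ff.any_charge ? &ks : nullptr);
  return e1.total() - e0.total();
}

// analytic LJ tail contribution of inserting the given species set into the
// current host, at the current volume (used to correct mu_ex estimates)
// [[Rcpp::export]]
double cpp_insertion_tail(List ffl, List statel, IntegerVector ins_species) {
  FF ff = parse_ff(ffl);
  State st = parse_state(statel);
  if (!ff.tail) return 0.0;
  std::vector<double> nh(ff.ntype, 0.0), ni(ff.ntype, 0.0);
  for (int m = 0; m < st.nmol(); ++m) {
    if (st.isfrac[m]) continue;
    const Species& sp = ff.sp[st.spid[m]];
    for (int j = 0; j < sp.ns; ++j) nh[sp.type[j]] += 1.0;
  }
  for (int i = 0; i < ins_species.size(); ++i) {
    const Species& sp = ff.sp[ins_species[i] - 1];
    for (int j = 0; j < sp.ns; ++j) ni[sp.type[j]] += 1.0;
  }
  double V = st.L * st.L * st.L, e = 0.0;
  for (int a = 0; a < ff.ntype; ++a)
    for (int b = 0; b < ff.ntype; ++b) {
      double epsij = ff.epsp(a, b);
      if (epsij == 0.0) continue;
      double sij = ff.sigp(a, b);
      double sr3 = std::pow(sij / ff.rc, 3.0), sr9 = sr3 * sr3 * sr3;
      double c = (16.0 * M_PI / 3.0) * epsij * sij * sij * sij *
                 (sr9 / 3.0 - sr3);
      e += ni[a] * (nh[b] + 0.5 * ni[b]) / V * c;
    }
  return e;
}

// -------------------------------------------------------------- MC run ----
struct MoveStats { long att = 0, acc = 0; };

// [[Rcpp::export]]
List cpp_run_npt(List ffl, List statel, List run) {
  FF ff = parse_ff(ffl);
  State st = parse_state(statel);
  const double T = as<double>(run["T"]);
  const double beta = 1.0 / (KB * T);
  const double Pbar = as<double>(run["P"]);
  const double Pint = Pbar * PBAR;
  const long n_equil = as<double>(run["nsteps_equil"]);
  const long n_prod = as<double>(run["nsteps_prod"]);
  const int nblocks = as<int>(run["nblocks"]);
  NumericVector mw = run["move_weights"];   // trans rot vol lambda reinsert
  double dmax = as<double>(run["dmax"]);
  double rotmax = as<double>(run["rotmax"]);
  double dlnV = as<double>(run["dlnV"]);
  double dlam = as<double>(run["dlam"]);
  const int nbins = as<int>(run["nbins"]);
  double wl_f = as<double>(run["wl_f0"]);
  const double wl_flat = as<double>(run["wl_flat"]);
  const double wl_fmin = as<double>(run["wl_fmin"]);
  const long wl_check = as<double>(run["wl_check"]);
  const bool adapt = as<bool>(run["adapt"]);
  const long widom_every = as<double>(run["widom_every"]);
  const int widom_n = as<int>(run["widom_n"]);
  const int widom_spid = as<int>(run["widom_species"]);   // 1-based, 0 = off
  const bool widom_ecs = as<std::string>(run["widom_surface"]) == "ECS";
  const long sample_every = as<double>(run["sample_every"]);
  const bool sample_pair = run.containsElementNamed("sample_pair") &&
                           as<bool>(run["sample_pair"]);
  Rng rng((uint64_t)as<double>(run["seed"]));

  const bool has_frac = !st.frac.empty();
  const bool do_lambda = has_frac && (mw[3] > 0 || mw[4] > 0);
  // cumulative move weights
  double wsum = 0.0;
  std::vector<double> cw(5);
  for (int i = 0; i < 5; ++i) { wsum += mw[i]; cw[i] = wsum; }
  if (wsum <= 0) stop("move weights must not all be zero");
  for (int i = 0; i < 5; ++i) cw[i] /= wsum;

  KSpace ks;
  double h_self = 0, h_excl = 0;
  host_self_excl(ff, st, h_self, h_excl);
  double U = fast_total(ff, st, ff.any_charge ? &ks : nullptr,
                        h_self, h_excl);
  double Erec = ff.any_charge ? ks.energy() : 0.0;   // cached recip energy

  // Wang-Landau bias (natural-log units)
  std::vector<double> eta(nbins, 0.0);
  std::vector<long> wl_hist(nbins, 0);
  bool wl_frozen = !do_lambda;
  auto bin_of = [&](double lam) {
    int b = (int)(lam * nbins);
    return b >= nbins ? nbins - 1 : b;
  };

  MoveStats ms[5];
  // accumulators
  std::vector<double> blk_rho(nblocks, 0.0), blk_u(nblocks, 0.0),
      blk_v(nblocks, 0.0), blk_rho_mass(nblocks, 0.0);
  std::vector<long> blk_ns(nblocks, 0);
  std::vector<std::vector<double>> blk_hist(
      nblocks, std::vector<double>(nbins, 0.0));
  std::vector<double> wid_sum(nblocks, 0.0), wid_v(nblocks, 0.0);
  std::vector<long> wid_n(nblocks, 0);
  std::vector<double> pair_dist;
  if (sample_pair) pair_dist.reserve(n_prod / sample_every + 1);
  // free-energy-perturbation endpoint accumulators (terminal lambda bins)
  std::vector<double> fep0_sum(nblocks, 0.0), fep1_sum(nblocks, 0.0);
  std::vector<double> fep0_n(nblocks, 0.0), fep1_n(nblocks, 0.0);
  const long fep_every = 5;
  double mass_tot = 0.0;
  for (int m = 0; m < st.nmol(); ++m) mass_tot += ff.sp[st.spid[m]].mass;

  Sites sa, sb;
  std::vector<double> dSr, dSi;

  auto attempt_displace = [&](bool rotate_move) {
    MoveStats& stat = ms[rotate_move ? 1 : 0];
    stat.att++;
    int m = rng.idx(st.nmol());
    double ocx = st.cx[m], ocy = st.cy[m], ocz = st.cz[m];
    double oqw = st.qw[m], oqx = st.qx[m], oqy = st.qy[m], oqz = st.qz[m];
    std::vector<int> just_m(1, m);
    double e_old = set_interaction(ff, st, just_m);
    Sites olds;
    if (ff.any_charge) mol_sites(ff, st, m, olds);
    if (!rotate_move) {
      st.cx[m] += rng.unif(-dmax, dmax);
      st.cy[m] += rng.unif(-dmax, dmax);
      st.cz[m] += rng.unif(-dmax, dmax);
      // wrap reference point
      st.cx[m] -= st.L * std::floor(st.cx[m] / st.L);
      st.cy[m] -= st.L * std::floor(st.cy[m] / st.L);
      st.cz[m] -= st.L * std::floor(st.cz[m] / st.L);
    } else {
      // axis-angle perturbation quaternion, applied on the left
      double ax = rng.gauss(), ay = rng.gauss(), az = rng.gauss();
      double an = std::sqrt(ax * ax + ay * ay + az * az);
      if (an < 1e-12) { ax = 1; ay = 0; az = 0; an = 1; }
      double th = rng.unif(-rotmax, rotmax) * 0.5;
      double sw = std::cos(th), sv = std::sin(th) / an;
      double pw = sw, px = sv * ax, py = sv * ay, pz = sv * az;
      double nw = pw * oqw - px * oqx - py * oqy - pz * oqz;
      double nx = pw * oqx + px * oqw + py * oqz - pz * oqy;
      double ny = pw * oqy - px * oqz + py * oqw + pz * oqx;
      double nz = pw * oqz + px * oqy - py * oqx + pz * oqw;
      double nn = std::sqrt(nw * nw + nx * nx + ny * ny + nz * nz);
      st.qw[m] = nw / nn; st.qx[m] = nx / nn;
      st.qy[m] = ny / nn; st.qz[m] = nz / nn;
    }
    double e_new = set_interaction(ff, st, just_m);
    double dU = e_new - e_old;
    double dRecip = 0.0;
    if (ff.any_charge && !std::isinf(dU)) {
      mol_sites(ff, st, m, sa);
      dSr.assign(ks.kx.size(), 0.0);
      dSi.assign(ks.kx.size(), 0.0);
      ks.contrib(olds, dSr, dSi, -1.0);
      ks.contrib(sa, dSr, dSi, 1.0);
      dRecip = ks.energy_with(dSr, dSi) - Erec;
      dU += dRecip;
    }
    bool acc = !std::isinf(dU) &&
               (dU <= 0.0 || rng.unif() < std::exp(-beta * dU));
    if (acc) {
      stat.acc++;
      U += dU;
      if (ff.any_charge) {
        Erec += dRecip;
        for (size_t k = 0; k < dSr.size(); ++k) {
          ks.Sr[k] += dSr[k];
          ks.Si[k] += dSi[k];
        }
      }
    } else {
      st.cx[m] = ocx; st.cy[m] = ocy; st.cz[m] = ocz;
      st.qw[m] = oqw; st.qx[m] = oqx; st.qy[m] = oqy; st.qz[m] = oqz;
    }
  };

  auto attempt_volume = [&]() {
    ms[2].att++;
    double V = st.L * st.L * st.L;
    double lnV = std::log(V) + rng.unif(-dlnV, dlnV);
    double Vn = std::exp(lnV);
    double s = std::cbrt(Vn / V);
    State old = st;
    double Uold = U;
    for (int m = 0; m < st.nmol(); ++m) {
      st.cx[m] *= s; st.cy[m] *= s; st.cz[m] *= s;
    }
    st.L *= s;
    KSpace ks2;
    double Un = fast_total(ff, st, ff.any_charge ? &ks2 : nullptr,
                           h_self, h_excl);
    double arg = -beta * (Un - Uold + Pint * (Vn - V)) +
                 (st.nmol() + 1) * std::log(Vn / V);
    if (!std::isinf(Un) && (arg >= 0.0 || rng.unif() < std::exp(arg))) {
      ms[2].acc++;
      U = Un;
      if (ff.any_charge) {
        ks = ks2;
        Erec = ks.energy();
      }
    } else {
      st = old;
      U = Uold;
    }
  };

  // group electrostatic coefficients for lambda moves:
  // E_elec,group(lq) = lq*c1 + lq^2*c2 (real space) and recip via Sg
  auto attempt_lambda = [&](bool reinsert) {
    MoveStats& stat = ms[reinsert ? 4 : 3];
    stat.att++;
    double lam_old = st.lambda;
    State old;
    if (reinsert) old = st;
    double e_old = set_interaction(ff, st, st.frac);
    double self_o = 0, excl_o = 0;
    std::vector<double> dr, di;
    if (ff.any_charge) {
      group_self_excl(ff, st, self_o, excl_o);
      dr.assign(ks.kx.size(), 0.0);
      di.assign(ks.kx.size(), 0.0);
      for (int m : st.frac) {
        mol_sites(ff, st, m, sa);
        ks.contrib(sa, dr, di, -1.0);
      }
    }
    if (reinsert) {
      for (int m : st.frac) {
        st.cx[m] = rng.unif() * st.L;
        st.cy[m] = rng.unif() * st.L;
        st.cz[m] = rng.unif() * st.L;
        double g1 = rng.gauss(), g2 = rng.gauss(), g3 = rng.gauss(),
               g4 = rng.gauss();
        double nn = std::sqrt(g1 * g1 + g2 * g2 + g3 * g3 + g4 * g4);
        if (nn < 1e-12) { g1 = 1; nn = 1; }
        st.qw[m] = g1 / nn; st.qx[m] = g2 / nn;
        st.qy[m] = g3 / nn; st.qz[m] = g4 / nn;
      }
    } else {
      double ln = st.lambda + rng.unif(-dlam, dlam);
      if (ln < 0.0 || ln > 1.0) {
        // out-of-range proposal rejected (symmetric proposal kept)
        if (!wl_frozen) {
          int b = bin_of(st.lambda);
          eta[b] -= wl_f;
          wl_hist[b]++;
        }
        return;
      }
      st.lambda = ln;
    }
    double e_new = set_interaction(ff, st, st.frac);
    double dU = e_new - e_old;
    double dRecip = 0.0;
    if (ff.any_charge && !std::isinf(dU)) {
      double self_n = 0, excl_n = 0;
      group_self_excl(ff, st, self_n, excl_n);
      for (int m : st.frac) {
        mol_sites(ff, st, m, sa);
        ks.contrib(sa, dr, di, 1.0);
      }
      dRecip = ks.energy_with(dr, di) - Erec;
      dU += dRecip + (self_n - self_o) + (excl_n - excl_o);
    }
    double dbias = 0.0;
    if (!reinsert)
      dbias = eta[bin_of(st.lambda)] - eta[bin_of(lam_old)];
    double arg = -beta * dU + dbias;
    bool acc = !std::isinf(dU) && (arg >= 0.0 || rng.unif() < std::exp(arg));
    if (acc) {
      stat.acc++;
      U += dU;
      if (ff.any_charge) {
        Erec += dRecip;
        for (size_t k = 0; k < dr.size(); ++k) {
          ks.Sr[k] += dr[k];
          ks.Si[k] += di[k];
        }
      }
    } else {
      if (reinsert) st = old;
      else st.lambda = lam_old;
    }
    if (!wl_frozen) {
      int b = bin_of(st.lambda);
      eta[b] -= wl_f;
      wl_hist[b]++;
    }
  };

  // energy change of moving the group's coupling from the current lambda
  // to lam_t, without committing the move
  auto lambda_delta_energy = [&](double lam_t) {
    double lam_save = st.lambda;
    double e_old = set_interaction(ff, st, st.frac);
    double self_o = 0, excl_o = 0;
    std::vector<double> dr, di;
    if (ff.any_charge) {
      group_self_excl(ff, st, self_o, excl_o);
      dr.assign(ks.kx.size(), 0.0);
      di.assign(ks.kx.size(), 0.0);
      for (int m : st.frac) {
        mol_sites(ff, st, m, sa);
        ks.contrib(sa, dr, di, -1.0);
      }
    }
    st.lambda = lam_t;
    double e_new = set_interaction(ff, st, st.frac);
    double dU = e_new - e_old;
    if (ff.any_charge && !std::isinf(dU)) {
      double self_n = 0, excl_n = 0;
      group_self_excl(ff, st, self_n, excl_n);
      for (int m : st.frac) {
        mol_sites(ff, st, m, sa);
        ks.contrib(sa, dr, di, 1.0);
      }
      dU += (ks.energy_with(dr, di) - Erec) + (self_n - self_o) +
            (excl_n - excl_o);
    }
    st.lambda = lam_save;
    return dU;
  };

  // exact endpoint estimates by free-energy perturbation from the
  // terminal bins: <exp(-beta [U(edge) - U(lambda)])> removes the
  // bin-discretization bias of the histogram estimator
  auto endpoint_sample = [&](int block) {
    int b = bin_of(st.lambda);
    if (b != 0 && b != nbins - 1) return;
    double lam_t = (b == 0) ? 0.0 : 1.0;
    double dU = lambda_delta_energy(lam_t);
    double w = std::isinf(dU) ? 0.0 : std::exp(-beta * dU);
    if (b == 0) { fep0_sum[block] += w; fep0_n[block] += 1.0; }
    else { fep1_sum[block] += w; fep1_n[block] += 1.0; }
  };

  auto widom_insert = [&](int block) {
    const Species& sp = ff.sp[widom_spid - 1];
    double V = st.L * st.L * st.L;
    int n = st.nmol();
    std::vector<Sites> all(n);
    for (int m = 0; m < n; ++m) mol_sites(ff, st, m, all[m]);
    for (int t = 0; t < widom_n; ++t) {
      // build ghost molecule
      Sites g;
      double cx = rng.unif() * st.L, cy = rng.unif() * st.L,
             cz = rng.unif() * st.L;
      double g1 = rng.gauss(), g2 = rng.gauss(), g3 = rng.gauss(),
             g4 = rng.gauss();
      double nn = std::sqrt(g1 * g1 + g2 * g2 + g3 * g3 + g4 * g4);
      if (nn < 1e-12) { g1 = 1; nn = 1; }
      double w = g1 / nn, x = g2 / nn, y = g3 / nn, z = g4 / nn;
      double R[3][3] = {
        {1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y)},
        {2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x)},
        {2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)}};
      for (int j = 0; j < sp.ns; ++j) {
        double bx = sp.bx[j], by = sp.by[j], bz = sp.bz[j];
        g.x.push_back(cx + R[0][0] * bx + R[0][1] * by + R[0][2] * bz);
        g.y.push_back(cy + R[1][0] * bx + R[1][1] * by + R[1][2] * bz);
        g.z.push_back(cz + R[2][0] * bx + R[2][1] * by + R[2][2] * bz);
        double q0 = widom_ecs ? sp.q_ecs[j] : sp.q_pes[j];
        g.q.push_back(q0);
        g.q0.push_back(q0);
        g.type.push_back(sp.type[j]);
      }
      double dU = 0.0;
      for (int m = 0; m < n && !std::isinf(dU); ++m)
        dU += pair_energy(ff, g, all[m], st.L, false, 1.0, ff.any_charge);
      if (ff.any_charge && !std::isinf(dU)) {
        dSr.assign(ks.kx.size(), 0.0);
        dSi.assign(ks.kx.size(), 0.0);
        ks.contrib(g, dSr, dSi, 1.0);
        dU += ks.energy_with(dSr, dSi) - Erec;
        // ghost self + exclusion
        for (size_t i = 0; i < g.q.size(); ++i) {
          dU -= KE * ff.alpha / std::sqrt(M_PI) * g.q[i] * g.q[i];
          for (size_t j = i + 1; j < g.q.size(); ++j) {
            double dx = g.x[i] - g.x[j], dy = g.y[i] - g.y[j],
                   dz = g.z[i] - g.z[j];
            double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (r > 1e-12)
              dU -= KE * g.q[i] * g.q[j] * std::erf(ff.alpha * r) / r;
          }
        }
      }
      double bf = std::isinf(dU) ? 0.0 : std::exp(-beta * dU);
      wid_sum[block] += V * bf;
      wid_v[block] += V;
      wid_n[block]++;
    }
  };

  auto do_step = [&](bool production, int block) {
    double u = rng.unif();
    if (u < cw[0]) attempt_displace(false);
    else if (u < cw[1]) attempt_displace(true);
    else if (u < cw[2]) attempt_volume();
    else if (u < cw[3]) { if (do_lambda) attempt_lambda(false); }
    else { if (do_lambda) attempt_lambda(true); }
    if (production && do_lambda) blk_hist[block][bin_of(st.lambda)] += 1.0;
  };

  // ---- equilibration / Wang-Landau stage ----
  long adapt_every = 2000;
  for (long s = 0; s < n_equil; ++s) {
    do_step(false, 0);
    if (!wl_frozen && (s + 1) % wl_check == 0) {
      long tot = 0, mn = wl_hist[0];
      for (int b = 0; b < nbins; ++b) {
        tot += wl_hist[b];
        if (wl_hist[b] < mn) mn = wl_hist[b];
      }
      double mean = (double)tot / nbins;
      // guard against premature freezing: demand a minimum visit count
      // per bin before the flatness rule may halve the factor
      if (mean >= 100.0 && mn >= wl_flat * mean) {
        wl_f *= 0.5;
        std::fill(wl_hist.begin(), wl_hist.end(), 0L);
        if (wl_f < wl_fmin) wl_frozen = true;
      }
    }
    if (adapt && (s + 1) % adapt_every == 0) {
      auto tune = [&](MoveStats& t, double& par, double cap) {
        if (t.att < 50) return;
        double r = (double)t.acc / t.att;
        if (r > 0.5) par = std::min(par * 1.1, cap);
        else if (r < 0.3) par *= 0.9;
        t.att = t.acc = 0;
      };
      tune(ms[0], dmax, st.L / 2.0);
      tune(ms[1], rotmax, M_PI);
      tune(ms[2], dlnV, 0.5);
      tune(ms[3], dlam, 1.0);
    }
    if ((s + 1) % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  bool wl_converged = wl_frozen;
  wl_frozen = true;   // bias frozen for production regardless
  for (int i = 0; i < 5; ++i) { ms[i].att = 0; ms[i].acc = 0; }

  // ---- production ----
  long per_block = n_prod / nblocks;
  if (per_block < 1) per_block = 1;
  for (long s = 0; s < n_prod; ++s) {
    int block = (int)std::min((long)(s / per_block), (long)(nblocks - 1));
    do_step(true, block);
    if ((s + 1) % sample_every == 0) {
      double V = st.L * st.L * st.L;
      blk_rho[block] += st.nmol() / V;
      blk_rho_mass[block] += mass_tot / V * 1.66053906892;
      blk_u[block] += U / st.nmol();
      blk_v[block] += V;
      blk_ns[block]++;
      if (sample_pair && st.nmol() >= 2) {
        double dx = min_img(st.cx[0] - st.cx[1], st.L);
        double dy = min_img(st.cy[0] - st.cy[1], st.L);
        double dz = min_img(st.cz[0] - st.cz[1], st.L);
        pair_dist.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
      }
    }
    if (do_lambda && (s + 1) % fep_every == 0) endpoint_sample(block);
    if (widom_spid > 0 && (s + 1) % widom_every == 0) widom_insert(block);
    if ((s + 1) % 20000 == 0) Rcpp::checkUserInterrupt();
    // periodic full recompute to suppress incremental drift
    if ((s + 1) % 200000 == 0) {
      U = fast_total(ff, st, ff.any_charge ? &ks : nullptr, h_self, h_excl);
      if (ff.any_charge) Erec = ks.energy();
    }
  }

  // finalize
  double drift = U - fast_total(ff, st, ff.any_charge ? &ks : nullptr,
                                h_self, h_excl);
  NumericVector rho(nblocks), rho_mass(nblocks), umol(nblocks), vmean(nblocks);
  for (int b = 0; b < nblocks; ++b) {
    double ns = blk_ns[b] > 0 ? (double)blk_ns[b] : 1.0;
    rho[b] = blk_rho[b] / ns;
    rho_mass[b] = blk_rho_mass[b] / ns;
    umol[b] = blk_u[b] / ns;
    vmean[b] = blk_v[b] / ns;
  }
  NumericMatrix hist(nblocks, nbins);
  for (int b = 0; b < nblocks; ++b)
    for (int k = 0; k < nbins; ++k) hist(b, k) = blk_hist[b][k];
  NumericVector etaout(nbins);
  for (int k = 0; k < nbins; ++k) etaout[k] = eta[k];
  NumericVector acc(5), att(5);
  for (int i = 0; i < 5; ++i) {
    att[i] = (double)ms[i].att;
    acc[i] = ms[i].att > 0 ? (double)ms[i].acc / ms[i].att : NA_REAL;
  }
  acc.names() = CharacterVector::create("translate", "rotate", "volume",
                                        "lambda", "reinsert");
  return List::create(
    _["rho_blocks"] = rho, _["rho_mass_blocks"] = rho_mass,
    _["u_blocks"] = umol, _["v_blocks"] = vmean,
    _["hist_blocks"] = hist, _["eta"] = etaout,
    _["wl_converged"] = wl_converged, _["wl_f_final"] = wl_f,
    _["acceptance"] = acc, _["attempts"] = att,
    _["widom_sum"] = NumericVector(wid_sum.begin(), wid_sum.end()),
    _["widom_v"] = NumericVector(wid_v.begin(), wid_v.end()),
    _["widom_n"] = NumericVector(wid_n.begin(), wid_n.end()),
    _["pair_dist"] = NumericVector(pair_dist.begin(), pair_dist.end()),
    _["fep0_sum"] = NumericVector(fep0_sum.begin(), fep0_sum.end()),
    _["fep0_n"] = NumericVector(fep0_n.begin(), fep0_n.end()),
    _["fep1_sum"] = NumericVector(fep1_sum.begin(), fep1_sum.end()),
    _["fep1_n"] = NumericVector(fep1_n.begin(), fep1_n.end()),
    _["energy_drift"] = drift,
    _["final_state"] = state_to_list(st),
    _["settings"] = List::create(_["dmax"] = dmax, _["rotmax"] = rotmax,
                                 _["dlnV"] = dlnV, _["dlam"] = dlam,
                                 _["alpha"] = ff.alpha, _["rc"] = ff.rc,
                                 _["nbins"] = nbins));
}
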