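// Numerical core: ventricular cell model with stochastic Ca-spark recruitment,
// ten-state L-type Ca channel Markov scheme, four-compartment Ca cycling, and
// a monodomain tissue solver (operator splitting, 5-point Laplacian, no-flux).
//
// Units throughout: mV, ms, uA/uF, uM (Ca), mM (Na/K and formula-level Ca).
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG: splitmix64 stream, keyed by (seed, row, col, epoch) so
// every cell owns an independent reproducible stream regardless of grid
// traversal order or domain decomposition.
// ---------------------------------------------------------------------------
struct SplitMix {
  uint64_t s;
  inline uint64_t next() {
    uint64_t z = (s += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  inline double unif() {  // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

static SplitMix make_stream(uint64_t seed, uint64_t a, uint64_t b, uint64_t epoch) {
  SplitMix t{seed};
  t.s ^= t.next() + 0x9E3779B97f4A7C15ULL * (a + 1);
  t.s ^= t.next() + 0xC2B2AE3D27D4EB4FULL * (b + 1);
  t.s ^= t.next() + 0x165667B19E3779F9ULL * (epoch + 1);
  t.next();
  return t;
}

// Binomial draw on a SplitMix stream.  Exact CDF inversion when the mean is
// small; normal approximation with continuity correction (clamped to [0,n])
// when n*p*(1-p) is large.  Moment accuracy is what the model needs; the
// clamped tail error is far below per-step binomial noise.
static int rbinom_sm(SplitMix &r, int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  bool flip = p > 0.5;
  double q = flip ? 1.0 - p : p;
  double mean = n * q;
  int k = 0;
  if (mean < 30.0) {
    double u = r.unif();
    double pm = std::exp(n * std::log1p(-q));
    double cdf = pm;
    double odds = q / (1.0 - q);
    while (u > cdf && k < n) {
      pm *= ((double)(n - k) / (double)(k + 1)) * odds;
      cdf += pm;
      ++k;
      if (pm < 1e-300 && cdf < u) { // deep tail guard
        k = (int)std::floor(mean + 0.5);
        break;
      }
    }
  } else {
    double sd = std::sqrt(n * q * (1.0 - q));
    double u1 = r.unif(), u2 = r.unif();
    double z = std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
    double kk = std::floor(n * q + sd * z + 0.5);
    if (kk < 0) kk = 0;
    if (kk > n) kk = n;
    k = (int)kk;
  }
  return flip ? n - k : k;
}

// ---------------------------------------------------------------------------
// Model parameters
// ---------------------------------------------------------------------------
struct Params {
  // ionic conductances / scales (uA/uF based)
  double gna, gtof, gkr, gks, gk1, gnak, gnaca, pca;
  double tauj_scale;   // scales the j-gate time constant (recovery memory)
  double vkr, skr;     // IKr inward-rectification midpoint / slope (mV)
  // fixed ionic milieu (mM)
  double nao, ko, ki, cao;
  double rtf;          // RT/F in mV
  // LCC Markov
  double a24o, a34o, aca, cth, cspark;
  double k12, v12, s12, k23, v23, s23;
  double r42a, r42b, v42, s42, r43a, r43b, v43, s43;
  int couple_all;      // 1: all corresponding states exchange at alpha/beta
  // spark dynamics
  double alpha0, ksr, beta_b;
  // Ca compartments
  double gb, vup_b, vup_i, kup, tau_c, tau_sr;
  double vb, vi, vsrb, vsri;
  double buf_cb, buf_ci, buf_csrb, buf_csri;
  int jri_on; double gi, cith;
  // membrane <-> Ca conversions
  double conv_ica, conv_ncx, conv_na, allo_c;
  int na_dynamic;
  // stimulus
  double stim_amp, stim_dur;
  // numerics
  double dt_fast, dt_slow, dvdt_fast;
};

static double getd(const List &L, const char *nm) {
  if (!L.containsElementNamed(nm)) stop("missing parameter '%s'", nm);
  return as<double>(L[nm]);
}
static double getd(const List &L, const char *nm, double def) {
  if (!L.containsElementNamed(nm)) return def;
  return as<double>(L[nm]);
}

static Params load_params(const List &L) {
  Params p;
  p.gna = getd(L, "gna"); p.gtof = getd(L, "gtof"); p.gkr = getd(L, "gkr");
  p.gks = getd(L, "gks"); p.gk1 = getd(L, "gk1"); p.gnak = getd(L, "gnak");
  p.gnaca = getd(L, "gnaca"); p.pca = getd(L, "pca");
  p.tauj_scale = getd(L, "tauj_scale", 1.0);
  p.vkr = getd(L, "vkr", -33.0); p.skr = getd(L, "skr", 22.4);
  p.nao = getd(L, "nao", 136.0); p.ko = getd(L, "ko", 5.4);
  p.ki = getd(L, "ki", 140.0); p.cao = getd(L, "cao", 1.8);
  p.rtf = getd(L, "rtf", 26.54);
  p.a24o = getd(L, "a24o"); p.a34o = getd(L, "a34o");
  p.aca = getd(L, "aca"); p.cth = getd(L, "cth");
  p.cspark = getd(L, "cspark", 100.0);
  p.k12 = getd(L, "k12"); p.v12 = getd(L, "v12"); p.s12 = getd(L, "s12");
  p.k23 = getd(L, "k23"); p.v23 = getd(L, "v23"); p.s23 = getd(L, "s23");
  p.r42a = getd(L, "r42a"); p.r42b = getd(L, "r42b");
  p.v42 = getd(L, "v42"); p.s42 = getd(L, "s42");
  p.r43a = getd(L, "r43a"); p.r43b = getd(L, "r43b");
  p.v43 = getd(L, "v43"); p.s43 = getd(L, "s43");
  p.couple_all = (int)getd(L, "couple_all", 1.0);
  p.alpha0 = getd(L, "alpha0"); p.ksr = getd(L, "ksr"); p.beta_b = getd(L, "beta_b");
  p.gb = getd(L, "gb"); p.vup_b = getd(L, "vup_b"); p.vup_i = getd(L, "vup_i");
  p.kup = getd(L, "kup"); p.tau_c = getd(L, "tau_c"); p.tau_sr = getd(L, "tau_sr");
  p.vb = getd(L, "vb"); p.vi = getd(L, "vi");
  p.vsrb = getd(L, "vsrb"); p.vsri = getd(L, "vsri");
  p.buf_cb = getd(L, "buf_cb"); p.buf_ci = getd(L, "buf_ci");
  p.buf_csrb = getd(L, "buf_csrb", 1.0); p.buf_csri = getd(L, "buf_csri", 1.0);
  p.jri_on = (int)getd(L, "jri_on", 0.0);
  p.gi = getd(L, "gi", 0.0); p.cith = getd(L, "cith", 1.0);
  p.conv_ica = getd(L, "conv_ica"); p.conv_ncx = getd(L, "conv_ncx");
  p.conv_na = getd(L, "conv_na", 6.0e-6); p.allo_c = getd(L, "allo_c", 0.3);
  p.na_dynamic = (int)getd(L, "na_dynamic", 1.0);
  p.stim_amp = getd(L, "stim_amp", -80.0); p.stim_dur = getd(L, "stim_dur", 1.0);
  p.dt_fast = getd(L, "dt_fast", 0.01); p.dt_slow = getd(L, "dt_slow", 0.1);
  p.dvdt_fast = getd(L, "dvdt_fast", 1.0);
  return p;
}

// ---------------------------------------------------------------------------
// Voltage lookup table.  All purely voltage-dependent quantities are
// tabulated on a 0.05 mV grid and linearly interpolated; this is the standard
// speedup in cardiac monodomain codes and keeps results deterministic.
// ---------------------------------------------------------------------------
static const double TV0 = -110.0, TV1 = 90.0, TDV = 0.05;
static const int TN = (int)((TV1 - TV0) / TDV) + 1;

enum {
  T_MINF, T_ME1, T_ME2, T_HINF, T_HE1, T_HE2, T_JINF, T_JE1, T_JE2,
  T_XRINF, T_XRE1, T_XRE2, T_XSINF, T_XSE1, T_XSE2,
  T_XTINF, T_XTE1, T_XTE2, T_YTINF, T_YTE1, T_YTE2,
  T_A12, T_A21, T_A23, T_A32, T_A42, T_A43,
  T_RKR, T_XK1, T_FNAK, T_ZA, T_ZB, T_D1, T_D2,
  T_NCOL
};

struct Table {
  std::vector<double> col[T_NCOL];
  double ek;
};

static inline double sigm(double v, double vh, double s) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / s));
}

static void build_table(const Params &p, Table &T) {
  for (int c = 0; c < T_NCOL; ++c) T.col[c].assign(TN, 0.0);
  double ek = p.rtf * std::log(p.ko / p.ki);
  T.ek = ek;
  for (int i = 0; i < TN; ++i) {
    double v = TV0 + i * TDV;
    // --- INa gates (Luo-Rudy formulation used by the adopted rabbit model)
    double am = (std::fabs(v + 47.13) < 1e-6)
                  ? 3.2
                  : 0.32 * (v + 47.13) / (1.0 - std::exp(-0.1 * (v + 47.13)));
    double bm = 0.08 * std::exp(-v / 11.0);
    double ah, bh, aj, bj;
    if (v >= -40.0) {
      ah = 0.0;
      bh = 1.0 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
      aj = 0.0;
      bj = 0.3 * std::exp(-2.535e-7 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
    } else {
      ah = 0.135 * std::exp(-(80.0 + v) / 6.8);
      bh = 3.56 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.35 * v);
      aj = (-1.2714e5 * std::exp(0.2444 * v) - 3.474e-5 * std::exp(-0.04391 * v)) *
           (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
      bj = 0.1212 * std::exp(-0.01052 * v) / (1.0 + std::exp(-0.1378 * (v + 40.14)));
    }
    double tm = 1.0 / (am + bm), th = 1.0 / (ah + bh);
    double tj = p.tauj_scale / (aj + bj);
    T.col[T_MINF][i] = am * tm; T.col[T_HINF][i] = ah * th; T.col[T_JINF][i] = aj * tj;
    T.col[T_ME1][i] = std::exp(-p.dt_fast / tm); T.col[T_ME2][i] = std::exp(-p.dt_slow / tm);
    T.col[T_HE1][i] = std::exp(-p.dt_fast / th); T.col[T_HE2][i] = std::exp(-p.dt_slow / th);
    T.col[T_JE1][i] = std::exp(-p.dt_fast / tj); T.col[T_JE2][i] = std::exp(-p.dt_slow / tj);
    // --- IKr activation
    double xrinf = sigm(v, -50.0, 7.5);
    double t1 = (std::fabs(v + 7.0) < 1e-6) ? 0.00138 / 0.123
                : 0.00138 * (v + 7.0) / (1.0 - std::exp(-0.123 * (v + 7.0)));
    double t2 = (std::fabs(v + 10.0) < 1e-6) ? 0.00061 / 0.145
                : 0.00061 * (v + 10.0) / (std::exp(0.145 * (v + 10.0)) - 1.0);
    double tkr = 1.0 / (t1 + t2);
    T.col[T_XRINF][i] = xrinf;
    T.col[T_XRE1][i] = std::exp(-p.dt_fast / tkr); T.col[T_XRE2][i] = std::exp(-p.dt_slow / tkr);
    // --- IKs activation (single gate, squared at evaluation)
    double xsinf = sigm(v, 1.5, 16.7);
    double u1 = (std::fabs(v + 30.0) < 1e-6) ? 7.19e-5 / 0.148
                : 7.19e-5 * (v + 30.0) / (1.0 - std::exp(-0.148 * (v + 30.0)));
    double u2 = (std::fabs(v + 30.0) < 1e-6) ? 1.31e-4 / 0.0687
                : 1.31e-4 * (v + 30.0) / (std::exp(0.0687 * (v + 30.0)) - 1.0);
    double txs = 1.0 / (u1 + u2);
    T.col[T_XSINF][i] = xsinf;
    T.col[T_XSE1][i] = std::exp(-p.dt_fast / txs); T.col[T_XSE2][i] = std::exp(-p.dt_slow / txs);
    // --- Ito (fast component)
    double xtinf = sigm(v, -3.0, 15.0);
    double txt = 3.5 * std::exp(-(v / 30.0) * (v / 30.0)) + 1.5;
    double ytinf = 1.0 - sigm(v, -33.5, 10.0);
    double tyt = 20.0 + 20.0 / (1.0 + std::exp((v + 33.5) / 10.0));
    T.col[T_XTINF][i] = xtinf;
    T.col[T_XTE1][i] = std::exp(-p.dt_fast / txt); T.col[T_XTE2][i] = std::exp(-p.dt_slow / txt);
    T.col[T_YTINF][i] = ytinf;
    T.col[T_YTE1][i] = std::exp(-p.dt_fast / tyt); T.col[T_YTE2][i] = std::exp(-p.dt_slow / tyt);
    // --- LCC voltage-dependent rates
    T.col[T_A12][i] = p.k12 * sigm(v, p.v12, p.s12);
    T.col[T_A21][i] = p.k12 * (1.0 - sigm(v, p.v12, p.s12));
    T.col[T_A23][i] = p.k23 * sigm(v, p.v23, p.s23);
    T.col[T_A32][i] = p.k23 * (1.0 - sigm(v, p.v23, p.s23));
    T.col[T_A42][i] = p.r42a + p.r42b * (1.0 - sigm(v, -p.v42, p.s42));
    T.col[T_A43][i] = p.r43a + p.r43b * (1.0 - sigm(v, -p.v43, p.s43));
    // --- current factors
    T.col[T_RKR][i] = 1.0 / (1.0 + std::exp((v - p.vkr) / p.skr));
    double dk = v - ek;
    double ak1 = 1.02 / (1.0 + std::exp(0.2385 * (dk - 59.215)));
    double bk1 = (0.49124 * std::exp(0.08032 * (dk + 5.476)) +
                  std::exp(0.06175 * (dk - 594.31))) /
                 (1.0 + std::exp(-0.5143 * (dk + 4.753)));
    T.col[T_XK1][i] = ak1 / (ak1 + bk1);
    double vfrt = v / p.rtf;
    double sig = (std::exp(p.nao / 67.3) - 1.0) / 7.0;
    T.col[T_FNAK][i] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * vfrt) +
                              0.0365 * sig * std::exp(-vfrt));
    T.col[T_ZA][i] = std::exp(0.35 * vfrt);
    T.col[T_ZB][i] = std::exp(-0.65 * vfrt);
    double z2 = 2.0 * vfrt;
    if (std::fabs(z2) < 1e-5) {
      T.col[T_D1][i] = 1.0 + 0.5 * z2;
      T.col[T_D2][i] = 1.0 - 0.5 * z2;
    } else {
      double ez = std::exp(z2);
      T.col[T_D1][i] = z2 * ez / (ez - 1.0);
      T.col[T_D2][i] = z2 / (ez - 1.0);
    }
  }
}

struct Row { double x[T_NCOL]; };
static inline void table_row(const Table &T, double v, Row &r) {
  double u = (v - TV0) / TDV;
  if (u < 0.0) u = 0.0;
  if (u > TN - 1.001) u = TN - 1.001;
  int i = (int)u;
  double f = u - i;
  for (int c = 0; c < T_NCOL; ++c)
    r.x[c] = T.col[c][i] + f * (T.col[c][i + 1] - T.col[c][i]);
}

// ---------------------------------------------------------------------------
// Cell state
// ---------------------------------------------------------------------------
struct Currents {
  double ina, ikr, iks, ik1, ito, inak, inaca, ical, jca, jnaca;
};

struct Cell {
  double V, Nai;
  double m, h, j, xr, xs, xtof, ytof;
  double occ[10];          // C1 C2 O I1 I2 | CS1 CS2 OS IS1 IS2
  double cb, ci, csrb, csri;
  int nb;
  double pb;
  double dvdt;
  Currents last;         // currents from the most recent substep
  SplitMix rng;
  // event tracker
  double last_up, last_down;
  int up_armed;            // 1 when V has recovered below rearm level
};

static void default_cell(Cell &c) {
  c.V = -87.0; c.Nai = 12.0;
  c.m = 0.001; c.h = 1.0; c.j = 1.0;
  c.xr = 0.0; c.xs = 0.02; c.xtof = 0.0; c.ytof = 1.0;
  for (int k = 0; k < 10; ++k) c.occ[k] = 0.0;
  c.occ[0] = 1.0;
  c.cb = 0.15; c.ci = 0.15; c.csrb = 800.0; c.csri = 800.0;
  c.nb = 0; c.pb = 0.0; c.dvdt = 0.0;
  c.last = Currents{};
  c.last_up = NA_REAL; c.last_down = NA_REAL; c.up_armed = 1;
}

static inline double fca_of(double cb, double cth) {
  double r = cth / cb;
  return 1.0 / (1.0 + r * r);
}


// Membrane currents at the given state (table row already fetched for V).
static void eval_currents(const Cell &c, const Params &p, const Table &T,
                          const Row &r, Currents &I) {
  double ena = p.rtf * std::log(p.nao / c.Nai);
  double eks = p.rtf * std::log((p.ko + 0.018 * p.nao) / (p.ki + 0.018 * c.Nai));
  double ek = T.ek;
  I.ina = p.gna * c.m * c.m * c.m * c.h * c.j * (c.V - ena);
  I.ikr = p.gkr * std::sqrt(p.ko / 5.4) * c.xr * r.x[T_RKR] * (c.V - ek);
  I.iks = p.gks * c.xs * c.xs * (c.V - eks);
  I.ik1 = p.gk1 * std::sqrt(p.ko / 5.4) * r.x[T_XK1] * (c.V - ek);
  I.ito = p.gtof * c.xtof * c.ytof * (c.V - ek);
  double nai3 = c.Nai * c.Nai * c.Nai;
  I.inak = p.gnak * r.x[T_FNAK] * (p.ko / (p.ko + 1.5)) /
           (1.0 + (12.0 / c.Nai) * (12.0 / c.Nai));
  // NCX senses junctional cytosolic Ca (uM -> mM in the formula)
  double cbm = c.cb * 1e-3;
  double nao3 = p.nao * p.nao * p.nao;
  double num = r.x[T_ZA] * nai3 * p.cao - r.x[T_ZB] * nao3 * cbm;
  double den = (87.5 * 87.5 * 87.5 + nao3) * (1.38 + p.cao) *
               (1.0 + 0.1 * r.x[T_ZB]);
  double allo = 1.0 / (1.0 + (p.allo_c / c.cb) * (p.allo_c / c.cb));
  I.inaca = p.gnaca * allo * num / den;
  // GHK driving force; spark-on channels face the local spark concentration
  double drive_off = r.x[T_D1] * cbm - r.x[T_D2] * 0.341 * p.cao;
  double drive_on = r.x[T_D1] * (p.cspark * 1e-3) - r.x[T_D2] * 0.341 * p.cao;
  double o_off = c.occ[2], o_on = c.occ[7];
  I.ical = p.pca * (o_off * drive_off + o_on * drive_on);
  I.jca = -p.conv_ica * I.ical;
  I.jnaca = p.conv_ncx * I.inaca;
}

// One explicit substep of the LCC master equation (both groups + exchange).
static void lcc_step_inplace(double occ[10], const Row &r, double cb,
                             double alpha_b, double beta_b, const Params &p,
                             double dt) {
  double f_off = fca_of(cb, p.cth);
  double d[10];
  for (int g = 0; g < 2; ++g) {
    int o = 5 * g;
    double f = g ? 1.0 : f_off;
    double a24 = p.a24o + p.aca * f;
    double a34 = p.a34o + p.aca * f;
    double a12 = r.x[T_A12], a21 = r.x[T_A21];
    double a23 = r.x[T_A23], a32 = r.x[T_A32];
    double a42 = r.x[T_A42], a43 = r.x[T_A43];
    double C1 = occ[o + 0], C2 = occ[o + 1], O = occ[o + 2],
           I1 = occ[o + 3], I2 = occ[o + 4];
    d[o + 0] = a21 * C2 - a12 * C1;
    d[o + 1] = a12 * C1 + a32 * O + a43 * I2 - (a21 + a23 + a34) * C2;
    d[o + 2] = a23 * C2 + a42 * I1 - (a32 + a24) * O;
    d[o + 3] = a24 * O - a42 * I1;
    d[o + 4] = a34 * C2 - a43 * I2;
  }
  // spark-on/off exchange
  if (p.couple_all) {
    for (int k = 0; k < 5; ++k) {
      double ex = alpha_b * occ[k] - beta_b * occ[k + 5];
      d[k] -= ex;
      d[k + 5] += ex;
    }
  } else {
    double ex = alpha_b * occ[2] - beta_b * occ[7];
    d[2] -= ex;
    d[7] += ex;
  }
  for (int k = 0; k < 10; ++k) occ[k] += dt * d[k];
}

static void renorm_occ(double occ[10]) {
  double s = 0.0;
  for (int k = 0; k < 10; ++k) {
    if (occ[k] < 0.0) occ[k] = 0.0;
    s += occ[k];
  }
  if (s > 0.0)
    for (int k = 0; k < 10; ++k) occ[k] /= s;
}

// Spark recruitment rate: alpha0 * (spark-off open fraction) * Hill SR load
static inline double alpha_of(const Params &p, double o_off, double csrb) {
  double s = csrb * csrb / (csrb * csrb + p.ksr * p.ksr);
  return p.alpha0 * o_off * s;
}

struct CaFluxes {
  double jrb, jri, jupb, jupi, jdsr, jdc, jca, jnaca;
};

static void ca_fluxes(const Cell &c, const Params &p, double jca, double jnaca,
                      CaFluxes &F) {
  F.jrb = p.gb * c.csrb * c.pb;
  if (p.jri_on) {
    double act = 1.0 / (1.0 + std::pow(p.cith / c.ci, 4.0));
    F.jri = p.gi * c.csri * act;
  } else F.jri = 0.0;
  F.jupb = p.vup_b * c.cb * c.cb / (c.cb * c.cb + p.kup * p.kup);
  F.jupi = p.vup_i * c.ci * c.ci / (c.ci * c.ci + p.kup * p.kup);
  F.jdsr = (c.csri - c.csrb) / p.tau_sr;   // destination: SR near J
  F.jdc = (c.cb - c.ci) / p.tau_c;         // destination: cytosol near NJ
  F.jca = jca;
  F.jnaca = jnaca;
}

// Volume- and buffer-weighted compartment update (fluxes are per destination
// volume; the source compartment is debited with the matching volume ratio).
static void ca_step_inplace(Cell &c, const Params &p, const CaFluxes &F,
                            double dt) {
  double dcb = p.buf_cb * (F.jrb + F.jca + F.jnaca -
                           (p.vsrb / p.vb) * F.jupb - (p.vi / p.vb) * F.jdc);
  double dci = p.buf_ci * (F.jdc + F.jri - (p.vsri / p.vi) * F.jupi);
  double dcsrb = p.buf_csrb * (F.jupb + F.jdsr - (p.vb / p.vsrb) * F.jrb);
  double dcsri = p.buf_csri * (F.jupi - (p.vsrb / p.vsri) * F.jdsr -
                               (p.vi / p.vsri) * F.jri);
  c.cb += dt * dcb;
  c.ci += dt * dci;
  c.csrb += dt * dcsrb;
  c.csri += dt * dcsri;
  if (c.cb < 1e-6) c.cb = 1e-6;
  if (c.ci < 1e-6) c.ci = 1e-6;
  if (c.csrb < 1e-3) c.csrb = 1e-3;
  if (c.csri < 1e-3) c.csri = 1e-3;
}

// One reaction substep.  Fixed order: gating -> LCC -> sparks -> Ca ->
// currents -> voltage, all rates evaluated at the entry state.
static void cell_substep(Cell &c, const Params &p, const Table &T, double dt,
                         bool fast, bool stochastic, int Nb, double istim) {
  Row r;
  table_row(T, c.V, r);
  Currents I;
  eval_currents(c, p, T, r, I);

  // Hodgkin-Huxley gates (Rush-Larsen with tabulated exponentials)
  int e = fast ? 0 : 1;
  c.m = r.x[T_MINF] + (c.m - r.x[T_MINF]) * r.x[T_ME1 + e];
  c.h = r.x[T_HINF] + (c.h - r.x[T_HINF]) * r.x[T_HE1 + e];
  c.j = r.x[T_JINF] + (c.j - r.x[T_JINF]) * r.x[T_JE1 + e];
  c.xr = r.x[T_XRINF] + (c.xr - r.x[T_XRINF]) * r.x[T_XRE1 + e];
  c.xs = r.x[T_XSINF] + (c.xs - r.x[T_XSINF]) * r.x[T_XSE1 + e];
  c.xtof = r.x[T_XTINF] + (c.xtof - r.x[T_XTINF]) * r.x[T_XTE1 + e];
  c.ytof = r.x[T_YTINF] + (c.ytof - r.x[T_YTINF]) * r.x[T_YTE1 + e];

  // spark recruitment rate from the entry state
  double o_off = c.occ[2];
  double ab = alpha_of(p, o_off, c.csrb);
  double bb = p.beta_b;

  lcc_step_inplace(c.occ, r, c.cb, ab, bb, p, dt);

  if (stochastic) {
    // subdivide so that both success probabilities stay <= 0.5
    double pmax = std::max(ab, bb) * dt;
    int m = 1 + (int)(pmax / 0.5);
    double dts = dt / m;
    for (int s = 0; s < m; ++s) {
      int up = rbinom_sm(c.rng, Nb - c.nb, ab * dts);
      int dn = rbinom_sm(c.rng, c.nb, bb * dts);
      c.nb += up - dn;
    }
    c.pb = (double)c.nb / (double)Nb;
  } else {
    c.pb += dt * (ab * (1.0 - c.pb) - bb * c.pb);
    if (c.pb < 0.0) c.pb = 0.0;
    if (c.pb > 1.0) c.pb = 1.0;
  }

  CaFluxes F;
  ca_fluxes(c, p, I.jca, I.jnaca, F);
  ca_step_inplace(c, p, F, dt);

  if (p.na_dynamic)
    c.Nai -= dt * p.conv_na * (I.ina + 3.0 * I.inaca + 3.0 * I.inak);

  double iion = I.ina + I.ikr + I.iks + I.ik1 + I.ito + I.inak + I.inaca + I.ical;
  c.last = I;
  c.dvdt = -(iion + istim);
  c.V += dt * c.dvdt;
}

// Advance one outer frame (dt_slow) with adaptive substeps.
static void advance_frame(Cell &c, const Params &p, const Table &T,
                          bool stochastic, int Nb, double istim) {
  bool fast = (std::fabs(c.dvdt) > p.dvdt_fast) || (istim != 0.0);
  if (fast) {
    int n = (int)std::lround(p.dt_slow / p.dt_fast);
    for (int s = 0; s < n; ++s)
      cell_substep(c, p, T, p.dt_fast, true, stochastic, Nb, istim);
  } else {
    cell_substep(c, p, T, p.dt_slow, false, stochastic, Nb, istim);
  }
}

// Track upstroke (-20 mV upward, rearm below -50 mV) and -40 mV downward
// crossings; events pushed as (type, time).
static void track_events(Cell &c, double vprev, double t0, double dt,
                         std::vector<double> &etype, std::vector<double> &etime,
                         int rr, int cc, std::vector<double> &er,
                         std::vector<double> &ec) {
  if (c.up_armed && vprev < -20.0 && c.V >= -20.0) {
    double f = (-20.0 - vprev) / (c.V - vprev);
    etype.push_back(1.0); etime.push_back(t0 + f * dt);
    er.push_back(rr); ec.push_back(cc);
    c.up_armed = 0;
  }
  if (!c.up_armed && vprev > -40.0 && c.V <= -40.0) {
    double f = (vprev - (-40.0)) / (vprev - c.V);
    etype.push_back(2.0); etime.push_back(t0 + f * dt);
    er.push_back(rr); ec.push_back(cc);
  }
  if (!c.up_armed && c.V < -50.0) c.up_armed = 1;
}

// Explicit 5-point Laplacian with no-flux boundaries via ghost-cell
// mirroring.  Shared by the tissue solver and the exported substep.
static void diffuse_field(std::vector<double> &v, int nr, int nc,
                          double dcoef) {
  static thread_local std::vector<double> tmp;
  tmp = v;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int i = r * nc + c;
      // zero-flux boundary: the out-of-range neighbour is the cell itself,
      // which makes the discrete operator exactly conservative
      double vu = tmp[(r > 0 ? r - 1 : r) * nc + c];
      double vd = tmp[(r < nr - 1 ? r + 1 : r) * nc + c];
      double vl = tmp[r * nc + (c > 0 ? c - 1 : c)];
      double vr = tmp[r * nc + (c < nc - 1 ? c + 1 : c)];
      v[i] = tmp[i] + dcoef * (vu + vd + vl + vr - 4.0 * tmp[i]);
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix vmat, double DV, double dx,
                          double dt) {
  double dcoef = DV * dt / (dx * dx);
  if (dcoef > 0.25) stop("diffusion substep unstable: DV*dt/dx^2 = %g > 0.25",
                         dcoef);
  int nr = vmat.nrow(), nc = vmat.ncol();
  std::vector<double> v((std::size_t)nr * nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) v[r * nc + c] = vmat(r, c);
  diffuse_field(v, nr, nc, dcoef);
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) out(r, c) = v[r * nc + c];
  return out;
}

// ------------------------- state <-> R conversion --------------------------
static List cell_to_list(const Cell &c) {
  NumericVector occ(10);
  for (int k = 0; k < 10; ++k) occ[k] = c.occ[k];
  return List::create(
      _["v"] = c.V, _["nai"] = c.Nai, _["m"] = c.m, _["h"] = c.h, _["j"] = c.j,
      _["xr"] = c.xr, _["xs"] = c.xs, _["xtof"] = c.xtof, _["ytof"] = c.ytof,
      _["lcc"] = occ, _["cb"] = c.cb, _["ci"] = c.ci, _["csrb"] = c.csrb,
      _["csri"] = c.csri, _["nb"] = c.nb, _["pb"] = c.pb, _["dvdt"] = c.dvdt);
}

static void list_to_cell(const List &L, Cell &c) {
  default_cell(c);
  c.V = getd(L, "v"); c.Nai = getd(L, "nai");
  c.m = getd(L, "m"); c.h = getd(L, "h"); c.j = getd(L, "j");
  c.xr = getd(L, "xr"); c.xs = getd(L, "xs");
  c.xtof = getd(L, "xtof"); c.ytof = getd(L, "ytof");
  NumericVector occ = L["lcc"];
  for (int k = 0; k < 10; ++k) c.occ[k] = occ[k];
  c.cb = getd(L, "cb"); c.ci = getd(L, "ci");
  c.csrb = getd(L, "csrb"); c.csri = getd(L, "csri");
  c.nb = (int)getd(L, "nb"); c.pb = getd(L, "pb");
  c.dvdt = getd(L, "dvdt", 0.0);
}

// ---------------------------------------------------------------------------
// Exported: module-surface helpers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_binom_stream(int n_draws, int size, double prob, double seed,
                               double key1 = 0, double key2 = 0) {
  SplitMix r = make_stream((uint64_t)seed, (uint64_t)key1, (uint64_t)key2, 0);
  IntegerVector out(n_draws);
  for (int i = 0; i < n_draws; ++i) out[i] = rbinom_sm(r, size, prob);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_spark_trajectory(int nb, int Nb, NumericVector alpha,
                                   NumericVector beta, double dt, double seed,
                                   double key1 = 0, double key2 = 0,
                                   double epoch = 0) {
  // alpha/beta may be length-1 (constant) or per-step prescribed time courses
  int n = std::max(alpha.size(), beta.size());
  SplitMix r = make_stream((uint64_t)seed, (uint64_t)key1, (uint64_t)key2,
                           (uint64_t)epoch);
  IntegerVector out(n + 1);
  out[0] = nb;
  for (int i = 0; i < n; ++i) {
    double a = alpha[alpha.size() == 1 ? 0 : i];
    double b = beta[beta.size() == 1 ? 0 : i];
    double pmax = std::max(a, b) * dt;
    int m = 1 + (int)(pmax / 0.5);
    double dts = dt / m;
    for (int s = 0; s < m; ++s) {
      int up = rbinom_sm(r, Nb - nb, a * dts);
      int dn = rbinom_sm(r, nb, b * dts);
      nb += up - dn;
    }
    out[i + 1] = nb;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_lcc_step(NumericVector occ, double V, double cb,
                           double alpha_b, double beta_b, List params,
                           double dt, int n_steps) {
  Params p = load_params(params);
  Table T;
  build_table(p, T);
  Row r;
  table_row(T, V, r);
  double o[10];
  for (int k = 0; k < 10; ++k) o[k] = occ[k];
  for (int s = 0; s < n_steps; ++s)
    lcc_step_inplace(o, r, cb, alpha_b, beta_b, p, dt);
  NumericVector out(10);
  for (int k = 0; k < 10; ++k) out[k] = o[k];
  return out;
}

// [[Rcpp::export]]
List cpp_lcc_current(NumericVector occ, double V, double cb, List params) {
  Params p = load_params(params);
  Table T;
  build_table(p, T);
  Row r;
  table_row(T, V, r);
  Cell c;
  default_cell(c);
  c.V = V; c.cb = cb;
  for (int k = 0; k < 10; ++k) c.occ[k] = occ[k];
  Currents I;
  eval_currents(c, p, T, r, I);
  return List::create(_["ical"] = I.ical, _["jca"] = I.jca);
}

// [[Rcpp::export]]
NumericVector cpp_ca_fluxes(List state, double pb, double jca, double jnaca,
                            List params) {
  Params p = load_params(params);
  Cell c;
  default_cell(c);
  c.cb = getd(state, "cb"); c.ci = getd(state, "ci");
  c.csrb = getd(state, "csrb"); c.csri = getd(state, "csri");
  c.pb = pb;
  CaFluxes F;
  ca_fluxes(c, p, jca, jnaca, F);
  return NumericVector::create(
      _["jrb"] = F.jrb, _["jri"] = F.jri, _["jupb"] = F.jupb,
      _["jupi"] = F.jupi, _["jdsr"] = F.jdsr, _["jdc"] = F.jdc,
      _["jca"] = F.jca, _["jnaca"] = F.jnaca);
}

// [[Rcpp::export]]
NumericVector cpp_ca_step(List state, NumericVector fluxes, List params,
                          double dt) {
  Params p = load_params(params);
  Cell c;
  default_cell(c);
  c.cb = getd(state, "cb"); c.ci = getd(state, "ci");
  c.csrb = getd(state, "csrb"); c.csri = getd(state, "csri");
  CaFluxes F;
  F.jrb = fluxes["jrb"]; F.jri = fluxes["jri"];
  F.jupb = fluxes["jupb"]; F.jupi = fluxes["jupi"];
  F.jdsr = fluxes["jdsr"]; F.jdc = fluxes["jdc"];
  F.jca = fluxes["jca"]; F.jnaca = fluxes["jnaca"];
  ca_step_inplace(c, p, F, dt);
  return NumericVector::create(_["cb"] = c.cb, _["ci"] = c.ci,
                               _["csrb"] = c.csrb, _["csri"] = c.csri);
}

// [[Rcpp::export]]
List cpp_ionic_currents(List state, List params) {
  Params p = load_params(params);
  Table T;
  build_table(p, T);
  Cell c;
  list_to_cell(state, c);
  Row r;
  table_row(T, c.V, r);
  Currents I;
  eval_currents(c, p, T, r, I);
  double iion = I.ina + I.ikr + I.iks + I.ik1 + I.ito + I.inak + I.inaca + I.ical;
  return List::create(
      _["ina"] = I.ina, _["ikr"] = I.ikr, _["iks"] = I.iks, _["ik1"] = I.ik1,
      _["ito"] = I.ito, _["inak"] = I.inak, _["inaca"] = I.inaca,
      _["ical"] = I.ical, _["iion"] = iion, _["jca"] = I.jca,
      _["jnaca"] = I.jnaca);
}

// [[Rcpp::export]]
List cpp_default_state() {
  Cell c;
  default_cell(c);
  return cell_to_list(c);
}

// ---------------------------------------------------------------------------
// Exported: single-cell runner
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sim_cell(List params, Nullable<List> state0, NumericVector stim_times,
                  double t_end, double record_dt, bool stochastic, int Nb,
                  double seed, double key1, double key2, double epoch,
                  double record_start, bool record_ca) {
  Params p = load_params(params);
  Table T;
  build_table(p, T);
  Cell c;
  if (state0.isNotNull()) list_to_cell(List(state0), c);
  else default_cell(c);
  c.rng = make_stream((uint64_t)seed, (uint64_t)key1, (uint64_t)key2,
                      (uint64_t)epoch);
  if (stochastic) c.nb = (int)std::lround(c.pb * Nb);

  long nframes = (long)std::ceil(t_end / p.dt_slow - 1e-9);
  int rec_every = std::max(1, (int)std::lround(record_dt / p.dt_slow));
  long cap = nframes / rec_every + 2;
  std::vector<double> rt, rv, rcb, rci, rcsrb, rcsri, rpb, rnb, ro, rical,
      rikr, riks, rinaca;
  rt.reserve(cap); rv.reserve(cap);
  if (record_ca) {
    rcb.reserve(cap); rci.reserve(cap); rcsrb.reserve(cap);
    rcsri.reserve(cap); rpb.reserve(cap); rnb.reserve(cap);
    ro.reserve(cap); rical.reserve(cap); rikr.reserve(cap);
    riks.reserve(cap); rinaca.reserve(cap);
  }
  std::size_t si = 0;
  for (long f = 0; f < nframes; ++f) {
    double t = f * p.dt_slow;
    // stimulus bookkeeping
    while (si < (std::size_t)stim_times.size() &&
           t >= stim_times[si] + p.stim_dur - 1e-9)
      ++si;
    double istim = 0.0;
    if (si < (std::size_t)stim_times.size() && t >= stim_times[si] - 1e-9 &&
        t < stim_times[si] + p.stim_dur - 1e-9) {
      istim = p.stim_amp;
      if (std::fabs(t - stim_times[si]) < 0.5 * p.dt_slow) renorm_occ(c.occ);
    }
    advance_frame(c, p, T, stochastic, Nb, istim);
    if (!std::isfinite(c.V) || std::fabs(c.V) > 300.0)
      stop("numerical instability at t=%.2f ms (V=%g)", t, c.V);
    double tn = (f + 1) * p.dt_slow;
    if ((f + 1) % rec_every == 0 && tn >= record_start - 1e-9) {
      rt.push_back(tn); rv.push_back(c.V);
      if (record_ca) {
        rcb.push_back(c.cb); rci.push_back(c.ci); rcsrb.push_back(c.csrb);
        rcsri.push_back(c.csri); rpb.push_back(c.pb); rnb.push_back(c.nb);
        ro.push_back(c.occ[2] + c.occ[7]); rical.push_back(c.last.ical);
        rikr.push_back(c.last.ikr); riks.push_back(c.last.iks);
        rinaca.push_back(c.last.inaca);
      }
    }
  }
  List trace;
  if (record_ca)
    trace = List::create(_["t"] = wrap(rt), _["v"] = wrap(rv),
                         _["cb"] = wrap(rcb), _["ci"] = wrap(rci),
                         _["csrb"] = wrap(rcsrb), _["csri"] = wrap(rcsri),
                         _["pb"] = wrap(rpb), _["nb"] = wrap(rnb),
                         _["o"] = wrap(ro), _["ical"] = wrap(rical),
                         _["ikr"] = wrap(rikr), _["iks"] = wrap(riks),
                         _["inaca"] = wrap(rinaca));
  else
    trace = List::create(_["t"] = wrap(rt), _["v"] = wrap(rv));
  return List::create(_["trace"] = trace, _["state"] = cell_to_list(c));
}

// ---------------------------------------------------------------------------
// Exported: tissue runner (monodomain, Lie splitting: reaction then diffusion)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sim_tissue(List params, int nr, int nc, Nullable<List> states0,
                    IntegerVector stim_region, NumericVector stim_times,
                    double t_end, double DV, double dx,
                    IntegerVector probe_r, IntegerVector probe_c,
                    double record_dt, double snap_dt, bool stochastic, int Nb,
                    double seed, double epoch, bool return_states,
                    bool track) {
  Params p = load_params(params);
  Table T;
  build_table(p, T);
  double dcoef = DV * p.dt_slow / (dx * dx);
  if (dcoef > 0.25)
    stop("diffusion substep unstable: DV*dt/dx^2 = %g > 0.25", dcoef);

  int ncell = nr * nc;
  std::vector<Cell> grid(ncell);
  bool have0 = states0.isNotNull();
  List s0;
  if (have0) s0 = List(states0);
  for (int r = 0; r < nr; ++r)
    for (int cidx = 0; cidx < nc; ++cidx) {
      Cell &c = grid[r * nc + cidx];
      if (have0) {
        if (s0.size() == ncell) list_to_cell(List(s0[r * nc + cidx]), c);
        else list_to_cell(s0, c);
      } else default_cell(c);
      c.rng = make_stream((uint64_t)seed, (uint64_t)r, (uint64_t)cidx,
                          (uint64_t)epoch);
      if (stochastic) c.nb = (int)std::lround(c.pb * Nb);
    }

  int r0 = stim_region[0], r1 = stim_region[1], c0 = stim_region[2],
      c1 = stim_region[3];

  long nframes = (long)std::ceil(t_end / p.dt_slow - 1e-9);
  int rec_every = std::max(1, (int)std::lround(record_dt / p.dt_slow));
  int snap_every = snap_dt > 0 ? std::max(1, (int)std::lround(snap_dt / p.dt_slow)) : 0;
  int np = probe_r.size();
  std::vector<std::vector<double>> ptr_v(np);
  std::vector<double> ptr_t;
  std::vector<double> etype, etime, er, ec;
  std::vector<double> snap_t;
  std::vector<double> snaps; // frames x ncell, row-major by frame

  std::vector<double> vprev(ncell), vnew(ncell);
  std::size_t si = 0;
  for (long f = 0; f < nframes; ++f) {
    double t = f * p.dt_slow;
    while (si < (std::size_t)stim_times.size() &&
           t >= stim_times[si] + p.stim_dur - 1e-9)
      ++si;
    bool stim_on = (si < (std::size_t)stim_times.size() &&
                    t >= stim_times[si] - 1e-9 &&
                    t < stim_times[si] + p.stim_dur - 1e-9);
    bool stim_first = stim_on && std::fabs(t - stim_times[si]) < 0.5 * p.dt_slow;

    // reaction substep
    for (int r = 0; r < nr; ++r)
      for (int cidx = 0; cidx < nc; ++cidx) {
        Cell &c = grid[r * nc + cidx];
        double istim = 0.0;
        if (stim_on && r >= r0 && r <= r1 && cidx >= c0 && cidx <= c1)
          istim = p.stim_amp;
        if (stim_first) renorm_occ(c.occ);
        vprev[r * nc + cidx] = c.V;
        advance_frame(c, p, T, stochastic, Nb, istim);
      }
    // diffusion substep (explicit 5-point, no-flux via mirroring)
    if (DV > 0.0) {
      for (int i = 0; i < ncell; ++i) vnew[i] = grid[i].V;
      diffuse_field(vnew, nr, nc, dcoef);
      for (int i = 0; i < ncell; ++i) grid[i].V = vnew[i];
    }
    double tn = (f + 1) * p.dt_slow;
    if (track) {
      for (int r = 0; r < nr; ++r)
        for (int cidx = 0; cidx < nc; ++cidx) {
          int i = r * nc + cidx;
          track_events(grid[i], vprev[i], t, p.dt_slow, etype, etime, r, cidx,
                       er, ec);
        }
    }
    if ((f + 1) % rec_every == 0) {
      ptr_t.push_back(tn);
      for (int k = 0; k < np; ++k)
        ptr_v[k].push_back(grid[probe_r[k] * nc + probe_c[k]].V);
    }
    if (snap_every && (f + 1) % snap_every == 0) {
      snap_t.push_back(tn);
      for (int i = 0; i < ncell; ++i) snaps.push_back(grid[i].V);
    }
    if ((f & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  List probes = List::create(_["t"] = wrap(ptr_t));
  for (int k = 0; k < np; ++k) {
    char nm[32];
    snprintf(nm, sizeof(nm), "v_%d_%d", (int)probe_r[k], (int)probe_c[k]);
    probes.push_back(wrap(ptr_v[k]), nm);
  }
  NumericMatrix snapmat(snap_t.size(), snap_every ? ncell : 0);
  if (snap_every)
    for (std::size_t fr = 0; fr < snap_t.size(); ++fr)
      for (int i = 0; i < ncell; ++i) snapmat(fr, i) = snaps[fr * ncell + i];

  List states = R_NilValue;
  if (return_states) {
    List out(ncell);
    for (int i = 0; i < ncell; ++i) out[i] = cell_to_list(grid[i]);
    states = out;
  }
  return List::create(
      _["probes"] = probes,
      _["events"] = DataFrame::create(_["row"] = wrap(er), _["col"] = wrap(ec),
                                      _["type"] = wrap(etype),
                                      _["time"] = wrap(etime)),
      _["snap_t"] = wrap(snap_t), _["snapshots"] = snapmat,
      _["states"] = states);
}
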