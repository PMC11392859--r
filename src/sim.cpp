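// Event-driven (Gillespie) simulation of a chain of 24-state thin-filament
// regulatory units with nearest-neighbor tropomyosin coupling.
//
// State encoding per unit: s = ca*12 + sp*6 + ip*3 + x, with x the
// tropomyosin position (0=B, 1=C, 2=M). Forward tropomyosin shifts are
// gated by troponin (full rate only when sp docked and ip off, lam
// otherwise). Neighbor coupling enters three ways: B<->C rates carry
// exp(-(gamma/RT)*Delta(sum |x - x_nbr|)), f_XY adds to the C->M rate per
// myosin-bound neighbor, and the M->C rate is retarded by
// exp(-(gamma/RT) * nM) (chain-stiffness holding of the open state).
// Calcium is
// piecewise constant in time (segments supplied by the caller); within a
// segment all rates are constant, so jumping to segment boundaries and
// redrawing the exponential waiting time is exact by memorylessness.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// splitmix64: seeds the per-trajectory xoshiro-style generator streams
inline uint64_t splitmix64(uint64_t& x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double u01() {  // in (0, 1]
    return ((next() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
  inline double rexp() { return -std::log(u01()); }
};

struct Params {
  double kCa_plus, kCa_minus, kSP_plus, kSP_minus, kIP_plus, kIP_minus;
  double kMD_plus, kMD_minus, kref_BC, K_BC, f_XY, delta, lam, eta, mu, g_rt;
};

class ChainSim {
public:
  Params p;
  int n;            // units
  bool periodic;
  // per-state troponin flip rates/targets (3 slots: ca, sp, ip) and
  // tropomyosin base rates; troponin ca-binding entries depend on [Ca2+]
  double tropR[72];
  int tropTo[72];
  double bcBase[24];          // B->C base rate (includes troponin gate)
  double cbBase;              // C->B base rate
  double gate[24];            // lam unless (sp docked, ip off)
  double gfacBC[16], gfacCB[16];  // B<->C coupling, index ln*4+rn (3=none)
  double gfacMC[3];           // M->C holding factor by number of M neighbors

  std::vector<int> st;        // unit states
  std::vector<double> rates;  // 5 slots per unit: ca, sp, ip, tpm-down, tpm-up
  std::vector<double> exitR;
  double totRate;
  int mcount;

  ChainSim(const Params& pp, int n_units, bool periodic_)
      : p(pp), n(n_units), periodic(periodic_),
        st(n_units), rates(5 * n_units), exitR(n_units) {
    cbBase = p.kref_BC * std::pow(p.K_BC, p.delta - 1.0);
    for (int s = 0; s < 24; ++s) {
      int ip = (s / 3) % 2, sp = (s / 6) % 2;
      gate[s] = (sp == 1 && ip == 0) ? 1.0 : p.lam;
      bcBase[s] = p.kref_BC * std::pow(p.K_BC, p.delta) * gate[s];
    }
    for (int ln = 0; ln < 4; ++ln)
      for (int rn = 0; rn < 4; ++rn) {
        double d = 0.0;
        if (ln < 3) d += std::abs(1 - ln) - std::abs(0 - ln);
        if (rn < 3) d += std::abs(1 - rn) - std::abs(0 - rn);
        gfacBC[ln * 4 + rn] = std::exp(-p.g_rt * d);
        gfacCB[ln * 4 + rn] = std::exp(p.g_rt * d);
      }
    for (int nM = 0; nM < 3; ++nM)
      gfacMC[nM] = std::exp(-p.g_rt * nM);
  }

  void buildTropRates(double ca) {
    for (int s = 0; s < 24; ++s) {
      int x = s % 3, ip = (s / 3) % 2, sp = (s / 6) % 2, caB = s / 12;
      (void)x;
      if (caB == 0) { tropR[s * 3 + 0] = p.kCa_plus * ca; tropTo[s * 3 + 0] = s + 12; }
      else { tropR[s * 3 + 0] = p.kCa_minus / (sp ? p.eta : 1.0); tropTo[s * 3 + 0] = s - 12; }
      if (sp == 0) {
        tropR[s * 3 + 1] = p.kSP_plus * (caB ? p.eta : 1.0) / (ip ? p.mu : 1.0);
        tropTo[s * 3 + 1] = s + 6;
      } else { tropR[s * 3 + 1] = p.kSP_minus; tropTo[s * 3 + 1] = s - 6; }
      if (ip == 0) {
        tropR[s * 3 + 2] = p.kIP_plus / (sp ? p.mu : 1.0);
        tropTo[s * 3 + 2] = s + 3;
      } else { tropR[s * 3 + 2] = p.kIP_minus; tropTo[s * 3 + 2] = s - 3; }
    }
  }

  inline int nbrCode(int u, int side) const {  // side -1 = left, +1 = right
    int v = u + side;
    if (v < 0 || v >= n) {
      if (!periodic || n < 2) return 3;
      v = (v + n) % n;
    }
    return st[v] % 3;
  }

  inline void unitRates(int u) {
    int s = st[u];
    double* R = &rates[5 * u];
    R[0] = tropR[s * 3 + 0]; R[1] = tropR[s * 3 + 1]; R[2] = tropR[s * 3 + 2];
    int x = s % 3;
    int ln = nbrCode(u, -1), rn = nbrCode(u, +1);
    int nM = (ln == 2) + (rn == 2);
    double dn = 0.0, up = 0.0;
    if (x == 0) {
      up = bcBase[s] * gfacBC[ln * 4 + rn];
    } else if (x == 1) {
      dn = cbBase * gfacCB[ln * 4 + rn];
      up = (p.kMD_plus + p.f_XY * nM) * gate[s];
    } else {
      dn = p.kMD_minus * gfacMC[nM];
    }
    R[3] = dn; R[4] = up;
    exitR[u] = R[0] + R[1] + R[2] + R[3] + R[4];
  }

  void rebuildAll() {
    mcount = 0;
    for (int u = 0; u < n; ++u) if (st[u] % 3 == 2) ++mcount;
    for (int u = 0; u < n; ++u) unitRates(u);
    sumRates();
  }

  inline void sumRates() {
    double s = 0.0;
    for (int u = 0; u < n; ++u) s += exitR[u];
    totRate = s;
  }

  // apply transition slot k (0..4) at unit u
  inline void applyEvent(int u, int k) {
    int s = st[u];
    int x0 = s % 3;
    int ns;
    if (k < 3) ns = tropTo[s * 3 + k];
    else if (k == 3) ns = s - 1;
    else ns = s + 1;
    st[u] = ns;
    int x1 = ns % 3;
    if (x0 == 2 && x1 != 2) --mcount;
    else if (x0 != 2 && x1 == 2) ++mcount;
    unitRates(u);
    if (n > 1) {
      if (u > 0) unitRates(u - 1);
      else if (periodic) unitRates(n - 1);
      if (u < n - 1) unitRates(u + 1);
      else if (periodic) unitRates(0);
    }
    sumRates();
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_sim_chain(NumericVector par, int n_units, bool periodic,
                   NumericVector ca_times, NumericVector ca_values,
                   double t_end, double rec0, double sample_dt,
                   double w0, double w1,
                   int n_traj, bool record_occ, double seed1, double seed2,
                   int init_state) {
  Params p;
  p.kCa_plus = par["kCa_plus"]; p.kCa_minus = par["kCa_minus"];
  p.kSP_plus = par["kSP_plus"]; p.kSP_minus = par["kSP_minus"];
  p.kIP_plus = par["kIP_plus"]; p.kIP_minus = par["kIP_minus"];
  p.kMD_plus = par["kMD_plus"]; p.kMD_minus = par["kMD_minus"];
  p.kref_BC = par["kref_BC"]; p.K_BC = par["K_BC"]; p.f_XY = par["f_XY"];
  p.delta = par["delta"]; p.lam = par["lam"]; p.eta = par["eta"];
  p.mu = par["mu"]; p.g_rt = par["g_rt"];

  const int nSeg = ca_times.size();
  const double t0 = ca_times[0];
  const int n_s = (int)std::floor((t_end - rec0) / sample_dt + 1e-9) + 1;
  if (n_s < 1) stop("no sample points in the recording interval");
  const bool useWindow = (w1 > w0);

  std::vector<double> forceSum(n_s, 0.0), forceSq(n_s, 0.0);
  std::vector<double> occSum(record_occ ? (size_t)n_s * 24 : 0, 0.0);
  NumericVector windowMeans(useWindow ? n_traj : 0);
  double eventsTotal = 0.0;

  ChainSim sim(p, n_units, periodic);

  for (int traj = 0; traj < n_traj; ++traj) {
    if (traj % 64 == 0) Rcpp::checkUserInterrupt();
    uint64_t sd = (uint64_t)seed1 * 0x100000000ULL + (uint64_t)seed2
                  + 0x9E3779B97F4A7C15ULL * (uint64_t)(traj + 1);
    Xoshiro256pp rng(sd);

    for (int u = 0; u < n_units; ++u) sim.st[u] = init_state;
    int seg = 0;
    sim.buildTropRates(ca_values[0]);
    sim.rebuildAll();

    double t = t0;
    int nextS = 0;
    double integral = 0.0;
    double segEnd = (nSeg > 1) ? ca_times[1] : R_PosInf;
    long long nev = 0;

    auto advanceTo = [&](double tnew) {
      if (useWindow) {
        double a = std::max(t, w0), b = std::min(tnew, w1);
        if (b > a) integral += sim.mcount * (b - a);
      }
      while (nextS < n_s) {
        double ts = rec0 + nextS * sample_dt;
        if (ts > tnew + 1e-12) break;
        double f = (double)sim.mcount / n_units;
        forceSum[nextS] += f;
        forceSq[nextS] += f * f;
        if (record_occ) {
          double* occ = &occSum[(size_t)nextS * 24];
          for (int u = 0; u < n_units; ++u) occ[sim.st[u]] += 1.0;
        }
        ++nextS;
      }
      t = tnew;
    };

    while (true) {
      double te = (sim.totRate > 0.0) ? t + rng.rexp() / sim.totRate
                                      : R_PosInf;
      double tb = std::min(segEnd, t_end);
      if (te >= tb) {
        advanceTo(tb);
        if (tb >= t_end) break;
        ++seg;
        sim.buildTropRates(ca_values[seg]);
        for (int u = 0; u < n_units; ++u) sim.unitRates(u);
        sim.sumRates();
        segEnd = (seg + 1 < nSeg) ? ca_times[seg + 1] : R_PosInf;
        continue;
      }
      advanceTo(te);
      // pick unit, then transition slot
      double r = rng.u01() * sim.totRate;
      int u = 0;
      while (u < n_units - 1 && r >= sim.exitR[u]) { r -= sim.exitR[u]; ++u; }
      const double* R = &sim.rates[5 * u];
      int k = 0;
      while (k < 4 && r >= R[k]) { r -= R[k]; ++k; }
      while (k > 0 && R[k] <= 0.0) --k;  // guard against rounding overshoot
      sim.applyEvent(u, k);
      ++nev;
    }
    if (useWindow) windowMeans[traj] = integral / ((w1 - w0) * n_units);
    eventsTotal += (double)nev;
  }

  NumericVector time(n_s), force(n_s), fvar(n_s);
  for (int k = 0; k < n_s; ++k) {
    time[k] = rec0 + k * sample_dt;
    double m = forceSum[k] / n_traj;
    force[k] = m;
    fvar[k] = (n_traj > 1)
        ? std::max(0.0, (forceSq[k] - n_traj * m * m) / (n_traj - 1))
        : 0.0;
  }
  List out = List::create(
      _["time"] = time, _["force"] = force, _["force_var"] = fvar,
      _["window_means"] = windowMeans, _["n_events"] = eventsTotal);
  if (record_occ) {
    NumericMatrix occ(n_s, 24);
    for (int k = 0; k < n_s; ++k)
      for (int s = 0; s < 24; ++s)
        occ(k, s) = occSum[(size_t)k * 24 + s] / ((double)n_traj * n_units);
    out["occupancy"] = occ;
  }
  return out;
}
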