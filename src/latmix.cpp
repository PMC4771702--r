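// Compiled core of the chaperone-client lattice model: energy bookkeeping,
// biased grand-canonical Monte Carlo, Wang-Landau bias construction and the
// truncated exact-enumeration oracle.
//
// Site states: -1 = empty, otherwise species*24 + orientation with
// species 0 = client (s), 1 = chaperone (c) and orientation in 0..23.
// Faces: 0:+x 1:-x 2:+y 3:-y 4:+z 5:-z; the opposite face is f ^ 1.
// A directional bond requires both partners to present a patch on the
// shared pair of faces; every adjacent occupied pair also contributes one
// isotropic contact.  Energies are dimensionless:
//   E = -(eps*n_iso + e_ss*n_ss + e_cs*n_cs + e_cc*n_cc).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

static inline int oppface(int f) { return f ^ 1; }

// Fast internal generator (xoshiro256+), seeded from R's RNG stream at the
// entry of every exported sampling routine so that set.seed() in R fixes
// the full seed chain while the hot loop avoids per-call R API overhead.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  void seed_from_r() {
    // two uniform draws give 2 x ~32 bits of entropy from the R stream
    uint64_t a = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t b = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t x = (a << 32) ^ b;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t res = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return res;
  }
  inline double runif() { return (next() >> 11) * 0x1.0p-53; }
};

struct Counts {
  long iso = 0, ss = 0, cs = 0, cc = 0;
  Counts& operator+=(const Counts& o) { iso += o.iso; ss += o.ss; cs += o.cs; cc += o.cc; return *this; }
  Counts& operator-=(const Counts& o) { iso -= o.iso; ss -= o.ss; cs -= o.cs; cc -= o.cc; return *this; }
};

struct Geometry {
  int nx, ny, nz, V;
  bool periodic;
  std::vector<int> nbr;  // V*6 neighbour table, -1 past an open boundary

  void build(const IntegerVector& dims, bool per) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    V = nx * ny * nz; periodic = per;
    nbr.assign(static_cast<size_t>(V) * 6, -1);
    const int dx[6] = {1, -1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, 1, -1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, 1, -1};
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int s = x + nx * (y + ny * z);
          for (int f = 0; f < 6; ++f) {
            int X = x + dx[f], Y = y + dy[f], Z = z + dz[f];
            if (periodic) {
              X = (X + nx) % nx; Y = (Y + ny) % ny; Z = (Z + nz) % nz;
            } else if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) {
              continue;
            }
            nbr[static_cast<size_t>(s) * 6 + f] = X + nx * (Y + ny * Z);
          }
        }
  }
};

struct Sim {
  Geometry g;
  std::vector<int> pm;          // 48 x 6 patch mask, row-major [state][face]
  std::vector<int> state;       // site occupancy
  std::vector<int> occ, occIdx; // occupied-site list + inverse index
  int Ns = 0, Nc = 0;
  Counts C;
  double eps = 0, e_ss = 0, e_cs = 0, e_cc = 0, mu_s = 0, mu_c = 0;

  void init(const IntegerVector& dims, bool periodic, const IntegerMatrix& patch,
            const NumericVector& fpar) {
    g.build(dims, periodic);
    pm.assign(48 * 6, 0);
    for (int r = 0; r < 48; ++r)
      for (int f = 0; f < 6; ++f) pm[r * 6 + f] = patch(r, f);
    state.assign(g.V, -1);
    occ.clear();
    occIdx.assign(g.V, -1);
    Ns = Nc = 0;
    C = Counts();
    eps = fpar[0]; e_ss = fpar[1]; e_cs = fpar[2]; e_cc = fpar[3];
    mu_s = fpar[4]; mu_c = fpar[5];
  }

  double energy_of(const Counts& d) const {
    return -(eps * d.iso + e_ss * d.ss + e_cs * d.cs + e_cc * d.cc);
  }

  // Contact contributions of a (possibly hypothetical) particle with state st
  // at `site`, against currently occupied neighbours, skipping `skip`.
  void local_counts(int site, int st, int skip, Counts& d) const {
    for (int f = 0; f < 6; ++f) {
      int j = g.nbr[static_cast<size_t>(site) * 6 + f];
      if (j < 0 || j == skip) continue;
      int stj = state[j];
      if (stj < 0) continue;
      d.iso++;
      if (pm[st * 6 + f] && pm[stj * 6 + oppface(f)]) {
        int spa = st / 24, spb = stj / 24;
        if (spa == 0 && spb == 0) d.ss++;
        else if (spa == 1 && spb == 1) d.cc++;
        else d.cs++;
      }
    }
  }

  void place(int site, int st) {
    Counts d; local_counts(site, st, -1, d);
    C += d;
    state[site] = st;
    occIdx[site] = static_cast<int>(occ.size());
    occ.push_back(site);
    if (st < 24) Ns++; else Nc++;
  }

  void remove(int site) {
    int st = state[site];
    state[site] = -1;
    Counts d; local_counts(site, st, -1, d);
    C -= d;
    int idx = occIdx[site], last = occ.back();
    occ[idx] = last; occIdx[last] = idx;
    occ.pop_back(); occIdx[site] = -1;
    if (st < 24) Ns--; else Nc--;
  }

  int N() const { return Ns + Nc; }
};

struct MoveCounters {
  long att[4] = {0, 0, 0, 0};
  long acc[4] = {0, 0, 0, 0};
};

// One attempted move.  species_mode: 0 = both, 1 = client-only, 2 = chaperone-only.
// eta spans total N in [n_lo, n_hi]; moves leaving the range are rejected.
// Sampling measure: pi(config) ~ exp(-E + mu_s*Ns + mu_c*Nc + eta(N)), with each
// distinct (site, species, orientation) labelling a separate microstate.
static void attempt_move(Sim& S, const double* eta, int n_lo, int n_hi,
                         int species_mode, double q_c,
                         double p_ins, double p_del, double p_tr,
                         MoveCounters& mc, Xoshiro& rng) {
  const int V = S.g.V;
  double u = rng.runif();
  int N = S.N();
  if (u < p_ins) {  // insertion
    mc.att[0]++;
    if (N + 1 > n_hi) return;
    int site = static_cast<int>(rng.runif() * V); if (site >= V) site = V - 1;
    if (S.state[site] >= 0) return;
    int sp; double q_sp;
    if (species_mode == 1) { sp = 0; q_sp = 1.0; }
    else if (species_mode == 2) { sp = 1; q_sp = 1.0; }
    else { sp = (rng.runif() < q_c) ? 1 : 0; q_sp = (sp == 1) ? q_c : 1.0 - q_c; }
    int ori = static_cast<int>(rng.runif() * 24); if (ori > 23) ori = 23;
    int st = sp * 24 + ori;
    Counts d; S.local_counts(site, st, -1, d);
    double dE = S.energy_of(d);
    double mu = (sp == 0) ? S.mu_s : S.mu_c;
    double deta = eta[N + 1 - n_lo] - eta[N - n_lo];
    double lacc = mu - dE + deta + std::log(24.0 * V / (q_sp * (N + 1)));
    if (lacc >= 0 || rng.runif() < std::exp(lacc)) { S.place(site, st); mc.acc[0]++; }
  } else if (u < p_ins + p_del) {  // deletion (uniform over occupied sites)
    mc.att[1]++;
    if (N == 0 || N - 1 < n_lo) return;
    int k = static_cast<int>(rng.runif() * N); if (k >= N) k = N - 1;
    int site = S.occ[k];
    int st = S.state[site];
    Counts d; S.local_counts(site, st, -1, d);
    double dE = -S.energy_of(d);
    int sp = st / 24;
    double q_sp;
    if (species_mode == 0) q_sp = (sp == 1) ? q_c : 1.0 - q_c; else q_sp = 1.0;
    double mu = (sp == 0) ? S.mu_s : S.mu_c;
    double deta = eta[N - 1 - n_lo] - eta[N - n_lo];
    double lacc = -mu - dE + deta + std::log(q_sp * N / (24.0 * V));
    if (lacc >= 0 || rng.runif() < std::exp(lacc)) { S.remove(site); mc.acc[1]++; }
  } else if (u < p_ins + p_del + p_tr) {  // nonlocal translation
    mc.att[2]++;
    if (N == 0) return;
    int k = static_cast<int>(rng.runif() * N); if (k >= N) k = N - 1;
    int site = S.occ[k];
    int dest = static_cast<int>(rng.runif() * V); if (dest >= V) dest = V - 1;
    if (S.state[dest] >= 0) return;
    int st = S.state[site];
    Counts d1; S.local_counts(site, st, -1, d1);
    Counts d2; S.local_counts(dest, st, site, d2);
    double dE = S.energy_of(d2) - S.energy_of(d1);
    if (dE <= 0 || rng.runif() < std::exp(-dE)) {
      S.remove(site); S.place(dest, st); mc.acc[2]++;
    }
  } else {  // rotation
    mc.att[3]++;
    if (N == 0) return;
    int k = static_cast<int>(rng.runif() * N); if (k >= N) k = N - 1;
    int site = S.occ[k];
    int st = S.state[site];
    int ori = static_cast<int>(rng.runif() * 24); if (ori > 23) ori = 23;
    int st2 = (st / 24) * 24 + ori;
    if (st2 == st) { mc.acc[3]++; return; }
    Counts d1; S.local_counts(site, st, -1, d1);
    Counts d2; S.local_counts(site, st2, -1, d2);
    double dE = S.energy_of(d2) - S.energy_of(d1);
    if (dE <= 0 || rng.runif() < std::exp(-dE)) {
      S.remove(site); S.place(site, st2); mc.acc[3]++;
    }
  }
}

static void load_initial(Sim& S, const IntegerVector& init_state,
                         int n_lo, int species_mode, double q_c, Xoshiro& rng) {
  const int V = S.g.V;
  if (init_state.size() == V) {
    for (int s = 0; s < V; ++s) {
      int st = init_state[s];
      if (st >= 0) {
        if (st > 47) stop("invalid site state in initial configuration");
        S.place(s, st);
      }
    }
  }
  // Random fill up to the lower edge of the biased range.
  int guard = 0;
  while (S.N() < n_lo && guard < 100 * V) {
    int site = static_cast<int>(rng.runif() * V); if (site >= V) site = V - 1;
    if (S.state[site] >= 0) { guard++; continue; }
    int sp;
    if (species_mode == 1) sp = 0;
    else if (species_mode == 2) sp = 1;
    else sp = (rng.runif() < q_c) ? 1 : 0;
    int ori = static_cast<int>(rng.runif() * 24); if (ori > 23) ori = 23;
    S.place(site, sp * 24 + ori);
  }
  if (S.N() < n_lo) stop("could not fill lattice to the lower edge of the N range");
}

// [[Rcpp::export]]
List cpp_total_energy(IntegerVector state, IntegerVector dims, bool periodic,
                      IntegerMatrix patch, NumericVector fpar) {
  Sim S; S.init(dims, periodic, patch, fpar);
  if (state.size() != S.g.V) stop("state vector length does not match lattice dimensions");
  for (int s = 0; s < S.g.V; ++s)
    if (state[s] >= 0) {
      if (state[s] > 47) stop("invalid site state");
      S.place(s, state[s]);
    }
  return List::create(
    _["energy"] = S.energy_of(S.C),
    _["n_iso"] = (double)S.C.iso, _["n_ss"] = (double)S.C.ss,
    _["n_cs"] = (double)S.C.cs, _["n_cc"] = (double)S.C.cc,
    _["n_s"] = S.Ns, _["n_c"] = S.Nc);
}

// Energy change of inserting (or of the already-present particle at `site`
// when remove = true); used by the R-level delta_energy().
// [[Rcpp::export]]
List cpp_local_energy(IntegerVector state, IntegerVector dims, bool periodic,
                      IntegerMatrix patch, NumericVector fpar,
                      int site, int st, int skip) {
  Sim S; S.init(dims, periodic, patch, fpar);
  if (state.size() != S.g.V) stop("state vector length does not match lattice dimensions");
  for (int s = 0; s < S.g.V; ++s)
    if (state[s] >= 0) S.place(s, state[s]);
  Counts d; S.local_counts(site, st, skip, d);
  return List::create(_["energy"] = S.energy_of(d),
                      _["n_iso"] = (double)d.iso, _["n_ss"] = (double)d.ss,
                      _["n_cs"] = (double)d.cs, _["n_cc"] = (double)d.cc);
}

// Wang-Landau construction of the flat-histogram bias over total N.
// [[Rcpp::export]]
List cpp_wl_bias(IntegerVector dims, bool periodic, IntegerMatrix patch,
                 NumericVector fpar, int species_mode, double q_c,
                 int n_lo, int n_hi, NumericVector eta0,
                 double lnf_init, double lnf_final, double flat_tol,
                 int check_sweeps, int max_sweeps, IntegerVector init_state,
                 NumericVector move_probs) {
  Sim S; S.init(dims, periodic, patch, fpar);
  const int V = S.g.V;
  if (n_lo < 0 || n_hi > V || n_lo > n_hi) stop("invalid N range");
  int R = n_hi - n_lo + 1;
  std::vector<double> eta(R, 0.0);
  if (eta0.size() == R) for (int i = 0; i < R; ++i) eta[i] = eta0[i];
  std::vector<double> hist(R, 0.0);
  MoveCounters mc;
  Xoshiro rng; rng.seed_from_r();
  load_initial(S, init_state, n_lo, species_mode, q_c, rng);

  double lnf = lnf_init;
  int sweeps = 0, stages = 0;
  bool converged = false;
  double p_ins = move_probs[0], p_del = move_probs[1], p_tr = move_probs[2];

  while (sweeps < max_sweeps) {
    for (int sw = 0; sw < check_sweeps && sweeps < max_sweeps; ++sw, ++sweeps) {
      for (int a = 0; a < V; ++a) {
        attempt_move(S, eta.data(), n_lo, n_hi, species_mode, q_c,
                     p_ins, p_del, p_tr, mc, rng);
        int i = S.N() - n_lo;
        eta[i] -= lnf;
        hist[i] += 1.0;
      }
    }
    // flatness: every N visited and min >= flat_tol * mean
    double hmin = hist[0], hsum = 0.0;
    for (int i = 0; i < R; ++i) { if (hist[i] < hmin) hmin = hist[i]; hsum += hist[i]; }
    if (hmin > 0 && hmin >= flat_tol * hsum / R) {
      lnf *= 0.5;
      stages++;
      std::fill(hist.begin(), hist.end(), 0.0);
      if (lnf < lnf_final) { converged = true; break; }
    }
    Rcpp::checkUserInterrupt();
  }

  // centre eta so that max(eta) = 0
  double emax = eta[0];
  for (int i = 1; i < R; ++i) if (eta[i] > emax) emax = eta[i];
  NumericVector etaR(R), histR(R);
  for (int i = 0; i < R; ++i) { etaR[i] = eta[i] - emax; histR[i] = hist[i]; }
  IntegerVector stateR(V);
  for (int s = 0; s < V; ++s) stateR[s] = S.state[s];
  return List::create(_["eta"] = etaR, _["hist"] = histR,
                      _["converged"] = converged, _["sweeps"] = sweeps,
                      _["stages"] = stages, _["lnf"] = lnf,
                      _["state"] = stateR);
}

// Production run: frozen bias, snapshots every `spacing` sweeps after burn-in.
// [[Rcpp::export]]
List cpp_run_gcmc(IntegerVector dims, bool periodic, IntegerMatrix patch,
                  NumericVector fpar, int species_mode, double q_c,
                  int n_lo, int n_hi, NumericVector eta0,
                  int burnin, int n_samples, int spacing,
                  IntegerVector init_state, NumericVector move_probs) {
  Sim S; S.init(dims, periodic, patch, fpar);
  const int V = S.g.V;
  if (n_lo < 0 || n_hi > V || n_lo > n_hi) stop("invalid N range");
  int R = n_hi - n_lo + 1;
  std::vector<double> eta(R, 0.0);
  if (eta0.size() == R) for (int i = 0; i < R; ++i) eta[i] = eta0[i];
  else if (eta0.size() != 0) stop("bias weight vector does not match the N range");
  std::vector<double> visits(R, 0.0);
  MoveCounters mc;
  Xoshiro rng; rng.seed_from_r();
  load_initial(S, init_state, n_lo, species_mode, q_c, rng);
  double p_ins = move_probs[0], p_del = move_probs[1], p_tr = move_probs[2];

  IntegerMatrix samples(n_samples, 6);
  NumericVector eta_v(n_samples);

  for (int sw = 0; sw < burnin; ++sw) {
    for (int a = 0; a < V; ++a)
      attempt_move(S, eta.data(), n_lo, n_hi, species_mode, q_c, p_ins, p_del, p_tr, mc, rng);
    Rcpp::checkUserInterrupt();
  }
  for (long i = 0; i < 4; ++i) { mc.att[i] = 0; mc.acc[i] = 0; }

  for (int v = 0; v < n_samples; ++v) {
    for (int sw = 0; sw < spacing; ++sw)
      for (int a = 0; a < V; ++a) {
        attempt_move(S, eta.data(), n_lo, n_hi, species_mode, q_c, p_ins, p_del, p_tr, mc, rng);
        visits[S.N() - n_lo] += 1.0;
      }
    samples(v, 0) = S.Ns; samples(v, 1) = S.Nc;
    samples(v, 2) = (int)S.C.iso; samples(v, 3) = (int)S.C.ss;
    samples(v, 4) = (int)S.C.cs; samples(v, 5) = (int)S.C.cc;
    eta_v[v] = eta[S.N() - n_lo];
    if (v % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector att(4), acc(4), visitsR(R);
  for (int i = 0; i < 4; ++i) { att[i] = (double)mc.att[i]; acc[i] = (double)mc.acc[i]; }
  for (int i = 0; i < R; ++i) visitsR[i] = visits[i];
  IntegerVector stateR(V);
  for (int s = 0; s < V; ++s) stateR[s] = S.state[s];
  return List::create(_["samples"] = samples, _["eta_v"] = eta_v,
                      _["attempts"] = att, _["accepts"] = acc,
                      _["visits"] = visitsR, _["state"] = stateR);
}

// Exact truncated grand-canonical enumeration on a tiny lattice.
// Enumerates every placement of at most n_max monomers (allowed species x 24
// orientations per site) and accumulates exact grand-canonical sums.
// [[Rcpp::export]]
List cpp_enumerate(IntegerVector dims, bool periodic, IntegerMatrix patch,
                   NumericVector fpar, int species_mode, int n_max,
                   double state_budget) {
  Sim S; S.init(dims, periodic, patch, fpar);
  const int V = S.g.V;
  int s_from = (species_mode == 2) ? 24 : 0;
  int s_to = (species_mode == 1) ? 24 : 48;
  double A = s_to - s_from;

  // predicted state count: sum_k C(V,k) A^k
  double nstates = 1.0, term = 1.0;
  for (int k = 1; k <= n_max; ++k) {
    term *= (double)(V - k + 1) / k * A;
    nstates += term;
  }
  if (nstates > state_budget)
    stop("enumeration would visit %.3g states, over the budget of %.3g",
         nstates, state_budget);

  double Z = 1.0;  // empty lattice
  double sNs = 0, sNc = 0, sU = 0, sncc = 0, sniso = 0, snss = 0, sncs = 0;
  std::vector<double> pN(n_max + 1, 0.0);
  pN[0] = 1.0;
  double E = 0.0;

  std::function<void(int, int)> rec = [&](int start, int n) {
    for (int site = start; site < V; ++site) {
      for (int st = s_from; st < s_to; ++st) {
        Counts d; S.local_counts(site, st, -1, d);
        double dE = S.energy_of(d);
        E += dE;
        S.place(site, st);
        double w = std::exp(-E + S.mu_s * S.Ns + S.mu_c * S.Nc);
        Z += w;
        sNs += w * S.Ns; sNc += w * S.Nc; sU += w * E;
        sncc += w * S.C.cc; sniso += w * S.C.iso;
        snss += w * S.C.ss; sncs += w * S.C.cs;
        pN[n + 1] += w;
        if (n + 1 < n_max) rec(site + 1, n + 1);
        S.remove(site);
        E -= dE;
      }
      if (n == 0) Rcpp::checkUserInterrupt();
    }
  };
  if (n_max > 0) rec(0, 0);

  NumericVector pNR(n_max + 1);
  for (int k = 0; k <= n_max; ++k) pNR[k] = pN[k] / Z;
  return List::create(
    _["log_z"] = std::log(Z),
    _["mean_n_s"] = sNs / Z, _["mean_n_c"] = sNc / Z,
    _["mean_u"] = sU / Z, _["mean_n_cc"] = sncc / Z,
    _["mean_n_iso"] = sniso / Z, _["mean_n_ss"] = snss / Z,
    _["mean_n_cs"] = sncs / Z,
    _["p_n"] = pNR, _["n_states"] = nstates);
}
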