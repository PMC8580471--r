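// Core kernels: potentials with analytic gradients, neighbour search,
// thermal noise and the overdamped Euler/RK4 split integrator.
//
// Positions are stored unwrapped (node-major, 3 doubles per node); bonded
// terms use direct differences, inter-fibre terms use the minimum image of
// wrapped coordinates. Aggregation couples each node to its nearest node on
// each neighbouring fibre within the threshold a_th (zipper-like lateral
// aggregation); repulsion acts on every inter-fibre pair closer than the
// fibrinogen diameter.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <utility>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
// xorwow uniform generator (five 32-bit words + Weyl counter) feeding a
// Box-Muller transform. Bit-reproducible for a given seed.
struct NoiseGen {
  uint32_t x, y, z, w, v, d;
  bool have_spare;
  double spare;

  void seed(uint64_t s) {
    // splitmix64 expansion of the seed into the state words
    auto mix = [&s]() {
      s += 0x9E3779B97f4A7C15ULL;
      uint64_t r = s;
      r = (r ^ (r >> 30)) * 0xBF58476D1CE4E5B9ULL;
      r = (r ^ (r >> 27)) * 0x94D049BB133111EBULL;
      return r ^ (r >> 31);
    };
    uint64_t a = mix(), b = mix(), c = mix();
    x = (uint32_t)a;       y = (uint32_t)(a >> 32);
    z = (uint32_t)b;       w = (uint32_t)(b >> 32);
    v = (uint32_t)c;
    if (!(x | y | z | w | v)) x = 0x6C078965u; // state must be nonzero
    d = (uint32_t)(c >> 32);
    have_spare = false;
    spare = 0.0;
  }

  inline uint32_t next_u32() {
    uint32_t t = x ^ (x >> 2);
    x = y; y = z; z = w; w = v;
    v = (v ^ (v << 4)) ^ (t ^ (t << 1));
    d += 362437u;
    return v + d;
  }

  // uniform on (0, 1): never returns 0, safe inside log()
  inline double unif() {
    return (next_u32() + 0.5) * (1.0 / 4294967296.0);
  }

  // standard normal via Box-Muller on xorwow uniforms
  inline double normal() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// [[Rcpp::export]]
SEXP rng_create_cpp(double seed) {
  NoiseGen* g = new NoiseGen();
  g->seed((uint64_t)seed);
  XPtr<NoiseGen> p(g, true);
  p.attr("class") = "bd_rng";
  return p;
}

// [[Rcpp::export]]
NumericMatrix rng_normal_cpp(SEXP rng, int n, int m) {
  XPtr<NoiseGen> g(rng);
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) out(i, j) = g->normal();
  return out;
}

// [[Rcpp::export]]
NumericVector rng_uniform_cpp(SEXP rng, int n) {
  XPtr<NoiseGen> g(rng);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g->unif();
  return out;
}

// ------------------------------------------------------------- helpers ----
inline double mimg(double d, double L) {
  // minimum image: result in [-L/2, L/2)
  return d - L * std::floor(d / L + 0.5);
}

struct Par {
  double kS, kB, kT, kA, kR;
  double r0S, r0A, r0R, ath, theta0;
  double c, dt, kb, temperature, skin;
  int pairing;   // 0 = nearest (1:1), 1 = nearest per fibre, 2 = all pairs
};

static Par read_par(const List& par) {
  Par p;
  p.kS = par["k_S"];  p.kB = par["k_B"];  p.kT = par["k_T"];
  p.kA = par["k_A"];  p.kR = par["k_R"];
  p.r0S = par["r0_S"]; p.r0A = par["r0_A"]; p.r0R = par["r0_R"];
  p.ath = par["a_th"]; p.theta0 = par["theta0"];
  p.c = par["c"]; p.dt = par["dt"];
  p.kb = par["k_b"]; p.temperature = par["temperature"];
  p.skin = par.containsElementNamed("verlet_skin") ?
    (double)par["verlet_skin"] : 1e-8;
  p.pairing = par.containsElementNamed("pairing_mode") ?
    (int)par["pairing_mode"] : 0;
  return p;
}

static void wrap_copy(const std::vector<double>& pos, const double* L,
                      std::vector<double>& wpos) {
  int n3 = (int)pos.size();
  wpos.resize(n3);
  for (int i = 0; i < n3; ++i) {
    double Lk = L[i % 3];
    wpos[i] = pos[i] - Lk * std::floor(pos[i] / Lk);
  }
}

// ------------------------------------------------------- pair search ------
typedef std::vector<std::pair<int, int> > PairVec;

// all unordered inter-fibre node pairs with min-image distance < cutoff
static void pairs_brute(const std::vector<double>& pos, int n_nodes, int npf,
                        const double* L, double cutoff, PairVec& out) {
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n_nodes; ++i) {
    for (int j = i + 1; j < n_nodes; ++j) {
      if (i / npf == j / npf) continue;
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = mimg(pos[3 * j + k] - pos[3 * i + k], L[k]);
        d2 += d * d;
      }
      if (d2 < c2) out.push_back(std::make_pair(i, j));
    }
  }
}

// Cell-list pair search on coordinates already wrapped into [0, L).
static void pairs_cell_wrapped(const std::vector<double>& wpos, int n_nodes,
                               int npf, const double* L, double cutoff,
                               PairVec& out) {
  int nc[3];
  for (int k = 0; k < 3; ++k) nc[k] = (int)std::floor(L[k] / cutoff);
  if (nc[0] < 3 || nc[1] < 3 || nc[2] < 3) { // too few cells: exact fallback
    pairs_brute(wpos, n_nodes, npf, L, cutoff, out);
    return;
  }
  double inv[3];
  for (int k = 0; k < 3; ++k) inv[k] = nc[k] / L[k];
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(n_nodes, -1);
  for (int i = 0; i < n_nodes; ++i) {
    int ix[3];
    for (int k = 0; k < 3; ++k) {
      int c = (int)(wpos[3 * i + k] * inv[k]);
      if (c >= nc[k]) c = nc[k] - 1;
      if (c < 0) c = 0;
      ix[k] = c;
    }
    int ci = ix[0] + nc[0] * (ix[1] + nc[1] * ix[2]);
    nxt[i] = head[ci];
    head[ci] = i;
  }
  // half-shell neighbour offsets (13) + self
  static const int off[14][3] = {
    {0,0,0},
    {1,0,0},{-1,1,0},{0,1,0},{1,1,0},
    {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},
    {-1,1,1},{0,1,1},{1,1,1}
  };
  double c2 = cutoff * cutoff;
  double Lh0 = 0.5 * L[0], Lh1 = 0.5 * L[1], Lh2 = 0.5 * L[2];
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int ci = cx + nc[0] * (cy + nc[1] * cz);
        if (head[ci] < 0) continue;
        for (int o = 0; o < 14; ++o) {
          int jx = (cx + off[o][0] + nc[0]) % nc[0];
          int jy = (cy + off[o][1] + nc[1]) % nc[1];
          int jz = (cz + off[o][2] + nc[2]) % nc[2];
          int cj = jx + nc[0] * (jy + nc[1] * jz);
          if (head[cj] < 0) continue;
          for (int i = head[ci]; i >= 0; i = nxt[i]) {
            int i3 = 3 * i, fi = i / npf;
            double xi = wpos[i3], yi = wpos[i3 + 1], zi = wpos[i3 + 2];
            int jstart = (o == 0) ? nxt[i] : head[cj];
            for (int j = jstart; j >= 0; j = nxt[j]) {
              if (fi == j / npf) continue;
              int j3 = 3 * j;
              double dx = wpos[j3] - xi;
              double dy = wpos[j3 + 1] - yi;
              double dz = wpos[j3 + 2] - zi;
              if (dx >= Lh0) dx -= L[0]; else if (dx < -Lh0) dx += L[0];
              if (dy >= Lh1) dy -= L[1]; else if (dy < -Lh1) dy += L[1];
              if (dz >= Lh2) dz -= L[2]; else if (dz < -Lh2) dz += L[2];
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < c2)
                out.push_back(i < j ? std::make_pair(i, j)
                                    : std::make_pair(j, i));
            }
          }
        }
      }
}

static void pairs_cell(const std::vector<double>& pos, int n_nodes, int npf,
                       const double* L, double cutoff, PairVec& out) {
  std::vector<double> wpos;
  wrap_copy(pos, L, wpos);
  pairs_cell_wrapped(wpos, n_nodes, npf, L, cutoff, out);
}

// [[Rcpp::export]]
List pairs_cpp(NumericMatrix posm, int npf, NumericVector box,
               double cutoff, bool brute) {
  int n = posm.nrow();
  std::vector<double> pos(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) pos[3 * i + k] = posm(i, k);
  double L[3] = {box[0], box[1], box[2]};
  PairVec pv;
  if (brute) pairs_brute(pos, n, npf, L, cutoff, pv);
  else       pairs_cell(pos, n, npf, L, cutoff, pv);
  int m = (int)pv.size();
  IntegerVector pi(m), pj(m);
  NumericVector pd(m);
  for (int q = 0; q < m; ++q) {
    int i = pv[q].first, j = pv[q].second;
    double d2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = mimg(pos[3 * j + k] - pos[3 * i + k], L[k]);
      d2 += d * d;
    }
    pi[q] = i + 1; pj[q] = j + 1; pd[q] = std::sqrt(d2);
  }
  return List::create(_["i"] = pi, _["j"] = pj, _["distance"] = pd);
}

// ------------------------------------------- aggregation pair selection ---
inline double pair_dist2(const std::vector<double>& wpos, int i, int j,
                         const double* L) {
  double d2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = wpos[3 * j + k] - wpos[3 * i + k];
    double Lh = 0.5 * L[k];
    if (d >= Lh) d -= L[k]; else if (d < -Lh) d += L[k];
    d2 += d * d;
  }
  return d2;
}

// Persistent 1:1 bonds (pairing mode 0): an existing bond breaks only when
// its minimum-image distance reaches a_th; free nodes then bind greedily,
// closest candidate pair first. Deterministic given positions and state.
static void bonds_update(const std::vector<double>& wpos, const PairVec& cand,
                         const double* L, double ath,
                         std::vector<int>& partner) {
  int n = (int)partner.size();
  double ath2 = ath * ath;
  for (int i = 0; i < n; ++i) {
    int j = partner[i];
    if (j > i && pair_dist2(wpos, i, j, L) >= ath2) {
      partner[i] = -1;
      partner[j] = -1;
    }
  }
  std::vector<std::pair<double, std::pair<int, int> > > fc;
  for (size_t q = 0; q < cand.size(); ++q) {
    int i = cand[q].first, j = cand[q].second;
    if (partner[i] >= 0 || partner[j] >= 0) continue;
    double d2 = pair_dist2(wpos, i, j, L);
    if (d2 < ath2) fc.push_back(std::make_pair(d2, std::make_pair(i, j)));
  }
  std::sort(fc.begin(), fc.end());
  for (size_t q = 0; q < fc.size(); ++q) {
    int i = fc[q].second.first, j = fc[q].second.second;
    if (partner[i] < 0 && partner[j] < 0) {
      partner[i] = j;
      partner[j] = i;
    }
  }
}

// Harmonic aggregation over the current bonds.
static void bonds_apply(const std::vector<double>& wpos,
                        const std::vector<int>& partner, const double* L,
                        const Par& p, double* F, double* WA, int* count) {
  int n = (int)partner.size();
  for (int i = 0; i < n; ++i) {
    int j = partner[i];
    if (j <= i) continue;
    int i3 = 3 * i, j3 = 3 * j;
    double dx = wpos[j3]     - wpos[i3];
    double dy = wpos[j3 + 1] - wpos[i3 + 1];
    double dz = wpos[j3 + 2] - wpos[i3 + 2];
    double Lh0 = 0.5 * L[0], Lh1 = 0.5 * L[1], Lh2 = 0.5 * L[2];
    if (dx >= Lh0) dx -= L[0]; else if (dx < -Lh0) dx += L[0];
    if (dy >= Lh1) dy -= L[1]; else if (dy < -Lh1) dy += L[1];
    if (dz >= Lh2) dz -= L[2]; else if (dz < -Lh2) dz += L[2];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d <= 0.0) stop("zero separation between interacting nodes");
    if (count) ++(*count);
    double dl = d - p.r0A;
    if (WA) *WA += 0.5 * p.kA * dl * dl;
    if (F) {
      double fac = p.kA * dl / d;
      F[i3]     += fac * dx; F[j3]     -= fac * dx;
      F[i3 + 1] += fac * dy; F[j3 + 1] -= fac * dy;
      F[i3 + 2] += fac * dz; F[j3 + 2] -= fac * dz;
    }
  }
}

// Stateless nearest-partner bookkeeping (pairing mode 1), epoch-stamped so
// the per-node tables need no clearing per step.
struct AggState {
  std::vector<int> best_j, stamp;
  std::vector<double> best_d2;
  std::vector<int> touched;
  int epoch;
  void init(int n_nodes) {
    best_j.assign(n_nodes, -1);
    best_d2.assign(n_nodes, 0.0);
    stamp.assign(n_nodes, -1);
    epoch = -1;
    touched.clear();
  }
  inline void update(int i, int j, double d2) {
    if (stamp[i] != epoch) {
      stamp[i] = epoch;
      best_j[i] = j;
      best_d2[i] = d2;
      touched.push_back(i);
    } else if (d2 < best_d2[i]) {
      best_j[i] = j;
      best_d2[i] = d2;
    }
  }
};

// One pass over the candidate list (wrapped coordinates): updates the
// aggregation selection (or, in all-pairs mode, applies the aggregation
// force directly) and applies the repulsive force to pairs closer than
// r0R. Distances are minimum-image.
static void pair_pass(const std::vector<double>& wpos, const PairVec& cand,
                      const double* L, const Par& p,
                      AggState* st, double* F, bool do_rep, double* WR,
                      bool do_agg_all = false, double* WA = NULL,
                      int* n_agg_all = NULL) {
  double ath2 = p.ath * p.ath, rep2 = p.r0R * p.r0R;
  double Lh0 = 0.5 * L[0], Lh1 = 0.5 * L[1], Lh2 = 0.5 * L[2];
  for (size_t q = 0; q < cand.size(); ++q) {
    int i = cand[q].first, j = cand[q].second;
    int i3 = 3 * i, j3 = 3 * j;
    double dx = wpos[j3]     - wpos[i3];
    double dy = wpos[j3 + 1] - wpos[i3 + 1];
    double dz = wpos[j3 + 2] - wpos[i3 + 2];
    if (dx >= Lh0) dx -= L[0]; else if (dx < -Lh0) dx += L[0];
    if (dy >= Lh1) dy -= L[1]; else if (dy < -Lh1) dy += L[1];
    if (dz >= Lh2) dz -= L[2]; else if (dz < -Lh2) dz += L[2];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 >= ath2) continue;
    if (st) {
      st->update(i, j, d2);
      st->update(j, i, d2);
    }
    if (do_agg_all) {
      double d = std::sqrt(d2);
      if (d <= 0.0) stop("zero separation between interacting nodes");
      if (n_agg_all) ++(*n_agg_all);
      double dl = d - p.r0A;
      if (WA) *WA += 0.5 * p.kA * dl * dl;
      if (F) {
        double fac = p.kA * dl / d;
        F[i3]     += fac * dx; F[j3]     -= fac * dx;
        F[i3 + 1] += fac * dy; F[j3 + 1] -= fac * dy;
        F[i3 + 2] += fac * dz; F[j3 + 2] -= fac * dz;
      }
    }
    if (do_rep && d2 < rep2) {
      double d = std::sqrt(d2);
      if (d <= 0.0) stop("zero separation between interacting nodes");
      double dl = d - p.r0R;
      if (WR) *WR += 0.5 * p.kR * dl * dl;
      if (F) {
        double fac = p.kR * dl / d;   // dl < 0: pushes the nodes apart
        F[i3]     += fac * dx; F[j3]     -= fac * dx;
        F[i3 + 1] += fac * dy; F[j3 + 1] -= fac * dy;
        F[i3 + 2] += fac * dz; F[j3 + 2] -= fac * dz;
      }
    }
  }
}

// Emit the deduplicated union of directed nearest-partner selections.
static void agg_emit(const AggState& st, PairVec& agg) {
  agg.clear();
  for (size_t q = 0; q < st.touched.size(); ++q) {
    int i = st.touched[q];
    int j = st.best_j[i];
    if (j > i) {
      agg.push_back(std::make_pair(i, j));
    } else {
      // emit only if j does not select i back (mutual pairs were emitted
      // from the smaller index)
      if (!(st.stamp[j] == st.epoch && st.best_j[j] == i))
        agg.push_back(std::make_pair(j, i));
    }
  }
}

// Harmonic aggregation force/energy over the selected pairs.
static void agg_apply(const std::vector<double>& wpos, const PairVec& agg,
                      const double* L, const Par& p, double* F, double* WA) {
  double Lh0 = 0.5 * L[0], Lh1 = 0.5 * L[1], Lh2 = 0.5 * L[2];
  for (size_t q = 0; q < agg.size(); ++q) {
    int i3 = 3 * agg[q].first, j3 = 3 * agg[q].second;
    double dx = wpos[j3]     - wpos[i3];
    double dy = wpos[j3 + 1] - wpos[i3 + 1];
    double dz = wpos[j3 + 2] - wpos[i3 + 2];
    if (dx >= Lh0) dx -= L[0]; else if (dx < -Lh0) dx += L[0];
    if (dy >= Lh1) dy -= L[1]; else if (dy < -Lh1) dy += L[1];
    if (dz >= Lh2) dz -= L[2]; else if (dz < -Lh2) dz += L[2];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d <= 0.0) stop("zero separation between interacting nodes");
    double dl = d - p.r0A;
    if (WA) *WA += 0.5 * p.kA * dl * dl;
    if (F) {
      double fac = p.kA * dl / d;     // attractive beyond r0A = 2a
      F[i3]     += fac * dx; F[j3]     -= fac * dx;
      F[i3 + 1] += fac * dy; F[j3 + 1] -= fac * dy;
      F[i3 + 2] += fac * dz; F[j3 + 2] -= fac * dz;
    }
  }
}

// Read the R-side partner vector (1-based, 0 = free; length 0 or NULL =
// all free) into the 0-based internal convention.
static std::vector<int> partner_in(SEXP partnerSEXP, int n) {
  std::vector<int> partner(n, -1);
  if (partnerSEXP != R_NilValue) {
    IntegerVector pv(partnerSEXP);
    if (pv.size() == n)
      for (int i = 0; i < n; ++i) partner[i] = pv[i] - 1;
    else if (pv.size() != 0)
      stop("partner vector length must equal the node count");
  }
  return partner;
}

static IntegerVector partner_out(const std::vector<int>& partner) {
  IntegerVector pv(partner.size());
  for (size_t i = 0; i < partner.size(); ++i) pv[i] = partner[i] + 1;
  return pv;
}

// [[Rcpp::export]]
List agg_pairs_cpp(NumericMatrix posm, int npf, NumericVector box,
                   List parl, SEXP partnerSEXP) {
  Par p = read_par(parl);
  int n = posm.nrow();
  std::vector<double> pos(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) pos[3 * i + k] = posm(i, k);
  double L[3] = {box[0], box[1], box[2]};
  std::vector<double> wpos;
  wrap_copy(pos, L, wpos);
  PairVec cand;
  pairs_cell_wrapped(wpos, n, npf, L, p.ath, cand);
  PairVec agg;
  std::vector<int> partner = partner_in(partnerSEXP, n);
  if (p.pairing == 2) {
    agg = cand;                   // all-pairs mode: every candidate binds
  } else if (p.pairing == 1) {
    AggState st;
    st.init(n);
    st.epoch = 0;
    pair_pass(wpos, cand, L, p, &st, NULL, false, NULL);
    agg_emit(st, agg);
  } else {
    bonds_update(wpos, cand, L, p.ath, partner);
    for (int i = 0; i < n; ++i)
      if (partner[i] > i) agg.push_back(std::make_pair(i, partner[i]));
  }
  int m = (int)agg.size();
  IntegerVector pi(m), pj(m);
  NumericVector pd(m);
  for (int q = 0; q < m; ++q) {
    int i = agg[q].first, j = agg[q].second;
    pi[q] = i + 1; pj[q] = j + 1;
    pd[q] = std::sqrt(pair_dist2(wpos, i, j, L));
  }
  return List::create(_["i"] = pi, _["j"] = pj, _["distance"] = pd,
                      _["partner"] = partner_out(partner));
}

// --------------------------------------------------------- potentials -----
// All force routines ADD into F (length 3N) and return the term energy.

static double force_stretch(const std::vector<double>& pos, int nf, int npf,
                            const Par& p, double* F) {
  double W = 0.0;
  for (int f = 0; f < nf; ++f) {
    int base = f * npf;
    for (int b = 0; b < npf - 1; ++b) {
      int i = base + b, j = i + 1;
      double r[3], rn = 0.0;
      for (int k = 0; k < 3; ++k) {
        r[k] = pos[3 * j + k] - pos[3 * i + k];
        rn += r[k] * r[k];
      }
      rn = std::sqrt(rn);
      if (rn <= 0.0) stop("coincident bonded nodes: bond direction undefined");
      double dl = rn - p.r0S;
      W += 0.5 * p.kS * dl * dl;
      if (F) {
        double fac = p.kS * dl / rn;
        for (int k = 0; k < 3; ++k) {
          F[3 * i + k] += fac * r[k];   // pulls i towards j when stretched
          F[3 * j + k] -= fac * r[k];
        }
      }
    }
  }
  return W;
}

static double force_bend(const std::vector<double>& pos, int nf, int npf,
                         const Par& p, double* F) {
  double W = 0.0;
  for (int f = 0; f < nf; ++f) {
    int base = f * npf;
    for (int b = 1; b < npf - 1; ++b) {
      int i = base + b, j = i - 1, k = i + 1;  // angle at i between j and k
      double u[3], v[3], un = 0.0, vn = 0.0, uv = 0.0;
      for (int q = 0; q < 3; ++q) {
        u[q] = pos[3 * j + q] - pos[3 * i + q];
        v[q] = pos[3 * k + q] - pos[3 * i + q];
        un += u[q] * u[q]; vn += v[q] * v[q]; uv += u[q] * v[q];
      }
      un = std::sqrt(un); vn = std::sqrt(vn);
      if (un <= 0.0 || vn <= 0.0)
        stop("coincident bonded nodes: bending angle undefined");
      double ct = uv / (un * vn);
      if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      double th = std::acos(ct);
      double dth = th - p.theta0;
      W += 0.5 * p.kB * dth * dth;
      if (F) {
        double st = std::sqrt(1.0 - ct * ct);
        if (st < 1e-8) continue;  // collinear: gradient limit is zero at theta0=pi
        double coef = p.kB * dth / st;
        for (int q = 0; q < 3; ++q) {
          double du = coef * (v[q] / (un * vn) - ct * u[q] / (un * un));
          double dv = coef * (u[q] / (un * vn) - ct * v[q] / (vn * vn));
          F[3 * j + q] += du;
          F[3 * k + q] += dv;
          F[3 * i + q] -= (du + dv);
        }
      }
    }
  }
  return W;
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Torsion over consecutive quadruples (i,j,k,l); plane normals
// m = r_ij x r_ik, n = r_ki x r_kl; W = kT/2 * phi^2 with phi0 = 0.
// Since phi enters squared, only |phi| = acos(m.n/|m||n|) matters for W.
static double force_torsion(const std::vector<double>& pos, int nf, int npf,
                            const Par& p, double* F) {
  double W = 0.0;
  for (int f = 0; f < nf; ++f) {
    int base = f * npf;
    for (int b = 0; b < npf - 3; ++b) {
      int ia = base + b, ib = ia + 1, ic = ia + 2, id = ia + 3;
      double pv[3], qv[3], rv[3], tv[3];
      for (int q = 0; q < 3; ++q) {
        pv[q] = pos[3 * ib + q] - pos[3 * ia + q];  // r_ij
        qv[q] = pos[3 * ic + q] - pos[3 * ia + q];  // r_ik
        rv[q] = pos[3 * ia + q] - pos[3 * ic + q];  // r_ki
        tv[q] = pos[3 * id + q] - pos[3 * ic + q];  // r_kl
      }
      double m[3], n[3];
      cross3(pv, qv, m);
      cross3(rv, tv, n);
      double M = std::sqrt(m[0]*m[0] + m[1]*m[1] + m[2]*m[2]);
      double N = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
      if (M < 1e-30 || N < 1e-30) continue;  // collinear: angle undefined
      double u = (m[0]*n[0] + m[1]*n[1] + m[2]*n[2]) / (M * N);
      if (u > 1.0) u = 1.0; else if (u < -1.0) u = -1.0;
      double phi = std::acos(u);
      W += 0.5 * p.kT * phi * phi;
      if (!F) continue;
      double s = std::sqrt(1.0 - u * u);
      double ratio;                      // phi/sin(phi)
      if (s < 1e-8) {
        if (u > 0.0) ratio = 1.0;        // phi -> 0 limit
        else continue;                   // phi -> pi: energy maximum
      } else ratio = phi / s;
      double coef = p.kT * ratio;        // force = +coef * du/dr
      // du/d{p,q,r,t} with u = (m.n)/(MN)
      double mh[3], nh[3];
      for (int q = 0; q < 3; ++q) { mh[q] = m[q] / M; nh[q] = n[q] / N; }
      double gS_p[3], gS_q[3], gS_r[3], gS_t[3];
      double gM_p[3], gM_q[3], gN_r[3], gN_t[3];
      cross3(qv, n, gS_p);   // d(m.n)/dp = q x n
      cross3(n, pv, gS_q);   // d(m.n)/dq = n x p
      cross3(tv, m, gS_r);   // d(m.n)/dr = t x m
      cross3(m, rv, gS_t);   // d(m.n)/dt = m x r
      cross3(qv, mh, gM_p);  // d|m|/dp = q x m^
      cross3(mh, pv, gM_q);  // d|m|/dq = m^ x p
      cross3(tv, nh, gN_r);  // d|n|/dr = t x n^
      cross3(nh, rv, gN_t);  // d|n|/dt = n^ x r
      double inv = 1.0 / (M * N);
      for (int q = 0; q < 3; ++q) {
        double gp = inv * gS_p[q] - (u / M) * gM_p[q];
        double gq = inv * gS_q[q] - (u / M) * gM_q[q];
        double gr = inv * gS_r[q] - (u / N) * gN_r[q];
        double gt = inv * gS_t[q] - (u / N) * gN_t[q];
        // chain to nodes: p=b-a, q=c-a, r=a-c, t=d-c
        F[3 * ia + q] += coef * (-gp - gq + gr);
        F[3 * ib + q] += coef * gp;
        F[3 * ic + q] += coef * (gq - gr - gt);
        F[3 * id + q] += coef * gt;
      }
    }
  }
  return W;
}

// terms mask bits: 1 stretch, 2 bend, 4 torsion, 8 aggregation, 16 repulsion
// [[Rcpp::export]]
List field_cpp(NumericMatrix posm, int npf, NumericVector box, List parl,
               int terms, bool forces, SEXP partnerSEXP) {
  Par p = read_par(parl);
  int n = posm.nrow();
  if (n % npf != 0) stop("node count is not a multiple of nodes_per_fibre");
  int nf = n / npf;
  std::vector<double> pos(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) pos[3 * i + k] = posm(i, k);
  double L[3] = {box[0], box[1], box[2]};
  std::vector<double> Fv;
  double* F = NULL;
  if (forces) { Fv.assign(3 * n, 0.0); F = &Fv[0]; }
  double WS = 0, WB = 0, WT = 0, WA = 0, WR = 0;
  int n_agg = 0;
  if (terms & 1) WS = force_stretch(pos, nf, npf, p, F);
  if (terms & 2) WB = force_bend(pos, nf, npf, p, F);
  if (terms & 4) WT = force_torsion(pos, nf, npf, p, F);
  std::vector<int> partner = partner_in(partnerSEXP, n);
  if (terms & 24) {
    std::vector<double> wpos;
    wrap_copy(pos, L, wpos);
    PairVec cand;
    pairs_cell_wrapped(wpos, n, npf, L, p.ath, cand);
    bool do_agg = (terms & 8) != 0;
    if (do_agg && p.pairing == 2) {
      pair_pass(wpos, cand, L, p, NULL, F, (terms & 16) != 0, &WR,
                true, &WA, &n_agg);
    } else if (do_agg && p.pairing == 0) {
      pair_pass(wpos, cand, L, p, NULL, F, (terms & 16) != 0, &WR);
      bonds_update(wpos, cand, L, p.ath, partner);
      bonds_apply(wpos, partner, L, p, F, &WA, &n_agg);
    } else {
      AggState st;
      if (do_agg) { st.init(n); st.epoch = 0; }
      pair_pass(wpos, cand, L, p, do_agg ? &st : NULL, F,
                (terms & 16) != 0, &WR);
      if (do_agg) {
        PairVec agg;
        agg_emit(st, agg);
        agg_apply(wpos, agg, L, p, F, &WA);
        n_agg = (int)agg.size();
      }
    }
  }
  List out = List::create(
    _["W_S"] = WS, _["W_B"] = WB, _["W_T"] = WT,
    _["W_A"] = WA, _["W_R"] = WR,
    _["W_total"] = WS + WB + WT + WA + WR,
    _["n_agg"] = n_agg,
    _["partner"] = partner_out(partner));
  if (forces) {
    NumericMatrix Fm(n, 3);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) Fm(i, k) = Fv[3 * i + k];
    out["forces"] = Fm;
  }
  return out;
}

// --------------------------------------------------------- integrator -----
// One step: (1) Euler displacement from bend+torsion+aggregation+repulsion,
// (2) thermal kick sqrt(2 kb T dt / c) per component, (3) stretch advanced
// by one classical RK4 step of dr/dt = fS(r)/c with the rest frozen.
// [[Rcpp::export]]
List bd_run_cpp(NumericMatrix posm, int npf, NumericVector box, List parl,
                double n_steps_d, int sample_every, SEXP rng, bool noise,
                double t0, SEXP partnerSEXP) {
  Par p = read_par(parl);
  long n_steps = (long)n_steps_d;
  int n = posm.nrow();
  if (n % npf != 0) stop("node count is not a multiple of nodes_per_fibre");
  int nf = n / npf;
  std::vector<double> pos(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) pos[3 * i + k] = posm(i, k);
  double L[3] = {box[0], box[1], box[2]};
  XPtr<NoiseGen> gen(rng);

  double amp = noise ? std::sqrt(2.0 * p.kb * p.temperature * p.dt / p.c) : 0.0;
  double dtc = p.dt / p.c;

  PairVec cand, agg;
  std::vector<int> partner = partner_in(partnerSEXP, n);
  AggState st;
  st.init(n);
  std::vector<double> ref(pos);          // positions at last list build
  double list_cut = p.ath + p.skin;
  double half_skin2 = 0.25 * p.skin * p.skin;
  bool need_build = true;

  std::vector<double> F(3 * n), wpos(3 * n), y0(3 * n), yt(3 * n),
                      k1(3 * n), k2(3 * n), k3(3 * n), k4(3 * n);
  wrap_copy(pos, L, wpos);

  int n_samples = (sample_every > 0) ? (int)(n_steps / sample_every) : 0;
  NumericMatrix log(n_samples, 8);
  int srow = 0;

  for (long step = 1; step <= n_steps; ++step) {
    if (need_build) {
      cand.clear();
      pairs_cell_wrapped(wpos, n, npf, L, list_cut, cand);
      ref = pos;
      need_build = false;
    }
    // (1) non-stretch forces, Euler displacement
    std::fill(F.begin(), F.end(), 0.0);
    double WR = 0;
    force_bend(pos, nf, npf, p, &F[0]);
    force_torsion(pos, nf, npf, p, &F[0]);
    if (p.pairing == 2) {
      pair_pass(wpos, cand, L, p, NULL, &F[0], true, &WR, true, NULL, NULL);
    } else if (p.pairing == 0) {
      pair_pass(wpos, cand, L, p, NULL, &F[0], true, &WR);
      bonds_update(wpos, cand, L, p.ath, partner);
      bonds_apply(wpos, partner, L, p, &F[0], NULL, NULL);
    } else {
      st.epoch = (int)step;
      st.touched.clear();
      pair_pass(wpos, cand, L, p, &st, &F[0], true, &WR);
      agg_emit(st, agg);
      agg_apply(wpos, agg, L, p, &F[0], NULL);
    }
    for (int q = 0; q < 3 * n; ++q) pos[q] += dtc * F[q];
    // (2) thermal kick (Box-Muller pairs generated in-line)
    if (noise) {
      int q = 0, n3 = 3 * n;
      for (; q + 1 < n3; q += 2) {
        double u1 = gen->unif(), u2 = gen->unif();
        double r = std::sqrt(-2.0 * std::log(u1));
        double a = 2.0 * M_PI * u2;
        pos[q]     += amp * r * std::cos(a);
        pos[q + 1] += amp * r * std::sin(a);
      }
      if (q < n3) pos[q] += amp * gen->normal();
    }
    // (3) RK4 on the stretch term alone
    y0 = pos;
    std::fill(k1.begin(), k1.end(), 0.0);
    force_stretch(y0, nf, npf, p, &k1[0]);
    for (int q = 0; q < 3 * n; ++q) yt[q] = y0[q] + 0.5 * dtc * k1[q];
    std::fill(k2.begin(), k2.end(), 0.0);
    force_stretch(yt, nf, npf, p, &k2[0]);
    for (int q = 0; q < 3 * n; ++q) yt[q] = y0[q] + 0.5 * dtc * k2[q];
    std::fill(k3.begin(), k3.end(), 0.0);
    force_stretch(yt, nf, npf, p, &k3[0]);
    for (int q = 0; q < 3 * n; ++q) yt[q] = y0[q] + dtc * k3[q];
    std::fill(k4.begin(), k4.end(), 0.0);
    force_stretch(yt, nf, npf, p, &k4[0]);
    for (int q = 0; q < 3 * n; ++q)
      pos[q] = y0[q] + (dtc / 6.0) * (k1[q] + 2.0 * k2[q] + 2.0 * k3[q] + k4[q]);

    // refresh the wrapped view, displacement bookkeeping, finiteness guard
    double maxd2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double x = pos[3 * i + k];
        wpos[3 * i + k] = x - L[k] * std::floor(x / L[k]);
        double d = x - ref[3 * i + k];
        d2 += d * d;
      }
      if (d2 > maxd2) maxd2 = d2;
    }
    if (!std::isfinite(maxd2)) {
      stop("non-finite coordinate at t = %g s; "
           "reduce dt or check the configuration", t0 + step * p.dt);
    }
    if (maxd2 > half_skin2) need_build = true;

    if (sample_every > 0 && step % sample_every == 0 && srow < n_samples) {
      double WS2 = force_stretch(pos, nf, npf, p, NULL);
      double WB2 = force_bend(pos, nf, npf, p, NULL);
      double WT2 = force_torsion(pos, nf, npf, p, NULL);
      double WA2 = 0, WR2 = 0;
      int n_agg2 = 0;
      PairVec fresh, agg2;
      pairs_cell_wrapped(wpos, n, npf, L, p.ath, fresh);
      if (p.pairing == 2) {
        pair_pass(wpos, fresh, L, p, NULL, NULL, true, &WR2,
                  true, &WA2, &n_agg2);
      } else if (p.pairing == 0) {
        pair_pass(wpos, fresh, L, p, NULL, NULL, true, &WR2);
        bonds_apply(wpos, partner, L, p, NULL, &WA2, &n_agg2);
      } else {
        st.epoch = -(int)step - 2;  // distinct epoch for the sampling pass
        st.touched.clear();
        pair_pass(wpos, fresh, L, p, &st, NULL, true, &WR2);
        agg_emit(st, agg2);
        agg_apply(wpos, agg2, L, p, NULL, &WA2);
        n_agg2 = (int)agg2.size();
      }
      log(srow, 0) = t0 + step * p.dt;
      log(srow, 1) = WS2; log(srow, 2) = WB2; log(srow, 3) = WT2;
      log(srow, 4) = WA2; log(srow, 5) = WR2;
      log(srow, 6) = WS2 + WB2 + WT2 + WA2 + WR2;
      log(srow, 7) = (double)n_agg2;
      ++srow;
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = pos[3 * i + k];
  return List::create(_["positions"] = out, _["log"] = log,
                      _["time"] = t0 + n_steps * p.dt,
                      _["partner"] = partner_out(partner));
}
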