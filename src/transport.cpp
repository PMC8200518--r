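// Analog Monte Carlo photon transport for a nested-cylinder HDR source in a
// water / air / vacuum phantom, with track-length tallies on (r, theta) ring
// voxels and on the 10 x 10 x 0.05 cm^3 air scoring box at 1 m, plus a
// deterministic first-flight (uncollided) estimator.
//
// All randomness comes from a self-contained xoshiro256** generator so a run
// is bit-reproducible for a given seed on any platform; per-batch child seeds
// are consecutive outputs of a splitmix64 stream started at the root seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

static const double MEC2 = 0.51099895;   // electron rest energy, MeV
static const double TGEOM_EPS = 1e-12;

// ---------------------------------------------------------------- RNG ------
struct RNG {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t se) { uint64_t x = se; for (int i = 0; i < 4; ++i) s[i] = splitmix64(x); }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53 + 0x1.0p-54; }  // open (0,1)
};

static uint64_t child_seed(uint64_t root, int b) {
  uint64_t x = root, v = 0;
  for (int i = 0; i < b; ++i) v = RNG::splitmix64(x);
  return v;
}

// ------------------------------------------------------- cross sections ----
// log-log tables of LINEAR attenuation coefficients (cm^-1) per process.
struct XSTab {
  std::vector<double> logE, pe, ic, co, tot;  // logs
  bool empty() const { return logE.empty(); }
  double interp(double E, int proc) const {
    const std::vector<double> &y = (proc == 0) ? pe : (proc == 1) ? ic
                                 : (proc == 2) ? co : tot;
    double lx = std::log(E);
    if (lx <= logE.front()) return std::exp(y.front());
    if (lx >= logE.back())  return std::exp(y.back());
    size_t hi = std::upper_bound(logE.begin(), logE.end(), lx) - logE.begin();
    size_t lo = hi - 1;
    double w = (lx - logE[lo]) / (logE[hi] - logE[lo]);
    return std::exp(y[lo] * (1.0 - w) + y[hi] * w);
  }
};

static XSTab xs_from_matrix(NumericMatrix m) {
  XSTab t;
  if (m.nrow() == 0) return t;
  for (int i = 0; i < m.nrow(); ++i) {
    t.logE.push_back(m(i, 0)); t.pe.push_back(m(i, 1));
    t.ic.push_back(m(i, 2));   t.co.push_back(m(i, 3));
    t.tot.push_back(m(i, 4));
  }
  return t;
}

// mass energy-absorption lookup (log-log), cm^2/g
struct MuEn {
  std::vector<double> logE, logv;
  bool empty() const { return logE.empty(); }
  double interp(double E) const {
    double lx = std::log(E);
    if (lx <= logE.front()) return std::exp(logv.front());
    if (lx >= logE.back())  return std::exp(logv.back());
    size_t hi = std::upper_bound(logE.begin(), logE.end(), lx) - logE.begin();
    size_t lo = hi - 1;
    double w = (lx - logE[lo]) / (logE[hi] - logE[lo]);
    return std::exp(logv[lo] * (1.0 - w) + logv[hi] * w);
  }
};

// ------------------------------------------------------------ geometry -----
struct Model {
  double core_r, half_L, cap_r, tip, prox, cable_r, cable_len;
  bool bare;  // no source structure at all (verification runs)
  double z_cap_top() const { return half_L + tip; }
  double z_cap_bot() const { return -half_L - prox; }
  double z_cable_bot() const { return z_cap_bot() - cable_len; }
};

struct Phantom {
  int type;      // 0 = cube (half width), 1 = sphere (radius)
  double size;
  bool vacuum;   // medium has zero cross section
};

// material/region index: 0 core, 1 capsule, 2 cable, 3 medium, -1 outside.
// Boundary points belong to the innermost region (test order).
static int region_of(double x, double y, double z, const Model &M, const Phantom &P) {
  bool inside = (P.type == 0)
    ? (std::fabs(x) <= P.size && std::fabs(y) <= P.size && std::fabs(z) <= P.size)
    : (x * x + y * y + z * z <= P.size * P.size);
  if (!M.bare) {
    double rho2 = x * x + y * y;
    if (rho2 <= M.core_r * M.core_r && std::fabs(z) <= M.half_L) return 0;
    if (rho2 <= M.cap_r * M.cap_r && z >= M.z_cap_bot() && z <= M.z_cap_top()) return 1;
    if (rho2 <= M.cable_r * M.cable_r && z >= M.z_cable_bot() && z < M.z_cap_bot()) return 2;
  }
  return inside ? 3 : -1;
}

// distance along +dir to the phantom exit (origin assumed inside)
static double exit_distance(const double *A, const double *D, const Phantom &P) {
  if (P.type == 0) {
    double t = R_PosInf;
    for (int i = 0; i < 3; ++i) {
      if (std::fabs(D[i]) > 0) {
        double ti = ((D[i] > 0 ? P.size : -P.size) - A[i]) / D[i];
        if (ti < t) t = ti;
      }
    }
    return t;
  }
  double b = A[0] * D[0] + A[1] * D[1] + A[2] * D[2];
  double c = A[0] * A[0] + A[1] * A[1] + A[2] * A[2] - P.size * P.size;
  double disc = b * b - c;
  if (disc <= 0) return 0.0;
  return -b + std::sqrt(disc);
}

static void push_cyl_roots(const double *A, const double *D, double R,
                           double tmax, std::vector<double> &ts) {
  double a = D[0] * D[0] + D[1] * D[1];
  if (a < 1e-30) return;
  double b = A[0] * D[0] + A[1] * D[1];
  double c = A[0] * A[0] + A[1] * A[1] - R * R;
  double disc = b * b - a * c;
  if (disc <= 0) return;
  double sq = std::sqrt(disc);
  double t1 = (-b - sq) / a, t2 = (-b + sq) / a;
  if (t1 > TGEOM_EPS && t1 < tmax) ts.push_back(t1);
  if (t2 > TGEOM_EPS && t2 < tmax) ts.push_back(t2);
}

// ordered material segments from A along D up to t_end (t_end <= exit distance)
struct Seg { int mat; double len; };

static void segment_ray(const double *A, const double *D, double t_end,
                        const Model &M, const Phantom &P, std::vector<Seg> &out) {
  out.clear();
  if (t_end <= 0) return;
  std::vector<double> ts;
  ts.reserve(24);
  if (!M.bare) {
    push_cyl_roots(A, D, M.core_r, t_end, ts);
    push_cyl_roots(A, D, M.cap_r, t_end, ts);
    if (M.cable_r != M.cap_r) push_cyl_roots(A, D, M.cable_r, t_end, ts);
    double zp[5] = { M.half_L, -M.half_L, M.z_cap_top(), M.z_cap_bot(), M.z_cable_bot() };
    if (std::fabs(D[2]) > 0) {
      for (int i = 0; i < 5; ++i) {
        double t = (zp[i] - A[2]) / D[2];
        if (t > TGEOM_EPS && t < t_end) ts.push_back(t);
      }
    }
  }
  ts.push_back(0.0);
  ts.push_back(t_end);
  std::sort(ts.begin(), ts.end());
  for (size_t i = 0; i + 1 < ts.size(); ++i) {
    double len = ts[i + 1] - ts[i];
    if (len <= TGEOM_EPS) continue;
    double tm = 0.5 * (ts[i] + ts[i + 1]);
    int mat = region_of(A[0] + tm * D[0], A[1] + tm * D[1], A[2] + tm * D[2], M, P);
    if (!out.empty() && out.back().mat == mat) out.back().len += len;
    else out.push_back({mat, len});
  }
}

// ------------------------------------------------------------- tallies -----
struct RingGrid {
  std::vector<double> r_edges;    // ascending
  std::vector<double> cth_edges;  // DESCENDING cos(theta), theta ascending
  int nr = 0, nt = 0;
  bool empty() const { return nr == 0; }
  int bin(double r, double cth) const {
    if (r < r_edges.front() || r >= r_edges.back()) return -1;
    int ir = int(std::upper_bound(r_edges.begin(), r_edges.end(), r) - r_edges.begin()) - 1;
    // descending search on cos(theta)
    int it = int(std::lower_bound(cth_edges.begin(), cth_edges.end(), cth,
                                  std::greater<double>()) - cth_edges.begin()) - 1;
    if (it < 0) it = 0;
    if (ir < 0 || ir >= nr || it >= nt) return -1;
    return it * nr + ir;
  }
};

struct BoxTally {
  double x0, x1, yh, zh;    // x slab, |y| <= yh, |z| <= zh
  double e0, de; int ne;    // energy bins
  // chord of [t0, t1] portion of ray within the box
  double chord(const double *A, const double *D, double t0, double t1) const {
    double lo = t0, hi = t1;
    // x slab
    if (std::fabs(D[0]) < 1e-30) { if (A[0] < x0 || A[0] > x1) return 0.0; }
    else {
      double ta = (x0 - A[0]) / D[0], tb = (x1 - A[0]) / D[0];
      if (ta > tb) std::swap(ta, tb);
      lo = std::max(lo, ta); hi = std::min(hi, tb);
    }
    double hw[2] = { yh, zh };
    for (int i = 1; i <= 2; ++i) {
      if (std::fabs(D[i]) < 1e-30) { if (std::fabs(A[i]) > hw[i - 1]) return 0.0; }
      else {
        double ta = (-hw[i - 1] - A[i]) / D[i], tb = (hw[i - 1] - A[i]) / D[i];
        if (ta > tb) std::swap(ta, tb);
        lo = std::max(lo, ta); hi = std::min(hi, tb);
      }
    }
    return (hi > lo) ? (hi - lo) : 0.0;
  }
  int ebin(double E) const {
    int k = int(std::floor((E - e0) / de));
    return (k >= 0 && k < ne) ? k : -1;
  }
};

// collect ring-chord sub-segments of flight [0, s] from A along D
static void ring_score(const RingGrid &G, const double *A, const double *D, double s,
                       double E, double muen, bool collided,
                       double *fl_tot, double *fl_sc, double *d_tot, double *d_sc) {
  // clip to outer sphere
  double Rmax = G.r_edges.back();
  double b = A[0] * D[0] + A[1] * D[1] + A[2] * D[2];
  double c = A[0] * A[0] + A[1] * A[1] + A[2] * A[2] - Rmax * Rmax;
  double disc = b * b - c;
  if (disc <= 0) return;
  double sq = std::sqrt(disc);
  double lo = std::max(0.0, -b - sq), hi = std::min(s, -b + sq);
  if (hi <= lo) return;
  std::vector<double> ts;
  ts.reserve(2 * (G.r_edges.size() + G.cth_edges.size()));
  ts.push_back(lo); ts.push_back(hi);
  // sphere crossings
  for (size_t i = 0; i < G.r_edges.size(); ++i) {
    double ci = A[0] * A[0] + A[1] * A[1] + A[2] * A[2] - G.r_edges[i] * G.r_edges[i];
    double di = b * b - ci;
    if (di <= 0) continue;
    double sqi = std::sqrt(di);
    double t1 = -b - sqi, t2 = -b + sqi;
    if (t1 > lo && t1 < hi) ts.push_back(t1);
    if (t2 > lo && t2 < hi) ts.push_back(t2);
  }
  // cone crossings (cos(theta) = cc); skip degenerate |cc| = 1
  for (size_t i = 0; i < G.cth_edges.size(); ++i) {
    double cc = G.cth_edges[i];
    if (std::fabs(cc) >= 1.0 - 1e-12) continue;
    if (std::fabs(cc) < 1e-12) {   // plane z = 0
      if (std::fabs(D[2]) > 1e-30) {
        double t = -A[2] / D[2];
        if (t > lo && t < hi) ts.push_back(t);
      }
      continue;
    }
    double c2 = cc * cc;
    double qa = D[2] * D[2] - c2;
    double qb = A[2] * D[2] - c2 * (A[0] * D[0] + A[1] * D[1] + A[2] * D[2]);
    double qc = A[2] * A[2] - c2 * (A[0] * A[0] + A[1] * A[1] + A[2] * A[2]);
    if (std::fabs(qa) < 1e-30) {
      if (std::fabs(qb) > 1e-30) {
        double t = -qc / (2.0 * qb);
        if (t > lo && t < hi && (A[2] + t * D[2]) * cc > 0) ts.push_back(t);
      }
      continue;
    }
    double dd = qb * qb - qa * qc;
    if (dd <= 0) continue;
    double sqd = std::sqrt(dd);
    for (int spm = -1; spm <= 1; spm += 2) {
      double t = (-qb + spm * sqd) / qa;
      if (t > lo && t < hi && (A[2] + t * D[2]) * cc > 0) ts.push_back(t);
    }
  }
  std::sort(ts.begin(), ts.end());
  for (size_t i = 0; i + 1 < ts.size(); ++i) {
    double len = ts[i + 1] - ts[i];
    if (len <= TGEOM_EPS) continue;
    double tm = 0.5 * (ts[i] + ts[i + 1]);
    double px = A[0] + tm * D[0], py = A[1] + tm * D[1], pz = A[2] + tm * D[2];
    double r = std::sqrt(px * px + py * py + pz * pz);
    if (r <= 0) continue;
    int k = G.bin(r, pz / r);
    if (k < 0) continue;
    fl_tot[k] += len;
    d_tot[k] += len * E * muen;
    if (collided) { fl_sc[k] += len; d_sc[k] += len * E * muen; }
  }
}

// ------------------------------------------------------ physics sampling ---
static double kn_sample(double E, RNG &g, double &cth) {
  double a = E / MEC2;
  double rmin = 1.0 / (1.0 + 2.0 * a);
  double gmax = rmin + 1.0 / rmin;
  double r, gr, c;
  do {
    r = rmin + (1.0 - rmin) * g.unif();
    c = 1.0 - (1.0 / r - 1.0) / a;
    if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
    gr = r + 1.0 / r - (1.0 - c * c);
  } while (g.unif() * gmax > gr);
  cth = c;
  return r * E;
}

static double thomson_sample(RNG &g) {
  double c;
  do { c = 2.0 * g.unif() - 1.0; } while (g.unif() > 0.5 * (1.0 + c * c));
  return c;
}

static void rotate_direction(double *D, double cth, double phi) {
  double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
  double u = D[0], v = D[1], w = D[2];
  double cp = std::cos(phi), sp = std::sin(phi);
  double s2 = std::sqrt(std::max(1e-30, 1.0 - w * w));
  double nu, nv, nw;
  if (s2 > 1e-10) {
    nu = u * cth + sth * (u * w * cp - v * sp) / s2;
    nv = v * cth + sth * (v * w * cp + u * sp) / s2;
    nw = w * cth - sth * s2 * cp;
  } else {
    nu = sth * cp; nv = sth * sp; nw = (w > 0 ? cth : -cth);
  }
  double n = std::sqrt(nu * nu + nv * nv + nw * nw);
  D[0] = nu / n; D[1] = nv / n; D[2] = nw / n;
}

// ------------------------------------------------- model/phantom parsing ---
static Model parse_model(List m) {
  Model M;
  M.core_r = as<double>(m["core_radius"]);
  M.half_L = as<double>(m["core_length"]) / 2.0;
  M.cap_r = as<double>(m["capsule_radius"]);
  M.tip = as<double>(m["tip_thickness"]);
  M.prox = as<double>(m["proximal_thickness"]);
  M.cable_r = as<double>(m["cable_radius"]);
  M.cable_len = as<double>(m["cable_length"]);
  M.bare = as<bool>(m["bare"]);
  return M;
}

static Phantom parse_phantom(List p) {
  Phantom P;
  std::string ty = as<std::string>(p["shape"]);
  P.type = (ty == "cube") ? 0 : 1;
  P.size = as<double>(p["size"]);
  P.vacuum = as<bool>(p["vacuum"]);
  return P;
}

// ---------------------------------------------------------- R interface ----

// [[Rcpp::export]]
List cpp_trace_path(NumericVector origin, NumericVector direction, List model,
                    List phantom, Nullable<NumericVector> target) {
  Model M = parse_model(model);
  Phantom P = parse_phantom(phantom);
  double A[3] = { origin[0], origin[1], origin[2] };
  double D[3] = { direction[0], direction[1], direction[2] };
  double nrm = std::sqrt(D[0] * D[0] + D[1] * D[1] + D[2] * D[2]);
  if (nrm < 1e-12) stop("degenerate direction (zero vector)");
  for (int i = 0; i < 3; ++i) D[i] /= nrm;
  if (region_of(A[0], A[1], A[2], M, P) < 0) stop("origin outside phantom");
  double t_end = exit_distance(A, D, P);
  if (target.isNotNull()) {
    NumericVector tg(target);
    double dx = tg[0] - A[0], dy = tg[1] - A[1], dz = tg[2] - A[2];
    double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
    t_end = std::min(t_end, dist);
  }
  std::vector<Seg> segs;
  segment_ray(A, D, t_end, M, P, segs);
  int n = segs.size();
  IntegerVector mat(n); NumericVector len(n);
  for (int i = 0; i < n; ++i) { mat[i] = segs[i].mat; len[i] = segs[i].len; }
  return List::create(_["material"] = mat, _["length"] = len, _["ray_length"] = t_end);
}

// [[Rcpp::export]]
int cpp_locate(NumericVector point, List model, List phantom) {
  Model M = parse_model(model);
  Phantom P = parse_phantom(phantom);
  return region_of(point[0], point[1], point[2], M, P);
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_core(int n, List model, double seed) {
  Model M = parse_model(model);
  RNG g; g.seed((uint64_t)seed);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double rho = M.core_r * std::sqrt(g.unif());
    double phi = 2.0 * M_PI * g.unif();
    out(i, 0) = rho * std::cos(phi);
    out(i, 1) = rho * std::sin(phi);
    out(i, 2) = M.half_L * (2.0 * g.unif() - 1.0);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double E, int n, double seed) {
  RNG g; g.seed((uint64_t)seed);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double c; double Ep = kn_sample(E, g, c);
    out(i, 0) = Ep; out(i, 1) = c;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_rayleigh(int n, double seed) {
  RNG g; g.seed((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = thomson_sample(g);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_free_flight(int n, NumericVector mu, NumericVector len,
                                     double seed) {
  // mu, len: per-segment linear attenuation (cm^-1) and length (cm).
  // Returns sampled interaction distances; Inf = escape beyond the last segment.
  RNG g; g.seed((uint64_t)seed);
  int ns = mu.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double tau = -std::log(1.0 - g.unif());
    double s = 0.0; bool hit = false;
    for (int j = 0; j < ns; ++j) {
      double od = mu[j] * len[j];
      if (tau <= od) { s += (mu[j] > 0 ? tau / mu[j] : len[j]); hit = true; break; }
      tau -= od; s += len[j];
    }
    out[i] = hit ? s : R_PosInf;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ring_chords(NumericVector origin, NumericVector direction,
                              double smax, NumericVector r_edges,
                              NumericVector theta_edges_deg) {
  RingGrid G;
  G.r_edges.assign(r_edges.begin(), r_edges.end());
  for (int i = 0; i < theta_edges_deg.size(); ++i)
    G.cth_edges.push_back(std::cos(theta_edges_deg[i] * M_PI / 180.0));
  G.nr = G.r_edges.size() - 1; G.nt = G.cth_edges.size() - 1;
  int nb = G.nr * G.nt;
  std::vector<double> ft(nb, 0.0), fs(nb, 0.0), dt(nb, 0.0), ds(nb, 0.0);
  double A[3] = { origin[0], origin[1], origin[2] };
  double D[3] = { direction[0], direction[1], direction[2] };
  double nrm = std::sqrt(D[0]*D[0]+D[1]*D[1]+D[2]*D[2]);
  for (int i = 0; i < 3; ++i) D[i] /= nrm;
  ring_score(G, A, D, smax, 1.0, 1.0, false, ft.data(), fs.data(), dt.data(), ds.data());
  // return non-zero chords as (ir, it, length), 1-based indices
  std::vector<std::array<double,3>> rows;
  for (int k = 0; k < nb; ++k) if (ft[k] > 0) {
    rows.push_back({double(k % G.nr + 1), double(k / G.nr + 1), ft[k]});
  }
  NumericMatrix out(rows.size(), 3);
  for (size_t i = 0; i < rows.size(); ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = rows[i][j];
  colnames(out) = CharacterVector::create("ir", "itheta", "length");
  return out;
}

// main transport driver
// [[Rcpp::export]]
List cpp_run_transport(List model, List phantom, List xs, List cfg) {
  Model M = parse_model(model);
  Phantom P = parse_phantom(phantom);
  XSTab tab[4];
  List xl = xs["tables"];  // list of 4 matrices: core, capsule, cable, medium
  for (int i = 0; i < 4; ++i) tab[i] = xs_from_matrix(as<NumericMatrix>(xl[i]));
  MuEn muen;
  NumericMatrix mm = as<NumericMatrix>(xs["muen"]);
  for (int i = 0; i < mm.nrow(); ++i) {
    muen.logE.push_back(mm(i, 0)); muen.logv.push_back(mm(i, 1));
  }

  long histories = (long)as<double>(cfg["histories_per_batch"]);
  int nb = as<int>(cfg["batches"]);
  uint64_t root = (uint64_t)as<double>(cfg["seed"]);
  double cutoff = as<double>(cfg["cutoff_MeV"]);
  bool coherent_on = as<bool>(cfg["coherent"]);
  bool point_source = as<bool>(cfg["point_source"]);
  NumericVector lineE = cfg["line_energies"];
  NumericVector lineC = cfg["line_cdf"];     // cumulative probabilities
  int tally_mode = as<int>(cfg["tally_mode"]);  // 0 ring, 1 air box

  RingGrid G;
  BoxTally B; B.ne = 0;
  int nbin = 0;
  if (tally_mode == 0) {
    NumericVector re = cfg["r_edges"], te = cfg["theta_edges_deg"];
    G.r_edges.assign(re.begin(), re.end());
    for (int i = 0; i < te.size(); ++i)
      G.cth_edges.push_back(std::cos(te[i] * M_PI / 180.0));
    G.nr = G.r_edges.size() - 1; G.nt = G.cth_edges.size() - 1;
    nbin = G.nr * G.nt;
  } else {
    NumericVector bx = cfg["box"];   // cx, dx, dy, dz
    B.x0 = bx[0] - bx[1] / 2.0; B.x1 = bx[0] + bx[1] / 2.0;
    B.yh = bx[2] / 2.0; B.zh = bx[3] / 2.0;
    B.e0 = as<double>(cfg["ebin_min"]); B.de = as<double>(cfg["ebin_width"]);
    B.ne = as<int>(cfg["ebin_n"]);
    nbin = B.ne;
  }

  NumericMatrix fl_tot(nbin, nb), fl_sc(nbin, nb), d_tot(nbin, nb), d_sc(nbin, nb);
  NumericMatrix counters(8, nb);
  rownames(counters) = CharacterVector::create(
    "escaped", "photoelectric", "cutoff_terminated", "compton", "rayleigh",
    "n_flights", "max_scored_E", "min_scored_E");

  int nlines = lineE.size();
  std::vector<Seg> segs;

  for (int b = 0; b < nb; ++b) {
    RNG g; g.seed(child_seed(root, b + 1));
    double *ftc = &fl_tot(0, b), *fsc = &fl_sc(0, b);
    double *dtc = &d_tot(0, b), *dsc = &d_sc(0, b);
    double maxE = 0.0, minE = R_PosInf;
    for (long h = 0; h < histories; ++h) {
      double A[3] = { 0.0, 0.0, 0.0 };
      if (!point_source) {
        double rho = M.core_r * std::sqrt(g.unif());
        double phi = 2.0 * M_PI * g.unif();
        A[0] = rho * std::cos(phi); A[1] = rho * std::sin(phi);
        A[2] = M.half_L * (2.0 * g.unif() - 1.0);
      }
      double cth = 2.0 * g.unif() - 1.0, aphi = 2.0 * M_PI * g.unif();
      double sth = std::sqrt(1.0 - cth * cth);
      double D[3] = { sth * std::cos(aphi), sth * std::sin(aphi), cth };
      double u = g.unif(), E = lineE[nlines - 1];
      for (int i = 0; i < nlines; ++i) if (u <= lineC[i]) { E = lineE[i]; break; }
      bool collided = false, alive = true;
      while (alive) {
        double t_exit = exit_distance(A, D, P);
        segment_ray(A, D, t_exit, M, P, segs);
        double tau = -std::log(1.0 - g.unif());
        double s_hit = -1.0; int mat_hit = -1; double off = 0.0;
        for (size_t j = 0; j < segs.size(); ++j) {
          int m = segs[j].mat;
          double mu = 0.0;
          if (m >= 0 && !(m == 3 && P.vacuum) && !tab[m].empty())
            mu = tab[m].interp(E, 3);
          double od = mu * segs[j].len;
          if (tau <= od && mu > 0) { s_hit = off + tau / mu; mat_hit = m; break; }
          tau -= od; off += segs[j].len;
        }
        double s_end = (s_hit > 0) ? s_hit : t_exit;
        // score the flight
        if (E >= cutoff) {
          if (tally_mode == 0) {
            double me = muen.empty() ? 0.0 : muen.interp(E);
            ring_score(G, A, D, s_end, E, me, collided, ftc, fsc, dtc, dsc);
            if (s_end > 0) { if (E > maxE) maxE = E; if (E < minE) minE = E; }
          } else {
            double ch = B.chord(A, D, 0.0, s_end);
            if (ch > 0) {
              int k = B.ebin(E);
              if (k >= 0) {
                ftc[k] += ch; dtc[k] += ch * E;
                if (collided) { fsc[k] += ch; dsc[k] += ch * E; }
                if (E > maxE) maxE = E; if (E < minE) minE = E;
              }
            }
          }
        }
        counters(5, b) += 1;
        if (s_hit < 0) { counters(0, b) += 1; break; }   // escaped
        for (int i = 0; i < 3; ++i) A[i] += s_hit * D[i];
        // choose process
        double pe = tab[mat_hit].interp(E, 0);
        double ic = tab[mat_hit].interp(E, 1);
        double co = coherent_on ? tab[mat_hit].interp(E, 2) : 0.0;
        double x = g.unif() * (pe + ic + co);
        if (x <= pe) { counters(1, b) += 1; alive = false; }
        else if (x <= pe + ic) {
          counters(3, b) += 1;
          double c; double Ep = kn_sample(E, g, c);
          rotate_direction(D, c, 2.0 * M_PI * g.unif());
          E = Ep; collided = true;
          if (E < cutoff) { counters(2, b) += 1; alive = false; }
        } else {
          counters(4, b) += 1;
          rotate_direction(D, thomson_sample(g), 2.0 * M_PI * g.unif());
          collided = true;
        }
      }
    }
    counters(6, b) = maxE;
    counters(7, b) = (minE == R_PosInf) ? NA_REAL : minE;
  }
  return List::create(_["fluence_total"] = fl_tot, _["fluence_scatter"] = fl_sc,
                      _["dose_total"] = d_tot, _["dose_scatter"] = d_sc,
                      _["counters"] = counters);
}

// deterministic first-flight (uncollided) fluence at detector points,
// averaged over a fixed lattice of emission points in the core volume.
// Returns an ndet x nlines matrix of fluence per initial photon (cm^-2).
// [[Rcpp::export]]
NumericMatrix cpp_uncollided(NumericMatrix det, NumericVector lineE, List model,
                             List phantom, List xs, int n_rho, int n_phi, int n_z,
                             bool point_source) {
  Model M = parse_model(model);
  Phantom P = parse_phantom(phantom);
  XSTab tab[4];
  List xl = xs["tables"];
  for (int i = 0; i < 4; ++i) tab[i] = xs_from_matrix(as<NumericMatrix>(xl[i]));
  int nlines = lineE.size();
  // per-material, per-line linear attenuation cache
  std::vector<std::vector<double>> mu(4, std::vector<double>(nlines, 0.0));
  for (int m = 0; m < 4; ++m) {
    if (m == 3 && P.vacuum) continue;
    if (tab[m].empty()) continue;
    for (int l = 0; l < nlines; ++l) mu[m][l] = tab[m].interp(lineE[l], 3);
  }
  // emission lattice (midpoint rule in rho^2, phi, z)
  std::vector<std::array<double,3>> src;
  if (point_source) src.push_back({0.0, 0.0, 0.0});
  else {
    for (int i = 0; i < n_rho; ++i) {
      double rho = M.core_r * std::sqrt((i + 0.5) / n_rho);
      for (int j = 0; j < n_phi; ++j) {
        double phi = 2.0 * M_PI * (j + 0.5) / n_phi;
        for (int k = 0; k < n_z; ++k) {
          double z = M.half_L * (2.0 * (k + 0.5) / n_z - 1.0);
          src.push_back({rho * std::cos(phi), rho * std::sin(phi), z});
        }
      }
    }
  }
  int ndet = det.nrow();
  NumericMatrix out(ndet, nlines);
  std::vector<Seg> segs;
  for (int d = 0; d < ndet; ++d) {
    double T[3] = { det(d, 0), det(d, 1), det(d, 2) };
    std::vector<double> acc(nlines, 0.0);
    for (size_t sidx = 0; sidx < src.size(); ++sidx) {
      const auto &S = src[sidx];
      double D[3] = { T[0] - S[0], T[1] - S[1], T[2] - S[2] };
      double dist = std::sqrt(D[0]*D[0] + D[1]*D[1] + D[2]*D[2]);
      if (dist < 1e-9) continue;
      for (int i = 0; i < 3; ++i) D[i] /= dist;
      double A[3] = { S[0], S[1], S[2] };
      segment_ray(A, D, dist, M, P, segs);
      double geom = 1.0 / (4.0 * M_PI * dist * dist);
      for (int l = 0; l < nlines; ++l) {
        double od = 0.0;
        for (size_t j = 0; j < segs.size(); ++j) {
          int m = segs[j].mat;
          if (m >= 0 && !(m == 3 && P.vacuum)) od += mu[m][l] * segs[j].len;
        }
        acc[l] += geom * std::exp(-od);
      }
    }
    for (int l = 0; l < nlines; ++l) out(d, l) = acc[l] / double(src.size());
  }
  return out;
}
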