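// Frequency-domain photon-packet Monte Carlo on piecewise-constant
// triangular meshes.  Packets carry a complex weight: absorption attenuates
// the modulus along the path, the modulation frequency advances the phase
// with the total optical path length.  Per-(detector, element) path-length
// and scatter-count accumulators are tallied so that absorption and
// (perturbation Monte Carlo) scattering Jacobians can be assembled from a
// single simulation.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG: one independent substream per (seed, source, packet),
// so reruns with a perturbed medium reuse identical random numbers
// (common random numbers for finite-difference validation).

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256p {
  uint64_t s[4];
  void seed(uint64_t a) {
    uint64_t x = a;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  double u01() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static inline void seed_packet(Xoshiro256p &rng, uint64_t root,
                               uint64_t source, uint64_t packet) {
  uint64_t x = root;
  uint64_t h = splitmix64(x);
  x = h ^ ((source + 1) * 0xBF58476D1CE4E5B9ULL);
  h = splitmix64(x);
  x = h ^ ((packet + 1) * 0x94D049BB133111EBULL);
  rng.seed(splitmix64(x));
}

// ---------------------------------------------------------------------------
// Henyey-Greenstein, 2D branch: density (1/2pi)(1-g^2)/(1+g^2-2g cos t),
// exact inverse CDF.

static inline double hg_angle(double g, double u) {
  if (g == 0.0) return 2.0 * M_PI * (u - 0.5);
  double t = std::tan(M_PI * (u - 0.5));
  return 2.0 * std::atan(((1.0 - g) / (1.0 + g)) * t);
}

// ---------------------------------------------------------------------------
// Mesh view (no copies; matrices owned by R)

struct MeshView {
  NumericMatrix nodes;   // N x 2
  IntegerMatrix tri;     // K x 3, 0-based, CCW
  IntegerMatrix adj;     // K x 3, neighbor across edge e=(v_e, v_{e+1}), -1 = boundary
  int K;
  double nudge;          // absolute advance past a crossed edge
  MeshView(NumericMatrix nodes_, IntegerMatrix tri_, IntegerMatrix adj_,
           double scale)
    : nodes(nodes_), tri(tri_), adj(adj_), K(tri_.nrow()),
      nudge(1e-12 * scale) {}
};

// Exit search inside triangle k from p along unit d.
// Returns edge index (0..2) and distance s >= 0, or -1 on geometric failure.
static inline int find_exit(const MeshView &m, int k,
                            double px, double py, double dx, double dy,
                            double &s_out) {
  double best = R_PosInf;
  int edge = -1;
  for (int e = 0; e < 3; ++e) {
    int ia = m.tri(k, e), ib = m.tri(k, (e + 1) % 3);
    double ax = m.nodes(ia, 0), ay = m.nodes(ia, 1);
    double bx = m.nodes(ib, 0), by = m.nodes(ib, 1);
    // outward (unnormalized) normal of CCW edge a->b
    double nx = by - ay, ny = -(bx - ax);
    double denom = nx * dx + ny * dy;
    if (denom <= 0.0) continue;
    double s = (nx * (ax - px) + ny * (ay - py)) / denom;
    if (s < 0.0) s = 0.0;
    if (s < best) { best = s; edge = e; }
  }
  s_out = best;
  return edge;
}

// ---------------------------------------------------------------------------
// Per-packet scratch: sparse path-length / scatter-count record

struct PathBuf {
  std::vector<double> l;
  std::vector<int> nsc;
  std::vector<unsigned char> seen;
  std::vector<int> visited;
  explicit PathBuf(int K) : l(K, 0.0), nsc(K, 0), seen(K, 0) {
    visited.reserve(256);
  }
  inline void touch(int k) {
    if (!seen[k]) { seen[k] = 1; visited.push_back(k); }
  }
  inline void reset() {
    for (int k : visited) { l[k] = 0.0; nsc[k] = 0; seen[k] = 0; }
    visited.clear();
  }
};

struct PacketOutcome {
  bool exited;      // left the domain through the boundary
  bool terminated;  // weight fell below the threshold
  bool lost;        // geometric failure / step cap
  int exit_tri, exit_edge;
  double exit_x, exit_y;
  double s_tot;     // total geometric path length (mm)
  double mua_len;   // accumulated integral of mua along the path
  long steps;
};

// Propagate one packet.  Fills buf with per-element path lengths and
// scattering counts.  term_log = -log(threshold), Inf disables termination.
static void propagate(const MeshView &m, const double *mua, const double *mus,
                      double g, double term_log, long max_steps,
                      Xoshiro256p &rng, int k0, double px, double py,
                      double dx, double dy, PathBuf &buf, PacketOutcome &out) {
  int k = k0;
  out.exited = false; out.terminated = false; out.lost = false;
  out.s_tot = 0.0; out.mua_len = 0.0; out.steps = 0;
  out.exit_tri = -1; out.exit_edge = -1;
  out.exit_x = NA_REAL; out.exit_y = NA_REAL;

  double depth = -std::log(1.0 - rng.u01());  // sampled optical depth

  for (;;) {
    if (++out.steps > max_steps) { out.lost = true; return; }
    double s_exit;
    int edge = find_exit(m, k, px, py, dx, dy, s_exit);
    if (edge < 0 || !R_finite(s_exit)) { out.lost = true; return; }

    double msk = mus[k];
    if (msk > 0.0 && msk * s_exit >= depth) {
      // scattering site inside element k
      double dl = depth / msk;
      px += dl * dx; py += dl * dy;
      buf.touch(k);
      buf.l[k] += dl;
      buf.nsc[k] += 1;
      out.s_tot += dl;
      out.mua_len += mua[k] * dl;
      if (out.mua_len > term_log) { out.terminated = true; return; }
      double th = hg_angle(g, rng.u01());
      double ct = std::cos(th), st = std::sin(th);
      double ndx = ct * dx - st * dy, ndy = st * dx + ct * dy;
      dx = ndx; dy = ndy;
      depth = -std::log(1.0 - rng.u01());
      continue;
    }

    // traverse element k fully
    buf.touch(k);
    buf.l[k] += s_exit;
    out.s_tot += s_exit;
    out.mua_len += mua[k] * s_exit;
    depth -= msk * s_exit;
    px += s_exit * dx; py += s_exit * dy;
    if (out.mua_len > term_log) { out.terminated = true; return; }

    int nb = m.adj(k, edge);
    if (nb < 0) {
      out.exited = true;
      out.exit_tri = k; out.exit_edge = edge;
      out.exit_x = px; out.exit_y = py;
      return;
    }
    k = nb;
    px += m.nudge * dx; py += m.nudge * dy;  // step past the shared edge
  }
}

// ---------------------------------------------------------------------------
// Source sampling: segments of boundary chords covered by the source arc.
// segs columns: ax ay bx by len tri inx iny  (inward unit normal)

struct SourceView {
  NumericMatrix segs;
  std::vector<double> cum;
  double total;
  explicit SourceView(NumericMatrix s) : segs(s), cum(s.nrow()) {
    double acc = 0.0;
    for (int i = 0; i < s.nrow(); ++i) { acc += s(i, 4); cum[i] = acc; }
    total = acc;
  }
  // uniform position along covered length, cosine-law direction about the
  // inward normal
  void emit(Xoshiro256p &rng, double &px, double &py,
            double &dx, double &dy, int &tri) const {
    double target = rng.u01() * total;
    int i = 0, n = segs.nrow();
    while (i < n - 1 && cum[i] < target) ++i;
    double prev = (i == 0) ? 0.0 : cum[i - 1];
    double t = (segs(i, 4) > 0.0) ? (target - prev) / segs(i, 4) : 0.5;
    px = segs(i, 0) + t * (segs(i, 2) - segs(i, 0));
    py = segs(i, 1) + t * (segs(i, 3) - segs(i, 1));
    double psi = std::asin(2.0 * rng.u01() - 1.0);  // density cos(psi)/2
    double nx = segs(i, 6), ny = segs(i, 7);
    double c = std::cos(psi), s = std::sin(psi);
    dx = c * nx - s * ny;
    dy = s * nx + c * ny;
    tri = (int) segs(i, 5);
  }
};

static inline double ang_diff(double a, double b) {
  double d = a - b;
  while (d > M_PI) d -= 2.0 * M_PI;
  while (d < -M_PI) d += 2.0 * M_PI;
  return d;
}

// detector index for an exit point, or -1
static inline int which_detector(double x, double y,
                                 const NumericVector &det_center,
                                 const NumericVector &det_half) {
  double phi = std::atan2(y, x);
  for (int b = 0; b < det_center.size(); ++b) {
    if (std::fabs(ang_diff(phi, det_center[b])) <= det_half[b]) return b;
  }
  return -1;
}

// ---------------------------------------------------------------------------
// Full simulation of one source

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix nodes, IntegerMatrix tri, IntegerMatrix adj,
                  double mesh_scale,
                  NumericVector mua, NumericVector mus, double g,
                  double omega_over_c, double w0, double term_threshold,
                  NumericMatrix source_segs,
                  NumericVector det_center, NumericVector det_half,
                  double P, double seed, int source_index,
                  bool record_jacobian, double max_steps,
                  int pert_element = -1, double pert_mus = 0.0) {
  MeshView m(nodes, tri, adj, mesh_scale);
  SourceView src(source_segs);
  const int K = m.K, B = det_center.size();
  const long Pl = (long) P;
  const double term_log =
    (term_threshold > 0.0) ? -std::log(term_threshold) : R_PosInf;

  PathBuf buf(K);
  PacketOutcome out;
  Xoshiro256p rng;

  std::vector<double> Wre(B, 0.0), Wim(B, 0.0);
  std::vector<double> W2re(B, 0.0), W2im(B, 0.0);  // per-packet second moments
  std::vector<double> Sa_re, Sa_im, Ss_re, Ss_im;
  if (record_jacobian) {
    Sa_re.assign((size_t) B * K, 0.0); Sa_im.assign((size_t) B * K, 0.0);
    Ss_re.assign((size_t) B * K, 0.0); Ss_im.assign((size_t) B * K, 0.0);
  }
  double tot_re = 0.0, tot_im = 0.0;
  long n_exit = 0, n_term = 0, n_lost = 0;
  // perturbation Monte Carlo: reweight each stored path for a modified
  // scattering coefficient in one element, w * (mus~/mus)^n * exp(-(mus~-mus) l)
  const bool do_pert = pert_element >= 0;
  std::vector<double> Wp_re, Wp_im;
  if (do_pert) {
    if (pert_element >= K) stop("pert_element out of range");
    if (mus[pert_element] <= 0.0 && pert_mus != mus[pert_element])
      stop("perturbation of an element with mus = 0 is not supported");
    Wp_re.assign(B, 0.0); Wp_im.assign(B, 0.0);
  }

  for (long p = 0; p < Pl; ++p) {
    seed_packet(rng, (uint64_t) seed, (uint64_t) source_index, (uint64_t) p);
    double px, py, dx, dy; int k0;
    src.emit(rng, px, py, dx, dy, k0);
    buf.reset();
    propagate(m, REAL(mua), REAL(mus), g, term_log, (long) max_steps,
              rng, k0, px, py, dx, dy, buf, out);
    if (out.lost) { ++n_lost; continue; }
    if (out.terminated) { ++n_term; continue; }
    ++n_exit;
    double amp = w0 * std::exp(-out.mua_len);
    double ph = -omega_over_c * out.s_tot;
    double wre = amp * std::cos(ph), wim = amp * std::sin(ph);
    tot_re += wre; tot_im += wim;
    int b = which_detector(out.exit_x, out.exit_y, det_center, det_half);
    if (b < 0) continue;
    Wre[b] += wre; Wim[b] += wim;
    W2re[b] += wre * wre; W2im[b] += wim * wim;
    if (do_pert) {
      double lk = buf.l[pert_element];
      int nk = buf.nsc[pert_element];
      double fac = std::exp(-(pert_mus - mus[pert_element]) * lk);
      if (nk > 0) fac *= std::pow(pert_mus / mus[pert_element], (double) nk);
      Wp_re[b] += fac * wre;
      Wp_im[b] += fac * wim;
    }
    if (record_jacobian) {
      for (int k : buf.visited) {
        size_t idx = (size_t) b + (size_t) B * k;
        double lk = buf.l[k];
        Sa_re[idx] += lk * wre;
        Sa_im[idx] += lk * wim;
        double t = -lk;
        if (buf.nsc[k] > 0) {
          if (mus[k] <= 0.0)
            stop("scattering event recorded in an element with mus = 0");
          t += buf.nsc[k] / mus[k];
        }
        Ss_re[idx] += t * wre;
        Ss_im[idx] += t * wim;
      }
    }
  }

  ComplexVector W(B);
  for (int b = 0; b < B; ++b) { W[b].r = Wre[b]; W[b].i = Wim[b]; }
  ComplexVector tot(1);
  tot[0].r = tot_re; tot[0].i = tot_im;
  List res = List::create(
    _["W"] = W,
    _["W2_re"] = wrap(W2re),
    _["W2_im"] = wrap(W2im),
    _["total_exit_weight"] = tot,
    _["n_exit"] = (double) n_exit,
    _["n_terminated"] = (double) n_term,
    _["n_lost"] = (double) n_lost);
  if (record_jacobian) {
    ComplexMatrix Sa(B, K), Ss(B, K);
    for (int k = 0; k < K; ++k) {
      for (int b = 0; b < B; ++b) {
        size_t idx = (size_t) b + (size_t) B * k;
        Sa(b, k) = Rcomplex{Sa_re[idx], Sa_im[idx]};
        Ss(b, k) = Rcomplex{Ss_re[idx], Ss_im[idx]};
      }
    }
    res["S_a"] = Sa;
    res["S_s"] = Ss;
  }
  if (do_pert) {
    ComplexVector Wp(B);
    for (int b = 0; b < B; ++b) { Wp[b].r = Wp_re[b]; Wp[b].i = Wp_im[b]; }
    res["W_pert"] = Wp;
  }
  return res;
}

// ---------------------------------------------------------------------------
// Single-packet propagation with full path record (for validation)

// [[Rcpp::export]]
List cpp_propagate_one(NumericMatrix nodes, IntegerMatrix tri,
                       IntegerMatrix adj, double mesh_scale,
                       NumericVector mua, NumericVector mus, double g,
                       double omega_over_c, double w0, double term_threshold,
                       int start_tri, NumericVector start_pos,
                       NumericVector start_dir, double seed,
                       double max_steps) {
  MeshView m(nodes, tri, adj, mesh_scale);
  PathBuf buf(m.K);
  PacketOutcome out;
  Xoshiro256p rng;
  seed_packet(rng, (uint64_t) seed, 0, 0);
  const double term_log =
    (term_threshold > 0.0) ? -std::log(term_threshold) : R_PosInf;
  double nd = std::sqrt(start_dir[0] * start_dir[0] + start_dir[1] * start_dir[1]);
  propagate(m, REAL(mua), REAL(mus), g, term_log, (long) max_steps, rng,
            start_tri, start_pos[0], start_pos[1],
            start_dir[0] / nd, start_dir[1] / nd, buf, out);
  int nv = buf.visited.size();
  IntegerVector elems(nv), nsc(nv);
  NumericVector lens(nv);
  for (int i = 0; i < nv; ++i) {
    int k = buf.visited[i];
    elems[i] = k + 1;
    lens[i] = buf.l[k];
    nsc[i] = buf.nsc[k];
  }
  double amp = w0 * std::exp(-out.mua_len);
  double ph = -omega_over_c * out.s_tot;
  ComplexVector w(1);
  w[0].r = amp * std::cos(ph);
  w[0].i = amp * std::sin(ph);
  return List::create(
    _["elements"] = elems, _["lengths"] = lens, _["n_scatter"] = nsc,
    _["s_tot"] = out.s_tot, _["mua_len"] = out.mua_len,
    _["w"] = w,
    _["exited"] = out.exited, _["terminated"] = out.terminated,
    _["lost"] = out.lost,
    _["exit_point"] = NumericVector::create(out.exit_x, out.exit_y),
    _["exit_tri"] = out.exit_tri + 1, _["exit_edge"] = out.exit_edge + 1,
    _["steps"] = (double) out.steps);
}

// ---------------------------------------------------------------------------
// March a ray to a given optical depth (free-path sampling across a
// piecewise-constant medium): returns the scattering site or the boundary
// exit, with all element crossings.

// [[Rcpp::export]]
List cpp_trace_to_depth(NumericMatrix nodes, IntegerMatrix tri,
                        IntegerMatrix adj, double mesh_scale,
                        NumericVector mus, int start_tri,
                        NumericVector start_pos, NumericVector start_dir,
                        double depth, double max_steps) {
  MeshView m(nodes, tri, adj, mesh_scale);
  double nd = std::sqrt(start_dir[0] * start_dir[0] + start_dir[1] * start_dir[1]);
  double dx = start_dir[0] / nd, dy = start_dir[1] / nd;
  double px = start_pos[0], py = start_pos[1];
  int k = start_tri;
  std::vector<int> elems;
  std::vector<double> lens;
  double remaining = depth, s_tot = 0.0;
  long steps = 0;
  bool scattered = false, exited = false;
  int exit_tri = -1, exit_edge = -1;
  for (;;) {
    if (++steps > (long) max_steps)
      stop("ray failed to advance (geometric degeneracy) at element %d", k + 1);
    double s_exit;
    int edge = find_exit(m, k, px, py, dx, dy, s_exit);
    if (edge < 0 || !R_finite(s_exit))
      stop("ray failed to advance (geometric degeneracy) at element %d", k + 1);
    double msk = mus[k];
    if (msk > 0.0 && msk * s_exit >= remaining) {
      double dl = remaining / msk;
      px += dl * dx; py += dl * dy;
      elems.push_back(k + 1); lens.push_back(dl);
      s_tot += dl;
      scattered = true;
      break;
    }
    elems.push_back(k + 1); lens.push_back(s_exit);
    s_tot += s_exit;
    remaining -= msk * s_exit;
    px += s_exit * dx; py += s_exit * dy;
    int nb = m.adj(k, edge);
    if (nb < 0) { exited = true; exit_tri = k; exit_edge = edge; break; }
    k = nb;
    px += m.nudge * dx; py += m.nudge * dy;
  }
  return List::create(
    _["scattered"] = scattered, _["exited"] = exited,
    _["site"] = NumericVector::create(px, py),
    _["elements"] = wrap(elems), _["lengths"] = wrap(lens),
    _["s_tot"] = s_tot, _["element"] = k + 1,
    _["exit_tri"] = exit_tri + 1, _["exit_edge"] = exit_edge + 1);
}
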