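// Forward Monte-Carlo spectral photon transport in a triangle-soup canopy.
//
// Analog per-bin transport: each ray carries the full emitted power of one
// spectral bin (bin chosen from the source spectrum), interaction events
// are sampled from the exact per-bin probabilities, and every ray's weight
// ends in exactly one ledger bucket (leaf / stem / ground absorption,
// escape, or depth truncation), so the per-bin energy ledger closes to
// floating precision for every run.  Paired runs (Phong vs diffuse,
// reflections on vs off) with the same seed share ray origins, bins and
// event draws until their physics first diverges, which is what makes the
// paired comparisons of the study statistically efficient.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
// splitmix64: tiny, seedable, independent stream per ray.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// ---------------------------------------------------------------- vec ------
struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
  V3 operator+(const V3 &o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator-(const V3 &o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator*(double k) const { return V3(x * k, y * k, z * k); }
};
static inline double dot(const V3 &a, const V3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x);
}
static inline V3 normalize(const V3 &a) {
  double l = std::sqrt(dot(a, a));
  return V3(a.x / l, a.y / l, a.z / l);
}

// orthonormal basis around unit w
static inline void basis(const V3 &w, V3 &t1, V3 &t2) {
  V3 a = (std::fabs(w.z) < 0.9) ? V3(0, 0, 1) : V3(1, 0, 0);
  t1 = normalize(a - w * dot(a, w));
  t2 = cross(w, t1);
}

static inline V3 cosine_hemisphere(Rng &rng, const V3 &n) {
  double u1 = rng.unif(), u2 = rng.unif();
  double r = std::sqrt(u1), ph = 2.0 * M_PI * u2;
  V3 t1, t2;
  basis(n, t1, t2);
  return t1 * (r * std::cos(ph)) + t2 * (r * std::sin(ph)) +
         n * std::sqrt(std::max(0.0, 1.0 - u1));
}

// ---------------------------------------------------------------- BVH -----
struct Tri {
  V3 a, e1, e2, n; // n = geometric normal (unit), winding = adaxial side
  int plant, organ, order;  // organ: 0 leaf, 1 stem
};

struct BvhNode {
  V3 lo, hi;
  int left, right;   // children, or -1 for leaf
  int start, count;  // triangle range for leaves
};

struct Bvh {
  std::vector<Tri> tris;
  std::vector<int> order; // triangle permutation
  std::vector<BvhNode> nodes;

  void grow(V3 &lo, V3 &hi, const V3 &p) {
    lo.x = std::min(lo.x, p.x); lo.y = std::min(lo.y, p.y);
    lo.z = std::min(lo.z, p.z);
    hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y);
    hi.z = std::max(hi.z, p.z);
  }

  int build(std::vector<V3> &cent, int start, int count) {
    BvhNode nd;
    nd.lo = V3(1e300, 1e300, 1e300);
    nd.hi = V3(-1e300, -1e300, -1e300);
    for (int i = start; i < start + count; ++i) {
      const Tri &t = tris[order[i]];
      grow(nd.lo, nd.hi, t.a);
      grow(nd.lo, nd.hi, t.a + t.e1);
      grow(nd.lo, nd.hi, t.a + t.e2);
    }
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 4) {
      nodes[id].left = nodes[id].right = -1;
      nodes[id].start = start;
      nodes[id].count = count;
      return id;
    }
    V3 ext = nd.hi - nd.lo;
    int ax = 0;
    if (ext.y > ext.x) ax = 1;
    if (ext.z > (ax == 0 ? ext.x : ext.y)) ax = 2;
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count,
                     [&](int a, int b) {
                       double ca = ax == 0 ? cent[a].x : (ax == 1 ? cent[a].y : cent[a].z);
                       double cb = ax == 0 ? cent[b].x : (ax == 1 ? cent[b].y : cent[b].z);
                       return ca < cb;
                     });
    int l = build(cent, start, mid - start);
    int r = build(cent, mid, start + count - mid);
    nodes[id].left = l;
    nodes[id].right = r;
    nodes[id].start = -1;
    nodes[id].count = 0;
    return id;
  }

  void init(const NumericMatrix &verts, const IntegerMatrix &faces,
            const IntegerMatrix &tags) {
    int m = faces.nrow();
    tris.resize(m);
    order.resize(m);
    std::vector<V3> cent(m);
    for (int i = 0; i < m; ++i) {
      V3 a(verts(faces(i, 0), 0), verts(faces(i, 0), 1), verts(faces(i, 0), 2));
      V3 b(verts(faces(i, 1), 0), verts(faces(i, 1), 1), verts(faces(i, 1), 2));
      V3 c(verts(faces(i, 2), 0), verts(faces(i, 2), 1), verts(faces(i, 2), 2));
      tris[i].a = a;
      tris[i].e1 = b - a;
      tris[i].e2 = c - a;
      tris[i].n = normalize(cross(tris[i].e1, tris[i].e2));
      tris[i].plant = tags(i, 0);
      tris[i].organ = tags(i, 1);
      tris[i].order = tags(i, 2);
      order[i] = i;
      cent[i] = a + (tris[i].e1 + tris[i].e2) * (1.0 / 3.0);
    }
    nodes.clear();
    nodes.reserve(2 * m);
    if (m > 0) build(cent, 0, m);
  }

  static bool hit_tri(const Tri &t, const V3 &o, const V3 &d,
                      double tmax, double &tout) {
    // Moller-Trumbore, two-sided
    V3 p = cross(d, t.e2);
    double det = dot(t.e1, p);
    if (std::fabs(det) < 1e-14) return false;
    double inv = 1.0 / det;
    V3 s = o - t.a;
    double u = dot(s, p) * inv;
    if (u < -1e-9 || u > 1.0 + 1e-9) return false;
    V3 q = cross(s, t.e1);
    double v = dot(d, q) * inv;
    if (v < -1e-9 || u + v > 1.0 + 1e-9) return false;
    double tt = dot(t.e2, q) * inv;
    if (tt <= 1e-7 || tt >= tmax) return false;
    tout = tt;
    return true;
  }

  static bool hit_box(const V3 &lo, const V3 &hi, const V3 &o,
                      const V3 &inv, double tmax) {
    double t0 = (lo.x - o.x) * inv.x, t1 = (hi.x - o.x) * inv.x;
    if (t0 > t1) std::swap(t0, t1);
    double tmin = t0, tmx = t1;
    t0 = (lo.y - o.y) * inv.y; t1 = (hi.y - o.y) * inv.y;
    if (t0 > t1) std::swap(t0, t1);
    tmin = std::max(tmin, t0); tmx = std::min(tmx, t1);
    t0 = (lo.z - o.z) * inv.z; t1 = (hi.z - o.z) * inv.z;
    if (t0 > t1) std::swap(t0, t1);
    tmin = std::max(tmin, t0); tmx = std::min(tmx, t1);
    return tmx >= std::max(tmin, 0.0) && tmin < tmax;
  }

  // returns triangle index or -1; thit updated
  int intersect(const V3 &o, const V3 &d, double &thit) const {
    if (nodes.empty()) return -1;
    V3 inv(1.0 / (d.x == 0 ? 1e-300 : d.x),
           1.0 / (d.y == 0 ? 1e-300 : d.y),
           1.0 / (d.z == 0 ? 1e-300 : d.z));
    int stack[64];
    int sp = 0;
    stack[sp++] = 0;
    int best = -1;
    while (sp > 0) {
      int id = stack[--sp];
      const BvhNode &nd = nodes[id];
      if (!hit_box(nd.lo, nd.hi, o, inv, thit)) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          double tt;
          if (hit_tri(tris[order[i]], o, d, thit, tt)) {
            thit = tt;
            best = order[i];
          }
        }
      } else {
        stack[sp++] = nd.left;
        stack[sp++] = nd.right;
      }
    }
    return best;
  }

  int intersect_brute(const V3 &o, const V3 &d, double &thit) const {
    int best = -1;
    for (size_t i = 0; i < tris.size(); ++i) {
      double tt;
      if (hit_tri(tris[i], o, d, thit, tt)) {
        thit = tt;
        best = (int)i;
      }
    }
    return best;
  }
};

// ------------------------------------------------------------- optics -----
struct SideOptics {
  // per bin: kd, ks, n_exp, tau (phong) or rho in kd / tau (diffuse)
  std::vector<double> kd, ks, nexp, tau;
  // above-horizon lobe energy fraction A(n_b, theta_i), theta_i = 0..90 deg
  std::vector<double> atab; // nbins x 91, row-major per bin
  bool diffuse;
  double A(int b, double theta_deg) const {
    if (diffuse) return 1.0;
    double t = std::min(std::max(theta_deg, 0.0), 90.0);
    int i = (int)t;
    if (i >= 90) return atab[b * 91 + 90];
    double f = t - i;
    return atab[b * 91 + i] * (1 - f) + atab[b * 91 + i + 1] * f;
  }
};

static SideOptics make_side(const NumericMatrix &m, const NumericMatrix &atab,
                            bool diffuse) {
  SideOptics s;
  s.diffuse = diffuse;
  int B = m.nrow();
  s.kd.resize(B); s.ks.resize(B); s.nexp.resize(B); s.tau.resize(B);
  for (int b = 0; b < B; ++b) {
    s.kd[b] = m(b, 0);
    s.ks[b] = diffuse ? 0.0 : m(b, 1);
    s.nexp[b] = diffuse ? 0.0 : m(b, 2);
    s.tau[b] = diffuse ? m(b, 1) : m(b, 3);
  }
  if (!diffuse) {
    s.atab.resize(B * 91);
    for (int b = 0; b < B; ++b)
      for (int j = 0; j <= 90; ++j) s.atab[b * 91 + j] = atab(b, j);
  }
  return s;
}

// sample outgoing direction of the specular branch: density proportional to
// cos(alpha)^n * cos(theta_o) above the horizon (rejection from the bare
// lobe with acceptance cos(theta_o)).
static bool sample_lobe(Rng &rng, const V3 &m, const V3 &nrm, double nexp,
                        V3 &out) {
  V3 t1, t2;
  basis(m, t1, t2);
  for (int k = 0; k < 256; ++k) {
    double ca = std::pow(rng.unif(), 1.0 / (nexp + 1.0));
    double sa = std::sqrt(std::max(0.0, 1.0 - ca * ca));
    double ph = 2.0 * M_PI * rng.unif();
    V3 d = t1 * (sa * std::cos(ph)) + t2 * (sa * std::sin(ph)) + m * ca;
    double cz = dot(d, nrm);
    if (cz > 0 && rng.unif() < cz) {
      out = d;
      return true;
    }
  }
  return false; // vanishing lobe mass above horizon: treat as absorbed
}

// ------------------------------------------------------------- sensors ----
struct Sensor {
  V3 c, n; // center, facing direction (unit)
  double r2, inv_area;
};

// --------------------------------------------------------------- trace ----

// [[Rcpp::export]]
List trace_cpp(NumericMatrix verts, IntegerMatrix faces, IntegerMatrix tags,
               int n_plants, double ground_radius,
               NumericMatrix optics_ad, NumericMatrix optics_ab,
               NumericMatrix atab_ad, NumericMatrix atab_ab,
               bool diffuse_mode, double stem_reflectance,
               NumericMatrix source_dirs, NumericVector source_power,
               NumericVector spectrum,
               NumericMatrix sensor_mat,
               double n_rays, int max_depth, int scatter_mode,
               double seed) {
  // scatter_mode: 0 = full transport; 1 = reflection disabled (diffuse
  // transmission still active); 2 = every path ends at its first surface
  // interaction; 3 = at most one reflection per path (transmission
  // unrestricted): the "without multiple reflection" comparison run.
  if (faces.nrow() == 0 && sensor_mat.nrow() == 0)
    stop("empty scene: no geometry and no sensors");
  if (n_rays < 1) stop("n_rays must be >= 1");
  if (max_depth < 1) stop("max_depth must be >= 1");

  Bvh bvh;
  bvh.init(verts, faces, tags);

  int B = spectrum.size();
  SideOptics side[2] = {make_side(optics_ad, atab_ad, diffuse_mode),
                        make_side(optics_ab, atab_ab, diffuse_mode)};

  // bounding sphere of geometry plus sensors (emission disk circumscribes
  // it; the black ground outside the beam footprint absorbs nothing by
  // construction, so restricting emission to this sphere is exact)
  V3 lo(1e300, 1e300, 1e300), hi(-1e300, -1e300, -1e300);
  if (!bvh.nodes.empty()) { lo = bvh.nodes[0].lo; hi = bvh.nodes[0].hi; }
  for (int k = 0; k < sensor_mat.nrow(); ++k) {
    double r = sensor_mat(k, 6);
    lo.x = std::min(lo.x, sensor_mat(k, 0) - r);
    lo.y = std::min(lo.y, sensor_mat(k, 1) - r);
    lo.z = std::min(lo.z, sensor_mat(k, 2) - r);
    hi.x = std::max(hi.x, sensor_mat(k, 0) + r);
    hi.y = std::max(hi.y, sensor_mat(k, 1) + r);
    hi.z = std::max(hi.z, sensor_mat(k, 2) + r);
  }
  V3 cen = (lo + hi) * 0.5;
  double rad = std::sqrt(dot(hi - cen, hi - cen)) * 1.05 + 0.01;

  int S = source_dirs.nrow();
  double disk_area = M_PI * rad * rad;
  std::vector<double> cdf_src(S);
  double ptot = 0;
  for (int s = 0; s < S; ++s) {
    ptot += source_power[s] * disk_area; // power through emission disk
    cdf_src[s] = ptot;
  }
  std::vector<double> cdf_bin(B);
  double btot = 0;
  for (int b = 0; b < B; ++b) { btot += spectrum[b]; cdf_bin[b] = btot; }
  for (int b = 0; b < B; ++b) cdf_bin[b] /= btot;

  int K = sensor_mat.nrow();
  std::vector<Sensor> sensors(K);
  for (int k = 0; k < K; ++k) {
    sensors[k].c = V3(sensor_mat(k, 0), sensor_mat(k, 1), sensor_mat(k, 2));
    sensors[k].n = normalize(V3(sensor_mat(k, 3), sensor_mat(k, 4),
                                sensor_mat(k, 5)));
    double r = sensor_mat(k, 6);
    sensors[k].r2 = r * r;
    sensors[k].inv_area = 1.0 / (M_PI * r * r);
  }

  // tallies
  std::vector<double> leaf_abs((size_t)n_plants * 5 * B, 0.0);
  std::vector<double> stem_abs((size_t)n_plants * B, 0.0);
  std::vector<double> ground_abs(B, 0.0), escaped(B, 0.0),
      truncated(B, 0.0), emitted(B, 0.0);
  std::vector<double> sens((size_t)K * B, 0.0);

  uint64_t useed = (uint64_t)seed;
  long N = (long)n_rays;
  double w = ptot / (double)N;

  for (long i = 0; i < N; ++i) {
    Rng rng(useed * 0x2545F4914F6CDD1DULL + (uint64_t)i * 0x9E3779B97F4A7C15ULL);
    // systematic source allocation by power
    double x = ((double)i + 0.5) / (double)N * ptot;
    int s = (int)(std::lower_bound(cdf_src.begin(), cdf_src.end(), x) -
                  cdf_src.begin());
    if (s >= S) s = S - 1;
    // spectral bin from the source spectrum
    double ub = rng.unif();
    int b = (int)(std::lower_bound(cdf_bin.begin(), cdf_bin.end(), ub) -
                  cdf_bin.begin());
    if (b >= B) b = B - 1;
    emitted[b] += w;

    V3 d(source_dirs(s, 0), source_dirs(s, 1), source_dirs(s, 2));
    V3 t1, t2;
    basis(d, t1, t2);
    double rr = rad * std::sqrt(rng.unif());
    double ph = 2.0 * M_PI * rng.unif();
    V3 o = cen - d * (2.0 * rad) + t1 * (rr * std::cos(ph)) +
           t2 * (rr * std::sin(ph));

    bool alive = true;
    int n_refl = 0;
    for (int depth = 1; alive; ++depth) {
      double thit = 1e300;
      int tri = bvh.intersect(o, d, thit);
      // ground disk at z = 0
      bool ground = false;
      if (d.z < -1e-14) {
        double tg = -o.z / d.z;
        if (tg > 1e-7 && tg < thit) {
          double gx = o.x + tg * d.x, gy = o.y + tg * d.y;
          if (gx * gx + gy * gy <= ground_radius * ground_radius) {
            ground = true;
            thit = tg;
            tri = -1;
          }
        }
      }
      // sensor crossings along this segment
      for (int k = 0; k < K; ++k) {
        double den = dot(d, sensors[k].n);
        if (den >= -1e-12) continue; // only from the facing side
        double t = dot(sensors[k].c - o, sensors[k].n) / den;
        if (t <= 1e-7 || t >= thit) continue;
        V3 p = o + d * t - sensors[k].c;
        if (dot(p, p) <= sensors[k].r2)
          sens[(size_t)k * B + b] += w * sensors[k].inv_area;
      }
      if (tri < 0 && !ground) { escaped[b] += w; break; }
      if (ground) { ground_abs[b] += w; break; }

      const Tri &t = bvh.tris[tri];
      V3 hitp = o + d * thit;
      if (t.organ == 1) { // stem: broadband diffuse, non-transmitting
        V3 nl = (dot(d, t.n) < 0) ? t.n : t.n * -1.0;
        double u = rng.unif();
        bool stem_ok = depth < max_depth &&
          (scatter_mode == 0 || (scatter_mode == 3 && n_refl == 0));
        if (u < stem_reflectance && stem_ok) {
          ++n_refl;
          d = cosine_hemisphere(rng, nl);
          o = hitp + nl * 1e-7;
          continue;
        } else if (u < stem_reflectance) {
          truncated[b] += w;  // reflection suppressed or depth exhausted
          break;
        } else {
          stem_abs[(size_t)(t.plant - 1) * B + b] += w;
          break;
        }
      }
      // leaf: struck side from the face orientation
      int sd = (dot(d, t.n) < 0) ? 0 : 1; // 0 adaxial, 1 abaxial
      V3 nl = (sd == 0) ? t.n : t.n * -1.0;
      const SideOptics &op = side[sd];
      double cos_i = -dot(d, nl);
      if (cos_i < 1e-9) cos_i = 1e-9;
      double theta_i = std::acos(std::min(1.0, cos_i)) * 180.0 / M_PI;
      double p_d = op.kd[b];
      double p_s = op.diffuse ? 0.0 : op.ks[b] * op.A(b, theta_i);
      double p_t = op.tau[b];
      double u = rng.unif();
      int ev; // 0 diffuse refl, 1 specular refl, 2 transmit, 3 absorb
      if (u < p_d) ev = 0;
      else if (u < p_d + p_s) ev = 1;
      else if (u < p_d + p_s + p_t) ev = 2;
      else ev = 3;
      if (ev == 3) {
        leaf_abs[((size_t)(t.plant - 1) * 5 + (t.order - 1)) * B + b] += w;
        break;
      }
      bool allowed = depth < max_depth &&
        (scatter_mode == 0 ||
         (scatter_mode == 1 && ev == 2) ||
         (scatter_mode == 3 && (ev == 2 || n_refl == 0)));
      if (!allowed) {
        truncated[b] += w; // scattering suppressed / depth exhausted
        break;
      }
      if (ev == 0 || ev == 1) ++n_refl;
      if (ev == 0) {
        d = cosine_hemisphere(rng, nl);
        o = hitp + nl * 1e-7;
      } else if (ev == 1) {
        V3 wi = d * -1.0;
        V3 m = nl * (2.0 * dot(wi, nl)) - wi;
        V3 out;
        if (!sample_lobe(rng, m, nl, op.nexp[b], out)) {
          leaf_abs[((size_t)(t.plant - 1) * 5 + (t.order - 1)) * B + b] += w;
          break;
        }
        d = out;
        o = hitp + nl * 1e-7;
      } else {
        V3 nt = nl * -1.0;
        d = cosine_hemisphere(rng, nt);
        o = hitp + nt * 1e-7;
      }
    }
  }

  return List::create(
      _["leaf_abs"] = NumericVector(leaf_abs.begin(), leaf_abs.end()),
      _["stem_abs"] = NumericVector(stem_abs.begin(), stem_abs.end()),
      _["ground"] = NumericVector(ground_abs.begin(), ground_abs.end()),
      _["escaped"] = NumericVector(escaped.begin(), escaped.end()),
      _["truncated"] = NumericVector(truncated.begin(), truncated.end()),
      _["emitted"] = NumericVector(emitted.begin(), emitted.end()),
      _["sensors"] = NumericVector(sens.begin(), sens.end()));
}

// Nearest-hit intersection of arbitrary rays, with BVH or brute force.
// Exposed for the traversal-equivalence oracle test.
// [[Rcpp::export]]
List intersect_rays_cpp(NumericMatrix verts, IntegerMatrix faces,
                        NumericMatrix origins, NumericMatrix dirs,
                        bool brute) {
  IntegerMatrix tags(faces.nrow(), 3);
  Bvh bvh;
  bvh.init(verts, faces, tags);
  int n = origins.nrow();
  IntegerVector tri(n);
  NumericVector tt(n);
  for (int i = 0; i < n; ++i) {
    V3 o(origins(i, 0), origins(i, 1), origins(i, 2));
    V3 d = normalize(V3(dirs(i, 0), dirs(i, 1), dirs(i, 2)));
    double thit = 1e300;
    int id = brute ? bvh.intersect_brute(o, d, thit)
                   : bvh.intersect(o, d, thit);
    tri[i] = id < 0 ? NA_INTEGER : id + 1;
    tt[i] = id < 0 ? NA_REAL : thit;
  }
  return List::create(_["tri"] = tri, _["t"] = tt);
}
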