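// Coarse-grained Brownian-dynamics core for SV docking at the AZ membrane.
// Units: nm, ns, pN (energies in pN nm). Membranes are triangulated meshes
// with two particles per thickness; bending is a dihedral potential
// lambda * (1 - cos(theta - theta0)) with lambda = 2*sqrt(3)*kappa (sphere-
// exact mapping for near-equilateral triangulations). The patch is periodic
// in x and y (minimum image on all pair vectors).

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

struct Box { double Lx, Ly; bool periodic; };

// Counter-based thermal-noise stream: each (step, particle, axis) deviate
// is a pure hash of the run seed (drawn once from R's uniform stream, so
// set.seed reproduces runs), making the noise of a given particle
// independent of how many other particles exist - systems differing only
// in appended particles share identical noise on the common ones (common
// random numbers across simulation arms).
struct NoiseGen {
  uint64_t seed = 0;
  void seed_from_R() {
    seed = (uint64_t)(unif_rand() * 9007199254740992.0) * 2862933555777941757ULL
           + 3037000493ULL;
  }
  static inline uint64_t mix(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
  }
  // all three axis deviates of one particle-step from two Box-Muller pairs
  inline void norm3(long long step, int particle, double* out) {
    uint64_t key = seed ^ mix(0x9E3779B97F4A7C15ULL * (uint64_t)step
                              ^ (uint64_t)particle);
    uint64_t a = mix(key);
    uint64_t b = mix(key ^ 0xD1B54A32D192ED03ULL);
    uint64_t c = mix(key ^ 0x8CB92BA72F3D8DD7ULL);
    double u1 = ((a >> 11) + 0.5) * 1.1102230246251565e-16;
    double u2 = (b >> 11) * 1.1102230246251565e-16;
    double u3 = ((c >> 11) + 0.5) * 1.1102230246251565e-16;
    double r1 = std::sqrt(-2.0 * std::log(u1));
    double ang = 6.283185307179586 * u2;
    out[0] = r1 * std::cos(ang);
    out[1] = r1 * std::sin(ang);
    out[2] = std::sqrt(-2.0 * std::log(u3)) *
             std::cos(6.283185307179586 * ((a & 0x7FF) / 2048.0));
  }
};

static inline void minimg(double* d, const Box& box) {
  if (!box.periodic) return;
  if (std::fabs(d[0]) > 0.5 * box.Lx)
    d[0] -= box.Lx * std::round(d[0] / box.Lx);
  if (std::fabs(d[1]) > 0.5 * box.Ly)
    d[1] -= box.Ly * std::round(d[1] / box.Ly);
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

struct System {
  int n;
  std::vector<double> pos;            // 3n
  std::vector<int> comp;              // component codes
  std::vector<int> body;              // rigid-exclusion group per particle
  // bonds
  std::vector<int> b_i, b_j; std::vector<double> b_rest, b_k;
  std::vector<int> b_type;
  // dihedrals (torsion order k,i,j,l with shared edge i-j)
  std::vector<int> q1, q2, q3, q4;
  std::vector<double> lambda, theta0, cos0, sin0;
  void set_theta0(int q, double val) {
    theta0[q] = val; cos0[q] = std::cos(val); sin0[q] = std::sin(val);
  }
  // volume (SV outer faces)
  std::vector<int> f1, f2, f3;
  double V0, kV;
  // repulsion
  double rep_k, rep_cut;
  // snare attraction pairs
  std::vector<int> s_i, s_j; double s_eps, s_rc;
  // tethers (angle term)
  std::vector<int> t_sv, t_anchor; double t_kang; bool t_active;
  Box box;
  std::unordered_set<long long> bonded;
  // Verlet pair list (cross-body, non-bonded) with skin
  std::vector<int> vp_i, vp_j;
  std::vector<double> vref;            // positions at last rebuild
  double vskin = 2.0;
  bool vlist_valid = false;

  long long pairkey(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (long long)i * n + j;
  }
};

static System make_system(List sys) {
  System S;
  NumericMatrix pos = sys["pos"];
  S.n = pos.nrow();
  S.pos.resize(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) S.pos[3 * i + d] = pos(i, d);
  S.comp = as<std::vector<int>>(sys["comp"]);
  S.body = as<std::vector<int>>(sys["body"]);
  NumericMatrix bonds = sys["bonds"];
  for (int b = 0; b < bonds.nrow(); ++b) {
    S.b_i.push_back((int)bonds(b, 0)); S.b_j.push_back((int)bonds(b, 1));
    S.b_rest.push_back(bonds(b, 2)); S.b_k.push_back(bonds(b, 3));
    S.b_type.push_back((int)bonds(b, 4));
  }
  IntegerMatrix quads = sys["quads"];
  for (int q = 0; q < quads.nrow(); ++q) {
    S.q1.push_back(quads(q, 0)); S.q2.push_back(quads(q, 1));
    S.q3.push_back(quads(q, 2)); S.q4.push_back(quads(q, 3));
  }
  S.lambda = as<std::vector<double>>(sys["lambda"]);
  S.theta0 = as<std::vector<double>>(sys["theta0"]);
  S.cos0.resize(S.theta0.size()); S.sin0.resize(S.theta0.size());
  for (size_t q = 0; q < S.theta0.size(); ++q) {
    S.cos0[q] = std::cos(S.theta0[q]); S.sin0[q] = std::sin(S.theta0[q]);
  }
  IntegerMatrix faces = sys["faces"];
  for (int f = 0; f < faces.nrow(); ++f) {
    S.f1.push_back(faces(f, 0)); S.f2.push_back(faces(f, 1));
    S.f3.push_back(faces(f, 2));
  }
  S.V0 = as<double>(sys["V0"]); S.kV = as<double>(sys["kV"]);
  S.rep_k = as<double>(sys["rep_k"]); S.rep_cut = as<double>(sys["rep_cut"]);
  IntegerMatrix sp = sys["snare_pairs"];
  for (int s = 0; s < sp.nrow(); ++s) {
    S.s_i.push_back(sp(s, 0)); S.s_j.push_back(sp(s, 1));
  }
  S.s_eps = as<double>(sys["snare_eps"]); S.s_rc = as<double>(sys["snare_rc"]);
  IntegerMatrix te = sys["tethers"];
  for (int t = 0; t < te.nrow(); ++t) {
    S.t_sv.push_back(te(t, 0)); S.t_anchor.push_back(te(t, 1));
  }
  S.t_kang = as<double>(sys["tether_kang"]);
  S.t_active = as<bool>(sys["tether_active"]);
  NumericVector bx = sys["box"];
  S.box = { bx[0], bx[1], as<bool>(sys["periodic"]) };
  for (size_t b = 0; b < S.b_i.size(); ++b)
    S.bonded.insert(S.pairkey(S.b_i[b], S.b_j[b]));
  return S;
}

// sin/cos of the signed dihedral deviation from flat, without
// transcendentals; fills dtheta/dx if grad != null
static void dihedral_sincos(const System& S, int q, double* sc,
                            double* grad) {
  const double* x1 = &S.pos[3 * S.q1[q]];
  const double* x2 = &S.pos[3 * S.q2[q]];
  const double* x3 = &S.pos[3 * S.q3[q]];
  const double* x4 = &S.pos[3 * S.q4[q]];
  double b1[3], b2[3], b3[3];
  for (int d = 0; d < 3; ++d) {
    b1[d] = x2[d] - x1[d]; b2[d] = x3[d] - x2[d]; b3[d] = x4[d] - x3[d];
  }
  minimg(b1, S.box); minimg(b2, S.box); minimg(b3, S.box);
  double n1[3], n2[3], m1[3];
  cross3(b1, b2, n1); cross3(b2, b3, n2);
  double lb2 = norm3(b2);
  double ln1 = dot3(n1, n1), ln2 = dot3(n2, n2);
  if (lb2 < 1e-12 || ln1 < 1e-14 || ln2 < 1e-14) {
    sc[0] = 0.0; sc[1] = 1.0;
    if (grad) std::fill(grad, grad + 12, 0.0);
    return;
  }
  cross3(n1, n2, m1);
  double nn = std::sqrt(ln1 * ln2);
  // phi = atan2(m1.b2/lb2, n1.n2); theta = pi - phi:
  // sin(theta) = sin(phi), cos(theta) = -cos(phi)
  sc[0] = dot3(m1, b2) / (lb2 * nn);   // sin theta
  sc[1] = -dot3(n1, n2) / nn;          // cos theta
  if (grad) {
    double g1[3], g4[3];
    for (int d = 0; d < 3; ++d) {
      g1[d] = -lb2 / ln1 * n1[d];          // dphi/dx1
      g4[d] = lb2 / ln2 * n2[d];           // dphi/dx4
    }
    double c12 = dot3(b1, b2) / (lb2 * lb2);
    double c32 = dot3(b3, b2) / (lb2 * lb2);
    for (int d = 0; d < 3; ++d) {
      double g2 = -(c12 + 1.0) * g1[d] + c32 * g4[d];
      double g3 = -(c32 + 1.0) * g4[d] + c12 * g1[d];
      grad[0 + d] = -g1[d]; grad[3 + d] = -g2;
      grad[6 + d] = -g3;    grad[9 + d] = -g4[d];
    }
  }
}

// signed dihedral deviation from flat (diagnostics only)
static double dihedral_theta(const System& S, int q, double* grad) {
  const double* x1 = &S.pos[3 * S.q1[q]];
  const double* x2 = &S.pos[3 * S.q2[q]];
  const double* x3 = &S.pos[3 * S.q3[q]];
  const double* x4 = &S.pos[3 * S.q4[q]];
  double b1[3], b2[3], b3[3];
  for (int d = 0; d < 3; ++d) {
    b1[d] = x2[d] - x1[d]; b2[d] = x3[d] - x2[d]; b3[d] = x4[d] - x3[d];
  }
  minimg(b1, S.box); minimg(b2, S.box); minimg(b3, S.box);
  double n1[3], n2[3], m1[3];
  cross3(b1, b2, n1); cross3(b2, b3, n2);
  double lb2 = norm3(b2);
  if (lb2 < 1e-12) { if (grad) std::fill(grad, grad + 12, 0.0); return 0.0; }
  cross3(n1, n2, m1);
  double phi = std::atan2(dot3(m1, b2) / lb2, dot3(n1, n2));
  double theta = M_PI - phi;
  if (theta > M_PI) theta -= 2 * M_PI;
  if (theta <= -M_PI) theta += 2 * M_PI;
  if (grad) {
    double ln1 = dot3(n1, n1), ln2 = dot3(n2, n2);
    if (ln1 < 1e-14 || ln2 < 1e-14) { std::fill(grad, grad + 12, 0.0); return theta; }
    double g1[3], g4[3];
    for (int d = 0; d < 3; ++d) {
      g1[d] = -lb2 / ln1 * n1[d];          // dphi/dx1
      g4[d] = lb2 / ln2 * n2[d];           // dphi/dx4
    }
    double c12 = dot3(b1, b2) / (lb2 * lb2);
    double c32 = dot3(b3, b2) / (lb2 * lb2);
    // dphi/dx2 = -(c12 + 1) g1 + c32 g4 ; dphi/dx3 = -(c32 + 1) g4 + c12 g1
    for (int d = 0; d < 3; ++d) {
      double g2 = -(c12 + 1.0) * g1[d] + c32 * g4[d];
      double g3 = -(c32 + 1.0) * g4[d] + c12 * g1[d];
      // dtheta = -dphi
      grad[0 + d] = -g1[d]; grad[3 + d] = -g2;
      grad[6 + d] = -g3;    grad[9 + d] = -g4[d];
    }
  }
  return theta;
}

static double sv_volume(const System& S, std::vector<double>* grad) {
  double V = 0.0;
  if (grad) std::fill(grad->begin(), grad->end(), 0.0);
  for (size_t f = 0; f < S.f1.size(); ++f) {
    const double* a = &S.pos[3 * S.f1[f]];
    const double* b = &S.pos[3 * S.f2[f]];
    const double* c = &S.pos[3 * S.f3[f]];
    double bc[3]; cross3(b, c, bc);
    V += dot3(a, bc) / 6.0;
    if (grad) {
      double ca[3], ab[3];
      cross3(c, a, ca); cross3(a, b, ab);
      for (int d = 0; d < 3; ++d) {
        (*grad)[3 * S.f1[f] + d] += bc[d] / 6.0;
        (*grad)[3 * S.f2[f] + d] += ca[d] / 6.0;
        (*grad)[3 * S.f3[f] + d] += ab[d] / 6.0;
      }
    }
  }
  return V;
}

// rebuild the Verlet list via linked cells at range rep_cut + skin
static void build_vlist(System& S) {
  S.vp_i.clear(); S.vp_j.clear();
  double rc = S.rep_cut + S.vskin;
  double xmin = 1e30, ymin = 1e30, zmin = 1e30, zmax = -1e30;
  for (int i = 0; i < S.n; ++i) {
    xmin = std::min(xmin, S.pos[3 * i]);
    ymin = std::min(ymin, S.pos[3 * i + 1]);
    zmin = std::min(zmin, S.pos[3 * i + 2]);
    zmax = std::max(zmax, S.pos[3 * i + 2]);
  }
  int ncx = std::max(1, (int)(S.box.Lx / rc));
  int ncy = std::max(1, (int)(S.box.Ly / rc));
  int ncz = std::max(1, (int)((zmax - zmin) / rc) + 1);
  double cx = S.box.Lx / ncx, cy = S.box.Ly / ncy;
  double cz = (zmax - zmin) / ncz + 1e-9;
  // linked-cell list with persistent buffers (no per-step allocation)
  static thread_local std::vector<int> head, nxt;
  int ncell = ncx * ncy * ncz;
  head.assign(ncell, -1);
  nxt.assign(S.n, -1);
  for (int i = 0; i < S.n; ++i) {
    double px = S.pos[3 * i], py = S.pos[3 * i + 1], pz = S.pos[3 * i + 2];
    int ix = (int)std::floor(px / cx); ix = ((ix % ncx) + ncx) % ncx;
    int iy = (int)std::floor(py / cy); iy = ((iy % ncy) + ncy) % ncy;
    int iz = std::min(ncz - 1, std::max(0, (int)((pz - zmin) / cz)));
    int c = (iz * ncy + iy) * ncx + ix;
    nxt[i] = head[c]; head[c] = i;
  }
  double rc2 = rc * rc;
  static thread_local std::vector<int> cix, ciy, ciz;
  cix.resize(S.n); ciy.resize(S.n); ciz.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    double px = S.pos[3 * i], py = S.pos[3 * i + 1];
    int ix = (int)std::floor(px / cx); cix[i] = ((ix % ncx) + ncx) % ncx;
    int iy = (int)std::floor(py / cy); ciy[i] = ((iy % ncy) + ncy) % ncy;
    ciz[i] = std::min(ncz - 1, std::max(0,
              (int)((S.pos[3 * i + 2] - zmin) / cz)));
  }
  for (int i = 0; i < S.n; ++i) {
    for (int dz = -1; dz <= 1; ++dz) {
      int jz = ciz[i] + dz; if (jz < 0 || jz >= ncz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int jy = ciy[i] + dy; jy = ((jy % ncy) + ncy) % ncy;
        for (int dx = -1; dx <= 1; ++dx) {
          int jx = cix[i] + dx; jx = ((jx % ncx) + ncx) % ncx;
          for (int j = head[(jz * ncy + jy) * ncx + jx]; j >= 0;
               j = nxt[j]) {
            if (j <= i || S.body[i] == S.body[j]) continue;
            double d[3];
            for (int dd = 0; dd < 3; ++dd)
              d[dd] = S.pos[3 * i + dd] - S.pos[3 * j + dd];
            minimg(d, S.box);
            double r2 = dot3(d, d);
            if (r2 >= rc2) continue;
            if (S.bonded.count(S.pairkey(i, j))) continue;
            S.vp_i.push_back(i); S.vp_j.push_back(j);
          }
        }
      }
    }
  }
  S.vlist_valid = true;
  S.vref = S.pos;
}

// soft harmonic repulsion between different bodies via the Verlet list
static double repulsion(System& S, std::vector<double>* force) {
  if (S.rep_cut <= 0) return 0.0;
  if (!S.vlist_valid) build_vlist(S);
  double E = 0.0;
  double rc = S.rep_cut, rc2 = rc * rc;
  for (size_t p = 0; p < S.vp_i.size(); ++p) {
    int i = S.vp_i[p], j = S.vp_j[p];
    double d[3];
    for (int dd = 0; dd < 3; ++dd)
      d[dd] = S.pos[3 * i + dd] - S.pos[3 * j + dd];
    minimg(d, S.box);
    double r2 = dot3(d, d);
    if (r2 >= rc2 || r2 < 1e-12) continue;
    double r = std::sqrt(r2);
    double ov = rc - r;
    E += 0.5 * S.rep_k * ov * ov;
    if (force) {
      double fmag = S.rep_k * ov / r;
      for (int dd = 0; dd < 3; ++dd) {
        (*force)[3 * i + dd] += fmag * d[dd];
        (*force)[3 * j + dd] -= fmag * d[dd];
      }
    }
  }
  return E;
}

// total energy and (optionally) forces; returns named breakdown
static NumericVector compute(System& S, std::vector<double>* force) {
  if (force) std::fill(force->begin(), force->end(), 0.0);
  double Ebond = 0, Ebend = 0, Evol = 0, Erep = 0, Esnare = 0, Etether = 0;

  for (size_t b = 0; b < S.b_i.size(); ++b) {
    int i = S.b_i[b], j = S.b_j[b];
    double d[3];
    for (int dd = 0; dd < 3; ++dd)
      d[dd] = S.pos[3 * i + dd] - S.pos[3 * j + dd];
    minimg(d, S.box);
    double r = norm3(d);
    if (r < 1e-12) continue;
    double dr = r - S.b_rest[b];
    Ebond += 0.5 * S.b_k[b] * dr * dr;
    if (force) {
      double fmag = -S.b_k[b] * dr / r;
      for (int dd = 0; dd < 3; ++dd) {
        (*force)[3 * i + dd] += fmag * d[dd];
        (*force)[3 * j + dd] -= fmag * d[dd];
      }
    }
  }

  double grad[12], sc[2];
  for (size_t q = 0; q < S.q1.size(); ++q) {
    dihedral_sincos(S, q, sc, force ? grad : nullptr);
    // E = lambda (1 - cos(theta - theta0))
    Ebend += S.lambda[q] *
      (1.0 - (sc[1] * S.cos0[q] + sc[0] * S.sin0[q]));
    if (force) {
      double dEdth = S.lambda[q] *
        (sc[0] * S.cos0[q] - sc[1] * S.sin0[q]);
      int idx[4] = { S.q1[q], S.q2[q], S.q3[q], S.q4[q] };
      for (int v = 0; v < 4; ++v)
        for (int d = 0; d < 3; ++d)
          (*force)[3 * idx[v] + d] -= dEdth * grad[3 * v + d];
    }
  }

  if (S.kV > 0 && !S.f1.empty()) {
    static std::vector<double> vgrad;
    if (force) vgrad.assign(3 * S.n, 0.0);
    double V = sv_volume(S, force ? &vgrad : nullptr);
    double rel = (V - S.V0) / S.V0;
    Evol = 0.5 * S.kV * rel * rel;
    if (force) {
      double pref = -S.kV * rel / S.V0;
      for (int i = 0; i < 3 * S.n; ++i) (*force)[i] += pref * vgrad[i];
    }
  }

  Erep = repulsion(S, force);

  for (size_t s = 0; s < S.s_i.size(); ++s) {
    int i = S.s_i[s], j = S.s_j[s];
    double d[3];
    for (int dd = 0; dd < 3; ++dd)
      d[dd] = S.pos[3 * i + dd] - S.pos[3 * j + dd];
    minimg(d, S.box);
    double r2 = dot3(d, d), rc2 = S.s_rc * S.s_rc;
    if (r2 >= rc2) continue;
    double u = 1.0 - r2 / rc2;
    Esnare += -S.s_eps * u * u;
    if (force) {
      // dE/dr_vec = 4 eps u / rc^2 * d
      double pref = -4.0 * S.s_eps * u / rc2;
      for (int dd = 0; dd < 3; ++dd) {
        (*force)[3 * i + dd] += pref * d[dd];
        (*force)[3 * j + dd] -= pref * d[dd];
      }
    }
  }

  if (S.t_active && S.t_kang > 0) {
    for (size_t t = 0; t < S.t_sv.size(); ++t) {
      int i = S.t_sv[t], j = S.t_anchor[t];
      double d[3];
      for (int dd = 0; dd < 3; ++dd)
        d[dd] = S.pos[3 * i + dd] - S.pos[3 * j + dd];
      minimg(d, S.box);
      double r = norm3(d);
      if (r < 1e-9) continue;
      double uz = d[2] / r;
      Etether += S.t_kang * uz;
      if (force) {
        // dE/dx_i = kang * (e_z - u uz)/r
        double u[3] = { d[0] / r, d[1] / r, d[2] / r };
        for (int dd = 0; dd < 3; ++dd) {
          double g = S.t_kang * (((dd == 2) ? 1.0 : 0.0) - u[dd] * uz) / r;
          (*force)[3 * i + dd] -= g;
          (*force)[3 * j + dd] += g;
        }
      }
    }
  }

  return NumericVector::create(
    _["stretching"] = Ebond, _["bending"] = Ebend, _["volume"] = Evol,
    _["repulsion"] = Erep, _["snare"] = Esnare, _["tether_angle"] = Etether);
}

// [[Rcpp::export]]
NumericVector cpp_cg_energy(List sys) {
  System S = make_system(sys);
  NumericVector e = compute(S, nullptr);
  e.push_back(sum(e), "total");
  return e;
}

// [[Rcpp::export]]
double cpp_sv_volume(List sys) {
  System S = make_system(sys);
  return sv_volume(S, nullptr);
}

static double bend_energy_of(const System& S,
                             const std::vector<int>& qidx) {
  double E = 0.0, sc[2];
  for (int q : qidx) {
    dihedral_sincos(S, q, sc, nullptr);
    E += S.lambda[q] * (1.0 - (sc[1] * S.cos0[q] + sc[0] * S.sin0[q]));
  }
  return E;
}

// [[Rcpp::export]]
List cpp_cg_run(List sys, int nsteps, double dt, NumericVector mobility,
                double kT, int sample_every, int mc_every,
                List protein_quads, NumericVector theta0_active,
                LogicalVector mask_state, bool masks_enabled,
                double max_disp, int mc_extra_sweeps) {
  System S = make_system(sys);
  int n = S.n;
  std::vector<double> force(3 * n);
  std::vector<double> noise_amp(n), mob(n);
  for (int i = 0; i < n; ++i) {
    mob[i] = mobility[i];
    noise_amp[i] = std::sqrt(2.0 * mobility[i] * kT * dt);
  }
  int nprot = protein_quads.size();
  std::vector<std::vector<int>> pq(nprot);
  for (int p = 0; p < nprot; ++p)
    pq[p] = as<std::vector<int>>(protein_quads[p]);
  std::vector<int> mask(nprot);
  for (int p = 0; p < nprot; ++p) mask[p] = mask_state[p] ? 1 : 0;
  // apply current masks to theta0
  for (int p = 0; p < nprot; ++p)
    for (int q : pq[p])
      S.set_theta0(q, mask[p] ? theta0_active[q] : 0.0);

  RNGScope scope;
  NoiseGen ng; ng.seed_from_R();
  int nsamples = (sample_every > 0) ? nsteps / sample_every : 0;
  NumericVector e_series(nsamples), v_series(nsamples), t_series(nsamples);
  int mc_prop_on = 0, mc_acc_on = 0, mc_prop_off = 0, mc_acc_off = 0;
  bool unstable = false;
  double worst_disp = 0.0;
  int si = 0;

  auto mc_sweep = [&]() {
    for (int p = 0; p < nprot; ++p) {
      double e_old = bend_energy_of(S, pq[p]);
      for (int q : pq[p])
        S.set_theta0(q, mask[p] ? 0.0 : theta0_active[q]);
      double e_new = bend_energy_of(S, pq[p]);
      double dE = e_new - e_old;
      bool accept = (dE <= 0) || (unif_rand() < std::exp(-dE / kT));
      if (mask[p]) { ++mc_prop_off; if (accept) ++mc_acc_off; }
      else { ++mc_prop_on; if (accept) ++mc_acc_on; }
      if (accept) mask[p] = 1 - mask[p];
      else for (int q : pq[p])
        S.set_theta0(q, mask[p] ? theta0_active[q] : 0.0);
    }
  };

  // hard-contact spikes (e.g. the SV squeezing the protein crowd) are
  // regularised by capping the deterministic displacement; persistent
  // capping indicates real integrator failure and is flagged
  const double disp_cap = 0.5;
  long long n_capped = 0;
  for (int step = 0; step < nsteps && !unstable; ++step) {
    compute(S, &force);
    double step_max = 0.0;
    for (int i = 0; i < n; ++i) {
      double det2 = 0.0, det[3];
      for (int d = 0; d < 3; ++d) {
        det[d] = mob[i] * force[3 * i + d] * dt;
        det2 += det[d] * det[d];
      }
      if (det2 > disp_cap * disp_cap) {
        double sc = disp_cap / std::sqrt(det2);
        for (int d = 0; d < 3; ++d) det[d] *= sc;
        ++n_capped;
      }
      double dx2 = 0.0, nz[3] = {0, 0, 0};
      if (kT > 0) ng.norm3(step, i, nz);
      for (int d = 0; d < 3; ++d) {
        double dx = det[d] + noise_amp[i] * nz[d];
        S.pos[3 * i + d] += dx;
        dx2 += dx * dx;
      }
      step_max = std::max(step_max, dx2);
    }
    step_max = std::sqrt(step_max);
    worst_disp = std::max(worst_disp, step_max);
    if (step_max > max_disp ||
        (step > 100 && n_capped > 0.005 * (double)n * step)) {
      unstable = true; break;
    }
    // invalidate the pair list once any particle has drifted half a skin
    if (S.vlist_valid && step % 5 == 4) {
      double lim2 = 0.09 * S.vskin * S.vskin;     // (0.3 skin)^2
      for (int i = 0; i < 3 * n; i += 3) {
        double ddx = S.pos[i] - S.vref[i];
        double ddy = S.pos[i + 1] - S.vref[i + 1];
        double ddz = S.pos[i + 2] - S.vref[i + 2];
        if (ddx * ddx + ddy * ddy + ddz * ddz > lim2) {
          S.vlist_valid = false; break;
        }
      }
    }
    if (masks_enabled && mc_every > 0 && (step + 1) % mc_every == 0)
      mc_sweep();
    if (sample_every > 0 && (step + 1) % sample_every == 0 && si < nsamples) {
      NumericVector e = compute(S, nullptr);
      e_series[si] = sum(e);
      v_series[si] = S.f1.empty() ? 0.0 : sv_volume(S, nullptr);
      t_series[si] = (step + 1) * dt;
      ++si;
    }
  }
  for (int s = 0; s < mc_extra_sweeps; ++s) mc_sweep();

  NumericMatrix out_pos(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out_pos(i, d) = S.pos[3 * i + d];
  LogicalVector out_mask(nprot);
  for (int p = 0; p < nprot; ++p) out_mask[p] = mask[p] == 1;
  return List::create(
    _["pos"] = out_pos, _["mask_state"] = out_mask,
    _["energy_series"] = e_series, _["volume_series"] = v_series,
    _["time_series"] = t_series,
    _["unstable"] = unstable, _["max_disp"] = worst_disp,
    _["mc"] = IntegerVector::create(
      _["prop_on"] = mc_prop_on, _["acc_on"] = mc_acc_on,
      _["prop_off"] = mc_prop_off, _["acc_off"] = mc_acc_off));
}

// [[Rcpp::export]]
NumericVector cpp_dihedral_angles(List sys) {
  System S = make_system(sys);
  NumericVector out(S.q1.size());
  for (size_t q = 0; q < S.q1.size(); ++q)
    out[q] = dihedral_theta(S, q, nullptr);
  return out;
}
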