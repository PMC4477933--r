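// Explicit dynamic FE kernels: total-Lagrangian constant-strain-triangle
// membranes with a Fung-type anisotropic law, tension-only Ogden cable
// chordae, node-to-triangle / node-to-segment penalty contact with a
// Coulomb friction cap, and a central-difference time integrator with
// mass-proportional damping and prescribed-node motion programs.
//
// Units: mm, ms, mg  =>  force mN, stress kPa, density mg/mm^3.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

static inline Vec3 getrow(const NumericMatrix& M, int i) {
  return Vec3(M(i, 0), M(i, 1), M(i, 2));
}
static inline void addrow(NumericMatrix& M, int i, const Vec3& v) {
  M(i, 0) += v.x; M(i, 1) += v.y; M(i, 2) += v.z;
}

// ---------------------------------------------------------------------
// Fung membrane: W = c/2 (exp(Q) - 1),
// Q = a1 E11^2 + a2 E22^2 + 2 a3 E11 E22 + a4 E12^2
// (E12 = the single in-plane shear coordinate; dW/dE12 = c e^Q a4 E12)
struct FungMat { double c, a1, a2, a3, a4; };

// membrane force assembly; returns total strain energy, fills forces and
// per-element Green strains (E11,E22,E12); sets inverted flag
static double membrane_assemble(const NumericMatrix& pos,
                                const IntegerMatrix& tris,
                                const NumericMatrix& invR,  // m x 4 (a,b,c,d)
                                const NumericVector& arearef,
                                const NumericVector& thick,
                                const IntegerVector& matid,
                                const std::vector<FungMat>& mats,
                                NumericMatrix& force,
                                NumericMatrix& Eout,
                                int* inverted_elem) {
  const int m = tris.nrow();
  double W_total = 0.0;
  for (int e = 0; e < m; ++e) {
    int i0 = tris(e, 0) - 1, i1 = tris(e, 1) - 1, i2 = tris(e, 2) - 1;
    Vec3 d1 = getrow(pos, i1) - getrow(pos, i0);
    Vec3 d2 = getrow(pos, i2) - getrow(pos, i0);
    const double a = invR(e, 0), b = invR(e, 1), c_ = invR(e, 2),
                 d = invR(e, 3);
    // F columns f1, f2 (3-vectors): [d1 d2] * invR
    Vec3 f1 = d1 * a + d2 * c_;
    Vec3 f2 = d1 * b + d2 * d;
    double C11 = f1.dot(f1), C22 = f2.dot(f2), C12 = f1.dot(f2);
    double E11 = 0.5 * (C11 - 1.0), E22 = 0.5 * (C22 - 1.0), E12 = 0.5 * C12;
    if (Eout.nrow() == m) { Eout(e, 0) = E11; Eout(e, 1) = E22; Eout(e, 2) = E12; }
    // det C = (det F2d)^2: a vanishing value means the element has
    // collapsed (the in-plane Jacobian passes through zero)
    double J2 = C11 * C22 - C12 * C12;
    if (J2 < 1e-10 && inverted_elem && *inverted_elem < 0)
      *inverted_elem = e + 1;
    const FungMat& M = mats[matid[e]];
    double Q = M.a1 * E11 * E11 + M.a2 * E22 * E22 +
               2.0 * M.a3 * E11 * E22 + M.a4 * E12 * E12;
    if (Q > 250.0) Q = 250.0;  // saturate; NaN guard happens upstream
    double eQ = std::exp(Q);
    double W1 = M.c * eQ * (M.a1 * E11 + M.a3 * E22);
    double W2 = M.c * eQ * (M.a2 * E22 + M.a3 * E11);
    double W12 = M.c * eQ * M.a4 * E12;
    double V = thick[e] * arearef[e];
    W_total += V * (M.c * 0.5) * (eQ - 1.0);
    // dE11/dx1 = a f1 ; dE22/dx1 = b f2 ; dE12/dx1 = 0.5 (a f2 + b f1)
    Vec3 g1 = f1 * (W1 * a) + f2 * (W2 * b) + (f2 * a + f1 * b) * (0.5 * W12);
    Vec3 g2 = f1 * (W1 * c_) + f2 * (W2 * d) + (f2 * c_ + f1 * d) * (0.5 * W12);
    Vec3 F1 = g1 * (-V), F2 = g2 * (-V);
    addrow(force, i1, F1);
    addrow(force, i2, F2);
    addrow(force, i0, (F1 + F2) * -1.0);
  }
  return W_total;
}

// [[Rcpp::export]]
List cpp_membrane_forces(NumericMatrix pos, IntegerMatrix tris,
                         NumericMatrix invR, NumericVector arearef,
                         NumericVector thick, IntegerVector matid,
                         NumericMatrix matpar) {
  std::vector<FungMat> mats;
  for (int i = 0; i < matpar.nrow(); ++i)
    mats.push_back({matpar(i, 0), matpar(i, 1), matpar(i, 2), matpar(i, 3),
                    matpar(i, 4)});
  NumericMatrix force(pos.nrow(), 3), E(tris.nrow(), 3);
  int inverted = -1;
  double W = membrane_assemble(pos, tris, invR, arearef, thick, matid, mats,
                               force, E, &inverted);
  return List::create(_["force"] = force, _["energy"] = W,
                      _["strain"] = E, _["inverted"] = inverted);
}

// ---------------------------------------------------------------------
// Ogden cable: sigma(l) = sum mu_p (l^a_p - l^(-a_p/2)) for l >= 1
static inline double ogden_sigma(double l, const NumericVector& mu,
                                 const NumericVector& al) {
  if (l < 1.0) return 0.0;
  double s = 0.0;
  for (int p = 0; p < mu.size(); ++p)
    s += mu[p] * (std::pow(l, al[p]) - std::pow(l, -0.5 * al[p]));
  return s;
}
static inline double ogden_psi(double l, const NumericVector& mu,
                               const NumericVector& al) {
  // int_1^l sigma ds  (strain energy per unit reference volume)
  if (l < 1.0) return 0.0;
  double s = 0.0;
  for (int p = 0; p < mu.size(); ++p) {
    double A = al[p];
    s += mu[p] * ((std::pow(l, A + 1.0) - 1.0) / (A + 1.0) +
                  (std::pow(l, 1.0 - 0.5 * A) - 1.0) / (0.5 * A - 1.0));
  }
  return s;
}

// chordae forces; origins are rows of `tips` indexed by `origin` (0/1).
// Returns energy; fills per-chorda stretch and tension and nodal forces
// (+ reaction rows in tipforce).
static double chordae_assemble(const NumericMatrix& pos,
                               const NumericMatrix& tips,
                               const IntegerVector& origin,
                               const IntegerVector& insertion,
                               const NumericVector& area,
                               const NumericVector& rest,
                               const IntegerVector& ogid,
                               const List& ogpars,
                               NumericMatrix& force,
                               NumericMatrix& tipforce,
                               NumericVector& lambda,
                               NumericVector& tension) {
  double Wtot = 0.0;
  for (int k = 0; k < insertion.size(); ++k) {
    int ins = insertion[k] - 1;
    Vec3 o = getrow(tips, origin[k]);
    Vec3 p = getrow(pos, ins);
    Vec3 dvec = p - o;
    double L = dvec.norm();
    if (L < 1e-12) stop("chordae: zero-length chord %d", k + 1);
    double lam = L / rest[k];
    lambda[k] = lam;
    List par = ogpars[ogid[k]];
    NumericVector mu = par["mu"], al = par["alpha"];
    double sig = ogden_sigma(lam, mu, al);
    tension[k] = sig * area[k];                 // mN
    Wtot += ogden_psi(lam, mu, al) * area[k] * rest[k];
    Vec3 f = dvec * (-(sig * area[k]) / L);     // pulls insertion toward tip
    addrow(force, ins, f);
    addrow(tipforce, origin[k], f * -1.0);
  }
  return Wtot;
}

// [[Rcpp::export]]
List cpp_chordae_forces(NumericMatrix pos, NumericMatrix tips,
                        IntegerVector origin, IntegerVector insertion,
                        NumericVector area, NumericVector rest,
                        IntegerVector ogid, List ogpars) {
  NumericMatrix force(pos.nrow(), 3), tipforce(tips.nrow(), 3);
  NumericVector lambda(insertion.size()), tension(insertion.size());
  double W = chordae_assemble(pos, tips, origin, insertion, area, rest,
                              ogid, ogpars, force, tipforce, lambda, tension);
  return List::create(_["force"] = force, _["tip_force"] = tipforce,
                      _["energy"] = W, _["lambda"] = lambda,
                      _["tension"] = tension);
}

// ---------------------------------------------------------------------
// contact: node-to-triangle penalty with two-sided detection shell and a
// Coulomb cap on the tangential (viscous-regularized) force
struct ContactAccum {
  std::vector<int> node, tri;
  std::vector<double> depth, fn;
};

static void closest_on_tri(const Vec3& p, const Vec3& a, const Vec3& b,
                           const Vec3& c, Vec3& q, double* w) {
  // barycentric closest point (Ericson, Real-Time Collision Detection)
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = ab.dot(ap), d2 = ac.dot(ap);
  if (d1 <= 0 && d2 <= 0) { q = a; w[0] = 1; w[1] = 0; w[2] = 0; return; }
  Vec3 bp = p - b;
  double d3 = ab.dot(bp), d4 = ac.dot(bp);
  if (d3 >= 0 && d4 <= d3) { q = b; w[0] = 0; w[1] = 1; w[2] = 0; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    q = a + ab * v; w[0] = 1 - v; w[1] = v; w[2] = 0; return;
  }
  Vec3 cp = p - c;
  double d5 = ab.dot(cp), d6 = ac.dot(cp);
  if (d6 >= 0 && d5 <= d6) { q = c; w[0] = 0; w[1] = 0; w[2] = 1; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double v = d2 / (d2 - d6);
    q = a + ac * v; w[0] = 1 - v; w[1] = 0; w[2] = v; return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double v = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    q = b + (c - b) * v; w[0] = 0; w[1] = 1 - v; w[2] = v; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, u = vc * denom;
  q = a + ab * v + ac * u;
  w[0] = 1 - v - u; w[1] = v; w[2] = u;
}

static double contact_assemble(const NumericMatrix& pos,
                               const NumericMatrix& vel,
                               const IntegerMatrix& tris,
                               const IntegerVector& excl_ptr,
                               const IntegerVector& excl_idx,
                               double kn, double mu_f, double h,
                               double kt,
                               NumericMatrix& force,
                               ContactAccum* acc,
                               double* fric_power) {
  const int n = pos.nrow(), m = tris.nrow();
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c)
      if (!std::isfinite(pos(i, c)))
        stop("contact: non-finite coordinates at node %d", i + 1);
  // uniform grid over nodes
  double cell = 2.0 * h;
  double minx = R_PosInf, miny = R_PosInf, minz = R_PosInf;
  for (int i = 0; i < n; ++i) {
    minx = std::min(minx, pos(i, 0));
    miny = std::min(miny, pos(i, 1));
    minz = std::min(minz, pos(i, 2));
  }
  auto cidx = [&](double x, double mn) { return (int)std::floor((x - mn) / cell); };
  std::vector<int> cx(n), cy(n), cz(n);
  int maxcx = 0, maxcy = 0, maxcz = 0;
  for (int i = 0; i < n; ++i) {
    cx[i] = cidx(pos(i, 0), minx); cy[i] = cidx(pos(i, 1), miny);
    cz[i] = cidx(pos(i, 2), minz);
    maxcx = std::max(maxcx, cx[i]); maxcy = std::max(maxcy, cy[i]);
    maxcz = std::max(maxcz, cz[i]);
  }
  int nx = maxcx + 1, ny = maxcy + 1, nz = maxcz + 1;
  if ((double)nx * ny * nz > 2e6)
    stop("contact: grid overflow (coordinates diverged?)");
  std::vector<std::vector<int> > cells((size_t)nx * ny * nz);
  for (int i = 0; i < n; ++i)
    cells[(size_t)(cx[i] * ny + cy[i]) * nz + cz[i]].push_back(i);

  double energy = 0.0;
  for (int e = 0; e < m; ++e) {
    int i0 = tris(e, 0) - 1, i1 = tris(e, 1) - 1, i2 = tris(e, 2) - 1;
    Vec3 a = getrow(pos, i0), b = getrow(pos, i1), c = getrow(pos, i2);
    double lox = std::min(a.x, std::min(b.x, c.x)) - h;
    double hix = std::max(a.x, std::max(b.x, c.x)) + h;
    double loy = std::min(a.y, std::min(b.y, c.y)) - h;
    double hiy = std::max(a.y, std::max(b.y, c.y)) + h;
    double loz = std::min(a.z, std::min(b.z, c.z)) - h;
    double hiz = std::max(a.z, std::max(b.z, c.z)) + h;
    int cx0 = std::max(0, cidx(lox, minx)), cx1 = std::min(nx - 1, cidx(hix, minx));
    int cy0 = std::max(0, cidx(loy, miny)), cy1 = std::min(ny - 1, cidx(hiy, miny));
    int cz0 = std::max(0, cidx(loz, minz)), cz1 = std::min(nz - 1, cidx(hiz, minz));
    for (int gx = cx0; gx <= cx1; ++gx)
      for (int gy = cy0; gy <= cy1; ++gy)
        for (int gz = cz0; gz <= cz1; ++gz) {
          const std::vector<int>& bucket = cells[(size_t)(gx * ny + gy) * nz + gz];
          for (size_t bi = 0; bi < bucket.size(); ++bi) {
            int i = bucket[bi];
            if (i == i0 || i == i1 || i == i2) continue;
            // exclusion list: sorted triangle ids per node (CSR, 0-based)
            bool skip = false;
            {
              int lo = excl_ptr[i], hi = excl_ptr[i + 1] - 1;
              while (lo <= hi) {
                int mid = (lo + hi) / 2;
                if (excl_idx[mid] == e) { skip = true; break; }
                if (excl_idx[mid] < e) lo = mid + 1; else hi = mid - 1;
              }
            }
            if (skip) continue;
            Vec3 p = getrow(pos, i);
            if (p.x < lox || p.x > hix || p.y < loy || p.y > hiy ||
                p.z < loz || p.z > hiz) continue;
            Vec3 q; double w[3];
            closest_on_tri(p, a, b, c, q, w);
            Vec3 g = p - q;
            double d = g.norm();
            if (d >= h || d < 1e-12) continue;
            Vec3 nrm = g * (1.0 / d);
            double depth = h - d;
            double fn = kn * depth;
            Vec3 Fn = nrm * fn;
            // relative velocity at the contact point
            Vec3 vrel = getrow(vel, i) -
              (getrow(vel, i0) * w[0] + getrow(vel, i1) * w[1] +
               getrow(vel, i2) * w[2]);
            Vec3 vt = vrel - nrm * vrel.dot(nrm);
            double vtn = vt.norm();
            Vec3 Ft(0, 0, 0);
            if (vtn > 1e-12) {
              double fmag = std::min(mu_f * fn, kt * vtn);
              Ft = vt * (-fmag / vtn);
              if (fric_power) *fric_power += fmag * vtn;
            }
            Vec3 Ftot = Fn + Ft;
            addrow(force, i, Ftot);
            addrow(force, i0, Ftot * (-w[0]));
            addrow(force, i1, Ftot * (-w[1]));
            addrow(force, i2, Ftot * (-w[2]));
            energy += 0.5 * kn * depth * depth;
            if (acc) {
              acc->node.push_back(i + 1); acc->tri.push_back(e + 1);
              acc->depth.push_back(depth); acc->fn.push_back(fn);
            }
          }
        }
  }
  return energy;
}

// leaflet-node vs chorda-segment penalty (normal only)
static double chord_contact_assemble(const NumericMatrix& pos,
                                     const NumericMatrix& tips,
                                     const IntegerVector& origin,
                                     const IntegerVector& insertion,
                                     double kn, double h,
                                     NumericMatrix& force) {
  double energy = 0.0;
  for (int k = 0; k < insertion.size(); ++k) {
    int ins = insertion[k] - 1;
    Vec3 a = getrow(tips, origin[k]);
    Vec3 b = getrow(pos, ins);
    Vec3 ab = b - a;
    double L2 = ab.dot(ab);
    if (L2 < 1e-12) continue;
    for (int i = 0; i < pos.nrow(); ++i) {
      if (i == ins) continue;
      Vec3 p = getrow(pos, i);
      double t = (p - a).dot(ab) / L2;
      if (t <= 0.02 || t >= 0.98) continue;
      Vec3 q = a + ab * t;
      Vec3 g = p - q;
      double d = g.norm();
      if (d >= h || d < 1e-12) continue;
      double depth = h - d;
      Vec3 f = g * (kn * depth / d);
      addrow(force, i, f);
      // reaction onto the insertion node, weighted by t
      addrow(force, ins, f * (-t));
      energy += 0.5 * kn * depth * depth;
    }
  }
  return energy;
}

// [[Rcpp::export]]
List cpp_contact_forces(NumericMatrix pos, NumericMatrix vel,
                        IntegerMatrix tris, IntegerVector excl_ptr,
                        IntegerVector excl_idx, double kn, double mu_f,
                        double h, double kt) {
  NumericMatrix force(pos.nrow(), 3);
  ContactAccum acc;
  double fp = 0.0;
  double en = contact_assemble(pos, vel, tris, excl_ptr, excl_idx, kn, mu_f,
                               h, kt, force, &acc, &fp);
  int np = acc.node.size();
  IntegerVector pn(np), pt(np);
  NumericVector pd(np), pf(np);
  for (int i = 0; i < np; ++i) {
    pn[i] = acc.node[i]; pt[i] = acc.tri[i];
    pd[i] = acc.depth[i]; pf[i] = acc.fn[i];
  }
  return List::create(_["force"] = force, _["energy"] = en,
                      _["pairs"] = DataFrame::create(
                        _["node"] = pn, _["tri"] = pt, _["depth"] = pd,
                        _["normal_force"] = pf),
                      _["friction_power"] = fp);
}

// ---------------------------------------------------------------------
// full explicit run
// prescribed motion: x_i(t) = base_i + g(t) * dir_i for nodes presc_ids;
// papillary tips fixed at `tips`.
// [[Rcpp::export]]
List cpp_run_sim(NumericMatrix pos0, IntegerMatrix tris, NumericMatrix invR,
                 NumericVector arearef, NumericVector thick,
                 IntegerVector matid, NumericMatrix matpar,
                 NumericVector mass,
                 NumericMatrix tips, IntegerVector ch_origin,
                 IntegerVector ch_insertion, NumericVector ch_area,
                 NumericVector ch_rest, IntegerVector ch_ogid, List ogpars,
                 NumericMatrix press_samples,  // t, dP(kPa) -> converted below
                 NumericVector press_scale,    // length 1: kPa -> kPa (1)
                 IntegerVector presc_ids, NumericMatrix presc_base,
                 NumericMatrix presc_dir, NumericMatrix gating,  // t, g
                 IntegerVector excl_ptr, IntegerVector excl_idx,
                 double kn, double mu_f, double hcont, double kt,
                 double chord_kn, double chord_h,
                 double dt, double tend, double damping,
                 int stride, int contact_every) {
  const int n = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel(n, 3);
  NumericMatrix fcont(n, 3);

  std::vector<FungMat> mats;
  for (int i = 0; i < matpar.nrow(); ++i)
    mats.push_back({matpar(i, 0), matpar(i, 1), matpar(i, 2), matpar(i, 3),
                    matpar(i, 4)});

  int nsteps = (int)std::ceil(tend / dt);
  int nframes = nsteps / stride + 1;
  NumericVector times(nframes);
  NumericVector fr_ke(nframes), fr_strain(nframes), fr_contact(nframes),
      fr_wext(nframes), fr_diss(nframes), fr_npairs(nframes);
  List fr_pos(nframes), fr_lambda(nframes), fr_pairs(nframes);

  auto interp = [](const NumericMatrix& tab, double t) {
    int k = tab.nrow();
    if (t <= tab(0, 0)) return tab(0, 1);
    if (t >= tab(k - 1, 0)) return tab(k - 1, 1);
    int lo = 0, hi = k - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2;
      if (tab(mid, 0) <= t) lo = mid; else hi = mid; }
    double f = (t - tab(lo, 0)) / (tab(hi, 0) - tab(lo, 0));
    return tab(lo, 1) * (1 - f) + tab(hi, 1) * f;
  };

  // initialize prescribed nodes at t = 0
  double g0 = interp(gating, 0.0);
  for (int k = 0; k < presc_ids.size(); ++k) {
    int i = presc_ids[k] - 1;
    for (int c = 0; c < 3; ++c)
      pos(i, c) = presc_base(k, c) + g0 * presc_dir(k, c);
  }

  NumericVector lambda(ch_insertion.size()), tension(ch_insertion.size());
  NumericMatrix tipforce(tips.nrow(), 3);
  NumericMatrix Edummy(0, 3);
  std::vector<bool> is_presc(n, false);
  for (int k = 0; k < presc_ids.size(); ++k) is_presc[presc_ids[k] - 1] = true;

  double Wext = 0.0, Diss = 0.0;
  int frame = 0, status = 0;
  double t = 0.0;
  std::string errmsg = "";
  // divergence bound: generous multiple of the initial bounding span
  double span0 = 0.0;
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) span0 = std::max(span0, std::fabs(pos0(i, c)));
  const double pos_limit = 20.0 * span0 + 100.0;

  for (int step = 0; step <= nsteps; ++step) {
    t = step * dt;
    NumericMatrix force(n, 3);
    int inverted = -1;
    double Wm = membrane_assemble(pos, tris, invR, arearef, thick, matid,
                                  mats, force, Edummy, &inverted);
    // chordae
    std::fill(tipforce.begin(), tipforce.end(), 0.0);
    double Wc = 0.0;
    if (ch_insertion.size() > 0)
      Wc = chordae_assemble(pos, tips, ch_origin, ch_insertion, ch_area,
                            ch_rest, ch_ogid, ogpars, force, tipforce,
                            lambda, tension);
    // pressure (follower load on current normals; winding = atrial)
    double dP = interp(press_samples, t) * press_scale[0];
    NumericMatrix fpress(n, 3);
    if (dP != 0.0) {
      for (int e = 0; e < tris.nrow(); ++e) {
        int i0 = tris(e, 0) - 1, i1 = tris(e, 1) - 1, i2 = tris(e, 2) - 1;
        Vec3 d1 = getrow(pos, i1) - getrow(pos, i0);
        Vec3 d2 = getrow(pos, i2) - getrow(pos, i0);
        Vec3 an = d1.cross(d2) * 0.5;     // area-weighted normal
        Vec3 fp = an * (dP / 3.0);
        addrow(fpress, i0, fp); addrow(fpress, i1, fp); addrow(fpress, i2, fp);
      }
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c) force(i, c) += fpress(i, c);
    }
    // contact (recomputed every contact_every steps)
    double Wcontact = 0.0, fricP = 0.0;
    ContactAccum acc;
    if (step % contact_every == 0) {
      std::fill(fcont.begin(), fcont.end(), 0.0);
      Wcontact = contact_assemble(pos, vel, tris, excl_ptr, excl_idx, kn,
                                  mu_f, hcont, kt, fcont, &acc, &fricP);
      if (chord_kn > 0 && ch_insertion.size() > 0)
        Wcontact += chord_contact_assemble(pos, tips, ch_origin,
                                           ch_insertion, chord_kn, chord_h,
                                           fcont);
    }
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) force(i, c) += fcont(i, c);

    // frame output
    if (step % stride == 0 && frame < nframes) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        Vec3 v = getrow(vel, i);
        ke += 0.5 * mass[i] * v.dot(v);
      }
      times[frame] = t;
      fr_ke[frame] = ke;
      fr_strain[frame] = Wm + Wc;
      fr_contact[frame] = Wcontact;
      fr_wext[frame] = Wext;
      fr_diss[frame] = Diss;
      fr_npairs[frame] = (double)acc.node.size();
      fr_pos[frame] = clone(pos);
      fr_lambda[frame] = clone(lambda);
      int np = acc.node.size();
      IntegerVector pn(np), pt(np); NumericVector pd(np), pf(np);
      for (int i = 0; i < np; ++i) { pn[i] = acc.node[i]; pt[i] = acc.tri[i];
        pd[i] = acc.depth[i]; pf[i] = acc.fn[i]; }
      fr_pairs[frame] = DataFrame::create(_["node"] = pn, _["tri"] = pt,
                                          _["depth"] = pd,
                                          _["normal_force"] = pf);
      ++frame;
    }
    if (step == nsteps) break;

    // central-difference update with mass-proportional damping;
    // prescribed nodes follow their motion program exactly
    double gnext = interp(gating, t + dt);
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      if (is_presc[i]) continue;
      double mi = mass[i];
      for (int c = 0; c < 3; ++c) {
        double a = force(i, c) / mi - damping * vel(i, c);
        double vnew = vel(i, c) + dt * a;
        double dx = dt * vnew;
        Diss += damping * mi * vnew * vnew * dt;
        Wext += fpress(i, c) * dx;
        pos(i, c) += dx;
        vel(i, c) = vnew;
        if (!std::isfinite(pos(i, c)) || std::fabs(pos(i, c)) > pos_limit)
          bad = true;
      }
    }
    Diss += fricP * dt;
    for (int k = 0; k < presc_ids.size(); ++k) {
      int i = presc_ids[k] - 1;
      for (int c = 0; c < 3; ++c) {
        double xn = presc_base(k, c) + gnext * presc_dir(k, c);
        double dx = xn - pos(i, c);
        double vnew = dx / dt;
        // external work at a driven node: constraint reaction work
        // (m a - f_applied) . dx plus the pressure work there
        Wext += (mass[i] * (vnew - vel(i, c)) / dt - force(i, c)) * dx +
                fpress(i, c) * dx;
        pos(i, c) = xn;
        vel(i, c) = vnew;
      }
    }
    if (bad) { status = 1;
      errmsg = "instability (non-finite or diverging coordinates)"; break; }
  }

  return List::create(
    _["times"] = times[Range(0, std::max(frame - 1, 0))],
    _["positions"] = fr_pos, _["lambda"] = fr_lambda,
    _["pairs"] = fr_pairs,
    _["kinetic"] = fr_ke, _["strain"] = fr_strain,
    _["contact_energy"] = fr_contact, _["wext"] = fr_wext,
    _["dissipation"] = fr_diss, _["n_pairs"] = fr_npairs,
    _["n_frames"] = frame, _["status"] = status, _["error"] = errmsg,
    _["final_pos"] = pos);
}
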