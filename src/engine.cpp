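// Minimal constrained velocity-Verlet engine for toy molecular systems.
//
// Units: positions in Angstrom, velocities in Angstrom/fs, masses in amu,
// energies in kcal/mol.  Accelerations use the single conversion constant
// KCAL = 4.184e-4 Angstrom/fs^2 per (kcal/mol/Angstrom)/amu.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KCAL = 4.184e-4; // (kcal/mol/A)/amu -> A/fs^2
static const double KB = 0.0019872;  // kcal/mol/K

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline Vec3 operator-(const Vec3 &a, const Vec3 &b) {
  return Vec3(a.x - b.x, a.y - b.y, a.z - b.z);
}
static inline Vec3 operator+(const Vec3 &a, const Vec3 &b) {
  return Vec3(a.x + b.x, a.y + b.y, a.z + b.z);
}
static inline Vec3 operator*(double s, const Vec3 &a) {
  return Vec3(s * a.x, s * a.y, s * a.z);
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct ForceFieldC {
  // bonds: i j kb r0 ; angles: i j k ka th0 ; torsions: i j k l vn n phase ;
  // lj: i j eps sigma  (indices 0-based)
  std::vector<int> bi, bj;
  std::vector<double> bk, br0;
  std::vector<int> ai, aj, ak;
  std::vector<double> aka, ath0;
  std::vector<int> ti, tj, tk, tl;
  std::vector<double> tvn, tn, tph;
  std::vector<int> li, lj;
  std::vector<double> leps, lsig;
};

static ForceFieldC unpack_ff(const List &ff, int n) {
  ForceFieldC f;
  NumericMatrix b = ff["bonds"], a = ff["angles"], t = ff["torsions"],
                l = ff["lj"];
  auto chk = [&](double v) {
    int i = (int)v - 1;
    if (i < 0 || i >= n) stop("force field index %d out of range", (int)v);
    return i;
  };
  for (int r = 0; r < b.nrow(); ++r) {
    int i = chk(b(r, 0)), j = chk(b(r, 1));
    if (i == j) stop("bond with identical endpoints");
    f.bi.push_back(i); f.bj.push_back(j);
    f.bk.push_back(b(r, 2)); f.br0.push_back(b(r, 3));
  }
  for (int r = 0; r < a.nrow(); ++r) {
    f.ai.push_back(chk(a(r, 0))); f.aj.push_back(chk(a(r, 1)));
    f.ak.push_back(chk(a(r, 2)));
    f.aka.push_back(a(r, 3)); f.ath0.push_back(a(r, 4));
  }
  for (int r = 0; r < t.nrow(); ++r) {
    f.ti.push_back(chk(t(r, 0))); f.tj.push_back(chk(t(r, 1)));
    f.tk.push_back(chk(t(r, 2))); f.tl.push_back(chk(t(r, 3)));
    f.tvn.push_back(t(r, 4)); f.tn.push_back(t(r, 5)); f.tph.push_back(t(r, 6));
  }
  for (int r = 0; r < l.nrow(); ++r) {
    f.li.push_back(chk(l(r, 0))); f.lj.push_back(chk(l(r, 1)));
    f.leps.push_back(l(r, 2)); f.lsig.push_back(l(r, 3));
  }
  return f;
}

// Potential energy and forces (negative gradient).
// Bond:   E = 1/2 kb (r - r0)^2
// Angle:  E = 1/2 ka (theta - theta0)^2
// Torsion:E = vn/2 (1 + cos(n phi - phase))
// LJ:     E = 4 eps ((sig/r)^12 - (sig/r)^6)
static double forces(const std::vector<Vec3> &x, const ForceFieldC &f,
                     std::vector<Vec3> &F) {
  const int n = (int)x.size();
  for (int i = 0; i < n; ++i) F[i] = Vec3();
  double E = 0.0;

  for (size_t b = 0; b < f.bi.size(); ++b) {
    Vec3 d = x[f.bi[b]] - x[f.bj[b]];
    double r = norm(d);
    double dr = r - f.br0[b];
    E += 0.5 * f.bk[b] * dr * dr;
    double fac = -f.bk[b] * dr / r;
    F[f.bi[b]] = F[f.bi[b]] + fac * d;
    F[f.bj[b]] = F[f.bj[b]] - fac * d;
  }

  for (size_t a = 0; a < f.ai.size(); ++a) {
    Vec3 u = x[f.ai[a]] - x[f.aj[a]];
    Vec3 v = x[f.ak[a]] - x[f.aj[a]];
    double nu = norm(u), nv = norm(v);
    double c = dot(u, v) / (nu * nv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-10) s = 1e-10; // collinear guard
    double dth = th - f.ath0[a];
    E += 0.5 * f.aka[a] * dth * dth;
    double dEdth = f.aka[a] * dth;
    // dtheta/dxi = (c*uhat - vhat)/(nu*s) etc.
    Vec3 uh = (1.0 / nu) * u, vh = (1.0 / nv) * v;
    Vec3 dthi = (1.0 / (nu * s)) * Vec3(c * uh.x - vh.x, c * uh.y - vh.y,
                                        c * uh.z - vh.z);
    Vec3 dthk = (1.0 / (nv * s)) * Vec3(c * vh.x - uh.x, c * vh.y - uh.y,
                                        c * vh.z - uh.z);
    F[f.ai[a]] = F[f.ai[a]] - dEdth * dthi;
    F[f.ak[a]] = F[f.ak[a]] - dEdth * dthk;
    F[f.aj[a]] = F[f.aj[a]] + dEdth * (dthi + dthk);
  }

  for (size_t t = 0; t < f.ti.size(); ++t) {
    Vec3 b1 = x[f.tj[t]] - x[f.ti[t]];
    Vec3 b2 = x[f.tk[t]] - x[f.tj[t]];
    Vec3 b3 = x[f.tl[t]] - x[f.tk[t]];
    Vec3 m = cross(b1, b2), nn = cross(b2, b3);
    double nm = dot(m, m), n2 = dot(nn, nn);
    double nb2 = norm(b2);
    if (nm < 1e-12 || n2 < 1e-12) continue; // degenerate
    double phi = std::atan2(dot(cross(m, nn), (1.0 / nb2) * b2), dot(m, nn));
    double ang = f.tn[t] * phi - f.tph[t];
    E += 0.5 * f.tvn[t] * (1.0 + std::cos(ang));
    double dEdphi = -0.5 * f.tvn[t] * f.tn[t] * std::sin(ang);
    // standard dihedral force distribution (Bekker et al.)
    Vec3 Fi = (dEdphi * nb2 / nm) * m;
    Vec3 Fl = (-dEdphi * nb2 / n2) * nn;
    double sv = dot(b1, b2) / (nb2 * nb2);
    double sw = dot(b3, b2) / (nb2 * nb2);
    Vec3 Fj = (-(1.0 + sv)) * Fi + sw * Fl;
    Vec3 Fk = (-1.0) * (Fi + Fj + Fl);
    F[f.ti[t]] = F[f.ti[t]] + Fi;
    F[f.tj[t]] = F[f.tj[t]] + Fj;
    F[f.tk[t]] = F[f.tk[t]] + Fk;
    F[f.tl[t]] = F[f.tl[t]] + Fl;
  }

  for (size_t p = 0; p < f.li.size(); ++p) {
    Vec3 d = x[f.li[p]] - x[f.lj[p]];
    double r2 = dot(d, d);
    double s2 = f.lsig[p] * f.lsig[p] / r2;
    double s6 = s2 * s2 * s2;
    double s12 = s6 * s6;
    E += 4.0 * f.leps[p] * (s12 - s6);
    double fac = 24.0 * f.leps[p] * (2.0 * s12 - s6) / r2;
    F[f.li[p]] = F[f.li[p]] + fac * d;
    F[f.lj[p]] = F[f.lj[p]] - fac * d;
  }
  return E;
}

struct ConsC {
  std::vector<int> i, j;
  std::vector<double> d;
  double tol;
  int maxit;
};

static ConsC unpack_cons(SEXP consSexp, int n) {
  ConsC c;
  c.tol = 1e-8;
  c.maxit = 500;
  if (Rf_isNull(consSexp)) return c;
  List cons(consSexp);
  NumericMatrix p = cons["pairs"];
  c.tol = as<double>(cons["tolerance"]);
  c.maxit = as<int>(cons["max_iterations"]);
  for (int r = 0; r < p.nrow(); ++r) {
    int i = (int)p(r, 0) - 1, j = (int)p(r, 1) - 1;
    if (i < 0 || i >= n || j < 0 || j >= n || i == j)
      stop("constraint indices out of range");
    if (p(r, 2) <= 0) stop("constraint target length must be positive");
    c.i.push_back(i);
    c.j.push_back(j);
    c.d.push_back(p(r, 2));
  }
  return c;
}

// SHAKE: iteratively project `x` onto the constraint manifold using
// mass-weighted corrections along the reference bond vectors.
// Returns iterations used; -1 on non-convergence.
static int shake(std::vector<Vec3> &x, const std::vector<Vec3> &ref,
                 const ConsC &c, const std::vector<double> &mass) {
  const size_t nc = c.i.size();
  if (nc == 0) return 0;
  for (int it = 1; it <= c.maxit; ++it) {
    for (size_t k = 0; k < nc; ++k) {
      int i = c.i[k], j = c.j[k];
      Vec3 r = x[i] - x[j];
      double d2 = c.d[k] * c.d[k];
      double diff = dot(r, r) - d2;
      double rel = std::fabs(std::sqrt(dot(r, r)) - c.d[k]) / c.d[k];
      if (rel > c.tol) {
        Vec3 s = ref[i] - ref[j];
        double rs = dot(r, s);
        if (std::fabs(rs) < 1e-12) rs = (rs < 0 ? -1e-12 : 1e-12);
        double invm = 1.0 / mass[i] + 1.0 / mass[j];
        double g = diff / (2.0 * rs * invm);
        x[i] = x[i] - (g / mass[i]) * s;
        x[j] = x[j] + (g / mass[j]) * s;
      }
    }
    // convergence check on actual distances
    double mx = 0.0;
    for (size_t k = 0; k < nc; ++k) {
      Vec3 r = x[c.i[k]] - x[c.j[k]];
      double rel = std::fabs(norm(r) - c.d[k]) / c.d[k];
      if (rel > mx) mx = rel;
    }
    if (mx <= c.tol) return it;
  }
  return -1;
}

// RATTLE velocity stage: remove relative velocity components along
// constrained bonds.
static int rattle_v(std::vector<Vec3> &v, const std::vector<Vec3> &x,
                    const ConsC &c, const std::vector<double> &mass,
                    double vtol) {
  const size_t nc = c.i.size();
  if (nc == 0) return 0;
  for (int it = 1; it <= c.maxit; ++it) {
    double mx = 0.0;
    for (size_t k = 0; k < nc; ++k) {
      int i = c.i[k], j = c.j[k];
      Vec3 r = x[i] - x[j];
      double d2 = dot(r, r);
      double rv = dot(v[i] - v[j], r);
      double resid = std::fabs(rv) / std::sqrt(d2);
      if (resid > mx) mx = resid;
      double invm = 1.0 / mass[i] + 1.0 / mass[j];
      double g = rv / (d2 * invm);
      v[i] = v[i] - (g / mass[i]) * r;
      v[j] = v[j] + (g / mass[j]) * r;
    }
    if (mx <= vtol) return it;
  }
  return -1;
}

static double kinetic(const std::vector<Vec3> &v,
                      const std::vector<double> &m) {
  double ke = 0.0;
  for (size_t i = 0; i < v.size(); ++i) ke += m[i] * dot(v[i], v[i]);
  return 0.5 * ke / KCAL;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, List ff) {
  int n = pos.nrow();
  ForceFieldC f = unpack_ff(ff, n);
  std::vector<Vec3> x(n), F(n);
  for (int i = 0; i < n; ++i) x[i] = Vec3(pos(i, 0), pos(i, 1), pos(i, 2));
  double E = forces(x, f, F);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = F[i].x;
    out(i, 1) = F[i].y;
    out(i, 2) = F[i].z;
  }
  return List::create(_["forces"] = out, _["potential"] = E);
}

// [[Rcpp::export]]
List cpp_shake(NumericMatrix pos, NumericMatrix ref, List cons,
               NumericVector mass) {
  int n = pos.nrow();
  ConsC c = unpack_cons(cons, n);
  std::vector<Vec3> x(n), r(n);
  std::vector<double> m(mass.begin(), mass.end());
  for (int i = 0; i < n; ++i) {
    x[i] = Vec3(pos(i, 0), pos(i, 1), pos(i, 2));
    r[i] = Vec3(ref(i, 0), ref(i, 1), ref(i, 2));
  }
  int it = shake(x, r, c, m);
  if (it < 0)
    stop("SHAKE failed to converge within %d iterations", c.maxit);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i].x;
    out(i, 1) = x[i].y;
    out(i, 2) = x[i].z;
  }
  return List::create(_["positions"] = out, _["iterations"] = it);
}

// Run `n_steps` of velocity Verlet, saving every `save_interval` steps.
// The initial conformation (step 0) is not a saved frame.
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
             List ff, SEXP cons, double dt, int n_steps, int save_interval,
             bool thermostat, double t_target, double tau_t,
             bool save_energies) {
  const int n = pos.nrow();
  ForceFieldC f = unpack_ff(ff, n);
  ConsC c = unpack_cons(cons, n);
  std::vector<double> m(mass.begin(), mass.end());
  std::vector<Vec3> x(n), v(n), F(n), xref(n);
  for (int i = 0; i < n; ++i) {
    x[i] = Vec3(pos(i, 0), pos(i, 1), pos(i, 2));
    v[i] = Vec3(vel(i, 0), vel(i, 1), vel(i, 2));
  }
  const int ncons = (int)c.i.size();
  const double ndof = 3.0 * n - ncons;
  const double vtol = c.tol > 0 ? c.tol : 1e-8;

  double E = forces(x, f, F);
  const int nframes = n_steps / save_interval;
  NumericVector frames(nframes * n * 3);
  frames.attr("dim") = IntegerVector::create(n, 3, nframes);
  IntegerVector steps(nframes);
  NumericVector pot(save_energies ? nframes : 0),
      kin(save_energies ? nframes : 0);

  int fr = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // half kick
    for (int i = 0; i < n; ++i)
      v[i] = v[i] + (0.5 * dt * KCAL / m[i]) * F[i];
    // drift (+ SHAKE projection and velocity correction)
    for (int i = 0; i < n; ++i) {
      xref[i] = x[i];
      x[i] = x[i] + dt * v[i];
    }
    if (ncons > 0) {
      std::vector<Vec3> xun = x;
      int it = shake(x, xref, c, m);
      if (it < 0)
        stop("SHAKE failed to converge at step %d (time step too large?)",
             step);
      for (int i = 0; i < n; ++i)
        v[i] = v[i] + (1.0 / dt) * (x[i] - xun[i]);
    }
    // new forces, second half kick
    E = forces(x, f, F);
    for (int i = 0; i < n; ++i)
      v[i] = v[i] + (0.5 * dt * KCAL / m[i]) * F[i];
    if (ncons > 0) {
      int it = rattle_v(v, x, c, m, vtol);
      if (it < 0)
        stop("RATTLE velocity projection failed at step %d", step);
    }
    if (thermostat) {
      double ke = kinetic(v, m);
      double t_inst = 2.0 * ke / (ndof * KB);
      if (t_inst <= 0)
        stop("degenerate state: non-positive instantaneous temperature at "
             "step %d",
             step);
      double lam = std::sqrt(1.0 + (dt / tau_t) * (t_target / t_inst - 1.0));
      for (int i = 0; i < n; ++i) v[i] = lam * v[i];
    }
    if (step % save_interval == 0) {
      for (int i = 0; i < n; ++i) {
        frames[fr * 3 * n + 0 * n + i] = x[i].x;
        frames[fr * 3 * n + 1 * n + i] = x[i].y;
        frames[fr * 3 * n + 2 * n + i] = x[i].z;
      }
      steps[fr] = step;
      if (save_energies) {
        pot[fr] = E;
        kin[fr] = kinetic(v, m);
      }
      ++fr;
    }
  }
  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i) {
    xout(i, 0) = x[i].x; xout(i, 1) = x[i].y; xout(i, 2) = x[i].z;
    vout(i, 0) = v[i].x; vout(i, 1) = v[i].y; vout(i, 2) = v[i].z;
  }
  List out = List::create(
      _["frames"] = frames, _["step_indices"] = steps, _["final_positions"] =
          xout,
      _["final_velocities"] = vout);
  if (save_energies) {
    out["potential"] = pot;
    out["kinetic"] = kin;
  }
  return out;
}
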