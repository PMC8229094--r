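// Analytic 2D magnetostatics of uniformly magnetized rectangles (equivalent
// surface-charge sheets) and the overdamped trajectory integrator.
//
// Geometry convention: x along the flow axis, z normal to the array,
// z = 0 at the magnet top surface, channel interior z in [wall, wall+height].
//
// A segment row is (type, a1, a2, pos, coef):
//   type 0: horizontal charge sheet at z = pos spanning x in [a1, a2]
//   type 1: vertical   charge sheet at x = pos spanning z in [a1, a2]
//   coef = mu0 * sigma / (2*pi), sigma = M . n  (A/m)

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Field2D {
  int n;
  const double *type, *a1, *a2, *pos, *coef;

  explicit Field2D(const NumericMatrix& segs)
    : n(segs.nrow()), type(&segs(0, 0)), a1(&segs(0, 1)), a2(&segs(0, 2)),
      pos(&segs(0, 3)), coef(&segs(0, 4)) {
    // column pointers are valid because NumericMatrix is column-major
  }

  // B field (Tesla) and, if deriv, S1 = dBx/dx and S2 = dBx/dz.
  // Outside the magnets dBz/dx = S2 and dBz/dz = -S1 (curl- and div-free).
  void eval(double x, double z, double& Bx, double& Bz,
            double& S1, double& S2, bool deriv) const {
    Bx = Bz = S1 = S2 = 0.0;
    const double eps = 1e-9, eps2 = 1e-18;  // 1 nm corner regularization
    for (int k = 0; k < n; ++k) {
      double u1, u2, a;
      bool horiz = type[k] < 0.5;
      if (horiz) { u1 = x - a1[k]; u2 = x - a2[k]; a = z - pos[k]; }
      else       { u1 = z - a1[k]; u2 = z - a2[k]; a = x - pos[k]; }
      double r1 = u1 * u1 + a * a, r2 = u2 * u2 + a * a;
      if (r1 < eps2 || r2 < eps2) {
        a += (a >= 0.0) ? eps : -eps;
        r1 = u1 * u1 + a * a; r2 = u2 * u2 + a * a;
      }
      double c = coef[k];
      double blog = 0.5 * c * (std::log(r1) - std::log(r2));
      double batn = c * (std::atan(u1 / a) - std::atan(u2 / a));
      if (horiz) { Bx += blog; Bz += batn; } else { Bz += blog; Bx += batn; }
      if (deriv) {
        double d1 = c * (u1 / r1 - u2 / r2);
        double d2 = c * (a / r1 - a / r2);
        if (horiz) { S1 += d1; S2 += d2; } else { S1 -= d1; S2 += d2; }
      }
    }
  }

  // |B| and its gradient (analytic)
  void mag_grad(double x, double z, double& Bm, double& gx, double& gz) const {
    double Bx, Bz, S1, S2;
    eval(x, z, Bx, Bz, S1, S2, true);
    Bm = std::hypot(Bx, Bz);
    if (Bm > 0.0) {
      gx = (Bx * S1 + Bz * S2) / Bm;
      gz = (Bx * S2 - Bz * S1) / Bm;
    } else {
      gx = gz = 0.0;
    }
  }
};

// Bilinear table of |B|, d|B|/dx, d|B|/dz on a rectilinear grid.
struct FieldGrid {
  double x0, dx, z0, dz;
  int nx, nz;
  const double *Bm, *Gx, *Gz;  // each nx*nz, index i*nz + j

  void interp(double x, double z, double& B, double& gx, double& gz) const {
    double fx = (x - x0) / dx, fz = (z - z0) / dz;
    int i = (int)std::floor(fx), j = (int)std::floor(fz);
    if (i < 0) i = 0; if (i > nx - 2) i = nx - 2;
    if (j < 0) j = 0; if (j > nz - 2) j = nz - 2;
    double tx = fx - i, tz = fz - j;
    if (tx < 0) tx = 0; if (tx > 1) tx = 1;
    if (tz < 0) tz = 0; if (tz > 1) tz = 1;
    int i00 = i * nz + j, i10 = (i + 1) * nz + j;
    double w00 = (1 - tx) * (1 - tz), w01 = (1 - tx) * tz;
    double w10 = tx * (1 - tz), w11 = tx * tz;
    B  = w00 * Bm[i00] + w01 * Bm[i00 + 1] + w10 * Bm[i10] + w11 * Bm[i10 + 1];
    gx = w00 * Gx[i00] + w01 * Gx[i00 + 1] + w10 * Gx[i10] + w11 * Gx[i10 + 1];
    gz = w00 * Gz[i00] + w01 * Gz[i00 + 1] + w10 * Gz[i10] + w11 * Gz[i10 + 1];
  }
};

struct SimParams {
  int force_mode;       // 0 grid, 1 exact, 2 constant force, 3 none
  int variant;          // 0 arctan, 1 saturated, 2 linear
  double m_s, Bs;       // moment law (Am^2, T)
  double Fcx, Fcz;      // constant-force mode (N)
  double wall, hch, length, vmean;
  double invdrag;       // 1/(6 pi eta r)
  double Fg;            // signed gravitational force on z (N)
  double zcap, ztop;    // capture plane and top clearance (absolute z)
  double tmax, rtol, atol;
  const Field2D* fld;
  const FieldGrid* grid;

  double moment(double B) const {
    switch (variant) {
      case 1: return m_s;
      case 2: return M_2_PI * (m_s / Bs) * B;        // 2/pi * m_s/Bs * B
      default: return M_2_PI * m_s * std::atan(B / Bs);
    }
  }

  void mag_force(double x, double z, double& Fx, double& Fz) const {
    if (force_mode == 3) { Fx = Fz = 0.0; return; }
    if (force_mode == 2) { Fx = Fcx; Fz = Fcz; return; }
    double B, gx, gz;
    if (force_mode == 0) grid->interp(x, z, B, gx, gz);
    else fld->mag_grad(x, z, B, gx, gz);
    double m = moment(B);
    Fx = m * gx; Fz = m * gz;
  }

  void rhs(double x, double z, double& dx, double& dz) const {
    double zl = z - wall;
    if (zl < 0) zl = 0; else if (zl > hch) zl = hch;
    double vf = 6.0 * vmean * (zl / hch) * (1.0 - zl / hch);
    double Fx, Fz;
    mag_force(x, z, Fx, Fz);
    dx = vf + Fx * invdrag;
    dz = (Fz + Fg) * invdrag;
    if (z >= ztop && dz > 0) dz = 0.0;  // cell cannot overlap the far wall
  }
};

// Dormand-Prince 5(4) with standard step control and capture/exit events.
// outcome: 0 captured, 1 exited, 2 stalled
struct TrajOut { int outcome; double capture_x; double t_end; };

TrajOut integrate_cell(const SimParams& P, double z0,
                       std::vector<double>* path = nullptr) {
  static const double
    a21 = 1.0 / 5,
    a31 = 3.0 / 40, a32 = 9.0 / 40,
    a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9,
    a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
    a54 = -212.0 / 729,
    a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
    a64 = 49.0 / 176, a65 = -5103.0 / 18656,
    b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
    b5 = -2187.0 / 6784, b6 = 11.0 / 84,
    e1 = 35.0 / 384 - 5179.0 / 57600, e3 = 500.0 / 1113 - 7571.0 / 16695,
    e4 = 125.0 / 192 - 393.0 / 640, e5 = -2187.0 / 6784 + 92097.0 / 339200,
    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

  double t = 0.0, x = 0.0, z = z0;
  double k1x, k1z;
  P.rhs(x, z, k1x, k1z);
  double h = 1e-3;
  TrajOut out{2, NA_REAL, 0.0};
  if (path) { path->push_back(t); path->push_back(x); path->push_back(z); }
  if (z <= P.zcap) { out.outcome = 0; out.capture_x = x; return out; }

  int iter = 0;
  while (t < P.tmax) {
    if (++iter > 2000000) break;                      // defensive: stalled
    if (h < 1e-12) break;                             // step underflow: stalled
    if (t + h > P.tmax) h = P.tmax - t;

    double k2x, k2z, k3x, k3z, k4x, k4z, k5x, k5z, k6x, k6z, k7x, k7z;
    P.rhs(x + h * a21 * k1x, z + h * a21 * k1z, k2x, k2z);
    P.rhs(x + h * (a31 * k1x + a32 * k2x), z + h * (a31 * k1z + a32 * k2z),
          k3x, k3z);
    P.rhs(x + h * (a41 * k1x + a42 * k2x + a43 * k3x),
          z + h * (a41 * k1z + a42 * k2z + a43 * k3z), k4x, k4z);
    P.rhs(x + h * (a51 * k1x + a52 * k2x + a53 * k3x + a54 * k4x),
          z + h * (a51 * k1z + a52 * k2z + a53 * k3z + a54 * k4z), k5x, k5z);
    P.rhs(x + h * (a61 * k1x + a62 * k2x + a63 * k3x + a64 * k4x + a65 * k5x),
          z + h * (a61 * k1z + a62 * k2z + a63 * k3z + a64 * k4z + a65 * k5z),
          k6x, k6z);
    double xn = x + h * (b1 * k1x + b3 * k3x + b4 * k4x + b5 * k5x + b6 * k6x);
    double zn = z + h * (b1 * k1z + b3 * k3z + b4 * k4z + b5 * k5z + b6 * k6z);
    P.rhs(xn, zn, k7x, k7z);
    double ex = h * (e1 * k1x + e3 * k3x + e4 * k4x + e5 * k5x + e6 * k6x +
                     e7 * k7x);
    double ez = h * (e1 * k1z + e3 * k3z + e4 * k4z + e5 * k5z + e6 * k6z +
                     e7 * k7z);
    double sx = P.atol + P.rtol * std::max(std::fabs(x), std::fabs(xn));
    double sz = P.atol + P.rtol * std::max(std::fabs(z), std::fabs(zn));
    double err = std::sqrt(0.5 * ((ex / sx) * (ex / sx) +
                                  (ez / sz) * (ez / sz)));
    if (err <= 1.0) {
      double tprev = t, xprev = x, zprev = z;
      t += h; x = xn; z = zn;
      k1x = k7x; k1z = k7z;  // FSAL
      if (path) { path->push_back(t); path->push_back(x); path->push_back(z); }
      if (z <= P.zcap) {
        double f = (zprev - P.zcap) / (zprev - z);
        out.outcome = 0;
        out.capture_x = xprev + f * (x - xprev);
        out.t_end = tprev + f * h;
        if (out.capture_x < 0) out.capture_x = 0;
        if (out.capture_x > P.length) { out.outcome = 1; out.capture_x = NA_REAL; }
        return out;
      }
      if (x >= P.length) { out.outcome = 1; out.t_end = t; return out; }
    }
    double fac = (err > 1e-10) ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2; if (fac > 5.0) fac = 5.0;
    h *= fac;
  }
  out.t_end = t;
  return out;  // stalled
}

SimParams make_params(const List& pars, const Field2D* fld,
                      const FieldGrid* grid) {
  SimParams P;
  P.force_mode = as<int>(pars["force_mode"]);
  P.variant = as<int>(pars["variant"]);
  P.m_s = as<double>(pars["m_s"]);
  P.Bs = as<double>(pars["Bs"]);
  P.Fcx = as<double>(pars["Fcx"]);
  P.Fcz = as<double>(pars["Fcz"]);
  P.wall = as<double>(pars["wall"]);
  P.hch = as<double>(pars["height"]);
  P.length = as<double>(pars["length"]);
  P.vmean = as<double>(pars["vmean"]);
  P.invdrag = as<double>(pars["invdrag"]);
  P.Fg = as<double>(pars["Fg"]);
  P.zcap = as<double>(pars["zcap"]);
  P.ztop = as<double>(pars["ztop"]);
  P.tmax = as<double>(pars["tmax"]);
  P.rtol = as<double>(pars["rtol"]);
  P.atol = as<double>(pars["atol"]);
  P.fld = fld;
  P.grid = grid;
  return P;
}

FieldGrid make_grid(const List& g, const NumericVector& tab) {
  FieldGrid G;
  G.x0 = as<double>(g["x0"]); G.dx = as<double>(g["dx"]);
  G.z0 = as<double>(g["z0"]); G.dz = as<double>(g["dz"]);
  G.nx = as<int>(g["nx"]); G.nz = as<int>(g["nz"]);
  int nn = G.nx * G.nz;
  G.Bm = &tab[0]; G.Gx = &tab[nn]; G.Gz = &tab[2 * nn];
  return G;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_field(NumericMatrix segs, NumericVector x, NumericVector z,
                        bool deriv = false) {
  Field2D F(segs);
  int n = x.size();
  NumericMatrix out(n, deriv ? 4 : 2);
  double Bx, Bz, S1, S2;
  for (int i = 0; i < n; ++i) {
    F.eval(x[i], z[i], Bx, Bz, S1, S2, deriv);
    out(i, 0) = Bx; out(i, 1) = Bz;
    if (deriv) { out(i, 2) = S1; out(i, 3) = S2; }
  }
  return out;
}

// Table of |B| and its analytic gradient on a grid, index i*nz + j,
// laid out as three stacked blocks (Bm, Gx, Gz).
// [[Rcpp::export]]
NumericVector cpp_field_grid(NumericMatrix segs, double x0, double dx, int nx,
                             double z0, double dz, int nz) {
  Field2D F(segs);
  NumericVector out(3 * nx * nz);
  int nn = nx * nz;
  double Bm, gx, gz;
  for (int i = 0; i < nx; ++i) {
    double x = x0 + i * dx;
    for (int j = 0; j < nz; ++j) {
      F.mag_grad(x, z0 + j * dz, Bm, gx, gz);
      int id = i * nz + j;
      out[id] = Bm; out[nn + id] = gx; out[2 * nn + id] = gz;
    }
  }
  return out;
}

// Batch simulation: every start height against every saturation moment.
// [[Rcpp::export]]
List cpp_simulate_batch(List pars, NumericVector start_z, NumericVector m_s,
                        Nullable<NumericMatrix> segs,
                        Nullable<List> gridspec,
                        Nullable<NumericVector> gridtab) {
  Field2D* fld = nullptr;
  NumericMatrix segs_;
  if (segs.isNotNull()) { segs_ = segs.get(); fld = new Field2D(segs_); }
  FieldGrid grid;
  bool has_grid = gridspec.isNotNull();
  NumericVector tab;
  if (has_grid) { tab = gridtab.get(); grid = make_grid(gridspec.get(), tab); }

  int nc = start_z.size(), nm = m_s.size();
  IntegerMatrix outcome(nc, nm);
  NumericMatrix capx(nc, nm);
  SimParams P = make_params(pars, fld, has_grid ? &grid : nullptr);
  for (int m = 0; m < nm; ++m) {
    P.m_s = m_s[m];
    for (int c = 0; c < nc; ++c) {
      TrajOut o = integrate_cell(P, start_z[c]);
      outcome(c, m) = o.outcome;
      capx(c, m) = o.capture_x;
    }
  }
  if (fld) delete fld;
  return List::create(_["outcome"] = outcome, _["capture_x"] = capx);
}

// Single trajectory with recorded path.
// [[Rcpp::export]]
List cpp_trajectory(List pars, double start_z,
                    Nullable<NumericMatrix> segs,
                    Nullable<List> gridspec,
                    Nullable<NumericVector> gridtab) {
  Field2D* fld = nullptr;
  NumericMatrix segs_;
  if (segs.isNotNull()) { segs_ = segs.get(); fld = new Field2D(segs_); }
  FieldGrid grid;
  bool has_grid = gridspec.isNotNull();
  NumericVector tab;
  if (has_grid) { tab = gridtab.get(); grid = make_grid(gridspec.get(), tab); }
  SimParams P = make_params(pars, fld, has_grid ? &grid : nullptr);
  std::vector<double> path;
  TrajOut o = integrate_cell(P, start_z, &path);
  int np = path.size() / 3;
  NumericMatrix pm(np, 3);
  for (int i = 0; i < np; ++i) {
    pm(i, 0) = path[3 * i]; pm(i, 1) = path[3 * i + 1];
    pm(i, 2) = path[3 * i + 2];
  }
  colnames(pm) = CharacterVector::create("t", "x", "z");
  if (fld) delete fld;
  return List::create(_["outcome"] = o.outcome, _["capture_x"] = o.capture_x,
                      _["t_end"] = o.t_end, _["path"] = pm);
}
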