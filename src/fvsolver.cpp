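// Cell-centred finite-volume solver for steady incompressible 2D flow on
// triangle meshes: SIMPLEC pressure-velocity coupling with Rhie-Chow flux
// interpolation, first/second-order upwind convection (second order via
// deferred correction with least-squares gradients), and an optional
// k-epsilon closure (standard or RNG) with equilibrium wall functions.
// Approximate inner solves: symmetric Gauss-Seidel for transported scalars,
// DIC-preconditioned conjugate gradients for the pressure correction.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Topo {
  int nc, nn, nf;
  // faces
  std::vector<int> fn1, fn2, fown, fneigh, ftag; // tag: 0 int, 1 inlet, 2 outlet, 3 wall
  std::vector<double> sfx, sfy, farea, fcx, fcy;
  std::vector<double> ddx, ddy, dmag, aOverD, wf;
  std::vector<int> fsign;                 // +1 if Sf is the right-normal of n1->n2
  // cells
  std::vector<double> cx, cy, vol;
  std::vector<int> cface;                 // 3 per cell
  // least-squares gradient: per-cell inverse normal matrix
  std::vector<double> g11, g12, g22;
  double inlet_width = 0.0;
};

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

void build_topology(const NumericMatrix& nodes, const IntegerMatrix& tris,
                    const IntegerMatrix& bedges, const IntegerVector& btags,
                    Topo& tp) {
  const int nc = tris.nrow(), nn = nodes.nrow();
  tp.nc = nc; tp.nn = nn;
  tp.cx.assign(nc, 0.0); tp.cy.assign(nc, 0.0); tp.vol.assign(nc, 0.0);
  for (int c = 0; c < nc; ++c) {
    int a = tris(c, 0) - 1, b = tris(c, 1) - 1, d = tris(c, 2) - 1;
    double x1 = nodes(a, 0), y1 = nodes(a, 1), x2 = nodes(b, 0), y2 = nodes(b, 1),
           x3 = nodes(d, 0), y3 = nodes(d, 1);
    double ar = 0.5 * ((x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1));
    if (ar <= 0) stop("triangle %d is not positively oriented", c + 1);
    tp.vol[c] = ar;
    tp.cx[c] = (x1 + x2 + x3) / 3.0;
    tp.cy[c] = (y1 + y2 + y3) / 3.0;
  }
  // boundary tag lookup
  std::unordered_map<int64_t, int> btag_of;
  btag_of.reserve(bedges.nrow() * 2);
  for (int i = 0; i < bedges.nrow(); ++i) {
    int a = bedges(i, 0) - 1, b = bedges(i, 1) - 1;
    int64_t key = (int64_t)std::min(a, b) * nn + std::max(a, b);
    btag_of[key] = btags[i];
  }
  std::unordered_map<int64_t, int> face_of;
  face_of.reserve(nc * 2);
  tp.cface.assign(3 * nc, -1);
  for (int c = 0; c < nc; ++c) {
    for (int e = 0; e < 3; ++e) {
      int a = tris(c, e) - 1, b = tris(c, (e + 1) % 3) - 1;
      int64_t key = (int64_t)std::min(a, b) * nn + std::max(a, b);
      auto it = face_of.find(key);
      if (it == face_of.end()) {
        int f = (int)tp.fn1.size();
        face_of[key] = f;
        tp.fn1.push_back(a); tp.fn2.push_back(b);
        tp.fown.push_back(c); tp.fneigh.push_back(-1);
        tp.ftag.push_back(0);
        tp.cface[3 * c + e] = f;
      } else {
        int f = it->second;
        if (tp.fneigh[f] != -1) stop("edge shared by more than two triangles");
        tp.fneigh[f] = c;
        tp.cface[3 * c + e] = f;
      }
    }
  }
  tp.nf = (int)tp.fn1.size();
  tp.sfx.assign(tp.nf, 0); tp.sfy.assign(tp.nf, 0); tp.farea.assign(tp.nf, 0);
  tp.fcx.assign(tp.nf, 0); tp.fcy.assign(tp.nf, 0);
  tp.ddx.assign(tp.nf, 0); tp.ddy.assign(tp.nf, 0); tp.dmag.assign(tp.nf, 0);
  tp.aOverD.assign(tp.nf, 0); tp.wf.assign(tp.nf, 0.5);
  tp.fsign.assign(tp.nf, 1);
  tp.inlet_width = 0.0;
  for (int f = 0; f < tp.nf; ++f) {
    int a = tp.fn1[f], b = tp.fn2[f];
    double tx = nodes(b, 0) - nodes(a, 0), ty = nodes(b, 1) - nodes(a, 1);
    double len = std::sqrt(tx * tx + ty * ty);
    tp.farea[f] = len;
    tp.fcx[f] = 0.5 * (nodes(a, 0) + nodes(b, 0));
    tp.fcy[f] = 0.5 * (nodes(a, 1) + nodes(b, 1));
    // right-normal of the edge direction
    double nx = ty, ny = -tx;
    int P = tp.fown[f];
    // orient Sf outward from the owner
    if (nx * (tp.fcx[f] - tp.cx[P]) + ny * (tp.fcy[f] - tp.cy[P]) < 0) {
      nx = -nx; ny = -ny; tp.fsign[f] = -1;
    }
    tp.sfx[f] = nx; tp.sfy[f] = ny;
    int N = tp.fneigh[f];
    if (N >= 0) {
      tp.ddx[f] = tp.cx[N] - tp.cx[P];
      tp.ddy[f] = tp.cy[N] - tp.cy[P];
      double dP = std::hypot(tp.fcx[f] - tp.cx[P], tp.fcy[f] - tp.cy[P]);
      double dN = std::hypot(tp.fcx[f] - tp.cx[N], tp.fcy[f] - tp.cy[N]);
      tp.wf[f] = dN / std::max(dP + dN, 1e-300);
    } else {
      tp.ddx[f] = tp.fcx[f] - tp.cx[P];
      tp.ddy[f] = tp.fcy[f] - tp.cy[P];
      tp.wf[f] = 1.0;
      int64_t key = (int64_t)std::min(a, b) * nn + std::max(a, b);
      auto it = btag_of.find(key);
      if (it == btag_of.end()) stop("boundary face without a tag (malformed mesh)");
      tp.ftag[f] = it->second;
      if (tp.ftag[f] == 1) tp.inlet_width += len;
    }
    double dm = std::hypot(tp.ddx[f], tp.ddy[f]);
    tp.dmag[f] = dm;
    double sd = tp.sfx[f] * tp.ddx[f] + tp.sfy[f] * tp.ddy[f];
    double s2 = tp.farea[f] * tp.farea[f];
    sd = std::max(sd, 0.05 * tp.farea[f] * dm);   // non-orthogonality clip
    tp.aOverD[f] = s2 / sd;
  }
  // least-squares gradient normal matrices
  std::vector<double> a11(nc, 0), a12(nc, 0), a22(nc, 0);
  for (int f = 0; f < tp.nf; ++f) {
    double dx = tp.ddx[f], dy = tp.ddy[f];
    double w = 1.0 / std::max(dx * dx + dy * dy, 1e-300);
    int P = tp.fown[f], N = tp.fneigh[f];
    a11[P] += w * dx * dx; a12[P] += w * dx * dy; a22[P] += w * dy * dy;
    if (N >= 0) { a11[N] += w * dx * dx; a12[N] += w * dx * dy; a22[N] += w * dy * dy; }
  }
  tp.g11.assign(nc, 0); tp.g12.assign(nc, 0); tp.g22.assign(nc, 0);
  for (int c = 0; c < nc; ++c) {
    double det = a11[c] * a22[c] - a12[c] * a12[c];
    if (std::fabs(det) < 1e-300) stop("degenerate gradient stencil in cell %d", c + 1);
    tp.g11[c] = a22[c] / det; tp.g12[c] = -a12[c] / det; tp.g22[c] = a11[c] / det;
  }
}

// Least-squares gradient of a cell field. bval holds boundary-face values;
// passing the owner value there encodes a zero-gradient boundary.
void lsq_gradient(const Topo& tp, const std::vector<double>& phi,
                  const std::vector<double>& bval,
                  std::vector<double>& gx, std::vector<double>& gy) {
  const int nc = tp.nc;
  std::vector<double> bx(nc, 0.0), by(nc, 0.0);
  for (int f = 0; f < tp.nf; ++f) {
    double dx = tp.ddx[f], dy = tp.ddy[f];
    double w = 1.0 / std::max(dx * dx + dy * dy, 1e-300);
    int P = tp.fown[f], N = tp.fneigh[f];
    double dphi = (N >= 0 ? phi[N] : bval[f]) - phi[P];
    bx[P] += w * dx * dphi; by[P] += w * dy * dphi;
    if (N >= 0) { bx[N] += w * dx * dphi; by[N] += w * dy * dphi; }
  }
  for (int c = 0; c < nc; ++c) {
    gx[c] = tp.g11[c] * bx[c] + tp.g12[c] * by[c];
    gy[c] = tp.g12[c] * bx[c] + tp.g22[c] * by[c];
  }
}

// Barth-Jespersen limiter: scales each cell gradient so reconstructed face
// values stay within the min/max of the cell and its face neighbours.
void bj_limiter(const Topo& tp, const std::vector<double>& phi,
                const std::vector<double>& bval,
                const std::vector<double>& gx, const std::vector<double>& gy,
                std::vector<double>& alpha, double venkat_k2) {
  const int nc = tp.nc;
  std::vector<double> phimin(phi), phimax(phi);
  for (int f = 0; f < tp.nf; ++f) {
    int P = tp.fown[f], N = tp.fneigh[f];
    double vN = (N >= 0) ? phi[N] : bval[f];
    phimin[P] = std::min(phimin[P], vN);
    phimax[P] = std::max(phimax[P], vN);
    if (N >= 0) {
      phimin[N] = std::min(phimin[N], phi[P]);
      phimax[N] = std::max(phimax[N], phi[P]);
    }
  }
  std::fill(alpha.begin(), alpha.end(), 1.0);
  for (int c = 0; c < nc; ++c) {
    double range = phimax[c] - phimin[c];
    double eps2 = venkat_k2 * range * range + 1e-300;
    for (int e = 0; e < 3; ++e) {
      int f = tp.cface[3 * c + e];
      double d2 = gx[c] * (tp.fcx[f] - tp.cx[c]) + gy[c] * (tp.fcy[f] - tp.cy[c]);
      if (std::fabs(d2) < 1e-300) continue;
      double d1 = (d2 > 0 ? phimax[c] : phimin[c]) - phi[c];
      double a;
      if (venkat_k2 > 0) {
        // Venkatakrishnan's smooth form
        a = ((d1 * d1 + eps2) + 2.0 * d2 * d1) /
            (d1 * d1 + 2.0 * d2 * d2 + d1 * d2 + eps2);
      } else {
        a = d1 / d2;            // plain Barth-Jespersen
      }
      alpha[c] = std::min(alpha[c], std::max(0.0, std::min(1.0, a)));
    }
  }
}

// Symmetric Gauss-Seidel sweeps on the compact cell-face matrix.
void gs_solve(const Topo& tp, const std::vector<double>& diag,
              const std::vector<double>& off, const std::vector<double>& rhs,
              std::vector<double>& x, int nsweep) {
  const int nc = tp.nc;
  for (int s = 0; s < nsweep; ++s) {
    for (int c = 0; c < nc; ++c) {
      double acc = rhs[c];
      for (int e = 0; e < 3; ++e) {
        int f = tp.cface[3 * c + e];
        int N = (tp.fown[f] == c) ? tp.fneigh[f] : tp.fown[f];
        if (N >= 0) acc -= off[3 * c + e] * x[N];
      }
      x[c] = acc / diag[c];
    }
    for (int c = nc - 1; c >= 0; --c) {
      double acc = rhs[c];
      for (int e = 0; e < 3; ++e) {
        int f = tp.cface[3 * c + e];
        int N = (tp.fown[f] == c) ? tp.fneigh[f] : tp.fown[f];
        if (N >= 0) acc -= off[3 * c + e] * x[N];
      }
      x[c] = acc / diag[c];
    }
  }
}

double gs_residual(const Topo& tp, const std::vector<double>& diag,
                   const std::vector<double>& off, const std::vector<double>& rhs,
                   const std::vector<double>& x, double& scale) {
  double r = 0.0; scale = 0.0;
  for (int c = 0; c < tp.nc; ++c) {
    double acc = diag[c] * x[c];
    for (int e = 0; e < 3; ++e) {
      int f = tp.cface[3 * c + e];
      int N = (tp.fown[f] == c) ? tp.fneigh[f] : tp.fown[f];
      if (N >= 0) acc += off[3 * c + e] * x[N];
    }
    r += std::fabs(rhs[c] - acc);
    scale += std::fabs(diag[c] * x[c]);
  }
  return r;
}

// Matrix-vector product for the (symmetric) pressure-correction system.
void pmatvec(const Topo& tp, const std::vector<double>& diag,
             const std::vector<double>& coef, const std::vector<double>& x,
             std::vector<double>& y) {
  const int nc = tp.nc;
  for (int c = 0; c < nc; ++c) y[c] = diag[c] * x[c];
  for (int f = 0; f < tp.nf; ++f) {
    int N = tp.fneigh[f];
    if (N < 0) continue;
    int P = tp.fown[f];
    y[P] -= coef[f] * x[N];
    y[N] -= coef[f] * x[P];
  }
}

// DIC-preconditioned conjugate gradients (Dirichlet closure via boundary
// coefficients folded into the diagonal, so the system is SPD).
int pcg_solve(const Topo& tp, const std::vector<double>& diag,
              const std::vector<double>& coef, const std::vector<double>& rhs,
              std::vector<double>& x, double reltol, int maxit) {
  const int nc = tp.nc;
  // faces ordered by the higher cell index for the factorization and sweeps
  std::vector<int> ford;
  ford.reserve(tp.nf);
  for (int f = 0; f < tp.nf; ++f) if (tp.fneigh[f] >= 0) ford.push_back(f);
  std::sort(ford.begin(), ford.end(), [&](int a, int b) {
    return std::max(tp.fown[a], tp.fneigh[a]) < std::max(tp.fown[b], tp.fneigh[b]);
  });
  // DIC diagonal (processed in ascending higher-index order so lower
  // diagonals are final when used)
  std::vector<double> rd(diag);
  for (size_t i = 0; i < ford.size(); ++i) {
    int f = ford[i];
    int P = tp.fown[f], N = tp.fneigh[f];
    int lo = std::min(P, N), hi = std::max(P, N);
    rd[hi] -= coef[f] * coef[f] / rd[lo];
  }
  for (int c = 0; c < nc; ++c) rd[c] = 1.0 / rd[c];
  auto precond = [&](const std::vector<double>& r, std::vector<double>& w) {
    for (int c = 0; c < nc; ++c) w[c] = r[c] * rd[c];
    for (int idx = 0; idx < (int)ford.size(); ++idx) {
      int f = ford[idx];
      int P = tp.fown[f], N = tp.fneigh[f];
      int lo = std::min(P, N), hi = std::max(P, N);
      w[hi] += rd[hi] * coef[f] * w[lo];
    }
    for (int idx = (int)ford.size() - 1; idx >= 0; --idx) {
      int f = ford[idx];
      int P = tp.fown[f], N = tp.fneigh[f];
      int lo = std::min(P, N), hi = std::max(P, N);
      w[lo] += rd[lo] * coef[f] * w[hi];
    }
  };
  std::vector<double> r(rhs), w(nc), p(nc), q(nc);
  for (int c = 0; c < nc; ++c) x[c] = 0.0;
  double r0 = 0.0;
  for (int c = 0; c < nc; ++c) r0 += std::fabs(r[c]);
  if (r0 < 1e-300) return 0;
  precond(r, w);
  p = w;
  double rho_old = 0.0;
  for (int c = 0; c < nc; ++c) rho_old += r[c] * w[c];
  int it = 0;
  for (; it < maxit; ++it) {
    pmatvec(tp, diag, coef, p, q);
    double pq = 0.0;
    for (int c = 0; c < nc; ++c) pq += p[c] * q[c];
    if (std::fabs(pq) < 1e-300) break;
    double alpha = rho_old / pq;
    double rn = 0.0;
    for (int c = 0; c < nc; ++c) {
      x[c] += alpha * p[c];
      r[c] -= alpha * q[c];
      rn += std::fabs(r[c]);
    }
    if (rn < reltol * r0) { ++it; break; }
    precond(r, w);
    double rho_new = 0.0;
    for (int c = 0; c < nc; ++c) rho_new += r[c] * w[c];
    double beta = rho_new / rho_old;
    rho_old = rho_new;
    for (int c = 0; c < nc; ++c) p[c] = w[c] + beta * p[c];
  }
  return it;
}

} // namespace

// [[Rcpp::export]]
List fv_solve(NumericMatrix nodes, IntegerMatrix tris, IntegerMatrix bedges,
              IntegerVector btags, List opt) {
  Topo tp;
  build_topology(nodes, tris, bedges, btags, tp);
  const int nc = tp.nc, nf = tp.nf, nn = tp.nn;

  const double rho = as<double>(opt["rho"]);
  const double mu = as<double>(opt["mu"]);
  const double p_in = as<double>(opt["p_in"]);
  const double p_out = as<double>(opt["p_out"]);
  const double intens = as<double>(opt["intensity"]);
  const int turb = as<int>(opt["turb_mode"]);      // 0 laminar, 1 std k-eps, 2 RNG
  const int scheme = as<int>(opt["scheme"]);       // 1 upwind, 2 second-order upwind
  const double urf_u = as<double>(opt["urf_u"]);
  const double urf_p = as<double>(opt["urf_p"]);
  const double urf_t = as<double>(opt["urf_t"]);
  const double tol = as<double>(opt["tol"]);
  const double tol_c = as<double>(opt["tol_continuity"]);
  const double tol_turb = as<double>(opt["tol_turb"]);
  const int max_iter = as<int>(opt["max_iter"]);
  const int ramp_iters = as<int>(opt["ramp_iters"]);
  const int gs_sweeps = as<int>(opt["gs_sweeps"]);
  const double pcg_tol = as<double>(opt["pcg_tol"]);
  const int pcg_maxit = as<int>(opt["pcg_maxit"]);
  const double ptc_cfl = as<double>(opt["ptc_cfl"]);
  const double venkat_k2 = as<double>(opt["venkat_k2"]);

  // turbulence constants
  const bool rng = (turb == 2);
  const double Cmu = rng ? 0.0845 : 0.09;
  const double C1e = rng ? 1.42 : 1.44;
  const double C2e = rng ? 1.68 : 1.92;
  const double sig_k = rng ? 0.7194 : 1.0;
  const double sig_e = rng ? 0.7194 : 1.3;
  const double eta0 = 4.38, beta_rng = 0.012;
  const double kappa = 0.4187, Ewall = 9.793;
  const double Cmu25 = std::pow(Cmu, 0.25), Cmu75 = std::pow(Cmu, 0.75);

  std::vector<double> u(nc, 0), v(nc, 0), p(nc, 0), pc(nc, 0);
  std::vector<double> kf(nc, 0), ef(nc, 0), mut(nc, 0);
  double Dh_in = 2.0 * tp.inlet_width;     // hydraulic diameter of a wide slot
  double k0 = 1.5 * intens * intens;       // intensity on a 1 m/s scale
  double l_in = 0.07 * std::max(Dh_in, 1e-6);
  double e0 = Cmu75 * std::pow(k0, 1.5) / l_in;
  if (turb > 0) {
    for (int c = 0; c < nc; ++c) { kf[c] = k0; ef[c] = e0; mut[c] = rho * Cmu * k0 * k0 / e0; }
  }
  SEXP init_sexp = opt.containsElementNamed("init") ? (SEXP)opt["init"] : R_NilValue;
  if (!Rf_isNull(init_sexp)) {
    List init(init_sexp);
    NumericVector iu = init["u"], iv = init["v"], ip = init["p"];
    if (iu.size() != nc) stop("init fields must have one value per cell");
    for (int c = 0; c < nc; ++c) { u[c] = iu[c]; v[c] = iv[c]; p[c] = ip[c]; }
    if (turb > 0 && init.containsElementNamed("k")) {
      NumericVector ik = init["k"], ie = init["epsilon"];
      for (int c = 0; c < nc; ++c) {
        kf[c] = std::max(ik[c], 1e-10);
        ef[c] = std::max(ie[c], 1e-12);
        mut[c] = clampd(rho * Cmu * kf[c] * kf[c] / ef[c], 0.0, 1e5 * mu);
      }
    }
  }
  std::vector<double> mdot(nf, 0.0), dP(nc, 0.0);
  std::vector<double> gpx(nc, 0), gpy(nc, 0), gux(nc, 0), guy(nc, 0),
      gvx(nc, 0), gvy(nc, 0);
  std::vector<double> diag(nc), off(3 * nc), rhsu(nc), rhsv(nc), rhs1(nc);
  std::vector<double> bval(nf, 0.0), bvalu(nf, 0.0), bvalv(nf, 0.0);
  std::vector<double> pdiag(nc), pcoef(nf), prhs(nc);
  std::vector<double> muw(nf, mu);         // wall effective viscosity
  std::vector<double> S2(nc, 0.0), resid_cell(nc, 0.0);
  std::vector<double> lim_u(nc, 1.0), lim_v(nc, 1.0), lim_s(nc, 1.0);
  // pseudo-transient continuation: local inertial damping rho*V/dtau with
  // dtau = ptc_cfl * h_cell / U_ref; vanishes from the converged solution
  // (it multiplies phi - phi_old) but tames the pressure-driven start-up
  double Uref = std::max(std::sqrt(2.0 * std::fabs(p_in - p_out) / rho), 0.05);
  std::vector<double> aPtc(nc, 0.0);
  if (ptc_cfl > 0)
    for (int c = 0; c < nc; ++c)
      aPtc[c] = rho * tp.vol[c] * Uref / (ptc_cfl * std::sqrt(tp.vol[c]));

  NumericMatrix resid(max_iter, 5);
  colnames(resid) = CharacterVector::create("u", "v", "continuity", "k", "epsilon");
  bool converged = false, diverged = false;
  int it_done = 0;
  long pcg_total = 0;
  double mass_imb = NA_REAL, flux_in = 0.0, flux_out = 0.0;

  for (int iter = 0; iter < max_iter; ++iter) {
    it_done = iter + 1;
    double ramp = ramp_iters > 0 ? std::min(1.0, (iter + 1.0) / ramp_iters) : 1.0;
    double p_in_eff = p_out + (p_in - p_out) * ramp;

    // --- pressure gradient ---
    for (int f = 0; f < nf; ++f) {
      if (tp.ftag[f] == 1) bval[f] = p_in_eff;
      else if (tp.ftag[f] == 2) bval[f] = p_out;
      else bval[f] = p[tp.fown[f]];        // wall: zero normal gradient
    }
    lsq_gradient(tp, p, bval, gpx, gpy);

    // --- velocity boundary values and gradients ---
    for (int f = 0; f < nf; ++f) {
      int P = tp.fown[f];
      if (tp.ftag[f] == 3) { bvalu[f] = 0.0; bvalv[f] = 0.0; }
      else if (tp.ftag[f] == 1) {
        double un = mdot[f] / (rho * tp.farea[f]);
        bvalu[f] = un * tp.sfx[f] / tp.farea[f];
        bvalv[f] = un * tp.sfy[f] / tp.farea[f];
      } else { bvalu[f] = u[P]; bvalv[f] = v[P]; }
    }
    lsq_gradient(tp, u, bvalu, gux, guy);
    lsq_gradient(tp, v, bvalv, gvx, gvy);
    if (scheme == 2) {
      bj_limiter(tp, u, bvalu, gux, guy, lim_u, venkat_k2);
      bj_limiter(tp, v, bvalv, gvx, gvy, lim_v, venkat_k2);
    }

    // --- wall functions (effective wall viscosity) ---
    if (turb > 0) {
      for (int f = 0; f < nf; ++f) {
        if (tp.ftag[f] != 3) continue;
        int P = tp.fown[f];
        double nxu = tp.sfx[f] / tp.farea[f], nyu = tp.sfy[f] / tp.farea[f];
        double yp = std::fabs(tp.ddx[f] * nxu + tp.ddy[f] * nyu);
        yp = std::max(yp, 1e-9);
        double ustar = Cmu25 * std::sqrt(std::max(kf[P], 1e-12));
        double ystar = rho * ustar * yp / mu;
        if (ystar > 11.225)
          muw[f] = rho * ustar * kappa * yp / std::log(Ewall * ystar);
        else muw[f] = mu;
      }
    }

    // --- momentum assembly ---
    std::fill(diag.begin(), diag.end(), 0.0);
    std::fill(off.begin(), off.end(), 0.0);
    for (int c = 0; c < nc; ++c) {
      rhsu[c] = -tp.vol[c] * gpx[c];
      rhsv[c] = -tp.vol[c] * gpy[c];
    }
    for (int f = 0; f < nf; ++f) {
      int P = tp.fown[f], N = tp.fneigh[f];
      double m = mdot[f];
      if (N >= 0) {
        double muf = mu + (turb > 0 ? tp.wf[f] * mut[P] + (1 - tp.wf[f]) * mut[N] : 0.0);
        double Df = muf * tp.aOverD[f];
        double aPN = -(Df + std::max(-m, 0.0));
        double aNP = -(Df + std::max(m, 0.0));
        // local face slots
        for (int e = 0; e < 3; ++e) if (tp.cface[3 * P + e] == f) off[3 * P + e] += aPN;
        for (int e = 0; e < 3; ++e) if (tp.cface[3 * N + e] == f) off[3 * N + e] += aNP;
        diag[P] += Df + std::max(m, 0.0);
        diag[N] += Df + std::max(-m, 0.0);
        // deferred second-order upwind correction
        if (scheme == 2) {
          int up = m >= 0 ? P : N;
          double rx = tp.fcx[f] - tp.cx[up], ry = tp.fcy[f] - tp.cy[up];
          double du = lim_u[up] * (gux[up] * rx + guy[up] * ry);
          double dv = lim_v[up] * (gvx[up] * rx + gvy[up] * ry);
          rhsu[P] -= m * du; rhsu[N] += m * du;
          rhsv[P] -= m * dv; rhsv[N] += m * dv;
        }
        // non-orthogonal diffusion correction
        double tx = tp.sfx[f] - tp.ddx[f] * tp.aOverD[f];
        double ty = tp.sfy[f] - tp.ddy[f] * tp.aOverD[f];
        double gfx = tp.wf[f] * gux[P] + (1 - tp.wf[f]) * gux[N];
        double gfy = tp.wf[f] * guy[P] + (1 - tp.wf[f]) * guy[N];
        double cu = muf * (gfx * tx + gfy * ty);
        gfx = tp.wf[f] * gvx[P] + (1 - tp.wf[f]) * gvx[N];
        gfy = tp.wf[f] * gvy[P] + (1 - tp.wf[f]) * gvy[N];
        double cv = muf * (gfx * tx + gfy * ty);
        rhsu[P] += cu; rhsu[N] -= cu;
        rhsv[P] += cv; rhsv[N] -= cv;
      } else if (tp.ftag[f] == 3) {        // wall: no-slip
        double Dw = (turb > 0 ? muw[f] : mu) * tp.aOverD[f];
        diag[P] += Dw;
      } else if (tp.ftag[f] == 1) {        // pressure inlet
        if (m < 0) {                       // inflow: normal-direction momentum
          rhsu[P] -= m * bvalu[f];
          rhsv[P] -= m * bvalv[f];
        } else {                           // local outflow: implicit upwind
          diag[P] += m;
        }
      } else {                              // pressure outlet
        diag[P] += std::max(m, 0.0);
      }
    }
    for (int c = 0; c < nc; ++c) {
      diag[c] += aPtc[c];
      rhsu[c] += aPtc[c] * u[c];
      rhsv[c] += aPtc[c] * v[c];
    }
    // residuals on the unrelaxed system
    double scale_u = 0.0, scale_v = 0.0, ru = 0.0, rv = 0.0;
    for (int c = 0; c < nc; ++c) {
      double au = diag[c] * u[c], av = diag[c] * v[c];
      for (int e = 0; e < 3; ++e) {
        int f = tp.cface[3 * c + e];
        int N = (tp.fown[f] == c) ? tp.fneigh[f] : tp.fown[f];
        if (N >= 0) { au += off[3 * c + e] * u[N]; av += off[3 * c + e] * v[N]; }
      }
      double rc_u = std::fabs(rhsu[c] - au), rc_v = std::fabs(rhsv[c] - av);
      ru += rc_u; rv += rc_v;
      resid_cell[c] = rc_u + rc_v;
      scale_u += std::fabs(diag[c] * u[c]); scale_v += std::fabs(diag[c] * v[c]);
    }
    double su_den = std::max(scale_u, 1e-14), sv_den = std::max(scale_v, 1e-14);
    // under-relax and solve
    for (int c = 0; c < nc; ++c) {
      double d0 = diag[c], dr = d0 / urf_u;
      rhsu[c] += (dr - d0) * u[c];
      rhsv[c] += (dr - d0) * v[c];
      diag[c] = dr;
    }
    gs_solve(tp, diag, off, rhsu, u, gs_sweeps);
    gs_solve(tp, diag, off, rhsv, v, gs_sweeps);

    // SIMPLEC coupling coefficient
    for (int c = 0; c < nc; ++c) {
      double s = diag[c];
      for (int e = 0; e < 3; ++e) s += off[3 * c + e];
      dP[c] = tp.vol[c] / std::max(s, 1e-300);
    }

    // --- face fluxes with Rhie-Chow interpolation ---
    for (int f = 0; f < nf; ++f) {
      int P = tp.fown[f], N = tp.fneigh[f];
      if (N >= 0) {
        double w = tp.wf[f];
        double ubSf = (w * u[P] + (1 - w) * u[N]) * tp.sfx[f] +
                      (w * v[P] + (1 - w) * v[N]) * tp.sfy[f];
        double Dfc = w * dP[P] + (1 - w) * dP[N];
        double gpd = (w * gpx[P] + (1 - w) * gpx[N]) * tp.ddx[f] +
                     (w * gpy[P] + (1 - w) * gpy[N]) * tp.ddy[f];
        mdot[f] = rho * (ubSf - Dfc * tp.aOverD[f] * ((p[N] - p[P]) - gpd));
        pcoef[f] = rho * Dfc * tp.aOverD[f];
      } else if (tp.ftag[f] == 3) {
        mdot[f] = 0.0; pcoef[f] = 0.0;
      } else {
        double pb = (tp.ftag[f] == 1) ? p_in_eff : p_out;
        double gpd = gpx[P] * tp.ddx[f] + gpy[P] * tp.ddy[f];
        double ubSf = u[P] * tp.sfx[f] + v[P] * tp.sfy[f];
        mdot[f] = rho * (ubSf - dP[P] * tp.aOverD[f] * ((pb - p[P]) - gpd));
        pcoef[f] = rho * dP[P] * tp.aOverD[f];
      }
    }

    // --- pressure correction ---
    double imb = 0.0;
    flux_in = 0.0; flux_out = 0.0;
    for (int c = 0; c < nc; ++c) { pdiag[c] = 0.0; prhs[c] = 0.0; }
    for (int f = 0; f < nf; ++f) {
      int P = tp.fown[f], N = tp.fneigh[f];
      if (N >= 0) {
        pdiag[P] += pcoef[f]; pdiag[N] += pcoef[f];
        prhs[P] -= mdot[f]; prhs[N] += mdot[f];
      } else {
        pdiag[P] += pcoef[f];
        prhs[P] -= mdot[f];
        if (tp.ftag[f] == 1) flux_in -= mdot[f] / rho;
        if (tp.ftag[f] == 2) flux_out += mdot[f] / rho;
      }
    }
    for (int c = 0; c < nc; ++c) imb += std::fabs(prhs[c]);
    double mflux_in = std::max(std::fabs(flux_in) * rho, 1e-10);
    double rc = imb / mflux_in;
    pcg_total += pcg_solve(tp, pdiag, pcoef, prhs, pc, pcg_tol, pcg_maxit);

    // corrections
    for (int f = 0; f < nf; ++f) {
      int P = tp.fown[f], N = tp.fneigh[f];
      if (N >= 0) mdot[f] += pcoef[f] * (pc[P] - pc[N]);
      else if (tp.ftag[f] != 3) mdot[f] += pcoef[f] * pc[P];
      bval[f] = (tp.ftag[f] == 0 || tp.ftag[f] == 3) ? pc[tp.fown[f]] : 0.0;
    }
    {
      std::vector<double> gcx(nc), gcy(nc);
      lsq_gradient(tp, pc, bval, gcx, gcy);
      for (int c = 0; c < nc; ++c) {
        p[c] += urf_p * pc[c];
        u[c] -= dP[c] * gcx[c];
        v[c] -= dP[c] * gcy[c];
      }
    }

    // --- turbulence ---
    double rk = 0.0, re = 0.0;
    if (turb > 0) {
      for (int c = 0; c < nc; ++c) {
        double sxx = gux[c], syy = gvy[c], sxy = guy[c] + gvx[c];
        S2[c] = 2.0 * (sxx * sxx + syy * syy) + sxy * sxy;
      }
      // inlet values from intensity and hydraulic diameter
      std::vector<double> kin(nf, 0.0), ein(nf, 0.0);
      for (int f = 0; f < nf; ++f) {
        if (tp.ftag[f] != 1) continue;
        double Uf = std::max(std::fabs(mdot[f]) / (rho * tp.farea[f]), 0.05);
        double kv = 1.5 * intens * intens * Uf * Uf;
        kin[f] = kv;
        ein[f] = Cmu75 * std::pow(kv, 1.5) / l_in;
      }
      // wall-cell production and dissipation from wall functions
      std::vector<double> Gk(nc, 0.0);
      std::vector<char> wallcell(nc, 0);
      std::vector<double> ewall(nc, 0.0), warea(nc, 0.0);
      for (int c = 0; c < nc; ++c) Gk[c] = std::min(mut[c] * S2[c], 10.0 * rho * ef[c]);
      for (int f = 0; f < nf; ++f) {
        if (tp.ftag[f] != 3) continue;
        int P = tp.fown[f];
        double nxu = tp.sfx[f] / tp.farea[f], nyu = tp.sfy[f] / tp.farea[f];
        double yp = std::max(std::fabs(tp.ddx[f] * nxu + tp.ddy[f] * nyu), 1e-9);
        double un = u[P] * nxu + v[P] * nyu;
        double utx = u[P] - un * nxu, uty = v[P] - un * nyu;
        double ut = std::hypot(utx, uty);
        double ustar = Cmu25 * std::sqrt(std::max(kf[P], 1e-12));
        double tauw = muw[f] * ut / yp;
        double gw = tauw * ustar / (kappa * yp);
        double ew = std::pow(ustar, 3) / (kappa * yp);
        if (!wallcell[P]) { Gk[P] = 0.0; ewall[P] = 0.0; warea[P] = 0.0; wallcell[P] = 1; }
        Gk[P] += gw * tp.farea[f];
        ewall[P] += ew * tp.farea[f];
        warea[P] += tp.farea[f];
      }
      for (int c = 0; c < nc; ++c) {
        if (wallcell[c] && warea[c] > 0) { Gk[c] /= warea[c]; ewall[c] /= warea[c]; }
      }
      // ---- k equation ----
      std::fill(diag.begin(), diag.end(), 0.0);
      std::fill(off.begin(), off.end(), 0.0);
      for (int c = 0; c < nc; ++c)
        rhs1[c] = Gk[c] * tp.vol[c];
      std::vector<double> gkx(nc), gky(nc);
      for (int f = 0; f < nf; ++f)
        bval[f] = (tp.ftag[f] == 1) ? kin[f] : kf[tp.fown[f]];
      lsq_gradient(tp, kf, bval, gkx, gky);
      if (scheme == 2) bj_limiter(tp, kf, bval, gkx, gky, lim_s, venkat_k2);
      for (int f = 0; f < nf; ++f) {
        int P = tp.fown[f], N = tp.fneigh[f];
        double m = mdot[f];
        if (N >= 0) {
          double muf = mu + (tp.wf[f] * mut[P] + (1 - tp.wf[f]) * mut[N]) / sig_k;
          double Df = muf * tp.aOverD[f];
          double aPN = -(Df + std::max(-m, 0.0));
          double aNP = -(Df + std::max(m, 0.0));
          for (int e = 0; e < 3; ++e) if (tp.cface[3 * P + e] == f) off[3 * P + e] += aPN;
          for (int e = 0; e < 3; ++e) if (tp.cface[3 * N + e] == f) off[3 * N + e] += aNP;
          diag[P] += Df + std::max(m, 0.0);
          diag[N] += Df + std::max(-m, 0.0);
          if (scheme == 2) {
            int up = m >= 0 ? P : N;
            double rx = tp.fcx[f] - tp.cx[up], ry = tp.fcy[f] - tp.cy[up];
            double dk = lim_s[up] * (gkx[up] * rx + gky[up] * ry);
            rhs1[P] -= m * dk; rhs1[N] += m * dk;
          }
        } else if (tp.ftag[f] == 1) {
          double muf = mu + mut[P] / sig_k;
          double Df = muf * tp.aOverD[f];
          diag[P] += Df + std::max(m, 0.0);
          rhs1[P] += Df * kin[f] + std::max(-m, 0.0) * kin[f];
        } else if (tp.ftag[f] == 2) {
          diag[P] += std::max(m, 0.0);
        } // walls: zero diffusive flux of k
      }
      for (int c = 0; c < nc; ++c) {
        diag[c] += rho * ef[c] / std::max(kf[c], 1e-12) * tp.vol[c] + aPtc[c];
        rhs1[c] += aPtc[c] * kf[c];
      }
      {
        double sc;
        rk = gs_residual(tp, diag, off, rhs1, kf, sc);
        rk /= std::max(sc, 1e-14);
      }
      for (int c = 0; c < nc; ++c) {
        double d0 = diag[c], dr = d0 / urf_t;
        rhs1[c] += (dr - d0) * kf[c];
        diag[c] = dr;
      }
      gs_solve(tp, diag, off, rhs1, kf, gs_sweeps);
      for (int c = 0; c < nc; ++c) kf[c] = std::max(kf[c], 1e-10);
      // ---- epsilon equation ----
      std::fill(diag.begin(), diag.end(), 0.0);
      std::fill(off.begin(), off.end(), 0.0);
      for (int c = 0; c < nc; ++c) {
        double ek = ef[c] / std::max(kf[c], 1e-12);
        double C2s = C2e;
        if (rng) {
          double eta = std::sqrt(S2[c]) * std::max(kf[c], 1e-12) / std::max(ef[c], 1e-12);
          eta = clampd(eta, 0.0, 50.0);
          C2s += Cmu * eta * eta * eta * (1.0 - eta / eta0) /
                 (1.0 + beta_rng * eta * eta * eta);
          C2s = std::max(C2s, 0.1);
        }
        rhs1[c] = C1e * ek * Gk[c] * tp.vol[c];
        diag[c] = C2s * rho * ek * tp.vol[c];
      }
      std::vector<double> gex(nc), gey(nc);
      for (int f = 0; f < nf; ++f)
        bval[f] = (tp.ftag[f] == 1) ? ein[f] : ef[tp.fown[f]];
      lsq_gradient(tp, ef, bval, gex, gey);
      if (scheme == 2) bj_limiter(tp, ef, bval, gex, gey, lim_s, venkat_k2);
      for (int f = 0; f < nf; ++f) {
        int P = tp.fown[f], N = tp.fneigh[f];
        double m = mdot[f];
        if (N >= 0) {
          double muf = mu + (tp.wf[f] * mut[P] + (1 - tp.wf[f]) * mut[N]) / sig_e;
          double Df = muf * tp.aOverD[f];
          double aPN = -(Df + std::max(-m, 0.0));
          double aNP = -(Df + std::max(m, 0.0));
          for (int e = 0; e < 3; ++e) if (tp.cface[3 * P + e] == f) off[3 * P + e] += aPN;
          for (int e = 0; e < 3; ++e) if (tp.cface[3 * N + e] == f) off[3 * N + e] += aNP;
          diag[P] += Df + std::max(m, 0.0);
          diag[N] += Df + std::max(-m, 0.0);
          if (scheme == 2) {
            int up = m >= 0 ? P : N;
            double rx = tp.fcx[f] - tp.cx[up], ry = tp.fcy[f] - tp.cy[up];
            double de = lim_s[up] * (gex[up] * rx + gey[up] * ry);
            rhs1[P] -= m * de; rhs1[N] += m * de;
          }
        } else if (tp.ftag[f] == 1) {
          double muf = mu + mut[P] / sig_e;
          double Df = muf * tp.aOverD[f];
          diag[P] += Df + std::max(m, 0.0);
          rhs1[P] += Df * ein[f] + std::max(-m, 0.0) * ein[f];
        } else if (tp.ftag[f] == 2) {
          diag[P] += std::max(m, 0.0);
        }
      }
      for (int c = 0; c < nc; ++c) {
        diag[c] += aPtc[c];
        rhs1[c] += aPtc[c] * ef[c];
      }
      // wall cells: fixed epsilon from the log law
      for (int c = 0; c < nc; ++c) {
        if (!wallcell[c]) continue;
        diag[c] = 1.0;
        for (int e = 0; e < 3; ++e) off[3 * c + e] = 0.0;
        rhs1[c] = ewall[c];
      }
      {
        double sc;
        re = gs_residual(tp, diag, off, rhs1, ef, sc);
        re /= std::max(sc, 1e-14);
      }
      for (int c = 0; c < nc; ++c) {
        if (wallcell[c]) continue;
        double d0 = diag[c], dr = d0 / urf_t;
        rhs1[c] += (dr - d0) * ef[c];
        diag[c] = dr;
      }
      gs_solve(tp, diag, off, rhs1, ef, gs_sweeps);
      for (int c = 0; c < nc; ++c) ef[c] = std::max(ef[c], 1e-12);
      // eddy viscosity
      for (int c = 0; c < nc; ++c) {
        double mn = rho * Cmu * kf[c] * kf[c] / ef[c];
        mn = clampd(mn, 0.0, 1e5 * mu);
        mut[c] = (1 - urf_t) * mut[c] + urf_t * mn;
      }
    }

    resid(iter, 0) = ru / su_den;
    resid(iter, 1) = rv / sv_den;
    resid(iter, 2) = rc;
    resid(iter, 3) = rk;
    resid(iter, 4) = re;
    mass_imb = rc;

    // divergence guard
    double umax = 0.0;
    bool bad = false;
    for (int c = 0; c < nc; ++c) {
      double m = std::fabs(u[c]) + std::fabs(v[c]);
      if (!std::isfinite(m)) { bad = true; break; }
      umax = std::max(umax, m);
    }
    for (int j = 0; j < 5 && !bad; ++j)
      if (!std::isfinite(resid(iter, j))) bad = true;
    if (bad || umax > 100.0) { diverged = true; break; }
    if (iter >= std::max(30, ramp_iters) &&
        resid(iter, 0) < tol && resid(iter, 1) < tol && rc < tol_c &&
        (turb == 0 || (rk < tol_turb && re < tol_turb))) {
      converged = true;
      break;
    }
  }

  // final boundary fluxes from the corrected mdot field
  flux_in = 0.0; flux_out = 0.0;
  for (int f = 0; f < nf; ++f) {
    if (tp.ftag[f] == 1) flux_in -= mdot[f] / rho;
    else if (tp.ftag[f] == 2) flux_out += mdot[f] / rho;
  }

  // nodal averages (inverse-distance) with no-slip enforced on wall nodes
  std::vector<double> un(nn, 0), vn(nn, 0), pn(nn, 0), knod(nn, 0), enod(nn, 0),
      wsum(nn, 0);
  for (int c = 0; c < nc; ++c) {
    for (int e = 0; e < 3; ++e) {
      int a = tris(c, e) - 1;
      double w = 1.0 / std::max(std::hypot(nodes(a, 0) - tp.cx[c],
                                           nodes(a, 1) - tp.cy[c]), 1e-12);
      un[a] += w * u[c]; vn[a] += w * v[c]; pn[a] += w * p[c];
      knod[a] += w * kf[c]; enod[a] += w * ef[c];
      wsum[a] += w;
    }
  }
  for (int a = 0; a < nn; ++a) {
    un[a] /= wsum[a]; vn[a] /= wsum[a]; pn[a] /= wsum[a];
    knod[a] /= wsum[a]; enod[a] /= wsum[a];
  }
  for (int f = 0; f < nf; ++f) {
    if (tp.ftag[f] == 3) { un[tp.fn1[f]] = vn[tp.fn1[f]] = 0.0;
                           un[tp.fn2[f]] = vn[tp.fn2[f]] = 0.0; }
  }

  IntegerMatrix faces(nf, 5);
  for (int f = 0; f < nf; ++f) {
    faces(f, 0) = tp.fn1[f] + 1; faces(f, 1) = tp.fn2[f] + 1;
    faces(f, 2) = tp.fown[f] + 1;
    faces(f, 3) = tp.fneigh[f] >= 0 ? tp.fneigh[f] + 1 : NA_INTEGER;
    faces(f, 4) = tp.ftag[f];
  }
  colnames(faces) = CharacterVector::create("n1", "n2", "owner", "neighbor", "tag");

  int nkeep = it_done;
  NumericMatrix rhist(nkeep, 5);
  for (int i = 0; i < nkeep; ++i)
    for (int j = 0; j < 5; ++j) rhist(i, j) = resid(i, j);
  colnames(rhist) = CharacterVector::create("u", "v", "continuity", "k", "epsilon");

  return List::create(
      _["u"] = u, _["v"] = v, _["p"] = p, _["k"] = kf, _["epsilon"] = ef,
      _["mu_t"] = mut,
      _["u_node"] = un, _["v_node"] = vn, _["p_node"] = pn,
      _["k_node"] = knod, _["epsilon_node"] = enod,
      _["faces"] = faces, _["mdot"] = mdot,
      _["fsign"] = IntegerVector(tp.fsign.begin(), tp.fsign.end()),
      _["cell_cx"] = tp.cx, _["cell_cy"] = tp.cy, _["cell_area"] = tp.vol,
      _["resid_cell"] = resid_cell,
      _["residuals"] = rhist, _["iterations"] = it_done,
      _["pcg_iterations"] = (double)pcg_total,
      _["converged"] = converged, _["diverged"] = diverged,
      _["mass_imbalance"] = mass_imb,
      _["flux_in"] = flux_in, _["flux_out"] = flux_out);
}

// Node streamfunction from face volumetric fluxes: psi(n2) - psi(n1) equals
// the flux crossing the edge (right-normal convention), integrated by a BFS
// over the edge graph.  Exact for a divergence-free flux field.
// [[Rcpp::export]]
NumericVector fv_streamfunction(int nnodes, IntegerMatrix faces,
                                IntegerVector fsign, NumericVector q) {
  int nf = faces.nrow();
  std::vector<std::vector<std::pair<int, double> > > adj(nnodes);
  for (int f = 0; f < nf; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1;
    double dq = fsign[f] * q[f];
    adj[a].push_back(std::make_pair(b, dq));
    adj[b].push_back(std::make_pair(a, -dq));
  }
  NumericVector psi(nnodes, 0.0);
  std::vector<char> seen(nnodes, 0);
  std::vector<int> stack;
  for (int s = 0; s < nnodes; ++s) {
    if (seen[s]) continue;
    seen[s] = 1;
    stack.push_back(s);
    while (!stack.empty()) {
      int a = stack.back(); stack.pop_back();
      for (size_t i = 0; i < adj[a].size(); ++i) {
        int b = adj[a][i].first;
        if (!seen[b]) {
          seen[b] = 1;
          psi[b] = psi[a] + adj[a][i].second;
          stack.push_back(b);
        }
      }
    }
  }
  return psi;
}
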