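#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-phase-field monolayer kernel.
//
// Fields live on an (nx, ny, nz) lattice with spacing a0 = 1, periodic in x
// and y, zero-flux in z.  Each cell i carries a scalar field phi_i stored as
// a column of an nnode x N matrix (node index x + nx*(y + ny*z)).  The free
// energy combines a double-well + gradient interface term, a soft volume
// constraint, phi^2 phi^2 overlap repulsions and gradient adhesion
// cross-terms with the other cells and with the static substrate field.
//
// Discrete consistency: the gradient energy uses forward differences, whose
// exact discrete variation is -2 * (7-point Laplacian with zero-flux z
// clamps).  The functional derivative assembled here is therefore the exact
// gradient of the discrete free energy, which the finite-difference tests
// rely on.

namespace {

struct Grid {
  int nx, ny, nz, nnode;
  // precomputed periodic neighbour tables (avoids modulo in hot loops)
  std::vector<int> xm, xp, ym, yp;
  void build_tables() {
    xm.resize(nx); xp.resize(nx); ym.resize(ny); yp.resize(ny);
    for (int x = 0; x < nx; ++x) {
      xm[x] = (x == 0) ? nx - 1 : x - 1;
      xp[x] = (x == nx - 1) ? 0 : x + 1;
    }
    for (int y = 0; y < ny; ++y) {
      ym[y] = (y == 0) ? ny - 1 : y - 1;
      yp[y] = (y == ny - 1) ? 0 : y + 1;
    }
  }
};

inline int wrapi(int i, int n) { return (i + n) % n; }

// 7-point Laplacian, periodic x/y, zero-flux z
void laplacian(const double* f, double* out, const Grid& g) {
  const int sxy = g.nx * g.ny;
  for (int z = 0; z < g.nz; ++z) {
    const int zm = (z == 0) ? 0 : z - 1;
    const int zp = (z == g.nz - 1) ? g.nz - 1 : z + 1;
    for (int y = 0; y < g.ny; ++y) {
      const double* row = f + g.nx * (y + g.ny * z);
      const double* rym = f + g.nx * (g.ym[y] + g.ny * z);
      const double* ryp = f + g.nx * (g.yp[y] + g.ny * z);
      const double* rzm = f + g.nx * (y + g.ny * zm);
      const double* rzp = f + g.nx * (y + g.ny * zp);
      double* o = out + g.nx * (y + g.ny * z);
      for (int x = 0; x < g.nx; ++x) {
        o[x] = row[g.xm[x]] + row[g.xp[x]] + rym[x] + ryp[x] + rzm[x] +
               rzp[x] - 6.0 * row[x];
      }
    }
  }
  (void)sxy;
}

// sum over nodes of forward-difference |grad f|^2 (top z face term dropped,
// matching the zero-flux Laplacian)
double grad_sq_sum(const double* f, const Grid& g) {
  double acc = 0.0;
  for (int z = 0; z < g.nz; ++z) {
    for (int y = 0; y < g.ny; ++y) {
      const int yp = wrapi(y + 1, g.ny);
      for (int x = 0; x < g.nx; ++x) {
        const int xp = wrapi(x + 1, g.nx);
        const int i = x + g.nx * (y + g.ny * z);
        double d;
        d = f[xp + g.nx * (y + g.ny * z)] - f[i]; acc += d * d;
        d = f[x + g.nx * (yp + g.ny * z)] - f[i]; acc += d * d;
        if (z < g.nz - 1) { d = f[x + g.nx * (y + g.ny * (z + 1))] - f[i]; acc += d * d; }
      }
    }
  }
  return acc;
}

// sum over nodes of forward-difference grad f . grad h
double grad_dot_sum(const double* f, const double* h, const Grid& g) {
  double acc = 0.0;
  for (int z = 0; z < g.nz; ++z) {
    for (int y = 0; y < g.ny; ++y) {
      const int yp = wrapi(y + 1, g.ny);
      for (int x = 0; x < g.nx; ++x) {
        const int xp = wrapi(x + 1, g.nx);
        const int i = x + g.nx * (y + g.ny * z);
        acc += (f[xp + g.nx * (y + g.ny * z)] - f[i]) *
               (h[xp + g.nx * (y + g.ny * z)] - h[i]);
        acc += (f[x + g.nx * (yp + g.ny * z)] - f[i]) *
               (h[x + g.nx * (yp + g.ny * z)] - h[i]);
        if (z < g.nz - 1)
          acc += (f[x + g.nx * (y + g.ny * (z + 1))] - f[i]) *
                 (h[x + g.nx * (y + g.ny * (z + 1))] - h[i]);
      }
    }
  }
  return acc;
}

// central-difference gradient (one-sided in z at the faces)
void gradient(const double* f, double* gx, double* gy, double* gz, const Grid& g) {
  for (int z = 0; z < g.nz; ++z) {
    const double zfac = (z == 0 || z == g.nz - 1) ? 1.0 : 0.5;
    const int zm = (z == 0) ? 0 : z - 1;
    const int zp = (z == g.nz - 1) ? g.nz - 1 : z + 1;
    for (int y = 0; y < g.ny; ++y) {
      const double* row = f + g.nx * (y + g.ny * z);
      const double* rym = f + g.nx * (g.ym[y] + g.ny * z);
      const double* ryp = f + g.nx * (g.yp[y] + g.ny * z);
      const double* rzm = f + g.nx * (y + g.ny * zm);
      const double* rzp = f + g.nx * (y + g.ny * zp);
      const int off = g.nx * (y + g.ny * z);
      for (int x = 0; x < g.nx; ++x) {
        gx[off + x] = 0.5 * (row[g.xp[x]] - row[g.xm[x]]);
        gy[off + x] = 0.5 * (ryp[x] - rym[x]);
        gz[off + x] = zfac * (rzp[x] - rzm[x]);
      }
    }
  }
}

struct Coefs {
  double c_bulk, lam2, mu, V0, c_rep, c_adh, c_repw, c_adhw;
  double Gamma, xi, alpha, tau_pol, Dr, dt;
};

Coefs read_coefs(const List& par) {
  Coefs c;
  c.c_bulk = as<double>(par["c_bulk"]);
  double lam = as<double>(par["lam"]);
  c.lam2 = lam * lam;
  c.mu = as<double>(par["mu"]);
  c.V0 = as<double>(par["V0"]);
  c.c_rep = as<double>(par["c_rep"]);
  c.c_adh = as<double>(par["c_adh"]);
  c.c_repw = as<double>(par["c_repw"]);
  c.c_adhw = as<double>(par["c_adhw"]);
  c.Gamma = as<double>(par["Gamma"]);
  c.xi = as<double>(par["xi_fric"]);
  c.alpha = as<double>(par["alpha"]);
  c.tau_pol = as<double>(par["tau_pol"]);
  c.Dr = as<double>(par["Dr"]);
  c.dt = as<double>(par["dt"]);
  return c;
}

Grid read_grid(const IntegerVector& dims, int nnode) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.nnode = g.nx * g.ny * g.nz;
  if (g.nnode != nnode) stop("grid dimensions do not match field length");
  g.build_tables();
  return g;
}

// functional derivative dF/dphi_i at every node.
// Requires precomputed: lap_i = Laplacian(phi_i), lap_tot = Laplacian(sum_j phi_j),
// s2 = sum_j phi_j^2, Vi = sum phi_i^2, wall2 = wall^2, lapw = Laplacian(wall).
void fderiv_field(const double* phi, const double* lap_i, const double* lap_tot,
                  const double* s2, double Vi, const double* wall2,
                  const double* lapw, const Coefs& c, const Grid& g,
                  double* out) {
  const double volpref = -(4.0 * c.mu / c.V0) * (1.0 - Vi / c.V0);
  for (int i = 0; i < g.nnode; ++i) {
    const double p = phi[i];
    double v = c.c_bulk * (8.0 * p * (1.0 - p) * (1.0 - 2.0 * p) - 2.0 * c.lam2 * lap_i[i]);
    v += volpref * p;
    // the double sum over ordered pairs puts each unordered pair in the
    // energy twice, so the variation carries a factor 4
    v += 4.0 * c.c_rep * p * (s2[i] - p * p);
    v -= 2.0 * c.c_adh * (lap_tot[i] - lap_i[i]);
    v += 2.0 * c.c_repw * p * wall2[i];
    v -= c.c_adhw * lapw[i];
    out[i] = v;
  }
}

}  // namespace

// Free-energy terms, each retrievable individually.  Returns a named vector
// (bulk, gradient, volume, rep_cc, adh_cc, rep_cw, adh_cw) plus per-cell
// volumes as an attribute.
// [[Rcpp::export]]
NumericVector fe_terms_cpp(NumericMatrix phi, NumericVector wall,
                           IntegerVector dims, List par) {
  const Grid g = read_grid(dims, phi.nrow());
  const Coefs c = read_coefs(par);
  const int N = phi.ncol();

  double bulk = 0, grad = 0, vol = 0, rep_cc = 0, adh_cc = 0, rep_cw = 0, adh_cw = 0;
  std::vector<double> s2(g.nnode, 0.0), s1(g.nnode, 0.0), s4(g.nnode, 0.0);
  NumericVector volumes(N);

  for (int ci = 0; ci < N; ++ci) {
    const double* f = &phi(0, ci);
    double b = 0, Vi = 0, rw = 0;
    for (int i = 0; i < g.nnode; ++i) {
      const double p = f[i];
      if (!std::isfinite(p)) stop("non-finite phase field for cell %d", ci + 1);
      const double q = 1.0 - p;
      b += 4.0 * p * p * q * q;
      Vi += p * p;
      rw += p * p * wall[i] * wall[i];
      s1[i] += p;
      s2[i] += p * p;
      s4[i] += p * p * p * p;
    }
    bulk += b;
    volumes[ci] = Vi;
    vol += c.mu * (1.0 - Vi / c.V0) * (1.0 - Vi / c.V0);
    rep_cw += rw;
    grad += c.lam2 * grad_sq_sum(f, g);
    adh_cw += grad_dot_sum(f, &wall[0], g);
  }
  double cross = 0, self_g = 0;
  for (int i = 0; i < g.nnode; ++i) cross += s2[i] * s2[i] - s4[i];
  rep_cc = c.c_rep * cross;
  // adh_cc = c_adh * ( |grad sum phi|^2 - sum |grad phi_i|^2 )
  double tot_g = grad_sq_sum(&s1[0], g);
  for (int ci = 0; ci < N; ++ci) self_g += grad_sq_sum(&phi(0, ci), g);
  adh_cc = c.c_adh * (tot_g - self_g);

  NumericVector out = NumericVector::create(
      _["bulk"] = c.c_bulk * bulk, _["gradient"] = c.c_bulk * grad,
      _["volume"] = vol, _["rep_cc"] = rep_cc, _["adh_cc"] = adh_cc,
      _["rep_cw"] = c.c_repw * rep_cw, _["adh_cw"] = c.c_adhw * adh_cw);
  out.attr("volumes") = volumes;
  return out;
}

// Functional derivative dF/dphi_i for one cell (1-based index).
// [[Rcpp::export]]
NumericVector fderiv_cpp(NumericMatrix phi, NumericVector wall,
                         IntegerVector dims, List par, int cell) {
  const Grid g = read_grid(dims, phi.nrow());
  const Coefs c = read_coefs(par);
  const int N = phi.ncol();
  if (cell < 1 || cell > N) stop("cell index out of range");
  const int ci = cell - 1;

  std::vector<double> s2(g.nnode, 0.0), s1(g.nnode, 0.0), wall2(g.nnode);
  for (int j = 0; j < N; ++j) {
    const double* f = &phi(0, j);
    for (int i = 0; i < g.nnode; ++i) { s1[i] += f[i]; s2[i] += f[i] * f[i]; }
  }
  for (int i = 0; i < g.nnode; ++i) wall2[i] = wall[i] * wall[i];

  std::vector<double> lap_i(g.nnode), lap_tot(g.nnode), lapw(g.nnode);
  laplacian(&phi(0, ci), &lap_i[0], g);
  laplacian(&s1[0], &lap_tot[0], g);
  laplacian(&wall[0], &lapw[0], g);

  double Vi = 0;
  for (int i = 0; i < g.nnode; ++i) Vi += phi(i, ci) * phi(i, ci);

  NumericVector out(g.nnode);
  fderiv_field(&phi(0, ci), &lap_i[0], &lap_tot[0], &s2[0], Vi, &wall2[0],
               &lapw[0], c, g, &out[0]);
  return out;
}

// Passive traction of one cell: T = -sum_nodes (dF/dphi_i) grad phi_i.
// [[Rcpp::export]]
NumericVector traction_cpp(NumericMatrix phi, NumericVector wall,
                           IntegerVector dims, List par, int cell) {
  const Grid g = read_grid(dims, phi.nrow());
  NumericVector df = fderiv_cpp(phi, wall, dims, par, cell);
  std::vector<double> gx(g.nnode), gy(g.nnode), gz(g.nnode);
  gradient(&phi(0, cell - 1), &gx[0], &gy[0], &gz[0], g);
  double tx = 0, ty = 0, tz = 0;
  for (int i = 0; i < g.nnode; ++i) {
    tx -= df[i] * gx[i];
    ty -= df[i] * gy[i];
    tz -= df[i] * gz[i];
  }
  return NumericVector::create(tx, ty, tz);
}

// One explicit Euler step.  Mutates phi and theta IN PLACE (callers own
// private copies).  noise: N(0,1) draws, one per cell.  Returns per-cell
// tractions, velocities, clamp count and max speed; optionally the per-node
// traction density (passive + active) of the pre-step state.
// [[Rcpp::export]]
List step_cpp(NumericMatrix phi, NumericVector theta, NumericVector wall,
              IntegerVector dims, List par, NumericVector noise,
              bool want_tdens) {
  const Grid g = read_grid(dims, phi.nrow());
  const Coefs c = read_coefs(par);
  const int N = phi.ncol();
  if (theta.size() != N || noise.size() != N) stop("theta/noise length mismatch");

  std::vector<double> s2(g.nnode, 0.0), s1(g.nnode, 0.0), wall2(g.nnode);
  std::vector<double> Vi(N, 0.0);
  for (int j = 0; j < N; ++j) {
    const double* f = &phi(0, j);
    double v = 0;
    for (int i = 0; i < g.nnode; ++i) {
      s1[i] += f[i];
      s2[i] += f[i] * f[i];
      v += f[i] * f[i];
    }
    Vi[j] = v;
  }
  for (int i = 0; i < g.nnode; ++i) wall2[i] = wall[i] * wall[i];

  std::vector<double> lap_tot(g.nnode), lapw(g.nnode), lap_i(g.nnode);
  std::vector<double> gx(g.nnode), gy(g.nnode), gz(g.nnode);
  laplacian(&s1[0], &lap_tot[0], g);
  laplacian(&wall[0], &lapw[0], g);

  NumericMatrix dfall(g.nnode, N);
  NumericMatrix traction(N, 3), velocity(N, 3);
  NumericMatrix tdens(want_tdens ? g.nnode : 1, want_tdens ? 3 : 1);
  if (want_tdens) std::fill(tdens.begin(), tdens.end(), 0.0);

  double maxspeed = 0.0;
  for (int ci = 0; ci < N; ++ci) {
    const double* f = &phi(0, ci);
    laplacian(f, &lap_i[0], g);
    double* df = &dfall(0, ci);
    fderiv_field(f, &lap_i[0], &lap_tot[0], &s2[0], Vi[ci], &wall2[0],
                 &lapw[0], c, g, df);
    gradient(f, &gx[0], &gy[0], &gz[0], g);
    double tx = 0, ty = 0, tz = 0;
    for (int i = 0; i < g.nnode; ++i) {
      tx -= df[i] * gx[i];
      ty -= df[i] * gy[i];
      tz -= df[i] * gz[i];
    }
    if (!std::isfinite(tx) || !std::isfinite(ty) || !std::isfinite(tz))
      stop("non-finite traction for cell %d", ci + 1);
    traction(ci, 0) = tx; traction(ci, 1) = ty; traction(ci, 2) = tz;
    const double fx = c.alpha * std::cos(theta[ci]);
    const double fy = c.alpha * std::sin(theta[ci]);
    velocity(ci, 0) = (tx + fx) / c.xi;
    velocity(ci, 1) = (ty + fy) / c.xi;
    velocity(ci, 2) = tz / c.xi;
    const double sp = std::sqrt(velocity(ci, 0) * velocity(ci, 0) +
                                velocity(ci, 1) * velocity(ci, 1) +
                                velocity(ci, 2) * velocity(ci, 2));
    if (sp > maxspeed) maxspeed = sp;

    if (want_tdens) {
      const double apref = (Vi[ci] > 0) ? c.alpha / Vi[ci] : 0.0;
      for (int i = 0; i < g.nnode; ++i) {
        tdens(i, 0) += -df[i] * gx[i] + apref * std::cos(theta[ci]) * f[i] * f[i];
        tdens(i, 1) += -df[i] * gy[i] + apref * std::sin(theta[ci]) * f[i] * f[i];
        tdens(i, 2) += -df[i] * gz[i];
      }
    }
  }

  if (maxspeed * c.dt > 0.45)
    stop("CFL violation: max speed %g with dt %g exceeds the advection bound",
         maxspeed, c.dt);

  // advance fields: upwind advection + relaxation, then clamp to [0, 1]
  int clamped = 0;
  std::vector<double> newcol(g.nnode);
  for (int ci = 0; ci < N; ++ci) {
    double* f = &phi(0, ci);
    const double* df = &dfall(0, ci);
    const double vx = velocity(ci, 0), vy = velocity(ci, 1), vz = velocity(ci, 2);
    for (int z = 0; z < g.nz; ++z) {
      const int zm = (z == 0) ? 0 : z - 1;
      const int zp = (z == g.nz - 1) ? g.nz - 1 : z + 1;
      for (int y = 0; y < g.ny; ++y) {
        const double* row = f + g.nx * (y + g.ny * z);
        const double* rym = f + g.nx * (g.ym[y] + g.ny * z);
        const double* ryp = f + g.nx * (g.yp[y] + g.ny * z);
        const double* rzm = f + g.nx * (y + g.ny * zm);
        const double* rzp = f + g.nx * (y + g.ny * zp);
        const int off = g.nx * (y + g.ny * z);
        for (int x = 0; x < g.nx; ++x) {
          double adv = 0.0;
          adv += vx * (vx > 0 ? row[x] - row[g.xm[x]] : row[g.xp[x]] - row[x]);
          adv += vy * (vy > 0 ? row[x] - rym[x] : ryp[x] - row[x]);
          adv += vz * (vz > 0 ? row[x] - rzm[x] : rzp[x] - row[x]);
          double v = row[x] + c.dt * (-adv - c.Gamma * df[off + x]);
          if (v < 0.0) { v = 0.0; ++clamped; }
          else if (v > 1.0) { v = 1.0; ++clamped; }
          newcol[off + x] = v;
        }
      }
    }
    for (int i = 0; i < g.nnode; ++i) f[i] = newcol[i];
  }

  // polarity update: align toward the in-plane traction direction
  for (int ci = 0; ci < N; ++ci) {
    const double tx = traction(ci, 0), ty = traction(ci, 1);
    const double tmag = std::sqrt(tx * tx + ty * ty);
    double drift = 0.0;
    if (tmag > 1e-12) {
      double d = theta[ci] - std::atan2(ty, tx);
      while (d > M_PI) d -= 2.0 * M_PI;
      while (d <= -M_PI) d += 2.0 * M_PI;
      drift = -(tmag / c.tau_pol) * d;
    }
    double th = theta[ci] + c.dt * drift + c.Dr * std::sqrt(c.dt) * noise[ci];
    while (th > M_PI) th -= 2.0 * M_PI;
    while (th <= -M_PI) th += 2.0 * M_PI;
    theta[ci] = th;
  }

  List out = List::create(_["traction"] = traction, _["velocity"] = velocity,
                          _["clamped"] = clamped, _["max_speed"] = maxspeed);
  if (want_tdens) out["tdens"] = tdens;
  return out;
}

// Per-node traction density (passive + active) of a state, without stepping.
// [[Rcpp::export]]
NumericMatrix nodal_traction_cpp(NumericMatrix phi, NumericVector theta,
                                 NumericVector wall, IntegerVector dims,
                                 List par) {
  const Grid g = read_grid(dims, phi.nrow());
  const Coefs c = read_coefs(par);
  const int N = phi.ncol();

  std::vector<double> s2(g.nnode, 0.0), s1(g.nnode, 0.0), wall2(g.nnode);
  std::vector<double> Vi(N, 0.0);
  for (int j = 0; j < N; ++j) {
    const double* f = &phi(0, j);
    double v = 0;
    for (int i = 0; i < g.nnode; ++i) {
      s1[i] += f[i]; s2[i] += f[i] * f[i]; v += f[i] * f[i];
    }
    Vi[j] = v;
  }
  for (int i = 0; i < g.nnode; ++i) wall2[i] = wall[i] * wall[i];

  std::vector<double> lap_tot(g.nnode), lapw(g.nnode), lap_i(g.nnode);
  std::vector<double> gx(g.nnode), gy(g.nnode), gz(g.nnode), df(g.nnode);
  laplacian(&s1[0], &lap_tot[0], g);
  laplacian(&wall[0], &lapw[0], g);

  NumericMatrix tdens(g.nnode, 3);
  std::fill(tdens.begin(), tdens.end(), 0.0);
  for (int ci = 0; ci < N; ++ci) {
    const double* f = &phi(0, ci);
    laplacian(f, &lap_i[0], g);
    fderiv_field(f, &lap_i[0], &lap_tot[0], &s2[0], Vi[ci], &wall2[0],
                 &lapw[0], c, g, &df[0]);
    gradient(f, &gx[0], &gy[0], &gz[0], g);
    const double apref = (Vi[ci] > 0) ? c.alpha / Vi[ci] : 0.0;
    const double cth = std::cos(theta[ci]), sth = std::sin(theta[ci]);
    for (int i = 0; i < g.nnode; ++i) {
      tdens(i, 0) += -df[i] * gx[i] + apref * cth * f[i] * f[i];
      tdens(i, 1) += -df[i] * gy[i] + apref * sth * f[i] * f[i];
      tdens(i, 2) += -df[i] * gz[i];
    }
  }
  return tdens;
}

// Coarse-grained stress on the complementary (dual) lattice.  Each 2D
// analysis node sits at the dual in-plane position (ix-1/2, iy-1/2) at the
// mid-height of the slab; its neighbourhood is the four facially adjacent
// original-lattice columns, contracted over z.  The moment formula
// sigma_i = (1/a0^3) sum_{j in N_i} r_ij (x) T_j (symmetrized) uses
// r_ij = x_i - x_j, i.e. in-plane offsets of +/- a0/2 and the full vertical
// offset z_mid - z_j, so the 2D field embeds a non-degenerate out-of-plane
// component (the column's vertical force moment; a plain z-sum of per-layer
// dual-cell stresses telescopes sigma_zz to boundary terms).  The offsets
// sum to zero over the stencil, so any globally uniform traction maps to
// zero stress exactly, and the map is linear in the tractions.
// Output is an (nx+1)*(ny+1) x 6 matrix with columns
// (xx, yy, zz, xy, xz, yz); the first/last dual rows and columns are
// periodic duplicates so the analysis lattice has (Lx+1) x (Ly+1) nodes.
// [[Rcpp::export]]
NumericMatrix coarse_stress_cpp(NumericMatrix tdens, IntegerVector dims) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.nnode = g.nx * g.ny * g.nz;
  if (tdens.nrow() != g.nnode) stop("traction field does not match grid");

  const int mx = g.nx + 1, my = g.ny + 1;
  const double zmid = 0.5 * (g.nz - 1);
  NumericMatrix out(mx * my, 6);
  std::fill(out.begin(), out.end(), 0.0);

  for (int iy = 0; iy < my; ++iy) {
    for (int ix = 0; ix < mx; ++ix) {
      const int o = ix + mx * iy;
      double sxx = 0, syy = 0, szz = 0, sxy = 0, sxz = 0, syz = 0;
      for (int cy = 0; cy < 2; ++cy) {
        const int oy = wrapi(iy - 1 + cy, g.ny);
        const double ry = (cy == 0) ? 0.5 : -0.5;
        for (int cx = 0; cx < 2; ++cx) {
          const int ox = wrapi(ix - 1 + cx, g.nx);
          const double rx = (cx == 0) ? 0.5 : -0.5;
          for (int oz = 0; oz < g.nz; ++oz) {
            const double rz = zmid - oz;
            const int j = ox + g.nx * (oy + g.ny * oz);
            const double tx = tdens(j, 0), ty = tdens(j, 1), tz = tdens(j, 2);
            sxx += rx * tx;
            syy += ry * ty;
            szz += rz * tz;
            sxy += 0.5 * (rx * ty + ry * tx);
            sxz += 0.5 * (rx * tz + rz * tx);
            syz += 0.5 * (ry * tz + rz * ty);
          }
        }
      }
      out(o, 0) = sxx; out(o, 1) = syy; out(o, 2) = szz;
      out(o, 3) = sxy; out(o, 4) = sxz; out(o, 5) = syz;
    }
  }
  return out;
}

// Phase-field centroids (periodic-aware circular mean in x and y, weighted
// by phi^2) and volumes.  Returns a list (centroid N x 3, volume N).
// [[Rcpp::export]]
List centroid_cpp(NumericMatrix phi, IntegerVector dims) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.nnode = g.nx * g.ny * g.nz;
  if (phi.nrow() != g.nnode) stop("grid dimensions do not match field length");
  const int N = phi.ncol();
  NumericMatrix cen(N, 3);
  NumericVector vol(N);
  const double twopi = 2.0 * M_PI;
  for (int ci = 0; ci < N; ++ci) {
    const double* f = &phi(0, ci);
    double m = 0, cxs = 0, cxc = 0, cys = 0, cyc = 0, zsum = 0;
    for (int z = 0; z < g.nz; ++z) {
      for (int y = 0; y < g.ny; ++y) {
        for (int x = 0; x < g.nx; ++x) {
          const int i = x + g.nx * (y + g.ny * z);
          const double w = f[i] * f[i];
          if (w == 0) continue;
          m += w;
          cxc += w * std::cos(twopi * x / g.nx);
          cxs += w * std::sin(twopi * x / g.nx);
          cyc += w * std::cos(twopi * y / g.ny);
          cys += w * std::sin(twopi * y / g.ny);
          zsum += w * z;
        }
      }
    }
    vol[ci] = m;
    if (m > 0) {
      double ax = std::atan2(cxs, cxc), ay = std::atan2(cys, cyc);
      if (ax < 0) ax += twopi;
      if (ay < 0) ay += twopi;
      cen(ci, 0) = ax * g.nx / twopi;
      cen(ci, 1) = ay * g.ny / twopi;
      cen(ci, 2) = zsum / m;
    } else {
      cen(ci, 0) = NA_REAL; cen(ci, 1) = NA_REAL; cen(ci, 2) = NA_REAL;
    }
  }
  return List::create(_["centroid"] = cen, _["volume"] = vol);
}
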