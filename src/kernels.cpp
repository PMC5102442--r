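// Core compute kernels for the peridynamic membrane simulator.
//
// Internal unit system: micrometres, seconds, kilograms.  In these units a
// pressure of 1 MPa is numerically 1 (kg / (um s^2)), so moduli supplied in
// MPa pass through unchanged; densities in kg/m^3 are converted by 1e-18.
//
// All kernels are single-threaded and use a fixed summation order, so a run
// is bit-reproducible for a given configuration.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <queue>

using namespace Rcpp;

namespace {

struct Engine {
  int N;
  double D0;                       // initial diameter (um)
  // reference and current kinematics
  std::vector<double> rx, ry;      // reference positions
  std::vector<double> px, py;      // current positions
  std::vector<double> vx, vy;      // velocities
  std::vector<double> ax, ay;      // acceleration at current accepted state
  bool accel_valid;
  // directed bond network, CSR layout
  std::vector<int> bptr;           // length N+1
  std::vector<int> bj;             // neighbour index per directed bond
  std::vector<int> brev;           // index of the reverse directed bond
  std::vector<double> blen;        // reference bond length
  std::vector<char> intact;
  std::vector<int> n0;             // initial bond count per particle
  std::vector<int> nbroken;        // broken bond count per particle
  std::vector<double> mi;          // weighted volume (um^4), frozen at build
  // constraints
  std::vector<char> pinned, blayer;
  std::vector<double> bvx, bvy;    // prescribed boundary-layer velocity
  // material (internal units)
  double K, G, sc, Csr, eps, h, rho, area, dpi_cap, contact_cutoff;
  // time
  double t;
  long step_index;
  long zero_len_bonds, contact_coincident;
  // first time a particle's damage reached 0.5 (-1 = never)
  std::vector<double> cross_time;
  // scratch
  std::vector<double> theta, fx, fy;
  std::vector<double> y1x, y1y, v1x, v1y, y2x, y2y, v2x, v2y, asx, asy;
};

Engine* get_engine(SEXP xp) {
  Rcpp::XPtr<Engine> p(xp);
  return p.get();
}

// force density (not acceleration) at positions (yx, yy) into eng->fx/fy
void compute_force(Engine* E, const double* yx, const double* yy,
                   bool internal, bool contact) {
  const int N = E->N;
  std::fill(E->fx.begin(), E->fx.end(), 0.0);
  std::fill(E->fy.begin(), E->fy.end(), 0.0);

  if (internal) {
    // pass 1: dilatation theta_i = (2/m_i) sum omega |xi| e A
    std::fill(E->theta.begin(), E->theta.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      double th = 0.0;
      for (int b = E->bptr[i]; b < E->bptr[i + 1]; ++b) {
        if (!E->intact[b]) continue;
        const int j = E->bj[b];
        const double dx = yx[j] - yx[i], dy = yy[j] - yy[i];
        const double d = std::sqrt(dx * dx + dy * dy);
        th += E->blen[b] * (d - E->blen[b]) * E->area;
      }
      E->theta[i] = (E->mi[i] > 0.0) ? 2.0 * th / E->mi[i] : 0.0;
    }
    // pass 2: scalar force state t = (2K/(eps m)) theta |xi| +
    // (8G/(eps m)) e_dev; the 1/eps makes the thickness factor of the
    // equation of motion cancel, as in the 3D->2D reduction of the LPS
    // weighted volume (m_3D = eps * m_2D).  Assembled pairwise so momentum
    // balances to machine precision.
    const double cK = 2.0 * E->K / E->eps, cG = 8.0 * E->G / E->eps;
    for (int i = 0; i < N; ++i) {
      for (int b = E->bptr[i]; b < E->bptr[i + 1]; ++b) {
        const int j = E->bj[b];
        if (j < i || !E->intact[b]) continue;
        const double dx = yx[j] - yx[i], dy = yy[j] - yy[i];
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d < 1e-12) { E->zero_len_bonds++; continue; }
        const double L = E->blen[b];
        const double e = d - L;
        const double ti = (cK * E->theta[i] * L +
                           cG * (e - 0.5 * E->theta[i] * L)) / E->mi[i];
        const double tj = (cK * E->theta[j] * L +
                           cG * (e - 0.5 * E->theta[j] * L)) / E->mi[j];
        const double f = E->eps * (ti + tj) * E->area / d;
        const double fxv = f * dx, fyv = f * dy;
        E->fx[i] += fxv; E->fy[i] += fyv;
        E->fx[j] -= fxv; E->fy[j] -= fyv;
      }
    }
  }

  if (contact && E->Csr > 0.0) {
    // cell list over current positions; repulsion vanishes beyond
    // d_pi <= 1.35 h, so a 1.36 h cell suffices inside the 6 h search bound
    const double cut = 1.35 * E->h;
    const double cs = 1.36 * E->h;
    double minx = yx[0], maxx = yx[0], miny = yy[0], maxy = yy[0];
    for (int i = 1; i < N; ++i) {
      minx = std::min(minx, yx[i]); maxx = std::max(maxx, yx[i]);
      miny = std::min(miny, yy[i]); maxy = std::max(maxy, yy[i]);
    }
    const int ncx = (int)((maxx - minx) / cs) + 1;
    const int ncy = (int)((maxy - miny) / cs) + 1;
    std::vector<int> head((size_t)ncx * ncy, -1), nxt(N, -1);
    std::vector<int> ci(N), cj(N);
    for (int i = 0; i < N; ++i) {
      int cx = (int)((yx[i] - minx) / cs); if (cx >= ncx) cx = ncx - 1;
      int cy = (int)((yy[i] - miny) / cs); if (cy >= ncy) cy = ncy - 1;
      ci[i] = cx; cj[i] = cy;
      const int c = cy * ncx + cx;
      nxt[i] = head[c]; head[c] = i;
    }
    const double cut2 = cut * cut;
    for (int i = 0; i < N; ++i) {
      for (int dcx = -1; dcx <= 1; ++dcx) {
        const int cx = ci[i] + dcx; if (cx < 0 || cx >= ncx) continue;
        for (int dcy = -1; dcy <= 1; ++dcy) {
          const int cy = cj[i] + dcy; if (cy < 0 || cy >= ncy) continue;
          for (int j = head[cy * ncx + cx]; j != -1; j = nxt[j]) {
            if (j <= i) continue;
            const double dx = yx[j] - yx[i], dy = yy[j] - yy[i];
            const double d2 = dx * dx + dy * dy;
            if (d2 >= cut2) continue;
            const double rdx = E->rx[j] - E->rx[i], rdy = E->ry[j] - E->ry[i];
            const double refd = std::sqrt(rdx * rdx + rdy * rdy);
            const double dpi = std::min(0.9 * refd, E->dpi_cap);
            const double d = std::sqrt(d2);
            if (d >= dpi) continue;
            const double fmag = E->Csr * (d - dpi);   // < 0: repulsive
            double ux, uy;
            if (d < 1e-12) { ux = 1.0; uy = 0.0; E->contact_coincident++; }
            else { ux = dx / d; uy = dy / d; }
            const double fxv = E->eps * fmag * ux * E->area;
            const double fyv = E->eps * fmag * uy * E->area;
            E->fx[i] += fxv; E->fy[i] += fyv;
            E->fx[j] -= fxv; E->fy[j] -= fyv;
          }
        }
      }
    }
  }
}

void accel_into(Engine* E, const double* yx, const double* yy,
                double* ox, double* oy) {
  compute_force(E, yx, yy, true, true);
  const double inv = 1.0 / E->rho;
  for (int i = 0; i < E->N; ++i) { ox[i] = E->fx[i] * inv; oy[i] = E->fy[i] * inv; }
}

void ensure_accel(Engine* E) {
  if (!E->accel_valid) {
    accel_into(E, E->px.data(), E->py.data(), E->ax.data(), E->ay.data());
    E->accel_valid = true;
  }
}

void project_constraints(Engine* E, double dt,
                         double* yx, double* yy, double* vx, double* vy) {
  for (int i = 0; i < E->N; ++i) {
    if (E->pinned[i]) {
      yx[i] = E->rx[i]; yy[i] = E->ry[i]; vx[i] = 0.0; vy[i] = 0.0;
    } else if (E->blayer[i]) {
      vx[i] = E->bvx[i]; vy[i] = E->bvy[i];
      yx[i] = E->px[i] + dt * E->bvx[i];
      yy[i] = E->py[i] + dt * E->bvy[i];
    }
  }
}

// attempt one trapezoidal step; commits state only on convergence
bool trap_step(Engine* E, double dt, int max_iter, double tol, int* iters_out) {
  const int N = E->N;
  ensure_accel(E);
  double* y1x = E->y1x.data(); double* y1y = E->y1y.data();
  double* v1x = E->v1x.data(); double* v1y = E->v1y.data();
  double* asx = E->asx.data(); double* asy = E->asy.data();
  // forward-Euler predictor
  for (int i = 0; i < N; ++i) {
    y1x[i] = E->px[i] + dt * E->vx[i];
    y1y[i] = E->py[i] + dt * E->vy[i];
    v1x[i] = E->vx[i] + dt * E->ax[i];
    v1y[i] = E->vy[i] + dt * E->ay[i];
  }
  project_constraints(E, dt, y1x, y1y, v1x, v1y);
  bool converged = false;
  int it = 0;
  double prev_delta = R_PosInf;
  for (it = 1; it <= max_iter; ++it) {
    accel_into(E, y1x, y1y, asx, asy);
    double delta = 0.0;
    for (int i = 0; i < N; ++i) {
      double vnx = E->vx[i] + 0.5 * dt * (E->ax[i] + asx[i]);
      double vny = E->vy[i] + 0.5 * dt * (E->ay[i] + asy[i]);
      double ynx = E->px[i] + 0.5 * dt * (E->vx[i] + vnx);
      double yny = E->py[i] + 0.5 * dt * (E->vy[i] + vny);
      if (E->pinned[i]) {
        ynx = E->rx[i]; yny = E->ry[i]; vnx = 0.0; vny = 0.0;
      } else if (E->blayer[i]) {
        vnx = E->bvx[i]; vny = E->bvy[i];
        ynx = E->px[i] + dt * E->bvx[i];
        yny = E->py[i] + dt * E->bvy[i];
      }
      delta = std::max(delta, std::max(std::fabs(ynx - y1x[i]),
                                       std::fabs(yny - y1y[i])));
      y1x[i] = ynx; y1y[i] = yny; v1x[i] = vnx; v1y[i] = vny;
    }
    if (!std::isfinite(delta)) return false;     // blow-up: reject
    // position change relative to the lattice spacing: an absolute measure
    // that tightens automatically where crack-tip dynamics localise, which
    // is what drives the time step down during active rupture
    if (delta <= tol * E->h) { converged = true; break; }
    // growing iterate change = divergent stiff mode: reject early so the
    // controller shrinks dt to the true fixed-point stability boundary
    if (it > 1 && delta > prev_delta) { *iters_out = it; return false; }
    prev_delta = delta;
  }
  *iters_out = std::min(it, max_iter);
  if (!converged) return false;
  // commit
  std::copy(y1x, y1x + N, E->px.begin());
  std::copy(y1y, y1y + N, E->py.begin());
  std::copy(v1x, v1x + N, E->vx.begin());
  std::copy(v1y, v1y + N, E->vy.begin());
  std::copy(asx, asx + N, E->ax.begin());
  std::copy(asy, asy + N, E->ay.begin());
  E->t += dt;
  E->step_index++;
  return true;
}

// break bonds stretched beyond s_c at the current accepted positions
int break_bonds(Engine* E) {
  int newly = 0;
  const int N = E->N;
  for (int i = 0; i < N; ++i) {
    for (int b = E->bptr[i]; b < E->bptr[i + 1]; ++b) {
      const int j = E->bj[b];
      if (j < i || !E->intact[b]) continue;
      const double dx = E->px[j] - E->px[i], dy = E->py[j] - E->py[i];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d > E->blen[b] * (1.0 + E->sc)) {
        E->intact[b] = 0; E->intact[E->brev[b]] = 0;
        E->nbroken[i]++; E->nbroken[j]++;
        newly += 2;
      }
    }
  }
  if (newly > 0) {
    E->accel_valid = false;
    for (int i = 0; i < N; ++i) {
      if (E->cross_time[i] < 0.0 && E->n0[i] > 0 &&
          (double)E->nbroken[i] / (double)E->n0[i] >= 0.5)
        E->cross_time[i] = E->t;
    }
  }
  return newly / 2;
}

double expansion_ratio_of(Engine* E) {
  double r2 = 0.0;
  for (int i = 0; i < E->N; ++i)
    r2 = std::max(r2, E->px[i] * E->px[i] + E->py[i] * E->py[i]);
  return 2.0 * std::sqrt(r2) / E->D0;
}

NumericVector damage_of(Engine* E) {
  NumericVector d(E->N);
  for (int i = 0; i < E->N; ++i)
    d[i] = (E->n0[i] > 0) ? (double)E->nbroken[i] / (double)E->n0[i] : 1.0;
  return d;
}

List snapshot_of(Engine* E) {
  const int N = E->N;
  NumericMatrix y(N, 2), v(N, 2);
  for (int i = 0; i < N; ++i) {
    y(i, 0) = E->px[i]; y(i, 1) = E->py[i];
    v(i, 0) = E->vx[i]; v(i, 1) = E->vy[i];
  }
  return List::create(_["t"] = E->t, _["positions"] = y, _["velocities"] = v,
                      _["damage"] = damage_of(E),
                      _["ratio"] = expansion_ratio_of(E),
                      _["broken_bonds"] = [&]{
                        long s = 0; for (int i = 0; i < E->N; ++i) s += E->nbroken[i];
                        return (double)(s / 2); }());
}

} // namespace

// [[Rcpp::export]]
List cpp_build_bonds(NumericMatrix x, double delta) {
  const int N = x.nrow();
  std::vector<double> px(N), py(N);
  for (int i = 0; i < N; ++i) { px[i] = x(i, 0); py[i] = x(i, 1); }
  double minx = px[0], maxx = px[0], miny = py[0], maxy = py[0];
  for (int i = 1; i < N; ++i) {
    minx = std::min(minx, px[i]); maxx = std::max(maxx, px[i]);
    miny = std::min(miny, py[i]); maxy = std::max(maxy, py[i]);
  }
  const double cs = delta * (1.0 + 1e-12);
  const int ncx = (int)((maxx - minx) / cs) + 1;
  const int ncy = (int)((maxy - miny) / cs) + 1;
  std::vector<int> head((size_t)ncx * ncy, -1), nxt(N, -1);
  for (int i = 0; i < N; ++i) {
    int cx = (int)((px[i] - minx) / cs); if (cx >= ncx) cx = ncx - 1;
    int cy = (int)((py[i] - miny) / cs); if (cy >= ncy) cy = ncy - 1;
    const int c = cy * ncx + cx;
    nxt[i] = head[c]; head[c] = i;
  }
  // closed ball: ||xi|| <= delta, with a tiny tolerance so lattice points at
  // exactly delta are kept despite floating-point rounding
  const double d2max = delta * delta * (1.0 + 1e-9);
  std::vector<std::vector<int> > nb(N);
  for (int i = 0; i < N; ++i) {
    const int cx0 = (int)((px[i] - minx) / cs), cy0 = (int)((py[i] - miny) / cs);
    for (int dcx = -1; dcx <= 1; ++dcx) {
      const int cx = std::min(cx0, ncx - 1) + dcx; if (cx < 0 || cx >= ncx) continue;
      for (int dcy = -1; dcy <= 1; ++dcy) {
        const int cy = std::min(cy0, ncy - 1) + dcy; if (cy < 0 || cy >= ncy) continue;
        for (int j = head[cy * ncx + cx]; j != -1; j = nxt[j]) {
          if (j == i) continue;
          const double dx = px[j] - px[i], dy = py[j] - py[i];
          if (dx * dx + dy * dy <= d2max) nb[i].push_back(j);
        }
      }
    }
    std::sort(nb[i].begin(), nb[i].end());
  }
  IntegerVector bptr(N + 1);
  long M = 0;
  for (int i = 0; i < N; ++i) { bptr[i] = (int)M; M += (long)nb[i].size(); }
  bptr[N] = (int)M;
  IntegerVector bjv((int)M), brev((int)M);
  NumericVector blen((int)M);
  for (int i = 0; i < N; ++i) {
    int b = bptr[i];
    for (size_t k = 0; k < nb[i].size(); ++k, ++b) {
      const int j = nb[i][k];
      bjv[b] = j;
      const double dx = px[j] - px[i], dy = py[j] - py[i];
      blen[b] = std::sqrt(dx * dx + dy * dy);
    }
  }
  // reverse bond: binary search for i in the sorted neighbour list of j
  for (int i = 0; i < N; ++i) {
    for (int b = bptr[i]; b < bptr[i + 1]; ++b) {
      const int j = bjv[b];
      int lo = bptr[j], hi = bptr[j + 1] - 1, pos = -1;
      while (lo <= hi) {
        const int mid = (lo + hi) / 2;
        if (bjv[mid] == i) { pos = mid; break; }
        if (bjv[mid] < i) lo = mid + 1; else hi = mid - 1;
      }
      brev[b] = pos;
    }
  }
  return List::create(_["bptr"] = bptr, _["bj"] = bjv, _["brev"] = brev,
                      _["blen"] = blen);
}

// [[Rcpp::export]]
SEXP cpp_engine_create(NumericMatrix xref, List bonds, LogicalVector pinned,
                       LogicalVector blayer, List material, double spacing_h,
                       double thickness, double loading_rate, double D0,
                       double r_junction) {
  Engine* E = new Engine();
  const int N = xref.nrow();
  E->N = N; E->D0 = D0;
  E->rx.resize(N); E->ry.resize(N);
  for (int i = 0; i < N; ++i) { E->rx[i] = xref(i, 0); E->ry[i] = xref(i, 1); }
  E->px = E->rx; E->py = E->ry;
  E->vx.assign(N, 0.0); E->vy.assign(N, 0.0);
  E->ax.assign(N, 0.0); E->ay.assign(N, 0.0);
  E->accel_valid = false;
  IntegerVector bptr = bonds["bptr"], bjv = bonds["bj"], brev = bonds["brev"];
  NumericVector blen = bonds["blen"];
  E->bptr.assign(bptr.begin(), bptr.end());
  E->bj.assign(bjv.begin(), bjv.end());
  E->brev.assign(brev.begin(), brev.end());
  E->blen.assign(blen.begin(), blen.end());
  E->intact.assign(E->bj.size(), 1);
  E->n0.resize(N); E->nbroken.assign(N, 0);
  E->h = spacing_h; E->area = spacing_h * spacing_h;
  E->eps = thickness;
  E->K = as<double>(material["K"]);
  E->G = as<double>(material["G"]);
  E->sc = as<double>(material["critical_stretch"]);
  E->rho = as<double>(material["rho_internal"]);   // kg/um^3, mass-scaled
  E->Csr = as<double>(material["Csr"]);
  E->dpi_cap = 1.35 * spacing_h;
  E->contact_cutoff = as<double>(material["contact_cutoff_mult"]) * spacing_h;
  E->mi.assign(N, 0.0);
  for (int i = 0; i < N; ++i) {
    E->n0[i] = E->bptr[i + 1] - E->bptr[i];
    double m = 0.0;
    for (int b = E->bptr[i]; b < E->bptr[i + 1]; ++b)
      m += E->blen[b] * E->blen[b] * E->area;
    E->mi[i] = m;
  }
  E->pinned.resize(N); E->blayer.resize(N);
  E->bvx.assign(N, 0.0); E->bvy.assign(N, 0.0);
  for (int i = 0; i < N; ++i) {
    E->pinned[i] = pinned[i] ? 1 : 0;
    E->blayer[i] = (blayer[i] && !pinned[i]) ? 1 : 0;
    if (E->blayer[i]) {
      const double r = std::sqrt(E->rx[i] * E->rx[i] + E->ry[i] * E->ry[i]);
      if (r > 0) { E->bvx[i] = loading_rate * E->rx[i] / r;
                   E->bvy[i] = loading_rate * E->ry[i] / r; }
    }
  }
  // transient-free start: seed the quasi-static co-moving velocity field
  // (uniform radial strain rate inside the driven layer) so the impulsive
  // plug launch does not dump an unphysical displacement jump - and hence
  // spurious fracture - onto the layer junction
  if (loading_rate > 0 && r_junction > 0) {
    const double sdot = loading_rate / r_junction;
    for (int i = 0; i < N; ++i) {
      if (E->pinned[i]) continue;
      if (E->blayer[i]) { E->vx[i] = E->bvx[i]; E->vy[i] = E->bvy[i]; }
      else { E->vx[i] = sdot * E->rx[i]; E->vy[i] = sdot * E->ry[i]; }
    }
  }
  E->t = 0.0; E->step_index = 0;
  E->zero_len_bonds = 0; E->contact_coincident = 0;
  E->cross_time.assign(N, -1.0);
  E->theta.assign(N, 0.0); E->fx.assign(N, 0.0); E->fy.assign(N, 0.0);
  E->y1x.resize(N); E->y1y.resize(N); E->v1x.resize(N); E->v1y.resize(N);
  E->y2x.resize(N); E->y2y.resize(N); E->v2x.resize(N); E->v2y.resize(N);
  E->asx.resize(N); E->asy.resize(N);
  Rcpp::XPtr<Engine> ptr(E, true);
  return ptr;
}

// [[Rcpp::export]]
NumericMatrix cpp_engine_force(SEXP xp, NumericMatrix y, bool internal,
                               bool contact) {
  Engine* E = get_engine(xp);
  std::vector<double> yx(E->N), yy(E->N);
  for (int i = 0; i < E->N; ++i) { yx[i] = y(i, 0); yy[i] = y(i, 1); }
  compute_force(E, yx.data(), yy.data(), internal, contact);
  NumericMatrix out(E->N, 2);
  for (int i = 0; i < E->N; ++i) { out(i, 0) = E->fx[i]; out(i, 1) = E->fy[i]; }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_engine_dilatation(SEXP xp, NumericMatrix y) {
  Engine* E = get_engine(xp);
  std::vector<double> yx(E->N), yy(E->N);
  for (int i = 0; i < E->N; ++i) { yx[i] = y(i, 0); yy[i] = y(i, 1); }
  compute_force(E, yx.data(), yy.data(), true, false);
  return NumericVector(E->theta.begin(), E->theta.end());
}

// [[Rcpp::export]]
List cpp_engine_step(SEXP xp, double dt, int max_iter, double tol) {
  Engine* E = get_engine(xp);
  int iters = 0;
  const bool ok = trap_step(E, dt, max_iter, tol, &iters);
  return List::create(_["converged"] = ok, _["iterations"] = iters);
}

// [[Rcpp::export]]
int cpp_engine_break(SEXP xp) {
  return break_bonds(get_engine(xp));
}

// [[Rcpp::export]]
List cpp_engine_state(SEXP xp) {
  Engine* E = get_engine(xp);
  List s = snapshot_of(E);
  s["step_index"] = (double)E->step_index;
  s["first_cross"] = NumericVector(E->cross_time.begin(), E->cross_time.end());
  LogicalVector it(E->intact.size());
  for (size_t b = 0; b < E->intact.size(); ++b) it[b] = E->intact[b] != 0;
  s["intact"] = it;
  s["weighted_volume"] = NumericVector(E->mi.begin(), E->mi.end());
  return s;
}

// [[Rcpp::export]]
void cpp_engine_set_state(SEXP xp, NumericMatrix y, NumericMatrix v, double t) {
  Engine* E = get_engine(xp);
  for (int i = 0; i < E->N; ++i) {
    E->px[i] = y(i, 0); E->py[i] = y(i, 1);
    E->vx[i] = v(i, 0); E->vy[i] = v(i, 1);
  }
  E->t = t;
  E->accel_valid = false;
}

// [[Rcpp::export]]
void cpp_engine_sync_intact(SEXP xp, LogicalVector intact) {
  Engine* E = get_engine(xp);
  std::fill(E->nbroken.begin(), E->nbroken.end(), 0);
  for (int i = 0; i < E->N; ++i) {
    for (int b = E->bptr[i]; b < E->bptr[i + 1]; ++b) {
      E->intact[b] = intact[b] ? 1 : 0;
      if (!E->intact[b]) E->nbroken[i]++;
    }
  }
  E->accel_valid = false;
}

// [[Rcpp::export]]
List cpp_engine_run(SEXP xp, List settings) {
  Engine* E = get_engine(xp);
  double dt = as<double>(settings["dt_initial"]);
  const double dt_min = as<double>(settings["dt_min"]);
  const double dt_max = as<double>(settings["dt_max"]);
  const double grow = as<double>(settings["dt_grow"]);
  const double shrink = as<double>(settings["dt_shrink"]);
  const int grow_thresh = as<int>(settings["grow_iters"]);
  const int max_iter = as<int>(settings["max_fp_iterations"]);
  const double tol = as<double>(settings["fp_tolerance"]);
  const double stop_ratio = as<double>(settings["stop_ratio"]);
  const double t_max = as<double>(settings["t_max"]);
  const long max_steps = (long)as<double>(settings["max_steps"]);
  const double snap_dt = as<double>(settings["snapshot_dt"]);

  List snaps;
  snaps.push_back(snapshot_of(E));
  double next_snap = snap_dt;
  std::vector<double> log_t, log_dt, log_ratio;
  std::vector<int> log_iters, log_broken;
  std::string status = "stop_ratio";
  long steps = 0;

  while (true) {
    if (expansion_ratio_of(E) >= stop_ratio) { status = "stop_ratio"; break; }
    if (E->t >= t_max) { status = "t_max"; break; }
    if (steps >= max_steps) { status = "max_steps"; break; }
    int iters = 0;
    bool ok = trap_step(E, dt, max_iter, tol, &iters);
    if (!ok) {
      dt *= shrink;
      if (dt < dt_min) { status = "dt_underflow"; break; }
      continue;
    }
    steps++;
    const int newly = break_bonds(E);
    log_t.push_back(E->t); log_dt.push_back(dt);
    log_iters.push_back(iters); log_broken.push_back(newly);
    log_ratio.push_back(expansion_ratio_of(E));
    if (iters <= grow_thresh) dt = std::min(dt * grow, dt_max);
    if (E->t >= next_snap - 1e-15) {
      snaps.push_back(snapshot_of(E));
      while (next_snap <= E->t + 1e-15) next_snap += snap_dt;
    }
    if (steps % 256 == 0) Rcpp::checkUserInterrupt();
  }
  // final state always recorded
  snaps.push_back(snapshot_of(E));
  const int nl = (int)log_t.size();
  NumericMatrix log(nl, 5);
  for (int k = 0; k < nl; ++k) {
    log(k, 0) = log_t[k]; log(k, 1) = log_dt[k]; log(k, 2) = log_iters[k];
    log(k, 3) = log_broken[k]; log(k, 4) = log_ratio[k];
  }
  colnames(log) = CharacterVector::create("t", "dt", "iterations",
                                          "new_broken", "ratio");
  return List::create(_["snapshots"] = snaps, _["log"] = log,
                      _["status"] = status,
                      _["first_cross"] = NumericVector(E->cross_time.begin(),
                                                       E->cross_time.end()),
                      _["steps"] = (double)steps);
}

// 8-connected component labeling of a binary raster (column-major matrix).
// Labels are 1..k in first-encounter (column-major scan) order; 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        const int rr = stack.back().first, cc = stack.back().second;
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(std::make_pair(r2, c2));
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
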