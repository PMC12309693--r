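// Core of the midline vertex model: tissue energy, analytic forces, and the
// stochastic time-stepping engine.  Cells are quadrilaterals in a shared-vertex
// chain; vertex order within a cell is fixed as (anterior-basal, posterior-basal,
// posterior-apical, anterior-apical).  Each tissue carries its own frame
// (basal reference line + apical direction sign) so mirrored tissues reuse the
// same potentials.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Mech {
  double a, b, c, d, V0, h, hth, ell, tau, sigma;
};

static Mech as_mech(const List& m) {
  Mech p;
  p.a = as<double>(m["a"]);
  p.b = as<double>(m["b"]);
  p.c = as<double>(m["c"]);
  p.d = as<double>(m["d"]);
  p.V0 = as<double>(m["V0"]);
  p.h = as<double>(m["h"]);
  p.hth = as<double>(m["h_th"]);
  p.ell = as<double>(m["ell"]);
  p.tau = as<double>(m["tau"]);
  p.sigma = as<double>(m["sigma"]);
  return p;
}

// Basal adhesion potential.  The first quadratic branch is extended to
// negative distances so a vertex crossing the basal line still feels a smooth
// restoring force; f is C1 at both breakpoints by construction.
static inline double pot_f(double x, double h, double hth) {
  double mid = 0.5 * (h + hth);
  if (x < mid) return 0.5 * (x - h) * (x - h) - 0.25 * (hth - h) * (hth - h);
  if (x < hth) return -0.5 * (x - hth) * (x - hth);
  return 0.0;
}
static inline double pot_f_d(double x, double h, double hth) {
  double mid = 0.5 * (h + hth);
  if (x < mid) return x - h;
  if (x < hth) return hth - x;
  return 0.0;
}
// Apical repulsion beyond the confinement distance ell.
static inline double pot_g(double x, double ell) {
  return (x < ell) ? 0.0 : 0.5 * (x - ell) * (x - ell);
}
static inline double pot_g_d(double x, double ell) {
  return (x < ell) ? 0.0 : (x - ell);
}

struct TisSpec {
  double basal_y;
  double asign;      // +1 apical above the basal line, -1 mirrored
  bool migrate;
  bool strain_div;
  int clock_mode;    // 0 none, 1 all cells, 2 posterior-most cell only
  double V0;
};

struct EngineState {
  std::vector<double> X, Y;
  std::vector<char> fixed_x;
  std::vector<int> C;         // 4 vertex ids per cell, 0-based
  std::vector<int> ct;        // tissue index per cell
  std::vector<double> v;      // migration force per cell
  std::vector<double> w;      // migration activity per cell
  std::vector<double> age;    // time since birth (clock divisions)
  std::vector<double> Tl;     // latch time, NaN = unset
  std::vector<double> Dc;     // clock period per cell
  std::vector<TisSpec> ts;
  Mech mech;
  int n() const { return (int)X.size(); }
  int m() const { return (int)ct.size(); }
};

// Total energy; if FX/FY given, accumulates -gradient into them.
// Returns NaN and sets *bad_cell on nonpositive/nonfinite oriented area.
static double energy_forces(const EngineState& E,
                            std::vector<double>* FX, std::vector<double>* FY,
                            int* bad_cell) {
  const int m = E.m();
  double U = 0.0;
  *bad_cell = -1;
  for (int i = 0; i < m; i++) {
    const TisSpec& T = E.ts[E.ct[i]];
    int id[4];
    double x[4], y[4];
    for (int k = 0; k < 4; k++) {
      id[k] = E.C[4 * i + k];
      x[k] = E.X[id[k]];
      y[k] = E.Y[id[k]];
    }
    double A = 0.0;
    for (int k = 0; k < 4; k++) {
      int k1 = (k + 1) & 3;
      A += x[k] * y[k1] - x[k1] * y[k];
    }
    A *= 0.5;
    double V = T.asign * A;  // oriented area, positive for valid cells
    if (!std::isfinite(V) || V <= 0.0) { *bad_cell = i; return NA_REAL; }
    U += 0.5 * E.mech.a * (V - T.V0) * (V - T.V0);

    double L = 0.0, ex[4], ey[4], el[4];
    for (int k = 0; k < 4; k++) {
      int k1 = (k + 1) & 3;
      ex[k] = x[k1] - x[k];
      ey[k] = y[k1] - y[k];
      el[k] = std::sqrt(ex[k] * ex[k] + ey[k] * ey[k]);
      L += el[k];
    }
    U += 0.5 * E.mech.b * L * L;

    double dist[4];
    for (int k = 0; k < 4; k++) dist[k] = T.asign * (y[k] - T.basal_y);
    for (int k = 0; k < 2; k++) U += E.mech.c * pot_f(dist[k], E.mech.h, E.mech.hth);
    for (int k = 2; k < 4; k++) U += E.mech.d * pot_g(dist[k], E.mech.ell);

    if (FX) {
      double cA = E.mech.a * (V - T.V0) * T.asign;  // dU/dA
      for (int k = 0; k < 4; k++) {
        int km = (k + 3) & 3, k1 = (k + 1) & 3;
        (*FX)[id[k]] -= cA * 0.5 * (y[k1] - y[km]);
        (*FY)[id[k]] -= cA * 0.5 * (x[km] - x[k1]);
        double dLx = 0.0, dLy = 0.0;
        if (el[km] > 0) { dLx += ex[km] / el[km]; dLy += ey[km] / el[km]; }
        if (el[k] > 0)  { dLx -= ex[k] / el[k];   dLy -= ey[k] / el[k]; }
        (*FX)[id[k]] -= E.mech.b * L * dLx;
        (*FY)[id[k]] -= E.mech.b * L * dLy;
      }
      for (int k = 0; k < 2; k++)
        (*FY)[id[k]] -= E.mech.c * pot_f_d(dist[k], E.mech.h, E.mech.hth) * T.asign;
      for (int k = 2; k < 4; k++)
        (*FY)[id[k]] -= E.mech.d * pot_g_d(dist[k], E.mech.ell) * T.asign;
    }
  }
  return U;
}

static EngineState build_state(NumericMatrix vertices, IntegerMatrix cells,
                               IntegerVector cell_tissue, LogicalVector vfixed,
                               List tissue_spec, List mech) {
  EngineState E;
  int n = vertices.nrow(), m = cells.nrow();
  E.X.resize(n); E.Y.resize(n); E.fixed_x.assign(n, 0);
  for (int j = 0; j < n; j++) {
    E.X[j] = vertices(j, 0);
    E.Y[j] = vertices(j, 1);
    E.fixed_x[j] = vfixed[j] ? 1 : 0;
  }
  E.C.resize(4 * m); E.ct.resize(m);
  for (int i = 0; i < m; i++) {
    for (int k = 0; k < 4; k++) E.C[4 * i + k] = cells(i, k) - 1;
    E.ct[i] = cell_tissue[i] - 1;
  }
  int nt = tissue_spec.size();
  E.ts.resize(nt);
  for (int t = 0; t < nt; t++) {
    List s = tissue_spec[t];
    E.ts[t].basal_y = as<double>(s["basal_y"]);
    E.ts[t].asign = as<double>(s["apical_sign"]);
    E.ts[t].migrate = as<bool>(s["migrate"]);
    E.ts[t].strain_div = as<bool>(s["strain_div"]);
    E.ts[t].clock_mode = as<int>(s["clock_mode"]);
    E.ts[t].V0 = as<double>(s["V0"]);
  }
  E.mech = as_mech(mech);
  return E;
}

// [[Rcpp::export]]
double energy_cpp(NumericMatrix vertices, IntegerMatrix cells,
                  IntegerVector cell_tissue, List tissue_spec, List mech) {
  LogicalVector vf(vertices.nrow(), false);
  EngineState E = build_state(vertices, cells, cell_tissue, vf, tissue_spec, mech);
  int bad;
  double U = energy_forces(E, nullptr, nullptr, &bad);
  if (bad >= 0)
    stop("geometry error: nonpositive oriented area in cell %d", bad + 1);
  return U;
}

// [[Rcpp::export]]
NumericMatrix forces_cpp(NumericMatrix vertices, IntegerMatrix cells,
                         IntegerVector cell_tissue, List tissue_spec, List mech) {
  LogicalVector vf(vertices.nrow(), false);
  EngineState E = build_state(vertices, cells, cell_tissue, vf, tissue_spec, mech);
  std::vector<double> FX(E.n(), 0.0), FY(E.n(), 0.0);
  int bad;
  double U = energy_forces(E, &FX, &FY, &bad);
  if (bad >= 0)
    stop("geometry error: nonpositive oriented area in cell %d", bad + 1);
  (void)U;
  NumericMatrix out(E.n(), 2);
  for (int j = 0; j < E.n(); j++) { out(j, 0) = FX[j]; out(j, 1) = FY[j]; }
  return out;
}

static double cell_centroid_x(const EngineState& E, int i) {
  double s = 0.0;
  for (int k = 0; k < 4; k++) s += E.X[E.C[4 * i + k]];
  return 0.25 * s;
}

// Migration activity w_i = vmax * ((x_i - xmin)/(xmax - xmin))^alpha per
// migrating tissue; degenerate range (single cell) maps every cell to vmax.
static void update_activity(EngineState& E, double vmax, double alpha) {
  int m = E.m();
  int nt = (int)E.ts.size();
  std::vector<double> xmin(nt, R_PosInf), xmax(nt, R_NegInf);
  std::vector<double> cx(m);
  for (int i = 0; i < m; i++) {
    cx[i] = cell_centroid_x(E, i);
    int t = E.ct[i];
    if (E.ts[t].migrate) {
      xmin[t] = std::min(xmin[t], cx[i]);
      xmax[t] = std::max(xmax[t], cx[i]);
    }
  }
  for (int i = 0; i < m; i++) {
    int t = E.ct[i];
    if (!E.ts[t].migrate) { E.w[i] = 0.0; continue; }
    double range = xmax[t] - xmin[t];
    if (range <= 0) { E.w[i] = vmax; continue; }
    double s = (cx[i] - xmin[t]) / range;
    E.w[i] = vmax * std::pow(s, alpha);
  }
}

// One classical RK4 step of eta dv/dt = -v + w with w frozen.
static inline double rk4_relax(double v, double w, double eta, double dt) {
  double k1 = (w - v) / eta;
  double k2 = (w - (v + 0.5 * dt * k1)) / eta;
  double k3 = (w - (v + 0.5 * dt * k2)) / eta;
  double k4 = (w - (v + dt * k3)) / eta;
  return v + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
}

struct EventLog {
  std::vector<double> t, cx, rel;
  std::vector<int> cell, tissue;
};

static void tissue_extent(const EngineState& E, int tis, double* lo, double* hi) {
  *lo = R_PosInf; *hi = R_NegInf;
  for (int i = 0; i < E.m(); i++) {
    if (E.ct[i] != tis) continue;
    for (int k = 0; k < 4; k++) {
      double x = E.X[E.C[4 * i + k]];
      *lo = std::min(*lo, x);
      *hi = std::max(*hi, x);
    }
  }
}

// Split cell i at the midpoints of its apical and basal edges.  The parent
// slot becomes the anterior daughter; the posterior daughter is appended, so
// pre-existing vertices (including any tether vertex) are untouched.
static void divide_cell_engine(EngineState& E, int i, double t, EventLog& ev) {
  int ab = E.C[4 * i + 0], pb = E.C[4 * i + 1], pa = E.C[4 * i + 2], aa = E.C[4 * i + 3];
  double bl = std::hypot(E.X[pb] - E.X[ab], E.Y[pb] - E.Y[ab]);
  double al = std::hypot(E.X[aa] - E.X[pa], E.Y[aa] - E.Y[pa]);
  if (bl <= 0 || al <= 0)
    stop("geometry error: zero-length apical or basal edge at division (cell %d, t=%g)",
         i + 1, t);
  double lo, hi;
  tissue_extent(E, E.ct[i], &lo, &hi);
  double cx = cell_centroid_x(E, i);
  double rel = (hi > lo) ? (cx - lo) / (hi - lo) : 0.5;
  rel = std::min(1.0, std::max(0.0, rel));
  ev.t.push_back(t);
  ev.cell.push_back(i + 1);
  ev.tissue.push_back(E.ct[i] + 1);
  ev.cx.push_back(cx);
  ev.rel.push_back(rel);

  int mb = E.n();
  E.X.push_back(0.5 * (E.X[ab] + E.X[pb]));
  E.Y.push_back(0.5 * (E.Y[ab] + E.Y[pb]));
  E.fixed_x.push_back(0);
  int ma = E.n();
  E.X.push_back(0.5 * (E.X[pa] + E.X[aa]));
  E.Y.push_back(0.5 * (E.Y[pa] + E.Y[aa]));
  E.fixed_x.push_back(0);

  // anterior daughter reuses the parent slot
  E.C[4 * i + 1] = mb;
  E.C[4 * i + 2] = ma;
  // posterior daughter appended
  E.C.push_back(mb); E.C.push_back(pb); E.C.push_back(pa); E.C.push_back(ma);
  E.ct.push_back(E.ct[i]);
  E.v[i] = 0.0;   E.v.push_back(0.0);
  E.w.push_back(E.w[i]);
  E.age[i] = 0.0; E.age.push_back(0.0);
  E.Tl[i] = NA_REAL; E.Tl.push_back(NA_REAL);
  E.Dc.push_back(E.Dc[i]);
}

static List snapshot(const EngineState& E, double t, double U) {
  int n = E.n(), m = E.m();
  NumericMatrix V(n, 2);
  for (int j = 0; j < n; j++) { V(j, 0) = E.X[j]; V(j, 1) = E.Y[j]; }
  IntegerMatrix C(m, 4);
  IntegerVector ct(m);
  NumericVector v(m);
  for (int i = 0; i < m; i++) {
    for (int k = 0; k < 4; k++) C(i, k) = E.C[4 * i + k] + 1;
    ct[i] = E.ct[i] + 1;
    v[i] = E.v[i];
  }
  return List::create(_["t"] = t, _["vertices"] = V, _["cells"] = C,
                      _["tissue"] = ct, _["v"] = v, _["energy"] = U);
}

// [[Rcpp::export]]
List run_engine_cpp(NumericMatrix vertices, IntegerMatrix cells,
                    IntegerVector cell_tissue, LogicalVector vertex_fixed,
                    List tissue_spec, List mech, List migration, List division,
                    double dt, double t0, double t_end, double record_every,
                    NumericVector init_v, NumericVector init_age,
                    NumericVector init_Tlatch, NumericVector cell_D) {
  EngineState E = build_state(vertices, cells, cell_tissue, vertex_fixed,
                              tissue_spec, mech);
  int m0 = E.m();
  E.v.assign(init_v.begin(), init_v.end());
  E.w.assign(m0, 0.0);
  E.age.assign(init_age.begin(), init_age.end());
  E.Tl.assign(init_Tlatch.begin(), init_Tlatch.end());
  E.Dc.assign(cell_D.begin(), cell_D.end());

  double eta = as<double>(migration["eta"]);
  double vmax = as<double>(migration["vmax"]);
  double alpha = as<double>(migration["exponent"]);
  double Uth = as<double>(division["U_th"]);
  double Sd = as<double>(division["S_default"]);
  bool latch_and_fire = as<std::string>(division["rearm_policy"]) == "latch-and-fire";

  long nsteps = (long)std::llround((t_end - t0) / dt);
  if (nsteps < 0) stop("t_end must be >= t0");

  bool any_clock = false, any_strain = false, any_migrate = false;
  for (size_t t = 0; t < E.ts.size(); t++) {
    if (E.ts[t].clock_mode > 0) any_clock = true;
    if (E.ts[t].strain_div) any_strain = true;
    if (E.ts[t].migrate) any_migrate = true;
  }

  EventLog ev;
  List frames;
  NumericVector energy_series(nsteps + 1);
  std::vector<double> frame_times;
  {
    int bad;
    double U0 = energy_forces(E, nullptr, nullptr, &bad);
    if (bad >= 0)
      stop("geometry error: nonpositive oriented area in cell %d at t=%g", bad + 1, t0);
    frames.push_back(snapshot(E, t0, U0));
    frame_times.push_back(t0);
  }
  double next_record = t0 + record_every;
  double sqdt = std::sqrt(dt);
  std::vector<double> FX, FY;
  std::vector<int> due;

  for (long step = 0; step < nsteps; step++) {
    double t = t0 + (step + 1) * dt;

    // migration forces (activity frozen within the RK4 step)
    if (any_migrate) {
      update_activity(E, vmax, alpha);
      for (int i = 0; i < E.m(); i++)
        if (E.ts[E.ct[i]].migrate)
          E.v[i] = rk4_relax(E.v[i], E.w[i], eta, dt);
    }

    // forces and Euler-Maruyama vertex update
    int n = E.n();
    FX.assign(n, 0.0);
    FY.assign(n, 0.0);
    int bad;
    double U = energy_forces(E, &FX, &FY, &bad);
    if (bad >= 0)
      stop("geometry error: nonpositive oriented area in cell %d at t=%g", bad + 1, t);
    energy_series[step] = U;
    if (any_migrate)
      for (int i = 0; i < E.m(); i++)
        if (E.ts[E.ct[i]].migrate)
          FX[E.C[4 * i + 1]] += E.v[i];  // applied at the posterior basal vertex

    double amp = E.mech.sigma / E.mech.tau * sqdt;
    for (int j = 0; j < n; j++) {
      if (!E.fixed_x[j]) {
        double nx = (amp > 0) ? amp * norm_rand() : 0.0;
        E.X[j] += FX[j] / E.mech.tau * dt + nx;
      }
      double ny = (amp > 0) ? amp * norm_rand() : 0.0;
      E.Y[j] += FY[j] / E.mech.tau * dt + ny;
      if (!std::isfinite(E.X[j]) || !std::isfinite(E.Y[j]))
        stop("integration blow-up: nonfinite vertex %d at t=%g", j + 1, t);
    }

    // divisions, checked once per step after the vertex update
    if (any_strain || any_clock) {
      due.clear();
      if (any_clock)
        for (int i = 0; i < E.m(); i++)
          if (E.ts[E.ct[i]].clock_mode > 0) E.age[i] += dt;
      if (any_strain) {
        for (int i = 0; i < E.m(); i++) {
          if (!E.ts[E.ct[i]].strain_div) continue;
          int ab = E.C[4 * i], pb = E.C[4 * i + 1], pa = E.C[4 * i + 2], aa = E.C[4 * i + 3];
          double bl2 = (E.X[pb] - E.X[ab]) * (E.X[pb] - E.X[ab]) +
                       (E.Y[pb] - E.Y[ab]) * (E.Y[pb] - E.Y[ab]);
          double al2 = (E.X[aa] - E.X[pa]) * (E.X[aa] - E.X[pa]) +
                       (E.Y[aa] - E.Y[pa]) * (E.Y[aa] - E.Y[pa]);
          double Ui = 0.5 * E.mech.b * (al2 + bl2);
          if (ISNAN(E.Tl[i])) {
            if (Ui > Uth) E.Tl[i] = t;
          } else if (t > E.Tl[i] + Sd) {
            if (latch_and_fire || Ui > Uth) due.push_back(i);
            else E.Tl[i] = NA_REAL;  // relaxed below threshold: rearm
          }
        }
      }
      if (any_clock) {
        for (size_t ti = 0; ti < E.ts.size(); ti++) {
          if (E.ts[ti].clock_mode == 1) {
            for (int i = 0; i < E.m(); i++)
              if (E.ct[i] == (int)ti && E.age[i] >= E.Dc[i]) due.push_back(i);
          } else if (E.ts[ti].clock_mode == 2) {
            int best = -1;
            double bx = R_NegInf;
            for (int i = 0; i < E.m(); i++) {
              if (E.ct[i] != (int)ti) continue;
              double cx = cell_centroid_x(E, i);
              if (cx > bx) { bx = cx; best = i; }
            }
            if (best >= 0 && E.age[best] >= E.Dc[best]) due.push_back(best);
          }
        }
      }
      if (!due.empty()) {
        std::sort(due.begin(), due.end());
        due.erase(std::unique(due.begin(), due.end()), due.end());
        for (size_t k = 0; k < due.size(); k++)
          divide_cell_engine(E, due[k], t, ev);
      }
    }

    if (record_every > 0 && (t >= next_record - 0.5 * dt || step == nsteps - 1)) {
      int b2;
      double Urec = energy_forces(E, nullptr, nullptr, &b2);
      frames.push_back(snapshot(E, t, Urec));
      frame_times.push_back(t);
      while (next_record <= t + 0.5 * dt) next_record += record_every;
    }
    if (step % 10000 == 0) Rcpp::checkUserInterrupt();
  }
  {
    int bad;
    energy_series[nsteps] = energy_forces(E, nullptr, nullptr, &bad);
  }
  if (nsteps == 0) energy_series[0] = as<double>(as<List>(frames[0])["energy"]);

  int m = E.m(), n = E.n();
  NumericMatrix Vfin(n, 2);
  LogicalVector fixfin(n);
  for (int j = 0; j < n; j++) {
    Vfin(j, 0) = E.X[j];
    Vfin(j, 1) = E.Y[j];
    fixfin[j] = E.fixed_x[j] != 0;
  }
  IntegerMatrix Cfin(m, 4);
  IntegerVector ctfin(m);
  NumericVector vfin(m), agefin(m), tlfin(m), dcfin(m);
  for (int i = 0; i < m; i++) {
    for (int k = 0; k < 4; k++) Cfin(i, k) = E.C[4 * i + k] + 1;
    ctfin[i] = E.ct[i] + 1;
    vfin[i] = E.v[i];
    agefin[i] = E.age[i];
    tlfin[i] = E.Tl[i];
    dcfin[i] = E.Dc[i];
  }
  return List::create(
      _["frames"] = frames,
      _["frame_times"] = NumericVector(frame_times.begin(), frame_times.end()),
      _["energy_series"] = energy_series,
      _["events"] = List::create(_["t"] = NumericVector(ev.t.begin(), ev.t.end()),
                                 _["cell"] = IntegerVector(ev.cell.begin(), ev.cell.end()),
                                 _["tissue"] = IntegerVector(ev.tissue.begin(), ev.tissue.end()),
                                 _["centroid_x"] = NumericVector(ev.cx.begin(), ev.cx.end()),
                                 _["relative_position"] = NumericVector(ev.rel.begin(), ev.rel.end())),
      _["final"] = List::create(_["t"] = t0 + nsteps * dt, _["vertices"] = Vfin,
                                _["cells"] = Cfin, _["tissue"] = ctfin,
                                _["fixed"] = fixfin, _["v"] = vfin,
                                _["age"] = agefin, _["T_latch"] = tlfin,
                                _["D"] = dcfin));
}
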