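// Coarse-grained aggregation model: cells are point-like agents in a 2-D box.
// Each agent senses the summed analytic cAMP profile of all other agents
// (exponential spatial decay, rear-weighted secretion), fires a pulse when the
// sensed concentration crosses c1, chemotaxes when the gradient magnitude
// crosses grad_c2, and is subject to volume exclusion.  All randomness goes
// through R's RNG so set.seed() gives bitwise reproducibility.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

constexpr int PH_QUIESCENT = 0;
constexpr int PH_FIRING = 1;
constexpr int PH_REFRACTORY = 2;

struct Cfg {
  double L;
  double dt;
  double speed;
  double lambda;
  double leak_amp;
  double pulse_amp;
  double pulse_duration;
  double pulse_decay_time;
  double pulse_rise_time;
  double c1;
  double grad_c2;
  double refractory_min;
  double excl;
  double turn_rad;      // turn half-angle in radians
  double noise_sd;      // multiplicative sensing noise sd (baseline * multiplier)
  bool uniform_secretion;
  bool adhesion_on;
  double adh_strength;
  double adh_range;
  bool async_pulsing;
  double async_rate;    // per-cell pulse onset rate (1/min), async variant
  bool periodic;
  double cutoff;        // field evaluation cutoff (um)
  int packing_threshold;
  double crowding_slowdown;  // speed factor inside densely packed regions
};

Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.L = as<double>(cfg["box_length"]);
  c.dt = as<double>(cfg["dt"]);
  c.speed = as<double>(cfg["speed"]);
  c.lambda = as<double>(cfg["decay_const"]);
  c.leak_amp = as<double>(cfg["leak_amplitude"]);
  c.pulse_amp = as<double>(cfg["pulse_amplitude"]);
  c.pulse_duration = as<double>(cfg["pulse_duration"]);
  c.pulse_decay_time = as<double>(cfg["pulse_decay_time"]);
  c.pulse_rise_time = as<double>(cfg["pulse_rise_time"]);
  c.c1 = as<double>(cfg["conc_threshold_c1"]);
  c.grad_c2 = as<double>(cfg["grad_threshold_c2"]);
  c.refractory_min = as<double>(cfg["refractory_min"]);
  c.excl = as<double>(cfg["exclusion_radius"]);
  c.turn_rad = as<double>(cfg["turn_half_angle"]) * M_PI / 180.0;
  c.noise_sd = as<double>(cfg["sensing_noise_sd"]) * as<double>(cfg["baseline_noise_sd"]);
  c.uniform_secretion = as<std::string>(cfg["secretion_mode"]) == "uniform";
  c.adhesion_on = as<bool>(cfg["adhesion_on"]);
  c.adh_strength = as<double>(cfg["adhesion_strength"]);
  c.adh_range = as<double>(cfg["adhesion_range"]);
  c.async_pulsing = as<bool>(cfg["async_pulsing"]);
  c.async_rate = as<double>(cfg["async_rate"]);
  c.periodic = as<std::string>(cfg["boundary"]) == "periodic";
  c.cutoff = as<double>(cfg["field_cutoff"]);
  c.packing_threshold = as<int>(cfg["packing_threshold"]);
  c.crowding_slowdown = as<double>(cfg["crowding_slowdown"]);
  return c;
}

inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;  // guard against floating-point roundup
  return x;
}

// minimum-image displacement component
inline double mindiff(double d, double L, bool periodic) {
  if (!periodic) return d;
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

// Cell-linked neighbor grid.  Grid cell size >= cutoff so the 3x3 block of
// grid cells around a query covers all candidates.  Falls back to brute force
// when the box holds fewer than 3 grid cells per side.
struct Grid {
  int ncell;
  double csize;
  double L;
  bool periodic;
  std::vector<int> head, nxt;
  const double* x;
  const double* y;
  int n;

  void build(const double* px, const double* py, int nn, double L_, double cutoff,
             bool periodic_) {
    x = px; y = py; n = nn; L = L_; periodic = periodic_;
    ncell = std::max(1, (int)std::floor(L / cutoff));
    if (ncell < 3) ncell = 1;  // brute force
    csize = L / ncell;
    head.assign(ncell * ncell, -1);
    nxt.assign(n, -1);
    if (ncell == 1) return;
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor(x[i] / csize);
      int cy = (int)std::floor(y[i] / csize);
      if (cx < 0) cx = 0; if (cx >= ncell) cx = ncell - 1;
      if (cy < 0) cy = 0; if (cy >= ncell) cy = ncell - 1;
      int c = cy * ncell + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  template <typename F>
  void for_neighbors(double qx, double qy, F&& f) const {
    if (ncell == 1) {
      for (int i = 0; i < n; ++i) f(i);
      return;
    }
    int cx = (int)std::floor(qx / csize);
    int cy = (int)std::floor(qy / csize);
    for (int dy = -1; dy <= 1; ++dy) {
      int gy = cy + dy;
      if (periodic) gy = (gy + ncell) % ncell;
      else if (gy < 0 || gy >= ncell) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int gx = cx + dx;
        if (periodic) gx = (gx + ncell) % ncell;
        else if (gx < 0 || gx >= ncell) continue;
        for (int i = head[gy * ncell + gx]; i >= 0; i = nxt[i]) f(i);
      }
    }
  }
};

struct Pert {
  int kind;       // 0 none, 1 global, 2 point
  double amount;
  double px, py;
  bool active;
};

// concentration + gradient of the summed secretion field at (qx,qy),
// excluding cell `excl` (-1 for none)
inline void field_at(const Grid& g, const std::vector<double>& amp,
                     const double* hx, const double* hy, const Cfg& c,
                     double qx, double qy, int excl, const Pert& pert,
                     double& conc, double& gx, double& gy) {
  double cc = 0, ggx = 0, ggy = 0;
  const double lam = c.lambda, cutoff = c.cutoff;
  g.for_neighbors(qx, qy, [&](int k) {
    if (k == excl) return;
    double dx = mindiff(qx - g.x[k], c.L, c.periodic);
    double dy = mindiff(qy - g.y[k], c.L, c.periodic);
    double d2 = dx * dx + dy * dy;
    if (d2 > cutoff * cutoff || d2 < 1e-18) return;
    double d = std::sqrt(d2);
    double ux = dx / d, uy = dy / d;
    double e = amp[k] * std::exp(-lam * d);
    if (c.uniform_secretion) {
      // radially symmetric secretion conserving the total emitted amount:
      // the rear-cosine weight integrates to 2 over the circle, so the
      // equal-total uniform weight is 1/pi
      e *= M_1_PI;
      cc += e;
      ggx += e * (-lam) * ux;
      ggy += e * (-lam) * uy;
    } else {
      // rear weight w = cos(angle between (q-p) and -heading), clipped at 0
      double w = -(hx[k] * ux + hy[k] * uy);
      if (w <= 0) return;
      cc += e * w;
      // grad of e(d)*w: e' = -lam*e; grad w = (-h - w*u)/d
      ggx += e * (-lam * w * ux + (-hx[k] - w * ux) / d);
      ggy += e * (-lam * w * uy + (-hy[k] - w * uy) / d);
    }
  });
  if (pert.active) {
    if (pert.kind == 1) {
      cc += pert.amount;
    } else if (pert.kind == 2) {
      double dx = mindiff(qx - pert.px, c.L, c.periodic);
      double dy = mindiff(qy - pert.py, c.L, c.periodic);
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > 1e-12) {
        double e = pert.amount * std::exp(-lam * d);
        cc += e;
        ggx += e * (-lam) * dx / d;
        ggy += e * (-lam) * dy / d;
      } else {
        cc += pert.amount;
      }
    }
  }
  conc = cc; gx = ggx; gy = ggy;
}

inline double amplitude_of(int phase, double clock, const Cfg& c) {
  if (phase == PH_FIRING) {
    // finite release kinetics: linear rise over pulse_rise_time, then
    // exponential decay; the rise sets the cell-to-cell relay latency and
    // hence the wave speed, independent of the integration step
    double rise = c.pulse_rise_time > 0
                      ? std::min(1.0, clock / c.pulse_rise_time)
                      : 1.0;
    return c.pulse_amp * rise * std::exp(-clock / c.pulse_decay_time);
  }
  return c.leak_amp;
}

}  // namespace

// [[Rcpp::export]]
List cpp_sensed_field(NumericMatrix pos, NumericMatrix heading,
                      IntegerVector phase, NumericVector clock, List cfg,
                      NumericVector query, int exclude, List pert_list) {
  Cfg c = read_cfg(cfg);
  int n = pos.nrow();
  std::vector<double> px(n), py(n), hx(n), hy(n), amp(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1);
    hx[i] = heading(i, 0); hy[i] = heading(i, 1);
    amp[i] = amplitude_of(phase[i], clock[i], c);
  }
  Grid g;
  g.build(px.data(), py.data(), n, c.L, c.cutoff, c.periodic);
  Pert pert;
  pert.kind = as<int>(pert_list["kind"]);
  pert.amount = as<double>(pert_list["amount"]);
  pert.px = as<double>(pert_list["x"]);
  pert.py = as<double>(pert_list["y"]);
  pert.active = pert.kind != 0;
  double conc, gx, gy;
  field_at(g, amp, hx.data(), hy.data(), c, query[0], query[1], exclude, pert,
           conc, gx, gy);
  return List::create(_["concentration"] = conc,
                      _["gradient"] = NumericVector::create(gx, gy));
}

// Advance the swarm n_steps and record every record_every steps.
// Returns final state + recorded positions/phases/times.
// [[Rcpp::export]]
List cpp_swarm_run(NumericMatrix pos0, NumericMatrix heading0,
                   IntegerVector phase0, NumericVector clock0,
                   NumericMatrix heading_fire0, NumericVector refr_dur0,
                   List cfg, int n_steps, int record_every, double t0,
                   List pert_list) {
  Cfg c = read_cfg(cfg);
  const int n = pos0.nrow();
  std::vector<double> px(n), py(n), hx(n), hy(n), fx(n), fy(n);
  std::vector<int> phase(n);
  std::vector<double> clock(n), refr(n), amp(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1);
    hx[i] = heading0(i, 0); hy[i] = heading0(i, 1);
    fx[i] = heading_fire0(i, 0); fy[i] = heading_fire0(i, 1);
    phase[i] = phase0[i];
    clock[i] = clock0[i];
    refr[i] = refr_dur0[i];
  }
  Pert pert;
  pert.kind = as<int>(pert_list["kind"]);
  pert.amount = as<double>(pert_list["amount"]);
  pert.px = as<double>(pert_list["x"]);
  pert.py = as<double>(pert_list["y"]);
  int pert_step = as<int>(pert_list["step"]);  // 0-based step index; -1 never

  const double step_len = c.speed * c.dt;
  const double ca = std::cos(c.turn_rad), sa = std::sin(c.turn_rad);

  int n_frames = n_steps / record_every + 1;
  NumericMatrix rec_x(n, n_frames), rec_y(n, n_frames);
  IntegerMatrix rec_ph(n, n_frames);
  NumericVector rec_t(n_frames);
  int fi = 0;
  for (int i = 0; i < n; ++i) {
    rec_x(i, 0) = px[i]; rec_y(i, 0) = py[i]; rec_ph(i, 0) = phase[i];
  }
  rec_t[0] = t0;
  fi = 1;

  std::vector<double> nhx(n), nhy(n);
  std::vector<int> nphase(n);
  std::vector<double> nclock(n), nrefr(n), nfx(n), nfy(n);
  Grid g;
  std::vector<int> neigh_count(n);

  RNGScope scope;

  for (int s = 0; s < n_steps; ++s) {
    // amplitudes and grid from the beginning-of-step state (synchronous update)
    for (int i = 0; i < n; ++i) amp[i] = amplitude_of(phase[i], clock[i], c);
    g.build(px.data(), py.data(), n, c.L, c.cutoff, c.periodic);
    pert.active = (s == pert_step) && pert.kind != 0;

    // packing state at the start of the step: cells in densely packed
    // neighborhoods move at a reduced speed (crowding in the aggregate)
    {
      double ncut = 3.0 * c.excl;
      Grid gp;
      gp.build(px.data(), py.data(), n, c.L, std::max(ncut, c.L / 64.0),
               c.periodic);
      for (int i = 0; i < n; ++i) {
        int cnt = 0;
        gp.for_neighbors(px[i], py[i], [&](int j) {
          if (j == i) return;
          double dx = mindiff(px[i] - gp.x[j], c.L, c.periodic);
          double dy = mindiff(py[i] - gp.y[j], c.L, c.periodic);
          if (dx * dx + dy * dy <= ncut * ncut) ++cnt;
        });
        neigh_count[i] = cnt;
      }
    }

    for (int i = 0; i < n; ++i) {
      double conc, gx, gy;
      nfx[i] = fx[i]; nfy[i] = fy[i];
      nrefr[i] = refr[i];
      if (phase[i] == PH_REFRACTORY) {
        // can neither fire nor repolarize: keeps the motion it had while pulsing
        nhx[i] = fx[i]; nhy[i] = fy[i];
        double cl = clock[i] + c.dt;
        if (cl >= refr[i]) {
          nphase[i] = PH_QUIESCENT;
          nclock[i] = 0.0;
        } else {
          nphase[i] = PH_REFRACTORY;
          nclock[i] = cl;
        }
        continue;
      }
      if (phase[i] == PH_FIRING) {
        // pulsing motion: the heading chosen at fire onset (facing the
        // incoming wave) is maintained through firing and refractory — the
        // model's answer to the back-of-the-wave problem
        nhx[i] = fx[i]; nhy[i] = fy[i];
        double cl = clock[i] + c.dt;
        if (cl >= c.pulse_duration) {
          nphase[i] = PH_REFRACTORY;
          nclock[i] = 0.0;
          nrefr[i] = c.async_pulsing
                         ? (0.5 + R::unif_rand()) * c.refractory_min
                         : c.refractory_min;
        } else {
          nphase[i] = PH_FIRING;
          nclock[i] = cl;
        }
        continue;
      }
      // quiescent cells sense the field and pick a pseudopod
      field_at(g, amp, hx.data(), hy.data(), c, px[i], py[i], i, pert,
               conc, gx, gy);
      if (c.noise_sd > 0) {
        conc *= 1.0 + c.noise_sd * R::norm_rand();
        double gscale = 1.0 + c.noise_sd * R::norm_rand();
        gx *= gscale; gy *= gscale;
      }
      // two-pseudopod movement: rotate previous heading by +/- half-angle
      double h1x = ca * hx[i] - sa * hy[i], h1y = sa * hx[i] + ca * hy[i];
      double h2x = ca * hx[i] + sa * hy[i], h2y = -sa * hx[i] + ca * hy[i];
      double gmag = std::sqrt(gx * gx + gy * gy);
      bool pick_first;
      if (gmag >= c.grad_c2) {
        double c1c, c2c, dgx, dgy;
        field_at(g, amp, hx.data(), hy.data(), c,
                 c.periodic ? wrap(px[i] + step_len * h1x, c.L) : px[i] + step_len * h1x,
                 c.periodic ? wrap(py[i] + step_len * h1y, c.L) : py[i] + step_len * h1y,
                 i, pert, c1c, dgx, dgy);
        field_at(g, amp, hx.data(), hy.data(), c,
                 c.periodic ? wrap(px[i] + step_len * h2x, c.L) : px[i] + step_len * h2x,
                 c.periodic ? wrap(py[i] + step_len * h2y, c.L) : py[i] + step_len * h2y,
                 i, pert, c2c, dgx, dgy);
        if (c.noise_sd > 0) {
          c1c *= 1.0 + c.noise_sd * R::norm_rand();
          c2c *= 1.0 + c.noise_sd * R::norm_rand();
        }
        if (c1c > c2c) pick_first = true;
        else if (c2c > c1c) pick_first = false;
        else pick_first = R::unif_rand() < 0.5;
      } else {
        pick_first = R::unif_rand() < 0.5;
      }
      nhx[i] = pick_first ? h1x : h2x;
      nhy[i] = pick_first ? h1y : h2y;
      bool fire;
      if (c.async_pulsing) {
        fire = R::unif_rand() < -std::expm1(-c.async_rate * c.dt);
      } else {
        fire = conc >= c.c1;
      }
      if (fire) {
        nphase[i] = PH_FIRING;
        nclock[i] = 0.0;
        nfx[i] = nhx[i]; nfy[i] = nhy[i];
      } else {
        nphase[i] = PH_QUIESCENT;
        nclock[i] = clock[i] + c.dt;
      }
    }

    // move
    for (int i = 0; i < n; ++i) {
      double sl = neigh_count[i] > c.packing_threshold
                      ? step_len * c.crowding_slowdown
                      : step_len;
      px[i] += sl * nhx[i];
      py[i] += sl * nhy[i];
      hx[i] = nhx[i]; hy[i] = nhy[i];
      fx[i] = nfx[i]; fy[i] = nfy[i];
      phase[i] = nphase[i];
      clock[i] = nclock[i];
      refr[i] = nrefr[i];
    }

    // adhesion: short-range pairwise attraction (truncated 12-6 force),
    // displacement increment capped at one step length
    if (c.adhesion_on) {
      Grid ga;
      double acut = c.adh_range;
      ga.build(px.data(), py.data(), n, c.L, std::max(acut, c.L / 64.0), c.periodic);
      std::vector<double> ax(n, 0.0), ay(n, 0.0);
      double sig = c.excl;
      for (int i = 0; i < n; ++i) {
        ga.for_neighbors(px[i], py[i], [&](int j) {
          if (j <= i) return;
          double dx = mindiff(px[i] - px[j], c.L, c.periodic);
          double dy = mindiff(py[i] - py[j], c.L, c.periodic);
          double d2 = dx * dx + dy * dy;
          if (d2 > acut * acut || d2 < 1e-12) return;
          double d = std::sqrt(d2);
          double s6 = std::pow(sig / d, 6.0);
          // positive = repulsive, negative = attractive
          double f = 24.0 * c.adh_strength * (2.0 * s6 * s6 - s6) / d;
          double disp = f * c.dt;
          double cap = step_len;
          if (disp > cap) disp = cap;
          if (disp < -cap) disp = -cap;
          double ux = dx / d, uy = dy / d;
          ax[i] += 0.5 * disp * ux; ay[i] += 0.5 * disp * uy;
          ax[j] -= 0.5 * disp * ux; ay[j] -= 0.5 * disp * uy;
        });
      }
      for (int i = 0; i < n; ++i) { px[i] += ax[i]; py[i] += ay[i]; }
    }

    // boundary
    for (int i = 0; i < n; ++i) {
      if (c.periodic) {
        px[i] = wrap(px[i], c.L);
        py[i] = wrap(py[i], c.L);
      } else {
        if (px[i] < 0) { px[i] = -px[i]; hx[i] = -hx[i]; fx[i] = -fx[i]; }
        if (px[i] > c.L) { px[i] = 2 * c.L - px[i]; hx[i] = -hx[i]; fx[i] = -fx[i]; }
        if (py[i] < 0) { py[i] = -py[i]; hy[i] = -hy[i]; fy[i] = -fy[i]; }
        if (py[i] > c.L) { py[i] = 2 * c.L - py[i]; hy[i] = -hy[i]; fy[i] = -fy[i]; }
      }
    }

    // volume exclusion: pairs closer than excl are separated symmetrically,
    // unless either member sits in a densely packed neighborhood (override)
    {
      double ncut = 3.0 * c.excl;
      Grid gv;
      gv.build(px.data(), py.data(), n, c.L, std::max(ncut, c.L / 64.0), c.periodic);
      for (int i = 0; i < n; ++i) {
        int cnt = 0;
        gv.for_neighbors(px[i], py[i], [&](int j) {
          if (j == i) return;
          double dx = mindiff(px[i] - px[j], c.L, c.periodic);
          double dy = mindiff(py[i] - py[j], c.L, c.periodic);
          if (dx * dx + dy * dy <= ncut * ncut) ++cnt;
        });
        neigh_count[i] = cnt;
      }
      for (int sweep = 0; sweep < 2; ++sweep) {
        gv.build(px.data(), py.data(), n, c.L, std::max(ncut, c.L / 64.0), c.periodic);
        for (int i = 0; i < n; ++i) {
          gv.for_neighbors(px[i], py[i], [&](int j) {
            if (j <= i) return;
            if (neigh_count[i] > c.packing_threshold ||
                neigh_count[j] > c.packing_threshold)
              return;
            double dx = mindiff(px[i] - px[j], c.L, c.periodic);
            double dy = mindiff(py[i] - py[j], c.L, c.periodic);
            double d2 = dx * dx + dy * dy;
            if (d2 >= c.excl * c.excl) return;
            double d = std::sqrt(d2);
            double ux, uy;
            if (d < 1e-9) { ux = 1.0; uy = 0.0; d = 0.0; }
            else { ux = dx / d; uy = dy / d; }
            double push = 0.5 * (c.excl - d);
            px[i] += push * ux; py[i] += push * uy;
            px[j] -= push * ux; py[j] -= push * uy;
            if (c.periodic) {
              px[i] = wrap(px[i], c.L); py[i] = wrap(py[i], c.L);
              px[j] = wrap(px[j], c.L); py[j] = wrap(py[j], c.L);
            } else {
              if (px[i] < 0) px[i] = 0; if (px[i] > c.L) px[i] = c.L;
              if (py[i] < 0) py[i] = 0; if (py[i] > c.L) py[i] = c.L;
              if (px[j] < 0) px[j] = 0; if (px[j] > c.L) px[j] = c.L;
              if (py[j] < 0) py[j] = 0; if (py[j] > c.L) py[j] = c.L;
            }
          });
        }
      }
    }

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(px[i]) || !std::isfinite(py[i]))
        stop("non-finite position for cell %d at step %d", i + 1, s + 1);
    }

    if ((s + 1) % record_every == 0) {
      for (int i = 0; i < n; ++i) {
        rec_x(i, fi) = px[i]; rec_y(i, fi) = py[i]; rec_ph(i, fi) = phase[i];
      }
      rec_t[fi] = t0 + (s + 1) * c.dt;
      ++fi;
    }
  }

  NumericMatrix pos_out(n, 2), head_out(n, 2), hf_out(n, 2);
  IntegerVector ph_out(n);
  NumericVector cl_out(n), rf_out(n);
  for (int i = 0; i < n; ++i) {
    pos_out(i, 0) = px[i]; pos_out(i, 1) = py[i];
    head_out(i, 0) = hx[i]; head_out(i, 1) = hy[i];
    hf_out(i, 0) = fx[i]; hf_out(i, 1) = fy[i];
    ph_out[i] = phase[i];
    cl_out[i] = clock[i];
    rf_out[i] = refr[i];
  }
  return List::create(
      _["position"] = pos_out, _["heading"] = head_out,
      _["phase"] = ph_out, _["phase_clock"] = cl_out,
      _["heading_at_fire"] = hf_out, _["refr_duration"] = rf_out,
      _["rec_x"] = rec_x, _["rec_y"] = rec_y, _["rec_phase"] = rec_ph,
      _["rec_t"] = rec_t);
}
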