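#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact stochastic simulation of one cell's CRM.
//
// Markovian channels (monomer/dimer binding and unbinding, Pol II
// recruitment) compete through the Gillespie direct method; the two
// deterministic clocks (monomer deactivation at age tau_res, refractory
// expiry at pol_ready_at) are interleaved by advancing to whichever comes
// first and redrawing the exponential waiting time, which is exact by
// memorylessness.
//
// Occupancy codes: 0 empty, 1 monomer, 2 dimer.
// Event codes in the log: 1 monomer_bind, 2 monomer_unbind, 3 dimer_bind,
// 4 dimer_unbind, 5 pol_recruit, 6 deactivate.

static const double INF = std::numeric_limits<double>::infinity();

struct Params {
  int n;
  std::vector<double> pos, kd_m, kd_d;
  std::vector<int> functional;
  double kon_m, kon_d, k_pol, pol_gap, tau;
  int res_mode;       // 0 time, 1 count
  int res_count;
  bool inherit_bind_time;
  double on_boost;
  int coop_mode;      // 0 none, 1 equal, 2 distance
  double c_mono, c_dim, d_ref;
  bool mono_neigh_any;   // monomer stabilised by any occupied neighbour
  bool dimer_neigh_dimer; // dimer stabilised only by dimer neighbours
};

static double weight(const Params &p, int i, int j) {
  if (p.coop_mode == 1) return 1.0;
  double d = std::fabs(p.pos[i] - p.pos[j]);
  double w = p.d_ref / d;
  return w > 1.0 ? 1.0 : w;
}

static double eff_off_rate(const Params &p, const std::vector<int> &occ, int i) {
  double base = (occ[i] == 1) ? p.kd_m[i] * p.kon_m : p.kd_d[i] * p.kon_d;
  if (p.coop_mode == 0) return base;
  double c = (occ[i] == 1) ? p.c_mono : p.c_dim;
  double fac = 1.0;
  for (int j = 0; j < p.n; ++j) {
    if (j == i || occ[j] == 0) continue;
    bool qual = (occ[i] == 1)
      ? (p.mono_neigh_any ? occ[j] > 0 : occ[j] == 1)
      : (p.dimer_neigh_dimer ? occ[j] == 2 : occ[j] > 0);
    if (qual) fac *= std::pow(c, weight(p, i, j));
  }
  return base * fac;
}

static double on_factor(const Params &p, const std::vector<int> &occ, int i) {
  if (p.on_boost == 1.0 || p.coop_mode == 0) return 1.0;
  double wsum = 0.0;
  for (int j = 0; j < p.n; ++j)
    if (j != i && occ[j] > 0) wsum += weight(p, i, j);
  return std::pow(p.on_boost, wsum);
}

// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(NumericVector position, NumericVector kd_monomer,
                 NumericVector kd_dimer, IntegerVector functional,
                 List kinetics, List coop, double d_ref,
                 double dose, double t_end, double burnin_frac,
                 bool record_events, int max_events) {
  Params p;
  p.n = position.size();
  p.pos.assign(position.begin(), position.end());
  p.kd_m.assign(kd_monomer.begin(), kd_monomer.end());
  p.kd_d.assign(kd_dimer.begin(), kd_dimer.end());
  p.functional.assign(functional.begin(), functional.end());
  p.kon_m = as<double>(kinetics["kon_monomer"]);
  p.kon_d = as<double>(kinetics["kon_dimer"]);
  p.k_pol = as<double>(kinetics["k_pol"]);
  p.pol_gap = as<double>(kinetics["pol_gap"]);
  p.tau = as<double>(kinetics["residence_limit"]);
  std::string rm = as<std::string>(kinetics["residence_mode"]);
  p.res_mode = (rm == "count") ? 1 : 0;
  p.res_count = as<int>(kinetics["residence_count"]);
  std::string dbt = as<std::string>(kinetics["dimer_bind_time"]);
  p.inherit_bind_time = (dbt == "inherit");
  p.on_boost = as<double>(kinetics["on_rate_boost"]);
  std::string cm = as<std::string>(coop["mode"]);
  p.coop_mode = (cm == "none") ? 0 : (cm == "equal" ? 1 : 2);
  p.c_mono = as<double>(coop["c_monomer"]);
  p.c_dim = as<double>(coop["c_dimer"]);
  p.d_ref = d_ref;
  p.mono_neigh_any = as<std::string>(coop["monomer_neighbours"]) == "any";
  p.dimer_neigh_dimer = as<std::string>(coop["dimer_neighbours"]) == "dimer";

  const int n = p.n;
  std::vector<int> occ(n, 0), active(n, 0), pol_count(n, 0);
  std::vector<double> bind_time(n, NA_REAL);
  double t = 0.0, pol_ready_at = 0.0;
  long mrna = 0, mrna_burn = 0;
  const double burn_start = burnin_frac * t_end;

  std::vector<double> time_empty(n, 0.0), time_mono(n, 0.0),
      time_dimer(n, 0.0), time_active(n, 0.0);
  std::vector<double> init_times;
  std::vector<double> ev_time;
  std::vector<int> ev_code, ev_elem;

  // propensities: per element up to 2 channels + pol channel
  std::vector<double> a(2 * n + 1);

  auto n_active_monomers = [&]() {
    int k = 0;
    for (int i = 0; i < n; ++i)
      if (occ[i] == 1 && active[i]) ++k;
    return k;
  };

  auto accumulate = [&](double from, double to) {
    double lo = std::max(from, burn_start), hi = to;
    if (hi <= lo) return;
    double dt = hi - lo;
    for (int i = 0; i < n; ++i) {
      if (occ[i] == 0) time_empty[i] += dt;
      else if (occ[i] == 1) {
        time_mono[i] += dt;
        if (active[i]) time_active[i] += dt;
      } else time_dimer[i] += dt;
    }
  };

  auto log_event = [&](double tt, int code, int elem) {
    if (!record_events) return;
    if ((int)ev_time.size() >= max_events) return;
    ev_time.push_back(tt);
    ev_code.push_back(code);
    ev_elem.push_back(elem + 1); // 1-based, 0 -> NA handled in R
  };

  while (t < t_end) {
    // --- propensities
    double a0 = 0.0;
    for (int i = 0; i < n; ++i) {
      double a_on = 0.0, a_off = 0.0;
      if (p.functional[i]) {
        if (occ[i] == 0) {
          a_on = p.kon_m * dose * on_factor(p, occ, i);
        } else if (occ[i] == 1) {
          a_off = eff_off_rate(p, occ, i);
          a_on = p.kon_d * dose; // dimer formation
        } else {
          a_off = eff_off_rate(p, occ, i);
        }
      }
      a[2 * i] = a_on;
      a[2 * i + 1] = a_off;
      a0 += a_on + a_off;
    }
    int n_act = n_active_monomers();
    double a_pol = (p.k_pol > 0 && n_act > 0 && t >= pol_ready_at)
                       ? p.k_pol * n_act : 0.0;
    a[2 * n] = a_pol;
    a0 += a_pol;

    // --- next deterministic event
    double t_det = INF;
    int det_kind = 0; // 1 deactivation, 2 refractory expiry
    if (p.res_mode == 0 && std::isfinite(p.tau)) {
      for (int i = 0; i < n; ++i) {
        if (occ[i] == 1 && active[i]) {
          double td = bind_time[i] + p.tau;
          if (td < t_det) { t_det = td; det_kind = 1; }
        }
      }
    }
    if (p.k_pol > 0 && pol_ready_at > t && n_act > 0 && pol_ready_at < t_det) {
      t_det = pol_ready_at;
      det_kind = 2;
    }

    double t_next = (a0 > 0) ? t + R::exp_rand() / a0 : INF;

    if (t_det <= t_next) {
      if (t_det >= t_end || det_kind == 0) { // nothing before t_end
        accumulate(t, t_end);
        t = t_end;
        break;
      }
      accumulate(t, t_det);
      t = t_det;
      if (det_kind == 1) {
        for (int i = 0; i < n; ++i) {
          if (occ[i] == 1 && active[i] && bind_time[i] + p.tau <= t) {
            active[i] = 0;
            log_event(t, 6, i);
          }
        }
      }
      // det_kind == 2: propensity table changes; just redraw
      continue;
    }

    if (t_next >= t_end) {
      accumulate(t, t_end);
      t = t_end;
      break;
    }

    accumulate(t, t_next);
    t = t_next;

    // --- pick event
    double u = R::unif_rand() * a0, cum = 0.0;
    int chosen = -1;
    for (int k = 0; k < 2 * n + 1; ++k) {
      cum += a[k];
      if (u <= cum) { chosen = k; break; }
    }
    if (chosen < 0) chosen = 2 * n; // numerical guard

    if (chosen == 2 * n) {
      // Pol II recruitment
      mrna += 1;
      if (t >= burn_start) mrna_burn += 1;
      init_times.push_back(t);
      pol_ready_at = t + p.pol_gap;
      log_event(t, 5, -1);
      if (p.res_mode == 1) {
        // attribute to one active monomer uniformly
        int n_act2 = n_active_monomers();
        int pick = (int)std::floor(R::unif_rand() * n_act2);
        if (pick >= n_act2) pick = n_act2 - 1;
        int seen = 0;
        for (int i = 0; i < n; ++i) {
          if (occ[i] == 1 && active[i]) {
            if (seen == pick) {
              pol_count[i] += 1;
              if (pol_count[i] >= p.res_count) {
                active[i] = 0;
                log_event(t, 6, i);
              }
              break;
            }
            ++seen;
          }
        }
      }
    } else {
      int i = chosen / 2;
      bool is_on = (chosen % 2) == 0;
      if (is_on) {
        if (occ[i] == 0) {
          occ[i] = 1;
          bind_time[i] = t;
          active[i] = 1;
          pol_count[i] = 0;
          log_event(t, 1, i);
        } else {
          occ[i] = 2; // dimer formation; age clock keeps running
          log_event(t, 3, i);
        }
      } else {
        if (occ[i] == 1) {
          occ[i] = 0;
          active[i] = 0;
          bind_time[i] = NA_REAL;
          log_event(t, 2, i);
        } else {
          occ[i] = 1; // dimer -> monomer
          if (!p.inherit_bind_time) {
            bind_time[i] = t;
            pol_count[i] = 0;
            active[i] = 1;
          } else {
            active[i] = (p.res_mode == 0)
              ? (!std::isfinite(p.tau) || (t - bind_time[i]) < p.tau)
              : (pol_count[i] < p.res_count);
          }
          log_event(t, 4, i);
        }
      }
    }
  }

  return List::create(
      _["occupancy"] = IntegerVector(occ.begin(), occ.end()),
      _["bind_time"] = NumericVector(bind_time.begin(), bind_time.end()),
      _["active"] = LogicalVector(active.begin(), active.end()),
      _["pol_ready_at"] = pol_ready_at,
      _["t"] = t,
      _["mrna"] = (double)mrna,
      _["mrna_post_burnin"] = (double)mrna_burn,
      _["time_empty"] = NumericVector(time_empty.begin(), time_empty.end()),
      _["time_monomer"] = NumericVector(time_mono.begin(), time_mono.end()),
      _["time_dimer"] = NumericVector(time_dimer.begin(), time_dimer.end()),
      _["time_active"] = NumericVector(time_active.begin(), time_active.end()),
      _["window"] = t_end - burnin_frac * t_end,
      _["initiation_times"] = NumericVector(init_times.begin(), init_times.end()),
      _["event_time"] = NumericVector(ev_time.begin(), ev_time.end()),
      _["event_code"] = IntegerVector(ev_code.begin(), ev_code.end()),
      _["event_element"] = IntegerVector(ev_elem.begin(), ev_elem.end()));
}
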