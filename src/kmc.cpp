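#include <Rcpp.h>
using namespace Rcpp;

// Two-state kinetic Monte Carlo of constant-velocity stretch/release cycles.
//
// The ramp variable is the force the B branch reads at the current trap
// position; it moves at the loading rate r = K_eff * v. Fraying is
// deterministic in force (it re-equilibrates instantly), so each state's
// force is a fixed function of trap position: the B branch is the ramp line
// itself, and the S branch satisfies F = F_line - K_eff * dX(F) with
// dX(F) = dX_tr - fray * (F - F_tr), i.e.
//   F_S = (F_line - K_eff * (dX_tr + fray * F_tr)) / (1 - K_eff * fray).
// A switch moves the force from one branch to the other at fixed trap
// position; the transition extension logged for the event is the frayed
// extension dX at the pre-jump force. Switching is evaluated every substep
// dt with probability 1 - exp(-k dt), k the Bell-Evans rate of the
// occupied state at the current force.
//
// Returns sampled (time, trap_position, force, state, direction) at the
// recording rate plus the microscopic event log (every switch).
// [[Rcpp::export(name = ".sim_cycles_cpp")]]
List sim_cycles_cpp(int n_cycles,
                    double F_min, double F_max,
                    double rate_load, double K_eff,
                    double branch_d0,
                    double F_tr, double dX_tr, double fray_slope,
                    double X_b_ts, double X_s_ts,
                    double k_tr, double kbt,
                    double dt, int sample_every,
                    bool record_truth) {
  const double half_T = (F_max - F_min) / rate_load;
  const long steps_half = (long)std::llround(half_T / dt);
  const long steps_cycle = 2 * steps_half;
  const long n_sub = (long)n_cycles * steps_cycle;
  const long n_samp = n_sub / sample_every + 1;

  std::vector<double> s_time, s_trap, s_force;
  std::vector<int> s_state, s_cycle, s_dir;
  s_time.reserve(n_samp); s_trap.reserve(n_samp); s_force.reserve(n_samp);
  s_state.reserve(n_samp); s_cycle.reserve(n_samp); s_dir.reserve(n_samp);

  std::vector<double> e_time, e_force, e_force_after, e_dx;
  std::vector<int> e_cycle, e_dir;

  const double aB = X_b_ts / kbt;   // forward Bell-Evans slope
  const double aS = X_s_ts / kbt;   // reverse Bell-Evans slope
  const double s_denom = 1.0 - K_eff * fray_slope;
  const double s_shift = K_eff * (dX_tr + fray_slope * F_tr);

  double t = 0.0;
  long sub_since_sample = 0;

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    int state = 0;                 // B
    double F_line = F_min;         // B-branch ramp force
    for (int half = 0; half < 2; ++half) {
      const int dir = (half == 0) ? 1 : -1;
      for (long i = 0; i < steps_half; ++i) {
        double F = (state == 0) ? F_line : (F_line - s_shift) / s_denom;
        if (state == 1 && F > F_line) F = F_line;  // dX floored at 0
        // sample before evolving so the first sample sits at the ramp start
        if (sub_since_sample == 0) {
          s_time.push_back(t);
          s_trap.push_back(branch_d0 + F_line / K_eff);
          s_force.push_back(F);
          s_state.push_back(state);
          s_cycle.push_back(cyc + 1);
          s_dir.push_back(dir);
        }
        if (++sub_since_sample == sample_every) sub_since_sample = 0;

        const double k = (state == 0)
          ? k_tr * std::exp(aB * (F - F_tr))
          : k_tr * std::exp(-aS * (F - F_tr));
        if (R::unif_rand() < -std::expm1(-k * dt)) {
          double dX = dX_tr - fray_slope * (F - F_tr);
          if (dX < 0.0) dX = 0.0;
          e_cycle.push_back(cyc + 1);
          e_time.push_back(t);
          e_dir.push_back(state == 0 ? 1 : -1);   // +1 B->S, -1 S->B
          e_force.push_back(F);
          e_dx.push_back(dX);
          state = 1 - state;
          double F2 = (state == 0) ? F_line : (F_line - s_shift) / s_denom;
          if (state == 1 && F2 > F_line) F2 = F_line;
          e_force_after.push_back(F2);
        }
        F_line += dir * rate_load * dt;
        t += dt;
      }
    }
  }

  List samples = List::create(
    _["time"] = wrap(s_time), _["trap_position"] = wrap(s_trap),
    _["force"] = wrap(s_force), _["cycle"] = wrap(s_cycle),
    _["direction"] = wrap(s_dir),
    _["state"] = record_truth ? wrap(s_state) : R_NilValue);
  List events = List::create(
    _["cycle"] = wrap(e_cycle), _["time"] = wrap(e_time),
    _["direction"] = wrap(e_dir), _["force"] = wrap(e_force),
    _["force_after"] = wrap(e_force_after), _["delta_x"] = wrap(e_dx));
  return List::create(_["samples"] = samples, _["events"] = events);
}

// Force-clamp variant: fixed force, used to check detailed balance of the
// generator against the two-state occupancy.
// [[Rcpp::export(name = ".sim_clamp_cpp")]]
List sim_clamp_cpp(double F, double duration,
                   double F_tr, double X_b_ts, double X_s_ts,
                   double k_tr, double kbt, double dt, int sample_every) {
  const long n_sub = (long)std::llround(duration / dt);
  std::vector<double> s_time; std::vector<int> s_state;
  s_time.reserve(n_sub / sample_every + 1);
  s_state.reserve(n_sub / sample_every + 1);
  const double kf = k_tr * std::exp(X_b_ts * (F - F_tr) / kbt);
  const double kr = k_tr * std::exp(-X_s_ts * (F - F_tr) / kbt);
  int state = 0;
  long sub_since_sample = 0;
  long n_switch = 0;
  double time_S = 0.0;
  for (long i = 0; i < n_sub; ++i) {
    if (sub_since_sample == 0) {
      s_time.push_back(i * dt);
      s_state.push_back(state);
    }
    if (++sub_since_sample == sample_every) sub_since_sample = 0;
    if (state == 1) time_S += dt;
    const double k = (state == 0) ? kf : kr;
    if (R::unif_rand() < -std::expm1(-k * dt)) {
      state = 1 - state;
      ++n_switch;
    }
  }
  return List::create(_["time"] = wrap(s_time), _["state"] = wrap(s_state),
                      _["fraction_S"] = time_S / duration,
                      _["n_switch"] = (double)n_switch);
}
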