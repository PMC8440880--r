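#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integrator for the multipopulation neural mass model
//
//   tau * dr_k/dt = Delta / (tau * pi) + 2 r_k v_k
//   tau * dv_k/dt = v_k^2 + eta_k + I_B + I_S^(k)(t)
//                   - (pi tau r_k)^2 + tau * sum_l J_kl r_l
//
// The stimulus is a rectangular pulse of amplitude `stim_amp` applied to
// `stim_targets` (0-based) for stim_on <= t < stim_off, evaluated at the
// RK4 substep times. State is recorded every `record_every` steps.

static inline double stim_at(double t, double stim_on, double stim_off,
                             double stim_amp) {
  return (t >= stim_on && t < stim_off) ? stim_amp : 0.0;
}

static void nm_rhs(int n, const double* r, const double* v,
                   const double* eta, double delta, double tau, double ib,
                   const double* J, const int* is_target, double istim,
                   double* dr, double* dv) {
  const double pi = M_PI;
  const double a = delta / (tau * pi);
  for (int k = 0; k < n; ++k) {
    double coup = 0.0;
    const double* Jrow = J + (size_t)k;          // column-major: J[k + n*l]
    for (int l = 0; l < n; ++l) coup += Jrow[(size_t)n * l] * r[l];
    double pir = pi * tau * r[k];
    double I = ib + (is_target[k] ? istim : 0.0);
    dr[k] = (a + 2.0 * r[k] * v[k]) / tau;
    dv[k] = (v[k] * v[k] + eta[k] + I - pir * pir + tau * coup) / tau;
  }
}

// [[Rcpp::export(name = ".rk4_network")]]
List rk4_network(NumericVector r0, NumericVector v0, NumericVector eta,
                 double delta, double tau, double IB, NumericMatrix J,
                 IntegerVector stim_targets, double stim_amp,
                 double stim_on, double stim_off,
                 double t0, double t_end, double dt, int record_every) {
  int n = r0.size();
  if (v0.size() != n || eta.size() != n || J.nrow() != n || J.ncol() != n)
    stop("dimension mismatch between state, parameters and coupling matrix");
  if (dt <= 0) stop("dt must be positive");
  long nsteps = (long)std::llround((t_end - t0) / dt);
  if (nsteps < 1) stop("time span must cover at least one step");
  if (record_every < 1) record_every = 1;

  std::vector<int> tgt(n, 0);
  for (int i = 0; i < stim_targets.size(); ++i) {
    int k = stim_targets[i];
    if (k < 0 || k >= n) stop("stimulus target out of range");
    tgt[k] = 1;
  }

  long nrec = nsteps / record_every + 1 + ((nsteps % record_every) ? 1 : 0);
  NumericMatrix rec_r(nrec, n), rec_v(nrec, n);
  NumericVector rec_t(nrec), rec_I(nrec);

  std::vector<double> r(r0.begin(), r0.end()), v(v0.begin(), v0.end());
  std::vector<double> k1r(n), k1v(n), k2r(n), k2v(n), k3r(n), k3v(n),
      k4r(n), k4v(n), tr(n), tv(n);
  const double* Jp = J.begin();

  long irec = 0;
  rec_t[0] = t0;
  rec_I[0] = stim_at(t0, stim_on, stim_off, stim_amp);
  for (int k = 0; k < n; ++k) { rec_r(0, k) = r[k]; rec_v(0, k) = v[k]; }
  irec = 1;

  for (long s = 0; s < nsteps; ++s) {
    double t = t0 + s * dt;
    double i0 = stim_at(t, stim_on, stim_off, stim_amp);
    double ih = stim_at(t + 0.5 * dt, stim_on, stim_off, stim_amp);
    double i1 = stim_at(t + dt, stim_on, stim_off, stim_amp);

    nm_rhs(n, r.data(), v.data(), eta.begin(), delta, tau, IB, Jp,
           tgt.data(), i0, k1r.data(), k1v.data());
    for (int k = 0; k < n; ++k) {
      tr[k] = r[k] + 0.5 * dt * k1r[k];
      tv[k] = v[k] + 0.5 * dt * k1v[k];
    }
    nm_rhs(n, tr.data(), tv.data(), eta.begin(), delta, tau, IB, Jp,
           tgt.data(), ih, k2r.data(), k2v.data());
    for (int k = 0; k < n; ++k) {
      tr[k] = r[k] + 0.5 * dt * k2r[k];
      tv[k] = v[k] + 0.5 * dt * k2v[k];
    }
    nm_rhs(n, tr.data(), tv.data(), eta.begin(), delta, tau, IB, Jp,
           tgt.data(), ih, k3r.data(), k3v.data());
    for (int k = 0; k < n; ++k) {
      tr[k] = r[k] + dt * k3r[k];
      tv[k] = v[k] + dt * k3v[k];
    }
    nm_rhs(n, tr.data(), tv.data(), eta.begin(), delta, tau, IB, Jp,
           tgt.data(), i1, k4r.data(), k4v.data());

    bool bad = false;
    for (int k = 0; k < n; ++k) {
      r[k] += dt / 6.0 * (k1r[k] + 2.0 * k2r[k] + 2.0 * k3r[k] + k4r[k]);
      v[k] += dt / 6.0 * (k1v[k] + 2.0 * k2v[k] + 2.0 * k3v[k] + k4v[k]);
      if (!std::isfinite(r[k]) || !std::isfinite(v[k])) bad = true;
    }
    if (bad)
      stop("integration diverged (non-finite state) at t = %f ms", t + dt);

    if ((s + 1) % record_every == 0 || s == nsteps - 1) {
      double tnow = t0 + (s + 1) * dt;
      rec_t[irec] = tnow;
      rec_I[irec] = stim_at(tnow, stim_on, stim_off, stim_amp);
      for (int k = 0; k < n; ++k) { rec_r(irec, k) = r[k]; rec_v(irec, k) = v[k]; }
      ++irec;
    }
  }

  if (irec < nrec) {
    rec_t = rec_t[Range(0, irec - 1)];
    rec_I = rec_I[Range(0, irec - 1)];
    rec_r = rec_r(Range(0, irec - 1), _);
    rec_v = rec_v(Range(0, irec - 1), _);
  }
  return List::create(_["times"] = rec_t, _["r"] = rec_r, _["v"] = rec_v,
                      _["stimulus"] = rec_I);
}

// Simulation of N all-to-all coupled QIF neurons (no autapses):
//
//   tau * dV_i/dt = V_i^2 + eta_i + I_B + I_S(t) + tau * (J/N) sum_j S_j(t)
//
// A neuron spikes when V_i >= V_peak and is reset to -V_peak. Delta-pulse
// synapses integrate to an instantaneous increment J/N of every other
// neuron's voltage per presynaptic spike; kicks are accumulated over a step
// and delivered at its end. Between kicks the drift a = eta_i + I is
// constant, so the flow is advanced with the exact solution of
// dV/ds = V^2 + a (s = t/tau): a phase rotation V = sqrt(a) tan(theta) for
// a > 0, the corresponding tanh map for a < 0, and the hyperbola 1/V for
// a = 0. Spikes are exact threshold crossings of the phase, so there is no
// Euler overshoot at the (numerically stiff) high-|V| excursions.
// The ideal QIF neuron spends a time 2 tau / V_peak per spike travelling
// from V_peak to +infinity and from -infinity to -V_peak; truncating at a
// finite threshold would shorten every period by that amount and bias the
// rate upward. After each threshold crossing the neuron is therefore held
// refractory for 2 tau / V_peak, with its voltage represented as +V_peak
// for the first half and -V_peak for the second (so the tail dwell enters
// the mean-voltage estimate antisymmetrically), before resuming from
// -V_peak. Population rate and mean voltage are accumulated in bins of
// `record_bin` ms; the mean voltage averages all neurons over all steps in
// the bin, or excludes held (refractory) neurons when mask_refractory is
// set.

static inline double qif_advance(double v, double a, double s,
                                 double vpeak, bool* spiked) {
  // advance dV/ds = V^2 + a by s; on crossing +vpeak the return value is
  // the re-entry voltage at -vpeak advanced by the residual phase, so the
  // sampling grid stays symmetric around both poles
  *spiked = false;
  const double tiny = 1e-12;
  if (a > tiny) {
    double b = std::sqrt(a);
    double thp = std::atan(vpeak / b);
    double th = std::atan(v / b) + b * s;
    if (th >= thp) {  // crossed the threshold phase within this step
      *spiked = true;
      th = -thp + (th - thp);
    }
    return b * std::tan(th);
  } else if (a < -tiny) {
    double b = std::sqrt(-a);
    double tb = std::tanh(b * s);
    double den = b - v * tb;
    if (den <= 0) { *spiked = true; return -vpeak; }
    double vn = b * (v - b * tb) / den;
    if (vn >= vpeak) { *spiked = true; return -vpeak; }
    return vn;
  } else {
    double den = 1.0 - v * s;
    if (den <= 0) { *spiked = true; return -vpeak; }
    double vn = v / den;
    if (vn >= vpeak) { *spiked = true; return -vpeak; }
    return vn;
  }
}

// [[Rcpp::export(name = ".qif_simulate")]]
List qif_simulate_cpp(NumericVector V0, NumericVector eta, double tau,
                      double J, double IB, double stim_amp, double stim_on,
                      double stim_off, double Vpeak, double dt,
                      double duration, double record_bin, bool keep_spikes,
                      bool mask_refractory) {
  int n = V0.size();
  if (eta.size() != n) stop("eta_samples length must equal N");
  if (Vpeak <= 0 || dt <= 0) stop("V_peak and dt must be positive");
  // one spike per neuron per step at most: phase advance must stay < pi
  double bmax = 0.0;
  for (int i = 0; i < n; ++i)
    bmax = std::max(bmax, std::sqrt(std::fabs(eta[i]) + std::fabs(IB) +
                                    std::fabs(stim_amp)));
  if (bmax * dt / tau >= M_PI)
    stop("dt too large for the given excitabilities (phase step >= pi)");
  long nsteps = (long)std::llround(duration / dt);
  int steps_per_bin = std::max(1, (int)std::llround(record_bin / dt));
  long nbins = (nsteps + steps_per_bin - 1) / steps_per_bin;
  // flight-time compensation: 2 tau / V_peak split evenly around the spike
  int half_hold = (int)std::llround(tau / (Vpeak * dt));

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> Vre(n, 0.0);  // re-entry voltage stashed during hold
  std::vector<int> hold(n, 0);
  NumericVector bin_spikes(nbins), bin_vsum(nbins), bin_vcnt(nbins);
  std::vector<double> sp_t;
  std::vector<int> sp_i;

  const double kick = J / (double)n;
  const double sstep = dt / tau;
  for (long s = 0; s < nsteps; ++s) {
    double t = s * dt;
    double I = IB + stim_at(t, stim_on, stim_off, stim_amp);
    long bin = s / steps_per_bin;
    int nspk = 0;
    double vsum = 0.0;
    long vcnt = 0;
    std::vector<int> spiked;
    for (int i = 0; i < n; ++i) {
      if (hold[i] > 0) {
        // travelling the truncated tails: +V_peak then -V_peak
        if (!mask_refractory) {
          vsum += (hold[i] > half_hold) ? Vpeak : -Vpeak;
          ++vcnt;
        }
        if (--hold[i] == 0) V[i] = Vre[i];
        continue;
      }
      bool spk;
      double aa = eta[i] + I;
      double v0 = V[i];
      double vi = qif_advance(v0, aa, sstep, Vpeak, &spk);
      if (!std::isfinite(vi))
        stop("QIF integration overflow at t = %f ms (dt too large?)", t);
      // exact time-average of V over the step: the antiderivative of V
      // along the flow dV/ds = V^2 + a is (1/2) ln|V^2 + a|, and the
      // expression telescopes through the wrap at +-V_peak, so flight
      // sampling contributes no aliasing bias to the voltage estimate
      double num = vi * vi + aa, den = v0 * v0 + aa;
      double vbar;
      if (!spk && std::fabs(vi - v0) < 1e-9 * (1.0 + std::fabs(v0))) {
        vbar = 0.5 * (v0 + vi);  // flow numerically stalled (near rest)
      } else if (num != 0.0 && den != 0.0 && (num / den) > 0.0) {
        vbar = 0.5 * std::log(num / den) / sstep;
        if (!std::isfinite(vbar)) vbar = 0.5 * (v0 + vi);
      } else {
        vbar = 0.5 * (v0 + vi);
      }
      if (spk) {
        ++nspk;
        if (keep_spikes) { sp_t.push_back(t + dt); sp_i.push_back(i + 1); }
        if (kick != 0.0) spiked.push_back(i);
        if (half_hold > 0) {
          // hold for the tail transit (balanced +-V_peak dwell); resume
          // from the residual-phase re-entry value afterwards
          Vre[i] = vi;
          hold[i] = 2 * half_hold;
        }
      }
      if (hold[i] == 0) V[i] = vi;
      vsum += vbar;
      ++vcnt;
    }
    if (kick != 0.0 && nspk > 0) {
      double inc = kick * nspk;
      for (int i = 0; i < n; ++i)
        if (hold[i] == 0) V[i] += inc;
      // remove autaptic contribution from the spiking neurons themselves
      for (size_t q = 0; q < spiked.size(); ++q)
        if (hold[spiked[q]] == 0) V[spiked[q]] -= kick;
    }
    bin_spikes[bin] += nspk;
    bin_vsum[bin] += vsum;
    bin_vcnt[bin] += vcnt;
  }

  NumericVector rate(nbins), vmean(nbins), times(nbins);
  for (long b = 0; b < nbins; ++b) {
    double width = std::min((double)steps_per_bin,
                            (double)(nsteps - b * steps_per_bin)) * dt;
    times[b] = b * steps_per_bin * dt + 0.5 * width;
    rate[b] = bin_spikes[b] / ((double)n * width);
    vmean[b] = bin_vcnt[b] > 0 ? bin_vsum[b] / bin_vcnt[b] : NA_REAL;
  }

  List out = List::create(_["times"] = times, _["rate"] = rate,
                          _["v_mean"] = vmean, _["V_final"] = wrap(V));
  if (keep_spikes)
    out["spikes"] = DataFrame::create(_["time"] = wrap(sp_t),
                                      _["neuron"] = wrap(sp_i));
  return out;
}
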