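// Time-stepped simulator for spiking winner-take-all circuits with
// stochastic STDP synaptic sampling and structural plasticity.
//
// Neuron model: u_k = sum_i w_eff[k,i] x_i(t) + beta_k(t); instantaneous
// rate rho_k = rho_net * exp(u_k) / sum_l exp(u_l) (divisive inhibition,
// computed overflow-safe per circuit); spikes drawn per step with
// probability rho_k * dt. EPSP and adaptation kernels are differences of
// exponentials kept as two exactly-decayed state variables per trace.
//
// Plasticity (per synapse parameter theta, w = exp(theta - theta0),
// w_eff = max(0, w - exp(-theta0))):
//   - at each postsynaptic spike the likelihood jump
//       b * N * w * (x_pre - alpha * exp(w)),
//     clipped at +/- max_jump, is applied to all incoming synapses;
//   - the prior drift b/sigma^2 (mu - theta) and the diffusion
//     sqrt(2 b T) dW are integrated once per input frame (Euler-Maruyama
//     with the frame length as step; b * frame << 1).
// Parameters are clamped below at clip_low. Lateral synapses transmit and
// accumulate their plasticity trace with a fixed delay.
//
// All randomness is drawn from R's RNG so chunked runs are reproducible
// from set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double wmap(double th, double theta0) {
  return std::exp(th - theta0);
}

// [[Rcpp::export]]
List wta_sim_chunk(List state, List params, NumericMatrix rates,
                   IntegerVector frame_steps, bool plasticity,
                   bool likelihood, bool record_spikes, bool record_rates,
                   Nullable<IntegerMatrix> events_) {
  NumericMatrix th_ff = clone(as<NumericMatrix>(state["theta_ff"]));
  IntegerMatrix mask_ff = state["mask_ff"];
  IntegerVector alive = state["alive"];
  IntegerVector circ = state["circuit"];
  const int H = th_ff.nrow(), nIn = th_ff.ncol(), F = frame_steps.size();

  const bool has_lat = !Rf_isNull(state["theta_lat"]);
  NumericMatrix th_lat;
  IntegerMatrix ban_lat;
  if (has_lat) {
    th_lat = clone(as<NumericMatrix>(state["theta_lat"]));
    ban_lat = as<IntegerMatrix>(state["ban_lat"]);
  }

  NumericVector in_r = clone(as<NumericVector>(state["in_rise"]));
  NumericVector in_f = clone(as<NumericVector>(state["in_fall"]));
  NumericVector lat_r = clone(as<NumericVector>(state["lat_rise"]));
  NumericVector lat_f = clone(as<NumericVector>(state["lat_fall"]));
  NumericVector be_r = clone(as<NumericVector>(state["beta_rise"]));
  NumericVector be_f = clone(as<NumericVector>(state["beta_fall"]));
  NumericMatrix dbuf = clone(as<NumericMatrix>(state["delay_buf"]));
  int rpos = as<int>(state["ring_pos"]);
  const int ring_len = dbuf.ncol();

  const double dt = as<double>(params["dt"]);
  const double rho_net = as<double>(params["rho_net"]);
  const double tau_r = as<double>(params["tau_r"]);
  const double tau_f = as<double>(params["tau_f"]);
  const double atau_r = as<double>(params["adapt_tau_r"]);
  const double atau_f = as<double>(params["adapt_tau_f"]);
  const double gam = as<double>(params["gamma"]);
  const double b = as<double>(params["b"]);
  const double Nmult = as<double>(params["N"]);
  const double alpha = as<double>(params["alpha"]);
  const double theta0 = as<double>(params["theta0"]);
  const double mu = as<double>(params["prior_mean"]);
  const double sig2 = std::pow(as<double>(params["prior_sd"]), 2);
  const double Temp = as<double>(params["temperature"]);
  const double clip_low = as<double>(params["clip_low"]);
  const double max_jump = as<double>(params["max_jump"]);
  const int delay = as<int>(params["delay_steps"]);

  const double dr = std::exp(-dt / tau_r), df = std::exp(-dt / tau_f);
  const double adr = std::exp(-dt / atau_r), adf = std::exp(-dt / atau_f);
  const double w0 = std::exp(-theta0);
  // adaptation kernel normalized to unit integral: gamma is the membrane
  // offset per Hz of the neuron's smoothed output rate
  const double gam_eff = gam / (atau_f - atau_r);

  // cached efficacies; non-existent synapses keep w_eff = 0 throughout
  NumericMatrix w_ff(H, nIn), weff_ff(H, nIn);
  for (int i = 0; i < nIn; ++i)
    for (int k = 0; k < H; ++k)
      if (alive[k] && mask_ff(k, i)) {
        double w = wmap(th_ff(k, i), theta0);
        w_ff(k, i) = w;
        weff_ff(k, i) = std::max(0.0, w - w0);
      }
  NumericMatrix w_lat, weff_lat;
  if (has_lat) {
    w_lat = NumericMatrix(H, H);
    weff_lat = NumericMatrix(H, H);
    for (int j = 0; j < H; ++j)
      for (int k = 0; k < H; ++k)
        if (alive[k] && alive[j] && k != j && !ban_lat(k, j)) {
          double w = wmap(th_lat(k, j), theta0);
          w_lat(k, j) = w;
          weff_lat(k, j) = std::max(0.0, w - w0);
        }
  }

  // circuits (alive members only)
  int nCirc = 0;
  for (int k = 0; k < H; ++k) nCirc = std::max(nCirc, circ[k]);
  std::vector<std::vector<int>> members(nCirc);
  for (int k = 0; k < H; ++k)
    if (alive[k]) members[circ[k] - 1].push_back(k);

  int total_steps = 0;
  for (int f = 0; f < F; ++f) total_steps += frame_steps[f];

  IntegerMatrix counts(H, F);
  std::vector<int> sp_step, sp_neuron;
  NumericMatrix rho_hist;
  if (record_rates) rho_hist = NumericMatrix(H, total_steps);
  bool thinning_warn = false;

  // external events (0-based global step within chunk, 0-based input id),
  // sorted by step; when absent, inputs are drawn per frame from `rates`
  bool use_events = events_.isNotNull();
  IntegerMatrix events;
  int ep = 0, nev = 0;
  if (use_events) {
    events = events_.get();
    nev = events.nrow();
  }

  std::vector<double> x(nIn), xl(H), u(H);
  std::vector<int> ev_s, ev_i, bucket_off;

  int gstep = 0;
  for (int f = 0; f < F; ++f) {
    const int steps = frame_steps[f];
    if (!use_events) {
      // pre-draw Poisson input spikes for this frame, bucketed by step
      ev_s.clear(); ev_i.clear();
      for (int i = 0; i < nIn; ++i) {
        double lam = rates(i, f) * steps * dt;
        if (lam <= 0) continue;
        int n = (int)R::rpois(lam);
        for (int q = 0; q < n; ++q) {
          int s = (int)(unif_rand() * steps);
          if (s >= steps) s = steps - 1;
          ev_s.push_back(s); ev_i.push_back(i);
        }
      }
      bucket_off.assign(steps + 1, 0);
      for (size_t q = 0; q < ev_s.size(); ++q) bucket_off[ev_s[q] + 1]++;
      for (int s = 0; s < steps; ++s) bucket_off[s + 1] += bucket_off[s];
      std::vector<int> pos(bucket_off.begin(), bucket_off.end() - 1);
      std::vector<int> sorted_i(ev_s.size());
      for (size_t q = 0; q < ev_s.size(); ++q) sorted_i[pos[ev_s[q]]++] = ev_i[q];
      ev_i.swap(sorted_i);
    }

    for (int s = 0; s < steps; ++s, ++gstep) {
      // exact exponential decay of all traces
      for (int i = 0; i < nIn; ++i) { in_r[i] *= dr; in_f[i] *= df; }
      for (int k = 0; k < H; ++k) {
        lat_r[k] *= dr; lat_f[k] *= df;
        be_r[k] *= adr; be_f[k] *= adf;
      }
      // delayed lateral spike delivery
      if (has_lat) {
        rpos = (rpos + 1) % ring_len;
        for (int k = 0; k < H; ++k) {
          double c = dbuf(k, rpos);
          if (c > 0) { lat_r[k] += c; lat_f[k] += c; dbuf(k, rpos) = 0; }
        }
      }
      // input spike arrivals this step
      if (use_events) {
        while (ep < nev && events(ep, 0) == gstep) {
          int i = events(ep, 1);
          in_r[i] += 1; in_f[i] += 1; ++ep;
        }
      } else {
        for (int q = bucket_off[s]; q < bucket_off[s + 1]; ++q) {
          int i = ev_i[q];
          in_r[i] += 1; in_f[i] += 1;
        }
      }
      for (int i = 0; i < nIn; ++i) x[i] = in_f[i] - in_r[i];
      if (has_lat) for (int k = 0; k < H; ++k) xl[k] = lat_f[k] - lat_r[k];

      // membrane potentials (column-major accumulation)
      for (int k = 0; k < H; ++k)
        u[k] = alive[k] ? gam_eff * (be_f[k] - be_r[k]) : R_NegInf;
      {
        const double *W = &weff_ff(0, 0);
        for (int i = 0; i < nIn; ++i) {
          const double xi = x[i];
          if (xi == 0) continue;
          const double *col = W + (size_t)i * H;
          for (int k = 0; k < H; ++k) u[k] += col[k] * xi;
        }
        if (has_lat) {
          const double *L = &weff_lat(0, 0);
          for (int j = 0; j < H; ++j) {
            const double xj = xl[j];
            if (xj == 0) continue;
            const double *col = L + (size_t)j * H;
            for (int k = 0; k < H; ++k) u[k] += col[k] * xj;
          }
        }
        for (int k = 0; k < H; ++k) if (!alive[k]) u[k] = R_NegInf;
      }

      // divisive inhibition per circuit, spike draws
      for (int c = 0; c < nCirc; ++c) {
        const std::vector<int> &mem = members[c];
        if (mem.empty()) continue;
        double mx = R_NegInf;
        for (int k : mem) mx = std::max(mx, u[k]);
        double ssum = 0;
        for (int k : mem) ssum += std::exp(u[k] - mx);
        for (int k : mem) {
          double rho = rho_net * std::exp(u[k] - mx) / ssum;
          double p = rho * dt;
          if (record_rates) rho_hist(k, gstep) = rho;
          if (p > 0.2) thinning_warn = true;
          if (unif_rand() < p) {
            counts(k, f)++;
            if (record_spikes) { sp_step.push_back(gstep); sp_neuron.push_back(k + 1); }
            be_r[k] += 1; be_f[k] += 1;
            if (has_lat) dbuf(k, (rpos + delay) % ring_len) += 1;
            if (plasticity && likelihood) {
              // likelihood jumps on all incoming synapses of neuron k
              for (int i = 0; i < nIn; ++i) {
                if (!mask_ff(k, i)) continue;
                double w = w_ff(k, i);
                double d = b * Nmult * w * (x[i] - alpha * std::exp(w));
                if (d > max_jump) d = max_jump;
                else if (d < -max_jump) d = -max_jump;
                double th = th_ff(k, i) + d;
                if (th < clip_low) th = clip_low;
                th_ff(k, i) = th;
                w = wmap(th, theta0);
                w_ff(k, i) = w;
                weff_ff(k, i) = std::max(0.0, w - w0);
              }
              if (has_lat) {
                for (int j = 0; j < H; ++j) {
                  if (j == k || !alive[j] || ban_lat(k, j)) continue;
                  double w = w_lat(k, j);
                  double d = b * Nmult * w * (xl[j] - alpha * std::exp(w));
                  if (d > max_jump) d = max_jump;
                  else if (d < -max_jump) d = -max_jump;
                  double th = th_lat(k, j) + d;
                  if (th < clip_low) th = clip_low;
                  th_lat(k, j) = th;
                  w = wmap(th, theta0);
                  w_lat(k, j) = w;
                  weff_lat(k, j) = std::max(0.0, w - w0);
                }
              }
            }
          }
        }
      }
    }

    // prior drift + diffusion over the frame: the prior-only dynamics is an
    // Ornstein-Uhlenbeck process, so its transition over the frame length
    // is applied exactly (no discretization error for any frame length)
    if (plasticity) {
      const double Delta = steps * dt;
      const double lam = b / sig2;
      const double decay = std::exp(-lam * Delta);
      const double sd = std::sqrt(Temp * sig2 * (1.0 - decay * decay));
      for (int i = 0; i < nIn; ++i)
        for (int k = 0; k < H; ++k) {
          if (!alive[k] || !mask_ff(k, i)) continue;
          double th = mu + (th_ff(k, i) - mu) * decay + sd * norm_rand();
          if (th < clip_low) th = clip_low;
          th_ff(k, i) = th;
          double w = wmap(th, theta0);
          w_ff(k, i) = w;
          weff_ff(k, i) = std::max(0.0, w - w0);
        }
      if (has_lat) {
        for (int j = 0; j < H; ++j)
          for (int k = 0; k < H; ++k) {
            if (k == j || !alive[k] || !alive[j] || ban_lat(k, j)) continue;
            double th = mu + (th_lat(k, j) - mu) * decay + sd * norm_rand();
            if (th < clip_low) th = clip_low;
            th_lat(k, j) = th;
            double w = wmap(th, theta0);
            w_lat(k, j) = w;
            weff_lat(k, j) = std::max(0.0, w - w0);
          }
      }
    }
  }

  List newstate = List::create(
    _["theta_ff"] = th_ff, _["mask_ff"] = mask_ff,
    _["theta_lat"] = has_lat ? (RObject)th_lat : (RObject)R_NilValue,
    _["ban_lat"] = has_lat ? (RObject)ban_lat : (RObject)R_NilValue,
    _["alive"] = alive, _["circuit"] = circ,
    _["in_rise"] = in_r, _["in_fall"] = in_f,
    _["lat_rise"] = lat_r, _["lat_fall"] = lat_f,
    _["beta_rise"] = be_r, _["beta_fall"] = be_f,
    _["delay_buf"] = dbuf, _["ring_pos"] = rpos);

  List out = List::create(
    _["state"] = newstate, _["counts"] = counts,
    _["thinning_warning"] = thinning_warn);
  if (record_spikes)
    out["spikes"] = DataFrame::create(_["neuron"] = wrap(sp_neuron),
                                      _["step"] = wrap(sp_step));
  if (record_rates) out["rho"] = rho_hist;
  return out;
}
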