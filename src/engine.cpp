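// Clock-driven LIF network engine with a ring-buffer delay queue.
//
// Mirrors the scalar R reference stepper (membrane_step) operation for
// operation: per step, (1) deliver queued recurrent arrivals and external
// input, (2) refractory clamp or forward-Euler membrane update, (3)
// threshold/reset + spike emission with Tsodyks-Markram efficacy evaluated
// at emission time, (4) exact exponential conductance decay.  Spikes
// detected while advancing step k are stamped (k+1)*dt; a synapse with
// delay of d steps is delivered at the start of absolute step k+1+d.
// All randomness comes from R's RNG so runs are seed-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List run_lif_engine(int n,
                    LogicalVector neuron_is_inh,
                    IntegerVector syn_src,    // 0-based, sorted ascending
                    IntegerVector syn_tgt,    // 0-based
                    NumericVector syn_w,      // nS
                    IntegerVector syn_delay,  // steps, >= 1
                    List par) {
  const double El     = as<double>(par["E_leak"]);
  const double tau_m  = as<double>(par["tau_m"]);
  const double c_m    = as<double>(par["c_m"]);
  const double Ee     = as<double>(par["E_exc"]);
  const double Eg     = as<double>(par["E_gaba"]);
  const double tau_e  = as<double>(par["tau_exc"]);
  const double tau_i  = as<double>(par["tau_inh"]);
  const double Vt     = as<double>(par["V_threshold"]);
  const double Vr     = as<double>(par["V_reset"]);
  const double tauref = as<double>(par["tau_ref"]);
  const double g_ext  = as<double>(par["g_ext"]);
  const double dt     = as<double>(par["dt"]);        // ms
  const int    nsteps = as<int>(par["n_steps"]);
  const double p_ext  = as<double>(par["p_ext"]);     // per-step Bernoulli
  const bool   use_poisson = as<bool>(par["use_poisson"]);
  const bool   stp_on      = as<bool>(par["stp_enabled"]);
  const bool   stp_exc_only = as<bool>(par["stp_exc_only"]);
  const double U       = as<double>(par["U"]);
  const double tau_dep = as<double>(par["tau_dep"]);
  const double tau_fac = as<double>(par["tau_fac"]);
  const int    record_v_id = as<int>(par["record_v_id"]); // 0-based or -1

  NumericVector V = clone(as<NumericVector>(par["init_V"]));
  if (V.size() != n) stop("init_V length mismatch");

  // deterministic external events (oracle mode)
  IntegerVector ext_step = as<IntegerVector>(par["ext_step"]); // sorted
  IntegerVector ext_id   = as<IntegerVector>(par["ext_id"]);   // 0-based

  const int nsyn = syn_src.size();
  // CSR rows by source
  std::vector<int> row_ptr(n + 1, 0);
  for (int s = 0; s < nsyn; ++s) {
    if (s > 0 && syn_src[s] < syn_src[s - 1]) stop("synapses not sorted by source");
    row_ptr[syn_src[s] + 1]++;
  }
  for (int i = 0; i < n; ++i) row_ptr[i + 1] += row_ptr[i];

  int max_delay = 1;
  for (int s = 0; s < nsyn; ++s) {
    if (syn_delay[s] < 1) stop("delays must round to >= 1 step");
    if (syn_delay[s] > max_delay) max_delay = syn_delay[s];
  }
  const int nslots = max_delay + 2;
  std::vector<double> bufE((size_t)nslots * n, 0.0);
  std::vector<double> bufI((size_t)nslots * n, 0.0);

  std::vector<double> ge(n, 0.0), gi(n, 0.0), refr(n, 0.0);
  std::vector<double> stp_u(n, 0.0), stp_x(n, 1.0);
  std::vector<int> last_spike_step(n, -1);

  const double decE = std::exp(-dt / tau_e);
  const double decI = std::exp(-dt / tau_i);

  std::vector<double> sp_t;
  std::vector<int> sp_id;
  sp_t.reserve(1 << 16);
  sp_id.reserve(1 << 16);

  NumericVector v_trace(record_v_id >= 0 ? nsteps : 0);

  RNGScope rng;
  int ext_ptr = 0;
  const int next = ext_step.size();

  for (int k = 0; k < nsteps; ++k) {
    const int slot = k % nslots;
    double *be = &bufE[(size_t)slot * n];
    double *bi = &bufI[(size_t)slot * n];
    for (int i = 0; i < n; ++i) {
      ge[i] += be[i]; be[i] = 0.0;
      gi[i] += bi[i]; bi[i] = 0.0;
    }
    if (use_poisson && p_ext > 0) {
      for (int i = 0; i < n; ++i) {
        if (unif_rand() < p_ext) ge[i] += g_ext;
      }
    }
    while (ext_ptr < next && ext_step[ext_ptr] == k) {
      ge[ext_id[ext_ptr]] += g_ext;
      ++ext_ptr;
    }

    for (int i = 0; i < n; ++i) {
      if (refr[i] > 0) {
        V[i] = Vr;
        refr[i] -= dt;
        if (refr[i] < 0) refr[i] = 0;
      } else {
        const double dv = (El - V[i]) / tau_m +
          (ge[i] * (Ee - V[i]) + gi[i] * (Eg - V[i])) / c_m;
        V[i] = V[i] + dt * dv;
        if (!R_finite(V[i])) {
          stop("membrane potential diverged at step %d, neuron %d", k, i + 1);
        }
        if (V[i] >= Vt) {
          sp_t.push_back((k + 1) * dt);
          sp_id.push_back(i + 1);
          V[i] = Vr;
          refr[i] = tauref;

          double f = 1.0;
          if (stp_on && !(stp_exc_only && neuron_is_inh[i])) {
            double u = stp_u[i], x = stp_x[i];
            if (last_spike_step[i] >= 0) {
              const double dms = (k - last_spike_step[i]) * dt;
              u *= std::exp(-dms / tau_fac);
              x = 1.0 - (1.0 - x) * std::exp(-dms / tau_dep);
            } else {
              u = 0.0; x = 1.0;
            }
            u = u + U * (1.0 - u);
            f = u * x / U;           // efficacy / U: first spike => 1
            x = x * (1.0 - u);
            stp_u[i] = u; stp_x[i] = x;
          }
          last_spike_step[i] = k;

          const bool inh = neuron_is_inh[i];
          for (int s = row_ptr[i]; s < row_ptr[i + 1]; ++s) {
            const int dslot = (k + 1 + syn_delay[s]) % nslots;
            const double w = syn_w[s] * f;
            if (inh) bufI[(size_t)dslot * n + syn_tgt[s]] += w;
            else     bufE[(size_t)dslot * n + syn_tgt[s]] += w;
          }
        }
      }
    }

    for (int i = 0; i < n; ++i) {
      ge[i] *= decE;
      gi[i] *= decI;
    }
    if (record_v_id >= 0) v_trace[k] = V[record_v_id];
  }

  return List::create(_["times_ms"] = NumericVector(sp_t.begin(), sp_t.end()),
                      _["ids"] = IntegerVector(sp_id.begin(), sp_id.end()),
                      _["v_trace"] = v_trace);
}

// Sum over all pairs of exp(-|a_i - b_j| / tau) for sorted spike trains a, b.
// Linear-time merge with decaying accumulators; numerically safe for long
// recordings (no exp of large positive arguments).
// [[Rcpp::export]]
double vr_cross_sum(NumericVector a, NumericVector b, double tau) {
  const int na = a.size(), nb = b.size();
  if (na == 0 || nb == 0) return 0.0;
  double total = 0.0, Sa = 0.0, Sb = 0.0, tlast = R_NegInf;
  int i = 0, j = 0;
  while (i < na || j < nb) {
    double t;
    bool from_a;
    if (j >= nb || (i < na && a[i] <= b[j])) { t = a[i]; from_a = true; }
    else { t = b[j]; from_a = false; }
    const double dec = (tlast == R_NegInf) ? 0.0 : std::exp(-(t - tlast) / tau);
    Sa *= dec; Sb *= dec;
    if (from_a) { total += Sb; Sa += 1.0; ++i; }
    else        { total += Sa; Sb += 1.0; ++j; }
    tlast = t;
  }
  return total;
}
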