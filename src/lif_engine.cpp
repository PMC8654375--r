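// Conductance-based leaky integrate-and-fire network integrator.
//
// Dynamics per neuron:
//   C dV/dt = gL (EL - V) + sum_s g_s (E_s - V) + I_inj
// with one exponentially decaying conductance per synapse class
// (exponential-Euler decay, forward-Euler voltage update). Presynaptic
// spikes from neurons within the network take effect on the step after they
// are emitted; external ensemble spikes take effect on the step they occur.
// Ensemble spike trains are homogeneous Poisson processes realised by
// per-step Bernoulli thinning of each source (equivalently a binomial draw
// of the number of spiking sources followed by sampling distinct ids).
// All randomness is taken from R's RNG, so results are reproducible with
// set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sample k distinct integers in [0, n). k << n in practice; rejection is
// cheap. Falls back to a partial Fisher-Yates when k is a large share of n.
static void sample_distinct(int n, int k, std::vector<int> &out) {
  out.clear();
  if (k <= 0) return;
  if (k > n) k = n;
  if (k * 4 < n) {
    out.reserve(k);
    while ((int)out.size() < k) {
      int cand = (int)(unif_rand() * n);
      if (cand >= n) cand = n - 1;
      bool dup = false;
      for (int v : out) {
        if (v == cand) { dup = true; break; }
      }
      if (!dup) out.push_back(cand);
    }
  } else {
    std::vector<int> pool(n);
    for (int i = 0; i < n; ++i) pool[i] = i;
    for (int i = 0; i < k; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(pool[i], pool[j]);
    }
    out.assign(pool.begin(), pool.begin() + k);
  }
}

// [[Rcpp::export]]
List lif_engine(int n_neurons,
                List neuron,
                NumericVector syn_tau_ms,
                NumericVector syn_reversal_mV,
                IntegerVector rec_ptr,
                IntegerVector rec_tgt,
                NumericVector rec_w,
                IntegerVector rec_syn,
                List ensembles,
                LogicalVector silenced,
                NumericVector i_inj_pA,
                double duration_ms,
                double dt_ms,
                IntegerVector record_ids,
                int record_every) {
  // neuron: capacitance_pF, leak_nS, resting_mV, threshold_mV, reset_mV,
  //         refractory_ms, v0 (initial potential per neuron)
  // rec_*: CSR by presynaptic neuron (0-based ptr of length n_neurons + 1);
  //        rec_syn holds the 1-based synapse class per connection
  // ensembles: each a list with n_sources, rate_Hz, synapse, ptr, tgt, w
  // record_ids: 1-based neuron ids to sample, may be empty
  const double C = as<double>(neuron["capacitance_pF"]);
  const double gL = as<double>(neuron["leak_nS"]);
  const double EL = as<double>(neuron["resting_mV"]);
  const double Vth = as<double>(neuron["threshold_mV"]);
  const double Vre = as<double>(neuron["reset_mV"]);
  const double tref = as<double>(neuron["refractory_ms"]);
  NumericVector v0 = as<NumericVector>(neuron["v0"]);
  if (v0.size() != n_neurons) stop("v0 must have one entry per neuron");

  const int n_syn = syn_tau_ms.size();
  const int n_steps = (int)std::lround(duration_ms / dt_ms);

  std::vector<double> decay(n_syn);
  for (int s = 0; s < n_syn; ++s) decay[s] = std::exp(-dt_ms / syn_tau_ms[s]);

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> g((size_t)n_syn * n_neurons, 0.0);
  std::vector<double> refr(n_neurons, 0.0);
  std::vector<int> counts(n_neurons, 0);

  struct Ens {
    int n_sources;
    double p_step;
    int syn;
    IntegerVector ptr, tgt;
    NumericVector w;
  };
  std::vector<Ens> ens;
  for (int e = 0; e < ensembles.size(); ++e) {
    List el = ensembles[e];
    Ens en;
    en.n_sources = as<int>(el["n_sources"]);
    en.p_step = as<double>(el["rate_Hz"]) * dt_ms / 1000.0;
    en.syn = as<int>(el["synapse"]) - 1;
    en.ptr = as<IntegerVector>(el["ptr"]);
    en.tgt = as<IntegerVector>(el["tgt"]);
    en.w = as<NumericVector>(el["w"]);
    if (en.p_step > 1.0) stop("timestep too large for ensemble rate");
    ens.push_back(en);
  }

  std::vector<int> spikes_now, spikes_prev, active;
  std::vector<int> spike_id;
  std::vector<double> spike_t;

  const int n_rec = record_ids.size();
  int n_samples = 0;
  if (n_rec > 0 && record_every > 0) n_samples = n_steps / record_every + 1;
  NumericMatrix vm(n_samples, n_rec);
  NumericVector vm_time(n_samples);
  int sample_row = 0;
  if (n_samples > 0) {
    for (int j = 0; j < n_rec; ++j) vm(0, j) = V[record_ids[j] - 1];
    vm_time[0] = 0.0;
    sample_row = 1;
  }

  GetRNGstate();
  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt_ms;

    // external ensemble spikes (take effect this step)
    for (Ens &en : ens) {
      int k = (int)R::rbinom(en.n_sources, en.p_step);
      if (k == 0 || en.w.size() == 0) continue;
      sample_distinct(en.n_sources, k, active);
      double *gs = &g[(size_t)en.syn * n_neurons];
      for (int src : active) {
        for (int c = en.ptr[src]; c < en.ptr[src + 1]; ++c) {
          gs[en.tgt[c] - 1] += en.w[c];
        }
      }
    }

    // recurrent spikes from the previous step
    for (int src : spikes_prev) {
      for (int c = rec_ptr[src]; c < rec_ptr[src + 1]; ++c) {
        g[(size_t)(rec_syn[c] - 1) * n_neurons + (rec_tgt[c] - 1)] += rec_w[c];
      }
    }

    // integrate and detect spikes
    spikes_now.clear();
    for (int i = 0; i < n_neurons; ++i) {
      if (silenced[i]) { V[i] = EL; continue; }
      if (refr[i] > 0.0) {
        refr[i] -= dt_ms;
        V[i] = Vre;
        continue;
      }
      double isyn = 0.0;
      for (int s = 0; s < n_syn; ++s) {
        isyn += g[(size_t)s * n_neurons + i] * (syn_reversal_mV[s] - V[i]);
      }
      V[i] += dt_ms * (gL * (EL - V[i]) + isyn + i_inj_pA[i]) / C;
      if (!std::isfinite(V[i])) {
        PutRNGstate();
        stop("non-finite membrane potential in neuron %d at t = %.3f ms",
             i + 1, t);
      }
      if (V[i] >= Vth) {
        spikes_now.push_back(i);
        V[i] = Vre;
        refr[i] = tref;
        counts[i] += 1;
        spike_id.push_back(i + 1);
        spike_t.push_back(t);
      }
    }

    // conductance decay
    for (size_t j = 0; j < g.size(); ++j) g[j] *= decay[j / n_neurons];

    std::swap(spikes_prev, spikes_now);

    if (n_samples > 0 && (step + 1) % record_every == 0 && sample_row < n_samples) {
      for (int j = 0; j < n_rec; ++j) vm(sample_row, j) = V[record_ids[j] - 1];
      vm_time[sample_row] = (step + 1) * dt_ms;
      ++sample_row;
    }
  }
  PutRNGstate();

  List out = List::create(
    _["spike_id"] = wrap(spike_id),
    _["spike_time_ms"] = wrap(spike_t),
    _["counts"] = wrap(counts));
  if (n_samples > 0) {
    out["vm"] = vm;
    out["vm_time_ms"] = vm_time;
  }
  return out;
}
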