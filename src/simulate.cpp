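#include <Rcpp.h>
using namespace Rcpp;

// Network state advances on a fixed Euler grid. Adjacency is passed in
// compressed form: `targets` concatenates the postsynaptic targets of
// presynaptic neuron 0, 1, ... and `offsets` (length n+1) delimits them.
// All indices are 0-based on the C++ side.

static inline double leak_step(double v, double v_r, double dt_over_tau) {
  return v + dt_over_tau * (v_r - v);
}

// Full-mode dynamics: recurrent spikes are delivered at the next
// integration step; external Poisson input targets the driven subset.
// Each neuron fires at most once per step (threshold test after all
// inputs of the step are applied) and resets to v_r.
// [[Rcpp::export]]
List simulate_full_cpp(int n, int n_exc,
                       IntegerVector targets, IntegerVector offsets,
                       IntegerVector active, NumericVector v0,
                       double v_r, double v_theta, double tau_mem,
                       double j_ext, double j_exc, double j_inh,
                       double f_max, double dt, int n_steps) {
  NumericVector v = clone(v0);
  const double dt_over_tau = dt / tau_mem;
  const int n_active = active.size();
  const double ext_mean = n_active * f_max * dt;

  std::vector<int> spike_step, spike_neuron;
  std::vector<int> prev_spikes;  // spikes emitted at the previous step
  IntegerVector ext_counts(n_steps);

  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) v[i] = leak_step(v[i], v_r, dt_over_tau);

    // recurrent input from last step's spikes (one-step delivery delay)
    for (size_t k = 0; k < prev_spikes.size(); ++k) {
      int j = prev_spikes[k];
      double w = (j < n_exc) ? j_exc : -j_inh;
      for (int e = offsets[j]; e < offsets[j + 1]; ++e) v[targets[e]] += w;
    }

    // external Poisson drive: total count over the driven subset, each
    // event assigned to a uniformly chosen driven neuron
    int k_ext = 0;
    if (n_active > 0 && ext_mean > 0) {
      k_ext = (int) R::rpois(ext_mean);
      for (int e = 0; e < k_ext; ++e) {
        int who = active[(int)(R::unif_rand() * n_active) % n_active];
        v[who] += j_ext;
      }
    }
    ext_counts[t] = k_ext;

    prev_spikes.clear();
    for (int i = 0; i < n; ++i) {
      if (!R_finite(v[i]))
        stop("non-finite membrane potential (neuron %d, step %d)", i + 1, t + 1);
      if (v[i] >= v_theta) {
        v[i] = v_r;
        prev_spikes.push_back(i);
        spike_step.push_back(t + 1);
        spike_neuron.push_back(i + 1);
      }
    }
  }

  return List::create(_["spike_step"] = wrap(spike_step),
                      _["spike_neuron"] = wrap(spike_neuron),
                      _["ext_counts"] = ext_counts,
                      _["v_final"] = v);
}

// Avalanche-mode dynamics (separation of timescales): any threshold
// crossing within a step triggers an instantaneous cascade that
// propagates generation by generation until no new neuron crosses
// threshold.  A neuron fires at most once per cascade and is held at
// v_r afterwards; size = distinct neurons fired, duration = generations.
// [[Rcpp::export]]
List simulate_avalanche_cpp(int n, int n_exc,
                            IntegerVector targets, IntegerVector offsets,
                            IntegerVector active, NumericVector v0,
                            double v_r, double v_theta, double tau_mem,
                            double j_ext, double j_exc, double j_inh,
                            double f_max, double dt, int n_steps) {
  NumericVector v = clone(v0);
  const double dt_over_tau = dt / tau_mem;
  const int n_active = active.size();
  const double ext_mean = n_active * f_max * dt;

  std::vector<int> spike_step, spike_neuron;
  std::vector<int> av_step, av_size, av_dur;
  std::vector<char> fired(n, 0);
  std::vector<int> frontier, next_frontier, all_fired;
  IntegerVector ext_counts(n_steps);

  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) v[i] = leak_step(v[i], v_r, dt_over_tau);

    int k_ext = 0;
    if (n_active > 0 && ext_mean > 0) {
      k_ext = (int) R::rpois(ext_mean);
      for (int e = 0; e < k_ext; ++e) {
        int who = active[(int)(R::unif_rand() * n_active) % n_active];
        v[who] += j_ext;
      }
    }
    ext_counts[t] = k_ext;

    // generation 1: all simultaneous crossings form one avalanche
    frontier.clear();
    for (int i = 0; i < n; ++i) {
      if (!R_finite(v[i]))
        stop("non-finite membrane potential (neuron %d, step %d)", i + 1, t + 1);
      if (v[i] >= v_theta) frontier.push_back(i);
    }
    if (frontier.empty()) continue;

    all_fired.clear();
    int generations = 0;
    for (size_t k = 0; k < frontier.size(); ++k) fired[frontier[k]] = 1;

    while (!frontier.empty()) {
      ++generations;
      if (generations > n) stop("cascade exceeded N generations");  // unreachable
      for (size_t k = 0; k < frontier.size(); ++k) {
        int j = frontier[k];
        all_fired.push_back(j);
        spike_step.push_back(t + 1);
        spike_neuron.push_back(j + 1);
        double w = (j < n_exc) ? j_exc : -j_inh;
        for (int e = offsets[j]; e < offsets[j + 1]; ++e) {
          int i = targets[e];
          if (!fired[i]) v[i] += w;  // fired neurons are held at v_r
        }
      }
      next_frontier.clear();
      for (int i = 0; i < n; ++i) {
        if (!fired[i] && v[i] >= v_theta) {
          fired[i] = 1;
          next_frontier.push_back(i);
        }
      }
      frontier.swap(next_frontier);
    }

    for (size_t k = 0; k < all_fired.size(); ++k) {
      v[all_fired[k]] = v_r;
      fired[all_fired[k]] = 0;
    }
    av_step.push_back(t + 1);
    av_size.push_back((int) all_fired.size());
    av_dur.push_back(generations);
  }

  return List::create(_["spike_step"] = wrap(spike_step),
                      _["spike_neuron"] = wrap(spike_neuron),
                      _["ext_counts"] = ext_counts,
                      _["av_step"] = wrap(av_step),
                      _["av_size"] = wrap(av_size),
                      _["av_dur"] = wrap(av_dur),
                      _["v_final"] = v);
}
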