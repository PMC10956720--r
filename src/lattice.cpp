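#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Synchronous three-state excitable lattice dynamics.
//
// States: 0 rest, 1 active (firing), 2 and 3 refractory. A resting unit
// fires on the next step with probability 1 - (1-h) * (1-P)^a, where a is
// the number of its currently active presynaptic inputs: each active unit
// independently transmits to each of its K targets with probability P, and
// the Poisson drive h acts as one more independent Bernoulli source.
// Firing units pass through two refractory steps (1 -> 2 -> 3 -> 0).
//
// Uses R's RNG so set.seed() on the R side makes runs bit-reproducible.
//
// The interaction graph is passed in compressed form: nbr_off (length
// N + 1, 0-based offsets) and nbr_idx (1-based unit indices), so both
// symmetric couplings (variable degree) and strictly directed wiring fit.
// record_units: 1-based indices whose binned spike counts are returned.
// Returns counts (recorded units x bins), active count per recorded step,
// and the total number of spikes over the recorded period.
// [[Rcpp::export]]
List sim_lattice_cpp(IntegerVector nbr_off, IntegerVector nbr_idx, int steps,
                     int burn_in, double P, double h,
                     IntegerVector record_units, int bin_steps,
                     IntegerVector init_active, bool sparse_out) {
  const int N = nbr_off.size() - 1;
  std::vector<unsigned char> state(N, 0), marked(N, 0);
  std::vector<int> active, next_active, refr2, refr3, mark_list;
  active.reserve(N); next_active.reserve(N);
  refr2.reserve(N); refr3.reserve(N); mark_list.reserve(N);

  for (int i = 0; i < init_active.size(); ++i) {
    int u = init_active[i] - 1;
    if (state[u] == 0) { state[u] = 1; active.push_back(u); }
  }

  std::vector<int> rec_row(N, -1);
  const int n_rec = record_units.size();
  for (int i = 0; i < n_rec; ++i) rec_row[record_units[i] - 1] = i;
  const int n_bins = (steps + bin_steps - 1) / bin_steps;
  IntegerMatrix counts(sparse_out ? 0 : n_rec, sparse_out ? 0 : n_bins);
  std::vector<int> sp_unit, sp_bin;  // triplet output when sparse_out
  IntegerVector active_per_step(steps);
  double total_spikes = 0.0;

  RNGScope scope;
  const int total_steps = burn_in + steps;
  for (int t = 0; t < total_steps; ++t) {
    // synaptic transmission from active units to resting targets
    mark_list.clear();
    for (size_t ai = 0; ai < active.size(); ++ai) {
      const int u = active[ai];
      for (int k = nbr_off[u]; k < nbr_off[u + 1]; ++k) {
        const int v = nbr_idx[k] - 1;
        if (state[v] == 0 && !marked[v] && unif_rand() < P) {
          marked[v] = 1; mark_list.push_back(v);
        }
      }
    }
    // Poisson drive: thinned Bernoulli(h) over all units, rejecting
    // non-resting draws, equivalent to per-resting-unit drive
    if (h > 0) {
      int m = (int) R::rbinom((double) N, h);
      for (int j = 0; j < m; ++j) {
        int v = (int) (unif_rand() * N);
        if (v == N) v = N - 1;
        if (state[v] == 0 && !marked[v]) { marked[v] = 1; mark_list.push_back(v); }
      }
    }
    // synchronous state transitions
    for (size_t i = 0; i < refr3.size(); ++i) state[refr3[i]] = 0;
    refr3.clear();
    for (size_t i = 0; i < refr2.size(); ++i) { state[refr2[i]] = 3; refr3.push_back(refr2[i]); }
    refr2.clear();
    for (size_t i = 0; i < active.size(); ++i) { state[active[i]] = 2; refr2.push_back(active[i]); }
    next_active.clear();
    for (size_t i = 0; i < mark_list.size(); ++i) {
      const int v = mark_list[i];
      marked[v] = 0; state[v] = 1; next_active.push_back(v);
    }
    active.swap(next_active);
    // record firing at this (post-transition) step index t+1 relative to start
    const int rt = t + 1 - burn_in;  // 0-based recorded step
    if (rt >= 0 && rt < steps) {
      active_per_step[rt] = (int) active.size();
      total_spikes += (double) active.size();
      const int b = rt / bin_steps;
      for (size_t i = 0; i < active.size(); ++i) {
        const int r = rec_row[active[i]];
        if (r < 0) continue;
        if (sparse_out) { sp_unit.push_back(r + 1); sp_bin.push_back(b + 1); }
        else counts(r, b) += 1;
      }
    }
  }
  return List::create(_["counts"] = counts,
                      _["sp_unit"] = wrap(sp_unit), _["sp_bin"] = wrap(sp_bin),
                      _["n_bins"] = n_bins,
                      _["active_per_step"] = active_per_step,
                      _["total_spikes"] = total_spikes);
}
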