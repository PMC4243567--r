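// Reduced-biophysics network core: passive multicompartment cable dynamics
// (backward-Euler Hines solve on each cell's tree), two-state conductance
// synapses with exponential rise/decay state variables, a threshold/reset
// soma surrogate with absolute refractoriness, and event-driven delivery of
// delayed presynaptic spikes.
//
// All cells are concatenated into flat compartment arrays; compartments are
// ordered so that every parent index precedes its children, which lets one
// backward sweep eliminate the whole forest and one forward sweep back-solve.
//
// Units: mV, ms, nF, uS, nA.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Arguments, in order: compartment arrays (global, parent-before-child,
// parent = -1 at cell roots); per-cell soma-surrogate arrays (cell_offset is
// each cell's first compartment); per-contact synapse arrays (syn_weight is
// g_max times the peak normalisation, uS); pre-scheduled input events;
// network contacts mapping a presynaptic cell to a synapse after a delay;
// constant current injections; run control.
// [[Rcpp::export(name = ".sim_core")]]
List sim_core(
    IntegerVector parent, NumericVector cap_nf, NumericVector g_leak,
    NumericVector e_leak, NumericVector g_axial,
    IntegerVector cell_offset,
    NumericVector v_threshold, NumericVector v_reset,
    NumericVector t_refrac,
    IntegerVector syn_comp, NumericVector syn_weight,
    NumericVector syn_tau_rise, NumericVector syn_tau_decay,
    NumericVector syn_e_rev,
    IntegerVector ev_syn, IntegerVector ev_step,
    IntegerVector net_src_cell, IntegerVector net_syn,
    IntegerVector net_delay_steps,
    IntegerVector ic_comp, NumericVector ic_amp_na,
    IntegerVector ic_start_step, IntegerVector ic_end_step,
    double dt, int n_steps, IntegerVector record_cells,
    bool log_events) {

  const int nc = parent.size();
  const int ncell = cell_offset.size();
  const int nsyn = syn_comp.size();

  // static diagonal: C/dt + G_leak + own axial + children's axial couplings
  std::vector<double> d_static(nc), v(nc), cdt(nc);
  for (int i = 0; i < nc; ++i) {
    cdt[i] = cap_nf[i] / dt;
    d_static[i] = cdt[i] + g_leak[i];
    v[i] = e_leak[i];
  }
  for (int i = 0; i < nc; ++i) {
    if (parent[i] >= 0) {
      d_static[i] += g_axial[i];
      d_static[parent[i]] += g_axial[i];
    }
  }

  // synapse state and per-step decay factors
  std::vector<double> sA(nsyn, 0.0), sB(nsyn, 0.0), fr(nsyn), fd(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    if (!(syn_tau_rise[s] < syn_tau_decay[s]))
      stop("synapse tau_rise must be < tau_decay");
    fr[s] = std::exp(-dt / syn_tau_rise[s]);
    fd[s] = std::exp(-dt / syn_tau_decay[s]);
  }

  // event buckets per step
  std::vector< std::vector<int> > pending(n_steps + 1);
  for (int k = 0; k < ev_syn.size(); ++k) {
    int st = ev_step[k];
    if (st >= 0 && st <= n_steps) pending[st].push_back(ev_syn[k]);
  }

  // outgoing contact lists per presynaptic cell
  std::vector< std::vector<int> > out_syn(ncell), out_del(ncell);
  for (int k = 0; k < net_src_cell.size(); ++k) {
    out_syn[net_src_cell[k]].push_back(net_syn[k]);
    out_del[net_src_cell[k]].push_back(net_delay_steps[k]);
  }

  std::vector<double> refrac_until(ncell, -1e30);
  std::vector<int> spike_cell; std::vector<double> spike_time;
  std::vector<int> logged_syn, logged_step;

  const int nrec = record_cells.size();
  NumericMatrix traces(nrec, n_steps + 1);
  for (int r = 0; r < nrec; ++r)
    traces(r, 0) = v[cell_offset[record_cells[r]]];

  std::vector<double> dvec(nc), rhs(nc), gs(nc), ge(nc);

  for (int step = 0; step < n_steps; ++step) {
    const double t_new = (step + 1) * dt;

    // decay synapse states, then deliver this step's events
    for (int s = 0; s < nsyn; ++s) { sA[s] *= fr[s]; sB[s] *= fd[s]; }
    for (size_t k = 0; k < pending[step].size(); ++k) {
      int s = pending[step][k];
      sA[s] += syn_weight[s];
      sB[s] += syn_weight[s];
      if (log_events) { logged_syn.push_back(s); logged_step.push_back(step); }
    }

    // accumulate synaptic conductance per compartment
    std::fill(gs.begin(), gs.end(), 0.0);
    std::fill(ge.begin(), ge.end(), 0.0);
    for (int s = 0; s < nsyn; ++s) {
      double g = sB[s] - sA[s];
      if (g > 0) {
        gs[syn_comp[s]] += g;
        ge[syn_comp[s]] += g * syn_e_rev[s];
      }
    }

    // assemble
    for (int i = 0; i < nc; ++i) {
      dvec[i] = d_static[i] + gs[i];
      rhs[i] = cdt[i] * v[i] + g_leak[i] * e_leak[i] + ge[i];
    }
    for (int k = 0; k < ic_comp.size(); ++k) {
      if (step >= ic_start_step[k] && step < ic_end_step[k])
        rhs[ic_comp[k]] += ic_amp_na[k];
    }

    // Hines elimination (children first) and back-substitution
    for (int i = nc - 1; i > 0; --i) {
      int p = parent[i];
      if (p >= 0) {
        double f = g_axial[i] / dvec[i];
        dvec[p] -= f * g_axial[i];
        rhs[p] += f * rhs[i];
      }
    }
    for (int i = 0; i < nc; ++i) {
      int p = parent[i];
      v[i] = (p < 0) ? rhs[i] / dvec[i]
                     : (rhs[i] + g_axial[i] * v[p]) / dvec[i];
    }

    // soma surrogate: refractory clamp, threshold, reset, spike delivery
    for (int c = 0; c < ncell; ++c) {
      int soma = cell_offset[c];
      if (t_new < refrac_until[c]) {
        v[soma] = v_reset[c];
      } else if (v[soma] >= v_threshold[c]) {
        spike_cell.push_back(c + 1);
        spike_time.push_back(t_new);
        v[soma] = v_reset[c];
        refrac_until[c] = t_new + t_refrac[c];
        const std::vector<int>& os = out_syn[c];
        const std::vector<int>& od = out_del[c];
        for (size_t k = 0; k < os.size(); ++k) {
          int arr = step + 1 + od[k];
          if (arr <= n_steps) pending[arr].push_back(os[k]);
        }
      }
    }

    for (int r = 0; r < nrec; ++r)
      traces(r, step + 1) = v[cell_offset[record_cells[r]]];

    if ((step & 255) == 0) {
      for (int c = 0; c < ncell; ++c)
        if (!std::isfinite(v[cell_offset[c]]))
          stop("non-finite membrane potential at t = %f ms (cell %d)",
               t_new, c + 1);
    }
  }

  List out = List::create(
      _["spike_cell"] = wrap(spike_cell),
      _["spike_time"] = wrap(spike_time),
      _["traces"] = traces);
  if (log_events) {
    out["event_syn"] = wrap(logged_syn);
    out["event_step"] = wrap(logged_step);
  }
  return out;
}
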