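// Fast simulation engine for the plastic spiking reservoir.
//
// One call advances the network over one stimulus segment on a fixed dt
// grid. Per step:
//   1. synaptic currents decay (exponential, exact factors)
//   2. this step's input spikes and the previous step's reservoir spikes
//      are delivered (one-step synaptic delay)
//   3. synaptic traces decay to the current time
//   4. membrane integration (exact exponential leak, piecewise-constant
//      current), optional Gaussian current noise, spike detection, reset,
//      refractoriness, homeostatic threshold increment
//   5. plasticity: power-law STDP on input synapses at post spikes,
//      exponential weight-dependent STDP on E->E synapses at pre/post
//      spikes, then the non-Hebbian decay toward w0 on every E->E weight.
//      All rules read traces BEFORE this step's increments (traces carry
//      strictly-prior spikes).
//   6. traces increment by +1 per spike; theta decays.
//
// The pure-R reference implementation run_segment_r() mirrors this loop
// exactly and is used as the correctness oracle in the test suite.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct SparseGroup {
  int n_pre = 0, n_post = 0, nnz = 0;
  std::vector<int> csr_ptr, post0, pre0, csc_ptr, csc_perm;
  std::vector<double> w, colsum_target;
};

static std::vector<int> as_ivec(SEXP x) {
  IntegerVector v(x);
  return std::vector<int>(v.begin(), v.end());
}
static std::vector<double> as_dvec(SEXP x) {
  NumericVector v(x);
  return std::vector<double>(v.begin(), v.end());
}

static SparseGroup load_group(List g) {
  SparseGroup s;
  s.n_pre = as<int>(g["n_pre"]);
  s.n_post = as<int>(g["n_post"]);
  s.w = as_dvec(g["w"]);
  s.nnz = (int)s.w.size();
  s.csr_ptr = as_ivec(g["csr_ptr"]);
  s.post0 = as_ivec(g["post0"]);
  s.pre0 = as_ivec(g["pre0"]);
  s.csc_ptr = as_ivec(g["csc_ptr"]);
  s.csc_perm = as_ivec(g["csc_perm"]);
  if (g.containsElementNamed("colsum_target"))
    s.colsum_target = as_dvec(g["colsum_target"]);
  return s;
}

// [[Rcpp::export]]
List cpp_run_segment(List state, List g_in, List g_ee, List g_ei,
                     List g_ie, List g_ii, List input, int n_steps,
                     List params, List flags) {
  // ---- unpack -----------------------------------------------------------
  std::vector<double> v = as_dvec(state["v"]);
  std::vector<double> theta = as_dvec(state["theta"]);
  std::vector<double> refrac = as_dvec(state["refrac_remaining"]);
  std::vector<double> ge = as_dvec(state["ge"]);
  std::vector<double> gi = as_dvec(state["gi"]);
  LogicalVector last_in = state["last_spike_flags"];
  std::vector<double> x_pre_in = as_dvec(state["x_pre_in"]);
  std::vector<double> x_pre_fast = as_dvec(state["x_pre_fast"]);
  std::vector<double> x_post = as_dvec(state["x_post"]);

  const int nE = (int)theta.size();
  const int N = (int)v.size();
  const int nI = N - nE;

  SparseGroup in_e = load_group(g_in), e_e = load_group(g_ee),
              e_i = load_group(g_ei), i_e = load_group(g_ie),
              i_i = load_group(g_ii);

  List exc = params["exc"], inh = params["inh"], pl = params["plast"];
  const double dt = as<double>(params["dt"]);
  const double ev_rest = as<double>(exc["v_rest"]),
               ev_reset = as<double>(exc["v_reset"]),
               ev_thr = as<double>(exc["v_thresh"]),
               etau = as<double>(exc["tau_m"]),
               etref = as<double>(exc["t_refrac"]),
               eth_plus = as<double>(exc["theta_plus"]),
               etau_th = as<double>(exc["tau_theta"]);
  const double iv_rest = as<double>(inh["v_rest"]),
               iv_reset = as<double>(inh["v_reset"]),
               iv_thr = as<double>(inh["v_thresh"]),
               itau = as<double>(inh["tau_m"]),
               itref = as<double>(inh["t_refrac"]);
  const double tau_se = as<double>(params["tau_syn_e"]),
               tau_si = as<double>(params["tau_syn_i"]);
  const double gain_in = as<double>(params["gain_in"]),
               gain_ee = as<double>(params["gain_ee"]),
               gain_ei = as<double>(params["gain_ei"]),
               gain_ie = as<double>(params["gain_ie"]),
               gain_ii = as<double>(params["gain_ii"]);

  const double eta_in = as<double>(pl["eta_in"]),
               w_max_in = as<double>(pl["w_max_in"]),
               offset = as<double>(pl["offset"]),
               eta1 = as<double>(pl["eta1"]), eta2 = as<double>(pl["eta2"]),
               w_max_ee = as<double>(pl["w_max_ee"]),
               mu = as<double>(pl["mu"]), w0 = as<double>(pl["w0"]),
               k_decay = as<double>(pl["k_decay"]),
               tau_pre_in = as<double>(pl["tau_pre_in"]),
               tau_pre_fast = as<double>(pl["tau_pre_fast"]),
               tau_post = as<double>(pl["tau_post"]);
  const int decay_stride = pl.containsElementNamed("decay_stride")
                             ? as<int>(pl["decay_stride"]) : 1;

  const bool plastic_in = as<bool>(flags["plastic_in"]);
  const bool plastic_ee = as<bool>(flags["plastic_ee"]);
  const bool eq3_on = as<bool>(flags["eq3_on"]);
  const bool theta_adapt = as<bool>(flags["theta_adapt"]);
  const bool record_raster = as<bool>(flags["record_raster"]);
  const double noise_n0 = as<double>(flags["noise_n0"]);
  const unsigned int seed = (unsigned int)as<double>(flags["seed"]);
  const double v_thr_ref = std::fabs(ev_thr);

  // exact per-step decay factors
  const double d_ge = std::exp(-dt / tau_se), d_gi = std::exp(-dt / tau_si);
  const double em_e = std::exp(-dt / etau), em_i = std::exp(-dt / itau);
  const double ik_e = etau * (1.0 - em_e), ik_i = itau * (1.0 - em_i);
  const double d_xin = std::exp(-dt / tau_pre_in),
               d_xpf = std::exp(-dt / tau_pre_fast),
               d_xpo = std::exp(-dt / tau_post);
  const double d_th = std::exp(-dt / etau_th);

  // input spec
  std::string mode = as<std::string>(input["mode"]);
  std::vector<int> act_chan;
  std::vector<double> act_p;
  std::vector<int> ras_step, ras_chan;
  if (mode == "rates") {
    std::vector<double> rates = as_dvec(input["rates"]);
    if ((int)rates.size() != in_e.n_pre)
      stop("input rate vector length mismatch");
    for (int i = 0; i < (int)rates.size(); ++i) {
      if (!std::isfinite(rates[i]) || rates[i] < 0)
        stop("input rates must be finite and >= 0");
      double p = rates[i] * dt / 1000.0;
      if (p >= 1.0) stop("rate aliasing: rate * dt >= 1");
      if (p > 0) { act_chan.push_back(i); act_p.push_back(p); }
    }
  } else if (mode == "raster") {
    ras_step = as_ivec(input["step0"]);
    ras_chan = as_ivec(input["chan0"]);
  } else stop("unknown input mode");

  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> norm(0.0, 1.0);

  std::vector<int> counts(N, 0);
  std::vector<int> rec_step, rec_id;
  std::vector<int> prev_spikes;  // reservoir ids (0-based) of previous step
  for (int i = 0; i < N; ++i) if (last_in[i]) prev_spikes.push_back(i);

  std::vector<int> in_spk;  in_spk.reserve(64);
  std::vector<int> e_spk;   e_spk.reserve(64);
  std::vector<int> cur_spikes; cur_spikes.reserve(128);
  size_t ras_pos = 0;
  long total_spikes = 0;

  for (int t = 0; t < n_steps; ++t) {
    // 1. current decay
    for (int i = 0; i < N; ++i) { ge[i] *= d_ge; gi[i] *= d_gi; }

    // 2a. input spikes for this step
    in_spk.clear();
    if (mode == "rates") {
      for (size_t a = 0; a < act_chan.size(); ++a)
        if (unif(rng) < act_p[a]) in_spk.push_back(act_chan[a]);
    } else {
      while (ras_pos < ras_step.size() && ras_step[ras_pos] == t)
        in_spk.push_back(ras_chan[ras_pos++]);
    }
    for (int i : in_spk)
      for (int k = in_e.csr_ptr[i]; k < in_e.csr_ptr[i + 1]; ++k)
        ge[in_e.post0[k]] += gain_in * in_e.w[k];

    // 2b. previous step's reservoir spikes
    for (int id : prev_spikes) {
      if (id < nE) {
        for (int k = e_e.csr_ptr[id]; k < e_e.csr_ptr[id + 1]; ++k)
          ge[e_e.post0[k]] += gain_ee * e_e.w[k];
        for (int k = e_i.csr_ptr[id]; k < e_i.csr_ptr[id + 1]; ++k)
          ge[nE + e_i.post0[k]] += gain_ei * e_i.w[k];
      } else {
        int ii = id - nE;
        for (int k = i_e.csr_ptr[ii]; k < i_e.csr_ptr[ii + 1]; ++k)
          gi[i_e.post0[k]] += gain_ie * i_e.w[k];
        for (int k = i_i.csr_ptr[ii]; k < i_i.csr_ptr[ii + 1]; ++k)
          gi[nE + i_i.post0[k]] += gain_ii * i_i.w[k];
      }
    }

    // 3. trace decay (traces now reflect history up to t-1, decayed to t)
    for (int i = 0; i < (int)x_pre_in.size(); ++i) x_pre_in[i] *= d_xin;
    for (int j = 0; j < nE; ++j) { x_pre_fast[j] *= d_xpf; x_post[j] *= d_xpo; }

    // 4. membrane update + spike detection
    cur_spikes.clear(); e_spk.clear();
    for (int i = 0; i < N; ++i) {
      double nz = (noise_n0 > 0) ? noise_n0 * norm(rng) : 0.0;
      if (refrac[i] > 0) { refrac[i] -= dt; continue; }
      bool is_e = i < nE;
      double I = ge[i] - gi[i] + nz;
      double thr, vr, vres, em, ik, tref;
      if (is_e) { thr = ev_thr + theta[i]; vr = ev_rest; vres = ev_reset;
                  em = em_e; ik = ik_e; tref = etref; }
      else { thr = iv_thr; vr = iv_rest; vres = iv_reset;
             em = em_i; ik = ik_i; tref = itref; }
      v[i] = vr + (v[i] - vr) * em + I * ik;
      if (v[i] >= thr) {
        v[i] = vres; refrac[i] = tref;
        cur_spikes.push_back(i);
        if (is_e) {
          e_spk.push_back(i);
          if (theta_adapt) theta[i] += eth_plus;
        }
      }
    }

    // 5. plasticity (reads pre-increment traces)
    if (plastic_in && !e_spk.empty()) {
      for (int j : e_spk) {
        for (int q = in_e.csc_ptr[j]; q < in_e.csc_ptr[j + 1]; ++q) {
          int k = in_e.csc_perm[q];
          double w = in_e.w[k];
          double dw = eta_in * (x_pre_in[in_e.pre0[k]] - offset) *
                      std::pow(w_max_in - w, mu);
          w += dw;
          in_e.w[k] = w < 0 ? 0 : (w > w_max_in ? w_max_in : w);
        }
      }
    }
    if (plastic_ee && !e_spk.empty()) {
      for (int i : e_spk) {  // depression: i as pre
        for (int k = e_e.csr_ptr[i]; k < e_e.csr_ptr[i + 1]; ++k) {
          double w = e_e.w[k];
          double xp = x_post[e_e.post0[k]];
          if (xp > 0 && w > 0) {
            w -= eta1 * xp * std::pow(w, mu);
            e_e.w[k] = w < 0 ? 0 : w;
          }
        }
      }
      for (int j : e_spk) {  // potentiation: j as post
        double xpo = x_post[j];
        if (xpo <= 0) continue;
        for (int q = e_e.csc_ptr[j]; q < e_e.csc_ptr[j + 1]; ++q) {
          int k = e_e.csc_perm[q];
          double xpf = x_pre_fast[e_e.pre0[k]];
          if (xpf <= 0) continue;
          double w = e_e.w[k];
          w += eta2 * xpo * xpf * std::pow(w_max_ee - w, mu);
          e_e.w[k] = w > w_max_ee ? w_max_ee : w;
        }
      }
    }
    if (eq3_on && (t % decay_stride == 0)) {
      double sdt = dt * decay_stride;
      for (int j = 0; j < nE; ++j) {
        double xp = x_post[j];
        if (xp == 0) continue;
        double gamma = k_decay * xp * xp * (1.0 + theta[j] / v_thr_ref);
        double m = gamma * sdt;
        if (m >= 1.0) stop("unstable decay step: gamma * dt >= 1");
        if (m == 0.0) continue;
        for (int q = e_e.csc_ptr[j]; q < e_e.csc_ptr[j + 1]; ++q) {
          int k = e_e.csc_perm[q];
          e_e.w[k] -= m * (e_e.w[k] - w0);
        }
      }
    }

    // 6. trace increments
    for (int i : in_spk) x_pre_in[i] += 1.0;
    for (int j : e_spk) { x_pre_fast[j] += 1.0; x_post[j] += 1.0; }

    // 7. homeostatic threshold decay
    if (theta_adapt)
      for (int j = 0; j < nE; ++j) theta[j] *= d_th;

    // 8. bookkeeping
    for (int id : cur_spikes) {
      ++counts[id]; ++total_spikes;
      if (record_raster) { rec_step.push_back(t); rec_id.push_back(id); }
    }
    prev_spikes = cur_spikes;
  }

  // divisive re-normalization of each excitatory neuron's input-weight
  // budget (once per segment)
  if (plastic_in && !in_e.colsum_target.empty()) {
    for (int j = 0; j < in_e.n_post; ++j) {
      double s = 0;
      for (int q = in_e.csc_ptr[j]; q < in_e.csc_ptr[j + 1]; ++q)
        s += in_e.w[in_e.csc_perm[q]];
      if (s <= 0) continue;
      double f = in_e.colsum_target[j] / s;
      for (int q = in_e.csc_ptr[j]; q < in_e.csc_ptr[j + 1]; ++q) {
        int k = in_e.csc_perm[q];
        double w = in_e.w[k] * f;
        in_e.w[k] = w > w_max_in ? w_max_in : w;
      }
    }
  }

  LogicalVector last_out(N, false);
  for (int id : prev_spikes) last_out[id] = true;

  List st = List::create(
      _["v"] = NumericVector(v.begin(), v.end()),
      _["theta"] = NumericVector(theta.begin(), theta.end()),
      _["refrac_remaining"] = NumericVector(refrac.begin(), refrac.end()),
      _["ge"] = NumericVector(ge.begin(), ge.end()),
      _["gi"] = NumericVector(gi.begin(), gi.end()),
      _["last_spike_flags"] = last_out,
      _["x_pre_in"] = NumericVector(x_pre_in.begin(), x_pre_in.end()),
      _["x_pre_fast"] = NumericVector(x_pre_fast.begin(), x_pre_fast.end()),
      _["x_post"] = NumericVector(x_post.begin(), x_post.end()));

  List out = List::create(
      _["state"] = st,
      _["w_in"] = NumericVector(in_e.w.begin(), in_e.w.end()),
      _["w_ee"] = NumericVector(e_e.w.begin(), e_e.w.end()),
      _["counts"] = IntegerVector(counts.begin(), counts.end()),
      _["total_spikes"] = (double)total_spikes);
  if (record_raster) {
    out["raster_step"] = IntegerVector(rec_step.begin(), rec_step.end());
    out["raster_id"] = IntegerVector(rec_id.begin(), rec_id.end());
  }
  return out;
}
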