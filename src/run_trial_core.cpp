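// Compiled float-backend trial loop. Mirrors the plain-R reference loop
// (run_trial_r) statement for statement, including the order in which
// uniform random draws are consumed, so that both paths produce the same
// trajectories from the same RNG state.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct FilterBank {
  // hist[tap][channel]; tap 0 holds the spike of the previous step.
  std::vector<std::vector<double>> hist;
  std::vector<double> taps;
  std::vector<double> s;
  FilterBank(int n_channels, const std::vector<double>& taps_)
      : hist(taps_.size(), std::vector<double>(n_channels, 0.0)),
        taps(taps_), s(n_channels, 0.0) {}
  void update(const std::vector<int>& spikes) {
    const int n_taps = hist.size(), n = s.size();
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      for (int i = 0; i < n_taps; ++i) acc += hist[i][j] * taps[i];
      s[j] = acc;
    }
    for (int i = n_taps - 1; i > 0; --i) hist[i] = hist[i - 1];
    for (int j = 0; j < n; ++j) hist[0][j] = spikes[j];
  }
};

inline double sigmoid(double v) { return 1.0 / (1.0 + std::exp(-v)); }

inline void bernoulli(std::vector<int>& out, const std::vector<double>& p) {
  for (size_t j = 0; j < out.size(); ++j) {
    out[j] = unif_rand() < p[j] ? 1 : 0;
  }
}

inline void drop_noise(std::vector<int>& spk, double p) {
  for (size_t j = 0; j < spk.size(); ++j) {
    double u = unif_rand();
    if (spk[j] == 1 && u < p) spk[j] = 0;
  }
}

} // namespace

// [[Rcpp::export]]
List run_trial_core(NumericMatrix W0, NumericVector b0, NumericMatrix W1,
                    NumericVector b1, NumericMatrix Y,
                    NumericVector in_prob, NumericVector gE, NumericVector gI,
                    List par, int n_steps, bool train, int t_forward,
                    int delta_t, bool delta_window, double drop_prob,
                    int noise_where, bool record) {
  const int n_in = W0.ncol(), n_hidden = W0.nrow(), n_out = W1.nrow();
  const double phi_max = par["phi_max"], tau_l = par["tau_l"],
               tau_s = par["tau_s"], g_l = par["g_l"], g_b = par["g_b"],
               g_a = par["g_a"], g_d = par["g_d"], E_E = par["E_E"],
               E_I = par["E_I"], V_res = par["V_res"], C_m = par["C_m"],
               dt = par["dt"];
  const int t_target = n_steps - t_forward;

  std::vector<double> taps(10);
  for (int i = 0; i < 10; ++i) {
    double t = i + 1;
    taps[i] = (std::exp(-t / tau_l) - std::exp(-t / tau_s)) / (tau_l - tau_s);
  }
  FilterBank in_bank(n_in, taps), hid_bank(n_hidden, taps),
      out_bank(n_out, taps);

  std::vector<double> V0(n_hidden, V_res), V1(n_out, V_res);
  std::vector<double> phi0(n_hidden), phi1(n_out);
  std::vector<int> in_spk(n_in), hid_spk(n_hidden), out_spk(n_out);
  std::vector<double> p_in(in_prob.begin(), in_prob.end());

  NumericVector counts(n_out);
  // accumulators
  int n_f = 0, n_t = 0;
  NumericVector V0a_f(n_hidden), V0a_t(n_hidden), V0_f(n_hidden),
      x_f(n_in), V1_f(n_out), V1_t(n_out), s0_f(n_hidden);
  std::vector<double> V0b(n_hidden), V0a(n_hidden), V1b(n_out);

  NumericMatrix trV0, trV1;
  IntegerMatrix trIn, trOut;
  if (record) {
    trV0 = NumericMatrix(n_steps, n_hidden);
    trV1 = NumericMatrix(n_steps, n_out);
    trIn = IntegerMatrix(n_steps, n_in);
    trOut = IntegerMatrix(n_steps, n_out);
  }

  for (int t = 1; t <= n_steps; ++t) {
    bernoulli(in_spk, p_in);
    if ((noise_where == 1 || noise_where == 3) && drop_prob > 0)
      drop_noise(in_spk, drop_prob);
    in_bank.update(in_spk);
    const std::vector<double>& x = in_bank.s;

    for (int i = 0; i < n_hidden; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n_in; ++j) acc += W0(i, j) * x[j];
      V0b[i] = acc + b0[i];
      double fb = 0.0;
      for (int j = 0; j < n_out; ++j) fb += Y(i, j) * out_bank.s[j];
      V0a[i] = fb;
      V0[i] += (g_l * (V_res - V0[i]) + g_b * (V0b[i] - V0[i]) +
                g_a * (V0a[i] - V0[i])) / C_m;
      phi0[i] = phi_max * sigmoid(V0[i]) * dt;
    }
    bernoulli(hid_spk, phi0);
    if ((noise_where == 2 || noise_where == 3) && drop_prob > 0)
      drop_noise(hid_spk, drop_prob);
    hid_bank.update(hid_spk);
    const std::vector<double>& s0 = hid_bank.s;

    const bool target_phase = train && t > t_forward;
    for (int i = 0; i < n_out; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n_hidden; ++j) acc += W1(i, j) * s0[j];
      V1b[i] = acc + b1[i];
      double I = 0.0;
      if (target_phase) I = gE[i] * (E_E - V1[i]) + gI[i] * (E_I - V1[i]);
      V1[i] += (g_l * (V_res - V1[i]) + g_d * (V1b[i] - V1[i]) + I) / C_m;
      phi1[i] = phi_max * sigmoid(V1[i]) * dt;
    }
    bernoulli(out_spk, phi1);
    if (noise_where == 2 && drop_prob > 0) drop_noise(out_spk, drop_prob);
    out_bank.update(out_spk);
    for (int i = 0; i < n_out; ++i) counts[i] += out_spk[i];

    if (train) {
      const bool fwd = t <= t_forward;
      const int within = fwd ? t : t - t_forward;
      const int t_phase = fwd ? t_forward : t_target;
      const bool in_window =
          delta_window ? within > t_phase - delta_t : within > delta_t;
      if (in_window) {
        if (fwd) {
          ++n_f;
          for (int i = 0; i < n_hidden; ++i) {
            V0a_f[i] += V0a[i];
            V0_f[i] += V0[i];
            s0_f[i] += s0[i];
          }
          for (int j = 0; j < n_in; ++j) x_f[j] += x[j];
          for (int i = 0; i < n_out; ++i) V1_f[i] += V1[i];
        } else {
          ++n_t;
          for (int i = 0; i < n_hidden; ++i) V0a_t[i] += V0a[i];
          for (int i = 0; i < n_out; ++i) V1_t[i] += V1[i];
        }
      }
    }
    if (record) {
      for (int i = 0; i < n_hidden; ++i) trV0(t - 1, i) = V0[i];
      for (int i = 0; i < n_out; ++i) trV1(t - 1, i) = V1[i];
      for (int j = 0; j < n_in; ++j) trIn(t - 1, j) = in_spk[j];
      for (int i = 0; i < n_out; ++i) trOut(t - 1, i) = out_spk[i];
    }
  }

  List acc = List::create(
      _["n_f"] = n_f, _["n_t"] = n_t, _["V0a_f"] = V0a_f,
      _["V0a_t"] = V0a_t, _["V0_f"] = V0_f, _["x_f"] = x_f,
      _["V1_f"] = V1_f, _["V1_t"] = V1_t, _["s0_f"] = s0_f);
  List out = List::create(_["counts"] = counts, _["acc"] = acc);
  if (record) {
    out["trace"] = List::create(_["V0"] = trV0, _["V1"] = trV1,
                                _["in_spikes"] = trIn,
                                _["out_spikes"] = trOut);
  }
  return out;
}
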