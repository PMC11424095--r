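// Fast path for the 200-cycle trial settling loop.  Mirrors the pure-R
// reference implementation (settle_cycle / run_trial_reference) exactly:
// synchronous net-input computation, tie-tolerant kWTA inhibition,
// sinusoidal oscillation, S-shaped activation with exponential approach,
// running-average traces, and the end-of-trial U-shaped weight update.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct LayerPar {
  int n, k, k_max;
  double kwta_point, target_diff, osc, gain, clamp_gain, threshold;
};

struct ProjPar {
  int s, r;                 // 0-based layer indices
  NumericMatrix W;          // n_s x n_r, shared by both directions
  double fs, fb;            // forward / backward weight scales
  bool learnable;
  double u[5];              // dthr, drev, drev_mag, thrp, dmax_mag
};

double ushape_eval(double kappa, const double* u) {
  const double dthr = u[0], drev = u[1], drev_mag = u[2], thrp = u[3],
               dmax_mag = u[4];
  if (kappa <= dthr) return 0.0;
  if (kappa <= drev) return drev_mag * (kappa - dthr) / (drev - dthr);
  if (kappa <= thrp) return drev_mag * (thrp - kappa) / (thrp - drev);
  return dmax_mag * (kappa - thrp) / (1.0 - thrp);
}

// kWTA with tie tolerance; g_thr is modified (sorted descending).
double kwta_gi(std::vector<double>& g_thr, const LayerPar& L) {
  std::sort(g_thr.begin(), g_thr.end(), std::greater<double>());
  const int n = static_cast<int>(g_thr.size());
  int k_max = std::min(L.k_max, n);
  int k_eff = L.k;
  while (k_eff < k_max && g_thr[L.k - 1] - g_thr[k_eff] <= L.target_diff) {
    ++k_eff;
  }
  // when the whole layer is admitted, the "first loser" value is 0
  const double g_next = (k_eff < n) ? g_thr[k_eff] : 0.0;
  double gi = g_thr[k_eff - 1] - L.kwta_point * (g_thr[k_eff - 1] - g_next);
  return gi > 0.0 ? gi : 0.0;
}

}  // namespace

// [[Rcpp::export]]
List settle_trial_cpp(List layers, List projections, List ext, bool train,
                      int n_cycles, double dt, double lrate, bool record_gi,
                      bool record_act) {
  const int nl = layers.size();
  std::vector<LayerPar> L(nl);
  for (int i = 0; i < nl; ++i) {
    List li = layers[i];
    L[i].n = as<int>(li["n"]);
    L[i].k = as<int>(li["k"]);
    L[i].k_max = as<int>(li["k_max"]);
    L[i].kwta_point = as<double>(li["kwta_point"]);
    L[i].target_diff = as<double>(li["target_diff"]);
    L[i].osc = as<double>(li["osc"]);
    L[i].gain = as<double>(li["gain"]);
    L[i].clamp_gain = as<double>(li["clamp_gain"]);
    L[i].threshold = as<double>(li["threshold"]);
  }

  const int np = projections.size();
  std::vector<ProjPar> P(np);
  for (int i = 0; i < np; ++i) {
    List pi = projections[i];
    P[i].s = as<int>(pi["s"]) - 1;
    P[i].r = as<int>(pi["r"]) - 1;
    P[i].W = as<NumericMatrix>(pi["W"]);
    P[i].fs = as<double>(pi["fs"]);
    P[i].fb = as<double>(pi["fb"]);
    P[i].learnable = as<bool>(pi["learnable"]);
    NumericVector u = pi["u"];
    for (int j = 0; j < 5; ++j) P[i].u[j] = u[j];
  }

  std::vector<NumericVector> extv(nl);
  for (int i = 0; i < nl; ++i) extv[i] = as<NumericVector>(ext[i]);

  // state
  std::vector<std::vector<double> > act(nl), netin(nl), uss(nl), us(nl),
      uraw(nl), umed(nl);
  for (int i = 0; i < nl; ++i) {
    act[i].assign(L[i].n, 0.0);
    netin[i].assign(L[i].n, 0.0);
    uss[i].assign(L[i].n, 0.0);
    us[i].assign(L[i].n, 0.0);
    uraw[i].assign(L[i].n, 0.0);
    umed[i].assign(L[i].n, 0.0);
  }

  NumericMatrix gi_base_log, gi_eff_log;
  std::vector<NumericMatrix> act_log(nl);
  if (record_gi) {
    gi_base_log = NumericMatrix(n_cycles, nl);
    gi_eff_log = NumericMatrix(n_cycles, nl);
  }
  if (record_act) {
    for (int i = 0; i < nl; ++i) act_log[i] = NumericMatrix(n_cycles, L[i].n);
  }

  const int osc_start = 125;
  const double period = 75.0;
  std::vector<double> g_thr;

  for (int cycle = 1; cycle <= n_cycles; ++cycle) {
    // net inputs from previous-cycle activities (synchronous update)
    for (int i = 0; i < nl; ++i) std::fill(netin[i].begin(), netin[i].end(), 0.0);
    for (int p = 0; p < np; ++p) {
      const ProjPar& pp = P[p];
      const int ns = L[pp.s].n, nr = L[pp.r].n;
      const double* W = pp.W.begin();
      // forward: receiver j gets fs * mean_i(W[i,j] * act_s[i])
      // (normalization by sender-layer unit count)
      {
        const double scale = pp.fs / L[pp.s].n;
        const std::vector<double>& a = act[pp.s];
        std::vector<double>& out = netin[pp.r];
        for (int j = 0; j < nr; ++j) {
          double acc = 0.0;
          const double* col = W + static_cast<size_t>(j) * ns;
          for (int i = 0; i < ns; ++i) acc += col[i] * a[i];
          out[j] += scale * acc;
        }
      }
      // backward (skipped for recurrent projections)
      if (pp.s != pp.r) {
        const double scale = pp.fb / L[pp.r].n;
        const std::vector<double>& a = act[pp.r];
        std::vector<double>& out = netin[pp.s];
        for (int j = 0; j < nr; ++j) {
          const double aj = a[j];
          if (aj == 0.0) continue;
          const double* col = W + static_cast<size_t>(j) * ns;
          const double w = scale * aj;
          for (int i = 0; i < ns; ++i) out[i] += w * col[i];
        }
      }
    }
    for (int i = 0; i < nl; ++i) {
      if (L[i].clamp_gain > 0.0 && extv[i].size() == L[i].n) {
        for (int j = 0; j < L[i].n; ++j)
          netin[i][j] += L[i].clamp_gain * extv[i][j];
      }
    }

    // inhibition, activation, traces
    for (int i = 0; i < nl; ++i) {
      const LayerPar& li = L[i];
      g_thr.resize(li.n);
      for (int j = 0; j < li.n; ++j) g_thr[j] = netin[i][j] - li.threshold;
      double gi = kwta_gi(g_thr, li);
      double gi_eff = gi;
      if (train && li.osc > 0.0 && cycle >= osc_start) {
        gi_eff = gi * (1.0 + li.osc * std::sin(2.0 * M_PI *
                                               (cycle - osc_start) / period));
      }
      if (record_gi) {
        gi_base_log(cycle - 1, i) = gi;
        gi_eff_log(cycle - 1, i) = gi_eff;
      }
      for (int j = 0; j < li.n; ++j) {
        double x = netin[i][j] - li.threshold - gi_eff;
        double target = 0.0;
        if (x > 0.0) {
          const double y = li.gain * x;
          target = y / (y + 1.0);
        }
        double a = act[i][j] + dt * (target - act[i][j]);
        act[i][j] = a;
        double ss = uss[i][j] + 0.5 * (a - uss[i][j]);
        double s = us[i][j] + 0.5 * (ss - us[i][j]);
        double raw = uraw[i][j] + 0.1 * (s - uraw[i][j]);
        uss[i][j] = ss;
        us[i][j] = s;
        uraw[i][j] = raw;
        umed[i][j] = 0.9 * raw + 0.1 * s;
        if (record_act) act_log[i](cycle - 1, j) = a;
      }
    }
  }

  // end-of-trial U-shaped weight update (training trials only)
  List w_out(np);
  if (train && lrate > 0.0) {
    for (int p = 0; p < np; ++p) {
      const ProjPar& pp = P[p];
      if (!pp.learnable) {
        w_out[p] = R_NilValue;
        continue;
      }
      const int ns = L[pp.s].n, nr = L[pp.r].n;
      NumericMatrix W = clone(pp.W);
      const std::vector<double>& ms = umed[pp.s];
      const std::vector<double>& mr = umed[pp.r];
      const bool recurrent = (pp.s == pp.r);
      for (int j = 0; j < nr; ++j) {
        for (int i = 0; i < ns; ++i) {
          if (recurrent && i == j) continue;
          const double kappa = ms[i] * mr[j];
          const double dw = lrate * ushape_eval(kappa, pp.u);
          if (dw != 0.0) {
            double w = W(i, j) + dw;
            if (w < 0.0) w = 0.0;
            if (w > 1.0) w = 1.0;
            W(i, j) = w;
          }
        }
      }
      w_out[p] = W;
    }
  }

  List act_out(nl), umed_out(nl);
  for (int i = 0; i < nl; ++i) {
    act_out[i] = NumericVector(act[i].begin(), act[i].end());
    umed_out[i] = NumericVector(umed[i].begin(), umed[i].end());
  }

  List res = List::create(_["act"] = act_out, _["mu_medium"] = umed_out,
                          _["weights"] = w_out);
  if (record_gi) {
    res["gi_base"] = gi_base_log;
    res["gi_eff"] = gi_eff_log;
  }
  if (record_act) {
    List al(nl);
    for (int i = 0; i < nl; ++i) al[i] = act_log[i];
    res["act_history"] = al;
  }
  return res;
}
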