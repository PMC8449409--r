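// Photon-level synthetic confocal smFRET generator and a photon-pair
// correlator. Molecules arrive as a Poisson process, diffuse in 3-D inside
// an absorbing shell (so genuine re-entries into the detection volume
// occur), and emit photons at a rate set by a 3-D Gaussian detection
// profile; donor/acceptor splitting follows the current transfer
// efficiency, which is driven either by a two-state telegraph process or by
// an Ornstein-Uhlenbeck distance coordinate.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
List gen_photons_cpp(double duration_s, double arrival_rate,
                     double brightness_hz, double bg_donor_hz,
                     double bg_acceptor_hz,
                     double w_xy_um, double w_z_um, double shell_um,
                     double D_um2s, double dt_s,
                     int mode,                      // 0 two-state, 1 ou
                     double E1, double E2, double k12, double k21,
                     double ou_mean_nm, double ou_sd_nm, double ou_D_nm2us,
                     double R0_nm, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> t_out; std::vector<int> ch_out, mol_out;
  std::vector<double> truth_out;                    // state (1/2) or r (nm)

  int n_mol = std::poisson_distribution<int>(arrival_rate * duration_s)(rng);
  const double shell2 = shell_um * shell_um;
  const double tau_ou_us = (mode == 1) ? ou_sd_nm * ou_sd_nm / ou_D_nm2us : 0.0;
  const double peq1 = (k12 + k21 > 0) ? k21 / (k12 + k21) : 1.0;
  // far from the focus the detection profile is numerically zero; take
  // coarser diffusion steps there (state/distance processes are advanced
  // with the matching exact per-step kinetics)
  const double far2 = (4.0 * w_xy_um) * (4.0 * w_xy_um);
  const int far_mult = 10;
  double step_sd_c[2], phi_c[2], ou_sd_c[2], p12_c[2], p21_c[2], dt_c[2];
  for (int m2 = 0; m2 < 2; ++m2) {
    double dte = dt_s * (m2 ? far_mult : 1);
    dt_c[m2] = dte;
    step_sd_c[m2] = std::sqrt(2.0 * D_um2s * dte);
    double dte_us = dte * 1e6;
    phi_c[m2] = (mode == 1) ? std::exp(-dte_us / tau_ou_us) : 0.0;
    ou_sd_c[m2] = (mode == 1) ? ou_sd_nm * std::sqrt(1.0 - phi_c[m2]*phi_c[m2]) : 0.0;
    p12_c[m2] = 1.0 - std::exp(-k12 * dte);
    p21_c[m2] = 1.0 - std::exp(-k21 * dte);
  }

  for (int m = 0; m < n_mol; ++m) {
    double t = unif(rng) * duration_s;
    // start uniformly inside the shell
    double x, y, z;
    do {
      x = (2.0*unif(rng) - 1.0) * shell_um;
      y = (2.0*unif(rng) - 1.0) * shell_um;
      z = (2.0*unif(rng) - 1.0) * shell_um;
    } while (x*x + y*y + z*z > shell2);
    int state = (unif(rng) < peq1) ? 1 : 2;
    double r = ou_mean_nm + ou_sd_nm * gauss(rng);

    while (t < duration_s) {
      double rad2 = x*x + y*y + z*z;
      int far = (rad2 > far2) ? 1 : 0;
      if (!far) {
        double E;
        if (mode == 0) {
          E = (state == 1) ? E1 : E2;
        } else {
          double rr = std::max(r, 1e-3);
          E = 1.0 / (1.0 + std::pow(rr / R0_nm, 6.0));
        }
        double inten = brightness_hz *
          std::exp(-2.0*(x*x + y*y)/(w_xy_um*w_xy_um) - 2.0*z*z/(w_z_um*w_z_um));
        int k = std::poisson_distribution<int>(inten * dt_s)(rng);
        for (int p = 0; p < k; ++p) {
          t_out.push_back(t + unif(rng) * dt_s);
          ch_out.push_back(unif(rng) < E ? 1 : 0);
          mol_out.push_back(m + 1);
          truth_out.push_back(mode == 0 ? (double)state : r);
        }
      }
      // advance
      x += step_sd_c[far] * gauss(rng);
      y += step_sd_c[far] * gauss(rng);
      z += step_sd_c[far] * gauss(rng);
      if (mode == 0) {
        if (state == 1) { if (unif(rng) < p12_c[far]) state = 2; }
        else            { if (unif(rng) < p21_c[far]) state = 1; }
      } else {
        r = ou_mean_nm + phi_c[far] * (r - ou_mean_nm) + ou_sd_c[far] * gauss(rng);
      }
      t += dt_c[far];
      if (x*x + y*y + z*z > shell2) break;   // absorbed: molecule replaced
    }
  }

  // background
  for (int c = 0; c < 2; ++c) {
    double rate = (c == 0) ? bg_donor_hz : bg_acceptor_hz;
    int k = std::poisson_distribution<int>(rate * duration_s)(rng);
    for (int p = 0; p < k; ++p) {
      t_out.push_back(unif(rng) * duration_s);
      ch_out.push_back(c);
      mol_out.push_back(0);
      truth_out.push_back(NA_REAL);
    }
  }

  // sort by time
  std::vector<size_t> ord(t_out.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b){ return t_out[a] < t_out[b]; });
  R_xlen_t np = (R_xlen_t)ord.size();
  NumericVector T(np), TR(np); IntegerVector CH(np), MO(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    T[i] = t_out[ord[i]]; CH[i] = ch_out[ord[i]];
    MO[i] = mol_out[ord[i]]; TR[i] = truth_out[ord[i]];
  }
  return List::create(_["time_s"] = T, _["channel"] = CH,
                      _["molecule"] = MO, _["truth"] = TR);
}

// Pair-count correlator: for sorted photon times a, b, counts pairs with
// lag t_b - t_a falling in [edges[k], edges[k+1]).
// [[Rcpp::export]]
NumericVector pair_counts_cpp(NumericVector ta, NumericVector tb,
                              NumericVector edges) {
  int nb = edges.size() - 1;
  NumericVector counts(nb);
  double lo = edges[0], hi = edges[nb];
  R_xlen_t j0 = 0;
  for (R_xlen_t i = 0; i < ta.size(); ++i) {
    double t = ta[i];
    while (j0 < tb.size() && tb[j0] < t + lo) ++j0;
    for (R_xlen_t j = j0; j < tb.size() && tb[j] < t + hi; ++j) {
      double lag = tb[j] - t;
      int k = (int)(std::upper_bound(edges.begin(), edges.end(), lag) -
                    edges.begin()) - 1;
      if (k >= 0 && k < nb) counts[k] += 1.0;
    }
  }
  return counts;
}
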