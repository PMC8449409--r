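// Overdamped (Brownian) dynamics of the one-bead-per-residue HPS model:
// harmonic bonds, Ashbaugh-Hatch short-range potential scaled by the global
// epsilon, Debye-Hueckel electrostatics, optional native-contact wells of
// depth zeta, and harmonic position restraints. A capped steepest-descent
// minimization phase relaxes steric overlaps before dynamics.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List run_langevin_cpp(NumericMatrix pos0,
                      IntegerVector bond_i, IntegerVector bond_j,
                      NumericVector bond_r0, NumericVector bond_k,
                      NumericVector charges, NumericVector lambdas,
                      NumericVector sigmas,
                      IntegerVector nc_i, IntegerVector nc_j,
                      NumericVector nc_r0,
                      double epsilon, double zeta,
                      double kT, double mobility, double noise_D,
                      double debye_length, double dh_pref,
                      double ah_cut, double dh_cut,
                      IntegerVector restr_idx, NumericMatrix restr_ref,
                      double restr_k,
                      double dt, int n_steps, int stride, int seed,
                      int min_steps) {
  const int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i,0); y[i] = pos0(i,1); z[i] = pos0(i,2); }

  // pair classification: 0 = plain nonbonded, -1 = excluded (bonded),
  // k > 0 = native contact k
  std::vector<int> pairclass((size_t)n * n, 0);
  for (int b = 0; b < bond_i.size(); ++b) {
    int i = bond_i[b], j = bond_j[b];
    pairclass[(size_t)i * n + j] = pairclass[(size_t)j * n + i] = -1;
  }
  const double two16 = std::pow(2.0, 1.0/6.0);
  std::vector<double> nc_smin(nc_i.size());
  for (int c = 0; c < nc_i.size(); ++c) {
    nc_smin[c] = nc_r0[c] / two16;
    int i = nc_i[c], j = nc_j[c];
    pairclass[(size_t)i * n + j] = pairclass[(size_t)j * n + i] = c + 1;
  }

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> fx(n), fy(n), fz(n);
  const double maxcut = std::max(ah_cut, dh_cut);
  const double maxcut2 = maxcut * maxcut;

  auto compute_forces = [&]() -> double {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    double energy = 0.0;

    for (int b = 0; b < bond_i.size(); ++b) {
      int i = bond_i[b], j = bond_j[b];
      double dxv = x[j]-x[i], dyv = y[j]-y[i], dzv = z[j]-z[i];
      double r = std::sqrt(dxv*dxv + dyv*dyv + dzv*dzv);
      if (r < 1e-9) r = 1e-9;
      double dr = r - bond_r0[b];
      energy += 0.5 * bond_k[b] * dr * dr;
      double f = -bond_k[b] * dr / r;
      fx[j] += f*dxv; fy[j] += f*dyv; fz[j] += f*dzv;
      fx[i] -= f*dxv; fy[i] -= f*dyv; fz[i] -= f*dzv;
    }

    for (int i = 0; i < n; ++i) {
      for (int j = i+1; j < n; ++j) {
        int pc = pairclass[(size_t)i * n + j];
        if (pc == -1) continue;
        double dxv = x[j]-x[i], dyv = y[j]-y[i], dzv = z[j]-z[i];
        double r2 = dxv*dxv + dyv*dyv + dzv*dzv;
        if (r2 > maxcut2) continue;
        double r = std::sqrt(r2);
        if (r < 1e-6) r = 1e-6;
        double fmag = 0.0;                  // -dU/dr

        if (pc > 0) {
          double s = nc_smin[pc - 1];
          double sr2 = (s/r)*(s/r), sr6 = sr2*sr2*sr2, sr12 = sr6*sr6;
          energy += 4.0 * zeta * (sr12 - sr6);
          fmag += 4.0 * zeta * (12.0*sr12 - 6.0*sr6) / r;
        } else if (epsilon > 0.0 && r < ah_cut) {
          double sij = 0.5 * (sigmas[i] + sigmas[j]);
          double lij = 0.5 * (lambdas[i] + lambdas[j]);
          double sr2 = (sij/r)*(sij/r), sr6 = sr2*sr2*sr2, sr12 = sr6*sr6;
          double ulj = 4.0 * epsilon * (sr12 - sr6);
          double flj = 4.0 * epsilon * (12.0*sr12 - 6.0*sr6) / r;
          if (r <= two16 * sij) {
            energy += ulj + (1.0 - lij) * epsilon;
            fmag += flj;
          } else {
            energy += lij * ulj;
            fmag += lij * flj;
          }
        }
        double qq = charges[i] * charges[j];
        if (qq != 0.0 && r < dh_cut) {
          double ue = dh_pref * qq * std::exp(-r / debye_length) / r;
          energy += ue;
          fmag += ue * (1.0 / r + 1.0 / debye_length);
        }
        if (fmag != 0.0) {
          double f = fmag / r;
          fx[j] += f*dxv; fy[j] += f*dyv; fz[j] += f*dzv;
          fx[i] -= f*dxv; fy[i] -= f*dyv; fz[i] -= f*dzv;
        }
      }
    }

    for (int k = 0; k < restr_idx.size(); ++k) {
      int i = restr_idx[k];
      double dxv = x[i]-restr_ref(k,0), dyv = y[i]-restr_ref(k,1), dzv = z[i]-restr_ref(k,2);
      energy += 0.5 * restr_k * (dxv*dxv + dyv*dyv + dzv*dzv);
      fx[i] -= restr_k * dxv; fy[i] -= restr_k * dyv; fz[i] -= restr_k * dzv;
    }
    return energy;
  };

  // capped steepest-descent minimization (relaxes overlaps)
  const double cap = 0.005;  // nm per minimization step
  for (int s = 0; s < min_steps; ++s) {
    compute_forces();
    for (int i = 0; i < n; ++i) {
      double fn = std::sqrt(fx[i]*fx[i] + fy[i]*fy[i] + fz[i]*fz[i]);
      if (fn < 1e-12) continue;
      double step = std::min(cap, mobility * dt * fn) / fn;
      x[i] += step * fx[i]; y[i] += step * fy[i]; z[i] += step * fz[i];
    }
  }

  const int n_frames = n_steps / stride;
  NumericVector frames((R_xlen_t)n_frames * n * 3);
  NumericVector energies(n_frames), times(n_frames);
  const double drift = mobility * dt;
  const double sig_step = std::sqrt(2.0 * noise_D * dt);
  const double fmax = 1e5;

  for (int step = 1; step <= n_steps; ++step) {
    double energy = compute_forces();
    for (int i = 0; i < n; ++i) {
      double fm = std::max({std::fabs(fx[i]), std::fabs(fy[i]), std::fabs(fz[i])});
      if (fm > fmax)
        stop("force overflow at step %d (bead %d): overlapping beads, minimize or reduce timestep", step, i+1);
      x[i] += drift * fx[i] + sig_step * gauss(rng);
      y[i] += drift * fy[i] + sig_step * gauss(rng);
      z[i] += drift * fz[i] + sig_step * gauss(rng);
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
        stop("NaN position at step %d (frame %d)", step, step / stride);
    }
    if (step % stride == 0) {
      int f = step / stride - 1;
      for (int i = 0; i < n; ++i) {
        frames[f + (R_xlen_t)n_frames * i] = x[i];
        frames[f + (R_xlen_t)n_frames * (n + i)] = y[i];
        frames[f + (R_xlen_t)n_frames * (2*n + i)] = z[i];
      }
      energies[f] = energy;
      times[f] = step * dt;
    }
  }
  frames.attr("dim") = IntegerVector::create(n_frames, n, 3);
  return List::create(_["frames"] = frames, _["energy"] = energies,
                      _["times"] = times);
}
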