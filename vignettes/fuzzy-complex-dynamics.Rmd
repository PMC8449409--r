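---
title: "Quantifying the diffusion of a disordered protein on a folded ligand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the diffusion of a disordered protein on a folded ligand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`fuzzyscape` implements a complete computational pipeline for studying how an
intrinsically disordered protein (IDP) moves on the surface of a folded
binding partner — a "fuzzy" complex in which binding does not quench chain
dynamics. The pipeline has five layers that mirror how such a study is
actually carried out:

1. **Sequence charge analytics** (`compute_charge_metrics`, `swap_charges`,
   `fit_polyampholyte`): net charge, net charge per residue (NCPR), and the
   sequence charge decoration metric (SCD) that links charge patterning to
   chain dimensions.
2. **FRET models** (`mean_efficiency`, `lifetime_ratio`,
   `distribution_from_model`, `infer_distance`): conversions between polymer
   distance distributions and single-molecule FRET observables.
3. **Coarse-grained simulation** (`build_system`, `run_langevin`): a
   one-bead-per-residue heteropolymer with the HPS hydropathy scale,
   Debye–Hückel electrostatics, and tunable crystallographic contacts.
4. **Photon-level analysis** (`burst_search`, `histogram_and_fit`, `recolor`,
   `nsfcs_correlate`, `rasp`, `fit_isotherm`): from raw photon streams to
   micro-to-millisecond interconversion kinetics via recurrence analysis of
   single particles (RASP).
5. **Diffusive landscape** (`pmf_from_distribution`,
   `smoluchowski_propagate`, `fit_diffusion`, `zwanzig_roughness`,
   `fit_temperature`): barrier-less diffusion in a potential of mean force,
   intrachain diffusion coefficients, and energy-landscape roughness.

Seeded synthetic generators (`gen_sequence`, `gen_ou_trajectory`,
`gen_photon_stream`, `gen_toy_complex`) provide ground truth for every layer.

# Models and assumptions

## Sequence metrics

Charges are assigned at pH 7.4: D, E → −1; K, R → +1; histidine neutral;
termini uncharged (the analyzed constructs are internal segments of a longer
chain). The SCD follows the Sawle–Ghosh convention,
$$\mathrm{SCD} = \frac{1}{N}\sum_{i<j} q_i q_j \sqrt{j-i},$$
with $N$ the segment length and pair distance measured in residues. A
screened variant multiplies each pair term by
$\exp(-b\sqrt{j-i}/\kappa^{-1})$, where $b = 0.38$ nm is the per-residue
contour step (shared with the simulator bond length) and $b\sqrt{j-i}$
approximates the root-mean-square pair separation of an ideal chain. Both
variants are exposed; neither is asserted to be the unique "low-salt" form
used elsewhere, and the plain form is the default.

The mean-field polyampholyte salt response is fitted as
$$R(I) = R_0\left[1 + a_{rep} f_{net}^2 \kappa^{-2}(I) -
  a_{att} f_+ f_- \kappa^{-1}(I)\right]^{1/3},$$
a Higgs–Joanny-type competition between Debye-screened net-charge repulsion
($\propto \kappa^{-2}$) and charge-fluctuation attraction
($\propto \kappa^{-1}$). The bracket acts as an effective excluded volume
relative to the baseline distance $R_0$; $a_{rep}$ and $a_{att}$ are the two
fitted amplitudes. The composition factors $f_{net}$ (net charge per
residue) and $f_\pm$ (fractions of charged residues) come from the sequence,
so a chargeless chain is predicted salt-independent and a purely
net-charged one compacts monotonically with ionic strength. Degenerate
compositions fix the corresponding amplitude at zero rather than fitting an
unidentifiable parameter.

## FRET observables

Transfer efficiency follows the Förster relation
$E(r) = [1+(r/R_0)^6]^{-1}$ with a default Förster radius of 5.4 nm for the
Alexa 488/594 pair (configurable). Dye linkers contribute +9 effective
residues of contour (configurable). The ensemble-averaged relative donor
lifetime is reported as
$\tau_{DA}/\tau_D = \langle(1-E)^2\rangle/\langle 1-E\rangle$, which reduces
to $1-\langle E\rangle$ exactly for a single fixed distance; the excess
above that line is the standard signature of distance heterogeneity.

Distance-distribution families: single distance, Gaussian chain
($p \propto r^2 e^{-3r^2/2\langle r^2\rangle}$), a $\nu$-parameterized
self-avoiding family ($p \propto x^{2+\theta}e^{-ax^{\delta}}$ with
$\delta = 1/(1-\nu)$, $\theta = (\gamma-1)/\nu$, $\gamma = 1.1615$), and a
worm-like chain radial closed form
$$p(r) \propto r^2\,(1-(r/L)^2)^{-9/2}
  \exp\!\left[-\frac{3L/4l_p}{1-(r/L)^2}\right],$$
an interpolation formula chosen because its small-$r/L$ limit reproduces the
ideal-chain $\langle r^2\rangle = 2 l_p L$ exactly while diverging smoothly
toward the rod limit. Exact WLC numerics were deliberately not used: the
closed form is reproducible, fast, and the model-family choice dominates the
uncertainty budget anyway.

Quadrature is trapezoidal on a 2000-point grid spanning three times the
relevant length scale; the test suite asserts agreement with a 10× finer
reference grid to 1e-4.

## Coarse-grained simulator

One bead per residue at the Cα position. Short-range interactions use the
Ashbaugh–Hatch form: the Lennard-Jones attraction is scaled by the pair
hydropathy $\lambda_{ij}$ (arithmetic mean of the published, normalized
Kapcha–Rossky per-residue values shipped in `hps_params()`), the repulsion
is preserved, and a single global prefactor $\varepsilon$ (kcal/mol) tunes
overall hydrophobic strength; $\varepsilon = 0.16$ kcal/mol is the default
because that single value reproduces free-chain FRET data in this class of
models. Electrostatics are Debye–Hückel with the Debye length computed from
ionic strength (validity declared up to ~500 mM; the high-salt salting-out
regime is out of scope). Bonds are harmonic, $r_0 = 0.38$ nm,
$k = 1000$ kcal mol⁻¹ nm⁻².

Complexes add crystallographic information: intermolecular residue pairs
with any heavy-atom distance below 4.5 Å in *either* copy of the asymmetric
unit (the union, since all contacts share one strength) become
native-contact wells — Lennard-Jones-shaped, minimum at the crystallographic
Cα distance, depth $\zeta$ (default 0.6 kcal/mol). The folded ligand is held
near-rigid by a stiff internal distance network (pairs within 1.2 nm,
$k = 100$) plus position restraints, rather than frozen coordinates, so
contact kinetics at the interface remain well defined. In `rigid` mode the
crystallographically resolved IDP residues are additionally
position-restrained; `flexible` mode encodes the interface only through the
$\zeta$ wells.

Dynamics are overdamped (Brownian) Euler–Maruyama:
$x \leftarrow x + \mu F \Delta t + \sqrt{2D\Delta t}\,\xi$, with the bead
mobility set by a Stokes diffusivity at 0.38 nm radius and a 10 fs default
step (0.1 ps in the tests, which is stable for these force constants).
Only relative, dimensionless dynamics are interpreted — CG time runs orders
of magnitude faster than atomistic time. A capped steepest-descent
minimization (1000 steps, 0.005 nm cap) precedes dynamics to relax steric
overlaps in built systems. Identical seed and parameters give bit-identical
trajectories. The pair loop is $O(N^2)$ per step; this is adequate for the
chain and toy-complex sizes used here (≤ ~150 beads) and is the main
scalability limitation for full-size complexes.

## Photon tools

Burst search is a sliding-window rate threshold (defaults 1 ms window,
20 kHz, 50 photons — standard diffusing-molecule smFRET practice; the tests
use tighter windows matched to the generator's fast transits). Corrections
are applied in a fixed order (background subtraction, crosstalk, gamma) with
neutral defaults. Histogram fits are maximum-likelihood mixtures of Gaussian
and/or log-normal peaks with BIC model selection. Recoloring redraws each
burst's acceptor count from a binomial at fixed mean efficiency, giving the
shot-noise-limited histogram width.

RASP pairs bursts separated by 100 µs–20 ms: when a molecule leaves the
confocal volume, its chance of returning within a short interval exceeds the
chance of a new molecule arriving, so close-in-time burst pairs predominantly
report on the same molecule. The fraction of second bursts below the split
efficiency (default: the histogram mean) versus delay is fitted with
$F(\Delta) = F_{eq} + (F_0 - F_{eq})e^{-\Delta/\tau}$. A same-molecule
probability per delay bin is estimated from a competing-rates model (Poisson
new-molecule arrivals at the measured burst rate versus a
$(1+\Delta/t_d)^{-3/2}$ diffusion-return kernel) and reported alongside; it
is *not* used to reweight the decay by default, since the return kernel is a
declared operationalization rather than a measured quantity. Two known
biases of the exponential $\tau$ are documented by the tests: burst-duration
averaging (reduced by fast transits) and same-molecule dilution at long
delays (reduced by restricting the fit window); at the packaged generator
conditions the estimator recovers two-state exchange times within 15%.

nsFCS correlations are photon-pair lag histograms normalized by the Poisson
expectation (so $g = 1$ when uncorrelated), with adaptive merging of empty
bins, fitted by a product of selectable exponential terms (antibunching,
distance dynamics, triplet) with multi-start Levenberg–Marquardt. The
binned-lag correlator is checked against a brute-force $O(n^2)$ pair count.

## Diffusive landscape

The potential of mean force is $V(r) = -\ln\max(P(r), 10^{-8})$ in $k_BT$
units, min-shifted to zero; cells at the floor are excluded from dynamics
(the floor avoids infinite walls from sampling zeros). The 1-D Smoluchowski
equation is discretized as nearest-neighbour hopping with rates
$w_{i\to i\pm1} = (D/\Delta r^2)e^{-(V_{nb}-V_i)/2}$, which satisfies
detailed balance by construction and converges to the Boltzmann density.
Time evolution uses the exact eigendecomposition of the symmetrized rate
matrix, so there is no step-size stability limit, probability is conserved
to numerical precision, and relaxation times come directly from the
spectrum; the exponential-fit relaxation time is reported alongside for
comparability with the two fitting styles in common use.

`fit_diffusion` does one-parameter least squares over $D$; because the
entire rate matrix scales linearly with $D$, the predicted decay at any $D$
is the $D = 1$ decay at rescaled delays, which makes the fit cheap and
exactly explains the covariance "doubling all delays halves $D$".

Zwanzig roughness inverts $D = D_0 e^{-\beta^2\sigma^2}$ (Gaussian well
depths, super-Arrhenius) and $D = D_0 e^{-2\beta\sigma}$ (periodic
modulation) at fixed temperature, returning $\sigma$ in $k_BT$:
$\sigma_{gauss} = \sqrt{\ln(D_0/D)}$, $\sigma_{per} = \ln(D_0/D)/2$.
Because the single-temperature inversion is exact, the package provides it
as the default route; a joint fit across temperatures is possible through
`fit_temperature` plus `roughness_to_D` when both $D(T)$ series are
available. Temperature analysis offers a plain Arrhenius regression of
$\ln\tau$ on $1/T$ and a viscosity-corrected variant
$\tau \propto \eta(T)/T\,e^{E_a/k_BT}$ with water viscosity from the Vogel
form $\eta = 2.414\times10^{-5}\,10^{247.8/(T-140)}$ Pa s (accurate to ~1%
over 0–40 °C). Negative fitted activation energies are reported with a
warning, never clipped.

# What the synthetic generators emulate — and what they do not

`gen_photon_stream` models molecules arriving as a Poisson process inside an
absorbing shell at 8 beam waists, diffusing in 3-D, and emitting photons at
a rate set by a 3-D Gaussian detection profile — enough physics to make
recurrences genuine (the RASP premise is checked against generator truth:
within 1 ms a recurring burst is more likely the same molecule than a new
one). Far from the focus, where the detection profile is numerically zero,
diffusion advances with 10× coarser steps; switching and distance kinetics
use the matching exact per-step probabilities, so the coarse stepping does
not distort the emulated kinetics. Defaults (400 molecules/s, 800 kHz peak
brightness, 300 µm²/s, 0.35/1.0 µm waists, 800 Hz background per channel)
were chosen once to give realistic burst rates (~45/s) with transits short
against the slowest emulated kinetics. Not modeled: realistic point-spread
functions, detector afterpulsing and dead time, photophysics beyond Förster
transfer (no quenching, no triplet shelving in the emission process — the
triplet term exists only on the fitting side). Passing tests therefore
demonstrate correctness of the analysis chain on idealized optics, not
robustness to instrument artifacts.

`gen_ou_trajectory` uses the exact OU discretization (not Euler), so its
stationary distribution and autocorrelation are exact at any step size; it
still refuses steps above $\tau/5$ to keep downstream lag analyses sensible.

`gen_toy_complex` builds a spherical scaffold (Fibonacci lattice, 80 beads,
1.6 nm radius) with a 40-residue chain and planted contacts realized on a
periodic schedule, so duty cycles and lifetimes are exact by construction.
Its two-copy PDB fixture resolves residues 1–29 in one copy and 12–40 in the
other (shared fraction 18/40 = 0.45 of the union), emulating the
asymmetric-unit ambiguity of real crystal structures of fuzzy complexes.
The fixture is synthetic: it exercises the real structure-parsing code paths
but does not reproduce any particular deposited structure.

# Problem sizes and numerical choices in the shipped tests

The test suite runs chains of 30–32 beads for 4×10⁵–10⁶ steps (burn-in
halves discarded), a 120-bead toy complex for 6×10⁵ steps, photon streams of
60–300 s, and Smoluchowski grids of 201–641 points. These sizes were chosen
so each statistical assertion has comfortable margin at its stated
tolerance while the whole suite completes on a single CPU in minutes;
they are scientific choices about the smallest systems that exhibit each
property, and the generator parameters themselves are never tuned per-test.

Other numerical choices: contact cutoff 1.0 nm between bead centers (~1.5×
a typical pair diameter); residue classes C = {D,E,K,R},
H = {A,V,L,I,M,F,W,Y}, P = {S,T,N,Q,C,H}, O = {G,P}, shipped as an editable
map because class assignments vary between studies; surface beads defined by
coordination number below 14 within 1.2 nm in the isolated ligand;
reconfiguration times via integrated correlation (integrated to the first
nonpositive point) rather than a single-exponential fit, because the former
is robust for non-exponential decays — both are available.

# Known limitations

* The simulator has no neighbour lists; full-size complexes (≈700 beads,
  microseconds of CG time) are possible but slow.
* The RASP exponential fit inherits a small downward bias from
  burst-duration averaging and an upward bias from same-molecule dilution;
  at the packaged conditions these partially cancel and stay within the
  stated 15%, but other regimes deserve the same bias audit.
* The same-molecule probability model is a declared operationalization, not
  a calibrated detector model.
* The polyampholyte closed form is one member of a family of mean-field
  dialects; its amplitudes are effective parameters, not microscopic ones.
* The packaged tail sequence is a synthetic stand-in constructed from
  published aggregate charge descriptors (length, net charge, segment NCPRs,
  N-terminal charge segregation); analyses that depend on the literal
  residue order of the real protein require the real sequence as input.
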