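# Shared fixtures, built once per test run and cached. All generators are
# seed-deterministic; the heavier simulations are reused across test files.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fx_cache)) assign(name, build(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# reference trapezoid quadrature (independent of the package's internals)
trapz_ref <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# all permutations of a short character vector
combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(combinat_perms(x[-i]), function(p) c(x[i], p)))
  out
}

# two-state photon stream: E = 0.3/0.7, k12 = k21 = 1000 /s (tau = 500 us)
fx_two_state <- function() fx("two_state", function()
  gen_photon_stream("two_state", duration_s = 300, seed = 1,
                    E_states = c(0.3, 0.7), k12_hz = 1000, k21_hz = 1000))

fx_two_state_bursts <- function() fx("ts_bursts", function()
  burst_search(fx_two_state()$stream, window_ms = 0.1, min_rate_khz = 120,
               min_photons = 15))

# diffusive-distance stream driven by an OU coordinate
# (D = 5e-3 nm^2/us, P(r) Gaussian mean 5 nm sd 1.5 nm, tau = 450 us)
fx_diffusive <- function() fx("diffusive", function()
  gen_photon_stream("diffusive", duration_s = 300, seed = 11,
                    ou_mean_nm = 5, ou_sd_nm = 1.5, ou_D_nm2us = 5e-3))

fx_diffusive_bursts <- function() fx("diff_bursts", function()
  burst_search(fx_diffusive()$stream, window_ms = 0.1, min_rate_khz = 120,
               min_photons = 15))

# uncharged ideal chain (epsilon = 0): 32 beads, equilibrated second half
fx_ideal_chain <- function() fx("ideal_chain", function() {
  s <- residue_sequence(strrep("G", 32), name = "ideal32")
  pp <- interaction_params(epsilon = 0, seed = 5, timestep_ps = 0.1)
  tr <- run_langevin(build_system(s, params = pp), pp,
                     n_steps = 1e6, report_every = 500)
  traj_window(tr, 1001, 2000)
})

# toy complex (scripted trajectory + two-copy PDB fixture)
fx_toy <- function() fx("toy", function() {
  pdb <- file.path(tempdir(), "toy_complex.pdb")
  gen_toy_complex(seed = 3, pdb_path = pdb)
})

fx_toy_structure <- function() fx("toy_structure", function()
  read_complex_pdb(fx_toy()$pdb_path, c("A", "C"), c("B", "D")))

# flexible CG complex simulation at the study interaction strengths
# (epsilon = 0.16, zeta = 0.6 kcal/mol), burn-in discarded
fx_flex_traj <- function() fx("flex_traj", function() {
  pp <- interaction_params(epsilon = 0.16, zeta = 0.6, seed = 21,
                           timestep_ps = 0.1)
  sys <- build_system(fx_toy()$idp_seq, fx_toy_structure(), pp,
                      mode = "flexible")
  tr <- run_langevin(sys, pp, n_steps = 6e5, report_every = 600)
  traj_window(tr, 201, 1000)
})

# gaussian-chain pmf on a uniform grid (bound-state-like scales)
fx_gauss_pmf <- function() fx("gauss_pmf", function() {
  r <- seq(0.5, 10.5, length.out = 201)
  P <- distance_distribution(r, dnorm(r, 5, 1.5), normalize = TRUE)
  pmf_from_distribution(P)
})
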