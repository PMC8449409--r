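test_that("Debye length matches the closed form and its scalings", {
  # constants plugged into the closed form at 100 mM, 298 K, eps_r = 80
  expect_equal(debye_length(100, 298, 80), 0.9708, tolerance = 1e-3)
  expect_equal(debye_length(400), debye_length(100) / 2, tolerance = 1e-12)
  expect_lt(debye_length(1e8), 1e-3)
  expect_error(debye_length(-1), "positive")
})

test_that("pair energy reproduces the Ashbaugh-Hatch and screened-Coulomb forms", {
  rmin <- 2^(1 / 6) * 0.6
  # lambda = 0: -eps + eps cancellation at the minimum
  expect_equal(pair_energy(rmin, 0, 0.6, 0.16), 0)
  # lambda = 1: pure Lennard-Jones, depth -eps
  expect_equal(pair_energy(rmin, 1, 0.6, 0.16), -0.16)
  # repulsion preserved regardless of lambda
  expect_gt(pair_energy(0.4, 0, 0.6, 0.16), 0)
  # two +1 charges beyond the LJ range: hand-computed screened Coulomb
  r <- 2.0; kap <- 1.0; epsr <- 80
  hand <- 332.0636 / 10 / epsr * exp(-r / kap) / r
  expect_equal(pair_energy(r, 0, 0.3, 0, q_i = 1, q_j = 1,
                           debye_length_nm = kap, dielectric = epsr),
               hand, tolerance = 1e-10)
})

test_that("system building covers free and complex modes", {
  s <- residue_sequence(strrep("GS", 10))
  sys <- build_system(s, params = interaction_params(seed = 1))
  expect_equal(nrow(sys$topology$positions), 20)
  expect_equal(nrow(sys$topology$bonds), 19)
  expect_equal(nrow(sys$contacts), 0)

  toy <- fx_toy()
  st <- fx_toy_structure()
  pp <- interaction_params(seed = 2)
  flex <- build_system(toy$idp_seq, st, pp, mode = "flexible")
  rig <- build_system(toy$idp_seq, st, pp, mode = "rigid")
  # native contacts are exactly the planted pairs, union over copies
  got <- flex$contacts[order(flex$contacts$idp_resno), ]
  pl <- toy$planted[order(toy$planted$idp_resno), ]
  expect_equal(got$idp_resno, pl$idp_resno)
  expect_equal(got$ligand_resno, pl$scaffold_bead)
  # rigid vs flexible differ only in restraint flags
  expect_equal(rig$contacts, flex$contacts)
  expect_gt(sum(rig$topology$restrained), sum(flex$topology$restrained))
  expect_identical(rig$topology$bonds, flex$topology$bonds)
  expect_error(build_system(toy$idp_seq, mode = "rigid"), "requires")
  # sequence mismatch detection
  wrong <- gen_sequence(40, 0.5, 0.3, "random", seed = 99)
  expect_error(build_system(wrong, st, pp, mode = "flexible"), "mismatch")
})

test_that("shared resolved fraction reflects the constructed two-copy layout", {
  expect_equal(shared_resolved_fraction(fx_toy_structure()),
               fx_toy()$shared_fraction)
  expect_equal(fx_toy()$shared_fraction, 18 / 40)
})

test_that("a free bead obeys the Einstein relation", {
  topo <- bead_topology(matrix(0, 1, 3), "G",
                       data.frame(i = integer(), j = integer(),
                                  r0 = numeric(), k = numeric()))
  pp <- interaction_params(epsilon = 0, seed = 3, timestep_ps = 0.1)
  tr <- run_langevin(topo, pp, n_steps = 1e4, report_every = 1,
                     minimize_steps = 0)
  x <- tr$frames[, 1, ]
  lag <- 10
  msd <- mean(rowSums((x[(lag + 1):nrow(x), ] - x[1:(nrow(x) - lag), ])^2))
  expect_equal(msd / (6 * lag * 0.1), pp$bead_D_nm2ps, tolerance = 0.05)
})

test_that("a harmonic dimer samples the Boltzmann bond-length distribution", {
  topo <- bead_topology(matrix(c(0, 0, 0, 0.38, 0, 0), 2, 3, byrow = TRUE),
                        c("G", "G"), data.frame(i = 1L, j = 2L, r0 = 0.38,
                                                k = 100))
  pp <- interaction_params(epsilon = 0, seed = 11, timestep_ps = 0.1)
  tr <- run_langevin(topo, pp, n_steps = 4e5, report_every = 40)
  r <- sqrt(rowSums((tr$frames[, 1, ] - tr$frames[, 2, ])^2))
  kT <- 0.0019872 * 297
  rg <- seq(0.01, 1.5, length.out = 3000)
  pdf <- rg^2 * exp(-100 * (rg - 0.38)^2 / (2 * kT))
  cdf <- cumsum(pdf) / sum(pdf)
  ks <- ks.test(r, function(q) approx(rg, cdf, q, rule = 2)$y)
  expect_gt(ks$p.value, 0.01)
})

test_that("zero-temperature dynamics from a minimum are static", {
  topo <- bead_topology(matrix(c(0, 0, 0, 0.38, 0, 0), 2, 3, byrow = TRUE),
                        c("G", "G"), data.frame(i = 1L, j = 2L, r0 = 0.38,
                                                k = 100))
  pp <- interaction_params(epsilon = 0, temperature_K = 0, seed = 1,
                           timestep_ps = 0.1)
  tr <- run_langevin(topo, pp, n_steps = 1000, report_every = 100,
                     minimize_steps = 0)
  expect_equal(max(abs(tr$frames[10, , ] - tr$frames[1, , ])), 0)
})

test_that("identical seeds give bit-identical trajectories, different seeds differ", {
  s <- residue_sequence(strrep("GE", 8))
  pp <- interaction_params(seed = 17, timestep_ps = 0.1)
  t1 <- run_langevin(build_system(s, params = pp), pp, n_steps = 5e3,
                     report_every = 50)
  t2 <- run_langevin(build_system(s, params = pp), pp, n_steps = 5e3,
                     report_every = 50)
  expect_identical(t1$frames, t2$frames)
  pp3 <- interaction_params(seed = 18, timestep_ps = 0.1)
  t3 <- run_langevin(build_system(s, params = pp), pp3, n_steps = 5e3,
                     report_every = 50)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("uncharged chain at epsilon = 0 shows ideal-chain statistics", {
  tr <- fx_ideal_chain()
  sm <- scaling_map(tr)
  n <- nrow(sm$nu)
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  # nu ~ 0.5 and <R_ij^2> ~ b^2 |i-j| within 10% at long separation
  expect_equal(mean(sm$nu[sep >= 10]), 0.5, tolerance = 0.1)
  ratio <- exp(2 * sm$nu[sep >= 10] * log(sep[sep >= 10])) / sep[sep >= 10]
  expect_equal(mean(ratio), 1, tolerance = 0.1)
  expect_equal(sm$nu, t(sm$nu))
})

test_that("chain size responds to hydrophobic strength and charge screening", {
  seqr <- gen_sequence(30, 0.1, 0.1, "random", seed = 2)
  rg_eps <- vapply(c(0.05, 0.2, 0.4, 0.7, 1.0), function(eps) {
    pp <- interaction_params(epsilon = eps, seed = 9, timestep_ps = 0.1)
    tr <- run_langevin(build_system(seqr, params = pp), pp,
                       n_steps = 4e5, report_every = 400)
    mean(radius_of_gyration(traj_window(tr, 301, 1000)))
  }, numeric(1))
  expect_true(all(diff(rg_eps) < 0))
  # net-negative chain expands as the Debye length grows (lower salt)
  seqn <- gen_sequence(30, 0.0, 0.3, "random", seed = 4)
  rg_salt <- vapply(c(500, 300, 150, 60, 20), function(I) {
    pp <- interaction_params(epsilon = 0.16, ionic_strength_mM = I,
                             seed = 13, timestep_ps = 0.1)
    tr <- run_langevin(build_system(seqn, params = pp), pp,
                       n_steps = 4e5, report_every = 400)
    mean(radius_of_gyration(traj_window(tr, 301, 1000)))
  }, numeric(1))
  # sign test over all ordered salt pairs: expansion with Debye length
  pairs <- outer(rg_salt, rg_salt, `-`)[lower.tri(matrix(0, 5, 5))]
  expect_gte(mean(pairs > 0), 0.8)
  expect_gt(rg_salt[5], rg_salt[1] * 1.03)
})

test_that("trajectory text round trip preserves frames", {
  tr <- traj_window(fx_ideal_chain(), 1, 11)
  path <- file.path(tempdir(), "traj.xyz")
  write_trajectory_xyz(tr, path)
  back <- read_trajectory_xyz(path)
  expect_equal(back$frames, tr$frames, tolerance = 1e-5)
  expect_equal(back$times_ns, tr$times_ns, tolerance = 1e-9)
})
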