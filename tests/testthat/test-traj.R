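test_that("distance dynamics recover OU ground truth", {
  # two-bead trajectory whose distance is an exact OU process
  ou <- gen_ou_trajectory(D_nm2us = 0.02, mean_nm = 5, sd_nm = 1,
                          dt_us = 2, n = 1e5, seed = 7)
  n <- length(ou$r_nm)
  frames <- array(0, c(n, 2, 3))
  frames[, 2, 1] <- ou$r_nm
  topo <- bead_topology(frames[1, , ], c("G", "G"),
                        data.frame(i = 1L, j = 2L, r0 = 5, k = 1))
  tr <- cg_trajectory(frames, ou$t_us * 1000, topo)   # us -> ns
  dyn <- distance_dynamics(tr, 1, 2)
  tau_true_ns <- ou$truth$tau_us * 1000
  expect_equal(dyn$tau_r_ns, tau_true_ns, tolerance = 0.1)
  # D = var/tau mapping recovers the generator diffusion coefficient
  expect_equal(dyn$D_nm2us, 0.02, tolerance = 0.1)
  # empirical P(r) integrates to 1 and matches generator variance within 5%
  expect_equal(trapz_ref(dyn$distribution$r, dyn$distribution$p), 1,
               tolerance = 1e-6)
  expect_equal(dyn$var_nm2, 1, tolerance = 0.05)
  # shuffled frames decorrelate
  set.seed(1)
  tr_sh <- cg_trajectory(frames[sample(n), , , drop = FALSE],
                         ou$t_us * 1000, topo)
  dyn_sh <- distance_dynamics(tr_sh, 1, 2)
  expect_lt(max(abs(dyn_sh$C$corr[-1])), 0.05)
})

test_that("contact statistics recover planted duty cycles and lifetimes", {
  toy <- fx_toy()
  cs <- contact_stats(toy$trajectory)
  pl <- toy$planted
  for (k in seq_len(nrow(pl))) {
    expect_equal(cs$probability[pl$scaffold_bead[k], pl$idp_resno[k]],
                 pl$duty_cycle[k], tolerance = 0.02 / pl$duty_cycle[k])
    # scheduled on-run length (frames * dt) is the mean lifetime
    expect_equal(cs$mean_lifetime_ns[pl$scaffold_bead[k], pl$idp_resno[k]],
                 pl$lifetime_frames[k], tolerance = 0.15)
  }
  expect_equal(sum(cs$type_histogram), 1)
  expect_true(all(cs$probability >= 0 & cs$probability <= 1))
  # frozen complex: probabilities are exactly 0/1 and match geometry
  frozen <- cg_trajectory(toy$trajectory$frames[rep(1, 3), , , drop = FALSE],
                          0:2, toy$topology)
  csf <- contact_stats(frozen)
  expect_true(all(csf$probability %in% c(0, 1)))
  P1 <- toy$trajectory$frames[1, , ]
  li <- which(toy$topology$groups == "ligand")
  ii <- which(toy$topology$groups == "idp")
  d2 <- outer(P1[li, 1], P1[ii, 1], `-`)^2 +
    outer(P1[li, 2], P1[ii, 2], `-`)^2 + outer(P1[li, 3], P1[ii, 3], `-`)^2
  expect_equal(csf$probability, (d2 < 1) * 1)
  # single-chain trajectory rejected
  expect_error(contact_stats(fx_ideal_chain()), "two-group")
})

test_that("center-of-mass distributions behave under constructed geometries", {
  toy <- fx_toy()
  cd <- com_distribution(toy$trajectory, segment = c(30, 36))
  expect_equal(trapz_ref(cd$angular$deg, cd$angular$density) +
                 mean(diff(cd$angular$deg)) *
                 (cd$angular$density[1] + tail(cd$angular$density, 1)) / 2,
               1, tolerance = 0.05)
  # synthetic uniform ring: flat angular histogram by chi-squared test
  nfr <- 3600
  frames <- array(0, c(nfr, 3, 3))
  ang <- runif(nfr, -pi, pi)
  set.seed(4); ang <- runif(nfr, -pi, pi)
  frames[, 1, ] <- matrix(c(0, 0, -2), nfr, 3, byrow = TRUE)
  frames[, 2, ] <- matrix(c(0, 0, 2), nfr, 3, byrow = TRUE)
  frames[, 3, 1] <- 3 * cos(ang); frames[, 3, 2] <- 3 * sin(ang)
  topo <- bead_topology(frames[1, , ], c("G", "G", "G"),
                        data.frame(i = integer(), j = integer(),
                                   r0 = numeric(), k = numeric()),
                        groups = c("ligand", "ligand", "idp"))
  tr <- cg_trajectory(frames, seq_len(nfr) - 1, topo)
  cd2 <- com_distribution(tr, segment = c(1, 1),
                          axis_beads = list(from = 1L, to = 2L), n_bins = 12)
  counts <- cd2$angular$density * sum(!is.na(cd2$samples$deg))
  cnt <- table(cut(cd2$samples$deg, seq(-180, 180, length.out = 13)))
  expect_gt(chisq.test(cnt)$p.value, 0.01)
  # rigid rotation about the axis shifts azimuth, leaves axial unchanged
  th <- 60 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  frames_rot <- frames
  for (f in 1:nfr) frames_rot[f, , ] <- frames[f, , ] %*% t(Rz)
  cd3 <- com_distribution(cg_trajectory(frames_rot, seq_len(nfr) - 1, topo),
                          segment = c(1, 1),
                          axis_beads = list(from = 1L, to = 2L), n_bins = 12)
  shift <- (cd3$samples$deg - cd2$samples$deg) %% 360
  expect_lt(diff(range(shift)), 1e-6)
  expect_equal(cd3$samples$nm, cd2$samples$nm, tolerance = 1e-9)
  # segment pinned on the axis: angular flagged undefined, axial a point mass
  frames_axis <- frames
  frames_axis[, 3, ] <- matrix(c(0, 0, 1), nfr, 3, byrow = TRUE)
  cd4 <- com_distribution(cg_trajectory(frames_axis, seq_len(nfr) - 1, topo),
                          segment = c(1, 1),
                          axis_beads = list(from = 1L, to = 2L))
  expect_true(cd4$angular_undefined)
  expect_lt(var(cd4$samples$nm), 1e-12)
})

test_that("surface coverage has the static-geometry and monotonicity properties", {
  toy <- fx_toy()
  # scripted chain hovers away from the surface except planted contacts:
  # with an empty contact list the coverage is zero
  empty <- gen_toy_complex(seed = 5, contacts = data.frame(
    idp_resno = integer(), duty_cycle = numeric(),
    lifetime_frames = integer()), n_frames = 200)
  expect_equal(surface_coverage(empty$trajectory)$coverage, 0)
  # frozen pose: coverage equals the brute-force static interface fraction
  frozen <- cg_trajectory(toy$trajectory$frames[rep(1, 2), , , drop = FALSE],
                          0:1, toy$topology)
  sc <- surface_coverage(frozen)
  P1 <- toy$trajectory$frames[1, , ]
  li <- which(toy$topology$groups == "ligand")
  ii <- which(toy$topology$groups == "idp")
  d2 <- outer(P1[li, 1], P1[ii, 1], `-`)^2 +
    outer(P1[li, 2], P1[ii, 2], `-`)^2 + outer(P1[li, 3], P1[ii, 3], `-`)^2
  expect_equal(sc$coverage, mean(apply(d2, 1, min) < 1))
  # coverage non-decreasing with trajectory length
  c_half <- surface_coverage(traj_window(toy$trajectory, 1, 500))$coverage
  c_full <- surface_coverage(toy$trajectory)$coverage
  expect_gte(c_full, c_half)
})

test_that("scaling map demands sufficient sampling", {
  short <- traj_window(fx_ideal_chain(), 1, 50)
  expect_error(scaling_map(short), "insufficient frames")
})
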