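test_that("burst search finds planted spikes and respects rate bounds", {
  expect_equal(nrow(burst_search(photon_stream(numeric(0), character(0)))), 0)
  # uniform background at half the rate threshold: no bursts
  set.seed(2)
  bg <- photon_stream(sort(runif(5000, 0, 1)),
                      sample(c("donor", "acceptor"), 5000, TRUE))
  expect_equal(nrow(burst_search(bg, window_ms = 1, min_rate_khz = 10,
                                 min_photons = 20)), 0)
  # one planted 80-photon spike over sparse background
  set.seed(3)
  spike <- sort(runif(80, 0.50, 0.5008))
  bgt <- sort(runif(200, 0, 1))
  st <- photon_stream(sort(c(spike, bgt)),
                      rep("donor", 280))
  b <- burst_search(st, window_ms = 1, min_rate_khz = 20, min_photons = 40)
  expect_equal(nrow(b), 1)
  expect_gte(b$n_total, 0.95 * 80)
})

test_that("burst efficiencies and corrections behave", {
  b <- fx_two_state_bursts()
  expect_true(all(b$E >= 0 & b$E <= 1))
  expect_gt(nrow(b), 1000)
  # gamma correction shifts E down for gamma > 1
  md <- fx_two_state()$stream$metadata
  s2 <- photon_stream(fx_two_state()$stream$time_s,
                      fx_two_state()$stream$channel,
                      list(gamma = 2))
  b2 <- burst_search(s2, window_ms = 0.1, min_rate_khz = 120,
                     min_photons = 15)
  expect_lt(mean(b2$E), mean(b$E))
})

test_that("histogram mixture fitting separates populations and selects model order", {
  # slow switching: states static within bursts, two resolvable peaks
  g <- gen_photon_stream("two_state", duration_s = 60, seed = 9,
                         E_states = c(0.3, 0.7), k12_hz = 20, k21_hz = 20)
  b <- burst_search(g$stream, window_ms = 0.1, min_rate_khz = 120,
                    min_photons = 20)
  hf <- histogram_and_fit(b)
  expect_equal(hf$n_components, 2L)
  expect_equal(hf$means, c(0.3, 0.7), tolerance = 0.05)
  expect_equal(hf$area_fractions, c(0.5, 0.5), tolerance = 0.1)
  expect_equal(sum(hf$area_fractions), 1, tolerance = 1e-9)
  # single-state data: one component preferred by BIC
  g1 <- gen_photon_stream("two_state", duration_s = 20, seed = 10,
                          E_states = c(0.45, 0.45))
  b1 <- burst_search(g1$stream, window_ms = 0.1, min_rate_khz = 120,
                     min_photons = 20)
  expect_equal(histogram_and_fit(b1)$n_components, 1L)
})

test_that("recoloring gives the binomial shot-noise limit", {
  b <- fx_two_state_bursts()
  b <- b[seq_len(min(nrow(b), 1e4)), ]
  expect_error(recolor(b, 1.2), "mean_E")
  expect_true(all(recolor(b, 1, seed = 1) == 1))
  rc <- recolor(b, 0.5, seed = 2)
  expect_equal(var(rc), mean(0.25 / b$n_total), tolerance = 0.05)
  # dynamic data: observed histogram broader than the shot-noise limit
  rc_mean <- recolor(b, mean(b$E), seed = 3)
  expect_gt(sd(b$E), sd(rc_mean))
})

test_that("isotherm fitting recovers a known affinity", {
  set.seed(2)
  conc <- c(0.5, 1, 2, 4, 8, 16, 50, 200)
  f <- pmin(conc / (conc + 4) * (1 + rnorm(8, 0, 0.05)), 1)
  it <- fit_isotherm(conc, f)
  expect_equal(it$KD_nM, 4, tolerance = 0.25)
  # half-saturation identity of the fitted curve
  expect_equal(it$KD_nM / (it$KD_nM + it$KD_nM), 0.5)
  expect_error(fit_isotherm(c(1, 2, 4), c(0.2, 0.3, 0.5)), "4 concentrations")
  expect_error(fit_isotherm(c(1, 2, 4, 8), c(0.01, 0.02, 0.03, 0.05)),
               "transition")
})

test_that("photon correlator matches the brute-force pair count and Poisson limit", {
  set.seed(1)
  ta <- sort(runif(500, 0, 1)); tb <- sort(runif(400, 0, 1))
  e <- seq(0, 0.01, length.out = 11)
  expect_equal(as.numeric(fuzzyscape:::pair_counts_cpp(ta, tb, e)),
               pair_counts_direct(ta, tb, e))
  # Poisson stream: flat g within sampling error
  set.seed(5)
  tp <- sort(runif(2e5, 0, 10))
  ps <- photon_stream(tp, sample(c("donor", "acceptor"), 2e5, TRUE))
  ns <- nsfcs_correlate(ps, c("donor", "acceptor"),
                        lag_range_s = c(5e-7, 8e-5), n_bins = 20,
                        fit_terms = NULL)
  expect_lt(max(abs(ns$curve$g - 1)), 0.05)
})

test_that("nsFCS fits recover telegraph kinetics and the anticorrelation sign", {
  g <- gen_photon_stream("two_state", duration_s = 60, seed = 5,
                         E_states = c(0.1, 0.9), k12_hz = 5e4, k21_hz = 5e4,
                         bg_donor_hz = 0, bg_acceptor_hz = 0)
  ns <- nsfcs_correlate(g$stream, c("acceptor", "acceptor"),
                        lag_range_s = c(5e-7, 1.5e-5), n_bins = 20)
  expect_equal(ns$fit[["tau_cd"]], 1e-5, tolerance = 0.15)
  expect_gt(ns$fit[["c_cd"]], 0)       # bunching in the autocorrelation
  # distance dynamics in the lag window: donor-acceptor cross-correlation
  # is anticorrelated (OU relaxation ~10 us)
  gd <- gen_photon_stream("diffusive", duration_s = 60, seed = 6,
                          ou_mean_nm = 5.4, ou_sd_nm = 1.2,
                          ou_D_nm2us = 0.15,
                          bg_donor_hz = 0, bg_acceptor_hz = 0)
  ns2 <- nsfcs_correlate(gd$stream, c("donor", "acceptor"),
                         lag_range_s = c(5e-7, 2.5e-5), n_bins = 25)
  expect_lt(ns2$fit[["c_cd"]], 0)
})

test_that("RASP recovers two-state exchange times across rates", {
  b <- fx_two_state_bursts()
  r <- rasp(b, initial_E_window = c(0.65, 1), split_E = 0.5,
            delay_window = c(1e-4, 1e-2), n_bins = 14, min_pairs_bin = 40)
  expect_false(r$tau_unconstrained)
  expect_equal(r$tau_s, 5e-4, tolerance = 0.15)
  expect_true(all(r$decay$p_same >= 0 & r$decay$p_same <= 1))
  expect_true(all(diff(r$decay$p_same) < 0))
  # a second switching rate (tau = 250 us)
  g2 <- gen_photon_stream("two_state", duration_s = 150, seed = 7,
                          E_states = c(0.3, 0.7), k12_hz = 2000,
                          k21_hz = 2000)
  b2 <- burst_search(g2$stream, window_ms = 0.1, min_rate_khz = 120,
                     min_photons = 15)
  r2 <- rasp(b2, initial_E_window = c(0.65, 1), split_E = 0.5,
             delay_window = c(1e-4, 3e-3), n_bins = 14, min_pairs_bin = 40)
  expect_equal(r2$tau_s, 2.5e-4, tolerance = 0.25)
  # static single-state stream: flat decay flagged unconstrained
  g0 <- gen_photon_stream("two_state", duration_s = 120, seed = 8,
                          E_states = c(0.5, 0.5))
  b0 <- burst_search(g0$stream, window_ms = 0.1, min_rate_khz = 120,
                     min_photons = 15)
  r0 <- rasp(b0, initial_E_window = c(0.5, 1), split_E = 0.5,
             delay_window = c(1e-4, 1e-2), n_bins = 10)
  expect_true(r0$tau_unconstrained)
})
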