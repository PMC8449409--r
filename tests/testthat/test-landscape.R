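test_that("potential of mean force inverts the distribution and handles floors", {
  r <- seq(0, 10, length.out = 401)
  # uniform density: flat potential
  Pu <- distance_distribution(r, rep(1 / 10, 401))
  expect_lt(max(pmf_from_distribution(Pu)$V), 1e-12)
  # gaussian density: quadratic potential with curvature 1/s^2
  s <- 1.2
  Pg <- distance_distribution(r, dnorm(r, 5, s), normalize = TRUE)
  V <- pmf_from_distribution(Pg)
  mid <- abs(V$r - 5) < 2
  fit <- lm(V$V[mid] ~ I((V$r[mid] - 5)^2))
  expect_equal(unname(coef(fit)[2]), 1 / (2 * s^2), tolerance = 0.01)
  # round trip through exp(-V)
  back <- exp(-V$V[V$active])
  back <- back / trapz_ref(V$r[V$active], back)
  expect_equal(back, Pg$p[V$active] / trapz_ref(V$r[V$active],
                                                Pg$p[V$active]),
               tolerance = 1e-6)
  expect_error(pmf_from_distribution(
    distance_distribution(r, rep(1e-12, 401), normalize = FALSE)), "mass")
})

test_that("Smoluchowski solver matches the OU relaxation and conserves mass", {
  # harmonic well V = x^2/(2 a^2): slowest relaxation a^2/D
  x <- seq(0, 10, length.out = 321)
  P <- distance_distribution(x, dnorm(x, 5, 1), normalize = TRUE)
  V <- pmf_from_distribution(P, floor = 1e-12)
  sol <- smoluchowski_propagate(V, 1, pmf_equilibrium(V),
                                times = c(0.1, 0.5, 1, 5))
  expect_equal(sol$relaxation_times[1], 1, tolerance = 0.01)
  expect_lt(max(sol$mass_drift), 1e-10)
  # equilibrium initial condition is stationary
  drift <- max(abs(sol$densities[, 4] - sol$equilibrium))
  expect_lt(drift, 1e-8)
  # convergence to Boltzmann from a localized start, for random potentials
  set.seed(6)
  for (i in 1:5) {
    Vr <- V
    bump <- 0.8 * sin(seq(0, 3 * pi, length.out = length(x)) + runif(1) * pi)
    Vr$V <- V$V + bump - min(V$V + bump)
    p0 <- numeric(length(x)); p0[150:170] <- 1
    p0 <- p0 / trapz_ref(x, p0)
    so <- smoluchowski_propagate(Vr, 1, p0, times = c(50))
    expect_equal(so$densities[Vr$active, 1],
                 so$equilibrium[Vr$active], tolerance = 1e-6)
  }
  # grid refinement: halving the spacing moves the slowest time < 1%
  x2 <- seq(0, 10, length.out = 641)
  P2 <- distance_distribution(x2, dnorm(x2, 5, 1), normalize = TRUE)
  V2 <- pmf_from_distribution(P2, floor = 1e-12)
  sol2 <- smoluchowski_propagate(V2, 1, pmf_equilibrium(V2), times = 1)
  expect_equal(sol2$relaxation_times[1], sol$relaxation_times[1],
               tolerance = 0.01)
})

test_that("predicted recurrence decays follow the eigenmode structure", {
  V <- fx_gauss_pmf()
  R0 <- 5.4
  # full-range initial window: flat decay at the equilibrium fraction
  delays <- c(1, 10, 100, 1000)
  full <- predict_rasp(V, 0.0095, R0, c(0, 1), 0.5, delays)
  eqf <- attr(full, "equilibrium_fraction_low")
  expect_lt(diff(range(full$fraction_low)), 1e-9)
  expect_equal(full$fraction_low[1], eqf, tolerance = 1e-9)
  # harmonic well: once the fast modes have died, the decay is single-
  # exponential with the slowest eigen time
  pr0 <- predict_rasp(V, 0.0095, R0, c(0.6, 1), 0.5, c(1, 4000))
  tau1 <- attr(pr0, "relaxation_times")[1]
  dl <- exp(seq(log(0.8 * tau1), log(8 * tau1), length.out = 10))
  pr <- predict_rasp(V, 0.0095, R0, c(0.6, 1), 0.5, dl)
  df <- data.frame(t = dl, f = pr$fraction_low)
  fo <- minpack.lm::nlsLM(f ~ A + B * exp(-t / tau),
                          start = list(A = tail(df$f, 1), B = -0.3,
                                       tau = tau1), data = df)
  expect_equal(coef(fo)[["tau"]], tau1, tolerance = 0.05)
  # long-time limit equals the equilibrium low-E mass
  expect_equal(tail(pr0$fraction_low, 1),
               attr(pr0, "equilibrium_fraction_low"), tolerance = 1e-3)
})

test_that("diffusion-coefficient fitting is self-consistent and scales correctly", {
  V <- fx_gauss_pmf()
  delays <- exp(seq(log(20), log(5000), length.out = 12))
  pr <- predict_rasp(V, 0.0095, 5.4, c(0.6, 1), 0.5, delays)
  fit <- fit_diffusion(delays, pr$fraction_low, V, 5.4, c(0.6, 1), 0.5)
  expect_equal(fit$D, 0.0095, tolerance = 0.02)
  # doubling all delays halves the fitted D
  fit2 <- fit_diffusion(delays * 2, pr$fraction_low, V, 5.4, c(0.6, 1), 0.5)
  expect_equal(fit2$D / fit$D, 0.5, tolerance = 1e-3)
  expect_error(fit_diffusion(delays, rep(0.4, 12), V, 5.4, c(0.6, 1), 0.5),
               "flat")
})

test_that("photon-level pipeline recovers the generator diffusion coefficient", {
  b <- fx_diffusive_bursts()
  split_E <- mean(b$E)
  r <- rasp(b, initial_E_window = c(split_E, 1), split_E = split_E,
            delay_window = c(1e-4, 5e-3), n_bins = 10, min_pairs_bin = 40)
  V <- fx_gauss_pmf()
  fit <- fit_diffusion(r$decay$delay_s * 1e6, r$decay$fraction_low, V, 5.4,
                       c(split_E, 1), split_E)
  expect_equal(fit$D, 5e-3, tolerance = 0.2)
})

test_that("Zwanzig roughness closed forms and round trips", {
  z <- zwanzig_roughness(D = 9.5e-3, D0 = 42)
  expect_equal(z$sigma_gaussian, sqrt(log(42 / 9.5e-3)), tolerance = 1e-12)
  expect_equal(z$sigma_gaussian, 2.90, tolerance = 0.01)
  expect_equal(z$sigma_periodic, log(42 / 9.5e-3) / 2, tolerance = 1e-12)
  expect_equal(z$sigma_periodic, 4.20, tolerance = 0.01)
  z0 <- zwanzig_roughness(D = 3, D0 = 3)
  expect_equal(z0$sigma_gaussian, 0)
  expect_equal(z0$sigma_periodic, 0)
  expect_error(zwanzig_roughness(5, 3), "undefined")
  # exact inversion
  expect_equal(roughness_to_D(z$sigma_gaussian, 42, "gaussian"), 9.5e-3)
  expect_equal(roughness_to_D(z$sigma_periodic, 42, "periodic"), 9.5e-3)
})

test_that("temperature models reproduce hand-computed activation energies", {
  # tau doubling from 296 K to 278 K: Ea = R ln2 / (1/278 - 1/296)
  Ea_hand <- 8.314462618e-3 * log(2) / (1 / 278 - 1 / 296)
  tm <- fit_temperature(c(278, 296), c(2, 1), mode = "arrhenius")
  expect_equal(tm$Ea_kJmol, Ea_hand, tolerance = 1e-9)
  expect_equal(tm$Ea_kJmol, 26.3, tolerance = 0.01)
  # equal tau at all T: Ea = 0
  tm0 <- fit_temperature(c(278, 288, 296), c(1, 1, 1), mode = "arrhenius")
  expect_equal(tm0$Ea_kJmol, 0, tolerance = 1e-9)
  # viscosity-corrected model with Ea = 0: ~1.7-1.8x slowdown over 23 -> 5 C
  sl <- predict_slowdown(NULL, T_from = 296.15, T_to = 278.15,
                         Ea_kJmol = 0, mode = "viscosity")
  expect_gt(sl, 1.7); expect_lt(sl, 1.9)
  # negative Ea reported with a warning, not clipped
  expect_warning(fit_temperature(c(278, 296), c(1, 2), mode = "arrhenius"),
                 "negative")
})
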