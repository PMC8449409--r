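# Diffusive-landscape layer: potential of mean force, 1-D Smoluchowski
# dynamics, recurrence-decay prediction and diffusion-coefficient fitting,
# Zwanzig roughness, and temperature models.

#' Potential of mean force from a distance distribution
#'
#' \eqn{V(r) = -\ln \max(P(r), \mathrm{floor})} in units of \eqn{k_B T},
#' shifted so that \eqn{\min V = 0}. Grid cells at the floor are flagged and
#' excluded from dynamics.
#'
#' @param P a [distance_distribution()].
#' @param floor probability floor applied before taking the logarithm
#'   (avoids infinite walls from sampling zeros).
#' @return Object of class `pmf`: list `r`, `V` (kT), `active` (logical).
#' @export
pmf_from_distribution <- function(P, floor = 1e-8) {
  stopifnot(inherits(P, "distance_distribution"))
  if (all(P$p <= 0)) stop_fs("all-zero distribution")
  active <- P$p > floor
  V <- -log(pmax(P$p, floor))
  V <- V - min(V[active])
  structure(list(r = P$r, V = V, active = active), class = "pmf")
}

#' @export
print.pmf <- function(x, ...) {
  cat(sprintf("<pmf> %d grid points on [%.3g, %.3g] nm, max V = %.2f kT (%d active)\n",
              length(x$r), min(x$r), max(x$r), max(x$V[x$active]), sum(x$active)))
  invisible(x)
}

# Rate matrix of the discretized Smoluchowski operator on the active grid.
# Nearest-neighbour hopping with detailed balance:
#   w_{i -> i+-1} = (D / dr^2) exp(-(V_nb - V_i)/2)
# reflecting boundaries. Returns the matrix plus the symmetrizing weights.
smol_rates <- function(pmf, D) {
  keep <- which(pmf$active)
  if (length(keep) < 3L) stop_fs("fewer than 3 active grid cells")
  r <- pmf$r[keep]; V <- pmf$V[keep]
  n <- length(r)
  dr <- diff(r)
  if (max(dr) / min(dr) > 1.001 + 1e-9)
    dr <- rep(mean(dr), n - 1L)  # tolerate tiny float jitter on uniform grids
  h <- mean(dr)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    up <- (D / h^2) * exp(-(V[i + 1L] - V[i]) / 2)
    dn <- (D / h^2) * exp(-(V[i] - V[i + 1L]) / 2)
    W[i + 1L, i] <- up
    W[i, i + 1L] <- dn
  }
  diag(W) <- -colSums(W)
  list(W = W, r = r, V = V, keep = keep, h = h)
}

# Symmetric eigendecomposition of the rate matrix (detailed balance makes
# S = diag(e^{V/2}) W diag(e^{-V/2}) symmetric).
smol_eigen <- function(rs) {
  s <- exp(rs$V / 2)
  S <- sweep(sweep(rs$W, 1, s, `*`), 2, s, `/`)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  list(values = es$values, vectors = es$vectors, s = s)
}

#' Propagate a density under the 1-D Smoluchowski equation
#'
#' Finite-volume discretization with nearest-neighbour hopping rates that
#' satisfy detailed balance,
#' \eqn{w_{i\to i\pm1} = (D/\Delta r^2)\,e^{-(V_{nb}-V_i)/2}}, and reflecting
#' boundaries; time evolution through the exact eigendecomposition of the
#' (symmetrized) rate matrix, so arbitrary times are reached without a
#' stability limit. The stationary state is \eqn{\propto e^{-V}}.
#'
#' @param pmf a [pmf_from_distribution()] result.
#' @param D diffusion coefficient (nm^2 per time unit of `times`).
#' @param p0 initial density on the pmf grid (normalized; values on inactive
#'   cells must be zero).
#' @param times times at which to report the density.
#' @return Object of class `smoluchowski_solution`: `r`, `times`, `densities`
#'   (matrix, one column per time), `relaxation_times` (sorted, slowest
#'   first), `equilibrium`.
#' @export
smoluchowski_propagate <- function(pmf, D, p0, times) {
  stopifnot(inherits(pmf, "pmf"))
  if (D <= 0) stop_fs("D must be positive")
  if (length(p0) != length(pmf$r)) stop_fs("p0 must live on the pmf grid")
  mass0 <- trapz(pmf$r, p0)
  if (abs(mass0 - 1) > 1e-6) stop_fs("p0 not normalized (mass %.6f)", mass0)
  rs <- smol_rates(pmf, D)
  es <- smol_eigen(rs)
  q0 <- p0[rs$keep] * rs$h          # cell masses
  q0 <- q0 / sum(q0)
  y0 <- crossprod(es$vectors, es$s * q0)
  dens <- matrix(0, length(pmf$r), length(times))
  mass_drift <- numeric(length(times))
  for (k in seq_along(times)) {
    qt <- es$vectors %*% (exp(es$values * times[k]) * y0)
    qt <- as.numeric(qt) / es$s
    mass_drift[k] <- abs(sum(qt) - 1)
    dens[rs$keep, k] <- qt / rs$h
  }
  lam <- sort(es$values, decreasing = TRUE)
  relax <- -1 / lam[-1]
  peq <- exp(-rs$V); peq <- peq / sum(peq)
  eq <- numeric(length(pmf$r)); eq[rs$keep] <- peq / rs$h
  structure(list(r = pmf$r, times = times, densities = dens,
                 relaxation_times = relax, equilibrium = eq,
                 mass_drift = mass_drift),
            class = "smoluchowski_solution")
}

#' Equilibrium density of a pmf on its grid
#' @param pmf a `pmf` object.
#' @return normalized density vector (zero on inactive cells).
#' @export
pmf_equilibrium <- function(pmf) {
  p <- ifelse(pmf$active, exp(-pmf$V), 0)
  p / trapz(pmf$r, p)
}

#' Predict a recurrence (fraction-low-FRET) decay from diffusive dynamics
#'
#' Starts from the equilibrium density restricted to the initial-efficiency
#' window (through \eqn{E(r) = [1+(r/R_0)^6]^{-1}}), propagates it with
#' [smoluchowski_propagate()], and reports the probability mass in the low-E
#' region versus delay.
#'
#' @param pmf potential of mean force.
#' @param D diffusion coefficient (nm^2 per delay time unit).
#' @param R0 Foerster radius (nm).
#' @param initial_E_window length-2 vector, efficiency window selecting the
#'   initial bursts.
#' @param split_E efficiency below which a burst counts as "low".
#' @param delays delay times.
#' @return data.frame `delay`, `fraction_low`, plus attributes
#'   `equilibrium_fraction_low` and `relaxation_times`.
#' @export
predict_rasp <- function(pmf, D, R0, initial_E_window, split_E, delays) {
  E_of_r <- 1 / (1 + (pmf$r / R0)^6)
  init <- E_of_r >= initial_E_window[1] & E_of_r <= initial_E_window[2] & pmf$active
  low <- E_of_r < split_E
  if (!any(init)) stop_fs("initial efficiency window selects no grid cells")
  p0 <- pmf_equilibrium(pmf)
  p0[!init] <- 0
  m <- trapz(pmf$r, p0)
  if (m <= 0) stop_fs("empty initial window")
  p0 <- p0 / m
  sol <- smoluchowski_propagate(pmf, D, p0, delays)
  frac <- vapply(seq_along(delays), function(k)
    trapz(pmf$r, sol$densities[, k] * low), numeric(1))
  eqf <- trapz(pmf$r, sol$equilibrium * low)
  out <- data.frame(delay = delays, fraction_low = frac)
  attr(out, "equilibrium_fraction_low") <- eqf
  attr(out, "relaxation_times") <- sol$relaxation_times
  out
}

#' Fit the intrachain diffusion coefficient to a recurrence decay
#'
#' One-parameter least squares over \eqn{D}: predicted decays are generated
#' by [predict_rasp()] on the supplied potential of mean force. Because the
#' whole rate matrix scales linearly with \eqn{D}, the predicted decay at
#' \eqn{D} equals the \eqn{D=1} decay evaluated at rescaled delays, which is
#' exploited for speed. Uncertainty is taken from the curvature of the
#' residual sum of squares at the optimum.
#'
#' @param delays,fraction_low measured decay (e.g. from [rasp()]).
#' @param pmf potential of mean force of the probed distance.
#' @param R0 Foerster radius (nm).
#' @param initial_E_window,split_E windows used when the decay was built.
#' @param D_range search interval for D (nm^2 per delay unit).
#' @return Object of class `diffusion_fit`: `D`, `D_se`, `fitted`
#'   (data.frame delay/fraction_low/fit), `residuals`.
#' @export
fit_diffusion <- function(delays, fraction_low, pmf, R0, initial_E_window,
                          split_E, D_range = NULL) {
  if (length(delays) < 5L) stop_fs("need at least 5 decay bins")
  if (sd(fraction_low) < 1e-6)
    stop_fs("flat decay: D not identifiable")
  # reference decay at D = 1 on a dense log-grid of scaled delays
  if (is.null(D_range)) D_range <- c(1e-6, 1e6) * 1 / max(delays)
  tgrid <- exp(seq(log(min(delays) * min(D_range)),
                   log(max(delays) * max(D_range)), length.out = 400))
  ref <- predict_rasp(pmf, 1, R0, initial_E_window, split_E, tgrid)
  pred <- function(D) approx(log(tgrid), ref$fraction_low,
                             xout = log(delays * D), rule = 2)$y
  obj <- function(logD) sum((pred(exp(logD)) - fraction_low)^2)
  op <- optimize(obj, log(D_range), tol = 1e-10)
  D <- exp(op$minimum)
  if (abs(log(D) - log(D_range[1])) < 1e-3 ||
      abs(log(D) - log(D_range[2])) < 1e-3)
    stop_fs("D not identifiable within search range (hit boundary)")
  # curvature-based standard error on log D
  h <- 0.05
  f0 <- op$objective
  fp <- obj(log(D) + h); fm <- obj(log(D) - h)
  curv <- (fp + fm - 2 * f0) / h^2
  n <- length(delays)
  s2 <- f0 / max(n - 1L, 1L)
  se_logD <- if (curv > 0) sqrt(2 * s2 / curv) else NA_real_
  structure(list(D = D, D_se = D * se_logD,
                 fitted = data.frame(delay = delays,
                                     fraction_low = fraction_low,
                                     fit = pred(D)),
                 residuals = fraction_low - pred(D)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("intrachain diffusion fit: D = %.4g +/- %.2g nm^2 per delay unit\n",
              x$D, x$D_se))
  invisible(x)
}

#' Energy-landscape roughness from a diffusion-coefficient ratio
#'
#' Zwanzig's expressions for diffusion on a rugged 1-D landscape:
#' Gaussian-distributed well depths of amplitude \eqn{\sigma} give the
#' super-Arrhenius rescaling \eqn{D = D_0 e^{-\beta^2\sigma^2}}; a periodic
#' modulation gives \eqn{D = D_0 e^{-2\beta\sigma}}. Inverting at fixed
#' temperature (\eqn{\beta\sigma} in \eqn{k_B T} units):
#' \eqn{\sigma_{gauss} = \sqrt{\ln(D_0/D)}},
#' \eqn{\sigma_{per} = \ln(D_0/D)/2}.
#'
#' @param D apparent diffusion coefficient on the rugged landscape (nm^2/us).
#' @param D0 diffusion coefficient without ruggedness (nm^2/us).
#' @return Object of class `roughness_estimate`: `sigma_gaussian`,
#'   `sigma_periodic` (both in kT), `D`, `D0`.
#' @examples
#' zwanzig_roughness(D = 9.5e-3, D0 = 42)  # sigma_gaussian ~ 2.9 kT
#' @export
zwanzig_roughness <- function(D, D0) {
  if (D <= 0 || D0 <= 0) stop_fs("diffusion coefficients must be positive")
  if (D > D0) stop_fs("D > D0: roughness undefined")
  lr <- log(D0 / D)
  structure(list(sigma_gaussian = sqrt(lr), sigma_periodic = lr / 2,
                 D = D, D0 = D0),
            class = "roughness_estimate")
}

#' @export
print.roughness_estimate <- function(x, ...) {
  cat(sprintf(
    "roughness from D0 = %.3g, D = %.3g nm^2/us: sigma = %.2f kT (Gaussian), %.2f kT (periodic)\n",
    x$D0, x$D, x$sigma_gaussian, x$sigma_periodic))
  invisible(x)
}

#' Invert a roughness estimate back to a diffusion coefficient
#' @param sigma roughness amplitude (kT).
#' @param D0 smooth-landscape diffusion coefficient.
#' @param kind `"gaussian"` or `"periodic"`.
#' @return D (same units as D0).
#' @export
roughness_to_D <- function(sigma, D0, kind = c("gaussian", "periodic")) {
  kind <- match.arg(kind)
  if (sigma < 0) stop_fs("sigma must be nonnegative")
  if (kind == "gaussian") D0 * exp(-sigma^2) else D0 * exp(-2 * sigma)
}

#' Dynamic viscosity of water
#'
#' Vogel-type empirical form \eqn{\eta(T) = A\,10^{B/(T-C)}} with
#' A = 2.414e-5 Pa s, B = 247.8 K, C = 140 K, accurate to ~1% over 0--40 C.
#'
#' @param temperature_K temperature (K).
#' @return viscosity in Pa s.
#' @export
water_viscosity <- function(temperature_K) {
  if (any(temperature_K < 270 | temperature_K > 320))
    stop_fs("temperature outside liquid-water validity range")
  2.414e-5 * 10^(247.8 / (temperature_K - 140))
}

#' Temperature dependence of a relaxation time
#'
#' Two models for \eqn{\tau(T)}:
#' * `"arrhenius"`: \eqn{\tau = A\,e^{E_a/k_B T}}; fitted by linear
#'   regression of \eqn{\ln\tau} on \eqn{1/T}.
#' * `"viscosity"`: \eqn{\tau \propto \eta(T)/T \cdot e^{E_a/k_B T}}, i.e.
#'   the Kramers-type prefactor tracks solvent viscosity; \eqn{E_a} is fitted
#'   after removing the \eqn{\eta(T)/T} trend (so \eqn{E_a = 0} means the
#'   slowdown is purely viscous).
#'
#' @param temperature_K temperatures (K).
#' @param tau relaxation times (any consistent unit).
#' @param mode `"arrhenius"` or `"viscosity"`.
#' @return Object of class `temperature_model`: `Ea_kJmol`, `Ea_se_kJmol`,
#'   `mode`, `prediction` (data.frame `temperature_K`, `tau`), and
#'   `slowdown(T1, T2)` helper via [predict_slowdown()].
#' @export
fit_temperature <- function(temperature_K, tau,
                            mode = c("arrhenius", "viscosity")) {
  mode <- match.arg(mode)
  if (length(temperature_K) < 2L) stop_fs("need at least 2 temperatures")
  R <- 8.314462618e-3  # kJ/(mol K)
  y <- log(tau)
  if (mode == "viscosity")
    y <- y - log(water_viscosity(temperature_K) / temperature_K)
  x <- 1 / temperature_K
  fit <- lm(y ~ x)
  Ea <- unname(coef(fit)[2]) * R
  se <- if (length(temperature_K) > 2L)
    sqrt(vcov(fit)[2, 2]) * R else NA_real_
  if (!is.na(Ea) && Ea < 0)
    warning("negative fitted activation energy (reported, not clipped)")
  Tg <- seq(min(temperature_K), max(temperature_K), length.out = 50)
  ly <- unname(coef(fit)[1]) + unname(coef(fit)[2]) / Tg
  if (mode == "viscosity") ly <- ly + log(water_viscosity(Tg) / Tg)
  structure(list(Ea_kJmol = Ea, Ea_se_kJmol = se, mode = mode,
                 intercept = unname(coef(fit)[1]),
                 prediction = data.frame(temperature_K = Tg, tau = exp(ly))),
            class = "temperature_model")
}

#' @export
print.temperature_model <- function(x, ...) {
  cat(sprintf("temperature model (%s): Ea = %.1f kJ/mol", x$mode, x$Ea_kJmol))
  if (!is.na(x$Ea_se_kJmol)) cat(sprintf(" +/- %.1f", x$Ea_se_kJmol))
  cat("\n"); invisible(x)
}

#' Predicted slowdown factor between two temperatures
#'
#' @param model a [fit_temperature()] result, or `NULL` for a pure
#'   viscosity/Kramers prediction with the given activation energy.
#' @param T_from,T_to temperatures (K); the factor is
#'   \eqn{\tau(T_{to})/\tau(T_{from})}.
#' @param Ea_kJmol activation energy when `model` is NULL (default 0).
#' @param mode prediction mode when `model` is NULL.
#' @return scalar slowdown factor.
#' @export
predict_slowdown <- function(model = NULL, T_from, T_to, Ea_kJmol = 0,
                             mode = c("viscosity", "arrhenius")) {
  R <- 8.314462618e-3
  if (!is.null(model)) {
    Ea_kJmol <- model$Ea_kJmol
    mode <- model$mode
  } else mode <- match.arg(mode)
  arr <- exp(Ea_kJmol / R * (1 / T_to - 1 / T_from))
  if (mode == "arrhenius") return(arr)
  visc <- (water_viscosity(T_to) / T_to) / (water_viscosity(T_from) / T_from)
  arr * visc
}

#' Closed-form bookkeeping of complex lifetime and reconfiguration
#'
#' From a macroscopic dissociation rate and an equilibrium reconfiguration
#' time: the mean complex lifetime \eqn{1/k_{diss}} and the number of
#' reconfiguration events per complex lifetime. Also computes the affinity
#' boost \eqn{\ln(K_D^{core}/K_D^{full})} in \eqn{k_B T} contributed by
#' segments outside a core-binding region.
#'
#' @param k_diss_per_s macroscopic dissociation rate (1/s).
#' @param tau_reconfig_s reconfiguration time (s).
#' @param KD_core,KD_full dissociation constants (same units) of the isolated
#'   core region and the full-length chain; optional.
#' @return list `lifetime_s`, `n_reconfigurations`, `affinity_boost_kT`
#'   (NA if the K_D pair is not given).
#' @export
complex_bookkeeping <- function(k_diss_per_s, tau_reconfig_s,
                                KD_core = NULL, KD_full = NULL) {
  if (k_diss_per_s <= 0 || tau_reconfig_s <= 0)
    stop_fs("rates and times must be positive")
  lt <- 1 / k_diss_per_s
  boost <- if (!is.null(KD_core) && !is.null(KD_full)) {
    if (KD_core <= 0 || KD_full <= 0) stop_fs("K_D values must be positive")
    log(KD_core / KD_full)
  } else NA_real_
  list(lifetime_s = lt,
       n_reconfigurations = lt / tau_reconfig_s,
       affinity_boost_kT = boost)
}
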