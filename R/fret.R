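# Distance distributions, polymer-model families, and FRET observables.

#' Gridded donor--acceptor distance distribution
#'
#' @param r radii (nm), strictly increasing and nonnegative.
#' @param p density values (1/nm), nonnegative; must integrate to 1 unless
#'   `normalize = TRUE`.
#' @param normalize renormalize `p` to unit mass.
#' @return Object of class `distance_distribution` (list `r`, `p`).
#' @export
distance_distribution <- function(r, p, normalize = FALSE) {
  if (length(r) != length(p) || length(r) < 2L)
    stop_fs("r and p must be equal-length vectors (>= 2 points)")
  if (is.unsorted(r, strictly = TRUE)) stop_fs("r must be strictly increasing")
  if (any(r < 0)) stop_fs("r must be nonnegative")
  if (any(p < -1e-12)) stop_fs("p must be nonnegative")
  p <- pmax(p, 0)
  mass <- trapz(r, p)
  if (normalize) {
    if (mass <= 0) stop_fs("distribution has zero mass")
    p <- p / mass
  } else if (abs(mass - 1) > 1e-6) {
    stop_fs("distribution not normalized: mass = %.8f", mass)
  }
  structure(list(r = r, p = p), class = "distance_distribution")
}

#' Point-mass (single fixed distance) distribution
#' @param r0 the fixed donor--acceptor distance (nm).
#' @return A `distance_distribution` carrying a `point` attribute.
#' @export
dist_point <- function(r0) {
  if (r0 < 0) stop_fs("distance must be nonnegative")
  d <- structure(list(r = c(r0, r0), p = c(Inf, Inf)),
                 class = "distance_distribution")
  attr(d, "point") <- r0
  d
}

dist_moment <- function(P, fun) {
  pt <- attr(P, "point")
  if (!is.null(pt)) return(fun(pt))
  trapz(P$r, P$p * fun(P$r))
}

#' Mean FRET transfer efficiency of a distance distribution
#'
#' \deqn{\langle E\rangle = \int p(r)\,[1 + (r/R_0)^6]^{-1}\,dr}
#' computed by trapezoidal quadrature on the distribution's grid.
#'
#' @param P a [distance_distribution()].
#' @param R0 Foerster radius (nm); default 5.4 nm for the Alexa 488/594 pair.
#' @return mean efficiency in `[0, 1]`.
#' @export
mean_efficiency <- function(P, R0 = 5.4) {
  stopifnot(inherits(P, "distance_distribution"))
  if (R0 <= 0) stop_fs("R0 must be positive")
  dist_moment(P, function(r) 1 / (1 + (r / R0)^6))
}

#' Ensemble-averaged relative donor lifetime
#'
#' For a heterogeneous ensemble the intensity-weighted relative donor
#' lifetime is
#' \deqn{\tau_{DA}/\tau_D = \langle (1-E(r))^2 \rangle / \langle 1-E(r)\rangle,}
#' which equals \eqn{1 - \langle E\rangle} only for a single fixed distance;
#' any genuine distance heterogeneity pushes it above that line (the
#' signature used in lifetime--efficiency maps).
#'
#' @inheritParams mean_efficiency
#' @return the ratio \eqn{\tau_{DA}/\tau_D} in `[0, 1]`.
#' @export
lifetime_ratio <- function(P, R0 = 5.4) {
  stopifnot(inherits(P, "distance_distribution"))
  m1 <- dist_moment(P, function(r) 1 - 1 / (1 + (r / R0)^6))
  if (m1 < 1e-12) stop_fs("all-transfer limit: <1-E> = 0, ratio undefined")
  m2 <- dist_moment(P, function(r) (1 - 1 / (1 + (r / R0)^6))^2)
  m2 / m1
}

#' Polymer distance-distribution model
#'
#' Families:
#' * `"single"`: one fixed distance; parameter `rms_nm`.
#' * `"gaussian"`: Gaussian chain, \eqn{p(r) \propto r^2 e^{-3r^2/2\langle r^2\rangle}};
#'   parameter `rms_nm` (root-mean-square distance).
#' * `"saw"`: self-avoiding-walk-like family
#'   \eqn{p(x) \propto x^{2+\theta} e^{-a x^{\delta}}} with
#'   \eqn{\delta = 1/(1-\nu)}, \eqn{\theta = (\gamma-1)/\nu}
#'   (\eqn{\gamma = 1.1615}); parameters `rms_nm`, `nu`.
#' * `"wlc"`: worm-like chain radial closed form
#'   \eqn{p(r) \propto r^2 (1-(r/L)^2)^{-9/2}
#'        \exp[-(3L/4 l_p)/(1-(r/L)^2)]}
#'   (an interpolation formula whose small-\eqn{r/L} limit reproduces the
#'   ideal-chain \eqn{\langle r^2\rangle = 2 l_p L}); parameters
#'   `contour_nm` (L), `lp_nm` (persistence length, `lp < L`).
#'
#' @param family one of `"single"`, `"gaussian"`, `"saw"`, `"wlc"`.
#' @param rms_nm root-mean-square distance (nm), for single/gaussian/saw.
#' @param nu scaling exponent for `"saw"`.
#' @param contour_nm,lp_nm contour and persistence length (nm) for `"wlc"`.
#' @return Object of class `polymer_model`.
#' @export
polymer_model <- function(family = c("gaussian", "single", "saw", "wlc"),
                          rms_nm = NULL, nu = 0.588,
                          contour_nm = NULL, lp_nm = NULL) {
  family <- match.arg(family)
  if (family == "wlc") {
    if (is.null(contour_nm) || is.null(lp_nm))
      stop_fs("wlc requires contour_nm and lp_nm")
    if (contour_nm <= 0 || lp_nm <= 0) stop_fs("length parameters must be positive")
    if (lp_nm >= contour_nm) stop_fs("wlc requires lp < contour length")
  } else {
    if (is.null(rms_nm) || rms_nm <= 0) stop_fs("rms_nm must be positive")
    if (family == "saw" && (nu <= 0.2 || nu >= 0.95))
      stop_fs("nu outside supported range (0.2, 0.95)")
  }
  structure(list(family = family, rms_nm = rms_nm, nu = nu,
                 contour_nm = contour_nm, lp_nm = lp_nm),
            class = "polymer_model")
}

#' Gridded distance distribution of a polymer model
#'
#' @param m a [polymer_model()].
#' @param n_grid number of grid points (default 2000).
#' @return A normalized [distance_distribution()]; for `"single"` a point
#'   mass.
#' @export
distribution_from_model <- function(m, n_grid = 2000) {
  stopifnot(inherits(m, "polymer_model"))
  switch(m$family,
    single = dist_point(m$rms_nm),
    gaussian = {
      r <- seq(1e-6, 3 * m$rms_nm, length.out = n_grid)
      p <- r^2 * exp(-3 * r^2 / (2 * m$rms_nm^2))
      distance_distribution(r, p, normalize = TRUE)
    },
    saw = {
      delta <- 1 / (1 - m$nu)
      theta <- (1.1615 - 1) / m$nu
      r <- seq(1e-6, 3.5 * m$rms_nm, length.out = n_grid)
      x <- r / m$rms_nm
      p <- x^(2 + theta) * exp(-1.5 * x^delta)
      d <- distance_distribution(r, p, normalize = TRUE)
      # rescale grid so the realized rms matches the requested one
      rms <- sqrt(dist_moment(d, function(r) r^2))
      distance_distribution(d$r * m$rms_nm / rms, d$p * rms / m$rms_nm,
                            normalize = TRUE)
    },
    wlc = {
      L <- m$contour_nm; lp <- m$lp_nm
      r <- seq(1e-6, L * (1 - 1e-4), length.out = n_grid)
      x2 <- (r / L)^2
      logp <- 2 * log(r) - 4.5 * log1p(-x2) - (3 * L / (4 * lp)) / (1 - x2)
      p <- exp(logp - max(logp))
      distance_distribution(r, p, normalize = TRUE)
    })
}

model_rms <- function(P) sqrt(dist_moment(P, function(r) r^2))

#' Infer a polymer-model parameter from a measured mean efficiency
#'
#' Root-finds the family parameter whose [mean_efficiency()] equals the
#' observed value. For the WLC family the contour length is fixed at
#' `0.38 nm * (n_residues + linker_offset)` and the persistence length is
#' fitted.
#'
#' @param E_obs observed mean transfer efficiency, strictly in (0, 1).
#' @param family model family (see [polymer_model()]).
#' @param R0 Foerster radius (nm).
#' @param n_residues dye sequence separation (residues); required for `"wlc"`.
#' @param linker_offset effective extra residues of contour contributed by the
#'   dye linkers (default 9).
#' @param nu scaling exponent for the `"saw"` family.
#' @return The fitted [polymer_model()] with an `rms_nm` element (for wlc the
#'   rms of the fitted distribution) and, for wlc, `lp_nm`.
#' @export
infer_distance <- function(E_obs, family = "gaussian", R0 = 5.4,
                           n_residues = NULL, linker_offset = 9, nu = 0.588) {
  if (E_obs <= 0 || E_obs >= 1) stop_fs("E_obs must lie strictly in (0,1)")
  eff <- function(m) mean_efficiency(distribution_from_model(m), R0 = R0)
  if (family == "single") {
    return(polymer_model("single", rms_nm = R0 * ((1 - E_obs) / E_obs)^(1 / 6)))
  }
  if (family == "wlc") {
    if (is.null(n_residues)) stop_fs("wlc inference requires n_residues")
    L <- 0.38 * (n_residues + linker_offset)
    f <- function(lp) eff(polymer_model("wlc", contour_nm = L, lp_nm = lp)) - E_obs
    lo <- 1e-3 * L; hi <- 0.995 * L
    flo <- f(lo); fhi <- f(hi)
    if (flo * fhi > 0)
      stop_fs("E_obs = %.3f outside attainable range [%.3f, %.3f] for wlc (L = %.2f nm)",
              E_obs, min(E_obs + flo, E_obs + fhi), max(E_obs + flo, E_obs + fhi), L)
    lp <- uniroot(f, c(lo, hi), tol = 1e-8)$root
    m <- polymer_model("wlc", contour_nm = L, lp_nm = lp)
    m$rms_nm <- model_rms(distribution_from_model(m))
    return(m)
  }
  mk <- function(rms) polymer_model(family, rms_nm = rms, nu = nu)
  f <- function(rms) eff(mk(rms)) - E_obs
  lo <- 0.02 * R0; hi <- 20 * R0
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0)
    stop_fs("E_obs = %.3f outside attainable range [%.4f, %.4f] for family '%s'",
            E_obs, E_obs + fhi, E_obs + flo, family)
  rms <- uniroot(f, c(lo, hi), tol = 1e-9)$root
  mk(rms)
}

#' Persistence length from a measured efficiency (WLC route)
#'
#' Convenience wrapper of [infer_distance()] for the worm-like-chain family.
#'
#' @inheritParams infer_distance
#' @return list with `lp_nm`, `contour_nm`, `rms_nm`.
#' @export
persistence_length <- function(E_obs, n_residues, R0 = 5.4, linker_offset = 9) {
  m <- infer_distance(E_obs, family = "wlc", R0 = R0, n_residues = n_residues,
                      linker_offset = linker_offset)
  list(lp_nm = m$lp_nm, contour_nm = m$contour_nm, rms_nm = m$rms_nm)
}
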