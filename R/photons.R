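# Photon-stream smFRET pipeline: streams, burst search, efficiency
# histograms with mixture fits, recoloring, and binding isotherms.

#' Photon stream container
#'
#' @param time_s photon arrival times (s), nondecreasing.
#' @param channel per-photon channel tag: `"donor"`, `"acceptor"`, or
#'   `"acceptor_direct"` (integer 0/1/2 also accepted).
#' @param metadata list of correction factors and provenance; recognized
#'   entries: `gamma` (detection-efficiency ratio, default 1), `crosstalk`
#'   (donor -> acceptor leakage fraction, default 0), `bg_donor_hz`,
#'   `bg_acceptor_hz` (background rates, default 0).
#' @return object of class `photon_stream`.
#' @export
photon_stream <- function(time_s, channel, metadata = list()) {
  if (length(time_s) != length(channel)) stop_fs("time/channel length mismatch")
  if (is.unsorted(time_s)) stop_fs("timestamps must be nondecreasing")
  lv <- c("donor", "acceptor", "acceptor_direct")
  if (is.numeric(channel)) channel <- lv[channel + 1L]
  if (any(!(channel %in% lv)))
    stop_fs("channel tags must be one of: %s", paste(lv, collapse = ", "))
  meta <- utils::modifyList(
    list(gamma = 1, crosstalk = 0, bg_donor_hz = 0, bg_acceptor_hz = 0),
    metadata)
  structure(list(time_s = time_s, channel = channel, metadata = meta),
            class = "photon_stream")
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf("<photon_stream> %d photons over %.3g s (%d donor / %d acceptor)\n",
              length(x$time_s), diff(range(x$time_s)),
              sum(x$channel == "donor"), sum(x$channel == "acceptor")))
  invisible(x)
}

#' Read a photon stream from two-column CSV
#'
#' Documented fallback dialect: columns `time_s` and `channel`
#' (donor/acceptor/acceptor_direct or 0/1/2).
#' @param path CSV file.
#' @param metadata passed to [photon_stream()].
#' @return a `photon_stream`.
#' @export
read_photon_csv <- function(path, metadata = list()) {
  d <- read.csv(path)
  photon_stream(d$time_s, d$channel, metadata)
}

#' @rdname read_photon_csv
#' @param stream a `photon_stream` to write.
#' @export
write_photon_csv <- function(stream, path) {
  write.csv(data.frame(time_s = stream$time_s, channel = stream$channel),
            path, row.names = FALSE)
  invisible(path)
}

#' Sliding-window burst search
#'
#' Selects maximal runs of photons whose local rate (photons inside a
#' centered window) exceeds `min_rate_khz`, keeping runs with at least
#' `min_photons` photons. Per burst, the corrected transfer efficiency is
#' computed after background subtraction and crosstalk/gamma correction:
#' \eqn{E = n_A'/(n_A' + \gamma n_D')}.
#'
#' @param stream a [photon_stream()].
#' @param window_ms sliding-window width (default 1 ms).
#' @param min_rate_khz rate threshold (default 20 kHz).
#' @param min_photons minimum photons per burst (default 50).
#' @return Object of class `burst_table` (data.frame): `start_s`,
#'   `duration_ms`, `n_donor`, `n_acceptor`, `n_total`, `E`, `clipped`.
#' @export
burst_search <- function(stream, window_ms = 1, min_rate_khz = 20,
                         min_photons = 50) {
  stopifnot(inherits(stream, "photon_stream"))
  t <- stream$time_s
  out0 <- data.frame(start_s = numeric(), duration_ms = numeric(),
                     n_donor = integer(), n_acceptor = integer(),
                     n_total = integer(), E = numeric(), clipped = logical())
  class(out0) <- c("burst_table", "data.frame")
  if (!length(t)) return(out0)
  w <- window_ms * 1e-3
  hi <- findInterval(t + w / 2, t)
  lo <- findInterval(t - w / 2, t, left.open = TRUE)
  rate_khz <- (hi - lo) / w / 1000
  inb <- rate_khz >= min_rate_khz
  r <- rle(inb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_photons)
  if (!length(keep)) return(out0)
  md <- stream$metadata
  rows <- lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    ch <- stream$channel[i0:i1]
    dur <- t[i1] - t[i0]
    nd <- sum(ch == "donor"); na_ <- sum(ch == "acceptor")
    ndc <- nd - md$bg_donor_hz * dur
    nac <- na_ - md$bg_acceptor_hz * dur - md$crosstalk * ndc
    E <- nac / (nac + md$gamma * ndc)
    clip <- is.na(E) | E < 0 | E > 1
    data.frame(start_s = t[i0], duration_ms = dur * 1e3,
               n_donor = nd, n_acceptor = na_, n_total = i1 - i0 + 1L,
               E = min(max(E, 0), 1), clipped = clip)
  })
  out <- do.call(rbind, rows)
  raw_out <- mean(out$clipped)
  if (raw_out > 0.01)
    warning(sprintf("%.1f%% of bursts had corrected E outside [-0.1, 1.1]-style bounds; check corrections",
                    100 * raw_out))
  class(out) <- c("burst_table", "data.frame")
  out
}

# mixture log-likelihood: components are gaussian or lognormal densities in E
mix_loglik <- function(par, E, shapes) {
  k <- length(shapes)
  w <- if (k == 1) 1 else {
    ew <- exp(c(0, par[seq_len(k - 1)]))
    ew / sum(ew)
  }
  off <- if (k == 1) 0 else k - 1
  dens <- sapply(seq_len(k), function(c) {
    mu <- par[off + 2 * c - 1]; sdl <- exp(par[off + 2 * c])
    if (shapes[c] == "gaussian") dnorm(E, mu, sdl)
    else dlnorm(pmax(E, 1e-6), log(pmax(mu, 1e-6)), sdl)
  })
  if (k == 1) dens <- cbind(dens)
  sum(log(pmax(as.numeric(dens %*% w), 1e-300)))
}

#' Fit a transfer-efficiency histogram with a peak mixture
#'
#' Maximum-likelihood fit of the burst efficiencies with a superposition of
#' Gaussian and/or log-normal peaks; the number of components is selected by
#' BIC unless forced. Typical use: two-population mode separating free and
#' bound molecules.
#'
#' @param bursts a [burst_search()] table (or numeric vector of
#'   efficiencies).
#' @param n_components candidate component counts (default `1:2`).
#' @param shapes peak shape per component, `"gaussian"` or `"lognormal"`
#'   (recycled).
#' @return Object of class `efficiency_fit`: `means`, `widths`,
#'   `area_fractions` (sum to 1), `n_components`, `bic` (per candidate),
#'   `loglik`.
#' @export
histogram_and_fit <- function(bursts, n_components = 1:2,
                              shapes = "gaussian") {
  E <- if (is.data.frame(bursts)) bursts$E else as.numeric(bursts)
  E <- E[!is.na(E)]
  if (length(E) < 100) stop_fs("need at least 100 bursts (got %d)", length(E))
  best <- NULL
  bics <- setNames(numeric(0), character(0))
  for (k in n_components) {
    shp <- rep(shapes, length.out = k)
    # starting values from quantiles
    qs <- quantile(E, probs = (seq_len(k) - 0.5) / k)
    par0 <- c(if (k > 1) rep(0, k - 1),
              as.numeric(rbind(qs, log(max(sd(E) / k, 0.02)))))
    op <- try(optim(par0, function(p) -mix_loglik(p, E, shp),
                    method = "BFGS", control = list(maxit = 500)),
              silent = TRUE)
    if (inherits(op, "try-error"))
      stop_fs("mixture fit failed to converge for k = %d", k)
    npar <- length(par0)
    bic <- 2 * op$value + npar * log(length(E))
    bics[as.character(k)] <- bic
    if (is.null(best) || bic < best$bic) {
      w <- if (k == 1) 1 else {
        ew <- exp(c(0, op$par[seq_len(k - 1)])); ew / sum(ew)
      }
      off <- if (k == 1) 0 else k - 1
      best <- list(bic = bic, k = k, ll = -op$value,
                   means = op$par[off + 2 * seq_len(k) - 1],
                   widths = exp(op$par[off + 2 * seq_len(k)]),
                   w = w, shapes = shp)
    }
  }
  ord <- order(best$means)
  structure(list(means = best$means[ord], widths = best$widths[ord],
                 area_fractions = best$w[ord], n_components = best$k,
                 shapes = best$shapes[ord], bic = bics, loglik = best$ll),
            class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("efficiency histogram fit: %d component(s)\n", x$n_components))
  for (c in seq_len(x$n_components))
    cat(sprintf("  peak %d (%s): E = %.3f, width %.3f, area %.3f\n",
                c, x$shapes[c], x$means[c], x$widths[c],
                x$area_fractions[c]))
  invisible(x)
}

#' Shot-noise-limited histogram by recoloring
#'
#' Redraws each burst's acceptor count from a binomial at a fixed mean
#' efficiency and the burst's observed total count; the spread of the
#' resulting efficiencies is the shot-noise limit. Excess width of the
#' measured histogram over this limit indicates millisecond-scale dynamics
#' or static heterogeneity.
#'
#' @param bursts a [burst_search()] table (uses `n_total`).
#' @param mean_E the fixed transfer efficiency in `[0, 1]`.
#' @param seed RNG seed.
#' @return numeric vector of recolored per-burst efficiencies.
#' @export
recolor <- function(bursts, mean_E, seed = 1L) {
  if (mean_E < 0 || mean_E > 1) stop_fs("mean_E must lie in [0, 1]")
  n <- if (is.data.frame(bursts)) bursts$n_total else as.integer(bursts)
  set.seed(seed)
  rbinom(length(n), n, mean_E) / n
}

#' Fit a single-site binding isotherm
#'
#' Least squares of \eqn{f(c) = c/(c + K_D)} to bound fractions versus
#' ligand concentration.
#'
#' @param concentration_nM concentrations (nM), at least 4 spanning the
#'   transition.
#' @param bound_fraction bound fractions in `[0, 1]` (e.g. peak-area
#'   fractions from [histogram_and_fit()]).
#' @return Object of class `isotherm_fit`: `KD_nM`, `KD_ci_nM` (95%),
#'   `fitted` data.frame.
#' @export
fit_isotherm <- function(concentration_nM, bound_fraction) {
  if (length(concentration_nM) < 4L) stop_fs("need at least 4 concentrations")
  if (max(bound_fraction) < 0.6 || min(bound_fraction) > 0.4)
    stop_fs("no transition in the sampled range: K_D outside [%.3g, %.3g] nM",
            min(concentration_nM), max(concentration_nM))
  fit <- minpack.lm::nlsLM(
    bound_fraction ~ concentration_nM / (concentration_nM + KD),
    start = list(KD = stats::median(concentration_nM)),
    lower = 1e-6)
  KD <- coef(fit)[["KD"]]
  se <- summary(fit)$coefficients["KD", "Std. Error"]
  structure(list(KD_nM = KD, KD_ci_nM = KD + c(-1.96, 1.96) * se,
                 fitted = data.frame(concentration_nM = concentration_nM,
                                     bound_fraction = bound_fraction,
                                     fit = predict(fit))),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("binding isotherm: K_D = %.3g nM (95%% CI %.3g - %.3g)\n",
              x$KD_nM, x$KD_ci_nM[1], x$KD_ci_nM[2]))
  invisible(x)
}
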