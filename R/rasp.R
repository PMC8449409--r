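# Recurrence analysis of single particles (RASP): micro- to millisecond
# interconversion kinetics from burst pairs caused by re-entries of the same
# molecule into the confocal volume.

#' Recurrence kinetics from a burst table
#'
#' Collects ordered pairs of bursts whose start-time separation falls inside
#' `delay_window` and whose first burst has efficiency inside
#' `initial_E_window`; per (log-spaced) delay bin it reports the fraction of
#' second bursts with `E < split_E`. An exponential
#' \eqn{F(\Delta) = F_{eq} + (F_0 - F_{eq}) e^{-\Delta/\tau}} is fitted to
#' extract the relaxation time. A same-molecule probability per bin is
#' estimated from a competing-rates model: Poisson arrivals of new molecules
#' at the measured burst rate versus a 3-D diffusion return kernel
#' \eqn{\propto (1 + \Delta/t_d)^{-3/2}} (reported, not used for
#' reweighting).
#'
#' @param bursts a [burst_search()] table.
#' @param initial_E_window length-2 vector selecting first-burst
#'   efficiencies.
#' @param split_E efficiency split between "low" and "high" classes; default
#'   the mean burst efficiency.
#' @param delay_window length-2 vector (s), default `c(100e-6, 20e-3)`.
#' @param n_bins number of log-spaced delay bins.
#' @param min_pairs_bin bins with fewer pairs are merged (default 50).
#' @param t_diffusion_s diffusion-time scale of the return kernel.
#' @param return_amplitude amplitude of the return kernel at zero delay.
#' @return Object of class `rasp_decay`: `decay` (data.frame `delay_s`,
#'   `fraction_low`, `n_pairs`, `p_same`), `tau_s`, `tau_se_s`, `F0`, `Feq`,
#'   `tau_unconstrained` flag, `split_E`.
#' @export
rasp <- function(bursts, initial_E_window = NULL, split_E = NULL,
                 delay_window = c(100e-6, 20e-3), n_bins = 8,
                 min_pairs_bin = 50, t_diffusion_s = 1e-3,
                 return_amplitude = 0.3) {
  stopifnot(is.data.frame(bursts), nrow(bursts) > 1)
  if (diff(range(bursts$start_s)) < 100 * delay_window[2])
    stop_fs("burst start times span less than 100x the maximum delay")
  if (is.null(split_E)) split_E <- mean(bursts$E)
  if (is.null(initial_E_window)) initial_E_window <- c(split_E, 1)
  t0 <- bursts$start_s; E <- bursts$E
  ord <- order(t0); t0 <- t0[ord]; E <- E[ord]
  n <- length(t0)
  # ordered pairs within the delay window (bursts are sparse: advance window)
  d_list <- vector("list", n); e_list <- vector("list", n)
  jmax <- findInterval(t0 + delay_window[2], t0)
  jmin <- findInterval(t0 + delay_window[1], t0, left.open = TRUE) + 1L
  sel <- which(E >= initial_E_window[1] & E <= initial_E_window[2] &
                 jmax >= jmin)
  for (i in sel) {
    js <- seq.int(jmin[i], jmax[i])
    d_list[[i]] <- t0[js] - t0[i]
    e_list[[i]] <- E[js]
  }
  delays <- unlist(d_list); e2 <- unlist(e_list)
  if (length(delays) < 500)
    stop_fs("only %d recurrence pairs (need >= 500)", length(delays))
  edges <- exp(seq(log(delay_window[1]), log(delay_window[2]),
                   length.out = n_bins + 1))
  bin <- findInterval(delays, edges, rightmost.closed = TRUE)
  cnt <- tabulate(bin, n_bins)
  lows <- tapply(e2 < split_E, factor(bin, levels = seq_len(n_bins)), sum)
  lows[is.na(lows)] <- 0
  lo_e <- edges[-length(edges)]; hi_e <- edges[-1]
  # merge thin bins forward
  k <- 1L
  while (k <= length(cnt)) {
    if (cnt[k] < min_pairs_bin && length(cnt) > 2) {
      m <- if (k == length(cnt)) k - 1L else k + 1L
      lo <- min(k, m); hi <- max(k, m)
      cnt[lo] <- cnt[lo] + cnt[hi]; lows[lo] <- lows[lo] + lows[hi]
      hi_e[lo] <- hi_e[hi]
      cnt <- cnt[-hi]; lows <- lows[-hi]; lo_e <- lo_e[-hi]; hi_e <- hi_e[-hi]
    } else k <- k + 1L
  }
  mids <- sqrt(lo_e * hi_e)
  frac <- as.numeric(lows) / cnt
  burst_rate <- n / diff(range(t0))
  p_new <- 1 - exp(-burst_rate * mids)
  p_ret <- return_amplitude * (1 + mids / t_diffusion_s)^(-1.5)
  p_same <- p_ret / (p_ret + p_new)
  decay <- data.frame(delay_s = mids, fraction_low = frac, n_pairs = cnt,
                      p_same = p_same)
  # exponential fit
  Feq0 <- tail(frac, 1); F00 <- frac[1]
  tau_unconstrained <- FALSE
  tau <- NA_real_; tau_se <- NA_real_; F0 <- F00; Feq <- Feq0
  fo <- try(minpack.lm::nlsLM(
    frac ~ Feq + (F0 - Feq) * exp(-mids / tau),
    start = list(Feq = Feq0, F0 = F00, tau = exp(mean(log(mids)))),
    weights = cnt, lower = c(0, 0, delay_window[1] / 100),
    upper = c(1, 1, delay_window[2] * 100),
    control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
  if (!inherits(fo, "try-error")) {
    cf <- coef(fo)
    tau <- cf[["tau"]]; F0 <- cf[["F0"]]; Feq <- cf[["Feq"]]
    sm <- try(summary(fo)$coefficients, silent = TRUE)
    if (!inherits(sm, "try-error")) tau_se <- sm["tau", "Std. Error"]
    # flat decay: amplitude within noise, or tau pinned at the window edge
    if (abs(F0 - Feq) < 2 * sd(frac) / sqrt(length(frac)) ||
        tau <= delay_window[1] / 50 || tau >= delay_window[2] * 50 ||
        (!is.na(tau_se) && tau_se > 10 * tau))
      tau_unconstrained <- TRUE
  } else tau_unconstrained <- TRUE
  structure(list(decay = decay, tau_s = tau, tau_se_s = tau_se,
                 F0 = F0, Feq = Feq,
                 tau_unconstrained = tau_unconstrained, split_E = split_E,
                 n_pairs = sum(cnt)),
            class = "rasp_decay")
}

#' @export
print.rasp_decay <- function(x, ...) {
  cat(sprintf("<rasp_decay> %d pairs in %d bins; split E = %.3f\n",
              x$n_pairs, nrow(x$decay), x$split_E))
  if (x$tau_unconstrained)
    cat("relaxation time unconstrained (flat decay)\n")
  else
    cat(sprintf("tau = %.3g s (+/- %.2g), F0 = %.3f -> Feq = %.3f\n",
                x$tau_s, x$tau_se_s, x$F0, x$Feq))
  invisible(x)
}
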