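# Sub-microsecond photon correlation (nsFCS-style) with a product-of-
# exponentials fit.

#' Photon-pair correlation between two channels
#'
#' Histogram of photon-pair lags normalized by the Poisson expectation, so
#' \eqn{g(\tau) = 1} for an uncorrelated stream and at long lags. Lags are
#' taken in both orders (a before b and b before a) and pooled by absolute
#' value. Empty lag bins are merged adaptively. Optionally fits
#' \deqn{g(\tau) = 1 + \frac{1}{N}\,(1 - c_{ab} e^{-\tau/\tau_{ab}})
#'   (1 + c_{cd} e^{-\tau/\tau_{cd}}) (1 - c_t e^{-\tau/\tau_t})}
#' with selectable antibunching (ab), distance-dynamics (cd) and triplet (t)
#' terms. For a donor--acceptor cross-correlation, distance dynamics make the
#' dynamics amplitude `c_cd` negative (anticorrelated dip at short lag).
#'
#' @param stream a [photon_stream()].
#' @param channel_pair length-2 character vector of channel tags (identical
#'   for an autocorrelation).
#' @param lag_range_s length-2 vector (min, max lag in seconds).
#' @param n_bins number of (linear) lag bins.
#' @param fit_terms character subset of `c("antibunching", "dynamics",
#'   "triplet")`; `NULL` skips fitting.
#' @return Object of class `nsfcs_curve`: `curve` (data.frame `lag_s`, `g`,
#'   `pairs`), `fit` (named coefficients or NULL), `fitted_g`.
#' @export
nsfcs_correlate <- function(stream, channel_pair = c("donor", "acceptor"),
                            lag_range_s = c(1e-7, 1e-4), n_bins = 40,
                            fit_terms = "dynamics") {
  stopifnot(inherits(stream, "photon_stream"))
  ta <- stream$time_s[stream$channel == channel_pair[1]]
  tb <- stream$time_s[stream$channel == channel_pair[2]]
  if (length(ta) < 1000 || length(tb) < 1000)
    warning("fewer than 1000 photons per channel; correlation will be noisy")
  edges <- seq(lag_range_s[1], lag_range_s[2], length.out = n_bins + 1)
  cnt <- pair_counts_cpp(ta, tb, edges)
  if (!identical(channel_pair[1], channel_pair[2])) {
    cnt <- cnt + pair_counts_cpp(tb, ta, edges)
    directions <- 2
  } else directions <- 2  # i<j and j>i lags are mirror images; count both
  if (identical(channel_pair[1], channel_pair[2]))
    cnt <- 2 * cnt
  Tspan <- diff(range(stream$time_s))
  expect <- directions * length(ta) * length(tb) * diff(edges) / Tspan
  # adaptive merge of empty bins
  g_lo <- edges[-length(edges)]; g_hi <- edges[-1]
  while (any(cnt == 0) && length(cnt) > 5) {
    k <- which(cnt == 0)[1]
    m <- if (k == length(cnt)) k - 1L else k + 1L
    lo <- min(k, m); hi <- max(k, m)
    cnt[lo] <- cnt[lo] + cnt[hi]; expect[lo] <- expect[lo] + expect[hi]
    g_hi[lo] <- g_hi[hi]
    cnt <- cnt[-hi]; expect <- expect[-hi]
    g_lo <- g_lo[-hi]; g_hi <- g_hi[-hi]
  }
  mids <- (g_lo + g_hi) / 2
  g <- cnt / expect
  curve <- data.frame(lag_s = mids, g = g, pairs = cnt)
  fit <- NULL; fitted_g <- NULL
  if (!is.null(fit_terms)) {
    use_ab <- "antibunching" %in% fit_terms
    use_cd <- "dynamics" %in% fit_terms
    use_t <- "triplet" %in% fit_terms
    parts <- character(0)
    p0 <- list(N = 1 / max(abs(g[1] - 1), 0.05))
    if (use_ab) {
      parts <- c(parts, "(1 - c_ab * exp(-tau_lag / tau_ab))")
      p0 <- c(p0, c_ab = 0.5, tau_ab = mids[2])
    }
    if (use_cd) {
      parts <- c(parts, "(1 + c_cd * exp(-tau_lag / tau_cd))")
      p0 <- c(p0, c_cd = if (g[1] < tail(g, 1)) -0.5 else 0.5,
              tau_cd = mids[ceiling(length(mids) / 3)])
    }
    if (use_t) {
      parts <- c(parts, "(1 - c_t * exp(-tau_lag / tau_t))")
      p0 <- c(p0, c_t = 0.1, tau_t = mids[2] * 5)
    }
    rhs <- paste0("1 + (1 / N) * ", paste(parts, collapse = " * "))
    df <- data.frame(tau_lag = mids, g = g)
    wt <- pmax(cnt, 1)
    # multi-start over dynamics amplitude sign and timescale
    starts <- list(unlist(p0))
    if (use_cd) {
      for (cc in c(-0.3, 0.3, -0.8, 0.8))
        for (tc in mids[pmax(1, round(length(mids) * c(0.25, 0.6)))]) {
          s <- unlist(p0); s[["c_cd"]] <- cc; s[["tau_cd"]] <- tc
          starts <- c(starts, list(s))
        }
    }
    fo <- NULL
    for (s in starts) {
      cand <- try(minpack.lm::nlsLM(
        stats::as.formula(paste("g ~", rhs)),
        data = df, start = s, weights = wt,
        control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
      if (!inherits(cand, "try-error") &&
          (is.null(fo) || stats::deviance(cand) < stats::deviance(fo)))
        fo <- cand
    }
    if (is.null(fo))
      stop_fs("nsFCS fit did not converge from any starting point")
    fit <- coef(fo)
    fitted_g <- predict(fo)
  }
  structure(list(curve = curve, fit = fit, fitted_g = fitted_g),
            class = "nsfcs_curve")
}

#' @export
print.nsfcs_curve <- function(x, ...) {
  cat(sprintf("<nsfcs_curve> %d bins, g(first) = %.3f, g(last) = %.3f\n",
              nrow(x$curve), x$curve$g[1], tail(x$curve$g, 1)))
  if (!is.null(x$fit)) {
    cat("fit: ")
    cat(paste(sprintf("%s = %.4g", names(x$fit), x$fit), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Direct O(n^2) pair correlation (reference implementation)
#'
#' Brute-force pair counting used as an independent check of the binned-lag
#' correlator on small streams.
#' @param ta,tb sorted photon times.
#' @param edges lag-bin edges (s).
#' @return vector of pair counts per bin.
#' @export
pair_counts_direct <- function(ta, tb, edges) {
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  for (i in seq_along(ta)) {
    lag <- tb - ta[i]
    lag <- lag[lag >= edges[1] & lag < edges[length(edges)]]
    if (length(lag))
      counts <- counts + tabulate(findInterval(lag, edges), nbins = nb)
  }
  counts
}
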