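# Seeded synthetic-data generators: ground truth for every pipeline stage.

#' Generate a charged/neutral amino-acid sequence
#'
#' Builds sequences with an exact charge composition and a controlled
#' arrangement: `"random"` permutation, `"blocky"` (positive block, neutral
#' middle, negative block), `"alternating"` (charges interleaved along the
#' chain), or `"target_scd"` (annealed pair swaps until the sequence charge
#' decoration is within `tolerance` of `target_scd`).
#'
#' @param length chain length.
#' @param frac_pos,frac_neg fractions of positive (K) and negative (E)
#'   residues; must sum to at most 1 (the rest is G/S filler).
#' @param arrangement see above.
#' @param target_scd,tolerance target for `"target_scd"` mode.
#' @param seed RNG seed (mandatory).
#' @return a [residue_sequence()].
#' @export
gen_sequence <- function(length, frac_pos = 0.2, frac_neg = 0.2,
                         arrangement = c("random", "blocky", "alternating",
                                         "target_scd"),
                         target_scd = NULL, tolerance = 0.05, seed) {
  arrangement <- match.arg(arrangement)
  if (missing(seed)) stop_fs("seed is mandatory")
  if (frac_pos + frac_neg > 1) stop_fs("charge fractions exceed 1")
  set.seed(seed)
  npos <- round(frac_pos * length); nneg <- round(frac_neg * length)
  nneu <- length - npos - nneg
  neutral <- sample(c("G", "S"), nneu, replace = TRUE)
  res <- switch(arrangement,
    blocky = c(rep("K", npos), neutral, rep("E", nneg)),
    alternating = {
      # strict +/- alternation while both species last, remainder appended
      m <- min(npos, nneg)
      charged <- c(rep(c("K", "E"), m),
                   rep("K", npos - m), rep("E", nneg - m))
      # place charges at evenly spaced positions
      out <- character(length)
      if (npos + nneg > 0) {
        at <- round(seq(1, length, length.out = npos + nneg))
        out[at] <- charged
      }
      out[out == ""] <- neutral
      out
    },
    random = sample(c(rep("K", npos), rep("E", nneg), neutral)),
    target_scd = {
      if (is.null(target_scd)) stop_fs("target_scd required")
      cur <- sample(c(rep("K", npos), rep("E", nneg), neutral))
      scd_of <- function(r) compute_charge_metrics(residue_sequence(r))$scd
      s <- scd_of(cur)
      best <- cur; bs <- s
      range_probe <- replicate(200, scd_of(sample(cur)))
      for (it in seq_len(4000)) {
        if (abs(bs - target_scd) < tolerance) break
        ij <- sample(length, 2)
        cand <- best; cand[ij] <- cand[rev(ij)]
        cs <- scd_of(cand)
        # accept moves toward the target, occasionally sideways
        if (abs(cs - target_scd) < abs(bs - target_scd) ||
            runif(1) < 0.02) { best <- cand; bs <- cs }
      }
      if (abs(bs - target_scd) >= tolerance)
        stop_fs("SCD target %.3f unreachable for this composition (sampled range [%.3f, %.3f])",
                target_scd, min(range_probe), max(range_probe))
      best
    })
  residue_sequence(res, name = sprintf("synth_%s_L%d", arrangement, length))
}

#' Ornstein--Uhlenbeck distance trajectory
#'
#' Exact discretization (not Euler) of the OU process with stationary mean
#' `mean_nm`, stationary standard deviation `sd_nm` and diffusion coefficient
#' `D_nm2us`; the relaxation time is \eqn{\tau = sd^2/D}.
#'
#' @param D_nm2us diffusion coefficient (nm^2/us).
#' @param mean_nm,sd_nm stationary distribution parameters.
#' @param dt_us time step (us); must satisfy `dt <= tau/5`.
#' @param n number of samples.
#' @param seed RNG seed (mandatory).
#' @return Object of class `ou_trajectory`: `r_nm`, `t_us`, and the
#'   ground-truth spec as attributes.
#' @export
gen_ou_trajectory <- function(D_nm2us, mean_nm, sd_nm, dt_us, n, seed) {
  if (missing(seed)) stop_fs("seed is mandatory")
  if (any(c(D_nm2us, sd_nm, dt_us, n) <= 0)) stop_fs("parameters must be positive")
  tau <- sd_nm^2 / D_nm2us
  if (dt_us > tau / 5)
    stop_fs("dt too large: require dt <= tau/5 = %.4g us", tau / 5)
  set.seed(seed)
  phi <- exp(-dt_us / tau)
  innov_sd <- sd_nm * sqrt(1 - phi^2)
  eps <- rnorm(n, 0, innov_sd)
  x0 <- rnorm(1, 0, sd_nm)
  r <- mean_nm + as.numeric(filter(eps, phi, method = "recursive",
                                   init = x0))
  structure(list(r_nm = r, t_us = (seq_len(n) - 1) * dt_us,
                 truth = list(D_nm2us = D_nm2us, mean_nm = mean_nm,
                              sd_nm = sd_nm, tau_us = tau, seed = seed)),
            class = "ou_trajectory")
}

#' Synthetic confocal photon stream
#'
#' Molecules arrive as a Poisson process, start uniformly inside an absorbing
#' shell of radius `shell_factor` beam waists, diffuse in 3-D (so genuine
#' re-entries into the detection volume occur -- the premise of recurrence
#' analysis), and emit photons at `brightness_khz` scaled by a 3-D Gaussian
#' detection profile. Donor/acceptor splitting follows the current
#' efficiency from either a two-state telegraph process (`kind =
#' "two_state"`) or an Ornstein--Uhlenbeck distance coordinate mapped through
#' the Foerster relation (`kind = "diffusive"`). Uniform background is added
#' per channel. The ground truth (per-photon molecule identity and
#' state/distance) is returned as a sidecar.
#'
#' @param kind `"two_state"` or `"diffusive"`.
#' @param duration_s measurement length.
#' @param seed RNG seed (mandatory).
#' @param arrival_rate_hz new-molecule rate.
#' @param brightness_khz peak photon rate at the focus.
#' @param bg_donor_hz,bg_acceptor_hz background rates.
#' @param w_xy_um,w_z_um lateral/axial beam waists.
#' @param shell_factor absorbing-shell radius in units of `w_xy_um`.
#' @param D_um2s translational diffusion coefficient.
#' @param dt_s propagation step.
#' @param E_states,k12_hz,k21_hz two-state efficiencies and switching rates.
#' @param ou_mean_nm,ou_sd_nm,ou_D_nm2us,R0_nm diffusive-mode distance
#'   process and Foerster radius.
#' @return list: `stream` (a [photon_stream()]) and `truth` (data.frame
#'   `molecule`, `state_or_r` per photon, plus the generator spec).
#' @export
gen_photon_stream <- function(kind = c("two_state", "diffusive"),
                              duration_s = 60, seed,
                              arrival_rate_hz = 400,
                              brightness_khz = 800,
                              bg_donor_hz = 800, bg_acceptor_hz = 800,
                              w_xy_um = 0.35, w_z_um = 1.0,
                              shell_factor = 8,
                              D_um2s = 300, dt_s = 1e-6,
                              E_states = c(0.3, 0.7),
                              k12_hz = 1000, k21_hz = 1000,
                              ou_mean_nm = 5, ou_sd_nm = 1.5,
                              ou_D_nm2us = 5e-3, R0_nm = 5.4) {
  kind <- match.arg(kind)
  if (missing(seed)) stop_fs("seed is mandatory")
  if (duration_s <= 0 || arrival_rate_hz <= 0) stop_fs("rates and durations must be positive")
  exp_bursts <- arrival_rate_hz * duration_s * 0.1
  if (exp_bursts < 1)
    stop_fs("parameter combination yields < 1 expected burst")
  res <- gen_photons_cpp(duration_s, arrival_rate_hz, brightness_khz * 1000,
                         bg_donor_hz, bg_acceptor_hz,
                         w_xy_um, w_z_um, shell_factor * w_xy_um,
                         D_um2s, dt_s,
                         if (kind == "two_state") 0L else 1L,
                         E_states[1], E_states[2], k12_hz, k21_hz,
                         ou_mean_nm, ou_sd_nm, ou_D_nm2us, R0_nm,
                         as.integer(seed))
  stream <- photon_stream(res$time_s, res$channel)
  truth <- data.frame(molecule = res$molecule, state_or_r = res$truth)
  attr(truth, "spec") <- list(kind = kind, seed = seed,
                              E_states = E_states, k12_hz = k12_hz,
                              k21_hz = k21_hz,
                              tau_exchange_s = 1 / (k12_hz + k21_hz),
                              ou = list(mean_nm = ou_mean_nm,
                                        sd_nm = ou_sd_nm,
                                        D_nm2us = ou_D_nm2us,
                                        tau_us = ou_sd_nm^2 / ou_D_nm2us),
                              R0_nm = R0_nm)
  list(stream = stream, truth = truth)
}

#' Write a generator ground-truth sidecar as JSON
#' @param truth the `truth` element of a generator result.
#' @param path output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(attr(truth, "spec"), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
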