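# Trajectory observables: scaling-exponent maps, distance dynamics, contact
# statistics, center-of-mass distributions, surface coverage.

traj_dims <- function(traj) {
  stopifnot(inherits(traj, "cg_trajectory"))
  d <- dim(traj$frames)
  list(n_frames = d[1], n_beads = d[2])
}

pair_distance_series <- function(traj, i, j) {
  dx <- traj$frames[, i, 1] - traj$frames[, j, 1]
  dy <- traj$frames[, i, 2] - traj$frames[, j, 2]
  dz <- traj$frames[, i, 3] - traj$frames[, j, 3]
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Length-scaling exponent map
#'
#' For every residue pair with \eqn{|i-j| \ge } `min_sep`,
#' \deqn{\nu_{ij} = \ln(\langle R_{ij}^2\rangle^{1/2}/b)\,/\,\ln|i-j|.}
#' Ideal-chain statistics give \eqn{\nu = 0.5}; collapse pushes long-range
#' exponents down, expansion up.
#'
#' @param traj a `cg_trajectory` (disordered chain; for complexes pass bead
#'   indices of the chain through `beads`).
#' @param b prefactor (nm), the per-residue contour step.
#' @param beads bead indices forming the chain (default all).
#' @param min_sep minimum sequence separation (default 2).
#' @param min_frames required number of frames (default 200).
#' @return Object of class `scaling_map`: `nu` (symmetric matrix, NA on and
#'   near the diagonal), `b`.
#' @export
scaling_map <- function(traj, b = 0.38, beads = NULL, min_sep = 2,
                        min_frames = 200) {
  td <- traj_dims(traj)
  if (td$n_frames < min_frames)
    stop_fs("insufficient frames: %d < %d", td$n_frames, min_frames)
  if (is.null(beads)) beads <- seq_len(td$n_beads)
  n <- length(beads)
  # mean squared distances via per-frame accumulation
  msd <- matrix(0, n, n)
  for (f in seq_len(td$n_frames)) {
    x <- traj$frames[f, beads, , drop = TRUE]
    msd <- msd + as.matrix(stats::dist(x))^2
  }
  msd <- msd / td$n_frames
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  nu <- log(sqrt(msd) / b) / log(sep)
  nu[sep < min_sep] <- NA
  structure(list(nu = nu, b = b), class = "scaling_map")
}

#' @export
print.scaling_map <- function(x, ...) {
  cat(sprintf("<scaling_map> %d x %d, median nu = %.3f\n",
              nrow(x$nu), ncol(x$nu), median(x$nu, na.rm = TRUE)))
  invisible(x)
}

#' Distance dynamics between two sites
#'
#' Normalized distance autocorrelation \eqn{C(t)} (C(0)=1), the
#' reconfiguration time as the integrated correlation time
#' \eqn{\tau_r = \int_0^{t_0} C(t)\,dt} (integrated to the first
#' nonpositive value of C), the Ornstein--Uhlenbeck-mapped intrachain
#' diffusion coefficient \eqn{D = \mathrm{var}(r)/\tau_r}, and the empirical
#' distance distribution.
#'
#' @param traj a `cg_trajectory`.
#' @param site_i,site_j bead indices.
#' @param n_bins bins for the empirical P(r).
#' @return Object of class `dynamics_summary`: `C` (data.frame `t_ns`,
#'   `corr`), `tau_r_ns`, `D_nm2us`, `distribution`
#'   ([distance_distribution()]), `var_nm2`.
#' @export
distance_dynamics <- function(traj, site_i, site_j, n_bins = 60) {
  td <- traj_dims(traj)
  if (any(c(site_i, site_j) < 1) || any(c(site_i, site_j) > td$n_beads))
    stop_fs("sites outside chain")
  r <- pair_distance_series(traj, site_i, site_j)
  dt <- traj$times_ns[2] - traj$times_ns[1]
  lag_max <- floor(td$n_frames / 3)
  ac <- stats::acf(r, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  tneg <- which(ac <= 0)[1]
  cut <- if (is.na(tneg)) length(ac) else tneg
  tau <- trapz((seq_len(cut) - 1) * dt, ac[seq_len(cut)])
  if (is.na(tneg) && cut * dt >= (td$n_frames * dt) / 3)
    stop_fs("trajectory too short: correlation has not decayed (tau > span/3)")
  h <- graphics::hist(r, breaks = n_bins, plot = FALSE)
  P <- distance_distribution(h$mids, h$density, normalize = TRUE)
  v <- var(r)
  structure(list(
    C = data.frame(t_ns = (seq_along(ac) - 1) * dt, corr = ac),
    tau_r_ns = tau,
    D_nm2us = v / (tau / 1000),
    distribution = P, var_nm2 = v
  ), class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf("distance dynamics: tau_r = %.3g ns, var = %.3g nm^2, D = %.3g nm^2/us\n",
              x$tau_r_ns, x$var_nm2, x$D_nm2us))
  invisible(x)
}

# default residue-class map: charged, hydrophobic, polar, other
.default_class_map <- c(
  D = "C", E = "C", K = "C", R = "C",
  A = "H", V = "H", L = "H", I = "H", M = "H", F = "H", W = "H", Y = "H",
  S = "P", T = "P", N = "P", Q = "P", C = "P", H = "P",
  G = "O", P = "O"
)

#' Residue-class map used for contact typing
#' @return named character vector residue -> class (C/H/P/O).
#' @export
residue_classes <- function() .default_class_map

#' Intermolecular contact statistics
#'
#' Per (ligand residue, IDP residue) pair: contact probability (fraction of
#' frames with bead--bead distance below `cutoff_nm`), mean contact lifetime
#' (from contiguous runs), and a histogram of contact types using a
#' residue-class map (C charged, H hydrophobic, P polar, O other), weighted
#' by frames in contact.
#'
#' @param traj a `cg_trajectory` containing both groups.
#' @param cutoff_nm bead-center contact cutoff (default 1.0 nm).
#' @param class_map named residue -> class vector (default
#'   [residue_classes()]).
#' @return Object of class `contact_stats`: `probability` (ligand x idp
#'   matrix), `mean_lifetime_ns` (same shape), `type_histogram` (named,
#'   sums to 1), `pairs` (data.frame of realized contacts).
#' @export
contact_stats <- function(traj, cutoff_nm = 1.0,
                          class_map = residue_classes()) {
  topo <- traj$topology
  li <- which(topo$groups == "ligand"); ii <- which(topo$groups == "idp")
  if (!length(li) || !length(ii))
    stop_fs("contact statistics require a two-group (complex) trajectory")
  td <- traj_dims(traj)
  nl <- length(li); ni <- length(ii)
  prob <- matrix(0, nl, ni)
  # lifetimes need the full contact time series; store as bit matrix in list
  contact_runs_on <- matrix(0, nl, ni)   # number of on-runs
  contact_frames <- matrix(0, nl, ni)
  prev <- matrix(FALSE, nl, ni)
  for (f in seq_len(td$n_frames)) {
    L <- traj$frames[f, li, , drop = TRUE]
    X <- traj$frames[f, ii, , drop = TRUE]
    d2 <- outer(L[, 1], X[, 1], `-`)^2 + outer(L[, 2], X[, 2], `-`)^2 +
      outer(L[, 3], X[, 3], `-`)^2
    on <- d2 < cutoff_nm^2
    contact_frames <- contact_frames + on
    contact_runs_on <- contact_runs_on + (on & !prev)
    prev <- on
  }
  prob <- contact_frames / td$n_frames
  dt <- if (td$n_frames > 1) traj$times_ns[2] - traj$times_ns[1] else 1
  life <- ifelse(contact_runs_on > 0, contact_frames * dt / contact_runs_on, NA)
  # type histogram over realized contacts, weighted by frames in contact
  cls_l <- class_map[topo$residues[li]]
  cls_i <- class_map[topo$residues[ii]]
  idx <- which(contact_frames > 0, arr.ind = TRUE)
  th <- setNames(numeric(0), character(0))
  if (nrow(idx)) {
    lab <- vapply(seq_len(nrow(idx)), function(k) {
      a <- sort(c(cls_l[idx[k, 1]], cls_i[idx[k, 2]]))
      paste(a, collapse = "-")
    }, character(1))
    th <- tapply(contact_frames[idx], lab, sum)
    th <- th / sum(th)
  }
  pairs <- if (nrow(idx)) data.frame(
    ligand_bead = li[idx[, 1]], idp_bead = ii[idx[, 2]],
    probability = prob[idx], mean_lifetime_ns = life[idx]
  ) else data.frame(ligand_bead = integer(), idp_bead = integer(),
                    probability = numeric(), mean_lifetime_ns = numeric())
  structure(list(probability = prob, mean_lifetime_ns = life,
                 type_histogram = th, pairs = pairs,
                 cutoff_nm = cutoff_nm),
            class = "contact_stats")
}

#' @export
print.contact_stats <- function(x, ...) {
  cat(sprintf("<contact_stats> %d x %d pairs, %d realized contacts\n",
              nrow(x$probability), ncol(x$probability), nrow(x$pairs)))
  if (length(x$type_histogram)) {
    cat("contact types: ")
    cat(paste(sprintf("%s %.2f", names(x$type_histogram), x$type_histogram),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Angular and axial center-of-mass distribution of a chain segment
#'
#' The ligand long axis is the unit vector from the center of mass of the
#' first ligand block to that of the last (by default the first and last 10%
#' of ligand beads). Per frame, the segment's center of mass is decomposed
#' into an axial projection onto that axis and an azimuth about it (reference
#' direction fixed from the first frame).
#'
#' @param traj a complex `cg_trajectory`.
#' @param segment IDP residue interval (indices within the IDP chain),
#'   length-2 vector.
#' @param axis_beads optional list(from, to) of ligand bead index vectors
#'   defining the axis endpoints.
#' @param n_bins histogram bins.
#' @return Object of class `com_distribution`: `angular` (data.frame
#'   `deg`, `density`; normalized), `axial` (`nm`, `density`),
#'   `angular_undefined` flag.
#' @export
com_distribution <- function(traj, segment, axis_beads = NULL, n_bins = 36) {
  topo <- traj$topology
  li <- which(topo$groups == "ligand"); ii <- which(topo$groups == "idp")
  if (!length(li) || !length(ii)) stop_fs("complex trajectory required")
  td <- traj_dims(traj)
  if (is.null(axis_beads)) {
    k <- max(1L, floor(length(li) / 10))
    axis_beads <- list(from = li[seq_len(k)],
                       to = li[(length(li) - k + 1):length(li)])
  }
  seg <- ii[segment[1]:segment[2]]
  ang <- numeric(td$n_frames); axl <- numeric(td$n_frames)
  radial <- numeric(td$n_frames)
  ref <- NULL
  for (f in seq_len(td$n_frames)) {
    P <- traj$frames[f, , , drop = TRUE]
    a0 <- colMeans(P[axis_beads$from, , drop = FALSE])
    a1 <- colMeans(P[axis_beads$to, , drop = FALSE])
    ax <- a1 - a0; axn <- sqrt(sum(ax^2))
    if (axn < 1) stop_fs("degenerate ligand axis (length %.2f nm < 1 nm)", axn)
    u <- ax / axn
    com <- colMeans(P[seg, , drop = FALSE]) - a0
    axl[f] <- sum(com * u)
    perp <- com - axl[f] * u
    radial[f] <- sqrt(sum(perp^2))
    if (is.null(ref)) {
      # azimuth reference: lab axis least aligned with u, orthogonalized
      cand <- diag(3)[, which.min(abs(u))]
      e1 <- cand - sum(cand * u) * u; e1 <- e1 / sqrt(sum(e1^2))
      ref <- list(e1 = e1, e2 = c(u[2] * e1[3] - u[3] * e1[2],
                                  u[3] * e1[1] - u[1] * e1[3],
                                  u[1] * e1[2] - u[2] * e1[1]))
    }
    ang[f] <- atan2(sum(perp * ref$e2), sum(perp * ref$e1)) * 180 / pi
  }
  angular_undefined <- median(radial) < 0.05
  ab <- seq(-180, 180, length.out = n_bins + 1)
  ah <- graphics::hist(ang, breaks = ab, plot = FALSE)
  xh <- graphics::hist(axl, breaks = n_bins, plot = FALSE)
  structure(list(
    angular = data.frame(deg = ah$mids, density = ah$density),
    axial = data.frame(nm = xh$mids, density = xh$density),
    angular_undefined = angular_undefined,
    samples = data.frame(deg = ang, nm = axl, radial_nm = radial)
  ), class = "com_distribution")
}

#' Fraction of the ligand surface explored by the disordered chain
#'
#' Surface beads are ligand beads whose coordination number (neighbours
#' within `burial_cutoff_nm` in the ligand's reference conformation, frame 1)
#' is below `burial_threshold`. Coverage is the fraction of surface beads
#' contacted by any IDP bead (within `cutoff_nm`) in at least one frame.
#'
#' @param traj a complex `cg_trajectory`.
#' @param cutoff_nm contact cutoff (default 1.0 nm).
#' @param burial_cutoff_nm neighbour cutoff defining burial (default 1.2 nm).
#' @param burial_threshold maximum coordination for a surface bead
#'   (default 14).
#' @return list `coverage` (fraction), `surface_beads`, `touched`.
#' @export
surface_coverage <- function(traj, cutoff_nm = 1.0, burial_cutoff_nm = 1.2,
                             burial_threshold = 14) {
  topo <- traj$topology
  li <- which(topo$groups == "ligand"); ii <- which(topo$groups == "idp")
  if (!length(li) || !length(ii)) stop_fs("complex trajectory required")
  td <- traj_dims(traj)
  L0 <- traj$frames[1, li, , drop = TRUE]
  dl <- as.matrix(stats::dist(L0))
  coord <- rowSums(dl < burial_cutoff_nm) - 1
  surf <- which(coord < burial_threshold)
  if (!length(surf)) stop_fs("no surface beads under burial threshold %d",
                             burial_threshold)
  touched <- rep(FALSE, length(surf))
  for (f in seq_len(td$n_frames)) {
    L <- traj$frames[f, li[surf], , drop = TRUE]
    X <- traj$frames[f, ii, , drop = TRUE]
    d2 <- outer(L[, 1], X[, 1], `-`)^2 + outer(L[, 2], X[, 2], `-`)^2 +
      outer(L[, 3], X[, 3], `-`)^2
    touched <- touched | (apply(d2, 1, min) < cutoff_nm^2)
  }
  list(coverage = mean(touched), surface_beads = li[surf],
       touched = li[surf][touched])
}
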