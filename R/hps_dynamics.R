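# Overdamped Langevin (Brownian) dynamics driver for CG bead systems.

#' Run overdamped Langevin dynamics
#'
#' Integrates the bead system with the Euler--Maruyama Brownian scheme
#' \eqn{x \leftarrow x + \mu F \Delta t + \sqrt{2 D \Delta t}\,\xi}, with the
#' bead mobility \eqn{\mu} fixed by the reference diffusivity at 297 K and
#' \eqn{D = \mu k_B T}, so a zero-temperature run has no noise but retains
#' deterministic drift. Identical seed and parameters give bit-identical
#' trajectories.
#'
#' Interpreted timescales are CG time: relative dynamics are meaningful,
#' absolute times are typically orders of magnitude faster than atomistic.
#'
#' @param system a `list(topology, contacts)` from [build_system()], or a
#'   bare [bead_topology()] (then no native contacts).
#' @param params an [interaction_params()] list.
#' @param n_steps number of integration steps.
#' @param report_every frame stride.
#' @param minimize_steps capped steepest-descent steps run before dynamics to
#'   relax steric overlaps (default 1000).
#' @return Object of class `cg_trajectory`: `frames` (array
#'   frames x beads x 3, nm), `times_ns`, `energy_kcal`, `topology`,
#'   `params`.
#' @export
run_langevin <- function(system, params = interaction_params(),
                         n_steps = 1e5, report_every = 100,
                         minimize_steps = 1000) {
  if (inherits(system, "bead_topology"))
    system <- list(topology = system,
                   contacts = data.frame(ligand_bead = integer(),
                                         idp_bead = integer(),
                                         r0_nm = numeric()))
  topo <- system$topology
  contacts <- system$contacts
  stopifnot(inherits(topo, "bead_topology"))
  if (n_steps <= 0) stop_fs("n_steps must be positive")
  report_every <- max(1L, as.integer(report_every))

  kT <- .kB_kcal * params$temperature_K
  kT_ref <- .kB_kcal * 297
  mobility <- params$bead_D_nm2ps / kT_ref        # nm^2 / (ps kcal/mol)
  noise_D <- mobility * kT                         # nm^2/ps at run temperature

  ri <- which(topo$restrained)
  rref <- topo$positions[ri, , drop = FALSE]
  bonds <- topo$bonds
  dh_cut <- min(3.5, 5 * params$debye_length_nm)

  res <- run_langevin_cpp(
    topo$positions,
    as.integer(bonds$i - 1L), as.integer(bonds$j - 1L),
    as.numeric(bonds$r0), as.numeric(bonds$k),
    as.numeric(topo$charges), as.numeric(topo$lambdas),
    as.numeric(topo$sigmas),
    as.integer(if (nrow(contacts)) contacts$ligand_bead - 1L else integer()),
    as.integer(if (nrow(contacts)) contacts$idp_bead - 1L else integer()),
    as.numeric(if (nrow(contacts)) contacts$r0_nm else numeric()),
    params$epsilon, params$zeta,
    kT, mobility, noise_D,
    params$debye_length_nm, .ke_kcal_A / 10 / params$dielectric,
    2.0, dh_cut,
    as.integer(ri - 1L), rref, topo$restraint_k,
    params$timestep_ps, as.integer(n_steps), report_every,
    params$seed, as.integer(minimize_steps))

  structure(list(frames = res$frames,
                 times_ns = res$times / 1000,
                 energy_kcal = res$energy,
                 topology = topo, params = params),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cg_trajectory> %d frames x %d beads, %.3g ns span\n",
              d[1], d[2], max(x$times_ns)))
  invisible(x)
}

#' Assemble a trajectory object from precomputed frames
#'
#' Used by the synthetic generators for scripted trajectories; also the entry
#' point for externally computed frames.
#'
#' @param frames array (frames x beads x 3, nm).
#' @param times_ns frame times (uniform spacing).
#' @param topology the matching [bead_topology()].
#' @param params optional parameter echo.
#' @return `cg_trajectory` object.
#' @export
cg_trajectory <- function(frames, times_ns, topology, params = NULL) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] == 3L)
  if (dim(frames)[1] != length(times_ns))
    stop_fs("frame/time length mismatch")
  if (dim(frames)[1] < 1L) stop_fs("empty trajectory")
  dt <- diff(times_ns)
  if (length(dt) && (max(dt) - min(dt)) > 1e-9 * max(dt))
    stop_fs("frame spacing must be uniform")
  structure(list(frames = frames, times_ns = times_ns,
                 energy_kcal = NULL, topology = topology, params = params),
            class = "cg_trajectory")
}

#' Extract a frame window from a trajectory
#'
#' Typical use: discarding an equilibration burn-in before computing
#' observables.
#' @param traj a `cg_trajectory`.
#' @param from,to frame indices (inclusive).
#' @return a `cg_trajectory` over the selected frames (times re-zeroed).
#' @export
traj_window <- function(traj, from, to = NULL) {
  d <- dim(traj$frames)
  if (is.null(to)) to <- d[1]
  stopifnot(from >= 1, to <= d[1], from < to)
  cg_trajectory(traj$frames[from:to, , , drop = FALSE],
                traj$times_ns[from:to] - traj$times_ns[from],
                traj$topology, traj$params)
}

#' Radius of gyration per frame
#' @param traj a `cg_trajectory`.
#' @param beads bead subset (default all).
#' @return numeric vector (nm) per frame.
#' @export
radius_of_gyration <- function(traj, beads = NULL) {
  d <- dim(traj$frames)
  if (is.null(beads)) beads <- seq_len(d[2])
  vapply(seq_len(d[1]), function(f) {
    x <- traj$frames[f, beads, , drop = TRUE]
    sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
  }, numeric(1))
}

#' Write / read a trajectory as headered XYZ text
#'
#' Plain-text trajectory interchange: a JSON header line (beads, frames,
#' times) followed by one line per bead per frame.
#'
#' @param traj a `cg_trajectory`.
#' @param path output file.
#' @return `path`, invisibly (`read_trajectory_xyz` returns frames+times).
#' @export
write_trajectory_xyz <- function(traj, path) {
  d <- dim(traj$frames)
  hdr <- jsonlite::toJSON(list(n_frames = d[1], n_beads = d[2],
                               times_ns = traj$times_ns), auto_unbox = TRUE,
                          digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  for (f in seq_len(d[1])) {
    m <- traj$frames[f, , , drop = TRUE]
    writeLines(sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory_xyz
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  dat <- do.call(rbind, strsplit(lines[-1], " "))
  storage.mode(dat) <- "double"
  frames <- array(NA_real_, c(hdr$n_frames, hdr$n_beads, 3))
  for (f in seq_len(hdr$n_frames)) {
    rows <- (f - 1L) * hdr$n_beads + seq_len(hdr$n_beads)
    frames[f, , ] <- dat[rows, ]
  }
  list(frames = frames, times_ns = hdr$times_ns)
}
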