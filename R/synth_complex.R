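# Toy folded-scaffold / disordered-chain complex: a desk-scale stand-in for
# a crystallographic complex with planted, schedule-controlled intermolecular
# contacts and a two-copy PDB fixture emulating asymmetric-unit ambiguity.

fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

write_pdb_text <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (row in seq_len(nrow(df))) {
    serial <- serial + 1L
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, bio3d::aa123(df$aa[row]), df$chain[row], df$resno[row],
      df$x[row] * 10, df$y[row] * 10, df$z[row] * 10), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Generate a toy scaffold/chain complex with planted contacts
#'
#' Builds (a) a rigid spherical scaffold plus a flexible chain as a
#' [bead_topology()]; (b) a scripted trajectory in which each planted
#' (scaffold bead, chain residue) contact is realized periodically with a
#' stated duty cycle and on-lifetime, giving exact ground truth for contact
#' statistics; and (c) a two-copy PDB fixture in which the two copies
#' resolve different, partially overlapping parts of the chain (emulating
#' asymmetric-unit ambiguity), with the planted contacts geometrically
#' realized so structure-based contact extraction recovers exactly the
#' planted set.
#'
#' @param chain_length disordered-chain length (residues).
#' @param scaffold_n number of scaffold beads.
#' @param scaffold_radius_nm scaffold sphere radius.
#' @param contacts data.frame with columns `idp_resno`, `duty_cycle`
#'   (fraction of frames in contact), `lifetime_frames` (mean on-run
#'   length). Scaffold partners are assigned around the scaffold equator. A
#'   chain residue may appear only once (overlapping schedules would be
#'   contradictory).
#' @param n_frames scripted-trajectory length.
#' @param frame_dt_ns frame spacing.
#' @param resolved_copy1,resolved_copy2 inclusive residue intervals of the
#'   chain resolved in each PDB copy (defaults give a shared resolved
#'   fraction of 18/40 = 0.45).
#' @param idp_seq optional [residue_sequence()] of length `chain_length`.
#' @param pdb_path if non-NULL, the two-copy fixture is written here.
#' @param seed RNG seed (mandatory).
#' @return list of class `toy_complex`: `topology`, `trajectory`
#'   (scripted `cg_trajectory`), `planted` (contact table with scaffold
#'   partners), `pdb_path`, `shared_fraction` (constructed value),
#'   `idp_seq`, and `truth` spec.
#' @export
gen_toy_complex <- function(chain_length = 40, scaffold_n = 80,
                            scaffold_radius_nm = 1.6,
                            contacts = data.frame(
                              idp_resno = c(14, 18, 20, 22, 26),
                              duty_cycle = c(0.3, 0.5, 0.7, 0.5, 0.3),
                              lifetime_frames = c(10, 12, 20, 12, 10)),
                            n_frames = 2000, frame_dt_ns = 1,
                            resolved_copy1 = c(1, 29),
                            resolved_copy2 = c(12, 40),
                            idp_seq = NULL, pdb_path = NULL, seed) {
  if (missing(seed)) stop_fs("seed is mandatory")
  if (nrow(contacts) && anyDuplicated(contacts$idp_resno))
    stop_fs("contradictory schedules: chain residue planted in two contacts")
  if (nrow(contacts) && (any(contacts$idp_resno < 1) ||
                         any(contacts$idp_resno > chain_length)))
    stop_fs("planted contact references residue outside the chain")
  set.seed(seed)
  if (is.null(idp_seq))
    idp_seq <- gen_sequence(chain_length, frac_pos = 0.15, frac_neg = 0.25,
                            arrangement = "random", seed = seed + 1L)
  stopifnot(length(idp_seq$residues) == chain_length)

  scaf_pos <- fibonacci_sphere(scaffold_n, scaffold_radius_nm)
  scaf_res <- rep(c("L", "K", "S", "A", "E", "T", "F", "G"),
                  length.out = scaffold_n)

  # assign scaffold partners around the equator (|z| small), spread in azimuth
  eq_idx <- order(abs(scaf_pos[, 3]))[seq_len(max(12L, 2L * nrow(contacts)))]
  eq_idx <- eq_idx[order(atan2(scaf_pos[eq_idx, 2], scaf_pos[eq_idx, 1]))]
  partner <- if (nrow(contacts))
    eq_idx[round(seq(1, length(eq_idx), length.out = nrow(contacts)))] else
      integer()
  planted <- contacts
  planted$scaffold_bead <- partner

  # chain rest positions: great-circle path at 1.5 nm above the surface
  r_out <- scaffold_radius_nm + 1.5
  ang <- seq(0, 1.6 * pi, length.out = chain_length)
  chain_rest <- cbind(r_out * cos(ang), r_out * sin(ang),
                      seq(-0.4, 0.4, length.out = chain_length))
  # contact residues: "on" position 0.5 nm radially outside the partner bead,
  # "off" position 1.5 nm further out
  on_pos <- off_pos <- matrix(NA_real_, nrow(planted), 3)
  for (k in seq_len(nrow(planted))) {
    u <- scaf_pos[planted$scaffold_bead[k], ] / scaffold_radius_nm
    on_pos[k, ] <- scaf_pos[planted$scaffold_bead[k], ] + 0.5 * u
    off_pos[k, ] <- scaf_pos[planted$scaffold_bead[k], ] + 2.0 * u
  }

  frames <- array(NA_real_, c(n_frames, scaffold_n + chain_length, 3))
  for (f in seq_len(n_frames)) {
    frames[f, seq_len(scaffold_n), ] <- scaf_pos
    frames[f, scaffold_n + seq_len(chain_length), ] <- chain_rest
  }
  phase <- if (nrow(planted)) sample(1000L, nrow(planted), replace = TRUE) else integer()
  schedule <- matrix(FALSE, n_frames, max(nrow(planted), 1L))
  for (k in seq_len(nrow(planted))) {
    on_len <- planted$lifetime_frames[k]
    period <- max(round(on_len / planted$duty_cycle[k]), on_len + 1L)
    on <- ((seq_len(n_frames) + phase[k]) %% period) < on_len
    schedule[, k] <- on
    b <- scaffold_n + planted$idp_resno[k]
    frames[on, b, ] <- matrix(on_pos[k, ], sum(on), 3, byrow = TRUE)
    frames[!on, b, ] <- matrix(off_pos[k, ], sum(!on), 3, byrow = TRUE)
  }

  # topology: scaffold restrained, chain bonded
  bonds <- rbind(chain_bonds(seq_len(scaffold_n)),
                 chain_bonds(scaffold_n + seq_len(chain_length)))
  topo <- bead_topology(frames[1, , ],
                        c(scaf_res, idp_seq$residues), bonds,
                        groups = c(rep("ligand", scaffold_n),
                                   rep("idp", chain_length)),
                        restrained = c(rep(TRUE, scaffold_n),
                                       rep(FALSE, chain_length)))
  traj <- cg_trajectory(frames, (seq_len(n_frames) - 1) * frame_dt_ns, topo)

  # two-copy PDB fixture
  shared <- length(intersect(seq(resolved_copy1[1], resolved_copy1[2]),
                             seq(resolved_copy2[1], resolved_copy2[2]))) /
    length(union(seq(resolved_copy1[1], resolved_copy1[2]),
                 seq(resolved_copy2[1], resolved_copy2[2])))
  if (!is.null(pdb_path)) {
    rows <- list()
    # resolved chain residues sit 0.9 nm above the surface along the path,
    # except planted contacts, which sit at 0.42 nm above their partner
    chain_xyz <- matrix(NA_real_, chain_length, 3)
    path_pos <- cbind((scaffold_radius_nm + 0.9) * cos(ang),
                      (scaffold_radius_nm + 0.9) * sin(ang),
                      seq(-0.4, 0.4, length.out = chain_length))
    chain_xyz[] <- path_pos
    for (k in seq_len(nrow(planted))) {
      u <- scaf_pos[planted$scaffold_bead[k], ] / scaffold_radius_nm
      chain_xyz[planted$idp_resno[k], ] <-
        scaf_pos[planted$scaffold_bead[k], ] + 0.42 * u
    }
    mk_chain <- function(ch, resno, aa, xyz)
      data.frame(chain = ch, resno = resno, aa = aa,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    r1 <- seq(resolved_copy1[1], resolved_copy1[2])
    r2 <- seq(resolved_copy2[1], resolved_copy2[2])
    df <- rbind(
      mk_chain("A", seq_len(scaffold_n), scaf_res, scaf_pos),
      mk_chain("B", r1, idp_seq$residues[r1], chain_xyz[r1, , drop = FALSE]),
      mk_chain("C", seq_len(scaffold_n), scaf_res, scaf_pos),
      mk_chain("D", r2, idp_seq$residues[r2], chain_xyz[r2, , drop = FALSE]))
    write_pdb_text(df, pdb_path)
  }

  structure(list(
    topology = topo, trajectory = traj, planted = planted,
    pdb_path = pdb_path, shared_fraction = shared, idp_seq = idp_seq,
    truth = list(seed = seed, n_frames = n_frames,
                 duty_cycles = planted$duty_cycle,
                 lifetimes_ns = planted$lifetime_frames * frame_dt_ns,
                 realized_duty = colMeans(schedule)[seq_len(nrow(planted))])
  ), class = "toy_complex")
}
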