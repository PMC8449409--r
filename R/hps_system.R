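# System construction for the coarse-grained HPS simulator: bead topologies,
# the Ashbaugh-Hatch + Debye-Hueckel pair potential, structure parsing, and
# native-contact extraction.

#' Interaction parameters of the coarse-grained model
#'
#' @param epsilon global hydrophobic interaction strength (kcal/mol);
#'   0.16 kcal/mol reproduces the free-chain FRET data.
#' @param zeta strength of the intermolecular native-contact wells
#'   (kcal/mol); 0.6 kcal/mol in the flexible-complex model.
#' @param ionic_strength_mM sets the Debye length (82 mM is the reference
#'   buffer condition).
#' @param temperature_K temperature.
#' @param dielectric solvent dielectric constant.
#' @param timestep_ps integrator timestep (CG time).
#' @param bead_D_nm2ps reference bead diffusivity at 297 K (Stokes radius
#'   ~0.38 nm in water).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return list of class `interaction_params`, including the derived
#'   `debye_length_nm`.
#' @export
interaction_params <- function(epsilon = 0.16, zeta = 0.6,
                               ionic_strength_mM = 82, temperature_K = 297,
                               dielectric = 80, timestep_ps = 0.01,
                               bead_D_nm2ps = 6.4e-4, seed = 1L) {
  if (epsilon < 0 || zeta < 0) stop_fs("epsilon and zeta must be nonnegative")
  if (timestep_ps <= 0) stop_fs("timestep must be positive")
  structure(list(
    epsilon = epsilon, zeta = zeta,
    ionic_strength_mM = ionic_strength_mM,
    debye_length_nm = debye_length(ionic_strength_mM, max(temperature_K, 273),
                                   dielectric),
    temperature_K = temperature_K, dielectric = dielectric,
    timestep_ps = timestep_ps, bead_D_nm2ps = bead_D_nm2ps,
    seed = as.integer(seed)
  ), class = "interaction_params")
}

#' Pairwise CG interaction energy
#'
#' Ashbaugh--Hatch potential (attractive branch scaled by the pair
#' hydropathy) plus a Debye--Hueckel screened-Coulomb term:
#' \deqn{\Phi_{AH} = \Phi_{LJ} + (1-\lambda_{ij})\epsilon \;(r \le 2^{1/6}\sigma_{ij}),
#'       \quad \lambda_{ij}\Phi_{LJ} \;\mathrm{otherwise}}
#' with \eqn{\Phi_{LJ} = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}, and
#' \deqn{\Phi_{DH} = \frac{k_e q_i q_j}{\epsilon_r r} e^{-r/\kappa^{-1}}.}
#'
#' @param r distance (nm), positive.
#' @param lambda_ij pair hydropathy (mean of the two bead lambdas).
#' @param sigma_ij pair diameter (nm).
#' @param epsilon hydrophobic strength (kcal/mol).
#' @param q_i,q_j charges (e).
#' @param debye_length_nm Debye length (nm).
#' @param dielectric solvent dielectric.
#' @return energy in kcal/mol.
#' @export
pair_energy <- function(r, lambda_ij, sigma_ij, epsilon, q_i = 0, q_j = 0,
                        debye_length_nm = 1, dielectric = 80) {
  if (any(r <= 0)) stop_fs("r must be positive")
  sr6 <- (sigma_ij / r)^6
  ulj <- 4 * epsilon * (sr6^2 - sr6)
  ah <- ifelse(r <= 2^(1 / 6) * sigma_ij,
               ulj + (1 - lambda_ij) * epsilon,
               lambda_ij * ulj)
  dh <- (.ke_kcal_A / 10 / dielectric) * q_i * q_j *
    exp(-r / debye_length_nm) / r
  ah + dh
}

#' Bead topology constructor
#'
#' @param positions N x 3 matrix of bead coordinates (nm).
#' @param residues one-letter codes (supplies charges/hydropathies/diameters
#'   from the HPS tables).
#' @param bonds data.frame with columns `i`, `j` (1-based), `r0` (nm), `k`
#'   (kcal/mol/nm^2).
#' @param groups character vector, `"ligand"` or `"idp"` per bead.
#' @param restrained logical per bead; restrained beads are tethered to their
#'   input position.
#' @param restraint_k restraint stiffness (kcal/mol/nm^2).
#' @return object of class `bead_topology`.
#' @export
bead_topology <- function(positions, residues, bonds,
                          groups = rep("idp", nrow(positions)),
                          restrained = rep(FALSE, nrow(positions)),
                          restraint_k = 50) {
  n <- nrow(positions)
  stopifnot(length(residues) == n, length(groups) == n, length(restrained) == n)
  hp <- hps_params()
  lam <- setNames(hp$lambda, hp$aa); sig <- setNames(hp$sigma_nm, hp$aa)
  if (any(!(residues %in% hp$aa))) stop_fs("unknown residue code in topology")
  if (nrow(bonds)) {
    if (any(bonds$i == bonds$j)) stop_fs("bonds must connect distinct beads")
    if (any(c(bonds$i, bonds$j) < 1 | c(bonds$i, bonds$j) > n))
      stop_fs("bond index outside topology")
  }
  structure(list(
    positions = positions, residues = residues,
    charges = unname(.aa_charge[residues]),
    lambdas = unname(lam[residues]), sigmas = unname(sig[residues]),
    bonds = bonds, groups = groups, restrained = restrained,
    restraint_k = restraint_k
  ), class = "bead_topology")
}

#' @export
print.bead_topology <- function(x, ...) {
  cat(sprintf("<bead_topology> %d beads (%d ligand, %d idp), %d bonds, %d restrained\n",
              nrow(x$positions), sum(x$groups == "ligand"),
              sum(x$groups == "idp"), nrow(x$bonds), sum(x$restrained)))
  invisible(x)
}

chain_bonds <- function(idx, r0 = 0.38, k = 1000) {
  if (length(idx) < 2L) return(data.frame(i = integer(), j = integer(),
                                          r0 = numeric(), k = numeric()))
  data.frame(i = idx[-length(idx)], j = idx[-1], r0 = r0, k = k)
}

# deterministic self-avoiding-ish initial coil
init_coil <- function(n, b = 0.38, seed = 1L, origin = c(0, 0, 0)) {
  set.seed(seed)
  pos <- matrix(0, n, 3)
  pos[1, ] <- origin
  for (i in seq_len(n - 1L)) {
    repeat {
      v <- rnorm(3); v <- v / sqrt(sum(v^2))
      cand <- pos[i, ] + b * v
      if (i < 2L) break
      d2 <- rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                       matrix(cand, i - 1L, 3, byrow = TRUE))^2)
      if (min(d2) > 0.45^2) break
    }
    pos[i + 1L, ] <- pos[i, ] + b * v
  }
  pos
}

#' Read a two-copy complex structure from a PDB file
#'
#' Parses a crystal structure whose asymmetric unit contains one or more
#' copies of a ligand/IDP chain pair. Nonstandard residues are rejected with
#' their identities.
#'
#' @param path PDB file.
#' @param ligand_chains,idp_chains chain identifiers; copy `k` pairs
#'   `ligand_chains[k]` with `idp_chains[k]`.
#' @return list of class `complex_structure` with one element per copy, each
#'   a list `ligand`/`idp` of data.frames (`resno`, `aa`, `x`, `y`, `z` in nm
#'   for the Calpha bead, plus an `atoms` data.frame of all heavy atoms).
#' @export
read_complex_pdb <- function(path, ligand_chains = c("A", "C"),
                             idp_chains = c("B", "D")) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$elety != "H" & !grepl("^H", at$elety), ]
  aa1 <- bio3d::aa321(at$resid)
  chain_tab <- function(ch) {
    sel <- at$chain == ch
    if (!any(sel)) stop_fs("chain '%s' not found in %s", ch, path)
    a <- at[sel, ]
    a1 <- aa1[sel]
    bad <- unique(a$resid[is.na(a1) | !(a1 %in% names(.aa_charge))])
    if (length(bad))
      stop_fs("unresolvable residues in chain %s: %s", ch,
              paste(bad, collapse = ", "))
    ca <- a[a$elety == "CA", ]
    list(
      ca = data.frame(resno = ca$resno, aa = aa1[sel][a$elety == "CA"],
                      x = ca$x / 10, y = ca$y / 10, z = ca$z / 10),
      atoms = data.frame(resno = a$resno, x = a$x / 10, y = a$y / 10,
                         z = a$z / 10)
    )
  }
  copies <- lapply(seq_along(ligand_chains), function(k)
    list(ligand = chain_tab(ligand_chains[k]),
         idp = chain_tab(idp_chains[k])))
  structure(copies, class = "complex_structure")
}

#' Shared fraction of IDP residues resolved in both structure copies
#'
#' Bookkeeping of crystallographic ambiguity: of all IDP residues resolved in
#' at least one copy of the asymmetric unit, which fraction is resolved in
#' every copy?
#'
#' @param structure a [read_complex_pdb()] result.
#' @return fraction in `[0, 1]`.
#' @export
shared_resolved_fraction <- function(structure) {
  stopifnot(inherits(structure, "complex_structure"))
  res <- lapply(structure, function(cp) unique(cp$idp$ca$resno))
  all_res <- Reduce(union, res)
  shared <- Reduce(intersect, res)
  if (!length(all_res)) stop_fs("no resolved IDP residues")
  length(shared) / length(all_res)
}

#' Extract intermolecular native contacts from a structure
#'
#' A (ligand residue, IDP residue) pair is a native contact if any heavy-atom
#' distance is below `cutoff_nm` in at least one crystallographic copy
#' (union over copies — all contacts share one interaction strength zeta).
#' The rest distance assigned to a contact is the Calpha--Calpha distance in
#' the first copy where it occurs.
#'
#' @param structure a [read_complex_pdb()] result.
#' @param cutoff_nm heavy-atom cutoff (default 0.45 nm).
#' @return data.frame of class `native_contact_set`: `ligand_resno`,
#'   `idp_resno`, `r0_nm`, `source` (copy index).
#' @export
native_contacts <- function(structure, cutoff_nm = 0.45) {
  stopifnot(inherits(structure, "complex_structure"))
  found <- list()
  for (k in seq_along(structure)) {
    cp <- structure[[k]]
    la <- cp$ligand$atoms; ia <- cp$idp$atoms
    # residue-pair minimum heavy-atom distances, chunked over idp residues
    for (ir in unique(ia$resno)) {
      sub <- ia[ia$resno == ir, c("x", "y", "z"), drop = FALSE]
      d2 <- outer(la$x, sub$x, `-`)^2 + outer(la$y, sub$y, `-`)^2 +
        outer(la$z, sub$z, `-`)^2
      near <- which(apply(d2, 1, min) < cutoff_nm^2)
      for (lr in unique(la$resno[near])) {
        key <- paste(lr, ir)
        if (is.null(found[[key]])) {
          lca <- cp$ligand$ca[cp$ligand$ca$resno == lr, ]
          ica <- cp$idp$ca[cp$idp$ca$resno == ir, ]
          if (nrow(lca) && nrow(ica))
            found[[key]] <- data.frame(
              ligand_resno = lr, idp_resno = ir,
              r0_nm = sqrt((lca$x - ica$x)^2 + (lca$y - ica$y)^2 +
                             (lca$z - ica$z)^2),
              source = k)
        }
      }
    }
  }
  out <- if (length(found)) do.call(rbind, found) else
    data.frame(ligand_resno = integer(), idp_resno = integer(),
               r0_nm = numeric(), source = integer())
  rownames(out) <- NULL
  class(out) <- c("native_contact_set", "data.frame")
  out
}

#' Build a simulation system
#'
#' Assembles a [bead_topology()] (and, for complexes, a native-contact set)
#' for the CG simulator. One bead per residue at the Calpha position; chain
#' bonds with rest length 0.38 nm.
#'
#' Modes:
#' * `"free"`: the IDP chain alone, started from a seeded random coil.
#' * `"rigid"`: ligand near-rigid (stiff internal distance network plus
#'   position restraints); IDP residues resolved in any X-ray copy are
#'   additionally position-restrained at their crystal coordinates.
#' * `"flexible"`: same ligand treatment, but the resolved IDP parts move
#'   freely and the crystallographic interface is encoded only through
#'   native-contact wells of depth `zeta`.
#'
#' @param idp_seq a [residue_sequence()] for the disordered chain.
#' @param ligand_structure a [read_complex_pdb()] result (required unless
#'   `mode = "free"`).
#' @param params an [interaction_params()] list.
#' @param mode `"free"`, `"rigid"`, or `"flexible"`.
#' @param contact_cutoff_nm heavy-atom native-contact cutoff.
#' @param network_cutoff_nm ligand internal-network cutoff.
#' @return list with elements `topology` ([bead_topology()]) and `contacts`
#'   ([native_contacts()] table, empty for free mode).
#' @export
build_system <- function(idp_seq, ligand_structure = NULL,
                         params = interaction_params(),
                         mode = c("free", "rigid", "flexible"),
                         contact_cutoff_nm = 0.45,
                         network_cutoff_nm = 1.2) {
  mode <- match.arg(mode)
  stopifnot(inherits(idp_seq, "residue_sequence"))
  n_idp <- length(idp_seq$residues)
  if (mode == "free") {
    pos <- init_coil(n_idp, seed = params$seed)
    topo <- bead_topology(pos, idp_seq$residues,
                          chain_bonds(seq_len(n_idp)))
    empty <- data.frame(ligand_resno = integer(), idp_resno = integer(),
                        r0_nm = numeric(), source = integer(),
                        ligand_bead = integer(), idp_bead = integer())
    class(empty) <- c("native_contact_set", "data.frame")
    return(list(topology = topo, contacts = empty))
  }
  if (is.null(ligand_structure))
    stop_fs("mode '%s' requires a ligand structure", mode)
  stopifnot(inherits(ligand_structure, "complex_structure"))
  cp1 <- ligand_structure[[1]]
  lig_ca <- cp1$ligand$ca
  n_lig <- nrow(lig_ca)

  # sequence consistency between structure and supplied IDP sequence
  for (cp in ligand_structure) {
    ca <- cp$idp$ca
    ok <- ca$resno >= 1 & ca$resno <= n_idp
    if (!all(ok))
      stop_fs("structure IDP residue numbers outside sequence (e.g. %d)",
              ca$resno[!ok][1])
    mism <- ca$resno[ca$aa != idp_seq$residues[ca$resno]]
    if (length(mism))
      stop_fs("IDP sequence/structure mismatch at residues: %s",
              paste(mism, collapse = ", "))
  }

  contacts <- native_contacts(ligand_structure, contact_cutoff_nm)

  # IDP initial positions: crystal coordinates where resolved (first copy
  # wins), random-coil continuation elsewhere
  idp_pos <- matrix(NA_real_, n_idp, 3)
  for (cp in rev(ligand_structure)) {
    ca <- cp$idp$ca
    idp_pos[ca$resno, ] <- as.matrix(ca[, c("x", "y", "z")])
  }
  resolved <- !is.na(idp_pos[, 1])
  if (any(!resolved)) {
    com <- colMeans(as.matrix(lig_ca[, c("x", "y", "z")]))
    set.seed(params$seed)
    for (i in which(!resolved)) {
      anchor <- if (i > 1 && !is.na(idp_pos[i - 1, 1])) idp_pos[i - 1, ] else
        if (i < n_idp && !is.na(idp_pos[i + 1, 1])) idp_pos[i + 1, ] else
          com + c(0, 0, 3)
      v <- anchor - com; nv <- sqrt(sum(v^2))
      dir <- if (nv > 1e-6) v / nv else c(0, 0, 1)
      idp_pos[i, ] <- anchor + 0.38 * (dir + 0.3 * rnorm(3)) /
        sqrt(sum((dir + 0.3 * rnorm(3))^2))
    }
  }

  pos <- rbind(as.matrix(lig_ca[, c("x", "y", "z")]), idp_pos)
  residues <- c(lig_ca$aa, idp_seq$residues)
  groups <- c(rep("ligand", n_lig), rep("idp", n_idp))

  # ligand: chain bonds at observed rest lengths + stiff internal distance
  # network (near-rigid)
  lx <- as.matrix(lig_ca[, c("x", "y", "z")])
  lb <- chain_bonds(seq_len(n_lig))
  if (nrow(lb))
    lb$r0 <- sqrt(rowSums((lx[lb$j, , drop = FALSE] -
                             lx[lb$i, , drop = FALSE])^2))
  d <- as.matrix(stats::dist(lx))
  idx <- which(upper.tri(d) & d < network_cutoff_nm, arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] > 1, , drop = FALSE]
  net <- data.frame(i = idx[, 1], j = idx[, 2],
                    r0 = d[idx], k = 100)
  ib <- chain_bonds(n_lig + seq_len(n_idp))
  bonds <- rbind(lb, net, ib)

  restrained <- c(rep(TRUE, n_lig), rep(FALSE, n_idp))
  if (mode == "rigid") restrained[n_lig + which(resolved)] <- TRUE

  topo <- bead_topology(pos, residues, bonds, groups, restrained,
                        restraint_k = 50)
  # map contact residue numbers to bead indices
  lig_index <- setNames(seq_len(n_lig), lig_ca$resno)
  contacts$ligand_bead <- unname(lig_index[as.character(contacts$ligand_resno)])
  contacts$idp_bead <- n_lig + contacts$idp_resno
  list(topology = topo, contacts = contacts)
}
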