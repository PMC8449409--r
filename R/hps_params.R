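# Published HPS (hydropathy scale) coarse-grained parameter set:
# one bead per residue, hydropathy lambda in [0,1] (Kapcha-Rossky atomic
# hydrophobicities summed per residue and min-max normalized, giving the
# familiar n/37 values) and van der Waals diameters sigma (nm) from the
# residue-size set used with this model. Charges at pH 7.4 as in seqfeat.R.

.hps_table <- data.frame(
  aa = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  lambda = c(0.72973, 0.00000, 0.43243, 0.37838, 0.59459, 0.51351, 0.45946,
             0.64865, 0.51351, 0.97297, 0.97297, 0.51351, 0.83784, 1.00000,
             1.00000, 0.59459, 0.67568, 0.94595, 0.86486, 0.89189),
  sigma_nm = c(0.504, 0.656, 0.568, 0.558, 0.548, 0.602, 0.592, 0.450, 0.608,
               0.618, 0.618, 0.636, 0.618, 0.636, 0.556, 0.518, 0.562, 0.678,
               0.646, 0.586),
  stringsAsFactors = FALSE
)

#' Per-residue parameters of the HPS coarse-grained model
#'
#' One-bead-per-residue parameter table: hydropathy \eqn{\lambda \in [0,1]}
#' (normalized Kapcha--Rossky scale) and bead diameter \eqn{\sigma} (nm),
#' as used by the Ashbaugh--Hatch pair potential of the simulator.
#'
#' @return data.frame with columns `aa`, `lambda`, `sigma_nm`.
#' @export
hps_params <- function() .hps_table

#' Debye screening length
#'
#' \deqn{\kappa^{-1} = \sqrt{\epsilon_0 \epsilon_r k_B T / (2 N_A e^2 I)}}
#'
#' @param ionic_strength_mM ionic strength (mM).
#' @param temperature_K temperature (K).
#' @param dielectric relative permittivity of the solvent.
#' @return Debye length in nm.
#' @examples
#' debye_length(100)  # ~0.96 nm
#' @export
debye_length <- function(ionic_strength_mM, temperature_K = 298,
                         dielectric = 80) {
  if (any(ionic_strength_mM <= 0) || temperature_K <= 0 || dielectric <= 0)
    stop_fs("ionic strength, temperature and dielectric must be positive")
  eps0 <- 8.8541878128e-12   # F/m
  kB <- 1.380649e-23         # J/K
  NA_ <- 6.02214076e23       # 1/mol
  e <- 1.602176634e-19       # C
  # 1 mM = 1 mol/m^3; number density of each ion species in 1/m^3
  I_per_m3 <- ionic_strength_mM * NA_
  kappa_inv_m <- sqrt(eps0 * dielectric * kB * temperature_K /
                        (2 * e^2 * I_per_m3))
  kappa_inv_m * 1e9
}

#' Bjerrum length
#'
#' Distance at which two unit charges interact with thermal energy
#' \eqn{k_B T}: \eqn{\ell_B = e^2/(4\pi\epsilon_0\epsilon_r k_B T)}.
#'
#' @inheritParams debye_length
#' @return Bjerrum length in nm.
#' @export
bjerrum_length <- function(temperature_K = 298, dielectric = 80) {
  # ke (kcal A / mol e^2) / (dielectric * kT kcal/mol) -> Angstrom
  (.ke_kcal_A / (dielectric * .kB_kcal * temperature_K)) / 10
}
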