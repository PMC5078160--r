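## Composite QM/MM binding scores. The subtractive QM/MM energy, interaction
## energies, basis-set correction, quasi-RRHO thermal correction, and the
## six-term composite binding free energy assembled from a component table.

#' Subtractive-scheme QM/MM total energy
#'
#' E = E_QM1+ptch2(HL) + E_MM12,q1=0(CL) - E_MM1,q1=0(HL): the QM energy of
#' the link-atom-capped QM region embedded in the surrounding point charges,
#' plus the classical energy of the full system with QM charges zeroed,
#' minus the classical energy of the capped QM region without electrostatics.
#'
#' @param e_qm1_ptch2_hl,e_mm12_q1_0_cl,e_mm1_q1_0_hl The three components,
#'   kJ/mol.
#' @return Total QM/MM energy, kJ/mol.
#' @examples
#' qmmm_energy(-5, -100, -2)  # -103
#' @export
qmmm_energy <- function(e_qm1_ptch2_hl, e_mm12_q1_0_cl, e_mm1_q1_0_hl) {
  vals <- c(e_qm1_ptch2_hl, e_mm12_q1_0_cl, e_mm1_q1_0_hl)
  if (!all(is.finite(vals))) stop("all components must be finite", call. = FALSE)
  e_qm1_ptch2_hl + e_mm12_q1_0_cl - e_mm1_q1_0_hl
}

#' Interaction energy from complex/protein/ligand energies
#'
#' dE_int = E(complex) - E(protein) - E(ligand), with all three energies
#' from the same energy model.
#'
#' @param e_complex,e_protein,e_ligand Energies, kJ/mol.
#' @return Interaction energy, kJ/mol.
#' @export
interaction_energy <- function(e_complex, e_protein, e_ligand) {
  vals <- c(e_complex, e_protein, e_ligand)
  if (!all(is.finite(vals))) stop("all energies must be finite", call. = FALSE)
  e_complex - e_protein - e_ligand
}

#' Basis-set correction
#'
#' dE_bsc = E(large basis) - E(small basis), e.g. quadruple-zeta minus
#' split-valence energies of the same structure.
#'
#' @param e_large,e_small Energies, kJ/mol.
#' @return Correction, kJ/mol.
#' @export
basis_set_correction <- function(e_large, e_small) {
  if (!all(is.finite(c(e_large, e_small)))) {
    stop("energies must be finite", call. = FALSE)
  }
  e_large - e_small
}

## Physical constants (SI)
PLANCK_H <- 6.62607015e-34     # J s
BOLTZMANN_KB <- 1.380649e-23   # J/K
SPEED_OF_LIGHT_CM <- 2.99792458e10  # cm/s
AVOGADRO_NA <- 6.02214076e23

#' Quasi-RRHO damping weight
#'
#' The interpolation weight between harmonic-oscillator and free-rotor
#' entropy for a mode of wavenumber `omega`, w = 1/(1 + (omega0/omega)^4).
#'
#' @param omega Wavenumber(s), 1/cm.
#' @param omega0 Interpolation wavenumber, 1/cm (default 100).
#' @return Weight(s) in (0, 1); exactly 0.5 at `omega == omega0`.
#' @export
qrrho_weight <- function(omega, omega0 = 100) {
  1 / (1 + (omega0 / omega)^4)
}

#' Quasi-RRHO thermal Gibbs correction from vibrational modes
#'
#' Ideal-gas rigid-rotor harmonic-oscillator vibrational free-energy
#' correction with the low-frequency entropy interpolated towards a
#' free-rotor value: G = sum over modes of \[ZPE + U_vib\] - T * S, with
#' per-mode entropy S = w * S_HO + (1 - w) * S_FR and damping
#' w = 1/(1 + (omega0/omega)^4). The free-rotor entropy uses the effective
#' moment of inertia mu' = mu * B_av / (mu + B_av) with
#' mu = h / (8 pi^2 c omega) and an average molecular moment
#' B_av = 1e-44 kg m^2. Non-positive (imaginary) wavenumbers are excluded;
#' their count is returned as an attribute.
#'
#' @param wavenumbers Mode wavenumbers, 1/cm; imaginary modes as negative
#'   values.
#' @param temperature Temperature, K (default 298.15).
#' @param omega0 Interpolation wavenumber, 1/cm (default 100).
#' @param b_av Average molecular moment of inertia, kg m^2 (default 1e-44).
#' @return G_therm in kJ/mol with attributes `zpe`, `u_vib`, `entropy`
#'   (kJ/mol; entropy as -T*S contribution) and `n_imaginary`.
#' @examples
#' quasi_rrho_gibbs(100, temperature = 298.15)
#' @export
quasi_rrho_gibbs <- function(wavenumbers, temperature = 298.15, omega0 = 100,
                             b_av = 1e-44) {
  if (temperature <= 0) stop("`temperature` must be positive", call. = FALSE)
  wavenumbers <- as.numeric(wavenumbers)
  n_imag <- sum(wavenumbers <= 0)
  if (n_imag > 0) {
    warning(sprintf("%d imaginary/zero mode(s) excluded", n_imag), call. = FALSE)
  }
  nu <- wavenumbers[wavenumbers > 0]
  if (length(nu) == 0L) stop("no real vibrational modes", call. = FALSE)

  # per-mode quantities, J then kJ/mol
  kbt <- BOLTZMANN_KB * temperature
  e_mode <- PLANCK_H * SPEED_OF_LIGHT_CM * nu  # h c nu, J
  x <- e_mode / kbt
  to_kj <- AVOGADRO_NA / 1000

  zpe <- sum(e_mode / 2) * to_kj
  u_vib <- sum(e_mode / (exp(x) - 1)) * to_kj
  s_ho <- BOLTZMANN_KB * (x / (exp(x) - 1) - log1p(-exp(-x)))  # J/K per mode
  mu <- PLANCK_H / (8 * pi^2 * SPEED_OF_LIGHT_CM * nu)         # kg m^2
  mu_eff <- mu * b_av / (mu + b_av)
  s_fr <- BOLTZMANN_KB *
    (0.5 + log(sqrt(8 * pi^3 * mu_eff * kbt) / PLANCK_H))
  w <- qrrho_weight(nu, omega0)
  s_total <- sum(w * s_ho + (1 - w) * s_fr) * to_kj  # kJ/mol/K
  g <- zpe + u_vib - temperature * s_total
  attr(g, "zpe") <- zpe
  attr(g, "u_vib") <- u_vib
  attr(g, "entropy") <- -temperature * s_total
  attr(g, "n_imaginary") <- n_imag
  g
}

#' Composite six-term QM/MM binding free energy
#'
#' Assembles dG_bind from a Table-5-style component row: the big-QM
#' interaction energy in continuum solvent, the basis-set correction, the
#' dispersion correction, the thermal correction, the ligand strain
#' (relaxation) energy, and the ligand solvation-correction term
#' ddG_L,solv = dG_solv(COSMO-RS) - dG_solv(COSMO).
#'
#' The `ligand_relax_printed` component is stored with the tabulated sign
#' (negative) and negated on assembly, so the strain contribution entering
#' the score is positive. The `"as_submitted"` variant applies the ligand
#' solvation difference with the opposite (erroneous) sign,
#' `+ (dG_COSMO - dG_COSMO-RS)`, reproducing the originally submitted
#' scores; `"corrected"` applies it properly. The two variants differ by
#' exactly `2 * (solv_cosmors - solv_cosmo)`.
#'
#' @param components Named list or one-row data.frame with `bigqm_cosmo`,
#'   `basis_correction`, `dispersion`, `g_therm`, `ligand_relax_printed`,
#'   `solv_cosmo`, `solv_cosmors` (kJ/mol).
#' @param variant `"corrected"` or `"as_submitted"`.
#' @param exclusions Character subset of `c("g_therm", "ligand_relax")` to
#'   drop from the sum (the tabulated dG' column corresponds to excluding
#'   `g_therm` only).
#' @return List of class `binding_score`: `dg_bind`, `variant`, `exclusions`.
#' @export
composite_binding_energy <- function(components,
                                     variant = c("corrected", "as_submitted"),
                                     exclusions = character(0)) {
  variant <- match.arg(variant)
  need <- c("bigqm_cosmo", "basis_correction", "dispersion", "g_therm",
            "ligand_relax_printed", "solv_cosmo", "solv_cosmors")
  components <- as.list(components)
  missing_fields <- setdiff(need, names(components))
  if (length(missing_fields) > 0) {
    stop("missing component(s): ", paste(missing_fields, collapse = ", "),
         call. = FALSE)
  }
  vals <- vapply(components[need], as.numeric, numeric(1))
  if (!all(is.finite(vals))) stop("components must be finite", call. = FALSE)
  bad <- setdiff(exclusions, c("g_therm", "ligand_relax"))
  if (length(bad) > 0) {
    stop("unknown exclusion(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  solv_diff <- vals[["solv_cosmors"]] - vals[["solv_cosmo"]]
  if (variant == "as_submitted") solv_diff <- -solv_diff
  strain <- -vals[["ligand_relax_printed"]]
  total <- vals[["bigqm_cosmo"]] + vals[["basis_correction"]] +
    vals[["dispersion"]] + solv_diff
  if (!("g_therm" %in% exclusions)) total <- total + vals[["g_therm"]]
  if (!("ligand_relax" %in% exclusions)) total <- total + strain
  structure(list(dg_bind = unname(total), variant = variant,
                 exclusions = exclusions),
            class = "binding_score")
}

#' @export
print.binding_score <- function(x, ...) {
  excl <- if (length(x$exclusions)) paste0(" (excluding ",
                                           paste(x$exclusions, collapse = ", "), ")") else ""
  cat(sprintf("<binding_score> %s%s: %.1f kJ/mol\n", x$variant, excl, x$dg_bind))
  invisible(x)
}

#' Score a whole component table
#'
#' Applies [composite_binding_energy()] to every row of a Table-5-style
#' component data.frame (as returned by [load_fixtures()]`$table5`).
#'
#' @param tab Data.frame with a `ligand` column and the component columns of
#'   [composite_binding_energy()].
#' @param variant,exclusions Passed through.
#' @return Data.frame: ligand, dg_bind.
#' @export
score_component_table <- function(tab, variant = "corrected",
                                  exclusions = character(0)) {
  stopifnot(is.data.frame(tab), "ligand" %in% names(tab))
  dg <- vapply(seq_len(nrow(tab)), function(i) {
    composite_binding_energy(tab[i, ], variant, exclusions)$dg_bind
  }, numeric(1))
  data.frame(ligand = tab$ligand, dg_bind = dg, stringsAsFactors = FALSE)
}
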