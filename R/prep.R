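#' Solution-preparation arithmetic
#'
#' Helpers that reproduce the bench arithmetic behind a ferrous sulfate
#' exposure experiment: molarity of a stock made by dissolving a weighed mass
#' of salt, and the concentration after a series of aliquot dilutions.
#'
#' @name prep
NULL

#' Molar mass of iron(II) sulfate heptahydrate (g/mol)
#'
#' FeSO4.7H2O, the salt dissolved to make the ferrous stock solution.
#' 20 mg dissolved in 1.0 ml gives a 71.9 mM stock.
#'
#' @export
MOLAR_MASS_FESO4_7H2O <- 278.01

#' Stock solution molarity
#'
#' Concentration, in mM, of a stock prepared by dissolving `mass_mg`
#' milligrams of a solute of molar mass `molar_mass_g_per_mol` in
#' `volume_ml` milliliters of solvent. Volumes are treated as additive and
#' the solute volume as negligible, the usual bench assumption.
#'
#' @param mass_mg mass of solute, milligrams. Must be positive.
#' @param volume_ml volume of solvent, milliliters. Must be positive.
#' @param molar_mass_g_per_mol molar mass of the solute, g/mol. Defaults to
#'   iron(II) sulfate heptahydrate ([MOLAR_MASS_FESO4_7H2O]).
#' @return concentration in mM (numeric scalar).
#' @examples
#' stock_molarity(20, 1.0)           # 71.94 mM ferrous sulfate stock
#' stock_molarity(10, 1.0)           # half the mass, half the molarity
#' @export
stock_molarity <- function(mass_mg, volume_ml,
                           molar_mass_g_per_mol = MOLAR_MASS_FESO4_7H2O) {
  for (v in list(mass_mg, volume_ml, molar_mass_g_per_mol)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("stock_molarity(): all arguments must be positive finite scalars",
           call. = FALSE)
    }
  }
  # mmol of solute / ml of solvent -> mol/l = M; report mM
  (mass_mg / molar_mass_g_per_mol) / volume_ml * 1000
}

#' A single dilution step
#'
#' An aliquot of `aliquot_ul` microliters of the concentrated species is
#' assembled into a pool so that the final volume is
#' `aliquot_ul + diluent_ul`.
#'
#' @param aliquot_ul volume transferred, microliters (> 0).
#' @param diluent_ul volume of the receiving pool, microliters (>= 0).
#' @return an object of class `"dilution_step"`.
#' @export
dilution_step <- function(aliquot_ul, diluent_ul) {
  if (!is.numeric(aliquot_ul) || length(aliquot_ul) != 1L ||
      !is.finite(aliquot_ul) || aliquot_ul <= 0) {
    stop("dilution_step(): aliquot_ul must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(diluent_ul) || length(diluent_ul) != 1L ||
      !is.finite(diluent_ul) || diluent_ul < 0) {
    stop("dilution_step(): diluent_ul must be a nonnegative scalar",
         call. = FALSE)
  }
  structure(list(aliquot_ul = aliquot_ul, diluent_ul = diluent_ul),
            class = "dilution_step")
}

#' Concentration after a series of dilutions
#'
#' Applies `C <- C * aliquot / (aliquot + diluent)` for each step in order,
#' starting from a stock concentration in mM, and returns the final
#' concentration in µM. This is the exact mass-balance value; rounding to a
#' nominal label (e.g. "1700 µM" for the 71.9 mM stock assembled as
#' 100 µl into a 4200 µl total) is left to the caller.
#'
#' @param stock_mM starting concentration, mM (>= 0).
#' @param steps a list of [dilution_step()] objects (at least one), or a
#'   single `dilution_step`.
#' @return concentration in µM (numeric scalar).
#' @examples
#' # 71.9 mM stock, 100 ul assembled into 4.2 ml total:
#' dilution_series(71.9, dilution_step(100, 4100))   # ~1712 uM
#' @export
dilution_series <- function(stock_mM, steps) {
  if (!is.numeric(stock_mM) || length(stock_mM) != 1L || !is.finite(stock_mM) ||
      stock_mM < 0) {
    stop("dilution_series(): stock_mM must be a nonnegative scalar",
         call. = FALSE)
  }
  if (inherits(steps, "dilution_step")) steps <- list(steps)
  if (!is.list(steps) || length(steps) == 0L) {
    stop("dilution_series(): need at least one dilution step", call. = FALSE)
  }
  conc <- stock_mM * 1000  # mM -> uM
  for (s in steps) {
    if (!inherits(s, "dilution_step")) {
      stop("dilution_series(): every step must be a dilution_step",
           call. = FALSE)
    }
    conc <- conc * s$aliquot_ul / (s$aliquot_ul + s$diluent_ul)
  }
  conc
}
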