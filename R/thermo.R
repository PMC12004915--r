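#' @title Thermodynamic decomposition of micellization
#' @description Helpers converting the fitted CMC and demicellization
#'   enthalpy into the standard thermodynamic quantities of micelle
#'   formation.
#' @name thermo
NULL

#' Gas constant, J mol^-1 K^-1
#' @export
R_GAS <- 8.314

#' Joules per thermochemical calorie (for calorimeter-native cal values)
#' @export
J_PER_CAL <- 4.184

#' Micellization enthalpy from demicellization enthalpy
#'
#' The demicellization experiment measures micelle dissolution; the standard
#' micellization enthalpy is its negative.
#'
#' @param dH_demic Demicellization enthalpy, J/mol.
#' @return Micellization enthalpy, J/mol.
#' @export
micellization_enthalpy <- function(dH_demic) -dH_demic

#' Standard Gibbs energy of micellization from the CMC
#'
#' For nonionic and zwitterionic surfactants (negligible counterion
#' association) `dG = R * T * ln(cmc / c_std)`. The default standard
#' concentration is 1 mol/L; a mole-fraction convention (`c_std = 55.5`)
#' only shifts all values by an additive constant.
#'
#' @param cmc Critical micelle concentration, mol/L (> 0).
#' @param temperature Temperature, K (> 0).
#' @param c_std Standard concentration, mol/L.
#' @return Gibbs energy of micellization, J/mol; strictly increasing in
#'   `cmc` and negative whenever `cmc < c_std`.
#' @examples
#' gibbs_energy(3.6e-3, 298.15)  # about -13.95 kJ/mol
#' @export
gibbs_energy <- function(cmc, temperature, c_std = 1) {
  if (any(!is.finite(cmc)) || any(cmc <= 0))
    stop("cmc must be positive", call. = FALSE)
  stopifnot(all(temperature > 0), all(c_std > 0))
  R_GAS * temperature * log(cmc / c_std)
}

#' Entropy terms from Gibbs energy and enthalpy
#'
#' `dS = (dH_mic - dG) / T` and `-T*dS = dG - dH_mic`, so that the identity
#' `dG = dH_mic - T*dS` holds exactly.
#'
#' @param dG Gibbs energy of micellization, J/mol.
#' @param dH_mic Micellization enthalpy, J/mol.
#' @param temperature Temperature, K (> 0).
#' @return List with `dS` (J mol^-1 K^-1) and `minus_TdS` (J/mol).
#' @export
entropy_terms <- function(dG, dH_mic, temperature) {
  stopifnot(all(temperature > 0))
  list(dS = (dH_mic - dG) / temperature, minus_TdS = dG - dH_mic)
}

#' Per-condition thermodynamic record
#'
#' Bundles CMC, Gibbs energy, enthalpy and entropy terms for one
#' (condition, temperature) pair, enforcing the decomposition identity
#' `dG = dH_mic + (-T*dS)`.
#'
#' @param condition_label Condition tag.
#' @param temperature Temperature, K.
#' @param cmc CMC, mol/L.
#' @param dH_mic Micellization enthalpy, J/mol.
#' @param c_std Standard concentration, mol/L.
#' @return A one-row data frame of class `thermo_record`.
#' @export
thermo_record <- function(condition_label, temperature, cmc, dH_mic,
                          c_std = 1) {
  dG <- gibbs_energy(cmc, temperature, c_std)
  ent <- entropy_terms(dG, dH_mic, temperature)
  rec <- data.frame(condition = condition_label,
                    T_K = temperature,
                    cmc_M = cmc,
                    dG_J_per_mol = dG,
                    dH_mic_J_per_mol = dH_mic,
                    minus_TdS_J_per_mol = ent$minus_TdS,
                    dS_J_per_mol_K = ent$dS)
  stopifnot(abs(rec$dG_J_per_mol - rec$dH_mic_J_per_mol -
                  rec$minus_TdS_J_per_mol) <=
              1e-9 * max(abs(rec$dG_J_per_mol), 1))
  class(rec) <- c("thermo_record", "data.frame")
  rec
}

#' Heat capacity of micellization from an enthalpy-temperature series
#'
#' Ordinary least squares of `dH_mic` on temperature: the slope is the heat
#' capacity change `dCp`, and the root of the fitted line is the
#' compensation temperature `T_H` at which the micellization enthalpy is
#' zero (endothermic below, exothermic above for `dCp < 0`). `T_H` is
#' undefined (`NA`) when the fitted slope is zero; the `extrapolated` flag is
#' set when `T_H` falls more than 50 K outside the measured range.
#'
#' @param series Data frame with columns `temperature_K` and
#'   `dH_mic_J_per_mol` (>= 2 distinct temperatures), e.g. from
#'   [simulate_temperature_series()].
#' @return An object of class `heat_capacity_fit` with elements `dCp`
#'   (J mol^-1 K^-1), `T_H` (K or `NA`), `slope_stderr`, `intercept`,
#'   `n_points` and `extrapolated`.
#' @examples
#' heat_capacity(data.frame(temperature_K = c(283.15, 308.15),
#'                          dH_mic_J_per_mol = c(3000, -7000)))
#' @export
heat_capacity <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("temperature_K", "dH_mic_J_per_mol") %in% names(series)))
  Tk <- series$temperature_K
  dH <- series$dH_mic_J_per_mol
  if (length(unique(Tk)) < 2L)
    stop("need at least 2 distinct temperatures", call. = FALSE)
  fit <- stats::lm(dH ~ Tk)
  dCp <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  se <- if (length(Tk) > 2L)
    suppressWarnings(summary(fit)$coefficients[2, 2]) else NA_real_
  scale_dH <- max(abs(dH), 1e-300)
  T_H <- if (abs(dCp) * diff(range(Tk)) <= 1e-12 * scale_dH) NA_real_
         else -b / dCp
  extrap <- is.finite(T_H) &&
    (T_H < min(Tk) - 50 || T_H > max(Tk) + 50)
  structure(list(dCp = dCp, T_H = T_H, slope_stderr = se, intercept = b,
                 n_points = length(Tk), extrapolated = extrap),
            class = "heat_capacity_fit")
}

#' @export
print.heat_capacity_fit <- function(x, ...) {
  cat("Heat capacity of micellization (linear dH vs T)\n")
  cat(sprintf("  dCp : %.4g J/mol/K (stderr %.3g, n = %d)\n",
              x$dCp, x$slope_stderr, x$n_points))
  cat(sprintf("  T_H : %s%s\n",
              if (is.na(x$T_H)) "undefined (dCp = 0)"
              else sprintf("%.2f K", x$T_H),
              if (isTRUE(x$extrapolated)) " [extrapolated]" else ""))
  invisible(x)
}
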