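## Docking thermodynamics: conversion between binding free energies and
## inhibition constants under the AutoDock convention Ki = exp(dG / RT),
## with R = 1.98720425e-3 kcal/mol/K and T = 298.15 K by default.

#' Thermodynamic configuration for the dG <-> Ki conversion
#'
#' @param temperature absolute temperature in kelvin (> 0), default 298.15.
#' @param gas_constant in kcal/mol/K; fixed by definition, exposed for
#'   sensitivity checks.
#' @return a `thermo_config` object.
#' @export
thermo_config <- function(temperature = 298.15,
                          gas_constant = 1.98720425e-3) {
  if (!is.finite(temperature) || temperature <= 0)
    stop_domain("temperature must be > 0 K")
  if (!is.finite(gas_constant) || gas_constant <= 0)
    stop_domain("gas_constant must be > 0")
  structure(list(temperature = temperature, gas_constant = gas_constant),
            class = "thermo_config")
}

#' Inhibition constant from binding free energy
#'
#' `Ki(nM) = exp(dG / RT) * 1e9`. A binding energy of 0 gives 1 M = 1e9 nM;
#' more negative energies give strictly smaller Ki.
#'
#' @param dg binding free energy in kcal/mol (vectorized).
#' @param config a [thermo_config()].
#' @return inhibition constant(s) in nM.
#' @export
#' @examples
#' ki_from_dg(-10.07)   # ~41.6 nM
ki_from_dg <- function(dg, config = thermo_config()) {
  if (!inherits(config, "thermo_config"))
    stop_config("config must be a thermo_config object")
  if (any(!is.finite(dg))) stop_validation("dg must be finite")
  exp(dg / (config$gas_constant * config$temperature)) * 1e9
}

#' Binding free energy from inhibition constant
#'
#' Exact inverse of [ki_from_dg()].
#'
#' @param ki inhibition constant(s) in nM (> 0).
#' @param config a [thermo_config()].
#' @return binding free energy in kcal/mol.
#' @export
#' @examples
#' dg_from_ki(41.62)    # ~ -10.07 kcal/mol
dg_from_ki <- function(ki, config = thermo_config()) {
  if (!inherits(config, "thermo_config"))
    stop_config("config must be a thermo_config object")
  if (any(!is.finite(ki)) || any(ki <= 0)) stop_domain("ki must be > 0")
  log(ki / 1e9) * config$gas_constant * config$temperature
}

#' Verify a docking table's reported inhibition constants
#'
#' Recomputes Ki from each row's binding energy and compares it with the
#' reported value at a relative tolerance.
#'
#' @param records a docking table (see [load_table()]).
#' @param config a [thermo_config()].
#' @param rel_tol maximum allowed `|computed - reported| / reported`. The
#'   default 0.01 absorbs the ~0.85% Ki spread induced by 2-dp rounding of dG.
#' @return a `data.frame` with `compound`, `target`, `dg_kcalmol`,
#'   `reported_ki`, `computed_ki`, `rel_error`, `pass` per row.
#' @export
#' @examples
#' verify_docking_table(bundled_fixture("docking_beta"))
verify_docking_table <- function(records, config = thermo_config(),
                                 rel_tol = 0.01) {
  if (!is.finite(rel_tol) || rel_tol < 0) stop_domain("rel_tol must be >= 0")
  computed <- ki_from_dg(records$dg_kcalmol, config)
  rel_error <- abs(computed - records$ki_nM) / records$ki_nM
  data.frame(
    compound = records$compound,
    target = records$target,
    dg_kcalmol = records$dg_kcalmol,
    reported_ki = records$ki_nM,
    computed_ki = computed,
    rel_error = rel_error,
    pass = rel_error <= rel_tol,
    stringsAsFactors = FALSE
  )
}
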