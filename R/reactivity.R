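## Conceptual-DFT global reactivity descriptors from frontier-orbital energies.
##
## Under the Koopmans-style identification the vertical ionization potential
## and electron affinity are read off the frontier orbitals, I = -E_HOMO and
## A = -E_LUMO (both converted from hartree to eV), and the derived global
## descriptors are
##
##   Eg  = I - A                (energy gap, eV)
##   chi = (I + A) / 2          (electronegativity, eV)
##   V   = -chi                 (chemical potential, eV)
##   eta = (I - A) / 2          (hardness, eV)
##   S   = 1 / (2 * eta)        (softness, 1/eV)
##   omega = chi^2 / (2 * eta)  (electrophilicity, eV)
##   N   = I_TCE - I            (nucleophilicity, eV, relative to the
##                               tetracyanoethylene ionization energy)
##
## All intermediates are kept unrounded; rounding happens only at reporting.

#' Hartree to electronvolt conversion factor
#' @format a single number, 27.211386 eV per hartree.
#' @export
hartree_to_ev <- 27.211386

#' Convert an energy from hartree (atomic units) to eV
#'
#' @param x energy in hartree; any finite numeric vector.
#' @return `x * 27.211386`.
#' @export
au_to_ev <- function(x) {
  if (any(!is.finite(x))) stop_validation("energy must be finite")
  x * hartree_to_ev
}

#' Global reactivity descriptors from one pair of orbital energies
#'
#' @param e_homo HOMO energy in hartree (must be below `e_lumo`).
#' @param e_lumo LUMO energy in hartree.
#' @param i_tce nucleophilicity reference: ionization energy of
#'   tetracyanoethylene in eV. The default 4.21 eV is the value implied
#'   jointly by the study's descriptor table (see [calibrate_i_tce()]); it is
#'   an empirical fitted constant, not an endorsement of a physical value.
#' @return a one-row `data.frame` with columns `e_homo_ev`, `e_lumo_ev`,
#'   `i_pot`, `e_aff`, `e_gap`, `chi`, `eta`, `s_soft`, `v_pot`, `omega`,
#'   `n_nuc` (eV throughout except `s_soft` in 1/eV).
#' @export
#' @examples
#' compute_global_descriptors(-0.23738, -0.11034)
compute_global_descriptors <- function(e_homo, e_lumo, i_tce = 4.21) {
  if (!is.finite(e_homo) || !is.finite(e_lumo))
    stop_validation("orbital energies must be finite")
  if (e_homo >= e_lumo)
    stop_domain("e_homo must be strictly below e_lumo (hardness would be <= 0)")
  if (!is.finite(i_tce) || i_tce <= 0)
    stop_domain("i_tce must be a positive energy in eV")
  .global_descriptors_vec(e_homo, e_lumo, i_tce)
}

## vectorized core shared by compute_global_descriptors and descriptor_table
.global_descriptors_vec <- function(e_homo, e_lumo, i_tce) {
  i_pot <- -au_to_ev(e_homo)
  e_aff <- -au_to_ev(e_lumo)
  eta   <- (i_pot - e_aff) / 2
  chi   <- (i_pot + e_aff) / 2
  data.frame(
    e_homo_ev = au_to_ev(e_homo),
    e_lumo_ev = au_to_ev(e_lumo),
    i_pot = i_pot,
    e_aff = e_aff,
    e_gap = i_pot - e_aff,
    chi   = chi,
    eta   = eta,
    s_soft = 1 / (2 * eta),
    v_pot = -chi,
    omega = chi^2 / (2 * eta),
    n_nuc = i_tce - i_pot
  )
}

#' Calibrate the nucleophilicity reference I_TCE from descriptor rows
#'
#' Since N = I_TCE - I, every (I, N) pair implies I_TCE = N + I. This returns
#' the mean implied value together with the largest absolute residual, so a
#' table computed with a single consistent reference has residual ~0.
#'
#' @param i_pot ionization potentials in eV.
#' @param n_nuc nucleophilicities in eV, same length.
#' @return a list with `i_tce` (mean of `n_nuc + i_pot`) and `max_residual`.
#' @export
#' @examples
#' calibrate_i_tce(c(6.46, 6.09), c(-2.25, -1.88))
calibrate_i_tce <- function(i_pot, n_nuc) {
  if (length(i_pot) != length(n_nuc))
    stop_dimension("i_pot and n_nuc must have equal length")
  if (length(i_pot) == 0) stop_domain("at least one row is required")
  sums <- n_nuc + i_pot
  est <- mean(sums)
  list(i_tce = est, max_residual = max(abs(sums - est)))
}

#' Solvation energy from gas- and aqueous-phase total energies
#'
#' The total-energy difference aqueous minus gas, converted to eV. Negative
#' values mean the molecule is stabilized in water.
#'
#' @param e_total_gas total electronic energy in the gas phase (hartree).
#' @param e_total_aq total electronic energy in water (hartree).
#' @return energy difference in eV.
#' @export
#' @examples
#' solvation_energy(-1483.19061, -1483.22089)   # about -0.8 eV
solvation_energy <- function(e_total_gas, e_total_aq) {
  if (!is.finite(e_total_gas) || !is.finite(e_total_aq))
    stop_validation("total energies must be finite")
  au_to_ev(e_total_aq - e_total_gas)
}

#' Per-compound descriptor table for one phase
#'
#' Applies [compute_global_descriptors()] to every record of the requested
#' phase. Suspect-flagged rows must already have been excluded (the default
#' loaders drop them).
#'
#' @param records a quantum table (see [load_table()]) with `e_homo_au` and
#'   `e_lumo_au` present.
#' @param phase `"gas"` or `"aqueous"`.
#' @param i_tce nucleophilicity reference in eV.
#' @param compounds optional character vector restricting and ordering the
#'   output; every requested compound must have a record in the phase.
#' @return a `data.frame` with one row per compound: `compound`, `phase`, and
#'   the descriptor columns of [compute_global_descriptors()]. Values are
#'   unrounded; round only for display.
#' @export
#' @examples
#' q <- bundled_fixture("reactivity_inputs")
#' round(descriptor_table(q, "gas")$omega, 2)
descriptor_table <- function(records, phase = c("gas", "aqueous"),
                             i_tce = 4.21, compounds = NULL) {
  phase <- match.arg(phase)
  sub <- records[records$phase == phase & !is.na(records$e_homo_au) &
                   !is.na(records$e_lumo_au), , drop = FALSE]
  if ("suspect" %in% names(sub)) sub <- sub[!sub$suspect, , drop = FALSE]
  if (is.null(compounds)) {
    compounds <- unique(sub$compound)
  } else {
    missing <- setdiff(compounds, sub$compound)
    if (length(missing) > 0) {
      stop_lookup(sprintf("no %s-phase record for compound(s): %s",
                          phase, paste(missing, collapse = ", ")))
    }
  }
  if (length(compounds) == 0) {
    out <- cbind(data.frame(compound = character(), phase = character(),
                            stringsAsFactors = FALSE),
                 compute_global_descriptors(-0.2, -0.1, i_tce)[0, ])
    rownames(out) <- NULL
    return(out)
  }
  idx <- match(compounds, sub$compound)   # first record per compound
  e_homo <- sub$e_homo_au[idx]
  e_lumo <- sub$e_lumo_au[idx]
  if (any(e_homo >= e_lumo))
    stop_domain("e_homo must be strictly below e_lumo (hardness would be <= 0)")
  out <- cbind(data.frame(compound = compounds, phase = phase,
                          stringsAsFactors = FALSE),
               .global_descriptors_vec(e_homo, e_lumo, i_tce))
  rownames(out) <- NULL
  out
}
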