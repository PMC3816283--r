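# Perfusate composition bookkeeping.

#' Bicarbonate-buffered physiological perfusate composition
#'
#' The salt composition of the bicarbonate-buffered saline used for cardiac
#' perfusion, as millimolar concentrations with per-salt ion stoichiometry.
#' Useful for checking total ion loads (the perfusate is formulated to a
#' physiological total sodium).
#'
#' @return data.frame with columns `salt`, `mM`, and stoichiometry columns
#'   `Na`, `K`, `Ca`, `Mg`, `Cl`.
#' @examples
#' buf <- perfusion_buffer()
#' total_ion(buf, "Na")  # 154.4 mM
#' @export
perfusion_buffer <- function() {
  data.frame(
    salt = c("NaCl", "NaHCO3", "KCl", "NaH2PO4", "CaCl2", "MgSO4",
             "glucose"),
    mM = c(128, 24, 4.2, 2.4, 1.5, 0.9, 9),
    Na = c(1, 1, 0, 1, 0, 0, 0),
    K  = c(0, 0, 1, 0, 0, 0, 0),
    Ca = c(0, 0, 0, 0, 1, 0, 0),
    Mg = c(0, 0, 0, 0, 0, 1, 0),
    Cl = c(1, 0, 1, 0, 2, 0, 0)
  )
}

#' Total concentration of one ion in a buffer recipe
#'
#' @param buffer data.frame as returned by [perfusion_buffer()].
#' @param ion name of a stoichiometry column, e.g. `"Na"`.
#' @return total ion concentration in mM.
#' @export
total_ion <- function(buffer, ion) {
  if (!ion %in% names(buffer)) {
    stop(sprintf("no stoichiometry column `%s` in buffer", ion),
         call. = FALSE)
  }
  sum(buffer$mM * buffer[[ion]])
}
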