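# Electron-dose and stain-content arithmetic: fluence budgeting against
# the shrinkage limit, and stain concentration from block densities.

#' Acquisition settings for a dual-energy SBEM run
#'
#' @param probe_current_pA Probe current in pA.
#' @param dwell_us Per-energy pixel dwell times in microseconds (one per
#'   landing energy).
#' @param pixel_nm Pixel size in nm.
#' @param energies_keV Landing energies in keV (same length as
#'   `dwell_us`).
#' @param cut_nm Cutting increment in nm.
#' @return An `acquisition_settings` object.
#' @export
acquisition_settings <- function(probe_current_pA, dwell_us,
                                 pixel_nm = 12.5,
                                 energies_keV = NULL, cut_nm = 25) {
  stopifnot(probe_current_pA > 0, all(dwell_us > 0), pixel_nm > 0,
            cut_nm > 0)
  if (!is.null(energies_keV))
    stopifnot(length(energies_keV) == length(dwell_us))
  structure(list(probe_current_pA = probe_current_pA,
                 dwell_us = dwell_us, pixel_nm = pixel_nm,
                 energies_keV = energies_keV, cut_nm = cut_nm),
            class = "acquisition_settings")
}

#' Electrons delivered by a probe current over a dwell time
#'
#' `count = I * t / e` with the elementary charge
#' `e = 1.602176634e-19 C`.
#'
#' @param current_pA Probe current in pA (>= 0).
#' @param dwell_us Dwell time in microseconds (>= 0).
#' @return Electron count (not rounded).
#' @examples
#' electrons_from_current(75, 3.5)   # ~1638 electrons
#' @export
electrons_from_current <- function(current_pA, dwell_us) {
  stopifnot(all(current_pA >= 0), all(dwell_us >= 0))
  current_pA * 1e-12 * dwell_us * 1e-6 / .E_CHARGE
}

#' Total electron fluence of an acquisition
#'
#' Sum over landing energies of the per-image electron count divided by
#' the pixel area.
#'
#' @param settings An [acquisition_settings()].
#' @return Fluence in electrons/nm^2.
#' @examples
#' total_fluence(acquisition_settings(75, c(3.5, 1.5)))   # ~15 e/nm^2
#' @export
total_fluence <- function(settings) {
  stopifnot(inherits(settings, "acquisition_settings"))
  sum(electrons_from_current(settings$probe_current_pA,
                             settings$dwell_us)) / settings$pixel_nm^2
}

#' Check a fluence against the block-shrinkage budget
#'
#' Above roughly 15-20 e/nm^2 the resin block shrinks under irradiation
#' and cutting becomes non-uniform; this check records the margin to a
#' configured limit. A fluence exactly at the limit passes with zero
#' margin.
#'
#' @param fluence Fluence in e/nm^2 (>= 0).
#' @param limit Budget limit in e/nm^2 (default 15, the conservative end
#'   of the 15-20 band).
#' @return A list `pass` (logical), `fluence`, `limit`, `margin`
#'   (`limit - fluence`). A warning is raised when over budget.
#' @export
fluence_budget_check <- function(fluence, limit = 15) {
  stopifnot(fluence >= 0, limit > 0)
  margin <- limit - fluence
  pass <- fluence <= limit
  if (!pass)
    warning(sprintf(
      "fluence %.3g e/nm^2 exceeds the shrinkage budget of %.3g e/nm^2",
      fluence, limit))
  list(pass = pass, fluence = fluence, limit = limit, margin = margin)
}

#' Stain mass per unit resin mass from block densities
#'
#' `(rho_stained - rho_resin) / rho_resin`, grams of stain per gram of
#' resin.
#'
#' @param rho_stained Density of the stained block, g/cm^3.
#' @param rho_resin Density of the unstained resin, g/cm^3.
#' @return Mass ratio in g/g.
#' @examples
#' stain_mass_ratio(1.51, 1.22)   # ~0.24 g/g
#' @export
stain_mass_ratio <- function(rho_stained, rho_resin) {
  stopifnot(rho_resin > 0)
  if (any(rho_stained < rho_resin))
    stop("stained density must be at least the resin density",
         call. = FALSE)
  (rho_stained - rho_resin) / rho_resin
}

#' Heavy-atom atomic fraction from a stain mass ratio
#'
#' Converts grams of stain per gram of resin into the fraction of all
#' atoms that are heavy: with stain mean atomic mass `M_s` and resin
#' mean atomic mass `M_r`,
#' `fraction = (m/M_s) / (m/M_s + 1/M_r)`.
#'
#' @param mass_ratio Stain mass per resin mass, g/g (>= 0).
#' @param resin A [material()] giving the resin composition.
#' @param stain_mean_mass Mean atomic mass of the stain, g/mol (default
#'   207.2, lead; configure for an Os/Pb/U mix).
#' @return Atomic fraction of heavy atoms.
#' @export
heavy_atom_fraction <- function(mass_ratio, resin = epon812(),
                                stain_mean_mass = 207.2) {
  stopifnot(mass_ratio >= 0, stain_mean_mass > 0,
            inherits(resin, "material"))
  ns <- mass_ratio / stain_mean_mass
  nr <- 1 / resin$mean_atomic_mass
  ns / (ns + nr)
}
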