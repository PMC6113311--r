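# Electron-interaction physics: elemental cross sections, ionization
# potentials, stopping powers and elastic mean free paths for compounds.
# These quantities drive the Monte Carlo engine; the same closed forms are
# evaluated inside the compiled stepping loop.

# Small internal table of the elements this package routinely meets.
.ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O", "Os", "Pb", "U"),
  Z = c(1, 6, 7, 8, 76, 82, 92),
  A_w = c(1.008, 12.011, 14.007, 15.999, 190.23, 207.2, 238.029),
  stringsAsFactors = FALSE
)

.lookup_element <- function(x) {
  if (is.character(x)) {
    i <- match(x, .ELEMENTS$symbol)
    if (is.na(i)) stop("unknown element symbol: ", x, call. = FALSE)
  } else {
    i <- match(as.integer(x), .ELEMENTS$Z)
    if (is.na(i)) stop("no tabulated atomic mass for Z = ", x,
                       "; pass A_w explicitly via element()", call. = FALSE)
  }
  .ELEMENTS[i, ]
}

#' Define a single element of a compound
#'
#' @param symbol Element symbol (e.g. `"C"`) or atomic number.
#' @param atomic_fraction Fraction of all atoms in the compound that are
#'   this element (dimensionless, in `[0, 1]`).
#' @param Z,A_w Atomic number and atomic mass (g/mol); looked up from the
#'   built-in table when a known symbol or Z is given.
#' @return A one-row data frame with columns `symbol`, `Z`, `A_w`,
#'   `atomic_fraction`.
#' @export
element <- function(symbol, atomic_fraction, Z = NULL, A_w = NULL) {
  if (is.null(Z) || is.null(A_w)) {
    e <- .lookup_element(symbol)
    if (is.null(Z)) Z <- e$Z
    if (is.null(A_w)) A_w <- e$A_w
    symbol <- e$symbol
  }
  stopifnot(Z >= 1, A_w > 0,
            atomic_fraction >= 0, atomic_fraction <= 1)
  data.frame(symbol = as.character(symbol), Z = Z, A_w = A_w,
             atomic_fraction = atomic_fraction, stringsAsFactors = FALSE)
}

#' Define a compound material
#'
#' A material is a list of elements with atomic fractions summing to one,
#' plus a bulk mass density. Per-element number densities (atoms/nm^3) and
#' mass fractions are derived at construction time so that all downstream
#' unit conversions happen in one place.
#'
#' @param elements Data frame of element rows (see [element()]), or a list
#'   of such rows which will be row-bound.
#' @param mass_density Bulk density in g/cm^3.
#' @param name Optional label carried through provenance records.
#' @return An object of class `material`.
#' @examples
#' epon812()
#' material(rbind(element("C", 1)), mass_density = 2.0, name = "carbon")
#' @export
material <- function(elements, mass_density, name = NULL) {
  if (is.list(elements) && !is.data.frame(elements))
    elements <- do.call(rbind, elements)
  stopifnot(is.data.frame(elements), nrow(elements) >= 1,
            mass_density > 0)
  f <- elements$atomic_fraction
  if (abs(sum(f) - 1) > 1e-9)
    stop("atomic fractions must sum to 1 (got ", format(sum(f)), ")",
         call. = FALSE)
  mean_A <- sum(f * elements$A_w)               # g/mol per atom
  # total atoms/nm^3 = rho [g/cm^3] * N_A / mean_A * 1e-21 [cm^3/nm^3]
  n_total <- mass_density * .AVOGADRO / mean_A * 1e-21
  elements$n <- f * n_total                     # atoms/nm^3
  elements$mass_fraction <- f * elements$A_w / mean_A
  structure(list(elements = elements,
                 mass_density = mass_density,
                 mean_atomic_mass = mean_A,
                 number_density = n_total,
                 name = name %||% "material"),
            class = "material")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material: %s>  rho = %.3f g/cm^3, %.2f atoms/nm^3\n",
              x$name, x$mass_density, x$number_density))
  print(x$elements[, c("symbol", "Z", "A_w", "atomic_fraction", "n")],
        row.names = FALSE)
  invisible(x)
}

# List form handed to the compiled code
.material_clist <- function(m) {
  list(Z = m$elements$Z, A_w = m$elements$A_w, n = m$elements$n,
       mass_fraction = m$elements$mass_fraction,
       mass_density = m$mass_density)
}

#' Epon 812 epoxy embedding resin
#'
#' H/C/O resin with atomic fractions 0.53/0.35/0.12 at 1.22 g/cm^3, the
#' standard light-element matrix for heavy-metal-stained blocks.
#' @return A [material()].
#' @export
epon812 <- function() {
  material(rbind(element("H", 0.53), element("C", 0.35),
                 element("O", 0.12)),
           mass_density = 1.22, name = "epon812")
}

#' Lead-stained epoxy resin
#'
#' Epon 812 with a lead atomic fraction `fraction` replacing a
#' proportional share of the matrix atoms. The default 3 at% lead at
#' 1.52 g/cm^3 is the benchmark stained material used for calibration
#' cuboids.
#'
#' @param fraction Lead atomic fraction (of all atoms).
#' @param mass_density Bulk density in g/cm^3 of the stained material.
#' @return A [material()].
#' @export
epon812_pb <- function(fraction = 0.03, mass_density = 1.52) {
  stopifnot(fraction >= 0, fraction < 0.5)
  if (fraction == 0) return(epon812())
  material(rbind(element("H", 0.53 * (1 - fraction)),
                 element("C", 0.35 * (1 - fraction)),
                 element("O", 0.12 * (1 - fraction)),
                 element("Pb", fraction)),
           mass_density = mass_density,
           name = sprintf("epon812+Pb(%.3g)", fraction))
}

.check_energy <- function(E, lo = 0.05, hi = 30) {
  if (any(!is.finite(E)) || any(E < lo) || any(E > hi))
    stop("landing energy must be in [", lo, ", ", hi, "] keV",
         call. = FALSE)
  invisible(E)
}

#' Total elastic scattering cross section per atom
#'
#' Screened-Rutherford analytic form with relativistic correction:
#' \deqn{\sigma = 5.21\times 10^{-21}\frac{Z^2}{E^2}
#'   \frac{4\pi}{\alpha(1+\alpha)}
#'   \left(\frac{E+511}{E+1024}\right)^2 \;\mathrm{cm}^2,}
#' with screening parameter \eqn{\alpha = 3.4\times10^{-3} Z^{0.67}/E}
#' (E in keV). Returned in nm^2. Tabulated Mott cross sections can be
#' substituted through the `model` argument of the Monte Carlo drivers;
#' for high-Z elements below ~1 keV the analytic form can differ from
#' partial-wave values by tens of percent.
#'
#' @param Z Atomic number, 1..92.
#' @param E Landing energy in keV, 0.05..30.
#' @return Cross section in nm^2.
#' @examples
#' elastic_cross_section(6, 1.0)   # ~5.1e-3 nm^2
#' @export
elastic_cross_section <- function(Z, E) {
  stopifnot(Z >= 1, Z <= 92)
  .check_energy(E)
  mapply(sigma_el_cpp, Z, E)
}

#' Screening parameter of the screened-Rutherford cross section
#'
#' @inheritParams elastic_cross_section
#' @return Dimensionless screening parameter alpha.
#' @export
screening_parameter <- function(Z, E) {
  stopifnot(Z >= 1)
  .check_energy(E)
  3.4e-3 * Z^0.67 / E
}

#' Sample the polar scattering cosine
#'
#' Inverse-CDF sampling of the screened-Rutherford angular distribution:
#' `cos(theta) = 1 - 2*alpha*u / (1 + alpha - u)` for a uniform variate
#' `u` in `[0, 1]`.
#'
#' @param alpha Screening parameter (> 0), see [screening_parameter()].
#' @param u Uniform variate(s) in `[0, 1]`.
#' @return Scattering cosine(s) in `[-1, 1]`.
#' @export
sample_scatter_cosine <- function(alpha, u) {
  stopifnot(alpha > 0, all(u >= 0), all(u <= 1))
  1 - 2 * alpha * u / (1 + alpha - u)
}

#' Mean ionization potential (Berger-Seltzer fit)
#'
#' `J = (9.76 Z + 58.5 Z^-0.19) * 1e-3` keV. The fit is known to be
#' unreliable for hydrogen (Z = 1); an override value can be supplied
#' where that matters.
#'
#' @param Z Atomic number (>= 1).
#' @param override Optional named numeric vector mapping Z to J (keV),
#'   e.g. `c("1" = 0.0195)`.
#' @return J in keV.
#' @export
mean_ionization_potential <- function(Z, override = NULL) {
  stopifnot(all(Z >= 1))
  J <- (9.76 * Z + 58.5 * Z^-0.19) * 1e-3
  if (!is.null(override)) {
    i <- match(as.character(Z), names(override))
    J[!is.na(i)] <- override[i[!is.na(i)]]
  }
  J
}

#' Stopping power of a compound (Joy-Luo modified Bethe)
#'
#' Mass-fraction-weighted (Bragg additivity) Joy-Luo expression,
#' \deqn{-dE/ds = 7.85\times10^{-3}\frac{\rho}{E}\sum_i c_i \frac{Z_i}{A_i}
#'   \ln\!\frac{1.166(E + k J_i)}{J_i}\ \mathrm{keV/nm},}
#' with the low-energy correction constant `k` (default 0.77).
#'
#' @param material A [material()].
#' @param E Energy in keV (> 0).
#' @param k Joy-Luo low-energy correction constant.
#' @return Energy loss rate in keV/nm (positive).
#' @export
stopping_power <- function(material, E, k = 0.77) {
  stopifnot(inherits(material, "material"))
  if (any(E <= 0)) stop("energy must be positive", call. = FALSE)
  vapply(E, function(e) dEds_cpp(.material_clist(material), e, k),
         numeric(1))
}

#' Elastic mean free path in a compound
#'
#' `lambda = 1 / sum_i n_i sigma_i(E)` over the per-element number
#' densities `n_i` (atoms/nm^3).
#'
#' @inheritParams stopping_power
#' @return Mean free path in nm.
#' @export
elastic_mfp <- function(material, E) {
  stopifnot(inherits(material, "material"))
  .check_energy(E)
  vapply(E, function(e) 1 / inv_mfp_cpp(.material_clist(material), e),
         numeric(1))
}
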