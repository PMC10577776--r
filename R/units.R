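# Hartree atomic units throughout (hbar = 1, electron mass = 1);
# cm^-1, angstrom and fs appear only at I/O boundaries.

#' Unit conversions between atomic units and spectroscopic units
#'
#' All internal quantities are Hartree atomic units with \eqn{\hbar = 1}.
#' Spectra are reported in wavenumbers (cm\eqn{^{-1}}), geometries read from
#' XYZ files in angstrom, and times occasionally quoted in femtoseconds.
#' These helpers are the single conversion site.
#'
#' @param E energy in hartree (or wavenumber in cm\eqn{^{-1}} for the inverse).
#' @param t time in atomic units (or femtoseconds for the inverse).
#' @param x length in bohr (or angstrom for the inverse).
#' @return Numeric vector in the target unit.
#' @examples
#' au_to_wavenumber(0.01)     # 2194.746 cm^-1
#' au_time_to_fs(25000)       # about 605 fs
#' @name units
NULL

# CODATA conversion factors
.hartree_to_cm1 <- 219474.6313702
.au_time_to_fs <- 0.02418884254
.bohr_to_angstrom <- 0.529177210903
.amu_to_me <- 1822.888486209

#' @rdname units
#' @export
au_to_wavenumber <- function(E) E * .hartree_to_cm1

#' @rdname units
#' @export
wavenumber_to_au <- function(E) E / .hartree_to_cm1

#' @rdname units
#' @export
au_time_to_fs <- function(t) t * .au_time_to_fs

#' @rdname units
#' @export
fs_to_au_time <- function(t) t / .au_time_to_fs

#' @rdname units
#' @export
bohr_to_angstrom <- function(x) x * .bohr_to_angstrom

#' @rdname units
#' @export
angstrom_to_bohr <- function(x) x / .bohr_to_angstrom

# atomic masses (amu) for common elements, converted to electron-mass units
.element_masses_amu <- c(
  H = 1.00782503207, D = 2.01410177785, He = 4.002602,
  C = 12.0, N = 14.0030740048, O = 15.9949146196,
  F = 18.99840322, P = 30.97376163, S = 31.97207100, Cl = 34.96885268
)

#' Atomic masses in electron-mass units
#'
#' @param elements character vector of element symbols.
#' @return Numeric vector of masses in electron-mass units.
#' @export
element_masses <- function(elements) {
  m <- .element_masses_amu[elements]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m) * .amu_to_me
}
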