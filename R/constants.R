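#' Physical constants used throughout the package
#'
#' Returns the pinned set of physical constants used by every coupling and
#' Förster-equation computation in the package. Pinning them in one place
#' makes every derived number in the documentation and tests reproducible
#' to the printed digits.
#'
#' The Coulomb prefactor converts a sum of \eqn{q_i q_j / r_{ij}} (charges
#' in units of the elementary charge e, distances in Ångström) directly
#' into wavenumbers:
#' \deqn{e^2/(4\pi\varepsilon_0) = 14.39964500\ \mathrm{eV\cdot\AA},\quad
#'       1\ \mathrm{eV} = 8065.543937\ \mathrm{cm^{-1}},}
#' giving \code{coulomb_cm1_angstrom} = 14.399645 x 8065.543937
#' = 116140.9732 cm\eqn{^{-1}}·Å (1.161410e5 to 7 significant digits).
#'
#' @return A list with components:
#'   \item{N_A}{Avogadro constant, 6.02214076e23 mol\eqn{^{-1}} (exact, SI).}
#'   \item{e2_4pieps0_eV_A}{\eqn{e^2/(4\pi\varepsilon_0)} in eV·Å.}
#'   \item{eV_to_cm1}{Wavenumbers per eV.}
#'   \item{coulomb_cm1_angstrom}{\eqn{e^2/(4\pi\varepsilon_0)} in cm\eqn{^{-1}}·Å.}
#'   \item{liters_to_cm3}{1000, the L to cm\eqn{^3} factor used to convert a
#'     spectral overlap in M\eqn{^{-1}}cm\eqn{^3} to cm\eqn{^6} mol\eqn{^{-1}}.}
#' @examples
#' cc <- fret_constants()
#' cc$coulomb_cm1_angstrom  # 116140.97 cm^-1 Angstrom
#' @export
fret_constants <- function() {
  e2_4pieps0_eV_A <- 14.399645
  eV_to_cm1 <- 8065.543937
  list(
    N_A = 6.02214076e23,
    e2_4pieps0_eV_A = e2_4pieps0_eV_A,
    eV_to_cm1 = eV_to_cm1,
    coulomb_cm1_angstrom = e2_4pieps0_eV_A * eV_to_cm1,
    liters_to_cm3 = 1000
  )
}

# Standard atomic masses (Da), IUPAC 2021 abridged values.
.atomic_masses <- c(
  H = 1.008, He = 4.003, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085,
  P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078,
  Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546,
  Zn = 65.38, Se = 78.971, Br = 79.904, I = 126.90
)

#' Standard atomic masses
#'
#' Looks up standard atomic masses (Da) for element symbols. Symbols are
#' matched case-insensitively ("MG" and "Mg" both work, as PDB element
#' columns are upper case).
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of masses in Da.
#' @examples
#' atomic_mass(c("C", "H", "MG"))
#' @export
atomic_mass <- function(elements) {
  key <- paste0(
    toupper(substr(elements, 1, 1)),
    tolower(substr(elements, 2, nchar(elements)))
  )
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    bad <- unique(elements[is.na(m)])
    stop("no standard atomic mass for element(s): ",
         paste(bad, collapse = ", "),
         " (supply masses explicitly)", call. = FALSE)
  }
  unname(m)
}
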