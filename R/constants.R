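#' Physical constants used throughout the package
#'
#' The package works in one fixed unit system: lengths in angstrom (\eqn{\AA}),
#' energies in kcal mol\eqn{^{-1}}, temperatures in kelvin, pressures in atm
#' and charges in elementary charge units. `emip_constants()` returns the
#' conversion factors that tie these units together.
#'
#' @return Named list with elements
#'   \describe{
#'     \item{coulomb}{Coulomb prefactor, kcal mol\eqn{^{-1}} \eqn{\AA} e\eqn{^{-2}}.}
#'     \item{kB}{Boltzmann constant, kcal mol\eqn{^{-1}} K\eqn{^{-1}}.}
#'     \item{atm_A3}{1 atm \eqn{\times} 1 \eqn{\AA^3} in kcal mol\eqn{^{-1}}.}
#'     \item{hartree_kcal}{1 hartree in kcal mol\eqn{^{-1}}.}
#'     \item{faraday}{Faraday constant, C mol\eqn{^{-1}}.}
#'   }
#' @examples
#' emip_constants()$kB
#' @export
emip_constants <- function() {
  list(
    coulomb      = 332.06371,
    kB           = 0.0019872041,
    atm_A3       = 101325 * 1e-30 * 6.02214076e23 / 4184,
    hartree_kcal = 627.5095,
    faraday      = 96485
  )
}

.COULOMB  <- 332.06371
.KB       <- 0.0019872041
.ATM_A3   <- 101325 * 1e-30 * 6.02214076e23 / 4184
.HARTREE  <- 627.5095
.FARADAY  <- 96485

# atomic masses (g/mol) for the elements the toy force fields use;
# box sizing from a target density needs nothing more exotic
.ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, Cl = 35.45
)

element_mass <- function(element) {
  m <- .ELEMENT_MASS[element]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "),
         "; supported: ", paste(names(.ELEMENT_MASS), collapse = ", "))
  }
  unname(m)
}
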