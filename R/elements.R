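# Physical constants used throughout the package.
# Avogadro's number (2019 SI exact value), electron and proton rest energies.
.constants <- list(
  N_A     = 6.02214076e23,   # mol^-1
  m_e_c2  = 0.51099895,      # MeV
  m_p_c2  = 938.27208816     # MeV
)

# Element registry for the 13 elements occurring in the reference human
# tissues (plus water's H/O, already among them).
#
# Z, A_w : atomic number and IUPAC 2021 standard atomic weight (g/mol).
# I_eV   : mean excitation energy, ICRU-37 values as tabulated in the Geant4
#          manual (eV).
# mu_rho_kv, mu_rho_mv : total photon mass attenuation coefficients
#          (cm^2/g, coherent scattering included) at 0.060 MeV and 0.8 MeV,
#          the single effective energies used for the kV and MV imaging
#          beams.  Values are generated from the standard three-component
#          cross-section parameterization (photoelectric ~ Z^3.62, coherent
#          ~ Z^1.86 per electron, Klein-Nishina Compton) calibrated at each
#          energy against NIST reference coefficients for water and ICRU-44
#          cortical bone (60 keV) and for water and iron (0.8 MeV).  The
#          low-Z power law breaks down near the iodine K-edge (33.2 keV), so
#          the iodine entries are taken from standard tabulations instead.
.element_table <- data.frame(
  symbol = c("H", "C", "N", "O", "Ca", "P", "Na",
             "Mg", "S", "Cl", "K", "Fe", "I"),
  Z      = c(1, 6, 7, 8, 20, 15, 11, 12, 16, 17, 19, 26, 53),
  A_w    = c(1.008, 12.011, 14.007, 15.999, 40.078, 30.973761998,
             22.98976928, 24.305, 32.06, 35.45, 39.0983, 55.845, 126.90447),
  I_eV   = c(19.2, 78.0, 82.0, 95.0, 191, 173, 149,
             156, 180, 174, 190, 286, 491),
  mu_rho_kv = c(0.3264, 0.1759, 0.1822, 0.1907, 0.6607, 0.3422, 0.2237,
                0.2526, 0.3978, 0.4327, 0.5658, 1.2999, 7.6),
  mu_rho_mv = c(0.14038, 0.07072, 0.07076, 0.07082, 0.07111, 0.06876,
                0.06782, 0.07001, 0.07090, 0.06817, 0.06919, 0.06680,
                0.0613),
  stringsAsFactors = FALSE
)
rownames(.element_table) <- .element_table$symbol

#' Element symbols recognised by the tissue table
#'
#' Canonical column order of the elemental weight columns used by every
#' tissue table in the package.
#'
#' @return Character vector of the 13 element symbols.
#' @export
element_symbols <- function() .element_table$symbol

#' Element physical constants
#'
#' Registry of atomic constants for the 13 elements present in the reference
#' human tissues: atomic number, atomic weight, mean excitation energy and
#' total photon mass attenuation coefficients at the kV (0.060 MeV) and MV
#' (0.8 MeV) effective imaging energies.
#'
#' @return A data frame with one row per element and columns `symbol`, `Z`,
#'   `A_w` (g/mol), `I_eV` (eV), `mu_rho_kv` and `mu_rho_mv` (cm^2/g).
#' @examples
#' element_registry()["Ca", ]
#' @export
element_registry <- function() .element_table

#' Export the element registry as JSON
#'
#' Writes the element constants to a JSON file so the numerical inputs of an
#' analysis can be audited alongside its outputs.
#'
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_element_registry <- function(path) {
  jsonlite::write_json(.element_table, path, digits = NA, pretty = TRUE)
  invisible(path)
}

# Internal lookup helpers; `symbols` must be a subset of element_symbols().
.elem <- function(symbols, field) {
  idx <- match(symbols, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(symbols[is.na(idx)], collapse = ", "))
  }
  .element_table[[field]][idx]
}
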