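# Narrow-beam photon attenuation and the kV vs MV CT-number linearity
# comparison.
#
# CT numbers here come from the analytic expectation of an unscattered-
# photon counting experiment: a photon survives a thickness t of material
# with probability exp(-mu * t), so the estimand of the surviving fraction
# is exactly the Beer-Lambert linear attenuation coefficient
# mu = rho * sum(omega_i / 100 * (mu/rho)_i) (elemental mixture rule, total
# coefficients including coherent scattering, since a coherently scattered
# photon no longer counts as unscattered).

.beam_energies <- c(kV = 0.060, MV = 0.8)

#' Photon imaging beam
#'
#' Single effective energies standing in for the imaging spectra: 0.060 MeV
#' for a 120 kVp beam (near the tungsten characteristic x rays) and 0.8 MeV
#' for a 2.5 MV imaging beam (near its average energy).
#'
#' @param label `"kV"` or `"MV"`.
#' @return An object of class `photon_beam` with fields `label` and
#'   `energy_MeV`.
#' @export
photon_beam <- function(label = c("kV", "MV")) {
  label <- match.arg(label)
  structure(list(label = label, energy_MeV = unname(.beam_energies[label])),
            class = "photon_beam")
}

.mu_rho_column <- function(beam) {
  switch(beam$label, kV = "mu_rho_kv", MV = "mu_rho_mv",
         stop("no mass attenuation table for beam '", beam$label, "'"))
}

#' Elemental mass attenuation coefficients at an arbitrary energy
#'
#' Log-log interpolation between the two embedded tabulation energies
#' (0.060 and 0.8 MeV).  This is a coarse utility for sensitivity probing
#' only; the default analyses use the embedded energies directly.
#'
#' @param symbols Element symbols.
#' @param energy_MeV Photon energy within [0.060, 0.8] MeV.
#' @return Mass attenuation coefficients (cm^2/g).
#' @export
mass_attenuation <- function(symbols, energy_MeV) {
  stopifnot(length(energy_MeV) == 1,
            energy_MeV >= 0.060, energy_MeV <= 0.8)
  lo <- .elem(symbols, "mu_rho_kv")
  hi <- .elem(symbols, "mu_rho_mv")
  f <- (log(energy_MeV) - log(0.060)) / (log(0.8) - log(0.060))
  exp((1 - f) * log(lo) + f * log(hi))
}

#' Linear photon attenuation coefficient of a tissue
#'
#' Mixture rule: `mu = rho * sum(omega_i / 100 * (mu/rho)_i)` with the total
#' (coherent-inclusive) elemental coefficients at the beam energy.  Exactly
#' linear in density.
#'
#' @param tissues A tissue set.
#' @param beam A [photon_beam()].
#' @return Linear attenuation coefficients in 1/cm, named by tissue.
#' @examples
#' linear_attenuation(water_reference(), photon_beam("MV"))  # ~0.0786
#' @export
linear_attenuation <- function(tissues, beam = photon_beam("kV")) {
  mu_rho <- .elem(element_symbols(), .mu_rho_column(beam))
  mu <- tissues$density * drop((weight_matrix(tissues) / 100) %*% mu_rho)
  names(mu) <- tissues$name
  mu
}

#' Scaled CT number from attenuation coefficients
#'
#' `HU_scale = 1000 + 1000 * (mu - mu_water) / mu_water = 1000 * mu / mu_water`:
#' water maps to exactly 1000 and vacuum to 0.
#'
#' @param mu Linear attenuation coefficient(s), 1/cm.
#' @param mu_water Water's coefficient at the same energy (> 0).
#' @return Scaled CT numbers.
#' @export
hu_from_mu <- function(mu, mu_water) {
  if (any(mu_water <= 0)) stop("mu_water must be positive")
  1000 * mu / mu_water
}

#' Scaled CT numbers of a tissue set for an imaging beam
#'
#' @param tissues A tissue set.
#' @param beam A [photon_beam()].
#' @return Scaled CT numbers, named by tissue.
#' @export
beam_hu_scale <- function(tissues, beam = photon_beam("kV")) {
  hu_from_mu(linear_attenuation(tissues, beam),
             linear_attenuation(water_reference(), beam))
}

#' Linearity of CT number against RED for kV and MV beams
#'
#' Fits, per beam and per tissue category, an unweighted line of the
#' beam-model scaled CT number against RED, and reports the coefficient of
#' determination.  At MV energies attenuation is Compton-dominated and
#' almost exactly proportional to electron density, so the MV fits are
#' near-perfect; the photoelectric and coherent terms degrade the kV fits,
#' most visibly in the three-point fat category.
#'
#' @param tissues A tissue set (each category needs at least 3 tissues).
#' @param beams List of [photon_beam()]s to compare.
#' @return Data frame with columns `beam`, `category`, `slope`, `intercept`,
#'   `r_squared` (unrounded; round to 4 decimals for display), `n_points`.
#' @examples
#' linearity_comparison(load_tissue_table("icrp23_reference"))
#' @export
linearity_comparison <- function(tissues,
                                 beams = list(photon_beam("kV"),
                                              photon_beam("MV"))) {
  red <- relative_electron_density(tissues)
  rows <- lapply(beams, function(beam) {
    hu <- beam_hu_scale(tissues, beam)
    do.call(rbind, lapply(.categories, function(cc) {
      in_cat <- tissues$category == cc
      if (sum(in_cat) < 3) {
        stop("category '", cc, "' has fewer than 3 tissues")
      }
      m <- stats::lm(hu[in_cat] ~ red[in_cat])
      data.frame(beam = beam$label, category = cc,
                 slope = unname(stats::coef(m)[2]),
                 intercept = unname(stats::coef(m)[1]),
                 r_squared = .r_squared(m),
                 n_points = sum(in_cat),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
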