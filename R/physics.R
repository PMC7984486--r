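# Physics of the stoichiometric calibration model.
#
# All functions are vectorized over the rows of a tissue set.  Elemental
# weights are percentages summing to 100; every derived quantity is kept in
# double precision with no intermediate rounding.

# omega_i * Z_i / A_i summed over elements; the electron "moles per gram"
# before multiplying by Avogadro's number.
.electron_moles <- function(tissues) {
  w <- weight_matrix(tissues) / 100
  za <- .elem(element_symbols(), "Z") / .elem(element_symbols(), "A_w")
  drop(w %*% za)
}

#' Electrons per unit mass
#'
#' Total number of electrons per gram, N_g = N_A * sum_i(omega_i * Z_i / A_i),
#' with omega_i the elemental mass fractions.
#'
#' @param tissues A tissue set.
#' @return Numeric vector of N_g values (electrons per gram), named by tissue.
#' @examples
#' electrons_per_gram(water_reference()) / 6.02214076e23  # ~0.5551 mol/g
#' @export
electrons_per_gram <- function(tissues) {
  ng <- .constants$N_A * .electron_moles(tissues)
  names(ng) <- tissues$name
  ng
}

#' Relative electron density
#'
#' RED = (rho * N_g) / (rho_w * N_w): electrons per unit volume relative to
#' water, the quantity a well-calibrated MV CT scan can image directly.
#'
#' @param tissues A tissue set.
#' @return Numeric vector of RED values, named by tissue; water maps to 1.
#' @export
relative_electron_density <- function(tissues) {
  water <- water_reference()
  red <- tissues$density * .electron_moles(tissues) /
    (water$density * .electron_moles(water))
  names(red) <- tissues$name
  red
}

#' Effective atomic numbers of the kV CT-number model
#'
#' Power means of the atomic number over electron fractions
#' lambda_i = N_g,i / N_g: the photoelectric effective atomic number uses
#' exponent 3.62 and the coherent-scatter one exponent 1.86.  The exponents
#' are fixed constants of the model, not fit parameters, and the power-mean
#' inequality guarantees `Z_hat <= Z_tilde`.
#'
#' @param tissues A tissue set.
#' @return Data frame with columns `Z_tilde` and `Z_hat`, one row per tissue.
#' @export
effective_atomic_numbers <- function(tissues) {
  w <- weight_matrix(tissues) / 100
  za <- .elem(element_symbols(), "Z") / .elem(element_symbols(), "A_w")
  z <- .elem(element_symbols(), "Z")
  lam <- sweep(sweep(w, 2, za, `*`), 1, drop(w %*% za), `/`)
  data.frame(
    name = tissues$name,
    Z_tilde = drop(lam %*% z^3.62)^(1 / 3.62),
    Z_hat   = drop(lam %*% z^1.86)^(1 / 1.86),
    stringsAsFactors = FALSE
  )
}

#' Bragg-additivity mean excitation energy
#'
#' Electron-fraction-weighted mean of the logarithmic elemental mean
#' excitation energies:
#' ln I_m = sum(omega_i Z_i / A_i * ln I_i) / sum(omega_i Z_i / A_i).
#'
#' @param tissues A tissue set.
#' @return Numeric vector of ln(I_m) with I_m in eV, named by tissue.
#'   `exp()` of the result gives I_m in eV (about 69 eV for water).
#' @export
mean_excitation <- function(tissues) {
  w <- weight_matrix(tissues) / 100
  za <- .elem(element_symbols(), "Z") / .elem(element_symbols(), "A_w")
  lnI <- log(.elem(element_symbols(), "I_eV"))
  out <- drop(w %*% (za * lnI)) / drop(w %*% za)
  names(out) <- tissues$name
  out
}

#' Squared proton speed ratio
#'
#' beta^2 = 1 - (m_p c^2 / (T + m_p c^2))^2 for a proton of kinetic energy
#' `T` MeV (relativistic kinematics, m_p c^2 = 938.272 MeV).
#'
#' @param T Proton kinetic energy in MeV (> 0).
#' @return beta^2, strictly increasing in `T` and < 1.
#' @examples
#' beta_squared(175)  # ~0.290
#' @export
beta_squared <- function(T) {
  if (any(T <= 0)) stop("proton kinetic energy must be positive")
  1 - (.constants$m_p_c2 / (T + .constants$m_p_c2))^2
}

#' Proton beam description
#'
#' @param energy_MeV Proton kinetic energy in MeV.  The default of 175 MeV
#'   is a mid-range therapeutic energy; downstream percentage-deviation
#'   statistics are nearly insensitive to this choice.
#' @return An object of class `proton_beam` with fields `energy_MeV`,
#'   `beta_sq` and `m_e_c2` (MeV).
#' @export
proton_beam <- function(energy_MeV = 175) {
  structure(list(energy_MeV = energy_MeV,
                 beta_sq = beta_squared(energy_MeV),
                 m_e_c2 = .constants$m_e_c2),
            class = "proton_beam")
}

# ln I_w (eV): either Bragg additivity over water's own composition (so that
# SPR(water) is exactly 1 by construction) or a fixed tabulated value.
.ln_iw <- function(iw_mode = c("bragg_additivity", "fixed"), iw_eV = 78) {
  iw_mode <- match.arg(iw_mode)
  if (iw_mode == "bragg_additivity") {
    unname(mean_excitation(water_reference()))
  } else {
    if (iw_eV <= 0) stop("iw_eV must be positive")
    log(iw_eV)
  }
}

#' Proton stopping-power ratio relative to water
#'
#' Ratio of the tissue mass stopping power to that of water at the same
#' proton energy, from the Bethe stopping number without shell or density
#' corrections:
#' `SPR = RED * (ln(2 m_e c^2 beta^2 / (I_m (1 - beta^2))) - beta^2) /
#'              (ln(2 m_e c^2 beta^2 / (I_w (1 - beta^2))) - beta^2)`.
#'
#' Because I_w enters truth and calibration identically, percentage-deviation
#' statistics computed downstream are invariant to any positive rescaling of
#' I_w; the `iw_mode` switch exists to make that explicit.
#'
#' @param tissues A tissue set.
#' @param beam A [proton_beam()].
#' @param iw_mode `"bragg_additivity"` (default): I_w from water's own
#'   composition, making SPR(water) exactly 1; `"fixed"`: use `iw_eV`.
#' @param iw_eV Water mean excitation energy in eV when `iw_mode = "fixed"`.
#' @return Numeric vector of SPR values, named by tissue.
#' @export
proton_spr <- function(tissues, beam = proton_beam(),
                       iw_mode = c("bragg_additivity", "fixed"), iw_eV = 78) {
  b2 <- beam$beta_sq
  # ln(2 m_e c^2 beta^2 / (1 - beta^2)) with m_e c^2 in eV
  ln_kin <- log(2 * beam$m_e_c2 * 1e6 * b2 / (1 - b2))
  num <- ln_kin - mean_excitation(tissues) - b2
  den <- ln_kin - .ln_iw(iw_mode, iw_eV) - b2
  if (den <= 0) stop("stopping number of water is non-positive at beta^2 = ", b2)
  if (any(num <= 0)) {
    stop("non-positive stopping number for tissue(s): ",
         paste(tissues$name[num <= 0], collapse = ", "))
  }
  relative_electron_density(tissues) * num / den
}

#' kV CT-number model fit parameters
#'
#' Container for the (A, B, C) coefficients of the scaled-CT-number model
#' `HU_scale = RED * (A * Z_tilde^3.62 + B * Z_hat^1.86 + C)`, whose three
#' terms represent photoelectric interaction, coherent scattering and
#' Compton scattering.  The coefficients are machine and energy dependent.
#'
#' @param A,B,C Model coefficients (A, B >= 0, C > 0).
#' @return An object of class `kv_fit_parameters`.
#' @seealso [default_kv_fit()] for the packaged 120 kVp scanner values,
#'   [fit_kv_parameters()] to fit from phantom measurements.
#' @export
kv_fit_parameters <- function(A, B, C) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C), length(A) == 1,
            length(B) == 1, length(C) == 1)
  if (C <= 0 || A < 0 || B < 0) {
    stop("require A >= 0, B >= 0, C > 0")
  }
  structure(list(A = A, B = B, C = C), class = "kv_fit_parameters")
}

#' Default kV fit parameters
#'
#' Coefficients determined for a 120 kVp helical CT scanner from electron
#' density phantom measurements: A = 1.995e-2, B = 1.899e-1, C = 964.0.
#' These are the packaged defaults; refit with [fit_kv_parameters()] for a
#' different scanner.
#'
#' @return A [kv_fit_parameters()] object.
#' @export
default_kv_fit <- function() kv_fit_parameters(1.995e-2, 1.899e-1, 9.640e2)

#' @export
print.kv_fit_parameters <- function(x, ...) {
  cat(sprintf("kV CT-number model: HU_scale = RED * (%.4g * Z~^3.62 + %.4g * Z^^1.86 + %.4g)\n",
              x$A, x$B, x$C))
  invisible(x)
}

#' Scaled kV CT number from the stoichiometric model
#'
#' `HU_scale = RED * (A * Z_tilde^3.62 + B * Z_hat^1.86 + C)`, i.e. the CT
#' number plus 1000, so water is close to 1000 and vacuum is 0.
#'
#' @param tissues A tissue set.
#' @param fit A [kv_fit_parameters()] object.
#' @return Numeric vector of scaled CT numbers, named by tissue.
#' @export
kv_hu_scale <- function(tissues, fit = default_kv_fit()) {
  zz <- effective_atomic_numbers(tissues)
  red <- relative_electron_density(tissues)
  red * (fit$A * zz$Z_tilde^3.62 + fit$B * zz$Z_hat^1.86 + fit$C)
}

#' All derived physical quantities of a tissue set
#'
#' Convenience wrapper computing, per tissue: electrons per gram, RED,
#' effective atomic numbers, mean excitation energy, the model kV CT number
#' and the proton SPR.
#'
#' @inheritParams proton_spr
#' @param fit A [kv_fit_parameters()] object for the CT-number model.
#' @return Data frame with columns `name`, `category`, `density`, `Ng`,
#'   `RED`, `Z_tilde`, `Z_hat`, `I_m_eV`, `HU_scale`, `SPR`.
#' @examples
#' head(tissue_physics(load_tissue_table("icrp23_reference")))
#' @export
tissue_physics <- function(tissues, fit = default_kv_fit(),
                           beam = proton_beam(),
                           iw_mode = c("bragg_additivity", "fixed"),
                           iw_eV = 78) {
  zz <- effective_atomic_numbers(tissues)
  data.frame(
    name = tissues$name,
    category = tissues$category,
    density = tissues$density,
    Ng = unname(electrons_per_gram(tissues)),
    RED = unname(relative_electron_density(tissues)),
    Z_tilde = zz$Z_tilde,
    Z_hat = zz$Z_hat,
    I_m_eV = unname(exp(mean_excitation(tissues))),
    HU_scale = unname(kv_hu_scale(tissues, fit)),
    SPR = unname(proton_spr(tissues, beam, iw_mode, iw_eV)),
    stringsAsFactors = FALSE
  )
}
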