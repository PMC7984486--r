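ref <- load_tissue_table("icrp23_reference")
N_A <- 6.02214076e23

test_that("electrons per gram agrees with a brute-force per-element sum", {
  ng <- electrons_per_gram(ref) / N_A
  for (i in seq_len(nrow(ref))) {
    expect_equal(ng[[i]], oracle_electron_moles(ref[i, ]), tolerance = 1e-12)
  }
  # water: 0.111907 * (1/1.008) + 0.888093 * (8/15.999) ~ 0.5551 mol e-/g
  expect_equal(unname(electrons_per_gram(water_reference()) / N_A),
               0.555092, tolerance = 1e-5)
})

test_that("pure-element compositions reduce to Z/A", {
  h <- water_reference()
  h[, element_symbols()] <- 0
  h$H <- 100
  expect_equal(unname(electrons_per_gram(h) / N_A), 1 / 1.008,
               tolerance = 1e-12)
})

test_that("relative electron density is water-normalized and linear in density", {
  expect_identical(unname(relative_electron_density(water_reference())), 1)
  red <- relative_electron_density(ref)
  heavy <- ref
  heavy$density <- 2 * heavy$density
  expect_equal(unname(relative_electron_density(heavy)), unname(2 * red),
               tolerance = 1e-14)
  # Adipose: rho * Ng / Ng_water by hand
  adipose <- ref[ref$name == "Adipose", ]
  expect_equal(red[["Adipose"]],
               0.95 * oracle_electron_moles(adipose) /
                 oracle_electron_moles(water_reference()),
               tolerance = 1e-12)
})

test_that("effective atomic numbers match the power-mean oracle for water", {
  zz <- effective_atomic_numbers(water_reference())
  # electron fractions of water: lambda_H ~ 0.2000, lambda_O ~ 0.8000
  lam_h <- (11.1896 / 100) * (1 / 1.008) / 0.555087
  lam_o <- 1 - lam_h
  expect_equal(zz$Z_tilde, (lam_h * 1 + lam_o * 8^3.62)^(1 / 3.62),
               tolerance = 1e-4)
  expect_equal(zz$Z_hat, (lam_h * 1 + lam_o * 8^1.86)^(1 / 1.86),
               tolerance = 1e-4)
  expect_equal(round(zz$Z_tilde, 2), 7.52)
  expect_equal(round(zz$Z_hat, 2), 7.12)
})

test_that("a single-element tissue has Z_tilde = Z_hat = Z", {
  o2 <- water_reference()
  o2[, element_symbols()] <- 0
  o2$O <- 100
  zz <- effective_atomic_numbers(o2)
  expect_equal(zz$Z_tilde, 8, tolerance = 1e-12)
  expect_equal(zz$Z_hat, 8, tolerance = 1e-12)
})

test_that("Z_hat <= Z_tilde for all reference tissues (power-mean inequality)", {
  zz <- effective_atomic_numbers(ref)
  expect_true(all(zz$Z_hat <= zz$Z_tilde + 1e-12))
})

test_that("Bragg-additivity mean excitation energy matches hand evaluation", {
  # water: exp((wH*ZH/AH*ln19.2 + wO*ZO/AO*ln95) / sum)
  el_h <- (11.1896 / 100) * (1 / 1.008)
  el_o <- (88.8104 / 100) * (8 / 15.999)
  lniw <- (el_h * log(19.2) + el_o * log(95)) / (el_h + el_o)
  expect_equal(unname(mean_excitation(water_reference())), lniw,
               tolerance = 1e-5)
  expect_equal(exp(lniw), 68.98, tolerance = 1e-3)

  carbon <- water_reference()
  carbon[, element_symbols()] <- 0
  carbon$C <- 100
  expect_equal(unname(exp(mean_excitation(carbon))), 78, tolerance = 1e-12)

  # any mixture lies between the elemental extremes
  lnim <- mean_excitation(ref)
  expect_true(all(lnim > log(19.2) & lnim < log(491)))
})

test_that("beta squared follows relativistic kinematics", {
  expect_equal(beta_squared(175), 1 - (938.27208816 / (175 + 938.27208816))^2,
               tolerance = 1e-15)
  expect_equal(beta_squared(175), 0.290, tolerance = 2e-3)
  tt <- seq(10, 300, by = 10)
  expect_true(all(diff(beta_squared(tt)) > 0))
  expect_lt(beta_squared(1e-6), 1e-8)
  expect_error(beta_squared(0), "positive")
})

test_that("model kV CT number behaves like Eq-of-state in RED and composition", {
  # water under the packaged scanner constants sits within 0.3% of 1000
  expect_equal(unname(kv_hu_scale(water_reference())), 1000,
               tolerance = 3e-3)
  # Compton-only limit: HU_scale = C * RED for any composition
  compton <- kv_fit_parameters(0, 0, 1000)
  expect_equal(unname(kv_hu_scale(ref, compton)),
               unname(1000 * relative_electron_density(ref)),
               tolerance = 1e-12)
  # exactly linear in RED at fixed composition
  heavy <- ref
  heavy$density <- 1.7 * heavy$density
  expect_equal(unname(kv_hu_scale(heavy)), unname(1.7 * kv_hu_scale(ref)),
               tolerance = 1e-12)
})

test_that("proton SPR of water is exactly 1 under Bragg-additivity I_w", {
  expect_equal(unname(proton_spr(water_reference())), 1, tolerance = 1e-15)
})

test_that("proton SPR matches a direct scalar evaluation for Adipose", {
  adipose <- ref[ref$name == "Adipose", ]
  el <- oracle_elements()
  za <- numeric(0)
  for (k in seq_len(nrow(el))) {
    za[el$symbol[k]] <- (adipose[[el$symbol[k]]] / 100) * el$Z[k] / el$A[k]
  }
  lnim <- sum(za * log(el$I_eV)) / sum(za)
  wat <- water_reference()
  za_w <- c(H = (wat$H / 100) * 1 / 1.008, O = (wat$O / 100) * 8 / 15.999)
  lniw <- sum(za_w * c(log(19.2), log(95))) / sum(za_w)
  b2 <- 1 - (938.27208816 / (175 + 938.27208816))^2
  lnk <- log(2 * 0.51099895e6 * b2 / (1 - b2))
  red <- 0.95 * sum(za) / sum(za_w)
  spr_oracle <- red * (lnk - lnim - b2) / (lnk - lniw - b2)
  expect_equal(unname(proton_spr(adipose, proton_beam(175))), spr_oracle,
               tolerance = 1e-12)
})

test_that("rescaling I_w rescales all SPRs by a common factor", {
  spr69 <- proton_spr(ref, iw_mode = "fixed", iw_eV = 69)
  spr78 <- proton_spr(ref, iw_mode = "fixed", iw_eV = 78)
  ratio <- spr69 / spr78
  expect_lt(diff(range(ratio)), 1e-14)
})
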