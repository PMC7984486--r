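ref <- load_tissue_table("icrp23_reference")

test_that("percentage deviation is the textbook formula", {
  expect_equal(percent_deviation(1000, 1000), 0)
  expect_equal(percent_deviation(1000, 1005), 0.5)
  expect_equal(percent_deviation(7, 14), 100)
  expect_error(percent_deviation(0, 1), "zero")
})

test_that("total uncertainty is the root sum of squares", {
  expect_equal(round(total_uncertainty(0.32, 0.11), 2), 0.34)
  expect_equal(round(total_uncertainty(0.44, 0.63), 2), 0.77)
  expect_equal(total_uncertainty(0.5, 0), 0.5)
  expect_equal(total_uncertainty(c(0.3, 0.4), c(0.4, 0.3)), c(0.5, 0.5))
  expect_error(total_uncertainty(-0.1, 0.2), "non-negative")
})

test_that("zero deviations give zero spread and zero maxima", {
  recs <- data.frame(tissue_name = ref$name, parent = ref$name,
                     category = ref$category, quantity = "SPR",
                     truth = 1, estimate = 1, pct_dev = 0,
                     stringsAsFactors = FALSE)
  out <- systematic_uncertainty(recs)
  expect_equal(out$sigma, rep(0, 4))
  expect_equal(out$max_abs, rep(0, 4))
  expect_equal(out$category, c("fat", "soft", "bone", "all"))
})

test_that("zero rel_sigma makes every statistical spread exactly zero", {
  sims <- simulate_all(ref, simulation_config(3, 0, seed = 1))
  curve <- build_calibration_curve(ref, "SPR")
  st <- statistical_uncertainty(deviation_records(sims, curve),
                                deviation_records(ref, curve))
  expect_equal(st$sigma, rep(0, 4), tolerance = 1e-12)
  expect_equal(st$max_abs, rep(0, 4), tolerance = 1e-12)
})

test_that("simulated records without a known parent are rejected", {
  curve <- build_calibration_curve(ref, "SPR")
  sims <- simulate_all(ref[1:3, ], simulation_config(2, 0.05, seed = 1))
  ref_recs <- deviation_records(ref[4:6, ], curve)
  sim_recs <- deviation_records(sims, curve)
  expect_error(statistical_uncertainty(sim_recs, ref_recs), "no parent")
})

test_that("sample and population sigmas differ only by the n-1 factor", {
  curve <- build_calibration_curve(ref, "HU_scale")
  recs <- deviation_records(ref, curve)
  s <- systematic_uncertainty(recs, "sample")
  p <- systematic_uncertainty(recs, "population")
  n <- s$n
  expect_equal(p$sigma, s$sigma * sqrt((n - 1) / n), tolerance = 1e-12)
  # the convention shifts the pooled value by far less than 0.02 points
  expect_lt(abs(s$sigma[4] - p$sigma[4]), 0.02)
})

test_that("the report grid is complete and internally consistent", {
  rep <- build_report(ref, config = simulation_config(10, 0.05, seed = 7))
  tab <- rep$table
  expect_equal(nrow(tab), 8)  # 4 categories x 2 quantities
  expect_setequal(unique(tab$quantity), c("HU_scale", "SPR"))
  expect_true(all(tab$systematic_sigma >= 0 & tab$statistical_sigma >= 0))
  # root-sum-square identity holds exactly, before any rounding
  expect_equal(tab$total_sigma,
               sqrt(tab$systematic_sigma^2 + tab$statistical_sigma^2),
               tolerance = 1e-12)
  expect_equal(unique(tab$n_simulated[tab$category == "all"]), 320)
  # pooled rows pool deviations; they are not averages of category sigmas
  hu <- tab[tab$quantity == "HU_scale", ]
  expect_false(isTRUE(all.equal(hu$systematic_sigma[4],
                                mean(hu$systematic_sigma[1:3]))))
})

test_that("SPR uncertainties are invariant to rescaling I_w", {
  cfg <- simulation_config(5, 0.05, seed = 13)
  r69 <- build_report(ref, config = cfg, iw_mode = "fixed", iw_eV = 69)
  r78 <- build_report(ref, config = cfg, iw_mode = "fixed", iw_eV = 78)
  rbr <- build_report(ref, config = cfg, iw_mode = "bragg_additivity")
  for (col in c("systematic_sigma", "statistical_sigma", "total_sigma",
                "max_abs_systematic", "max_abs_statistical")) {
    a <- r69$table[r69$table$quantity == "SPR", col]
    b <- r78$table[r78$table$quantity == "SPR", col]
    c <- rbr$table[rbr$table$quantity == "SPR", col]
    expect_equal(a, b, tolerance = 1e-10)
    expect_equal(a, c, tolerance = 1e-10)
  }
})

test_that("pooled SPR systematic sigma barely moves across proton energies", {
  sig <- vapply(c(100, 250), function(e) {
    curve <- build_calibration_curve(ref, "SPR", beam = proton_beam(e))
    recs <- deviation_records(ref, curve, beam = proton_beam(e))
    systematic_uncertainty(recs)$sigma[4]
  }, numeric(1))
  expect_lt(abs(sig[1] - sig[2]), 0.05)
})
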