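test_that("generate_design builds the complete balanced crossing", {
  default <- generate_design(design_spec())
  expect_equal(nrow(default), 9 * 2 * 4 * 2)
  expect_true(all(table(default$time, default$temperature,
                        default$material) == 2))

  single <- generate_design(design_spec(1, 1, "PP", 1))
  expect_equal(nrow(single), 1)

  spec <- design_spec(time_levels = c(1, 2), temperature_levels = c(10, 25),
                      material_levels = c("A", "B"), n_replicates = 3)
  d <- generate_design(spec)
  expect_equal(nrow(d), 24)
  expect_true(all(table(d$time, d$temperature, d$material) == 3))
  expect_false(anyDuplicated(d$row_id) > 0)

  # deterministic given the spec
  expect_identical(d, generate_design(spec))
})

test_that("invalid design specs are rejected", {
  expect_error(design_spec(time_levels = numeric()), "non-empty")
  expect_error(design_spec(material_levels = c("PP", "PP")), "duplicate")
  expect_error(design_spec(n_replicates = 0), "integer >= 1")
  expect_error(design_spec(n_replicates = 1.5), "integer")
})

test_that("chemistry kinetics honor baselines and degenerate rates", {
  design <- generate_design(tiny_spec())
  flat <- oxidation_params(growth_rate = 0, noise_sd = 0)
  chem <- simulate_chemistry(design, flat, seed = 1)
  expect_true(all(chem$pv == flat$pv0))
  expect_true(all(chem$k232 == flat$k232_0))
  expect_true(all(chem$k268 == flat$k268_0))

  expect_error(oxidation_params(growth_rate = -1), ">= 0")
  expect_error(oxidation_params(noise_sd = -0.1), ">= 0")
  expect_error(
    oxidation_params(material_factor = c(PP = 0.1, CG = 0.6, AG = 0.45, AGA = 1)),
    "AGA <= AG <= CG <= PP")
})

test_that("time-zero markers equal the fresh-oil extinction coefficients", {
  spec <- design_spec(time_levels = c(0, 90, 270))
  chem <- simulate_chemistry(generate_design(spec),
                             oxidation_params(noise_sd = 0), seed = 1)
  at0 <- chem[generate_design(spec)$time == 0, ]
  expect_equal(unique(at0$k232), 4.26)
  expect_equal(unique(at0$k268), 1.25)
})

test_that("oxidation severity is monotone in the combined rate multiplier", {
  design <- generate_design(design_spec())
  chem <- simulate_chemistry(design, oxidation_params(noise_sd = 0), seed = 1)
  at25 <- design$temperature == 25 & design$replicate == 1
  for (t in unique(design$time)) {
    pv <- chem$pv[at25 & design$time == t]
    mat <- design$material[at25 & design$time == t]
    expect_true(pv[mat == "PP"] >= pv[mat == "CG"])
    expect_true(pv[mat == "CG"] >= pv[mat == "AG"])
    expect_true(pv[mat == "AG"] >= pv[mat == "AGA"])
  }
  # temperature ordering at fixed material and time
  for (m in levels(design$material)) {
    sel <- design$material == m & design$replicate == 1
    pv25 <- chem$pv[sel & design$temperature == 25]
    pv10 <- chem$pv[sel & design$temperature == 10]
    expect_true(all(pv25 >= pv10))
  }
})

test_that("chemistry and spectra are reproducible bit-for-bit given a seed", {
  design <- generate_design(tiny_spec())
  c1 <- simulate_chemistry(design, seed = 7)
  c2 <- simulate_chemistry(design, seed = 7)
  c3 <- simulate_chemistry(design, seed = 8)
  expect_identical(c1, c2)
  expect_false(isTRUE(all.equal(c1$pv, c3$pv)))

  s1 <- simulate_spectra(c1, seed = 3)
  s2 <- simulate_spectra(c1, seed = 3)
  expect_identical(s1, s2)

  full1 <- simulate_shelf_life(seed = 5)
  full2 <- simulate_shelf_life(seed = 5)
  expect_identical(full1, full2)
})

test_that("the spectral forward model is linear in band sensitivities", {
  design <- generate_design(tiny_spec())
  chem <- simulate_chemistry(design, seed = 1)

  # no sensitivity, no noise, no baseline -> every spectrum identical
  nb <- length(spectral_basis()$band_centers)
  flat_basis <- spectral_basis(band_sensitivities = matrix(0, nb, 2))
  flat <- simulate_spectra(chem, flat_basis, seed = 1, noise_sd = 0,
                           baseline_offset_sd = 0, baseline_slope_sd = 0)
  expect_true(all(abs(sweep(flat, 2, flat[1, ])) < 1e-12))

  # a single sensitive band: doubling its sensitivity doubles the spectral
  # difference between the most and least oxidized samples
  sens1 <- matrix(0, nb, 2)
  sens1[7, 1] <- 0.05 # the 5678 cm^-1 methylenic band, PV-driven
  sens2 <- sens1
  sens2[7, 1] <- 0.10
  sp1 <- simulate_spectra(chem, spectral_basis(band_sensitivities = sens1),
                          seed = 1, noise_sd = 0, baseline_offset_sd = 0,
                          baseline_slope_sd = 0)
  sp2 <- simulate_spectra(chem, spectral_basis(band_sensitivities = sens2),
                          seed = 1, noise_sd = 0, baseline_offset_sd = 0,
                          baseline_slope_sd = 0)
  hi <- which.max(chem$pv)
  lo <- which.min(chem$pv)
  keep <- colMeans(sp1) <= 2.5 # outside clipped regions the model is linear
  d1 <- (sp1[hi, ] - sp1[lo, ])[keep]
  d2 <- (sp2[hi, ] - sp2[lo, ])[keep]
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
})

test_that("default spectra saturate inside the instrument's blind regions", {
  sim <- default_sim()
  wn <- wavenumbers(sim$spectra)
  mn <- colMeans(sim$spectra)
  in_sat <- (wn >= 4000 & wn <= 4440) | (wn >= 5770 & wn <= 5875)
  expect_true(all(mn[in_sat] > 2.5))
  expect_true(all(mn[!in_sat] <= 2.5))
})
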