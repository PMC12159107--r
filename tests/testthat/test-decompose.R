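test_that("noise-free contrast series decompose exactly into components", {
  geom <- nucleosome_geometry(); comp <- nucleosome_composition()
  sim <- simulate_contrast_series(
    geom, comp, fractions = c(0, 0.2, 0.7, 0.95),
    noise = list(exposure_scale = Inf, incoherent_level = 0), seed = 1)
  ci <- decompose_component_intensities(sim$profiles, comp)
  # ground truth: the generator's partial sums on the same grid
  model <- build_nucleosome_beads(geom, 5, comp)
  tp <- debye_partial_intensities(model, ci$q)
  nden <- 1e-3 * 6.02214076e23 / (comp$protein$mw + comp$dna$mw)
  # decomposition coefficients use contrasts in 1e-6 A^-2 (1e10 cm^-2)
  expect_equal(ci$i_protein, nden * 1e20 * tp$i_protein, tolerance = 1e-6)
  expect_equal(ci$i_dna, nden * 1e20 * tp$i_dna, tolerance = 1e-6)
  expect_equal(ci$i_cross, nden * 1e20 * tp$i_cross, tolerance = 1e-6)
  # forward limit: amplitudes add in phase at zero angle
  expect_equal(ci$i_cross[1], 2 * sqrt(ci$i_protein[1] * ci$i_dna[1]),
               tolerance = 1e-3)
  # component forward intensities are non-negative
  expect_gte(ci$i_protein[1], 0)
  expect_gte(ci$i_dna[1], 0)
})

test_that("noisy decompositions recover components within propagated errors", {
  geom <- nucleosome_geometry(); comp <- nucleosome_composition()
  sim <- contrast_series_relnoise(c(0, 0.2, 0.7, 0.8, 0.95),
                                  rel_noise = 0.02, seed = 5)
  ci <- decompose_component_intensities(sim$profiles, comp)
  model <- build_nucleosome_beads(geom, 5, comp)
  tp <- debye_partial_intensities(model, ci$q)
  nden <- 1e-3 * 6.02214076e23 / (comp$protein$mw + comp$dna$mw)
  z_p <- (ci$i_protein - nden * 1e20 * tp$i_protein) / ci$i_protein_se
  z_d <- (ci$i_dna - nden * 1e20 * tp$i_dna) / ci$i_dna_se
  z_x <- (ci$i_cross - nden * 1e20 * tp$i_cross) / ci$i_cross_se
  # ~99.7% of per-q pulls within 3 sigma; allow a small margin
  expect_gt(mean(abs(c(z_p, z_d, z_x)) < 3), 0.97)
})

test_that("reconstruction reproduces every measured contrast", {
  comp <- nucleosome_composition()
  sim <- contrast_series_relnoise(c(0, 0.2, 0.7, 0.8, 0.95),
                                  rel_noise = 0.02, seed = 9)
  ci <- decompose_component_intensities(sim$profiles, comp)
  for (j in seq_along(sim$profiles)) {
    p <- sim$profiles[[j]]
    rec <- reconstruct_intensity(ci, ci$contrasts$drho_protein[j],
                                 ci$contrasts$drho_dna[j])
    ip <- approx(p$q, p$intensity, ci$q)$y
    is <- approx(p$q, p$sigma, ci$q)$y
    expect_gt(mean(abs(rec - ip) <= 3 * is), 0.95)
  }
})

test_that("underdetermined contrast designs are rejected", {
  comp <- nucleosome_composition()
  sim <- contrast_series_relnoise(c(0, 0.95), rel_noise = 0.02, seed = 2)
  expect_error(decompose_component_intensities(sim$profiles, comp),
               "at least 3")
})
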