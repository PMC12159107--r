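test_that("native geometry produces a disc-like particle near 110 A across", {
  geom <- nucleosome_geometry()
  m <- build_nucleosome_beads(geom, 5)
  dmax <- max(dist(as.matrix(m[, c("x", "y", "z")])))
  expect_gt(dmax, 0.9 * 110)
  expect_lt(dmax, 1.1 * 110)
})

test_that("full extension approaches the straight-rod contour length", {
  geom <- nucleosome_geometry(extension_fraction = 1)
  m <- build_nucleosome_beads(geom, 5)
  dna <- m[m$component_tag == "dna", ]
  dmax <- max(dist(as.matrix(dna[, c("x", "y", "z")])))
  expect_gt(dmax, 0.95 * 147 * 3.4)
  expect_lt(dmax, 1.05 * 147 * 3.4)
})

test_that("bead scattering lengths partition the composition's totals", {
  comp <- nucleosome_composition()
  m <- build_nucleosome_beads(nucleosome_geometry(), 5, comp)
  bp <- sum(m$scattering_length[m$component_tag == "protein"])
  bd <- sum(m$scattering_length[m$component_tag == "dna"])
  expect_equal(bp / bd, comp$protein$b_h / comp$dna$b_h, tolerance = 0.01)
  vp <- sum(m$volume[m$component_tag == "protein"])
  expect_equal(vp, comp$protein$mw / (0.602214076 * 1.35),
               tolerance = 1e-6)
})

test_that("geometry invariants are enforced", {
  expect_error(nucleosome_geometry(unwrap_bp_each_end = 80), "impossible")
  expect_error(nucleosome_geometry(extension_fraction = 1.2), "0, 1")
  expect_error(build_nucleosome_beads(nucleosome_geometry(), 2), "3, 15")
})

test_that("seeding makes simulated profiles bit-reproducible", {
  geom <- nucleosome_geometry(); comp <- nucleosome_composition()
  m <- build_nucleosome_beads(geom, 6, comp)
  q <- seq(0.01, 0.25, length.out = 60)
  a <- simulate_profile(m, comp, q, fraction_d2o = 0.2, seed = 7)
  b <- simulate_profile(m, comp, q, fraction_d2o = 0.2, seed = 7)
  c3 <- simulate_profile(m, comp, q, fraction_d2o = 0.2, seed = 8)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c3$intensity))
  # different seeds share the underlying curve within 5 sigma
  expect_true(all(abs(a$intensity - c3$intensity) <=
                    5 * sqrt(a$sigma^2 + c3$sigma^2)))
})

test_that("infinite exposure gives the noise-free model evaluation", {
  geom <- nucleosome_geometry(); comp <- nucleosome_composition()
  m <- build_nucleosome_beads(geom, 6, comp)
  q <- seq(0.01, 0.25, length.out = 40)
  p <- simulate_profile(m, comp, q, fraction_d2o = 0.2,
                        noise = list(exposure_scale = Inf,
                                     incoherent_level = 0.05), seed = 1)
  tp <- debye_partial_intensities(m, q)
  drp <- component_contrast(comp, "protein", 0.2) * 1e10
  drd <- component_contrast(comp, "dna", 0.2) * 1e10
  nden <- 1e-3 * 6.02214076e23 / (comp$protein$mw + comp$dna$mw)
  expect_equal(p$intensity,
               nden * (drp^2 * tp$i_protein + drp * drd * tp$i_cross +
                         drd^2 * tp$i_dna), tolerance = 1e-10)
})

test_that("quadrupling the exposure scale halves the relative uncertainty", {
  geom <- nucleosome_geometry(); comp <- nucleosome_composition()
  m <- build_nucleosome_beads(geom, 6, comp)
  q <- seq(0.01, 0.25, length.out = 60)
  p1 <- simulate_profile(m, comp, q, noise = list(exposure_scale = 100,
                                                  incoherent_level = 0.05),
                         seed = 1)
  p4 <- simulate_profile(m, comp, q, noise = list(exposure_scale = 400,
                                                  incoherent_level = 0.05),
                         seed = 1)
  expect_equal(mean(p1$sigma / p4$sigma), 4, tolerance = 1e-10)
})

test_that("noise-free Guinier Rg agrees with the bead second moment", {
  geom <- nucleosome_geometry(); comp <- nucleosome_composition()
  m <- build_nucleosome_beads(geom, 5, comp)
  q <- seq(0.005, 0.1, length.out = 80)
  for (f in c(0, 0.8)) {
    p <- simulate_profile(m, comp, q, fraction_d2o = f,
                          noise = list(exposure_scale = Inf,
                                       incoherent_level = 0), seed = 1)
    g <- guinier_fit(p, qrg_max = 0.8)
    cp <- contrast_point(comp, f)
    truth <- bead_rg(m, c(protein = cp$delta_rho_protein,
                          dna = cp$delta_rho_dna))
    expect_equal(g$rg, truth$rg, tolerance = 0.01)
  }
})

test_that("contrast-series manifests record reproducible ground truth", {
  geom <- nucleosome_geometry(); comp <- nucleosome_composition()
  s1 <- simulate_contrast_series(geom, comp, c(0, 0.8),
                                 q_grid = seq(0.01, 0.2, length.out = 40),
                                 seed = 3, bead_spacing = 6)
  s2 <- simulate_contrast_series(geom, comp, c(0, 0.8),
                                 q_grid = seq(0.01, 0.2, length.out = 40),
                                 seed = 3, bead_spacing = 6)
  expect_identical(s1$profiles[[1]]$intensity, s2$profiles[[1]]$intensity)
  expect_equal(s1$manifest$per_profile[[2]]$drho_dna,
               component_contrast(comp, "dna", 0.8))
  expect_length(s1$manifest$per_profile, 2)
})

test_that("mixture forward intensity is linear in the state weights", {
  geom <- nucleosome_geometry(); comp <- nucleosome_composition()
  q <- seq(0.01, 0.2, length.out = 30)
  mk <- function(w) {
    sm <- data.frame(native = w[1], unwrapped = w[2], extended = w[3],
                     label = "x")
    simulate_pressure_series(geom, comp, 5, sm,
                             q_grid = q, bead_spacing = 6,
                             noise = list(exposure_scale = Inf,
                                          incoherent_level = 0),
                             seed = 1)$profiles[[1]]$intensity
  }
  i_nat <- mk(c(1, 0, 0)); i_un <- mk(c(0, 1, 0)); i_ext <- mk(c(0, 0, 1))
  i_mix <- mk(c(0.5, 0.3, 0.2))
  expect_equal(i_mix, 0.5 * i_nat + 0.3 * i_un + 0.2 * i_ext,
               tolerance = 1e-10)
  expect_error(simulate_pressure_series(
    geom, comp, 5, data.frame(native = 0.7, unwrapped = 0.2,
                              extended = 0.2, label = "bad"),
    q_grid = q, seed = 1), "sum to 1")
})
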