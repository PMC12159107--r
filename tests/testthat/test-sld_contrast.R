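# Atomic constants for the independent per-atom oracles
bH <- -3.7390; bD <- 6.6710; bC <- 6.6460; bN <- 9.3600; bO <- 5.8030

test_that("water endpoint SLDs match the per-atom closed form", {
  # H2O at 1.0 g/cm3: (2 b_H + b_O) / (MW / (0.6022 d)), in 1e-6 A^-2
  # b[fm]*1e-5 A / (MW/(0.6022 d) A^3) in 1e-6 A^-2 units -> factor 10
  mw_h2o <- 2 * 1.00794 + 15.9994
  expect_equal(solvent_sld(0),
               (2 * bH + bO) * 10 * 0.602214076 / mw_h2o,
               tolerance = 1e-10)
  # the familiar printed value
  expect_equal(round(solvent_sld(0), 2), -0.56)
  mw_d2o <- 2 * 2.01410 + 15.9994
  expect_equal(solvent_sld(1),
               (2 * bD + bO) * 10 * 0.602214076 * 1.105 / mw_d2o,
               tolerance = 1e-10)
  # midpoint mixture is the arithmetic mean of the endpoints
  expect_equal(solvent_sld(0.5), (solvent_sld(0) + solvent_sld(1)) / 2)
  expect_error(solvent_sld(1.2), "0, 1")
})

test_that("solvent and component SLD/contrast are linear in D2O fraction", {
  comp <- nucleosome_composition()
  set.seed(7)
  f <- sort(runif(6))
  # linearity: second differences vanish on any evenly spaced grid
  g <- seq(0.1, 0.9, length.out = 5)
  for (fun in list(solvent_sld,
                   function(x) component_contrast(comp, "protein", x),
                   function(x) component_contrast(comp, "dna", x),
                   function(x) component_contrast(comp, "complex", x))) {
    y <- vapply(g, fun, 0)
    expect_lt(max(abs(diff(diff(y)))), 1e-9)
  }
  # interpolation consistency at random fractions
  for (ff in f) {
    y0 <- component_contrast(comp, "protein", 0)
    y1 <- component_contrast(comp, "protein", 1)
    expect_equal(component_contrast(comp, "protein", ff),
                 y0 + ff * (y1 - y0), tolerance = 1e-10)
  }
})

test_that("poly-glycine contrast equals an explicit atom-inventory sum", {
  # 20-residue poly-glycine chain: 20 x (C2 H3 N O) + H2O termini
  comp <- composition_spec(protein_chains = list(strrep("G", 20)),
                           dna_basepairs = 8, exchange_fraction = 0.5)
  nC <- 40; nH <- 62; nN <- 20; nOx <- 21
  mw <- nC * 12.0107 + nH * 1.00794 + nN * 14.0067 + nOx * 15.9994
  vol <- mw / (0.602214076 * 1.35)                      # A^3
  b <- nC * bC + nH * bH + nN * bN + nOx * bO           # fm, no exchange
  sld <- b * 1e-5 / vol * 1e6
  expect_equal(component_contrast(comp, "protein", 0),
               sld - solvent_sld(0), tolerance = 1e-9)
  # at fraction f with exchange 0.5: 20 backbone NH labile
  f <- 0.7
  b_f <- b + 20 * 0.5 * f * (bD - bH)
  expect_equal(component_contrast(comp, "protein", f),
               b_f * 1e-5 / vol * 1e6 - solvent_sld(f), tolerance = 1e-9)
})

test_that("match points order correctly and sit in the expected windows", {
  comp <- nucleosome_composition()
  # contrast changes sign exactly once: linear with opposite-sign endpoints
  for (cmp in c("protein", "dna", "complex")) {
    expect_lt(component_contrast(comp, cmp, 1) *
                component_contrast(comp, cmp, 0), 0)
    mp <- theoretical_match_point(comp, cmp)
    expect_equal(component_contrast(comp, cmp, mp), 0, tolerance = 1e-9)
  }
  expect_lt(theoretical_match_point(comp, "protein"),
            theoretical_match_point(comp, "dna"))
  # classical full-exchange windows: protein ~40-45%, DNA ~60-67% D2O
  compf <- nucleosome_composition(exchange_fraction = 1)
  expect_gt(theoretical_match_point(compf, "protein"), 0.38)
  expect_lt(theoretical_match_point(compf, "protein"), 0.47)
  expect_gt(theoretical_match_point(compf, "dna"), 0.58)
  expect_lt(theoretical_match_point(compf, "dna"), 0.68)
  # a component denser than any accessible solvent has no match point
  dense <- composition_spec(protein_chains = list(strrep("G", 20)),
                            dna_basepairs = 8, mass_density_protein = 5)
  expect_error(theoretical_match_point(dense, "protein"), "no match point")
})

test_that("complex contrast is the volume-weighted mean of the components", {
  comp <- nucleosome_composition()
  vp <- comp$protein$mw / (0.602214076 * comp$mass_density_protein)
  vd <- comp$dna$mw / (0.602214076 * comp$mass_density_dna)
  for (f in c(0, 0.3, 0.9)) {
    expect_equal(component_contrast(comp, "complex", f),
                 (vp * component_contrast(comp, "protein", f) +
                    vd * component_contrast(comp, "dna", f)) / (vp + vd),
                 tolerance = 1e-10)
  }
})

test_that("X-ray electron-density contrasts fall in the reported ranges", {
  comp <- nucleosome_composition()
  # protein ~90 e-/nm^3, DNA ~220 e-/nm^3, both within +/- 20-ish %
  expect_gt(xray_contrast(comp, "protein"), 72)
  expect_lt(xray_contrast(comp, "protein"), 108)
  expect_gt(xray_contrast(comp, "dna"), 176)
  expect_lt(xray_contrast(comp, "dna"), 264)
  # a hypothetical solvent-matched component has zero contrast
  blk <- xray_contrast(comp, "protein", rho_water_e = 0)
  expect_equal(xray_contrast(comp, "protein", rho_water_e = blk), 0)
})

test_that("experimental match point: exact two-point line and recovery", {
  # exact: sqrt(I0/c) of 4 at f=0 and (signed) -4 at f=1 crosses at 0.5
  mp <- experimental_match_point(c(0, 1), c(16, 16), c(1, 1))
  expect_equal(mp$match_point, 0.5, tolerance = 1e-12)
  expect_error(experimental_match_point(0.5, 4, 1), "at least 2")
  expect_error(experimental_match_point(c(0.5, 0.5), c(4, 5), c(1, 1)),
               "identical")
})

test_that("match-point intercept is recovered without bias from noisy lines", {
  # truth: y = 8 - 16 f -> intercept 0.5; 3% noise on I0, many replicates
  truth <- 0.5
  f <- c(0, 0.2, 0.7, 0.8, 0.95)
  y <- 8 - 16 * f
  i0_true <- y^2
  set.seed(1234)
  ests <- ses <- numeric(300)
  for (k in seq_len(300)) {
    i0 <- i0_true * (1 + rnorm(5, 0, 0.03))
    r <- experimental_match_point(f, i0, rep(1, 5),
                                  sigma_i0 = 0.03 * i0_true)
    ests[k] <- r$match_point; ses[k] <- r$match_point_se
  }
  expect_lt(abs(mean(ests) - truth), 3 * sd(ests) / sqrt(300))
  # ~95% of estimates within 2 reported sigma of truth
  expect_gt(mean(abs(ests - truth) <= 2 * ses), 0.9)
})

test_that("residue tables agree with their own atom inventories", {
  for (which in c("aa", "dna")) {
    tab <- sas_residue_table(which)
    b_manual <- tab$C * bC + tab$H * bH + tab$N * bN + tab$O * bO +
      tab$P * 5.1300 + tab$S * 2.8470
    expect_equal(tab$b_h_fm, b_manual, tolerance = 1e-9)
    expect_true(all(tab$n_labile <= tab$H))
  }
})

test_that("composition files round-trip FASTA and record styles", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# example composition",
               ">H3like copies=2", "ARTKQTARKS", "TGGKAPRKQL",
               "protein 2 SGRGKGGKGL",
               "dna 147",
               "exchange_fraction=0.6"), f)
  comp <- read_composition(f)
  expect_length(comp$protein_chains, 2)
  expect_equal(comp$protein_chains[[1]]$copies, 2L)
  expect_equal(comp$protein_chains[[1]]$sequence, "ARTKQTARKSTGGKAPRKQL")
  expect_equal(comp$dna_basepairs, 147L)
  expect_equal(comp$exchange_fraction, 0.6)
  # explicit DNA sequence records count base pairs from the strand
  writeLines(c("protein 1 GGGGGGGGGG", "dna ACGTACGT"), f)
  comp2 <- read_composition(f)
  expect_equal(comp2$dna_basepairs, 8L)
})
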