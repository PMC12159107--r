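test_that("core-shell cylinder reduces to the uniform cylinder when SLDs match", {
  p <- core_shell_cylinder(19, 23, 60, sld_core = 3.5, sld_shell = 3.5,
                           sld_solvent = 0)
  q <- seq(0.01, 0.3, length.out = 40)
  got <- core_shell_cylinder_intensity(p, q, n_quad = 200)
  # independent uniform-cylinder average (radius 42, length 106)
  gl <- pracma::gaussLegendre(400, 0, pi / 2)
  Vo <- pi * 42^2 * 106
  unif <- vapply(q, function(qq) {
    a <- qq * cos(gl$x) * 106 / 2
    b <- qq * sin(gl$x) * 42
    A <- 3.5 * Vo * (sin(a) / a) * (2 * besselJ(b, 1) / b)
    sum(A^2 * sin(gl$x) * gl$w)
  }, 0)
  expect_equal(got, unif, tolerance = 1e-8)
})

test_that("forward limit equals the squared total excess scattering length", {
  p <- core_shell_cylinder(19, 23, 60, 2.0, 3.5, 0.5,
                           scale = 2, background = 0.7)
  Vc <- pi * 19^2 * 60
  Vs <- pi * 42^2 * 106 - Vc
  i0_expect <- 2 * (Vc * (2.0 - 0.5) + Vs * (3.5 - 0.5))^2 + 0.7
  expect_equal(core_shell_cylinder_intensity(p, 1e-5), i0_expect,
               tolerance = 1e-6 * i0_expect)
})

test_that("the default quadrature matches a 10x-order oracle to 1e-4", {
  p <- core_shell_cylinder(19, 23, 60, 2.0, 3.5, 0.0)
  q <- seq(0.01, 0.3, length.out = 60)
  i76 <- core_shell_cylinder_intensity(p, q, n_quad = 76)
  i760 <- core_shell_cylinder_intensity(p, q, n_quad = 760)
  expect_lt(max(abs(i76 - i760) / i760), 1e-4)
  expect_error(core_shell_cylinder_intensity(p, q, n_quad = 8), "16")
})

test_that("contrast-weighted cylinder Rg obeys limits and a Monte-Carlo oracle", {
  # rod limit: thin homogeneous cylinder -> L/sqrt(12)
  rod <- core_shell_cylinder(1e-4, 1e-5, 100, 2, 2, 0)
  expect_equal(cylinder_rg(rod), 100 / sqrt(12), tolerance = 1e-3)
  # disc limit: flat homogeneous cylinder -> R/sqrt(2)
  disc <- core_shell_cylinder(50, 1e-5, 1e-4, 2, 2, 0)
  expect_equal(cylinder_rg(disc), 50 / sqrt(2), tolerance = 1e-3)
  # two-phase case vs contrast-weighted MC second moment
  p <- core_shell_cylinder(19, 23, 60, 2.0, 3.5, 0.0)
  set.seed(4)
  N <- 2e5
  pts <- cbind(runif(N, -42, 42), runif(N, -42, 42), runif(N, -53, 53))
  r2 <- pts[, 1]^2 + pts[, 2]^2
  incore <- r2 <= 19^2 & abs(pts[, 3]) <= 30
  inshell <- r2 <= 42^2 & !incore
  w <- ifelse(incore, 2.0, ifelse(inshell, 3.5, 0))
  rg_mc <- sqrt(sum(w * rowSums(pts^2)) / sum(w))
  expect_equal(cylinder_rg(p), rg_mc, tolerance = 0.005)
  # zero net contrast is undefined
  expect_error(cylinder_rg(core_shell_cylinder(10, 10, 10, 1, 1, 1)),
               "zero total contrast")
})

test_that("Debye sums follow the closed forms and the histogram agrees", {
  q <- seq(0.01, 0.5, length.out = 30)
  one <- bead_model(0, 0, 0, scattering_length = 3)
  expect_equal(debye_intensity(one, q), rep(9, 30))
  d <- 25
  two <- bead_model(c(0, d), c(0, 0), c(0, 0), scattering_length = 2)
  expect_equal(debye_intensity(two, q, method = "direct"),
               2 * 4 * (1 + sin(q * d) / (q * d)), tolerance = 1e-12)
  # histogram acceleration vs direct double sum on 500 random beads
  set.seed(8)
  mdl <- bead_model(runif(500, -50, 50), runif(500, -50, 50),
                    runif(500, -50, 50), scattering_length = 1)
  dir <- debye_intensity(mdl, q, method = "direct")
  his <- debye_intensity(mdl, q, method = "histogram", bin_width = 0.25)
  expect_lt(max(abs(his - dir) / dir), 1e-3)
})

test_that("Debye sums are invariant under rigid rotation and translation", {
  set.seed(15)
  q <- seq(0.02, 0.4, length.out = 20)
  xyz <- matrix(runif(90, -30, 30), ncol = 3)
  m1 <- bead_model(xyz[, 1], xyz[, 2], xyz[, 3], scattering_length = 1.5)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz2 <- xyz %*% Rz + matrix(c(100, -40, 7), 30, 3, byrow = TRUE)
  m2 <- bead_model(xyz2[, 1], xyz2[, 2], xyz2[, 3], scattering_length = 1.5)
  expect_equal(debye_intensity(m1, q, method = "direct"),
               debye_intensity(m2, q, method = "direct"), tolerance = 1e-10)
})

test_that("the Gaussian coil curve has the right limits and Kratky plateau", {
  q <- seq(1e-4, 1, length.out = 400)
  i0 <- 7
  I <- gaussian_coil_intensity(30, i0, q)
  expect_equal(I[1], i0, tolerance = 1e-5)
  # x = (qRg)^2 = 1 -> I = 2 i0 / e
  expect_equal(gaussian_coil_intensity(30, i0, 1 / 30), 2 * i0 / exp(1),
               tolerance = 1e-10)
  # normalized Kratky: monotone rise to a plateau at 2, no interior peak
  qq <- seq(0.001, 0.5, length.out = 2000)
  p <- sas_profile(qq, gaussian_coil_intensity(30, i0, qq),
                   0.01 * gaussian_coil_intensity(30, i0, qq))
  k <- kratky_transform(p, "normalized", rg = 30, i0 = i0)
  expect_true(is.na(attr(k, "peak_x")))
  expect_true(all(diff(k$y) > 0))
  expect_equal(max(k$y), 2, tolerance = 0.02)
  expect_error(gaussian_coil_intensity(0, 1, q), "positive")
})

test_that("bead models round-trip through PDB-format records", {
  m <- bead_model(c(1.25, -3.5), c(0, 2), c(10, -20),
                  scattering_length = c(1.5, 2.25),
                  component_tag = c("protein", "dna"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_bead_pdb(m, f)
  back <- read_bead_pdb(f)
  expect_equal(back$x, m$x, tolerance = 1e-3)
  expect_equal(back$component_tag, m$component_tag)
  expect_equal(back$scattering_length, m$scattering_length,
               tolerance = 1e-2)
})
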