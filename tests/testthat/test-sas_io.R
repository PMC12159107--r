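test_that("profiles round-trip through the 3-column dialect losslessly", {
  p <- sas_profile(q = seq(0.01, 0.3, length.out = 20),
                   intensity = exp(-seq(0.01, 0.3, length.out = 20)),
                   sigma = rep(0.01, 20), source = "neutron",
                   fraction_d2o = 0.8, concentration = 1.9,
                   pressure = 5, temperature = 6,
                   absolute_scale = TRUE, label = "cv80")
  f <- withr::local_tempfile(fileext = ".dat")
  write_profile(p, f)
  hdr <- readLines(f)
  expect_true(any(grepl("fraction_d2o=0.8", hdr)))
  expect_true(any(grepl("units=cm\\^-1", hdr)))
  p2 <- read_profile(f)
  expect_equal(p2$q, p$q)
  expect_equal(p2$intensity, p$intensity)
  expect_equal(p2$sigma, p$sigma)
  expect_equal(p2$meta, p$meta)
})

test_that("header metadata and 2-column sigma imputation are honored", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# fraction_d2o=0.8", "# source=neutron",
               sprintf("%g %g", seq(0.01, 0.1, by = 0.01),
                       10 * exp(-seq(0.01, 0.1, by = 0.01)))), f)
  p <- read_profile(f)
  expect_equal(p$meta$fraction_d2o, 0.8)
  expect_true(p$meta$sigma_imputed)
  expect_equal(p$sigma, 0.02 * p$intensity)
})

test_that("format violations are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 1 0.1", "0.03 1 0.1", "0.02 1 0.1", "0.04 1 0.1",
               "0.05 1 .1", "0.06 1 .1", "0.07 1 .1", "0.08 1 .1"), f)
  expect_error(read_profile(f), "row 3")
  writeLines(sprintf("%g 1 -0.1", seq(0.01, 0.08, by = 0.01)), f)
  expect_error(read_profile(f), "negative sigma")
  writeLines(character(), f)
  expect_error(read_profile(f), "empty")
  p <- sas_profile(seq(0.01, 0.08, by = 0.01), rep(1, 8), rep(0.1, 8))
  expect_error(write_profile(p, ""), "path")
  expect_error(sas_profile(seq(0.01, 0.07, by = 0.01), rep(1, 7),
                           rep(0.1, 7)), "at least 8")
  expect_error(sas_profile(seq(0.01, 0.08, by = 0.01), rep(1, 8),
                           rep(0.1, 8), fraction_d2o = 1.2), "0, 1")
})

test_that("nm^-1 q units declared in the header are converted on read", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# q_units=nm^-1",
               sprintf("%g 1 0.1", seq(0.1, 0.8, by = 0.1))), f)
  p <- read_profile(f)
  expect_equal(p$q, seq(0.01, 0.08, by = 0.01))
})

test_that("exact split of a curve merges back to the original", {
  q <- seq(0.01, 0.3, length.out = 60)
  I <- 100 * exp(-(q * 40)^2 / 3)
  s <- 0.01 * I
  a <- sas_profile(q[1:40], I[1:40], s[1:40])
  b <- sas_profile(q[25:60], I[25:60], s[25:60])
  m <- trim_and_merge(list(a, b), overlap_policy = "no-scale")
  expect_equal(m$q, q)
  expect_equal(m$intensity, I, tolerance = 1e-12)
})

test_that("overlap scaling recovers a known inter-range factor", {
  q <- seq(0.01, 0.3, length.out = 80)
  I <- 100 * exp(-(q * 40)^2 / 3)
  s <- 0.005 * I
  a <- sas_profile(q[1:50], I[1:50], s[1:50])
  b <- sas_profile(q[30:80], I[30:80] * 1.3, s[30:80] * 1.3)
  m <- trim_and_merge(list(a, b), overlap_policy = "scale-to-first")
  fac <- attr(m, "scale_factors")[2]
  expect_equal(fac, 1 / 1.3, tolerance = 1e-6)
  expect_equal(m$intensity, I, tolerance = 1e-6)
})

test_that("merging rejects inconsistent solvent metadata", {
  q <- seq(0.01, 0.1, length.out = 20)
  a <- sas_profile(q, rep(1, 20), rep(0.1, 20), fraction_d2o = 0)
  b <- sas_profile(q, rep(1, 20), rep(0.1, 20), fraction_d2o = 0.8)
  expect_error(trim_and_merge(list(a, b)), "fraction_d2o")
})

test_that("merge is idempotent and never shrinks uncertainties below inputs", {
  q <- seq(0.01, 0.3, length.out = 50)
  I <- 10 * exp(-(q * 35)^2 / 3)
  set.seed(3)
  a <- sas_profile(q[1:35], I[1:35], 0.02 * I[1:35])
  b <- sas_profile(q[20:50], I[20:50], 0.03 * I[20:50])
  m <- trim_and_merge(list(a, b))
  m2 <- trim_and_merge(list(m))
  expect_identical(m2$q, m$q)
  expect_identical(m2$intensity, m$intensity)
  # sigma floor in the overlap: never below the smallest contributing sigma
  for (k in seq_along(m$q)) {
    cands <- c(a$sigma[abs(a$q - m$q[k]) < 1e-9],
               b$sigma[abs(b$q - m$q[k]) < 1e-9])
    if (length(cands))
      expect_gte(m$sigma[k] + 1e-12, min(cands))
  }
})

test_that("JSON-lines manifests bind profiles to series metadata", {
  dir <- withr::local_tempdir()
  q <- seq(0.01, 0.1, length.out = 20)
  ps <- lapply(c(0, 0.8), function(f)
    sas_profile(q, rep(1, 20), rep(0.1, 20), source = "neutron",
                fraction_d2o = f, concentration = 1))
  paths <- c("a.dat", "b.dat")
  for (i in 1:2) write_profile(ps[[i]], file.path(dir, paths[i]))
  mf <- file.path(dir, "series.jsonl")
  write_manifest(ps, paths, mf)
  back <- read_manifest(mf)
  expect_length(back, 2)
  expect_equal(vapply(back, function(p) p$meta$fraction_d2o, 0), c(0, 0.8))
})
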