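# Shared fixtures and independent oracles, built in code.

# analytic homogeneous-sphere intensity, I(0) = i0
sphere_intensity <- function(q, R, i0 = 1) {
  x <- q * R
  i0 * (3 * (sin(x) - x * cos(x)) / x^3)^2
}

sphere_profile <- function(R = 54, i0 = 541, qmax = 0.25, n = 150,
                           rel_sigma = 0.01) {
  q <- seq(0.005, qmax, length.out = n)
  I <- sphere_intensity(q, R, i0)
  sas_profile(q, I, sigma = rel_sigma * I + 1e-9 * i0)
}

# Monte-Carlo pair-distance distribution of a homogeneous sphere
sphere_pr_mc <- function(R, r_grid, n = 2e5, seed = 42) {
  set.seed(seed)
  draw <- function(m) {
    p <- matrix(stats::runif(3 * m * 2, -R, R), ncol = 3)
    p <- p[rowSums(p^2) <= R^2, , drop = FALSE]
    p
  }
  a <- draw(n); b <- draw(n)
  m <- min(nrow(a), nrow(b))
  d <- sqrt(rowSums((a[seq_len(m), ] - b[seq_len(m), ])^2))
  h <- graphics::hist(d, breaks = c(r_grid - diff(r_grid)[1] / 2,
                                    max(r_grid) + diff(r_grid)[1] / 2),
                      plot = FALSE)
  h$counts / sum(h$counts)
}

# exact two-phase (displaced spheres) Stuhrmann curve via second moments
two_sphere_points <- function(R1, R2, sld1, sld2, sep, rho_solvents) {
  V <- c(4 / 3 * pi * R1^3, 4 / 3 * pi * R2^3)
  rgs <- sqrt(3 / 5) * c(R1, R2)
  centers <- rbind(c(0, 0, 0), c(sep, 0, 0))
  t(vapply(rho_solvents, function(s) {
    o <- multiphase_rg2(V, rgs, c(sld1, sld2), centers, s)
    c(dr = o$delta_rho_mean, rg2 = o$rg2)
  }, c(dr = 0, rg2 = 0)))
}

# exact quadratic coefficients (Rc^2, alpha, beta) from three exact points
stuhrmann_oracle <- function(pts) {
  X <- cbind(1, 1 / pts[1:3, "dr"], -1 / pts[1:3, "dr"]^2)
  cf <- solve(X, pts[1:3, "rg2"])
  list(rc = sqrt(cf[1]), alpha = cf[2], beta = cf[3])
}

# multi-contrast core-shell cylinder fixture: SANS contrast curves plus
# one SAXS curve from a known shared geometry with 3% relative noise
make_cv_series <- function(seed, comp, true = c(R = 19, t = 23, L = 60),
                           frs = c(0, 0.2, 0.8, 0.95),
                           q = seq(0.01, 0.25, length.out = 80)) {
  profs <- list()
  for (i in seq_along(frs)) {
    f <- frs[i]
    par <- core_shell_cylinder(
      true["R"], true["t"], true["L"],
      sld_core = component_contrast(comp, "protein", f) + solvent_sld(f),
      sld_shell = component_contrast(comp, "dna", f) + solvent_sld(f),
      sld_solvent = solvent_sld(f))
    I <- core_shell_cylinder_intensity(par, q)
    set.seed(seed * 100 + i)
    sig <- 0.03 * abs(I) + 1e-12 * max(I)
    profs[[i]] <- sas_profile(q, I + rnorm(length(q), 0, sig), sig,
                              source = "neutron", fraction_d2o = f)
  }
  rex <- (xray_contrast(comp, "protein") + 334) * 1e-2
  rdx <- (xray_contrast(comp, "dna") + 334) * 1e-2
  parx <- core_shell_cylinder(true["R"], true["t"], true["L"],
                              rex, rdx, 3.34)
  Ix <- core_shell_cylinder_intensity(parx, q)
  set.seed(seed * 100 + 99)
  sigx <- 0.03 * abs(Ix)
  profs[[length(profs) + 1]] <-
    sas_profile(q, Ix + rnorm(length(q), 0, sigx), sigx, source = "xray")
  profs
}

# noise-free synthetic contrast series with exactly `rel_noise` relative
# Gaussian noise added (for criteria phrased as "x% noise")
contrast_series_relnoise <- function(fractions, rel_noise = 0.03, seed = 1,
                                     concentrations = 1,
                                     comp = nucleosome_composition(),
                                     geom = nucleosome_geometry()) {
  sim <- simulate_contrast_series(
    geom, comp, fractions, concentrations = concentrations,
    noise = list(exposure_scale = Inf, incoherent_level = 0), seed = seed)
  set.seed(seed)
  sim$profiles <- lapply(sim$profiles, function(p) {
    sig <- rel_noise * abs(p$intensity)
    p$intensity <- p$intensity + stats::rnorm(length(sig), 0, sig)
    p$sigma <- sig
    p
  })
  sim
}
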