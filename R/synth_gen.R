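## Synthetic nucleosome scattering generator: bead models of the
## DNA-wrapped particle, contrast series and pressure series with a
## recorded ground-truth manifest for every emitted profile.

#' Nucleosome geometry for the bead generator
#'
#' Defaults follow canonical nucleosome crystallographic conventions:
#' DNA superhelix radius 41.8 A, superhelical pitch 25.9 A, 1.65 wrap
#' turns of 147 bp around a protein core cylinder of radius 32 A and
#' height 55 A.  `extension_fraction` morphs the DNA path linearly toward
#' a straight B-form rod (0 = native wrap, 1 = fully extended chain);
#' `unwrap_bp_each_end` peels base pairs off each end onto straight
#' tangents.
#'
#' @param dna_superhelix_radius,dna_pitch Angstrom.
#' @param wrap_turns superhelical turns of the wrapped segment (> 0).
#' @param bp_total total base pairs.
#' @param unwrap_bp_each_end base pairs continuing as straight tangents at
#'   each end (<= bp_total/2).
#' @param core_radius,core_height protein core cylinder, Angstrom.
#' @param extension_fraction 0..1 morph toward the extended rod.
#' @param duplex_radius radial offset of the two strand bead tracks from
#'   the duplex axis, Angstrom.
#' @return list of class `nucleosome_geometry`.
#' @export
nucleosome_geometry <- function(dna_superhelix_radius = 41.8,
                                dna_pitch = 25.9, wrap_turns = 1.65,
                                bp_total = 147L, unwrap_bp_each_end = 0L,
                                core_radius = 32, core_height = 55,
                                extension_fraction = 0,
                                duplex_radius = 10) {
  if (wrap_turns <= 0) stop("wrap_turns must be positive")
  if (unwrap_bp_each_end > bp_total / 2)
    stop("impossible geometry: unwrap exceeds half the total bp")
  if (extension_fraction < 0 || extension_fraction > 1)
    stop("extension_fraction must lie in [0, 1]")
  structure(list(dna_superhelix_radius = dna_superhelix_radius,
                 dna_pitch = dna_pitch, wrap_turns = wrap_turns,
                 bp_total = as.integer(bp_total),
                 unwrap_bp_each_end = as.integer(unwrap_bp_each_end),
                 core_radius = core_radius, core_height = core_height,
                 extension_fraction = extension_fraction,
                 duplex_radius = duplex_radius),
            class = "nucleosome_geometry")
}

# per-bp DNA centerline: helix for wrapped bp, straight tangents for
# unwrapped bp, centered on the origin
.dna_centerline <- function(geom) {
  n <- geom$bp_total
  nu <- geom$unwrap_bp_each_end
  nw <- n - 2 * nu
  R <- geom$dna_superhelix_radius
  h <- geom$wrap_turns * geom$dna_pitch
  th <- seq(0, 2 * pi * geom$wrap_turns, length.out = nw)
  zz <- seq(-h / 2, h / 2, length.out = nw)
  helix <- cbind(R * cos(th), R * sin(th), zz)
  if (nu > 0) {
    # tangents at the helix ends, 3.4 A per bp
    tan_at <- function(t, sgn) {
      d <- cbind(-R * sin(t), R * cos(t), h / (2 * pi * geom$wrap_turns))
      sgn * d / sqrt(sum(d^2))
    }
    t0 <- tan_at(th[1], -1); t1 <- tan_at(th[nw], 1)
    pre <- helix[1, ] + t0[rep(1, nu), ] * (3.4 * rev(seq_len(nu)))
    post <- helix[nw, ] + t1[rep(1, nu), ] * (3.4 * seq_len(nu))
    helix <- rbind(pre, helix, post)
  }
  helix
}

#' Build a nucleosome bead model
#'
#' Protein beads fill the core cylinder on a cubic lattice of
#' `bead_spacing`; DNA beads trace the superhelical path (two strand
#' tracks offset by the duplex radius, twisting at one turn per 10.4 bp),
#' with unwrapped base pairs continuing as straight tangents.
#' `extension_fraction` morphs every DNA coordinate linearly toward the
#' straight-rod path.  Per-bead scattering lengths and volumes partition
#' the composition's component totals equally within each component, so
#' the protein:DNA total-scattering-length ratio of the model equals the
#' composition's.
#'
#' @param geom a [nucleosome_geometry].
#' @param bead_spacing protein lattice spacing, Angstrom, in [3, 15].
#' @param comp a [composition_spec]; defaults to
#'   [nucleosome_composition] with the geometry's bp count.
#' @return a [bead_model].
#' @export
build_nucleosome_beads <- function(geom, bead_spacing = 5, comp = NULL) {
  stopifnot(inherits(geom, "nucleosome_geometry"))
  if (bead_spacing < 3 || bead_spacing > 15)
    stop("bead_spacing must lie in [3, 15] A")
  if (is.null(comp)) comp <- nucleosome_composition(geom$bp_total)
  # protein lattice
  g <- seq(-geom$core_radius, geom$core_radius, by = bead_spacing)
  gz <- seq(-geom$core_height / 2, geom$core_height / 2, by = bead_spacing)
  lat <- expand.grid(x = g, y = g, z = gz)
  lat <- lat[lat$x^2 + lat$y^2 <= geom$core_radius^2, ]
  np <- nrow(lat)
  # DNA: morph centerline toward the straight rod, two strand tracks
  ctr <- .dna_centerline(geom)
  n <- geom$bp_total
  rod <- cbind((seq_len(n) - (n + 1) / 2) * 3.4, 0, 0)
  e <- geom$extension_fraction
  ctr_m <- (1 - e) * ctr + e * rod
  # local path direction (for the duplex offset plane)
  dirs <- rbind(ctr_m[2, ] - ctr_m[1, ],
                (ctr_m[-(1:2), , drop = FALSE] -
                   ctr_m[seq_len(n - 2), , drop = FALSE]) / 2,
                ctr_m[n, ] - ctr_m[n - 1, ])
  dirs <- dirs / sqrt(rowSums(dirs^2))
  # orthonormal frame per bp
  up <- cbind(0, 0, 1)
  u1 <- cbind(dirs[, 2] * up[, 3] - dirs[, 3] * up[, 2],
              dirs[, 3] * up[, 1] - dirs[, 1] * up[, 3],
              dirs[, 1] * up[, 2] - dirs[, 2] * up[, 1])
  bad <- sqrt(rowSums(u1^2)) < 1e-6
  if (any(bad)) u1[bad, ] <- matrix(c(0, 1, 0), sum(bad), 3, byrow = TRUE)
  u1 <- u1 / sqrt(rowSums(u1^2))
  u2 <- cbind(dirs[, 2] * u1[, 3] - dirs[, 3] * u1[, 2],
              dirs[, 3] * u1[, 1] - dirs[, 1] * u1[, 3],
              dirs[, 1] * u1[, 2] - dirs[, 2] * u1[, 1])
  tw <- 2 * pi * (seq_len(n) - 1) / 10.4
  off <- geom$duplex_radius *
    (u1 * cos(tw) + u2 * sin(tw))
  dna_xyz <- rbind(ctr_m + off, ctr_m - off)
  nd <- nrow(dna_xyz)
  bead_model(
    x = c(lat$x, dna_xyz[, 1]),
    y = c(lat$y, dna_xyz[, 2]),
    z = c(lat$z, dna_xyz[, 3]),
    scattering_length = c(rep(comp$protein$b_h / np, np),
                          rep(comp$dna$b_h / nd, nd)),
    component_tag = c(rep("protein", np), rep("dna", nd)),
    volume = c(rep(.component_block(comp, "protein")$volume / np, np),
               rep(.component_block(comp, "dna")$volume / nd, nd)))
}

#' Contrast-weighted Rg of a bead model
#'
#' Direct second moment of the bead coordinates weighted by per-bead
#' excess scattering length (optionally re-weighted by per-tag
#' contrasts).  `rg2` may be negative between the component match points.
#'
#' @param model a [bead_model].
#' @param contrast_per_tag optional named contrast map (see
#'   [debye_intensity]).
#' @return list with `rg` (NA when `rg2 < 0`) and `rg2`.
#' @export
bead_rg <- function(model, contrast_per_tag = NULL) {
  b <- .bead_b(model, contrast_per_tag)
  tb <- sum(b)
  if (abs(tb) < 1e-300) return(list(rg = NA_real_, rg2 = NA_real_))
  xyz <- as.matrix(model[, c("x", "y", "z")])
  ctr <- colSums(xyz * b) / tb
  rg2 <- sum(b * rowSums((xyz - matrix(ctr, nrow(xyz), 3,
                                       byrow = TRUE))^2)) / tb
  list(rg = if (rg2 > 0) sqrt(rg2) else NA_real_, rg2 = rg2)
}

#' Partial Debye intensities of a tagged bead model
#'
#' Returns the three partial sums of the contrast-variation
#' decomposition, computed with per-bead volumes as amplitudes:
#' `i_protein` (protein-protein), `i_dna` (DNA-DNA) and `i_cross`
#' (interference), such that at contrasts \eqn{(\Delta\rho_P,
#' \Delta\rho_D)} the particle intensity is \eqn{\Delta\rho_P^2 I_P +
#' \Delta\rho_P\Delta\rho_D I_{PD} + \Delta\rho_D^2 I_D}.  Volumes are
#' taken in cm^3 so that multiplying by contrasts in cm^-2 yields cm^2
#' per particle.
#'
#' @param model a [bead_model] with volumes.
#' @param q momentum transfer vector.
#' @param bin_width histogram resolution, Angstrom.
#' @return list with `q`, `i_protein`, `i_dna`, `i_cross`.
#' @export
debye_partial_intensities <- function(model, q, bin_width = 0.5) {
  stopifnot(inherits(model, "bead_model"))
  if (any(is.na(model$volume))) stop("bead volumes required")
  is_p <- model$component_tag == "protein"
  sub <- function(idx) {
    m <- model[idx, , drop = FALSE]
    class(m) <- c("bead_model", "data.frame")
    m
  }
  b <- model$volume * 1e-24  # cm^3
  xyz <- as.matrix(model[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  pair_sum <- function(maskA, maskB) {
    # sum over ordered pairs (i in A, j in B) of b_i b_j sinc(q d_ij)
    dv <- d[maskA, maskB, drop = FALSE]
    bb <- outer(b[maskA], b[maskB])
    bins <- floor(dv / bin_width)
    wsum <- tapply(as.vector(bb), as.vector(bins), sum)
    centers <- (as.numeric(names(wsum)) + 0.5) * bin_width
    zero <- centers < bin_width  # includes self/near-zero distances
    centers[zero] <- 0
    vapply(q, function(qq) {
      x <- qq * centers
      sum(wsum * ifelse(x < 1e-8, 1 - x^2 / 6, sin(x) / x))
    }, 0)
  }
  list(q = q,
       i_protein = pair_sum(is_p, is_p),
       i_dna = pair_sum(!is_p, !is_p),
       i_cross = 2 * pair_sum(is_p, !is_p))
}

#' Simulate one scattering profile from a bead model
#'
#' Evaluates the dilute-limit (structure factor = 1) particle intensity by
#' the Debye formula with per-component contrasts, places it on the
#' absolute scale via the particle number density, adds a flat incoherent
#' background proportional to the solvent H fraction for neutron sources,
#' and applies Gaussian counting noise with
#' \eqn{\sigma = \sqrt{I + bg}/exposure\_scale}.  `exposure_scale = Inf`
#' returns the noise-free curve (with a nominal small sigma).
#'
#' @param model a [bead_model] with volumes.
#' @param comp the [composition_spec] the model was built from.
#' @param q_grid momentum transfer grid, 1/Angstrom.
#' @param fraction_d2o solvent D2O fraction (neutron contrast point).
#' @param concentration mg/mL.
#' @param source `"neutron"` or `"xray"` (X-ray uses electron-density
#'   contrasts converted through the Thomson radius).
#' @param noise list with `exposure_scale` (larger = less noise) and
#'   `incoherent_level` (flat background at 0% D2O, 1/cm).
#' @param seed integer seed; the output is bit-reproducible given the
#'   seed.
#' @param subtract_background emulate upstream buffer subtraction: the
#'   incoherent background inflates the counting noise but is removed
#'   from the reported intensity (default TRUE, matching
#'   background-subtracted reduced data).  FALSE keeps the flat
#'   background in the curve.
#' @param pressure,label metadata passthrough.
#' @param partials optional precomputed [debye_partial_intensities] on
#'   `q_grid` (performance path for series generation).
#' @return a [sas_profile] on the absolute scale.
#' @export
simulate_profile <- function(model, comp, q_grid, fraction_d2o = 0,
                             concentration = 1,
                             source = c("neutron", "xray"),
                             noise = list(exposure_scale = 100,
                                          incoherent_level = 0.05),
                             seed = 1, subtract_background = TRUE,
                             pressure = 0.1013, label = "",
                             partials = NULL) {
  source <- match.arg(source)
  if (!length(q_grid)) stop("empty q grid")
  if (is.null(partials)) partials <- debye_partial_intensities(model, q_grid)
  if (source == "neutron") {
    drp <- component_contrast(comp, "protein", fraction_d2o) * 1e10
    drd <- component_contrast(comp, "dna", fraction_d2o) * 1e10
  } else {
    re_nm3 <- 2.8179403e-13 / 1e-21  # cm per e-/nm^3
    drp <- xray_contrast(comp, "protein") * re_nm3
    drd <- xray_contrast(comp, "dna") * re_nm3
  }
  per_particle <- drp^2 * partials$i_protein +
    drp * drd * partials$i_cross + drd^2 * partials$i_dna   # cm^2
  mw_tot <- comp$protein$mw + comp$dna$mw
  nden <- concentration * 1e-3 * 6.02214076e23 / mw_tot     # cm^-3
  I <- nden * per_particle                                  # cm^-1
  bg <- if (source == "neutron")
    noise$incoherent_level * (1 - fraction_d2o) else 0
  es <- noise$exposure_scale
  keep_bg <- if (subtract_background) 0 else bg
  if (is.infinite(es)) {
    sig <- rep(1e-8 * max(abs(I) + bg), length(q_grid))
    Iobs <- I + keep_bg
  } else {
    sig <- sqrt(pmax(I + bg, 1e-12)) / es
    set.seed(seed)
    Iobs <- I + keep_bg + stats::rnorm(length(I), 0, sig)
  }
  sas_profile(q = q_grid, intensity = Iobs, sigma = sig, source = source,
              fraction_d2o = fraction_d2o, concentration = concentration,
              pressure = pressure, absolute_scale = TRUE, label = label)
}

#' Simulate a neutron contrast-variation series
#'
#' One profile per (D2O fraction, concentration) pair from the native
#' nucleosome bead model, with a ground-truth manifest recording the
#' generating geometry, composition masses, per-profile contrasts, seeds
#' and the true contrast-weighted Rg at each point.
#'
#' @param geom a [nucleosome_geometry].
#' @param comp a [composition_spec].
#' @param fractions D2O fractions (>= 2).
#' @param concentrations mg/mL, recycled against `fractions`.
#' @param q_grid momentum transfer grid.
#' @param noise,seed see [simulate_profile]; per-profile seeds are
#'   `seed + index`.
#' @param bead_spacing passed to [build_nucleosome_beads].
#' @return list with `profiles` and `manifest` (class
#'   `ground_truth_manifest`).
#' @export
simulate_contrast_series <- function(geom, comp, fractions,
                                     concentrations = 1,
                                     q_grid = seq(0.009, 0.3, length.out = 120),
                                     noise = list(exposure_scale = 100,
                                                  incoherent_level = 0.05),
                                     seed = 1, bead_spacing = 5) {
  if (length(fractions) < 2) stop("need at least 2 D2O fractions")
  concentrations <- rep_len(concentrations, length(fractions))
  model <- build_nucleosome_beads(geom, bead_spacing, comp)
  partials <- debye_partial_intensities(model, q_grid)
  profiles <- list(); truth <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    profiles[[i]] <- simulate_profile(
      model, comp, q_grid, fraction_d2o = f,
      concentration = concentrations[i], source = "neutron",
      noise = noise, seed = seed + i, partials = partials,
      label = sprintf("fD2O=%.2f", f))
    cp <- contrast_point(comp, f)
    rg_true <- bead_rg(model, contrast_per_tag = c(
      protein = cp$delta_rho_protein, dna = cp$delta_rho_dna))
    truth[[i]] <- list(fraction_d2o = f,
                       concentration = concentrations[i],
                       seed = seed + i,
                       drho_protein = cp$delta_rho_protein,
                       drho_dna = cp$delta_rho_dna,
                       drho_complex = cp$delta_rho_complex,
                       rg2_true = rg_true$rg2)
  }
  manifest <- structure(list(
    geometry = geom,
    mw_protein = comp$protein$mw, mw_dna = comp$dna$mw,
    exchange_fraction = comp$exchange_fraction,
    noise = noise, seed = seed, kind = "contrast_series",
    per_profile = truth), class = "ground_truth_manifest")
  list(profiles = profiles, manifest = manifest)
}

#' Simulate a high-pressure SAXS series
#'
#' Each pressure point is a number-weighted mixture of three states:
#' `native` (wrapped bead model), `unwrapped` (bead model with DNA ends
#' peeled onto tangents and partial extension) and `extended` (Gaussian
#' coil at the rigid-rod-scale Rg of the full DNA length).  Hysteresis is
#' emulated by leaving residual extended weight at labeled
#' return-to-baseline points.
#'
#' @param geom native [nucleosome_geometry].
#' @param comp a [composition_spec].
#' @param pressures MPa, one per row of `state_map`.
#' @param state_map data.frame with columns `native`, `unwrapped`,
#'   `extended` (rows summing to 1) and optionally `label`.
#' @param unwrap_bp bp peeled per end in the unwrapped state.
#' @param unwrap_extension extension fraction of the unwrapped state.
#' @param q_grid,noise,seed,bead_spacing as in
#'   [simulate_contrast_series]; profiles are X-ray source.
#' @return list with `profiles` and `manifest`.
#' @export
simulate_pressure_series <- function(geom, comp, pressures, state_map,
                                     unwrap_bp = 25,
                                     unwrap_extension = 0.15,
                                     q_grid = seq(0.009, 0.3,
                                                  length.out = 140),
                                     noise = list(exposure_scale = 200,
                                                  incoherent_level = 0),
                                     seed = 1, bead_spacing = 5) {
  stopifnot(nrow(state_map) == length(pressures))
  wmat <- as.matrix(state_map[, c("native", "unwrapped", "extended")])
  if (any(abs(rowSums(wmat) - 1) > 1e-8))
    stop("state weights must sum to 1 at every pressure")
  labels <- if ("label" %in% names(state_map)) state_map$label
            else sprintf("P%g", pressures)
  m_nat <- build_nucleosome_beads(geom, bead_spacing, comp)
  geom_un <- geom
  geom_un$unwrap_bp_each_end <- as.integer(unwrap_bp)
  geom_un$extension_fraction <- unwrap_extension
  m_un <- build_nucleosome_beads(geom_un, bead_spacing, comp)
  p_nat <- debye_partial_intensities(m_nat, q_grid)
  p_un <- debye_partial_intensities(m_un, q_grid)
  re_nm3 <- 2.8179403e-13 / 1e-21
  drp <- xray_contrast(comp, "protein") * re_nm3
  drd <- xray_contrast(comp, "dna") * re_nm3
  per_part <- function(p) drp^2 * p$i_protein + drp * drd * p$i_cross +
    drd^2 * p$i_dna
  I_nat <- per_part(p_nat); I_un <- per_part(p_un)
  # extended chain: coil at the rod-scale Rg, forward value matched to
  # the particle's total excess scattering (conservation of I0)
  rod <- rigid_rod_metrics(geom$bp_total)
  tot_b <- drp * .component_block(comp, "protein")$volume * 1e-24 +
    drd * .component_block(comp, "dna")$volume * 1e-24
  i0_particle <- tot_b^2
  I_ext <- gaussian_coil_intensity(rod$rg, i0_particle, q_grid)
  mw_tot <- comp$protein$mw + comp$dna$mw
  profiles <- list(); truth <- list()
  for (i in seq_along(pressures)) {
    w <- wmat[i, ]
    conc <- 1.2
    nden <- conc * 1e-3 * 6.02214076e23 / mw_tot
    I <- nden * (w[1] * I_nat + w[2] * I_un + w[3] * I_ext)
    es <- noise$exposure_scale
    if (is.infinite(es)) {
      sig <- rep(1e-8 * max(I), length(q_grid)); Iobs <- I
    } else {
      sig <- sqrt(pmax(I, 1e-12)) / es
      set.seed(seed + i)
      Iobs <- I + stats::rnorm(length(I), 0, sig)
    }
    profiles[[i]] <- sas_profile(q = q_grid, intensity = Iobs, sigma = sig,
                                 source = "xray", concentration = conc,
                                 pressure = pressures[i],
                                 absolute_scale = TRUE, label = labels[i])
    truth[[i]] <- list(pressure = pressures[i], label = labels[i],
                       weights = as.list(w), seed = seed + i)
  }
  manifest <- structure(list(
    geometry = geom, unwrapped_geometry = geom_un,
    mw_protein = comp$protein$mw, mw_dna = comp$dna$mw,
    coil_rg = rod$rg, noise = noise, seed = seed,
    kind = "pressure_series", per_profile = truth),
    class = "ground_truth_manifest")
  list(profiles = profiles, manifest = manifest)
}
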