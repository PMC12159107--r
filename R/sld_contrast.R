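## Scattering-length densities, contrasts and match points for protein/DNA
## complexes as functions of the solvent D2O fraction and H/D exchange.
##
## Conventions: neutron SLDs in 1e-6 A^-2; electron densities in e-/nm^3;
## mass densities in g/cm^3; a single exchange_fraction scales the labile-H
## deuteration of both components (labile H replaced by D with probability
## exchange_fraction * fraction_d2o).

.NAVO <- 6.02214076e23
# Avogadro scaled for A^3 volumes from g/cm^3 densities: V[A^3] = MW/(0.6022*d)
.NAVO_A3 <- 0.602214076

#' Chemical composition of a protein-DNA particle
#'
#' Describes the protein chains (sequences and copy numbers) and the DNA of
#' a complex, together with the labile-hydrogen exchange fraction and the
#' component mass densities used to convert composition to volume.
#'
#' @param protein_chains named list of one-letter amino-acid sequences, or a
#'   list of `list(sequence=, copies=)` entries.  A plain character vector
#'   is taken as one copy each.
#' @param protein_copies integer copy numbers, recycled against
#'   `protein_chains` when the latter is a character vector.
#' @param dna_basepairs number of DNA base pairs (double-stranded).
#' @param dna_sequence optional explicit sequence of one strand (A/C/G/T);
#'   the complement is added automatically.  Overrides `dna_basepairs`.
#' @param exchange_fraction fraction of labile hydrogens that exchange with
#'   solvent deuterium (default 0.5, the mass-spectrometry-motivated value
#'   for folded nucleosomal protein).
#' @param mass_density_protein,mass_density_dna g/cm^3 (defaults 1.35 and
#'   1.69).
#' @param partial_specific_volume optional cm^3/g, reporting only.
#' @return An object of class `composition_spec` with precomputed component
#'   totals (`b_h` fm at zero exchange, `b_labile` fm full-exchange
#'   increment, `electrons`, `mw` Da, `volume` A^3).
#' @export
composition_spec <- function(protein_chains = list(), protein_copies = 1L,
                             dna_basepairs = 0L, dna_sequence = NULL,
                             exchange_fraction = 0.5,
                             mass_density_protein = 1.35,
                             mass_density_dna = 1.69,
                             partial_specific_volume = NA_real_) {
  if (exchange_fraction < 0 || exchange_fraction > 1)
    stop("exchange_fraction must lie in [0, 1]")
  if (mass_density_protein <= 0 || mass_density_dna <= 0)
    stop("mass densities must be positive")
  if (is.character(protein_chains))
    protein_chains <- as.list(protein_chains)
  chains <- lapply(seq_along(protein_chains), function(i) {
    ch <- protein_chains[[i]]
    if (is.list(ch)) return(list(sequence = toupper(ch$sequence),
                                 copies = as.integer(ch$copies)))
    list(sequence = toupper(ch),
         copies = as.integer(rep_len(protein_copies,
                                     length(protein_chains))[i]))
  })
  for (ch in chains) if (ch$copies < 1) stop("copy numbers must be >= 1")

  aa <- .nucsas_residue_props(.nucsas_aa_table)
  prot <- c(b_h = 0, b_labile = 0, electrons = 0, mw = 0)
  for (ch in chains) {
    res <- strsplit(ch$sequence, "")[[1]]
    idx <- match(res, aa$code)
    if (anyNA(idx))
      stop("unknown residue code(s): ",
           paste(unique(res[is.na(idx)]), collapse = ", "))
    # terminal groups: + H2O per chain (H and OH termini)
    prot <- prot + ch$copies * c(
      b_h = sum(aa$b_h[idx]) + 2 * .nucsas_b_coh["H"] + .nucsas_b_coh["O"],
      b_labile = sum(aa$b_per_exch[idx]),
      electrons = sum(aa$electrons[idx]) + 10,
      mw = sum(aa$mw[idx]) + 2 * .nucsas_atwt["H"] + .nucsas_atwt["O"])
  }

  nt <- .nucsas_residue_props(.nucsas_dna_table)
  if (!is.null(dna_sequence)) {
    s <- strsplit(toupper(dna_sequence), "")[[1]]
    if (!all(s %in% c("A", "C", "G", "T")))
      stop("unknown residue code(s) in DNA sequence")
    comp_map <- c(A = "T", T = "A", C = "G", G = "C")
    counts <- table(factor(c(s, comp_map[s]), levels = nt$code))
    dna_basepairs <- length(s)
  } else {
    # unspecified sequence: 50% GC, both strands
    counts <- stats::setNames(rep(dna_basepairs / 2, 4), nt$code)
  }
  dna_basepairs <- as.integer(dna_basepairs)
  cn <- as.numeric(counts)
  dna <- c(b_h = sum(cn * nt$b_h), b_labile = sum(cn * nt$b_per_exch),
           electrons = sum(cn * nt$electrons), mw = sum(cn * nt$mw))

  structure(list(
    protein_chains = chains,
    dna_basepairs = dna_basepairs,
    exchange_fraction = exchange_fraction,
    mass_density_protein = mass_density_protein,
    mass_density_dna = mass_density_dna,
    partial_specific_volume = partial_specific_volume,
    protein = as.list(prot),
    dna = as.list(dna)), class = "composition_spec")
}

#' @export
print.composition_spec <- function(x, ...) {
  cat(sprintf(paste0("composition_spec: %d protein chain type(s), %d bp ",
                     "DNA\n  MW(protein) = %.1f kDa, MW(DNA) = %.1f kDa, ",
                     "exchange = %.2f\n"),
              length(x$protein_chains), x$dna_basepairs,
              x$protein$mw / 1e3, x$dna$mw / 1e3, x$exchange_fraction))
  invisible(x)
}

.component_block <- function(comp, component) {
  component <- match.arg(component, c("protein", "dna"))
  blk <- comp[[component]]
  if (blk$mw <= 0) stop("empty component: ", component)
  d <- if (component == "protein") comp$mass_density_protein
       else comp$mass_density_dna
  blk$volume <- blk$mw / (.NAVO_A3 * d)  # A^3
  blk$density <- d
  blk
}

#' Read a composition specification from a text file
#'
#' Two record styles may be mixed, one record per line:
#' `protein <copies> <sequence>` and `dna <basepairs-or-sequence>`, plus
#' optional `exchange_fraction=`, `density_protein=`, `density_dna=`
#' settings.  FASTA blocks are also accepted for protein chains; a header
#' of the form `>name copies=2` sets the copy number (default 1).
#'
#' @param path input file.
#' @return a [composition_spec].
#' @export
read_composition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  chains <- list(); dna_bp <- 0L; dna_seq <- NULL
  opts <- list(exchange_fraction = 0.5, density_protein = 1.35,
               density_dna = 1.69)
  i <- 1
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      copies <- 1L
      m <- regmatches(ln, regexpr("copies=[0-9]+", ln))
      if (length(m)) copies <- as.integer(sub("copies=", "", m))
      seqs <- character()
      i <- i + 1
      while (i <= length(lines) && !startsWith(lines[i], ">") &&
             !grepl("^(protein|dna|[a-z_]+=)", lines[i])) {
        seqs <- c(seqs, lines[i]); i <- i + 1
      }
      chains[[length(chains) + 1]] <-
        list(sequence = paste(seqs, collapse = ""), copies = copies)
      next
    }
    if (grepl("^protein\\s", ln)) {
      parts <- strsplit(ln, "\\s+")[[1]]
      chains[[length(chains) + 1]] <-
        list(sequence = parts[3], copies = as.integer(parts[2]))
    } else if (grepl("^dna\\s", ln)) {
      val <- strsplit(ln, "\\s+")[[1]][2]
      n <- suppressWarnings(as.integer(val))
      if (is.na(n)) dna_seq <- val else dna_bp <- n
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      if (key %in% names(opts))
        opts[[key]] <- as.numeric(sub("^[^=]*=", "", ln))
    } else {
      stop("unrecognized composition record: ", ln)
    }
    i <- i + 1
  }
  composition_spec(protein_chains = chains, dna_basepairs = dna_bp,
                   dna_sequence = dna_seq,
                   exchange_fraction = opts$exchange_fraction,
                   mass_density_protein = opts$density_protein,
                   mass_density_dna = opts$density_dna)
}

#' Neutron scattering-length density of the H2O/D2O solvent
#'
#' Volume-fraction linear mixture of the pure-water endpoint SLDs, each
#' computed from tabulated bound coherent scattering lengths and the water
#' mass densities (H2O 0.9982, D2O 1.1050 g/cm^3 at room temperature).
#' At `fraction_d2o = 0` with unit density this evaluates to the familiar
#' -0.56e-6 A^-2.
#'
#' @param fraction_d2o D2O volume fraction in 0..1 (vectorized).
#' @param d_h2o,d_d2o endpoint mass densities, g/cm^3.
#' @return SLD in units of 1e-6 A^-2.
#' @export
solvent_sld <- function(fraction_d2o, d_h2o = 1.0, d_d2o = 1.105) {
  if (any(!is.finite(fraction_d2o)) ||
      any(fraction_d2o < 0 | fraction_d2o > 1))
    stop("fraction_d2o must lie in [0, 1]")
  b <- .nucsas_b_coh
  mw_h2o <- 2 * .nucsas_atwt["H"] + .nucsas_atwt["O"]
  mw_d2o <- 2 * .nucsas_atwt["D"] + .nucsas_atwt["O"]
  sld_h2o <- (2 * b["H"] + b["O"]) * 1e-5 / (mw_h2o / (.NAVO_A3 * d_h2o)) * 1e6
  sld_d2o <- (2 * b["D"] + b["O"]) * 1e-5 / (mw_d2o / (.NAVO_A3 * d_d2o)) * 1e6
  unname((1 - fraction_d2o) * sld_h2o + fraction_d2o * sld_d2o)
}

.component_sld <- function(comp, component, fraction_d2o) {
  blk <- .component_block(comp, component)
  b <- blk$b_h + comp$exchange_fraction * fraction_d2o * blk$b_labile  # fm
  b * 1e-5 / blk$volume * 1e6  # 1e-6 A^-2
}

#' Component neutron contrast
#'
#' SLD of the protein or DNA component -- with labile hydrogens exchanged at
#' `exchange_fraction * fraction_d2o` -- minus the solvent SLD.  Linear in
#' `fraction_d2o`; its root is the component match point.
#'
#' @param comp a [composition_spec].
#' @param component `"protein"`, `"dna"` or `"complex"` (volume-weighted
#'   mean of the two components).
#' @param fraction_d2o D2O fraction (vectorized).
#' @inheritParams solvent_sld
#' @return contrast in 1e-6 A^-2.
#' @export
component_contrast <- function(comp, component = c("protein", "dna",
                                                   "complex"),
                               fraction_d2o, d_h2o = 1.0, d_d2o = 1.105) {
  stopifnot(inherits(comp, "composition_spec"))
  component <- match.arg(component)
  rs <- solvent_sld(fraction_d2o, d_h2o, d_d2o)
  if (component == "complex") {
    bp <- .component_block(comp, "protein"); bd <- .component_block(comp, "dna")
    rho <- (bp$volume * .component_sld(comp, "protein", fraction_d2o) +
              bd$volume * .component_sld(comp, "dna", fraction_d2o)) /
      (bp$volume + bd$volume)
    return(rho - rs)
  }
  .component_sld(comp, component, fraction_d2o) - rs
}

#' Contrasts at one solvent composition
#'
#' Convenience bundle of solvent SLD and protein/DNA/complex contrasts at a
#' single D2O fraction.
#'
#' @inheritParams component_contrast
#' @return list of class `contrast_point` with fields `fraction_d2o`,
#'   `rho_solvent`, `delta_rho_protein`, `delta_rho_dna`,
#'   `delta_rho_complex` (all 1e-6 A^-2).
#' @export
contrast_point <- function(comp, fraction_d2o) {
  structure(list(
    fraction_d2o = fraction_d2o,
    rho_solvent = solvent_sld(fraction_d2o),
    delta_rho_protein = component_contrast(comp, "protein", fraction_d2o),
    delta_rho_dna = component_contrast(comp, "dna", fraction_d2o),
    delta_rho_complex = component_contrast(comp, "complex", fraction_d2o)),
    class = "contrast_point")
}

#' Theoretical match point of a component
#'
#' Root of the (linear) contrast-versus-D2O-fraction function: the solvent
#' composition at which the component's coherent neutron scattering
#' vanishes.
#'
#' @inheritParams component_contrast
#' @return D2O fraction in 0..1.
#' @export
theoretical_match_point <- function(comp, component = c("protein", "dna",
                                                        "complex")) {
  component <- match.arg(component)
  c0 <- component_contrast(comp, component, 0)
  c1 <- component_contrast(comp, component, 1)
  if (c0 * c1 > 0)
    stop("no match point: contrast does not change sign on [0, 1] (",
         format(c0, digits = 3), " to ", format(c1, digits = 3), ")")
  unname(c0 / (c0 - c1))
}

#' X-ray electron-density contrast of a component
#'
#' Electron count per volume from composition and mass density, minus
#' water's 334 e-/nm^3.
#'
#' @inheritParams component_contrast
#' @param rho_water_e solvent electron density, e-/nm^3.
#' @return contrast in e-/nm^3.
#' @export
xray_contrast <- function(comp, component = c("protein", "dna"),
                          rho_water_e = 334) {
  component <- match.arg(component, c("protein", "dna"))
  blk <- .component_block(comp, component)
  blk$electrons / (blk$volume * 1e-3) - rho_water_e  # A^3 -> nm^3
}

#' Experimental match point from I(0) measurements
#'
#' Weighted linear fit of the signed square root of \eqn{I_0/c} against the
#' D2O fraction; the x-intercept estimates the match point of the whole
#' particle.  Signs are assigned so the sequence is monotone in fraction
#' (positive below the intercept, negative above); with noisy data near the
#' match point the assignment minimizing the fit residual is chosen, and an
#' `ambiguous` flag is raised when the alternative assignment fits within
#' one standard error.
#'
#' @param fraction_d2o,i0,concentration numeric vectors (concentration in
#'   mg/mL, i0 > 0).
#' @param sigma_i0 optional I0 uncertainties for weighting.
#' @return list with `match_point`, `match_point_se`, `slope`, `intercept`,
#'   `ambiguous`, and the fitted `lm` object in `fit`.
#' @export
experimental_match_point <- function(fraction_d2o, i0, concentration,
                                     sigma_i0 = NULL) {
  n <- length(fraction_d2o)
  stopifnot(length(i0) == n, length(concentration) == n)
  if (n < 2) stop("need at least 2 points at distinct fractions")
  if (length(unique(fraction_d2o)) < 2)
    stop("degenerate: all fractions identical")
  if (any(i0 <= 0) || any(concentration <= 0))
    stop("i0 and concentration must be positive")
  y0 <- sqrt(i0 / concentration)
  # sigma of sqrt(I0/c) by the delta method: sigma_I0 / (2 sqrt(I0 c))
  w <- if (is.null(sigma_i0)) rep(1, n)
       else 1 / (sigma_i0 / (2 * sqrt(i0 * concentration)))^2
  ord <- order(fraction_d2o)
  # sign convention: sqrt(I0/c) is positive below the match point and
  # negative above; candidate assignments flip the sign for all points
  # beyond split position k in fraction order (k = n: all positive, i.e.
  # the series sits entirely below the intercept).  Assignments whose
  # fitted slope vanishes carry no intercept and are skipped.
  scale_y <- max(abs(y0))
  cands <- list()
  for (k in 1:n) {
    s <- rep(1, n)
    if (k < n) s[ord[(k + 1):n]] <- -1
    fit <- stats::lm(s * y0 ~ fraction_d2o, weights = w)
    if (abs(stats::coef(fit)[2]) < 1e-10 * scale_y) next
    cands[[length(cands) + 1]] <-
      list(fit = fit, rss = sum(w * stats::residuals(fit)^2), signs = s)
  }
  if (!length(cands))
    stop("degenerate: zero slope, match point undefined")
  rsss <- vapply(cands, `[[`, 0, "rss")
  best <- cands[[which.min(rsss)]]
  best$second <- if (length(rsss) > 1) sort(rsss)[2]
  fit <- best$fit
  cf <- stats::coef(fit)
  mp <- -cf[1] / cf[2]
  V <- stats::vcov(fit)
  if (!is.null(sigma_i0)) {
    # true uncertainties supplied: use the unscaled covariance
    X <- cbind(1, fraction_d2o)
    V <- solve(t(X * w) %*% X)
  }
  g <- c(-1 / cf[2], cf[1] / cf[2]^2)
  se <- sqrt(drop(t(g) %*% V %*% g))
  sig2 <- best$rss / max(1, n - 2)
  ambiguous <- !is.null(best$second) &&
    (best$second - best$rss) < max(sig2, 1e-12)
  list(match_point = unname(mp), match_point_se = unname(se),
       slope = unname(cf[2]), intercept = unname(cf[1]),
       ambiguous = ambiguous, signs = best$signs, fit = fit)
}
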